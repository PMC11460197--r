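#' GIS-anchored two-way median polish batch harmonization
#'
#' Removes technical batch variance from a log2 matrix the way a tunable
#' median-polish-of-ratios harmonization does. Per protein and batch, the
#' log2 abundance is expressed as a ratio to the batch's GIS (pooled
#' reference channel) median — or to the batch all-sample median when
#' `use_gis = FALSE` — and a Tukey two-way median polish is run on the
#' ratio matrix (alternately sweeping column then row medians). The
#' corrected abundance is reconstructed as `residual + row effect +
#' per-protein grand median of the input log2 values`; column effects are
#' treated as pure technical loading and discarded. GIS channels are
#' corrected too. Missing cells stay missing and are excluded from every
#' median. The median of an even count is the midpoint of the two central
#' values.
#'
#' @param matrix A log2-scale [abundance_matrix()].
#' @param metadata Sample metadata with `sample_id`, `batch` and `is_gis`.
#' @param use_gis Anchor ratios on GIS channels (default) or on the batch
#'   median over all channels.
#' @param tol Convergence tolerance: maximum absolute change of any row or
#'   column effect between sweeps.
#' @param max_iter Sweep cap; median polish converges fast, the cap guards
#'   against cycling on ties.
#' @return A list with `matrix` (scale `"corrected"`) and `state`, the
#'   polish state: iterations, row/column effects, residuals, and the last
#'   sweep's maximum effect change.
#' @export
tampor_correct <- function(matrix, metadata, use_gis = TRUE, tol = 1e-6,
                           max_iter = 100L) {
  stopifnot(is_abundance_matrix(matrix))
  if (!matrix$scale %in% c("log2", "corrected"))
    stop("tampor_correct expects a log2-scale matrix")
  meta <- check_metadata(matrix, metadata,
                         required = c("sample_id", "batch", "is_gis"))
  v <- matrix$values
  batches <- unique(meta$batch)

  # per-protein, per-batch anchor: GIS median or all-channel median
  ratio <- v
  for (b in batches) {
    in_b <- meta$batch == b
    anchor_cols <- if (use_gis) in_b & meta$is_gis else in_b
    if (use_gis && !any(anchor_cols))
      stop("batch without GIS channel: ", b)
    anchor <- apply(v[, anchor_cols, drop = FALSE], 1, stats::median,
                    na.rm = TRUE)
    all_na <- !is.finite(anchor)
    if (any(all_na)) {
      warning(sum(all_na), " protein(s) unobserved in every anchor channel",
              " of batch ", b, "; their ratios in that batch set missing")
      anchor[all_na] <- NA_real_
    }
    ratio[, in_b] <- v[, in_b, drop = FALSE] - anchor
  }

  ps <- median_polish(ratio, tol = tol, max_iter = max_iter)

  grand <- apply(v, 1, stats::median, na.rm = TRUE)
  corrected <- ps$residuals + ps$row_effects + grand
  # overall polish constant belongs to the discarded technical component
  out <- am_with_values(matrix, corrected, scale = "corrected")
  list(matrix = out, state = ps)
}

# Tukey two-way median polish with NA handling. Column medians are swept
# first, then row medians, until the largest absolute effect change in a
# sweep drops below tol. The overall constant is folded into row effects.
median_polish <- function(x, tol = 1e-6, max_iter = 100L) {
  res <- x
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  delta <- Inf
  iter <- 0L
  while (iter < max_iter && delta > tol) {
    iter <- iter + 1L
    cm <- apply(res, 2, stats::median, na.rm = TRUE)
    cm[!is.finite(cm)] <- 0
    res <- sweep(res, 2, cm, `-`)
    col_eff <- col_eff + cm
    rm_ <- apply(res, 1, stats::median, na.rm = TRUE)
    rm_[!is.finite(rm_)] <- 0
    res <- sweep(res, 1, rm_, `-`)
    row_eff <- row_eff + rm_
    delta <- max(abs(c(cm, rm_)))
  }
  list(iterations = iter,
       row_effects = stats::setNames(row_eff, rownames(x)),
       col_effects = stats::setNames(col_eff, colnames(x)),
       residuals = res,
       last_change = delta,
       converged = delta <= tol)
}

#' Non-parametric bootstrap regression of covariate effects
#'
#' Per protein, ordinary least squares of log2 abundance on the protected
#' plus unprotected model terms is fitted on each of `B` resamples of
#' samples (with replacement); the coefficient estimate is the median over
#' resamples. The corrected value subtracts only the unprotected terms,
#' centred at their mean, so protected effects (diagnosis by default) and
#' the protein's central tendency are retained. Proteins with fewer
#' complete observations than model terms + 2 are left uncorrected and
#' flagged.
#'
#' @param matrix A log2- or corrected-scale [abundance_matrix()]; columns
#'   restricted to the samples in `metadata` with non-missing covariates are
#'   used for fitting, all listed samples are corrected.
#' @param metadata Sample metadata (GIS rows are ignored).
#' @param covariates Character vector of metadata columns to remove
#'   (numeric used as-is; categorical one-hot encoded against a reference
#'   level).
#' @param protected Metadata columns whose effects must never be removed.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param .resample Internal: set `FALSE` to fit once on the full sample
#'   (plain OLS oracle).
#' @return A list with `matrix` (corrected), and `report`: per-protein
#'   median coefficients, the number of complete observations, and an
#'   `uncorrected` flag.
#' @export
bootstrap_regress <- function(matrix, metadata, covariates,
                              protected = "diagnosis", B = 200L, seed = 1L,
                              .resample = TRUE) {
  stopifnot(is_abundance_matrix(matrix))
  meta <- check_metadata(matrix, metadata,
                         required = c("sample_id", covariates, protected))
  bio <- if ("is_gis" %in% names(meta)) !meta$is_gis else rep(TRUE, nrow(meta))
  meta <- meta[bio, , drop = FALSE]
  v <- matrix$values[, meta$sample_id, drop = FALSE]

  terms <- c(protected, covariates)
  ok_meta <- stats::complete.cases(meta[, terms, drop = FALSE])
  meta <- meta[ok_meta, , drop = FALSE]
  v <- v[, ok_meta, drop = FALSE]

  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = meta)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient covariate design; collinear term(s) among: ",
         paste(terms, collapse = ", "))
  }
  # map design columns to protected / unprotected terms
  assign_ <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")
  col_term <- c("(Intercept)", term_labels)[assign_ + 1]
  unprot_cols <- which(!(col_term %in% c("(Intercept)", protected)))

  set.seed(as.integer(seed))
  p <- nrow(v)
  n <- ncol(v)
  coef_med <- matrix(NA_real_, p, ncol(X),
                     dimnames = list(rownames(v), colnames(X)))
  uncorrected <- rep(FALSE, p)
  min_obs <- ncol(X) + 2

  resamples <- if (.resample) {
    lapply(seq_len(B), function(i) sample.int(n, n, replace = TRUE))
  } else {
    rep(list(seq_len(n)), B)
  }

  corrected <- matrix$values
  for (i in seq_len(p)) {
    obs <- which(!is.na(v[i, ]))
    if (length(obs) < min_obs) {
      uncorrected[i] <- TRUE
      next
    }
    coefs <- matrix(NA_real_, B, ncol(X))
    for (b in seq_len(B)) {
      idx <- resamples[[b]]
      idx <- idx[idx %in% obs]
      if (length(idx) < min_obs) next
      fit <- tryCatch(stats::.lm.fit(X[idx, , drop = FALSE], v[i, idx]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      cf <- fit$coefficients
      cf[abs(cf) < .Machine$double.eps & fit$rank < ncol(X)] <- NA_real_
      if (fit$rank < ncol(X)) next
      coefs[b, ] <- cf
    }
    if (all(is.na(coefs))) {
      uncorrected[i] <- TRUE
      next
    }
    med <- apply(coefs, 2, stats::median, na.rm = TRUE)
    coef_med[i, ] <- med
    if (length(unprot_cols)) {
      adj <- as.numeric(
        sweep(X[, unprot_cols, drop = FALSE], 2,
              colMeans(X[, unprot_cols, drop = FALSE]), `-`) %*%
          med[unprot_cols])
      corrected[i, meta$sample_id] <- v[i, ] - adj
    }
  }

  report <- data.frame(protein_id = rownames(v),
                       n_complete = rowSums(!is.na(v)),
                       uncorrected = uncorrected,
                       stringsAsFactors = FALSE, row.names = NULL)
  report <- cbind(report, as.data.frame(coef_med, row.names = NULL))
  list(matrix = am_with_values(matrix, corrected, scale = "corrected"),
       report = report,
       B = B, protected = protected)
}
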