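#' Proteins eligible for ROC analysis
#'
#' Keeps proteins with meta p strictly below `meta_p_max` and (by default)
#' no missing values across the ROC cohort. Duplicate control samples —
#' the same subject appearing in both sets — are removed first, keeping the
#' first occurrence.
#'
#' @param meta A data frame from [combine_sets()].
#' @param matrix A corrected-scale [abundance_matrix()].
#' @param metadata Sample metadata (`subject_id` used for de-duplication
#'   when present).
#' @param meta_p_max Strict upper bound on meta p (default 1e-4).
#' @param require_complete Require zero missing values across the cohort.
#' @return A list: `proteins` (eligible ids) and `samples` (the
#'   de-duplicated non-GIS cohort sample ids).
#' @export
eligible_proteins <- function(meta, matrix, metadata, meta_p_max = 1e-4,
                              require_complete = TRUE) {
  stopifnot(is_abundance_matrix(matrix))
  md <- metadata
  if ("is_gis" %in% names(md)) md <- md[!md$is_gis, , drop = FALSE]
  md <- md[md$sample_id %in% colnames(matrix$values), , drop = FALSE]
  if ("subject_id" %in% names(md)) {
    dup <- duplicated(md$subject_id) & !is.na(md$subject_id)
    md <- md[!dup, , drop = FALSE]
  }
  samples <- md$sample_id
  sig <- meta$protein_id[!is.na(meta$meta_p) & meta$meta_p < meta_p_max]
  sig <- intersect(sig, rownames(matrix$values))
  if (require_complete && length(sig)) {
    v <- matrix$values[sig, samples, drop = FALSE]
    sig <- sig[rowSums(is.na(v)) == 0]
  }
  if (!length(sig)) warning("no eligible proteins at meta p < ", meta_p_max)
  list(proteins = sig, samples = samples)
}

#' Logistic (binomial GLM) panel fit
#'
#' Maximum-likelihood logistic regression of a binary label on one or more
#' feature rows, fitted by iteratively reweighted least squares (up to 100
#' iterations, convergence 1e-8). Features are standardized internally so
#' coefficients are log-odds per SD unit. Perfect separation is detected
#' (fitted probabilities numerically 0/1) and flagged; scores from the last
#' iterate are still returned.
#'
#' @param features Numeric matrix, rows = features, columns = samples (a
#'   single feature may be a vector).
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   second sorted level / TRUE / 1 is the positive class).
#' @return A list of class `PanelModel`: `coefficients`, `converged`,
#'   `separation`, `scores` (linear predictor per sample), `labels`.
#' @export
fit_logistic_panel <- function(features, labels) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (ncol(features) != length(y))
    stop("features and labels disagree on sample count")
  xs <- t(apply(features, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) r - mean(r) else (r - mean(r)) / s
  }))
  df <- as.data.frame(t(xs))
  names(df) <- if (!is.null(rownames(features))) rownames(features)
    else paste0("x", seq_len(nrow(features)))
  df$.y <- y
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  probs <- stats::fitted(fit)
  separation <- any(probs > 1 - 1e-8) || any(probs < 1e-8)
  structure(list(coefficients = stats::coef(fit),
                 converged = fit$converged,
                 separation = separation,
                 scores = as.numeric(stats::predict(fit, type = "link")),
                 labels = y),
            class = "PanelModel")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("labels must have exactly two levels")
  pos <- if ("AD" %in% lv) "AD" else lv[2]
  as.integer(as.character(labels) == pos)
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC is the Mann-Whitney pair probability (ties count one half); the
#' variance is DeLong's structural-component estimate and the 95% CI the
#' normal approximation clipped to `[0, 1]`. The threshold table reports
#' sensitivity, specificity and accuracy at every cut, with the
#' Youden-optimal row (max sens + spec - 1, ties to the lower threshold)
#' marked. Higher scores indicate the positive class.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (see [fit_logistic_panel()]).
#' @return A list of class `RocResult`: `auc`, `var`, `ci` (length 2),
#'   `n_pos`, `n_neg`, `curve` (FPR/TPR points), `thresholds` (with
#'   `youden` flag), and the underlying `pROC::roc` object in `roc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  r <- pROC::roc(response = y, predictor = scores, direction = "<",
                 levels = c(0, 1), quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # a degenerate curve (AUC 0 or 1) has zero DeLong variance; pROC warns
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * sqrt(v), 0), 1)
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity", "accuracy"),
                     transpose = FALSE)
  j <- co$sensitivity + co$specificity - 1
  best <- which(j == max(j))
  best <- best[which.min(co$threshold[best])]
  co$youden <- seq_len(nrow(co)) == best
  structure(list(auc = auc, var = v, ci = ci,
                 n_pos = sum(y == 1), n_neg = sum(y == 0),
                 curve = data.frame(fpr = 1 - co$specificity,
                                    tpr = co$sensitivity),
                 thresholds = co, roc = r),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two score vectors on the same samples via the
#' covariance of DeLong placement values; z = dAUC / SE with a two-sided
#' normal p. Identical score rankings give a zero-variance difference,
#' reported as p = 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels shared by both.
#' @return A list: `z`, `p`, `delta_auc`, `auc_a`, `auc_b`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  ra <- pROC::roc(response = y, predictor = scores_a, direction = "<",
                  levels = c(0, 1), quiet = TRUE)
  rb <- pROC::roc(response = y, predictor = scores_b, direction = "<",
                  levels = c(0, 1), quiet = TRUE)
  d <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  tst <- suppressWarnings(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE))
  z <- unname(tst$statistic)
  p <- tst$p.value
  # identical rankings leave the paired difference with zero variance
  degenerate <- identical(rank(scores_a), rank(scores_b))
  if (degenerate || !is.finite(z) || !is.finite(p)) {
    degenerate <- TRUE
    z <- 0; p <- 1
  }
  list(z = z, p = p, delta_auc = d,
       auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       degenerate = degenerate)
}

#' Rank single markers, build a top-k panel, compare against a covariate
#'
#' Computes the single-marker AUC of every feature row (orientation
#' corrected: markers discriminating in the negative direction are
#' sign-flipped and flagged, so AUC >= 0.5 ranks discriminative ability),
#' fits a logistic panel on the top `k`, fits the covariate marker alone
#' and covariate + panel, and DeLong-tests covariate alone vs
#' covariate + panel.
#'
#' @param matrix Numeric matrix, rows = candidate features (e.g. Z-scored
#'   protein abundances), columns = samples.
#' @param labels Binary labels.
#' @param covariate Numeric vector: the benchmark marker (e.g. plasma
#'   pTau181) on the same samples, or `NULL` to skip the comparison.
#' @param k Panel size (default 5); capped at the feature count with a
#'   warning.
#' @return A list: `ranking` (data frame of per-feature AUC and flip flag),
#'   `panel` (PanelModel), `panel_roc`, `covariate_roc`,
#'   `combined_roc`, `comparison` (DeLong covariate vs covariate+panel).
#' @export
rank_and_panel <- function(matrix, labels, covariate = NULL, k = 5) {
  if (is.null(dim(matrix))) matrix <- matrix(matrix, nrow = 1)
  y <- as_binary_labels(labels)
  n <- nrow(matrix)
  if (k > n) {
    warning("panel size ", k, " exceeds ", n, " eligible features; using all")
    k <- n
  }
  auc1 <- numeric(n); flipped <- logical(n)
  for (i in seq_len(n)) {
    a <- roc_auc(matrix[i, ], y)$auc
    flipped[i] <- a < 0.5
    auc1[i] <- max(a, 1 - a)
  }
  ranking <- data.frame(
    feature = if (!is.null(rownames(matrix))) rownames(matrix)
      else paste0("x", seq_len(n)),
    auc = auc1, flipped = flipped, stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$auc), , drop = FALSE]
  rownames(ranking) <- NULL

  top <- ranking$feature[seq_len(k)]
  top_idx <- match(top, if (!is.null(rownames(matrix))) rownames(matrix)
                   else paste0("x", seq_len(n)))
  panel <- fit_logistic_panel(matrix[top_idx, , drop = FALSE], y)
  panel_roc <- roc_auc(panel$scores, y)

  covariate_roc <- combined_roc <- comparison <- NULL
  if (!is.null(covariate)) {
    covariate_roc <- roc_auc(covariate, y)
    comb_features <- rbind(pTau = covariate, matrix[top_idx, , drop = FALSE])
    combined <- fit_logistic_panel(comb_features, y)
    combined_roc <- roc_auc(combined$scores, y)
    comparison <- delong_test(combined$scores, covariate, y)
  }
  list(ranking = ranking, panel = panel, panel_roc = panel_roc,
       covariate_roc = covariate_roc, combined_roc = combined_roc,
       comparison = comparison)
}
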