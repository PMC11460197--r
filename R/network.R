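#' Build a module network from a reference matrix and membership lists
#'
#' Computes, per module, the eigenprotein — the first principal component
#' of the standardized member profiles across reference samples — and its
#' explained-variance share. Grey (unassigned) membership holds no
#' eigenprotein.
#'
#' @param reference A log2/corrected-scale [abundance_matrix()] of the
#'   reference cohort.
#' @param members Named list: module label -> character vector of member
#'   protein ids (row names of `reference`).
#' @return An object of class `ModuleNetwork`: `modules` (member lists),
#'   `eigenproteins` (module x reference-sample matrix, unit-norm rows),
#'   `var_explained`, `reference_samples`.
#' @export
module_network <- function(reference, members) {
  stopifnot(is_abundance_matrix(reference))
  members <- members[setdiff(names(members), "grey")]
  eig <- matrix(NA_real_, length(members), ncol(reference$values),
                dimnames = list(names(members), colnames(reference$values)))
  ve <- stats::setNames(rep(NA_real_, length(members)), names(members))
  for (m in names(members)) {
    e <- compute_eigenprotein(reference, members[[m]])
    eig[m, ] <- e$eigenprotein
    ve[m] <- e$var_explained
  }
  structure(list(modules = members, eigenproteins = eig,
                 var_explained = ve,
                 reference_samples = colnames(reference$values)),
            class = "ModuleNetwork")
}

#' @export
print.ModuleNetwork <- function(x, ...) {
  cat(sprintf("ModuleNetwork: %d modules over %d reference samples\n",
              length(x$modules), length(x$reference_samples)))
  invisible(x)
}

#' Module eigenprotein (first principal component of members)
#'
#' Member rows are standardized (Z per protein over observed values),
#' missing cells are zero-filled post-standardization (mean imputation on
#' the standardized scale), and the first right-singular vector of the
#' member-by-sample matrix is taken, unit norm. The sign is oriented so the
#' mean correlation with member profiles is positive; an exact tie is
#' broken by aligning to the first member. Explained variance is the top
#' singular value's share of total variance.
#'
#' @param reference An [abundance_matrix()].
#' @param member_ids Protein ids (>= 2 usable rows with >= 3 samples).
#' @return A list: `eigenprotein` (named numeric, unit norm),
#'   `var_explained`, `n_members`.
#' @export
compute_eigenprotein <- function(reference, member_ids) {
  stopifnot(is_abundance_matrix(reference))
  member_ids <- intersect(member_ids, rownames(reference$values))
  x <- reference$values[member_ids, , drop = FALSE]
  usable <- rowSums(!is.na(x)) >= 3 & row_sds_na(x) > 0
  usable[is.na(usable)] <- FALSE
  x <- x[usable, , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 usable module members")
  if (ncol(x) < 3) stop("fewer than 3 reference samples")
  z <- (x - rowMeans(x, na.rm = TRUE)) / row_sds_na(x)
  z[is.na(z)] <- 0
  sv <- svd(z)
  e <- sv$v[, 1]
  mean_cor <- mean(apply(z, 1, function(r) stats::cor(r, e)))
  if (mean_cor < 0) e <- -e
  else if (mean_cor == 0 && stats::cor(z[1, ], e) < 0) e <- -e
  e <- e / sqrt(sum(e^2))
  list(eigenprotein = stats::setNames(e, colnames(x)),
       var_explained = sv$d[1]^2 / sum(sv$d^2),
       n_members = nrow(x))
}

#' Biweight midcorrelation
#'
#' Robust correlation built on median and raw MAD (no consistency
#' constant): with `u = (x - median(x)) / (9 * mad_raw(x))`, observations
#' get Tukey biweights `w = (1 - u^2)^2` inside `|u| < 1` and zero outside;
#' bicor is the weighted cross-product of the median-centred values
#' normalized by the weighted sums of squares. If either vector has zero
#' MAD the function falls back to Pearson correlation and flags it via the
#' `"pearson_fallback"` attribute.
#'
#' @param x,y Numeric vectors; pairwise-complete pairs are used
#'   (>= 3 required).
#' @return The correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("bicor needs at least 3 paired observations")
  mx <- stats::median(x); my <- stats::median(y)
  madx <- stats::median(abs(x - mx))
  mady <- stats::median(abs(y - my))
  if (madx == 0 || mady == 0) {
    r <- stats::cor(x, y)
    attr(r, "pearson_fallback") <- TRUE
    return(r)
  }
  ux <- (x - mx) / (9 * madx)
  uy <- (y - my) / (9 * mady)
  wx <- (1 - ux^2)^2 * (abs(ux) < 1)
  wy <- (1 - uy^2)^2 * (abs(uy) < 1)
  xt <- (x - mx) * wx
  yt <- (y - my) * wy
  sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

#' Assign proteins to modules by kME (bicor to eigenproteins)
#'
#' For each protein of the target matrix, the biweight midcorrelation to
#' every module eigenprotein over the shared reference samples is computed
#' (pairwise-complete); the protein is assigned to the module with the
#' highest positive kME if that kME is at least `kme_min`, otherwise to
#' grey. Ties between modules at exactly equal kME are broken by module
#' label order and flagged. Proteins with fewer than 3 usable samples
#' against every eigenprotein are grey with reason.
#'
#' @param target An [abundance_matrix()] sharing sample space with the
#'   network's reference samples.
#' @param network A [module_network()].
#' @param kme_min Minimum kME for assignment (default 0.30).
#' @return A data frame: `protein_id`, `module`, `kme`, `assigned`,
#'   `tie`, `reason`.
#' @export
assign_modules <- function(target, network, kme_min = 0.30) {
  stopifnot(is_abundance_matrix(target), inherits(network, "ModuleNetwork"))
  shared <- intersect(colnames(target$values),
                      colnames(network$eigenproteins))
  if (length(shared) < 3)
    stop("target and reference share fewer than 3 samples")
  v <- target$values[, shared, drop = FALSE]
  eig <- network$eigenproteins[, shared, drop = FALSE]
  mods <- rownames(eig)
  n <- nrow(v)
  module <- rep("grey", n); kme <- rep(NA_real_, n)
  assigned <- rep(FALSE, n); tie <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ks <- rep(NA_real_, length(mods))
    for (m in seq_along(mods)) {
      ok <- !is.na(v[i, ]) & !is.na(eig[m, ])
      if (sum(ok) < 3) next
      ks[m] <- tryCatch(as.numeric(bicor(v[i, ], eig[m, ])),
                        error = function(e) NA_real_)
    }
    if (all(is.na(ks))) { reason[i] <- "fewer than 3 usable samples"; next }
    best <- which.max(ks)
    kme[i] <- ks[best]
    if (!is.na(ks[best]) && ks[best] >= kme_min && ks[best] > 0) {
      module[i] <- mods[best]
      assigned[i] <- TRUE
      tie[i] <- sum(ks == ks[best], na.rm = TRUE) > 1
    } else {
      reason[i] <- sprintf("max kME %.3f below cutoff %.2f", ks[best], kme_min)
    }
  }
  data.frame(protein_id = rownames(v), module = module, kme = kme,
             assigned = assigned, tie = tie, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Module eigenprotein-trait association
#'
#' Biweight midcorrelation of each module eigenprotein with each trait over
#' the reference samples, with Student's p on n-2 df (same t transform as
#' Pearson). Constant traits give missing cells.
#'
#' @param network A [module_network()].
#' @param ref_metadata Data frame with `sample_id` and trait columns over
#'   the reference samples.
#' @param traits Character vector of trait columns.
#' @return A long data frame: `module`, `trait`, `bicor`, `n`, `p`.
#' @export
module_trait_correlation <- function(network, ref_metadata,
                                     traits = c("CERAD", "Braak", "MMSE")) {
  stopifnot(inherits(network, "ModuleNetwork"))
  idx <- match(colnames(network$eigenproteins), ref_metadata$sample_id)
  if (anyNA(idx)) stop("reference samples missing from ref_metadata")
  meta <- ref_metadata[idx, , drop = FALSE]
  out <- list()
  for (m in rownames(network$eigenproteins)) {
    for (tr in traits) {
      e <- network$eigenproteins[m, ]
      t_ <- meta[[tr]]
      ok <- !is.na(e) & !is.na(t_)
      r <- NA_real_
      if (sum(ok) >= 3 && stats::sd(t_[ok]) > 0)
        r <- as.numeric(bicor(e[ok], t_[ok]))
      out[[length(out) + 1]] <- data.frame(
        module = m, trait = tr, bicor = r, n = sum(ok),
        p = if (is.na(r)) NA_real_ else cor_t_p(r, sum(ok)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' One-tailed Fisher exact over-representation with Z-scores
#'
#' For each category, the overlap `k` between the query and the category
#' within the background universe is referred to the hypergeometric upper
#' tail (P(X >= k)); q-values are BH-adjusted across the categories of the
#' collection, and the standardized hypergeometric deviate
#' `Z = (k - n*K/N) / sqrt(n*K*(N-K)*(N-n) / (N^2*(N-1)))` is reported
#' together with the fold enrichment `k*N/(n*K)`. Categories with fewer
#' than `min_genes` members in the background are skipped.
#'
#' @param query Character vector (gene symbols), subset of `background`.
#' @param categories Named list of character vectors (e.g. from
#'   [read_gmt()] or module membership).
#' @param background Character vector: the universe.
#' @param min_genes Minimum background-intersected category size.
#' @return A data frame: `category`, `k`, `n`, `K`, `N`, `p`, `q`, `z`,
#'   `fold`.
#' @export
fet_enrichment <- function(query, categories, background, min_genes = 5) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  query <- unique(intersect(query, background))
  rows <- list()
  for (nm in names(categories)) {
    cat_bg <- unique(intersect(categories[[nm]], background))
    K <- length(cat_bg)
    if (K < min_genes) next
    N <- length(background)
    n <- length(query)
    k <- length(intersect(query, cat_bg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    # double arithmetic: the product overflows 32-bit integers readily
    Nn <- as.numeric(N); nn <- as.numeric(n); Kn <- as.numeric(K)
    mu <- nn * Kn / Nn
    sig2 <- nn * Kn * (Nn - Kn) * (Nn - nn) / (Nn^2 * (Nn - 1))
    z <- if (sig2 > 0) (k - mu) / sqrt(sig2) else NA_real_
    fold <- if (n > 0 && K > 0) k * N / (n * K) else NA_real_
    rows[[nm]] <- data.frame(category = nm, k = k, n = n, K = K, N = N,
                             p = p, z = z, fold = fold,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(category = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), z = numeric(0), fold = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("category", "k", "n", "K", "N", "p", "q", "z", "fold")]
}

#' Overlap and per-module coverage of two symbol sets
#'
#' @param plasma_symbols,brain_symbols Character vectors of gene symbols.
#' @param network A [module_network()] whose member ids are symbols in the
#'   brain set's namespace.
#' @return A list: `n_overlap`, `overlap_fraction` (of plasma symbols), and
#'   `coverage`, a data frame of per-module covered fractions
#'   (|module members also in plasma| / |module|).
#' @export
overlap_summary <- function(plasma_symbols, brain_symbols, network) {
  stopifnot(length(plasma_symbols) > 0, length(brain_symbols) > 0)
  plasma_symbols <- unique(plasma_symbols)
  brain_symbols <- unique(brain_symbols)
  ov <- intersect(plasma_symbols, brain_symbols)
  cov <- data.frame(
    module = names(network$modules),
    size = vapply(network$modules, length, integer(1)),
    covered = vapply(network$modules,
                     function(m) length(intersect(m, plasma_symbols)),
                     integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  cov$coverage <- cov$covered / cov$size
  list(n_overlap = length(ov),
       overlap_fraction = length(ov) / length(plasma_symbols),
       coverage = cov)
}
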