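#' Biomarker-positive (AT+) sample filtering
#'
#' Retains AD samples iff CSF tTau / A-beta 1-42 ratio is strictly greater
#' than `ratio_cut` and MoCA <= `moca_ad`; retains controls iff the ratio
#' is <= `ratio_cut` and MoCA >= `moca_ctl`. MoCA exactly at the cutoff
#' satisfies both rules, so the diagnosis label decides. Samples with a
#' missing required trait are excluded with reason, never aborted on.
#' GIS rows are ignored.
#'
#' @param metadata Sample metadata with `diagnosis`, `CSF_tTau`,
#'   `CSF_Abeta42` and `MoCA`.
#' @param ratio_cut CSF tTau/A-beta 1-42 positivity threshold
#'   (default 0.226).
#' @param moca_ad,moca_ctl MoCA cutoffs (AD <= 24, control >= 24).
#' @return A list with `retained` (sample ids) and `excluded`, a data frame
#'   of excluded ids and reasons.
#' @export
at_filter <- function(metadata, ratio_cut = 0.226, moca_ad = 24,
                      moca_ctl = 24) {
  meta <- metadata
  need <- c("sample_id", "diagnosis", "CSF_tTau", "CSF_Abeta42", "MoCA")
  absent <- setdiff(need, names(meta))
  if (length(absent))
    stop("metadata lacks required column(s): ",
         paste(absent, collapse = ", "))
  if ("is_gis" %in% names(meta)) meta <- meta[!meta$is_gis, , drop = FALSE]
  retained <- character(0)
  exc_id <- character(0); exc_reason <- character(0)
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, ]
    ratio <- row$CSF_tTau / row$CSF_Abeta42
    if (is.na(row$diagnosis) || is.na(ratio) || is.na(row$MoCA)) {
      exc_id <- c(exc_id, row$sample_id)
      exc_reason <- c(exc_reason, "missing trait")
      next
    }
    keep <- if (row$diagnosis == "AD") {
      if (ratio <= ratio_cut) "tTau/Abeta42 ratio <= cutoff"
      else if (row$MoCA > moca_ad) sprintf("MoCA > %g", moca_ad)
      else TRUE
    } else {
      if (ratio > ratio_cut) "tTau/Abeta42 ratio > cutoff"
      else if (row$MoCA < moca_ctl) sprintf("MoCA < %g", moca_ctl)
      else TRUE
    }
    if (isTRUE(keep)) retained <- c(retained, row$sample_id)
    else { exc_id <- c(exc_id, row$sample_id); exc_reason <- c(exc_reason, keep) }
  }
  list(retained = retained,
       excluded = data.frame(sample_id = exc_id, reason = exc_reason,
                             stringsAsFactors = FALSE))
}

#' Fisher combination of p-values
#'
#' `X2 = -2 * sum(log p)` referred to a chi-square with `2k` degrees of
#' freedom. A single p is returned unchanged; p = 0 is clamped to the
#' smallest positive double with a warning.
#'
#' @param p Numeric vector of p-values in `(0, 1]` (length >= 1).
#' @return The combined meta p-value.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  if (length(p) == 1) return(p)
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Combine two per-set differential tables into a meta table
#'
#' Meta p is the Fisher combination over the sets in which a protein was
#' tested; the effect is the mean log2 fold-change over available sets.
#' Proteins quantified in only one set pass through with that set's p and
#' fold-change, preserving them for downstream analyses.
#'
#' @param stat1,stat2 Data frames from [ttest_by_group()] for set 1 / set 2.
#' @return A data frame: per-set p and log2fc, `meta_p`, `mean_log2fc`,
#'   `n_sets`, and a `concordant` flag (same fold-change sign in both sets;
#'   `NA` for single-set proteins).
#' @export
combine_sets <- function(stat1, stat2) {
  ids <- union(stat1$protein_id, stat2$protein_id)
  i1 <- match(ids, stat1$protein_id)
  i2 <- match(ids, stat2$protein_id)
  p1 <- stat1$p[i1]; p2 <- stat2$p[i2]
  f1 <- stat1$log2fc[i1]; f2 <- stat2$log2fc[i2]
  sym <- ifelse(!is.na(i1), stat1$gene_symbol[i1], stat2$gene_symbol[i2])
  meta_p <- vapply(seq_along(ids), function(k)
    fisher_combine(c(p1[k], p2[k])), numeric(1))
  mean_fc <- rowMeans(cbind(f1, f2), na.rm = TRUE)
  mean_fc[is.na(f1) & is.na(f2)] <- NA_real_
  n_sets <- (!is.na(p1)) + (!is.na(p2))
  conc <- ifelse(!is.na(f1) & !is.na(f2), sign(f1) == sign(f2), NA)
  data.frame(protein_id = ids, gene_symbol = sym,
             p_set1 = p1, log2fc_set1 = f1,
             p_set2 = p2, log2fc_set2 = f2,
             meta_p = meta_p, meta_q = bh_adjust(meta_p),
             mean_log2fc = mean_fc, n_sets = n_sets, concordant = conc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-protein Z-transformation
#'
#' Each protein row is centred to mean 0 and scaled to SD 1 over its
#' observed values (sample SD, n-1 denominator). Missing cells are
#' preserved; zero-variance proteins are excluded with a warning.
#'
#' @param matrix A corrected- or log2-scale [abundance_matrix()].
#' @return An [abundance_matrix()] (scale `"corrected"`) of Z-scores.
#' @export
z_transform <- function(matrix) {
  stopifnot(is_abundance_matrix(matrix))
  v <- matrix$values
  mu <- rowMeans(v, na.rm = TRUE)
  s <- row_sds_na(v)
  bad <- is.na(s) | s == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance or under-observed protein(s) excluded",
            " from Z-transform")
    v <- v[!bad, , drop = FALSE]
    mu <- mu[!bad]; s <- s[!bad]
  }
  z <- (v - mu) / s
  abundance_matrix(z, matrix$gene_symbols[rownames(z)], scale = "corrected")
}

# Pearson r -> Student's t two-sided p with n-2 df
cor_t_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  p[r^2 >= 1] <- 0
  p
}

#' Protein-trait Pearson correlation grid
#'
#' Pairwise-complete Pearson correlation of every protein row against every
#' trait column, with Student's p from `t = r * sqrt((n-2)/(1-r^2))` on
#' n-2 df. Cells with fewer than 3 paired observations, or a constant
#' trait/protein over the pairing, are reported missing.
#'
#' @param matrix Typically the [z_transform()]ed matrix.
#' @param metadata Sample metadata holding the trait columns.
#' @param traits Character vector of trait column names.
#' @return A long data frame: `protein_id`, `gene_symbol`, `trait`, `r`,
#'   `n`, `p`.
#' @export
correlate_traits <- function(matrix, metadata,
                             traits = c("MoCA", "CSF_Abeta42", "CSF_tTau",
                                        "CSF_pTau181", "plasma_pTau181")) {
  stopifnot(is_abundance_matrix(matrix))
  meta <- check_metadata(matrix, metadata,
                         required = c("sample_id", traits))
  v <- matrix$values
  out <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    tr <- meta[[traits[k]]]
    r <- rep(NA_real_, nrow(v)); n <- integer(nrow(v))
    for (i in seq_len(nrow(v))) {
      ok <- !is.na(v[i, ]) & !is.na(tr)
      n[i] <- sum(ok)
      if (n[i] < 3) next
      if (stats::sd(tr[ok]) == 0 || stats::sd(v[i, ok]) == 0) next
      r[i] <- stats::cor(v[i, ok], tr[ok])
    }
    out[[k]] <- data.frame(protein_id = rownames(v),
                           gene_symbol = unname(matrix$gene_symbols[rownames(v)]),
                           trait = traits[k], r = r, n = n,
                           p = ifelse(is.na(r), NA_real_, cor_t_p(r, n)),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Fold-change concordance between two analyses
#'
#' Pearson correlation (with Student's p) between two named log2
#' fold-change vectors over their shared keys, plus the fraction of
#' sign-discordant pairs among keys passing `sig_mask`.
#'
#' @param fc_a,fc_b Named numeric vectors of log2 fold-changes.
#' @param sig_mask Optional character vector of keys considered significant
#'   (defaults to all shared keys) for the discordance count.
#' @return A list: `r`, `p`, `n`, `discordant_fraction`, `n_sig`.
#' @export
concordance <- function(fc_a, fc_b, sig_mask = NULL) {
  shared <- intersect(names(fc_a), names(fc_b))
  shared <- shared[is.finite(fc_a[shared]) & is.finite(fc_b[shared])]
  if (length(shared) < 3) stop("fewer than 3 shared finite fold-changes")
  r <- stats::cor(fc_a[shared], fc_b[shared])
  p <- cor_t_p(r, length(shared))
  if (is.null(sig_mask)) sig_mask <- shared
  sig <- intersect(sig_mask, shared)
  disc <- if (length(sig)) mean(sign(fc_a[sig]) != sign(fc_b[sig])) else NA_real_
  list(r = r, p = p, n = length(shared),
       discordant_fraction = disc, n_sig = length(sig))
}
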