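#' Per-protein two-group Student's t differential abundance
#'
#' Pooled-variance (equal-variance) two-sample t-test per protein on
#' pairwise-complete observed values, two-sided p from the t distribution
#' with n1 + n2 - 2 degrees of freedom, Benjamini-Hochberg q over all
#' tested proteins, and log2 fold-change = mean(case) - mean(reference).
#' GIS channels are excluded. Proteins with fewer than 2 observed values in
#' either group get missing statistics and are flagged.
#'
#' @param matrix A log2- or corrected-scale [abundance_matrix()].
#' @param metadata Sample metadata; `group_field` must have exactly two
#'   levels among non-GIS samples.
#' @param group_field Metadata column defining the two groups.
#' @param case Level treated as the case (numerator of the fold-change);
#'   defaults to `"AD"` when present, else the second sorted level.
#' @param welch Use Welch (unequal-variance) t instead of pooled.
#' @return A data frame (one row per protein): `protein_id`, `gene_symbol`,
#'   `log2fc`, `t`, `df`, `p`, `q`, `n_case`, `n_ref`, `direction`, `tested`.
#' @export
ttest_by_group <- function(matrix, metadata, group_field = "diagnosis",
                           case = NULL, welch = FALSE) {
  stopifnot(is_abundance_matrix(matrix))
  meta <- check_metadata(matrix, metadata,
                         required = c("sample_id", group_field))
  if ("is_gis" %in% names(meta)) meta <- meta[!meta$is_gis, , drop = FALSE]
  g <- meta[[group_field]]
  meta <- meta[!is.na(g), , drop = FALSE]
  g <- meta[[group_field]]
  levels <- sort(unique(g))
  if (length(levels) != 2)
    stop("group field '", group_field, "' must have exactly two levels, has ",
         length(levels))
  if (is.null(case)) case <- if ("AD" %in% levels) "AD" else levels[2]
  ref <- setdiff(levels, case)
  v <- matrix$values[, meta$sample_id, drop = FALSE]
  a <- v[, g == case, drop = FALSE]
  b <- v[, g == ref, drop = FALSE]
  if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2)
    stop("a group has fewer than 2 observations matrix-wide")

  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  s1 <- row_sds_na(a); s2 <- row_sds_na(b)
  tested <- n1 >= 2 & n2 >= 2

  if (welch) {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # identical groups: zero variance and zero difference => no evidence
  degenerate <- tested & se == 0 & (m1 - m2) == 0
  tt[degenerate] <- 0; p[degenerate] <- 1
  tt[!tested] <- NA_real_; p[!tested] <- NA_real_; df[!tested] <- NA_real_
  q <- bh_adjust(p)
  lfc <- m1 - m2
  lfc[!(n1 >= 1 & n2 >= 1)] <- NA_real_

  data.frame(protein_id = rownames(v),
             gene_symbol = unname(matrix$gene_symbols[rownames(v)]),
             log2fc = lfc, t = tt, df = df, p = p, q = q,
             n_case = n1, n_ref = n2,
             direction = ifelse(is.na(lfc), NA_character_,
                                ifelse(lfc > 0, "up",
                                       ifelse(lfc < 0, "down", "flat"))),
             tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up rule: with p sorted ascending, `q_(i) = min_{j >= i} p_(j)*m/j`
#' capped at 1, mapped back to input order. Missing p are excluded from the
#' family and returned missing.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Supervised hierarchical clustering of a protein subset
#'
#' Clusters both the selected protein profiles and the samples with
#' euclidean distance and complete linkage, the combination whose merge
#' heights are monotone non-decreasing. Missing values are handled by
#' pairwise-complete euclidean distance rescaled to full length (the
#' `stats::dist` convention). Ties are resolved by `hclust`'s deterministic
#' input-index order, so leaf orders are reproducible.
#'
#' @param matrix A log2- or corrected-scale [abundance_matrix()].
#' @param protein_subset Character vector of protein ids to cluster.
#' @param metric,linkage Distance and linkage method (defaults euclidean /
#'   complete).
#' @return A list with `proteins` and `samples`, each an `hclust` object,
#'   plus the corresponding leaf orders.
#' @export
supervised_cluster <- function(matrix, protein_subset, metric = "euclidean",
                               linkage = "complete") {
  stopifnot(is_abundance_matrix(matrix), length(protein_subset) > 0)
  sub <- matrix$values[protein_subset, , drop = FALSE]
  check_dist <- function(d, labels, what) {
    if (any(!is.finite(as.vector(d)))) {
      bad <- which(!is.finite(as.matrix(d)), arr.ind = TRUE)
      stop("no pairwise-complete overlap between ", what, " '",
           labels[bad[1, 1]], "' and '", labels[bad[1, 2]], "'")
    }
    d
  }
  dp <- check_dist(stats::dist(sub, method = metric), rownames(sub),
                   "proteins")
  ds <- check_dist(stats::dist(t(sub), method = metric), colnames(sub),
                   "samples")
  hp <- stats::hclust(dp, method = linkage)
  hs <- stats::hclust(ds, method = linkage)
  list(proteins = hp, samples = hs,
       protein_order = rownames(sub)[hp$order],
       sample_order = colnames(sub)[hs$order])
}

#' One-way ANOVA with Tukey HSD post-hoc pairwise comparisons
#'
#' @param values Numeric vector of measurements.
#' @param groups Factor/character of group labels (k >= 2 groups, each with
#'   at least 2 values).
#' @return A list with `f`, `p` (omnibus ANOVA), and `pairs`: a data frame
#'   of pairwise mean differences and Tukey-adjusted p-values from the
#'   studentized range distribution.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("anova_tukey needs at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  # all values identical: 0/0 up to float noise; report no evidence
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  tot_ss <- sum(an[["Sum Sq"]])
  degenerate_all <- tot_ss <= 1e-12 * max(1, mean(values)^2) * length(values)
  if (degenerate_all || (!is.finite(f) && an[["Sum Sq"]][1] == 0)) {
    f <- 0; p <- 1; pairs$p_adj[] <- 1
  }
  if (an[["Sum Sq"]][2] == 0 && !degenerate_all)
    pairs$p_adj[pairs$diff == 0] <- 1
  list(f = f, p = p, pairs = pairs)
}
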