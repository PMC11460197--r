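#' Channel-sum scaling of raw TMT reporter intensities
#'
#' Removes per-channel loading differences: each protein intensity is
#' divided by the sum of all reporter intensities of its TMT channel
#' (sample) and multiplied by the maximum channel sum, so every channel's
#' total intensity equals the largest pre-scaling total. Sums are taken
#' over the proteins observed in that channel; missing cells stay missing.
#'
#' @param matrix A raw-scale [abundance_matrix()].
#' @return A list with `matrix` (scale `"scaled"`) and `report`, a data
#'   frame of per-sample pre-scaling sums and the factor applied.
#' @export
channel_sum_scale <- function(matrix) {
  stopifnot(is_abundance_matrix(matrix))
  if (matrix$scale != "raw")
    stop("channel_sum_scale expects a raw-scale matrix, got ", matrix$scale)
  v <- matrix$values
  sums <- colSums(v, na.rm = TRUE)
  empty <- colSums(!is.na(v)) == 0
  if (any(empty))
    stop("sample(s) with no observed protein: ",
         paste(colnames(v)[empty], collapse = ", "))
  factor <- max(sums) / sums
  scaled <- sweep(v, 2, factor, `*`)
  report <- data.frame(sample_id = colnames(v), channel_sum = sums,
                       max_sum = max(sums), scale_factor = factor,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(matrix = am_with_values(matrix, scaled, scale = "scaled"),
       report = report)
}

#' Intensity-sum scaling for label-free data
#'
#' Identical arithmetic to [channel_sum_scale()] (divide by the per-sample
#' protein intensity sum, multiply by the maximum sum across samples); kept
#' as a distinct entry point so label-free runs are recorded as such.
#'
#' @inheritParams channel_sum_scale
#' @return As [channel_sum_scale()].
#' @export
intensity_sum_scale_labelfree <- function(matrix) {
  channel_sum_scale(matrix)
}

#' Remove proteins with too many missing values
#'
#' Retains a protein iff its missing fraction is at most `max_missing_frac`.
#' The rule is "more than 50\% missing is removed", i.e. strictly greater:
#' a protein missing in exactly half the samples survives the default cut.
#'
#' @param matrix An [abundance_matrix()] on any scale.
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.5).
#' @return A list with `matrix` (retained proteins) and `dropped` (ids of
#'   removed proteins).
#' @export
filter_missingness <- function(matrix, max_missing_frac = 0.5) {
  stopifnot(is_abundance_matrix(matrix))
  frac <- rowMeans(is.na(matrix$values))
  keep <- frac <= max_missing_frac
  list(matrix = am_subset(matrix, proteins = keep),
       dropped = rownames(matrix$values)[!keep])
}

#' Log2-transform a scaled matrix
#'
#' @param matrix A raw- or scaled-scale [abundance_matrix()]; all observed
#'   values must be strictly positive.
#' @return An [abundance_matrix()] with scale `"log2"`.
#' @export
log2_transform <- function(matrix) {
  stopifnot(is_abundance_matrix(matrix))
  if (!matrix$scale %in% c("raw", "scaled"))
    stop("log2_transform expects raw or scaled values, got ", matrix$scale)
  v <- matrix$values
  if (any(v[!is.na(v)] <= 0))
    stop("log2_transform: non-positive observed value(s) present")
  am_with_values(matrix, log2(v), scale = "log2")
}

#' Downshifted-normal imputation of missing log2 values
#'
#' Label-free path only. Per sample, missing values are drawn from a normal
#' distribution centred `downshift` sample-SDs below the sample mean with SD
#' `width` times the sample SD, the conventional left-censored imputation
#' for intensities missing because they fell below detection.
#'
#' @param matrix A log2-scale [abundance_matrix()].
#' @param width,downshift Imputation shape parameters (defaults 0.3 / 1.8).
#' @param seed Integer seed for reproducible draws.
#' @return An [abundance_matrix()] with no missing values.
#' @export
impute_downshifted_normal <- function(matrix, width = 0.3, downshift = 1.8,
                                      seed = 1L) {
  stopifnot(is_abundance_matrix(matrix))
  if (matrix$scale != "log2")
    stop("impute_downshifted_normal expects a log2-scale matrix")
  v <- matrix$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 3))
    stop("sample(s) with fewer than 3 observed values: ",
         paste(colnames(v)[n_obs < 3], collapse = ", "))
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    mu <- mean(v[, j], na.rm = TRUE)
    s <- stats::sd(v[, j], na.rm = TRUE)
    v[miss, j] <- stats::rnorm(sum(miss), mu - downshift * s, width * s)
  }
  am_with_values(matrix, v)
}
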