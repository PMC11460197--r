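# Internal helpers shared across stages.

# Row-wise means/sds over observed values only.
row_means_na <- function(m) rowMeans(m, na.rm = TRUE)

row_sds_na <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- sqrt(ss / pmax(n - 1, 1))
  out[n < 2] <- NA_real_
  out
}

# Deterministic polynomial rolling hash of a character scalar, returned as
# hex. Used to stamp result tables with a config fingerprint so that two
# runs from the same configuration are recognizably identical. Arithmetic
# stays below 2^53 so plain doubles are exact.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Fingerprint a run configuration
#'
#' Stable hash of a configuration list (order-normalized), used to stamp
#' every result table a pipeline run writes.
#'
#' @param config A named list.
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  config <- config[order(names(config))]
  fnv1a_hash(paste(deparse(config, control = "all"), collapse = "\n"))
}

# seed derivation: keep derived seeds < 2^31 and deterministic
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}
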