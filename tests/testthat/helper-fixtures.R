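# Shared fixture builders; everything is generated in code.

# small abundance matrix with optional missing cells
make_matrix <- function(values, scale = "raw", gene_symbols = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  abundance_matrix(values, gene_symbols, scale = scale)
}

# minimal metadata for a single-set, possibly multi-batch layout
make_metadata <- function(sample_ids, batch = "b1", is_gis = FALSE,
                          diagnosis = "control", set = "set1", ...) {
  df <- data.frame(sample_id = sample_ids, set = set,
                   batch = rep_len(batch, length(sample_ids)),
                   channel = sprintf("ch%02d", seq_along(sample_ids)),
                   is_gis = rep_len(is_gis, length(sample_ids)),
                   diagnosis = rep_len(diagnosis, length(sample_ids)),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], nrow(df))
  df
}

# batch fixture: additive log2 model base_i + sample_j + offset_b, with GIS
# channels per batch; exact structure for median-polish recovery checks
make_batch_fixture <- function(n_proteins = 50, n_per_batch = 6,
                               batch_offsets = c(0, 1), sample_sd = 0.3,
                               noise_sd = 0, seed = 1) {
  set.seed(seed)
  nb <- length(batch_offsets)
  base <- runif(n_proteins, 10, 30)
  cols <- list(); meta <- list()
  for (b in seq_len(nb)) {
    ids <- c(sprintf("b%d.s%d", b, seq_len(n_per_batch)),
             sprintf("b%d.GIS", b))
    samp_eff <- c(rnorm(n_per_batch, 0, sample_sd), 0)
    block <- outer(base, samp_eff, `+`) + batch_offsets[b] +
      matrix(rnorm(n_proteins * (n_per_batch + 1), 0, noise_sd),
             n_proteins)
    colnames(block) <- ids
    cols[[b]] <- block
    meta[[b]] <- make_metadata(ids, batch = sprintf("b%d", b),
                               is_gis = c(rep(FALSE, n_per_batch), TRUE),
                               diagnosis = c(rep("control", n_per_batch),
                                             NA))
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("P%03d", seq_len(n_proteins))
  list(matrix = make_matrix(m, scale = "log2"),
       metadata = do.call(rbind, meta))
}

# shift every log2 value by a constant
am_with_values_shift <- function(m, c) {
  abundance_matrix(m$values + c, m$gene_symbols, scale = m$scale)
}

# re-stamp a matrix as raw (e.g. to test idempotence of scaling)
am_with_values_for_test <- function(m) {
  abundance_matrix(m$values, m$gene_symbols, scale = "raw")
}

# brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) p[o[j]] * m / j)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force hypergeometric upper tail via choose()
fet_oracle <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# brute-force AUC by pair enumeration with half-credit ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# literal transcription of the biweight midcorrelation formula
bicor_oracle <- function(x, y) {
  med <- function(v) median(v)
  ux <- (x - med(x)) / (9 * median(abs(x - med(x))))
  uy <- (y - med(y)) / (9 * median(abs(y - med(y))))
  wx <- (1 - ux^2)^2 * (abs(ux) < 1)
  wy <- (1 - uy^2)^2 * (abs(uy) < 1)
  xt <- (x - med(x)) * wx
  yt <- (y - med(y)) * wy
  sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

# zooming grid search for the 2-parameter logistic MLE (independent of glm)
logistic_grid_oracle <- function(x, y, rounds = 6, span = 8, grid_n = 41) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  for (r in seq_len(rounds)) {
    b0s <- seq(centre[1] - span, centre[1] + span, length.out = grid_n)
    b1s <- seq(centre[2] - span, centre[2] + span, length.out = grid_n)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    centre <- c(b0s[best[1]], b1s[best[2]])
    span <- span * 2.2 / grid_n * 2   # shrink around the best cell
  }
  centre
}
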