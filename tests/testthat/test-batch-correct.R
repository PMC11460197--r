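test_that("median polish solves the 2x2 case in one sweep", {
  r <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("P1", "P2"), c("A", "B")))
  ps <- hepplasma:::median_polish(r)
  expect_true(ps$converged)
  expect_equal(unname(ps$residuals), matrix(0, 2, 2))
  expect_equal(unname(ps$col_effects - mean(ps$col_effects)), c(-0.5, 0.5))
  # decomposition reconstructs the input
  rec <- ps$residuals + outer(ps$row_effects, rep(1, 2)) +
    outer(rep(1, 2), ps$col_effects)
  expect_equal(unname(rec), unname(r))
})

test_that("polish residuals have near-zero row and column medians", {
  set.seed(10)
  x <- matrix(rnorm(600), 30, 20)
  x[sample(600, 60)] <- NA
  dimnames(x) <- list(paste0("P", 1:30), paste0("S", 1:20))
  ps <- hepplasma:::median_polish(x, tol = 1e-6)
  expect_true(ps$converged)
  expect_lt(max(abs(apply(ps$residuals, 1, median, na.rm = TRUE))), 1e-5)
  expect_lt(max(abs(apply(ps$residuals, 2, median, na.rm = TRUE))), 1e-5)
})

test_that("single-batch correction changes nothing but a per-protein constant", {
  fx <- make_batch_fixture(n_proteins = 40, n_per_batch = 8,
                           batch_offsets = 0, sample_sd = 0, seed = 11)
  out <- tampor_correct(fx$matrix, fx$metadata)
  delta <- out$matrix$values - fx$matrix$values
  expect_lt(max(apply(delta, 1, function(r) diff(range(r)))), 1e-8)
})

test_that("a uniform +1 log2 batch shift is removed exactly with GIS anchors", {
  fx <- make_batch_fixture(n_proteins = 500, n_per_batch = 10,
                           batch_offsets = c(0, 1), sample_sd = 0.3,
                           seed = 12)
  meta <- fx$metadata
  before <- fx$matrix$values
  med_diff <- function(v) {
    b1 <- meta$sample_id[meta$batch == "b1" & !meta$is_gis]
    b2 <- meta$sample_id[meta$batch == "b2" & !meta$is_gis]
    apply(v[, b2], 1, median) - apply(v[, b1], 1, median)
  }
  expect_equal(mean(med_diff(before)), 1, tolerance = 0.1)
  out <- tampor_correct(fx$matrix, meta)
  expect_lt(max(abs(med_diff(out$matrix$values))), 1e-6)
  # GIS medians agree across batches after correction
  g1 <- meta$sample_id[meta$batch == "b1" & meta$is_gis]
  g2 <- meta$sample_id[meta$batch == "b2" & meta$is_gis]
  expect_lt(max(abs(out$matrix$values[, g1] - out$matrix$values[, g2])),
            1e-6)
})

test_that("correction commutes with a global constant shift", {
  fx <- make_batch_fixture(n_proteins = 30, n_per_batch = 5,
                           batch_offsets = c(0, 0.7), noise_sd = 0.05,
                           seed = 13)
  a <- tampor_correct(fx$matrix, fx$metadata)$matrix$values
  shifted <- am_with_values_shift(fx$matrix, 3)
  b <- tampor_correct(shifted, fx$metadata)$matrix$values
  expect_equal(b, a + 3, tolerance = 1e-8)
})

test_that("GIS requirements and all-sample fallback are enforced", {
  fx <- make_batch_fixture(n_proteins = 20, n_per_batch = 4,
                           batch_offsets = c(0, 1), seed = 14)
  meta_no_gis <- fx$metadata
  meta_no_gis$is_gis <- FALSE
  expect_error(tampor_correct(fx$matrix, meta_no_gis[meta_no_gis$batch ==
    "b1", ]), "missing from metadata")
  meta2 <- fx$metadata
  meta2$is_gis[meta2$batch == "b2"] <- FALSE
  expect_error(tampor_correct(fx$matrix, meta2), "without GIS")
  # no-GIS mode still removes a uniform shift via the all-sample median
  out <- tampor_correct(fx$matrix, meta_no_gis, use_gis = FALSE)
  b1 <- fx$metadata$sample_id[fx$metadata$batch == "b1"]
  b2 <- fx$metadata$sample_id[fx$metadata$batch == "b2"]
  md <- apply(out$matrix$values[, b2], 1, median) -
    apply(out$matrix$values[, b1], 1, median)
  expect_lt(max(abs(md)), 1e-6)
})

test_that("bootstrap regression with a full-sample fit equals plain OLS", {
  set.seed(15)
  n <- 40
  meta <- make_metadata(sprintf("S%02d", 1:n),
                        diagnosis = rep(c("control", "AD"), each = n / 2),
                        age = rnorm(n, 70, 8))
  v <- matrix(rnorm(5 * n, 20, 1), 5, n,
              dimnames = list(paste0("P", 1:5), meta$sample_id))
  v <- v + outer(runif(5, -0.05, 0.05), meta$age - 65)
  m <- make_matrix(v, scale = "log2")
  out <- bootstrap_regress(m, meta, covariates = "age", B = 1L,
                           seed = 1, .resample = FALSE)
  for (i in 1:5) {
    fit <- lm(v[i, ] ~ meta$diagnosis + meta$age)
    beta <- coef(fit)[["meta$age"]]
    expected <- v[i, ] - beta * (meta$age - mean(meta$age))
    expect_equal(out$matrix$values[i, ], expected, tolerance = 1e-8)
    expect_equal(unname(out$report[i, "age"]), beta, tolerance = 1e-8)
  }
})

test_that("an injected age slope is recovered and removed", {
  set.seed(16)
  n <- 100
  meta <- make_metadata(sprintf("S%03d", 1:n),
                        diagnosis = rep(c("control", "AD"), each = n / 2),
                        age = rnorm(n, 70, 10))
  slope <- 0.05
  v <- matrix(rnorm(20 * n, 20, 0.3), 20, n,
              dimnames = list(sprintf("P%02d", 1:20), meta$sample_id))
  v <- v + slope * rep(meta$age - 65, each = 20)
  m <- make_matrix(v, scale = "log2")
  out <- bootstrap_regress(m, meta, covariates = "age", B = 200L, seed = 2)
  expect_lt(abs(median(out$report$age) - slope), 0.01)
  # corrected data no longer carry the age trend
  resid_slope <- apply(out$matrix$values, 1,
                       function(r) coef(lm(r ~ meta$age))[2])
  expect_lt(max(abs(resid_slope)), 0.02)
})

test_that("protected diagnosis effects survive covariate regression", {
  set.seed(17)
  n <- 60
  meta <- make_metadata(sprintf("S%02d", 1:n),
                        diagnosis = rep(c("control", "AD"), each = n / 2),
                        age = rnorm(n, 70, 8))
  v <- matrix(rnorm(10 * n, 20, 0.3), 10, n,
              dimnames = list(sprintf("P%02d", 1:10), meta$sample_id))
  v <- v + rep(as.numeric(meta$diagnosis == "AD"), each = 10) * 1.0 +
    0.03 * rep(meta$age - 65, each = 10)
  m <- make_matrix(v, scale = "log2")
  out <- bootstrap_regress(m, meta, covariates = "age", B = 100L, seed = 3)
  ad <- meta$diagnosis == "AD"
  diffs <- rowMeans(out$matrix$values[, ad]) -
    rowMeans(out$matrix$values[, !ad])
  expect_equal(unname(diffs), rep(1, 10), tolerance = 0.25)
})

test_that("null covariates leave the matrix essentially unchanged", {
  set.seed(18)
  n <- 80
  meta <- make_metadata(sprintf("S%02d", 1:n),
                        diagnosis = rep(c("control", "AD"), each = n / 2),
                        age = rnorm(n, 70, 8))
  v <- matrix(rnorm(15 * n, 20, 0.5), 15, n,
              dimnames = list(sprintf("P%02d", 1:15), meta$sample_id))
  m <- make_matrix(v, scale = "log2")
  out <- bootstrap_regress(m, meta, covariates = "age", B = 100L, seed = 4)
  expect_lt(max(abs(out$matrix$values - v)), 0.2)
  # under-observed proteins are flagged, not corrected
  v2 <- v; v2[1, 1:(n - 3)] <- NA
  out2 <- bootstrap_regress(make_matrix(v2, scale = "log2"), meta,
                            covariates = "age", B = 10L, seed = 5)
  expect_true(out2$report$uncorrected[1])
  expect_equal(out2$matrix$values[1, ], v2[1, ])
})

test_that("collinear covariates are rejected by name", {
  n <- 20
  meta <- make_metadata(sprintf("S%02d", 1:n),
                        diagnosis = rep(c("control", "AD"), each = n / 2),
                        age = 1:n, age2 = 2 * (1:n))
  v <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("P1", "P2"), meta$sample_id))
  expect_error(bootstrap_regress(make_matrix(v, scale = "log2"), meta,
                                 covariates = c("age", "age2"), B = 5L),
               "collinear")
})
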