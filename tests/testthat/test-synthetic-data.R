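test_that("identical designs give bit-identical datasets", {
  d <- synthetic_design(n_proteins = 120, n_modules = 3, module_size = 10, seed = 11)
  a <- simulate_dataset(d)
  b <- simulate_dataset(d)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$true_log2fc, b$truth$true_log2fc)
  r1 <- simulate_reference_brain(d)
  r2 <- simulate_reference_brain(d)
  expect_identical(r1$matrix$values, r2$matrix$values)
})

test_that("design validation rejects inconsistent configurations", {
  expect_error(synthetic_design(frac_de = 1.5), "frac_de")
  expect_error(synthetic_design(n_modules = 50, module_size = 30,
                                n_proteins = 100), "exceeds")
  expect_error(synthetic_design(module_purity = 0), "module_purity")
  expect_error(synthetic_design(gis_per_batch = 0), "gis_per_batch")
})

test_that("null design produces near-zero group differences", {
  d <- synthetic_design(n_proteins = 400, frac_de = 0, batch_log2_sd = 0,
                        n_modules = 0, mnar_intercept = -30, seed = 5)
  sim <- simulate_dataset(d)
  meta <- sim$metadata
  bio <- meta[!meta$is_gis & meta$set == "set2", ]
  lg <- log2(sim$matrix$values[, bio$sample_id])
  diff <- rowMeans(lg[, bio$diagnosis == "AD"]) -
    rowMeans(lg[, bio$diagnosis == "control"])
  # SE of a mean difference: sd * sqrt(1/49 + 1/36)
  sd_tot <- sqrt(d$biological_log2_sd^2 + d$noise_log2_sd^2)
  expect_lt(abs(mean(diff)), 4 * sd_tot * sqrt(1 / 49 + 1 / 36) / sqrt(400))
  expect_lt(max(abs(diff)), 5 * sd_tot * sqrt(1 / 49 + 1 / 36))
})

test_that("an injected log2 fold-change is recovered within standard error", {
  d <- synthetic_design(
    n_proteins = 1, frac_de = 1, effect_log2fc = c(mean = 1, sd = 0),
    n_samples_per_set = list(set1 = c(control = 200, AD = 200)),
    n_batches_per_set = c(set1 = 1), batch_log2_sd = 0,
    biological_log2_sd = 0, noise_log2_sd = 0.1, n_modules = 0,
    mnar_intercept = -30, seed = 7)
  sim <- simulate_dataset(d)
  meta <- sim$metadata[!sim$metadata$is_gis, ]
  lg <- log2(sim$matrix$values[, meta$sample_id, drop = FALSE])
  fc <- mean(lg[1, meta$diagnosis == "AD"]) -
    mean(lg[1, meta$diagnosis == "control"])
  # tolerance = 5 * sd * sqrt(2/n)
  expect_lt(abs(fc - 1), 0.05)
})

test_that("per-batch GIS medians reflect the true batch offsets", {
  d <- synthetic_design(n_proteins = 200, batch_log2_sd = 0.8,
                        noise_log2_sd = 0, n_modules = 0,
                        mnar_intercept = -30, seed = 13)
  sim <- simulate_dataset(d)
  meta <- sim$metadata
  off <- sim$truth$batch_offsets$set1
  lg <- log2(sim$matrix$values)
  for (b in c("set1.b1", "set1.b2")) {
    gis <- meta$sample_id[meta$batch == b & meta$is_gis]
    expect_equal(lg[, gis] - lg[, meta$sample_id[meta$batch == "set1.b3" &
                                                   meta$is_gis]],
                 off[, b] - off[, "set1.b3"], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("GIS channels equal the set mean of biological channels at zero noise", {
  d <- synthetic_design(n_proteins = 150, batch_log2_sd = 0,
                        noise_log2_sd = 0, n_modules = 3, module_size = 10,
                        mnar_intercept = -30, seed = 3)
  sim <- simulate_dataset(d)
  meta <- sim$metadata
  for (s in c("set1", "set2")) {
    bio <- meta$sample_id[meta$set == s & !meta$is_gis]
    gis <- meta$sample_id[meta$set == s & meta$is_gis]
    expected <- rowMeans(sim$matrix$values[, bio])
    for (g in gis)
      expect_equal(sim$matrix$values[, g], expected, tolerance = 1e-9)
  }
})

test_that("MNAR missingness matches its logistic model", {
  d0 <- synthetic_design(n_proteins = 300, mnar_slope = 0,
                         mnar_intercept = -30, seed = 2)
  sim0 <- simulate_dataset(d0)
  expect_false(anyNA(sim0$matrix$values))

  # flat 30% missingness: slope 0, intercept = logit(0.3)
  d3 <- synthetic_design(n_proteins = 300, mnar_slope = 0,
                         mnar_intercept = qlogis(0.3), seed = 2)
  sim3 <- simulate_dataset(d3)
  expect_equal(mean(is.na(sim3$matrix$values)), 0.3, tolerance = 0.02)

  # abundance-dependent: bottom decile loses more than top decile
  d <- synthetic_design(n_proteins = 500, seed = 4)
  sim <- simulate_dataset(d)
  base <- rowMeans(log2(sim$matrix$values), na.rm = TRUE)
  qs <- quantile(base, c(0.1, 0.9))
  lo <- mean(is.na(sim$matrix$values[base <= qs[1], ]))
  hi <- mean(is.na(sim$matrix$values[base >= qs[2], ]))
  expect_gt(lo, hi)
})

test_that("impose_missingness stores probabilities consistent with the draw", {
  d <- synthetic_design(n_proteins = 200, seed = 6)
  sim <- simulate_dataset(d)
  expect_identical(dim(sim$truth$miss_prob), dim(sim$matrix$values))
  pr <- sim$truth$miss_prob
  expect_true(all(pr[!is.na(pr)] >= 0 & pr[!is.na(pr)] <= 1))
  # cells that went missing should on average have had higher probability
  expect_gt(mean(pr[is.na(sim$matrix$values)], na.rm = TRUE),
            mean(pr[!is.na(sim$matrix$values)], na.rm = TRUE))
})

test_that("reference modules are tight blocks distinct from background", {
  d <- synthetic_design(n_proteins = 300, n_modules = 5, module_size = 15,
                        module_purity = 0.9, seed = 21)
  ref <- simulate_reference_brain(d)
  x <- ref$matrix$values
  truth <- ref$truth
  m1 <- x[truth == "M1", ]
  within <- cor(t(m1))
  within <- within[upper.tri(within)]
  m2 <- x[truth == "M2", ]
  between <- cor(t(m1), t(m2))
  expect_gt(median(within), median(abs(between)))
  expect_gt(median(within), 0.5)
})

test_that("pure modules at zero noise collapse onto their latent factor", {
  d <- synthetic_design(n_proteins = 60, n_modules = 2, module_size = 10,
                        module_purity = 1, noise_log2_sd = 0, seed = 8)
  ref <- simulate_reference_brain(d)
  m1 <- ref$matrix$values[ref$truth == "M1", ]
  centred <- m1 - rowMeans(m1)
  for (i in 2:nrow(centred))
    expect_equal(centred[i, ], centred[1, ], tolerance = 1e-9,
                 ignore_attr = TRUE)
  expect_equal(unname(ref$network$var_explained["M1"]), 1, tolerance = 1e-9)
})

test_that("shared-control option reuses set-1 control subjects", {
  d <- synthetic_design(n_proteins = 50, n_modules = 2, module_size = 5,
                        share_controls = TRUE, seed = 9)
  sim <- simulate_dataset(d)
  m <- sim$metadata
  s1 <- m[m$set == "set1" & !m$is_gis & m$diagnosis == "control", ]
  s2 <- m[m$set == "set2" & !m$is_gis & m$diagnosis == "control", ]
  expect_length(intersect(s1$subject_id, s2$subject_id), 13)
})
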