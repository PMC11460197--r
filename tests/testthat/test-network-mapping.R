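ref_from_values <- function(v) abundance_matrix(v, scale = "log2")

test_that("eigenproteins recover degenerate module structure", {
  set.seed(30)
  base <- rnorm(20)
  v <- rbind(a = base, b = base, c = base)
  colnames(v) <- sprintf("S%02d", 1:20)
  e <- compute_eigenprotein(ref_from_values(v), c("a", "b", "c"))
  expect_equal(e$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(e$eigenprotein, base)), 1, tolerance = 1e-12)
  expect_gt(cor(e$eigenprotein, base), 0)  # sign aligned to members
  expect_equal(sum(e$eigenprotein^2), 1, tolerance = 1e-12)
})

test_that("two-member explained variance equals (1 + rho) / 2", {
  set.seed(31)
  for (target in c(-0.5, 0.2, 0.8)) {
    x <- rnorm(40)
    y <- target * x + sqrt(1 - target^2) * rnorm(40)
    rho <- cor(x, y)
    v <- rbind(a = x, b = y)
    colnames(v) <- sprintf("S%02d", 1:40)
    e <- compute_eigenprotein(ref_from_values(v), c("a", "b"))
    expect_equal(e$var_explained, (1 + abs(rho)) / 2, tolerance = 1e-10)
  }
  # anti-correlated pair: documented tie-break aligns to the first member
  x <- rnorm(30)
  v <- rbind(a = x, b = -x)
  colnames(v) <- sprintf("S%02d", 1:30)
  e <- compute_eigenprotein(ref_from_values(v), c("a", "b"))
  expect_equal(e$var_explained, 1, tolerance = 1e-12)
  zx <- (x - mean(x)) / sd(x)
  expect_gt(cor(e$eigenprotein, zx), 0)
  expect_error(compute_eigenprotein(ref_from_values(v), "a"),
               "fewer than 2")
})

test_that("bicor matches a literal transcription of its formula", {
  set.seed(32)
  for (r in 1:100) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(bicor(x, y), bicor_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("bicor has the robust-correlation properties", {
  set.seed(33)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, 0, 0.3)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  expect_equal(bicor(2 * x + 5, y), bicor(x, y), tolerance = 1e-12)
  expect_equal(bicor(-x, y), -bicor(x, y), tolerance = 1e-12)
  # outlier robustness: bicor stays near the clean value, Pearson collapses
  xo <- c(1, 2, 3, 4, 100); yo <- c(1, 2, 3, 4, 5)
  expect_equal(bicor(xo, yo), bicor_oracle(xo, yo), tolerance = 1e-12)
  expect_gt(bicor(xo, yo), cor(xo, yo))
  expect_error(bicor(1:2, 1:2), "at least 3")
  # zero MAD falls back to Pearson with a flag
  z <- c(5, 5, 5, 5, 9)
  out <- bicor(z, c(1, 2, 3, 4, 5))
  expect_true(isTRUE(attr(out, "pearson_fallback")))
})

test_that("module assignment honours the kME cutoff and tie rules", {
  set.seed(34)
  d <- synthetic_design(n_proteins = 120, n_modules = 3, module_size = 15,
                        module_purity = 0.95, seed = 34)
  ref <- simulate_reference_brain(d)
  net <- ref$network
  # a protein equal to an eigenprotein maps to it with kME 1
  v <- rbind(E7 = net$eigenproteins["M2", ])
  tgt <- abundance_matrix(v, scale = "log2")
  asg <- assign_modules(tgt, net)
  expect_identical(asg$module, "M2")
  expect_equal(asg$kme, 1, tolerance = 1e-10)
  # pure noise stays grey with a reason
  noise <- matrix(rnorm(20 * length(net$reference_samples)), 20,
                  dimnames = list(sprintf("N%02d", 1:20),
                                  net$reference_samples))
  asg2 <- assign_modules(abundance_matrix(noise, scale = "log2"), net)
  expect_gt(mean(asg2$module == "grey"), 0.8)
  expect_true(all(grepl("below cutoff", asg2$reason[asg2$module == "grey"])))
  # cutoff boundary: kme_min above the achieved kME forces grey
  asg3 <- assign_modules(tgt, net, kme_min = 1.0000001)
  expect_identical(asg3$module, "grey")
})

test_that("simulated module members reassign to their true modules", {
  d <- synthetic_design(n_proteins = 400, n_modules = 6, module_size = 20,
                        module_purity = 0.9, n_reference_samples = 60,
                        seed = 35)
  ref <- simulate_reference_brain(d)
  asg <- assign_modules(ref$matrix, ref$network, kme_min = 0.30)
  truth <- ref$truth[asg$protein_id]
  members <- truth != "grey"
  expect_gt(mean(asg$module[members] == truth[members]), 0.9)
  expect_gt(mean(asg$module[!members] == "grey"), 0.95)
})

test_that("module-trait association matches its construction", {
  d <- synthetic_design(n_proteins = 100, n_modules = 2, module_size = 10,
                        seed = 36)
  ref <- simulate_reference_brain(d)
  net <- ref$network
  meta <- data.frame(sample_id = net$reference_samples,
                     up = as.numeric(net$eigenproteins["M1", ]),
                     down = -as.numeric(net$eigenproteins["M1", ]),
                     flat = 1,
                     stringsAsFactors = FALSE)
  out <- module_trait_correlation(net, meta, traits = c("up", "down", "flat"))
  m1 <- out[out$module == "M1", ]
  expect_equal(m1$bicor[m1$trait == "up"], 1, tolerance = 1e-10)
  expect_equal(m1$bicor[m1$trait == "down"], -1, tolerance = 1e-10)
  expect_true(is.na(m1$bicor[m1$trait == "flat"]))
})

test_that("FET enrichment matches the hand hypergeometric example", {
  bg <- sprintf("G%02d", 1:20)
  cats <- list(C1 = bg[1:5])
  q <- c(bg[1:4], bg[20])
  out <- fet_enrichment(q, cats, bg, min_genes = 3)
  expect_equal(out$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(out$k, 4L, ignore_attr = TRUE)
  expect_equal(out$fold, 4 * 20 / (5 * 5))
  # disjoint query: upper-tail p of k = 0 is 1
  out0 <- fet_enrichment(bg[6:10], list(C1 = bg[1:5]), bg, min_genes = 3)
  expect_equal(out0$p, 1)
  # categories under min_genes are skipped; empty background errors
  out_min <- fet_enrichment(q, list(small = bg[1:2], C1 = bg[1:5]), bg)
  expect_identical(out_min$category, "C1")
  expect_error(fet_enrichment(q, cats, character(0)), "empty background")
})

test_that("Z-scores and FET p-values are order-consistent", {
  set.seed(37)
  bg <- sprintf("G%03d", 1:200)
  cats <- lapply(1:8, function(i) sample(bg, 25))
  names(cats) <- paste0("C", 1:8)
  q <- sample(bg, 40)
  out <- fet_enrichment(q, cats, bg)
  expect_identical(order(out$p), order(-out$z))
  expect_true(all(out$k <= pmin(out$n, out$K)))
  expect_equal(out$q, bh_adjust(out$p))
})

test_that("overlap coverage counts per-module hits", {
  d <- synthetic_design(n_proteins = 60, n_modules = 2, module_size = 10,
                        seed = 38)
  ref <- simulate_reference_brain(d)
  net <- ref$network
  m1 <- net$modules$M1
  plasma <- c(m1[1:4], "ZZZ1", "ZZZ2")
  out <- overlap_summary(plasma, rownames(ref$matrix$values), net)
  cov <- out$coverage
  expect_equal(cov$coverage[cov$module == "M1"], 0.4)
  expect_equal(cov$coverage[cov$module == "M2"], 0)
  expect_identical(out$n_overlap, 4L)
  all_in <- overlap_summary(rownames(ref$matrix$values),
                            rownames(ref$matrix$values), net)
  expect_true(all(all_in$coverage$coverage == 1))
})
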