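test_that("median-of-ratios size factors follow the geometric-mean construction", {
  m <- matrix(c(10L, 10L, 40L, 10L, 10L, 40L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10L, 20L, 40L), b = c(20L, 40L, 80L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # the geometric-mean reference makes the estimator scale-invariant:
  # a common rescaling of all samples leaves every factor unchanged
  b <- simulate_counts(small_config(seed = 6))
  sf1 <- estimate_size_factors(b$counts)
  sf3 <- estimate_size_factors(b$counts * 3L)
  expect_equal(unname(sf3), unname(sf1), tolerance = 1e-12)

  z <- matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(estimate_size_factors(z), "normalization error")
})

test_that("size factors agree with DESeq2's implementation", {
  skip_if_not_installed("DESeq2")
  b <- simulate_counts(small_config(seed = 2))
  expect_equal(unname(estimate_size_factors(b$counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(b$counts)),
               tolerance = 1e-12)
})

test_that("dispersion estimation clamps, recovers truth, and shrinks to the trend", {
  # zero-variance positive-mean gene clamps the moment estimate at >= floor
  m <- matrix(c(rep(20L, 4), c(5L, 40L, 10L, 25L)), 2, 4, byrow = TRUE,
              dimnames = list(c("flat", "noisy"), paste0("s", 1:4)))
  sf <- setNames(rep(1, 4), colnames(m))
  d <- estimate_dispersion(m, sf, c("a", "a", "b", "b"), shrink_weight = 0)
  expect_lte(d[["flat"]], 1e-8)

  expect_error(estimate_dispersion(m, sf, c("a", "b", "b", "b")), "2 replicates")

  # Poisson counts at high mean: near-zero dispersion
  bp <- simulate_counts(sim_config(seed = 4, dispersion = 0, de_fraction = 0,
                                   baseline_log2_mean_range = c(5, 9)))
  s <- subset_cell_type(bp, "CD4")
  dp <- estimate_dispersion(s$counts, estimate_size_factors(s$counts),
                            s$samples$strain)
  expect_lt(median(dp), 0.02)

  # recovery at alpha = 0.2 with 10 replicates
  br <- simulate_counts(sim_config(seed = 3, n_replicates = 10,
                                   dispersion = 0.2, de_fraction = 0))
  sr <- subset_cell_type(br, "CD4")
  dr <- estimate_dispersion(sr$counts, estimate_size_factors(sr$counts),
                            sr$samples$strain)
  expect_gt(median(dr), 0.1)
  expect_lt(median(dr), 0.4)
})

test_that("Wald test is null-centred, antisymmetric and size-factor invariant", {
  b <- simulate_counts(small_config(seed = 3))
  s <- subset_cell_type(b, "CD4")
  contrast <- c("strain", "resistant", "susceptible")

  # identical group means: duplicate one group's columns as the other group
  cnt <- s$counts
  cnt[, s$samples$strain == "susceptible"] <- cnt[, s$samples$strain == "resistant"]
  de0 <- wald_test(cnt, s$samples, contrast)
  expect_true(all(abs(de0$log2fc) < 1e-12))
  expect_true(all(de0$wald_p[!is.na(de0$wald_p)] == 1))

  d1 <- wald_test(s$counts, s$samples, contrast)
  d2 <- wald_test(s$counts, s$samples, c("strain", "susceptible", "resistant"))
  m <- match(d1$gene_id, d2$gene_id)
  expect_equal(d1$log2fc, -d2$log2fc[m], tolerance = 1e-12)
  expect_equal(d1$wald_p, d2$wald_p[m], tolerance = 1e-12)

  cnt2 <- s$counts
  cnt2[, 2] <- cnt2[, 2] * 2L
  d3 <- wald_test(cnt2, s$samples, contrast)
  expect_lt(max(abs(d1$log2fc - d3$log2fc[match(d1$gene_id, d3$gene_id)])), 1e-6)

  expect_error(wald_test(s$counts, s$samples, c("strain", "resistant", "missing")),
               "contrast error")
})

test_that("planted log2FC = 2.5 genes are detected with the correct sign", {
  b <- simulate_counts(sim_config(seed = 1))
  s <- subset_cell_type(b, "CD4")
  de <- wald_test(s$counts, s$samples, c("strain", "resistant", "susceptible"))
  sc <- recovery_scorecard(b$truth, de)
  expect_gte(sc$de_detection_sign_correct_rate, 0.8)
})

test_that("type-I error is controlled on the null simulation", {
  b <- simulate_counts(sim_config(seed = 1, de_fraction = 0))
  s <- subset_cell_type(b, "CD4")
  de <- wald_test(s$counts, s$samples, c("strain", "resistant", "susceptible"))
  expect_lte(mean(de$padj < 0.05, na.rm = TRUE), 0.01)
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "domain error")

  # the all-tied hand-computed output is a fixed point of re-application
  expect_equal(adjust_bh(adjust_bh(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))

  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))            # monotone in rank
  }
})

test_that("volcano classes apply strict thresholds at both fold-change tiers", {
  res <- data.frame(log2fc = c(1.5, 1.5, -3, 2.5, -2.5),
                    padj = c(0.01, 0.01, 0.2, 0.001, 0.001))
  expect_identical(as.vector(classify_volcano(res, lfc = 1)),
                   c("up", "up", "ns", "up", "down"))
  expect_identical(as.vector(classify_volcano(res, lfc = 2)),
                   c("ns", "ns", "ns", "up", "down"))
  # boundary: log2fc exactly at the threshold is not called
  res2 <- data.frame(log2fc = c(1, -1), padj = c(0.01, 0.01))
  expect_identical(as.vector(classify_volcano(res2, lfc = 1)), c("ns", "ns"))
  # NA padj is never significant
  res3 <- data.frame(log2fc = 5, padj = NA_real_)
  expect_identical(as.vector(classify_volcano(res3)), "ns")
})
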