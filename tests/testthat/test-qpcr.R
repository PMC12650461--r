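make_ct <- function(gene_ct_by_group, ref_ct = 18, n_rep = 3) {
  rows <- list()
  for (g in names(gene_ct_by_group)) {
    for (grp in names(gene_ct_by_group[[g]])) {
      rows[[paste(g, grp)]] <- data.frame(
        gene_id = g, group = grp, replicate = seq_len(n_rep), well = 1L,
        ct = gene_ct_by_group[[g]][[grp]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(gene_id = "ref", group = rep(names(gene_ct_by_group[[1]]), each = n_rep),
               replicate = seq_len(n_rep), well = 1L, ct = ref_ct))))
  attr(out, "reference_gene") <- "ref"
  out
}

test_that("ddCt closed forms: null gene gives fold 1, one-cycle drop gives fold 2", {
  ct <- make_ct(list(gx = list(target = rep(25, 3), reference = rep(25, 3))))
  fc <- ddct_fold_change(ct, "gx", "target", "reference")
  expect_equal(fc$per_replicate$ddct, rep(0, 3))
  expect_equal(fc$mean_fold, 1)

  ct2 <- make_ct(list(gx = list(target = rep(24, 3), reference = rep(25, 3))))
  fc2 <- ddct_fold_change(ct2, "gx", "target", "reference")
  expect_equal(fc2$mean_fold, 2)
  expect_equal(fc2$geo_mean_fold, 2)
})

test_that("technical duplicates are averaged and wide spreads flagged", {
  ct <- make_ct(list(gx = list(target = rep(24, 3), reference = rep(25, 3))))
  dup <- ct[ct$gene_id == "gx" & ct$group == "target", ]
  dup$well <- 2L
  dup$ct <- dup$ct + c(0.2, 0.8, 0.1)  # replicate 2 spread > 0.5
  ct_dup <- rbind(ct, dup)
  attr(ct_dup, "reference_gene") <- "ref"
  fc <- ddct_fold_change(ct_dup, "gx", "target", "reference")
  expect_equal(fc$dct_target[["1"]], (24 + 24.2) / 2 - 18)
  expect_identical(nrow(fc$flagged_wells), 1L)
  expect_identical(fc$flagged_wells$replicate, 2L)
})

test_that("a plate shift common to one replicate cancels out of every quantity", {
  set.seed(2)
  ct <- make_ct(list(gx = list(target = 24 + rnorm(3, 0, 0.2),
                               reference = 25 + rnorm(3, 0, 0.2))))
  f1 <- ddct_fold_change(ct, "gx", "target", "reference")
  shifted <- ct
  sel <- shifted$replicate == 2 & shifted$group == "target"
  shifted$ct[sel] <- shifted$ct[sel] + 3.7
  f2 <- ddct_fold_change(shifted, "gx", "target", "reference")
  expect_equal(f1$per_replicate, f2$per_replicate, tolerance = 1e-12)
  expect_equal(f1$mean_fold, f2$mean_fold, tolerance = 1e-12)
})

test_that("swapping target and reference groups inverts the fold change exactly", {
  set.seed(3)
  ct <- make_ct(list(gx = list(a = 23 + rnorm(3, 0, 0.3),
                               b = 25 + rnorm(3, 0, 0.3))))
  fab <- ddct_fold_change(ct, "gx", "a", "b")
  fba <- ddct_fold_change(ct, "gx", "b", "a")
  expect_equal(fab$geo_mean_fold, 1 / fba$geo_mean_fold, tolerance = 1e-12)
})

test_that("group comparison is symmetric and handles degenerate input", {
  expect_identical(compare_groups(c(1, 1, 1), c(1, 1, 1)),
                   list(t = 0, p = 1, df = 4, mean_diff = 0))
  set.seed(4)
  a <- rnorm(3); b <- rnorm(3) + 1
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2)), "2 replicates")
})

test_that("planted qPCR differences reach significance at the stated power", {
  cfg <- small_config(seed = 9)
  b <- simulate_counts(cfg)
  de <- b$truth$de_genes$CD4
  gene1 <- de$gene_id[abs(de$true_log2fc) > 0][1]
  hits <- 0L
  n_tab <- 40L
  for (i in seq_len(n_tab)) {
    # planted |log2FC| = 2.5 at noise sd 0.2 cycles, n = 3
    ct <- simulate_ct_table(b$truth, gene1, seed = cfg$seed + 100L + i)
    fc <- ddct_fold_change(ct, gene1, "resistant", "susceptible")
    p <- compare_groups(fc$dct_target, fc$dct_reference)$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_tab, 0.8)
})

test_that("qPCR and RNA-seq calls agree in sign on the synthetic end-to-end run", {
  b <- simulate_dataset(small_config(seed = 1))
  s <- subset_cell_type(b, "CD4")
  de <- wald_test(s$counts, s$samples, c("strain", "resistant", "susceptible"))
  conc <- concordance_with_rnaseq(b$ct_table, de,
                                  target_group = "resistant",
                                  reference_group = "susceptible")
  expect_true(all(conc$agreement == "agree"))
  expect_equal(attr(conc, "agreement_fraction"), 1)
})

test_that("fold exactly 1 is reported neutral and empty panels flagged", {
  ct <- make_ct(list(gx = list(resistant = rep(25, 3), susceptible = rep(25, 3))))
  de <- data.frame(gene_id = "gx", log2fc = 2, se_log2fc = 1, wald_p = 0.01,
                   padj = 0.02)
  conc <- concordance_with_rnaseq(ct, de, genes = "gx",
                                  target_group = "resistant",
                                  reference_group = "susceptible")
  expect_identical(conc$agreement, "neutral")
  conc0 <- concordance_with_rnaseq(ct, de, genes = character(0),
                                   target_group = "resistant",
                                   reference_group = "susceptible")
  expect_identical(nrow(conc0), 0L)
  expect_true(is.na(attr(conc0, "agreement_fraction")))
})
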