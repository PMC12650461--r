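edge_df <- function(tf, target, mode = "unknown", source = "s1") {
  data.frame(tf = tf, target = target, mode = mode, source = source,
             stringsAsFactors = FALSE)
}

test_that("merging unions source tags, resolves conflicts, counts disjoint edges", {
  l1 <- edge_df("A", "g1", "activation", "s1")
  l2 <- edge_df("A", "g1", "activation", "s2")
  net <- merge_priors(list(l1, l2))
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$sources, "s1;s2")
  expect_identical(net$edges$mode, "activation")

  l3 <- edge_df("A", "g1", "repression", "s3")
  expect_message(net2 <- merge_priors(list(l1, l3)), "conflicting modes")
  expect_identical(net2$edges$mode, "unknown")
  expect_identical(attr(net2, "n_mode_conflicts"), 1L)

  mk <- function(src, off) edge_df(paste0("T", off + 1:10), paste0("t", off + 1:10),
                                   source = src)
  net3 <- merge_priors(list(mk("s1", 0), mk("s2", 100), mk("s3", 200)))
  expect_identical(nrow(net3$edges), 30L)

  expect_error(merge_priors(list(data.frame(x = 1))), "parse error")
  expect_error(merge_priors(list(edge_df(c("A", ""), c("g1", "g2")))),
               "malformed row")
})

test_that("merge is idempotent", {
  b <- simulate_counts(small_config(seed = 4))
  pr <- simulate_prior_network(small_config(seed = 4), b$truth)
  net <- merge_priors(split(pr$edges, pr$edges$source))
  net2 <- merge_priors(prior_edges_long(net))
  expect_identical(net$edges, net2$edges)
})

test_that("expression filter removes sub-threshold nodes and orphaned TFs", {
  # 5 TFs x 8 targets each (disjoint); TF5's targets all sub-threshold
  tfs <- paste0("TF", 1:5)
  edges <- do.call(rbind, lapply(1:5, function(i)
    edge_df(tfs[i], sprintf("t%02d", (i - 1) * 8 + 1:8))))
  net <- merge_priors(edges)
  all_nodes <- unique(c(net$edges$tf, net$edges$target))
  low <- c(sprintf("t%02d", 33:39))  # 7 of TF5's 8 targets below threshold
  counts <- matrix(50L, length(all_nodes), 3,
                   dimnames = list(all_nodes, paste0("s", 1:3)))
  counts[low, ] <- 2L
  counts["t40", ] <- 2L  # 8th also below: TF5 orphaned
  f <- filter_expressed(net, counts, min_count = 10)
  nodes_after <- unique(c(f$edges$tf, f$edges$target))
  expect_identical(length(all_nodes) - length(nodes_after), 9L)  # 8 targets + TF5
  expect_false("TF5" %in% nodes_after)

  f0 <- filter_expressed(net, counts, min_count = 0)
  expect_identical(nrow(f0$edges), nrow(net$edges))

  # monotone: raising the threshold never adds nodes or edges
  prev <- Inf
  for (mc in c(0, 10, 60, 200)) {
    fe <- filter_expressed(net, counts, min_count = mc)
    expect_lte(nrow(fe$edges), prev)
    prev <- nrow(fe$edges)
  }
})

test_that("DEG subnetwork keeps DEGs and their upstream regulators only", {
  de <- data.frame(gene_id = c(paste0("d", 1:5), "TFa", "x1"),
                   log2fc = c(3, -2.5, 2, 4, -3, 2.6, 0.1),
                   padj = c(rep(0.001, 6), 0.9))
  net <- merge_priors(rbind(
    edge_df("TFa", c("d1", "d2", "d3")),
    edge_df("TFb", c("d4", "x1")),
    edge_df("TFc", "x1")))
  snw <- deg_subnetwork(net, de, lfc = 2, alpha = 0.05)
  expect_setequal(snw$edges$target[snw$edges$regulator == "TFa"],
                  c("d1", "d2", "d3"))
  expect_false("TFc" %in% snw$nodes$id)     # targets no DEG
  expect_false("x1" %in% snw$nodes$id)      # not a DEG
  # a DEG that is itself a regulator appears once, as tf-kind with direction
  tfa <- snw$nodes[snw$nodes$id == "TFa", ]
  expect_identical(nrow(tfa), 1L)
  expect_identical(tfa$kind, "tf")
  expect_identical(tfa$de_direction, "up")
  # the lfc threshold is non-strict here (|lfc| >= 2 kept)
  expect_true("d3" %in% snw$nodes$id)

  empty <- deg_subnetwork(net, de, lfc = 10)
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("master regulators rank by distinct DEG connectivity with stable ties", {
  de <- data.frame(gene_id = paste0("d", 1:6),
                   log2fc = c(3, -2.5, 2.5, 4, -3, 2.2),
                   padj = rep(0.001, 6))
  net <- merge_priors(rbind(
    edge_df("Tbig", paste0("d", 1:4)),
    edge_df("Tz", paste0("d", 1:2)),
    edge_df("Ta", paste0("d", 3:4)),
    edge_df("Tdown", paste0("d", c(2, 5)))))
  snw <- deg_subnetwork(net, de)
  rep_all <- rank_master_regulators(snw, top_n = 10)
  expect_identical(rep_all$tf_id[1], "Tbig")
  expect_identical(rep_all$tf_id[2:4], c("Ta", "Tdown", "Tz"))  # tie broken by id
  expect_identical(nrow(rep_all), 4L)                  # no padding past supply
  expect_identical(rep_all$direction_class[rep_all$tf_id == "Tdown"], "down-linked")
  expect_identical(rep_all$direction_class[rep_all$tf_id == "Tbig"], "mixed")
  expect_true(all(rep_all$deg_targets_up + rep_all$deg_targets_down ==
                    rep_all$deg_target_count))
  rep1 <- rank_master_regulators(snw, top_n = 1)
  expect_identical(rep1$tf_id, "Tbig")
})

test_that("the planted master TF is recovered from the synthetic prior", {
  for (s in c(1, 2, 3)) {
    b <- simulate_dataset(small_config(seed = s))
    sct <- subset_cell_type(b, "CD4")
    de <- wald_test(sct$counts, sct$samples, c("strain", "resistant", "susceptible"))
    net <- merge_priors(split(b$prior$edges, b$prior$edges$source))
    netf <- filter_expressed(net, sct$counts)
    snw <- deg_subnetwork(netf, de)
    rep30 <- rank_master_regulators(snw)
    expect_identical(rep30$tf_id[1], b$truth$master_tfs$tf_id[1])
  }
})

test_that("refinement truncates to top targets and annotates edge classes", {
  de <- data.frame(gene_id = paste0("d", 1:15),
                   log2fc = seq(2.1, 4.9, by = 0.2) * rep(c(1, -1), length.out = 15),
                   padj = rep(0.001, 15))
  net <- merge_priors(rbind(edge_df("Tbig", paste0("d", 1:15)),
                            edge_df("Tsmall", paste0("d", 1:3))))
  snw <- deg_subnetwork(net, de)
  rep2 <- rank_master_regulators(snw)
  ref <- refine_subnetwork(snw, rep2, top_k_targets = 10)
  kept <- ref$edges$target[ref$edges$regulator == "Tbig"]
  expect_identical(length(kept), 10L)
  lfc <- setNames(de$log2fc, de$gene_id)
  expect_setequal(kept, names(sort(abs(lfc), decreasing = TRUE))[1:10])
  expect_identical(length(ref$edges$target[ref$edges$regulator == "Tsmall"]), 3L)
  # refined subgraph is a subgraph of the unrefined one
  key <- function(e) paste(e$regulator, e$target)
  expect_true(all(key(ref$edges) %in% key(snw$edges)))
  # classes match the targets' DE directions (no DE'd regulators here)
  dirs <- ifelse(lfc[ref$edges$target] > 0, "up", "down")
  expect_identical(ref$edges$regulation_class, unname(dirs))

  # mixed class when a DE regulator and its target disagree in direction
  de2 <- data.frame(gene_id = c("TFu", "ddown"), log2fc = c(3, -3),
                    padj = c(0.001, 0.001))
  net2 <- merge_priors(edge_df("TFu", "ddown"))
  snw2 <- deg_subnetwork(net2, de2)
  ref2 <- refine_subnetwork(snw2, rank_master_regulators(snw2))
  expect_identical(ref2$edges$regulation_class, "mixed")
})

test_that("regulator-set comparison performs the expected set algebra", {
  mk <- function(ids) data.frame(tf_id = ids,
                                 direction_class = rep("up-linked", length(ids)),
                                 stringsAsFactors = FALSE)
  same <- compare_regulator_sets(mk(letters[1:5]), mk(letters[1:5]))
  expect_identical(unname(same$sizes), c(5L, 0L, 0L))
  expect_equal(same$concordance_fraction, 1)
  disj <- compare_regulator_sets(mk(letters[1:4]), mk(letters[5:8]))
  expect_identical(unname(disj$sizes), c(0L, 4L, 4L))
  mixed <- compare_regulator_sets(mk(letters[1:8]), mk(letters[4:11]))
  expect_identical(unname(mixed$sizes), c(5L, 3L, 3L))
})

test_that("subnetworks export to igraph/GraphML with attributes intact", {
  de <- data.frame(gene_id = paste0("d", 1:3), log2fc = c(3, -2.5, 2.1),
                   padj = rep(0.001, 3))
  net <- merge_priors(edge_df("TFa", paste0("d", 1:3)))
  snw <- refine_subnetwork(deg_subnetwork(net, de),
                           rank_master_regulators(deg_subnetwork(net, de)))
  g <- subnetwork_to_igraph(snw)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  tmp <- tempfile(fileext = ".graphml")
  tmp2 <- tempfile(fileext = ".tsv")
  write_subnetwork(snw, tmp, tmp2)
  expect_true(file.exists(tmp) && file.exists(tmp2))
  reread <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::vcount(reread), 4)
})
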