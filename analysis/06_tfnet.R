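#!/usr/bin/env Rscript
# Stage 6: TF network analysis. Merge the three source-tagged prior edge
# lists, drop genes with raw counts < 10 in the contrasted samples, map
# DEGs (padj < 0.05, |log2FC| >= 2) onto the prior, rank the 30 most
# connected TFs as master regulators, refine each subnetwork to the top 10
# targets per TF, and compare the CD4 and CD8 regulator sets.
source("analysis/00_common.R")

edges <- read_prior_edges_tsv(require_stage(
  file.path(DATA_DIR, "prior_edges.tsv"), "01_simulate.R"))
counts <- read_counts_tsv(file.path(DATA_DIR, "counts.tsv"))
samples <- read_samples_tsv(file.path(DATA_DIR, "samples.tsv"))

net <- merge_priors(split(edges, edges$source))
cat(sprintf("prior: %d merged edges from %d assertions across %d sources\n",
            nrow(net$edges), nrow(edges), length(attr(net, "sources"))))

reports <- list()
for (ct in CELL_TYPES) {
  sub <- samples[samples$cell_type == ct, ]
  netf <- filter_expressed(net, counts[, sub$sample_id],
                           min_count = THRESHOLDS$expressed_min_count)
  de <- read_de(ct)
  snw <- deg_subnetwork(netf, de, lfc = THRESHOLDS$curated_lfc,
                        alpha = THRESHOLDS$de_alpha)
  rep30 <- rank_master_regulators(snw, top_n = THRESHOLDS$top_n_tfs)
  reports[[ct]] <- rep30
  utils::write.table(rep30,
                     file.path(OUTDIR, sprintf("master_regulators_%s.tsv", ct)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  refined <- refine_subnetwork(snw, rep30,
                               top_k_targets = THRESHOLDS$top_k_targets)
  write_subnetwork(refined,
                   file.path(OUTDIR, sprintf("subnetwork_%s.graphml", ct)),
                   file.path(OUTDIR, sprintf("subnetwork_%s.tsv", ct)))
  if (nrow(refined$edges) > 0) {
    plot_network_png(refined, file.path(FIG_DIR, sprintf("network_circle_%s.png", ct)),
                     layout = "circle")
    plot_network_png(refined, file.path(FIG_DIR, sprintf("network_tree_%s.png", ct)),
                     layout = "tree")
  }
  cat(sprintf("%s: %d TFs ranked; top regulator %s with %d DEG targets (%s)\n",
              ct, nrow(rep30), rep30$tf_id[1], rep30$deg_target_count[1],
              rep30$direction_class[1]))
}

cmp <- compare_regulator_sets(reports$CD4, reports$CD8)
cat(sprintf("regulators: %d common to CD4 and CD8, %d CD4-only, %d CD8-only\n",
            cmp$sizes["common"], cmp$sizes["unique_a"], cmp$sizes["unique_b"]))
jsonlite::write_json(
  list(sizes = as.list(cmp$sizes), common = cmp$common,
       concordance_fraction = cmp$concordance_fraction),
  file.path(OUTDIR, "regulator_comparison.json"), auto_unbox = TRUE)

write_manifest(OUTDIR, "tfnet", SEED, config = THRESHOLDS,
               files = list.files(OUTDIR, "master_regulators_|subnetwork_.*tsv",
                                  full.names = TRUE))
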