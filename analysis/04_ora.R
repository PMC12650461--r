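#!/usr/bin/env Rscript
# Stage 4: hypergeometric over-representation of the up- and down-regulated
# gene lists against the gene-set collection, per subset, with the
# expressed genes of the contrasted groups as the background universe.
source("analysis/00_common.R")

counts <- read_counts_tsv(require_stage(file.path(DATA_DIR, "counts.tsv"),
                                        "01_simulate.R"))
samples <- read_samples_tsv(file.path(DATA_DIR, "samples.tsv"))
sets <- read_gmt(file.path(DATA_DIR, "sets.gmt"))
eg <- expressed_gene_sets(counts, samples,
                          min_count = THRESHOLDS$expressed_min_count)

for (ct in CELL_TYPES) {
  de <- read_de(ct)
  universe <- union(eg[[paste0("resistant.", ct)]],
                    eg[[paste0("susceptible.", ct)]])
  for (dir in c("up", "down")) {
    query <- de$gene_id[de$class == dir]
    if (length(query) == 0) { cat(ct, dir, ": empty query, skipped\n"); next }
    res <- ora_test(query, sets, universe)
    out <- file.path(OUTDIR, sprintf("ora_results_%s_%s.tsv", ct, dir))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    n_sig <- sum(res$padj < THRESHOLDS$ora_alpha)
    cat(sprintf("%s %s-regulated: %d/%d sets enriched at padj<%.2f (top: %s)\n",
                ct, dir, n_sig, nrow(res), THRESHOLDS$ora_alpha, res$set_id[1]))
    ggplot2::ggsave(file.path(FIG_DIR, sprintf("ora_%s_%s.png", ct, dir)),
                    plot_ora_dotplot(res), width = 6, height = 4.5, dpi = 150)
  }
}

write_manifest(OUTDIR, "ora", SEED, config = THRESHOLDS,
               files = list.files(OUTDIR, "^ora_results_", full.names = TRUE))
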