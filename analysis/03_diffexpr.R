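#!/usr/bin/env Rscript
# Stage 3: NB Wald differential expression (resistant vs susceptible) within
# each T-cell subset, BH adjustment, volcano classes at the two fold-change
# tiers, and up/down gene lists for the enrichment stages.
source("analysis/00_common.R")

counts <- read_counts_tsv(require_stage(file.path(DATA_DIR, "counts.tsv"),
                                        "01_simulate.R"))
samples <- read_samples_tsv(file.path(DATA_DIR, "samples.tsv"))

for (ct in CELL_TYPES) {
  sub <- samples[samples$cell_type == ct, ]
  de <- wald_test(counts[, sub$sample_id], sub, CONTRAST,
                  alpha = THRESHOLDS$de_alpha,
                  lfc_threshold = THRESHOLDS$volcano_lfc)
  utils::write.table(de, file.path(OUTDIR, sprintf("de_results_%s.tsv", ct)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts_tab <- attr(classify_volcano(de, THRESHOLDS$de_alpha,
                                      THRESHOLDS$volcano_lfc), "counts")
  strict <- attr(classify_volcano(de, THRESHOLDS$de_alpha,
                                  THRESHOLDS$curated_lfc), "counts")
  cat(sprintf("%s: %d up / %d down at padj<%.2f & |lfc|>%d (%d/%d at |lfc|>%d)\n",
              ct, counts_tab["up"], counts_tab["down"], THRESHOLDS$de_alpha,
              THRESHOLDS$volcano_lfc, strict["up"], strict["down"],
              THRESHOLDS$curated_lfc))
  writeLines(de$gene_id[de$class == "up"],
             file.path(OUTDIR, sprintf("up_genes_%s.txt", ct)))
  writeLines(de$gene_id[de$class == "down"],
             file.path(OUTDIR, sprintf("down_genes_%s.txt", ct)))
  ggplot2::ggsave(file.path(FIG_DIR, sprintf("volcano_%s.png", ct)),
                  plot_volcano(de), width = 6, height = 4.5, dpi = 150)
}

write_manifest(OUTDIR, "diffexpr", SEED, config = THRESHOLDS,
               files = file.path(OUTDIR, sprintf("de_results_%s.tsv", CELL_TYPES)))
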