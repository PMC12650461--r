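#!/usr/bin/env Rscript
# Stage 2: FPKM normalisation, expressed-gene filter (group sum >= 10),
# Venn partitions of expressed genes between strains within each subset,
# and PCA ordination of log2(FPKM + 1).
source("analysis/00_common.R")

counts <- read_counts_tsv(require_stage(file.path(DATA_DIR, "counts.tsv"),
                                        "01_simulate.R"))
lengths <- read_gene_lengths_tsv(file.path(DATA_DIR, "gene_lengths.tsv"))
samples <- read_samples_tsv(file.path(DATA_DIR, "samples.tsv"))

fpkm <- compute_fpkm(counts, lengths)
utils::write.table(data.frame(gene_id = rownames(fpkm), round(fpkm, 4),
                              check.names = FALSE),
                   file.path(OUTDIR, "fpkm.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)

eg <- expressed_gene_sets(counts, samples,
                          min_count = THRESHOLDS$expressed_min_count)
venn <- list()
for (ct in CELL_TYPES) {
  v <- venn_partition(eg[[paste0("resistant.", ct)]],
                      eg[[paste0("susceptible.", ct)]])
  venn[[ct]] <- as.list(v$sizes)
  cat(sprintf("%s: %d resistant-only, %d shared, %d susceptible-only expressed genes\n",
              ct, v$sizes[1], v$sizes[2], v$sizes[3]))
}
jsonlite::write_json(venn, file.path(OUTDIR, "venn.json"), auto_unbox = TRUE)

pca <- pca_ordination(fpkm, samples)
utils::write.table(pca$coordinates, file.path(OUTDIR, "pca_coordinates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
ggplot2::ggsave(file.path(FIG_DIR, "pca.png"), plot_pca(pca),
                width = 6, height = 4.5, dpi = 150)
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2]))

write_manifest(OUTDIR, "quantify", SEED, config = THRESHOLDS,
               files = file.path(OUTDIR, c("fpkm.tsv", "venn.json",
                                           "pca_coordinates.tsv")))
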