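#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- 2 strains x 2 T-cell subsets x 3
# replicates of NB counts with planted DE genes (|log2FC| = 2.5, 5% of
# genes, half shared between subsets), shifted gene sets, a three-source
# TF-target prior with one planted master regulator, and a qPCR Ct table.
source("analysis/00_common.R")

cfg <- sim_config(seed = SEED)
b <- simulate_dataset(cfg)

write_counts_tsv(b$counts, file.path(DATA_DIR, "counts.tsv"))
write_gene_lengths_tsv(b$gene_lengths, file.path(DATA_DIR, "gene_lengths.tsv"))
write_samples_tsv(b$samples, file.path(DATA_DIR, "samples.tsv"))
write_gmt(b$gene_sets$sets, file.path(DATA_DIR, "sets.gmt"),
          b$gene_sets$descriptions)
write_prior_edges_tsv(b$prior$edges, file.path(DATA_DIR, "prior_edges.tsv"))
write_ct_tsv(b$ct_table, file.path(DATA_DIR, "ct.tsv"))
jsonlite::write_json(
  list(de_genes = b$truth$de_genes, shifted_sets = b$truth$shifted_sets,
       master_tfs = b$truth$master_tfs,
       size_factors_true = as.list(b$truth$size_factors_true)),
  file.path(DATA_DIR, "truth.json"), auto_unbox = TRUE, digits = NA)

files <- list.files(DATA_DIR, full.names = TRUE)
write_manifest(OUTDIR, "simulate", SEED,
               config = unclass(cfg), files = files)

cat(sprintf("simulated %d genes x %d samples; %d planted DE genes per cell type\n",
            nrow(b$counts), ncol(b$counts), nrow(b$truth$de_genes$CD4)))
cat(sprintf("%d gene sets (%d shifted), %d prior edges, master TF %s\n",
            length(b$gene_sets$sets), nrow(b$truth$shifted_sets),
            nrow(b$prior$edges), b$truth$master_tfs$tf_id[1]))
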