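#!/usr/bin/env Rscript
# Stage 5: ranked-list enrichment. Genes ranked by Wald z; running-sum ES
# with gene-set-permutation NES and FDR q; the significance gate is
# NES >= 1.5 and q <= 0.25.
source("analysis/00_common.R")

sets <- read_gmt(require_stage(file.path(DATA_DIR, "sets.gmt"), "01_simulate.R"))

for (ct in CELL_TYPES) {
  de <- read_de(ct)
  ranked <- rank_genes(de, metric = "z")
  write_rnk(ranked, file.path(OUTDIR, sprintf("ranked_%s.rnk", ct)))
  res <- gsea_test(ranked, sets, n_perm = THRESHOLDS$n_perm, seed = SEED,
                   nes_threshold = THRESHOLDS$gsea_nes,
                   q_threshold = THRESHOLDS$gsea_q)
  out <- file.path(OUTDIR, sprintf("gsea_results_%s.tsv", ct))
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- res[res$significant, ]
  cat(sprintf("%s: %d/%d sets pass NES>=%.1f & q<=%.2f\n", ct, nrow(sig),
              nrow(res), THRESHOLDS$gsea_nes, THRESHOLDS$gsea_q))
  if (nrow(sig) > 0)
    for (i in seq_len(min(3, nrow(sig)))) {
      cat(sprintf("  %s: NES = %.2f, q = %.3f\n", sig$set_id[i], sig$nes[i],
                  sig$fdr_q[i]))
      ggplot2::ggsave(
        file.path(FIG_DIR, sprintf("gsea_%s_%s.png", ct, sig$set_id[i])),
        plot_gsea_enrichment(ranked, sets[[sig$set_id[i]]],
                             title = sprintf("%s (%s)", sig$set_id[i], ct)),
        width = 6, height = 5, dpi = 150)
    }
}

write_manifest(OUTDIR, "gsea", SEED, config = THRESHOLDS,
               files = list.files(OUTDIR, "^gsea_results_", full.names = TRUE))
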