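#!/usr/bin/env Rscript
# Stage 7: qPCR validation. 2^-ddCt fold changes against the housekeeping
# reference, Student's t-tests on dCt, and sign concordance with the
# RNA-seq calls for the assayed panel.
source("analysis/00_common.R")

ct_table <- read_ct_tsv(require_stage(file.path(DATA_DIR, "ct.tsv"),
                                      "01_simulate.R"))
de <- read_de("CD4")

conc <- concordance_with_rnaseq(ct_table, de, target_group = "resistant",
                                reference_group = "susceptible")
utils::write.table(conc, file.path(OUTDIR, "qpcr_results.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(conc)))
  cat(sprintf("%s: fold = %.2f +/- %.2f, p = %.3g, RNA-seq lfc = %.2f [%s]\n",
              conc$gene_id[i], conc$mean_fold[i], conc$sem_fold[i], conc$p[i],
              conc$log2fc_rnaseq[i], conc$agreement[i]))
cat(sprintf("sign concordance: %.0f%%\n",
            100 * attr(conc, "agreement_fraction")))

df <- conc
df$sig <- ifelse(df$p < 0.05, "*", "")
gg <- ggplot2::ggplot(df, ggplot2::aes(gene_id, mean_fold)) +
  ggplot2::geom_col(fill = "steelblue") +
  ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_fold - sem_fold,
                                      ymax = mean_fold + sem_fold), width = 0.3) +
  ggplot2::geom_text(ggplot2::aes(label = sig, y = mean_fold + sem_fold),
                     vjust = -0.4, size = 6) +
  ggplot2::labs(x = NULL, y = "fold change (2^-ddCt), mean +/- SEM") +
  ggplot2::theme_bw()
ggplot2::ggsave(file.path(FIG_DIR, "qpcr.png"), gg, width = 5, height = 4,
                dpi = 150)

write_manifest(OUTDIR, "qpcr", SEED, config = THRESHOLDS,
               files = file.path(OUTDIR, "qpcr_results.tsv"))
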