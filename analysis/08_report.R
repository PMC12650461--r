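#!/usr/bin/env Rscript
# Stage 8: collect completed stages into a Markdown summary and score the
# analysis against the planted ground truth.
source("analysis/00_common.R")

b <- load_bundle()
de <- read_de("CD4")
gsea_path <- file.path(OUTDIR, "gsea_results_CD4.tsv")
gr <- if (file.exists(gsea_path))
  utils::read.delim(gsea_path, stringsAsFactors = FALSE) else NULL
if (!is.null(gr)) gr$significant <- as.logical(gr$significant)
mr_path <- file.path(OUTDIR, "master_regulators_CD4.tsv")
mr <- if (file.exists(mr_path))
  utils::read.delim(mr_path, stringsAsFactors = FALSE) else NULL

sc <- recovery_scorecard(b$truth, de, gr, mr, alpha = THRESHOLDS$de_alpha)
render_report(OUTDIR, thresholds = THRESHOLDS, scorecard = sc)
cat("report written to", file.path(OUTDIR, "report.md"), "\n")
for (k in names(sc))
  cat(sprintf("  %-34s %s\n", k, paste(format(sc[[k]], digits = 4), collapse = " ")))
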