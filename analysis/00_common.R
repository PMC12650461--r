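# Shared plumbing for the analysis drivers: argument parsing and paths.
# Every driver is run from the repository root, e.g.
#   Rscript analysis/01_simulate.R --seed 1 --outdir results
suppressMessages(library(mregnet))

.cli <- commandArgs(trailingOnly = TRUE)
cli_arg <- function(flag, default) {
  i <- which(.cli == flag)
  if (length(i) == 1 && i < length(.cli)) .cli[i + 1] else default
}
SEED <- as.integer(cli_arg("--seed", "1"))
OUTDIR <- cli_arg("--outdir", "results")
DATA_DIR <- file.path(OUTDIR, "data")
FIG_DIR <- file.path(OUTDIR, "figures")
for (d in c(OUTDIR, DATA_DIR, FIG_DIR))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)

CONTRAST <- c("strain", "resistant", "susceptible")
CELL_TYPES <- c("CD4", "CD8")

# thresholds used throughout; defaults are the study's stated values
THRESHOLDS <- list(expressed_min_count = 10, de_alpha = 0.05, volcano_lfc = 1,
                   curated_lfc = 2, ora_alpha = 0.05, gsea_nes = 1.5,
                   gsea_q = 0.25, n_perm = 1000, top_n_tfs = 30,
                   top_k_targets = 10)

require_stage <- function(path, stage) {
  if (!file.exists(path))
    stop("dependency error: missing ", path, "; run analysis/", stage,
         " first", call. = FALSE)
  path
}

read_de <- function(ct) {
  p <- require_stage(file.path(OUTDIR, sprintf("de_results_%s.tsv", ct)),
                     "03_diffexpr.R")
  utils::read.delim(p, stringsAsFactors = FALSE)
}

load_bundle <- function() {
  # regenerate the seeded bundle; cheap, and guarantees the drivers and the
  # written data files agree
  simulate_dataset(sim_config(seed = SEED))
}
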