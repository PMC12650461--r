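#' Recovery scorecard against the planted truth
#'
#' Compares what the analysis detected with what the generator planted:
#' differential expression (detection rate and sign accuracy of planted
#' genes, empirical false discovery), shifted gene sets passing the
#' enrichment gate, and the rank of the planted master regulator.
#' Components not supplied are skipped.
#'
#' @param truth the `truth` element of a simulation bundle.
#' @param de_results data.frame from [wald_test()] for the first cell
#'   type's contrast.
#' @param gsea_results optional data.frame from [gsea_test()].
#' @param master_report optional report from [rank_master_regulators()].
#' @param alpha adjusted-p threshold used for "detected".
#' @return named list of scalar metrics.
#' @export
recovery_scorecard <- function(truth, de_results, gsea_results = NULL,
                               master_report = NULL, alpha = 0.05) {
  out <- list()
  ct1 <- truth$config$cell_types[1]
  planted <- truth$de_genes[[ct1]]
  m <- match(planted$gene_id, de_results$gene_id)
  det <- !is.na(de_results$padj[m]) & de_results$padj[m] < alpha
  sign_ok <- det & sign(de_results$log2fc[m]) == sign(planted$true_log2fc)
  out$n_planted_de <- nrow(planted)
  out$de_detection_rate <- if (nrow(planted)) mean(det) else NA_real_
  out$de_detection_sign_correct_rate <- if (nrow(planted)) mean(sign_ok) else NA_real_
  called <- de_results$gene_id[!is.na(de_results$padj) & de_results$padj < alpha]
  out$de_empirical_fdr <- if (length(called))
    mean(!(called %in% planted$gene_id)) else 0

  if (!is.null(gsea_results) && !is.null(truth$shifted_sets) &&
      nrow(truth$shifted_sets)) {
    gm <- match(truth$shifted_sets$set_id, gsea_results$set_id)
    hit <- !is.na(gm) & gsea_results$significant[gm] &
      ifelse(truth$shifted_sets$direction == "up",
             gsea_results$nes[gm] > 0, gsea_results$nes[gm] < 0)
    out$shifted_sets_recovered <- sum(hit, na.rm = TRUE)
    out$shifted_sets_total <- nrow(truth$shifted_sets)
  }
  if (!is.null(master_report) && !is.null(truth$master_tfs) &&
      nrow(truth$master_tfs)) {
    out$master_tf_rank <- match(truth$master_tfs$tf_id[1], master_report$tf_id)
    out$master_tf_first <- identical(out$master_tf_rank, 1L)
  }
  out
}

#' Write a Markdown summary of a workflow run
#'
#' Collects whichever result tables are present in the run directory
#' (written by the analysis drivers) into a single Markdown report with
#' the thresholds used, and appends a recovery scorecard when a
#' `truth`-derived scorecard is supplied.
#'
#' @param run_dir directory holding the stage outputs.
#' @param path output Markdown path (default `report.md` in `run_dir`).
#' @param thresholds named list echoed into the report header.
#' @param scorecard optional result of [recovery_scorecard()].
#' @return the output path, invisibly.
#' @export
render_report <- function(run_dir, path = file.path(run_dir, "report.md"),
                          thresholds = list(), scorecard = NULL) {
  if (!dir.exists(run_dir)) stop("nothing to report: missing run directory")
  tsvs <- list.files(run_dir, pattern = "\\.tsv$", recursive = TRUE)
  if (length(tsvs) == 0 && is.null(scorecard))
    stop("nothing to report: no result tables in ", run_dir)
  lines <- c("# Workflow summary", "")
  if (length(thresholds)) {
    lines <- c(lines, "## Thresholds", "",
               paste0("- ", names(thresholds), ": ",
                      vapply(thresholds, function(x) paste(x, collapse = ", "), "")),
               "")
  }
  section <- function(title, pattern, describe) {
    f <- tsvs[grepl(pattern, tsvs)]
    if (length(f) == 0) return(character(0))
    c(paste0("## ", title), "", describe, "",
      paste0("- `", f, "` (", vapply(file.path(run_dir, f), function(p)
        length(readLines(p)) - 1L, 1L), " rows)"), "")
  }
  lines <- c(lines,
    section("Quantification", "fpkm|venn|pca", "FPKM matrix, expressed-gene Venn partitions and PCA coordinates."),
    section("Differential expression", "de_results", "Per-gene NB Wald statistics with BH adjustment and regulation classes."),
    section("Over-representation", "ora_", "Hypergeometric enrichment of up/down DEG lists."),
    section("Ranked-list enrichment", "gsea_", "Running-sum ES with permutation NES and FDR q."),
    section("TF networks", "master_regulators|subnetwork", "Connectivity-ranked master regulators and refined subnetworks."),
    section("qPCR validation", "qpcr", "2^-ddCt fold changes, t-tests and RNA-seq concordance."))
  if (!is.null(scorecard)) {
    lines <- c(lines, "## Recovery scorecard (planted vs detected)", "",
               paste0("- ", names(scorecard), ": ",
                      vapply(scorecard, function(x) paste(format(x, digits = 4),
                                                          collapse = ", "), "")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
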