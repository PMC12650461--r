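#' Relative quantification by the 2^-ddCt method
#'
#' Technical duplicate wells are averaged per (gene, group, replicate)
#' first (spreads above `well_spread_flag` cycles are flagged). Then per
#' replicate `dCt = Ct_gene - Ct_reference`, `ddCt = dCt(target group
#' replicate) - mean dCt(reference group)`, and the fold change is
#' `2^-ddCt`.
#'
#' @param ct_table data.frame (gene_id, group, replicate, ct; optional
#'   `well` column for technical duplicates).
#' @param gene gene of interest.
#' @param target_group,reference_group group labels; fold changes are for
#'   the target group relative to the reference group.
#' @param reference_gene housekeeping gene id (defaults to the table's
#'   `reference_gene` attribute).
#' @param well_spread_flag duplicate-well spread (cycles) above which a
#'   reaction is flagged.
#' @return list: `per_replicate` (data.frame replicate, dct, ddct, fold
#'   for the target group), `mean_fold` and `sem_fold` (arithmetic, as
#'   plotted), `geo_mean_fold` (`2^-mean(ddCt)`; exactly inverted by a
#'   group swap), `dct_target`, `dct_reference` (per-replicate dCt
#'   vectors), and `flagged_wells`.
#' @export
ddct_fold_change <- function(ct_table, gene, target_group, reference_group,
                             reference_gene = NULL, well_spread_flag = 0.5) {
  if (is.null(reference_gene))
    reference_gene <- attr(ct_table, "reference_gene")
  if (is.null(reference_gene))
    stop("pairing error: no reference gene supplied")
  need <- expand.grid(gene_id = c(gene, reference_gene),
                      group = c(target_group, reference_group),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(need)))
    if (!any(ct_table$gene_id == need$gene_id[i] & ct_table$group == need$group[i]))
      stop("pairing error: no wells for ", need$gene_id[i], " in group ",
           need$group[i])

  sub <- ct_table[ct_table$gene_id %in% c(gene, reference_gene), , drop = FALSE]
  agg <- stats::aggregate(ct ~ gene_id + group + replicate, sub, mean)
  spread <- stats::aggregate(ct ~ gene_id + group + replicate, sub,
                             function(x) diff(range(x)))
  flagged <- spread[spread$ct > well_spread_flag, c("gene_id", "group", "replicate")]

  dct_of <- function(grp) {
    g <- agg[agg$gene_id == gene & agg$group == grp, ]
    r <- agg[agg$gene_id == reference_gene & agg$group == grp, ]
    m <- merge(g, r, by = c("group", "replicate"), suffixes = c("_gene", "_ref"))
    if (nrow(m) == 0) stop("pairing error: missing reference well in group ", grp)
    stats::setNames(m$ct_gene - m$ct_ref, m$replicate)
  }
  dct_t <- dct_of(target_group)
  dct_r <- dct_of(reference_group)
  ddct <- dct_t - mean(dct_r)
  fold <- 2^(-ddct)
  list(per_replicate = data.frame(replicate = names(dct_t), dct = unname(dct_t),
                                  ddct = unname(ddct), fold = unname(fold),
                                  stringsAsFactors = FALSE),
       mean_fold = mean(fold),
       sem_fold = stats::sd(fold) / sqrt(length(fold)),
       geo_mean_fold = 2^(-(mean(dct_t) - mean(dct_r))),
       dct_target = dct_t, dct_reference = dct_r,
       flagged_wells = flagged)
}

#' Two-group comparison of qPCR measurements
#'
#' Student's t-test (equal variance by default; Welch available) applied
#' to per-replicate dCt values; the fold change is reported alongside but
#' the test is on dCt, which is closer to normal. Degenerate input with
#' zero variance in both groups and equal means returns t = 0, p = 1.
#'
#' @param dct_a,dct_b numeric vectors of per-replicate dCt values.
#' @param var_equal use the pooled-variance Student form (default TRUE).
#' @return list: `t`, `p`, `df`, `mean_diff` (a minus b on the dCt scale).
#' @export
compare_groups <- function(dct_a, dct_b, var_equal = TRUE) {
  if (length(dct_a) < 2 || length(dct_b) < 2)
    stop("need at least 2 replicates per group")
  if (stats::sd(dct_a) == 0 && stats::sd(dct_b) == 0) {
    d <- mean(dct_a) - mean(dct_b)
    if (d == 0) return(list(t = 0, p = 1,
                            df = length(dct_a) + length(dct_b) - 2, mean_diff = 0))
    return(list(t = sign(d) * Inf, p = 0,
                df = length(dct_a) + length(dct_b) - 2, mean_diff = d))
  }
  tt <- stats::t.test(dct_a, dct_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(dct_a) - mean(dct_b))
}

#' qPCR validation of a gene panel against RNA-seq calls
#'
#' Runs [ddct_fold_change()] and [compare_groups()] for each gene and
#' joins the RNA-seq log2 fold changes, reporting per-gene sign
#' agreement: `sign(log2 fold_qpcr) == sign(log2fc_rnaseq)`, with genes at
#' fold exactly 1 (or missing from either result) reported as neutral.
#'
#' @param ct_table Ct table (see [ddct_fold_change()]).
#' @param de_results data.frame from [wald_test()].
#' @param genes genes to validate (defaults to all non-reference genes in
#'   the table).
#' @param target_group,reference_group group labels (target in the
#'   numerator, matching the DE contrast orientation).
#' @param ... passed to [ddct_fold_change()].
#' @return data.frame: gene_id, mean_fold, sem_fold, log2_fold_qpcr, t, p,
#'   log2fc_rnaseq, agreement (agree/disagree/neutral); attribute
#'   `agreement_fraction` is the agree fraction among non-neutral genes
#'   (NA when empty).
#' @export
concordance_with_rnaseq <- function(ct_table, de_results, genes = NULL,
                                    target_group, reference_group, ...) {
  ref <- attr(ct_table, "reference_gene")
  if (is.null(genes))
    genes <- setdiff(unique(ct_table$gene_id), ref)
  rows <- lapply(genes, function(g) {
    fc <- ddct_fold_change(ct_table, g, target_group, reference_group, ...)
    tst <- compare_groups(fc$dct_target, fc$dct_reference)
    lfc_rna <- de_results$log2fc[match(g, de_results$gene_id)]
    l2q <- log2(fc$geo_mean_fold)
    agreement <- if (is.na(lfc_rna) || l2q == 0 || lfc_rna == 0) "neutral"
                 else if (sign(l2q) == sign(lfc_rna)) "agree" else "disagree"
    data.frame(gene_id = g, mean_fold = fc$mean_fold, sem_fold = fc$sem_fold,
               log2_fold_qpcr = l2q, t = tst$t, p = tst$p,
               log2fc_rnaseq = lfc_rna, agreement = agreement,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene_id = character(0))
  informative <- out$agreement[out$agreement != "neutral"]
  attr(out, "agreement_fraction") <-
    if (length(informative)) mean(informative == "agree") else NA_real_
  out
}
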