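#' FPKM normalisation
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM(g, s) = count(g, s) / ((length(g)/1e3) * (total(s)/1e6))`, using
#' each sample's total assigned counts as the depth denominator.
#'
#' @param counts non-negative integer matrix, genes x samples, with gene
#'   ids as rownames.
#' @param gene_lengths named numeric vector of gene lengths in bp (or a
#'   data.frame with columns gene_id, length).
#' @return numeric matrix of FPKM values, same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.data.frame(gene_lengths))
    gene_lengths <- stats::setNames(gene_lengths$length, gene_lengths$gene_id)
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing) > 0)
    stop("annotation error: no length for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("annotation error: gene lengths must be positive")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("degenerate-sample error: sample(s) with all-zero counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts / (len / 1e3), 2, totals / 1e6, "/")
}

#' Expressed-gene sets per strain x cell-type group
#'
#' A gene counts as expressed in a group when its raw counts summed over
#' the group's replicates reach `min_count` (default 10). The group-sum
#' rule is used because per-replicate thresholds are unstable at n = 3.
#'
#' @param counts integer count matrix, genes x samples.
#' @param samples data.frame with `sample_id` plus the grouping columns.
#' @param min_count group-summed raw-count threshold.
#' @param group_by sample columns defining the groups.
#' @return named list (group label -> character vector of gene ids).
#' @export
expressed_gene_sets <- function(counts, samples, min_count = 10,
                                group_by = c("strain", "cell_type")) {
  stopifnot(all(group_by %in% names(samples)),
            all(samples$sample_id %in% colnames(counts)))
  key <- interaction(samples[group_by], sep = ".", drop = TRUE)
  out <- lapply(levels(key), function(g) {
    ids <- samples$sample_id[key == g]
    if (length(ids) == 0) stop("grouping error: empty group ", g)
    rs <- rowSums(counts[, ids, drop = FALSE])
    rownames(counts)[rs >= min_count]
  })
  stats::setNames(out, levels(key))
}

#' Two-way Venn partition of gene sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with memberships `unique_a`, `shared`, `unique_b` and an
#'   integer `sizes` vector.
#' @export
venn_partition <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  ua <- setdiff(set_a, set_b)
  ub <- setdiff(set_b, set_a)
  list(unique_a = ua, shared = shared, unique_b = ub,
       sizes = c(unique_a = length(ua), shared = length(shared),
                 unique_b = length(ub)))
}

#' PCA ordination of samples on log2(FPKM + offset)
#'
#' Samples are observations, genes are (centred, unscaled) features. Each
#' component's sign is fixed so that its largest-magnitude gene loading is
#' positive, making coordinates reproducible across runs.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param samples optional sample table merged into the coordinates.
#' @param log_offset pseudo-value added before log2.
#' @return list with `coordinates` (data.frame: sample_id, PCs, any
#'   metadata), `var_explained` (non-increasing fractions summing to <= 1)
#'   and `rotation` (gene loadings).
#' @export
pca_ordination <- function(fpkm, samples = NULL, log_offset = 1) {
  if (ncol(fpkm) < 3) stop("degenerate error: need at least 3 samples")
  x <- t(log2(as.matrix(fpkm) + log_offset))
  v <- apply(x, 2, stats::var)
  if (all(v == 0)) {
    k <- min(nrow(x), 2L)
    coords <- matrix(0, nrow(x), k,
                     dimnames = list(rownames(x), paste0("PC", seq_len(k))))
    ve <- rep(0, k)
  } else {
    if (sum(v > 0) < 2)
      stop("degenerate error: fewer than 2 genes with nonzero variance")
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
    flip[flip == 0] <- 1
    pr$rotation <- sweep(pr$rotation, 2, flip, "*")
    coords <- sweep(pr$x, 2, flip, "*")
    ve <- pr$sdev^2 / sum(pr$sdev^2)
  }
  df <- data.frame(sample_id = rownames(coords), coords, row.names = NULL,
                   stringsAsFactors = FALSE)
  if (!is.null(samples)) df <- merge(df, samples, by = "sample_id", sort = FALSE)
  rot <- if (exists("pr", inherits = FALSE)) pr$rotation else NULL
  list(coordinates = df, var_explained = ve, rotation = rot)
}
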