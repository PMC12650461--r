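#' Rank genes for enrichment analysis
#'
#' Produces the descending ranked list consumed by the running-sum
#' statistic. The default metric is the Wald z (`log2fc / se_log2fc`);
#' alternatives are the raw log2 fold change and `-log10(p) * sign(lfc)`.
#' Ties are broken alphabetically by gene id so the ordering is
#' deterministic.
#'
#' @param de_results data.frame from [wald_test()].
#' @param metric one of "z", "log2fc", "signed_logp".
#' @return data.frame (gene_id, score), descending score.
#' @export
rank_genes <- function(de_results, metric = c("z", "log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  score <- switch(metric,
    z = de_results$log2fc / de_results$se_log2fc,
    log2fc = de_results$log2fc,
    signed_logp = -log10(pmax(de_results$wald_p, 1e-300)) * sign(de_results$log2fc))
  keep <- is.finite(score)
  if (!all(keep)) {
    message("rank_genes: dropped ", sum(!keep), " gene(s) with non-finite score")
    de_results <- de_results[keep, ]; score <- score[keep]
  }
  if (length(unique(score)) == 1L)
    warning("degenerate ranking: all scores equal")
  ord <- order(-score, de_results$gene_id)
  data.frame(gene_id = de_results$gene_id[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, the running sum increases by
#' `|score|^weight / sum(|score|^weight over hits)` at set members and
#' decreases by `1 / (N - N_hits)` at non-members; the enrichment score is
#' the signed maximum deviation. The leading edge contains the members up
#' to the extremum (from the top for positive ES, from the bottom for
#' negative). If every hit has zero weight the hit increments fall back to
#' equal steps.
#'
#' @param ranked data.frame (gene_id, score) from [rank_genes()].
#' @param set character vector of member gene ids.
#' @param weight exponent on |score| (1 = the classic weighted statistic).
#' @return list: `es`, `running` (full deviation profile), `hit_index`
#'   (positions of members), `leading_edge` (gene ids).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  N <- nrow(ranked)
  inset <- ranked$gene_id %in% set
  nh <- sum(inset)
  if (nh == 0) stop("empty intersection: no set member present in the ranked list")
  if (nh == N) stop("undefined-miss error: set covers the entire ranked list")
  w <- abs(ranked$score)^weight
  wh <- ifelse(inset, w, 0)
  if (sum(wh) == 0) wh <- as.numeric(inset)
  running <- cumsum(wh / sum(wh)) - cumsum(!inset) / (N - nh)
  hi <- max(running); lo <- min(running)
  # signed maximum deviation; an exact |hi| == |lo| tie resolves to the
  # negative extreme, matching the permutation kernel
  es <- if (hi > -lo) hi else lo
  i_ext <- if (es >= 0 && hi > 0) which.max(running) else which.min(running)
  hit_index <- which(inset)
  leading <- if (es >= 0) ranked$gene_id[hit_index[hit_index <= i_ext]]
             else ranked$gene_id[hit_index[hit_index > i_ext]]
  list(es = es, running = running, hit_index = hit_index,
       leading_edge = leading)
}

# ES from sorted hit positions only, O(k): extrema of the running sum can
# occur only immediately after a hit (maxima) or immediately before one
# (minima). `w` is the full |score|^weight vector over the ranked list.
.es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  wh <- w[pos]
  W <- sum(wh)
  if (W == 0) { wh <- rep(1, k); W <- k }
  cumhit <- cumsum(wh) / W
  miss <- (pos - seq_len(k)) / (N - k)
  dev_at <- cumhit - miss
  dev_before <- c(0, cumhit[-k]) - miss
  hi <- max(dev_at); lo <- min(dev_before)
  if (hi > -lo) hi else lo
}

#' Permutation normalisation and FDR for enrichment scores
#'
#' For each gene set, a null ES distribution is built from random gene
#' sets of the same size drawn from the ranked list (gene-set
#' permutation). `NES = ES / mean(|null ES| of matching sign)`; the
#' nominal p is the same-sign null exceedance fraction. The FDR q-value
#' compares, per the sign-stratified ratio, the fraction of pooled null
#' NES at least as extreme as the observed NES against the fraction of
#' observed NES at least as extreme, clamped to \[0, 1\]. A set is flagged
#' significant when `|NES| >= nes_threshold` and `q <= q_threshold`
#' (defaults 1.5 and 0.25). Sets with fewer than 10 same-sign null
#' samples get a warning and q = 1.
#'
#' @param ranked data.frame (gene_id, score), descending.
#' @param sets named list of gene-id vectors.
#' @param n_perm permutations per set (>= 100).
#' @param weight running-sum weight exponent.
#' @param seed integer seed for the permutation stream.
#' @param nes_threshold,q_threshold significance gate.
#' @param min_size minimum post-intersection set size.
#' @return data.frame: set_id, size, es, nes, nominal_p, fdr_q,
#'   significant, leading_edge (comma-separated), n_perm; ordered by
#'   descending nes.
#' @export
gsea_test <- function(ranked, sets, n_perm = 1000, weight = 1, seed = 1,
                      nes_threshold = 1.5, q_threshold = 0.25, min_size = 3) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  set.seed(seed)
  N <- nrow(ranked)
  w <- abs(ranked$score)^weight

  keep <- list()
  for (id in names(sets)) {
    members <- intersect(unique(sets[[id]]), ranked$gene_id)
    if (length(members) < min_size) {
      message("gsea_test: skipping ", id, " (fewer than ", min_size,
              " members in the ranked list)")
      next
    }
    if (length(members) == N)
      stop("undefined-miss error: set ", id, " covers the entire ranked list")
    keep[[id]] <- members
  }
  if (length(keep) == 0)
    return(data.frame(set_id = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), nominal_p = numeric(0),
                      fdr_q = numeric(0), significant = logical(0),
                      leading_edge = character(0), n_perm = integer(0)))

  ids <- names(keep)
  es_obs <- numeric(length(ids))
  lead <- character(length(ids))
  sizes <- integer(length(ids))
  null_nes <- vector("list", length(ids))
  nes <- numeric(length(ids))
  nominal_p <- numeric(length(ids))
  unstable <- logical(length(ids))

  for (i in seq_along(ids)) {
    es <- enrichment_score(ranked, keep[[i]], weight)
    es_obs[i] <- es$es
    lead[i] <- paste(es$leading_edge, collapse = ",")
    k <- length(es$hit_index)
    sizes[i] <- k
    null_es <- vapply(seq_len(n_perm), function(b)
      .es_from_positions(sort(sample.int(N, k)), w, N), numeric(1))
    pos_mean <- mean(null_es[null_es > 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    nes[i] <- if (es_obs[i] > 0) {
      if (is.finite(pos_mean) && pos_mean > 0) es_obs[i] / pos_mean else 0
    } else if (es_obs[i] < 0) {
      if (is.finite(neg_mean) && neg_mean > 0) es_obs[i] / neg_mean else 0
    } else 0
    same <- if (es_obs[i] >= 0) null_es[null_es > 0] else null_es[null_es < 0]
    if (length(same) < 10) {
      warning("unstable null for set ", ids[i],
              ": fewer than 10 same-sign permutation scores; q set to 1")
      unstable[i] <- TRUE
      nominal_p[i] <- 1
      null_nes[[i]] <- numeric(0)
    } else {
      nominal_p[i] <- mean(abs(same) >= abs(es_obs[i]))
      nn <- null_es
      nn[null_es > 0] <- if (is.finite(pos_mean) && pos_mean > 0)
        null_es[null_es > 0] / pos_mean else 0
      nn[null_es < 0] <- if (is.finite(neg_mean) && neg_mean > 0)
        null_es[null_es < 0] / neg_mean else 0
      null_nes[[i]] <- nn
    }
  }

  pool <- unlist(null_nes)
  fdr_q <- numeric(length(ids))
  for (i in seq_along(ids)) {
    if (unstable[i]) { fdr_q[i] <- 1; next }
    if (nes[i] >= 0) {
      denom_pool <- pool[pool >= 0]
      a <- if (length(denom_pool)) mean(denom_pool >= nes[i]) else 1
      b <- mean(nes[nes >= 0] >= nes[i])
    } else {
      denom_pool <- pool[pool <= 0]
      a <- if (length(denom_pool)) mean(denom_pool <= nes[i]) else 1
      b <- mean(nes[nes <= 0] <= nes[i])
    }
    fdr_q[i] <- min(1, max(0, if (b > 0) a / b else 1))
  }

  res <- data.frame(set_id = ids, size = sizes, es = es_obs, nes = nes,
                    nominal_p = nominal_p, fdr_q = fdr_q,
                    significant = abs(nes) >= nes_threshold & fdr_q <= q_threshold,
                    leading_edge = lead, n_perm = as.integer(n_perm),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$nes, res$set_id), ]
  rownames(res) <- NULL
  res
}
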