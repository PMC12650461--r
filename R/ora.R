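#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for overlap with a query list (e.g. up- or
#' down-regulated DEGs) within a background universe. The p-value is the
#' upper tail including the observed overlap, `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`; BH adjustment is applied across all
#' tested sets. Query genes and set members outside the universe are
#' dropped (with a message); sets smaller than `min_size` after
#' intersection are skipped.
#'
#' @param query character vector of gene ids.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe background gene ids (typically the expressed genes of
#'   the contrasted groups).
#' @param min_size minimum post-intersection set size tested.
#' @return data.frame: set_id, k (overlap), K (set size), n (query size),
#'   N (universe size), gene_ratio, p, padj, genes (overlap members,
#'   comma-separated), ordered by (p, set_id).
#' @export
ora_test <- function(query, sets, universe, min_size = 3) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("input error: empty universe")
  q0 <- unique(query)
  query <- intersect(q0, universe)
  dropped <- length(q0) - length(query)
  if (dropped > 0)
    message("ora_test: dropped ", dropped, " query gene(s) outside the universe")
  if (length(query) == 0)
    stop("input error: empty query after intersection with universe")

  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), universe)
    K <- length(members)
    if (K < min_size) return(NULL)
    hit <- intersect(members, query)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N,
               gene_ratio = k / n, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(set_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), gene_ratio = numeric(0),
                      p = numeric(0), padj = numeric(0), genes = character(0)))
  res <- do.call(rbind, rows)
  res$padj <- adjust_bh(res$p)
  res <- res[order(res$p, res$set_id),
             c("set_id", "k", "K", "n", "N", "gene_ratio", "p", "padj", "genes")]
  rownames(res) <- NULL
  res
}
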