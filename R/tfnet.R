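#' Merge source-tagged TF-target edge lists into a prior network
#'
#' Accepts either a list of data.frames (each with columns tf, target and
#' optionally mode, plus source or a per-list name) or a single long
#' data.frame with a `source` column. Identical (tf, target) pairs are
#' collapsed with their source tags unioned; conflicting regulation modes
#' (activation vs repression) resolve to "unknown" and are counted;
#' self-loops are retained but flagged.
#'
#' @param edge_lists list of data.frames or one long data.frame.
#' @return object of class `prior_network`: a list with `edges`
#'   (data.frame tf, target, mode, sources, self_loop), `tfs`, and
#'   attributes `n_mode_conflicts` and `sources`.
#' @export
merge_priors <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  long <- lapply(seq_along(edge_lists), function(i) {
    df <- edge_lists[[i]]
    if (!all(c("tf", "target") %in% names(df)))
      stop("parse error: edge list ", i, " lacks tf/target columns")
    bad <- which(is.na(df$tf) | is.na(df$target) | df$tf == "" | df$target == "")
    if (length(bad) > 0)
      stop("parse error: malformed row(s) in edge list ", i, " at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (is.null(df$mode)) df$mode <- "unknown"
    if (is.null(df$source))
      df$source <- if (!is.null(names(edge_lists)[i]) &&
                       !is.na(names(edge_lists)[i]) && names(edge_lists)[i] != "")
        names(edge_lists)[i] else paste0("source", i)
    df[, c("tf", "target", "mode", "source")]
  })
  long <- do.call(rbind, long)
  if (nrow(long) == 0) stop("integration error: empty merged network")

  key <- paste(long$tf, long$target, sep = "\r")
  n_conflicts <- 0L
  merged <- lapply(split(seq_len(nrow(long)), key), function(ix) {
    modes <- unique(long$mode[ix])
    signed <- intersect(modes, c("activation", "repression"))
    mode <- if (length(signed) == 2L) "conflict"
            else if (length(signed) == 1L) signed
            else "unknown"
    data.frame(tf = long$tf[ix[1]], target = long$target[ix[1]], mode = mode,
               sources = paste(sort(unique(long$source[ix])), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, merged)
  n_conflicts <- sum(edges$mode == "conflict")
  if (n_conflicts > 0) {
    message("merge_priors: ", n_conflicts,
            " edge(s) with conflicting modes resolved to 'unknown'")
    edges$mode[edges$mode == "conflict"] <- "unknown"
  }
  edges$self_loop <- edges$tf == edges$target
  edges <- edges[order(edges$tf, edges$target), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, tfs = sort(unique(edges$tf))),
            class = "prior_network",
            n_mode_conflicts = n_conflicts,
            sources = sort(unique(long$source)))
}

#' Explode a merged prior network back to one row per source assertion
#'
#' @param network a `prior_network`.
#' @return data.frame (tf, target, mode, source).
#' @export
prior_edges_long <- function(network) {
  e <- network$edges
  src <- strsplit(e$sources, ";", fixed = TRUE)
  n <- lengths(src)
  data.frame(tf = rep(e$tf, n), target = rep(e$target, n),
             mode = rep(e$mode, n), source = unlist(src),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter a prior network to sufficiently expressed genes
#'
#' Nodes whose total raw count across the supplied samples falls below
#' `min_count` are removed with their incident edges; TFs left without
#' outgoing edges (and not appearing as targets) are removed too. Genes
#' absent from the count matrix are dropped with a message.
#'
#' @param network a `prior_network`.
#' @param counts raw count matrix restricted to the samples of interest
#'   (e.g. the two contrasted groups of one cell type).
#' @param min_count raw-count threshold (default 10).
#' @return filtered `prior_network`.
#' @export
filter_expressed <- function(network, counts, min_count = 10) {
  e <- network$edges
  nodes <- unique(c(e$tf, e$target))
  uncovered <- setdiff(nodes, rownames(counts))
  if (length(uncovered) > 0)
    message("filter_expressed: dropping ", length(uncovered),
            " node(s) absent from the count matrix")
  totals <- rowSums(as.matrix(counts))
  expressed <- names(totals)[totals >= min_count]
  keep_nodes <- intersect(nodes, expressed)
  e <- e[e$tf %in% keep_nodes & e$target %in% keep_nodes, , drop = FALSE]
  # the node set is defined by the surviving edges, so a TF whose every
  # target fell below threshold cascades out automatically (unless it
  # survives as a target of another TF)
  rownames(e) <- NULL
  structure(list(edges = e, tfs = sort(unique(e$tf))),
            class = "prior_network",
            n_mode_conflicts = attr(network, "n_mode_conflicts"),
            sources = attr(network, "sources"))
}

# internal: DEG table at the TF-stage thresholds (non-strict lfc, per the
# network-figure convention |log2FC| >= lfc and padj < alpha)
.deg_table <- function(de_results, lfc = 2, alpha = 0.05) {
  sig <- !is.na(de_results$padj) & de_results$padj < alpha &
    abs(de_results$log2fc) >= lfc
  d <- de_results[sig, c("gene_id", "log2fc"), drop = FALSE]
  d$direction <- ifelse(d$log2fc > 0, "up", "down")
  d
}

#' DEG-centered regulatory subnetwork
#'
#' Maps DEGs (padj < alpha and |log2FC| >= lfc; the network stage uses the
#' non-strict fold-change tier, default 2) onto the prior and keeps the
#' DEGs together with every TF that targets at least one of them; edges
#' are the prior edges from those TFs into DEGs.
#'
#' @param network a `prior_network` (typically expression-filtered).
#' @param de_results data.frame from [wald_test()].
#' @param lfc,alpha DEG thresholds.
#' @return object of class `reg_subnetwork`: list with `nodes` (id, kind
#'   tf/gene, de_direction up/down/none, log2fc) and `edges` (regulator,
#'   target, mode, regulation_class NA at this stage).
#' @export
deg_subnetwork <- function(network, de_results, lfc = 2, alpha = 0.05) {
  degs <- .deg_table(de_results, lfc, alpha)
  if (nrow(degs) == 0) message("deg_subnetwork: zero DEGs; empty subnetwork")
  e <- network$edges[network$edges$target %in% degs$gene_id, , drop = FALSE]
  tfs <- sort(unique(e$tf))
  node_ids <- union(degs$gene_id, tfs)
  nodes <- data.frame(id = node_ids,
                      kind = ifelse(node_ids %in% tfs, "tf", "gene"),
                      stringsAsFactors = FALSE)
  m <- match(nodes$id, degs$gene_id)
  nodes$de_direction <- ifelse(is.na(m), "none", degs$direction[m])
  nodes$log2fc <- ifelse(is.na(m), NA_real_, degs$log2fc[m])
  nodes <- nodes[order(nodes$id), ]
  edges <- data.frame(regulator = e$tf, target = e$target, mode = e$mode,
                      regulation_class = rep(NA_character_, nrow(e)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), ]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 thresholds = c(lfc = lfc, alpha = alpha)),
            class = "reg_subnetwork")
}

#' Rank master regulators by DEG connectivity
#'
#' Connectivity is the number of distinct DEG targets a TF has within the
#' DEG-centered subnetwork. TFs are ranked by descending connectivity
#' (ties broken by id) and the top `top_n` are reported with their
#' up/down target split and a direction class: up-linked when every DEG
#' target is up, down-linked when every one is down, otherwise mixed.
#'
#' @param subnetwork a `reg_subnetwork` from [deg_subnetwork()].
#' @param top_n number of TFs retained (default 30).
#' @return data.frame: tf_id, deg_target_count, deg_targets_up,
#'   deg_targets_down, direction_class, with attribute `top_n`.
#' @export
rank_master_regulators <- function(subnetwork, top_n = 30) {
  e <- unique(subnetwork$edges[, c("regulator", "target")])
  if (nrow(e) == 0)
    return(structure(data.frame(tf_id = character(0),
                                deg_target_count = integer(0),
                                deg_targets_up = integer(0),
                                deg_targets_down = integer(0),
                                direction_class = character(0)),
                     top_n = top_n))
  dir <- stats::setNames(subnetwork$nodes$de_direction, subnetwork$nodes$id)
  e$target_dir <- dir[e$target]
  agg <- do.call(rbind, lapply(split(e, e$regulator), function(d) {
    data.frame(tf_id = d$regulator[1],
               deg_target_count = nrow(d),
               deg_targets_up = sum(d$target_dir == "up"),
               deg_targets_down = sum(d$target_dir == "down"),
               stringsAsFactors = FALSE)
  }))
  agg$direction_class <- ifelse(agg$deg_targets_down == 0, "up-linked",
                         ifelse(agg$deg_targets_up == 0, "down-linked", "mixed"))
  agg <- agg[order(-agg$deg_target_count, agg$tf_id), ]
  agg <- utils::head(agg, top_n)
  rownames(agg) <- NULL
  structure(agg, top_n = top_n)
}

#' Refine a subnetwork to selected regulators and top targets
#'
#' Keeps only the TFs in the master-regulator report; each retains at
#' most `top_k_targets` DEG targets ranked by |log2FC| (ties by gene id).
#' Nodes left isolated are dropped. Edges are annotated with a regulation
#' class from the endpoints' DE directions: `up` when the target is up,
#' `down` when the target is down, and `mixed` when both endpoints are
#' DEGs with opposite directions.
#'
#' @param subnetwork a `reg_subnetwork`.
#' @param report a master-regulator report from [rank_master_regulators()].
#' @param top_k_targets per-TF target cap (default 10).
#' @return refined `reg_subnetwork` (subgraph of the input).
#' @export
refine_subnetwork <- function(subnetwork, report, top_k_targets = 10) {
  keep_tfs <- report$tf_id
  e <- subnetwork$edges[subnetwork$edges$regulator %in% keep_tfs, , drop = FALSE]
  lfc <- stats::setNames(subnetwork$nodes$log2fc, subnetwork$nodes$id)
  dir <- stats::setNames(subnetwork$nodes$de_direction, subnetwork$nodes$id)
  if (nrow(e) > 0) {
    e <- do.call(rbind, lapply(split(e, e$regulator), function(d) {
      ord <- order(-abs(lfc[d$target]), d$target)
      utils::head(d[ord, , drop = FALSE], top_k_targets)
    }))
    tdir <- dir[e$target]
    rdir <- dir[e$regulator]
    e$regulation_class <- ifelse(
      rdir != "none" & tdir != "none" & rdir != tdir, "mixed", tdir)
  }
  kept <- unique(c(e$regulator, e$target))
  nodes <- subnetwork$nodes[subnetwork$nodes$id %in% kept, , drop = FALSE]
  e <- e[order(e$regulator, e$target), , drop = FALSE]
  rownames(nodes) <- rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e,
                 thresholds = subnetwork$thresholds),
            class = "reg_subnetwork")
}

#' Compare two master-regulator reports
#'
#' Set algebra on the selected TF ids plus direction-class concordance on
#' the shared TFs (e.g. CD4 vs CD8 subnetworks).
#'
#' @param report_a,report_b master-regulator reports at the same `top_n`.
#' @return list: `common`, `unique_a`, `unique_b` (ids), `sizes`, and
#'   `concordance` (data.frame tf_id, class_a, class_b, concordant) with
#'   `concordance_fraction`.
#' @export
compare_regulator_sets <- function(report_a, report_b) {
  a <- report_a$tf_id; b <- report_b$tf_id
  common <- sort(intersect(a, b))
  conc <- data.frame(tf_id = common,
                     class_a = report_a$direction_class[match(common, a)],
                     class_b = report_b$direction_class[match(common, b)],
                     stringsAsFactors = FALSE)
  conc$concordant <- conc$class_a == conc$class_b
  list(common = common, unique_a = sort(setdiff(a, b)),
       unique_b = sort(setdiff(b, a)),
       sizes = c(common = length(common), unique_a = length(setdiff(a, b)),
                 unique_b = length(setdiff(b, a))),
       concordance = conc,
       concordance_fraction = if (nrow(conc)) mean(conc$concordant) else NA_real_)
}

#' Export a regulatory subnetwork
#'
#' @param subnetwork a `reg_subnetwork`.
#' @return an `igraph` graph with node kind/de_direction/log2fc and edge
#'   mode/regulation_class attributes.
#' @export
subnetwork_to_igraph <- function(subnetwork) {
  igraph::graph_from_data_frame(
    d = subnetwork$edges[, c("regulator", "target", "mode", "regulation_class")],
    directed = TRUE,
    vertices = subnetwork$nodes)
}

#' Write a regulatory subnetwork to GraphML and edge-list TSV
#'
#' @param subnetwork a `reg_subnetwork`.
#' @param graphml_path,edges_path output file paths (NULL to skip either).
#' @return invisibly, the igraph object.
#' @export
write_subnetwork <- function(subnetwork, graphml_path = NULL, edges_path = NULL) {
  g <- subnetwork_to_igraph(subnetwork)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(subnetwork$edges, edges_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(g)
}
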