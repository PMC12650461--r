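#' Simulation configuration for the synthetic T-cell RNA-seq study
#'
#' Builds and validates the configuration object consumed by
#' [simulate_counts()], [simulate_gene_sets()], [simulate_prior_network()]
#' and [simulate_ct_table()]. Defaults emulate the study design the
#' downstream analysis assumes: two mouse strains (myocarditis-resistant
#' vs susceptible) by two sorted T-cell subsets (CD4, CD8) with three
#' biological replicates each, negative-binomial counts with a shared
#' dispersion, a fraction of genes planted as differentially expressed
#' between strains within each cell type, coherently shifted gene sets,
#' and a TF-target prior whose designated master regulators are loaded
#' with planted DEG targets.
#'
#' @param n_genes number of genes simulated.
#' @param n_replicates biological replicates per strain x cell-type group.
#' @param strains character pair; the first strain carries the planted
#'   differential-expression effects (it is the contrast numerator).
#' @param cell_types character pair of sorted T-cell subsets.
#' @param baseline_log2_mean_range per-gene baseline expression drawn
#'   uniformly on this log2 scale (relative abundance before library
#'   scaling).
#' @param dispersion shared negative-binomial dispersion alpha, with
#'   Var = mu + alpha * mu^2. Zero gives Poisson counts.
#' @param de_fraction fraction of genes planted as DE between strains
#'   within a cell type.
#' @param de_log2fc_magnitude absolute planted log2 fold change.
#' @param de_shared_fraction fraction of each cell type's planted DE panel
#'   shared (same genes, same signs) with the other cell type, emulating
#'   strain differences common to both T-cell subsets; this shared
#'   component is what makes the strain contrast the leading axis of
#'   variation.
#' @param celltype_effect_fraction,celltype_effect_size fraction of genes
#'   carrying a cell-type effect of the given log2 magnitude (random
#'   sign); gives the ordination a second axis of structure.
#' @param n_gene_sets,set_size_range number and size range of simulated
#'   gene sets.
#' @param n_shifted_sets number of sets composed predominantly of
#'   same-direction planted DE genes (directions alternate up/down).
#' @param shifted_de_fraction target fraction of a shifted set drawn from
#'   same-direction planted DE genes (>= 0.8 by contract).
#' @param n_tfs,targets_per_tf_range transcription-factor count and
#'   targets per TF in the simulated prior.
#' @param n_master_tfs TFs whose target lists are loaded with planted
#'   DEGs.
#' @param nonmaster_max_deg_targets cap on planted-DEG targets of a
#'   non-master TF; masters receive `2 * cap + 2` DEG targets so the 2x
#'   loading rule holds with margin.
#' @param library_size_range per-sample total count range.
#' @param gene_length_range gene lengths (bp), drawn once, shared across
#'   samples, independent of expression.
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param seed integer seed; all generators derive their streams from it.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_replicates = 3L,
                       strains = c("resistant", "susceptible"),
                       cell_types = c("CD4", "CD8"),
                       baseline_log2_mean_range = c(1, 9),
                       dispersion = 0.1,
                       de_fraction = 0.05,
                       de_log2fc_magnitude = 2.5,
                       de_shared_fraction = 0.5,
                       celltype_effect_fraction = 0.1,
                       celltype_effect_size = 1,
                       n_gene_sets = 50L,
                       set_size_range = c(15L, 50L),
                       n_shifted_sets = 4L,
                       shifted_de_fraction = 0.9,
                       n_tfs = 50L,
                       targets_per_tf_range = c(10L, 30L),
                       n_master_tfs = 1L,
                       nonmaster_max_deg_targets = 4L,
                       library_size_range = c(8e5, 1.2e6),
                       gene_length_range = c(500L, 5000L),
                       ct_noise_sd = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    strains = as.character(strains), cell_types = as.character(cell_types),
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    dispersion = as.numeric(dispersion), de_fraction = as.numeric(de_fraction),
    de_log2fc_magnitude = as.numeric(de_log2fc_magnitude),
    de_shared_fraction = as.numeric(de_shared_fraction),
    celltype_effect_fraction = as.numeric(celltype_effect_fraction),
    celltype_effect_size = as.numeric(celltype_effect_size),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_shifted_sets = as.integer(n_shifted_sets),
    shifted_de_fraction = as.numeric(shifted_de_fraction),
    n_tfs = as.integer(n_tfs),
    targets_per_tf_range = as.integer(targets_per_tf_range),
    n_master_tfs = as.integer(n_master_tfs),
    nonmaster_max_deg_targets = as.integer(nonmaster_max_deg_targets),
    library_size_range = as.numeric(library_size_range),
    gene_length_range = as.integer(gene_length_range),
    ct_noise_sd = as.numeric(ct_noise_sd), seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_replicates < 1L)
    stop("configuration error: n_genes and n_replicates must be positive")
  if (length(cfg$strains) != 2L || length(cfg$cell_types) != 2L)
    stop("configuration error: strains and cell_types must each be a label pair")
  if (is.na(cfg$de_fraction) || cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("configuration error: de_fraction must lie in [0, 1]")
  if (cfg$de_shared_fraction < 0 || cfg$de_shared_fraction > 1)
    stop("configuration error: de_shared_fraction must lie in [0, 1]")
  if (cfg$de_fraction > 0 && round(cfg$de_fraction * cfg$n_genes) < 1)
    stop("configuration error: de_fraction * n_genes must be >= 1 when de_fraction > 0")
  if (cfg$dispersion < 0)
    stop("configuration error: dispersion must be non-negative")
  if (cfg$de_log2fc_magnitude <= 0)
    stop("configuration error: de_log2fc_magnitude must be positive")
  if (any(cfg$set_size_range > cfg$n_genes))
    stop("configuration error: set sizes must not exceed n_genes")
  if (cfg$shifted_de_fraction < 0.8 || cfg$shifted_de_fraction > 1)
    stop("configuration error: shifted_de_fraction must lie in [0.8, 1]")
  if (any(cfg$library_size_range <= 0) || any(cfg$gene_length_range <= 0))
    stop("configuration error: library sizes and gene lengths must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts follow NB(mean = library_size * p_gene, alpha) where the per-gene
#' relative abundance is `2^(baseline + strain_effect + celltype_effect)`
#' renormalised within each sample. Planted DE genes carry a strain effect
#' of `+/- de_log2fc_magnitude` (first strain relative to second) within
#' each cell type; the DE gene panels are drawn independently per cell
#' type. Deterministic under the configuration seed.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_bundle` with elements `counts` (integer
#'   matrix, genes x samples), `gene_lengths` (named integer vector, bp),
#'   `samples` (data.frame: sample_id, strain, cell_type, replicate) and
#'   `truth` (planted DE tables per cell type, true size factors, gene
#'   universe, and the configuration).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  baseline <- stats::runif(n, config$baseline_log2_mean_range[1],
                           config$baseline_log2_mean_range[2])
  lengths <- sample(seq(config$gene_length_range[1],
                        config$gene_length_range[2]), n, replace = TRUE)
  names(lengths) <- genes

  ct_eff <- numeric(n)
  n_ct <- round(config$celltype_effect_fraction * n)
  if (n_ct > 0) {
    idx <- sample.int(n, n_ct)
    ct_eff[idx] <- sample(c(-1, 1), n_ct, replace = TRUE) * config$celltype_effect_size
  }

  n_de <- round(config$de_fraction * n)
  n_shared <- round(config$de_shared_fraction * n_de)
  de_genes <- stats::setNames(vector("list", 2L), config$cell_types)
  strain_eff <- matrix(0, n, 2L, dimnames = list(genes, config$cell_types))
  if (n_de > 0) {
    shared_idx <- sort(sample.int(n, n_shared))
    shared_sgn <- sample(c(-1, 1), n_shared, replace = TRUE)
    for (ct in config$cell_types) {
      own_idx <- sort(sample(setdiff(seq_len(n), shared_idx), n_de - n_shared))
      own_sgn <- sample(c(-1, 1), n_de - n_shared, replace = TRUE)
      idx <- c(shared_idx, own_idx)
      sgn <- c(shared_sgn, own_sgn)
      ord <- order(idx)
      idx <- idx[ord]; sgn <- sgn[ord]
      strain_eff[idx, ct] <- sgn * config$de_log2fc_magnitude
      de_genes[[ct]] <- data.frame(gene_id = genes[idx],
                                   true_log2fc = sgn * config$de_log2fc_magnitude,
                                   stringsAsFactors = FALSE)
    }
  } else {
    for (ct in config$cell_types)
      de_genes[[ct]] <- data.frame(gene_id = character(0), true_log2fc = numeric(0))
  }

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         cell_type = config$cell_types,
                         strain = config$strains,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "cell_type", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$strain, samples$cell_type,
                               samples$replicate)
  lib <- round(stats::runif(nrow(samples), config$library_size_range[1],
                            config$library_size_range[2]))

  counts <- matrix(0L, n, nrow(samples), dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    is_first_strain <- samples$strain[j] == config$strains[1]
    is_second_ct <- samples$cell_type[j] == config$cell_types[2]
    log2mu <- baseline +
      (if (is_second_ct) ct_eff else 0) +
      (if (is_first_strain) strain_eff[, samples$cell_type[j]] else 0)
    w <- 2^log2mu
    mu <- lib[j] * w / sum(w)
    counts[, j] <- if (config$dispersion == 0) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
  }
  storage.mode(counts) <- "integer"

  truth <- list(
    de_genes = de_genes,
    shifted_sets = NULL,  # filled by simulate_gene_sets()
    master_tfs = NULL,    # filled by simulate_prior_network()
    size_factors_true = stats::setNames(lib / mean(lib), samples$sample_id),
    gene_ids = genes,
    config = config
  )
  structure(list(counts = counts, gene_lengths = lengths,
                 samples = samples[, c("sample_id", "strain", "cell_type", "replicate")],
                 truth = truth),
            class = "sim_bundle")
}

#' Simulate gene-set collections with planted coherent shifts
#'
#' The first `n_shifted_sets` sets are composed predominantly
#' (`shifted_de_fraction`, at least 80%) of same-direction planted DE
#' genes of the first cell type, with directions alternating up/down;
#' the remaining sets are uniform draws from the non-DE gene pool.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of a [simulate_counts()] bundle.
#' @return list with `sets` (named list of unique gene-id vectors, GMT
#'   writable), `descriptions`, and `shifted` (data.frame set_id,
#'   direction).
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- truth$gene_ids
  de <- truth$de_genes[[config$cell_types[1]]]
  up_pool <- de$gene_id[de$true_log2fc > 0]
  down_pool <- de$gene_id[de$true_log2fc < 0]
  null_pool <- setdiff(genes, de$gene_id)

  ids <- sprintf("set%03d", seq_len(config$n_gene_sets))
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_gene_sets, replace = TRUE)
  if (config$n_shifted_sets > config$n_gene_sets)
    stop("generation error: n_shifted_sets exceeds n_gene_sets")

  sets <- vector("list", config$n_gene_sets)
  names(sets) <- ids
  directions <- character(0)
  for (i in seq_len(config$n_gene_sets)) {
    if (i <= config$n_shifted_sets) {
      dir <- if (i %% 2L == 1L) "up" else "down"
      pool <- if (dir == "up") up_pool else down_pool
      # shrink the set rather than fail when the same-direction pool is
      # smaller than the drawn size demands; composition stays >= 80%
      sizes[i] <- min(sizes[i], floor(length(pool) / config$shifted_de_fraction))
      n_hit <- ceiling(config$shifted_de_fraction * sizes[i])
      if (n_hit < 4L || n_hit > length(pool))
        stop("generation error: shifted-set size exceeds the ",
             dir, "-regulated planted gene pool (", length(pool), ")")
      n_fill <- sizes[i] - n_hit
      if (n_fill > length(null_pool))
        stop("generation error: requested set size exceeds available gene pool")
      sets[[i]] <- unique(c(sample(pool, n_hit), sample(null_pool, n_fill)))
      directions <- c(directions, dir)
    } else {
      if (sizes[i] > length(null_pool))
        stop("generation error: requested set size exceeds available gene pool")
      sets[[i]] <- unique(sample(null_pool, sizes[i]))
    }
  }
  shifted <- data.frame(set_id = ids[seq_len(config$n_shifted_sets)],
                        direction = directions, stringsAsFactors = FALSE)
  list(sets = sets,
       descriptions = stats::setNames(
         ifelse(ids %in% shifted$set_id, "planted shifted set", "null set"), ids),
       shifted = shifted)
}

#' Simulate a three-source TF-target prior with planted master regulators
#'
#' Emits a long edge list tagged with three source databases (emulating
#' curated TF-target resources such as TRRUST, RegNetwork and DoRothEA),
#' with about 20% of edges duplicated across a second source to exercise
#' merging. Master TFs receive `2 * nonmaster_max_deg_targets + 2`
#' planted-DEG targets (first cell type); every non-master receives at
#' most `nonmaster_max_deg_targets`, so each master has strictly more
#' planted-DEG targets than any non-master.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of a [simulate_counts()] bundle.
#' @return list with `edges` (data.frame tf, target, mode, source; one row
#'   per source assertion), `master_tfs` (data.frame tf_id,
#'   n_deg_targets), and `sources` (the three source tags).
#' @export
simulate_prior_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tfs < 1L) stop("generation error: n_tfs must be positive")
  set.seed(config$seed + 2L)
  genes <- truth$gene_ids
  de <- truth$de_genes[[config$cell_types[1]]]
  sources <- c("trrust", "regnetwork", "dorothea")
  modes <- c("activation", "repression", "unknown")

  tfs <- sample(genes, config$n_tfs)
  masters <- tfs[seq_len(config$n_master_tfs)]
  master_load <- 2L * config$nonmaster_max_deg_targets + 2L
  if (master_load > nrow(de))
    stop("generation error: not enough planted DE genes to load master TFs")

  rows <- vector("list", config$n_tfs)
  n_deg_by_tf <- integer(config$n_tfs)
  for (i in seq_along(tfs)) {
    tf <- tfs[i]
    deg_pool <- setdiff(de$gene_id, tf)
    null_pool <- setdiff(genes, c(de$gene_id, tf))
    n_t <- sample(seq(config$targets_per_tf_range[1],
                      config$targets_per_tf_range[2]), 1L)
    n_deg <- if (tf %in% masters) master_load
             else sample(0:config$nonmaster_max_deg_targets, 1L)
    n_t <- max(n_t, n_deg)
    targets <- c(sample(deg_pool, n_deg),
                 sample(null_pool, n_t - n_deg))
    n_deg_by_tf[i] <- n_deg
    rows[[i]] <- data.frame(
      tf = tf, target = targets,
      mode = sample(modes, n_t, replace = TRUE, prob = c(0.45, 0.35, 0.20)),
      source = sample(sources, n_t, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)

  # duplicate ~20% of assertions into a second source (same mode)
  n_dup <- round(0.2 * nrow(edges))
  if (n_dup > 0) {
    di <- sample.int(nrow(edges), n_dup)
    dup <- edges[di, ]
    dup$source <- vapply(dup$source, function(s) sample(setdiff(sources, s), 1L), "")
    edges <- rbind(edges, dup)
  }
  edges <- edges[order(edges$tf, edges$target, edges$source), ]
  rownames(edges) <- NULL

  master_tab <- data.frame(tf_id = masters,
                           n_deg_targets = n_deg_by_tf[match(masters, tfs)],
                           stringsAsFactors = FALSE)
  stopifnot(all(master_tab$n_deg_targets >
                  max(c(0L, n_deg_by_tf[!(tfs %in% masters)]))))
  list(edges = edges, master_tfs = master_tab, sources = sources)
}

#' Simulate a qPCR Ct table for selected genes
#'
#' Ct values follow `base_ct(gene) - strain_effect + N(0, sd)`, where the
#' strain effect equals the gene's planted log2 fold change for samples of
#' the first strain, so a planted log2FC of L yields an expected
#' delta-delta-Ct of -L against the flat reference gene. Reactions are
#' emitted in duplicate wells.
#'
#' @param truth the `truth` element of a [simulate_counts()] bundle.
#' @param genes gene ids to assay (must exist in the simulated universe).
#' @param n_replicates biological replicates per group.
#' @param cell_type which cell type's planted truth to use (default first).
#' @param noise_sd Gaussian Ct noise in cycles (default from config).
#' @param reference_gene housekeeping gene id added to the table.
#' @param n_wells technical duplicate wells per reaction.
#' @param seed optional seed override (defaults to config seed + 3).
#' @return data.frame (gene_id, group, replicate, well, ct) with the
#'   reference gene id stored in attribute `reference_gene`.
#' @export
simulate_ct_table <- function(truth, genes, n_replicates = 3L,
                              cell_type = NULL, noise_sd = NULL,
                              reference_gene = "Gapdh", n_wells = 2L,
                              seed = NULL) {
  config <- truth$config
  if (is.null(cell_type)) cell_type <- config$cell_types[1]
  if (is.null(noise_sd)) noise_sd <- config$ct_noise_sd
  if (is.null(seed)) seed <- config$seed + 3L
  unknown <- setdiff(genes, truth$gene_ids)
  if (length(unknown) > 0)
    stop("lookup error: unknown gene(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)

  de <- truth$de_genes[[cell_type]]
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(genes, de$gene_id)
  lfc[hit] <- de$true_log2fc[match(hit, de$gene_id)]

  all_genes <- c(genes, reference_gene)
  base_ct <- stats::setNames(c(stats::runif(length(genes), 20, 28), 18), all_genes)
  lfc <- c(lfc, stats::setNames(0, reference_gene))

  grid <- expand.grid(well = seq_len(n_wells),
                      replicate = seq_len(n_replicates),
                      group = config$strains,
                      gene_id = all_genes,
                      stringsAsFactors = FALSE)
  eff <- ifelse(grid$group == config$strains[1], lfc[grid$gene_id], 0)
  grid$ct <- base_ct[grid$gene_id] - eff + stats::rnorm(nrow(grid), 0, noise_sd)
  out <- grid[, c("gene_id", "group", "replicate", "well", "ct")]
  attr(out, "reference_gene") <- reference_gene
  out
}

#' Simulate the complete synthetic study
#'
#' Convenience wrapper running [simulate_counts()], [simulate_gene_sets()],
#' [simulate_prior_network()] and [simulate_ct_table()] (on a small panel
#' of planted DE genes plus the reference gene) and assembling the ground
#' truth needed for recovery testing.
#'
#' @param config a [sim_config()].
#' @param n_qpcr_genes planted DE genes assayed by the simulated qPCR.
#' @return a `sim_bundle` list additionally carrying `gene_sets`,
#'   `prior`, `ct_table`, with `truth$shifted_sets` and `truth$master_tfs`
#'   filled in.
#' @export
simulate_dataset <- function(config, n_qpcr_genes = 4L) {
  bundle <- simulate_counts(config)
  gs <- simulate_gene_sets(config, bundle$truth)
  pr <- simulate_prior_network(config, bundle$truth)
  bundle$truth$shifted_sets <- gs$shifted
  bundle$truth$master_tfs <- pr$master_tfs
  bundle$gene_sets <- gs
  bundle$prior <- pr
  de1 <- bundle$truth$de_genes[[config$cell_types[1]]]
  panel <- utils::head(de1$gene_id, n_qpcr_genes)
  bundle$ct_table <- simulate_ct_table(bundle$truth, panel)
  bundle
}
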