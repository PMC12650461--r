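#' Read and write the workflow's tabular formats
#'
#' Plain TSV readers/writers for count matrices (gene_id + one column per
#' sample), gene lengths, sample tables, TF-target prior edge lists and
#' qPCR Ct tables, plus GMT gene-set collections and RNK ranked lists.
#'
#' @param path file path.
#' @param counts,x object to write.
#' @name workflow_io
NULL

#' @rdname workflow_io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname workflow_io
#' @export
write_gene_lengths_tsv <- function(x, path) {
  utils::write.table(data.frame(gene_id = names(x), length = unname(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_gene_lengths_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$length, df$gene_id)
}

#' @rdname workflow_io
#' @export
write_samples_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_samples_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description, tab-separated members.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname workflow_io
#' @export
write_rnk <- function(x, path) {
  utils::write.table(x[, c("gene_id", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_rnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "score"))
  df[order(-df$score, df$gene_id), , drop = FALSE]
}

#' @rdname workflow_io
#' @export
write_prior_edges_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_prior_edges_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname workflow_io
#' @export
write_ct_tsv <- function(x, path) {
  df <- cbind(x, reference_gene = attr(x, "reference_gene"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ref <- unique(df$reference_gene)
  df$reference_gene <- NULL
  attr(df, "reference_gene") <- ref[1]
  df
}

#' Write a provenance manifest for an analysis stage
#'
#' Records the seed, configuration snapshot and md5 checksums of the
#' stage's output files so a rerun can be verified byte-for-byte.
#'
#' @param dir run directory containing the outputs.
#' @param stage stage name.
#' @param seed integer seed used.
#' @param config list serialisable to JSON.
#' @param files character vector of file paths to checksum.
#' @export
write_manifest <- function(dir, stage, seed, config = list(), files = character(0)) {
  manifest <- list(
    stage = stage, seed = seed, config = config,
    r_version = as.character(getRversion()),
    checksums = as.list(tools::md5sum(files))
  )
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
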