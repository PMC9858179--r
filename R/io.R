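# File readers and writers for the pipeline's tabular formats. All are
# plain TSV/CSV round-trippable text; BED export converts the package's
# 1-based closed intervals to BED's 0-based half-open convention.

#' Read a marker map TSV (`marker  chrom  pos_bp`)
#'
#' @param path File path.
#' @return A validated `marker_map`.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("empty marker map file: ", path)
  load_marker_map(df)
}

#' @rdname read_marker_map
#' @param map A `marker_map` to write.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix TSV plus line-metadata sidecar
#'
#' The genotype file has a `line` column followed by one column per
#' marker with cells `SC`, `PS` or `NA`; the sidecar has columns
#' `line  class  n_replicates  lenient`.
#'
#' @param path Genotype TSV path.
#' @param meta_path Line metadata TSV path.
#' @param map The `marker_map` the calls refer to.
#' @return An `introgression_map`.
#' @export
read_genotypes <- function(path, meta_path, map) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  if (!"line" %in% names(g)) stop("genotype file needs a 'line' column")
  calls <- as.matrix(g[setdiff(names(g), "line")])
  rownames(calls) <- g$line
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  introgression_map(map, calls, meta)
}

#' Read a replicate-level abundance CSV
#'
#' First column sample id, second column line id, remaining columns trait
#' abundances.
#'
#' @param path CSV path.
#' @return List `abundance` (matrix samples x traits), `sample_line`.
#' @export
read_abundance <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 3)
    stop("abundance file needs sample, line and at least one trait column: ",
         path)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric abundance value in ", path)
  rownames(mat) <- as.character(df[[1]])
  list(abundance = mat, sample_line = as.character(df[[2]]))
}

#' @rdname read_abundance
#' @param abundance Samples x traits matrix.
#' @param sample_line Line of each sample.
#' @export
write_abundance <- function(abundance, sample_line, path) {
  df <- data.frame(sample = rownames(abundance), line = sample_line,
                   as.data.frame(abundance, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a significance-pattern TSV
#'
#' Columns: `trait` then one column per line with entries -1/0/+1.
#'
#' @param path TSV path.
#' @return Integer matrix traits x lines.
#' @export
read_patterns <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"trait" %in% names(df)) stop("pattern file needs a 'trait' column")
  m <- as.matrix(df[setdiff(names(df), "trait")])
  if (!all(m %in% c(-1L, 0L, 1L)))
    stop("pattern entries must be -1, 0 or +1")
  storage.mode(m) <- "integer"
  rownames(m) <- df$trait
  m
}

#' @rdname read_patterns
#' @param patterns Integer matrix traits x lines.
#' @export
write_patterns <- function(patterns, path) {
  df <- data.frame(trait = rownames(patterns),
                   as.data.frame(patterns, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QTL call table as TSV
#'
#' @param calls QTL-call data.frame.
#' @param path Output path.
#' @export
write_qtl_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export intervals as BED (0-based half-open)
#'
#' @param chrom Chromosome label (recycled).
#' @param left_pos,right_pos 1-based closed interval bounds.
#' @param name Feature names.
#' @param path Output path.
#' @return The BED lines, invisibly (also written when `path` given).
#' @export
write_bed <- function(chrom, left_pos, right_pos, name, path = NULL) {
  df <- data.frame(chrom = chrom, start = as.integer(left_pos) - 1L,
                   end = as.integer(right_pos), name = name,
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(df)
}

#' Export a correlation network as an edge list (and optionally GraphML)
#'
#' @param net Result of [cna_groups()].
#' @param path Edge-list TSV path (`trait_a  trait_b  r`).
#' @param graphml Optional GraphML output path.
#' @export
write_edge_list <- function(net, path, graphml = NULL) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
    igraph::E(g)$r <- net$edges$r
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (via `ape::as.phylo`).
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a QTL summary as JSON
#'
#' @param summary Named list from [summarize_qtl_table()].
#' @param path Output path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
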