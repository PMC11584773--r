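# TSV / GraphML / JSON input-output. All floats are written with 9 decimal
# places so correlation values round-trip exactly at the precision used in
# neighbor tables; the unicode minus sign (U+2212) is normalized to ASCII
# on every numeric parse. Files ending in ".gz" are compressed
# transparently on both read and write.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sub("\\.?0+$", "", sprintf("%.9f", v))
  }, character(1))
  out
}

#' Parse numbers that may use the unicode minus sign
#'
#' @param x Character vector.
#' @return Numeric vector; U+2212 is treated as ASCII "-".
#' @export
parse_numeric <- function(x) {
  as.numeric(gsub("−", "-", x))
}

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write / read a multi-omics feature matrix as TSV
#'
#' Layout: one row per feature; columns `feature_id`, `layer`, then one
#' column per sample. Missing abundances are written as `NA` (empty cells
#' are also accepted on read).
#'
#' @param x An [omics_matrix()].
#' @param path Output TSV path (`.gz` for gzip).
#' @return `write_omics_matrix`: the path, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(
    feature_id = x$features$feature_id,
    layer = x$features$layer,
    stringsAsFactors = FALSE
  )
  vals <- x$abundance
  for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <- fmt_num(vals[, j])
  con <- open_conn(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_matrix
#' @param samples The sample table the matrix columns refer to.
#' @return `read_omics_matrix`: an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, samples) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  ab <- as.matrix(as.data.frame(
    lapply(df[, -(1:2), drop = FALSE],
           function(col) parse_numeric(as.character(col))),
    check.names = FALSE
  ))
  rownames(ab) <- df$feature_id
  omics_matrix(ab, df$layer, samples)
}

#' Write / read a sample table as TSV
#'
#' @param samples A [sample_table()].
#' @param path TSV path.
#' @export
write_sample_table <- function(samples, path) {
  samples <- validate_sample_table(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Write / read a correlation edge table as TSV
#'
#' Columns `feature_a`, `feature_b`, `rho`; rho printed with 9 decimals.
#'
#' @param edges Data.frame from [all_pairs_correlations()].
#' @param path TSV path (`.gz` for gzip).
#' @export
write_edges <- function(edges, path) {
  df <- data.frame(feature_a = edges$feature_a, feature_b = edges$feature_b,
                   rho = fmt_num(edges$rho), stringsAsFactors = FALSE)
  con <- open_conn(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$rho <- parse_numeric(as.character(df$rho))
  class(df) <- c("correlation_edges", "data.frame")
  df
}

#' Export a correlation network as GraphML
#'
#' Vertex attributes `name` (feature id) and `layer` (when present), edge
#' attributes `rho`, `weight` and `sign` are preserved.
#'
#' @param graph An `igraph` graph from [build_graph()].
#' @param path Output `.graphml` path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a packaged or exported neighbor table
#'
#' Parses a TSV of direct-neighbor correlations (columns `feature_id`,
#' optional `annotation` / `node_type`, and `rho`). Numbers using the
#' typographic minus sign are normalized. The package ships such a table at
#' `system.file("extdata", "sco2_neighbors_table2.tsv", package = "hubnet")`:
#' the published direct neighbors of the SCO2 transcript in the tomato
#' multi-omics network at the 0.95 threshold.
#'
#' @param path TSV path.
#' @return Data.frame with at least `feature_id` and numeric `rho`.
#' @export
read_neighbor_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = character(0), fileEncoding = "UTF-8")
  if (!all(c("feature_id", "rho") %in% names(df)))
    stop("neighbor table needs columns feature_id and rho")
  df$rho <- parse_numeric(as.character(df$rho))
  df
}

#' Turn a neighbor table into focal-feature edges
#'
#' @param neighbors Data.frame from [read_neighbor_table()].
#' @param focal_id Id to use for the focal feature.
#' @return A `correlation_edges` data.frame linking `focal_id` to every
#'   neighbor.
#' @export
neighbor_edges <- function(neighbors, focal_id) {
  a <- pmin(focal_id, neighbors$feature_id)
  b <- pmax(focal_id, neighbors$feature_id)
  out <- data.frame(feature_a = a, feature_b = b, rho = neighbors$rho,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_edges", "data.frame")
  out
}
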