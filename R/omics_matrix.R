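`%||%` <- function(a, b) if (is.null(a)) b else a

#' Layers recognised in a multi-omics feature matrix
#'
#' @return Character vector of valid layer names.
#' @export
omics_layers <- function() {
  c("transcript", "protein", "metab_primary", "metab_secondary", "metab_lipid")
}

#' Construct a multi-omics feature-by-sample matrix
#'
#' The central container of the package: a numeric abundance matrix (features
#' in rows, samples in columns) together with a per-feature layer assignment
#' and the sample table. Abundances are non-negative where observed; `NA`
#' encodes a missing measurement (typical for protein intensities below the
#' detection limit).
#'
#' @param abundance Numeric matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids). Values must be non-negative or
#'   `NA`.
#' @param layer Character vector, one layer per feature (see
#'   [omics_layers()]), recycled if length 1.
#' @param samples A sample table as returned by [sample_table()]; its
#'   `sample_id` column must equal `colnames(abundance)`.
#' @return An object of class `omics_matrix`: a list with elements
#'   `abundance`, `features` (data.frame of `feature_id`, `layer`) and
#'   `samples`.
#' @export
omics_matrix <- function(abundance, layer, samples) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("`abundance` must be a numeric matrix")
  if ((nrow(abundance) > 0L && is.null(rownames(abundance))) ||
      is.null(colnames(abundance)))
    stop("`abundance` needs feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(abundance)))
    stop("feature ids must be unique across layers")
  if (length(layer) == 1L) layer <- rep(layer, nrow(abundance))
  if (length(layer) != nrow(abundance))
    stop("`layer` must have one entry per feature")
  bad <- setdiff(unique(layer), omics_layers())
  if (length(bad))
    stop("unknown layer(s): ", paste(bad, collapse = ", "))
  samples <- validate_sample_table(samples)
  if (!identical(colnames(abundance), samples$sample_id))
    stop("column names of `abundance` must equal samples$sample_id (same order)")
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative where present")
  structure(
    list(
      abundance = abundance,
      features = data.frame(
        feature_id = rownames(abundance) %||% character(0),
        layer = as.character(layer),
        stringsAsFactors = FALSE
      ),
      samples = samples
    ),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  tab <- table(x$features$layer)
  cat(sprintf(
    "omics_matrix: %d features x %d samples\n",
    nrow(x$abundance), ncol(x$abundance)
  ))
  cat("  layers:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$abundance))
  cat(sprintf("  missing entries: %d (%.1f%%)\n",
              nmiss, 100 * nmiss / length(x$abundance)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$abundance)

#' Subset an omics matrix by features
#'
#' @param x An `omics_matrix`.
#' @param features Character vector of feature ids (or logical/integer index
#'   over rows).
#' @return An `omics_matrix` restricted to the requested features.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "omics_matrix"))
  ab <- x$abundance[features, , drop = FALSE]
  omics_matrix(ab, x$features$layer[match(rownames(ab), x$features$feature_id)],
               x$samples)
}
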