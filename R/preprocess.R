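# Matrix preprocessing: half-minimum imputation of missing intensities and
# normalization to wild-type reference samples.

#' Half-minimum imputation of missing values
#'
#' For every feature in the selected layers, missing entries are replaced by
#' half the minimum of that feature's observed entries — the usual
#' left-censoring heuristic for intensities below the detection limit.
#' Features with no observed entry at all cannot be imputed and are dropped;
#' their ids are recorded in the `dropped_features` attribute. Other layers
#' pass through untouched. Zeros count as observed; use
#' `zero_as_missing = TRUE` to first recode zeros to missing (useful for
#' count matrices where zero means "not detected").
#'
#' @param x An [omics_matrix()].
#' @param layers Layers to impute; default `"protein"`.
#' @param zero_as_missing Recode 0 to missing in the selected layers before
#'   imputing.
#' @return An `omics_matrix` with no missing entries in the selected layers;
#'   attribute `dropped_features` holds ids of all-missing features.
#' @export
half_min_impute <- function(x, layers = "protein", zero_as_missing = FALSE) {
  stopifnot(inherits(x, "omics_matrix"))
  layers <- match.arg(layers, omics_layers(), several.ok = TRUE)
  ab <- x$abundance
  sel <- which(x$features$layer %in% layers)
  dropped <- character(0)
  for (i in sel) {
    row <- ab[i, ]
    if (zero_as_missing) row[row == 0] <- NA_real_
    obs <- row[!is.na(row)]
    if (!length(obs)) {
      dropped <- c(dropped, x$features$feature_id[i])
      next
    }
    row[is.na(row)] <- min(obs) / 2
    ab[i, ] <- row
  }
  if (length(dropped)) {
    keep <- setdiff(rownames(ab), dropped)
    ab <- ab[keep, , drop = FALSE]
    message(length(dropped), " all-missing feature(s) dropped during imputation")
  }
  out <- omics_matrix(ab,
                      x$features$layer[match(rownames(ab), x$features$feature_id)],
                      x$samples)
  attr(out, "dropped_features") <- dropped
  out
}

#' Normalize features to a reference sample set
#'
#' Divides each feature by the arithmetic mean of its values over the
#' reference samples (typically the wild-type samples, see
#' [reference_samples()]), expressing every abundance as a ratio to the
#' reference. Features whose reference mean is zero or entirely missing are
#' dropped and recorded in the `dropped_features` attribute.
#'
#' @param x An [omics_matrix()].
#' @param reference_sample_ids Non-empty character vector of sample ids,
#'   a subset of the matrix's samples.
#' @return A normalized `omics_matrix` with attribute `dropped_features`.
#' @export
normalize_to_reference <- function(x, reference_sample_ids) {
  stopifnot(inherits(x, "omics_matrix"))
  if (!length(reference_sample_ids))
    stop("reference sample set must be non-empty")
  bad <- setdiff(reference_sample_ids, x$samples$sample_id)
  if (length(bad))
    stop("unknown reference sample(s): ", paste(bad, collapse = ", "))
  ab <- x$abundance
  ref_mean <- rowMeans(ab[, reference_sample_ids, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(ref_mean) & ref_mean > 0
  dropped <- rownames(ab)[!ok]
  if (length(dropped))
    message(length(dropped),
            " feature(s) with zero/missing reference mean dropped")
  ab <- ab[ok, , drop = FALSE] / ref_mean[ok]
  out <- omics_matrix(ab,
                      x$features$layer[match(rownames(ab), x$features$feature_id)],
                      x$samples)
  attr(out, "dropped_features") <- dropped
  out
}
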