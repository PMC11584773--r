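#' Build a sample table
#'
#' Describes the experimental design: one row per sample with genotype
#' (wildtype vs mutant), tissue and replicate number. The default layout
#' reproduces the 15-sample multi-omics design of the variegated tomato
#' study this package models: five genotype-by-tissue groups (wildtype has
#' no white-leaf tissue) with three biological replicates each.
#'
#' @param genotype,tissue,replicate Vectors of equal length; genotype in
#'   `{"wildtype","mutant"}`, tissue in `{"green_leaf","white_leaf","stem"}`,
#'   replicate a positive integer within each group. If all are `NULL` the
#'   default 15-sample design is returned.
#' @param sample_id Optional sample ids; auto-generated from group and
#'   replicate when `NULL`.
#' @return A data.frame with columns `sample_id`, `genotype`, `tissue`,
#'   `replicate`, classed `sample_table`.
#' @examples
#' sample_table()  # the 5 groups x 3 replicates design
#' @export
sample_table <- function(genotype = NULL, tissue = NULL, replicate = NULL,
                         sample_id = NULL) {
  if (is.null(genotype) && is.null(tissue) && is.null(replicate)) {
    groups <- data.frame(
      genotype = c("mutant", "mutant", "mutant", "wildtype", "wildtype"),
      tissue = c("white_leaf", "green_leaf", "stem", "green_leaf", "stem"),
      stringsAsFactors = FALSE
    )
    genotype <- rep(groups$genotype, each = 3L)
    tissue <- rep(groups$tissue, each = 3L)
    replicate <- rep(1:3, times = nrow(groups))
  }
  n <- length(genotype)
  if (length(tissue) != n || length(replicate) != n)
    stop("genotype, tissue and replicate must have equal length")
  if (is.null(sample_id)) {
    abbr <- c(wildtype = "wt", mutant = "mu")
    tabbr <- c(green_leaf = "gl", white_leaf = "wl", stem = "st")
    sample_id <- paste0(abbr[genotype], "_", tabbr[tissue], "_", replicate)
  }
  out <- data.frame(
    sample_id = as.character(sample_id),
    genotype = as.character(genotype),
    tissue = as.character(tissue),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_table", "data.frame")
  validate_sample_table(out)
}

validate_sample_table <- function(samples) {
  if (!is.data.frame(samples))
    stop("`samples` must be a data.frame (see sample_table())")
  need <- c("sample_id", "genotype", "tissue", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("sample_id must be unique")
  if (!all(samples$genotype %in% c("wildtype", "mutant")))
    stop("genotype must be 'wildtype' or 'mutant'")
  if (!all(samples$tissue %in% c("green_leaf", "white_leaf", "stem")))
    stop("tissue must be one of green_leaf, white_leaf, stem")
  if (any(samples$replicate < 1L))
    stop("replicate must be a positive integer")
  grp <- table(paste(samples$genotype, samples$tissue))
  if (any(grp < 2L))
    stop("every (genotype, tissue) group present must have >= 2 replicates")
  if (!inherits(samples, "sample_table"))
    class(samples) <- c("sample_table", "data.frame")
  samples
}

#' Sample ids of the reference (wild-type) samples
#'
#' @param samples A sample table.
#' @param genotype Which genotype serves as reference; default `"wildtype"`.
#' @return Character vector of sample ids.
#' @export
reference_samples <- function(samples, genotype = "wildtype") {
  samples <- validate_sample_table(samples)
  samples$sample_id[samples$genotype == genotype]
}
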