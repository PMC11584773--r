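# Exact tie-aware Spearman correlation over all feature pairs, blocked for
# memory, with streaming absolute-value prefiltering.

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-fractional ranks, computed from first
#' principles so ties are handled exactly. For tie-free inputs this equals
#' the classical \eqn{1 - 6\sum d^2 / (n(n^2-1))}.
#'
#' @param x,y Numeric vectors of equal length >= 3 with no missing values.
#' @return The correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(1:10, (1:10)^3)  # 1: monotone transform invariance
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed; impute first")
  rx <- rank(x)
  ry <- rank(y)
  rx <- rx - mean(rx)
  ry <- ry - mean(ry)
  den <- sqrt(sum(rx^2) * sum(ry^2))
  if (den == 0)
    stop("zero-variance input: Spearman correlation undefined")
  max(-1, min(1, sum(rx * ry) / den))
}

#' All-pairs Spearman correlations with prefiltering, blocked for memory
#'
#' Each feature row is rank-transformed once (average ranks for ties) and
#' standardized; correlations are then block inner products of the
#' standardized rank rows, which is exact and keeps peak memory at
#' O(block_size * (n_samples + block_size)) rather than quadratic in the
#' feature count. Pairs with `|rho| >= prefilter` are emitted once, in
#' canonical order (`feature_a < feature_b` lexicographically). Features
#' with zero rank variance (constant rows) cannot carry a correlation and
#' are skipped; their count is reported via the `skipped_zero_variance`
#' attribute.
#'
#' @param x An [omics_matrix()] (fully imputed) or a plain numeric matrix
#'   with feature rownames.
#' @param prefilter Keep pairs with `|rho| >=` this value (inclusive, per
#'   the "values below the threshold are filtered out" convention);
#'   in `[0, 1)`. Default 0.75.
#' @param block_size Number of features per block; >= 1. Default 256.
#' @return Data.frame of class `correlation_edges` with columns
#'   `feature_a`, `feature_b`, `rho`, ordered block-by-block (consumers
#'   must not rely on global order). Attribute `skipped_zero_variance`
#'   counts skipped constant features; attribute `n_samples` records n.
#' @export
all_pairs_correlations <- function(x, prefilter = 0.75, block_size = 256L) {
  if (inherits(x, "omics_matrix")) x <- x$abundance
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (is.null(rownames(x))) stop("x needs feature ids as rownames")
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  if (ncol(x) < 3L) stop("need at least 3 samples")
  if (prefilter < 0 || prefilter >= 1) stop("prefilter must be in [0, 1)")
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be >= 1")

  # rank-transform rows once, then standardize to unit sum of squares
  r <- t(apply(x, 1L, rank))
  r <- r - rowMeans(r)
  ss <- rowSums(r^2)
  skipped <- sum(ss == 0)
  keep <- ss > 0
  r <- r[keep, , drop = FALSE] / sqrt(ss[keep])
  ids <- rownames(r)
  n_f <- nrow(r)

  starts <- seq(1L, max(n_f, 1L), by = block_size)
  res <- vector("list", 0L)
  if (n_f >= 2L) {
    for (bi in seq_along(starts)) {
      i0 <- starts[bi]
      i1 <- min(i0 + block_size - 1L, n_f)
      Ri <- r[i0:i1, , drop = FALSE]
      for (bj in bi:length(starts)) {
        j0 <- starts[bj]
        j1 <- min(j0 + block_size - 1L, n_f)
        Rj <- r[j0:j1, , drop = FALSE]
        rho <- tcrossprod(Ri, Rj)
        pass <- abs(rho) >= prefilter
        if (bi == bj) pass <- pass & upper.tri(rho)
        if (!any(pass)) next
        idx <- which(pass, arr.ind = TRUE)
        ia <- ids[i0 - 1L + idx[, 1L]]
        ib <- ids[j0 - 1L + idx[, 2L]]
        vals <- pmax(-1, pmin(1, rho[idx]))
        swap <- ia > ib
        tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
        res[[length(res) + 1L]] <-
          data.frame(feature_a = ia, feature_b = ib, rho = vals,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(feature_a = character(0), feature_b = character(0),
               rho = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("correlation_edges", "data.frame")
  attr(out, "skipped_zero_variance") <- skipped
  attr(out, "n_samples") <- ncol(x)
  attr(out, "prefilter") <- prefilter
  out
}
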