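# One-sample Wilcoxon signed-rank machinery for the hub test: exact
# tie-aware null distribution (dynamic programming over doubled ranks) and
# the Hodges-Lehmann pseudo-median.

# Exact pmf of the positive-rank sum W+ for given |difference| ranks.
# Average ranks may be half-integers, so everything is doubled to stay on
# an integer lattice: returns list(support = possible 2*W values implicitly
# 0..sum(r2), pmf). Null: each sign independently +/- with prob 1/2.
signed_rank_pmf <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), pmf[seq_len(total + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf # index i corresponds to 2*W = i - 1
}

# Normal approximation with continuity correction on the true W lattice
# (tied average ranks shift the support to a finer grid) and a fourth-
# cumulant Edgeworth term; W is symmetric under H0 so the skewness term
# vanishes. Variance incorporates the usual tie correction implicitly via
# sum(r^2).
signed_rank_approx_p <- function(w, ranks) {
  gcd_vec <- function(v) Reduce(function(a, b) {
    while (b) {t <- a %% b; a <- b; b <- t}; a
  }, v)
  mu <- sum(ranks) / 2
  s2 <- sum(ranks^2) / 4
  s <- sqrt(s2)
  delta <- gcd_vec(as.integer(round(2 * ranks))) / 2 # lattice spacing of W
  g2 <- (-sum(ranks^4) / 8) / s2^2                   # excess kurtosis
  Fw <- function(x) {
    z <- (x + delta / 2 - mu) / s
    if (abs(z) > 8) return(stats::pnorm(z)) # correction is noise out here
    stats::pnorm(z) - stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z)
  }
  lo <- max(Fw(w), 0)
  hi <- max(1 - Fw(w - delta), 0)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided p for observed W+ given |difference| ranks.
signed_rank_exact_p <- function(w, ranks) {
  pmf <- signed_rank_pmf(ranks)
  w2 <- round(2 * w)
  lo <- sum(pmf[seq_len(w2 + 1L)])            # P(W <= w)
  hi <- sum(pmf[(w2 + 1L):length(pmf)])       # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' One-sample Wilcoxon signed-rank test against a fixed location
#'
#' Tests whether values are symmetric about `mu`. Zero differences are
#' dropped; tied absolute differences receive average ranks. For up to
#' `exact_limit` nonzero differences the exact null distribution of the
#' positive-rank sum is computed by dynamic programming (valid under ties,
#' where the textbook tables are not); beyond that a normal approximation
#' with tie correction, lattice-aware continuity correction and an
#' Edgeworth kurtosis term is used.
#'
#' @param values Numeric vector.
#' @param mu Null location.
#' @param exact_limit Maximum number of nonzero differences for the exact
#'   branch; default 25.
#' @return List with `W` (positive-rank sum), `p` (two-sided), `n_used`
#'   (nonzero differences) and `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(values, mu, exact_limit = 25L) {
  d <- values - mu
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero: signed-rank test undefined",
         call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(W, r)
    exact <- TRUE
  } else {
    p <- signed_rank_approx_p(W, r)
    exact <- FALSE
  }
  list(W = W, p = min(1, p), n_used = n, exact = exact)
}

#' Hodges-Lehmann pseudo-median
#'
#' The median of all Walsh averages \eqn{(x_i + x_j)/2, i \le j} — the
#' location estimand of the one-sample Wilcoxon signed-rank test. Computed
#' exactly up to `exact_limit` observations; beyond that from a fixed-seed
#' subsample of Walsh averages.
#'
#' @param x Numeric vector.
#' @param exact_limit Largest n for the exact (all-pairs) computation;
#'   default 2000.
#' @param subsample_pairs Number of Walsh averages drawn when subsampling.
#' @return The pseudo-median.
#' @export
hodges_lehmann <- function(x, exact_limit = 2000L, subsample_pairs = 2e6) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("no data")
  if (n <= exact_limit) {
    w <- outer(x, x, "+")[upper.tri(diag(n), diag = TRUE)] / 2
    return(stats::median(w))
  }
  local_seed(181181L, {
    i <- sample.int(n, subsample_pairs, replace = TRUE)
    j <- sample.int(n, subsample_pairs, replace = TRUE)
    stats::median((x[i] + x[j]) / 2)
  })
}

#' Test whether a focal feature is a network hub
#'
#' Compares the focal feature's centrality with the distribution of the
#' same metric over all other nodes: a one-sample Wilcoxon signed-rank
#' test of the non-focal values against the focal value, plus the
#' Hodges-Lehmann pseudo-median of the non-focal values. `direction`
#' reports whether the focal value lies above or below that pseudo-median
#' (`"none"` when they coincide, as for a perfectly symmetric network).
#'
#' @param metrics Data.frame from [node_metrics()].
#' @param focal_id Feature id of the focal node; must be present, with at
#'   least 10 non-focal nodes.
#' @param metric One of `"degree"`, `"closeness"`, `"betweenness"`.
#' @return List of class `hub_test` with fields `focal_id`, `metric`,
#'   `focal_value`, `network_pseudomedian`, `W`, `p`, `direction`,
#'   `n_nonfocal` and `exact`.
#' @export
hub_test <- function(metrics, focal_id,
                     metric = c("degree", "closeness", "betweenness")) {
  metric <- match.arg(metric)
  if (!focal_id %in% metrics$feature_id)
    stop("focal feature '", focal_id, "' not in metrics table")
  focal_value <- metrics[[metric]][metrics$feature_id == focal_id]
  others <- metrics[[metric]][metrics$feature_id != focal_id]
  if (length(others) < 10L)
    stop("need at least 10 non-focal nodes for the hub test")
  test <- wilcoxon_signed_rank(others, mu = focal_value)
  pm <- hodges_lehmann(others)
  tol <- sqrt(.Machine$double.eps) * max(1, abs(focal_value), abs(pm))
  direction <- if (abs(focal_value - pm) <= tol) "none" else
    if (focal_value > pm) "above" else "below"
  structure(
    list(
      focal_id = focal_id, metric = metric, focal_value = focal_value,
      network_pseudomedian = pm, W = test$W, p = test$p,
      direction = direction, n_nonfocal = length(others),
      exact = test$exact
    ),
    class = "hub_test"
  )
}

#' @export
print.hub_test <- function(x, ...) {
  cat(sprintf(
    "hub test (%s): focal '%s' = %.6g vs network pseudo-median %.6g\n",
    x$metric, x$focal_id, x$focal_value, x$network_pseudomedian
  ))
  cat(sprintf("  Wilcoxon signed-rank W = %.1f, p = %.4g (%s, n = %d), direction: %s\n",
              x$W, x$p, if (x$exact) "exact" else "normal approx.",
              x$n_nonfocal, x$direction))
  invisible(x)
}
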