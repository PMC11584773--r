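# Synthetic multi-omics data with a planted correlated hub module, plus
# deterministic rank fixtures for exact Spearman checks.

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Parameterization of a synthetic multi-omics study
#'
#' Fully describes a simulated dataset: feature budget per omics layer,
#' between-group and residual variation on the log scale, and the planted
#' hub module — a set of features sharing a per-sample latent factor with
#' the focal feature, a fraction of them with negative sign. All randomness
#' flows from `seed`.
#'
#' Defaults reproduce the study conditions the package validates against:
#' a hub of 29 members around the focal transcript, 6/29 of them negatively
#' correlated, with loading 0.99 and residual log-sd 0.05 across the
#' 15-sample design of [sample_table()].
#'
#' @param n_features_per_layer Named integer vector, features per layer.
#' @param group_effect_sd Sd (log scale) of genotype-by-tissue group effects;
#'   non-negative.
#' @param noise_sd Residual sd on the log scale; positive.
#' @param hub_size Number of hub-module members (excluding the focal
#'   feature itself).
#' @param hub_negative_fraction Fraction of members loading negatively.
#' @param hub_loading Loading in `[0, 1]` of members on the latent factor;
#'   controls the expected absolute correlation between the focal feature
#'   and module members.
#' @param protein_missing_quantile Per-feature quantile below which protein
#'   abundances are censored to missing (left-censoring); in `[0, 1)`.
#' @param focal_feature_id Id given to the focal (hub-seed) transcript.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_features_per_layer = c(
                             transcript = 300L, protein = 150L,
                             metab_primary = 50L, metab_secondary = 50L,
                             metab_lipid = 50L
                           ),
                           group_effect_sd = 1,
                           noise_sd = 0.05,
                           hub_size = 29L,
                           hub_negative_fraction = 6 / 29,
                           hub_loading = 0.99,
                           protein_missing_quantile = 0.2,
                           focal_feature_id = "tr_focal",
                           seed = 1L) {
  bad <- setdiff(names(n_features_per_layer), omics_layers())
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  if (group_effect_sd < 0) stop("group_effect_sd must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (hub_size < 1) stop("hub_size must be >= 1")
  if (hub_negative_fraction < 0 || hub_negative_fraction > 1)
    stop("hub_negative_fraction must be in [0, 1]")
  if (hub_loading < 0 || hub_loading > 1)
    stop("hub_loading must be in [0, 1]")
  if (protein_missing_quantile < 0 || protein_missing_quantile >= 1)
    stop("protein_missing_quantile must be in [0, 1)")
  if (hub_size > sum(n_features_per_layer))
    stop("hub_size exceeds the total feature budget")
  structure(
    list(
      n_features_per_layer = n_features_per_layer,
      group_effect_sd = group_effect_sd,
      noise_sd = noise_sd,
      hub_size = as.integer(hub_size),
      hub_negative_fraction = hub_negative_fraction,
      hub_loading = hub_loading,
      protein_missing_quantile = protein_missing_quantile,
      focal_feature_id = focal_feature_id,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

layer_prefix <- c(
  transcript = "tr", protein = "pr", metab_primary = "mp",
  metab_secondary = "ms", metab_lipid = "ml"
)

#' Generate a synthetic multi-omics dataset with a planted hub
#'
#' Log-abundances are Gaussian: per-feature baseline plus a genotype-by-
#' tissue group effect plus residual noise; abundance is the exponential.
#' The focal transcript carries a per-sample latent factor; each hub-module
#' member (also transcripts) replaces its group effect with
#' `sign * (hub_loading * factor + sqrt(1 - hub_loading^2) * idiosyncratic)`,
#' so that the focal-member correlation is approximately `hub_loading` while
#' member-member correlation is approximately `hub_loading^2` — the focal
#' feature, not the module clique, is the degree hub. Protein values below
#' the per-feature `protein_missing_quantile` are censored to `NA`
#' (missing-at-low-abundance).
#'
#' @param spec A [synthetic_spec()].
#' @param samples A [sample_table()]; defaults to the 15-sample design.
#' @return An [omics_matrix()]; attribute `hub_members` lists the planted
#'   member ids and attribute `hub_signs` their signs.
#' @examples
#' m <- generate_multiomics(synthetic_spec(seed = 42))
#' m
#' @export
generate_multiomics <- function(spec, samples = sample_table()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  samples <- validate_sample_table(samples)
  n_s <- nrow(samples)
  if (n_s == 0L) stop("`samples` must be nonempty")
  if (spec$n_features_per_layer[["transcript"]] < spec$hub_size + 1L)
    stop("transcript layer too small for focal feature + hub_size members")

  ids <- character(0)
  layers <- character(0)
  for (ly in names(spec$n_features_per_layer)) {
    k <- spec$n_features_per_layer[[ly]]
    if (k <= 0) next
    ids_ly <- sprintf("%s_%04d", layer_prefix[[ly]], seq_len(k))
    if (ly == "transcript") ids_ly[1L] <- spec$focal_feature_id
    ids <- c(ids, ids_ly)
    layers <- c(layers, rep(ly, k))
  }
  if (anyDuplicated(ids))
    stop("focal_feature_id collides with an auto-generated feature id")

  n_f <- length(ids)
  grp <- paste(samples$genotype, samples$tissue)
  grp_idx <- match(grp, unique(grp))
  n_g <- max(grp_idx)

  local_seed(spec$seed, {
    baseline <- stats::rnorm(n_f, mean = 5, sd = 1)
    group_eff <- matrix(stats::rnorm(n_f * n_g, sd = spec$group_effect_sd),
                        nrow = n_f)
    noise <- matrix(stats::rnorm(n_f * n_s, sd = spec$noise_sd), nrow = n_f)
    z <- stats::rnorm(n_s) # per-sample latent hub factor

    logab <- baseline + group_eff[, grp_idx, drop = FALSE] + noise

    # plant the module: focal transcript and hub_size further transcripts
    focal_row <- match(spec$focal_feature_id, ids)
    member_rows <- which(layers == "transcript")
    member_rows <- setdiff(member_rows, focal_row)[seq_len(spec$hub_size)]
    n_neg <- round(spec$hub_negative_fraction * spec$hub_size)
    signs <- rep(1, spec$hub_size)
    if (n_neg > 0) signs[sample.int(spec$hub_size, n_neg)] <- -1

    logab[focal_row, ] <- baseline[focal_row] + z + noise[focal_row, ]
    resid_load <- sqrt(1 - spec$hub_loading^2)
    for (j in seq_along(member_rows)) {
      u <- stats::rnorm(n_s)
      logab[member_rows[j], ] <- baseline[member_rows[j]] +
        signs[j] * (spec$hub_loading * z + resid_load * u) +
        noise[member_rows[j], ]
    }

    ab <- exp(logab)
    dimnames(ab) <- list(ids, samples$sample_id)

    # left-censor the protein layer
    if (spec$protein_missing_quantile > 0) {
      prot <- which(layers == "protein")
      for (i in prot) {
        cut <- stats::quantile(ab[i, ], probs = spec$protein_missing_quantile,
                               names = FALSE)
        ab[i, ab[i, ] < cut] <- NA_real_
      }
    }

    out <- omics_matrix(ab, layers, samples)
    attr(out, "hub_members") <- ids[member_rows]
    attr(out, "hub_signs") <- signs
    out
  })
}

#' Construct a tie-free rank pair with an exact squared rank-difference sum
#'
#' Returns two permutations of `1..n` whose Spearman rank-difference
#' statistic \eqn{\sum d_i^2} equals `target_d2` exactly, so that the
#' classical identity \eqn{\rho = 1 - 6\sum d^2 / (n(n^2-1))} can be probed
#' at chosen grid points. The pair is found by a complete depth-first
#' assignment search with rearrangement-inequality bounds and parity
#' pruning, so every feasible target is reached and infeasible targets
#' raise an error.
#'
#' @param n Length of the permutations (>= 2).
#' @param target_d2 Requested \eqn{\sum d^2}; must be even and within
#'   `[0, n(n^2-1)/3]`.
#' @return List of class `rank_pair` with `ranks_a` (identity), `ranks_b`
#'   and `d2_sum`.
#' @examples
#' p <- generate_rank_pair(15, 14)
#' spearman_rho(p$ranks_a, p$ranks_b)  # 1 - 6*14/(15*224) = 0.975
#' @export
generate_rank_pair <- function(n, target_d2) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  max_d2 <- n * (n^2 - 1) / 3
  if (target_d2 %% 2 != 0)
    stop("target_d2 must be even (sum of squared rank differences always is)")
  if (target_d2 < 0 || target_d2 > max_d2)
    stop(sprintf("target_d2 must lie in [0, %d]", as.integer(max_d2)))

  b <- rank_pair_search(n, as.integer(target_d2))
  if (is.null(b))
    stop(sprintf("no permutation of 1..%d attains sum(d^2) = %d", n, target_d2))
  structure(
    list(ranks_a = seq_len(n), ranks_b = b,
         d2_sum = sum((seq_len(n) - b)^2)),
    class = "rank_pair"
  )
}

# DFS: assign a value to each position in turn; prune with the exact
# min/max of the remaining assignment (sorted vs reverse-sorted matching,
# by the rearrangement inequality) and the fixed parity of the suffix sum.
rank_pair_search <- function(n, target) {
  suffix_bounds <- function(pos, vals) {
    if (!length(pos)) return(c(0L, 0L))
    v <- sort(vals)
    c(sum((pos - v)^2), sum((pos - rev(v))^2))
  }
  recurse <- function(i, used, remaining) {
    pos <- i:n
    vals <- which(!used)
    if (i > n) return(if (remaining == 0L) integer(0) else NULL)
    # parity of any completion is fixed by the suffix
    if ((sum(pos) + sum(vals) - remaining) %% 2L != 0L) return(NULL)
    for (v in vals[order(abs((i - vals)^2 - remaining / length(pos)))]) {
      contrib <- (i - v)^2
      rest <- remaining - contrib
      if (rest < 0L) next
      b <- suffix_bounds(if (i < n) (i + 1L):n else integer(0),
                         setdiff(vals, v))
      if (rest < b[1L] || rest > b[2L]) next
      used[v] <- TRUE
      tail <- recurse(i + 1L, used, rest)
      used[v] <- FALSE
      if (!is.null(tail)) return(c(v, tail))
    }
    NULL
  }
  recurse(1L, logical(n), target)
}

#' Simulate a differential-expression result table
#'
#' Null features receive Uniform(0,1) p-values and small log2 fold-changes;
#' signal features receive `|log2FC| >= effect_lfc` and near-zero p-values.
#' Adjusted p-values are attached with [bh_adjust()]. Deterministic under
#' `seed`.
#'
#' @param n Number of features.
#' @param frac_up,frac_down Fractions of up- / down-regulated signal
#'   features; must be non-negative with sum <= 1.
#' @param effect_lfc Minimum absolute log2 fold-change of signal features.
#' @param seed Integer seed.
#' @return A data.frame with columns `feature_id`, `log2fc`, `p`, `p_adj`.
#' @export
generate_de_table <- function(n, frac_up = 0, frac_down = 0,
                              effect_lfc = 2, seed = 1L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  if (frac_up < 0 || frac_down < 0) stop("fractions must be non-negative")
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must be <= 1")
  if (n == 0L) {
    return(data.frame(feature_id = character(0), log2fc = numeric(0),
                      p = numeric(0), p_adj = numeric(0)))
  }
  n_up <- round(frac_up * n)
  n_down <- round(frac_down * n)
  local_seed(seed, {
    lfc <- stats::rnorm(n, sd = 0.2)
    p <- stats::runif(n)
    if (n_up > 0) {
      i <- seq_len(n_up)
      lfc[i] <- effect_lfc + abs(stats::rnorm(n_up, sd = 0.25))
      p[i] <- stats::runif(n_up, 0, 1e-6)
    }
    if (n_down > 0) {
      i <- n_up + seq_len(n_down)
      lfc[i] <- -(effect_lfc + abs(stats::rnorm(n_down, sd = 0.25)))
      p[i] <- stats::runif(n_down, 0, 1e-6)
    }
    data.frame(
      feature_id = sprintf("f_%04d", seq_len(n)),
      log2fc = lfc, p = p, p_adj = bh_adjust(p)
    )
  })
}
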