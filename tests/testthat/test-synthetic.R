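test_that("rank pairs attain the requested squared rank-difference sum exactly", {
  p <- generate_rank_pair(15, 0)
  expect_identical(p$ranks_b, 1:15)
  expect_identical(p$d2_sum, 0)

  p <- generate_rank_pair(5, 40) # max = n(n^2-1)/3, only the full reversal
  expect_identical(p$ranks_b, 5:1)
  expect_identical(p$d2_sum, 40)

  set.seed(11)
  for (n in c(6L, 10L, 15L)) {
    max_d2 <- n * (n^2 - 1) / 3
    for (target in sample(seq(0, max_d2, by = 2), 5)) {
      p <- tryCatch(generate_rank_pair(n, target), error = function(e) NULL)
      if (!is.null(p)) {
        expect_identical(sum((p$ranks_a - p$ranks_b)^2), p$d2_sum)
        expect_identical(p$d2_sum, target)
        expect_identical(sort(p$ranks_b), seq_len(n)) # tie-free permutation
      }
    }
  }
})

test_that("rank-pair construction agrees with exhaustive feasibility search", {
  for (n in 3:6) {
    feasible <- sort(unique(vapply(
      all_perms(n), function(p) sum((seq_len(n) - p)^2), numeric(1)
    )))
    for (target in seq(0, n * (n^2 - 1) / 3, by = 2)) {
      got <- tryCatch(generate_rank_pair(n, target), error = function(e) NULL)
      if (target %in% feasible) {
        expect_false(is.null(got),
                     label = sprintf("n=%d d2=%d should be constructible", n, target))
        expect_identical(got$d2_sum, target)
      } else {
        expect_null(got,
                    label = sprintf("n=%d d2=%d should be infeasible", n, target))
      }
    }
  }
})

test_that("rank-pair preconditions are enforced", {
  expect_error(generate_rank_pair(10, 3), "even")
  expect_error(generate_rank_pair(10, -2), "lie in")
  expect_error(generate_rank_pair(5, 42), "lie in")
  expect_error(generate_rank_pair(1, 0), ">= 2")
})

small_spec <- function(...) {
  synthetic_spec(
    n_features_per_layer = c(transcript = 40L, protein = 10L),
    hub_size = 5L, ...
  )
}

test_that("same spec and seed give a byte-identical matrix", {
  m1 <- generate_multiomics(small_spec(seed = 3))
  m2 <- generate_multiomics(small_spec(seed = 3))
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  m3 <- generate_multiomics(small_spec(seed = 4))
  expect_false(identical(m1$abundance, m3$abundance))
})

test_that("zero hub loading leaves the focal feature uncorrelated", {
  rhos <- vapply(1:100, function(s) {
    m <- generate_multiomics(synthetic_spec(
      n_features_per_layer = c(transcript = 7L),
      hub_size = 5L, hub_loading = 0, group_effect_sd = 0, seed = s
    ))
    spearman_rho(m$abundance["tr_focal", ], m$abundance["tr_0002", ])
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("full loading with vanishing noise gives perfect +/-1 correlations", {
  m <- generate_multiomics(synthetic_spec(
    n_features_per_layer = c(transcript = 20L),
    hub_size = 10L, hub_loading = 1, noise_sd = 1e-12,
    hub_negative_fraction = 0.3, seed = 2
  ))
  signs <- attr(m, "hub_signs")
  for (k in seq_along(attr(m, "hub_members"))) {
    rho <- spearman_rho(m$abundance["tr_focal", ],
                        m$abundance[attr(m, "hub_members")[k], ])
    expect_equal(rho, signs[k], tolerance = 1e-12)
  }
})

test_that("default planted hub yields ~29 ego neighbors with ~6 negative", {
  m <- generate_multiomics(synthetic_spec(seed = 1))
  m <- half_min_impute(m, "protein")
  edges <- all_pairs_correlations(m, prefilter = 0.75)
  g <- build_graph(edges, threshold = 0.95)
  nb <- summarize_neighbors(g, "tr_focal")
  expect_gte(nrow(nb), 26)
  expect_lte(nrow(nb), 32)
  expect_gte(sum(nb$rho < 0), 4)
  expect_lte(sum(nb$rho < 0), 8)
})

test_that("generator rejects impossible configurations", {
  expect_error(synthetic_spec(n_features_per_layer = c(transcript = 5L),
                              hub_size = 10L), "budget")
  expect_error(
    generate_multiomics(small_spec(focal_feature_id = "tr_0002")),
    "collides"
  )
  expect_error(synthetic_spec(noise_sd = 0), "positive")
  expect_error(synthetic_spec(hub_loading = 1.2), "\\[0, 1\\]")
})

test_that("simulated DE tables honour their fractions and determinism", {
  empty <- generate_de_table(0)
  expect_identical(nrow(empty), 0L)

  t1 <- generate_de_table(10, frac_up = 1, frac_down = 0, effect_lfc = 5,
                          seed = 1)
  kept <- filter_differential(t1, lfc_min = 1, alpha = 0.1)
  expect_identical(nrow(kept), 10L)
  expect_true(all(kept$direction == "up"))

  t2 <- generate_de_table(50, frac_up = 0.2, frac_down = 0.3, seed = 9)
  expect_identical(t2, generate_de_table(50, frac_up = 0.2, frac_down = 0.3,
                                         seed = 9))
  expect_error(generate_de_table(10, frac_up = 0.8, frac_down = 0.5), "<= 1")
  expect_error(generate_de_table(10, frac_up = -0.1), "non-negative")
})
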