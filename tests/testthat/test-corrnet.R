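test_that("spearman_rho handles identity, reversal and monotone transforms", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(sort(x), rev(sort(x))), -1)
})

test_that("tie-free rank pairs reproduce the classical closed form", {
  # strongest published neighbor correlation: 1 - 6*14/(15*224) = 0.975
  p <- generate_rank_pair(15, 14)
  expect_equal(spearman_rho(p$ranks_a, p$ranks_b), 0.975)
  expect_equal(spearman_rho(p$ranks_a, p$ranks_b),
               1 - 6 * 14 / (15 * (15^2 - 1)))

  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    b <- sample(n)
    d2 <- sum((seq_len(n) - b)^2)
    expect_equal(spearman_rho(seq_len(n), b), 1 - 6 * d2 / (n * (n^2 - 1)))
  }
})

test_that("ties are handled exactly as Pearson on averaged ranks", {
  set.seed(8)
  for (i in 1:50) {
    x <- sample(1:4, 6, replace = TRUE) + runif(6) * (i %% 2) # ties when even
    y <- sample(1:3, 6, replace = TRUE)
    if (length(unique(x)) < 2L) x[1:2] <- c(0, 5)
    if (length(unique(y)) < 2L) y[1:2] <- c(1L, 3L)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "zero-variance")
})

random_feature_matrix <- function(n_features, n_samples, with_ties = FALSE) {
  vals <- if (with_ties) {
    matrix(sample(1:5, n_features * n_samples, replace = TRUE),
           nrow = n_features)
  } else {
    matrix(rnorm(n_features * n_samples), nrow = n_features)
  }
  rownames(vals) <- sprintf("f%03d", seq_len(n_features))
  colnames(vals) <- sprintf("s%02d", seq_len(n_samples))
  vals
}

test_that("all-pairs correlations at prefilter 0 enumerate every pair exactly", {
  set.seed(3)
  m <- abs(random_feature_matrix(10, 15))
  edges <- all_pairs_correlations(m, prefilter = 0, block_size = 4)
  expect_identical(nrow(edges), 45L)  # 10*9/2
  expect_true(all(edges$feature_a < edges$feature_b))
  for (k in seq_len(nrow(edges))) {
    expect_equal(
      edges$rho[k],
      spearman_rho(m[edges$feature_a[k], ], m[edges$feature_b[k], ]),
      tolerance = 1e-12
    )
  }
})

test_that("blocked computation equals the naive per-pair oracle for any block size", {
  set.seed(21)
  for (i in 1:10) {
    n_f <- sample(5:60, 1)
    n_s <- sample(c(4, 15), 1)
    m <- random_feature_matrix(n_f, n_s, with_ties = (i %% 3 == 0))
    pf <- sample(c(0, 0.287, 0.7503), 1)
    ref <- canon_edges(oracle_all_pairs(m, pf))
    for (bs in c(1L, 7L, n_f)) {
      got <- canon_edges(all_pairs_correlations(m, prefilter = pf,
                                                block_size = bs))
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("constant features are skipped and counted, never emitted", {
  set.seed(4)
  m <- random_feature_matrix(6, 10)
  m[2, ] <- 3 # zero variance
  edges <- all_pairs_correlations(m, prefilter = 0)
  expect_identical(attr(edges, "skipped_zero_variance"), 1L)
  expect_false("f002" %in% c(edges$feature_a, edges$feature_b))
  expect_identical(nrow(edges), 10L) # C(5,2)
})

test_that("duplicated rows correlate at exactly 1 and near-independent noise at ~0", {
  set.seed(6)
  m <- random_feature_matrix(5, 12)
  m[5, ] <- m[1, ]
  edges <- all_pairs_correlations(m, prefilter = 0.999)
  dup <- edges[edges$feature_a == "f001" & edges$feature_b == "f005", ]
  expect_identical(nrow(dup), 1L)
  expect_equal(dup$rho, 1)

  noise <- random_feature_matrix(20, 50)
  e2 <- all_pairs_correlations(noise, prefilter = 0.999)
  expect_identical(nrow(e2), 0L)
})

test_that("identical column permutations leave all correlations unchanged", {
  set.seed(9)
  m <- random_feature_matrix(8, 15)
  perm <- sample(ncol(m))
  e1 <- canon_edges(all_pairs_correlations(m, prefilter = 0))
  e2 <- canon_edges(all_pairs_correlations(m[, perm], prefilter = 0))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("tie-free n = 15 correlations lie on the 1 - k/560 grid", {
  set.seed(10)
  m <- random_feature_matrix(30, 15) # continuous: tie-free a.s.
  edges <- all_pairs_correlations(m, prefilter = 0)
  k <- (1 - edges$rho) * 560
  expect_true(all(abs(k - round(k)) < 1e-9))

  # ties move values off the grid (the published table's one off-grid value
  # is the signature of a tie-containing node)
  mt <- random_feature_matrix(30, 15, with_ties = TRUE)
  et <- all_pairs_correlations(mt, prefilter = 0)
  kt <- (1 - et$rho) * 560
  expect_gt(sum(abs(kt - round(kt)) > 1e-9), 0)
})

test_that("correlation engine validates its inputs", {
  m <- random_feature_matrix(4, 10)
  expect_error(all_pairs_correlations(m, prefilter = 1), "\\[0, 1\\)")
  expect_error(all_pairs_correlations(m, block_size = 0), ">= 1")
  m[1, 1] <- NA
  expect_error(all_pairs_correlations(m), "impute")
})
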