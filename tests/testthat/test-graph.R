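edge_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(feature_a = r[[1]], feature_b = r[[2]],
               rho = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

test_that("graph construction thresholds, signs and weights edges", {
  ed <- edge_df(list("A", "B", 0.96), list("B", "C", -0.97),
                list("C", "D", 0.80))
  g <- build_graph(ed, threshold = 0.95)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_identical(as.integer(igraph::ecount(g)), 2L)
  expect_identical(sum(igraph::E(g)$sign == "-"), 1L)
  expect_equal(igraph::E(g)$weight, abs(igraph::E(g)$rho))

  expect_identical(as.integer(igraph::vcount(build_graph(ed[0, ]))), 0L)
  expect_identical(as.integer(igraph::vcount(build_graph(ed, threshold = 0.99))), 0L)

  dup <- edge_df(list("A", "B", 0.96), list("B", "A", 0.97))
  expect_error(build_graph(dup, threshold = 0.95), "conflicting")
  same <- edge_df(list("A", "B", 0.96), list("B", "A", 0.96))
  expect_identical(as.integer(igraph::ecount(build_graph(same, threshold = 0.95))), 1L)

  pf <- all_pairs_correlations(
    matrix(rnorm(40), 4, 10, dimnames = list(letters[1:4], NULL)),
    prefilter = 0.5
  )
  expect_error(build_graph(pf, threshold = 0.3), ">= the prefilter")
})

test_that("largest component is extracted with a deterministic tie-break", {
  ed <- edge_df(list("A", "B", 1), list("B", "C", 1), list("C", "D", 1),
                list("D", "E", 1), list("X", "Y", 1))
  g <- build_graph(ed, threshold = 0.5)
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("A", "B", "C", "D", "E"))

  conn <- build_graph(edge_df(list("A", "B", 1), list("B", "C", 1)), 0.5)
  expect_setequal(igraph::V(largest_component(conn))$name,
                  igraph::V(conn)$name)

  tie <- build_graph(edge_df(list("C", "D", 1), list("A", "B", 1)), 0.5)
  expect_setequal(igraph::V(largest_component(tie))$name, c("A", "B"))

  empty <- build_graph(ed[0, ], 0.5)
  expect_identical(as.integer(igraph::vcount(largest_component(empty))), 0L)
})

test_that("centralities match hand-computed cases", {
  path <- build_graph(edge_df(list("A", "B", 1), list("B", "C", 1)), 0.5)
  nm <- node_metrics(path)
  expect_identical(nm$betweenness[nm$feature_id == "B"], 1)
  expect_identical(nm$betweenness[nm$feature_id %in% c("A", "C")], c(0, 0))
  expect_equal(nm$closeness[nm$feature_id == "B"], 2 / 2)

  k4 <- build_graph(edge_df(
    list("A", "B", 1), list("A", "C", 1), list("A", "D", 1),
    list("B", "C", 1), list("B", "D", 1), list("C", "D", 1)
  ), 0.5)
  nm4 <- node_metrics(k4)
  expect_identical(nm4$degree, rep(3L, 4))
  expect_equal(nm4$betweenness, rep(0, 4))

  star <- build_graph(edge_df(
    list("hub", "l1", 1), list("hub", "l2", 1), list("hub", "l3", 1),
    list("hub", "l4", 1), list("hub", "l5", 1)
  ), 0.5)
  nms <- node_metrics(star)
  expect_identical(nms$degree[nms$feature_id == "hub"], 5L)
  expect_equal(nms$betweenness[nms$feature_id == "hub"], 10) # C(5,2)
})

test_that("centralities agree with exhaustive path enumeration on random graphs", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    ed <- random_edge_table(n)
    g <- build_graph(ed, threshold = 0)
    for (mode in c("inverse_weight", "raw_weight")) {
      nm <- node_metrics(g, distance_mode = mode)
      ids <- igraph::V(g)$name
      w <- igraph::E(g)$weight
      ends <- igraph::ends(g, igraph::E(g))
      oracle_in <- data.frame(
        from_i = match(ends[, 1], ids), to_i = match(ends[, 2], ids),
        d = if (mode == "inverse_weight") 1 / w else w
      )
      o <- oracle_paths(length(ids), oracle_in)
      expect_equal(nm$betweenness, o$betweenness, tolerance = 1e-9)
      expect_equal(nm$closeness, o$closeness, tolerance = 1e-9)
    }
  }
})

test_that("ego subnetworks are induced on the focal vertex and its neighbors", {
  star <- build_graph(edge_df(list("h", "a", 1), list("h", "b", 1)), 0.5)
  expect_setequal(igraph::V(ego_subnetwork(star, "h"))$name,
                  igraph::V(star)$name)

  tri <- build_graph(edge_df(
    list("A", "B", 0.99), list("B", "C", 0.99), list("A", "C", 0.99),
    list("C", "D", 0.99)
  ), 0.5)
  ego <- ego_subnetwork(tri, "A")
  expect_setequal(igraph::V(ego)$name, c("A", "B", "C"))
  expect_identical(as.integer(igraph::ecount(ego)), 3L) # neighbor-neighbor edge kept

  expect_error(ego_subnetwork(tri, "Z"), "not present")
})

test_that("neighbor summaries are signed, sorted and consistent with degree", {
  set.seed(15)
  ed <- random_edge_table(7, p_edge = 0.6)
  g <- build_graph(ed, threshold = 0)
  for (v in igraph::V(g)$name) {
    nb <- summarize_neighbors(g, v)
    expect_identical(nrow(nb), as.integer(igraph::degree(g, v)))
    expect_identical(nrow(nb), as.integer(igraph::vcount(ego_subnetwork(g, v)) - 1L))
    expect_true(!is.unsorted(nb$rho))
  }

  iso <- build_graph(edge_df(list("A", "B", 1), list("C", "D", 1)), 0.5)
  expect_identical(nrow(summarize_neighbors(iso, "A")), 1L)
})

test_that("the packaged neighbor table reconstructs the published ego network", {
  path <- system.file("extdata", "sco2_neighbors_table2.tsv",
                      package = "hubnet")
  nb <- read_neighbor_table(path)
  expect_identical(nrow(nb), 29L)
  expect_identical(sum(nb$rho < 0), 6L)
  expect_identical(sum(nb$node_type == "protein"), 3L)

  focal <- "Solyc01g108200.3"
  g <- build_graph(neighbor_edges(nb, focal), threshold = 0.95)
  out <- summarize_neighbors(g, focal)
  expect_identical(nrow(out), 29L)
  expect_equal(out$rho[1], -0.971428571)
  expect_equal(out$rho[29], 0.975)
  expect_identical(out$neighbor_id[1], "Solyc06g053710.3")
  expect_identical(out$neighbor_id[29], "Solyc09g010110.3")
})
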