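# End-to-end fit: multi-omics matrix -> signed Spearman network -> hub test
# of a focal feature, packaged as a classed model object.

#' Fit a correlation-network hub model for a focal feature
#'
#' Runs the full analysis on a multi-omics abundance matrix: half-minimum
#' imputation of the selected layers, optional normalization to reference
#' samples, blocked all-pairs Spearman correlation with absolute-value
#' prefiltering, thresholded signed-network construction, largest connected
#' component, degree / closeness / betweenness centralities, one-sample
#' Wilcoxon signed-rank hub tests of the focal feature against the network
#' for each metric, and extraction of the focal ego subnetwork with its
#' signed neighbor table.
#'
#' @param x An [omics_matrix()] (e.g. from [generate_multiomics()] or
#'   [read_omics_matrix()]).
#' @param focal_id Feature id whose hub status is tested; must be present.
#' @param prefilter Streaming prefilter on `|rho|`; default 0.75.
#' @param threshold Network threshold on `|rho|`; default 0.95. Must be
#'   `>= prefilter`.
#' @param distance_mode Distance convention for closeness/betweenness, see
#'   [node_metrics()].
#' @param impute_layers Layers passed to [half_min_impute()]; default
#'   `"protein"`. Use `character(0)` to skip imputation.
#' @param reference_sample_ids Optional sample ids for
#'   [normalize_to_reference()] (rank correlations are invariant to this,
#'   but normalized matrices are part of the standard workflow); default
#'   `NULL` (no normalization).
#' @param component Compute metrics and the hub test on the `"full"`
#'   thresholded graph (default, the convention used when comparing a focal
#'   node to "the overall network") or only on its `"largest"` connected
#'   component (the subgraph one would visualize).
#' @param block_size Correlation block size, see [all_pairs_correlations()].
#' @return An object of class `hubnet`: a list with elements `config`,
#'   `edges`, `graph` (full thresholded network), `component`, `metrics`,
#'   `tests` (one [hub_test()] per metric), `ego`, `neighbors` and `log`
#'   (dropped/skipped counts).
#' @examples
#' m <- generate_multiomics(synthetic_spec(seed = 7))
#' fit <- hubnet(m, focal_id = "tr_focal")
#' fit
#' @export
hubnet <- function(x, focal_id,
                   prefilter = 0.75, threshold = 0.95,
                   distance_mode = c("inverse_weight", "raw_weight"),
                   impute_layers = "protein",
                   reference_sample_ids = NULL,
                   component = c("full", "largest"),
                   block_size = 256L) {
  stopifnot(inherits(x, "omics_matrix"))
  distance_mode <- match.arg(distance_mode)
  component <- match.arg(component)
  if (threshold < prefilter)
    stop("network threshold must be >= correlation prefilter")
  if (!focal_id %in% x$features$feature_id)
    stop("focal feature '", focal_id, "' not in the matrix")

  dropped_impute <- character(0)
  if (length(impute_layers)) {
    x <- half_min_impute(x, layers = impute_layers)
    dropped_impute <- attr(x, "dropped_features")
  }
  dropped_norm <- character(0)
  if (!is.null(reference_sample_ids)) {
    x <- normalize_to_reference(x, reference_sample_ids)
    dropped_norm <- attr(x, "dropped_features")
  }
  if (!focal_id %in% x$features$feature_id)
    stop("focal feature '", focal_id, "' was dropped during preprocessing")

  edges <- all_pairs_correlations(x, prefilter = prefilter,
                                  block_size = block_size)
  layer_map <- stats::setNames(x$features$layer, x$features$feature_id)
  graph <- build_graph(edges, threshold = threshold, layers = layer_map)
  if (!focal_id %in% igraph::V(graph)$name)
    stop("focal feature '", focal_id,
         "' has no edge at the network threshold; nothing to test")
  g <- if (component == "largest") largest_component(graph) else graph
  if (!focal_id %in% igraph::V(g)$name)
    stop("focal feature not in the largest component; ",
         "rerun with component = \"full\"")

  metrics <- node_metrics(g, distance_mode = distance_mode)
  tests <- lapply(c("degree", "closeness", "betweenness"), function(mt) {
    hub_test(metrics, focal_id, metric = mt)
  })
  names(tests) <- c("degree", "closeness", "betweenness")
  ego <- ego_subnetwork(g, focal_id)
  neighbors <- summarize_neighbors(g, focal_id)

  structure(
    list(
      config = list(
        focal_id = focal_id, prefilter = prefilter, threshold = threshold,
        distance_mode = distance_mode, impute_layers = impute_layers,
        reference_sample_ids = reference_sample_ids,
        component = component, block_size = as.integer(block_size),
        n_features = nrow(x$abundance), n_samples = ncol(x$abundance)
      ),
      edges = edges,
      graph = graph,
      component = g,
      metrics = metrics,
      tests = tests,
      ego = ego,
      neighbors = neighbors,
      log = list(
        dropped_imputation = dropped_impute,
        dropped_normalization = dropped_norm,
        skipped_zero_variance = attr(edges, "skipped_zero_variance")
      )
    ),
    class = "hubnet"
  )
}

#' @export
print.hubnet <- function(x, ...) {
  cat("hubnet fit\n")
  cat(sprintf("  matrix: %d features x %d samples; prefilter %.2f, threshold %.2f\n",
              x$config$n_features, x$config$n_samples,
              x$config$prefilter, x$config$threshold))
  cat(sprintf("  network: %d vertices, %d edges (%s component analysed: %d/%d)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$config$component, igraph::vcount(x$component),
              igraph::ecount(x$component)))
  nb <- x$neighbors
  cat(sprintf("  focal '%s': %d direct neighbors (%d negative, %d positive)\n",
              x$config$focal_id, nrow(nb), sum(nb$rho < 0), sum(nb$rho > 0)))
  dt <- x$tests$degree
  cat(sprintf("  degree hub test: %d vs pseudo-median %.3g, p = %.3g (%s)\n",
              as.integer(dt$focal_value), dt$network_pseudomedian, dt$p,
              dt$direction))
  invisible(x)
}

#' @export
summary.hubnet <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$tests, function(t) {
    data.frame(
      metric = t$metric, focal_value = t$focal_value,
      network_pseudomedian = t$network_pseudomedian,
      W = t$W, p = t$p, direction = t$direction,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  structure(list(config = object$config, tests = tab,
                 n_neighbors = nrow(object$neighbors),
                 n_negative = sum(object$neighbors$rho < 0)),
            class = "summary.hubnet")
}

#' @export
print.summary.hubnet <- function(x, ...) {
  cat(sprintf("hubnet summary for focal '%s' (threshold %.2f)\n",
              x$config$focal_id, x$config$threshold))
  cat(sprintf("  %d direct neighbors, %d negative\n\n",
              x$n_neighbors, x$n_negative))
  print(x$tests, digits = 4)
  invisible(x)
}

#' Plot a hubnet fit
#'
#' `which = "ego"` draws the focal ego subnetwork with edges colored by
#' correlation sign (solid blue positive, dashed red negative);
#' `which = "metrics"` shows the network distribution of each centrality
#' with the focal value marked.
#'
#' @param x A `hubnet` object.
#' @param which `"ego"` or `"metrics"`.
#' @param ... Further arguments passed to [igraph::plot.igraph()] (ego) or
#'   [graphics::boxplot()] (metrics).
#' @export
plot.hubnet <- function(x, which = c("ego", "metrics"), ...) {
  which <- match.arg(which)
  if (which == "ego") {
    g <- x$ego
    cols <- ifelse(igraph::E(g)$sign == "+", "steelblue", "firebrick")
    lty <- ifelse(igraph::E(g)$sign == "+", 1, 2)
    vcol <- ifelse(igraph::V(g)$name == x$config$focal_id,
                   "gold", "grey80")
    igraph::plot.igraph(g, edge.color = cols, edge.lty = lty,
                        vertex.color = vcol, vertex.size = 8,
                        vertex.label.cex = 0.6, ...)
  } else {
    old <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(old))
    for (mt in c("degree", "closeness", "betweenness")) {
      vals <- x$metrics[[mt]]
      graphics::boxplot(log1p(vals), main = mt, ylab = "log(1 + value)", ...)
      graphics::points(1, log1p(x$tests[[mt]]$focal_value),
                       pch = 10, col = "red", cex = 1.5)
    }
  }
  invisible(x)
}

#' Write all artifacts of a hubnet fit to a directory
#'
#' Produces `edges.tsv`, `network.graphml`, `metrics.tsv`,
#' `hub_tests.json`, `neighbors.tsv` and a `manifest.json` recording the
#' configuration, drop/skip counts and the md5 checksum of every artifact,
#' so a rerun on identical input is byte-identical and verifiable.
#'
#' @param fit A [hubnet()] object.
#' @param dir Output directory (created if absent).
#' @return The manifest as a list, invisibly.
#' @export
write_hubnet <- function(fit, dir) {
  stopifnot(inherits(fit, "hubnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_edges <- file.path(dir, "edges.tsv")
  write_edges(fit$edges, p_edges)
  p_gml <- file.path(dir, "network.graphml")
  write_graphml(fit$graph, p_gml)
  p_metrics <- file.path(dir, "metrics.tsv")
  mt <- fit$metrics
  mt$closeness <- fmt_num(mt$closeness)
  mt$betweenness <- fmt_num(mt$betweenness)
  utils::write.table(mt, p_metrics, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_tests <- file.path(dir, "hub_tests.json")
  jsonlite::write_json(lapply(fit$tests, unclass), p_tests,
                       auto_unbox = TRUE, digits = NA)
  p_nb <- file.path(dir, "neighbors.tsv")
  nb <- fit$neighbors
  nb$rho <- fmt_num(nb$rho)
  utils::write.table(nb, p_nb, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(edges = p_edges, graphml = p_gml, metrics = p_metrics,
             hub_tests = p_tests, neighbors = p_nb)
  manifest <- list(
    config = fit$config,
    log = fit$log,
    artifacts = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        names(files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
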