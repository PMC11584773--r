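# Thresholded signed correlation network: construction, largest component,
# centralities, ego extraction and neighbor summaries (igraph-backed).

#' Build a signed correlation network from an edge table
#'
#' Edges with `|rho| >=` the threshold become undirected edges weighted by
#' `|rho|`, with the sign of the correlation kept as an attribute. Vertices
#' are exactly the features incident to at least one surviving edge. When a
#' `layers` lookup is supplied, each vertex carries its omics layer.
#'
#' @param edges Data.frame with columns `feature_a`, `feature_b`, `rho`
#'   (e.g. from [all_pairs_correlations()] or [read_edges()]).
#' @param threshold Absolute-correlation threshold, default 0.95; must be at
#'   least the prefilter used to produce the stream (checked when the edge
#'   table carries a `prefilter` attribute).
#' @param layers Optional named character vector mapping feature id to layer.
#' @return An `igraph` graph with edge attributes `rho`, `weight = |rho|`,
#'   `sign` and graph attribute `threshold`.
#' @export
build_graph <- function(edges, threshold = 0.95, layers = NULL) {
  need <- c("feature_a", "feature_b", "rho")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop("edges lacks column(s): ", paste(miss, collapse = ", "))
  pf <- attr(edges, "prefilter")
  if (!is.null(pf) && threshold < pf)
    stop("threshold must be >= the prefilter used to produce the edges")
  keep <- abs(edges$rho) >= threshold
  ed <- edges[keep, need, drop = FALSE]
  if (any(ed$feature_a == ed$feature_b))
    stop("self-pairs are not allowed")
  key <- paste(pmin(ed$feature_a, ed$feature_b),
               pmax(ed$feature_a, ed$feature_b))
  if (anyDuplicated(key)) {
    nuniq <- tapply(ed$rho, key, function(v) length(unique(v)))
    if (any(nuniq > 1L))
      stop("conflicting duplicate pairs in edge stream")
    ed <- ed[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  igraph::E(g)$sign <- ifelse(igraph::E(g)$rho >= 0, "+", "-")
  if (!is.null(layers))
    igraph::V(g)$layer <- unname(layers[igraph::V(g)$name])
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Largest connected component of a graph
#'
#' Returns the induced subgraph on the largest connected vertex set. Size
#' ties are broken deterministically: the component containing the
#' lexicographically smallest vertex name wins.
#'
#' @param graph An `igraph` graph.
#' @return The induced subgraph (the empty graph maps to itself).
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) return(graph)
  comp <- igraph::components(graph)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(k) {
      min(igraph::V(graph)$name[comp$membership == k])
    }, character(1))
    big <- big[order(firsts)[1L]]
  }
  igraph::induced_subgraph(graph, which(comp$membership == big))
}

#' Degree, closeness and betweenness of every vertex
#'
#' Degree is the unweighted incident-edge count. Closeness and betweenness
#' use shortest-path distances derived from the edge weights: by default
#' `d(e) = 1 / weight` (a stronger correlation means a shorter distance);
#' `distance_mode = "raw_weight"` uses the weight itself as the distance.
#' Closeness of `v` is (number of other vertices reachable from `v`)
#' divided by the summed distances to them, with 0 for isolated vertices.
#' Betweenness follows the undirected convention in which each unordered
#' source-target pair is counted once.
#'
#' @param graph A non-empty `igraph` graph with positive edge weights.
#' @param distance_mode `"inverse_weight"` (default) or `"raw_weight"`.
#' @return Data.frame with columns `feature_id`, `degree`, `closeness`,
#'   `betweenness`; attribute `distance_mode` records the convention used.
#' @export
node_metrics <- function(graph,
                         distance_mode = c("inverse_weight", "raw_weight")) {
  distance_mode <- match.arg(distance_mode)
  if (igraph::vcount(graph) == 0L) stop("graph is empty")
  w <- igraph::E(graph)$weight
  if (!is.null(w) && any(w <= 0)) stop("edge weights must be positive")
  d <- if (is.null(w)) NULL else
    switch(distance_mode, inverse_weight = 1 / w, raw_weight = w)
  dm <- igraph::distances(graph, weights = d)
  diag(dm) <- Inf
  reach <- rowSums(is.finite(dm))
  tot <- rowSums(ifelse(is.finite(dm), dm, 0))
  clo <- ifelse(reach > 0, reach / tot, 0)
  btw <- igraph::betweenness(graph, weights = d, directed = FALSE)
  out <- data.frame(
    feature_id = igraph::V(graph)$name,
    degree = as.integer(igraph::degree(graph)),
    closeness = unname(clo),
    betweenness = unname(btw),
    stringsAsFactors = FALSE
  )
  attr(out, "distance_mode") <- distance_mode
  out
}

#' Ego subnetwork of a focal vertex
#'
#' The induced subgraph on the focal vertex and its direct neighbors;
#' neighbor-neighbor edges are retained.
#'
#' @param graph An `igraph` graph.
#' @param focal_id Vertex name; must be present.
#' @return An `igraph` graph.
#' @export
ego_subnetwork <- function(graph, focal_id) {
  if (!focal_id %in% igraph::V(graph)$name)
    stop("focal feature '", focal_id, "' not present in graph")
  igraph::make_ego_graph(graph, order = 1L, nodes = focal_id)[[1L]]
}

#' Signed correlations of a focal vertex's direct neighbors
#'
#' One row per direct neighbor with the signed correlation of its edge to
#' the focal vertex, sorted ascending by `rho` (most negative first, the
#' strongest positive neighbor last).
#'
#' @param graph An `igraph` graph with edge attribute `rho`.
#' @param focal_id Vertex name; must be present.
#' @return Data.frame with columns `neighbor_id`, `rho` (and `layer` when
#'   the graph carries vertex layers).
#' @export
summarize_neighbors <- function(graph, focal_id) {
  if (!focal_id %in% igraph::V(graph)$name)
    stop("focal feature '", focal_id, "' not present in graph")
  inc <- igraph::incident(graph, focal_id)
  if (!length(inc)) {
    out <- data.frame(neighbor_id = character(0), rho = numeric(0))
    return(out)
  }
  ends <- igraph::ends(graph, inc)
  nb <- ifelse(ends[, 1L] == focal_id, ends[, 2L], ends[, 1L])
  out <- data.frame(neighbor_id = nb, rho = inc$rho, stringsAsFactors = FALSE)
  if (!is.null(igraph::V(graph)$layer))
    out$layer <- igraph::V(graph)$layer[match(nb, igraph::V(graph)$name)]
  out <- out[order(out$rho, out$neighbor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
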