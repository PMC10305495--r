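# Topological statistics of interactomes and protein-drug networks.
#
# All distances treat the graph as unweighted and undirected; `binds` and
# `ppi` edges are equally traversable and self-pairs are ignored by the
# path-based measures.

#' Node degree
#'
#' Count of incident edges. A self-pair contributes 1 under the default
#' convention ("interacts with itself, counted once"); set
#' `self_loops = "double"` for the graph-theoretic convention where a loop
#' adds 2.
#'
#' @param net An [interactome()] or `protein_drug_network`.
#' @param node Node identifier.
#' @param self_loops `"single"` (default) or `"double"`.
#' @return Integer degree.
#' @export
node_degree <- function(net, node, self_loops = c("single", "double")) {
  self_loops <- match.arg(self_loops)
  if (!node %in% node_ids(net)) {
    stop("unknown node: ", node, call. = FALSE)
  }
  ed <- edge_frame(net)
  plain <- sum((ed$a == node) != (ed$b == node))
  loops <- sum(ed$a == node & ed$b == node)
  plain + loops * switch(self_loops, single = 1L, double = 2L)
}

#' Betweenness centrality
#'
#' Shortest-path betweenness of every node: the number of shortest paths
#' between other node pairs passing through it (each unordered pair counted
#' once, fractionally for tied paths). Unnormalized by default; with
#' `normalized = TRUE` values are scaled by 2/((n-1)(n-2)).
#'
#' @param net Graph object.
#' @param normalized Scale to [0, 1].
#' @return Named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  ids <- node_ids(net)
  if (length(ids) == 0) return(stats::setNames(numeric(0), character(0)))
  g <- as_igraph(net, drop_self = TRUE)
  b <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  b[ids]
}

#' Closeness centrality
#'
#' For a node reaching `r` other nodes at total distance `d`, closeness is
#' `(r / d) * (r / (n - 1))`: the reciprocal mean distance to reachable
#' nodes, scaled by the reachable fraction so that values remain comparable
#' across components of a disconnected graph. Isolated nodes score 0.
#'
#' @param net Graph object.
#' @return Named numeric vector in [0, 1] over all nodes.
#' @export
closeness_centrality <- function(net) {
  ids <- node_ids(net)
  n <- length(ids)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  if (n == 1) return(stats::setNames(0, ids))
  g <- as_igraph(net, drop_self = TRUE)
  d <- igraph::distances(g)
  out <- vapply(ids, function(v) {
    dv <- d[v, colnames(d) != v]
    dv <- dv[is.finite(dv)]
    r <- length(dv)
    if (r == 0) return(0)
    (r / sum(dv)) * (r / (n - 1))
  }, numeric(1))
  out
}

#' Diameter and radius
#'
#' Eccentricity extrema over the largest connected component (maximum and
#' minimum over nodes of the maximum distance to any other node), ignoring
#' self-pairs and edge types. Reported with the component count so callers
#' see when the measure was restricted.
#'
#' @param net Graph object; must be non-empty.
#' @return List with `diameter`, `radius`, `component_count`.
#' @export
diameter_radius <- function(net) {
  ids <- node_ids(net)
  if (length(ids) == 0) stop("empty network", call. = FALSE)
  g <- as_igraph(net, drop_self = TRUE)
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  if (igraph::vcount(sub) == 1) {
    ecc <- 0
  } else {
    ecc <- apply(igraph::distances(sub), 1, max)
  }
  list(diameter = as.integer(max(ecc)), radius = as.integer(min(ecc)),
       component_count = comp$no)
}

#' Graph summary
#'
#' Node/edge counts (with and without self-pairs), diameter, radius and
#' component count of a network.
#'
#' @param net Graph object.
#' @return List of class `graph_summary`.
#' @export
graph_summary <- function(net) {
  ed <- edge_frame(net)
  ns <- sum(ed$a == ed$b)
  dr <- diameter_radius(net)
  structure(list(n_nodes = length(node_ids(net)),
                 n_edges = nrow(ed),
                 n_edges_no_self = nrow(ed) - ns,
                 n_self_pairs = ns,
                 diameter = dr$diameter,
                 radius = dr$radius,
                 component_count = dr$component_count),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf(paste0("%d nodes, %d edges (%d self-pairs); diameter %d, ",
                     "radius %d, %d component(s)\n"),
              x$n_nodes, x$n_edges, x$n_self_pairs, x$diameter, x$radius,
              x$component_count))
  invisible(x)
}

#' Mean first-neighbor degree
#'
#' Arithmetic mean of the whole-interactome degrees of a target's first
#' neighbors (degrees are measured in the full interactome, not in any
#' extracted subnetwork). A hub surrounded by hubs scores high.
#'
#' @param net An [interactome()].
#' @param target Protein accession.
#' @param self_loops Degree convention, see [node_degree()].
#' @return Numeric mean degree.
#' @export
mean_neighbor_degree <- function(net, target,
                                 self_loops = c("single", "double")) {
  self_loops <- match.arg(self_loops)
  nb <- first_neighbors(net, target)$neighbors
  if (length(nb) == 0) {
    stop("target has no neighbors; mean neighbor degree undefined: ",
         target, call. = FALSE)
  }
  mean(vapply(nb, function(v) node_degree(net, v, self_loops), numeric(1)))
}

#' Per-node metric table
#'
#' Degree, betweenness and closeness for every node of a network, the rows
#' behind a topology report.
#'
#' @param net Graph object.
#' @param normalized Normalize betweenness, see [betweenness_centrality()].
#' @return Data.frame: node, degree, betweenness, closeness, sorted by
#'   decreasing degree then node id.
#' @export
node_metrics <- function(net, normalized = FALSE) {
  ids <- node_ids(net)
  deg <- vapply(ids, function(v) node_degree(net, v), integer(1))
  btw <- betweenness_centrality(net, normalized = normalized)
  cls <- closeness_centrality(net)
  df <- data.frame(node = ids, degree = deg, betweenness = unname(btw[ids]),
                   closeness = unname(cls[ids]), stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$node), ]
  rownames(df) <- NULL
  df
}
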