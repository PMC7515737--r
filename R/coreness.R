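#' Per-node degree and coreness (k-shell decomposition)
#'
#' The core of a node is the largest k such that the node belongs to the
#' k-core, the maximal subgraph in which every node has degree at least k.
#' Cores are obtained by k-shell decomposition: nodes of degree <= k are peeled
#' iteratively, and a node's shell index is the round at which it is removed.
#' The core can never exceed the degree; hubs of star-like substructures (many
#' degree-1 neighbors) receive core 1 despite a high degree, which is the
#' property exploited by the core-based normalization schemes.
#'
#' @param graph a connected simple \code{igraph} with named vertices and at
#'   least 2 nodes.
#' @return \code{data.frame} with columns \code{gene}, \code{degree},
#'   \code{core}, sorted by gene identifier.
#' @examples
#' g <- igraph::make_star(6, mode = "undirected", center = 1)
#' igraph::V(g)$name <- letters[1:6]
#' nodeMetrics(g)  # hub degree 5, all cores 1
#' @export
nodeMetrics <- function(graph) {
  .checkIgraph(graph)
  if (igraph::vcount(graph) < 2L) stop("network must have at least 2 nodes")
  if (!igraph::is_connected(graph))
    stop("network is disconnected; apply largestConnectedComponent() first")
  nm <- sort(igraph::V(graph)$name)
  deg <- igraph::degree(graph)
  core <- igraph::coreness(graph)
  out <- data.frame(gene = nm,
                    degree = as.integer(deg[nm]),
                    core = as.integer(core[nm]),
                    row.names = NULL, stringsAsFactors = FALSE)
  stopifnot(all(out$core >= 1L), all(out$core <= out$degree))
  out
}
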