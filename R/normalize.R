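#' Normalize an adjacency matrix into a column-stochastic transition matrix
#'
#' Builds the RWR transition matrix W under one of four schemes. Columns are
#' "from" nodes, so entry (i, j) is the probability of stepping from j to its
#' neighbor i:
#' \describe{
#'   \item{degree}{W = A D^-1: every neighbor of j receives 1/d_j.}
#'   \item{core}{entry (i, j) = k_i / sum of cores of j's neighbors, so densely
#'     embedded neighbors attract the walker more than peripheral ones.}
#'   \item{diff}{raw entry 1 / ((d_i - k_i) + 1), penalizing nodes whose degree
#'     far exceeds their core (the signature of study bias); columns are then
#'     rescaled to sum 1.}
#'   \item{ratio}{raw entry k_i / d_i (always <= 1 since core <= degree),
#'     rescaled per column.}
#' }
#' On any regular graph where core equals degree for all nodes the four schemes
#' coincide.
#'
#' @param graph a connected simple \code{igraph} with named vertices.
#' @param scheme normalization scheme.
#' @param metrics optional precomputed \code{\link{nodeMetrics}} table; must
#'   cover every node of \code{graph}.
#' @return a \code{\link{TransitionMatrix}} over the sorted node identifiers.
#' @examples
#' g <- igraph::make_star(6, mode = "undirected", center = 1)
#' igraph::V(g)$name <- letters[1:6]
#' W <- normalizeAdjacency(g, "degree")
#' transitionMatrix(W)["b", "a"]  # 0.2: hub 'a' has 5 neighbors
#' @export
normalizeAdjacency <- function(graph,
                               scheme = c("core", "degree", "diff", "ratio"),
                               metrics = NULL) {
  scheme <- match.arg(scheme)
  .checkPropagationGraph(graph)
  nodes <- sort(igraph::V(graph)$name)
  if (is.null(metrics)) metrics <- nodeMetrics(graph)
  missing <- setdiff(nodes, metrics$gene)
  if (length(missing))
    stop("metrics missing for node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))

  A <- igraph::as_adjacency_matrix(graph, type = "both", sparse = TRUE)
  A <- A[nodes, nodes]
  idx <- match(nodes, metrics$gene)
  d <- as.numeric(metrics$degree[idx])
  k <- as.numeric(metrics$core[idx])

  # all four schemes are a row factor applied to A followed by column rescaling
  f <- switch(scheme,
              degree = rep(1, length(nodes)),
              core   = k,
              diff   = 1 / ((d - k) + 1),
              ratio  = k / d)
  raw <- Matrix::Diagonal(x = f) %*% A
  cs <- Matrix::colSums(raw)
  if (any(cs <= 0))
    stop("zero column sum encountered; the network is not a connected simple graph")
  W <- raw %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(W) <- list(nodes, nodes)
  new("TransitionMatrix", matrix = as(W, "CsparseMatrix"), scheme = scheme)
}
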