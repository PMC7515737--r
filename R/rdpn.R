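#' Generate one random degree-preserving network (RDPN)
#'
#' Applies double-edge swaps -- replacing edges (u,v), (x,y) by (u,y), (x,v) --
#' to a connected simple graph. Every accepted swap preserves the full degree
#' sequence; a swap that would create an existing edge or a self-loop, or that
#' would disconnect the network, is rejected and rolled back, so every output
#' is connected with exactly the input degree sequence. Randomness comes from
#' R's RNG stream (use \code{set.seed} for reproducibility).
#'
#' @param graph a connected simple \code{igraph} with named vertices.
#' @param swapFactor attempted swaps = \code{swapFactor * ecount(graph)};
#'   default 100. The counter counts attempts, not accepted swaps, so the
#'   runtime is bounded.
#' @return an \code{igraph} with the same vertex names; attributes
#'   \code{attempts}, \code{accepted}, \code{rejectedClash} and
#'   \code{rejectedDisconnected} record the swap statistics. A warning is
#'   emitted (best-effort result) when fewer than 1\% of attempts were
#'   accepted, e.g. on rigid graphs such as triangles or trees.
#' @export
generateRDPN <- function(graph, swapFactor = 100) {
  .checkPropagationGraph(graph)
  if (swapFactor < 1) stop("swapFactor must be >= 1")
  el <- igraph::as_edgelist(graph, names = FALSE)
  res <- cpp_double_edge_swap(el - 1L, igraph::vcount(graph),
                              swapFactor * igraph::ecount(graph))
  g2 <- igraph::make_graph(as.vector(t(res$edges + 1L)),
                           n = igraph::vcount(graph), directed = FALSE)
  igraph::V(g2)$name <- igraph::V(graph)$name
  rate <- res$accepted / max(res$attempts, 1)
  if (rate < 0.01)
    warning(sprintf(
      "generateRDPN: only %.2f%% of %d swap attempts accepted; returning best-effort network",
      100 * rate, as.integer(res$attempts)))
  attr(g2, "attempts") <- res$attempts
  attr(g2, "accepted") <- res$accepted
  attr(g2, "rejectedClash") <- res$rejectedClash
  attr(g2, "rejectedDisconnected") <- res$rejectedDisconnected
  g2
}

#' Generate an ensemble of random degree-preserving networks
#'
#' Each network is generated under its own RNG seed derived from the current
#' RNG state at call time, so the ensemble is reproducible from a single
#' \code{set.seed} call and identical at any worker count.
#'
#' @inheritParams generateRDPN
#' @param n number of random networks (default 100; with the +1-smoothed
#'   permutation p-value this makes 1/101 the minimal achievable p-value).
#' @param workers parallel workers for generation (forked via
#'   \code{parallel::mclapply}; default 1).
#' @return list of \code{igraph} objects with attributes \code{seeds} (the
#'   per-network seeds) and \code{swapFactor}.
#' @export
rdpnEnsemble <- function(graph, n = 100L, swapFactor = 100, workers = 1L) {
  .checkPropagationGraph(graph)
  if (n < 1L) stop("n must be >= 1")
  seeds <- sample.int(.Machine$integer.max, n)
  gen <- function(s) withr::with_seed(s, generateRDPN(graph, swapFactor))
  ens <- if (workers > 1L) {
    parallel::mclapply(seeds, gen, mc.cores = workers)
  } else {
    lapply(seeds, gen)
  }
  attr(ens, "seeds") <- seeds
  attr(ens, "swapFactor") <- swapFactor
  ens
}

#' Propagate one input vector across an RDPN ensemble
#'
#' Recomputes node metrics (degrees are preserved by construction, but cores
#' are not) and the scheme-specific transition matrix for every random
#' network, then runs the closed-form RWR.
#'
#' @param ensemble list of RDPN graphs from \code{\link{rdpnEnsemble}}.
#' @param p0 input weights (named numeric or seed-gene character vector).
#' @inheritParams normalizeAdjacency
#' @inheritParams rwrClosedForm
#' @return matrix of propagated weights, one row per random network, columns
#'   named by gene.
#' @export
ensemblePropagate <- function(ensemble, p0, scheme = "core", alpha = 0.8) {
  if (!length(ensemble)) stop("ensemble is empty")
  nodes <- sort(igraph::V(ensemble[[1L]])$name)
  v <- alignWeights(nodes, p0, quiet = TRUE)
  rows <- lapply(ensemble, function(g) {
    W <- normalizeAdjacency(g, scheme)
    .rwrSolveMulti(W@matrix, matrix(v, ncol = 1L), alpha)[, 1L]
  })
  out <- do.call(rbind, rows)
  colnames(out) <- nodes
  out
}
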