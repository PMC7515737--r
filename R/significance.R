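#' Empirical permutation p-values for propagated weights
#'
#' For node v with observed propagated weight w(v) and random-network weights
#' w_1(v)..w_n(v), the p-value is
#' \deqn{p_v = (|\{i : w_i(v) \ge w(v)\}| + 1) / (n + 1)}
#' Ties count against the observed value (the comparison is inclusive), and
#' the +1 smoothing bounds p-values to [1/(n+1), 1]; with n = 100 the minimal
#' achievable p-value is 1/101 = 0.0099. The p-values are invariant under any
#' strictly monotone transform applied jointly to observed and ensemble
#' weights.
#'
#' @param observed named numeric vector of observed propagated weights.
#' @param ensembleWeights matrix with one row per random network and columns
#'   named by gene (as returned by \code{\link{ensemblePropagate}}), or a list
#'   of named vectors.
#' @return named numeric vector of p-values over \code{names(observed)}.
#' @export
empiricalPvalues <- function(observed, ensembleWeights) {
  if (is.list(ensembleWeights) && !is.matrix(ensembleWeights))
    ensembleWeights <- do.call(rbind, ensembleWeights)
  if (is.null(dim(ensembleWeights)) || nrow(ensembleWeights) < 1L)
    stop("ensemble is empty")
  if (is.null(names(observed)) || is.null(colnames(ensembleWeights)))
    stop("observed and ensemble weights must be named by gene")
  missing <- setdiff(names(observed), colnames(ensembleWeights))
  if (length(missing))
    stop("ensemble weights missing for gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  E <- ensembleWeights[, names(observed), drop = FALSE]
  n <- nrow(E)
  counts <- colSums(E >= matrix(observed, n, length(observed), byrow = TRUE))
  setNames((counts + 1) / (n + 1), names(observed))
}

#' Propagate weights and assess node significance in one step
#'
#' High-level driver: normalizes the adjacency matrix under \code{scheme},
#' runs RWR from the input weights (or binary seed weights), and -- unless
#' \code{nPermutations = 0} -- compares every node's propagated weight to its
#' weights on an ensemble of connectivity-preserving degree-preserving random
#' networks via \code{\link{empiricalPvalues}}.
#'
#' @param graph connected simple \code{igraph} with named vertices.
#' @param weights named non-negative weight vector (e.g. -log10 p-values);
#'   genes absent from the network are dropped with a message.
#' @param seeds alternatively, a character vector of seed genes scored with a
#'   binary scheme (1 on seeds, 0 elsewhere). Exactly one of \code{weights}
#'   and \code{seeds} must be given.
#' @param scheme normalization scheme (default \code{"core"}).
#' @param alpha restart probability (default 0.8).
#' @param nPermutations number of random networks (default 100; 0 skips the
#'   permutation test).
#' @param swapFactor swap attempts per edge for RDPN generation (default 100).
#' @param ensemble optional precomputed list of RDPN graphs (e.g. from a
#'   cache); overrides \code{nPermutations}/\code{swapFactor}.
#' @param pThreshold significance call threshold (default 0.01, the minimal
#'   level attainable with 100 permutations).
#' @param solver \code{"closed_form"} (sparse direct solve) or
#'   \code{"iterative"} (power iteration).
#' @param workers parallel workers for ensemble generation.
#' @return a \code{\link{PropagationResult}}.
#' @export
netPropagate <- function(graph, weights = NULL, seeds = NULL,
                         scheme = c("core", "degree", "diff", "ratio"),
                         alpha = 0.8, nPermutations = 100L, swapFactor = 100,
                         ensemble = NULL, pThreshold = 0.01,
                         solver = c("closed_form", "iterative"),
                         workers = 1L) {
  scheme <- match.arg(scheme)
  solver <- match.arg(solver)
  .checkPropagationGraph(graph)
  if (is.null(weights) == is.null(seeds))
    stop("give exactly one of 'weights' or 'seeds'")
  nodes <- sort(igraph::V(graph)$name)
  p0 <- if (is.null(seeds)) alignWeights(nodes, weights)
        else alignWeights(nodes, as.character(seeds))

  metrics <- nodeMetrics(graph)
  W <- normalizeAdjacency(graph, scheme, metrics)
  obs <- if (solver == "closed_form") rwrClosedForm(W, p0, alpha)
         else rwrIterative(W, p0, alpha)
  obs <- setNames(as.numeric(obs), nodes)

  pv <- rep(NA_real_, length(nodes))
  nPerm <- 0L
  if (is.null(ensemble) && nPermutations > 0L)
    ensemble <- rdpnEnsemble(graph, nPermutations, swapFactor,
                             workers = workers)
  if (!is.null(ensemble) && length(ensemble)) {
    ensW <- ensemblePropagate(ensemble, p0, scheme, alpha)
    pv <- empiricalPvalues(obs, ensW)
    nPerm <- length(ensemble)
  }

  tab <- data.frame(gene = nodes,
                    inputWeight = as.numeric(p0),
                    degree = metrics$degree[match(nodes, metrics$gene)],
                    core = metrics$core[match(nodes, metrics$gene)],
                    weight = as.numeric(obs),
                    rank = rank(-obs, ties.method = "min"),
                    pValue = as.numeric(pv),
                    significant = !is.na(pv) & pv < pThreshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  new("PropagationResult", table = tab, scheme = scheme, alpha = alpha,
      nPermutations = as.integer(nPerm))
}

#' Write a per-node propagation ranking table
#'
#' @param result a \code{\link{PropagationResult}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRanking <- function(result, path) {
  stopifnot(is(result, "PropagationResult"))
  tab <- result@table
  names(tab) <- c("gene", "input_weight", "degree", "core",
                  "propagated_weight", "rank", "p_value", "significant")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
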