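#' Random walk with restart, closed form
#'
#' Solves the steady state p = alpha (I - (1 - alpha) W)^-1 p0 of the RWR
#' recursion by a sparse direct solve of the linear system
#' (I - (1 - alpha) W) p = alpha p0 (no explicit inverse). With a
#' column-stochastic W and alpha > 0 the system is non-singular and the total
#' weight is conserved: sum(p) = sum(p0). At alpha = 1 the result is exactly
#' p0.
#'
#' @param W a \code{\link{TransitionMatrix}} (or a column-stochastic matrix
#'   with node dimnames).
#' @param p0 input weight vector: named numeric; genes absent from the network
#'   are dropped (with a message), network genes absent from \code{p0} carry 0.
#' @param alpha restart probability in (0, 1]; default 0.8 retains most of the
#'   input signal while still smoothing over the network.
#' @return named numeric vector of propagated weights over all network nodes.
#' @export
rwrClosedForm <- function(W, p0, alpha = 0.8) {
  Wm <- .tmMatrix(W)
  .checkAlpha(alpha)
  v <- alignWeights(colnames(Wm), p0)
  p <- .rwrSolveMulti(Wm, matrix(v, ncol = 1L), alpha)[, 1L]
  setNames(p, colnames(Wm))
}

#' Random walk with restart, power iteration
#'
#' Iterates p_k = alpha p0 + (1 - alpha) W p_{k-1} from p_0 until the maximum
#' absolute change drops below \code{tol}. Serves as an independent route to
#' the same steady state as \code{\link{rwrClosedForm}}; at alpha = 1 it
#' converges in a single iteration.
#'
#' @inheritParams rwrClosedForm
#' @param tol convergence tolerance on the max absolute per-node change
#'   (default 1e-8, well below reporting precision).
#' @param maxIterations iteration cap (default 10000).
#' @return named numeric vector with attributes \code{iterations} and
#'   \code{residual}.
#' @export
rwrIterative <- function(W, p0, alpha = 0.8, tol = 1e-8,
                         maxIterations = 10000L) {
  Wm <- .tmMatrix(W)
  .checkAlpha(alpha)
  if (tol <= 0) stop("tol must be positive")
  v <- alignWeights(colnames(Wm), p0)
  p <- v
  for (it in seq_len(maxIterations)) {
    pNew <- alpha * v + (1 - alpha) * as.numeric(Wm %*% p)
    delta <- max(abs(pNew - p))
    p <- pNew
    if (delta < tol) {
      p <- setNames(p, colnames(Wm))
      attr(p, "iterations") <- it
      attr(p, "residual") <- delta
      return(p)
    }
  }
  stop(sprintf("RWR did not converge in %d iterations (residual %.3e)",
               maxIterations, delta))
}

#' Align an input weight vector to a node universe
#'
#' @param nodes character vector of network node identifiers.
#' @param weights named non-negative numeric vector, or a character vector of
#'   seed genes (interpreted as binary weights of 1).
#' @param quiet suppress the dropped-gene message.
#' @return numeric vector ordered like \code{nodes}; absent genes carry 0.
#' @export
alignWeights <- function(nodes, weights, quiet = FALSE) {
  if (is.character(weights)) weights <- setNames(rep(1, length(weights)), weights)
  if (is.null(names(weights))) {
    if (length(weights) != length(nodes))
      stop("unnamed weight vector must match the node count")
    names(weights) <- nodes
  }
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  unknown <- setdiff(names(weights), nodes)
  if (length(unknown) && !quiet)
    message(sprintf("alignWeights: dropped %d gene(s) absent from the network",
                    length(unknown)))
  v <- setNames(numeric(length(nodes)), nodes)
  hit <- intersect(names(weights), nodes)
  v[hit] <- weights[hit]
  v
}

## internal ------------------------------------------------------------------

.tmMatrix <- function(W) {
  if (is(W, "TransitionMatrix")) return(W@matrix)
  if (is.null(colnames(W))) stop("transition matrix must carry node dimnames")
  W
}

.checkAlpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single number in (0, 1]")
}

# multi right-hand-side solve: one sparse factorization, many p0 columns
.rwrSolveMulti <- function(Wm, P0, alpha) {
  n <- ncol(Wm)
  A <- Matrix::Diagonal(n) - (1 - alpha) * Wm
  P <- Matrix::solve(A, alpha * P0)
  as.matrix(P)
}
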