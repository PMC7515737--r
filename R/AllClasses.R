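setOldClass("igraph")

#' Column-stochastic transition matrix for random walk with restart
#'
#' Holds the normalized adjacency matrix W of an interaction network under one
#' of the four supported normalization schemes, together with the scheme name.
#' Columns are "from" nodes: entry \code{W[i, j]} is the probability of the
#' walker stepping from node j to its neighbor i, so every column sums to 1.
#'
#' @slot matrix sparse non-negative square \code{Matrix} with identical row and
#'   column names (the sorted node identifiers).
#' @slot scheme one of \code{"degree"}, \code{"core"}, \code{"diff"},
#'   \code{"ratio"}.
#' @seealso \code{\link{normalizeAdjacency}}
#' @export
setClass("TransitionMatrix",
         representation(matrix = "Matrix", scheme = "character"))

setValidity("TransitionMatrix", function(object) {
  W <- object@matrix
  if (nrow(W) != ncol(W)) return("matrix must be square")
  if (is.null(rownames(W)) || !identical(rownames(W), colnames(W)))
    return("row and column names must be identical node identifiers")
  if (!object@scheme %in% c("degree", "core", "diff", "ratio"))
    return("unknown normalization scheme")
  x <- W@x
  if (length(x) && any(x < 0)) return("matrix must be non-negative")
  cs <- Matrix::colSums(W)
  if (any(abs(cs - 1) > 1e-10))
    return("every column must sum to 1 within 1e-10 (stochasticity)")
  if (any(Matrix::diag(W) != 0)) return("self-transitions are not allowed")
  TRUE
})

#' Propagation result: per-node weights and permutation p-values
#'
#' @slot table \code{data.frame} with columns \code{gene}, \code{inputWeight},
#'   \code{degree}, \code{core}, \code{weight} (propagated), \code{rank},
#'   \code{pValue}, \code{significant}; sorted by rank. \code{pValue} is
#'   \code{NA} when no permutation ensemble was used.
#' @slot scheme normalization scheme used.
#' @slot alpha restart probability.
#' @slot nPermutations number of random networks behind the p-values (0 if
#'   none).
#' @seealso \code{\link{netPropagate}}, \code{\link{empiricalPvalues}}
#' @export
setClass("PropagationResult",
         representation(table = "data.frame", scheme = "character",
                        alpha = "numeric", nPermutations = "integer"))

setValidity("PropagationResult", function(object) {
  need <- c("gene", "inputWeight", "degree", "core", "weight", "rank",
            "pValue", "significant")
  if (!all(need %in% names(object@table)))
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@table$gene)) return("duplicated gene identifiers")
  n <- object@nPermutations
  p <- object@table$pValue
  if (n > 0L) {
    if (anyNA(p)) return("pValue must be set when nPermutations > 0")
    if (any(p < 1 / (n + 1) - 1e-12 | p > 1 + 1e-12))
      return("pValue must lie in [1/(n+1), 1]")
  }
  if (object@alpha <= 0 || object@alpha > 1) return("alpha must be in (0, 1]")
  TRUE
})

#' Network modules: connected components of a (possibly extended) seed sub-network
#'
#' @slot graph the sub-network as an \code{igraph} object.
#' @slot nodes \code{data.frame} with columns \code{gene}, \code{module}
#'   (integer id, 1 = largest), \code{isSeed}, \code{weight}, \code{pValue}.
#' @slot seeds seed genes present in the scaffold network.
#' @slot wMin weight admission threshold used for candidates (\code{NA} for a
#'   pure seed-induced sub-network, \code{Inf} when no extension was possible).
#' @seealso \code{\link{seedSubnetwork}}, \code{\link{extendSubnetwork}}
#' @export
setClass("ModuleSet",
         representation(graph = "igraph", nodes = "data.frame",
                        seeds = "character", wMin = "numeric"))

setValidity("ModuleSet", function(object) {
  need <- c("gene", "module", "isSeed", "weight", "pValue")
  if (!all(need %in% names(object@nodes)))
    return(paste("nodes must contain columns:", paste(need, collapse = ", ")))
  if (!setequal(object@nodes$gene, igraph::V(object@graph)$name))
    return("node table and graph disagree on the gene set")
  TRUE
})

#' Connectedness of seed genes across modules, measured by entropy
#'
#' The entropy E of the distribution of seed genes over modules (seeds not
#' covered by any module count as singleton 'modules') is compared to the
#' maximum entropy E_max = log(n) attained when every seed is isolated;
#' connectedness = E_max - E, in nats.
#'
#' @slot entropy observed entropy E.
#' @slot maxEntropy E_max = log(n).
#' @slot connectedness E_max - E.
#' @slot seedCounts integer seed counts per module (singletons included).
#' @slot nSeeds total number of seed genes n.
#' @export
setClass("ConnectednessReport",
         representation(entropy = "numeric", maxEntropy = "numeric",
                        connectedness = "numeric", seedCounts = "integer",
                        nSeeds = "integer"))

setValidity("ConnectednessReport", function(object) {
  if (sum(object@seedCounts) != object@nSeeds)
    return("seed counts must sum to the number of seeds")
  if (object@connectedness < -1e-12 ||
      object@connectedness > object@maxEntropy + 1e-12)
    return("connectedness must lie in [0, maxEntropy]")
  TRUE
})

#' Cross-validation result for one normalization scheme
#'
#' @slot scheme normalization scheme evaluated.
#' @slot foldAuroc AUROC per fold (trapezoid rule on the common-grid curve).
#' @slot auroc consensus AUROC (mean of per-fold AUROCs; equals the trapezoid
#'   area under the vertically averaged ROC curve).
#' @slot consensusRoc \code{data.frame} with \code{fpr} and \code{tpr} columns.
#' @slot foldRocs per-fold interpolated ROC curves (list of data.frames).
#' @slot folds named integer vector of fold assignments for the gene set.
#' @seealso \code{\link{crossValidate}}
#' @export
setClass("CVResult",
         representation(scheme = "character", foldAuroc = "numeric",
                        auroc = "numeric", consensusRoc = "data.frame",
                        foldRocs = "list", folds = "integer"))

## ---- generics ----

#' Node identifiers of an object
#' @param x a \code{TransitionMatrix}, \code{ModuleSet} or
#'   \code{PropagationResult}.
#' @return character vector of gene identifiers.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Normalization scheme of an object
#' @param x a \code{TransitionMatrix}, \code{PropagationResult} or
#'   \code{CVResult}.
#' @return scheme name.
#' @export
setGeneric("normScheme", function(x) standardGeneric("normScheme"))

#' Per-node result table
#' @param x a \code{PropagationResult} or \code{ModuleSet}.
#' @return \code{data.frame}.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' Propagated node weights
#' @param x a \code{PropagationResult}.
#' @return named numeric vector.
#' @export
setGeneric("propagatedWeights",
           function(x) standardGeneric("propagatedWeights"))

#' Empirical p-values of propagated weights
#' @param x a \code{PropagationResult}.
#' @return named numeric vector (NA when no permutations were run).
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' Modules as a list of gene vectors
#' @param x a \code{ModuleSet}.
#' @param minSize drop modules below this size (default 1 = keep all).
#' @return named list of character vectors, largest module first.
#' @export
setGeneric("modules", function(x, minSize = 1L) standardGeneric("modules"))

#' Module sizes
#' @param x a \code{ModuleSet}.
#' @return integer vector of module sizes, decreasing.
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' Seed genes of a module set
#' @param x a \code{ModuleSet}.
#' @return character vector.
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' Candidate weight admission threshold
#' @param x a \code{ModuleSet}.
#' @return numeric.
#' @export
setGeneric("wMin", function(x) standardGeneric("wMin"))

#' Area under the consensus ROC curve
#' @param x a \code{CVResult}.
#' @return numeric in [0, 1].
#' @export
setGeneric("auroc", function(x) standardGeneric("auroc"))

#' Connectedness score (E_max - E)
#' @param x a \code{ConnectednessReport}.
#' @return numeric, in nats.
#' @export
setGeneric("connectednessScore",
           function(x) standardGeneric("connectednessScore"))
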