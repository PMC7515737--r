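## accessors and show methods

#' @describeIn nodeNames node identifiers (column order of W)
#' @export
setMethod("nodeNames", "TransitionMatrix", function(x) colnames(x@matrix))

#' @describeIn nodeNames genes in the module node table
#' @export
setMethod("nodeNames", "ModuleSet", function(x) x@nodes$gene)

#' @describeIn nodeNames genes in the result table
#' @export
setMethod("nodeNames", "PropagationResult", function(x) x@table$gene)

#' @describeIn normScheme scheme of a transition matrix
#' @export
setMethod("normScheme", "TransitionMatrix", function(x) x@scheme)

#' @describeIn normScheme scheme used for a propagation run
#' @export
setMethod("normScheme", "PropagationResult", function(x) x@scheme)

#' @describeIn normScheme scheme evaluated in cross-validation
#' @export
setMethod("normScheme", "CVResult", function(x) x@scheme)

#' @describeIn resultTable per-node propagation table
#' @export
setMethod("resultTable", "PropagationResult", function(x) x@table)

#' @describeIn resultTable per-node module membership table
#' @export
setMethod("resultTable", "ModuleSet", function(x) x@nodes)

#' @describeIn propagatedWeights named vector of post-propagation weights
#' @export
setMethod("propagatedWeights", "PropagationResult", function(x)
  setNames(x@table$weight, x@table$gene))

#' @describeIn pValues named vector of empirical p-values
#' @export
setMethod("pValues", "PropagationResult", function(x)
  setNames(x@table$pValue, x@table$gene))

#' @describeIn modules gene membership per module
#' @export
setMethod("modules", "ModuleSet", function(x, minSize = 1L) {
  sp <- split(x@nodes$gene, x@nodes$module)
  sp <- sp[order(as.integer(names(sp)))]
  names(sp) <- paste0("M", names(sp))
  sp[lengths(sp) >= minSize]
})

#' @describeIn moduleSizes sizes of the connected components
#' @export
setMethod("moduleSizes", "ModuleSet", function(x)
  lengths(modules(x)))

#' @describeIn seedGenes seeds present in the scaffold network
#' @export
setMethod("seedGenes", "ModuleSet", function(x) x@seeds)

#' @describeIn wMin candidate admission threshold
#' @export
setMethod("wMin", "ModuleSet", function(x) x@wMin)

#' @describeIn auroc consensus AUROC
#' @export
setMethod("auroc", "CVResult", function(x) x@auroc)

#' @describeIn connectednessScore connectedness in nats
#' @export
setMethod("connectednessScore", "ConnectednessReport",
          function(x) x@connectedness)

#' Extract the sub-network of a module set
#' @param x a \code{ModuleSet}.
#' @return \code{igraph} object.
#' @export
moduleGraph <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  x@graph
}

#' Sparse transition matrix of a TransitionMatrix object
#' @param x a \code{TransitionMatrix}.
#' @return sparse \code{Matrix}.
#' @export
transitionMatrix <- function(x) {
  stopifnot(is(x, "TransitionMatrix"))
  x@matrix
}

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d x %d, scheme = '%s', %d non-zero entries\n",
              nrow(object@matrix), ncol(object@matrix), object@scheme,
              length(object@matrix@x)))
})

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf(
    "PropagationResult: %d genes, scheme = '%s', alpha = %g, %d permutations\n",
    nrow(object@table), object@scheme, object@alpha, object@nPermutations))
  if (object@nPermutations > 0L)
    cat(sprintf("  %d genes significant at p < 0.01\n",
                sum(object@table$significant)))
  cat("  top genes:",
      paste(utils::head(object@table$gene, 5L), collapse = ", "), "\n")
})

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat(sprintf(
    "ModuleSet: %d modules over %d genes (%d seeds, %d candidates)\n",
    length(sz), nrow(object@nodes), sum(object@nodes$isSeed),
    sum(!object@nodes$isSeed)))
  cat("  module sizes:", paste(utils::head(sz, 10L), collapse = ", "),
      if (length(sz) > 10L) "..." else "", "\n")
  if (!is.na(object@wMin)) cat(sprintf("  wMin = %g\n", object@wMin))
})

setMethod("show", "ConnectednessReport", function(object) {
  cat(sprintf(
    "ConnectednessReport: E = %.4f, E_max = %.4f, connectedness = %.4f (n = %d seeds, %d modules)\n",
    object@entropy, object@maxEntropy, object@connectedness, object@nSeeds,
    length(object@seedCounts)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: scheme = '%s', %d folds, consensus AUROC = %.3f\n",
              object@scheme, length(object@foldAuroc), object@auroc))
  cat("  per-fold AUROC:",
      paste(sprintf("%.3f", object@foldAuroc), collapse = ", "), "\n")
})
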