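#' Seed-induced sub-network
#'
#' Extracts the induced subgraph on the seed genes (the seeds and their
#' interconnecting edges) and reports its connected components as modules.
#' Seeds absent from the network are excluded with a message.
#'
#' @param graph scaffold network (\code{igraph} with named vertices).
#' @param seeds character vector of seed genes.
#' @param result optional \code{\link{PropagationResult}} used to annotate
#'   seed weights/p-values in the node table.
#' @return a \code{\link{ModuleSet}} with every node labelled as seed.
#' @export
seedSubnetwork <- function(graph, seeds, result = NULL) {
  .checkIgraph(graph)
  seeds <- unique(as.character(seeds))
  seedIn <- intersect(seeds, igraph::V(graph)$name)
  if (!length(seedIn))
    stop("none of the seed genes are present in the network")
  if (length(seedIn) < length(seeds))
    message(sprintf("seedSubnetwork: excluded %d seed(s) absent from the network",
                    length(seeds) - length(seedIn)))
  sub <- igraph::induced_subgraph(graph, seedIn)
  .makeModuleSet(sub, seedIn, result, wMin = NA_real_)
}

#' Minimum admission weight for module extension
#'
#' w_min is a percentile (default the 75th) of the propagated weights of the
#' significant nodes that are not already in the seed sub-network. Candidates
#' must exceed w_min strictly to be admitted by
#' \code{\link{extendSubnetwork}}. Percentiles use linear interpolation
#' between order statistics (\code{quantile} type 7) by default.
#'
#' @param result a \code{\link{PropagationResult}} with permutation p-values.
#' @param seeds seed genes (excluded from the percentile population).
#' @param percentile percentile in (0, 100); default 75.
#' @param pThreshold significance threshold (default 0.01, strict).
#' @param type quantile interpolation rule passed to \code{\link[stats]{quantile}}.
#' @return numeric w_min; \code{+Inf} with a warning when no significant
#'   non-seed node exists (extension would add nothing).
#' @examples
#' # weights {1,2,3,4} at the 75th percentile -> 3.25 under linear interpolation
#' quantile(1:4, 0.75, type = 7)
#' @export
computeWmin <- function(result, seeds, percentile = 75, pThreshold = 0.01,
                        type = 7) {
  stopifnot(is(result, "PropagationResult"))
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  if (result@nPermutations < 1L)
    stop("result carries no permutation p-values; run netPropagate with nPermutations > 0")
  tab <- result@table
  pop <- tab$weight[tab$pValue < pThreshold & !(tab$gene %in% seeds)]
  if (!length(pop)) {
    warning("no significant non-seed nodes; w_min = +Inf (no extension possible)")
    return(Inf)
  }
  unname(quantile(pop, percentile / 100, type = type))
}

#' Extend the seed sub-network with significant propagated neighbors
#'
#' Semi-supervised module identification: starting from the seed-induced
#' sub-network, every non-seed node satisfying all three admission filters --
#' (a) significant propagated weight (p < \code{pThreshold}, strict), (b)
#' direct neighbor of at least one seed, (c) propagated weight strictly above
#' w_min -- is added together with all of its edges to seed nodes. The
#' connected components of the extended sub-network are the reported modules.
#'
#' @inheritParams seedSubnetwork
#' @param result a \code{\link{PropagationResult}} with permutation p-values.
#' @param pThreshold significance threshold (default 0.01).
#' @param percentile percentile defining w_min when \code{wMin} is not given.
#' @param wMin override the admission weight threshold (default: computed by
#'   \code{\link{computeWmin}}).
#' @param includeCandidateEdges also keep edges between two admitted
#'   candidates (default \code{FALSE}: only candidate-to-seed edges are added,
#'   besides the seed-seed edges of the induced sub-network).
#' @return a \code{\link{ModuleSet}}; modules are numbered by decreasing size.
#' @export
extendSubnetwork <- function(graph, seeds, result, pThreshold = 0.01,
                             percentile = 75, wMin = NULL,
                             includeCandidateEdges = FALSE) {
  .checkIgraph(graph)
  stopifnot(is(result, "PropagationResult"))
  seeds <- unique(as.character(seeds))
  seedIn <- intersect(seeds, igraph::V(graph)$name)
  if (!length(seedIn))
    stop("none of the seed genes are present in the network")
  if (is.null(wMin))
    wMin <- computeWmin(result, seedIn, percentile, pThreshold)

  tab <- result@table
  cand <- tab$gene[!is.na(tab$pValue) & tab$pValue < pThreshold &
                     tab$weight > wMin & !(tab$gene %in% seedIn)]
  if (length(cand)) {
    # admission filter (b): at least one seed neighbor
    nbSeed <- vapply(cand, function(g) {
      nb <- igraph::neighbors(graph, g)$name
      any(nb %in% seedIn)
    }, NA)
    cand <- cand[nbSeed]
  }

  sub <- igraph::induced_subgraph(graph, c(seedIn, cand))
  if (!includeCandidateEdges && length(cand)) {
    el <- igraph::as_edgelist(sub)
    drop <- which(el[, 1L] %in% cand & el[, 2L] %in% cand)
    if (length(drop)) sub <- igraph::delete_edges(sub, drop)
  }
  .makeModuleSet(sub, seedIn, result, wMin = wMin)
}

#' Connectedness of seed genes across modules
#'
#' Computes the entropy E = -sum_i p_i log p_i of the seed distribution over
#' modules, with p_i = k_i / n the fraction of the n seeds falling in module
#' i; seeds not covered by any module are counted as singleton 'modules'. The
#' natural logarithm is used (connectedness ratios are base-invariant).
#' Connectedness is E_max - E with E_max = log n: it is 0 when every seed is
#' isolated and log n when all seeds share one module. Because extending a
#' sub-network can only merge seed components, connectedness of an extended
#' sub-network is never below that of the seed sub-network.
#'
#' @param moduleSet a \code{\link{ModuleSet}}.
#' @param seeds seed universe; defaults to \code{seedGenes(moduleSet)}. At
#'   least 2 seeds are required (the entropy is degenerate otherwise).
#' @return a \code{\link{ConnectednessReport}}.
#' @export
connectedness <- function(moduleSet, seeds = NULL) {
  stopifnot(is(moduleSet, "ModuleSet"))
  if (is.null(seeds)) seeds <- seedGenes(moduleSet)
  seeds <- unique(as.character(seeds))
  n <- length(seeds)
  if (n < 2L) stop("at least 2 seed genes are required")
  tab <- moduleSet@nodes
  covered <- tab[tab$gene %in% seeds, , drop = FALSE]
  counts <- as.integer(table(covered$module))
  nUncovered <- n - nrow(covered)
  counts <- c(counts, rep(1L, nUncovered))
  counts <- counts[counts > 0L]
  p <- counts / n
  E <- -sum(p * log(p)) + 0  # + 0 normalizes IEEE negative zero
  Emax <- log(n)
  new("ConnectednessReport", entropy = E, maxEntropy = Emax,
      connectedness = Emax - E, seedCounts = counts, nSeeds = as.integer(n))
}

#' Write module tables (nodes, edges) and optional GML
#'
#' @param moduleSet a \code{\link{ModuleSet}}.
#' @param prefix output path prefix; writes \code{<prefix>_nodes.tsv} and
#'   \code{<prefix>_edges.tsv} (and \code{<prefix>.gml} when \code{gml}).
#' @param minSize drop modules smaller than this from the written tables
#'   (default 2).
#' @param gml also export the sub-network as GML.
#' @return character vector of written paths, invisibly.
#' @export
writeModules <- function(moduleSet, prefix, minSize = 2L, gml = TRUE) {
  stopifnot(is(moduleSet, "ModuleSet"))
  tab <- moduleSet@nodes
  keepMods <- as.integer(names(which(table(tab$module) >= minSize)))
  nt <- tab[tab$module %in% keepMods, , drop = FALSE]
  names(nt) <- c("gene", "module_id", "is_seed", "weight", "p_value")
  nodesPath <- paste0(prefix, "_nodes.tsv")
  write.table(nt, nodesPath, sep = "\t", quote = FALSE, row.names = FALSE)

  el <- igraph::as_edgelist(moduleSet@graph)
  mod <- tab$module[match(el[, 1L], tab$gene)]
  et <- data.frame(node1 = el[, 1L], node2 = el[, 2L], module_id = mod,
                   stringsAsFactors = FALSE)
  et <- et[et$module_id %in% keepMods, , drop = FALSE]
  edgesPath <- paste0(prefix, "_edges.tsv")
  write.table(et, edgesPath, sep = "\t", quote = FALSE, row.names = FALSE)

  out <- c(nodesPath, edgesPath)
  if (gml) out <- c(out, exportGml(moduleSet, paste0(prefix, ".gml")))
  invisible(out)
}

#' Seed fallback from input weights
#'
#' When no curated seed list is available, the seed set is formed from the
#' highest input weights. Ties at the cutoff are broken lexicographically by
#' gene identifier for determinism.
#'
#' @param weights named numeric input weights.
#' @param n number of seed genes to take (default 100).
#' @return character vector of seed genes.
#' @export
topWeightSeeds <- function(weights, n = 100L) {
  if (is.null(names(weights))) stop("weights must be named by gene")
  ord <- order(-weights, names(weights))
  names(weights)[utils::head(ord, n)]
}

## internal ------------------------------------------------------------------

# Label connected components deterministically: decreasing size, then
# lexicographically smallest member.
.makeModuleSet <- function(sub, seedIn, result, wMin) {
  comp <- igraph::components(sub)
  memb <- comp$membership
  firstMember <- vapply(seq_len(comp$no), function(ci)
    min(names(memb)[memb == ci]), "")
  ord <- order(-comp$csize, firstMember)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  genes <- names(memb)
  w <- p <- rep(NA_real_, length(genes))
  if (!is.null(result)) {
    stopifnot(is(result, "PropagationResult"))
    idx <- match(genes, result@table$gene)
    w <- result@table$weight[idx]
    p <- result@table$pValue[idx]
  }
  nodes <- data.frame(gene = genes,
                      module = relabel[memb],
                      isSeed = genes %in% seedIn,
                      weight = w, pValue = p,
                      row.names = NULL, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$module, nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  new("ModuleSet", graph = sub, nodes = nodes, seeds = seedIn, wMin = wMin)
}
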