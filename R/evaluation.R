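#' Cross-validated benchmark of a normalization scheme
#'
#' Splits a phenotype gene set into k folds (validation:training 1:4 at the
#' default k = 5). For each fold, the training genes are propagated with a
#' binary scoring scheme (1 on training genes, 0 elsewhere), permutation
#' p-values are computed against an RDPN ensemble, and a ROC curve is built
#' from the p-values with the held-out validation genes as positives and
#' degree-matched random nodes as negatives. The per-fold curves are
#' vertically averaged on a common grid of \code{nGrid} evenly spaced FPR
#' points and the AUROC is computed by the trapezoid rule; the consensus AUROC
#' is the mean of the per-fold AUROCs and therefore always lies between the
#' per-fold extremes.
#'
#' The random-network ensemble depends only on the scaffold network, so a
#' single precomputed \code{ensemble} can (and should) be shared across folds,
#' schemes and repetitions.
#'
#' @inheritParams netPropagate
#' @param geneSet phenotype-associated gene set; at least \code{k} genes must
#'   be present in the network.
#' @param k number of folds (default 5).
#' @param nGrid FPR grid size for vertical ROC averaging (default 100).
#' @param negativeRatio negatives sampled per validation gene (default 1,
#'   i.e. size-matched).
#' @return a \code{\link{CVResult}}.
#' @export
crossValidate <- function(graph, geneSet,
                          scheme = c("core", "degree", "diff", "ratio"),
                          k = 5L, alpha = 0.8, nPermutations = 100L,
                          swapFactor = 100, ensemble = NULL, nGrid = 100L,
                          negativeRatio = 1, workers = 1L) {
  scheme <- match.arg(scheme)
  .checkPropagationGraph(graph)
  nodes <- sort(igraph::V(graph)$name)
  genes <- intersect(unique(as.character(geneSet)), nodes)
  if (length(genes) < k)
    stop(sprintf("gene set covers only %d network gene(s); need at least k = %d",
                 length(genes), k))
  fold <- sample(rep_len(seq_len(k), length(genes)))
  names(fold) <- genes

  if (is.null(ensemble))
    ensemble <- rdpnEnsemble(graph, nPermutations, swapFactor,
                             workers = workers)

  # binary p0 per fold, solved in one factorization per matrix
  P0 <- matrix(0, length(nodes), k, dimnames = list(nodes, NULL))
  for (f in seq_len(k)) P0[genes[fold != f], f] <- 1
  W <- normalizeAdjacency(graph, scheme)
  obs <- .rwrSolveMulti(W@matrix, P0, alpha)
  counts <- matrix(0L, length(nodes), k)
  for (g in ensemble) {
    We <- normalizeAdjacency(g, scheme)
    counts <- counts + (.rwrSolveMulti(We@matrix, P0, alpha) >= obs)
  }
  pmat <- (counts + 1) / (length(ensemble) + 1)
  rownames(pmat) <- nodes

  grid <- seq(0, 1, length.out = nGrid)
  foldRocs <- vector("list", k)
  foldAuroc <- numeric(k)
  for (f in seq_len(k)) {
    val <- genes[fold == f]
    if (!length(val)) stop("fold ", f, " has no validation genes")
    train <- setdiff(genes, val)
    neg <- degreeMatchedNegatives(graph, train,
                                  size = ceiling(negativeRatio * length(val)),
                                  exclude = genes)
    tpr <- .rocOnGrid(pmat[val, f], pmat[neg, f], grid)
    foldRocs[[f]] <- data.frame(fpr = grid, tpr = tpr)
    foldAuroc[f] <- .trapezoid(grid, tpr)
  }
  consensus <- data.frame(
    fpr = grid,
    tpr = rowMeans(vapply(foldRocs, function(r) r$tpr, numeric(nGrid))))
  new("CVResult", scheme = scheme, foldAuroc = foldAuroc,
      auroc = mean(foldAuroc), consensusRoc = consensus,
      foldRocs = foldRocs, folds = fold)
}

#' Degree-matched negative sampling
#'
#' Draws \code{size} nodes from the network whose degrees match the degree
#' distribution of \code{reference} genes: target degrees are resampled from
#' the reference degrees, and for each target the pool is searched without
#' replacement within a +/-10\% degree tolerance, widened by 1.5x until a
#' match exists.
#'
#' @param graph the network.
#' @param reference genes whose degree distribution is matched (typically the
#'   training set).
#' @param size number of negatives to draw.
#' @param exclude nodes never eligible (typically the full phenotype gene
#'   set).
#' @return character vector of sampled node identifiers.
#' @export
degreeMatchedNegatives <- function(graph, reference, size, exclude = reference) {
  .checkIgraph(graph)
  degs <- igraph::degree(graph)
  pool <- setdiff(names(degs), exclude)
  if (length(pool) < size)
    stop("not enough eligible nodes to sample negatives from")
  refd <- degs[intersect(reference, names(degs))]
  if (!length(refd)) stop("no reference genes present in the network")
  targets <- sample(refd, size, replace = TRUE)
  chosen <- character(0L)
  for (t in targets) {
    tol <- 0.1
    repeat {
      cand <- pool[abs(degs[pool] - t) <= pmax(1, tol * t)]
      if (length(cand)) break
      tol <- tol * 1.5
      if (tol > 1e6) stop("degree matching failed to find a candidate")
    }
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
  }
  chosen
}

#' Over-representation analysis of a module against pathway gene sets
#'
#' Hypergeometric tail test: with a background universe of N genes, a pathway
#' covering m of them and a module of size n overlapping the pathway in x
#' genes, the enrichment p-value is P(X >= x) for X hypergeometric(N, m, n).
#' Q-values are Benjamini-Hochberg corrected over all tested pathways; the
#' returned table is filtered to overlaps of at least \code{minOverlap}
#' (default 2) and p-values strictly below \code{pCutoff} (default 0.01), and
#' sorted by q-value.
#'
#' @param moduleGenes genes of one module; at least \code{minModuleSize}
#'   (default 10) of them must lie in the background.
#' @param collection named list of pathway gene sets (see
#'   \code{\link{readGmt}}).
#' @param background background gene universe (must cover the module).
#' @param minOverlap minimum module/pathway overlap to report.
#' @param pCutoff p-value cutoff (strict).
#' @param minModuleSize minimum module size tested.
#' @return \code{data.frame} with columns \code{pathway},
#'   \code{pathwaySize}, \code{moduleSize}, \code{overlap}, \code{pValue},
#'   \code{qValue}.
#' @export
oraHypergeometric <- function(moduleGenes, collection, background,
                              minOverlap = 2L, pCutoff = 0.01,
                              minModuleSize = 10L) {
  background <- unique(as.character(background))
  if (!length(background)) stop("background gene universe is empty")
  if (!length(collection)) stop("pathway collection is empty")
  if (is.null(names(collection))) stop("pathway collection must be named")
  mod <- intersect(unique(as.character(moduleGenes)), background)
  if (length(mod) < minModuleSize)
    stop(sprintf("module covers %d background gene(s); minimum size is %d",
                 length(mod), minModuleSize))
  N <- length(background)
  nMod <- length(mod)
  m <- vapply(collection, function(s) length(intersect(s, background)), 0L)
  x <- vapply(collection, function(s) length(intersect(intersect(s, background), mod)), 0L)
  p <- phyper(x - 1L, m, N - m, nMod, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(pathway = names(collection), pathwaySize = m,
                    moduleSize = nMod, overlap = x, pValue = p, qValue = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$overlap >= minOverlap & out$pValue < pCutoff, , drop = FALSE]
  out <- out[order(out$qValue, out$pValue, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT pathway gene-set collection
#'
#' @param path GMT file (set name TAB description TAB genes...).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Paired comparison of per-gene-set AUROCs between two schemes
#'
#' Reporting utility: Wilcoxon signed-rank test on matched AUROC values (one
#' value per gene set) from two normalization schemes.
#'
#' @param aurocA,aurocB numeric vectors of equal length.
#' @param alternative passed to \code{\link[stats]{wilcox.test}}; the default
#'   \code{"greater"} tests whether scheme A outperforms scheme B.
#' @return an object of class \code{htest}.
#' @export
compareSchemeAUROC <- function(aurocA, aurocB, alternative = "greater") {
  if (length(aurocA) != length(aurocB))
    stop("AUROC vectors must be matched (equal length)")
  wilcox.test(aurocA, aurocB, paired = TRUE, alternative = alternative,
              exact = FALSE)
}

## internal ------------------------------------------------------------------

# ROC from p-value scores (lower p = stronger prediction), interpolated onto
# a common FPR grid. Sweeps all achievable thresholds; curve anchored at
# (0,0) and (1,1).
.rocOnGrid <- function(pPos, pNeg, grid) {
  thr <- sort(unique(c(pPos, pNeg)))
  tpr <- vapply(thr, function(t) mean(pPos <= t), 0)
  fpr <- vapply(thr, function(t) mean(pNeg <= t), 0)
  approx(x = c(0, fpr, 1), y = c(0, tpr, 1), xout = grid,
         method = "linear", ties = max, rule = 2)$y
}

.trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}
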