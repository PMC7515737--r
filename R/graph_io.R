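#' Read an undirected interaction network from a tab-separated edge list
#'
#' Parses a 2- or 3-column TSV file (\code{node1 TAB node2 [TAB confidence]}).
#' Lines starting with \code{#} are treated as comments/header and skipped.
#' Self-loops and duplicate edges are removed so the result is a simple graph;
#' when a confidence column is present and \code{confidenceThreshold} is given,
#' only edges with confidence strictly above the threshold are kept (the
#' high-confidence extraction convention, e.g. "above 0.95").
#'
#' @param path path to the edge-list file.
#' @param confidenceThreshold numeric scalar in [0, 1] or \code{NULL}; edges
#'   with confidence \code{<= confidenceThreshold} are dropped. May only be
#'   given when the file has a confidence column.
#' @return an undirected simple \code{igraph} with vertex attribute \code{name}
#'   and, when present, edge attribute \code{confidence}. Nodes appearing only
#'   in dropped edges are excluded (a message reports the counts).
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb\t0.99", "b\tc\t0.96", "c\ta\t0.50"), f)
#' g <- readEdgeList(f, confidenceThreshold = 0.95)
#' igraph::ecount(g)  # 2
#' @export
readEdgeList <- function(path, confidenceThreshold = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineNo <- seq_along(lines)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (!length(lines)) stop("empty network: no edges in ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 2 or 3 tab-separated fields, found %d",
                 lineNo[bad[1L]], path, nf[bad[1L]]))
  hasConf <- all(nf == 3L)
  if (!hasConf && any(nf == 3L))
    stop(sprintf("malformed line %d in %s: inconsistent number of columns",
                 lineNo[which(nf == 3L)[1L]], path))
  if (!is.null(confidenceThreshold) && !hasConf)
    stop("confidenceThreshold given but the file has no confidence column")

  m <- matrix(unlist(lapply(fields, `[`, 1:2)), ncol = 2L, byrow = TRUE)
  conf <- NULL
  if (hasConf) {
    conf <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(conf))
      stop(sprintf("malformed line %d in %s: confidence is not numeric",
                   lineNo[which(is.na(conf))[1L]], path))
  }

  nEdgesIn <- nrow(m)
  nodesIn <- unique(c(m))

  if (!is.null(confidenceThreshold)) {
    keepE <- conf > confidenceThreshold
    m <- m[keepE, , drop = FALSE]
    conf <- conf[keepE]
  }
  if (!nrow(m)) stop("empty network: no edges left after confidence filtering")

  loops <- m[, 1L] == m[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    m <- m[!loops, , drop = FALSE]
    if (hasConf) conf <- conf[!loops]
  }
  if (!nrow(m)) stop("empty network: only self-loops present")

  # canonical order so duplicates (either orientation) collapse; first wins
  swap <- m[, 1L] > m[, 2L]
  m[swap, ] <- m[swap, 2:1]
  key <- paste(m[, 1L], m[, 2L], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed")
    m <- m[!dup, , drop = FALSE]
    if (hasConf) conf <- conf[!dup]
  }

  g <- igraph::graph_from_edgelist(m, directed = FALSE)
  if (hasConf) igraph::E(g)$confidence <- conf
  nDroppedNodes <- length(setdiff(nodesIn, igraph::V(g)$name))
  message(sprintf(
    "readEdgeList: kept %d nodes / %d edges (dropped %d edges, %d isolated nodes)",
    igraph::vcount(g), igraph::ecount(g), nEdgesIn - igraph::ecount(g),
    nDroppedNodes))
  g
}

#' Restrict a network to its largest connected component
#'
#' RWR propagation requires a connected scaffold. Ties in component size are
#' broken deterministically in favor of the component containing the
#' lexicographically smallest node identifier.
#'
#' @param graph an \code{igraph} object.
#' @return the induced subgraph on the largest component; a message reports how
#'   many nodes were excluded.
#' @export
largestConnectedComponent <- function(graph) {
  .checkIgraph(graph)
  comp <- igraph::components(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component holding the lexicographically smallest member
    firstMember <- vapply(best, function(ci)
      min(igraph::V(graph)$name[comp$membership == ci]), "")
    best <- best[which.min(rank(firstMember, ties.method = "first"))]
  }
  keep <- igraph::V(graph)[comp$membership == best]
  excluded <- igraph::vcount(graph) - length(keep)
  if (excluded > 0L)
    message(sprintf("largestConnectedComponent: excluded %d node(s) outside the largest component",
                    excluded))
  igraph::induced_subgraph(graph, keep)
}

#' Summarize an interaction network
#'
#' @param graph a connected \code{igraph}.
#' @return \code{data.frame} with one row per node: \code{gene},
#'   \code{degree}, \code{core} (same as \code{\link{nodeMetrics}}), plus
#'   attributes \code{nNodes} and \code{nEdges}.
#' @export
networkSummary <- function(graph) {
  met <- nodeMetrics(graph)
  attr(met, "nNodes") <- igraph::vcount(graph)
  attr(met, "nEdges") <- igraph::ecount(graph)
  met
}

#' Export a network or module sub-network as GML
#'
#' @param x an \code{igraph} or \code{\link{ModuleSet}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportGml <- function(x, path) {
  g <- if (is(x, "ModuleSet")) moduleGraph(x) else x
  .checkIgraph(g)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' Read a two-column gene/weight table
#'
#' @param path TSV file with columns gene and weight; \code{#} lines skipped.
#' @return named numeric vector of non-negative weights.
#' @export
readWeights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = c("character", "numeric"),
                    col.names = c("gene", "weight"))
  if (anyDuplicated(tab$gene)) stop("duplicated genes in weights file")
  if (any(!is.finite(tab$weight)) || any(tab$weight < 0))
    stop("weights must be finite and non-negative")
  setNames(tab$weight, tab$gene)
}

#' Read a seed-gene list (one gene per line)
#'
#' @param path text file; blank and \code{#} lines skipped.
#' @return character vector of unique gene identifiers.
#' @export
readSeeds <- function(path) {
  if (!file.exists(path)) stop("seed file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

## internal checks -----------------------------------------------------------

.checkIgraph <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("expected an igraph object")
  if (is.null(igraph::V(graph)$name))
    stop("network nodes must carry 'name' identifiers")
  invisible(graph)
}

.checkPropagationGraph <- function(graph) {
  .checkIgraph(graph)
  if (!igraph::is_simple(graph))
    stop("network must be a simple graph (no self-loops or multi-edges)")
  if (!igraph::is_connected(graph))
    stop("network must be connected; apply largestConnectedComponent() first")
  invisible(graph)
}
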