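# Independent oracles and small graph builders shared across tests.

# Brute-force coreness: for each k, iteratively delete nodes of degree < k;
# a node's core is the largest k at which it survives. Deliberately avoids
# igraph::coreness so it can serve as an independent oracle.
bruteCoreness <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  core <- setNames(integer(length(nodes)), nodes)
  maxd <- max(igraph::degree(g))
  for (k in seq_len(maxd)) {
    alive <- nodes
    edges <- el
    repeat {
      if (!length(alive)) break
      deg <- table(factor(c(edges), levels = alive))
      drop <- names(deg)[deg < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
      keep <- edges[, 1] %in% alive & edges[, 2] %in% alive
      edges <- edges[keep, , drop = FALSE]
    }
    core[alive] <- k
  }
  core
}

# Undirected named graph from literal edge pairs: graphFromEdges("a","b", "b","c")
graphFromEdges <- function(...) {
  e <- matrix(c(...), ncol = 2L, byrow = TRUE)
  igraph::graph_from_edgelist(e, directed = FALSE)
}

# Connected random graph with named vertices (largest component of a G(n, p))
randomConnectedGraph <- function(n, p = 3 / n) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    if (igraph::vcount(g) >= max(3L, n %/% 2L) && igraph::ecount(g) >= 2L)
      return(g)
  }
}

# 25-node / 29-edge network with three k-shells (max core 3): a K4 core,
# a 4-cycle middle shell tied to the core, and a 17-node tree periphery.
threeShellGraph <- function() {
  graphFromEdges(
    "c1","c2", "c1","c3", "c1","c4", "c2","c3", "c2","c4", "c3","c4",
    "m1","m2", "m2","m3", "m3","m4", "m4","m1", "m1","c1", "m3","c2",
    "c3","p01", "c4","p02", "m2","p03", "m4","p04", "m1","p05",
    "c2","p06", "c1","p07", "m3","p08", "c4","p09", "m2","p10",
    "c1","q1", "q1","q2", "q2","q3",
    "m2","r1", "r1","r2",
    "p01","s1", "p01","s2")
}

# fake PropagationResult for module-identification tests
fakeResult <- function(genes, weights, pvalues, n = 100L) {
  tab <- data.frame(gene = genes,
                    inputWeight = 0,
                    degree = 1L, core = 1L,
                    weight = weights,
                    rank = rank(-weights, ties.method = "min"),
                    pValue = pvalues,
                    significant = pvalues < 0.01,
                    stringsAsFactors = FALSE)
  new("PropagationResult", table = tab, scheme = "core", alpha = 0.8,
      nPermutations = n)
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))
quietly2 <- function(expr) suppressWarnings(expr)  # keep messages observable
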