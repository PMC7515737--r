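#' Workflow run configuration
#'
#' Bundles every path and parameter of an end-to-end run. Defaults follow the
#' recommended production settings: restart probability 0.8, 100 random
#' networks, swap factor 100, significance threshold p < 0.01 (the minimal
#' level attainable with 100 permutations), 75th-percentile weight threshold,
#' core normalization.
#'
#' @param network path to the edge-list TSV (required).
#' @param weights path to a gene/weight TSV, or \code{NULL}.
#' @param seeds path to a seed-gene list, or \code{NULL}.
#' @param gmt path to a GMT pathway collection, or \code{NULL}.
#' @param cacheDir directory for the RDPN ensemble cache, or \code{NULL}
#'   (in-memory ensemble).
#' @param outDir output directory (created if needed).
#' @param confidenceThreshold optional edge-confidence filter.
#' @param alpha restart probability.
#' @param nPermutations random networks for the permutation test.
#' @param swapFactor swap attempts per edge.
#' @param pThreshold significance threshold.
#' @param percentile w_min percentile.
#' @param scheme normalization scheme.
#' @param seed master RNG seed; all randomness of a run derives from it.
#' @param workers parallel workers for ensemble generation.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(network, weights = NULL, seeds = NULL, gmt = NULL,
                      cacheDir = NULL, outDir = ".",
                      confidenceThreshold = NULL, alpha = 0.8,
                      nPermutations = 100L, swapFactor = 100,
                      pThreshold = 0.01, percentile = 75,
                      scheme = c("core", "degree", "diff", "ratio"),
                      seed = 1L, workers = 1L) {
  scheme <- match.arg(scheme)
  .checkAlpha(alpha)
  cfg <- list(network = network, weights = weights, seeds = seeds, gmt = gmt,
              cacheDir = cacheDir, outDir = outDir,
              confidenceThreshold = confidenceThreshold, alpha = alpha,
              nPermutations = as.integer(nPermutations),
              swapFactor = swapFactor, pThreshold = pThreshold,
              percentile = percentile, scheme = scheme,
              seed = as.integer(seed), workers = as.integer(workers))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a key = value configuration file into a RunConfig
#'
#' Lines of the form \code{key = value}; \code{#} comments and blank lines
#' are ignored. Keys match the arguments of \code{\link{runConfig}}. Values
#' in \code{overrides} (e.g. from command-line flags) take precedence.
#'
#' @param path configuration file.
#' @param overrides named list of overriding values.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path, overrides = list()) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]])
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 2L)
  vals <- modifyList(vals, overrides)
  do.call(runConfig, vals)
}

#' Content hash of a network
#'
#' MD5 of the canonical (sorted, orientation-normalized) edge list; used to
#' key the RDPN ensemble cache to the exact input network.
#'
#' @param graph an \code{igraph}.
#' @return hex string.
#' @export
networkHash <- function(graph) {
  .checkIgraph(graph)
  el <- igraph::as_edgelist(graph)
  swap <- el[, 1L] > el[, 2L]
  el[swap, ] <- el[swap, 2:1]
  canon <- sort(paste(el[, 1L], el[, 2L], sep = "\t"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

#' Populate (or reuse) the on-disk RDPN ensemble cache
#'
#' Generating the random networks is the expensive step of the workflow but
#' depends only on the input network, so the ensemble is written once to
#' \code{cacheDir} -- one edge-list TSV per network plus a JSON manifest
#' recording the network hash, master seed, per-network seeds and swap
#' statistics -- and reused by later runs. A cache built from the same
#' network but a different seed, swap factor or size is refused unless
#' \code{force = TRUE}.
#'
#' @param cfg a \code{\link{runConfig}} with \code{cacheDir} set.
#' @param force overwrite a mismatching cache.
#' @return list of cached RDPN graphs, invisibly.
#' @export
runRandomize <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.null(cfg$cacheDir)) stop("cfg$cacheDir must be set for runRandomize")
  g <- .loadNetwork(cfg)
  key <- list(hash = networkHash(g), seed = cfg$seed,
              swapFactor = cfg$swapFactor, n = cfg$nPermutations)
  manifestPath <- file.path(cfg$cacheDir, "manifest.json")
  if (file.exists(manifestPath)) {
    man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    if (identical(man$key$hash, key$hash) && man$key$seed == key$seed &&
        man$key$swapFactor == key$swapFactor && man$key$n == key$n) {
      message("runRandomize: cache hit, reusing ", key$n, " random networks")
      return(invisible(.loadEnsembleCache(cfg$cacheDir, g)))
    }
    if (!force)
      stop("cache at ", cfg$cacheDir,
           " was built with a different network/seed/swap configuration; use force = TRUE to overwrite")
  }
  dir.create(cfg$cacheDir, recursive = TRUE, showWarnings = FALSE)
  ens <- withr::with_seed(cfg$seed,
    rdpnEnsemble(g, cfg$nPermutations, cfg$swapFactor, workers = cfg$workers))
  files <- sprintf("rdpn_%03d.tsv", seq_along(ens))
  for (i in seq_along(ens)) {
    el <- igraph::as_edgelist(ens[[i]])
    write.table(el, file.path(cfg$cacheDir, files[i]), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  man <- list(key = key, files = files,
              networkSeeds = attr(ens, "seeds"),
              accepted = vapply(ens, function(x) attr(x, "accepted"), 0),
              attempts = vapply(ens, function(x) attr(x, "attempts"), 0))
  jsonlite::write_json(man, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(ens)
}

#' Run network propagation end to end and write the ranking table
#'
#' Loads the network (confidence-filtered, reduced to its largest connected
#' component), the input weights or seed list, obtains the RDPN ensemble
#' (from the cache when configured), propagates, and writes
#' \code{propagation.tsv} plus a JSON run manifest into \code{cfg$outDir}.
#' All randomness derives from \code{cfg$seed}, so reruns with an identical
#' configuration and cache are byte-identical.
#'
#' @param cfg a \code{\link{runConfig}}; needs \code{weights} or \code{seeds}.
#' @return the \code{\link{PropagationResult}}, invisibly.
#' @export
runPropagate <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.null(cfg$weights) && is.null(cfg$seeds))
    stop("usage: configuration needs a weights table or a seed list")
  g <- .loadNetwork(cfg)
  w <- if (!is.null(cfg$weights)) readWeights(cfg$weights) else NULL
  s <- if (is.null(w) && !is.null(cfg$seeds)) readSeeds(cfg$seeds) else NULL

  ens <- if (!is.null(cfg$cacheDir)) runRandomize(cfg) else NULL
  res <- withr::with_seed(cfg$seed + 1L,
    netPropagate(g, weights = w, seeds = s, scheme = cfg$scheme,
                 alpha = cfg$alpha, nPermutations = cfg$nPermutations,
                 swapFactor = cfg$swapFactor, ensemble = ens,
                 pThreshold = cfg$pThreshold, workers = cfg$workers))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  writeRanking(res, file.path(cfg$outDir, "propagation.tsv"))
  .writeManifest(cfg, g, file.path(cfg$outDir, "propagate_manifest.json"),
                 extra = list(stage = "propagate",
                              inputGenesDropped = if (!is.null(w))
                                sum(!(names(w) %in% igraph::V(g)$name)) else
                                sum(!(s %in% igraph::V(g)$name))))
  invisible(res)
}

#' Identify network modules and write module reports
#'
#' Runs (or reuses) the propagation, determines the seed set -- the supplied
#' seed list, or the top-100 genes by input weight when no list is given --
#' and writes the module node/edge tables, the extended sub-network as GML,
#' a connectedness JSON (seed sub-network vs extended sub-network) and a run
#' manifest into \code{cfg$outDir}.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param result optional precomputed \code{\link{PropagationResult}}.
#' @return the extended \code{\link{ModuleSet}}, invisibly.
#' @export
runModules <- function(cfg, result = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.null(cfg$weights) && is.null(cfg$seeds))
    stop("usage: configuration needs a weights table or a seed list")
  g <- .loadNetwork(cfg)
  if (is.null(result)) result <- runPropagate(cfg)

  if (!is.null(cfg$seeds)) {
    seeds <- readSeeds(cfg$seeds)
    seedSource <- "user list"
  } else {
    w <- readWeights(cfg$weights)
    w <- w[names(w) %in% igraph::V(g)$name]
    seeds <- topWeightSeeds(w, 100L)
    seedSource <- "top-100 input weights (fallback)"
    message("runModules: no seed list supplied; using the top 100 genes by input weight")
  }

  ss <- seedSubnetwork(g, seeds, result)
  ext <- extendSubnetwork(g, seeds, result, pThreshold = cfg$pThreshold,
                          percentile = cfg$percentile)
  if (nrow(ext@nodes) == nrow(ss@nodes))
    warning("no significant candidates; modules equal the seed components")

  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  writeModules(ext, file.path(cfg$outDir, "modules"), minSize = 2L)
  connJson <- list(
    seedSubnetwork = .connAsList(connectedness(ss)),
    extendedSubnetwork = .connAsList(connectedness(ext)),
    wMin = ext@wMin)
  jsonlite::write_json(connJson, file.path(cfg$outDir, "connectedness.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeManifest(cfg, g, file.path(cfg$outDir, "modules_manifest.json"),
                 extra = list(stage = "modules", seedSource = seedSource,
                              nSeeds = length(ext@seeds),
                              nModules = length(moduleSizes(ext)),
                              wMin = ext@wMin))
  invisible(ext)
}

## internal ------------------------------------------------------------------

# read cached RDPN edge lists back into igraph objects, keeping the full
# vertex set of the original network
.loadEnsembleCache <- function(cacheDir, graph) {
  man <- jsonlite::read_json(file.path(cacheDir, "manifest.json"),
                             simplifyVector = TRUE)
  nm <- igraph::V(graph)$name
  lapply(man$files, function(f) {
    el <- as.matrix(read.table(file.path(cacheDir, f), sep = "\t",
                               colClasses = "character"))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    missing <- setdiff(nm, igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                   name = missing)
    g
  })
}

.loadNetwork <- function(cfg) {
  g <- readEdgeList(cfg$network, cfg$confidenceThreshold)
  largestConnectedComponent(g)
}

.connAsList <- function(rep) {
  list(entropy = rep@entropy, maxEntropy = rep@maxEntropy,
       connectedness = rep@connectedness, nSeeds = rep@nSeeds,
       seedCounts = rep@seedCounts)
}

.writeManifest <- function(cfg, graph, path, extra = list()) {
  man <- c(list(config = unclass(cfg),
                networkHash = networkHash(graph),
                nNodes = igraph::vcount(graph),
                nEdges = igraph::ecount(graph),
                packageVersion = as.character(utils::packageVersion("coreprop")),
                rVersion = R.version.string),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
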