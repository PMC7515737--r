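test_that("seed sub-network components follow the induced edges", {
  g <- graphFromEdges("a","b", "b","x", "x","c")
  ms <- seedSubnetwork(g, c("a", "b", "c"))
  expect_setequal(nodeNames(ms), c("a", "b", "c"))
  expect_equal(unname(moduleSizes(ms)), c(2L, 1L))
  expect_setequal(modules(ms)$M1, c("a", "b"))

  clique <- igraph::make_full_graph(4)
  igraph::V(clique)$name <- letters[1:4]
  expect_equal(length(moduleSizes(seedSubnetwork(clique, letters[1:4]))), 1L)

  expect_error(seedSubnetwork(g, c("zz")), "none of the seed genes")
  expect_message(seedSubnetwork(g, c("a", "b", "zz")), "excluded 1")
})

test_that("a sparse 78-seed layout yields many small components", {
  # 78 seed genes with exactly 14 interconnecting edges: 5 pairs, 3 paths of
  # three, one path of four, 55 isolated seeds; background connectors keep the
  # full network connected.
  seeds <- sprintf("s%02d", 1:78)
  seedEdges <- c(rbind(seeds[seq(1, 9, 2)], seeds[seq(2, 10, 2)]))         # 5 pairs
  paths3 <- c("s11","s12", "s12","s13", "s14","s15", "s15","s16",
              "s17","s18", "s18","s19")                                    # 3 paths of 3
  path4 <- c("s20","s21", "s21","s22", "s22","s23")                        # 1 path of 4
  hubEdges <- c(rbind("hub", seeds))                                       # connectors
  g <- graphFromEdges(c(seedEdges, paths3, path4, hubEdges))
  ms <- seedSubnetwork(g, seeds)
  expect_equal(nrow(resultTable(ms)), 78L)
  expect_equal(igraph::ecount(moduleGraph(ms)), 14L)
  sz <- moduleSizes(ms)
  expect_true(all(sz >= 1L & sz <= 5L))
  expect_equal(sum(sz), 78L)
})

test_that("w_min is the interpolated percentile of significant non-seed weights", {
  genes <- c("seed1", "seed2", "a", "b", "c", "d", "e")
  res <- fakeResult(genes,
                    weights = c(9, 8, 1, 2, 3, 4, 7),
                    pvalues = c(0.5, 1 / 101, 1 / 101, 1 / 101, 1 / 101, 1 / 101, 0.5))
  # significant non-seed weights {1,2,3,4}; 75th percentile by linear interpolation
  expect_equal(computeWmin(res, c("seed1", "seed2")), 3.25)
  # a single significant non-seed node: its own weight
  res1 <- fakeResult(c("seed1", "a"), c(5, 2), c(0.5, 1 / 101))
  expect_equal(computeWmin(res1, "seed1"), 2)
  # all significant nodes are seeds: +Inf sentinel with warning
  resS <- fakeResult(c("seed1", "a"), c(5, 2), c(1 / 101, 0.5))
  expect_warning(w <- computeWmin(resS, "seed1"), "Inf")
  expect_identical(w, Inf)
})

test_that("extension admits only significant, high-weight seed neighbors", {
  # two disconnected seeds bridged by one candidate; a second candidate fails p
  g <- graphFromEdges("s1","cand", "cand","s2", "s1","bad", "s2","far",
                      "far","cand")
  res <- fakeResult(c("s1", "s2", "cand", "bad", "far"),
                    weights = c(1, 1, 10, 10, 10),
                    pvalues = c(0.5, 0.5, 1 / 101, 0.02, 0.5))
  ext <- extendSubnetwork(g, c("s1", "s2"), res, wMin = 5)
  expect_setequal(nodeNames(ext), c("s1", "s2", "cand"))
  expect_equal(length(moduleSizes(ext)), 1L)  # seed components merged
  expect_true(igraph::are_adjacent(moduleGraph(ext), "cand", "s1"))
  expect_true(igraph::are_adjacent(moduleGraph(ext), "cand", "s2"))
  tab <- resultTable(ext)
  expect_false(tab$isSeed[tab$gene == "cand"])

  # p = 0.02 at the default threshold: excluded regardless of weight
  expect_false("bad" %in% nodeNames(ext))
})

test_that("a hub neighbor of disconnected seeds forms one 11-node module", {
  seeds <- sprintf("s%02d", 1:10)
  edges <- c(rbind("hub", seeds), "hub", "out", "out", "other")
  g <- graphFromEdges(edges)
  # 'out' is significant too but low-weight (and keeps w_min below the hub's
  # weight, which the strict w > w_min rule requires for admission)
  res <- fakeResult(c(seeds, "hub", "out", "other"),
                    weights = c(rep(1, 10), 50, 0.1, 0.1),
                    pvalues = c(rep(0.5, 10), 1 / 101, 1 / 101, 0.5))
  ext <- extendSubnetwork(g, seeds, res)
  expect_false("out" %in% nodeNames(ext))  # significant but not seed-adjacent
  expect_equal(unname(moduleSizes(ext)), 11L)
  expect_setequal(modules(ext)$M1, c(seeds, "hub"))
})

test_that("candidate-candidate edges are kept only when requested", {
  g <- graphFromEdges("s1","c1", "s1","c2", "c1","c2")
  res <- fakeResult(c("s1", "c1", "c2"), c(1, 10, 10),
                    c(0.5, 1 / 101, 1 / 101))
  ext <- extendSubnetwork(g, "s1", res, wMin = 5)
  expect_false(igraph::are_adjacent(moduleGraph(ext), "c1", "c2"))
  extCC <- extendSubnetwork(g, "s1", res, wMin = 5,
                            includeCandidateEdges = TRUE)
  expect_true(igraph::are_adjacent(moduleGraph(extCC), "c1", "c2"))
})

test_that("connectedness matches analytic entropy cases", {
  clique <- igraph::make_full_graph(4)
  igraph::V(clique)$name <- letters[1:4]
  one <- connectedness(seedSubnetwork(clique, letters[1:4]))
  expect_equal(one@entropy, 0)
  expect_equal(connectednessScore(one), log(4))

  iso <- igraph::make_empty_graph(n = 4, directed = FALSE)
  igraph::V(iso)$name <- letters[1:4]
  all1 <- connectedness(seedSubnetwork(iso, letters[1:4]))
  expect_equal(connectednessScore(all1), 0)
  expect_equal(all1@maxEntropy, log(4))

  # 4 seeds split 2 + 2: connectedness = log 4 - log 2 = log 2
  g22 <- graphFromEdges("a","b", "c","d")
  half <- connectedness(seedSubnetwork(g22, letters[1:4]))
  expect_equal(half@entropy, log(2))
  expect_equal(connectednessScore(half), log(2))

  # uncovered seeds count as singletons
  gx <- graphFromEdges("a","b", "b","c")
  ms <- seedSubnetwork(gx, c("a", "b"))
  rep2 <- connectedness(ms, seeds = c("a", "b", "zz", "ww"))
  expect_equal(rep2@nSeeds, 4L)
  expect_equal(sum(rep2@seedCounts), 4L)

  expect_error(connectedness(seedSubnetwork(gx, "a")), "at least 2")
})

test_that("extension never decreases connectedness and filters are monotone", {
  for (s in 1:4) {
    fx <- syntheticFixture(nNodes = 150, plantedSizes = 25,
                           plantedDensity = 0.25, nStars = 1, starSize = 5,
                           rngSeed = 100 + s)
    res <- quietly(netPropagate(fx$network, weights = fx$weights,
                                nPermutations = 100, swapFactor = 5))
    ss <- quietly(seedSubnetwork(fx$network, fx$seeds, res))
    ext <- quietly(extendSubnetwork(fx$network, fx$seeds, res))
    expect_gte(connectednessScore(connectedness(ext)),
               connectednessScore(connectedness(ss)))
    expect_gte(nrow(resultTable(ext)), nrow(resultTable(ss)))
    expect_gte(igraph::ecount(moduleGraph(ext)),
               igraph::ecount(moduleGraph(ss)))
    # every candidate passes all three admission filters
    tab <- resultTable(ext)
    cand <- tab$gene[!tab$isSeed]
    if (length(cand)) {
      pv <- pValues(res)[cand]
      w <- propagatedWeights(res)[cand]
      expect_true(all(pv < 0.01))
      expect_true(all(w > wMin(ext)))
      expect_true(all(vapply(cand, function(x)
        any(igraph::neighbors(fx$network, x)$name %in% fx$seeds), NA)))
    }
    # stricter p-threshold / higher percentile never admit more nodes
    extStrict <- quietly(extendSubnetwork(fx$network, fx$seeds, res,
                                          pThreshold = 0.005))
    extHigh <- quietly(extendSubnetwork(fx$network, fx$seeds, res,
                                        percentile = 90))
    expect_lte(nrow(resultTable(extStrict)), nrow(resultTable(ext)))
    expect_lte(nrow(resultTable(extHigh)), nrow(resultTable(ext)))
    # reported modules are exactly the connected components
    comp <- igraph::components(moduleGraph(ext))
    expect_equal(length(moduleSizes(ext)), comp$no)
  }
})

test_that("top-weight seed fallback breaks ties lexicographically", {
  w <- c(b = 3, a = 3, d = 1, c = 2)
  expect_identical(topWeightSeeds(w, 2), c("a", "b"))
  expect_identical(topWeightSeeds(w, 3), c("a", "b", "c"))
})
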