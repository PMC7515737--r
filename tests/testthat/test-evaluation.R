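test_that("ORA p-values match exact hypergeometric summation", {
  background <- sprintf("b%02d", 1:20)
  pathway <- background[1:5]
  module <- c(background[1:4], background[10:15])  # 10 genes, overlap 4
  tab <- oraHypergeometric(module, list(pw = pathway), background,
                           pCutoff = 2)
  # independent oracle: direct summation of the hypergeometric pmf, P(X >= 4)
  N <- 20; m <- 5; k <- 10
  pExact <- sum(vapply(4:5, function(x)
    choose(m, x) * choose(N - m, k - x), 0)) / choose(N, k)
  expect_equal(tab$pValue[tab$pathway == "pw"], pExact, tolerance = 1e-12)
  expect_equal(tab$overlap[tab$pathway == "pw"], 4L)
})

test_that("ORA oracle equivalence holds across random small instances", {
  set.seed(51)
  for (i in 1:20) {
    N <- sample(15:50, 1)
    background <- sprintf("g%03d", seq_len(N))
    pathway <- sample(background, sample(3:10, 1))
    module <- sample(background, sample(10:min(15, N), 1))
    x <- length(intersect(pathway, module))
    tab <- oraHypergeometric(module, list(pw = pathway), background,
                             minOverlap = 0L, pCutoff = 2)
    m <- length(pathway); k <- length(intersect(module, background))
    pExact <- sum(vapply(x:min(m, k), function(xx)
      choose(m, xx) * choose(N - m, k - xx), 0)) / choose(N, k)
    expect_equal(tab$pValue, pExact, tolerance = 1e-12)
  }
})

test_that("ORA applies the overlap and p-value filters", {
  background <- sprintf("b%02d", 1:30)
  module <- background[1:10]
  coll <- list(hit = background[1:6],          # overlap 6, enriched
               single = c(background[1], background[25:29]),  # overlap 1
               null = background[20:25])       # overlap 0
  tab <- oraHypergeometric(module, coll, background)
  expect_false("single" %in% tab$pathway)      # min overlap 2
  expect_false("null" %in% tab$pathway)
  # a pathway equal to the whole background can never be enriched: p = 1
  tabAll <- oraHypergeometric(module, list(all = background), background,
                              pCutoff = 2)
  expect_equal(tabAll$pValue, 1)
  # q-values are BH-ordered with p-values
  expect_true(all(diff(tab$qValue) >= 0))
  expect_error(oraHypergeometric(module, coll, character(0)), "empty")
  expect_error(oraHypergeometric(background[1:3], coll, background),
               "minimum size")
})

test_that("the bundled GMT reader feeds ORA on the synthetic fixture", {
  gmt <- readGmt(system.file("extdata", "synthetic_pathways.gmt",
                             package = "coreprop"))
  expect_named(gmt)
  expect_true("planted_module" %in% names(gmt))
  ppi <- suppressMessages(readEdgeList(
    system.file("extdata", "synthetic_ppi.tsv", package = "coreprop")))
  seeds <- readSeeds(system.file("extdata", "synthetic_seeds.txt",
                                 package = "coreprop"))
  bg <- igraph::V(ppi)$name
  planted <- intersect(gmt$planted_module, bg)
  tab <- oraHypergeometric(planted, gmt, bg)
  expect_true("planted_module" %in% tab$pathway)
  expect_lt(tab$pValue[tab$pathway == "planted_module"], 1e-6)
})

test_that("degree-matched negatives track the reference degree distribution", {
  fx <- syntheticFixture(nNodes = 400, plantedSizes = 40, rngSeed = 52)
  g <- fx$network
  set.seed(52)
  neg <- degreeMatchedNegatives(g, fx$planted, size = 30,
                                exclude = fx$planted)
  expect_length(neg, 30)
  expect_length(unique(neg), 30)            # without replacement
  expect_true(!any(neg %in% fx$planted))
  mRef <- mean(igraph::degree(g)[fx$planted])
  mNeg <- mean(igraph::degree(g)[neg])
  expect_lt(abs(mNeg - mRef) / mRef, 0.2)
})

test_that("ROC machinery recovers chance and perfect separability", {
  grid <- seq(0, 1, length.out = 100)
  set.seed(53)
  # random scores: AUROC ~ 0.5 over 20 repetitions
  aurocs <- replicate(20, {
    pPos <- sample(seq(1, 101) / 101, 50, replace = TRUE)
    pNeg <- sample(seq(1, 101) / 101, 50, replace = TRUE)
    coreprop:::.trapezoid(grid, coreprop:::.rocOnGrid(pPos, pNeg, grid))
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
  # perfect separation: every positive outranks every negative
  tpr <- coreprop:::.rocOnGrid(rep(1 / 101, 20), rep(0.5, 20), grid)
  expect_equal(coreprop:::.trapezoid(grid, tpr), 1.0)
})

test_that("cross-validation returns coherent fold structure and AUROCs", {
  fx <- syntheticFixture(nNodes = 250, plantedSizes = 40,
                         plantedDensity = 0.25, rngSeed = 54)
  g <- fx$network
  set.seed(54)
  ens <- quietly(rdpnEnsemble(g, n = 30, swapFactor = 5))
  cv <- quietly(crossValidate(g, fx$planted, "core", ensemble = ens))
  expect_s4_class(cv, "CVResult")
  expect_length(cv@foldAuroc, 5L)
  expect_true(all(cv@foldAuroc >= 0 & cv@foldAuroc <= 1))
  expect_gte(auroc(cv), min(cv@foldAuroc))
  expect_lte(auroc(cv), max(cv@foldAuroc))
  # folds partition the covered gene set at ~1:4 validation:training
  expect_setequal(names(cv@folds), fx$planted)
  expect_true(all(table(cv@folds) >= floor(length(fx$planted) / 5)))
  # planted community held-out genes are recovered far above chance
  expect_gt(auroc(cv), 0.6)
  expect_error(crossValidate(g, fx$planted[1:3], "core", ensemble = ens),
               "at least")
})

test_that("the synthetic fixture is reproducible and shaped as designed", {
  fx1 <- syntheticFixture(nNodes = 120, plantedSizes = 15, nStars = 2,
                          starSize = 8, rngSeed = 55)
  fx2 <- syntheticFixture(nNodes = 120, plantedSizes = 15, nStars = 2,
                          starSize = 8, rngSeed = 55)
  expect_identical(igraph::as_edgelist(fx1$network),
                   igraph::as_edgelist(fx2$network))
  expect_identical(fx1$weights, fx2$weights)
  expect_identical(fx1$seeds, fx2$seeds)

  met <- nodeMetrics(fx1$network)
  hubs <- grep("_hub", met$gene)
  expect_true(all(met$degree[hubs] == 9L))  # starSize + anchor
  expect_true(all(met$core[hubs] == 1L))    # high degree, minimal core

  # planted members carry elevated weights
  expect_gt(mean(fx1$weights[fx1$planted]), mean(fx1$weights) + 0.5)
  expect_true(all(fx1$seeds %in% fx1$planted))

  # a planted clique is the densest structure: core = clique size - 1
  fxC <- syntheticFixture(nNodes = 80, attachM = 1, plantedSizes = 8,
                          plantedDensity = 1, nStars = 0, rngSeed = 56)
  metC <- nodeMetrics(fxC$network)
  expect_true(all(metC$core[metC$gene %in% fxC$planted] == 7L))

  expect_error(syntheticFixture(plantedDensity = 1.5), "density")
})

test_that("scheme AUROC comparison runs a paired signed-rank test", {
  a <- c(0.8, 0.75, 0.9, 0.85, 0.7)
  b <- c(0.7, 0.72, 0.8, 0.8, 0.71)
  ht <- compareSchemeAUROC(a, b)
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.2)
  expect_error(compareSchemeAUROC(a, b[-1]), "matched")
})
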