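# coreprop

Core-weighted network propagation and semi-supervised disease-module
identification over protein–protein interaction (PPI) networks.

## What it does and for whom

Gene-level scores from genomics experiments (GWAS −log10 p-values, mutation
significance, any per-gene summary) are noisy and sparse; propagating them
over a PPI network pools evidence across interacting genes. The standard
random walk with restart (RWR) normalizes its transition matrix by node
*degree* — but PPI degree is inflated by bait/prey experimental designs and
study frequency, so degree-normalized walks gravitate toward
technically-overconnected hubs. `coreprop` instead normalizes by node
*coreness* (the k-shell index): a star hub has high degree but core 1, so
the walk is steered toward genuinely dense neighborhoods.

The package is aimed at computational biologists who have (a) an undirected
PPI edge list, (b) per-gene weights and/or a curated seed-gene list, and
want re-ranked genes with permutation significance and connected network
modules around the seeds.

## The method

1. **Propagation.** `p = α (I − (1−α) W)^{−1} p₀` with restart α = 0.8 by
   default; `W` is column-stochastic under one of four schemes: `degree`
   (`W = AD^{−1}`), `core` (entry `(i,j) = k_i / Σ_{l∈N(j)} k_l`), `diff`
   (raw `1/((d_i−k_i)+1)`, column-rescaled), `ratio` (raw `k_i/d_i`,
   column-rescaled).
2. **Significance.** Each node's propagated weight is compared to its weight
   on `n = 100` random networks with the same degree sequence (connectivity
   -preserving double-edge swaps; cores recomputed per network):
   `p_v = (#{i : w_i(v) ≥ w(v)} + 1)/(n + 1)`, so the smallest achievable
   p-value is 1/101 ≈ 0.0099.
3. **Modules.** The seed-induced sub-network is extended with every
   significant (`p < 0.01`), seed-adjacent node whose weight exceeds the
   75th percentile of the significant non-sub-network weights (`w_min`);
   connected components of the result are the modules. Seed consolidation
   is measured as `connectedness = log n − E`, the entropy gap of the seed
   distribution over modules.

Evaluation utilities (5-fold CV with degree-matched negatives and averaged
ROC/AUROC, hypergeometric over-representation analysis of modules against
GMT collections) and a synthetic scale-free generator with planted dense
communities round out the package.

## Worked example

A synthetic study: a 500-node scale-free scaffold with three bait-style star
motifs, one sparsely wired 50-gene planted community (within-community edge
density 0.06, so the community does not show up as connected components on
its own), and a curated list of 25 of its members as seeds, scored with the
binary scheme:

```r
library(coreprop)
fx <- syntheticFixture(nNodes = 500, plantedSizes = 50, plantedDensity = 0.06,
                       nStars = 3, starSize = 10, plantedShift = 6, rngSeed = 7)
set.seed(7)
res <- netPropagate(fx$network, seeds = fx$seeds, scheme = "core",
                    nPermutations = 100, swapFactor = 20)
res
connectedness(seedSubnetwork(fx$network, fx$seeds, res))
ext <- extendSubnetwork(fx$network, fx$seeds, res)
ext
connectedness(ext)
```

which prints:

```
PropagationResult: 533 genes, scheme = 'core', alpha = 0.8, 100 permutations
  7 genes significant at p < 0.01
  top genes: g0237, g0271, g0063, g0194, g0284
ConnectednessReport: E = 1.4191, E_max = 3.2189, connectedness = 1.7998 (n = 25 seeds, 8 modules)
ModuleSet: 6 modules over 26 genes (25 seeds, 1 candidates)
  module sizes: 17, 5, 1, 1, 1, 1
  wMin = 0.113245
ConnectednessReport: E = 1.1225, E_max = 3.2189, connectedness = 2.0963 (n = 25 seeds, 6 modules)
```

Reading: 7 genes beat all 100 degree-preserving random networks (the
minimal achievable p-value, 1/101 ≈ 0.0099). The seed-induced sub-network
fragments into 8 components (connectedness 1.80 of a possible
log 25 = 3.22); admitting the significant, high-weight seed neighbors merges
seed components into a 17-gene largest module and raises connectedness to
2.10 — extension can only consolidate seeds, never disperse them. File-based
input works the same way (`readEdgeList(path, confidenceThreshold = 0.95)`
drops low-confidence edges; see the small TSV/GMT examples under
`inst/extdata/`), and the same pipeline is available from the shell via
`exec/coreprop` (`randomize | propagate | modules | evaluate | simulate`
subcommands).

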