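# commotif

Cell–cell communication networks, directed motif census with a
degree-preserving null, and tumor-microenvironment (TME) subtyping — as a
tested, reusable R package.

## The problem

Single-cell atlases of tumors let us ask not just *which* cell types are
present but *how they signal to each other*. A common analysis chain is:
score ligand–receptor activity between annotated cell types, view the
result as a weighted directed network, and then ask structural questions —
which cell type drives the network (the root, by weighted outdegree), how
the others arrange into layers below it, and which small interaction
patterns (2–4-node *motifs* such as feed-forward loops) are
over-represented relative to chance. "Chance" here is the degree-preserving
rewiring null: random networks with every node's in- and out-degree, and
the multiset of edge weights, held exactly fixed. Each motif class is
scored by its **sum strength** — total communication weight over all its
instances — and compared to the null ensemble by z-score and empirical
p-value. Downstream, single-sample enrichment scores of cell-type
signatures subtype bulk cohorts into immune interaction patterns
(barrier-dominant, exhaustion-dominant, both, desert).

`commotif` implements this entire chain for anyone with labeled
expression matrices and a ligand–receptor pair table — plus synthetic
generators (negative-binomial single-cell counts with planted signaling,
digraphs with exact degree sequences and planted motifs, bulk mixtures
with planted subtypes) so every claim the package makes is testable
without any external download.

Core quantities, in the field's usual notation:

- communication strength: `LR / (k_h + LR)` with `L`, `R` trimmed-mean
  log-normalized ligand/receptor expression in sender/receiver,
  `k_h = 0.5`;
- motif significance: `z = (obs − mean_null) / sd_null`,
  `p = (1 + #{null ≥ obs}) / (1 + n_random)` over independently rewired
  degree-preserving networks;
- subtyping: ssGSEA scores → Ward.D2 / k-means over k = 2..10, k chosen
  by mean silhouette.

## Worked example

Plant 8 weight-boosted feed-forward loops in a 15-node communication
network with all in/out degrees equal to 3, census its 3-node motifs, and
test them against 500 rewired networks:

```r
library(commotif)

spec <- graphSimSpec(rep(3, 15), rep(3, 15),
                     planted_motifs = list(list(class = "ffl", count = 8,
                                                boost = 8)),
                     seed = 1)
net <- simulateCommGraph(spec)
net
#> CommNetwork: 15 nodes, 45 directed edges
#>   weight range [0.09896, 5.679], total 76

topMotifs(enumerateMotifs(net, sizes = 3), n = 3)
#>   class_id size count strength   alias
#> 2 3:000110    3    91    295.8   chain
#> 5 3:001011    3    20    126.3     ffl
#> 1 3:000011    3    25     72.9 out_fan

ns <- motifSignificance(net, nullConfig(n_random = 500, seed = 42), sizes = 3)
s <- nullStats(ns)
head(s[order(-s$z_strength), c("alias", "obs_count", "obs_strength",
                               "null_mean_strength", "z_strength",
                               "p_strength")], 3)
#>            alias obs_count obs_strength null_mean_strength z_strength p_strength
#> 3:001011     ffl        20        126.3               38.7      5.030      0.002
#> 3:000110   chain        91        295.8              208.9      1.971      0.020
#> 3:000011 out_fan        25         72.9               64.8      0.439      0.299
```

The feed-forward-loop class is the clear strength outlier (z ≈ 5.0,
empirical p = 0.002 — the planted signal), while by raw count the chain
class is the most frequent: count and sum-strength answer different
questions, which is why both are reported.

Subtyping a synthetic bulk cohort whose 4 planted groups shift a barrier
and an exhaustion signature by 5 noise standard deviations:

```r
genes <- sprintf("G%05d", 1:200)
sigs <- list(barrier = genes[1:15], exhaustion = genes[16:30])
eff <- matrix(c(5, 0,  0, 5,  5, 5,  0, 0), 4, 2, byrow = TRUE,
              dimnames = list(NULL, names(sigs)))
cfg <- bulkSimConfig(n_samples = 60, n_genes = 200, signatures = sigs,
                     k_true = 4, group_effect = eff, seed = 3)
b <- simulateBulkMixtures(cfg)
a <- clusterScores(ssgseaScore(b, sigs), clusterConfig(seed = 1))
a <- labelSubtypes(a, "barrier", "exhaustion")
a
#> TMEAssignment: 60 samples in k = 4 clusters (mean silhouette 0.892)
#>   subtypes: barrier_dominant=15, barrier_with_exhaustion=15, desert=15,
#>             exhaustion_dominant=15
```

The silhouette criterion selects k = 4 and the assignment recovers the
planted groups exactly (adjusted Rand index 1.0).

The single-cell side of the chain (QC → markers → communication network →
hierarchy) is orchestrated end to end by `runPipeline(pipelineConfig())`,
which writes per-stage TSV/JSON outputs and a reproducible run manifest.

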