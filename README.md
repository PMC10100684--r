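# planknet

Community assembly and co-occurrence network stability for amplicon OTU
tables.

Microbial surveys along environmental gradients — the motivating system is
planktonic prokaryotes and microeukaryotes along an estuary-to-shelf
salinity gradient — routinely ask two questions that this package answers
with tested, reproducible code:

1. **Which process assembles the community?** Fit the Sloan neutral
   community model, where a taxon with metacommunity relative abundance
   *p* occurs in a sample with probability
   `1 − I_d(Nmp, Nm(1−p))` (the upper Beta tail above detection limit
   *d*), recovering the migration rate *m* and the fit quality R²; and
   compute the dispersal–niche continuum index (DNCI) from PER-SIMPER
   deviations `E = log10 Σ (obs − null)²` under occupancy-constrained,
   richness-constrained and doubly-constrained matrix randomisations —
   negative DNCI ⇒ dispersal assembly, positive ⇒ niche assembly.
2. **How stable is the interaction network?** Build Spearman co-occurrence
   networks (edges at `|r| ≥ 0.8`, `p < 0.01`, after a 0.01% mean-abundance
   filter), report the standard topology metrics including seeded Louvain
   modularity, and measure fragmentation `f = log(CL)/log(N)` under
   consecutive removal of the highest-betweenness "gatekeeper" nodes versus
   degree-ranked, abundance-ranked and random removals.

Around that core: α-diversity (richness, Shannon–Wiener, Gini–Simpson,
Pielou, Chao1, ACE) with Spearman correlations against salinity and
temperature, Bray–Curtis β-diversity, CAP ordination with squared canonical
correlations δ², one-way PERMANOVA with seeded permutations, and four
synthetic community generators (neutral, niche-gradient,
dispersal-structured, block-correlated) with known ground truth, so every
estimator is validated against the regime that generated its input.

## Worked example

```r
library(planknet)

# a neutrally assembled community at migration rate m = 0.213
spec <- community_sim_spec(n_taxa = 500, n_samples = 30,
                           reads_per_sample = 20000,
                           regime = "neutral", m = 0.213, seed = 7)
sim <- simulate_neutral(spec)
fit <- ncm_fit(sim$table)
fit
#> Sloan NCM fit: m = 0.2091 (Nm = 4205.6), R2 = 0.991
#>   50 taxa fitted (450 excluded): above 5 / within 44 / below 1 at 95% band
```

The fitted migration rate (0.209) recovers the generating value (0.213)
within 2%; R² near 1 says the occupancy–abundance curve is what neutral
assembly predicts; the excluded taxa are those never observed at this
library size. On a salinity-structured community the ordination machinery
finds the gradient instead:

```r
nich <- simulate_niche_gradient(community_sim_spec(80, 20, 5000, "niche",
                                                   seed = 7))
bc <- bray_curtis(nich$table, transform = "sqrt")
permanova(bc, nich$metadata$region, n_permutations = 999, seed = 1)
#> PERMANOVA: pseudo-F = 1271.692 (df 2, 17), R2 = 0.993, p = 0.001 (999 permutations)
cap(bc, nich$metadata$region)
#> CAP: m = 1 PCoA axes, LOO misclassification 0.000
#>   squared canonical correlations: 0.999
```

Network inference and a gatekeeper attack on a modular community with
three bridge taxa:

```r
blk <- simulate_block_network(
  community_sim_spec(40, 30, 10000, "block_network", n_modules = 4,
                     seed = 7),
  factor_correlation = 0.65, n_bridge_taxa = 3)
net <- infer_network(blk$table)
topology(net, seed = 1)
#> Network: 43 nodes, 231 edges (average degree 10.744)
#>   density 0.2558 | components 1 | diameter 6 | avg path 2.742
#>   avg clustering 0.923 | modularity 0.634
attack(net, strategy = "betweenness", k = 5, seed = 1)
#>   step removed_node n_remaining components         f
#>      0         <NA>          43           1 0.0000000
#>      1      OTU0041          42           2 0.1854490
#>      2      OTU0042          41           3 0.2958371
#>      ...
```

The first two removals are the bridge taxa and each one splits off a
module — the fragmentation signature of losing gatekeepers; random removal
needs a median of ~10 deletions to achieve the first split.

`run_pipeline()` chains all stages from a single seeded config and writes
TSV/JSON/GraphML artifacts plus a manifest; see the methods vignette
(`vignettes/assembly-and-network-stability.Rmd`) for the models,
parameter choices and numerical conventions.

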