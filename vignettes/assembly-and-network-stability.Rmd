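---
title: "Community assembly and co-occurrence network stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community assembly and co-occurrence network stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planknet)
```

planknet analyses amplicon OTU tables from communities distributed along an
environmental gradient — the motivating system is planktonic prokaryotes and
microeukaryotes along an estuary-to-shelf salinity gradient — and asks two
questions: *which assembly process structures the community* (neutral
dispersal versus environmental selection), and *how robust is the inferred
co-occurrence network to the loss of its most central taxa*. Every stage is
driven by synthetic generators with known ground truth, so each estimator in
the package can be validated against the regime that produced its input.

## The synthetic community generators

Four generators share one validated specification
(`community_sim_spec()`) and a seed-splitting scheme (`derive_seed()`)
that hashes a stage label into the master seed, so each stage draws from an
independent, reproducible stream.

**Neutral (`simulate_neutral`).** The generative twin of the Sloan neutral
model. Metacommunity relative abundances come from a stick-breaking (GEM)
process with concentration 5 — long-tailed, like observed amplicon
rank-abundance curves; a real survey would have observed abundances here,
so the concentration is a modelling choice, made once.
Each sample's local relative abundance for a taxon with metacommunity
abundance $p$ is $a \sim \mathrm{Beta}(Nmp,\; Nm(1-p))$ with $N$ the library
size and $m$ the migration rate, and counts are $\mathrm{Binomial}(N, a)$.
Small $Nm$ pushes local abundances toward 0 or 1 — dispersal limitation.

**Niche (`simulate_niche_gradient`).** Samples receive salinities from
three groups matching an estuary / nearshore / offshore design
(13.15 ± 0.93, 17.28 ± 0.56, 29.17 ± 0.24 psu); each taxon has a Gaussian
salinity response with width 3 psu (default) around an optimum drawn from
$5 + 28\,\mathrm{Beta}(1,2)$ psu. Expected abundance is proportional to the
response alone, and counts are one multinomial draw per sample. The skew of
the optimum pool toward fresh water means high-salinity samples draw on
fewer adapted taxa, so observed richness declines with salinity — the
filtering signature reported for real estuarine transects, where richness
correlates strongly negatively with salinity. Temperature is generated as
$12 - 0.35 \cdot \text{salinity} + \mathcal{N}(0, 0.5)$, warmer in the
estuary.

**Dispersal (`simulate_dispersal_structured`).** Community structure is
carried entirely by per-taxon occupancy probabilities (Uniform(0.05,
0.95)); presence at each site is an independent Bernoulli draw and
abundance conditional on presence is i.i.d. Sites are exchangeable by
construction, which is precisely the situation the dispersal-type null
model reproduces.

**Block network (`simulate_block_network`).** Taxa split into modules that
share a per-sample latent log-normal factor (loading 2, residual sd 0.3),
inducing within-module rank correlations near 1; counts are Poisson. With
defaults the factors are independent, so the true network is a disjoint
union of cliques. Because a node's correlations $r_1, r_2$ with two factors
satisfy $r_1^2 + r_2^2 \le 1 + \rho$, no taxon can exceed an 0.8 edge
threshold toward two *independent* modules: connected modular networks
require correlated factors. The options `factor_correlation` and
`n_bridge_taxa` therefore add a shared factor component and taxa that load
equally on two adjacent modules — synthetic gatekeepers. The attack
experiments use $\rho = 0.65$ with 3 bridges over 4 modules of 10 taxa,
which reliably yields one connected network whose highest-betweenness nodes
are the bridges.

What the generators deliberately do not emulate: chimeras, primer bias,
compositional coupling between domains, overdispersion beyond the sampling
models, and zero-inflation layers beyond what the sampling itself induces.
Passing tests therefore demonstrate correctness of the estimators under
clean sampling models, not robustness to every artefact of real amplicon
data.

## Diversity and ordination

`compute_alpha()` reports the six indices of the standard estuary survey
table: richness, Shannon–Wiener $H' = -\sum p_i \ln p_i$ (natural log — the
base is a convention choice), Gini–Simpson $1 - \sum p_i^2$ (bounded, the
conventional variant in these pipelines), Pielou $H'/\ln S$ (defined 0 for
$S = 1$), bias-corrected Chao1 $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (finite
when $F_2 = 0$) and ACE with the standard rare-taxon cutoff of 10. The
estimators are delegated to `vegan::estimateR()`; the one corner vegan
leaves as NaN — no rare taxa at all — reduces analytically to the observed
richness and is mapped there. Counts are not rarefied before α-diversity by
default; rarefaction curves (`rarefaction_curve()`) are a saturation
diagnostic, cross-checked in tests against the exact hypergeometric
expectation.

β-diversity is Bray–Curtis (`bray_curtis()`), with the transform (`none`,
`log1p`, `sqrt`) an explicit argument everywhere. The source material for
this pipeline describes its ordinations once as log-transformed and once as
square-root-transformed; rather than guess, the package refuses to default
— `run_pipeline()` requires the config to name a transform (the shipped
example uses `sqrt`).

CAP (`cap()`) follows the canonical discriminant formulation: PCoA by Gower
double-centering (negative eigenvalues retained and flagged), the first $m$
axes passed to a linear discriminant analysis, $m$ chosen (when `"auto"`)
to minimise leave-one-out misclassification with ties resolved to the
smallest $m$, and squared canonical correlations $\delta^2$ between the
retained axes and group membership reported per canonical axis.

PERMANOVA (`permanova()`) uses the direct distance formulation
($SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2$, within-group sums pooled
per group) with seeded label permutations and the $+1$ correction, so $p$
is never 0 and never smaller than $1/(n_{perm}+1)$. The implementation is
cross-checked in the test suite against `vegan::adonis2` (identical
pseudo-F and $R^2$), against exhaustive enumeration of all 20 assignments
at $n = 6$, and against a 500-replicate null calibration whose type-I rate
must sit in [0.03, 0.07] at $\alpha = 0.05$.

## The neutral community model fit

`ncm_fit()` estimates the migration rate by least squares of observed
occurrence frequencies on

$$\hat F(p) = 1 - I_d\!\left(Nmp,\; Nm(1-p)\right),$$

the upper Beta tail above the detection limit $d$, over taxa with
$0 < p < 1$ (taxa observed nowhere carry no information and are excluded
with a count). $N$ is the mean sample total; optimisation is a bounded
one-dimensional search on $m \in (0,1]$ at tolerance $10^{-8}$, so the fit
is deterministic. $R^2 = 1 - SSE/SS_{tot}$ can be negative for strongly
niche-structured data — that is the diagnostic contrast the model is used
for.

**Detection limit.** A taxon is scored present when at least one read is
observed. Given local relative abundance $a$, that event has probability
$1-(1-a)^N$, which crosses 50% at $a = \ln 2 / N$ — not at $1/N$. Using
$d = 1/N$ with count-based detection inflates the fitted $m$ (median
relative error 0.34 at $m = 0.2$ in recovery simulations); the
detection-consistent default $d = \ln 2/N$ brings recovery within ±25%
across $m \in \{0.05, 0.2, 0.8\}$. The conventional choice remains
available via `detection_limit = 1/N`.

The 95% band around the fitted curve is the Wilson score interval for a
proportion at $n$ samples, evaluated at each predicted frequency; taxa are
classified `above` / `within` / `below`. The band's nominal coverage is
approximate near the detection threshold because the hard cut $a > d$ only
approximates the smooth detection probability; the test suite checks decile
-level coverage accordingly.

## PER-SIMPER and the dispersal–niche continuum index

`dnci()` reduces the table to presence–absence, computes the rank-ordered
SIMPER decomposition of between-group Bray–Curtis for a pair of site
groups, and compares it (via $E = \log_{10} \sum_{\text{rank}} \Delta^2$,
floored at −12) with profiles from three constrained randomisations:

* `fix_taxa_totals` — taxon occupancies kept, site assignments random
  (dispersal-type null);
* `fix_site_totals` — site richness kept, taxon identities random
  (niche-type null);
* `fix_both` — both margins kept, via the sequential swap MCMC of
  `vegan::nullmodel` (burn-in 10× fill, thinning fill/2, seeded).

With $SES_x = (\bar E_x - \bar E_{both}) / sd(E_{both})$, the index is
$DNCI = SES_{dispersal} - SES_{niche}$: negative when the
occupancy-constrained null reproduces the observed profile better
(dispersal assembly), positive when the richness-constrained null does
(niche assembly).

**Profile scale.** The exported `simper_profile()` returns the classic
normalised SIMPER table (percentages summing to 100). Internally, however,
`dnci()` compares profiles on the *absolute* scale — each taxon's mean
contribution in percentage points of between-group dissimilarity, so the
curve sums to $100 \times$ the mean between-group Bray–Curtis. This is a
deliberate design choice with a sharp rationale: a shape-normalised profile
is blind to the *magnitude* of turnover, and the taxon-occupancy margin
then dominates the curve so completely that the occupancy-preserving null
is closer to the data for essentially any generator — the index loses its
positive (niche) half. On the absolute scale, a null that scatters
group-concentrated taxa shrinks the whole curve, while the
richness-preserving null retains the magnitude for filtering-structured
data; sign recovery then works in both directions (median DNCI ≈ −9 on
dispersal-structured replicates, ≈ +25 on niche replicates, at the same
order of magnitude as values reported for real estuarine communities).
For three or more groups the index is computed per pair and an overall
mean reported, since the group pairing behind a single published value is
generally not recoverable.

Degenerate inputs are refused loudly: saturated matrices (every taxon
everywhere) have no turnover; a `fix_both` chain with no 2×2 checkerboard
cannot mix and returns copies with a warning; an $E_{both}$ distribution
with zero spread makes the SES undefined.

## Co-occurrence networks and their stability

`infer_network()` scores all taxon pairs by Spearman correlation (average
ranks for ties; two-sided $p$ from the t approximation) and keeps edges
with $|r| \ge 0.8$ and $p < 0.01$ — raw $p$-values by default, matching
the thresholds this family of surveys reports; Benjamini–Hochberg is one
flag away. The closed threshold ($\ge$) versus the sometimes-printed
strict inequality is numerically immaterial and documented here once.
Taxa below 0.01% mean relative abundance are removed first
(`filter_low_abundance()`), the usual guard against rare-taxon artefacts,
interpreted per network (the samples entering that specific network).

`topology()` reports the conventional Gephi-style metric set; two
conventions needed fixing because disconnected graphs make them undefined:
the diameter is that of the largest component and the average path length
averages over connected pairs only (both echoed in the output). Modularity
comes from seeded multi-level (Louvain) optimisation — the partition
algorithm behind published values is typically a GUI default, so a
deterministic seeded choice is preferred here.

Fragmentation is $f = \log(CL)/\log(N)$ for $CL$ components among $N$
nodes: 0 when connected, 1 when fully atomised, base-invariant. `attack()`
removes $k$ nodes ranked by betweenness, degree, abundance, or at random
(seeded), re-evaluating $f$ on the remaining induced subgraph with $N$ the
remaining node count; ranking is static by default — matching the "top
$k$ nodes" phrasing of the underlying protocol — with adaptive re-ranking
available for sensitivity analysis. Ties break lexicographically by taxon
id, so trajectories are fully deterministic. `gatekeeper_table()` reports
the three rankings and their overlaps; `domain_subnetwork()` restricts the
meta-network to one domain, which the tests verify is identical to
re-running inference on the restricted table (rank correlations of a pair
do not depend on other taxa).

## The pipeline

`run_pipeline()` chains simulate → diversity → ordination → NCM → DNCI →
network → attack from a validated config (list or JSON), writes every
artifact (TSV tables, GraphML, JSON summaries) into the output directory,
and records them in a manifest with a hash of the analytic config (the
output path is excluded from the hash). All stage seeds derive from the
single config seed, so rerunning a config reproduces stochastic outputs
byte for byte. Validation happens before any stage runs; a stage failure
halts the run with the stage named and leaves a `failed` marker in the
manifest.

## Problem sizes and limitations

The shipped validation experiments use 500 taxa × 30 samples × 20k reads
for neutral-model recovery, 80 × 16 × 2k for DNCI sign recovery at 199
permutations per null, 4 × 10-taxon modules × 30 samples for network
recovery, and 300–500 replicates for permutation-test calibration; these
sizes keep the full suite to a few minutes while leaving each check
comfortably powered.

Known limitations: the NCM fit assumes a single well-mixed metacommunity
and one mean library size; DNCI group pairing for >2 groups is reported
per pair without a pooled test; threshold-Spearman networks are association
networks, not conditional-dependence estimates (SparCC/SPIEC-EASI-style
methods are out of scope by design); and UniFrac-type phylogenetic
distances and Hill numbers are not provided.
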