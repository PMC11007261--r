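---
title: "Testing phylosymbiosis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing phylosymbiosis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Phylosymbiosis is the observation that hosts with similar evolutionary
histories harbor similar microbial communities. Demonstrating it in a
wild, multi-population survey requires separating the host-genetic signal
from confounded ecology — sampling sites hundreds of kilometers apart, at
different altitudes, with different larval diets — and `phylosym`
packages the statistical chain for doing so: distance-based inference
(Mantel-family, MRM, PERMANOVA), topological congruence
(UPGMA/Robinson–Foulds), and co-occurrence structure (Zi–Pi roles), all
driven by either real inputs or a paired host–microbiome simulator.

## The synthetic-data model

Every stage of the package can be exercised, calibrated, and power-tested
without sequencing data via `simulate_communities()`. The generative
model is deliberately the simplest one that produces the phenomena the
statistics target:

* A **pure-birth (Yule) host phylogeny** over populations, rescaled to
  root height 1, and an analogous microbial phylogeny over taxa.
* Per-taxon latent log-abundances
  `mu_ij = b_i + sigma_phylo * g_i(j) + sigma_diet * delta_i * I(diet_j = A)`,
  where `b_i ~ N(0, 1)` is a baseline, `g_i` is a Brownian-motion
  realization on the host tree (unit-time variance 1), and `delta_i`
  marks diet-affected taxa. Brownian motion is the minimal process that
  makes community similarity decay with host phylogenetic distance —
  exactly the alternative hypothesis of Mantel-type phylosymbiosis tests.
* **Diet is clade-conserved on both sides.** Host populations get diet
  "A" as one basal clade (fraction `diet_split` of leaves), mirroring
  herbivores whose host-plant use follows their phylogeny. In `deep`
  mode the affected microbial taxa are the leaf sets of 1–3 clades whose
  stems originate in the oldest quartile of the microbial tree — a
  testable stand-in for diet effects that load on ancient microbial
  lineages; `shallow` mode scatters the effect over singleton leaves.
* Each sample adds taxon-wise noise `eps ~ N(0, sigma_noise^2)` and draws
  counts `Multinomial(depth, softmax(mu + eps))`. The softmax link keeps
  compositions valid without zero-inflation machinery; zeros arise only
  from multinomial sampling.

Defaults are the survey design the package targets: 12 populations x 4
samples, 150 taxa, depth 35,701 (so rarefaction at that depth is
exercised as the identity, and lower depths as real subsampling),
`sigma_noise = 0.5` (within-population heterogeneity is rarely reported
for wild surveys; 0.5 gives sample-to-sample Bray–Curtis spreads of the
magnitude amplicon studies show, and is a reported choice, not a fitted
one), coordinates uniform over a 28–40°N / 85–105°E box and altitudes
1500–4500 m, the ranges of an alpine butterfly survey.

**What the generator does not emulate.** Real ASV tables are sparse:
thousands of taxa, most absent from most samples. Under the softmax
model with `b_i ~ N(0, 1)`, the abundance spread across taxa is small
relative to `log(depth / n_taxa)`, so nearly every taxon is present in
every sample (~94% of cells at desk scale). Consequences follow for
presence/absence metrics (below). The generator also omits chimeras,
primer bias, compositional zero-inflation, and any realistic taxonomy —
passing tests demonstrate the statistics recover planted structure under
this model, not that they are robust to every artifact of real data.

## Distance metrics and their information content

Jaccard and Bray–Curtis are taxonomy-based (presence/absence and
abundance respectively); unweighted and weighted UniFrac weight
differences by shared branch length on the microbial tree, making them
sensitive to deep, clade-level divergence. Weighted UniFrac defaults to
the unnormalized variant `sum_b l_b |p_A(b) − p_B(b)|` (platforms differ;
the normalized form divides by the abundance-weighted tip depths and is
available by flag). Shannon uses log base 2 by default, the convention of
the major amplicon pipelines; Chao1 defaults to the classic estimator
with the bias-corrected form taking over when no doubletons exist (the
two variants are one flag apart).

A consequence of the generator's presence saturation is worth stating
explicitly because it shapes what the recovery tests can show: a
deep-clade **abundance** effect is essentially invisible to
presence/absence metrics (Jaccard, unweighted UniFrac) — there are
almost no presence flips to detect — while the abundance-weighted pair
separates cleanly, with weighted UniFrac concentrating the clade-level
diet effect more than Bray–Curtis in ~84% of replicates. The package's
acceptance suite asserts the weighted contrast and also carries the
presence-based contrast, which fails under this model (~40%, a coin
flip); we keep the failing assertion rather than silently narrowing the
claim, since it documents a real information limit of the model, not a
bug in the metrics (all four match independent oracles exactly).

## Permutation inference

All sampled permutation tests use the add-one convention
`p = (#{stat_perm >= stat_obs} + 1) / (n_perm + 1)`, so p-values live in
`[1/(n_perm+1), 1]`; exhaustive enumeration (available for n <= 7) reports
the exact proportion instead. Mantel tests are one-sided (greater) by
default, matching the ecology convention; Spearman ranks use average-rank
ties. The partial Mantel uses the residual method — both matrices'
unfolded (rank-transformed) lower triangles are regressed on the
controls, the statistic is the correlation of residuals, and the null is
built by row/column shuffling of the first matrix's residuals — the
dominant published implementation, supporting up to three simultaneous
controls. When a control absorbs a matrix completely the statistic is
degenerate and the test returns r = 0, p = 1 with a warning rather than
an arbitrary number. MRM fits OLS on unfolded lower triangles with
permutation p-values for both R² and |t|-like coefficient statistics;
PERMANOVA uses the Huygens decomposition of squared distances and label
permutation; pairwise runs are Benjamini–Hochberg adjusted (the standard
platform default; the adjustment procedure is an assumption, stated
here). Subsample schedules draw an independent derived RNG stream per
subsample index, so results are stable under partial or parallel
execution.

## The co-dendrogram test

Population representatives are either the mean of within-population
relative-abundance profiles or a single random sample (repeated, with
the mean RF reported — the replicate vector is retained). UPGMA places
each merge at half the average-linkage distance, so cophenetic distances
reproduce ultrametric inputs exactly; ties are broken by lexicographic
order of cluster representative labels, making dendrograms deterministic.
Trees are compared unrooted and RF is normalized by `2(n−3)`, its maximum
for resolved trees, so the statistic lives in [0, 1]. The null reference
is random sequential coalescence of lineage pairs with randomly permuted
labels, and the p-value counts random trees **at least as congruent** as
observed — the alternative is "more congruent than random", which we
state explicitly since "significant congruence" is ambiguous about
direction. The host tree is pruned (not errored) to the populations
present in the microbial data.

Two numerical properties of this test matter at small n. First, RF on n
populations has only `n − 2` attainable values, so p-values are coarse:
at n = 8 the achievable p jumps from ~0.07 (RF = 0.6) straight to ~0.014
(RF = 0.4), leaving no rejection region near 0.05 — the test is valid but
conservative, rejecting at roughly 1–3% under the null. Second, UPGMA
dendrograms of pure-noise data are not distributed like random
coalescence topologies (they sit slightly closer to RF = 1 against a
Yule host tree), which adds mild extra conservatism. Both effects fade
with more populations; with 12 or more the test has excellent power
(~98% at `sigma_phylo = 2` in the package's recovery simulations) while
never becoming anti-conservative. Users with few populations should
prefer the Mantel-family tests, which use the full quantitative
distances rather than topology alone.

## Co-occurrence networks

The edge rule is the reproducible criterion stated for such analyses:
Pearson correlation of relative abundances, `|r| > 0.6` and two-sided
`p < 0.05`, without multiple-testing correction by default (BH is a
flag), computed only for taxa passing the occurrence (>= 5 samples) and
top-100 mean-abundance filters, ties at the cutoff broken by taxon id.
Compositionality-aware correlation (CLR with pseudocount 0.5) is
available by flag. Module detection is greedy modularity maximization;
partitions that fail to beat the trivial single-community partition
(modularity 0) are collapsed, and isolated nodes become singleton
modules. Zi (within-module degree z-score, 0 where the module is too
small or degenerate) and Pi (participation coefficient) are classified
with the conventional 2.5 / 0.62 cuts into peripherals, connectors,
module hubs, and network hubs; both cuts are configurable.

## Numerical and design choices

* Distance matrices are plain labelled symmetric matrices; all inference
  functions align inputs by label and fail loudly on mismatch.
* Feature tables are integer matrices, samples as rows; readers accept
  the taxa-as-rows orientation by flag since the amplicon ecosystem is
  split on this.
* K2P distances use pairwise deletion of gaps/ambiguities; saturated
  pairs (`1 − 2P − Q <= 0`) are errors, not clamped values, because
  silent clamping distorts the ranks that Spearman Mantel tests consume.
* Geographic distances use the haversine formula on a sphere of mean
  radius 6371.0088 km; kilometer-scale error relative to ellipsoidal
  geodesics is immaterial to rank-based tests.
* Every stochastic stage derives its seed from a master seed by stable
  string hashing (`derive_seed`), so adding a stage never perturbs
  another stage's randomness and end-to-end reruns are byte-identical.
* Rarefaction drops under-depth samples (with a message) rather than
  erroring, matching standard practice.

## Simulation sizes used by the test suite

The suite calibrates all five inferential procedures (Mantel, partial
Mantel, MRM, PERMANOVA, congruence test) at the null over 1000 replicate
datasets of 8 populations x 3 samples, 40 taxa, depth 2000, with 199
permutations and 500 randomized trees — small enough to run a thousand
times, large enough that each test's empirical size is estimated to
within ±0.007. Recovery simulations use the generator's default 12 x 4
design at the same desk-scale taxon count and depth, 50 replicates per
claim. These sizes are the package's reporting choices; the same
functions run unchanged at full survey scale (the acceptance script does
exactly that).

## Known limitations

* The congruence test's conservatism at small population counts, above.
* Presence/absence metrics cannot detect abundance-scale clade effects
  under the softmax generator; claims about unweighted UniFrac's
  diet-sensitivity are therefore untestable with this simulator.
* The partial Mantel residual-permutation scheme is one of several in
  the literature; with strongly non-linear confounding none is exact.
* SparCC-style compositional network inference and RMT threshold
  scanning are out of scope; the CLR flag is the only compositionality
  concession.
* Pairwise PERMANOVA with few samples per group has a coarse attainable
  p-value set; adjusted significance across many pairs then requires
  more permutations than the defaults.
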