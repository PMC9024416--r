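---
title: "Methods: diversity, connectivity, and assembly processes in pelagos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, connectivity, and assembly processes in pelagos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelagos)
```

`pelagos` analyses depth-stratified microbial OTU tables the way a pelagic
survey is analysed: alpha diversity with rarefaction and between-layer
testing, compositional beta diversity, sample proportionality networks,
shared-OTU connectivity, null-model partitioning of assembly processes, and
constrained ordination against environmental gradients. This vignette
explains the models, the tunable parameters, the numerical choices, and what
the synthetic-data generator does and does not establish.

## Alpha diversity

Samples are normalized to the smallest library size by a single random
subsample without replacement (`normalize_to_min_depth()`); one draw, not an
average, mirrors the common USEARCH-style workflow and keeps the normalized
table an integer count table. The seed is recorded on the result. Expected
rarefaction curves use the exact hypergeometric form
\(E[S_n] = \sum_i \left(1 - \binom{N-N_i}{n}\big/\binom{N}{n}\right)\),
so the curve at full depth equals observed richness exactly.

Between-layer richness differences run through the conventional gate:
Shapiro–Wilk within every group and Bartlett across groups, both at
`gate_alpha` (0.05 by default, configurable). Both pass: one-way ANOVA,
followed — only when the ANOVA is significant — by Fisher's LSD letters.
Either fails: Kruskal–Wallis. Fisher's LSD is deliberately the *unadjusted*
pairwise t test with the pooled within-group mean square; that is the
procedure's definition, and the report records which branch ran. Letters are
maximal cliques of the non-significant-pair graph, ordered by group mean, so
two groups share a letter if and only if their pairwise LSD test is
non-significant. Groups too small for Shapiro–Wilk (n < 3) or with zero
within-group variance fail the gate and fall through to Kruskal–Wallis;
a table with identical richness everywhere is flagged degenerate rather than
producing NaN.

## Compositional beta diversity

Counts are compositions. Zeros are replaced by the count-zero-multiplicative
rule: a zero in a sample with total \(t\) becomes the pseudo-proportion
\(\delta/t\) (\(\delta = 0.65\) by default) and the non-zero entries are
multiplicatively rescaled so the row stays a composition. The CLR transform
\(\ln(x_{ij}/g(x_i))\) then maps each sample into Euclidean space; the
Aitchison distance is the Euclidean distance between CLR rows, invariant to
per-sample sequencing effort.

Clustering is agglomerative on the Aitchison matrix with Ward linkage by
default — valid because Aitchison distances are Euclidean, and more stable
for recovering depth groups than single or average linkage; the linkage is a
configuration knob because the choice is genuinely open. Flat groups are cut
where SIMPROF stops rejecting: starting from the root, each subtree's
samples are tested (`simprof_test()`, 999 permutations by default, recorded
in the result) and splitting continues only below significant nodes. The
SIMPROF statistic is \(\pi = \sum |d_{(k)} - \bar d_{(k)}^{null}|\) over the
sorted pairwise-distance profile, with null profiles from permuting each OTU
column independently across samples; the p-value is the fraction of permuted
\(\pi\) at least as large as the observed one. SIMPROF uses the Aitchison
distance for consistency with the clustering it gates (configurable). A
group of two cannot be tested and is non-significant by convention.

## Proportionality networks

Connectivity between samples is scored by the symmetric proportionality
statistic on CLR rows, \(\phi_s(x,y) = \mathrm{var}(x-y)/\mathrm{var}(x+y)\)
(0 = perfectly proportional); the symmetric variant is required for an
undirected graph, and the asymmetric Lovell variant is available behind a
flag for inspection. Edges connect pairs with \(\phi\) strictly below 0.15
with weight \(1-\phi\); isolated samples remain nodes. Pairs whose
denominator vanishes (anti-proportional profiles) are flagged undefined and
never become edges.

Community structure is summarized by the weighted Newman modularity of the
best Louvain partition (resolution 1, seeded — graphical tools are
interactively nondeterministic, this package is not) and by the unweighted
mean local clustering coefficient with degree-<2 nodes contributing zero,
averaged over all nodes; the convention is recorded in the report because
conventions differ between tools.

Shared-OTU connectivity tables report, per water layer (horizontal) or per
site within an inclusive depth window (vertical), the percentage of the
group's OTU pool that is shared. Because "shared among samples" admits
several readings, three modes are always emitted side by side: present in at
least two samples (default), present in all samples (intersection over
union), and mean pairwise Jaccard. Strict intersection is a subset of the
at-least-two reading, so `all` never exceeds `at_least_2`.

## Assembly processes

The two-stage null-model framework. Stage one is phylogenetic: the
abundance-weighted beta mean nearest taxon distance
\[
\beta MNTD(A,B) = \tfrac12\Big[\sum_{i\in A} f_{iA}\min_{j\in B} d_{ij}
 + \sum_{j\in B} f_{jB}\min_{i\in A} d_{ij}\Big]
\]
is standardized against a taxa-shuffle null (OTU labels permuted on the
patristic matrix, 999 shuffles by default) into the beta nearest taxon index
\(\beta NTI = (\beta MNTD_{obs} - \mu_{null})/\sigma_{null}\). One shuffle
per replicate is shared across all pairs, which keeps the replicates
mutually consistent and the computation vectorized. \(\beta NTI > 2\) is
read as variable (heterogeneous) selection, \(\beta NTI < -2\) as
homogeneous selection. Pairs with zero null spread (a star tree with equal
branch lengths leaves every shuffle identical) are flagged undefined and
excluded, with the exclusion counted.

Stage two is taxonomic, for the pairs not assigned to selection: the
Raup–Crick index on occurrence data. Each of 9,999 replicates draws one null
assemblage per sample — richness preserved, OTUs drawn without replacement
with probability proportional to occupancy across all samples (equal and
abundance weighting are options) — and
\(\beta_{RC} = 2(p - 0.5)\) where \(p\) counts null shared-species values
above the observed one, ties at half weight. Values above +0.95 indicate
dispersal limitation, below −0.95 homogenising dispersal, the middle drift.
The full (ungated) \(\beta_{RC}\) matrix is available behind a flag. By
default assembly runs on the depth-normalized table; relative abundances are
taken internally.

Numerical notes: the null cores are compiled; the R layer pre-generates the
permutations with R's RNG, so a seed makes every replicate stream exactly
reproducible; null standard deviations use the n−1 estimator, which is what
a Monte-Carlo estimate of the permutation-distribution sigma should use.

## Environmental selection

Constrained ordination of the CLR matrix on log-transformed, standardized
environmental factors. Because Aitchison distances are Euclidean on CLR
rows, dbRDA on the distance matrix and RDA on the CLR matrix are the same
analysis; both routes are implemented (`rda_fit()`, `dbrda_fit()`) and agree
to 1e-9, with vegan as an additional independent cross-check in the test
suite. The log offset for a factor containing zeros is half its smallest
positive value (shifted further if negatives occur), recorded in the result;
standardization is on by default. \(R^2\) is the constrained share of total
variance, adjusted by Ezekiel's formula; the global test permutes residual
rows (999 by default), and per-axis p-values are marginal permutation tests
on the ordered constrained eigenvalues — simpler than sequential axis
testing, and stated as such in the result.

Forward selection admits the factor with the largest cumulative adjusted
\(R^2\), if its conditional permutation test (residuals of the
already-selected model permuted) is below `alpha` (0.01 by default,
mirroring a stringent reporting threshold) and, from the second admission
on, the cumulative adjusted \(R^2\) does not exceed the all-factor adjusted
\(R^2\). The global cap is deliberately not applied to the first admission:
when the co-candidates are pure noise, the all-factor adjusted \(R^2\) sits
at or below the best single factor's in expectation, and the literal double
rule would veto a genuinely significant first factor about half the time. A
candidate whose squared multiple correlation on the already-selected factors
exceeds 0.99 is skipped (collinearity guard), so a duplicated factor is
admitted once.

## The synthetic world

`simulate_survey()` emulates a five-site, eight-layer water-column survey
(40 samples, 300 OTUs, 5,000 reads per sample by default — the shape of a
typical seamount transect study) with known truth, so every downstream stage
is testable without any sequencing data. A birth–death phylogeny with high
turnover (birth 1, death 0.9) gives tight terminal radiations separated by
long stems; niche optima evolve along it by Brownian motion whose rate
decays toward the present (early burst, `eb_decay = 2`), concentrating
divergence between deep clades — this is what "phylogenetically conserved
niches" means operationally, and without it the taxa-shuffle null has
almost no signal to find. The environmental axis is log-depth mapped onto
the inner 90% quantile span of the niche optima (the trait tails are
taxa-sparse), with small per-sample noise; the exported factor table
(temperature, nutrients, oxygen, chlorophyll, POC) consists of monotone or
peaked functions of depth plus noise with roughly field-realistic magnitudes.

Each sample's expected composition is the metacommunity profile (log-normal,
`meta_sd = 0.3`, a fairly even regional pool — evenness is what makes the
null models identifiable at desk scale) filtered by a Gaussian niche kernel
\(\exp(-\omega(\mathrm{niche}-\mathrm{env})^2)\), thinned by a
colonisation lottery (independent Bernoulli retention per taxon), perturbed
by log-normal drift noise, optionally mixed with the metacommunity at the
dispersal rate, and drawn as a multinomial. The five regimes are corners of
this parameter space (`regime_defaults()`):

* variable selection — filter on, environment tracking depth;
* homogeneous selection — filter on, environment identical, lottery
  turnover making samples share clades but not members (the taxa-shuffle
  null detects clade-level convergence, not identity);
* homogenising dispersal — no filter, all samples below 100 m are
  replicates of one shared realized community (vertical mixing); they share
  far more taxa than the occupancy-weighted null expects. A fully
  homogeneous table cannot express this process — exchangeable samples
  *are* the null — so the photic layers stay heterogeneous;
* dispersal limitation — no filter, each site colonised by its own random
  quarter of the pool; cross-site pairs share less than the null expects.
  Pure per-sample noise would not do: it reproduces the null itself;
* drift — no filter, strong independent noise, shallow depth (500 reads):
  assembly the way the null model assembles.

These defaults were fixed once, against the regimes' qualitative
definitions, and the parameter-recovery test (each regime's modal inferred
process equals the generating regime over five seeds; the
variable-selection regime yields >50% variable-selection pairs) is run at
exactly these defaults. What a green recovery test establishes is that the
pipeline identifies the processes in a world where the generating mechanism
matches the null models' assumptions. What it does not establish: behaviour
under uneven real-world metacommunities (`meta_sd` of 1.5–2 is common),
under weak phylogenetic signal, with compositional artefacts of PCR, or at
real OTU-table scale — the generator simulates none of sequencing error,
chimeras, copy-number variation, or taxonomy.

## Pipeline determinism

`run_pipeline()` fans the global seed out to fixed per-stage streams, so
changing one stage's permutation count cannot perturb another stage's
results, and two runs with one config and seed are bit-identical on every
TSV/JSON artifact (checksummed in the manifest). All randomized results
carry their seed and replicate counts in the run metadata.

## Known limitations

* The SIMPROF flavour is the top-down type-1 walk along the dendrogram; the
  permutation count defaults to 999 and is recorded, but small groups make
  the test conservative.
* Per-axis RDA significance is marginal, not sequential.
* The beta NTI and Raup–Crick statistics are pairwise; no per-taxon
  attribution is attempted.
* Modularity depends on the Louvain seed in graphs with degenerate optima;
  the seed is part of the result's metadata.
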