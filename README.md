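# pelagos

Quantitative analysis of depth-stratified pelagic microbial communities from
OTU count tables: who is where along the water column, how connected the
layers and sites are, and which ecological processes — selection, dispersal,
or drift — put the communities there.

The package is aimed at microbial ecologists working with amplicon surveys
of stratified water columns (open ocean, seamounts, lakes). It implements,
as tested and reusable functions:

- **Alpha diversity** — depth normalization by random subsampling, exact
  hypergeometric rarefaction curves, OTU richness with the
  Shapiro–Wilk/Bartlett gate into one-way ANOVA + Fisher's LSD letters or
  Kruskal–Wallis.
- **Compositional beta diversity** — count-zero-multiplicative zero
  replacement, centred log-ratio (CLR) transform, Aitchison distances, Ward
  clustering with SIMPROF-gated groups.
- **Connectivity networks** — the symmetric proportionality statistic
  φ_s(x, y) = var(x−y)/var(x+y) on CLR rows, edges at φ < 0.15 weighted by
  1−φ, Louvain modularity, mean clustering coefficients, and shared-OTU
  percentage tables along horizontal (layer) and vertical (site) axes.
- **Assembly processes** — abundance-weighted βMNTD, the βNTI z-score
  against a taxa-shuffle null (999 randomizations), the Raup–Crick index
  β_RC on occurrence data against an occupancy-weighted richness-preserving
  null (9,999 randomizations), and the five-way partition: βNTI > 2 variable
  selection, βNTI < −2 homogeneous selection, then β_RC > 0.95 dispersal
  limitation, β_RC < −0.95 homogeneous dispersal, otherwise drift. The null
  cores are compiled (Rcpp) and fully seeded.
- **Environmental selection** — RDA of CLR data on log-transformed factors
  (≡ dbRDA on Aitchison distances; both routes implemented and equal),
  adjusted R² (Ezekiel), permutation significance, and forward selection
  with the double stopping rule.
- **Synthetic surveys** — a generator for multi-site, multi-layer OTU
  tables with a phylogeny, conserved niches, and a configurable assembly
  regime, so the whole pipeline is validated against known truth.

Results come back as tibbles or small S3 objects with `tidy()`, `glance()`,
and `autoplot()` methods, so everything chains with the pipe.

## Worked example

A synthetic 5-site × 8-layer survey (40 samples, 300 OTUs) generated under
the variable-selection regime, pushed through the whole pipeline:

```r
library(pelagos)

sim  <- simulate_survey(simulation_config(regime = "variable_selection", seed = 1))
norm <- normalize_to_min_depth(sim$counts, seed = 1)

glance(richness_by_group(norm, sim$samples))
#>   method         statistic   p.value gate_passed n_groups n_samples
#> 1 kruskal-wallis      34.1 0.0000164 FALSE              8        40
```

Richness differs strongly between depth layers (the gate failed normality,
so the Kruskal–Wallis branch ran — the report always says which).

```r
cluster_samples(sim$counts, n_perm = 199, seed = 1)
#> Sample clustering (ward.D2 on Aitchison distances): 9 SIMPROF-supported
#> groups over 40 samples
```

The depth gradient fragments the 40 samples into depth-coherent clusters
supported by the similarity-profile test.

```r
part <- quantify_assembly(norm, sim$tree, seed = 1)
part
#> Assembly process partition over 780 pairs
#>   process               n_pairs fraction
#> 1 variable_selection        461   0.591
#> 2 homogeneous_selection      67   0.0859
#> 3 dispersal_limitation        0   0
#> 4 homogeneous_dispersal     162   0.208
#> 5 drift                      90   0.115
```

Variable selection dominates — correctly, since the survey was generated
under that regime (the 8.6% homogeneous selection comes from same-layer
pairs, which genuinely share their environment).

```r
clr <- clr_transform(replace_zeros(sim$counts))
fs  <- forward_select(clr, sim$samples, alpha = 0.01, n_perm = 999, seed = 1)
tidy(fs)
#>    step factor        r2_adj_cum p.value
#> 1     1 POC                0.135   0.001
#> 2     2 depth              0.292   0.001
#> 3     3 chlorophyll_a      0.362   0.001
#> 4     4 PO4_P              0.390   0.001
#> 5     5 SiO3_Si            0.410   0.001
#> 6     6 NO3_N              0.431   0.001
```

Forward selection admits depth and its tight proxies (POC, chlorophyll,
nutrients) — the generating gradient is depth, and every admitted factor is
a monotone function of it.

`run_pipeline(config, out_dir)` executes all stages from one config (R list
or JSON), writes labelled TSV matrices, GraphML networks, JSON summaries,
and a checksummed manifest, and is bit-reproducible for a given config and
seed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch: it simulates the
default synthetic survey with the given seed, runs every pipeline stage
(diversity, compositional clustering, proportionality network, the full
βNTI/Raup–Crick process partition at 999/9,999 randomizations, and RDA
forward selection), writes the pipeline artifacts next to the report, and
writes the JSON report to `--out`.

## Vignette

`vignettes/community-assembly-methods.Rmd` documents the models, the null
structures, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and the package's numerical
conventions.
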