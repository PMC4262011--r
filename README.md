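# discretus

Tools for asking how *discrete* genetic species are in densely sampled
single-locus (e.g. COI barcode) datasets, and for comparing that
discreteness between groups — originally motivated by the contrast between
obligately asexual and facultatively sexual lineages, where reproductive
isolation predicts larger interspecific gaps in the sexual group while
intraspecific variation stays similar.

The package covers the whole chain on already-ultrametric gene trees and
their alignments:

* **Species delimitation** — single-threshold Generalized Mixed Yule
  Coalescent (GMYC). Branching events older than a threshold T follow a
  diversification class with rate `λ_div · n^p_div`; younger events are
  coalescences within the clusters founded by branches crossing T, each
  contributing `λ_coal · (n_j(n_j−1))^p_coal`. Waiting times between events
  are exponential at the summed rate; the fit profiles the overall rate
  scale, maximizes over candidate thresholds, and tests against a
  single-process null `λ · (n(n−1))^p` by a χ² likelihood ratio
  (df = 3 by default; df = 2, the original convention, is available — see
  the vignette for the calibration behind the default).
* **Discreteness metrics** — per species: nucleotide diversity π (mean
  pairwise p-distance, pairwise deletion), TMRCA (basal node age),
  nearest-neighbour raw distance, and nearest-neighbour divergence time
  (minimum patristic distance halved).
* **Neutrality statistics** — Tajima's D, Fu & Li's D\* and F\*, Fu's
  F<sub>S</sub> (Ewens distribution via log-space Stirling numbers),
  Ramos-Onsins & Rozas' R<sub>2</sub>, computed per delimited species on
  multiplicity-expanded sequences.
* **Diversification** — pruning to one tip per species (longest sequence),
  Nee birth–death ML conditioned on crown age and survival, pooled across
  trees, with a pooled-vs-separate likelihood-ratio test
  (`χ² = 2(Σ separate − global)`, df = 2(groups−1)); the γ statistic with
  MCCR (simulate-complete-then-prune) and missing-species imputation
  corrections for under-sampling.
* **Group comparison** — exact Wilcoxon rank-sum, Cohen's d, retrospective
  power via the noncentral t, and a dataset-blocked permutation test (a
  documented, non-equivalent stand-in for mixed-effects models).
* **Synthetic data** — birth–death species trees with independent Kingman
  coalescents within species and Jukes–Cantor sequences, with
  `asexual_like` (r = 0.072 Myr⁻¹, sparse sampling, many singletons) and
  `sexual_like` (r = 0.048 Myr⁻¹, dense sampling) presets, so the whole
  pipeline is testable end to end with no external data.

## Worked example

Simulate one densely sampled sexual-like dataset (8 true species), run the
full analysis, then estimate its diversification rate:

```r
library(discretus)

b  <- make_scenario("sexual_like",
                    overrides = list(n_datasets = 1L, n_species = 8L),
                    seed = 42)
ds <- b$datasets[[1]]
res <- analyze_dataset(ds$gene_tree, ds$alignment, ds$meta)
res$fit
#> GMYC fit
#>   tips: 95   entities: 8 (8 clusters + 0 singletons)
#>   threshold: 1.792 (root age 25.24)
#>   loglik: null 352.0183  gmyc 362.1704  LR chi2 = 20.3041 (df 3), p = 0.0001468
```

The 250 sampled sequences collapse to 95 haplotypes; the GMYC threshold at
1.79 Myr recovers exactly the 8 species the generator planted, and the
two-class model beats the single-coalescent null decisively (χ² = 20.3,
p ≈ 1.5e-4). Per-species metrics (first rows):

```r
head(res$metrics[, c("species", "n_haplotypes", "pi", "tmrca", "nn_phylo")], 3)
#>   species n_haplotypes         pi     tmrca  nn_phylo
#> 1    sp01            8 0.01720238 0.7037457 25.238571
#> 2    sp02           14 0.01184982 0.5073876 18.191660
#> 3    sp03           28 0.01829806 0.9701212  5.647801
```

π ≈ 1–2% within species while the nearest heterospecific lies 5–25 Myr
away — exactly the "tight clusters, wide gaps" structure the metrics are
built to expose. Pruning to one tip per species and fitting the birth–death
model:

```r
sp <- prune_to_species(res$tree, res$partition,
                       setNames(ds$meta$seq_length, ds$meta$id))
bd_fit(sp)
#> birth-death fit: r = 0.05116 (se 0.0209), eps = 1.13e-07 [pure birth],
#>   loglik = -15.3112 (1 trees, 8 tips)
gamma_statistic(sp)
#> [1] -0.3817235
```

The estimated net diversification rate 0.051 Myr⁻¹ brackets the generating
0.048 Myr⁻¹, the extinction fraction collapses to the pure-birth boundary
(the truth), and γ is near zero, i.e. no detectable rate slowdown.

A command-line front end mirrors these stages, e.g.:

```sh
inst/cli/discretus gmyc --tree T.nwk --out fit.json --partition P.tsv
inst/cli/discretus simulate --preset sexual_like --seed 1 --out scenario/
```

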