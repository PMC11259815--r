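# stoichnet

Prior-free inference of co-regulation network modules and multi-omics
pathways from feature-by-sample abundance matrices.

Most pathway analyses start from curated annotation databases, which are
incomplete, biased toward well-studied genes, and often missing entirely
for the conditions under study. `stoichnet` instead infers modules and
pathways *de novo*, from the measurements alone, and uses annotations only
afterwards — to validate what was found. It is aimed at systems-biology
analyses of transcriptome, proteome, phosphoproteome, metabolome or
methylome matrices, alone or layered over shared samples.

## The association score

For every ordered feature pair (i, j) two raw scores are computed across
samples *s*:

* **Correlation**: the Spearman rank correlation of the two
  abundance profiles (optionally its absolute value).
* **Stoichiometry**: the quartile ratio Q3/Q1 of the per-sample abundance
  ratios x_is / x_js, computed over samples where both values are
  non-zero. A value of 1 means the two features hold a perfectly fixed
  stoichiometry across samples; larger values mean a looser relation.

Each feature then ranks all of its candidate partners: per feature, the
raw scores are rank-adjusted onto [0, 1] in equal increments (best
partner = 1, worst = 0; highest correlation and lowest stoichiometry are
best). The **combined score** of (i, j) is the product

    combined(i -> j) = adj_corr(i -> j) x adj_stoi(i -> j)

Modules are assembled from these scores:

1. A cut-off *t* is derived from two parameters: **C**, the minimum number
   of associations per feature, and **S**, the number of features assumed
   to have at least one true association (*t* = the S-th largest of the
   per-feature C-th-best combined scores). A discrepancy filter then
   removes pairs whose two directional scores disagree by more than a set
   number of grid steps.
2. For each feature, the maximally scoring three-feature clique of
   retained pairs is found; cliques are merged and trimmed by five fixed
   join rules (shared-feature joins gated by module size and a strong
   module score, default 0.66).
3. Pathways are inferred by re-running the same machinery on module-level
   expression profiles (sample-wise medians of member features) with the
   absolute Spearman correlation, so up- and downregulated modules combine
   equally — including across omics layers that share samples.

Modules and pathways are validated against annotation relations
(interaction pairs, or group memberships such as kinase -> substrates) by
counting recovered relations, comparing against 1000 size-preserving
randomized null rounds smoothed with an Epanechnikov kernel, and reading
the empirical p-value from the resulting CDF. Conservation in independent
datasets is summarized by the median adjusted score of the inferred
groups, with 0.5 the random-assignment baseline.

The package also ships the planted-module data simulator used for
calibration and testing, and a position-weight-matrix sliding-window
predictor of ADAM-protease cleavage sites constrained to 35 residues
upstream of a transmembrane domain.

## Worked example

```r
library(stoichnet)

sim <- simulate_dataset(seed = 11)        # 10 planted + 90 noise features
sug <- suggest_parameters(sim$matrix)     # data-driven S and C
sug
#> <parameter_suggestion> 100 features
#>   suggested S: 10 (split at max |rho| = 0.601)
#>   suggested C: 3 (estimated non-associated fraction 0.90)

mods <- infer_modules(sim$matrix,
                      inference_params(C = sug$suggested_C,
                                       S = sug$suggested_S))
mods
#> <module_set> layer 'sim_normal': 2 modules (sizes 5-5)

head(as.data.frame(mods))
#>   module_id feature module_score
#> 1        M1      x1    0.9696845
#> 2        M1      x2    0.9696845
#> ...

truth_groups <- split(names(sim$truth), sim$truth); truth_groups$none <- NULL
res <- validate_against_annotations(
  mods, annotation_relations(groups = truth_groups),
  universe = sim$matrix$feature_ids, rounds = 1000, seed = 12)
res
#> <validation_result> observed 20, null median 0 (1000 rounds)
#>   p = 0, relative distance = NA

recovery_metrics(mods, sim$truth)
#> <recovery_metrics> recall 1.00, misassigned 0, noise FPs 0, pair F1 1.000
```

The suggestion step reads the planted/noise split off the density of
per-feature maximum scores (S = 10 matches the 10 planted features); the
two planted modules are recovered exactly; all 20 within-module relation
pairs of the planted truth are found inside the modules while the
randomized null never finds any (null median 0, hence p = 0 and an
undefined relative distance, which is reported as `NA` with a warning).

A command-line interface wrapping the same functions is installed at
`exec/stoichnet` with subcommands `simulate`, `score`, `infer-modules`,
`infer-pathways`, `validate`, `suggest-params` and `predict-cleavage`;
every run writes a JSON manifest recording parameters, seed and input
checksums.

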