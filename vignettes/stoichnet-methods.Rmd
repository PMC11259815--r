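---
title: "Stoichiometry-scored network inference: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometry-scored network inference: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichnet)
```

## The model

`stoichnet` treats molecular association as a two-sided property. Two
co-regulated features should *covary* across samples, and they should do
so at a *conserved ratio*: members of a complex or a tightly coupled
pathway segment keep a near-fixed stoichiometry even as their absolute
abundance swings. Correlation alone misses the second property — two
features can be strongly correlated at wildly varying ratios — and ratio
conservation alone misses the first. The combined score multiplies
rank-adjusted versions of both.

For features $i, j$ with abundances $x_{is}$ over samples $s$:

* raw correlation $\rho_{ij}$: Spearman rank correlation (average ranks
  for tied observations);
* raw stoichiometry $q_{ij} = Q_3(r)/Q_1(r)$ over the per-sample ratios
  $r_s = x_{is}/x_{js}$, restricted to samples where both values are
  non-zero. $q = 1$ is a perfectly conserved ratio; $q$ grows as the
  relation loosens.

Each feature ranks its candidate partners separately for each raw score
and maps the ranks onto $[0, 1]$ in equal increments of $1/(m-1)$ ($m$ =
scorable partners); the highest correlation and the lowest stoichiometry
score receive 1. The combined score of the ordered pair is the product of
its two adjusted scores. Adjustment is feature-wise, so the two directions
of a pair differ; a later filter bounds that difference.

Rank adjustment is what lets the two heterogeneous raw scales multiply
meaningfully, and it is also the source of an important caveat: *every*
feature, associated or not, has some partner with adjusted score 1.
Thresholding must therefore never rely on a feature's single best score
alone on small datasets — this is exactly what the parameter C repairs
(below).

## Tunable parameters

All parameters live in one `inference_params()` object:

| parameter | default | meaning |
|---|---|---|
| `C` | 1 | minimum associations retained per feature; the cut-off is the S-th largest per-feature C-th-best combined score |
| `S` | all features | number of features assumed to have a true association; its complement is the estimated non-associated count |
| `use_absolute_correlation` | off (on for pathways) | score with the absolute Spearman correlation |
| `weighted_stoichiometry`, `stoichiometry_weight` | off, 1 | zero-inflated variant: the base score is multiplied by $(1 + w f_\text{one})/(1 + w f_\text{both})$, where $f_\text{one}$, $f_\text{both}$ are the fractions of samples with exactly one / both values zero |
| `single_join_max_size` | 5 | step-2 merge: both modules must be at most this size |
| `strong_module_score` | 0.66 | step-2 merge: both modules must score at least this |
| `small_join_max_size` | 10 | step-5 merge: maximum combined size |
| `discrepancy_count` | 10% of the grid | allowed directional difference, in grid steps $1/(n-2)$ |

The scoring switches deserve comment:

* **Zero handling.** When more than roughly 30% of entries are zero-coded
  missing values the weighted variant recovers more annotated relations;
  below roughly 25% the unweighted variant does. `score_all_pairs()`
  warns past 30% zeros but an explicit flag always wins. The weighted
  functional form above is this package's own construction (monotone
  punish-one-zero / reward-both-zero); only its direction, not its
  algebra, is dictated by the method description it implements.
* **`strong_module_score` = 0.66** gates the only merge step that joins
  modules sharing a single feature; both participating modules must clear
  it (a flag relaxes this to either).
* **`discrepancy_count`** has no published value; the default of
  `ceiling(0.1 * (n - 1))` grid steps (10% of the adjusted-score range)
  was fixed once as the loosest setting that still removed essentially
  all one-sided pairs in simulation, and is deliberately expressed in
  grid steps — the only natural unit on rank-adjusted scores.

### Choosing S and C

`suggest_parameters()` computes each feature's maximum absolute raw
correlation and maximum inverted raw stoichiometry, fits an Epanechnikov
kernel density (Silverman bandwidth) to each, and proposes S as the
number of features above the deepest internal minimum (antimode) of the
max-correlation density — in planted-module simulations the associated
and non-associated populations are cleanly bimodal and the antimode count
lands within ±20% of the true associated count. When no antimode exists
the count above a user-adjustable quantile (default 0.75) is used; for a
degenerate, fully associated matrix the suggestion is all features. The
antimode rule itself is this package's design choice.

The C recommendation is 1 above 300 features. Below 300, a sweep of C
over 1–4 at matched S on the built-in simulator (noise fractions 0.1,
0.5, 0.9; 100 and 200 features; five seeds each; pair-F1) found C = 3
optimal throughout with only weak dependence on the noise fraction, so
the table is simply: more than 300 features, 1; otherwise 3. The
direction of the size effect matters more than its exact boundary: on
large datasets permissive defaults plus C = 1 win because raising C only
lowers the threshold and admits noise, while on small datasets the
per-feature best score is saturated by rank coincidences and a stricter
per-feature guarantee (C = 3) is required.

## Module assembly

From the retained pair graph, each feature contributes its maximally
scoring three-feature clique (sum of the three symmetrized edge scores;
symmetrization is the mean of the two directions, justified because the
discrepancy filter has already bounded their difference). Cliques are
then merged in five ordered steps, each run to a fixed point: (1) merge
on two shared features; (2) merge on one shared feature, gated by size
and score; (3) step 1 again; (4) trim three-feature modules whose
features already sit in strictly larger modules, discarding remnants
under three features; (5) optionally join the remaining small modules
that still share a feature, capped by combined size. Module scores are
recomputed after every merge; modules are scanned in a fixed order
(descending score, then lexicographic members), so the whole procedure is
deterministic. A feature may belong to several modules.

Step 4 is restricted to *strictly larger* modules on purpose: removing
features shared between equal-size small modules would leave step 5
nothing to join and always destroy one of the two modules.

## Pathways

Module profiles are the sample-wise medians of their member features.
Pathway inference reruns the entire machinery on the module-by-sample
matrix with the absolute correlation, so anti-regulated modules combine
as readily as co-regulated ones. For the stoichiometry side this requires
a decision the correlation switch alone cannot make: the quartile ratio
of an anti-monotone pair is intrinsically poor. When absolute-correlation
mode is on and a pair's signed correlation is negative, the stoichiometry
is therefore computed on the per-sample *product* of the two profiles —
the ratio against the reciprocal partner — so a perfectly
anti-proportional pair scores 1 and reciprocal sign flips leave the
output invariant. Pathway-stage defaults are C = 1 with S equal to the
number of modules; the zero-inflation switch follows the layer with the
most zeros. Layers must share an identical ordered sample set; pathway
sets can be fed back in as input (super-pathways).

## Validation

Observed validation scores count annotated relations recovered inside
modules (for group annotations: within-module pairs sharing at least one
group, each counted once) or, for pathways, co-annotated feature pairs
spanning two different member modules. Nulls preserve the size profile:
features are redrawn without replacement across a round when the
observed modules are disjoint, per-module otherwise; for pathways a
connections-only mode instead permutes intact modules across pathways.
The null scores are smoothed with an Epanechnikov kernel at the Silverman
bandwidth and the upper-tail p-value is read from the numerically
integrated CDF; the upper tail is the only sensible direction since every
use asks whether *more* relations than chance were recovered. A
degenerate (constant) null skips the kernel and falls back to the point
mass with a warning. The relative distance
$(\text{observed} - \text{median})/\text{median}$ is reported alongside,
and is `NA` when the null median is zero.

Conservation re-scores previously inferred groups in an independent
dataset and reports the median adjusted score of the group-internal
pairs; 0.5 is the exact random-assignment baseline for a single adjusted
score (the combined score, being a product of two near-uniform scores,
has a lower random baseline — conservation comparisons at the 0.5 line
should use the correlation or stoichiometry component).

## The simulator

`simulate_dataset()` draws the two five-feature chain modules
(`x1..x5`, `x6..x10`) plus non-associated noise features, in three
distribution families with all chain coefficients 1 by default and the
difficulty level Y drawn once per dataset (normal: integer 2–30; negative
binomial 2–15; beta 2–10; 50 samples by default). Per-sample draws:
normal `s ~ N(Y, 1)`, `e ~ N(1, Y/10)` (the second argument is the
standard deviation); noise features are `s3 - e11` with `s3` a per-sample
integer from 1–35 and `e11 ~ N(0, 1)`. The negative binomial uses
(successes, success probability) and the beta the standard two-shape
form; values are never truncated, so noise features occasionally dip
below zero — the scoring eligibility rule (both values strictly positive)
absorbs this. A low-noise variant (`e ~ N(Y/5, Y/50)`, Y 2–10) serves
dimensionality sweeps. The default pool is 10 planted plus 90 noise
features, a realistic mid-scale screen.

What the simulator emulates is the *association structure*: chain-linked
co-regulation at conserved stoichiometry against an unstructured
background. What it does not emulate: library-size and batch effects,
heavy-tailed measurement noise, missingness mechanisms of real MS data,
or correlated noise pools. Passing the planted-recovery tests therefore
demonstrates correctness of the machinery under the stated generative
model, not performance on any particular real platform.

Simulation-backed properties reproduced by the test suite (problem sizes
chosen to keep the default run in minutes): planted features are never
assigned to the other planted module (20 seeds, default dataset);
permissive S inflates noise false positives while strict S inflates
false negatives, with cross-assignment zero throughout; C = 1 maximizes
pair-F1 on 320-feature datasets (twelve datasets, noise fractions
0.50–0.75) while C = 3 wins below 300 features; the conservation median
under random assignment is 0.5 within ±0.02 at 1000 permutations; and
empirical p-values are uniform on truly random module sets (200
replicates, 250-round nulls, Kolmogorov–Smirnov at α = 0.01).

## Numerical choices

* **Quartiles** interpolate between order statistics at the type-7
  positions, with the interpolation performed on the log scale. Plain
  linear interpolation on the ratios is not invariant under swapping the
  two features (the reciprocal of an interpolated quartile is not the
  interpolated quartile of the reciprocals), whereas log-scale
  interpolation makes the score exactly swap-symmetric and
  scale-invariant while agreeing with type 7 whenever a quartile lands on
  an order statistic.
* **Ties in rank adjustment** take the adjusted value of their best
  position (min-rank). This preserves the definitional guarantee that
  every feature's best partner scores exactly 1 even under ties —
  tie-averaging would let a tied-best pair score below 1 and silently
  break the "combined = 1 iff both components are best" property that
  the cut-off logic relies on. Ties are measure-zero in continuous data,
  so the choice only matters for constructed or heavily discretized
  inputs.
* **Eligibility** for stoichiometry is "both values strictly positive":
  zeros are excluded by definition and negative values (possible in
  simulated data) are excluded per sample the same way, rather than
  voiding the whole pair — voiding collapses the rank denominator and
  manufactures spurious perfect scores.
* **Degenerate inputs**: constant features are unscorable and simply
  drop out of their partners' rankings; a single scorable partner is by
  definition the best (adjusted score 1); KDE fitting falls back to the
  point mass on constant nulls; thresholds at saturated score levels are
  legal and simply retain fewer pairs.
* **Determinism**: all randomness flows from explicit seeds; merge scans
  and tie-breaks are lexicographic; two runs on the same inputs are
  byte-identical.

## Known limitations

Directionality of an association is not inferred — scores are
symmetrized before module assembly. Layers measured on different sample
sets cannot be combined. Datasets with more than ~200 features but fewer
than 10 samples are outside the method's comfortable regime: the
per-feature rankings that everything builds on become unstable. The
suggested-parameter heuristics (antimode split, C table) are calibrated
on the built-in simulator and should be sanity-checked against the
reported score densities on unusual data.
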