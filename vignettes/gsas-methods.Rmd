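---
title: "Gene set activity scoring and survival screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set activity scoring and survival screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multi-gene prognostic signatures for breast cancer abound, but a signature
fitted in one cohort often fails in the next. `gsascreen` implements a
single-sample, rank-based *gene set activity score* (GSAS) that makes gene
sets comparable across heterogeneous expression cohorts, and builds a full
screening pipeline on top of it: per-cohort Cox proportional hazards
screening, cross-cohort intersection of significant sets, metastasis
classification from set scores, a Jaccard overlap network over significant
sets with extraction of a *core gene set*, and an ablation experiment that
measures how much of the collection's prognostic signal that core carries.

# The score

For one sample, genes are ranked by relative expression in descending
order. Two empirical CDFs are walked along the ranking: the foreground
$F(i)$ (fraction of the target set's $m$ genes at rank $\le i$) and the
background $B(i)$ (same for the $G-m$ complement genes). The preliminary
score is the signed maximum deviation

$$d^+ = \max_i\,(F - B), \qquad d^- = \min_i\,(F - B), \qquad
s = \begin{cases} d^+ & d^+ \ge |d^-| \\ d^- & \text{otherwise,} \end{cases}$$

a signed Kolmogorov–Smirnov style D statistic in $[-1, 1]$: $+1$ exactly
when the set occupies the top $m$ ranks, $-1$ at the bottom, near 0 when
the set is spread evenly. The GSAS divides $s$ by the mean $|s|$ of
`n_perm` uniformly drawn gene sets of the same size (default 1000), so a
random set of any size has expected $|\mathrm{GSAS}| \approx 1$ and scores
are comparable across set sizes and samples.

Numerical notes:

* Extrema of $F - B$ can only occur at set-gene ranks (maxima) or just
  before them and at $G$ (minima), so a score costs $O(m)$ after one
  $O(G \log G)$ sort per sample; the permutation loop is compiled.
* Ties in expression break by ascending gene id — deterministic and
  platform independent.
* The permutation RNG stream is derived from `(seed, sample id, set
  size)`. The null depends only on the size, so caching one factor per
  (sample, size) is exact, not an approximation, and results do not
  depend on evaluation order.
* "Relative expression" is implemented as per-gene z-scoring across the
  samples of the matrix (`standardize = TRUE`). Two-channel log-ratios
  are already relative and can skip it. This is our convention for
  one-channel data; published microarray cohorts rarely document a
  preprocessing that can be reproduced exactly.
* A magnitude-weighted variant of both CDFs (weights $|z|$, the original
  flavor of rank-based regulatory activity scoring) is available behind
  `weighted = TRUE`, default off: the unweighted statistic is the one
  anchored to the KS D statistic.
* Sets with fewer than `min_set_size = 3` genes in the matrix (or
  covering every gene) are skipped and enumerated, never silently
  dropped.

# Survival screening

The screen fits one Cox proportional hazards model per gene set with the
*continuous* GSAS as covariate (Efron ties; Breslow by option) and reads
the per-covariate Wald p. Dichotomizing GSAS about 0 into high/low
activity groups is presentational: it feeds the Kaplan–Meier curves and
the log-rank test, not the screen. Grade enters adjusted models binarized
(2/3 vs 1). Multiple testing uses Benjamini–Hochberg within a screen. A
set is *robust*
when its univariate Wald p is below $\alpha = 0.05$ in every cohort
screened — an intersection, not a meta-analysis, and deliberately strict:
significance in 6 of 7 cohorts does not qualify.

Degenerate inputs are handled exactly: a zero-variance score returns
coefficient 0, hazard ratio 1, p 1 (not a failed fit); models that do not
converge are flagged, never silent; samples missing a used covariate are
dropped per model with counts reported.

# Metastasis classification

Features are gene sets whose GSAS differs between metastatic and
non-metastatic samples (two-sided Wilcoxon rank-sum, normal approximation
with tie and continuity correction, BH q < 0.01). The classifier is a
random forest — implemented in compiled code in this package because no
forest implementation is available in the target environment — with the
conventional defaults: 500 trees, $\lfloor\sqrt{p}\rfloor$ candidate
features per split, Gini impurity, grown to purity. Evaluation is
stratified 10-fold cross-validation repeated 10 times; out-of-fold
probabilities are pooled per repeat, AUC is the trapezoid area, and the
reported score is the mean over repeats. Stratification is a documented
deviation from plain random folds: it prevents one-class folds at small
cohort sizes. Cross-dataset transfer moves the *feature list* only; the
model is always retrained under CV inside the evaluation cohort, so
evaluation labels can never leak into selection.

# Overlap network and the core gene set

Nodes are sets with BH q < 0.01 in one designated reference screen, split
by hazard direction (hr $\ge$ 1 "negative"/deleterious vs hr < 1
"positive"/protective) — edges never cross directions. Edges are Jaccard
overlaps $|A \cap B| / |A \cup B|$ kept at $\ge 0.20$ (the filter is
defined by *removing* pairs below 0.20, hence the inclusive comparison).
Overlap is computed on the sets as stored in the GMT, not intersected
with any expression matrix: the network stage is expression-independent.

Module identification is traditionally a visual step over a network
layout; we operationalize it with the smallest assumption that
reproduces it: connected components,
picking the component with the most robust-flagged nodes (ties: larger
component, then lexicographically smallest member). A greedy-modularity
alternative sits behind `method = "modularity"`. Both hazard directions
are searched and the winning direction is reported, not assumed. The core
gene set keeps genes present in at least 40% of the module's sets; the
boundary is inclusive (2 of 5 sets qualifies).

# Ablation

`remove_core` deletes the core genes from every set (sets shrinking below
3 genes are dropped and listed, so "after" counts remain interpretable);
`substitute_core` replaces each core gene with a uniformly drawn gene not
already in the set *and not itself a core gene* — a narrower pool than
"any gene not already present", because allowing core genes back in
would defeat the substitution's purpose; this is a documented choice. Substitution
is exactly size-preserving and seeded per set. The experiment rescores
each variant collection with fresh normalization factors (removal changes
set sizes) and counts sets at univariate Cox p < 0.05 per cohort.

A property worth knowing when reading ablation results: the statistic is
*competitive*. Removing core genes from the sets does not remove them
from the ranking, so in samples with high program activity the displaced
ranks of all remaining genes still carry signal — residual significant
sets after removal are typically hr < 1 with scores anti-correlated with
the underlying program. Count reductions after core removal are
therefore real but partial by construction, and a cohort's count can
even tick upward: a set that loses its few program genes also loses the
foreground contribution that opposed its complement shift.

# The synthetic world

All guarantees are demonstrated on a generated multi-cohort benchmark
with planted ground truth; real breast-cancer cohorts are not
redistributable with the package. One latent activity $a_s$ per sample — a two-component
Gaussian mixture (means $\mp 1.2$, sd 0.4, equal weights), reproducing
the bimodal per-set score distributions seen in real cohorts — drives
everything:

* expression of 60 program genes among 2000: $e_{gs} = 0.8\,a_s +
  \varepsilon$, $\varepsilon \sim N(0, 1)$; all other genes pure noise;
* exponential survival with hazard $0.05\,e^{0.6 a_s}$ per month,
  administratively censored uniformly on [0, 120] months;
* metastasis $\sim$ Bernoulli$(\mathrm{logit}^{-1}(-0.5 + a_s))$;
* age, tumor size, ER and node status independent; grade weakly
  associated with $a_s$ (correlation $\approx 0.3$) so multivariate
  adjustment is exercised without making the score redundant;
* a 150-set collection: 20 program sets draw a uniform 30–70% of their
  genes from the program pool (sizes uniform 20–100, capped against the
  60-gene pool — which is what makes many pairwise Jaccard overlaps
  exceed 0.20), 130 sets fully random.

Cohorts of a benchmark differ only by a seed offset; program identity and
the collection are shared. Everything is reproducible from one master
seed via per-purpose derived streams, and a repeated call never perturbs
the caller's RNG state.

What the generator does *not* emulate: platform noise, batch effects,
probe-level artifacts, realistic censoring mechanisms, or subtype
structure. A green benchmark test therefore establishes that the pipeline
recovers a planted signal of realistic shape and strength — not that it
reproduces any particular published cohort's numbers.

Choices made where the design was open, and their defaults:

* `n_perm` 1000 (source value; tests run at 100 to fit time budgets —
  the permutation count only affects normalization noise, which shrinks
  like $1/\sqrt{n_\mathrm{perm}}$);
* uniform program-gene draws in program sets (no popularity weighting) —
  chosen before any acceptance measurement, verified to satisfy the
  overlap postcondition by design simulation;
* duplicate expression rows mean-collapsed at load (common microarray
  convention for multi-probe genes);
* scores equal to 0 fall in the "low" group at dichotomization (zeros
  have measure ~0 for continuous scores);
* no parametric (accelerated failure time) survival models: the screen
  is purely semi-parametric Cox.

# Known limitations

* The competitive-statistic complement shift above bounds how complete a
  core-removal knockdown can be.
* Wilcoxon p-values use the normal approximation everywhere; at $n \le 8$
  per group and $p < 0.05$ the relative error against exhaustive
  enumeration can exceed 10% (tests therefore assert the approximation
  bound at moderate p only).
* The forest computes mean-decrease-in-impurity importances only, which
  are biased toward features with many split points; fine for ranking
  set scores, not for formal inference.
* No proportional-hazards diagnostics, time-varying covariates, or
  subtype stratification.
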