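---
title: "Connectivity mapping from planted differential-expression signatures"
author: "connmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity mapping from planted differential-expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connmap)
```

## The problem

Connectivity mapping asks whether a disease-associated gene expression
signature is *reversed* by any compound in a reference database of
compound-induced expression profiles. A compound whose profile pushes the
signature's up-regulated genes down and its down-regulated genes up
("negative connectivity") is a repositioning candidate. `connmap`
implements the complete chain from raw probe-level intensity matrices to a
ranked list of such candidates:

1. a bespoke normalization built around a monotone piecewise-linear curve
   trained on rank-stable probes and a *computational naive control pool*;
2. a differential-expression filter (floored fold change plus Student
   t-test) that defines the up/down query signature;
3. hierarchical clustering as a sanity check that the signature separates
   the groups;
4. rank-based Kolmogorov–Smirnov (KS) connectivity scoring of the signature
   against each reference instance, with permutation p-values and a strict
   selection rule.

No real arrays or compound database ship with the package. Instead a
synthetic-data module plants known structure at every stage — known
differential probes, known signature reversers and mimics — so the whole
chain is testable against ground truth.

## The synthetic study

`synthetic_design()` emulates a two-group one-color array study with 5
control and 6 treated arrays over 1000 probes (the sample sizes of the
study design this package targets). Its model:

* per-probe baselines are log-uniform over `[50, 5000]`, matching the
  intensity scale of one-color arrays;
* a configurable fraction (default 5%) of non-planted probes is forced
  below the fold floor of 10, so the weak-signal flooring rule is always
  exercised;
* planted probes multiply (up) or divide (down) the treated means by
  `fold_planted`; noise is multiplicative log-normal with unit mean, so the
  expected treated/control ratio *is* the planted fold;
* 75% of probes carry a gene symbol by default — only annotated probes can
  enter a signature, mirroring the restriction of real analyses to probes
  with recognized gene symbols.

Planted probes are drawn from the non-weak baseline pool: planting an
effect below the floor would make it unmeasurable by construction and turn
the generator's own ground truth into a lie.

What the generator does **not** emulate: spatial array artifacts, dye and
hybridization chemistry, probe cross-hybridization, correlated noise
between probes of one gene, or the content of any real compound database.
Passing tests therefore demonstrate that the algorithms recover structure
they are designed to detect under clean planted conditions — not that they
would perform identically on real arrays.

`reference_db_design()` generates compound instances as complete
permutations of the gene universe. Every gene gets a latent uniform key and
the instance ranks genes by descending key; planted instances pull the
target signature's tag keys toward the extremes with weight
`effect_strength` (1 = tags occupy the exact extremes, 0 = indistinguishable
from a null instance). Reversers pull up-tags to the bottom and down-tags
to the top; mimics do the opposite.

## Normalization

The normalization chain (`normalize_matrix()`) follows an internally
developed scheme rather than any published family (quantile, RMA, loess
are deliberately out of scope):

1. optional local background subtraction on the raw scale, clamped at
   `floor_eps` (default 1 — any positive value below the fold floor of 10
   gives identical downstream results, it only keeps logs finite);
2. between any two samples, training probes are those whose intensity rank
   moves by less than `rank_tol` (default 0.10) of the probe count —
   per-probe rank displacement with average-rank ties;
3. a continuous piecewise-linear map from log intensities of the sample to
   log intensities of the reference is fitted by least squares with knots
   at quantiles of the training intensities (default `n_knots = 20`), then
   made monotone by isotonic adjustment of the knot values; beyond the
   outer knots the terminal slopes extrapolate linearly;
4. the *median array* is the control least distant from the other controls,
   with distance `1 - Spearman correlation` of log signals — a rank-based
   metric chosen to match the rank-centric design of the whole pipeline;
   ties break by sample order;
5. every control is normalized against the median array and the *control
   pool* is the per-probe mean of the normalized controls; finally every
   sample (control and treated) is normalized against the pool. The pool
   doubles as the "common sample" of step 3 — the pipeline needs no third
   external reference.

All logs are natural: the base cancels in every ratio the pipeline uses.
Design properties verified by the test suite: self-normalization is the
identity to 1e-6 relative; a column equal to `c × pool` returns to the pool
within 1% for `c` in `[0.25, 4]`; every fitted curve is monotone; Spearman
correlation between a column before and after normalization stays ≥ 0.99.

## Differential expression and the signature

Fold changes are computed from group means *after flooring both means at
10*, and reported signed: `+r` for up-regulation, `-1/r` for
down-regulation, so `|fold| ≥ 1` always. The flooring makes the fold of a
probe with both means at the noise floor exactly +1 (no call) — the price
is that antisymmetry between the two group orderings holds only above the
floor, which is the intended behavior of a weak-signal guard.

P-values come from a classical equal-variance two-sample Student t-test,
computed on log signals. The choice of scale was genuinely open; log was
chosen because the normalization operates in log space and multiplicative
noise is variance-stabilized there, and `log_scale = FALSE` selects the raw
scale. Zero-pooled-variance probes get p = 1 when means agree (and p = 0
otherwise). No multiple-testing correction is applied — the filter is the
published raw `p ≤ 0.05`, inclusive, combined with `|fold| ≥ 1.5`,
inclusive.

Probe-to-gene collapse: a gene enters a direction if any of its passing
probes supports it; a gene supported in both directions is dropped from
both with a warning. Unannotated probes count in the report but never
enter the signature.

Clustering validation (`cluster_samples()`): probe rows are mean-centered
and scaled to unit norm across samples, sample distance is
`1 - Pearson correlation`, and agglomeration is complete linkage. Constant
rows are dropped with a warning since their correlation is undefined. The
planted two-group design must split control from treated at the root, and
merge heights are checked against a naive O(n³) agglomeration oracle.

## Connectivity scoring

For a tag set at positions $V_{(1)} < \dots < V_{(t)}$ in a ranking of
$n$ genes:

$$a = \max_j\left(\frac{j}{t} - \frac{V_{(j)}}{n}\right),\qquad
  b = \max_j\left(\frac{V_{(j)}}{n} - \frac{j-1}{t}\right),$$

and the enrichment score is $a$ if $a > b$, else $-b$. The raw
connectivity score is `ks_up − ks_down` when the two enrichments have
opposite signs and 0 otherwise; across a database, positive raw scores are
divided by the largest positive raw score and negative ones by the
magnitude of the most negative, giving scaled scores in $[-1, 1]$. Among
the KS-statistic score families in the connectivity-mapping literature,
this package implements the classic two-sided max-deviation variant; the
scoring function is isolated behind `ks_enrichment()` so an alternate
scorer can be swapped in.

P-values permute the *query*: random disjoint tag sets of the query's
sizes are drawn over the universe and
$p = (1 + \#\{|s_\pi| \ge |s_{obs}|\})/(n_{perm}+1)$ (add-one, so p is
never 0; default `n_perm = 1999`, seed mandatory). The null distribution
depends only on the tag-set sizes and the universe size — not on the
particular profile — so `score_reference_db()` draws it once per distinct
size combination and shares it across instances, which is exact and makes
large calibration runs cheap.

**A known, structural limitation.** The same-sign rule places a large
probability atom (≈ 0.49 for 20+20 tags in a 500-gene universe) at raw
score 0 under the null, and the add-one estimator maps that atom to
p = 1. Null p-values are therefore exactly calibrated below the atom
(P(p ≤ α) = α for α up to ≈ 0.5 — the test suite verifies the 5% level
lands in [0.03, 0.07]) but are *not* globally uniform: about half the mass
sits at p = 1. Any deterministic tie-handling shares this property;
only randomized p-values would remove it, at the cost of irreproducible
per-instance values. Selection at small thresholds (p < 0.005) is
unaffected.

Selection is strict on both axes: scaled score < −0.5 **and** p < 0.005,
matching the published wording; an instance sitting exactly at −0.5 or
0.005 is excluded. Selected instances are reported most-negative first.

## Problem sizes and numerical choices

The test suite runs the chain at the sizes the package documents as its
reference conditions: 1000 probes, 5+6 samples, 20+20 planted probes at
2-fold, 10% noise; a 100-instance database with 5 reversers and 5 mimics
at maximal strength screened with `n_perm = 1999`; null calibration over
1000 random queries against a 50-instance database at `n_perm = 999`.
Exhaustive KS-oracle checks cover every tag set with `n ≤ 12`, `t ≤ 4`.
Tolerances: 1e-12 for the KS statistic against its oracle, 1e-10 for merge
heights, 1e-6 relative for normalization identities, 1% for scale-factor
removal.

Degenerate inputs are errors, not silent results: empty tag sets, empty
universes, non-positive signals in log space, groups with fewer than two
samples, fewer stable probes than knots (the error tells the caller to
relax `rank_tol`). Ties: average ranks in rank-stability, first-by-order
for the median-array tie, stable ordering for equal keys in the generator
and for equal scaled scores in selection (by instance id).

## Reproducibility

Every stochastic function takes an explicit seed; `run_pipeline()` expands
one global seed into fixed per-stage offsets so any stage can be
reproduced in isolation, and writes a run manifest with parameters, seeds
and md5 hashes of every output file. Reruns with the same configuration
are bit-identical.
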