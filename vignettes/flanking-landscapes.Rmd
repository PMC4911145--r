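---
title: "Methods: interval-wise testing and functional logistic regression for integration-site flanking landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flanking landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. Data model

Each *region* is a 64-kb stretch around an anchor: for an element (an ERV
or other transposable element) the anchor is the integration site and the
region is the pair of 32-kb flanks abutting the element body; for a control
it is the center of a contiguous 64-kb stretch. The region is divided into
`K = 64` windows of 1 kb, labelled `-32..-1, +1..+32` relative to the
anchor; minus-strand elements are inverted so that labels are always
element-relative (`build_flanks(..., oriented = TRUE)`).

Per window, a feature track is summarised by one of three measures:

* **content** — covered fraction of the window, overlapping track
  intervals merged first; in `[0, 1]`.
* **count** — number of records whose *start* coordinate falls in the
  window. Start-binning is a package decision: a multi-bp motif straddling
  a boundary is counted exactly once, and window totals are conserved.
* **weighted average (WA)** — `sum(value_i * overlap_i) / sum(overlap_i)`
  for a valued (bedGraph) track. Windows with no data are flagged missing
  and, because the interval testing procedure needs complete curves,
  mean-imputed from the same region's non-missing windows
  (`impute_wa_curves()`); regions with no data at all stay missing and are
  reported.

Filtering before quantification mirrors the analysis the package
implements: elements outside 60 bp–11 kb are rejected at construction;
elements whose flanks overlap assembly gaps by more than 320 bp (1% of a
flank — applied per flank; the per-flank-vs-per-region reading is
ambiguous in the source analysis, so the threshold is configurable) or
another element's flanks by more than 1 bp are excluded. The flank-overlap
rule is *symmetric*: both members of an overlapping pair are dropped. (An
alternative input-order-iterative rule was considered; the symmetric rule
is what the exclusion criterion actually states, and it is
order-independent.) Controls are placed by seeded rejection sampling —
the placement algorithm is not specified by the source analysis — with at
most 2% LTR overlap and 1% element-flank overlap per region, mutually
non-overlapping, erroring with the achieved count if the budget of
attempts is exhausted. chrY is excluded by default (most functional tracks
lack data there); configurable.

## 2. The permutation engine

All two-sample tests share one engine. A *plan* (`make_plan()`) is the set
of group-1 assignments: exhaustive (all `choose(n1+n2, n1)` distinct
assignments) when `n1 + n2 <= 10`, otherwise `n_perm` sampled assignments
with the identity (observed) assignment as row 1. Three statistics are
available: mean difference, median difference, and the variance ratio
oriented larger/smaller before two-siding. All alternatives are two-sided;
the sign of the observed statistic is reported separately (it drives
enrichment/depletion calls).

P-value conventions, chosen to guarantee validity:

* "at least as extreme" is `>=` — ties count as extreme;
* the observed assignment is in the reference set, so `p >= 1/n_perm`;
* comparisons are tolerance-aware (`1e-9` relative): complementary
  assignments have exactly tied statistics in exact arithmetic, but their
  dot products differ in the last ulp, and a naive `>=` would break those
  ties inconsistently. Statistics are quantized at `1e-9` relative
  resolution before ranking. Genuinely distinct values are never closer
  than this for the discrete p-values involved, so the quantization only
  restores exact-math ties.
* a variance ratio with both groups constant is undefined: the component
  reports `p = NA` (univariate) or contributes `p = 1` with a logged flag
  (inside the ITP).

## 3. The extended Interval Testing Procedure

Curves are represented on an order-1 B-spline (piecewise constant) basis:
65 nodes give `K = 64` coefficients equal to the raw window values, 33
nodes give `K = 32` adjacent-pair means (a piecewise-constant smoothing).
Both bases are run and reported by the pipeline; a feature significant in
either counts.

For one basis and one statistic:

1. every component gets a synchronized permutation test (the *same* plan
   for all components and statistics);
2. every contiguous component interval `[a, b]` gets a Nonparametric
   Combination test. The combining function is Fisher's
   `-2 * sum(log p)` over the interval's per-assignment p-values
   (the significance-level function of each component evaluated at every
   assignment), recomputed per assignment to form the interval's
   permutation distribution. The source framework does not name its
   combining rule; Fisher is the standard default and Tippett (min-p) is
   available via `combining = "tippett"`. No wrap-around intervals:
   flanking regions are linear, so exactly `K(K+1)/2` intervals are
   tested;
3. the adjusted matrix `A(L, k)` is the maximum interval p-value over all
   intervals of length at most `L` containing `k`, for every `L`.
   `A(1, k)` is the raw component p-value, `A(K, k)` reproduces the
   original single-scale adjustment, and `A(L, k)` is nondecreasing in
   `L` (asserted on every run in the tests).

### Feature-level inference and classification

This is the one place the package departs from a literal reading of its
design sketch, for a statistical reason. "Feature significant if any
component is significant at any scale" degenerates at `L = 1` to an
uncorrected 64-fold scan: essentially every null feature would be called
significant. Conversely, the plain Fisher global test (interval `[1, K]`)
is *underpowered for sharp localized effects* at finite `n_perm`: with
`B = 1000` the per-component p-value floor is `1/1001`, and under
relabelling the bump components share essentially one uniform variate, so
the null distribution of the global Fisher sum has a heavy upper tail —
measurably, a 5-window bump at 3 standard deviations can fail the global
test in a quarter of runs.

The package therefore uses *scan tests*: for each scale `L`, the maximum
NPC evidence over all length-`L` interval starts, referred to its own
permutation distribution — an exact test of the whole-curve null at every
scale. The feature-level call Bonferroni-combines the dyadic ladder
`L in {1, 2, 4, ..., K}` (7 scales at `K = 64`), keeping exact null
control while catching sharp signals at fine scales and distributed
shifts at coarse ones.

A significant feature is **IDL** when every component survives the full
adjustment (`A(K, k) < alpha` for all `k`), else **LDL**. The reported LDL
support is FWER-controlled at a data-proposed scale: the raw scan proposes
`L_hat` (the longest contiguous raw-significant run) and the support is
the set of raw-significant components covered by a length-`L_hat` window
whose evidence exceeds the `1 - alpha` quantile of the permutation
scan-max distribution (single-step maxT). Under the null the support is
empty with probability at least `1 - alpha`; thresholding on statistic
values rather than p-values avoids the `1/n_perm` floor. The maximum
significant scale `L*` is reported alongside (the analogue of per-feature
scale thresholds in landscape heatmaps), and `classify_feature(...,
L_star = )` lets the user impose a scale.

Across the two bases (and multiple statistics, if requested) the combined
class takes the precedence IDL > LDL > NS.

## 4. Feature screening

One value per region (the mean over the windows — the same reduction the
scalar predictors use; whether the source analysis correlated window-level
or region-level values is unstated), Spearman correlations, distance
`1 - |rho|`, complete linkage, tree cut at `1 - 0.8`. One representative
per cluster: lexicographically first by default (deterministic and
order-independent; features are processed in name order), overridable via
`prefer =` for domain judgment calls. Constant features have undefined
correlations and become singleton clusters with a warning. Raising the
threshold can only refine clusters, so the retained count is monotone — a
property test.

## 5. Functional logistic regression

Predictor construction: IDL features and significant low-resolution
scalars enter as scalar predictors `Z = mean over windows`; LDL features
enter as functional predictors. The flank is partitioned into contiguous
sub-intervals of near-equal width at most the feature's significant scale
(the detected support scale when there is one, else `L*`), covering the
whole flank — e.g. width <= 20 windows gives a 4-interval layout over 64
windows; explicit layouts (3/7/15-interval analogues) can be passed. Each
sub-interval contributes one term equal to the curve's mean over it: the
discretized `1/|I|` integral, so each fitted coefficient is the model
weight on that sub-interval — exactly the reporting granularity of
per-interval coefficient tables.

*Shifted log*: when |sample skewness| > 1 in either group (the trigger is
a package choice; the source states only "whenever skewed"), the predictor
becomes `log(x + s)` with `s` maximizing the smaller of the two groups'
Shapiro-Wilk p-values over a 200-point logarithmic grid on
`[1e-6, 10] * range(x)`, offset to keep `x + s > 0` (grid bounds are a
package choice; none are stated). Samples above 5000 are thinned for the
Shapiro-Wilk statistic (its implementation limit).

*Model building*: single fits score each predictor by
`DE = (D_null - D_model) / D_null`; DE > 20% (strictly) sets a predictor
aside as dominant. Remaining scalars are standardized and subset by LASSO
with the penalty minimizing 10-fold cross-validated misclassification —
the source text says "maximizing", read here as a typo for minimizing,
which is the only sensible direction; the one-standard-error rule is not
applied. Fold assignment is seeded. Columns aliased with earlier
selections (exact duplicates) are dropped before the unpenalized refit,
which needs a full-rank design. Functional predictors are then added
greedily (largest DE gain; accept if gain > 1% *and* AIC decreases), and
scalars with coefficient `p >= 0.05` are removed backward, worst first,
refitting each time (0.05 is a package choice matching the usual bolding
convention; backward removal applies to scalars only, as stated).
`RCDE = ((D_null - D_model) - (D_null - D_red)) / (D_null - D_model)` is
computed by explicit refit without each predictor (functional predictors
as a block); the tests verify the identity to 1e-10. Perfect separation
is flagged rather than hidden; non-converging candidate fits are skipped
with a log entry.

## 6. The synthetic world

`simulate_curves()` draws, per feature, a latent Gaussian AR(1) process
along windows (stationary, marginal SD = `noise_sd`), adds the group-1
mean shift (everywhere / in the bump / nowhere), and maps through the
marginal: identity (Gaussian), `exp` (lognormal, right-skewed — exercises
the shifted log), or inverse-logit (`beta_like`, bounded for content).
Counts are rounded and floored at zero. Consequences to keep in mind: the
stated `effect_size` is exact on the latent scale and only
monotone-preserved through nonlinear marginals; Gaussian content features
validate that the shifted mean stays inside `[0, 1]` and clip draws.

Defaults and why: `autocorrelation = 0.3` — genomic signals are locally
correlated, and uncorrelated windows would make the interval-wise
correction trivially easy to pass; `n_windows = 64` matching the flank
design; each feature draws from an RNG stream derived from
`(seed, feature name)` so adding a feature never perturbs another's draws
(a determinism property the tests check). `simulate_scalars()` adds the
group shift on the observation scale so the mean difference is exactly
`delta` even under the lognormal marginal. `simulate_tracks()` writes toy
BED/bedGraph realizing the simulated curves on a toy chromosome — content
values are snapped to 1-bp resolution so quantification round-trips
bit-identically.

What a green test does *not* establish: the generator reproduces the
statistical structure the methods assume (grouped curves, local
correlation, bounded/skewed marginals, localized and invariant shifts),
not real genomic feature distributions — no mosaic of feature-feature
dependence, no distance-decaying correlation between features, no
chromosome-scale non-stationarity, no realistic track sparsity patterns.
Power numbers measured here do not transfer to any particular genome-wide
dataset.

## 7. End-to-end behavior worth knowing

With effects strong enough that a feature is classified IDL (every window
significant after full FWER adjustment), the corresponding scalar
predictor's single-model DE is essentially always far above the 20%
dominance threshold — the 64-window mean multiplies the per-window
signal-to-noise by ~8. Such predictors are set aside as dominant, exactly
as the workflow prescribes, so the end-to-end test asserts that every true
effect appears either among the dominant predictors or in the final
multiple model (and that no null feature reaches either), rather than
forcing all true effects into the multiple model.

Determinism: every stage derives its RNG stream from the config seed and a
stage/feature label; reports contain no timestamps; identical config +
seed reruns are byte-identical (tested).

## 8. Known limitations

* The median-difference statistic requires a per-assignment pass (no
  closed matrix form), so it is the slow path at large `n_perm`.
* The scan-ladder Bonferroni is mildly conservative under strong
  inter-scale correlation.
* Backward elimination never removes functional predictors (stated
  scalars-only); no interaction terms; no smooth (higher-order) coefficient
  functions; no designs with more than two groups.
* `A(L, k)` is stored densely (`K x K` per statistic per basis), plus
  scan-max quantiles; memory grows with the number of features kept in a
  report.
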