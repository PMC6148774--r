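---
title: "Honest evaluation of survival classifiers on small unbalanced omics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Honest evaluation of survival classifiers on small unbalanced omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput molecular studies of patient survival routinely face three
compounding difficulties: the cohort is small (often around a hundred
patients), the outcome is strongly unbalanced (a quarter or fewer
non-survivors), and the number of measured variables — gene expression,
copy-number signal — exceeds the number of patients by orders of magnitude.
Under these conditions the apparent performance of a classifier depends at
least as much on *how* it was evaluated as on the data, because every
analytical step that sees the whole cohort leaks information into the
estimate. `synforest` packages a complete, reproducible protocol for this
setting: statistical and information-theoretic feature filters, Random
Forest models scored with the Matthews correlation coefficient, a
three-stage cross-validation design that decomposes the optimism bias into
interpretable components, an ensemble classifier assembled from the
cross-validation models, and integration of feature sets across data sets
with an explicit synergy score. A synthetic cohort generator with recorded
ground truth makes every one of these claims testable without access to any
restricted data.

## The data model

A `cohort_dataset` is a samples x variables numeric matrix with a binary
label (1 = non-survivor, the minority class) and a per-variable source tag.
Preprocessing follows fixed variable-level rules:

* variables with **more than 10%** missing values are removed (the boundary
  case, exactly 10%, is kept);
* remaining missing entries are replaced by the **median of the variable's
  observed values across all samples**. Imputing per class would write the
  label into the features, so the pooled median is used even though it is
  slightly biased toward the majority class;
* variables from RNA-seq-like sources are kept only if **at least 50% of
  entries are non-zero in each class separately**; a marker expressed in
  one class only at the detection floor is otherwise indistinguishable from
  a technical artefact. The rule can be extended to all variables.

The pipeline always filters before imputing, and the filters refuse
datasets that still contain missing values.

## Feature filters

Four filters identify *relevant* variables, i.e. variables significantly
associated with survival after multiple-testing correction at
`alpha = 0.05` (the correction level is a parameter; 0.05 is the
conventional default).

**Welch t-test.** The statistic is
`t = (mean_d - mean_s) / sqrt(V_d/n_d + V_s/n_s)` with the non-survivor
class first, two-sided p-values on Welch–Satterthwaite degrees of freedom,
and the Hochberg step-up correction for family-wise error control. The
unequal-variance form is used because nothing in a two-class omics contrast
justifies assuming equal variances.

**IG-1D.** The mutual information `IG(Y; x)` between the discretized
variable and the label, computed from the four-entropy identity
`IG(Y; x | S) = H(x,S) - H(Y,x,S) - [H(S) - H(Y,S)]` with `S` empty.
Entropies are plug-in estimates in bits.

**IG-2D.** The pairwise conditional information gain
`IG_max(x_i) = max_j IG(Y; x_i | x_j)` over all other variables, an
exhaustive O(m^2) scan. This is the filter that detects *synergistic*
variables: pairs that are jointly informative about survival while each
member is marginally indistinguishable from noise (the XOR pattern). The
search is deliberately limited to single-variable conditioning sets;
higher-order sets are both computationally prohibitive and statistically
undersampled at cohort sizes near 145. `IG-2D >= IG-1D` is *not* asserted
anywhere: the two statistics are computed for separate conditioning regimes
and calibrated against different nulls.

**t-test + lasso.** The t-test relevant set is refined by an L1-regularized
logistic model: walking the decreasing regularization path, the active set
at the first point with at least `N` non-zero coefficients is taken,
truncated to the `N` largest coefficients. The logistic family was chosen
because the response is binary; the path never being long enough simply
returns the largest active set attained, which is the correct behaviour for
data-poor sources where only a handful of variables are relevant.

### Discretization

The information-gain filters need discrete inputs. Continuous variables are
binned by **equal-frequency binning** (default 2 bins), repeated (default
30 times) with random jitter of the bin boundaries and random tie-breaking,
and the statistic is averaged over the repeats. Equal-frequency binning is
the only scheme that is invariant to monotone transformations of the
signal — important because the generator's RNA-seq-like model is an
exponentiated Gaussian — and the averaging removes the dependence of the
result on any single boundary placement. Two bins are the default because
with ~30 minority samples per fold a finer grid leaves cells too sparse for
stable entropy estimates.

### Significance of information-gain statistics

The null distribution of the IG statistics is generated by label
permutation: the per-variable statistics are recomputed under (default) 20
permutations of the outcome, using the same discretizations, and pooled.
Fitting the null to the observed statistics themselves would contaminate
the null with true positives, so permutation is used instead.

Calibration then proceeds in two regimes. Within the range of the pooled
null sample the p-value is the empirical permutation tail
`(1 + #{null >= stat}) / (N + 1)`, which is valid by exchangeability
regardless of the statistic's shape. Beyond the largest null value — where
discoveries live but the empirical tail has no resolution — the upper tail
of a Gumbel (type-I extreme-value) distribution fitted to the null sample
by maximum likelihood takes over, capped at `1/(N+1)` so the two regimes
join monotonically. The reason for the hybrid is practical and was measured
during development: `IG_max` is a maximum and is well approximated by an
extreme-value law, but the univariate IG statistic is not an extreme, and a
pure Gumbel fit to its null is anti-conservative in the tail (family-wise
error far above nominal on null data). The hybrid keeps both filters
calibrated — family-wise error within Monte-Carlo error of nominal on
fully null cohorts — while preserving far-tail resolution for genuine
discoveries. Both IG filters then apply the Hochberg correction, exactly as
the t-test does.

### Subset selection

Models are built on the top `N` variables by adjusted p-value
(`N` in 10, 20, 50, 100 in the original design; any `N` is accepted), ties
broken by larger absolute statistic and then lexicographic id. No
redundancy or correlation pruning is applied afterwards. When fewer than
`N` variables are relevant the whole relevant set is used as is — the
situation typical of copy-number data, where filters find only a handful
of markers. When *no* variable is relevant (possible in stage-3 folds on
weak data) the best-ranked `N` are used regardless of significance, with a
warning; every fold must yield a model for the protocol's bookkeeping to
stay balanced.

## Models and metric

Classifiers are Random Forests with default parameters: 500 trees,
`floor(sqrt(p))` candidate variables per split, no class weighting or
resampling. The imbalance is handled by the *metric*, not by the training
procedure: the Matthews correlation coefficient

MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

the geometric mean of informedness and markedness, treats both classes
symmetrically and equals 0 for any degenerate (single-class) prediction, by
the usual convention when a denominator factor vanishes. The out-of-bag
(OOB) estimate — each sample classified by majority vote of the trees whose
bootstrap excluded it — provides a near-independent error estimate without
sacrificing any data. OOB and holdout vote ties are broken toward the
training-set majority class, a deterministic rule that makes fixed-seed
runs bit-reproducible.

## The three-stage protocol

Cross-validation is stratified: each class is split into `k` near-equal
parts separately and the parts are merged, so every fold preserves the
minority fraction to within one sample. The defaults are `k = 5` and 100
repeats (3-fold splits were found to give visibly worse models in this
setting, and the high variance of small-cohort estimates demands many
repeats); with these defaults every MCC estimate in stages 2–3 averages
500 independent models. The package's own test-suite and acceptance runs
use 2–5 repeats and cohorts of up to 500 variables, sizes chosen so a
complete run remains a desk-scale computation; all cardinality claims are
asserted at the full 100-repeat scale as well, where only bookkeeping is
involved.

* **Stage 1 — minimum error, maximum bias.** Filter and model are fit on
  all data; only the OOB estimate is reported.
* **Stage 2 — intermediate.** Features are selected once on all data;
  models are trained and validated inside repeated cross-validation.
* **Stage 3 — minimum bias, maximum error.** The *entire* procedure,
  feature selection included, runs inside every fold. The validation part
  of a fold never reaches the filter; the test suite asserts this by
  mutating validation rows and checking that per-fold feature lists are
  bit-identical.

The pairwise aggregate differences decompose the optimism:
`OOB1 − OOB2` is the cost of the smaller cross-validation training sets;
`CV2 − OOB2` is the (usually slightly positive) difference between external
validation and OOB, which uses only about a third of the trees per sample;
`OOB3 − OOB2` is the inflation of the within-fold OOB estimate caused by
feature selection itself. The honest estimate of performance on new
subjects is the stage-3 cross-validated mean, and on synthetic cohorts with
planted signal it sits measurably below the stage-1 OOB estimate, with the
per-model OOB and validation estimates negatively correlated — both
signatures of the shared pool of hard-to-classify samples that dominates
small-cohort variance.

## The ensemble of forests

Every sample is held out exactly once per repeat, so a stage-3 run with
`R` repeats leaves `R` honest predictions per sample. Pooling them gives a
higher-level classifier: consensus by majority vote (ties to the cohort
majority class), an agreement fraction per sample, and an ensemble MCC that
is typically above the mean per-model cross-validated MCC — averaging
models recovers some of the variance lost to any single split. Thresholding
the agreement fraction (default 0.9) partitions the cohort into
consistently correct, unstable, and consistently wrong samples; the last
set flags patients whose recorded outcome contradicts their molecular
profile under essentially every model, and on synthetic cohorts with
deliberately flipped labels it recovers the flipped samples.

## Integrating data sets

To ask whether two data sets carry complementary information, the top-50
variables of the gene-expression-like result are extended by *all* relevant
variables of the copy-number-like result found by the same method, with ids
namespaced by source so nothing collides. Base, added, and merged sets are
then evaluated under the *identical* fold plan (a paired comparison, which
removes the split-to-split variance from the contrast), and

synergy = MCC(merged) − max(MCC(base), MCC(added))

per evaluation mode (OOB and CV). The gain over the base set alone is also
reported, since a merged panel is interesting to a practitioner even when
it only beats the gene-expression component. The alternative
merge-then-filter procedure (pool the variables first, filter the joint
matrix) is deliberately *not* the default: it dilutes the correction across
the union of variables and was found not to surface synergies.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, with
recorded ground truth. Defaults are fixed study conditions, not tuning
knobs:

* **38 minority / 107 majority** samples — the small-cohort class counts
  (26% non-survivors);
* **400 null variables, 20 marginal variables at d = 1.0, 5 synergy pairs
  at strength 0.2.** A standardized difference of one per-class SD is a
  strong but realistic transcriptomic survival marker; the variable count
  is scaled down from the tens of thousands of a real array so that a full
  protocol run is a desk-scale computation;
* three noise models: `gaussian` (microarray-like, normal per class),
  `lognormal_count` (RNA-seq-like: an exponentiated Gaussian with a
  configurable fraction, default 0.2, floored to zero — skewed,
  non-negative, excess zeros), and `cnv_gaussian` (copy-number-like,
  approximately normal in roughly [−3, 3], with entries missing completely
  at random at rate 0.1 by default).

Synergy pairs use a sign-product construction: two standard normal draws
whose sign product is made to predict the class with probability
`0.5 + strength`, by flipping the sign of the second member where needed.
Because the flip touches only the sign, and the sign of the first member is
symmetric and label-free, each member remains exactly standard normal
within each class — the pair is jointly informative with provably null
one-dimensional projections. The monotone transforms of the noise models
preserve this structure under equal-frequency binning.

What the generator does **not** emulate: gene–gene correlation structure,
batch effects, informative missingness, and any relationship between the
planted effect sizes and real neuroblastoma markers (no public source
states those effect sizes; the defaults are calibration choices). Passing
tests therefore demonstrate that the *protocol* behaves as claimed —
calibrated nulls, detected synergies, ordered optimism — not that any
particular biological signal is recoverable.

## Numerical and design choices

* All randomness flows through one master seed that deterministically
  spawns per-(repeat, fold, purpose) child seeds; a fixed seed reproduces
  every aggregate bit-identically, and temporary streams never disturb the
  caller's RNG state.
* "More than 10% missing" is a strict inequality; exactly 10% is kept.
* Entropies are in bits; any fixed base gives the same rankings.
* Conditional information gains are clamped at zero against floating-point
  noise; the identity itself is exact on empirical counts.
* The Gumbel fit starts from moment estimates and refines by BFGS on the
  negative log-likelihood; a degenerate (zero-variance) null is an error,
  as is a null sample smaller than 30.
* `welch_t` treats two constant identical samples as `t = 0, p = 1` and
  refuses constant samples with unequal means.
* Degenerate MCC denominators return 0 rather than NaN.

## Limitations

The protocol quantifies and orders evaluation biases; it cannot remove
them. The stage-3 estimate remains pessimistically biased on small cohorts
(the negative OOB–CV correlation is the visible symptom), and the ensemble
estimate, while typically closer to truth, has no formal guarantee. The
IG-2D scan is quadratic in the number of variables and is intended for use
after preprocessing has reduced the variable count, or on data sets that
are small to begin with. Batch correction, probe-to-gene mapping, and
survival-time regression are out of scope.
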