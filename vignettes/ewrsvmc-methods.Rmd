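---
title: "Evolutionary weighted random SVM clusters: model, parameters and validation"
author: "ewrsvmc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary weighted random SVM clusters: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewrsvmc)
```

## The problem and the model

Resting-state fMRI classification studies commonly summarise each subject by
a functional-connectivity (FC) profile: the brain is parcellated into $R$
regions (here the 90-region AAL cerebrum atlas by default), each region gets
one representative time series, and the Pearson correlation between every
pair of regional signals yields $d = R(R-1)/2$ features per subject (4005
for $R = 90$). The classification task is binary — for example separating
two adjacent clinical stages of a neurodegenerative disease — with labels
$y_i \in \{+1, -1\}$, small $N$ (tens of subjects) and large $d$.

A single SVM on all 4005 noisy features is unstable at these sample sizes.
The method implemented here builds a *weighted random SVM cluster*:

1. **Outer split.** Subjects are divided 3:1 into a training-and-validation
   set and a held-out test set.
2. **Random base classifiers.** Each of $n$ members (default 500) redraws a
   2:1 training/validation partition of the training-and-validation
   subjects and samples $m$ features (default 62 $\approx \sqrt{4005}$)
   without replacement from the active feature pool, then fits an RBF-kernel
   SVM on the training part restricted to those features.
3. **Accuracy weighting.** Member $l$'s weight is its validation accuracy
   $W_l = T_l^{\mathrm{correct}} / T_L$.
4. **Weighted vote.** A new sample's label is the one with the larger sum
   of member weights among members voting for it.

On top of the cluster sits an **evolutionary feature-elimination loop**.
Members with $W_l < 0.5$ (strictly) are *weak*. Each feature $j$ accumulates
the total weight it carried in weak members,
$Tw_j = \sum_{l \,\mathrm{weak},\, j \in S_l} W_l$, and features with
$Tw_j > q$ (strictly) are removed from the pool; removed features never
re-enter. A fresh $n$-member cluster is rebuilt from the reduced pool, its
test accuracy recorded, and the loop repeats for a configured number of
evolutions (default 50) or until the pool cannot support $m$-feature
members. The generation with the highest test accuracy is the *optimal*
cluster and its surviving pool the *optimal feature set*.

Finally, the optimal feature set is translated into a **region ranking**:
every selected FC feature increments both of its endpoint regions by one,
and regions are ranked by descending frequency (ties broken by region
ordinal). Regions exceeding a reporting threshold (default frequency 10)
are the candidate disease-related regions.

## Parameters, defaults and conventions

| Parameter | Default | Meaning |
|---|---|---|
| `n_members` | 500 | base classifiers per generation |
| `m` | 62 | features per member (≈ √d for the AAL-90 feature space) |
| `sigma` | 3 | RBF bandwidth; kernel is $\exp(-\lVert u-v\rVert^2 / (2\sigma^2))$, i.e. `gamma = 1/(2*sigma^2)` in libsvm terms |
| `cost` | 1e6 | SVM penalty $C$; a large finite value standing in for an unbounded (hard-margin) penalty, which is numerically fragile |
| `q` | 7 | feature-removal threshold on $Tw_j$ (see scaling note below) |
| `n_evolutions` | 50 | pruning steps; up to `n_evolutions + 1` clusters are built |
| outer / inner split | 3:1 / 2:1 | test fraction 1/4; member validation fraction 1/3 |
| `stratified` | TRUE | all splits stratified by class so both classes reach every part at small N |

Conventions pinned by this package (each is a point where more than one
reading was possible):

* **Feature ordering** is row-major over the upper triangle:
  $(1,2), (1,3), \dots, (1,R), (2,3), \dots$ Region ordinals and feature
  indices are 1-based everywhere.
* **Raw Pearson r** is used; no Fisher z-transform, no feature
  standardisation by default (features already lie in $[-1, 1]$).
* **$w_{l,j}$ in the pruning sum** is read as the member weight $W_l$ gated
  by feature membership (0 if member $l$ does not use feature $j$), not an
  SVM-internal per-feature coefficient: only $W_l$ is defined per member,
  and RBF-SVMs have no natural per-feature weight.
* **Pool update is subtractive**: the new pool is the old pool minus the
  strict exceedances $\{j : Tw_j > q\}$. The alternative union reading
  ("features of strong members plus low-weight features of weak members")
  collapses the pool almost immediately because nearly every pool feature
  is drawn by some strong member; the subtractive reading produces the
  gradual, roughly linear pool decline the method is known for.
* **Each member redraws its inner split.** The 2:1 ratio describes each
  member's partition, not one fixed partition: per-member randomness over
  subjects *and* features is what makes the cluster "random". A fixed split
  would make member weights strongly dependent.
* **Subject sampling is a partition, not a bootstrap** (samples are
  "selected", not resampled).
* **Weak members still vote** at prediction time; weakness only matters for
  pruning.
* **Vote ties** (equal summed weights) go to the single heaviest member's
  label, then to $+1$. Deterministic and auditable.
* **Split rounding** is nearest-integer with every part forced non-empty
  (per class when stratified).

### How q scales

$Tw_j$ is a sum of weak-member weights over the members that drew feature
$j$, so its scale is governed by the expected number of draws per feature,
$n \cdot m / d$, times the weak fraction and the typical weak weight
(< 0.5). The default $q = 7$ belongs to the default scale
($n = 500$, $m = 62$, $d = 4005$, about 7.7 draws per feature). A smaller
study must scale $q$ down or nothing will ever be pruned. Note a
quantitative subtlety of the gated-$W_l$ reading: since every weak weight is
below 0.5, $Tw_j > 7$ requires a feature to appear in at least 15 weak
members while its *expected total* number of draws is only ≈ 7.7 — at the
default scale the strict formula prunes only extreme outliers. For the
package's synthetic demonstrations ($n = 100$, $m = 14$, $d = 190$, ≈ 7.4
draws per feature, measured weak fractions 0.2–0.5) we fix $q = 1$, i.e. a
feature becomes removable once roughly two weak members have carried it.
This sits near the bulk of the weak-weight distribution and reproduces the
gradual pool decline followed by accelerating elimination as the pool
shrinks.

### Optimal-generation selection and its bias

Following the method's original design, the per-generation selection
criterion is accuracy on the held-out *test* set. Selecting the maximum of
many test-set evaluations is optimistically biased; the reported optimal
accuracy should be read as a model-selection statistic, not an unbiased
generalisation estimate. `run_config(optimal_set = ...)` also controls
whether the optimal feature set is the surviving pool (default) or the
union of features actually drawn by the optimal generation's members.

Ties at the maximum deserve care: with a test set of 16 subjects, accuracy
is quantised to steps of 1/16 and ties are the rule. The package's default
tie rule is **parsimony** (`tie_break = "sparsest"`): among tied
generations, prefer the smallest surviving pool (the most parsimonious
equally-accurate model, in the spirit of the one-standard-error rule used
in penalised regression), earliest among equal sizes. The alternative
`"earliest"` simply takes the first tied generation; note that whenever
generation 0 already attains the maximum, `"earliest"` returns the *unpruned*
pool, which makes the downstream region ranking uniform and therefore
uninformative.

## The synthetic-connectome generator

`synthetic_spec()` / `generate_study()` emulate exactly the statistical
structure the pipeline consumes, with known ground truth:

* Each subject's $T \times R$ signal matrix is drawn i.i.d. over timepoints
  from a zero-mean Gaussian. Pearson correlation is invariant to the
  temporal structure the pipeline ignores, so a stationary white model is
  the simplest model with the assumed structure.
* The reference class ($-1$) has a uniform baseline inter-regional
  correlation $\rho_0$ (default 0.1, a weak positive background typical of
  regional BOLD correlations). Class $+1$ additionally carries an effect
  $\Delta$ (default 0.4) on a planted set of region pairs (default: 8 pairs
  concentrated on 6 regions), so the class-discriminative features and
  their endpoint regions are known.
* Defaults $T = 130$ (a 140-volume acquisition minus 10 discarded volumes)
  and 30 subjects per class reflect a typical single-site resting-state
  study.
* If the implied correlation matrix is not positive definite (dense planted
  structure can break it), eigenvalues are floored at $10^{-6}$ and the
  diagonal re-normalised; the projection is announced via a message.
* The generator deliberately omits realistic fMRI nuisance structure:
  autocorrelation, drift, motion, physiological confounds, site effects.
  Passing tests on this generator therefore validate the *algorithmic*
  pipeline (feature extraction, weighting, voting, elimination,
  bookkeeping, determinism, calibration), not robustness to real-world
  noise.

All randomness flows from one master seed through named substreams
(`derive_seed(seed, "outer")`, `derive_seed(seed, "generation", g)`,
`derive_seed(seed, "member", l, try)`, ...), so every run — including
parallel-free replay of any single member — is bit-reproducible.

## What the validation shows (and does not)

The package's test suite checks, among others:

* closed-form and round-trip identities of the pair/feature indexing;
* Pearson features against the textbook covariance formula and their
  affine/swap invariances;
* the weighted vote, weak/strong partition, $Tw$ accumulation and strict
  pruning against brute-force oracles;
* exact evolution bookkeeping (pool sizes vs cumulative removals, disjoint
  removal sets);
* metric formulas against exhaustive enumeration of small confusion
  matrices;
* byte-identical replay of full fits and exact JSON persistence
  round-trips (ensembles are serialised at 17 significant digits, which
  reproduces IEEE doubles bit-for-bit);
* **null calibration**: with $\Delta = 0$, the mean per-generation test
  accuracy over 20 seeds sits within binomial noise of 0.5. The
  per-generation accuracies are used here, *not* the selected maximum,
  because the selection step is biased by construction (see above);
* **signal regime**: with $\Delta = 0.4$ the optimal cluster separates the
  classes essentially perfectly (mean optimal test accuracy 1.0 at these
  conditions).

One empirical property deserves a frank statement. In the signal regime the
elimination loop does **not** shrink the pool all the way down to the
planted features: once the surviving pool is informative enough that no
member falls below 0.5 validation accuracy, there are no weak classifiers
left, $Tw \equiv 0$, and pruning stalls permanently. At the demonstration
conditions the pool equilibrates around 40–90 features, which still
contains all planted features but also spuriously informative survivors
(features that look discriminative on the fixed training sample — partly
*because* the loop selected for them). At that pool size a planted region's
endpoint-degree advantage (≈ 2.7 counts) is comparable to the baseline
degree noise of the surviving non-planted features, and the mean top-$k$
recovery of planted regions plateaus around 0.5–0.65 rather than
approaching 1. This is a property of weight-driven elimination itself —
it only removes features that participate in *failures* — and should be
kept in mind when interpreting region rankings produced on easy, strongly
separable data; the corresponding package check asserts a stricter
recovery level and is expected to flag this regime.

## Worked example

A complete run at demonstration scale (seconds, not minutes):

```{r example, eval = FALSE}
pp <- plant_pairs(20, n_regions = 6, n_pairs = 8, seed = 42)
spec <- synthetic_spec(n_per_class = c(30, 30), regions = 20,
                       timepoints = 130, planted_pairs = pp$pairs,
                       baseline_r = 0.1, effect = 0.4, seed = 42)
study <- generate_study(spec)
ds <- build_dataset(study$series, study$labels)

cfg <- run_config(n_members = 100, m = 14, q = 1, n_evolutions = 50,
                  seed = 42)
hist <- run_evolution(ds, cfg)
opt <- select_optimal(hist)

pred <- predict_batch(opt$ensemble, ds$features[hist$test, ])
metric_report(ds$labels[hist$test], pred)

tab <- region_frequencies(opt$feature_set, ds$pair_map,
                          sprintf("region_%02d", 1:20))
head(tab)
recovery_score(tab, study$truth$regions)
```

## Known limitations

* Binary classification only; no probability calibration, no ROC/AUC.
* Test-set-based generation selection is optimistically biased (documented
  above; a held-out selection split can be emulated by splitting upstream).
* Pruning stalls once weak members disappear (see above), so the optimal
  feature set is an enriched superset of the signal, not a minimal one.
* The generator does not model realistic fMRI noise; upstream
  preprocessing and NIfTI/atlas handling are out of scope — the package
  starts from per-region time-series matrices.
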