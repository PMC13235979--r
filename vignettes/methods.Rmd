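---
title: "Estimating the prevalence of undercoded phenotypes with positive-unlabeled learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the prevalence of undercoded phenotypes with positive-unlabeled learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

A phenotype extracted from structured diagnosis codes gives a *lower bound*
on prevalence: every coded patient is a true positive (assuming codes are
precise), but an unknown fraction of the uncoded patients are positives
whose condition was documented only in notes, or never documented. In
positive-unlabeled (PU) terms, the cohort splits into a labeled-positive
set P and an unlabeled set U; the quantity of interest is the class prior

  α = P(truly positive | unlabeled),

from which the combined prevalence is (|P| + α·|U|) / (|P| + |U|).

`puprev` implements the full analysis: a balanced-undersampling PU
ensemble, class-prior estimation under two labeling mechanisms, per-record
calibrated probabilities, a probability-stratified chart-review audit, a
bias-only logit-shift recalibration with bootstrap uncertainty, and the
agreement/prevalence reporting around it. A synthetic-cohort generator
provides ground truth for every recovery claim; nothing in this vignette
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Labeling mechanisms: SCAR and SNAR

Everything hinges on *why* a positive ends up coded.

* **SCAR** (selected completely at random): the probability that a positive
  is coded does not depend on its attributes. Then the score distribution
  of labeled positives estimates that of *all* positives, and under the
  mixture `f_U = α f_P + (1 − α) f_N` with `f_N ≥ 0`, every threshold s
  yields the bound α ≤ S_U(s)/S_P(s) (survival functions of the unlabeled
  and positive score distributions). `estimate_alpha_scar()` minimises this
  ratio over a grid.
* **SNAR** (selected not at random): coding propensity depends on the kind
  of positive — for a behavioural phenotype, severe presentations get coded
  and mild ones do not. The labeled set then over-represents the
  well-coded subtypes, `f_P` is not the positive score density, and the
  SCAR bound collapses toward the prior of the over-coded subtype alone.
  The subtype extension (`pulsnar()`) clusters the labeled positives,
  treats each cluster as its own SCAR problem against the full unlabeled
  set, and sums the per-cluster priors: subtypes are modelled as disjoint
  events, so α = min(1, Σ_c α_c).

## The balanced-undersampling ensemble

With coded rates of 1–2%, a single classifier fit is dominated by the
majority class. The pipeline instead partitions U into k = ⌊|U|/|P|⌋
disjoint groups (`make_partition_plan()`), pairs each group with all of P,
cross-fits the classifier within each balanced dataset with stratified
5-fold cross-fitting (out-of-fold scores only — in-sample scores inflate
the separation between arms and bias α downward), estimates α once per
balanced dataset, and averages the k estimates. Disjointness is what lets
every unlabeled record receive exactly one out-of-fold probability: its
score from the one balanced dataset containing it. Labeled records are
scored in every balanced dataset and averaged. When the number of fitted
partitions is capped (see below), records of unfitted partitions are scored
by averaging the fitted partitions' full-data models.

### The classifier

The analysis this package re-implements used a gradient-boosted tree
ensemble (XGBoost with `max_depth = 12`, `n_estimators = 400`,
`learning_rate = 0.05`, `min_child_weight = 1`, `colsample_bytree = 0.3`,
`colsample_bylevel = 0.6`). The estimator contract, however, only needs a
classifier that outputs class-1 probabilities, and no gradient-boosted tree
implementation is available in this package's dependency footprint, so the
default engine is cross-fitted L1-penalised logistic regression (`glmnet`),
which handles the sparse binary design matrices natively and is fast enough
to fit hundreds of ensemble members at test scale. Scoring models use a
deep path (`lambda_min_ratio = 0.01`, near-unpenalised) so scores separate
well; any other engine can be plugged in through
`classifier_config(engine = "custom", fit = , predict = )`. For sparse
binary covariates drawn from the generator below, penalised logistic
regression is close to the Bayes rule, so nothing in the recovery
properties depends on tree ensembles; on real EHR data with strong
covariate interactions a boosted-tree engine may score better and should be
preferred when available.

## Class-prior estimation: why the tail ratio

The textbook mixture-proportion estimator takes the minimum of the per-bin
density ratio f_U/f_P over bins where f_P is supported. That minimum is an
order statistic of noisy ratios: with histogram cell counts of a few dozen,
the lowest random fluctuation — not the tightest true bound — wins, and the
estimate is biased low. Measured on this package's own SCAR recovery
setting (n = 20,000, truth 0.20) the per-bin rule returns 0.10–0.12;
measured on the closed-form Beta(8,2)/Beta(2,8) oracle (true minimum ratio
0.3, n = 10,000 per arm) it averages 0.20. Both are outside the tolerance
any recovery test can accept.

The default estimator therefore minimises the *survival-function* ratio
S_U(s)/S_P(s), which obeys the same pointwise bound (integrate the mixture
over the tail) but aggregates entire tails instead of single cells. The
ratio is evaluated only where the positive tail holds real mass:
`min_tail = 0.10` of the positive arm, and never fewer than 10 observations
in either arm. On the same two oracles the tail estimator returns
0.175–0.198 and 0.278–0.304 respectively. The per-bin rule is retained as
`estimate_alpha_scar(method = "bin")` for reference. Both are *upper-bound*
estimators in the infinite-data limit; their finite-sample error is
downward, which is why the recovery tests check two-sided tolerances rather
than one-sided bounds.

Scores are clipped into [1e−6, 1 − 1e−6] before any logit, and histogram
densities share a fixed [0, 1] grid with the automatic bin count
`max(20, min(100, round(sqrt(min(n_P, n_U)))))`.

## Subtype clustering

The method family implemented here is described as "divide and conquer"
clustering of the labeled positives on the informative covariates, without
a fixed algorithm. Two design choices here departed from the obvious defaults
after they measurably failed:

* **Feature subset.** Importance is the penalised-regression analogue of
  tree gain: the absolute coefficient magnitude averaged over up to five
  balanced-ensemble fits, at a *stronger* penalty than the scoring models
  (`importance_lambda_min_ratio = 0.05`). A near-unpenalised fit marks
  ~98% of covariates "informative", drowning the clustering step in noise
  dimensions; the reference analysis itself found only 0.82% of covariates
  informative. With the sparser penalty, the gain-positive set at the test
  scale is ~70–180 of 500 covariates and contains both subtypes' signal
  blocks.
* **Clustering model.** k-means on the binary (or gain-weighted) submatrix
  never isolates a minority subtype: across every weighting scheme tried,
  silhouettes stay at 0.02–0.10 and the rare subtype's members are absorbed
  into activity-level strata of the majority. The implemented model is a
  Bernoulli mixture fitted by EM (the natural generative model for 0/1
  covariates), with random and Ward-linkage initialisations and the best
  likelihood kept. The cluster count is selected by AIC over
  1..`max_clusters`. BIC is provably too conservative here: its penalty
  (d + 1)·log n exceeds the log-likelihood gain a 4–5% minority component
  can contribute at desk scale, and it selected one cluster in every trial.
  AIC finds the planted structure while still returning a single cluster on
  SCAR-consistent data (the single-subtype fallback, verified over seeds).
  An explicit `n_clusters` override is honoured exactly (Ward linkage backs
  it up if EM empties a component).

### Per-cluster ensembles for small clusters

A cluster holding 5% of the labeled positives generates balanced datasets
of a few dozen records a side under the strict ⌊|U|/|P_c|⌋ rule — far too
small for any tail estimate. Two stabilisers apply only in the per-cluster
runs: each balanced dataset draws at least `unlabeled_floor = 500`
unlabeled records (the partition count shrinks accordingly), and at most
`max_partitions = 20` partitions are actually fitted (sampled without
replacement; the per-partition estimates remain exchangeable, so their mean
is unchanged in expectation). The top-level SCAR ensemble keeps the exact
⌊|U|/|P|⌋ rule.

### Probability combination

Each cluster's unlabeled probabilities are anchored to its own α_c by a
bias-only logit shift (`calibrate_to_alpha()` — the same primitive as the
chart-review calibration, rather than a second calibration family), and
combined by summation capped at 1, treating subtypes as disjoint events.
The capped-record count is reported; when no records are capped the
combined probabilities sum to α·|U| by construction. Capping is an
acknowledged approximation: clusters are estimated, not true subtypes, and
overlapping clusters can double-count density. The recovery tests bound
the practical effect (mean recovery error ≲ 0.01 at the tested scales).

## Chart-review audit and post hoc calibration

Model probabilities deserve no trust without an external check. The audit
design (`sample_review_bins()`) stratifies the unlabeled records into 1%
calibrated-probability bins (half-open intervals, last bin closed) and
samples one record uniformly from each nonempty bin — extreme bins that
hold no records contribute no case, which is how an audit of 97 cases
arises from 100 bins.

Calibration is a *bias-only logit shift*: one constant c added to every
logit, solved so that the shifted probabilities of the reviewed cases sum
to the number of review-confirmed positives. The target sum is continuous
and strictly increasing in c, so the root is unique; it is found by
bracketed root-finding polished to a residual of at most 1e−9. A single
intercept (rather than Platt slope-and-intercept scaling) is deliberate:
it preserves the ranking exactly, cannot overfit 97 observations, and
matches the audited quantity (a count). Uncertainty comes from a
percentile bootstrap: resample the reviewed cases with replacement, re-solve
c against each resample's own label sum, and take the 2.5th/97.5th
percentiles. Resamples whose labels are all 0 or all 1 admit no finite
root and are redrawn (with ~40% positives among ~97 cases such draws are
vanishingly rare; the redraw count is recorded). The reference analysis
used B = 100,000; the tests use B = 2,000, which this package's coverage
simulation shows is already calibrated (≥ 90/100 nominal-95% intervals
cover the generating shift). Applying c and its CI bounds to every
unlabeled record's probability yields the calibrated positive count, rate
and interval (`extrapolate_prevalence()`); boundary probabilities (e.g.
capped at 1 by the subtype combination) are clipped to [1e−6, 1 − 1e−6]
before the logit.

The consensus used as the calibration target is the *reviewed* consensus:
in the reference analysis it was reached by expert discussion, which cannot
be reimplemented as a formula, so `consensus_labels()` passes an external
consensus through unchanged (`rule = "provided"`) and offers a majority
rule with ties broken toward positive (an inclusive screening stance) for
synthetic work.

## Agreement and reporting

`agreement_report()` assembles percent-agreement and Cohen-κ matrices over
raters, model and consensus, Fleiss' κ with its large-sample z and p, a
3×3 stratification of review outcome (unanimous-no / dissenting /
unanimous-yes, computed from the raw ratings) against risk categories
(low < 0.25 ≤ intermediate ≤ 0.75 < high, boundaries belonging to the
intermediate band), a Fisher exact test, and threshold classification
metrics (AUC by midrank statistic; precision/recall/F1 at 0.5 — the
threshold uniquely consistent with the reference analysis' printed
precision and recall). The r×c Fisher p-value is Monte-Carlo: tables with
the observed margins are drawn (`r2dtable`) and the p-value is the fraction
at most as probable as the observed table; the tests validate it against
full enumeration on small tables. 10^6 draws give ±0.001 around p ≈ 0.02.

Cohort characterisation uses cross-product odds ratios with log-scale Wald
intervals and Wald proportion intervals (Wilson available), which reproduce
the reference cohort table's checked rows at the printed two decimals. One
known paper-side wrinkle: the reference table's personality-disorder row
computes to 26.50 against a printed 26.48, and the calibrated-prevalence
numerator is printed both as 105,133 and as 24,625 + 80,574.7 = 105,199.7;
both printed ratios round to the same 7.91% and both are reproduced as
stated.

## The synthetic cohort: what it emulates and what it does not

No public data accompany the reference analysis, so the generator
(`generate_cohort()`) is the package's test bed. It draws a Bernoulli
world chosen to exercise exactly the structure the estimators assume:

* sparse binary covariates with background activation `baseline_rate`
  (default 0.02 over 500 covariates ≈ 10 active covariates per record —
  the same order of relative sparsity as the motivating cohort's ~1,200 of
  159,049);
* latent positives with prior `true_alpha = 0.25` and subtype labels;
* per-subtype blocks of `n_informative = 50` covariates activated at
  `min(1, baseline_rate · lift)` (default lift 8 → 0.16) in positives of
  the matching subtype;
* labeling propensities rescaled so the marginal coded fraction among
  positives is `coded_fraction = 0.25`; equal propensities give SCAR,
  unequal (the SNAR tests use 0.9 : 0.05) give SNAR.

The defaults put the true unlabeled-positive fraction at
0.25·0.75/(1 − 0.0625) = 0.20 exactly, the recovery target the acceptance
tests use. The defaults were chosen once, before the recovery tests were
run, and are not tuned to them.

What the generator does **not** emulate: covariate correlation beyond the
shared latent status (real diagnosis codes co-occur in hierarchies),
longitudinal structure, continuous covariates, label noise in the coded
set (coded patients are true positives by construction), and realistic
cluster counts (the motivating analysis found 14 subtypes at population
scale; desk-scale tests plant 1–2). A green recovery test therefore
establishes that the estimators recover the class prior *under the stated
mixture world at desk scale* — it does not certify performance on any
particular EHR system, where covariate correlation can widen the gap
between the SCAR bound and the truth in either direction.

## Numerical choices and degenerate inputs

* Seeds: every stochastic operation takes an explicit seed; derived seeds
  stay below 2^31. Identical configuration ⇒ bit-identical output.
* `solve_shift` brackets by doubling from [−1, 1] (|c| ≤ 800 always
  suffices after clipping) and Newton-polishes to residual ≤ 1e−9; the
  bootstrap path uses a safeguarded Newton from c = 0.
* Empty clusters are an error; an EM component that empties during model
  selection simply yields a smaller candidate count.
* `α·|U| = 0` in `calibrate_to_alpha` is anchored to an ε·|U| target with
  a warning instead of producing all-zero probabilities (zero probabilities
  have no logit).
* Degenerate histogram inputs (fewer than 5 nonempty bins, or fewer than
  30 scores per arm) are errors, not silent estimates.
* Probability-bin edges are half-open with the final bin closed, so 1.0 is
  a valid calibrated probability for the audit design.
* Activation probabilities and rescaled propensities exceeding 1 are capped
  with a warning (a convenience for coarse configurations, flagged because
  it changes the realised coded fraction).

## Known limitations

* The tail-ratio estimator, like all min-ratio mixture-proportion
  estimators, is an upper bound achieved only where negatives vanish from
  the top tail; when the classifier cannot separate any stratum of
  positives from negatives, α is underestimated with no internal warning.
  The chart-review calibration exists precisely to catch this externally.
* Per-cluster priors are summed as if clusters were disjoint true subtypes;
  with heavily overlapping estimated clusters the cap at 1 is the only
  guard against double counting.
* The bootstrap treats the 97 reviewed cases as an i.i.d. sample of the
  audited strata; the one-per-bin design is stratified, so the percentile
  interval is conservative for the shift but not exact.
* Wald intervals are used for published-table compatibility; they are known
  to undercover for proportions near 0 or 1 (Wilson is available via
  `proportion_ci(method = "wilson")`).
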