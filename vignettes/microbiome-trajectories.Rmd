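---
title: "Deriving and auditing microbiome maturation trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and auditing microbiome maturation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mbtraj)
library(dplyr)
```

## The model

The gut microbiome develops along a fairly stereotyped course: the relative
abundances of many taxa change systematically with age, diet switches and
other exposures. mbtraj operationalizes that idea as a *Microbiome
Maturation Index* (MMI): a regressor is trained on a *reference* set of
samples to predict each sample's time (age) from its feature abundances,
and the sample's MMI is simply that predicted time, in the dataset's own
time unit. A sample predicted "older" than it is sits above the reference
trajectory; one predicted "younger" sits below. Everything else in the
package — interval bands, anomaly detectors, explanations, intervention
simulations, group comparisons — is built on this one quantity.

The *trajectory* itself is a cubic smoothing spline of MMI against time,
fitted to grouped cross-validation (out-of-fold) predictions of the
reference samples. Two points deserve emphasis:

* **Out-of-fold, not resubstitution.** Flexible regressors (bagged trees,
  boosted trees) interpolate their training data, so resubstitution
  residuals are near zero and any band built from them would be far too
  narrow. Out-of-fold predictions of the training samples give an honest
  residual distribution, which is what makes the 90% prediction band
  actually cover ~90% of new reference samples.
* **Folds group by subject.** Longitudinal repeats of one subject are
  correlated; letting them straddle folds would leak information and
  overstate skill. Every cross-validation in the package (model fitting,
  leaderboards, denominator selection) splits by `subject_id`.

The band around the trajectory uses a time-varying residual scale:
per time bin, the mean absolute out-of-fold residual times
$\sqrt{\pi/2}$ (the Gaussian consistency factor), interpolated between bin
centers with a monotone shape-preserving Hermite spline so the scale stays
positive and cannot overshoot, and held constant beyond the observed
range. The *prediction* band is `curve(t) ± z · scale(t)`; the
*confidence* band divides the scale by the square root of the local bin
count. Outliers are always defined against the prediction band.

One numerical guard matters in practice: generalized cross-validation for
`smooth.spline` can pick a near-interpolating smoothing parameter on small
samples whose times are jittered ties. The package therefore caps the
effective degrees of freedom (10 for the main trajectory, 6 for the
per-group curves inside the permutation test) and refits at the cap when
GCV exceeds it.

## Compositional preprocessing

Sequencing abundances are compositional: only ratios carry information.
The package's canonical transform is the additive log-ratio
$\ln\!\big((v_{ij}+c)/(v_{iD}+c)\big)$ against a single denominator
feature $D$, with a pseudocount $c$ defaulting to half the smallest
non-zero value in the table (zeros are otherwise untreated; there is no
zero-inflation model in this version). With $c = 0$ on positive data the
transform is exactly scale-invariant per sample.

Three data-driven strategies choose the denominator:

* **crossings** — count, over all other features, how often each
  feature's binned median trajectory crosses the candidate's; the most
  "parallel" feature (fewest crossings, default 10 equal-width time bins)
  is temporally stable relative to the rest.
* **ranking_low / ranking_high** — the Spearman correlation of each
  feature's relative abundance with time; the extreme negative or positive
  feature. This is our operationalization of a "differential ranking"
  against time; other definitions exist, and the scores of all candidates
  are always reported so the choice can be audited.
* **performance** — fit the MMI regressor once per candidate denominator
  on log-ratio-transformed reference data under grouped cross-validation
  and keep the candidate with the best mean R². This is an exhaustive
  search over candidates by construction; ties break lexicographically and
  are flagged.

Feature filtering (`filter_features()`) runs a variance-quantile pass and
then a greedy correlation pass (scanning pairs by descending |r|, dropping
the lower-variance member), with a removal log for auditability. A
filtered relative table is re-closed to unit row sums; because log-ratios
are scale-free, this re-closure does not change any downstream log-ratio.

The reference set itself can be declared, taken from a group label, or
refined by novelty detection: an Isolation Forest is fitted on the seed
samples, non-seed samples whose novelty score falls inside the seed
score range are admitted, and the most extreme `novelty_frac` tail of the
seed set is expelled.

## Anomaly detection and explanation

All three detectors operate on trajectory residuals, not raw features —
the anomaly of interest is "off the maturation curve", not "unusual
composition per se".

* **interval** — outside the prediction band; score = |residual| in local
  residual-SD units.
* **lowpass** — residuals sorted by time, a centered rolling window
  (default width 5, shrinking at the edges) supplies the low-pass signal;
  a sample is scored by its deviation in robust units (rolling MAD ×
  1.4826) and flagged above `k = 3`. The deviation is centred on the
  rolling *median* rather than the rolling mean: a mean centre smears an
  isolated spike into every overlapping window, so the spike's innocent
  neighbours would be flagged too. When a window's MAD is exactly zero
  (flat stretches) the scale falls back to the global MAD of deviations,
  then the global mean absolute deviation, then zero — so exactly-flat
  series score zero everywhere. Slow drifts pass the filter by design.
* **isolation** — an Isolation Forest (implemented in the package: random
  axis-aligned splits, path-length score $2^{-E[h]/c(\psi)}$) on the
  per-sample vector (residual, rolling mean, rolling SD); exactly the top
  `ceiling(contamination · n)` samples are flagged.

`explain_outliers()` fits a gradient-boosted classifier separating flagged
outliers from a subsampled background (default: all non-outliers, capped
at 3× the outlier count), reports its stratified cross-validated AUROC
(macro-averaged over folds, since pooling out-of-fold probabilities across
differently calibrated folds understates separability), and ranks features
by mean absolute Shapley attribution over the outlier samples. Metadata
columns join only when explicitly listed; `subject_id` and `time` are
refused because they leak the trajectory itself.

## Shapley attributions

No SHAP library ships with this package's dependency set, so attributions
come from a permutation-sampling Shapley estimator written here
(`shapley_values()`): features are inserted in seeded random orders and
credited with the change in mean prediction over a background sample. The
marginal contributions telescope along each order, so per-sample
attributions sum *exactly* to prediction − base value for any number of
sampled permutations (the local-accuracy identity is structural, not
approximate); sampling noise affects only the split among correlated
features. Defaults (8 permutations, 25 background rows) keep tree-ensemble
explanations fast while leaving planted-signal recovery comfortably
stable; both are arguments where sharper estimates are needed.

## Comparing group trajectories

`compare_trajectories()` tests whether two groups share one trajectory.

* **linear** — `mmi ~ time + group + time:group` by least squares; the
  statistic is the F for the joint null that both group terms vanish.
* **spline_permutation** — per-group smoothing splines, statistic =
  integrated squared difference over the common time range (201-point
  grid, trapezoidal rule). The null permutes group labels at the
  *subject* level — all samples of a subject swap together, respecting
  longitudinal correlation — stratified by each subject's median-time bin
  so that groups with different time densities are only compared within
  comparable strata (for fully longitudinal designs every subject spans
  the range, the strata collapse, and this is a plain subject
  permutation). `p = (1 + #{null ≥ observed}) / (1 + B)`.

Both tests calibrate to nominal type-I error on null synthetic data and
reach full power at a two-residual-SD group shift (the acceptance suite
verifies both), with the caveat that the synthetic generator draws
independent within-subject noise; strongly autocorrelated subjects would
favour the permutation test over the linear F.

## The synthetic study design

The generator (`synthetic_spec()` / `generate_dataset()`) emulates a
longitudinal microbiome study of repeatedly sampled subjects: log-normal
feature abundances closed to relative abundances, a subset of informative
taxa whose log-abundance moves linearly with time (signs alternating so
both increasing and decreasing taxa exist), equally spaced sampling with
±5% jitter, an optional second group whose informative means are evaluated
at `t + group_shift` (a maturation lead/lag), and optional planted
anomalies that multiply one informative feature of a sample by
`exp(magnitude · noise_sd)` before re-closure.

The defaults — 40 subjects × 8 time points over a (0, 2)-month range,
30 features of which 5 are informative, effect size 1 per month on the log
scale, log-noise SD 0.3 — are sized after a small rodent diet-switch
cohort followed for about two months, scaled up in subjects so that
grouped cross-validation and held-out evaluation are meaningful. They were
fixed once, ahead of testing, and all tests run against them.

What the generator does *not* emulate — zero inflation, phylogenetic
correlation between taxa, taxon-taxon interaction networks, irregular
drop-out — bounds what passing tests show: they validate the estimators
under a clean compositional signal-plus-noise model, not performance on
messy real surveys.

Two workflow facts that the tests surfaced and users should know:

* A planted single-feature anomaly is *diluted by closure* in
  relative-abundance space (raising one feature lowers all others), but
  stays a single-coordinate shift in log-ratio space. Anomaly screening is
  therefore markedly more sensitive on the log-ratio workflow.
* Tree ensembles clip predictions at the training range, which dampens the
  displacement an out-of-range anomaly can cause; a linear or regularized
  linear MMI regressor extrapolates the displacement and is the better
  screening model, whereas the tree ensemble remains the more accurate
  default for the trajectory itself.

## Intervention simulation

`simulate_intervention()` is a model-space what-if: selected features of
an outlying sample are reset to the time-local reference median (median
and IQR over reference samples within `time ± bandwidth`, bandwidth
defaulting to a tenth of the time range and doubling up to three times if
fewer than 5 neighbours are found) and the MMI is recomputed. Features can
be named explicitly or chosen per sample by absolute Shapley attribution
with greedy escalation (k = 1, 2, … up to `k_max = 10`) stopping at the
smallest k that returns the sample inside the prediction band.
Post-intervention vectors are *not* re-normalized to sum to one: log-ratio
inputs are scale-free so re-closure would be a no-op there, and for
relative-abundance inputs the un-normalized vector is what the fitted
model understands. The simulation makes no causal claim; it reports which
coordinates, moved to reference values, would reposition the sample in
model space.

## Reproducibility and the pipeline

Every stochastic step takes an explicit seed; derived seeds are computed
deterministically from the master seed, all model fits run
single-threaded, and rerunning the pipeline with one seed reproduces every
CSV byte-for-byte (wall-clock timings are kept out of the CSVs for this
reason). `run_pipeline()` executes exploration → preparation → trajectory
→ anomaly → intervention with per-stage outputs, a resolved-config YAML
and a log; unknown configuration keys are rejected before any computation.
A thin command-line wrapper ships in `inst/scripts/mbtraj.R`.

```{r demo, eval = FALSE}
res <- run_demo(output_dir = tempfile("mbtraj"), seed = 42)
list.files(res$output_dir)
```

Problem sizes throughout the test and acceptance suites (hundreds of
samples, tens of features, tens to hundreds of replicates) were chosen as
the smallest designs at which the statistical properties under test —
coverage, calibration, power, recovery rates — are stable across seeds.

## Known limitations

* Single-denominator additive log-ratio only; no CLR/ILR bases.
* The MMI is a point prediction; regressor uncertainty enters only through
  the empirical residual bands.
* The novelty-based reference definition and the Isolation Forest detector
  share one isolation-scoring implementation; a one-class SVM alternative
  is not provided.
* Batch processing only — no streaming/online detection.
* No phylogenetic information is used anywhere; feature ids are opaque
  labels that may carry lineage strings.
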