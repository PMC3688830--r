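---
title: "Methods: scoring, validation statistics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, validation statistics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sresc)
```

## The scoring model

The S-ReSC score is a pure count: one point for each of nine
pre-determined pelvicalyceal sites involved by stone, regardless of the
number or size of stones at a site. The sites are the renal pelvis (#1),
the superior and inferior major calyceal groups (#2–3), and the
anterior/posterior minor calyceal groups of the superior (#4–5), middle
(#6–7) and inferior calyx (#8–9), with anterior/posterior divided by the
frontal plane of the kidney. The modelling assumption behind the count is
that surgical difficulty is driven by the *distributional complexity* of
the stone — each additional site to be reached costs access, not each
additional millimetre of stone. Scores collapse to three tiers, low (1–2),
medium (3–4) and high (5–9), which trade resolution for stability in small
strata.

Two deliberate simplifications are inherited from the score's design and
kept here: anatomical variants of the minor calyces are ignored (each
anterior/posterior group may contain several calyces but scores one
point), and a stone touching a boundary between sites scores whatever
sites the reader marks — the package scores the user's map and does not
adjudicate boundaries.

### Renometry classification

The staghorn definitions operate on *calyceal groups* while the score
operates on nine sites, so the classifier needs a site-to-group mapping.
We use three calyceal regions — superior = sites {2, 4, 5}, middle =
{6, 7}, inferior = {3, 8, 9} — a region counting as involved when any of
its sites is. A complete staghorn requires the pelvis, all three regions,
and a user-supplied fill fraction of at least 0.8 (the 80% criterion is
radiological and cannot be derived from a site map); a partial staghorn
requires the pelvis and at least two regions. The remaining five
categories follow from the pelvis flag and the count of involved calyceal
sites. This is the only reading consistent with a seven-category renometry
vocabulary in which "pelvis + single calyx" and "pelvis + multiple
calyces" are distinct from the staghorns.

### Stone volume

`stone_volume()` computes `length × width × depth × π × 0.52` exactly as
the development analysis defined it. Note this exceeds the scalene
ellipsoid volume (`× 0.52` alone, since 0.52 ≈ π/6) by a factor of π; the
formula is nevertheless implemented as defined so that volumes are
comparable with the original series, and the discrepancy is flagged in the
function documentation. Volumes enter no downstream statistic in this
package; they are descriptive covariates.

## The development cohort reconstruction

The development series reported, for each score 1–9, the stone-free
fraction among the patients at that score: 40/42, 32/33, 19/26, 10/16,
5/15, 3/9, 2/5, 0/6, 1/3. Because the score-outcome analysis depends on
the data only through this joint distribution, the 155-patient cohort can
be rebuilt *exactly*: `reconstructed_cohort()` emits one record per
patient with score, group and outcome, deterministically ordered. Sample
statistics use the n−1 standard deviation (which reproduces the published
3.15 ± 2.12); a single-record cohort reports SD 0 with a warning rather
than an error. The reconstruction carries no covariates and no stone
maps — those were never published per patient — and its documentation says
so, to prevent anyone mistaking fixture fields for clinical data.

## Validation statistics

**Logistic regression.** `fit_logistic()` is a plain IRLS maximum
likelihood fit with Wald 95% intervals `exp(β ± 1.96·SE)`. Convergence is
declared when the relative log-likelihood change drops below 1e−10
(capped at 50 iterations) — a tight tolerance chosen so that odds ratios
are stable to well past the 3 decimals at which they are reported.
Working weights are floored at 1e−10 to keep the normal equations stable
near fitted probabilities of 0 or 1, and any coefficient exceeding 15 in
absolute value raises a separation warning rather than being reported as
a converged estimate. Wald intervals (not profile likelihood) are used
throughout: on a saturated binary predictor they coincide with the
closed-form 2×2 interval `exp(log(ad/bc) ± 1.96·√(1/a+1/b+1/c+1/d))`,
which the test suite uses as an independent oracle, and they reproduce
the published group CIs at 3 decimals.

**Discrimination.** `auc_with_ties()` computes the Mann–Whitney AUC with
ties credited 0.5, via midranks, with the DeLong placement-value variance
for the CI. Orientation is explicit — the caller states which outcome is
the positive class — and no silent "report the larger of AUC and 1−AUC"
flip is applied; swapping class labels mirrors the AUC around 0.5. The
9-level score attains AUC 0.860 and the 3-tier grouping 0.853 on the
reconstruction, confirming that the coarsened score loses almost no
discrimination.

**Agreement.** `weighted_kappa()` implements the quadratic ("squared")
weighted kappa with the category space fixed to the full 1–9 scale even
when some scores are unobserved, so the chance-expected matrix is always
defined on the whole scale. The CI uses the large-sample
Fleiss–Cohen–Everitt standard error. The published inter- and
intra-observer kappas (0.832, 0.982) cannot be recomputed because the
per-patient rating pairs were not published; the package instead verifies
the estimator's identities (κ = 1 on identical ratings, κ ≈ 0 under
independence, quadratic = unweighted for two categories) and provides a
rater simulator that reproduces the qualitative regime — a second rater
who misses sites more often than they over-call scores systematically
lower, with disagreement concentrated at high scores.

**Association.** `chi_square_test()` is the Pearson statistic without
continuity correction (the group × outcome table is 3×2, where the Yates
correction is undefined), with the p-value from the χ² distribution. No
multiple-testing adjustment is applied anywhere, matching the
single-endpoint design. Tests cross-check against
`chisq.test(correct = FALSE)`.

## Calibration

`calibration_bootstrap()` performs Harrell-style optimism correction:
refit the model on each of 200 case resamples (n = 155 with replacement;
single-class resamples are redrawn and counted), evaluate the bootstrap
model's calibration error both on its own resample and on the original
cohort, and subtract the averaged difference from the apparent curve. The
curve is evaluated at the distinct predicted probabilities (one per score
level), the observed values are the per-level outcome proportions
(`smooth = "none"`, the default) or a lowess smooth of outcome on
prediction (`smooth = "lowess"`), and the mean absolute error is
patient-weighted. Internally patients are put in a canonical order before
resampling, so the seeded result is invariant to row order. The seed is a
mandatory argument: there is no silently irreproducible run.

The model being calibrated defaults to the univariate score model (the
group model is available via `model = "group"`; for that saturated model
the apparent error is exactly zero and the corrected MAE is pure
optimism, about 0.003 on the reconstruction). On the reconstruction the
score model's corrected MAE is ≈ 0.065 (raw per-level observed) or
≈ 0.046 (lowess). Both are substantially larger than the 0.027 reported
in the original validation. We attribute the difference to the model
behind the published calibration plot: 0.027 sits between the saturated
group model (≈ 0.003–0.007) and the univariate score model (≈ 0.05–0.065)
across every evaluation variant we examined, which is where a richer
multivariable model (score plus significant covariates) would land — and
the covariate data needed to fit that model were never published per
patient. The package reports what its stated model actually achieves
rather than tuning the procedure toward the published value.

## Decision curve analysis

`decision_curve()` computes, on a default grid of thresholds 0.01–0.99 in
steps of 0.01, the net benefit `TP/N − (FP/N)·p_t/(1−p_t)` of classifying
patients positive when the predicted event probability reaches `p_t`,
against treat-all and treat-none. The event is the *residual stone* (the
actionable event — net benefit counts treated events), so the calibration
and DCA stages use opposite orientations of the same fitted model; both
orientations are explicit in the outputs. On the reconstruction the score
model's curve beats both default policies for thresholds from about 0.04
to 0.88 — with a brief dip just below its second-largest attainable
prediction (0.79–0.80), an artefact of the predictor taking only nine
values — and the 3-tier model does the same up to its maximum attainable
prediction of ≈ 0.71.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: pelvis involvement Bernoulli(0.87)
(the fraction of pelvic-stone renometry categories in the development
series), each of the 8 calyceal sites Bernoulli(0.12), enriched 2.5-fold
when the pelvis is involved; empty maps are rejection-resampled, which
preserves the stated per-site probabilities conditional on non-emptiness.
The base rate and enrichment were chosen once so that the simulated mean
score falls within 0.3 of the development mean 3.15 at large n (the
realised mean is ≈ 3.23, with overall stone-free rate ≈ 73–74% against
72.3%). The outcome is Bernoulli with log-odds `a + b·score`, where
`(a, b)` default to the fit on the reconstruction. Covariates (age, BMI,
lognormal diameter, Hounsfield units, hydronephrosis grade, sex,
laterality) are drawn independently of the score, matching the published
demographic margins; complication indicators use the per-group rates
18.7/28.6/34.2% with grade mix 13:29:7:4 over I/II/IIIA/IIIB. All
randomness flows from a single mandatory integer seed through R's default
generator, so identical configurations give identical cohorts across runs
and platforms.

What the generator deliberately does **not** emulate: the full 9-site
dependence structure (a single pelvis-enrichment parameter cannot match
the development score SD of 2.12 — the simulated SD is ≈ 1.4, i.e. real
stone maps are more clustered than independent-sites draws), any
covariate–score correlation (off by default; available via configuration
for stress-testing adjustment behaviour), 3-D stone geometry, and
operative-course variables. Consequently, passing tests on synthetic data
demonstrate that the *estimators* behave correctly under the assumed
generating model, not that the score will attain AUC 0.86 in a new
clinical series.

## Problem sizes and numerical conventions in the test suite

The suite exercises: all 511 non-empty stone maps exhaustively; 1,000
random 2×2 tables against the closed-form odds-ratio oracle; pairwise
brute-force AUC checks up to n = 300; calibration stability over 50 seeds
at 200 resamples; and slope-recovery coverage over 500 simulated
155-patient cohorts, sizes chosen to keep the default run in the tens of
seconds while leaving Monte-Carlo error well below the asserted margins.
Ties in ranks use midranks everywhere; probabilities are clamped to
[1e−12, 1−1e−12] inside likelihood evaluations; and every stochastic
procedure takes an explicit seed.
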