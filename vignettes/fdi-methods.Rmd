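---
title: "The Florey Dementia Index: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Florey Dementia Index: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdindex)
```

## The problem and the model

Alzheimer disease progresses along a fairly stereotyped trajectory of the
Clinical Dementia Rating Sum of Boxes (CDR-SB, 0–18 in 0.5-point steps), but
individuals enter that trajectory at very different chronological ages. The
Florey Dementia Index (FDI) formalises this: every participant is assumed to
follow a common population mean curve $m(t)$, merely shifted along the time
axis. A participant with per-subject shift $\delta$ observed at age $a$ sits
at disease time

$$\mathrm{FDI} = a + \delta, \qquad \mathbb{E}[\,y \mid a\,] = m(a + \delta),$$

so a positive $\delta$ marks earlier-than-average progression. The mean
curve is a three-parameter logistic

$$m(t) = \frac{C}{1 + e^{-k (t - t_0)}},$$

with the ceiling fixed at the CDR-SB maximum, $C = 18$, unless the user
frees it. The logistic is strictly increasing and bounded by the valid score
range, and reproduces the characteristic shape of population CDR-SB means:
essentially flat before an FDI in the mid-70s and rising sharply between 75
and 100. The packaged reference curve uses the closed-form calibration
$k = \log(35/3)/6 \approx 0.4095$, $t_0 = 85 + \log 3 / k \approx 87.68$,
the unique logistic with $C = 18$ that crosses the MCI staging cut (0.5) at
FDI 79 and the AD cut (4.5) at FDI 85 — consistent with the reference onset
thresholds, but a reconstruction rather than a published cohort fit, which
the model's provenance field states explicitly.

Onset is defined on the FDI scale by survival analysis: events are the FDI
values of first MCI (or AD) diagnosis, right-censored at the last visit, and
the threshold $\theta$ for an endpoint is the first time the Kaplan–Meier
onset-free curve reaches 0.5. Prediction for a new participant is then pure
arithmetic: align their visits to the curve to get $\hat\delta$, and

$$\widehat{\text{age at onset}} = \theta - \hat\delta.$$

A consequence worth knowing: for a shift-only model the predicted AD onset
minus the predicted MCI onset is exactly $\theta_{AD} - \theta_{MCI}$ for
every participant.

## Estimating the shifts

`align_participant()` minimises

$$\sum_j \bigl(y_j - m(a_j + \delta)\bigr)^2 \;+\; \lambda\,\sigma^2\,\delta^2$$

over $\delta \in [-30, 30]$ years, by a coarse grid (0.25 y) followed by
golden-section refinement to $10^{-3}$ y. The ridge term is the Gaussian
random-effect posterior in disguise — a Gaussian prior on $\delta$ with a
Gaussian residual gives a penalty proportional to $\sigma^2/\sigma_\delta^2$
— which is why the penalty must scale with the residual noise variance
$\sigma^2$: with exact data the penalty vanishes and alignment is exact,
while noisy data are shrunk. $\lambda$ defaults to $10^{-3}$. The noise SD
is taken from the pooled curve fit when available, otherwise from the
subject's own residuals, and is floored at 0.25 — the maximum rounding
error of the 0.5-point score grid, below which differences in fit carry no
information. The floor also acts as a tie-break: a trajectory that never
leaves the curve floor has a plateau of equally good shifts, and the
residual penalty resolves it near $\delta = 0$ instead of letting the
optimum wander.

**Identifiability.** A flat trajectory cannot pin its shift down, and under
noise it can do worse than that: a handful of spurious 0.5 and 1.0 scores
can be "explained" by sliding the subject onto the rising part of the curve,
yielding a confidently wrong shift. The flag is therefore a likelihood-ratio
style test against the saturated fits: the shift is identifiable only when

$$\min\Bigl(\textstyle\sum_j y_j^2,\; \sum_j (y_j - C)^2\Bigr) - \mathrm{SSE}(\hat\delta) \;>\; 10\,\sigma^2 ,$$

i.e. the optimum must beat "the subject never left the floor (or ceiling)"
by more than noise could produce. The factor 10 is a $\chi^2_1$-with-
selection margin fixed a priori. For an unidentifiable subject the data
still bound the shift on one side — a floor-bound trajectory is compatible
with any sufficiently negative $\delta$ but not with large positive ones —
and `align_participant()` reports that bound (`delta_upper`/`delta_lower`,
the edge of the grid region whose SSE lies within the margin of the
optimum) together with the side (`censor_side`).

## Joint estimation and the scale anchor

`fit_alignment_model()` alternates: fit the curve to the pooled shifted
points of currently-identifiable subjects (all subjects on the first pass;
arbitrary placements would otherwise distort the curve), re-estimate every
shift, re-anchor, and repeat until the largest shift change is below 0.01 y
and the relative curve-parameter change below $10^{-4}$ (cap 100
iterations, with a warning and `converged = FALSE` beyond it).

The FDI scale has a one-parameter gauge freedom: adding a constant to all
shifts while subtracting it from $t_0$ changes nothing observable. We fix
the gauge so that the *population* shift distribution is centred at zero,
keeping FDI values age-like (60–100). Centring the identifiable shifts
alone would be biased: identifiability selects the more progressed
participants, whose true shifts average a few years above the population
mean, and the whole scale — and every threshold — would inherit that
offset. The anchor is therefore the location of a censored-Gaussian MLE
(`survival::survreg`, Gaussian error) in which identifiable shifts enter as
exact observations and unidentifiable ones as one-sided censored
observations at their compatible-range edge. This uses exactly the
information a flat trajectory does carry — "my onset had not happened yet".
After convergence, each unidentifiable shift is reported as the conditional
mean of the fitted shift distribution given its bound (a truncated-normal
mean), rather than the arbitrary within-plateau optimum. When there are too
few censored or identifiable subjects for the MLE, the anchor falls back to
the visit-weighted mean of identifiable shifts.

Because the identifiable set, the pooled curve data and the anchor can all
change between iterations, the recorded objective
($\sum \mathrm{SSE}_i + \lambda\sigma^2\sum\delta_i^2$) is not guaranteed
monotone step by step; in practice it drops by orders of magnitude and the
tests assert the weaker end-to-start decrease.

## Survival thresholds

`extract_onset_events()` takes the clinician diagnosis as authoritative and
falls back to CDR-SB staging (CU < 0.5, MCI 0.5–4.5, AD > 4.5) for visits
without one. Three policy decisions:

* **Direct CU→AD converters** count as MCI events at the AD visit — the MCI
  onset is latent but can be no later. A config switch
  (`cu_to_ad_counts_mci = FALSE`) excludes them from the MCI analysis
  instead.
* **Prevalent cases** (already at or past the endpoint at their first
  visit) are excluded and counted, rather than handled by delayed-entry
  survival methods: the onset-free curves are built from participants
  initially free of the endpoint.
* **The threshold is the first observed time with $S \le 0.5$**, with no
  interpolation between steps and no extrapolation — the KM estimate is a
  step function, and if it never reaches 0.5 the threshold is reported as
  undefined rather than guessed.

Kaplan–Meier estimation itself is delegated to the survival package
(`survfit`, log-log 95% intervals); the test suite cross-checks it against
a hand-written product-limit oracle on every event/censor configuration of
up to six subjects. Stratified thresholds (sex, comorbidity flags) rerun
the pipeline per stratum and refuse to report a threshold for strata below
20 participants (configurable) — small strata give wildly unstable medians.

## Evaluation

`evaluate_cohort()` scores predicted against observed onset ages with the
signed convention error = predicted − observed (positive = late
prediction). To avoid leakage, each participant is re-aligned using only
visits strictly before their observed onset, requiring at least two; a
corrupted-sentinel test asserts that post-onset scores cannot influence the
result. Pre-onset trajectories sit low on the curve by construction, so
their alignments are often flagged weakly identified; they are scored
regardless (the flag count is in the report) because excluding them would
empty the MCI evaluation entirely. MAE and RMSE come with percentile
bootstrap 95% intervals (B = 1000, seeded, caller's RNG untouched);
the bootstrap method is a package choice, made because the intervals a
reader might compare against do not name one. MAE ≤ RMSE is asserted
structurally in the report constructor.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage above is testable against
known ground truth. Defaults are the study conditions the package is
validated under, chosen once to mirror observational Alzheimer cohorts:
baseline age truncated-normal (mean 72, SD 7, support (60, 95]), visits
every 1.5 years, follow-up uniform on 3–10 years, shifts
$\delta^* \sim N(0, 6^2)$ (spreading onset ages with an SD comparable to
the ~6.5–7 y observed in such cohorts), observation noise SD 0.5 score
units, scores rounded to the 0.5 grid and clamped to [0, 18]. Ground truth
is defined on the *latent* noise-free trajectory, so true onset ages are
exact reals (`invert_curve(cut) − δ*`) while observations carry noise and
rounding — separating measurement error from the estimand in a way real
cohorts cannot. Diagnosis labels follow the latent stage (clean labels by
default; `label_delay_prob` adds a one-visit diagnosis lag). Covariate
effects shift the *diagnosis rule* along the FDI axis for carriers while
leaving scores untouched — the analogue of a comorbidity-dependent
diagnostic threshold — so stratified threshold recovery can be tested
without disturbing alignment.

What the generator does **not** emulate: attrition by death, non-AD
etiologies, heterogeneous progression *rates* (a per-subject slope is
deliberately out of scope — the model is shift-only), floor effects in the
assessment instrument beyond rounding, and informative censoring. Passing
tests therefore demonstrate internal consistency of the estimator under the
model's own assumptions, not performance on real cohort data.

Two estimator properties surfaced by the generator are worth stating
plainly. First, recorded onsets lag true crossings by up to one visit
interval (mean ≈ 0.75 y at 1.5-y spacing), so fitted thresholds sit
slightly above the designed crossing FDIs even with perfect alignment.
Second, with the censored-MLE anchor the fitted scale agrees with the
generator's to a few tenths of a year; recovery tests compare shifts after
centring both vectors identically so they measure estimation error, not the
gauge.

## Problem sizes and numerical settings

The validation suite uses n = 500 (noise SD 0.5) for threshold and
shift-correlation recovery, n = 200 noise-free for curve-parameter recovery
and prediction self-consistency, and smaller cohorts (n = 40–300) for
structural checks — sizes at which the recovery targets are comfortably
identifiable while the whole suite runs in well under a minute. Alignment
bounds are ±30 y with 0.25 y grid and $10^{-3}$ y refinement; curve fitting
is weighted least squares via L-BFGS-B (logit-linearised start, Nelder–Mead
fallback on line-search failure), with "no rising signal" reported for flat
input rather than a degenerate fit. Model files are JSON with an explicit
schema version; unknown versions are rejected outright.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(n = 500, seed = 1))
eligible <- apply_eligibility(sim$cohort)$cohort
al <- fit_alignment_model(eligible)
th <- overall_thresholds(eligible, al)
model <- build_model(al, th)

new_patient <- data.frame(age = c(71, 72.5, 74), cdr_sb = c(0.5, 1, 2))
predict_onset(new_patient, model)

# or skip fitting and use the packaged reference model
predict_onset(new_patient, default_model())
```

## Known limitations

* Shift-only random effects: participants whose progression *rate* differs
  from the population curve are mapped to the nearest time translation;
  systematic rate differences would appear as age-dependent bias.
* The reference curve is a reconstruction from the reference thresholds and
  staging cuts, not a published fit; fitted models should be preferred when
  cohort data are available.
* Thresholds are step-function medians; with few events they move in
  event-sized jumps, which is why small strata are refused.
* The MMSE can be run through the same machinery by orienting the score as
  30 − MMSE with ceiling 30, but staging cuts on that scale must be
  supplied by the user; none are packaged.
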