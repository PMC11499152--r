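---
title: "Divergence point analysis for blank-screen visual-world data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence point analysis for blank-screen visual-world data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the blank-screen variant of the visual world paradigm, listeners preview
two pictures — one showing the *factual* state of affairs described by a
sentence, the other the *illusory* alternative — and then hear the sentence
over a blank screen. Because fixations land on the remembered picture
locations, the timecourse of looks indexes when the listener has committed
to an interpretation. For negated sentences ("Sarah didn't pierce the
balloon", "Nobody pierced the balloon") the question is *when* looks to the
factual picture start to exceed looks to the illusory one, and whether that
divergence point differs between negation types and between a first and a
second language.

`gazedpa` implements the complete analysis chain: AOI scoring of raw gaze
samples, window segmentation, 200 ms binning, per-bin weighted
empirical-logit regression, bootstrap divergence-point estimation with
percentile confidence intervals, difference distributions between
conditions and languages, and the surrounding descriptive, mixed-model,
correlation, accuracy and power computations. A synthetic-data generator
with known ground-truth onsets makes every stage testable without human
data.

## The estimator

For one condition, let $y_{pb}$ and $z_{pb}$ be participant $p$'s counts of
gaze samples on the factual and the illusory picture in time bin $b$
(200 ms bins anchored at audio onset, spanning 4,000–8,000 ms by default).
With $N_{pb} = y_{pb} + z_{pb}$, each cell contributes an empirical logit
and sampling variance

$$\mathrm{elog} = \log\frac{y + 0.5}{N - y + 0.5}, \qquad
v = \frac{1}{y + 0.5} + \frac{1}{N - y + 0.5},$$

the 0.5 corrections keeping both finite at $y = 0$ and $y = N$. Per bin, a
weighted least-squares model regresses the two mirror-image elogs per
participant (factual and illusory) on a two-level target indicator with
weights $1/v$, and tests one-sidedly whether the factual exceeds the
illusory. The **divergence point** is the left edge of the first of
`k_consecutive = 3` consecutive bins with $p < .05$ — a preference
sustained for 600 ms. The sustained-run criterion is the error control; no
multiple-comparison correction is applied across bins, following the
standard divergence-point method.

The sampling distribution of the onset comes from a stratified
nonparametric bootstrap: trials are resampled with replacement within
participant × condition strata, the per-bin structure of each trial kept
intact; binning, fitting and onset detection are repeated (2,000 resamples
by default), and the distribution is summarised by the mean over
non-missing onsets and a 2.5–97.5 percentile interval. Differences between
conditions, and between languages, subtract two such distributions
resample-by-resample (independent draws paired by index); a contrast is
called significant when its 95% percentile interval excludes zero.

### Decisions where the method description is open

* **Resampling unit.** "Reshuffling within participants, conditions and
  time bins" is operationalised as trial-level resampling within
  participant × condition strata — the standard bootstrap for this analysis
  and the only unit that preserves both participant identity and the
  within-trial time structure. Participant-level resampling and per-bin
  sample-level resampling are available via `dpa_config(resample_unit=)`
  but are not the default.
* **Sidedness.** The onset criterion is directional (*more* looks to the
  factual), so the per-bin test is one-sided at $\alpha = .05$ by default;
  a two-sided variant is a configuration switch.
* **Missing onsets.** A resample with no qualifying run carries no onset.
  Such resamples are excluded from the mean and percentile interval and
  their count is reported; a flat resample has no interpretable onset, and
  imputing one (e.g. the span end) would bias the mean by an arbitrary
  constant.
* **Onset placement.** Onsets are reported at the bin's left edge, which
  keeps every reported onset and CI endpoint on the 200 ms grid anchored at
  audio onset (4,000 ms).
* **Analysis span.** The span for onset detection defaults to
  4,000–8,000 ms (anticipation plus integration), because divergence can
  legitimately complete its 600 ms confirmation run after the pictures
  reappear.
* **Denominator.** Proportions and the DPA use the AOI-only denominator
  (factual + illusory) by default, mapping "more looks to factual than
  illusory" onto elog > 0; an all-samples denominator (including looks at
  the blank background) is available for sensitivity analyses, since
  published figures do not always state which is used.
* **Multimodal onset distributions** (affirmative sentences often show an
  early and a late cluster) are summarised by the overall mean and
  percentile interval; the per-condition onset histogram
  (`plot()` on a fit) always makes the shape visible.

## The synthetic-data generator

`sim_config()` / `simulate_gaze()` emulate the design of a webcam
blank-screen negation experiment: 32 participants, 3 conditions
(`positive`, `negative`, `nobody`), 20 items per condition, 8,000 ms trials
(preview 0–4,000 ms, audio over a blank screen 4,000–7,000 ms, pictures
back 7,000–8,000 ms), two lateral 300 × 300 px AOIs, a ~20 Hz sampling
period (50 ms), near-ceiling button accuracy (0.995), and bounded-normal
proficiency scores (mean 43, range 36–47 of 50).

The probability of a factual look follows a **half-logistic ramp**: exactly
the baseline before the trial's true onset $\tau$, rising as
$2\,\mathrm{logistic}(k(t - \tau)) - 1$ of the baseline-to-asymptote
distance afterwards, with the illusory probability declining
complementarily and the remainder going to the blank background. Two
modelling points deserve emphasis:

* **Why a half-logistic.** A full logistic never equals its baseline, so
  wherever its midpoint is placed, looks diverge *before* the nominal
  onset, and at the design's statistical power even the foot of the curve
  is detectable — the parameter would not mean what it claims to mean. The
  half-logistic makes $\tau$ the exact first moment of divergence, which
  is what a ground-truth onset must be for one-bin-resolution validation.
  The default slope makes the 10–90% rise span 600 ms, matching the
  sigmoid fixation curves such experiments produce.
* **Why onset-heterogeneity SDs of 100/50 ms.** Participant and item onset
  offsets are additive Gaussian (the simplest exchangeable structure that
  supports the mixed-model stage). But the group-level divergence onset —
  what the DPA estimates — is earlier than the average individual onset
  whenever heterogeneity is large: early-diverging participants pull the
  group curve up before $\tau$. For $\tau$ to stay interpretable as the
  group onset at the 200 ms grid resolution, the heterogeneity-induced
  group divergence one bin before $\tau$ must stay below the per-bin
  detection threshold (an elog difference of roughly 0.03 at this design
  size). With participant SD 100 ms and item SD 50 ms (total ≈ 112 ms) the
  induced pre-onset difference is ≈ 0.006 — an order below threshold —
  while still exercising realistic between-participant variability.
* **Asymptote 0.50.** With equal AOI baselines of 0.35, the asymptote
  fixes the post-divergence conditional preference at
  $0.50/0.70 \approx 71\%$. Averaged over the anticipation window this
  reproduces published anticipation-window fixation proportions in the
  55–63% range (the window mean is approximately
  $50 + q\,(100c - 50)$ where $q$ is the diverged fraction of the window
  and $c$ the conditional plateau), and an integration-window preference
  near 70%.

During preview the factual and illusory probabilities are forced equal
(even screening of both pictures). Gaze coordinates are drawn uniformly
inside the role's rectangle — with a 0.1 px margin so that rounding cannot
cross the half-open AOI boundary — or uniformly over the off-picture screen
for background looks, so AOI scoring recovers the generated roles exactly.
An optional uniform `dropout_rate` emulates track loss; no particular value
is claimed to be faithful to webcam data. An optional
`proficiency_asymptote_r` couples a participant's proficiency to their
asymptote through a shared participant effect, giving the correlation stage
a non-null case to detect. One language is generated per dataset;
between-language contrasts are exercised by generating two datasets with
different onset maps.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: within-trial temporal autocorrelation of
gaze (real looks dwell; samples here are independent draws given the rate
curve, which is why simulated per-trial proportions have far smaller SDs
than the near-bimodal per-trial proportions of real data), saccade
kinematics and pixel-level gaze noise, calibration drift, audio-landmark
alignment beyond a single onset, and any systematic item effects beyond an
onset shift.

## Numerical and degenerate-input choices

* Rectangle membership is half-open ($[x_0, x_0+w) \times [y_0, y_0+h)$),
  so shared boundaries can never double-count; AOIs during the blank
  window are the remembered (identical) preview rectangles, with optional
  padding.
* Cells with $N = 0$ are flagged missing, not errors; bins with fewer than
  two contributing participants are marked untestable and never count as
  significant.
* A bin with zero residual variance gets $p = 0$, $0.5$ or $1$ by the sign
  of its estimate (one-sided), so degenerate-but-consistent data still
  yield a well-defined onset.
* Percentile intervals use the empirical `quantile()` defaults; with all
  resamples identical the interval collapses to zero width and equals the
  point estimate.
* The mixed model (`lmerTest`/`lme4`, REML) starts from the maximal
  random structure (by-participant target × condition slopes, by-item
  target slopes) and falls back stepwise on non-convergence or singular
  fits, warning with the structure actually used. The paired-means sample
  size iterates the noncentral-*t* power function over *n* and returns the
  smallest *n* reaching the target power.

## Problem sizes used in the test suite

Unit tests run on 4–8 participants and 3–5 items; ground-truth recovery
uses the full 32 × 20 design with 200 bootstrap resamples; the
coverage study uses 200 simulated moderate-effect datasets (asymptote
0.45, i.e. two-thirds of the default effect) at 200 resamples each; the
acceptance script uses the full design at the method's standard 2,000
resamples. These sizes were chosen so that each check exercises the same
code path as a full analysis while the whole suite remains quick to run on
a laptop.

## Known limitations

* No fixation-event parsing: samples are scored directly, appropriate for
  proportion-of-looks analyses but not for fixation-duration measures that
  depend on event segmentation.
* The bootstrap treats trials as exchangeable within participant ×
  condition; designs with structured within-block dependencies would need
  a different resampling unit.
* The onset grid is the bin width: differences smaller than one bin are
  not resolvable by construction.
* The generator's independence assumptions make simulated data *easier*
  than real webcam data in known ways (see above); recovery results bound
  what the method can do under its own assumptions, not under real-world
  noise.
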