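---
title: "Methods: gaze-event detection, scanpath congruence and the synthetic study generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-event detection, scanpath congruence and the synthetic study generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecraft)
```

## The analysis problem

`gazecraft` implements the complete eye-movement analysis of a
task-dependent image-viewing experiment: observers (here, art-history
students and controls) view a set of paintings for 5000 ms each under one
of three discrimination tasks, while gaze is recorded monocularly at
1000 Hz. The scientific questions are (a) whether the task reshapes
oculomotor behaviour (fixation durations, saccade amplitudes), (b) whether
observers agree on *where* to look (inter-observer congruence and spatial
dispersion of fixations), and (c) whether domain expertise shifts either.

The pipeline runs raw samples → event detection → exclusion rules →
spatial metrics → mixed-model statistics, and every stage can instead be
fed by a synthetic study generator with known ground truth, which is what
the package's validation rests on.

## Geometry

All spatial quantities are computed in degrees of visual angle through a
single isotropic pixels-per-degree scale evaluated at the screen centre:
for a display of width $w_{cm}$ spanning $w_{px}$ pixels viewed at
distance $d$,

$$\mathrm{ppd} = \left[\tfrac{180}{\pi}\arctan\!\big( (w_{cm}/w_{px}) / d \big)\right]^{-1},$$

about 39.0 px/deg for the default 1920 px / 51.5 cm display at 60 cm. The
vertical axis is used only as a square-pixel consistency check (1%
tolerance); eccentricity-dependent corrections are omitted, as their
effect is far below the kernel scale used downstream. Coordinates follow
the eye-tracker convention: origin top-left, y downward, 0-based pixel
indices, positions at pixel centres. Stimulus images are centred on the
screen unless told otherwise.

## Event detection

A sample belongs to a saccade when its smoothed instantaneous velocity
exceeds 30 deg/s **or** its acceleration exceeds 8000 deg/s², the
combined criterion of the EyeLink algorithm family. The OR reading
matters: an AND rule misses slow-onset saccades. Positions are smoothed
with a three-sample moving average before central-difference
differentiation (the halfwidth is configurable); the smoothing is needed
at 1 kHz because raw finite differences amplify sensor noise
quadratically in the acceleration channel.

Fixations are defined purely as the complement: every sample not in a
saccade or a blink (a maximal run of invalid samples) is a fixation
sample. Consequently blink + saccade + fixation durations always sum to
the trial duration — an invariant the tests enforce on every generated
trial. Two conventional floors suppress jitter events: threshold
crossings shorter than 4 ms return to the fixation class, and
inter-saccadic gaps shorter than 20 ms merge into the surrounding saccade.
Saccade runs touching a blink are not trusted (lid motion produces
spurious velocity spikes) and are relabelled so that the adjacent fixation
carries the `blink_adjacent` flag.

Exclusion rules mirror standard practice: fixations outside the image
rectangle and fixations immediately preceding or following a blink are
removed entirely (not trimmed), each with a machine-readable reason, and
ordinals are never renumbered. Saccades with unusual trajectories are
excluded by two ratio rules — duration/amplitude > 1.5 and
path-length/amplitude > 3.5. The unit of the first ratio is genuinely
ambiguous in the conventions this threshold circulates in: in ms/deg a
threshold of 1.5 excludes essentially all physiological saccades
(main-sequence durations are roughly $2.2A + 21$ ms, i.e. ratios near 6 at
5 deg), while in s/deg it excludes none. The package keeps the printed
convention (ms) as the default, exposes the unit as configuration, and
warns whenever the filter removes more than half of the saccades; the
pipeline's own default configuration uses seconds.

## Fixation maps, NSS and dispersion

Each fixation is modelled as an isotropic Gaussian with $\sigma =
1.5^\circ$ (in pixels via the geometry), truncated on a $\pm 4\sigma$
square window with no edge renormalization (truncation loses about
1.3e-4 of the kernel mass). The computation grid is the image pixel
rectangle, not the full screen: off-image fixations have already been
removed, and the dispersion statistic divides by the image pixel count. A
`grid_step` option evaluates the maps on every $s$-th pixel; NSS and
dispersion are ratios of map functionals and are nearly invariant to the
stride, which is how the heavy simulation tests stay within their time
budgets.

**Leave-one-out NSS.** For observer $i$ in an image × task cell, the
fixations of all *other* observers of that cell form a map $M_{-i}$,
z-normalized over image pixels ($\mu = 0$, $\sigma^2 = 1$, population
convention, enforced to 1e-9/1e-6). The values of $M_{-i}$ at observer
$i$'s fixation pixels (nearest-pixel lookup; interpolation differences are
sub-tolerance at 39 px/deg) are then aggregated. Positive values mean the
observer fixated where the group fixated; zero means uncorrelated; negative
means systematically avoided locations. Two aggregations are implemented
because the convention is ambiguous: the default `mean` (the standard NSS
definition, and the scale on which group means near 1.2 are plausible for
~15 fixations) and a literal `sum`. The leave-one-out pool deliberately
ignores the expertise group — group labels only annotate the records.

**Dispersion.** All fixation Gaussians of a trial are summed, the map is
normalized to a maximum of 1 and averaged over pixels, i.e.
$\mathrm{mean}(M)/\max(M) \in (0, 1]$: small when gaze piles onto one
spot, larger when it covers the image. The tests verify monotonicity both
geometrically (separating two fixations) and generatively (increasing the
ROI jitter).

**Heatmaps.** Group-level density maps weight each fixation by its
duration and divide by total duration; the result is mass-normalized so
difference maps between groups sum to zero exactly.

## Statistics

The four primary models are linear mixed models with task and expertise
as additive fixed effects (no interaction) and crossed random intercepts
for subject and image, fitted by maximum likelihood — never REML, which
would invalidate fixed-effect likelihood-ratio comparisons. Each effect is
tested by removing it and referring $2\Delta\ell$ to a $\chi^2$ with df
equal to the number of removed parameters (2 for the three-level task, 1
for expertise). Fixation durations are log-transformed before fitting (and
only there). Accuracy is modelled on the probability scale by default to
match the $\chi^2$ reporting convention, with a logistic variant
available. NSS and dispersion models use an image random intercept.
Singular fits raise an explicit error by default; simulation harnesses
downgrade this to a warning because boundary variance estimates are
expected under repeated resampling — the choice is an argument, never a
silent fallback.

The repeated-measures correlation between confidence and familiarity is
re-implemented from its ANCOVA definition: fit `y ~ subject + x`, take the
sign from the common slope and the magnitude from
$\sqrt{SS_x / (SS_x + SS_e)}$, with df $= n - k - 1$ (944 for 27 subjects
× 36 trials). This equals the correlation of within-subject-centred
residuals, which the tests use as an independent oracle.

Temporal profiles summarize fixation durations and saccade amplitudes per
ordinal position 2–13; the first fixation (long, centrally biased) and
first saccade (small) are reported separately, and empty bins are flagged
rather than imputed. Behavioural summaries reverse the 1–6 ratings
(`7 - raw`) so larger means more confident/familiar, and flag each group
as above chance via an exact binomial test against $1/6$ — whose
presentation form is the truncated 0.16, not a rounding.

## The synthetic generator: what it emulates

`generate_study()` produces a full study: 13 experts and 14 non-experts ×
36 images × 3 tasks by default, each trial 5000 ms at 1000 Hz, with a
balanced rotation design (images in three fixed sets; subjects rotate the
set→task mapping) such that no subject sees an image twice and each image
appears under each task equally often across the cohort.

Within a trial the scanpath starts with a long, centrally biased first
fixation (lognormal, mean ≈ 385 ms) followed by a small first saccade
(≈ 3.2°). Later fixation targets are congruent with probability $\kappa$
(default 0.5): a shared image ROI (six per image, proximity-weighted
selection, jittered by `spread_sigma_deg`), otherwise an observer-private
location reached by a saccade whose amplitude is drawn from a normal
distribution. Fixation durations are lognormal (median 210 ms ⇒ mean
≈ 229 ms at ordinal 2) with a +4 ms/ordinal drift and a +25 ms shift in
the medium task; amplitudes drift −0.15°/ordinal and shift −0.19° in the
medium task and +0.05° in the date task. Subject- and image-level random
intercepts (SDs: 0.35° / 0.2° for amplitude, 20 ms / 10 ms for duration)
supply the nuisance variability the crossed random effects are meant to
absorb. Saccades are rendered as minimum-jerk displacement profiles with
main-sequence durations ($2.2A + 21$ ms), fixational drift is a
random walk of 0.002°/ms (far below both detection thresholds after
smoothing), blinks are invalid-sample runs placed inside long fixations,
and artifact saccades are strongly curved quadratic-Bezier "hooks" whose
path/amplitude ratio ≈ 4 exercises the distance-ratio exclusion.

Two generator-level calibrations deserve explanation, both fixed at design
time:

* **Cohort-level effect injection.** Congruent saccade amplitudes are
  emergent (they depend on ROI geometry), identical across groups and
  tasks. The stated group/task effects are therefore injected only into
  the non-congruent draws, inflated by $1/(1-\kappa)$, so that the
  *cohort-level* difference equals the stated parameter (e.g.
  `expert_amp_delta_deg = 0.5` is the expert − non-expert cohort mean
  difference). The ordinal slope is a within-condition drift and enters
  uninflated. At $\kappa = 1$ amplitude effects cannot be expressed and
  the inflation is capped.
* **Expert congruence.** Experts' lower congruence / higher dispersion is
  produced by a larger ROI jitter (`spread_expert_factor = 1.25`) rather
  than a group-dependent $\kappa$, because the latter changes each group's
  congruent/free amplitude mix and would corrupt the calibrated amplitude
  delta. The jitter route has only a second-order effect on amplitudes
  (≈ +0.05° via $E|d+\varepsilon| \approx d + \sigma^2/d$), which is the
  main source of the small positive bias (~+0.07°) the recovery tests
  report — well inside their ±0.1° band, and left untouched.

Behavioural responses use group × task accuracy probabilities, reversed
familiarity means per group, and confidence linked to both correctness
and familiarity, so the repeated-measures correlation has a genuine
within-subject signal.

What the generator does **not** emulate: real image content (ROIs are
random points, not salience), pupil dynamics, calibration drift, smooth
pursuit, or any main-sequence curvature beyond the linear
duration-amplitude law. A green test therefore establishes that the
pipeline recovers the structure this model puts in — not that the model
exhausts real gaze data.

## Numerical and design choices

* Event intervals are half-open `[onset, offset)` in integer
  milliseconds, so durations add exactly and events align with samples.
* The final fixation of a trial is cut (or extended) by stimulus offset
  and flagged; oracle comparisons exclude flagged events because the
  stopping rule size-biases them.
* One master seed expands into per-trial substreams through a
  counter-based linear scheme (all seeds < 2³¹), so identical seeds give
  bit-identical studies and subsets regenerate independently.
* Truth event tables record motor onsets; the detector reports threshold
  crossings, which trail motor onset by a few ms for small, slow
  saccades. Detector precision is therefore tested against a brute-force
  threshold scan (within 2 samples on noiseless trials), while
  truth-vs-detected comparisons assert counts and amplitudes.
* Simulation-heavy validations keep their replicate counts but shrink the
  per-replicate world (fewer observers/images, shorter trials, coarser
  map strides). One consequence is measured directly: the $\chi^2$ LRT
  reference is visibly anticonservative in very small worlds (empirical
  type-I 0.072 at 8 subjects vs 0.054 at 12), so the null-calibration
  harness uses 12 subjects × 9 images.

## Known limitations

* The duration/amplitude ratio-filter unit ambiguity cannot be resolved
  without the original recordings; both conventions are supported and the
  default follows the printed value.
* Whether reported summary statistics aggregate over events, trials or
  images is likewise unresolved; the metric tables expose all three
  aggregations to the caller.
* The mean-vs-sum NSS aggregation is a configuration option, with `mean`
  as the documented default.
* Early-terminated trials are analyzed up to termination, not excluded.
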