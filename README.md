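# gazecraft

Eye-movement analysis for task-driven image-viewing experiments — the kind
of study where observers inspect paintings (or any static images) for a few
seconds each under different instructions, and the question is how the
task and the observer's expertise reshape where and how they look.

The package covers the complete path from raw 1000 Hz gaze samples to the
statistical conclusions:

* **Event detection** — saccades by the combined EyeLink-style criterion
  (velocity > 30 °/s **or** acceleration > 8000 °/s² on smoothed central
  differences), fixations as the complement of saccades and blinks, so
  that events always partition the trial.
* **Exclusion rules** — blink-adjacent and off-image fixations removed
  with machine-readable reasons; trajectory artifacts excluded by the
  duration/amplitude > 1.5 and path/amplitude > 3.5 ratio rules.
* **Scanpath congruence** — leave-one-out Normalized Scanpath Saliency
  (NSS): each fixation becomes a Gaussian with σ = 1.5°, the other
  observers' map is z-normalized over image pixels, and its values at the
  left-out observer's fixations are averaged. Positive ⇒ congruent gaze,
  ≈ 0 ⇒ uncorrelated, negative ⇒ incoherent.
* **Dispersion** — `mean(map)/max(map)` of the per-trial Gaussian sum, a
  score in (0, 1] measuring how much of the image gaze covered; plus
  duration-weighted group heatmaps and zero-sum difference maps.
* **Statistics** — linear mixed models (task + expertise, crossed random
  intercepts for subject and image, ML fits) compared by likelihood-ratio
  tests; repeated-measures correlation from its ANCOVA definition
  (df = n − k − 1); ordinal 2–13 temporal profiles with the centrally
  biased first event reported separately; behavioural summaries with
  exact binomial above-chance tests against 1/6 (displayed 0.16).
* **Synthetic studies** — `generate_study()` builds a full balanced
  cohort (13 experts + 14 non-experts × 36 images × 3 tasks by default)
  with known ground truth: central-bias first fixations (~385 ms), small
  first saccades (~3.2°), lognormal durations rising with ordinal number,
  amplitudes (~5.3°) falling over the trial, a +0.5° cohort-level expert
  amplitude effect, medium-task shifts, a congruence parameter κ, blinks
  and hook-shaped artifact saccades. Everything downstream is validated
  against this generator.

See `vignettes/gazecraft-methods.Rmd` for the model details and the
design decisions behind the generator.

## Worked example

```r
library(gazecraft)

cfg <- list(synthetic = TRUE, seed = 42,
            design = list(n_experts = 3, n_nonexperts = 3,
                          n_images = 6, trial_ms = 3000),
            grid_step = 8L)
res <- run_pipeline(cfg)
print(res$stats$lrt, digits = 3)
#>         response    effect  chi2 df       p
#> 1        correct      task 0.229  2 0.89200
#> 2        correct expertise 0.456  1 0.49964
#> 3     confidence      task 5.412  2 0.06679
#> 4     confidence expertise 2.347  1 0.12553
#> 5    duration_ms      task 1.088  2 0.58056
#> 6    duration_ms expertise 1.201  1 0.27302
#> 7  amplitude_deg      task 0.693  2 0.70726
#> 8  amplitude_deg expertise 9.591  1 0.00195
#> 9            nss expertise 0.294  1 0.58767
#> 10           nss      task 0.913  2 0.63341
#> 11    dispersion expertise 3.557  1 0.05929
#> 12    dispersion      task 5.028  2 0.08095
```

This is a deliberately small demo world (6 observers, 6 images, 3 s
trials), so only the strongest injected signal clears significance: the
expertise effect on saccade amplitude (χ²(1) = 9.59, p = 0.002 — experts
were generated with a +0.5° cohort-level amplitude advantage). The other
generated effects (medium-task duration/amplitude shifts, expert
dispersion) exist but need the full-size design to reach power.

`res$report` prints the group × task summary table (means and SDs of
accuracy, confidence, fixation duration, saccade amplitude, NSS and
dispersion), `res$metrics` holds the per-trial NSS/dispersion table, and
`res$manifest` records the seed, configuration and per-stage counts —
including the excluded-saccade count. With `out_dir =` the run also writes
`fixations.csv`, `saccades.csv`, `metrics.csv`, `stats.json`,
`report.txt` and `manifest.json`.

A command-line front end lives at `inst/cli/gazecraft.R`:

```sh
Rscript inst/cli/gazecraft.R run --seed 42 --out out/
Rscript inst/cli/gazecraft.R simulate --seed 1 --out sim/ --render
```

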