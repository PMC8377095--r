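# wsisurv

Patient-level deep survival and biomarker modeling from whole-slide image
patches, at desk scale.

## What problem this addresses

For lower-grade gliomas (WHO grade 2-3 diffuse gliomas), two predictions
drive management: how long the patient is likely to survive, and whether
the tumor carries an IDH 1/2 mutation (a favorable, ~85%-prevalent
biomarker in grade-2 disease). Both signals are partly visible in routine
H&E histology — cell density and nuclear atypia track prognosis — but
manual grading captures them coarsely. `wsisurv` implements an end-to-end
pipeline that learns them directly from slide images, for
statisticians/computational pathologists who want a fully testable,
CPU-sized implementation of the approach:

1. **Tiling** — slides are cut into non-overlapping tiles (224 px at full
   scale, 64 px in the desk profile); background tiles are excluded by
   color thresholding (a pixel is background when its minimum RGB channel
   exceeds 220; a tile is kept when >= 50% of pixels are tissue).
2. **Patient-bag model** — for each patient, k random tiles are embedded
   by a convolutional backbone into 512-vectors, average-pooled, and
   mapped by a two-layer head (512 -> 128 -> 1) to a risk score `x_i`.
   Training minimizes the negative log Cox partial likelihood
   `J = -(1/n) * sum_i y_i * [x_i - log sum_{j in R(T_i)} exp(x_j)]`
   with Breslow tie handling (`R(T_i)` = patients still under observation
   at `T_i`); the binary biomarker task uses two logits with weighted
   cross-entropy. Adam, cosine annealing, L1 on the head weights.
3. **Repeated splits + ensembling** — patients sorted by outcome are cut
   into blocks of 4; each block sends 2/1/1 patients to train/val/test.
   The split is repeated (8 tuning + 24 evaluation repeats at full scale)
   and all out-of-sample test predictions are averaged per patient.
4. **Bootstrap model comparison** — Cox/logistic models with and without
   the image scores are refit on 10,000 (configurable) with-replacement
   draws and compared on the out-of-bag patients (C-index / AUC, with
   percentile confidence intervals).
5. **Synthetic cohort generator** — a first-class module that emulates the
   cohort's statistical structure (16.6% event rate, 85% biomarker
   prevalence, age 40.9 +/- 13.0, proportional-hazards survival with
   uniform censoring) and renders slide images whose nuclear density and
   size carry the latent hazard, so the whole pipeline is testable on one
   CPU without any downloads.

## Worked example

```r
library(wsisurv)

# a small synthetic cohort: 24 patients, 256-px slides, 64-px tiles
dir <- tempfile()
spec <- cohort_spec(n_patients = 24, slide_px = 256, tile_px = 64,
                    beta_risk = 1.0, seed = 31)
cohort <- generate_cohort(spec, dir)

config <- run_config(
  cohort = spec,
  training = training_config(max_steps = 10, eval_every_patches = 320,
                             n_patients_per_batch = 4, seed = 2),
  n_tune = 1, n_eval = 1, n_boot = 40,
  tasks = "survival", master_seed = 3)
res <- run_experiment(config, file.path(dir, "run"))
res$tables$table1_survival[, c("base", "without", "with", "difference")]
```

This micro run prints the comparison table

```
  base without      with difference
1 none      NA 0.9250000         NA
2  age 0.53125 0.6916667  0.1604167
```

reading: an age-only Cox model evaluated out-of-bag reaches C-index ~0.53
on this toy cohort; adding the image-derived risk score raises it to ~0.69
(a 24-patient toy, so the bootstrap intervals around these numbers are
wide). The `report.md` in the output directory lists every artifact
(manifest, splits, per-repeat predictions, ensemble, KM/ROC tables) with
the config hash and seed.

At the other end, `training_config(profile = "paper")` freezes the
full-scale hyperparameters (224-px tiles, 8 x 8 batches, learning rates
1e-4 / 3e-7, L1 0.01, evaluation every 20,480 patches, 96,000 steps) for
use with real slides and a GPU-scale backbone.

A thin CLI covering `simulate` / `tile` / `split` / `run-all`
(`--validate-only` supported) is installed at
`inst/exec/wsisurv-pipeline.R`.

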