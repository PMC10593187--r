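# recyclect

Spatiotemporal unpaired denoising of low-dose multi-phase cardiac CT
angiography (MP-CTA) image sequences, in pure R.

ECG-gated MP-CTA reconstructs the heart at many cardiac phases per beat, but
tube-current modulation leaves most phases acquired at ~20% current and
correspondingly noisy. `recyclect` restores those low-dose phases using
unpaired image-to-image translation between a low-dose domain *A* and a
full-dose domain *B*:

* a **spatial baseline** (CycleGAN-style): generators G_AB, G_BA and patch
  discriminators D_A, D_B trained with adversarial losses plus a
  cycle-consistency loss, total
  `L = L_GAN(G_AB, D_B) + L_GAN(G_BA, D_A) + λ·L_cycle` with λ = 10;
* a **spatiotemporal model** (RecycleGAN-style): the phases of one slice are
  a looped video, so temporal predictors P_A, P_B forecast the next frame
  from a window of past frames, adding recurrent losses
  `L_τ(P) = Σ_t ‖x_{t+1} − P(x_{1:t})‖²` and recycle losses
  `Σ_t ‖x_{t+1} − G_BA(P_B(G_AB(x_{1:t})))‖²` (translate → predict →
  translate back), with weights λ_rx = 0.5, λ_ry = 50, λ_τx = 1, λ_τy = 100.

The package also ships the full evaluation protocol — PSNR
(`10·log10(4095²/MSE)`, 12-bit scale), single-window SSIM (l·c·s), aorta-ROI
noise STD, STD-threshold frame selection (full dose < 39 HU, low dose >
59 HU, ≥ 3 consecutive phases), the printed 9-fold cross-validation
rotation, and the learning-rate search over [5.00e-6, 1.26e-3] — plus a
synthetic dynamic cardiac phantom generator (8-phase looped sequences,
low dose = 20% of full dose, quantum noise scaling σ/√dose) so training and
evaluation run at desk scale with no external data.

See `vignettes/spatiotemporal-denoising.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(recyclect)

# 9 pairs of synthetic phantoms (two cohort labels per pair), 32x32, 8 phases
cohort <- generate_cohort(n_pairs = 9, master_seed = 17, image_size = 32)
train <- Filter(function(e) e$pair_id <= 6, cohort)
val   <- Filter(function(e) e$pair_id == 7, cohort)
test  <- Filter(function(e) e$pair_id >= 8, cohort)

dataset <- list(
  a   = lapply(train, `[[`, "low_dose"),
  b   = lapply(train, `[[`, "full_dose"),
  val = lapply(val, function(e) list(low_dose = e$low_dose, clean = e$clean)))

fit <- train_cyclegan(dataset, training_config(objective = "cyclegan", seed = 7))
den <- denoise_sequence(fit$models$g_ab, test[[1]]$low_dose)
evaluate_sequence(den, reference = test[[1]]$clean)
```

On this fixed seed the run prints (aggregates are mean ± SD over the 8
phases; the noisy input scores 35.29 dB PSNR and 0.9685 SSIM against the
clean reference, so the denoiser gains ~2.3 dB):

```
<metric_report> 8 phases
  mse      2940.4041 +/- 123.5177
  psnr     37.5643 +/- 0.1811
  ssim     0.9807 +/- 0.0015
```

The spatiotemporal trainer is `train_recyclegan()` with
`objective = "recyclegan"`; on the same split it gains ~2.0 dB. Both
comfortably beat the noisy input; their ranking at this tiny scale varies
with seed (see `scripts/exploratory_seeds.R`).

## Command line

`inst/cli/recyclect.R` exposes `generate`, `train`, `denoise`, `evaluate`,
`select-frames` and `lr-search` subcommands over the array-archive dataset
layout written by `generate`.
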