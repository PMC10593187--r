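---
title: "Spatiotemporal unpaired denoising of multi-phase cardiac CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal unpaired denoising of multi-phase cardiac CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recyclect)
```

## The problem

ECG-gated multi-phase CT angiography (MP-CTA) reconstructs the beating heart
at many cardiac phases per cycle. To limit radiation, tube-current modulation
delivers full current only inside a narrow pulsing window; the remaining
phases are acquired at a fraction of the current (here 20%) and are
correspondingly noisy. The goal is to restore those low-dose phases to
full-dose quality. Two obstacles shape the method:

* there are no aligned low-dose/full-dose pairs of the same phase, so
  training must be *unpaired*;
* the phases of one slice form a temporally ordered, looped sequence (one
  heart beat), and that temporal structure carries denoising information
  that frame-by-frame methods ignore.

`recyclect` implements both the spatial baseline (CycleGAN-style unpaired
translation between a low-dose domain $A$ and a full-dose domain $B$) and its
spatiotemporal extension (RecycleGAN-style, adding temporal predictors with
recurrent and recycle losses), together with the full evaluation protocol
and a synthetic dynamic phantom that makes everything testable on a desk.

## Objectives

Four networks are learned for the spatial objective: generators
$G_{AB}, G_{BA}$ and patch discriminators $D_A, D_B$. The adversarial loss is
the printed log-likelihood form

$$\mathcal{L}_{GAN}(G_{AB}, D_B) =
  \mathbb{E}_b[\log D_B(b)] + \mathbb{E}_a[\log(1 - D_B(G_{AB}(a)))],$$

and the cycle-consistency loss is the mean-L1 round-trip error
$\mathbb{E}_a\|G_{BA}(G_{AB}(a)) - a\|_1 + \mathbb{E}_b\|G_{AB}(G_{BA}(b)) - b\|_1$,
weighted by $\lambda = 10$.

The spatiotemporal objective adds two temporal predictors $P_A, P_B$, each
mapping a window of $w$ past frames to the next frame within its domain.
Its loss replaces the cycle term with

* **recurrent** losses $\mathcal{L}_\tau(P) = \sum_t \|x_{t+1} - P(x_{1:t})\|^2$
  (squared error of within-domain prediction), and
* **recycle** losses: translate the window frame-by-frame, forecast the next
  translated frame with the target-domain predictor, translate back, and
  compare with the true next frame —
  $\sum_t \|x_{t+1} - G_{BA}(P_B(G_{AB}(x_{1:t})))\|^2$ for the low-dose
  domain, symmetrically for the full-dose one.

The published weights are retained: $\lambda_{rx} = 0.5$,
$\lambda_{ry} = 50$, $\lambda_{\tau x} = 1$, $\lambda_{\tau y} = 100$
(x = low-dose domain, y = full-dose domain).

**Reduction convention.** The source notation writes unnormalized sums over
time; this package reduces every image difference as a *mean over pixels*
and then a *mean over time points*, so loss magnitudes are
resolution-invariant and length-invariant. The $\lambda$ defaults are kept at
their published values, with the caveat that they were originally tuned
under a different (sum-based) convention. The recycle-loss norm is squared
L2, matching the recurrent loss and the original video-translation
formulation (the equation itself is only rendered as a figure in the source
text).

All loss operations are exported as pure functions (`adversarial_loss()`,
`cycle_consistency_loss()`, `recurrent_loss()`, `recycle_loss()`,
`cyclegan_objective()`, `recyclegan_objective()`) with hand-checkable
semantics; discriminator scores are clamped to $[10^{-7}, 1-10^{-7}]$ before
logs so no gradient step can produce an infinite loss.

## Intensity conventions

All quantitative metrics operate on the 12-bit raw scale $[0, 4095]$ with
the fixed map $\mathrm{raw} = \mathrm{HU} + 1024$ (so PSNR's maximum signal
value is 4095, the 12-bit convention). Networks consume frames on the model
scale $[-1, 1]$ via the affine $x/2047.5 - 1$; out-of-range values are
clamped with a warning rather than an error so a stray intensity never
aborts a training run.

## Networks

The exact published architectures are delegated to external appendix
figures, so the package provides *configurable approximations* sized to
train on a CPU:

* **Generator** — residual encoder–decoder: lifting convolution,
  `levels` stride-2 downsamplings, `depth` residual blocks (instance
  normalization inside), nearest-neighbor upsampling, and a
  *zero-initialized* output convolution feeding a global identity skip with
  a hard $[-1,1]$ clamp. A fresh generator is therefore exactly the identity
  map — the stable starting point for adversarial training. The residual
  branch is additionally *mean-centered*, making the generator exactly
  mean-preserving: the frame's DC level is a loss-flat direction of the
  adversarial game (both generators can co-drift and the cycle loss cannot
  see it), and an Adam random walk along it was empirically the dominant
  PSNR cost in short runs; pinning it also preserves quantitative HU levels.
* **Discriminator** — a patch classifier whose input is centered (global
  mean subtracted, closing the DC-reward loophole from the critic's side)
  and whose first stage is a full-wave-rectified (absolute value) filter
  bank: a learnable local *energy detector*. The two dose domains differ
  chiefly in noise energy, and an energy-detecting critic both learns that
  difference within a 200-step run and is hard to fool without genuinely
  changing local noise energy. Two stride-2 layers follow; the sigmoid
  score map's entries are treated as independent patch scores. The default
  receptive field is 17 pixels (`receptive_field()` computes the
  closed form).
* **Predictor** — the $w$ window frames (default $w = 2$, the original
  video-translation convention) are channel-concatenated and passed through
  a small residual trunk whose zero-initialized output feeds a skip from the
  most recent frame: a fresh predictor is the persistence forecast.

All factories are pure in `(config, seed)`; checkpoints archive config,
seed and parameters for all six networks and restore bit-identical behavior.

## Training

Adam ($\beta_1 = 0.5$, $\beta_2 = 0.999$, no weight decay) with alternating
generator and discriminator updates. Several scheduling choices matter at
desk scale and are config-exposed:

* **Adversarial update rule** (`gan_mode`): the default is the least-squares
  variant, which proved markedly more stable for short CPU runs; the
  non-saturating log-likelihood update (`"vanilla"`) is available. The
  *logged* `gan_AB`/`gan_BA` values are always the printed log-likelihood
  objective, whichever rule drives the updates, so the loss-breakdown
  identity stays pinned to the printed formulas.
* **Two-timescale updates** (`disc_lr_multiplier`, default 8): the tiny
  critics need a faster clock than the generators to stay informative.
* **Critic warmup** (`disc_warmup_steps`): for the first steps only the
  discriminators (and, in the spatiotemporal objective, the predictors,
  which depend on neither the generators nor the critics) are updated. The
  generators start as the identity, so the critics first learn the
  dose-domain difference on honest inputs; generators then follow an
  informative gradient from their first step.
* **Per-objective defaults**: learning rate 1.26e-3 (spatial) / 6e-4
  (spatiotemporal) with warmups 60 / 40 — the values the desk-scale sweeps
  favor, analogous to the per-model learning-rate tuning of the source
  protocol. Rates are constrained to the published search range
  $[5.00\times10^{-6}, 1.26\times10^{-3}]$ unless explicitly overridden.
* **Model selection**: final-epoch parameters, unless the dataset carries a
  validation set, in which case the epoch with the best validation PSNR is
  returned (GAN trajectories at this scale are volatile across epochs, and
  validation-based selection is the protocol's own model-selection rule).
* Discriminators train on current-batch fakes (no replay buffer); windows
  for the spatiotemporal objective are uniform over (sequence, phase) with
  looped sequences exposing all phases.

`learning_rate_search()` trains one model per rate on a shared seed and
selects the rate with the *highest* mean validation PSNR. The source text
says "lowest PSNR", almost certainly a typo (higher PSNR = better throughout
its own metric definitions); the package maximizes and records the
discrepancy here rather than silently matching the letter of the text.
Ties break toward the smaller rate; failed rates are excluded.

`build_cv_folds()` reproduces the printed 9-fold rotation: fold $i$ tests on
pair $i$ and validates on pair $(8,9,2,6,3,7,4,1,5)_i$.
`finalize_and_evaluate()` retrains on training + validation pairs and
reports per-cohort-label subgroups.

## Evaluation metrics

`mse()`, `psnr()` (MAX = 4095; identical frames report an `Inf` sentinel,
never an exception, so identity-denoiser baselines aggregate cleanly) and
`ssim()` follow the printed single-window formulas: SSIM is computed
*globally per frame* by default because the formulas are presented without
any window size; a mean-pooled 8×8 sliding-window mode exists behind a flag
for comparability with common toolkits. The SSIM constants are unprinted in
the source, so the standard convention is used
($c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$, $c_3 = c_2/2$, $L = 4095$; all
overridable). The printed contrast term has $2\sigma_{xy}$ in its numerator
where the classical decomposition (which the source cites) uses
$2\sigma_x\sigma_y$; the package follows the classical $l \cdot c \cdot s$
product — with $c_3 = c_2/2$ it collapses to the familiar two-factor SSIM —
and documents the discrepancy instead of resolving it. Variances use the
sample ($n-1$) convention, as does `roi_std()`, the aorta-ROI noise proxy
used when no ground truth exists.

`select_low_full_frames()` implements the patient-data frame selection:
a phase qualifies as full dose (ROI STD < 39 HU) or low dose (> 59 HU) only
inside a run of at least 3 consecutive qualifying phases; runs may wrap when
the sequence is looped. ROI rectangles are user-supplied, 0-based and
half-open (the source draws the box in a figure without coordinates).

## The synthetic phantom

The licensed anthropomorphic phantom program and the clinical data behind
the original study are unavailable, so `generate_phantom()` renders a
desk-scale dynamic phantom: a body ellipse of soft tissue (40 HU), two lung
fields (−700 HU), a myocardial annulus (50 HU) around a contrast-filled
chamber whose radius follows a sinusoidal-in-phase trajectory between
end-diastole and end-systole (exactly periodic, so the 8-phase sequence is a
seamless loop), and a flat aorta disc (300 HU) for ROI noise measurements.
The blood-pool enhancement is drawn from 200–350 HU in cohorts, the printed
arterial-enhancement range. Two deliberate departures from anatomy:

* the background is water-like (−100 HU) rather than air, so the additive
  noise model remains exact everywhere on the clamped 12-bit scale (with an
  air background, low-dose noise would clip at 0 and bias every noise
  statistic the tests rely on);
* geometry is concentric smooth shapes at 32–128 px, not anatomy — the
  method's contract is spatiotemporal denoising, not anatomic fidelity.

Noise is additive Gaussian with quantum scaling
$\sigma(d) = \sigma_{\mathrm{full}} / \sqrt{d}$: the 20% dose level carries
$\sqrt{5} \approx 2.24$ times the full-dose noise. The default
$\sigma_{\mathrm{full}}$ is the calibrated constant 32 HU, chosen once so
that low-dose aorta-ROI STDs (~71.6 HU) sit clearly above the 59 HU
selection threshold and full-dose ones clearly below 39 HU; an optional box
smoothing of the noise field (rescaled back to the target SD) mimics
reconstruction-kernel correlation and is off by default so the noise
statistics stay exact. `generate_cohort()` mirrors the nine
female/male pairs structure with a binary cohort label (report structure
only; no biological claim) and derives per-phantom seeds deterministically
from a master seed.

**What a green test does and does not establish.** The phantom is piecewise
constant with white noise; real CT noise is correlated, non-stationary and
anatomy is textured. Passing the desk-scale suites establishes that the
objectives, metrics, protocol and optimization are implemented correctly and
that the training dynamics denoise in a controlled world — not that the tiny
networks would match the published clinical performance, which required the
full-scale phantom program, clinical data and multi-hour GPU training.

## Numerical choices and degenerate inputs

* Discriminator scores clamped at $10^{-7}$; PSNR of identical frames is
  `Inf`; SSIM of identical frames is exactly 1.
* Hard $[-1,1]$ output clamp (subgradient 0 outside) instead of tanh: a
  tanh around the identity skip would distort intensities by tens of HU at
  typical tissue values, defeating the identity initialization.
* Instance normalization uses population variance with $\epsilon = 10^{-5}$.
* `frame_window()` wraps modulo the phase count only for looped sequences;
  a too-short non-looped window is an error, not a silent truncation.
* Ties in `learning_rate_search()` go to the smaller rate; the grid is
  geometric with 8 points by default (the source shows a multi-point sweep
  without listing the grid).
* Whether patient 20-phase sequences were treated as looped during training
  is unstated in the source; `looped` is a per-dataset flag (default: true
  for 8-phase phantom-style sequences, false otherwise).

## Known limitations

* Pure-R training engine: fine at 32×32 with width-16 networks (minutes per
  200-step run), not intended for clinical resolutions.
* 2D + time only; volumetric (4D) extension is out of scope.
* The desk-scale comparison between the spatiotemporal and spatial models is
  exploratory: at 200 steps both comfortably beat the noisy input, but their
  ranking varies with seed (`scripts/exploratory_seeds.R` runs the
  multi-seed comparison; it is not part of the default suites for time
  reasons).
* DICOM I/O, projection-domain simulation, and perceptual/reader studies are
  out of scope.

## A worked example

```{r example, eval = FALSE}
library(recyclect)

cohort <- generate_cohort(n_pairs = 9, master_seed = 17, image_size = 32)
train <- Filter(function(e) e$pair_id <= 6, cohort)
val <- Filter(function(e) e$pair_id == 7, cohort)
test <- Filter(function(e) e$pair_id >= 8, cohort)

dataset <- list(
  a = lapply(train, `[[`, "low_dose"),
  b = lapply(train, `[[`, "full_dose"),
  val = lapply(val, function(e) list(low_dose = e$low_dose, clean = e$clean)))

fit <- train_recyclegan(dataset, training_config(objective = "recyclegan",
                                                 seed = 7))
denoised <- denoise_sequence(fit$models$g_ab, test[[1]]$low_dose)
evaluate_sequence(denoised, reference = test[[1]]$clean)
```
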