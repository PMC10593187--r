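Package: recyclect
Title: Spatiotemporal Unpaired Denoising of Multi-Phase Cardiac CT Sequences
Version: 0.1.0
Authors@R:
    person("recyclect", "developers", email = "recyclect@example.org",
           role = c("aut", "cre"))
Description: Unpaired image-to-image translation for denoising low-dose
    multi-phase cardiac CT angiography (MP-CTA) image sequences. Implements a
    CycleGAN baseline (adversarial plus cycle-consistency losses) and its
    spatiotemporal extension with recurrent and recycle losses over temporally
    ordered cardiac phases, together with the full evaluation protocol
    (PSNR/SSIM/ROI standard deviation, noise-based frame selection, 9-fold
    cross-validation, learning-rate search) and a synthetic dynamic cardiac
    phantom generator producing paired full-dose and low-dose 8-phase looped
    sequences, so that training and evaluation run at desk scale with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
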