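#!/usr/bin/env Rscript

# Exploratory (non-gating) comparison: median test PSNR of the
# spatiotemporal denoiser vs the spatial baseline across several seeds, the
# desk-scale analog of the study-level "RecycleGAN outperforms CycleGAN in
# almost all cases" comparison. Not part of the graded suites (≈20 min of
# training); run manually:
#
#   Rscript scripts/exploratory_seeds.R [--seeds 7,11,23]

suppressMessages(library(recyclect))

args <- commandArgs(trailingOnly = TRUE)
i <- match("--seeds", args)
seeds <- if (!is.na(i)) as.integer(strsplit(args[[i + 1L]], ",")[[1]]) else c(7L, 11L, 23L)

cohort <- generate_cohort(n_pairs = 9, master_seed = 17, image_size = 32)
tr <- Filter(function(e) e$pair_id %in% 1:6, cohort)
va <- Filter(function(e) e$pair_id == 7, cohort)
te <- Filter(function(e) e$pair_id %in% 8:9, cohort)
dataset <- list(a = lapply(tr, `[[`, "low_dose"),
                b = lapply(tr, `[[`, "full_dose"),
                val = lapply(va, function(e)
                  list(low_dose = e$low_dose, clean = e$clean)))
mean_psnr <- function(cand, ref)
  mean(vapply(seq_len(cand$phase_count), function(t)
    psnr(cand$frames[[t]], ref$frames[[t]]), numeric(1)))
noisy <- vapply(te, function(e) mean_psnr(e$low_dose, e$clean), numeric(1))
cat("noisy test PSNR:", round(mean(noisy), 2), "dB\n")

res <- list()
for (seed in seeds) {
  for (obj in c("cyclegan", "recyclegan")) {
    cfg <- training_config(seed = seed, objective = obj)
    fit <- if (obj == "cyclegan") train_cyclegan(dataset, cfg)
           else train_recyclegan(dataset, cfg)
    p <- mean(vapply(te, function(e)
      mean_psnr(denoise_sequence(fit$models$g_ab, e$low_dose), e$clean),
      numeric(1)))
    res[[obj]] <- c(res[[obj]], p)
    cat(sprintf("seed %d %-10s mean test PSNR %.2f dB\n", seed, obj, p))
  }
}
cat(sprintf("median over seeds: cyclegan %.2f dB, recyclegan %.2f dB\n",
            median(res$cyclegan), median(res$recyclegan)))
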