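# trainer behavior at toy scale; the full 200-step desk-scale runs live in
# test-acceptance.R

toy_config <- function(objective, seed = 3, epochs = 1L, ...) {
  training_config(objective = objective, seed = seed, epochs = epochs,
                  steps_per_epoch = 3L, batch_size = 1L, image_size = 16L,
                  width = 4L, depth = 1L, levels = 0L,
                  disc_warmup_steps = 0L, ...)
}

toy_dataset <- function(seed = 17, n_pairs = 1, size = 16) {
  co <- generate_cohort(n_pairs = n_pairs, master_seed = seed, image_size = size)
  list(a = lapply(co, `[[`, "low_dose"), b = lapply(co, `[[`, "full_dose"))
}

test_that("training_config validates the learning-rate range", {
  expect_error(training_config(learning_rate = 1e-2), "outside the search range")
  expect_silent(training_config(learning_rate = 1e-2,
                                allow_lr_outside_range = TRUE))
  expect_error(training_config(learning_rate = -1), "positive")
  expect_error(training_config(epochs = -1), "epochs")
})

test_that("epochs = 0 is a no-op returning fresh models and empty history", {
  ds <- toy_dataset()
  fit <- train_cyclegan(ds, toy_config("cyclegan", epochs = 0L))
  expect_named(fit$models, c("g_ab", "g_ba", "d_a", "d_b"))
  expect_equal(nrow(fit$history$steps), 0)
  # untouched generator is the identity
  x <- matrix(runif(256, -0.9, 0.9), 16, 16)
  expect_equal(fit$models$g_ab(x), x)
  fit2 <- train_recyclegan(ds, toy_config("recyclegan", epochs = 0L))
  expect_named(fit2$models, c("g_ab", "g_ba", "d_a", "d_b", "p_a", "p_b"))
})

test_that("training is bit-reproducible for a fixed seed", {
  ds <- toy_dataset()
  f1 <- train_cyclegan(ds, toy_config("cyclegan", epochs = 2L))
  f2 <- train_cyclegan(ds, toy_config("cyclegan", epochs = 2L))
  expect_identical(f1$history$steps$total, f2$history$steps$total)
  expect_identical(network_params(f1$models$g_ab), network_params(f2$models$g_ab))
  r1 <- train_recyclegan(ds, toy_config("recyclegan", epochs = 2L))
  r2 <- train_recyclegan(ds, toy_config("recyclegan", epochs = 2L))
  expect_identical(r1$history$steps$total, r2$history$steps$total)
  expect_identical(network_params(r1$models$p_b), network_params(r2$models$p_b))
})

test_that("logged totals re-equal the weighted sum of their components", {
  ds <- toy_dataset()
  fit <- train_cyclegan(ds, toy_config("cyclegan", epochs = 2L))
  h <- fit$history$steps
  expect_equal(h$total, h$gan_AB + h$gan_BA + 10 * h$cycle, tolerance = 1e-10)
  fr <- train_recyclegan(ds, toy_config("recyclegan", epochs = 2L))
  hr <- fr$history$steps
  w <- loss_weights()
  expect_equal(hr$total,
               hr$gan_AB + hr$gan_BA + w$lambda_rx * hr$recycle_x +
                 w$lambda_ry * hr$recycle_y + w$lambda_tau_x * hr$recurrent_x +
                 w$lambda_tau_y * hr$recurrent_y, tolerance = 1e-10)
})

test_that("zero lambdas freeze the predictors (pure adversarial updates)", {
  ds <- toy_dataset()
  cfg <- toy_config("recyclegan", epochs = 1L,
                    weights = loss_weights(0, 0, 0, 0, 0))
  fit <- train_recyclegan(ds, cfg)
  fresh <- make_predictor(predictor_config(4L, 2L, 16L), seed = cfg$seed + 55L)
  expect_identical(network_params(fit$models$p_a), network_params(fresh))
})

test_that("denoise_sequence preserves structure and metadata", {
  ph <- generate_phantom(phantom_params(image_size = 16, seed = 4))
  ident <- function(f) f
  den <- denoise_sequence(ident, ph$low_dose)
  expect_equal(den$phase_count, 8L)
  expect_true(den$looped)
  expect_equal(den$domain_label, "denoised")
  # identity generator: output equals input within model-scale rounding
  expect_true(max(abs(den$frames[[1]] - ph$low_dose$frames[[1]])) < 0.5)
  expect_warning(denoise_sequence(ident, ph$clean), "low_dose")
})

test_that("learning_rate_search maximizes mock validation PSNR", {
  tab <- c("1e-05" = 40, "1e-04" = 42, "0.001" = 39)
  train_fn <- function(rate) tab[[as.character(rate)]]
  res <- learning_rate_search(train_fn, grid = c(1e-5, 1e-4, 1e-3))
  expect_equal(res$best_rate, 1e-4)
  expect_equal(nrow(res$table), 3)
  # single-element grid
  expect_equal(learning_rate_search(function(r) 10, grid = 2e-4)$best_rate, 2e-4)
  # tie breaks toward the smaller rate
  res2 <- learning_rate_search(function(r) 41, grid = c(1e-4, 1e-5))
  expect_equal(res2$best_rate, 1e-5)
  # failures are excluded; all-failed errors
  res3 <- learning_rate_search(function(r) if (r > 1e-4) stop("boom") else 40,
                               grid = c(1e-5, 1e-3))
  expect_equal(res3$best_rate, 1e-5)
  expect_match(res3$table$status[2], "boom")
  expect_error(learning_rate_search(function(r) stop("x"), grid = c(1e-5, 1e-4)),
               "all learning rates failed")
  expect_error(learning_rate_search(function(r) 1, grid = numeric(0)), "empty")
})

test_that("the default learning-rate grid spans the published range", {
  g <- default_lr_grid()
  expect_length(g, 8)
  expect_equal(g[1], 5e-6)
  expect_equal(g[8], 1.26e-3)
  expect_true(all(diff(log(g)) > 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 7), tolerance = 1e-9)
})

test_that("build_cv_folds reproduces the printed rotation and partitions", {
  folds <- build_cv_folds(1:9)
  expect_length(folds, 9)
  f1 <- folds[[1]]
  expect_equal(f1$test_pair, 1)
  expect_equal(f1$validation_pair, 8)
  expect_setequal(f1$train_pairs, c(2, 3, 4, 5, 6, 7, 9))
  expect_equal(folds[[9]]$test_pair, 9)
  expect_equal(folds[[9]]$validation_pair, 5)
  # test sets partition the pairs; each fold's three sets are disjoint
  expect_setequal(vapply(folds, `[[`, 0, "test_pair"), 1:9)
  for (f in folds) {
    ids <- c(f$train_pairs, f$validation_pair, f$test_pair)
    expect_setequal(ids, 1:9)
    expect_equal(anyDuplicated(ids), 0L)
  }
  expect_error(build_cv_folds(1:8), "exactly 9")
})

test_that("finalize_and_evaluate with mock denoisers hits the analytic poles", {
  co <- tiny_cohort(n_pairs = 9, size = 16)
  folds <- build_cv_folds(1:9)
  cfg <- toy_config("cyclegan")
  # identity denoiser reproduces the noisy-input baseline
  res <- finalize_and_evaluate(folds[[1]], cfg, co,
                               denoiser = function(s) s)
  expect_length(res$reports, 2)
  e_test <- Filter(function(e) e$pair_id == 1, co)
  base <- evaluate_sequence(e_test[[1]]$low_dose, reference = e_test[[1]]$clean)
  expect_equal(res$reports[[1]]$report$aggregates$psnr[["mean"]],
               base$aggregates$psnr[["mean"]], tolerance = 1e-9)
  # clean-oracle denoiser: infinite PSNR, SSIM 1
  oracle <- local({
    lut <- co
    function(s) {
      hit <- Filter(function(e) identical(e$low_dose$frames, s$frames), lut)
      hit[[1]]$clean
    }
  })
  res2 <- finalize_and_evaluate(folds[[1]], cfg, co, denoiser = oracle)
  expect_equal(res2$reports[[1]]$report$aggregates$psnr[["mean"]], Inf)
  expect_equal(res2$reports[[1]]$report$aggregates$ssim[["mean"]], 1)
  expect_named(res2$subgroup, c("F", "M"))
  # a tiny end-to-end fold (real training) emits a schema-valid report
  res3 <- finalize_and_evaluate(folds[[1]], cfg, co)
  expect_named(res3, c("fold_id", "reports", "subgroup"))
  for (r in res3$reports) {
    expect_true(r$cohort %in% c("F", "M"))
    expect_true(all(c("mse", "psnr", "ssim") %in% names(r$report$per_frame)))
    expect_equal(r$report$aggregates$mse[["mean"]], mean(r$report$per_frame$mse))
  }
})

test_that("trainers reject malformed datasets and configs", {
  ds <- toy_dataset()
  expect_error(train_cyclegan(list(a = ds$a), toy_config("cyclegan")), "dataset")
  expect_error(train_cyclegan(ds, toy_config("recyclegan")), "cyclegan")
  expect_error(train_recyclegan(ds, toy_config("cyclegan")), "recyclegan")
  short <- phase_sequence(list(matrix(0, 16, 16), matrix(0, 16, 16)),
                          looped = FALSE)
  expect_error(train_recyclegan(list(a = list(short), b = ds$b),
                                toy_config("recyclegan")), "too short")
})
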