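test_that("factories are deterministic given (config, seed)", {
  cfg <- generator_config(width = 8, depth = 1, levels = 1, image_size = 16)
  g1 <- make_generator(cfg, seed = 42)
  g2 <- make_generator(cfg, seed = 42)
  expect_identical(network_params(g1), network_params(g2))
  set.seed(1); x <- matrix(runif(256, -1, 1), 16, 16)
  expect_identical(g1(x), g2(x))
  g3 <- make_generator(cfg, seed = 43)
  expect_false(identical(network_params(g1), network_params(g3)))
  d1 <- make_discriminator(discriminator_config(8, 2, 16), seed = 7)
  d2 <- make_discriminator(discriminator_config(8, 2, 16), seed = 7)
  expect_identical(d1(x), d2(x))
})

test_that("generator obeys shape and range contracts at any divisible size", {
  g <- make_generator(generator_config(width = 8, depth = 1, levels = 1,
                                       image_size = 32), seed = 2)
  for (d in c(16, 32, 48)) {
    x <- matrix(runif(d * d, -1, 1), d, d)
    y <- g(x)
    expect_equal(dim(y), c(d, d))
    expect_true(all(y >= -1 & y <= 1))
  }
  expect_error(make_generator(generator_config(image_size = 31, levels = 1)),
               "divisible")
  expect_error(g(matrix(0, 15, 15)), "divisible")
  # fresh generator is the identity map (zero-init residual, global skip)
  x <- matrix(runif(256, -0.9, 0.9), 16, 16)
  expect_equal(g(x), x)
})

test_that("generator parameter count matches closed-form layer arithmetic", {
  g <- make_generator(generator_config(width = 8, depth = 1, levels = 0,
                                       image_size = 16), seed = 1)
  w <- 8
  # lifting conv (9*1*w + w), one residual block 2*(9*w*w + w), output conv (9*w + 1)
  expected <- (9 * w + w) + 2 * (9 * w * w + w) + (9 * w + 1)
  expect_equal(network_parameter_count(g), expected)
  d <- make_discriminator(discriminator_config(width = 8, n_layers = 2,
                                               image_size = 16), seed = 1)
  # abs filter bank 9*1*8+8, strides 9*8*8+8 and 9*8*16+16, final 9*16+1
  expect_equal(network_parameter_count(d),
               (9 * 8 + 8) + (9 * 64 + 8) + (9 * 128 + 16) + (9 * 16 + 1))
})

test_that("discriminator emits a finite patch score map in (0,1)", {
  d <- make_discriminator(discriminator_config(width = 8, n_layers = 2,
                                               image_size = 16), seed = 3)
  y <- d(matrix(0.5, 16, 16))
  expect_equal(dim(y), c(4, 4))   # two stride-2 layers
  expect_true(all(is.finite(y) & y > 0 & y < 1))
})

test_that("receptive field matches the closed-form stride recurrence", {
  d <- make_discriminator(discriminator_config(width = 8, n_layers = 2,
                                               image_size = 16), seed = 3)
  # k3/s1, k3/s2, k3/s2, k3/s1: 1 +2*1 +2*1 +2*2 +2*4 = 17
  expect_equal(receptive_field(d), 17L)
  d3 <- make_discriminator(discriminator_config(8, 3, 16), seed = 3)
  expect_equal(receptive_field(d3), 17L + 2L * 8L)
})

test_that("predictor consumes exactly w frames and starts as persistence", {
  p <- make_predictor(predictor_config(width = 8, w = 2, image_size = 16),
                      seed = 4)
  f1 <- matrix(runif(256, -0.9, 0.9), 16, 16)
  f2 <- matrix(runif(256, -0.9, 0.9), 16, 16)
  y <- p(list(f1, f2))
  expect_equal(dim(y), dim(f1))
  expect_equal(y, f2)   # zero-init trunk + skip from the most recent frame
  expect_error(p(list(f1, f2, f1)), "w = 2")
  expect_error(p(list(f1)), "w = 2")
})

test_that("an untrained predictor has finite positive recurrent loss on noise", {
  p <- make_predictor(predictor_config(width = 8, w = 2, image_size = 8), seed = 5)
  s <- random_seq(T_ = 4, d = 8, looped = TRUE, seed = 9)
  rl <- recurrent_loss(s, p, w = 2)
  expect_true(is.finite(rl) && rl > 0)
})

test_that("ten predictor-only Adam steps decrease the recurrent loss", {
  ns <- asNamespace("recyclect")
  # deterministic periodic toy sequence: a bright square moving on a cycle
  frames <- lapply(0:3, function(t) {
    f <- matrix(-0.5, 16, 16)
    r <- 4 + 2 * t
    f[r:(r + 3), 6:9] <- 0.5
    f
  })
  s <- phase_sequence(frames, intensity_scale = "hu", looped = TRUE)
  p <- make_predictor(predictor_config(width = 8, w = 2, image_size = 16), seed = 6)
  e <- ns$nn_env(p)
  l0 <- recurrent_loss(s, p, w = 2)
  opt <- ns$adam_init(e$params)
  for (step in 1:10) {
    grads <- NULL
    for (t in 1:4) {
      win <- frame_window(s, t, 2)
      target <- s$frames[[ns$next_phase(s, t)]]
      stack <- array(unlist(win), c(16, 16, 2))
      fw <- ns$pred_fw(e, stack, keep = TRUE)
      err <- fw$y - array(target, c(16, 16, 1))
      bw <- ns$pred_bw(e, fw, 2 * err / 256, stack)
      grads <- ns$grads_add(grads, bw$grads)
    }
    st <- ns$adam_step(e$params, ns$grads_scale(grads, 1 / 4), opt, 1e-2)
    e$params <- st$params; opt <- st$state
  }
  l1 <- recurrent_loss(s, p, w = 2)
  expect_lt(l1, l0)
})

test_that("checkpoints restore bit-identical behavior for all six networks", {
  models <- list(
    g_ab = make_generator(generator_config(8, 1, 0, 16), seed = 1),
    g_ba = make_generator(generator_config(8, 1, 0, 16), seed = 2),
    d_a = make_discriminator(discriminator_config(8, 2, 16), seed = 3),
    d_b = make_discriminator(discriminator_config(8, 2, 16), seed = 4),
    p_a = make_predictor(predictor_config(8, 2, 16), seed = 5),
    p_b = make_predictor(predictor_config(8, 2, 16), seed = 6))
  # perturb one weight so the restored state differs from a fresh build
  pp <- network_params(models$g_ab)
  pp[[1]]$W[1] <- 0.123
  network_params(models$g_ab) <- pp
  path <- tempfile(fileext = ".rds")
  save_checkpoint(models, path)
  restored <- load_checkpoint(path)
  expect_identical(names(restored), names(models))
  x <- matrix(runif(256, -1, 1), 16, 16)
  expect_identical(restored$g_ab(x), models$g_ab(x))
  expect_identical(restored$d_b(x), models$d_b(x))
  expect_identical(restored$p_a(list(x, x)), models$p_a(list(x, x)))
  expect_identical(network_params(restored$g_ab), network_params(models$g_ab))
  unlink(path)
})
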