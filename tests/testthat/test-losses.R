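test_that("adversarial loss matches hand-computed values", {
  expect_equal(adversarial_loss(0.5, 0.5), log(0.5) + log(0.5), tolerance = 1e-12)
  expect_equal(adversarial_loss(0.8, 0.3), log(0.8) + log(0.7), tolerance = 1e-12)
  # discriminator optimum: scores at the clamp boundaries give ~0
  eps <- 1e-7
  expect_lt(abs(adversarial_loss(1 - eps, eps)), 1e-6)
  # scores at exactly 0/1 are clamped, not an error
  expect_true(is.finite(adversarial_loss(1, 0)))
  expect_error(adversarial_loss(numeric(0), 0.5), "empty")
  # score maps contribute every entry
  expect_equal(adversarial_loss(matrix(c(0.5, 0.5), 1), 0.5), 2 * log(0.5))
})

test_that("cycle-consistency loss is mean-L1 over the two cycles", {
  a <- matrix(1:4, 2); b <- matrix(5:8, 2)
  expect_equal(cycle_consistency_loss(a, a, b, b), 0)
  expect_equal(cycle_consistency_loss(a, a + 2, b, b), 2)
  set.seed(9)
  x <- matrix(sample(0:9, 4), 2); xr <- matrix(sample(0:9, 4), 2)
  y <- matrix(sample(0:9, 4), 2); yr <- matrix(sample(0:9, 4), 2)
  expect_equal(cycle_consistency_loss(x, xr, y, yr),
               sum(abs(x - xr)) / 4 + sum(abs(y - yr)) / 4, tolerance = 1e-12)
  expect_error(cycle_consistency_loss(a, matrix(0, 3, 3), b, b), "shape")
})

test_that("recurrent loss equals hand evaluation on scalar sequences", {
  s <- scalar_seq(c(1, 2, 3))
  persistence <- function(frames) frames[[length(frames)]]
  # targets (2, 3) predicted as (1, 2): mean of {1, 1} = 1
  expect_equal(recurrent_loss(s, persistence, w = 1), 1)
  truth <- local({
    i <- 0
    function(frames) matrix(frames[[length(frames)]] + 1, 1, 1)
  })
  expect_equal(recurrent_loss(s, truth, w = 1), 0)
  const <- phase_sequence(lapply(1:4, function(i) matrix(7, 2, 2)),
                          intensity_scale = "hu", looped = TRUE)
  expect_equal(recurrent_loss(const, function(fr) matrix(7, 2, 2), w = 2), 0)
  expect_error(recurrent_loss(scalar_seq(c(1, 2)), persistence, w = 2),
               "too short")
})

test_that("recycle loss composes generators and predictor as specified", {
  s <- scalar_seq(c(1, 2, 3))
  ident <- function(f) f
  persistence <- function(frames) frames[[length(frames)]]
  # g_fwd doubles, predictor persists, g_bwd halves: net persistence
  expect_equal(recycle_loss(s, function(f) 2 * f, function(f) f / 2,
                            persistence, w = 1), 1)
  expect_equal(recycle_loss(s, ident, ident,
                            function(fr) fr[[length(fr)]] + 1, w = 1), 0)
})

test_that("identity generators reduce recycle to recurrent on random fixtures", {
  ident <- function(f) f
  set.seed(11)
  for (i in 1:100) {
    s <- random_seq(T_ = sample(3:6, 1), d = sample(2:4, 1),
                    looped = sample(c(TRUE, FALSE), 1), seed = i)
    w <- sample(1:2, 1)
    pred_seed <- sample(1e6, 1)
    mk_pred <- function() {
      function(frames) {
        set.seed(pred_seed + length(frames))
        frames[[1]] + matrix(rnorm(length(frames[[1]])), nrow(frames[[1]]))
      }
    }
    expect_equal(recycle_loss(s, ident, ident, mk_pred(), w),
                 recurrent_loss(s, mk_pred(), w), tolerance = 1e-12)
  }
})

test_that("cyclegan objective recomposes from its component operations", {
  set.seed(5)
  batch <- list(a = lapply(1:2, function(i) matrix(rnorm(4), 2)),
                b = lapply(1:2, function(i) matrix(rnorm(4), 2)))
  models <- list(g_ab = function(f) f + 0.5, g_ba = function(f) f - 0.25,
                 d_a = function(f) 0.3 + 0.1 * tanh(mean(f)),
                 d_b = function(f) 0.6 + 0.2 * tanh(mean(f)))
  w <- loss_weights(lambda_cycle = 10)
  br <- cyclegan_objective(batch, models, w)
  gan_ab <- adversarial_loss(lapply(batch$b, models$d_b),
                             lapply(batch$a, function(f) models$d_b(models$g_ab(f))))
  gan_ba <- adversarial_loss(lapply(batch$a, models$d_a),
                             lapply(batch$b, function(f) models$d_a(models$g_ba(f))))
  cyc <- mean(vapply(batch$a, function(f)
    mean(abs(f - models$g_ba(models$g_ab(f)))), numeric(1))) +
    mean(vapply(batch$b, function(f)
      mean(abs(f - models$g_ab(models$g_ba(f)))), numeric(1)))
  expect_equal(br$terms$gan_AB, gan_ab, tolerance = 1e-12)
  expect_equal(br$terms$gan_BA, gan_ba, tolerance = 1e-12)
  expect_equal(br$terms$cycle, cyc, tolerance = 1e-12)
  expect_equal(br$total, gan_ab + gan_ba + 10 * cyc, tolerance = 1e-10)
  # degenerate weight: lambda = 0 leaves only the adversarial terms
  br0 <- cyclegan_objective(batch, models, loss_weights(lambda_cycle = 0))
  expect_equal(br0$total, gan_ab + gan_ba, tolerance = 1e-10)
  # perfect reconstructions: identity generators zero the cycle term
  ident_models <- within(models, { g_ab <- function(f) f; g_ba <- function(f) f })
  bri <- cyclegan_objective(batch, ident_models, w)
  expect_equal(bri$terms$cycle, 0)
  expect_error(cyclegan_objective(list(a = batch$a), models, w), "batch")
})

test_that("recyclegan objective recomposes and degenerates correctly", {
  set.seed(6)
  mk_win <- function() lapply(1:3, function(i) matrix(rnorm(4), 2))
  batch <- list(a = list(mk_win(), mk_win()), b = list(mk_win()))
  models <- list(g_ab = function(f) 1.1 * f, g_ba = function(f) f / 1.1,
                 d_a = function(f) 0.4, d_b = function(f) 0.55,
                 p_a = function(fr) 0.5 * (fr[[1]] + fr[[2]]),
                 p_b = function(fr) fr[[2]])
  w <- loss_weights()
  br <- recyclegan_objective(batch, models, w, w = 2)
  rx <- mean(vapply(batch$a, function(win) {
    tr <- lapply(win[1:2], models$g_ab)
    mean((win[[3]] - models$g_ba(models$p_b(tr)))^2)
  }, numeric(1)))
  ry <- mean(vapply(batch$b, function(win) {
    tr <- lapply(win[1:2], models$g_ba)
    mean((win[[3]] - models$g_ab(models$p_a(tr)))^2)
  }, numeric(1)))
  tx <- mean(vapply(batch$a, function(win)
    mean((win[[3]] - models$p_a(win[1:2]))^2), numeric(1)))
  ty <- mean(vapply(batch$b, function(win)
    mean((win[[3]] - models$p_b(win[1:2]))^2), numeric(1)))
  expect_equal(br$terms$recycle_x, rx, tolerance = 1e-12)
  expect_equal(br$terms$recycle_y, ry, tolerance = 1e-12)
  expect_equal(br$terms$recurrent_x, tx, tolerance = 1e-12)
  expect_equal(br$terms$recurrent_y, ty, tolerance = 1e-12)
  expect_equal(br$total,
               br$terms$gan_AB + br$terms$gan_BA + 0.5 * rx + 50 * ry +
                 1 * tx + 100 * ty, tolerance = 1e-10)
  expect_null(br$terms$cycle)
  # all lambdas zero: adversarial terms only
  w0 <- loss_weights(0, 0, 0, 0, 0)
  br0 <- recyclegan_objective(batch, models, w0, w = 2)
  expect_equal(br0$total, br0$terms$gan_AB + br0$terms$gan_BA, tolerance = 1e-12)
  # identity generators + perfect predictors zero all non-adversarial terms
  ident <- function(f) f
  pm <- within(models, {
    g_ab <- ident; g_ba <- ident
    p_a <- function(fr) fr[[2]]; p_b <- function(fr) fr[[2]]
  })
  batch_const <- list(a = list(lapply(1:3, function(i) matrix(2, 2, 2))),
                      b = list(lapply(1:3, function(i) matrix(3, 2, 2))))
  brc <- recyclegan_objective(batch_const, pm, w, w = 2)
  expect_equal(unlist(brc$terms[c("recycle_x", "recycle_y",
                                  "recurrent_x", "recurrent_y")]),
               c(recycle_x = 0, recycle_y = 0, recurrent_x = 0, recurrent_y = 0))
  expect_error(recyclegan_objective(list(a = list(mk_win()[1:2]), b = batch$b),
                                    models, w, w = 2), "w\\+1")
})

test_that("objectives are invariant to batch item permutation", {
  set.seed(8)
  batch <- list(a = lapply(1:3, function(i) matrix(rnorm(4), 2)),
                b = lapply(1:3, function(i) matrix(rnorm(4), 2)))
  models <- list(g_ab = function(f) f + 0.1, g_ba = function(f) f - 0.1,
                 d_a = function(f) plogis(mean(f)), d_b = function(f) plogis(sum(f)))
  b1 <- cyclegan_objective(batch, models)
  b2 <- cyclegan_objective(list(a = batch$a[c(3, 1, 2)], b = batch$b[c(2, 3, 1)]),
                           models)
  expect_equal(b1$total, b2$total, tolerance = 1e-12)
})
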