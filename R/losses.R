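#' Loss weights for the two objectives
#'
#' The coefficients weighting the non-adversarial terms. Defaults are the
#' published settings: `lambda_cycle = 10` for the cycle-consistency term of
#' the spatial objective, and `lambda_rx = 0.5`, `lambda_ry = 50`,
#' `lambda_tau_x = 1`, `lambda_tau_y = 100` for the recycle and recurrent
#' terms of the spatiotemporal objective (x = low-dose domain A,
#' y = full-dose domain B).
#'
#' @param lambda_cycle,lambda_rx,lambda_ry,lambda_tau_x,lambda_tau_y
#'   nonnegative reals.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_cycle = 10, lambda_rx = 0.5, lambda_ry = 50,
                         lambda_tau_x = 1, lambda_tau_y = 100) {
  w <- list(lambda_cycle = lambda_cycle, lambda_rx = lambda_rx,
            lambda_ry = lambda_ry, lambda_tau_x = lambda_tau_x,
            lambda_tau_y = lambda_tau_y)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  structure(w, class = "loss_weights")
}

# numerical guard keeping log() finite on discriminator scores
.gan_eps <- 1e-7

clamp_scores <- function(s) pmin(pmax(s, .gan_eps), 1 - .gan_eps)

#' Adversarial (vanilla GAN) loss
#'
#' The printed log-likelihood objective: `mean(log d_real) +
#' mean(log(1 - d_fake))`. The discriminator maximizes the whole expression;
#' the generator minimizes the fake term. Score maps from a patch
#' discriminator contribute every entry as an independent score. Scores are
#' clamped into `[eps, 1 - eps]` (eps = 1e-7) so the logs stay finite.
#'
#' @param d_real,d_fake discriminator scores in (0, 1): numeric vectors,
#'   matrices (patch score maps), or lists thereof.
#' @return Scalar loss value.
#' @examples
#' adversarial_loss(0.5, 0.5)   # 2 * log(0.5)
#' @export
adversarial_loss <- function(d_real, d_fake) {
  real <- unlist(d_real, use.names = FALSE)
  fake <- unlist(d_fake, use.names = FALSE)
  if (length(real) == 0L || length(fake) == 0L)
    stop("empty discriminator score list", call. = FALSE)
  mean(log(clamp_scores(real))) + mean(log1p(-clamp_scores(fake)))
}

check_same_shape <- function(x, y, what) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop(sprintf("shape mismatch in %s", what), call. = FALSE)
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between each input frame and its round-trip
#' reconstruction through both generators, summed over the two cycle
#' directions: `mean|a - G_BA(G_AB(a))| + mean|b - G_AB(G_BA(b))|`.
#' Reductions are means over pixels, so the value is resolution-invariant.
#'
#' @param a,b input frames from domains A and B.
#' @param a_reconstructed,b_reconstructed their round-trip reconstructions.
#' @return Scalar loss value.
#' @export
cycle_consistency_loss <- function(a, a_reconstructed, b, b_reconstructed) {
  check_same_shape(a, a_reconstructed, "cycle pair (a)")
  check_same_shape(b, b_reconstructed, "cycle pair (b)")
  mean(abs(a - a_reconstructed)) + mean(abs(b - b_reconstructed))
}

# valid prediction time points: every t on a looped sequence (targets wrap),
# t = w..T-1 otherwise
prediction_times <- function(seq, w) {
  T_ <- seq$phase_count
  if (seq$looped) return(seq_len(T_))
  if (T_ < w + 1L)
    stop(sprintf("non-looped sequence of %d phases too short for window w=%d plus target",
                 T_, w), call. = FALSE)
  w:(T_ - 1L)
}

#' Recurrent (temporal prediction) loss
#'
#' Squared error of a within-domain temporal predictor: for each valid time
#' point `t`, the predictor maps the chronological window of `w` frames
#' ending at `t` to a forecast of frame `t+1`; the loss is the mean over
#' pixels and over time points of the squared difference.
#'
#' @param seq a [phase_sequence()].
#' @param predictor function taking a list of `w` frames, returning one frame.
#' @param w window length.
#' @return Scalar loss value.
#' @export
recurrent_loss <- function(seq, predictor, w = 2L) {
  ts <- prediction_times(seq, w)
  errs <- vapply(ts, function(t) {
    target <- seq$frames[[next_phase(seq, t)]]
    pred <- predictor(frame_window(seq, t, w))
    check_same_shape(target, pred, "predictor output")
    mean((target - pred)^2)
  }, numeric(1))
  mean(errs)
}

#' Recycle (cross-domain spatiotemporal) loss
#'
#' The cross-domain consistency term: translate the window frame-by-frame
#' with `g_fwd`, forecast the next translated frame with the target-domain
#' predictor, translate back with `g_bwd`, and penalize the squared
#' difference to the true next frame; mean over pixels and time points.
#' With identity generators it reduces exactly to [recurrent_loss()].
#'
#' @param seq a [phase_sequence()].
#' @param g_fwd,g_bwd frame-to-frame generator functions.
#' @param predictor_target target-domain predictor (list of `w` frames to one).
#' @param w window length.
#' @return Scalar loss value.
#' @export
recycle_loss <- function(seq, g_fwd, g_bwd, predictor_target, w = 2L) {
  ts <- prediction_times(seq, w)
  errs <- vapply(ts, function(t) {
    target <- seq$frames[[next_phase(seq, t)]]
    translated <- lapply(frame_window(seq, t, w), g_fwd)
    back <- g_bwd(predictor_target(translated))
    check_same_shape(target, back, "recycle output")
    mean((target - back)^2)
  }, numeric(1))
  mean(errs)
}

new_loss_breakdown <- function(terms, total) {
  structure(list(total = total, terms = terms), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("<loss_breakdown> total =", format(x$total), "\n")
  for (nm in names(x$terms)) cat(sprintf("  %-12s %s\n", nm, format(x$terms[[nm]])))
  invisible(x)
}

#' Flatten a loss breakdown to a one-row data frame
#'
#' Used by the training loggers to stream per-step records to CSV/JSON-lines.
#'
#' @param x a `loss_breakdown`.
#' @return One-row data frame with `total` and one column per term.
#' @export
as.data.frame.loss_breakdown <- function(x, ...) {
  as.data.frame(c(list(total = x$total), x$terms))
}

check_batch_domains <- function(batch) {
  if (is.null(batch$a) || is.null(batch$b) ||
      length(batch$a) == 0L || length(batch$b) == 0L)
    stop("batch must contain non-empty `a` (low-dose) and `b` (full-dose) entries",
         call. = FALSE)
}

#' Full spatial (CycleGAN-style) objective
#'
#' `total = gan_AB + gan_BA + lambda_cycle * cycle`. The adversarial terms
#' use the printed log-likelihood form over all batch items; the cycle term
#' averages the per-item cycle-consistency losses.
#'
#' @param batch list with `a` and `b`: lists of frames from each domain.
#' @param models list with callables `g_ab`, `g_ba`, `d_a`, `d_b`.
#' @param weights a [loss_weights()].
#' @return A `loss_breakdown` with terms `gan_AB`, `gan_BA`, `cycle`.
#' @export
cyclegan_objective <- function(batch, models, weights = loss_weights()) {
  check_batch_domains(batch)
  fake_b <- lapply(batch$a, models$g_ab)
  fake_a <- lapply(batch$b, models$g_ba)
  gan_ab <- adversarial_loss(lapply(batch$b, models$d_b), lapply(fake_b, models$d_b))
  gan_ba <- adversarial_loss(lapply(batch$a, models$d_a), lapply(fake_a, models$d_a))
  cyc <- mean(vapply(seq_along(batch$a), function(i) {
    mean(abs(batch$a[[i]] - models$g_ba(fake_b[[i]])))
  }, numeric(1))) +
    mean(vapply(seq_along(batch$b), function(i) {
      mean(abs(batch$b[[i]] - models$g_ab(fake_a[[i]])))
    }, numeric(1)))
  terms <- list(gan_AB = gan_ab, gan_BA = gan_ba, cycle = cyc)
  new_loss_breakdown(terms, gan_ab + gan_ba + weights$lambda_cycle * cyc)
}

#' Full spatiotemporal (RecycleGAN-style) objective
#'
#' `total = gan_AB + gan_BA + lambda_rx * recycle_x + lambda_ry * recycle_y
#' + lambda_tau_x * recurrent_x + lambda_tau_y * recurrent_y`; there is no
#' plain cycle term. `recycle_x` is the low-dose-domain recycle loss
#' (translate with G_AB, predict with P_B, map back with G_BA) and
#' `recurrent_x` the within-domain prediction loss of P_A; `*_y` mirror them
#' on the full-dose domain.
#'
#' @param batch list with `a` and `b`: lists of windows, each window a
#'   chronological list of `w + 1` frames (the window plus the true next
#'   frame as prediction target).
#' @param models list with callables `g_ab`, `g_ba`, `d_a`, `d_b`, `p_a`, `p_b`.
#' @param weights a [loss_weights()].
#' @param w window length consumed by the predictors.
#' @return A `loss_breakdown` with terms `gan_AB`, `gan_BA`, `recycle_x`,
#'   `recycle_y`, `recurrent_x`, `recurrent_y`.
#' @export
recyclegan_objective <- function(batch, models, weights = loss_weights(), w = 2L) {
  check_batch_domains(batch)
  ok <- vapply(c(batch$a, batch$b), function(win) length(win) >= w + 1L, logical(1))
  if (!all(ok))
    stop(sprintf("every window must hold at least w+1 = %d frames", w + 1L),
         call. = FALSE)
  win_in <- function(win) win[seq_len(w)]
  win_tgt <- function(win) win[[w + 1L]]

  fake_b <- lapply(batch$a, function(win) lapply(win, models$g_ab))
  fake_a <- lapply(batch$b, function(win) lapply(win, models$g_ba))
  gan_ab <- adversarial_loss(lapply(batch$b, function(win) lapply(win, models$d_b)),
                             lapply(fake_b, function(win) lapply(win, models$d_b)))
  gan_ba <- adversarial_loss(lapply(batch$a, function(win) lapply(win, models$d_a)),
                             lapply(fake_a, function(win) lapply(win, models$d_a)))
  rec_term <- function(wins, fakes, g_back, pred) {
    mean(vapply(seq_along(wins), function(i) {
      back <- g_back(pred(fakes[[i]][seq_len(w)]))
      mean((win_tgt(wins[[i]]) - back)^2)
    }, numeric(1)))
  }
  recycle_x <- rec_term(batch$a, fake_b, models$g_ba, models$p_b)
  recycle_y <- rec_term(batch$b, fake_a, models$g_ab, models$p_a)
  tau_term <- function(wins, pred) {
    mean(vapply(wins, function(win) {
      mean((win_tgt(win) - pred(win_in(win)))^2)
    }, numeric(1)))
  }
  recurrent_x <- tau_term(batch$a, models$p_a)
  recurrent_y <- tau_term(batch$b, models$p_b)
  terms <- list(gan_AB = gan_ab, gan_BA = gan_ba,
                recycle_x = recycle_x, recycle_y = recycle_y,
                recurrent_x = recurrent_x, recurrent_y = recurrent_y)
  total <- gan_ab + gan_ba + weights$lambda_rx * recycle_x +
    weights$lambda_ry * recycle_y + weights$lambda_tau_x * recurrent_x +
    weights$lambda_tau_y * recurrent_y
  new_loss_breakdown(terms, total)
}
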