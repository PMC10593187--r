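# Independent oracle implementations used to pin down the package's
# numerics. These are deliberately naive (explicit loops, direct formulas)
# and share no code with the implementation under test.

# mean squared error by explicit pixel loop
oracle_mse <- function(x, y) {
  s <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    s <- s + (x[i, j] - y[i, j])^2
  s / (nrow(x) * ncol(x))
}

oracle_psnr <- function(x, y, maxv = 4095) {
  m <- oracle_mse(x, y)
  if (m == 0) Inf else 10 * log10(maxv^2 / m)
}

# direct luminance * contrast * structure product, sample (n-1) moments
oracle_ssim <- function(x, y, k1 = 0.01, k2 = 0.03, L = 4095) {
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2; c3 <- c2 / 2
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / (n - 1); vy <- sum((y - my)^2) / (n - 1)
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  l <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  cc <- (2 * sqrt(vx) * sqrt(vy) + c2) / (vx + vy + c2)
  s <- (cxy + c3) / (sqrt(vx) * sqrt(vy) + c3)
  l * cc * s
}

# brute-force run scan for frame selection: phase p qualifies for a class if
# some contiguous (optionally wrapping) block of >= k phases all satisfying
# the class threshold contains p
oracle_select <- function(stds, low_min, full_max, k, looped) {
  T_ <- length(stds)
  qualify <- function(mask) {
    sel <- logical(T_)
    idx_at <- function(start, len) (((start - 1L):(start + len - 2L)) %% T_) + 1L
    max_start <- if (looped) T_ else T_ - k + 1L
    if (max_start < 1L) return(integer(0))
    for (start in seq_len(max_start)) {
      for (len in k:T_) {
        if (!looped && start + len - 1L > T_) break
        ids <- idx_at(start, len)
        if (all(mask[ids])) sel[ids] <- TRUE else break
      }
    }
    which(sel)
  }
  list(low_dose = qualify(stds > low_min), full_dose = qualify(stds < full_max))
}

# naive direct convolution (stride s, zero 'same' padding) for the nn engine
oracle_conv <- function(x, W, b, k, stride) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  cout <- ncol(W)
  p <- (k - 1) %/% 2
  oh <- H %/% stride; ow <- Wd %/% stride
  out <- array(0, c(oh, ow, cout))
  for (oi in seq_len(oh)) for (oj in seq_len(ow)) for (co in seq_len(cout)) {
    acc <- b[co]
    for (di in 0:(k - 1)) for (dj in 0:(k - 1)) for (ci in seq_len(C)) {
      ri <- stride * (oi - 1) + 1 + di - p
      cj <- stride * (oj - 1) + 1 + dj - p
      v <- if (ri >= 1 && ri <= H && cj >= 1 && cj <= Wd) x[ri, cj, ci] else 0
      # weight row order: di fastest, then dj, then input channel
      wrow <- 1 + di + k * dj + k * k * (ci - 1)
      acc <- acc + v * W[wrow, co]
    }
    out[oi, oj, co] <- acc
  }
  out
}

# small deterministic test sequences ------------------------------------

scalar_seq <- function(values, looped = FALSE) {
  phase_sequence(lapply(values, function(v) matrix(v, 1, 1)),
                 intensity_scale = "hu", looped = looped)
}

random_seq <- function(T_ = 4, d = 4, looped = TRUE, seed = 1) {
  set.seed(seed)
  phase_sequence(lapply(seq_len(T_), function(t) matrix(rnorm(d * d), d, d)),
                 intensity_scale = "hu", looped = looped)
}

tiny_cohort <- function(n_pairs = 2, size = 32, seed = 17)
  generate_cohort(n_pairs = n_pairs, master_seed = seed, image_size = size)

mean_seq_psnr <- function(cand, ref) {
  mean(vapply(seq_len(cand$phase_count), function(t)
    psnr(cand$frames[[t]], ref$frames[[t]]), numeric(1)))
}
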