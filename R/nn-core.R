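# Minimal convolutional-network engine: im2col forward passes, hand-written
# backprop and Adam, sized for tiny CPU-trainable models on small frames.
# Images are arrays (H, W, C) handled internally as (H*W) x C matrices;
# gather/scatter index vectors are cached per (H, W, k, stride).

.conv_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, k, stride) {
  key <- paste(H, W, k, stride, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (H %% stride != 0L || W %% stride != 0L)
    stop(sprintf("image size %dx%d not divisible by stride %d", H, W, stride),
         call. = FALSE)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  oh <- H %/% stride; ow <- W %/% stride
  i <- rep(seq_len(oh), times = ow)
  j <- rep(seq_len(ow), each = oh)
  base_r <- stride * (i - 1L) + 1L
  base_c <- stride * (j - 1L) + 1L
  idx <- matrix(0L, oh * ow, k * k)
  q <- 0L
  for (dj in 0L:(k - 1L)) for (di in 0L:(k - 1L)) {
    q <- q + 1L
    idx[, q] <- (base_r + di) + (base_c + dj - 1L) * Hp
  }
  # column order q = 1 + di + k*dj matches the weight-row layout
  # (row offset fastest, then column offset, then input channel)
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  interior <- (r + p) + (cc + p - 1L) * Hp
  out <- list(idxvec = as.integer(idx), npix = oh * ow, k2 = k * k,
              Hp = Hp, Wp = Wp, oh = oh, ow = ow, interior = interior)
  .conv_cache[[key]] <- out
  out
}

act_forward <- function(z, act) {
  switch(act,
    linear  = z,
    lrelu   = ifelse(z > 0, z, 0.2 * z),
    abs     = abs(z),
    sigmoid = 1 / (1 + exp(-z)),
    tanh    = tanh(z),
    stop("unknown activation ", act))
}

act_backward <- function(dy, z, y, act) {
  switch(act,
    linear  = dy,
    lrelu   = dy * ifelse(z > 0, 1, 0.2),
    abs     = dy * sign(z),
    sigmoid = dy * y * (1 - y),
    tanh    = dy * (1 - y^2),
    stop("unknown activation ", act))
}

# instance normalization: each channel map standardized over its pixels;
# removes the large DC/content component so the small noise features the
# discriminators must detect are not drowned at initialization
.in_eps <- 1e-5

inorm_fw <- function(z) {
  m <- colMeans(z)
  zc <- z - rep(m, each = nrow(z))
  s <- sqrt(colMeans(zc^2) + .in_eps)
  list(zh = zc / rep(s, each = nrow(z)), s = s)
}

inorm_bw <- function(dzh, zh, s) {
  md <- colMeans(dzh)
  mdz <- colMeans(dzh * zh)
  (dzh - rep(md, each = nrow(dzh)) - zh * rep(mdz, each = nrow(dzh))) /
    rep(s, each = nrow(dzh))
}

conv_fw <- function(x, p, k, stride, act, norm = FALSE, keep = FALSE) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  ci <- conv_indices(H, W, k, stride)
  xm <- x; dim(xm) <- c(H * W, C)
  xp <- matrix(0, ci$Hp * ci$Wp, C)
  xp[ci$interior, ] <- xm
  M <- xp[ci$idxvec, , drop = FALSE]
  dim(M) <- c(ci$npix, ci$k2 * C)
  cout <- ncol(p$W)
  z <- M %*% p$W + rep(p$b, each = ci$npix)
  nrm <- if (norm) inorm_fw(z) else NULL
  zin <- if (norm) nrm$zh else z
  y <- act_forward(zin, act)
  out <- y; dim(out) <- c(ci$oh, ci$ow, cout)
  if (!keep) return(list(y = out))
  list(y = out, cache = list(M = M, z = zin, ym = y, nrm = nrm,
                             ci = ci, H = H, W = W, C = C))
}

conv_bw <- function(dy, cache, p, act) {
  ci <- cache$ci
  dym <- dy; dim(dym) <- dim(cache$z)
  dz <- act_backward(dym, cache$z, cache$ym, act)
  if (!is.null(cache$nrm)) dz <- inorm_bw(dz, cache$z, cache$nrm$s)
  dW <- crossprod(cache$M, dz)
  db <- colSums(dz)
  dM <- dz %*% t(p$W)
  dim(dM) <- c(ci$npix * ci$k2, cache$C)
  rs <- rowsum(dM, ci$idxvec)
  dxp <- matrix(0, ci$Hp * ci$Wp, cache$C)
  dxp[as.integer(rownames(rs)), ] <- rs
  dx <- dxp[ci$interior, , drop = FALSE]
  dim(dx) <- c(cache$H, cache$W, cache$C)
  list(dx = dx, grads = list(W = dW, b = db))
}

.up_cache <- new.env(parent = emptyenv())

up_indices <- function(H, W) {
  key <- paste(H, W, sep = "_")
  hit <- .up_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- rep(seq_len(2L * H), times = 2L * W)
  j <- rep(seq_len(2L * W), each = 2L * H)
  src <- ((i + 1L) %/% 2L) + (((j + 1L) %/% 2L) - 1L) * H
  .up_cache[[key]] <- src
  src
}

up_fw <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  src <- up_indices(H, W)
  xm <- x; dim(xm) <- c(H * W, C)
  y <- xm[src, , drop = FALSE]
  dim(y) <- c(2L * H, 2L * W, C)
  y
}

up_bw <- function(dy, H, W) {
  d <- dim(dy); C <- d[3L]
  src <- up_indices(H, W)
  dym <- dy; dim(dym) <- c(4L * H * W, C)
  dx <- rowsum(dym, src)   # groups 1..H*W, all present, sorted
  dim(dx) <- c(H, W, C)
  dx
}

# ---- layer stacks -------------------------------------------------------

# fan-in-scaled (He) initialization: without normalization layers the fixed
# small-SD convention fails to propagate signal in these tiny nets
init_conv_params <- function(k, cin, cout, zero_init = FALSE) {
  fan_in <- k * k * cin
  W <- if (zero_init) matrix(0, fan_in, cout)
       else matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  list(W = W, b = numeric(cout))
}

net_init <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      conv = init_conv_params(l$k, l$cin, l$cout, isTRUE(l$zero_init)),
      res  = list(c1 = init_conv_params(3L, l$width, l$width),
                  c2 = init_conv_params(3L, l$width, l$width)),
      up   = list(),
      center = list())
  })
}

net_forward <- function(layers, params, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_fw(x, params[[i]], l$k, l$stride, l$act, isTRUE(l$norm), keep)
      if (keep) caches[[i]] <- r$cache
      x <- r$y
    } else if (l$type == "res") {
      r1 <- conv_fw(x, params[[i]]$c1, 3L, 1L, "lrelu", TRUE, keep)
      r2 <- conv_fw(r1$y, params[[i]]$c2, 3L, 1L, "linear", TRUE, keep)
      if (keep) caches[[i]] <- list(c1 = r1$cache, c2 = r2$cache)
      x <- x + r2$y
    } else if (l$type == "up") {
      if (keep) caches[[i]] <- dim(x)
      x <- up_fw(x)
    } else if (l$type == "center") {
      # subtract the global mean: makes the stack insensitive to DC shifts,
      # closing the drift direction an adversary could otherwise exploit
      x <- x - mean(x)
    }
  }
  list(y = x, caches = caches)
}

net_backward <- function(layers, params, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_bw(dy, caches[[i]], params[[i]], l$act)
      grads[[i]] <- r$grads
      dy <- r$dx
    } else if (l$type == "res") {
      r2 <- conv_bw(dy, caches[[i]]$c2, params[[i]]$c2, "linear")
      r1 <- conv_bw(r2$dx, caches[[i]]$c1, params[[i]]$c1, "lrelu")
      grads[[i]] <- list(c1 = r1$grads, c2 = r2$grads)
      dy <- dy + r1$dx
    } else if (l$type == "up") {
      d <- caches[[i]]
      grads[[i]] <- list()
      dy <- up_bw(dy, d[1L], d[2L])
    } else if (l$type == "center") {
      grads[[i]] <- list()
      dy <- dy - mean(dy)
    }
  }
  list(dx = dy, grads = grads)
}

# elementwise walk over congruent nested parameter lists
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else f(a)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(`+`, a, b)
}

grads_scale <- function(g, s) tree_map(function(x) x * s, g)

param_count <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(params)
  n
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

clamp_unit <- function(z) pmin(pmax(z, -1), 1)
clamp_unit_bw <- function(dy, z) dy * (z > -1 & z < 1)
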