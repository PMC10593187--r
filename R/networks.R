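# Factories for the six learned functions: two generators (G_AB, G_BA), two
# patch discriminators (D_A, D_B), two temporal predictors (P_A, P_B). The
# exact published architectures are delegated to external references, so
# these are configurable approximations: a residual encoder-decoder
# generator, a strided patch classifier, and a generator-style predictor
# over channel-concatenated input frames.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

new_network_fn <- function(env, call_fn, class) {
  f <- function(...) call_fn(env, ...)
  attr(f, "env") <- env
  class(f) <- c(class, "network_fn", "function")
  f
}

nn_env <- function(f) attr(f, "env")

#' Inspect and modify network functions
#'
#' Every factory returns a plain callable carrying its parameter store in an
#' attached environment. `network_params` extracts the (nested) parameter
#' list, `network_params<-` replaces it (shapes must match),
#' `network_parameter_count` counts scalar weights, and `network_config`
#' returns the construction config including the seed.
#'
#' @param f a network function from [make_generator()],
#'   [make_discriminator()] or [make_predictor()].
#' @param value replacement parameter list.
#' @return See individual descriptions.
#' @export
network_params <- function(f) nn_env(f)$params

#' @rdname network_params
#' @export
`network_params<-` <- function(f, value) {
  e <- nn_env(f)
  e$params <- value
  f
}

#' @rdname network_params
#' @export
network_parameter_count <- function(f) param_count(nn_env(f)$params)

#' @rdname network_params
#' @export
network_config <- function(f) {
  e <- nn_env(f)
  c(e$config, list(seed = e$seed, kind = e$kind))
}

check_divisible <- function(image_size, levels, what) {
  fac <- 2L^levels
  if (any(image_size %% fac != 0L))
    stop(sprintf("%s image size %s not divisible by the downsampling factor %d",
                 what, paste(image_size, collapse = "x"), fac), call. = FALSE)
}

#' Configurations for the learned networks
#'
#' The `"tiny"` defaults (base width 16, 2 residual blocks, 1 downsampling
#' level) train on CPU at 32x32 in minutes and are the profile used
#' throughout the test suite.
#'
#' @param width base channel width.
#' @param depth number of residual blocks (generator) .
#' @param levels number of stride-2 downsampling levels; frames must be
#'   divisible by `2^levels`.
#' @param image_size frame side length the network will be applied to
#'   (divisibility is checked at construction, not at first call).
#' @param n_layers number of stride-2 layers in the discriminator.
#' @param w predictor window length (frames consumed per prediction).
#' @return A config list.
#' @export
generator_config <- function(width = 16L, depth = 2L, levels = 1L,
                             image_size = 32L) {
  list(width = as.integer(width), depth = as.integer(depth),
       levels = as.integer(levels), image_size = as.integer(image_size))
}

#' @rdname generator_config
#' @export
discriminator_config <- function(width = 16L, n_layers = 2L, image_size = 32L) {
  list(width = as.integer(width), n_layers = as.integer(n_layers),
       image_size = as.integer(image_size))
}

#' @rdname generator_config
#' @export
predictor_config <- function(width = 16L, w = 2L, image_size = 32L) {
  list(width = as.integer(width), w = as.integer(w),
       image_size = as.integer(image_size))
}

frame_to_a3 <- function(frame) {
  if (is.null(dim(frame)) || length(dim(frame)) != 2L)
    stop("network input must be a 2D frame", call. = FALSE)
  array(frame, c(dim(frame), 1L))
}

# forward through the residual trunk with a global identity skip and a hard
# [-1, 1] clamp, so a zero-initialized final conv makes the map the identity.
# The residual branch is centered (mean-free), making the generator exactly
# mean-preserving: the frame's DC level is a loss-flat direction for the
# adversarial game and would otherwise random-walk under Adam; pinning it
# also preserves quantitative HU levels through denoising.
skip_fw <- function(e, x3, keep = FALSE) {
  r <- net_forward(e$layers, e$params, x3, keep)
  z <- x3 + (r$y - mean(r$y))
  list(y = clamp_unit(z), z = z, caches = r$caches)
}

skip_bw <- function(e, fw, dy) {
  dz <- clamp_unit_bw(dy, fw$z)
  r <- net_backward(e$layers, e$params, fw$caches, dz - mean(dz))
  list(dx = dz + r$dx, grads = r$grads)
}

#' Create a generator network
#'
#' A residual encoder-decoder acting frame-to-frame on the model scale
#' `[-1, 1]`: a lifting convolution, `levels` stride-2 downsamplings,
#' `depth` residual blocks, nearest-neighbor upsampling back to full
#' resolution, and a zero-initialized output convolution feeding a global
#' identity skip with a hard `[-1, 1]` output bound — so a freshly built
#' generator is exactly the identity map, a stable starting point for
#' adversarial training. Deterministic given `(config, seed)`.
#'
#' @param config a [generator_config()].
#' @param seed integer seed for weight initialization.
#' @return A callable `frame -> frame` (see [network_params()] for access
#'   to its weights).
#' @export
make_generator <- function(config = generator_config(), seed = 1L) {
  check_divisible(config$image_size, config$levels, "generator")
  w <- config$width
  layers <- list(list(type = "conv", k = 3L, stride = 1L, cin = 1L, cout = w,
                      act = "lrelu", norm = TRUE))
  for (i in seq_len(config$levels))
    layers <- c(layers, list(list(type = "conv", k = 3L, stride = 2L, cin = w,
                                  cout = w, act = "lrelu", norm = TRUE)))
  for (i in seq_len(config$depth))
    layers <- c(layers, list(list(type = "res", width = w)))
  for (i in seq_len(config$levels))
    layers <- c(layers, list(list(type = "up"),
                             list(type = "conv", k = 3L, stride = 1L, cin = w,
                                  cout = w, act = "lrelu", norm = TRUE)))
  layers <- c(layers, list(list(type = "conv", k = 3L, stride = 1L, cin = w,
                                cout = 1L, act = "linear", zero_init = TRUE)))
  e <- new.env(parent = emptyenv())
  e$layers <- layers
  e$params <- with_seed(seed, net_init(layers))
  e$config <- config
  e$seed <- seed
  e$kind <- "generator"
  call_fn <- function(env, frame) {
    x3 <- frame_to_a3(frame)
    check_divisible(dim(x3)[1:2], env$config$levels, "generator")
    y <- skip_fw(env, x3)$y
    matrix(y, dim(y)[1L], dim(y)[2L])
  }
  new_network_fn(e, call_fn, "generator_fn")
}

#' Create a patch discriminator network
#'
#' A strided convolutional classifier emitting a patch score map in (0, 1)
#' (sigmoid output); every map entry is consumed as an independent score by
#' [adversarial_loss()]. Deterministic given `(config, seed)`.
#'
#' The input is centered (global mean subtracted) so the critic cannot
#' reward DC drift, and the first stage is a full-wave rectified (absolute
#' value) filter bank — a local amplitude/energy detector. The dose domains
#' of CT differ chiefly in noise energy, and an energy-detecting critic both
#' learns that difference within a short run and is hard for the generator
#' to fool without genuinely changing local noise energy.
#'
#' @param config a [discriminator_config()].
#' @param seed integer seed for weight initialization.
#' @return A callable `frame -> score map`.
#' @export
make_discriminator <- function(config = discriminator_config(), seed = 1L) {
  check_divisible(config$image_size, config$n_layers, "discriminator")
  w <- config$width
  layers <- list(list(type = "center"),
                 list(type = "conv", k = 3L, stride = 1L, cin = 1L, cout = w,
                      act = "abs"))
  cin <- w
  for (i in seq_len(config$n_layers)) {
    cout <- w * 2L^(i - 1L)
    layers <- c(layers, list(list(type = "conv", k = 3L, stride = 2L, cin = cin,
                                  cout = cout, act = "lrelu")))
    cin <- cout
  }
  layers <- c(layers, list(list(type = "conv", k = 3L, stride = 1L, cin = cin,
                                cout = 1L, act = "sigmoid")))
  e <- new.env(parent = emptyenv())
  e$layers <- layers
  e$params <- with_seed(seed, net_init(layers))
  e$config <- config
  e$seed <- seed
  e$kind <- "discriminator"
  call_fn <- function(env, frame) {
    x3 <- frame_to_a3(frame)
    check_divisible(dim(x3)[1:2], env$config$n_layers, "discriminator")
    y <- net_forward(env$layers, env$params, x3)$y
    matrix(y, dim(y)[1L], dim(y)[2L])
  }
  new_network_fn(e, call_fn, "discriminator_fn")
}

#' Receptive field of a discriminator
#'
#' Closed-form receptive field (in input pixels) of one entry of the patch
#' score map, from the standard kernel/stride recurrence.
#'
#' @param f a discriminator from [make_discriminator()].
#' @return Integer receptive-field side length.
#' @export
receptive_field <- function(f) {
  rf <- 1L; jump <- 1L
  for (l in nn_env(f)$layers) {
    if (l$type != "conv") next
    rf <- rf + (l$k - 1L) * jump
    jump <- jump * l$stride
  }
  rf
}

#' Create a temporal predictor network
#'
#' Maps a chronological window of `w` frames to a forecast of the next
#' frame. The frames are channel-concatenated and passed through a
#' generator-style trunk whose zero-initialized output feeds an identity
#' skip from the most recent frame — a fresh predictor is therefore the
#' persistence forecast (next frame = last frame). Deterministic given
#' `(config, seed)`.
#'
#' @param config a [predictor_config()].
#' @param seed integer seed for weight initialization.
#' @return A callable `list of w frames -> frame`; calling it with a
#'   different number of frames is an error naming the expected `w`.
#' @export
make_predictor <- function(config = predictor_config(), seed = 1L) {
  if (config$w < 1L) stop("predictor window w must be >= 1", call. = FALSE)
  w <- config$width
  layers <- list(
    list(type = "conv", k = 3L, stride = 1L, cin = config$w, cout = w,
         act = "lrelu", norm = TRUE),
    list(type = "res", width = w),
    list(type = "conv", k = 3L, stride = 1L, cin = w, cout = 1L,
         act = "linear", zero_init = TRUE))
  e <- new.env(parent = emptyenv())
  e$layers <- layers
  e$params <- with_seed(seed, net_init(layers))
  e$config <- config
  e$seed <- seed
  e$kind <- "predictor"
  call_fn <- function(env, frames) {
    y <- pred_fw(env, pred_stack(env, frames))$y
    matrix(y, dim(y)[1L], dim(y)[2L])
  }
  new_network_fn(e, call_fn, "predictor_fn")
}

pred_stack <- function(e, frames) {
  if (!is.list(frames) || length(frames) != e$config$w)
    stop(sprintf("predictor expects a list of exactly w = %d frames, got %d",
                 e$config$w, length(frames)), call. = FALSE)
  d <- dim(frames[[1L]])
  array(unlist(frames, use.names = FALSE), c(d, e$config$w))
}

pred_fw <- function(e, x3, keep = FALSE) {
  r <- net_forward(e$layers, e$params, x3, keep)
  last <- x3[, , e$config$w, drop = FALSE]
  z <- last + r$y
  list(y = clamp_unit(z), z = z, caches = r$caches)
}

pred_bw <- function(e, fw, dy, x3) {
  dz <- clamp_unit_bw(dy, fw$z)
  r <- net_backward(e$layers, e$params, fw$caches, dz)
  dx <- r$dx
  dx[, , e$config$w] <- dx[, , e$config$w] + dz[, , 1L]
  list(dx = dx, grads = r$grads)
}

# ---- checkpoints --------------------------------------------------------

#' Save and restore model checkpoints
#'
#' A checkpoint is a single archive holding, for all six networks, the
#' construction config, the initialization seed and the current parameters;
#' loading rebuilds the factories and restores bit-identical behavior.
#'
#' @param models named list of network functions.
#' @param path file path of the checkpoint archive.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the named list of rebuilt network functions.
#' @export
save_checkpoint <- function(models, path) {
  payload <- lapply(models, function(f) {
    e <- nn_env(f)
    list(kind = e$kind, config = e$config, seed = e$seed, params = e$params)
  })
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  out <- lapply(payload, function(p) {
    f <- switch(p$kind,
      generator = make_generator(p$config, p$seed),
      discriminator = make_discriminator(p$config, p$seed),
      predictor = make_predictor(p$config, p$seed),
      stop("unknown network kind in checkpoint: ", p$kind, call. = FALSE))
    network_params(f) <- p$params
    f
  })
  names(out) <- names(payload)
  out
}
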