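#' Ordered multi-phase CT image sequences
#'
#' A `phase_sequence` holds the temporally ordered 2D frames of one slice over
#' the cardiac cycle, together with its intensity-scale convention, a looped
#' flag (phase T is followed by phase 1, one full heart beat) and a dose-domain
#' label. All quantitative metrics in this package operate on the 12-bit raw
#' scale `[0, 4095]`; Hounsfield units map to it as `raw = HU + 1024`, clamped.
#'
#' @param frames list of 2D numeric matrices, all of identical dimensions,
#'   ordered by cardiac phase (phase indices are 1-based).
#' @param intensity_scale `"raw12bit"` (values in `[0, 4095]`) or `"hu"`
#'   (Hounsfield units, fixed offset `raw = HU + 1024`).
#' @param looped logical; if `NULL`, defaults to `TRUE` for 8-phase sequences
#'   (phantom-style looped video) and `FALSE` otherwise.
#' @param domain_label one of `"low_dose"`, `"full_dose"`, `"denoised"`,
#'   `"clean"`.
#' @return An object of class `phase_sequence`.
#' @export
phase_sequence <- function(frames, intensity_scale = "raw12bit",
                           looped = NULL, domain_label = "low_dose") {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(t) frames[, , t])
  }
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of 2D matrices", call. = FALSE)
  frames <- lapply(frames, function(f) {
    if (is.null(dim(f)) || length(dim(f)) != 2L)
      stop("each frame must be a 2D matrix", call. = FALSE)
    storage.mode(f) <- "double"
    f
  })
  d0 <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) identical(dim(f), d0), logical(1))
  if (!all(ok))
    stop(sprintf("frame shape mismatch: frame %d has dim %s, expected %s",
                 which(!ok)[1L], paste(dim(frames[[which(!ok)[1L]]]), collapse = "x"),
                 paste(d0, collapse = "x")), call. = FALSE)
  intensity_scale <- match.arg(intensity_scale, c("raw12bit", "hu"))
  domain_label <- match.arg(domain_label,
                            c("low_dose", "full_dose", "denoised", "clean"))
  T_ <- length(frames)
  if (is.null(looped)) looped <- (T_ == 8L)
  if (intensity_scale == "raw12bit") frames <- lapply(frames, clamp_raw12)
  structure(list(frames = frames,
                 intensity_scale = intensity_scale,
                 looped = isTRUE(looped),
                 domain_label = domain_label,
                 phase_count = T_),
            class = "phase_sequence")
}

#' @export
print.phase_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<phase_sequence> %d phases, %dx%d, scale=%s, looped=%s, domain=%s\n",
              x$phase_count, d[1L], d[2L], x$intensity_scale,
              x$looped, x$domain_label))
  invisible(x)
}

#' @export
length.phase_sequence <- function(x) x$phase_count

clamp_raw12 <- function(f) pmin(pmax(f, 0), 4095)

#' Convert between Hounsfield units and the 12-bit raw scale
#'
#' Fixed affine convention `raw = HU + 1024`, clamped to `[0, 4095]` on the
#' raw side (12-bit CT convention, so air -1000 HU maps to 24).
#'
#' @param hu,raw numeric arrays.
#' @return Numeric array on the other scale.
#' @export
hu_to_raw <- function(hu) clamp_raw12(hu + 1024)

#' @rdname hu_to_raw
#' @export
raw_to_hu <- function(raw) raw - 1024

seq_as_raw <- function(seq) {
  if (seq$intensity_scale == "raw12bit") return(seq$frames)
  lapply(seq$frames, hu_to_raw)
}

#' Map 12-bit raw intensities to the model scale `[-1, 1]` and back
#'
#' Networks consume frames on a symmetric unit scale; the map is the affine
#' `x/2047.5 - 1`. Values outside `[0, 4095]` are clamped with a warning
#' rather than raising, so a stray value never aborts a training run.
#'
#' @param frame 2D numeric array on the 12-bit raw scale.
#' @param m 2D numeric array on the model scale.
#' @return The rescaled array.
#' @examples
#' to_model_scale(matrix(c(0, 4095, 2047.5, 1024), 2))
#' @export
to_model_scale <- function(frame) {
  if (any(frame < 0 | frame > 4095)) {
    warning("values outside [0, 4095] clamped before model-scale conversion",
            call. = FALSE)
    frame <- clamp_raw12(frame)
  }
  frame / 2047.5 - 1
}

#' @rdname to_model_scale
#' @export
from_model_scale <- function(m) clamp_raw12((m + 1) * 2047.5)

#' Chronological window of frames ending at a phase
#'
#' Returns the `w` frames ending at (and including) phase `t`, in
#' chronological order. On a looped sequence indices wrap modulo the phase
#' count, so phase 1 is preceded by phase T; on a non-looped sequence `t >= w`
#' is required.
#'
#' @param seq a [phase_sequence()].
#' @param t 1-based phase index of the last frame of the window.
#' @param w window length (>= 1).
#' @return List of `w` frames, chronological.
#' @export
frame_window <- function(seq, t, w) {
  stopifnot(inherits(seq, "phase_sequence"))
  T_ <- seq$phase_count
  if (t < 1L || t > T_)
    stop(sprintf("phase index t=%d out of range 1..%d", t, T_), call. = FALSE)
  if (w < 1L) stop("window length w must be >= 1", call. = FALSE)
  idx <- (t - w + 1L):t
  if (seq$looped) {
    idx <- ((idx - 1L) %% T_) + 1L
  } else if (t < w) {
    stop(sprintf("window of length %d ending at phase %d needs a looped sequence",
                 w, t), call. = FALSE)
  }
  seq$frames[idx]
}

# index of the phase following t (wraps on looped sequences)
next_phase <- function(seq, t) {
  if (t < seq$phase_count) return(t + 1L)
  if (seq$looped) return(1L)
  stop("phase after the last frame of a non-looped sequence", call. = FALSE)
}

seq_dim <- function(seq) dim(seq$frames[[1L]])

# ---- file I/O -----------------------------------------------------------

#' Read and write phase sequences
#'
#' Two on-disk formats are supported. `"nifti"` writes a NIfTI-1 file
#' (`.nii` or `.nii.gz`) with the phase axis as the last (slowest) axis and a
#' JSON sidecar (`<path>.json`) carrying the looped flag, intensity scale and
#' domain label. `"array_archive"` is the native fixture format: a directory
#' holding `meta.json` plus `frames.dat` (little-endian float64,
#' column-major); integer intensities round-trip bit-exactly in both formats.
#'
#' @param path file (nifti) or directory (array_archive) path.
#' @param format `"nifti"` or `"array_archive"`; inferred from the path
#'   extension when `NULL` (`.nii`/`.nii.gz` vs anything else).
#' @param seq a [phase_sequence()].
#' @return `load_sequence` returns a `phase_sequence`; `save_sequence`
#'   returns `path` invisibly.
#' @export
load_sequence <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (!file.exists(path))
    stop(sprintf("no such file or directory: %s", path), call. = FALSE)
  if (format == "nifti") {
    arr <- nifti_read(path)
    if (length(dim(arr)) == 4L && dim(arr)[3L] == 1L)
      arr <- array(arr, dim(arr)[c(1L, 2L, 4L)])
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    if (length(dim(arr)) != 3L)
      stop(sprintf("NIfTI image has %d axes; expected 2D frames over a trailing phase axis",
                   length(dim(arr))), call. = FALSE)
    meta <- read_sidecar(paste0(path, ".json"))
    phase_sequence(arr,
                   intensity_scale = meta$intensity_scale %||% "raw12bit",
                   looped = meta$looped,
                   domain_label = meta$domain_label %||% "low_dose")
  } else {
    meta_path <- file.path(path, "meta.json")
    dat_path <- file.path(path, "frames.dat")
    if (!file.exists(meta_path) || !file.exists(dat_path))
      stop(sprintf("array archive at %s is missing meta.json or frames.dat", path),
           call. = FALSE)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    n <- prod(meta$dim)
    con <- file(dat_path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
    if (length(vals) != n)
      stop("frames.dat truncated: field `dim` disagrees with payload", call. = FALSE)
    arr <- array(vals, meta$dim)
    phase_sequence(arr, intensity_scale = meta$intensity_scale,
                   looped = meta$looped, domain_label = meta$domain_label)
  }
}

#' @rdname load_sequence
#' @export
save_sequence <- function(seq, path, format = NULL) {
  stopifnot(inherits(seq, "phase_sequence"))
  if (is.null(seq$intensity_scale) || is.na(seq$intensity_scale))
    stop("intensity_scale metadata is unset; refusing to write without a scale",
         call. = FALSE)
  format <- infer_format(path, format)
  arr <- array(unlist(seq$frames, use.names = FALSE),
               c(seq_dim(seq), seq$phase_count))
  meta <- list(intensity_scale = seq$intensity_scale, looped = seq$looped,
               domain_label = seq$domain_label, phase_count = seq$phase_count,
               dim = dim(arr))
  if (format == "nifti") {
    nifti_write(arr, path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
    con <- file(file.path(path, "frames.dat"), "wb")
    writeBin(as.double(arr), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("nifti", "array_archive")))
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "array_archive"
}

read_sidecar <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else list(looped = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- display rendering --------------------------------------------------

#' Display window for rendering
#'
#' An intensity window in HU (e.g. `[-1000, 550]` for thorax display).
#' Windows affect PNG export only — they are rendering parameters, never an
#' input transformation.
#'
#' @param lower,upper window bounds in HU, `lower < upper`.
#' @return An `intensity_window` list.
#' @export
intensity_window <- function(lower = -1000, upper = 550) {
  if (lower >= upper) stop("window lower bound must lie below upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "intensity_window")
}

#' Export a phase as a windowed PNG (visual inspection only)
#'
#' Renders one frame to an 8-bit grayscale PNG under a display window. The
#' export is lossy by construction and is never an input format.
#'
#' @param seq a [phase_sequence()].
#' @param path output PNG path.
#' @param t phase index to render.
#' @param window an [intensity_window()] in HU.
#' @return `path`, invisibly.
#' @export
export_png <- function(seq, path, t = 1L, window = intensity_window()) {
  stopifnot(inherits(seq, "phase_sequence"))
  hu <- raw_to_hu(seq_as_raw(seq)[[t]])
  z <- pmin(pmax((hu - window$lower) / (window$upper - window$lower), 0), 1)
  d <- dim(z)
  grDevices::png(path, width = d[2L], height = d[1L])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(t(z[d[1L]:1, , drop = FALSE]), col = grDevices::gray.colors(256, 0, 1),
                  zlim = c(0, 1), axes = FALSE, useRaster = TRUE)
  invisible(path)
}
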