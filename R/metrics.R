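#' Mean squared error between two frames
#'
#' `(1/mn) * sum((x - y)^2)` over an `m x n` frame; symmetric in its
#' arguments. All paired metrics operate on the 12-bit raw intensity scale.
#'
#' @param x,y 2D numeric arrays of identical shape.
#' @return Scalar MSE.
#' @export
mse <- function(x, y) {
  check_same_shape(x, y, "mse")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(max_value^2 / MSE)` with `max_value = 4095`, the maximum
#' signal value of 12-bit CT images. Identical frames (MSE = 0) report the
#' `Inf` sentinel rather than raising, so identity denoisers pass through
#' aggregation unharmed.
#'
#' @param x,y 2D numeric arrays of identical shape (raw 12-bit scale).
#' @param max_value dynamic range maximum (default 4095).
#' @return PSNR in dB (`Inf` when the frames are identical).
#' @export
psnr <- function(x, y, max_value = 4095) {
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Stabilization constants for SSIM
#'
#' Derived as `c1 = (k1 L)^2`, `c2 = (k2 L)^2`, `c3 = c2 / 2` with the
#' standard `k1 = 0.01`, `k2 = 0.03` and dynamic range `L = 4095` (12-bit).
#' The source text leaves the constants unprinted, so the conventional
#' values are the default; all are overridable.
#'
#' @param k1,k2 small positive constants.
#' @param L dynamic range of the intensity scale.
#' @param c3 structure-term constant; default `c2 / 2`, which collapses the
#'   three-factor `l * c * s` product to the familiar two-factor SSIM formula.
#' @return List with `c1`, `c2`, `c3`.
#' @export
ssim_constants <- function(k1 = 0.01, k2 = 0.03, L = 4095, c3 = NULL) {
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  if (is.null(c3)) c3 <- c2 / 2
  if (any(c(c1, c2, c3) <= 0)) stop("SSIM constants must be positive", call. = FALSE)
  list(c1 = c1, c2 = c2, c3 = c3)
}

ssim_terms <- function(x, y, k) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  l <- (2 * mx * my + k$c1) / (mx^2 + my^2 + k$c1)
  c_ <- (2 * sqrt(vx) * sqrt(vy) + k$c2) / (vx + vy + k$c2)
  s <- (cxy + k$c3) / (sqrt(vx) * sqrt(vy) + k$c3)
  l * c_ * s
}

#' Structural similarity index
#'
#' The product of luminance, contrast and structure comparisons,
#' `SSIM = l(x,y) * c(x,y) * s(x,y)`, computed globally over the whole frame
#' (single window) by default — the formulas are presented without a window
#' size, so no sliding window is assumed. A mean-pooled sliding-window mode
#' (`method = "window"`, 8x8, stride 1) is available for comparability with
#' common toolkits. Variances and covariance use the sample (n-1) convention.
#'
#' @param x,y 2D numeric arrays of identical shape (raw 12-bit scale).
#' @param constants a [ssim_constants()] list.
#' @param method `"global"` (default) or `"window"`.
#' @param window_size side of the square sliding window (window mode only).
#' @return SSIM value in `[-1, 1]`; 1 iff the frames are identical.
#' @export
ssim <- function(x, y, constants = ssim_constants(), method = c("global", "window"),
                 window_size = 8L) {
  check_same_shape(x, y, "ssim")
  method <- match.arg(method)
  if (method == "global") return(ssim_terms(x, y, constants))
  h <- nrow(x); w <- ncol(x)
  if (h < window_size || w < window_size)
    stop("frame smaller than the SSIM window", call. = FALSE)
  vals <- numeric(0)
  for (i in seq_len(h - window_size + 1L)) {
    rows <- i:(i + window_size - 1L)
    vals <- c(vals, vapply(seq_len(w - window_size + 1L), function(j) {
      cols <- j:(j + window_size - 1L)
      ssim_terms(x[rows, cols], y[rows, cols], constants)
    }, numeric(1)))
  }
  mean(vals)
}

#' Rectangular region of interest
#'
#' 0-based, half-open rectangle `[row0, row0 + height) x [col0, col0 + width)`
#' in frame coordinates, as drawn in the aorta for noise measurements.
#'
#' @param row0,col0 0-based top-left corner.
#' @param height,width extent in pixels; area must be at least 2 pixels.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(row0, col0, height, width) {
  if (height < 1L || width < 1L || height * width < 2L)
    stop("ROI must cover at least 2 pixels", call. = FALSE)
  if (row0 < 0L || col0 < 0L) stop("ROI corner must be nonnegative", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

roi_pixels <- function(frame, roi) {
  if (roi$row0 + roi$height > nrow(frame) || roi$col0 + roi$width > ncol(frame))
    stop("ROI extends outside the frame", call. = FALSE)
  frame[(roi$row0 + 1L):(roi$row0 + roi$height),
        (roi$col0 + 1L):(roi$col0 + roi$width)]
}

#' Noise level of a region of interest, in HU
#'
#' Sample standard deviation (n-1 denominator) of the Hounsfield-unit
#' intensities inside the rectangle — the proxy noise measure used when no
#' ground truth exists (the lower the STD, the better the denoising).
#' Raw 12-bit input is converted with the fixed `HU = raw - 1024` map.
#'
#' @param frame 2D numeric array.
#' @param roi a [roi_spec()] inside the frame.
#' @param intensity_scale `"raw12bit"` or `"hu"`.
#' @return Sample SD in HU.
#' @export
roi_std <- function(frame, roi, intensity_scale = "raw12bit") {
  px <- roi_pixels(frame, roi)
  if (match.arg(intensity_scale, c("raw12bit", "hu")) == "raw12bit")
    px <- raw_to_hu(px)
  stats::sd(px)
}

#' Criteria for noise-based training-frame selection
#'
#' A phase qualifies as full dose when its aorta-ROI STD is below
#' `full_dose_max_std` (default 39 HU) and as low dose when above
#' `low_dose_min_std` (default 59 HU), and only if it belongs to a run of at
#' least `min_consecutive` consecutive phases (default 3) all satisfying the
#' same threshold — the consecutive-phase requirement comes from the
#' temporal windows the spatiotemporal objective needs.
#'
#' @param full_dose_max_std,low_dose_min_std thresholds in HU.
#' @param min_consecutive minimal run length.
#' @param looped whether runs may wrap from the last phase to the first.
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(full_dose_max_std = 39, low_dose_min_std = 59,
                               min_consecutive = 3L, looped = FALSE) {
  if (full_dose_max_std >= low_dose_min_std)
    stop("full-dose threshold must lie below the low-dose threshold", call. = FALSE)
  structure(list(full_dose_max_std = full_dose_max_std,
                 low_dose_min_std = low_dose_min_std,
                 min_consecutive = as.integer(min_consecutive),
                 looped = isTRUE(looped)),
            class = "selection_criteria")
}

# phases in runs of >= k consecutive TRUEs; wraps across T -> 1 when looped
qualifying_runs <- function(mask, k, looped) {
  T_ <- length(mask)
  if (!any(mask)) return(integer(0))
  if (all(mask)) return(if (looped || T_ >= k) seq_len(T_) else integer(0))
  offset <- 0L
  if (looped) {
    # rotate so the scan starts just after a FALSE; runs then never wrap
    start <- which(!mask)[1L]
    offset <- start
    mask <- mask[((start + 0L:(T_ - 1L)) %% T_) + 1L]
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= k)
  idx <- unlist(lapply(keep, function(i) starts[i]:ends[i]), use.names = FALSE)
  if (length(idx) == 0L) return(integer(0))
  sort(((idx + offset - 1L) %% T_) + 1L)
}

#' Select low-dose and full-dose phases from per-phase noise levels
#'
#' Applies the STD thresholds and the consecutive-run requirement of
#' [selection_criteria()] to an ordered vector of per-phase aorta-ROI STDs.
#' The two returned phase sets are always disjoint.
#'
#' @param per_phase_stds numeric vector of ROI STDs (HU), ordered by phase.
#' @param criteria a [selection_criteria()].
#' @return List with integer phase vectors `low_dose` and `full_dose`.
#' @export
select_low_full_frames <- function(per_phase_stds, criteria = selection_criteria()) {
  if (length(per_phase_stds) < criteria$min_consecutive)
    stop("fewer phases than the minimal run length", call. = FALSE)
  low_mask <- per_phase_stds > criteria$low_dose_min_std
  full_mask <- per_phase_stds < criteria$full_dose_max_std
  list(low_dose = qualifying_runs(low_mask, criteria$min_consecutive, criteria$looped),
       full_dose = qualifying_runs(full_mask, criteria$min_consecutive, criteria$looped))
}

#' Evaluate a sequence against a reference or by ROI noise
#'
#' With a pixel-aligned reference, computes per-phase MSE/PSNR/SSIM (the
#' phantom protocol); without one, computes per-phase aorta-ROI STD (the
#' patient protocol, where no ground truth exists). Aggregates are the mean
#' and sample SD over phases and are always recomputable from the per-frame
#' rows.
#'
#' @param candidate a [phase_sequence()] to score.
#' @param reference optional [phase_sequence()] ground truth.
#' @param roi optional [roi_spec()]; required when `reference` is absent.
#' @param provenance optional named list recorded verbatim in the report.
#' @return A `metric_report`: list with `per_frame` (data frame),
#'   `aggregates` (named list of `c(mean, sd)`), and `provenance`.
#' @export
evaluate_sequence <- function(candidate, reference = NULL, roi = NULL,
                              provenance = list()) {
  stopifnot(inherits(candidate, "phase_sequence"))
  if (is.null(reference) && is.null(roi))
    stop("need a reference sequence for paired metrics or an ROI for noise STD",
         call. = FALSE)
  cand <- seq_as_raw(candidate)
  per <- data.frame(phase = seq_len(candidate$phase_count))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "phase_sequence"))
    if (reference$phase_count != candidate$phase_count)
      stop("candidate and reference phase counts differ", call. = FALSE)
    ref <- seq_as_raw(reference)
    per$mse <- vapply(per$phase, function(t) mse(cand[[t]], ref[[t]]), numeric(1))
    per$psnr <- vapply(per$phase, function(t) psnr(cand[[t]], ref[[t]]), numeric(1))
    per$ssim <- vapply(per$phase, function(t) ssim(cand[[t]], ref[[t]]), numeric(1))
  }
  if (!is.null(roi)) {
    per$roi_std <- vapply(per$phase, function(t) roi_std(cand[[t]], roi), numeric(1))
  }
  metrics <- setdiff(names(per), "phase")
  aggregates <- lapply(metrics, function(m)
    c(mean = mean(per[[m]]), sd = stats::sd(per[[m]])))
  names(aggregates) <- metrics
  structure(list(per_frame = per, aggregates = aggregates, provenance = provenance),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>", nrow(x$per_frame), "phases\n")
  for (m in names(x$aggregates))
    cat(sprintf("  %-8s %.4f +/- %.4f\n", m, x$aggregates[[m]]["mean"],
                x$aggregates[[m]]["sd"]))
  invisible(x)
}

#' Serialize a metric report
#'
#' Per-frame rows go to CSV; aggregates and provenance go to JSON.
#'
#' @param report a `metric_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_frame, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(aggregates = report$aggregates,
                              provenance = report$provenance),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
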