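# Signal extraction: containers for widefield movies and conversion of raw
# fluorescence to baseline-corrected Delta-F/F, for widefield (rank-order
# baseline) and two-photon (neuropil subtraction + median/Butterworth
# baseline) data.

#' Widefield fluorescence movie
#'
#' @param frames either a `T x (height*width)` matrix of pixel time series
#'   (pixels in column-major image order) or a `height x width x T` array.
#' @param height,width image dimensions in pixels (inferred from an array).
#' @param pixel_size_um pixel pitch in micrometers.
#' @param frame_rate_hz acquisition rate.
#' @param roi_mask,vessel_mask logical `height x width` masks; defaults:
#'   full-field ROI, no vessels. Vessel pixels are excluded from all
#'   downstream statistics.
#' @return object of class `wf_movie`; frames are stored as a
#'   `T x n_pixels` matrix (`$frames`), with `$height`, `$width` and masks.
#' @export
wf_movie <- function(frames, height = NULL, width = NULL, pixel_size_um,
                     frame_rate_hz, roi_mask = NULL, vessel_mask = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    d <- dim(frames)
    height <- d[1]; width <- d[2]
    frames <- t(matrix(frames, d[1] * d[2], d[3]))
  }
  stopifnot(is.matrix(frames), !is.null(height), !is.null(width),
            ncol(frames) == height * width, nrow(frames) >= 1,
            pixel_size_um > 0, frame_rate_hz > 0)
  if (any(frames < 0, na.rm = TRUE)) stop("fluorescence must be nonnegative")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, height, width)
  if (is.null(vessel_mask)) vessel_mask <- matrix(FALSE, height, width)
  stopifnot(all(dim(roi_mask) == c(height, width)),
            all(dim(vessel_mask) == c(height, width)))
  if (!any(roi_mask)) stop("roi_mask must be non-empty")
  m <- list(frames = frames, height = as.integer(height),
            width = as.integer(width), pixel_size_um = pixel_size_um,
            frame_rate_hz = frame_rate_hz, roi_mask = roi_mask,
            vessel_mask = vessel_mask)
  class(m) <- "wf_movie"
  m
}

#' @export
print.wf_movie <- function(x, ...) {
  cat(sprintf("<wf_movie> %d x %d px, %d frames, %.3g um/px, %.3g Hz\n",
              x$height, x$width, nrow(x$frames), x$pixel_size_um,
              x$frame_rate_hz))
  invisible(x)
}

# Valid analysis pixels: inside ROI and not vessels.
valid_mask <- function(movie) movie$roi_mask & !movie$vessel_mask

#' Motion-correction hook
#'
#' Rigid motion correction is assumed to have been applied upstream of this
#' package; this pass-through exists so pipelines can record that fact.
#' @param movie a [wf_movie()].
#' @return the movie, unchanged, with attribute `motion_corrected`.
#' @export
assume_motion_corrected <- function(movie) {
  attr(movie, "motion_corrected") <- TRUE
  movie
}

#' Sliding rank-order baseline
#'
#' For every sample, the baseline is the `rank`-th smallest value within a
#' window of `window` samples centred on it (a low quantile that tracks the
#' slow fluorescence trend while ignoring transients). At the trace edges
#' the window is truncated and the rank rescaled proportionally (rounded,
#' floored at 1). Defaults follow GCaMP6s widefield practice: rank 70
#' (excitatory; use 190 for inhibitory data) in a 30-s, 451-sample window.
#'
#' @param trace numeric vector.
#' @param rank order statistic within the window (1 = running minimum).
#' @param window odd window length in samples.
#' @return numeric vector of baseline values, same length as `trace`.
#' @export
rank_order_baseline <- function(trace, rank = 70L, window = 451L) {
  if (rank < 1 || window < 1) stop("rank and window must be positive")
  if (window %% 2 == 0) stop("window must be odd")
  if (rank > window) stop("rank must not exceed window")
  .rank_filter_vec(as.numeric(trace), as.integer(rank), as.integer(window))
}

# Window length in samples for a given duration, forced odd.
window_samples <- function(window_s, frame_rate_hz) {
  odd_window(window_s * frame_rate_hz + 1)
}

#' Compute Delta-F/F for a widefield movie
#'
#' Per-pixel rank-order baseline `F0` followed by `(F - F0)/F0`. Vessel
#' pixels are set to `NA` and excluded downstream. If `window` is `NULL`
#' it is derived from `window_s` seconds at the movie's frame rate (451
#' samples at 15 Hz), with `rank` rescaled from its 451-sample reference.
#'
#' @param movie a [wf_movie()].
#' @param rank,window rank-order filter parameters (see
#'   [rank_order_baseline()]).
#' @param window_s window duration used when `window` is `NULL`.
#' @return object of class `dff_movie`: same geometry, `$frames` holding
#'   Delta-F/F values.
#' @export
compute_dff <- function(movie, rank = 70L, window = NULL, window_s = 30) {
  stopifnot(inherits(movie, "wf_movie"))
  if (is.null(window)) {
    window <- window_samples(window_s, movie$frame_rate_hz)
    rank <- max(1L, as.integer(round(rank * window / 451)))
  }
  vm <- as.vector(valid_mask(movie))
  roi <- as.vector(movie$roi_mask)
  F0 <- .rank_filter_mat(movie$frames[, vm, drop = FALSE],
                         as.integer(rank), as.integer(window))
  if (any(F0 <= 0)) stop("nonpositive baseline inside ROI")
  dff <- matrix(NA_real_, nrow(movie$frames), ncol(movie$frames))
  dff[, vm] <- (movie$frames[, vm, drop = FALSE] - F0) / F0
  out <- movie
  out$frames <- dff
  class(out) <- c("dff_movie", "wf_movie")
  out
}

#' Neuropil subtraction
#'
#' `F_cell = F_raw - alpha * F_neuropil`, with the conventional
#' contamination coefficient `alpha = 0.6`.
#'
#' @param raw,neuropil numeric vectors (or matrices of traces in columns)
#'   of equal dimensions.
#' @param alpha contamination coefficient in `[0, 1]`.
#' @return corrected trace(s).
#' @export
neuropil_subtract <- function(raw, neuropil, alpha = 0.6) {
  if (!identical(dim(raw) %||% length(raw), dim(neuropil) %||% length(neuropil)))
    stop("raw and neuropil must have the same dimensions")
  stopifnot(alpha >= 0, alpha <= 1)
  raw - alpha * neuropil
}

#' Two-photon baseline correction and high-pass filtering
#'
#' Baseline `F0` is a sliding 60-s median of the trace; activity is
#' `(F - F0)/F0`, then high-pass filtered with a first-order Butterworth
#' filter (cutoff 1/60 Hz) applied forward and backward for zero phase.
#'
#' @param trace numeric fluorescence vector.
#' @param frame_rate_hz acquisition rate.
#' @param window_s median-filter window and high-pass cutoff time, seconds.
#' @return Delta-F/F trace, high-pass filtered.
#' @export
highpass_baseline_2p <- function(trace, frame_rate_hz, window_s = 60) {
  k <- window_samples(window_s, frame_rate_hz)
  if (length(trace) <= k)
    stop("trace shorter than the baseline window")
  F0 <- stats::runmed(trace, k, endrule = "median")
  if (any(F0 <= 0)) stop("nonpositive baseline")
  dff <- (trace - F0) / F0
  bf <- signal::butter(1, (1 / window_s) / (frame_rate_hz / 2), type = "high")
  as.numeric(signal::filtfilt(bf, dff))
}

#' Delta-F/F traces for a cell population
#'
#' Applies [neuropil_subtract()] and [highpass_baseline_2p()] to every cell
#' of a [synthesize_cell_population()] (or equivalently structured) object.
#'
#' @param pop a `cell_population`.
#' @param alpha neuropil contamination coefficient.
#' @param window_s baseline window, seconds.
#' @return `T x n_cells` matrix of Delta-F/F traces.
#' @export
cell_dff <- function(pop, alpha = 0.6, window_s = 60) {
  stopifnot(inherits(pop, "cell_population"))
  sub <- neuropil_subtract(pop$raw, pop$neuropil, alpha)
  apply(sub, 2, highpass_baseline_2p, frame_rate_hz = pop$frame_rate_hz,
        window_s = window_s)
}
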