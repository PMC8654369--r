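# Detection of spatially extended spontaneous events in Delta-F/F movies.
#
# A pixel is active when it exceeds its own temporal mean by a multiple of
# its temporal s.d.; isolated active specks below a minimum contiguous area
# are discarded; frames on which a large fraction of ROI pixels are active
# are merged into events, split at local minima of the ROI-mean trace.

#' Per-frame active-pixel mask
#'
#' `active[t, p] = dff[t, p] > mean_t(dff[, p]) + threshold_sd * sd_t(dff[, p])`.
#' Temporal statistics are computed once over the whole recording. Vessel
#' pixels are never active; zero-variance pixels are never active.
#'
#' @param dff a `dff_movie` from [compute_dff()].
#' @param threshold_sd threshold in per-pixel standard deviations; 3 is the
#'   GCaMP6s default, 2 is appropriate for lower-SNR indicators (jRCaMP1a).
#' @return `T x n_pixels` logical matrix.
#' @export
active_pixel_mask <- function(dff, threshold_sd = 3) {
  stopifnot(inherits(dff, "dff_movie"))
  X <- dff$frames
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  thr <- mu + threshold_sd * s
  thr[!is.finite(thr)] <- Inf
  s0 <- !is.finite(s) | s == 0
  thr[s0] <- Inf
  sweep(X, 2, thr, ">") & !is.na(X)
}

#' Remove small contiguous active regions from one mask frame
#'
#' Connected components (8-connectivity) smaller than
#' `ceiling(min_area_mm2 * 1e6 / pixel_size_um^2)` pixels are set inactive.
#'
#' @param frame logical `height x width` mask.
#' @param min_area_mm2 minimum contiguous area, square millimeters.
#' @param pixel_size_um pixel pitch.
#' @return filtered logical mask.
#' @export
filter_small_regions <- function(frame, min_area_mm2 = 0.01, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  min_px <- ceiling(min_area_mm2 * 1e6 / pixel_size_um^2)
  if (!any(frame)) return(frame)
  lab <- label_components_8(frame)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(frame), ncol(frame))
}

#' Detect spontaneous events
#'
#' Active frames are frames on which the fraction of valid ROI pixels that
#' are active (after small-region filtering) exceeds `active_fraction`.
#' Runs of consecutive active frames form events; a run is split at every
#' interior frame that is a strict local minimum of the ROI-mean Delta-F/F
#' trace (the minimum frame ends the earlier event, the next frame starts
#' the next). Each event records its maximally active frame (highest
#' ROI-mean activity) and amplitude (that frame's ROI mean).
#'
#' @param dff a `dff_movie`.
#' @param threshold_sd see [active_pixel_mask()].
#' @param min_area_mm2 see [filter_small_regions()].
#' @param active_fraction fraction of valid ROI pixels required active;
#'   0.5 default, 0.3 for low-SNR indicators.
#' @return object of class `event_set`: `$events` data frame (`start`,
#'   `end`, `max_frame`, `amplitude`), `$patterns` (`n x height x width`
#'   array of maximal frames), `$n_frames`, `$frame_rate_hz`, masks and
#'   parameters. Attribute `sufficient` is `FALSE` when fewer than 30
#'   events were found (such datasets are conventionally excluded from
#'   network analyses).
#' @export
detect_events <- function(dff, threshold_sd = 3, min_area_mm2 = 0.01,
                          active_fraction = 0.5) {
  stopifnot(inherits(dff, "dff_movie"))
  vm <- valid_mask(dff)
  nv <- sum(vm)
  act <- active_pixel_mask(dff, threshold_sd)
  T_n <- nrow(act)
  h <- dff$height; w <- dff$width
  frac <- numeric(T_n)
  for (t in seq_len(T_n)) {
    fr <- matrix(act[t, ], h, w) & vm
    if (any(fr)) fr <- filter_small_regions(fr, min_area_mm2, dff$pixel_size_um)
    frac[t] <- sum(fr) / nv
  }
  active_frame <- frac > active_fraction
  roi_mean <- rowMeans(dff$frames[, as.vector(vm), drop = FALSE])
  events <- split_runs(active_frame, roi_mean)
  if (nrow(events) > 0) {
    events$max_frame <- mapply(function(s, e) {
      fr <- s:e
      fr[which.max(roi_mean[fr])]
    }, events$start, events$end)
    events$amplitude <- roi_mean[events$max_frame]
    pat <- array(NA_real_, c(nrow(events), h, w))
    for (i in seq_len(nrow(events)))
      pat[i, , ] <- matrix(dff$frames[events$max_frame[i], ], h, w)
  } else {
    events$max_frame <- integer(0)
    events$amplitude <- numeric(0)
    pat <- array(NA_real_, c(0, h, w))
  }
  es <- list(
    events = events, patterns = pat, n_frames = T_n,
    frame_rate_hz = dff$frame_rate_hz, pixel_size_um = dff$pixel_size_um,
    roi_mask = dff$roi_mask, vessel_mask = dff$vessel_mask,
    params = list(threshold_sd = threshold_sd, min_area_mm2 = min_area_mm2,
                  active_fraction = active_fraction)
  )
  class(es) <- "event_set"
  attr(es, "sufficient") <- nrow(events) >= 30
  es
}

# Runs of TRUE in `active`, split at strict interior local minima of
# `trace`; ties do not split.
split_runs <- function(active, trace) {
  n <- length(active)
  starts <- integer(0); ends <- integer(0)
  t <- 1L
  while (t <= n) {
    if (!active[t]) { t <- t + 1L; next }
    s <- t
    while (t < n && active[t + 1L]) t <- t + 1L
    e <- t
    # split the run [s, e] at strict local minima of trace
    cur <- s
    if (e - s >= 2) {
      for (m in (s + 1L):(e - 1L)) {
        if (trace[m] < trace[m - 1L] && trace[m] < trace[m + 1L]) {
          starts <- c(starts, cur); ends <- c(ends, m)
          cur <- m + 1L
        }
      }
    }
    starts <- c(starts, cur); ends <- c(ends, e)
    t <- e + 1L
  }
  data.frame(start = starts, end = ends)
}

#' Number of detected events
#' @param es an `event_set`.
#' @return integer count.
#' @export
n_events <- function(es) nrow(es$events)

#' Event frequency in Hz
#'
#' Count of detected events divided by recording duration.
#' @param es an `event_set`.
#' @return events per second.
#' @export
event_frequency <- function(es) {
  n_events(es) / (es$n_frames / es$frame_rate_hz)
}
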