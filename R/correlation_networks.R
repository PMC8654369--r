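# Seed-point correlation networks: spatial band-pass and downsampling of
# event patterns, Pearson correlation tensors over ROI pixels, surrogate
# (rotation/translation/reflection) null ensembles, and the long-range
# correlation-strength bootstrap.

#' Event pattern stack
#'
#' Container for N filtered, downsampled maximal-frame event patterns on a
#' common grid. Pixels outside the ROI (or invalid in any pattern) are NA.
#'
#' @param patterns `N x (height*width)` matrix, pixels in column-major
#'   image order.
#' @param height,width grid size in pixels.
#' @param pixel_size_um pixel pitch of this grid.
#' @param roi optional logical `height x width` mask; defaults to pixels
#'   finite in every pattern.
#' @return object of class `pattern_stack`.
#' @export
pattern_stack <- function(patterns, height, width, pixel_size_um,
                          roi = NULL) {
  stopifnot(is.matrix(patterns), ncol(patterns) == height * width)
  if (is.null(roi)) {
    roi <- matrix(colSums(!is.finite(patterns)) == 0, height, width)
  }
  stopifnot(identical(dim(roi), c(as.integer(height), as.integer(width))))
  st <- list(patterns = patterns, height = as.integer(height),
             width = as.integer(width), pixel_size_um = pixel_size_um,
             roi = roi)
  class(st) <- "pattern_stack"
  st
}

#' @export
print.pattern_stack <- function(x, ...) {
  cat(sprintf("<pattern_stack> %d patterns, %d x %d px (%.3g um/px), %d ROI px\n",
              nrow(x$patterns), x$height, x$width, x$pixel_size_um,
              sum(x$roi)))
  invisible(x)
}

# Micrometer coordinates (x = column, y = row) of linear grid indices.
idx_coords_um <- function(idx, height, pixel_size_um) {
  r <- ((idx - 1L) %% height) + 1L
  c <- ((idx - 1L) %/% height) + 1L
  cbind(x = c * pixel_size_um, y = r * pixel_size_um)
}

#' Band-pass filter and downsample event patterns
#'
#' Applies a Gaussian difference-of-Gaussians spatial band-pass (blur at
#' `sigma_low_um` minus blur at `sigma_high_um`, both mask-aware) to each
#' event's maximal frame, then block-averages to a coarser grid.
#'
#' @param events an `event_set` from [detect_events()], or a
#'   [pattern_stack()] of raw patterns.
#' @param sigma_low_um,sigma_high_um band-pass sigmas in micrometers
#'   (defaults 26 and 195).
#' @param target_pixel_um approximate pixel pitch of the output grid; the
#'   integer block factor is `round(target_pixel_um / pixel_size_um)`.
#'   Default keeps the source pitch (factor 1).
#' @return a [pattern_stack()] of filtered, downsampled patterns.
#' @export
bandpass_and_downsample <- function(events, sigma_low_um = 26,
                                    sigma_high_um = 195,
                                    target_pixel_um = NULL) {
  if (sigma_low_um >= sigma_high_um)
    stop("sigma_low_um must be smaller than sigma_high_um")
  if (inherits(events, "event_set")) {
    n <- n_events(events)
    h <- dim(events$patterns)[2]; w <- dim(events$patterns)[3]
    px <- events$pixel_size_um
    pats <- matrix(aperm(events$patterns, c(2, 3, 1)), h * w, n)
    pats <- t(pats)
    mask <- events$roi_mask & !events$vessel_mask
  } else if (inherits(events, "pattern_stack")) {
    n <- nrow(events$patterns); h <- events$height; w <- events$width
    px <- events$pixel_size_um
    pats <- events$patterns
    mask <- events$roi
  } else stop("events must be an event_set or pattern_stack")
  if (n < 1) stop("no event patterns to filter")
  fac <- if (is.null(target_pixel_um)) 1L else
    max(1L, as.integer(round(target_pixel_um / px)))
  out <- matrix(NA_real_, n, (h %/% fac) * (w %/% fac))
  for (i in seq_len(n)) {
    fr <- matrix(pats[i, ], h, w)
    lo <- gaussian_blur_masked(fr, sigma_low_um / px, mask)
    hi <- gaussian_blur_masked(fr, sigma_high_um / px, mask)
    bp <- lo - hi
    if (fac > 1L) bp <- block_average(bp, fac)
    out[i, ] <- as.vector(bp)
  }
  pattern_stack(out, h %/% fac, w %/% fac, px * fac)
}

# NA-aware block averaging by an integer factor; blocks with fewer than
# half their pixels valid become NA.
block_average <- function(m, fac) {
  h <- (nrow(m) %/% fac) * fac
  w <- (ncol(m) %/% fac) * fac
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  v <- m; v[is.na(v)] <- 0
  cnt <- matrix(as.numeric(!is.na(m)), h, w)
  sum_blocks <- function(a) {
    a1 <- rowsum(a, rep(seq_len(h %/% fac), each = fac))
    t(rowsum(t(a1), rep(seq_len(w %/% fac), each = fac)))
  }
  s <- sum_blocks(v)
  nvalid <- sum_blocks(cnt)
  out <- s / nvalid
  out[nvalid < fac * fac / 2] <- NA_real_
  out
}

#' Seed-point correlation tensor
#'
#' Pearson correlation, across events, between each seed pixel and every
#' ROI pixel: `C(s, x)`. Zero-variance pixels are dropped from the ROI
#' with a warning (a zero-variance seed would be degenerate).
#'
#' @param stack a [pattern_stack()] with at least 2 patterns.
#' @param seeds optional integer vector of linear grid indices to use as
#'   seeds (must lie in the ROI); default all ROI pixels.
#' @return object of class `correlation_tensor`: `$C` (seeds x ROI pixels),
#'   `$seed_grid_idx`, `$roi_idx` (linear grid indices of columns), grid
#'   geometry and `$coords` (micrometer coordinates of columns).
#' @export
correlation_tensor <- function(stack, seeds = NULL) {
  stopifnot(inherits(stack, "pattern_stack"))
  N <- nrow(stack$patterns)
  if (N < 2) stop("at least 2 patterns are required for correlations")
  roi_idx <- which(as.vector(stack$roi))
  A <- stack$patterns[, roi_idx, drop = FALSE]
  sds <- apply(A, 2, sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance pixels dropped from ROI")
    roi_idx <- roi_idx[!bad]
    A <- A[, !bad, drop = FALSE]
  }
  if (is.null(seeds)) {
    seeds <- roi_idx
  } else {
    if (!all(seeds %in% roi_idx)) stop("degenerate seed: outside valid ROI")
  }
  sc <- match(seeds, roi_idx)
  C <- cor(A[, sc, drop = FALSE], A)
  tz <- list(C = C, seed_grid_idx = seeds, roi_idx = roi_idx,
             height = stack$height, width = stack$width,
             pixel_size_um = stack$pixel_size_um,
             coords = idx_coords_um(roi_idx, stack$height,
                                    stack$pixel_size_um))
  class(tz) <- "correlation_tensor"
  tz
}

#' @export
print.correlation_tensor <- function(x, ...) {
  cat(sprintf("<correlation_tensor> %d seeds x %d ROI px, %d x %d grid (%.3g um/px)\n",
              nrow(x$C), ncol(x$C), x$height, x$width, x$pixel_size_um))
  invisible(x)
}

#' Correlation pattern for one seed
#'
#' @param x a [correlation_tensor()] or [pattern_stack()].
#' @param seed seed position: linear grid index or `c(row, col)`.
#' @return `height x width` correlation map, NA outside the ROI.
#' @export
correlation_pattern <- function(x, seed) {
  if (inherits(x, "pattern_stack")) x <- correlation_tensor(x, seeds = seed_to_idx(x, seed))
  stopifnot(inherits(x, "correlation_tensor"))
  idx <- seed_to_idx(x, seed)
  row <- match(idx, x$seed_grid_idx)
  if (is.na(row)) stop("seed not among tensor seeds")
  map <- matrix(NA_real_, x$height, x$width)
  map[x$roi_idx] <- x$C[row, ]
  map
}

seed_to_idx <- function(x, seed) {
  if (length(seed) == 2) (seed[2] - 1L) * x$height + seed[1] else as.integer(seed)
}

#' Evenly subsample seed pixels from a stack's ROI
#'
#' @param stack a [pattern_stack()].
#' @param n approximate number of seeds.
#' @return integer vector of linear grid indices.
#' @export
seed_subsample <- function(stack, n) {
  roi_idx <- which(as.vector(stack$roi))
  if (n >= length(roi_idx)) return(roi_idx)
  roi_idx[round(seq(1, length(roi_idx), length.out = n))]
}

#' Surrogate pattern ensemble
#'
#' Each surrogate transforms every event pattern independently: rotation
#' about the ROI centroid (angles 0-350 degrees in 10-degree steps,
#' nearest-neighbour resampling), translation (uniform within
#' `+/- shift_max_um` in steps of `shift_step_um`, independently in x and
#' y), and reflection about the x and/or y axis through the ROI centroid
#' (each with probability 0.5). Pixels mapped from outside the original
#' ROI are undefined; a realized surrogate stack restricts its ROI to
#' pixels defined in every transformed pattern.
#'
#' @param stack a [pattern_stack()].
#' @param n number of surrogates (default 100).
#' @param seed RNG seed for the transform draws.
#' @param angle_step_deg,shift_max_um,shift_step_um transform grids.
#' @return object of class `surrogate_ensemble` storing the transform log;
#'   realize members with [realize_surrogate()].
#' @export
make_surrogates <- function(stack, n = 100, seed = 1,
                            angle_step_deg = 10, shift_max_um = 450,
                            shift_step_um = 26) {
  stopifnot(inherits(stack, "pattern_stack"))
  N <- nrow(stack$patterns)
  if (N < 1) stop("empty pattern stack")
  angles <- seq(0, 360 - angle_step_deg, by = angle_step_deg)
  nstep <- floor(shift_max_um / shift_step_um)
  shifts <- shift_step_um * seq(-nstep, nstep)
  with_rng_seed(seed, {
    se <- list(
      stack = stack, n = n,
      angle_deg = matrix(sample(angles, n * N, replace = TRUE), n, N),
      dx_um = matrix(sample(shifts, n * N, replace = TRUE), n, N),
      dy_um = matrix(sample(shifts, n * N, replace = TRUE), n, N),
      flip_x = matrix(runif(n * N) < 0.5, n, N),
      flip_y = matrix(runif(n * N) < 0.5, n, N)
    )
    class(se) <- "surrogate_ensemble"
    se
  })
}

#' Realize one surrogate pattern stack
#'
#' @param se a [make_surrogates()] ensemble.
#' @param i surrogate index in `1:se$n`.
#' @return a [pattern_stack()] whose ROI is the set of pixels defined in
#'   every transformed pattern.
#' @export
realize_surrogate <- function(se, i) {
  stopifnot(inherits(se, "surrogate_ensemble"), i >= 1, i <= se$n)
  st <- se$stack
  N <- nrow(st$patterns)
  out <- matrix(NA_real_, N, st$height * st$width)
  for (ev in seq_len(N)) {
    out[ev, ] <- transform_pattern(
      st$patterns[ev, ], st$height, st$width, st$pixel_size_um, st$roi,
      angle_deg = se$angle_deg[i, ev], dx_um = se$dx_um[i, ev],
      dy_um = se$dy_um[i, ev], flip_x = se$flip_x[i, ev],
      flip_y = se$flip_y[i, ev]
    )
  }
  pattern_stack(out, st$height, st$width, st$pixel_size_um)
}

# Rotate/translate/reflect one pattern about the ROI centroid with
# nearest-neighbour resampling. Forward transform: reflect, rotate by
# `angle_deg`, then shift; implemented by inverse-mapping target pixels.
transform_pattern <- function(v, h, w, px, roi, angle_deg, dx_um, dy_um,
                              flip_x, flip_y) {
  ctr_r <- mean(((which(roi) - 1L) %% h) + 1L) * px
  ctr_c <- mean(((which(roi) - 1L) %/% h) + 1L) * px
  th <- angle_deg * pi / 180
  # target pixel coordinates
  R <- rep(seq_len(h), w) * px
  Cc <- rep(seq_len(w), each = h) * px
  xr <- Cc - ctr_c - dx_um
  yr <- R - ctr_r - dy_um
  xs <- cos(th) * xr + sin(th) * yr
  ys <- -sin(th) * xr + cos(th) * yr
  if (flip_x) xs <- -xs
  if (flip_y) ys <- -ys
  sc <- round((xs + ctr_c) / px)
  sr <- round((ys + ctr_r) / px)
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  src <- ifelse(ok, (pmax(sc, 1) - 1L) * h + pmax(sr, 1), NA_integer_)
  in_roi <- !is.na(src) & as.vector(roi)[pmax(src, 1L, na.rm = TRUE)]
  res <- rep(NA_real_, h * w)
  res[in_roi] <- v[src[in_roi]]
  res
}

#' Local maxima of a correlation map with minimum separation
#'
#' Strict 8-neighbour local maxima, greedily retained in descending value
#' order subject to a pairwise distance of at least `min_separation_um`.
#' The seed's own peak (maxima within two pixels of the seed) is excluded.
#'
#' @param map `height x width` correlation map (NA outside ROI).
#' @param pixel_size_um pixel pitch.
#' @param seed_rc optional seed position `c(row, col)`.
#' @param min_separation_um minimum distance between retained maxima.
#' @return data frame with `row`, `col`, `x_um`, `y_um`, `value`,
#'   `dist_um` (NA if no seed given).
#' @export
correlation_maxima <- function(map, pixel_size_um, seed_rc = NULL,
                               min_separation_um = 800) {
  mx <- which(local_maxima_2d(map))
  if (!length(mx)) return(empty_maxima())
  h <- nrow(map)
  r <- ((mx - 1L) %% h) + 1L
  cc <- ((mx - 1L) %/% h) + 1L
  val <- map[mx]
  x <- cc * pixel_size_um; y <- r * pixel_size_um
  if (!is.null(seed_rc)) {
    dseed <- sqrt((x - seed_rc[2] * pixel_size_um)^2 +
                  (y - seed_rc[1] * pixel_size_um)^2)
    keep <- dseed > 2 * pixel_size_um
    r <- r[keep]; cc <- cc[keep]; val <- val[keep]
    x <- x[keep]; y <- y[keep]; dseed <- dseed[keep]
  } else dseed <- rep(NA_real_, length(val))
  if (!length(val)) return(empty_maxima())
  o <- order(val, decreasing = TRUE)
  kept <- integer(0)
  for (i in o) {
    if (!length(kept) ||
        all(sqrt((x[kept] - x[i])^2 + (y[kept] - y[i])^2) >=
            min_separation_um))
      kept <- c(kept, i)
  }
  data.frame(row = r[kept], col = cc[kept], x_um = x[kept], y_um = y[kept],
             value = val[kept], dist_um = dseed[kept])
}

empty_maxima <- function() {
  data.frame(row = integer(0), col = integer(0), x_um = numeric(0),
             y_um = numeric(0), value = numeric(0), dist_um = numeric(0))
}

# Median correlation value over all seeds' maxima whose distance from the
# seed lies in `band_um`.
band_maxima_statistic <- function(tensor, band_um, min_separation_um = 800) {
  vals <- numeric(0)
  h <- tensor$height
  for (k in seq_along(tensor$seed_grid_idx)) {
    idx <- tensor$seed_grid_idx[k]
    rc <- c(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L)
    map <- matrix(NA_real_, h, tensor$width)
    map[tensor$roi_idx] <- tensor$C[k, ]
    mx <- correlation_maxima(map, tensor$pixel_size_um, seed_rc = rc,
                             min_separation_um = min_separation_um)
    sel <- mx$dist_um >= band_um[1] & mx$dist_um <= band_um[2]
    vals <- c(vals, mx$value[sel])
  }
  list(statistic = if (length(vals)) median(vals) else NA_real_,
       n_values = length(vals))
}

#' Long-range correlation strength versus surrogate null
#'
#' Observed statistic: median correlation value over all seeds' local
#' maxima lying `band_um` (default 1.8-2.2 mm) from the seed. The null
#' distribution is the same statistic on each surrogate ensemble member;
#' the bootstrap p-value uses the add-one estimator
#' `(k + 1)/(n + 1)` with `k` surrogates at or above the observed value.
#'
#' @param tensor observed [correlation_tensor()].
#' @param surrogates a [make_surrogates()] ensemble built from the same
#'   pattern stack.
#' @param band_um distance band (micrometers) for qualifying maxima.
#' @param min_separation_um minimum separation between maxima.
#' @param alpha significance level.
#' @return list: `statistic`, `p`, `significant`, `surrogate_stats`,
#'   `n_values` (number of maxima entering the observed median; 0 flags an
#'   undefined statistic).
#' @export
long_range_strength <- function(tensor, surrogates,
                                band_um = c(1800, 2200),
                                min_separation_um = 800, alpha = 0.01) {
  stopifnot(inherits(tensor, "correlation_tensor"),
            inherits(surrogates, "surrogate_ensemble"))
  obs <- band_maxima_statistic(tensor, band_um, min_separation_um)
  if (obs$n_values == 0) {
    warning("no correlation maxima in the distance band; statistic undefined")
    return(list(statistic = NA_real_, p = NA_real_, significant = FALSE,
                surrogate_stats = numeric(0), n_values = 0))
  }
  stats <- numeric(surrogates$n)
  for (i in seq_len(surrogates$n)) {
    sst <- realize_surrogate(surrogates, i)
    keep <- tensor$seed_grid_idx[tensor$seed_grid_idx %in%
                                   which(as.vector(sst$roi))]
    tz <- suppressWarnings(correlation_tensor(sst, seeds = intersect(
      keep, surrogate_valid_seeds(sst))))
    stats[i] <- band_maxima_statistic(tz, band_um, min_separation_um)$statistic
  }
  stats <- stats[is.finite(stats)]
  k <- sum(stats >= obs$statistic)
  p <- (k + 1) / (length(stats) + 1)
  list(statistic = obs$statistic, p = p, significant = p < alpha,
       surrogate_stats = stats, n_values = obs$n_values)
}

# Seeds usable in a surrogate stack: ROI pixels with nonzero variance.
surrogate_valid_seeds <- function(stack) {
  roi_idx <- which(as.vector(stack$roi))
  A <- stack$patterns[, roi_idx, drop = FALSE]
  sds <- apply(A, 2, sd)
  roi_idx[is.finite(sds) & sds > 0]
}
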