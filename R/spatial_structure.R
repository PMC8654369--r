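# Spatial organization of correlation patterns: fracture strength and
# fracture lines, modular wavelength, local eccentricity of iso-correlation
# contours, and active-domain size via rotated 2D Gaussian fits.

#' Fracture strength field
#'
#' The rate at which the seed-point correlation pattern changes per
#' micrometer of seed displacement:
#' `strength(s) = mean over 4-neighbour seeds s' of
#' (1 - cor(C(s, .), C(s', .))) / dist_um(s, s')`.
#' Requires a tensor computed at every ROI pixel.
#'
#' @param tensor a full-seed [correlation_tensor()].
#' @return `height x width` matrix (units 1/um), NA outside the ROI or
#'   where a seed has no in-ROI neighbour.
#' @export
fracture_strength <- function(tensor) {
  stopifnot(inherits(tensor, "correlation_tensor"))
  if (!identical(tensor$seed_grid_idx, tensor$roi_idx))
    stop("fracture_strength requires seeds at every ROI pixel")
  h <- tensor$height; w <- tensor$width; px <- tensor$pixel_size_um
  idx <- tensor$roi_idx
  pos <- match(seq_len(h * w), idx)  # grid index -> tensor row (NA outside)
  Xc <- tensor$C - rowMeans(tensor$C)
  nrm <- sqrt(rowSums(Xc^2))
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    dr <- d[1]; dc <- d[2]
    g <- seq_len(h * w)
    r <- ((g - 1L) %% h) + 1L
    cc <- ((g - 1L) %/% h) + 1L
    ok <- r + dr <= h & cc + dc <= w
    a <- g[ok]; b <- a + dr + dc * h
    pa <- pos[a]; pb <- pos[b]
    good <- !is.na(pa) & !is.na(pb)
    a <- a[good]; b <- b[good]; pa <- pa[good]; pb <- pb[good]
    if (!length(a)) next
    r12 <- rowSums(Xc[pa, , drop = FALSE] * Xc[pb, , drop = FALSE]) /
      (nrm[pa] * nrm[pb])
    # constant correlation patterns (e.g. exact rank-1 stacks) have zero
    # variance across pixels; their rate of change is zero, not undefined
    r12[nrm[pa] < 1e-8 | nrm[pb] < 1e-8] <- 1
    val <- (1 - r12) / px
    acc[a] <- acc[a] + val; cnt[a] <- cnt[a] + 1L
    acc[b] <- acc[b] + val; cnt[b] <- cnt[b] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out[-idx] <- NA_real_
  out
}

#' Extract fracture lines and fracture magnitude
#'
#' Pipeline, in order: spatial median filter (window covering 78 um,
#' rounded to odd pixels); contrast-limited adaptive histogram equalization
#' (clip limit 20, tiles of 260 x 260 um^2); Gaussian high-pass (subtract a
#' blur with sigma 390 um); binarize at 0; erode once then dilate twice
#' (3 x 3 box); skeletonize. Fracture magnitude is the mean raw strength on
#' the skeleton minus the mean at ROI pixels more than 130 um from any
#' skeleton pixel.
#'
#' @param strength field from [fracture_strength()].
#' @param pixel_size_um pixel pitch of the strength field.
#' @param median_um,clahe_tile_um,clahe_limit,sigma_high_um,exclude_um
#'   pipeline parameters (defaults as above).
#' @return object of class `fracture_map`: `$strength`, `$lines` (logical
#'   skeleton), `$magnitude` (NA, with a warning, if the skeleton is
#'   empty).
#' @export
fracture_lines <- function(strength, pixel_size_um, median_um = 78,
                           clahe_tile_um = 260, clahe_limit = 20,
                           sigma_high_um = 390, exclude_um = 130) {
  roi <- is.finite(strength)
  if (!any(roi)) stop("strength field has no finite values")
  h <- nrow(strength); w <- ncol(strength)
  fill <- median(strength[roi])
  x <- strength
  x[!roi] <- fill
  rng <- range(x)
  xn <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
  med_r <- max(1L, as.integer(floor(median_um / pixel_size_um / 2)))
  xm <- as.matrix(EBImage::medianFilter(xn, med_r))
  nx <- max(1L, round(w * pixel_size_um / clahe_tile_um))
  ny <- max(1L, round(h * pixel_size_um / clahe_tile_um))
  xe <- tryCatch(
    as.matrix(EBImage::clahe(xm, nx = nx, ny = ny, limit = clahe_limit,
                             keep.range = TRUE)),
    error = function(e) xm)
  hp <- xe - gaussian_blur_masked(xe, sigma_high_um / pixel_size_um)
  bin <- hp > 0
  bin[!roi] <- FALSE
  brush <- EBImage::makeBrush(3, "box")
  bin <- EBImage::erode(bin * 1, brush)
  bin <- EBImage::dilate(EBImage::dilate(bin, brush), brush) > 0
  bin <- matrix(bin, h, w) & roi
  skel <- skeletonize(bin)
  mag <- NA_real_
  if (any(skel)) {
    dist_px <- EBImage::distmap(matrix(as.numeric(!skel), h, w))
    far <- roi & !skel & (as.matrix(dist_px) * pixel_size_um > exclude_um)
    if (any(far)) {
      mag <- mean(strength[skel & roi]) - mean(strength[far])
    } else warning("no ROI pixels beyond the exclusion distance")
  } else warning("empty fracture skeleton; magnitude undefined")
  fm <- list(strength = strength, lines = skel, magnitude = mag,
             pixel_size_um = pixel_size_um)
  class(fm) <- "fracture_map"
  fm
}

#' Modular wavelength of the correlation patterns
#'
#' For each seed, the correlation map within `window_radius_um` is centred
#' on the seed; maps are averaged across seeds, averaged over angle in
#' radial bins one pixel pitch wide, interpolated with a cubic smoothing
#' spline (GCV), and the wavelength is the radius of the first strict local
#' maximum at r > 0.
#'
#' @param tensor a [correlation_tensor()].
#' @param window_radius_um neighbourhood radius (default 1500).
#' @return list: `wavelength_mm` (NA, flagged by a warning, when no
#'   secondary maximum exists), `profile` (data frame r_um, value),
#'   `spline` fit.
#' @export
correlation_wavelength <- function(tensor, window_radius_um = 1500) {
  stopifnot(inherits(tensor, "correlation_tensor"))
  h <- tensor$height; w <- tensor$width; px <- tensor$pixel_size_um
  rad <- as.integer(ceiling(window_radius_um / px))
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs$d_um <- sqrt(offs$dr^2 + offs$dc^2) * px
  offs <- offs[offs$d_um <= window_radius_um, ]
  pos <- match(seq_len(h * w), tensor$roi_idx)
  acc <- numeric(nrow(offs)); cnt <- numeric(nrow(offs))
  for (k in seq_along(tensor$seed_grid_idx)) {
    g <- tensor$seed_grid_idx[k]
    r0 <- ((g - 1L) %% h) + 1L; c0 <- ((g - 1L) %/% h) + 1L
    rr <- r0 + offs$dr; cc <- c0 + offs$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    tgt <- (cc[ok] - 1L) * h + rr[ok]
    col <- pos[tgt]
    good <- !is.na(col)
    vals <- tensor$C[k, col[good]]
    id <- which(ok)[good]
    acc[id] <- acc[id] + vals
    cnt[id] <- cnt[id] + 1
  }
  avg <- acc / cnt
  prof <- radial_profile(offs$d_um, avg, bin = px)
  sp <- smooth.spline(prof$r, prof$value)
  rf <- seq(0, max(prof$r), by = px / 4)
  yf <- predict(sp, rf)$y
  lam <- secondary_peak(rf, yf)
  if (is.na(lam)) warning("no local maximum within the window; wavelength undefined")
  list(wavelength_mm = lam / 1000,
       profile = data.frame(r_um = prof$r, value = prof$value, n = prof$n),
       spline = sp)
}

# First strict local maximum of y(x) occurring after the initial descent
# from r = 0 (i.e. after the first local minimum).
secondary_peak <- function(x, y) {
  n <- length(y)
  seen_min <- FALSE
  for (i in 2:(n - 1)) {
    if (!seen_min && y[i] < y[i - 1] && y[i] <= y[i + 1]) seen_min <- TRUE
    if (seen_min && y[i] > y[i - 1] && y[i] >= y[i + 1]) return(x[i])
  }
  NA_real_
}

#' Eccentricity of the local correlation structure around a seed
#'
#' Extracts the innermost closed iso-correlation contour at `level`
#' enclosing the seed (marching squares with linear interpolation) and fits
#' an ellipse by direct least squares. Eccentricity is
#' `sqrt(s1^2 - s2^2)/s1` for semi-axes `s1 >= s2` (0 for a circle).
#'
#' @param map `height x width` correlation map.
#' @param seed_rc seed position `c(row, col)`.
#' @param pixel_size_um pixel pitch.
#' @param level contour level (default 0.7).
#' @return list `phi` (orientation, radians), `s1_um`, `s2_um`,
#'   `eccentricity`; or NULL when the contour is absent or open at the ROI
#'   boundary (seed excluded from summaries).
#' @export
local_eccentricity <- function(map, seed_rc, pixel_size_um, level = 0.7) {
  z <- map
  finite <- is.finite(z)
  if (!any(finite)) return(NULL)
  z[!finite] <- min(z[finite]) - 1
  xs <- seq_len(nrow(z)) * pixel_size_um   # row coordinate (y)
  ys <- seq_len(ncol(z)) * pixel_size_um   # col coordinate (x)
  cl <- contourLines(xs, ys, z, levels = level)
  if (!length(cl)) return(NULL)
  py <- seed_rc[1] * pixel_size_um; px_ <- seed_rc[2] * pixel_size_um
  best <- NULL; best_area <- Inf
  for (cc in cl) {
    n <- length(cc$x)
    closed <- sqrt((cc$x[1] - cc$x[n])^2 + (cc$y[1] - cc$y[n])^2) <
      pixel_size_um / 2
    if (!closed || n < 6) next
    if (!point_in_polygon(py, px_, cc$x, cc$y)) next
    area <- abs(sum(cc$x * c(cc$y[-1], cc$y[1]) -
                    c(cc$x[-1], cc$x[1]) * cc$y)) / 2
    if (area < best_area) { best <- cc; best_area <- area }
  }
  if (is.null(best)) return(NULL)
  ell <- fit_ellipse(best$y, best$x)   # (x, y) in image (col, row) terms
  if (is.null(ell)) return(NULL)
  list(phi = ell$phi, s1_um = ell$s1, s2_um = ell$s2,
       eccentricity = sqrt(ell$s1^2 - ell$s2^2) / ell$s1)
}

# Direct least-squares ellipse fit (eigen decomposition of the scatter
# under the conic constraint 4ac - b^2 = 1); returns centre, semi-axes
# (s1 >= s2) and orientation of the major axis.
fit_ellipse <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sc <- max(sd(x), sd(y))
  if (!is.finite(sc) || sc == 0) return(NULL)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  j <- which(cond > 0)
  if (!length(j)) return(NULL)
  a1 <- evec[, j[1]]
  par <- c(a1, Tm %*% a1)  # A, B, C, D, E, F in scaled coords
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]; F0 <- par[6]
  den <- 4 * A * C - B^2
  if (den <= 0) return(NULL)
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  Fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F0
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  e2 <- eigen(M2, symmetric = TRUE)
  ax2 <- -Fc / e2$values
  if (any(ax2 <= 0)) return(NULL)
  semi <- sqrt(ax2)          # aligned with eigenvalue order (decreasing)
  major <- which.max(semi)
  vec <- e2$vectors[, major]
  list(x0 = x0 * sc + mx, y0 = y0 * sc + my,
       s1 = max(semi) * sc, s2 = min(semi) * sc,
       phi = atan2(vec[2], vec[1]) %% pi)
}

#' Fit a rotated 2D Gaussian to an activity domain
#'
#' Nonlinear least squares of
#' `G(x, y) = y0 + H * exp(-(a dx^2 + 2 b dx dy + c dy^2))`
#' (with `a`, `b`, `c` derived from `sigma_x`, `sigma_y` and rotation
#' `theta`) over the disk of `fit_radius_um` around a domain peak.
#' Initialization from local moments. Fits are rejected when the optimizer
#' fails, the amplitude is nonpositive, or the centre drifts more than
#' half the fit radius from the peak.
#'
#' @param pattern `height x width` band-passed event image.
#' @param peak_rc peak position `c(row, col)` (a local maximum).
#' @param pixel_size_um pixel pitch.
#' @param fit_radius_um neighbourhood radius (default 600).
#' @return object of class `domain_fit` with `H`, `x1_um`, `y1_um`,
#'   `sigma_x_um`, `sigma_y_um`, `theta`, `y0`, quadratic-form
#'   coefficients `a`, `b`, `c` (1/um^2), `sigma_minor_um`,
#'   `fwhm_minor_um`, `fwtm_minor_um`, `fwtm_major_um`; or NULL when the
#'   fit is rejected.
#' @export
fit_domain <- function(pattern, peak_rc, pixel_size_um,
                       fit_radius_um = 600) {
  h <- nrow(pattern); w <- ncol(pattern)
  co <- grid_coords_um(h, w, pixel_size_um)
  py <- peak_rc[1] * pixel_size_um; px_ <- peak_rc[2] * pixel_size_um
  d <- sqrt((co$x - px_)^2 + (co$y - py)^2)
  sel <- d <= fit_radius_um & is.finite(pattern)
  if (sum(sel) < 10) return(NULL)
  xx <- co$x[sel]; yy <- co$y[sel]; vv <- pattern[sel]
  y0_init <- quantile(vv, 0.1, names = FALSE)
  wts <- pmax(vv - y0_init, 0)
  if (sum(wts) <= 0) return(NULL)
  sx0 <- sqrt(sum(wts * (xx - px_)^2) / sum(wts))
  sy0 <- sqrt(sum(wts * (yy - py)^2) / sum(wts))
  # orientation from second moments; a perfectly axis-aligned start makes
  # the theta gradient degenerate, so fall back to jittered starts
  mxy <- sum(wts * (xx - px_) * (yy - py)) / sum(wts)
  th0 <- 0.5 * atan2(2 * mxy, sx0^2 - sy0^2)
  fit <- NULL
  for (th_try in unique(c(th0, th0 + 0.2, th0 - 0.35))) {
    start <- list(H = max(vv) - y0_init, x1 = px_, y1 = py,
                  sx = max(sx0, pixel_size_um), sy = max(sy0, pixel_size_um),
                  th = th_try, y0 = y0_init)
    fit <- try_domain_fit(vv, xx, yy, start, px_, py, fit_radius_um,
                          pixel_size_um)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(NULL)
  p <- fit
  drift <- sqrt((p$x1 - px_)^2 + (p$y1 - py)^2)
  if (p$H <= 0 || drift > fit_radius_um / 2) return(NULL)
  s_min <- min(p$sx, p$sy); s_maj <- max(p$sx, p$sy)
  out <- list(
    H = p$H, x1_um = p$x1, y1_um = p$y1, sigma_x_um = p$sx,
    sigma_y_um = p$sy, theta = p$th, y0 = p$y0,
    a = cos(p$th)^2 / (2 * p$sx^2) + sin(p$th)^2 / (2 * p$sy^2),
    b = -sin(2 * p$th) / (4 * p$sx^2) + sin(2 * p$th) / (4 * p$sy^2),
    c = sin(p$th)^2 / (2 * p$sx^2) + cos(p$th)^2 / (2 * p$sy^2),
    sigma_minor_um = s_min,
    fwhm_minor_um = 2 * s_min * sqrt(2 * log(2)),
    fwtm_minor_um = 2 * s_min * sqrt(2 * log(10)),
    fwtm_major_um = 2 * s_maj * sqrt(2 * log(10))
  )
  class(out) <- "domain_fit"
  out
}

# One Levenberg-Marquardt attempt at the rotated-Gaussian fit; returns the
# coefficient list or NULL on failure.
try_domain_fit <- function(vv, xx, yy, start, px_, py, fit_radius_um,
                           pixel_size_um) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vv ~ y0 + H * exp(-((cos(th)^2 / (2 * sx^2) + sin(th)^2 / (2 * sy^2)) *
                            (xx - x1)^2 +
                          2 * (-sin(2 * th) / (4 * sx^2) +
                                 sin(2 * th) / (4 * sy^2)) *
                            (xx - x1) * (yy - y1) +
                          (sin(th)^2 / (2 * sx^2) + cos(th)^2 / (2 * sy^2)) *
                            (yy - y1)^2)),
      start = start,
      lower = c(H = 0, x1 = px_ - fit_radius_um, y1 = py - fit_radius_um,
                sx = pixel_size_um / 4, sy = pixel_size_um / 4,
                th = -pi, y0 = -Inf),
      upper = c(H = Inf, x1 = px_ + fit_radius_um, y1 = py + fit_radius_um,
                sx = 4 * fit_radius_um, sy = 4 * fit_radius_um,
                th = pi, y0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(coef(fit))
}

#' Fit all activity domains of a pattern stack
#'
#' Domains are strict local maxima with positive value in each band-passed
#' event pattern; each is fit with [fit_domain()], rejected fits dropped.
#'
#' @param stack a [pattern_stack()] of band-passed patterns.
#' @param fit_radius_um see [fit_domain()].
#' @param min_separation_um minimum distance between peaks taken per event.
#' @return data frame of accepted fits (one row per domain) with an
#'   `event` column.
#' @export
fit_event_domains <- function(stack, fit_radius_um = 600,
                              min_separation_um = 400) {
  stopifnot(inherits(stack, "pattern_stack"))
  rows <- list()
  for (i in seq_len(nrow(stack$patterns))) {
    map <- matrix(stack$patterns[i, ], stack$height, stack$width)
    map[!stack$roi] <- NA_real_
    mx <- correlation_maxima(map, stack$pixel_size_um,
                             min_separation_um = min_separation_um)
    mx <- mx[mx$value > 0, , drop = FALSE]
    for (j in seq_len(nrow(mx))) {
      f <- fit_domain(map, c(mx$row[j], mx$col[j]), stack$pixel_size_um,
                      fit_radius_um)
      if (!is.null(f))
        rows[[length(rows) + 1L]] <- data.frame(
          event = i, x1_um = f$x1_um, y1_um = f$y1_um, H = f$H,
          sigma_x_um = f$sigma_x_um, sigma_y_um = f$sigma_y_um,
          theta = f$theta, sigma_minor_um = f$sigma_minor_um,
          fwhm_minor_um = f$fwhm_minor_um, fwtm_minor_um = f$fwtm_minor_um,
          fwtm_major_um = f$fwtm_major_um)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Median eccentricity over a set of seeds
#'
#' Convenience wrapper applying [local_eccentricity()] at each tensor seed
#' and aggregating defined values.
#'
#' @param tensor a [correlation_tensor()].
#' @param level contour level.
#' @return list `median_eccentricity`, `values`, `n_defined`.
#' @export
eccentricity_summary <- function(tensor, level = 0.7) {
  h <- tensor$height
  vals <- numeric(0)
  for (k in seq_along(tensor$seed_grid_idx)) {
    g <- tensor$seed_grid_idx[k]
    rc <- c(((g - 1L) %% h) + 1L, ((g - 1L) %/% h) + 1L)
    map <- matrix(NA_real_, h, tensor$width)
    map[tensor$roi_idx] <- tensor$C[k, ]
    e <- local_eccentricity(map, rc, tensor$pixel_size_um, level)
    if (!is.null(e)) vals <- c(vals, e$eccentricity)
  }
  list(median_eccentricity = if (length(vals)) median(vals) else NA_real_,
       values = vals, n_defined = length(vals))
}
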