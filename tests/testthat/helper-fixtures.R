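# Shared fixtures and independent brute-force oracles.

# Small, fast generator configuration.
tiny_cfg <- function(...) {
  args <- list(grid_height_px = 48L, grid_width_px = 48L, pixel_size_um = 52,
               wavelength_um = 800, n_basis = 4L, n_events = 10L, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# Wrap a T x (h*w) Delta-F/F matrix as a dff_movie without running the
# baseline stage (for detector unit tests).
as_dff <- function(frames, h, w, pixel_size_um = 26, frame_rate_hz = 15,
                   roi_mask = NULL, vessel_mask = NULL) {
  m <- list(frames = frames, height = as.integer(h), width = as.integer(w),
            pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
            roi_mask = roi_mask %||% matrix(TRUE, h, w),
            vessel_mask = vessel_mask %||% matrix(FALSE, h, w))
  class(m) <- c("dff_movie", "wf_movie")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force sliding rank filter: sort every window explicitly.
rank_filter_oracle <- function(x, rank, window) {
  n <- length(x)
  half <- window %/% 2
  vapply(seq_len(n), function(t) {
    lo <- max(1, t - half); hi <- min(n, t + half)
    v <- sort(x[lo:hi])
    m <- length(v)
    r <- if (m < window) max(1, min(m, round(rank * m / window))) else rank
    v[r]
  }, numeric(1))
}

# Two-pass Pearson correlation oracle.
pearson_oracle <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Participation ratio straight from the pixel-space covariance matrix.
pr_oracle <- function(A) {
  S <- stats::cov(A)
  lam <- pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0)
  sum(lam)^2 / sum(lam^2)
}

# Flood-fill 8-connected labelling oracle (slow, obviously correct).
label8_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Isotropic or anisotropic Gaussian bump map on an h x w grid (um units).
gaussian_map <- function(h, w, pixel_size_um, center_rc, sx_um, sy_um = sx_um,
                         amp = 1, offset = 0) {
  co <- modcor:::grid_coords_um(h, w, pixel_size_um)
  cx <- center_rc[2] * pixel_size_um; cy <- center_rc[1] * pixel_size_um
  offset + amp * exp(-((co$x - cx)^2 / (2 * sx_um^2) +
                       (co$y - cy)^2 / (2 * sy_um^2)))
}

# Correlation tensor fixture with an analytic C(s, x) = f(dist) kernel.
analytic_tensor <- function(h, w, pixel_size_um, f, stride = 7) {
  n <- h * w
  idx <- seq_len(n)
  co <- modcor:::idx_coords_um(idx, h, pixel_size_um)
  sub <- idx[seq(1, n, by = stride)]
  C <- matrix(0, length(sub), n)
  for (i in seq_along(sub)) {
    d <- sqrt((co[, 1] - co[sub[i], 1])^2 + (co[, 2] - co[sub[i], 2])^2)
    C[i, ] <- f(d)
  }
  structure(list(C = C, seed_grid_idx = sub, roi_idx = idx, height = h,
                 width = w, pixel_size_um = pixel_size_um, coords = co),
            class = "correlation_tensor")
}

# Two-population block stack whose patterns crossfade from one fixed
# positive pattern to an orthogonal-in-time one across a known boundary.
crossfade_stack <- function(h = 48, w = 48, n = 60, px = 26,
                            boundary = c(21, 28), noise = 0.02,
                            seed = 7) {
  set.seed(seed)
  P <- h * w
  p1 <- runif(P, 0.5, 1.5); p2 <- runif(P, 0.5, 1.5)
  colg <- as.vector(col(matrix(0, h, w)))
  phi <- pmin(pmax((colg - (boundary[1] - 1)) / diff(boundary + c(-1, 0)), 0),
              1) * pi / 2
  A <- matrix(0, n, P)
  for (i in seq_len(n)) {
    a <- rnorm(1); b <- rnorm(1)
    A[i, ] <- cos(phi) * a * p1 + sin(phi) * b * p2 + noise * rnorm(P)
  }
  pattern_stack(A, h, w, px)
}

cell_positions <- function(pop) as.matrix(pop$cells[, c("x_um", "y_um")])
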