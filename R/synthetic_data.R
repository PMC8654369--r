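# Synthetic-data generator: modular activity movies with known ground truth.
#
# The generative model is deliberately statistical, not mechanistic: each
# spontaneous event is a random combination of a small set of fixed spatial
# basis patterns (band-pass filtered spatial noise whose angle-averaged
# autocorrelation peaks at a target wavelength), inserted into a positive
# fluorescence baseline with a smooth temporal envelope, slow drift and shot
# noise. This reproduces exactly the statistics the downstream analyses
# measure (modular scale, long-range correlations, low dimensionality)
# while keeping the ground truth known.

#' Configuration for the synthetic-data generator
#'
#' @param grid_height_px,grid_width_px image grid size in pixels.
#' @param pixel_size_um pixel pitch in micrometers.
#' @param wavelength_um target modular wavelength Lambda in micrometers: the
#'   radial position of the first secondary peak of the angle-averaged
#'   autocorrelation of the generated patterns.
#' @param n_basis number of underlying spatial basis patterns (sets the
#'   ground-truth dimensionality of the event ensemble).
#' @param n_events number of spontaneous events to insert.
#' @param event_duration_frames,inter_event_frames event length and gap
#'   between consecutive events, in frames.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param noise_sd additive Gaussian noise, in raw fluorescence units
#'   (baseline fluorescence is ~100 units).
#' @param baseline_drift_amp amplitude of a slow sinusoidal baseline drift,
#'   raw fluorescence units.
#' @param anisotropy_ratio >= 1; elongation of the band-pass kernel along a
#'   random axis, controlling local correlation eccentricity.
#' @param seed RNG seed; identical configurations and seeds give
#'   bit-identical output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(grid_height_px = 128L, grid_width_px = 128L,
                         pixel_size_um = 26, wavelength_um = 800,
                         n_basis = 8L, n_events = 20L,
                         event_duration_frames = 4L, inter_event_frames = 41L,
                         frame_rate_hz = 15, noise_sd = 2,
                         baseline_drift_amp = 2, anisotropy_ratio = 1,
                         seed = 1L) {
  cfg <- list(
    grid_height_px = as.integer(grid_height_px),
    grid_width_px = as.integer(grid_width_px),
    pixel_size_um = pixel_size_um, wavelength_um = wavelength_um,
    n_basis = as.integer(n_basis), n_events = as.integer(n_events),
    event_duration_frames = as.integer(event_duration_frames),
    inter_event_frames = as.integer(inter_event_frames),
    frame_rate_hz = frame_rate_hz, noise_sd = noise_sd,
    baseline_drift_amp = baseline_drift_amp,
    anisotropy_ratio = anisotropy_ratio, seed = seed
  )
  stopifnot(
    cfg$grid_height_px >= 4, cfg$grid_width_px >= 4,
    cfg$pixel_size_um > 0, cfg$n_basis >= 1, cfg$n_events >= 0,
    cfg$event_duration_frames >= 1, cfg$inter_event_frames >= 1,
    cfg$frame_rate_hz > 0, cfg$noise_sd >= 0, cfg$anisotropy_ratio >= 1
  )
  if (cfg$wavelength_um <= 2 * cfg$pixel_size_um)
    stop("wavelength_um must exceed twice the pixel size (Nyquist)")
  class(cfg) <- "synth_config"
  cfg
}

# Difference-of-Gaussians amplitude transfer function at angular spatial
# frequency k (rad/um): band-pass with peak set by sigma1 < sigma2 = 2*sigma1.
dog_transfer <- function(k, sigma1_um, sigma2_um) {
  exp(-k^2 * sigma1_um^2 / 2) - exp(-k^2 * sigma2_um^2 / 2)
}

# Gaussian annular band-pass in the frequency plane, centred on angular
# frequency k0 with width rel_width * k0. A narrow annulus makes the
# generated patterns quasi-periodic at a single spatial scale, so the
# measured wavelength is insensitive to the spectral tilt of any analysis
# band-pass applied downstream.
annulus_transfer <- function(k, k0, rel_width = 0.15) {
  sk <- rel_width * k0
  exp(-(k - k0)^2 / (2 * sk^2))
}

# Ensemble-expected radial autocorrelation of isotropic noise filtered by
# the annulus: C(r) proportional to the Hankel transform of the power
# spectrum.
annulus_radial_autocorr <- function(r_um, k0, rel_width = 0.15) {
  sk <- rel_width * k0
  k <- seq(1e-6, k0 + 6 * sk, length.out = 2048)
  P <- annulus_transfer(k, k0, rel_width)^2 * k
  vapply(r_um, function(r) sum(besselJ(k * r, 0) * P), numeric(1))
}

# Choose k0 so that the first secondary peak of the expected radial
# autocorrelation sits at `wavelength_um`. The peak position scales
# inversely with k0, so a fixed-point iteration converges in a couple of
# steps.
calibrate_annulus <- function(wavelength_um, rel_width = 0.15) {
  k0 <- 2 * pi / wavelength_um
  for (i in 1:3) {
    r <- seq(wavelength_um * 0.2, wavelength_um * 2.5, length.out = 800)
    cc <- annulus_radial_autocorr(r, k0, rel_width)
    pk <- first_local_max(r, cc)
    if (is.na(pk)) stop("autocorrelation calibration failed")
    k0 <- k0 * pk / wavelength_um
  }
  k0
}

# First strict interior local maximum of y(x), refined by quadratic
# interpolation of the three samples around the discrete peak.
first_local_max <- function(x, y) {
  n <- length(y)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) {
      d1 <- (y[i + 1] - y[i - 1]) / 2
      d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
      off <- if (d2 < 0) max(-1, min(1, -d1 / d2)) else 0
      return(x[i] + off * (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

# FFT frequencies (cycles per sample) for length n.
fft_freq <- function(n) {
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  f[seq_len(n)]
}

# Unseeded core: band-pass filtered white noise patterns, mean-subtracted,
# Gram-Schmidt orthogonalized, unit-normalized.
.modular_basis <- function(cfg) {
  h <- cfg$grid_height_px; w <- cfg$grid_width_px
  px <- cfg$pixel_size_um; lam <- cfg$wavelength_um
  if (lam > min(h, w) * px) stop("wavelength exceeds field of view")
  k0 <- calibrate_annulus(lam)
  fy <- fft_freq(h) / px
  fx <- fft_freq(w) / px
  theta <- runif(1, 0, pi)
  a <- cfg$anisotropy_ratio
  KX <- matrix(rep(fx, each = h), h, w) * 2 * pi
  KY <- matrix(rep(fy, w), h, w) * 2 * pi
  ku <- cos(theta) * KX + sin(theta) * KY
  kv <- -sin(theta) * KX + cos(theta) * KY
  keff <- sqrt((a * ku)^2 + kv^2)
  Fk <- annulus_transfer(keff, k0)
  P <- h * w
  B <- matrix(0, P, cfg$n_basis)
  for (j in seq_len(cfg$n_basis)) {
    # random-phase field with the exact band-pass power spectrum: the
    # phases of white noise are kept, the modulus equalized, so every
    # map's autocorrelation equals the calibrated kernel autocorrelation
    z <- matrix(rnorm(P), h, w)
    Z <- stats::fft(z)
    md <- Mod(Z)
    Z <- Z / ifelse(md > 0, md, 1)
    f <- Re(stats::fft(Z * Fk, inverse = TRUE)) / P
    v <- as.vector(f)
    v <- v - mean(v)
    if (j > 1) {
      prev <- B[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate basis pattern")
    B[, j] <- v / nv
  }
  list(basis = array(B, c(h, w, cfg$n_basis)),
       true_wavelength_um = lam, k0_rad_per_um = k0,
       anisotropy_axis = theta)
}

#' Generate an orthonormal modular pattern basis
#'
#' Each pattern is band-pass filtered spatial noise: white-noise phases
#' with a narrow Gaussian annular power spectrum whose peak frequency is
#' calibrated so that the angle-averaged autocorrelation has its first
#' secondary peak at the configured wavelength. Patterns are
#' mean-subtracted, orthogonalized and unit-normalized.
#'
#' @param cfg a [synth_config()].
#' @return list with `basis` (height x width x n_basis array),
#'   `true_wavelength_um`, and the calibrated peak frequency
#'   `k0_rad_per_um`.
#' @export
make_modular_basis <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_rng_seed(cfg$seed, .modular_basis(cfg))
}

# Event temporal envelope: half-cosine rise/fall over `d` frames, peak ~1.
event_envelope <- function(d) sin(pi * (seq_len(d) - 0.5) / d)

# Event spans for a movie: a lead-in gap, then alternating event/gap.
event_spans <- function(cfg) {
  d <- cfg$event_duration_frames; g <- cfg$inter_event_frames
  starts <- g + (seq_len(cfg$n_events) - 1L) * (d + g) + 1L
  cbind(start = starts, end = starts + d - 1L)
}

# Scale factor taking a weight-combination of unit-norm basis maps to
# approximately unit pixel standard deviation.
pattern_scale <- function(cfg) {
  sqrt(cfg$grid_height_px * cfg$grid_width_px / cfg$n_basis)
}

# Two jointly generated orthonormal bases on the same grid: `shared`
# carries the component common to paired populations, `independent` the
# population-private component.
dual_basis <- function(cfg) {
  cfg2 <- cfg
  cfg2$n_basis <- 2L * cfg$n_basis
  b <- .modular_basis(cfg2)
  k <- cfg$n_basis
  shared <- b
  shared$basis <- b$basis[, , seq_len(k), drop = FALSE]
  ind <- b
  ind$basis <- b$basis[, , k + seq_len(k), drop = FALSE]
  list(shared = shared, independent = ind)
}

# Build T x P fluorescence matrix given basis and event weights; an
# optional second basis/weight pair is added to the pattern fields.
.movie_frames <- function(cfg, basis, W, gain = 1, noise_sd = cfg$noise_sd,
                          mod_depth = 0.6, event_amplitude = 1,
                          f0_mean = 100, basis2 = NULL, W2 = NULL) {
  h <- cfg$grid_height_px; w <- cfg$grid_width_px; P <- h * w
  spans <- event_spans(cfg)
  T_n <- cfg$n_events * (cfg$event_duration_frames + cfg$inter_event_frames) +
    cfg$inter_event_frames
  B <- matrix(basis, P, cfg$n_basis)
  f0_tex <- gaussian_blur_masked(matrix(rnorm(P), h, w), min(h, w) / 4)
  f0_tex <- as.vector(f0_tex) / sd(as.vector(f0_tex))
  F0 <- f0_mean * (1 + 0.08 * f0_tex)
  drift <- cfg$baseline_drift_amp * sin(2 * pi * seq_len(T_n) / T_n)
  env <- event_envelope(cfg$event_duration_frames)
  Fmat <- matrix(rep(F0, each = T_n), T_n, P) + drift
  scl <- pattern_scale(cfg)
  if (cfg$n_events > 0) {
    Z <- (W %*% t(B)) * scl  # n_events x P pattern fields, unit pixel sd
    if (!is.null(basis2))
      Z <- Z + (W2 %*% t(matrix(basis2, P, cfg$n_basis))) * scl
    for (i in seq_len(cfg$n_events)) {
      u <- pmax(1 + mod_depth * Z[i, ], 0) * event_amplitude * gain
      fr <- spans[i, "start"]:spans[i, "end"]
      Fmat[fr, ] <- Fmat[fr, ] * (1 + outer(env, u))
    }
  }
  if (noise_sd > 0) Fmat <- Fmat + rnorm(length(Fmat), sd = noise_sd)
  Fmat[Fmat < 1e-3] <- 1e-3
  list(frames = Fmat, spans = spans, F0 = F0)
}

ground_truth <- function(cfg, basis_obj, W, spans) {
  lam <- if (!is.null(W) && nrow(W) >= 2)
    pmax(eigen(stats::cov(W), symmetric = TRUE,
               only.values = TRUE)$values, 0)
  else NA_real_
  gt <- list(
    basis_patterns = basis_obj$basis,
    event_weights = W,
    true_wavelength_um = basis_obj$true_wavelength_um,
    true_dimensionality = sum(lam)^2 / sum(lam^2),
    event_frame_spans = spans
  )
  class(gt) <- "ground_truth"
  gt
}

#' Synthesize a widefield fluorescence movie with known ground truth
#'
#' Events are inserted at known frame spans as a positive baseline field
#' modulated by `1 + g(t) * (event pattern)`, where the event pattern is a
#' random combination of the modular basis (rectified at zero), `g(t)` a
#' half-cosine envelope; slow sinusoidal drift and Gaussian noise are added.
#'
#' @param cfg a [synth_config()].
#' @param mod_depth modulation depth of the modular pattern relative to the
#'   spatially uniform event amplitude.
#' @param event_amplitude peak event amplitude as a fraction of baseline
#'   fluorescence (1 = 100 percent dF/F at the event peak).
#' @return list with `movie` (a [wf_movie()]) and `ground_truth`.
#' @export
synthesize_movie <- function(cfg, mod_depth = 0.6, event_amplitude = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  with_rng_seed(cfg$seed, {
    bs <- .modular_basis(cfg)
    W <- matrix(rnorm(cfg$n_events * cfg$n_basis), cfg$n_events, cfg$n_basis)
    mv <- .movie_frames(cfg, bs$basis, W, mod_depth = mod_depth,
                        event_amplitude = event_amplitude)
    movie <- wf_movie(
      frames = mv$frames, height = cfg$grid_height_px,
      width = cfg$grid_width_px, pixel_size_um = cfg$pixel_size_um,
      frame_rate_hz = cfg$frame_rate_hz
    )
    list(movie = movie, ground_truth = ground_truth(cfg, bs, W, mv$spans))
  })
}

#' Synthesize paired excitatory/inhibitory movies with a shared network
#'
#' With `alignment = 1` the two movies' events are identical weight draws
#' on one shared basis (they differ only by noise and indicator gain); with
#' `alignment = 0` the second movie's events come from an independent,
#' orthogonal pattern basis, so the two correlation networks are unrelated.
#' Intermediate values mix the shared and independent components with
#' amplitudes `alignment` and `sqrt(1 - alignment^2)`. (Sharing the basis
#' while only decorrelating weight draws would not destroy network
#' similarity: with more events than basis patterns both correlation
#' tensors converge to the same basis-determined structure regardless of
#' the weights.) The second movie is given a lower gain and higher noise,
#' emulating indicator differences.
#'
#' @param cfg a [synth_config()].
#' @param alignment in `[0, 1]`.
#' @inheritParams synthesize_movie
#' @return list with `movie_E`, `movie_I`, `ground_truth` (weights of both).
#' @export
synthesize_paired_EI_movies <- function(cfg, alignment = 1, mod_depth = 0.6,
                                        event_amplitude = 1) {
  stopifnot(inherits(cfg, "synth_config"), alignment >= 0, alignment <= 1)
  with_rng_seed(cfg$seed, {
    dbl <- dual_basis(cfg)
    bs <- dbl$shared; bs_ind <- dbl$independent
    n <- cfg$n_events; k <- cfg$n_basis
    WE <- matrix(rnorm(n * k), n, k)
    WI <- alignment * WE
    WI2 <- sqrt(1 - alignment^2) * matrix(rnorm(n * k), n, k)
    mvE <- .movie_frames(cfg, bs$basis, WE, gain = 1,
                         noise_sd = cfg$noise_sd, mod_depth = mod_depth,
                         event_amplitude = event_amplitude)
    mvI <- .movie_frames(cfg, bs$basis, WI, basis2 = bs_ind$basis, W2 = WI2,
                         gain = 0.8,
                         noise_sd = 1.3 * cfg$noise_sd, mod_depth = mod_depth,
                         event_amplitude = event_amplitude)
    gt <- ground_truth(cfg, bs, WE, mvE$spans)
    gt$event_weights_I <- WI
    gt$event_weights_I_independent <- WI2
    gt$alignment <- alignment
    list(
      movie_E = wf_movie(mvE$frames, cfg$grid_height_px, cfg$grid_width_px,
                         cfg$pixel_size_um, cfg$frame_rate_hz),
      movie_I = wf_movie(mvI$frames, cfg$grid_height_px, cfg$grid_width_px,
                         cfg$pixel_size_um, cfg$frame_rate_hz),
      ground_truth = gt
    )
  })
}

#' Synthesize an event pattern stack directly from the basis model
#'
#' Bypasses movie synthesis and event detection: returns band-limited event
#' patterns `A_i = scale * (W_i . basis) + noise` as a [pattern_stack()].
#' Useful for ensemble-level analyses (dimensionality, similarity,
#' surrogates) where the imaging and detection stages are not under test.
#'
#' @param cfg a [synth_config()].
#' @param n_events number of patterns (defaults to `cfg$n_events`).
#' @param noise_sd additive white noise in units of pattern standard
#'   deviation (patterns are scaled to unit pixel s.d.).
#' @param alignment optional; if not `NULL`, returns a list of two stacks
#'   sharing the network structure to degree `alignment` (see
#'   [synthesize_paired_EI_movies()]).
#' @return a [pattern_stack()], or a list of two for paired stacks.
#' @export
synthesize_pattern_stack <- function(cfg, n_events = NULL, noise_sd = 0,
                                     alignment = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- as.integer(n_events %||% cfg$n_events)
  with_rng_seed(cfg$seed, {
    P <- cfg$grid_height_px * cfg$grid_width_px
    scl <- pattern_scale(cfg)
    mk <- function(bs, Z, W) {
      A <- Z * scl
      if (noise_sd > 0) A <- A + rnorm(length(A), sd = noise_sd)
      st <- pattern_stack(A, cfg$grid_height_px, cfg$grid_width_px,
                          cfg$pixel_size_um)
      attr(st, "ground_truth") <- ground_truth(cfg, bs, W, NULL)
      st
    }
    if (is.null(alignment)) {
      bs <- .modular_basis(cfg)
      B <- matrix(bs$basis, P, cfg$n_basis)
      WE <- matrix(rnorm(n * cfg$n_basis), n, cfg$n_basis)
      return(mk(bs, WE %*% t(B), WE))
    }
    stopifnot(alignment >= 0, alignment <= 1)
    dbl <- dual_basis(cfg)
    B1 <- matrix(dbl$shared$basis, P, cfg$n_basis)
    B2 <- matrix(dbl$independent$basis, P, cfg$n_basis)
    WE <- matrix(rnorm(n * cfg$n_basis), n, cfg$n_basis)
    WI2 <- matrix(rnorm(n * cfg$n_basis), n, cfg$n_basis)
    ZE <- WE %*% t(B1)
    ZI <- alignment * (WE %*% t(B1)) + sqrt(1 - alignment^2) * (WI2 %*% t(B2))
    list(stack_E = mk(dbl$shared, ZE, WE),
         stack_I = mk(dbl$shared, ZI, alignment * WE))
  })
}

#' Synthesize a two-photon cell population with shared modular drive
#'
#' Cells are placed uniformly at random in a square field of view; each
#' cell's fluorescence follows the local value of the shared modular event
#' pattern at its position, plus private noise, plus a scaled common
#' neuropil trace. E/I labels are assigned independently of position.
#'
#' @param cfg a [synth_config()] (wavelength, events and noise are reused).
#' @param n_cells number of cells (>= 2).
#' @param frac_inhibitory fraction labelled inhibitory, in (0, 1).
#' @param fov_um side of the square field of view, micrometers.
#' @param neuropil_gain contamination gain of the shared neuropil trace
#'   added to each raw trace (recoverable by subtraction with alpha equal
#'   to this gain).
#' @param ei_alignment 1 = E and I cells share the same event patterns;
#'   0 = inhibitory cells are driven by an independent pattern draw.
#' @return an object of class `cell_population`: `cells` data frame
#'   (cell_id, x_um, y_um, type), `raw` and `neuropil` T x n_cells trace
#'   matrices, `frame_rate_hz`, and a `ground_truth` with the noiseless
#'   cellular signals and event spans.
#' @export
synthesize_cell_population <- function(cfg, n_cells = 80,
                                       frac_inhibitory = 0.35,
                                       fov_um = 1200, neuropil_gain = 0.6,
                                       ei_alignment = 1) {
  stopifnot(inherits(cfg, "synth_config"), n_cells >= 2,
            frac_inhibitory > 0, frac_inhibitory < 1)
  if (fov_um < cfg$pixel_size_um) stop("fov smaller than one pixel")
  with_rng_seed(cfg$seed, {
    px <- cfg$pixel_size_um
    npx <- as.integer(ceiling(fov_um / px)) + 2L
    gcfg <- cfg
    gcfg$grid_height_px <- npx
    gcfg$grid_width_px <- npx
    dbl <- dual_basis(gcfg)
    P <- npx * npx
    B1 <- matrix(dbl$shared$basis, P, cfg$n_basis)
    B2 <- matrix(dbl$independent$basis, P, cfg$n_basis)
    scl <- sqrt(P / cfg$n_basis)
    n <- cfg$n_events
    WE <- matrix(rnorm(n * cfg$n_basis), n, cfg$n_basis)
    WI2 <- matrix(rnorm(n * cfg$n_basis), n, cfg$n_basis)
    ZE <- (WE %*% t(B1)) * scl
    ZI <- (ei_alignment * (WE %*% t(B1)) +
             sqrt(1 - ei_alignment^2) * (WI2 %*% t(B2))) * scl
    xs <- runif(n_cells, 0, fov_um)
    ys <- runif(n_cells, 0, fov_um)
    type <- ifelse(runif(n_cells) < frac_inhibitory, "I", "E")
    # bilinear interpolation of a pattern field at the cell positions
    interp <- function(z, x_um, y_um) {
      zm <- matrix(z, npx, npx)
      gx <- x_um / px + 1; gy <- y_um / px + 1
      i0 <- pmin(pmax(floor(gy), 1), npx - 1); j0 <- pmin(pmax(floor(gx), 1), npx - 1)
      fy <- gy - i0; fx <- gx - j0
      zm[cbind(i0, j0)] * (1 - fy) * (1 - fx) +
        zm[cbind(i0 + 1, j0)] * fy * (1 - fx) +
        zm[cbind(i0, j0 + 1)] * (1 - fy) * fx +
        zm[cbind(i0 + 1, j0 + 1)] * fy * fx
    }
    spans <- event_spans(cfg)
    T_n <- n * (cfg$event_duration_frames + cfg$inter_event_frames) +
      cfg$inter_event_frames
    env <- event_envelope(cfg$event_duration_frames)
    sig <- matrix(0, T_n, n_cells)   # noiseless dF/F signal per cell
    np <- numeric(T_n)               # shared neuropil dF/F trace
    for (i in seq_len(n)) {
      vals_E <- pmax(1 + 0.6 * interp(ZE[i, ], xs, ys), 0)
      vals_I <- pmax(1 + 0.6 * interp(ZI[i, ], xs, ys), 0)
      v <- ifelse(type == "E", vals_E, vals_I)
      fr <- spans[i, "start"]:spans[i, "end"]
      sig[fr, ] <- sig[fr, ] + outer(env, v)
      np[fr] <- np[fr] + env * mean(pmax(1 + 0.6 * ZE[i, ], 0))
    }
    F0 <- 100
    neuropil <- F0 * (1 + np) +
      rnorm(T_n, sd = 0.2 * cfg$noise_sd)
    raw <- F0 * (1 + sig) + neuropil_gain * neuropil +
      matrix(rnorm(T_n * n_cells, sd = cfg$noise_sd), T_n, n_cells)
    pop <- list(
      cells = data.frame(cell_id = seq_len(n_cells), x_um = xs, y_um = ys,
                         type = type, stringsAsFactors = FALSE),
      raw = raw,
      neuropil = matrix(neuropil, T_n, n_cells),
      frame_rate_hz = cfg$frame_rate_hz,
      fov_um = fov_um,
      ground_truth = list(signal = sig, event_frame_spans = spans,
                          neuropil_trace = neuropil, f0 = F0,
                          neuropil_gain = neuropil_gain)
    )
    class(pop) <- "cell_population"
    pop
  })
}
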