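# Fractures, wavelength, eccentricity, domain fits.

test_that("fracture strength is zero when all seeds share one pattern", {
  set.seed(3)
  h <- 20
  A <- outer(rnorm(30), runif(h * h, 0.5, 1.5))  # rank-1, positive pattern
  tz <- suppressWarnings(correlation_tensor(pattern_stack(A, h, h, 26)))
  fs <- fracture_strength(tz)
  expect_equal(max(abs(fs), na.rm = TRUE), 0)
})

test_that("fracture strength localizes at a pattern boundary", {
  st <- crossfade_stack()
  tz <- correlation_tensor(st)
  fs <- fracture_strength(tz)
  expect_true(all(fs >= 0, na.rm = TRUE))
  colmax <- apply(fs, 2, max)
  band <- 21:28
  expect_gt(mean(colmax[band]), 10 * mean(colmax[c(1:15, 34:48)]))
  # smooth tensors change less than block tensors
  smooth_A <- outer(rnorm(60), runif(48 * 48, 0.5, 1.5)) +
    0.02 * matrix(rnorm(60 * 48 * 48), 60)
  tz_s <- correlation_tensor(pattern_stack(smooth_A, 48, 48, 26))
  expect_lt(max(fracture_strength(tz_s), na.rm = TRUE),
            max(fs, na.rm = TRUE))
})

test_that("fracture lines skeletonize the boundary and magnitude is positive", {
  st <- crossfade_stack()
  tz <- correlation_tensor(st)
  fs <- fracture_strength(tz)
  fm <- fracture_lines(fs, st$pixel_size_um)
  expect_s3_class(fm, "fracture_map")
  expect_gt(sum(fm$lines), 10)
  sk_cols <- ((which(fm$lines) - 1) %/% 48) + 1
  peak_col <- which.max(apply(fs, 2, max))
  expect_true(all(abs(sk_cols - peak_col) <= 2))
  expect_gt(fm$magnitude, 0)
  # constant strength: near-empty skeleton, undefined magnitude
  expect_warning(fm0 <- fracture_lines(matrix(1, 48, 48), 26),
                 "empty|exclusion")
  expect_true(is.na(fm0$magnitude))
})

test_that("fracture magnitude approximates the strength contrast", {
  # synthetic strength field: a band at 3e-3, background 1e-3 (per um)
  h <- 60; px <- 26
  k <- 1e-3
  strength <- matrix(k, h, h)
  strength[, 29:33] <- 3 * k
  fm <- fracture_lines(strength, px)
  expect_gt(sum(fm$lines), 0)
  sk_cols <- ((which(fm$lines) - 1) %/% h) + 1
  expect_true(all(sk_cols >= 28 & sk_cols <= 34))
  expect_equal(fm$magnitude, 2 * k, tolerance = 0.2)
})

test_that("wavelength is read off the angle-averaged correlation profile", {
  f_cos <- function(d) cos(2 * pi * d / 800)
  tz <- analytic_tensor(40, 40, 52, f_cos)
  wl <- correlation_wavelength(tz)
  expect_lt(abs(wl$wavelength_mm - 0.8), 0.052 + 1e-9)
  # positive scaling leaves the estimate unchanged
  tz2 <- tz; tz2$C <- 0.37 * tz$C
  expect_equal(correlation_wavelength(tz2)$wavelength_mm, wl$wavelength_mm)
  # monotone decay: flagged undefined
  tz3 <- analytic_tensor(40, 40, 52, function(d) exp(-d / 400))
  expect_warning(wl3 <- correlation_wavelength(tz3), "undefined")
  expect_true(is.na(wl3$wavelength_mm))
})

test_that("eccentricity of iso-correlation contours matches closed forms", {
  px <- 20
  iso <- gaussian_map(81, 81, px, c(41, 41), 200)
  e_iso <- local_eccentricity(iso, c(41, 41), px)
  expect_lt(e_iso$eccentricity, 0.05)
  # 2:1 axis ratio -> eccentricity sqrt(3)/2
  an <- gaussian_map(81, 81, px, c(41, 41), 400, 200)
  e_an <- local_eccentricity(an, c(41, 41), px)
  expect_equal(e_an$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  # orientation equivariance under 90-degree rotation of the map
  e_rot <- local_eccentricity(t(an), c(41, 41), px)
  expect_equal(abs(e_rot$phi - e_an$phi) %% pi, pi / 2, tolerance = 0.05)
  # contour absent (level above the map maximum elsewhere): NULL
  low <- gaussian_map(81, 81, px, c(41, 41), 200, amp = 0.5)
  expect_null(local_eccentricity(low, c(41, 41), px, level = 0.7))
})

test_that("direct ellipse fit is exact on noiseless ellipses", {
  th <- seq(0, 2 * pi, length.out = 100)[-100]
  x <- 300 * cos(th); y <- 150 * sin(th)
  phi0 <- 0.7
  xr <- cos(phi0) * x - sin(phi0) * y + 40
  yr <- sin(phi0) * x + cos(phi0) * y - 20
  f <- modcor:::fit_ellipse(xr, yr)
  expect_equal(f$s1, 300, tolerance = 1e-6)
  expect_equal(f$s2, 150, tolerance = 1e-6)
  expect_equal(f$phi, phi0, tolerance = 1e-6)
  # circle: eccentricity formula gives exactly zero
  fc <- modcor:::fit_ellipse(100 * cos(th), 100 * sin(th))
  expect_equal(sqrt(fc$s1^2 - fc$s2^2) / fc$s1, 0, tolerance = 1e-6)
})

test_that("domain fits recover closed-form widths and parameters", {
  px <- 20
  pat <- gaussian_map(81, 81, px, c(41, 41), 150, 100, amp = 2, offset = 0.1)
  f <- fit_domain(pat, c(41, 41), px)
  expect_equal(f$fwtm_minor_um, 2 * 100 * sqrt(2 * log(10)), tolerance = 1e-4)
  expect_equal(f$fwtm_minor_um / f$fwhm_minor_um, sqrt(log(10) / log(2)),
               tolerance = 1e-9)
  expect_equal(f$fwtm_minor_um, 429.193, tolerance = 1e-3)
  # zero-noise recovery of all 7 parameters of a rotated Gaussian
  co <- modcor:::grid_coords_um(81, 81, px)
  th0 <- 0.6; sx <- 150; sy <- 100
  a0 <- cos(th0)^2 / (2 * sx^2) + sin(th0)^2 / (2 * sy^2)
  b0 <- -sin(2 * th0) / (4 * sx^2) + sin(2 * th0) / (4 * sy^2)
  c0 <- sin(th0)^2 / (2 * sx^2) + cos(th0)^2 / (2 * sy^2)
  dx <- co$x - 41 * px; dy <- co$y - 41 * px
  pat2 <- 0.05 + 1.5 * exp(-(a0 * dx^2 + 2 * b0 * dx * dy + c0 * dy^2))
  f2 <- fit_domain(pat2, c(41, 41), px)
  expect_equal(f2$H, 1.5, tolerance = 1e-6)
  # (sx, sy, theta) is identified up to axis swap with theta +/- pi/2;
  # compare the canonical form: sorted sigmas, major-axis angle mod pi,
  # and the (invariant) quadratic-form coefficients
  expect_equal(sort(c(f2$sigma_x_um, f2$sigma_y_um)), c(sy, sx),
               tolerance = 1e-5)
  ax_fit <- if (f2$sigma_x_um >= f2$sigma_y_um) f2$theta else
    f2$theta + pi / 2
  expect_equal(ax_fit %% pi, th0 %% pi, tolerance = 1e-5)
  expect_equal(f2$y0, 0.05, tolerance = 1e-6)
  expect_equal(c(f2$a, f2$b, f2$c), c(a0, b0, c0), tolerance = 1e-6)
})

test_that("domain sizes are recovered from noisy synthetic domains", {
  set.seed(8)
  px <- 26
  errs <- numeric(0)
  for (i in 1:20) {
    sig <- runif(1, 80, 160)
    amp <- 1
    pat <- gaussian_map(61, 61, px, c(31, 31), sig * runif(1, 1, 1.4), sig,
                        amp = amp) +
      matrix(rnorm(61 * 61, sd = amp / 5), 61, 61)
    f <- fit_domain(pat, c(31, 31), px)
    if (!is.null(f)) errs <- c(errs, (f$sigma_minor_um - sig) / sig)
  }
  expect_gt(length(errs), 15)
  expect_lt(abs(median(errs)), 0.1)
})

test_that("fracture strength is invariant to linear rescaling of patterns", {
  st <- crossfade_stack(n = 30)
  tz1 <- correlation_tensor(st)
  st2 <- st
  st2$patterns <- 3.2 * st$patterns + 7
  tz2 <- correlation_tensor(st2)
  expect_equal(fracture_strength(tz1), fracture_strength(tz2),
               tolerance = 1e-10)
})
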