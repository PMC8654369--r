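# Band-pass filtering, correlation tensors, surrogates, maxima.

test_that("band-pass removes DC and matches the analytic transfer function", {
  h <- 128; px <- 26
  # constant frame -> zero
  stc <- pattern_stack(matrix(5, 2, h * h), h, h, px)
  out <- bandpass_and_downsample(stc)
  expect_lt(max(abs(out$patterns)), 1e-10)
  # sinusoid between the cutoffs: attenuation matches the DoG closed form
  co <- modcor:::grid_coords_um(h, h, px)
  lam_s <- 400
  fr <- sin(2 * pi * co$x / lam_s)
  st <- pattern_stack(rbind(as.vector(fr), as.vector(fr)), h, h, px)
  filt <- matrix(bandpass_and_downsample(st)$patterns[1, ], h, h)
  interior <- 30:99
  slope <- coef(lm(as.vector(filt[interior, interior]) ~
                     as.vector(fr[interior, interior])))[2]
  analytic <- modcor:::dog_transfer(2 * pi / lam_s, 26, 195)
  expect_lt(abs(slope - analytic) / analytic, 0.02)
  expect_error(bandpass_and_downsample(st, sigma_low_um = 200,
                                       sigma_high_um = 100), "smaller")
})

test_that("block downsampling preserves constant-by-block images", {
  h <- 12; fac_px <- 78  # factor 3 at 26 um/px
  blocks <- matrix(rep(rep(1:4, each = 3), 12), h, h) +
    matrix(rep(rep(c(0, 10, 20, 30), each = 3), each = 12), h, h)
  st <- pattern_stack(rbind(as.vector(blocks)), 12, 12, 26)
  ds <- modcor:::block_average(blocks, 3L)
  expect_equal(dim(ds), c(4, 4))
  expect_equal(as.vector(ds), as.vector(blocks[seq(1, 12, 3), seq(1, 12, 3)]))
})

test_that("correlation patterns equal a two-pass Pearson oracle", {
  # hand example: seed values (1,2,3), target (1,2,4)
  A <- cbind(c(1, 2, 3), c(1, 2, 4), c(2, 1, 3), c(-1, -2, -3))
  A <- cbind(A, matrix(rnorm(3 * 12, sd = 2), 3, 12))
  st <- pattern_stack(A, 4, 4, 26)
  tz <- correlation_tensor(st)
  expect_equal(tz$C[1, 2], pearson_oracle(A[, 1], A[, 2]))
  expect_equal(tz$C[1, 2], 0.9819805, tolerance = 1e-7)
  expect_equal(tz$C[1, 4], -1)
  # full oracle equivalence on a random stack
  set.seed(4)
  A2 <- matrix(rnorm(20 * 36), 20, 36)
  tz2 <- correlation_tensor(pattern_stack(A2, 6, 6, 26))
  for (i in c(1, 7, 30)) for (j in c(2, 19, 36)) {
    expect_equal(tz2$C[i, j], pearson_oracle(A2[, i], A2[, j]),
                 tolerance = 1e-12)
  }
  # symmetry and unit diagonal
  expect_lt(max(abs(tz2$C - t(tz2$C))), 1e-10)
  expect_lt(max(abs(diag(tz2$C) - 1)), 1e-10)
})

test_that("degenerate pixels are dropped; degenerate seeds rejected", {
  A <- matrix(rnorm(10 * 9), 10, 9)
  A[, 5] <- 2  # constant pixel
  st <- pattern_stack(A, 3, 3, 26)
  expect_warning(tz <- correlation_tensor(st), "zero-variance")
  expect_false(5 %in% tz$roi_idx)
  expect_error(suppressWarnings(correlation_tensor(st, seeds = 5)),
               "degenerate seed")
  expect_error(correlation_tensor(pattern_stack(A[1, , drop = FALSE],
                                                3, 3, 26)), "at least 2")
})

test_that("surrogate transforms behave as rigid motions of the grid", {
  set.seed(1)
  h <- 20
  v <- rnorm(h * h)
  roi <- matrix(TRUE, h, h)
  tp <- function(...) modcor:::transform_pattern(v, h, h, 26, roi, ...)
  expect_identical(tp(0, 0, 0, FALSE, FALSE), v)
  # 180-degree rotation applied twice is the identity
  t1 <- modcor:::transform_pattern(tp(180, 0, 0, FALSE, FALSE),
                                   h, h, 26, roi, 180, 0, 0, FALSE, FALSE)
  expect_equal(t1, v)
  # value multiset preserved for bijective transforms (90-degree subgroup)
  for (ang in c(0, 90, 180, 270)) {
    tv <- tp(ang, 26, -52, TRUE, FALSE)
    expect_true(all(sort(tv[!is.na(tv)]) %in% sort(v)))
  }
  # pure shift moves values where expected
  ts <- tp(0, 26, 0, FALSE, FALSE)   # shift one pixel in x (columns)
  expect_equal(matrix(ts, h, h)[, 2:h], matrix(v, h, h)[, 1:(h - 1)])
})

test_that("realized surrogates keep stack geometry and event count", {
  cfg <- tiny_cfg(n_events = 8L)
  st <- synthesize_pattern_stack(cfg)
  se <- make_surrogates(st, n = 3, seed = 2)
  s1 <- realize_surrogate(se, 1)
  expect_s3_class(s1, "pattern_stack")
  expect_equal(nrow(s1$patterns), nrow(st$patterns))
  expect_equal(s1$pixel_size_um, st$pixel_size_um)
  # determinism of the transform log
  se2 <- make_surrogates(st, n = 3, seed = 2)
  expect_identical(se$angle_deg, se2$angle_deg)
  expect_identical(realize_surrogate(se2, 1)$patterns, s1$patterns)
  expect_true(all(se$angle_deg %% 10 == 0))
  expect_true(all(abs(se$dx_um) <= 450) && all(se$dx_um %% 26 == 0))
})

test_that("correlation maxima are separated and exclude the seed peak", {
  h <- 60; px <- 26
  # single off-seed bump
  m1 <- gaussian_map(h, h, px, c(20, 45), 120)
  mx1 <- correlation_maxima(m1, px, seed_rc = c(50, 10))
  expect_equal(nrow(mx1), 1)
  expect_equal(c(mx1$row, mx1$col), c(20, 45))
  # two bumps 494 um apart: only the higher kept
  m2 <- gaussian_map(h, h, px, c(20, 20), 80, amp = 1) +
    gaussian_map(h, h, px, c(20, 39), 80, amp = 0.6)
  mx2 <- correlation_maxima(m2, px, seed_rc = c(55, 55),
                            min_separation_um = 800)
  expect_equal(nrow(mx2), 1)
  expect_equal(c(mx2$row, mx2$col), c(20, 20))
  # cosine ring: retained maxima mutually >= 800 um apart
  co <- modcor:::grid_coords_um(h, h, px)
  r <- sqrt((co$x - 30 * px)^2 + (co$y - 30 * px)^2)
  m3 <- cos(2 * pi * r / 800)
  mx3 <- correlation_maxima(m3, px, seed_rc = c(30, 30))
  expect_gt(nrow(mx3), 2)
  dmat <- as.matrix(dist(cbind(mx3$x_um, mx3$y_um)))
  expect_true(all(dmat[upper.tri(dmat)] >= 800))
})

test_that("self-identical surrogate null gives p = 1", {
  cfg <- tiny_cfg(n_events = 12L)
  st <- synthesize_pattern_stack(cfg)
  seeds <- seed_subsample(st, 40)
  tz <- correlation_tensor(st, seeds = seeds)
  se <- make_surrogates(st, n = 10, seed = 3)
  se$angle_deg[] <- 0; se$dx_um[] <- 0; se$dy_um[] <- 0
  se$flip_x[] <- FALSE; se$flip_y[] <- FALSE
  lr <- long_range_strength(tz, se, band_um = c(500, 1200))
  expect_equal(lr$p, 1)
  expect_equal(length(lr$surrogate_stats), 10)
  expect_true(all(lr$surrogate_stats == lr$statistic))
})
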