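# Participation-ratio dimensionality and second-order network similarity.

test_that("participation ratio matches closed forms", {
  # balanced +/- repeats of 10 orthonormal patterns: d_eff = 10
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(64 * 10), 64, 10)))
  A <- rbind(t(Q), -t(Q), t(Q), -t(Q))
  st <- pattern_stack(A, 8, 8, 26)
  expect_equal(effective_dimensionality(st)$d_eff, 10, tolerance = 1e-6)
  # eigenvalue spectrum {4, 1}: d_eff = 25/17
  a <- c(sqrt(3), -sqrt(3), sqrt(3), -sqrt(3))
  b <- c(sqrt(0.75), sqrt(0.75), -sqrt(0.75), -sqrt(0.75))
  A2 <- outer(a, Q[, 1]) + outer(b, Q[, 2])
  st2 <- pattern_stack(A2, 8, 8, 26)
  expect_equal(effective_dimensionality(st2)$d_eff, 25 / 17,
               tolerance = 1e-10)
  expect_error(effective_dimensionality(
    pattern_stack(matrix(1, 5, 64), 8, 8, 26)), "undefined|constant")
})

test_that("Gram-matrix route equals the pixel-covariance eigendecomposition", {
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(15 * 49), 15, 49)
    st <- pattern_stack(A, 7, 7, 26)
    expect_equal(effective_dimensionality(st)$d_eff, pr_oracle(A),
                 tolerance = 1e-8)
  }
})

test_that("d_eff is invariant to scaling and pixel permutation, bounded by rank", {
  set.seed(6)
  W <- matrix(rnorm(30 * 3), 30, 3)
  B <- matrix(rnorm(3 * 49), 3, 49)
  A <- W %*% B
  st <- pattern_stack(A, 7, 7, 26)
  d <- effective_dimensionality(st)$d_eff
  st_s <- st; st_s$patterns <- 11 * A
  expect_equal(effective_dimensionality(st_s)$d_eff, d, tolerance = 1e-10)
  st_p <- st; st_p$patterns <- A[, sample(49)]
  expect_equal(effective_dimensionality(st_p)$d_eff, d, tolerance = 1e-10)
  expect_gte(d, 1)
  expect_lte(d, 3 + 1e-10)
})

test_that("subsampled dimensionality is deterministic and degenerates correctly", {
  set.seed(7)
  # rank-1 stack (amplitude-jittered single pattern): d_eff = 1 always
  A1 <- outer(rnorm(40), rnorm(64))
  st1 <- pattern_stack(A1, 8, 8, 26)
  r1 <- subsampled_dimensionality(st1, n = 10, reps = 20, seed = 1)
  expect_equal(r1$median_d_eff, 1, tolerance = 1e-10)
  # determinism under a fixed seed
  A <- matrix(rnorm(40 * 64), 40, 64)
  st <- pattern_stack(A, 8, 8, 26)
  expect_identical(subsampled_dimensionality(st, 10, 30, seed = 4),
                   subsampled_dimensionality(st, 10, 30, seed = 4))
  # n = N: every draw equals the full-stack value
  rN <- subsampled_dimensionality(st, n = 40, reps = 5, seed = 2)
  expect_equal(rN$values, rep(effective_dimensionality(st)$d_eff, 5),
               tolerance = 1e-8)
  expect_error(subsampled_dimensionality(st, n = 41), "insufficient")
})

test_that("dimensionality of low-rank ensembles is recovered", {
  # the sample-covariance participation ratio is biased low by ~ (d + 1)/N,
  # so the tolerance must scale with d at N = 200 events
  for (d in c(4, 8, 16)) {
    cfg <- tiny_cfg(n_basis = d, seed = 30 + d)
    st <- synthesize_pattern_stack(cfg, n_events = 200, noise_sd = 0)
    tol <- if (d <= 8) 0.05 else 0.10
    expect_lt(abs(effective_dimensionality(st)$d_eff - d) / d, tol)
  }
})

test_that("network similarity is exact on identical and negated tensors", {
  cfg <- tiny_cfg(n_events = 20L)
  st <- synthesize_pattern_stack(cfg, noise_sd = 0.2)
  seeds <- seed_subsample(st, 30)
  tz <- correlation_tensor(st, seeds = seeds)
  s_same <- network_similarity(tz, tz)
  expect_true(all(abs(s_same$similarity - 1) < 1e-12))
  tz_neg <- tz; tz_neg$C <- -tz$C
  s_neg <- network_similarity(tz, tz_neg)
  expect_true(all(abs(s_neg$similarity + 1) < 1e-12))
  # symmetry in the two tensors
  st2 <- synthesize_pattern_stack(tiny_cfg(n_events = 20L, seed = 8L),
                                  noise_sd = 0.2)
  tz2 <- correlation_tensor(st2, seeds = seeds)
  sab <- network_similarity(tz, tz2)
  sba <- network_similarity(tz2, tz)
  expect_equal(sab$similarity, sba$similarity, tolerance = 1e-12)
})

test_that("split-half bound reflects sampling noise", {
  cfg <- tiny_cfg(n_events = 80L, seed = 9L)
  st_clean <- synthesize_pattern_stack(cfg, n_events = 80, noise_sd = 0)
  seeds <- seed_subsample(st_clean, 40)
  b_clean <- split_half_bound(st_clean, reps = 10, seed = 1, seeds = seeds)
  expect_gt(b_clean$median, 0.9)
  expect_gt(min(b_clean$values), 0.8)
  st_noise <- pattern_stack(matrix(rnorm(40 * 48 * 48), 40), 48, 48, 52)
  b_noise <- split_half_bound(st_noise, reps = 10, seed = 1, seeds = seeds)
  expect_lt(abs(b_noise$median), 0.15)
  expect_identical(split_half_bound(st_clean, reps = 5, seed = 3,
                                    seeds = seeds),
                   split_half_bound(st_clean, reps = 5, seed = 3,
                                    seeds = seeds))
  expect_error(split_half_bound(pattern_stack(matrix(rnorm(3 * 4), 3), 2, 2,
                                              26)), "at least 4")
})

test_that("E-vs-I similarity tracks the alignment parameter monotonically", {
  meds <- vapply(c(0, 0.5, 1), function(al) {
    vals <- vapply(1:5, function(s) {
      cfg <- tiny_cfg(n_events = 40L, seed = 100 + s)
      pr <- synthesize_pattern_stack(cfg, n_events = 40, noise_sd = 0.3,
                                     alignment = al)
      seeds <- seed_subsample(pr$stack_E, 60)
      tE <- correlation_tensor(pr$stack_E, seeds = seeds)
      tI <- correlation_tensor(pr$stack_I, seeds = seeds)
      median(network_similarity(tE, tI)$similarity)
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_gt(meds[3], 0.9)
  expect_lt(abs(meds[1]), 0.25)
})

test_that("aligned pairs sit at or above the split-half bound per seed draw", {
  cfg <- tiny_cfg(n_events = 40L, seed = 12L)
  pr <- synthesize_pattern_stack(cfg, n_events = 40, noise_sd = 0.3,
                                 alignment = 1)
  seeds <- seed_subsample(pr$stack_E, 60)
  tE <- correlation_tensor(pr$stack_E, seeds = seeds)
  tI <- correlation_tensor(pr$stack_I, seeds = seeds)
  obs <- median(network_similarity(tE, tI)$similarity)
  bound <- split_half_bound(pr$stack_I, reps = 20, seed = 2, seeds = seeds)
  expect_gte(obs, bound$ci95[1])
})

test_that("exclusion sweep reports identical tensors as similarity one", {
  cfg <- tiny_cfg(n_events = 20L, seed = 13L)
  st <- synthesize_pattern_stack(cfg, noise_sd = 0.2)
  seeds <- seed_subsample(st, 40)
  tz <- correlation_tensor(st, seeds = seeds)
  sw <- exclusion_sweep(tz, tz, st, radii_um = c(400, 800), n_surr = 5,
                        seed = 1, seeds = seeds)
  expect_true(all(abs(sw$similarity - 1) < 1e-12))
  expect_true(all(sw$exceeds_null))
})
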