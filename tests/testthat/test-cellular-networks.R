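# Two-photon cellular analyses.

make_pop <- function(seed = 5, n_cells = 90, ei_alignment = 1,
                     noise_sd = 1, n_events = 40L, fov_um = 1200) {
  cfg <- tiny_cfg(n_events = n_events, inter_event_frames = 26L,
                  noise_sd = noise_sd, seed = seed)
  synthesize_cell_population(cfg, n_cells = n_cells, fov_um = fov_um,
                             ei_alignment = ei_alignment)
}

test_that("population event frames are detected and z-scored per frame", {
  pop <- make_pop()
  dff <- cell_dff(pop)
  ev <- detect_cell_event_frames(dff)
  expect_equal(nrow(ev$blocks), 40)
  # frame-wise z-scoring: mean 0, sd 1 across cells in every event frame
  expect_lt(max(abs(colMeans(ev$z))), 1e-12)
  expect_equal(apply(ev$z, 2, sd), rep(1, ncol(ev$z)), tolerance = 1e-12)
  # silent population: no event frames
  expect_warning(ev0 <- detect_cell_event_frames(matrix(0, 500, 20)),
                 "no qualifying")
  expect_length(ev0$frames, 0)
})

test_that("pairwise correlations match the two-pass oracle exactly", {
  pop <- make_pop()
  dff <- cell_dff(pop)
  ev <- detect_cell_event_frames(dff)
  cm <- pairwise_cell_correlations(ev)
  X <- t(ev$z)
  for (p in list(c(1, 2), c(3, 17), c(40, 90))) {
    expect_equal(cm[p[1], p[2]], pearson_oracle(X[, p[1]], X[, p[2]]),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(cm))
  expect_true(all(diag(cm) == 1))
  # duplicated and sign-flipped traces
  ev2 <- ev
  ev2$z[2, ] <- ev2$z[1, ]
  ev2$z[3, ] <- -ev2$z[1, ]
  cm2 <- pairwise_cell_correlations(ev2)
  expect_equal(cm2[1, 2], 1, tolerance = 1e-12)
  expect_equal(cm2[1, 3], -1, tolerance = 1e-12)
})

test_that("correlation-vs-distance curves agree across type pairs", {
  pop <- make_pop(seed = 6)
  dff <- cell_dff(pop)
  cm <- pairwise_cell_correlations(detect_cell_event_frames(dff))
  cvd <- correlation_vs_distance(cm, cell_positions(pop), pop$cells$type,
                                 bins_um = seq(0, 1200, 150))
  # co-driven populations: curves within 2 sem of each other per bin
  for (b in unique(cvd$bin_lo_um)) {
    sub <- cvd[cvd$bin_lo_um == b & cvd$n >= 30, ]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
      tol <- 2 * sqrt(sub$sem[i]^2 + sub$sem[j]^2)
      expect_lt(abs(sub$mean_corr[i] - sub$mean_corr[j]), tol + 0.05)
    }
  }
  # modular structure: dip near half a wavelength, rebound near one
  ee <- cvd[cvd$pair == "EE", ]
  expect_lt(min(ee$mean_corr[ee$bin_lo_um %in% c(300, 450)]), -0.05)
  expect_gt(max(ee$mean_corr[ee$bin_lo_um %in% c(750, 900)]), 0)
  # empty bin reported with count 0
  cvd2 <- correlation_vs_distance(cm, cell_positions(pop), pop$cells$type,
                                  bins_um = c(0, 1, 2))
  expect_true(any(cvd2$n == 0))
})

test_that("matched-set similarity is one for duplicated E/I pairs", {
  # construct explicit co-located E/I twins with identical correlations
  set.seed(3)
  n_pairs <- 12
  base <- matrix(rnorm(n_pairs * 50), n_pairs, 50)
  z <- rbind(base, base)  # cells 1..12 are I, 13..24 their E twins
  pos <- cbind(runif(n_pairs, 0, 900), runif(n_pairs, 0, 900))
  pos <- rbind(pos, pos + 1e-6)
  types <- c(rep("I", n_pairs), rep("E", n_pairs))
  cm <- suppressWarnings(cor(t(z)))
  ms <- matched_set_similarity(cm, pos, types, match_um = 50,
                               exclusion_um = 200, n_shuffles = 20, seed = 1)
  expect_true(all(abs(ms$per_seed$similarity - 1) < 1e-10, na.rm = TRUE))
  expect_lt(ms$p, 0.05)
  # invariance to permuting cell order
  perm <- sample(2 * n_pairs)
  ms_p <- matched_set_similarity(cm[perm, perm], pos[perm, ], types[perm],
                                 match_um = 50, exclusion_um = 200,
                                 n_shuffles = 20, seed = 1)
  expect_equal(ms_p$median, ms$median, tolerance = 1e-10)
  expect_error(matched_set_similarity(cm, pos, rep("E", 2 * n_pairs),
                                      n_shuffles = 5), "matched pairs|types")
})

test_that("shuffle null is uniform-ish on structureless populations", {
  set.seed(4)
  ps <- vapply(1:10, function(s) {
    n <- 40
    z <- matrix(rnorm(n * 120), n, 120)
    pos <- cbind(runif(n, 0, 400), runif(n, 0, 400))
    types <- rep(c("E", "I"), n / 2)
    cm <- suppressWarnings(cor(t(z)))
    matched_set_similarity(cm, pos, types, match_um = 400,
                           exclusion_um = 50, n_shuffles = 40,
                           seed = s)$p
  }, numeric(1))
  expect_gte(sum(ps > 0.05), 7)
})

test_that("local E/I amplitude coupling follows the shared drive", {
  pop <- make_pop(seed = 7, noise_sd = 0)
  dff <- cell_dff(pop)
  ev <- detect_cell_event_frames(dff)
  la <- local_event_amplitude(dff, ev, cell_positions(pop), pop$cells$type)
  expect_gt(la$r, 0.95)
  # three-sample median filter removes single-sample transients
  expect_equal(runmed(c(0, 10, 0), 3)[2], 0)
})

test_that("independent E and I drives decouple local amplitudes", {
  # the event-shared component of r has sampling scale ~ 1/sqrt(n_events),
  # so many events are needed for a tight zero
  pop <- make_pop(seed = 8, n_cells = 130, ei_alignment = 0, noise_sd = 1,
                  n_events = 200L)
  dff <- cell_dff(pop)
  ev <- detect_cell_event_frames(dff)
  la <- local_event_amplitude(dff, ev, cell_positions(pop), pop$cells$type)
  expect_gt(nrow(la$pairs), 1000)
  expect_lt(abs(la$r), 0.1)
})
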