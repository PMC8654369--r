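# Effective dimensionality (participation ratio) of event ensembles and
# second-order similarity between two correlation tensors (e.g. excitatory
# vs inhibitory networks), with split-half upper bound, surrogate null and
# exclusion-radius sweep.

#' Effective dimensionality of an event pattern ensemble
#'
#' Participation ratio of the eigenvalues of the pixel covariance matrix
#' across events: `d_eff = (sum lambda)^2 / sum lambda^2`. Computed from
#' the N x N event Gram matrix of the pixel-mean-centred patterns, which
#' shares the covariance matrix's nonzero spectrum.
#'
#' @param stack a [pattern_stack()] with N >= 2 patterns.
#' @return list: `d_eff`, `eigenvalues` (nonzero spectrum, decreasing).
#' @export
effective_dimensionality <- function(stack) {
  stopifnot(inherits(stack, "pattern_stack"))
  A <- stack$patterns[, as.vector(stack$roi), drop = FALSE]
  N <- nrow(A)
  if (N < 2) stop("at least 2 patterns required")
  Ac <- sweep(A, 2, colMeans(A))
  if (all(abs(Ac) < 1e-14)) stop("all-zero (constant) stack: d_eff undefined")
  G <- tcrossprod(Ac) / (N - 1)
  lam <- pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
  list(d_eff = sum(lam)^2 / sum(lam^2), eigenvalues = lam)
}

#' Median dimensionality of random event subsamples
#'
#' Controls for event-number differences between datasets: `reps` random
#' subsamples of `n` events without replacement, median of the per-draw
#' participation ratios.
#'
#' @param stack a [pattern_stack()].
#' @param n subsample size (default 30).
#' @param reps number of draws (default 100).
#' @param seed RNG seed.
#' @return list: `median_d_eff`, `values` (per draw).
#' @export
subsampled_dimensionality <- function(stack, n = 30, reps = 100, seed = 1) {
  stopifnot(inherits(stack, "pattern_stack"))
  N <- nrow(stack$patterns)
  if (N < n) stop("insufficient events for the requested subsample size")
  with_rng_seed(seed, {
    vals <- vapply(seq_len(reps), function(i) {
      idx <- sample.int(N, n)
      sub <- stack
      sub$patterns <- stack$patterns[idx, , drop = FALSE]
      effective_dimensionality(sub)$d_eff
    }, numeric(1))
    list(median_d_eff = median(vals), values = vals)
  })
}

# Tensor columns (pixels) shared by two tensors; returns index pairs.
common_pixels <- function(ta, tb) {
  stopifnot(ta$height == tb$height, ta$width == tb$width)
  idx <- intersect(ta$roi_idx, tb$roi_idx)
  list(idx = idx, a = match(idx, ta$roi_idx), b = match(idx, tb$roi_idx))
}

#' Second-order similarity between two correlation tensors
#'
#' For every seed present in both tensors: Pearson correlation between the
#' two correlation patterns over shared ROI pixels farther than
#' `exclusion_um` from the seed (seeds with fewer than `min_pixels`
#' admissible pixels are skipped).
#'
#' @param tensor_a,tensor_b [correlation_tensor()]s on the same grid.
#' @param exclusion_um exclusion radius around the seed (default 400).
#' @param min_pixels minimum admissible pixels per seed (default 10).
#' @return data frame: `seed_grid_idx`, `similarity`, `n_pixels`.
#' @export
network_similarity <- function(tensor_a, tensor_b, exclusion_um = 400,
                               min_pixels = 10) {
  cp <- common_pixels(tensor_a, tensor_b)
  seeds <- intersect(tensor_a$seed_grid_idx, tensor_b$seed_grid_idx)
  co <- idx_coords_um(cp$idx, tensor_a$height, tensor_a$pixel_size_um)
  out <- data.frame(seed_grid_idx = seeds, similarity = NA_real_,
                    n_pixels = 0L)
  for (i in seq_along(seeds)) {
    g <- seeds[i]
    sco <- idx_coords_um(g, tensor_a$height, tensor_a$pixel_size_um)
    d <- sqrt((co[, "x"] - sco[1, "x"])^2 + (co[, "y"] - sco[1, "y"])^2)
    keep <- d > exclusion_um
    if (sum(keep) < min_pixels) next
    va <- tensor_a$C[match(g, tensor_a$seed_grid_idx), cp$a[keep]]
    vb <- tensor_b$C[match(g, tensor_b$seed_grid_idx), cp$b[keep]]
    if (sd(va) == 0 || sd(vb) == 0) next
    out$similarity[i] <- cor(va, vb)
    out$n_pixels[i] <- sum(keep)
  }
  out[!is.na(out$similarity), , drop = FALSE]
}

# Median per-seed similarity (the aggregate used for tests and sweeps).
median_similarity <- function(tensor_a, tensor_b, exclusion_um = 400) {
  median(network_similarity(tensor_a, tensor_b, exclusion_um)$similarity)
}

#' Split-half similarity bound
#'
#' Upper bound on attainable between-network similarity given finite event
#' numbers: events are randomly split in half, tensors computed per half,
#' and the median per-seed second-order similarity between halves recorded
#' for each of `reps` splits.
#'
#' @param stack a [pattern_stack()] with at least 4 events.
#' @param reps number of random splits (default 100).
#' @param seed RNG seed.
#' @param exclusion_um seed exclusion radius.
#' @param seeds optional seed subset (linear grid indices) to speed up
#'   tensor computation.
#' @return list: `values` (per split), `ci95` (2.5/97.5 percentiles),
#'   `median`.
#' @export
split_half_bound <- function(stack, reps = 100, seed = 1,
                             exclusion_um = 400, seeds = NULL) {
  stopifnot(inherits(stack, "pattern_stack"))
  N <- nrow(stack$patterns)
  if (N < 4) stop("at least 4 events required for split-half similarity")
  with_rng_seed(seed, {
    vals <- vapply(seq_len(reps), function(i) {
      idx <- sample.int(N, N %/% 2)
      s1 <- stack; s1$patterns <- stack$patterns[idx, , drop = FALSE]
      s2 <- stack; s2$patterns <- stack$patterns[-idx, , drop = FALSE]
      t1 <- suppressWarnings(correlation_tensor(s1, seeds = seeds))
      t2 <- suppressWarnings(correlation_tensor(s2, seeds = seeds))
      median_similarity(t1, t2, exclusion_um)
    }, numeric(1))
    list(values = vals,
         ci95 = quantile(vals, c(0.025, 0.975), names = FALSE),
         median = median(vals))
  })
}

#' Similarity versus surrogate null
#'
#' Median per-seed similarity between `tensor_a` and tensors computed from
#' surrogate transformations of `stack_b`, compared with the observed
#' similarity between `tensor_a` and the untransformed `stack_b` network.
#' p-value by the add-one rule: `(k + 1)/(n + 1)` with `k` surrogates at or
#' above the observed value.
#'
#' @param tensor_a observed reference [correlation_tensor()].
#' @param stack_b [pattern_stack()] of the comparison population's events.
#' @param n_surr number of surrogates (default 100).
#' @param seed RNG seed for the surrogate transforms.
#' @param exclusion_um seed exclusion radius.
#' @param seeds optional seed subset (linear grid indices).
#' @return list: `observed`, `surrogate` (vector), `p`.
#' @export
similarity_vs_surrogate <- function(tensor_a, stack_b, n_surr = 100,
                                    seed = 1, exclusion_um = 400,
                                    seeds = NULL) {
  tb <- suppressWarnings(correlation_tensor(stack_b, seeds = seeds))
  obs <- median_similarity(tensor_a, tb, exclusion_um)
  se <- make_surrogates(stack_b, n = n_surr, seed = seed)
  null <- vapply(seq_len(n_surr), function(i) {
    sst <- realize_surrogate(se, i)
    valid <- surrogate_valid_seeds(sst)
    sds <- if (is.null(seeds)) NULL else intersect(seeds, valid)
    tz <- suppressWarnings(correlation_tensor(sst, seeds = sds))
    median_similarity(tensor_a, tz, exclusion_um)
  }, numeric(1))
  null <- null[is.finite(null)]
  k <- sum(null >= obs)
  list(observed = obs, surrogate = null, p = (k + 1) / (length(null) + 1))
}

#' Exclusion-radius sweep of network similarity
#'
#' Recomputes the observed similarity and its surrogate null at each
#' exclusion radius (default 400-1400 um in 200 um steps), reusing one
#' surrogate ensemble across radii.
#'
#' @param tensor_a,tensor_b observed tensors.
#' @param stack_b pattern stack behind `tensor_b` (for surrogates).
#' @param radii_um exclusion radii.
#' @param n_surr surrogates per radius.
#' @param seed RNG seed.
#' @param seeds optional seed subset.
#' @return data frame per radius: `radius_um`, `similarity`,
#'   `null_q95`, `p`, `exceeds_null`.
#' @export
exclusion_sweep <- function(tensor_a, tensor_b, stack_b,
                            radii_um = seq(400, 1400, by = 200),
                            n_surr = 100, seed = 1, seeds = NULL) {
  se <- make_surrogates(stack_b, n = n_surr, seed = seed)
  obs <- vapply(radii_um, function(r)
    median_similarity(tensor_a, tensor_b, r), numeric(1))
  null <- matrix(NA_real_, n_surr, length(radii_um))
  for (i in seq_len(n_surr)) {
    sst <- realize_surrogate(se, i)
    valid <- surrogate_valid_seeds(sst)
    sds <- if (is.null(seeds)) NULL else intersect(seeds, valid)
    tz <- suppressWarnings(correlation_tensor(sst, seeds = sds))
    null[i, ] <- vapply(radii_um, function(r)
      median_similarity(tensor_a, tz, r), numeric(1))
  }
  p <- vapply(seq_along(radii_um), function(j) {
    nj <- null[is.finite(null[, j]), j]
    (sum(nj >= obs[j]) + 1) / (length(nj) + 1)
  }, numeric(1))
  q95 <- apply(null, 2, quantile, probs = 0.95, na.rm = TRUE)
  data.frame(radius_um = radii_um, similarity = obs, null_q95 = q95,
             p = p, exceeds_null = obs > q95)
}
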