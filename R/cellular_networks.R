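# Cellular-resolution (two-photon) analyses: population event frames,
# pairwise correlations, correlation-vs-distance by cell-type pair,
# spatially matched E/I similarity with a shuffle test, and local E/I
# event-amplitude coupling.

#' Detect population event frames in cellular traces
#'
#' A frame qualifies as an event frame when more than `frac` of the cells
#' exceed their own temporal mean by `sd_thresh` standard deviations.
#' Qualifying frames' activity vectors are z-scored across cells within
#' each frame.
#'
#' @param dff `T x n_cells` matrix of Delta-F/F traces (see [cell_dff()]).
#' @param frac minimum active-cell fraction (default 0.10).
#' @param sd_thresh per-cell activity threshold in s.d. (default 2).
#' @return object of class `cell_event_frames`: `$frames` (indices),
#'   `$z` (`n_cells x n_frames` frame-wise z-scored activity), `$blocks`
#'   (data frame of contiguous qualifying runs), `$pop_z` (population mean
#'   of cell-wise z-scored traces for all frames). Empty (with a warning)
#'   when no frame qualifies.
#' @export
detect_cell_event_frames <- function(dff, frac = 0.10, sd_thresh = 2) {
  stopifnot(is.matrix(dff))
  n_cells <- ncol(dff)
  if (n_cells < 10) warning("fewer than 10 cells; event frames unreliable")
  mu <- colMeans(dff)
  s <- apply(dff, 2, sd)
  thr <- mu + sd_thresh * s
  act <- sweep(dff, 2, thr, ">")
  qual <- rowMeans(act) > frac
  frames <- which(qual)
  if (!length(frames)) {
    warning("no qualifying event frames")
    res <- list(frames = integer(0),
                z = matrix(NA_real_, n_cells, 0),
                blocks = data.frame(start = integer(0), end = integer(0)),
                pop_z = numeric(nrow(dff)))
    class(res) <- "cell_event_frames"
    return(res)
  }
  sub <- dff[frames, , drop = FALSE]
  z <- t(apply(sub, 1, function(row) (row - mean(row)) / sd(row)))
  # contiguous qualifying runs
  br <- which(diff(frames) > 1)
  starts <- frames[c(1L, br + 1L)]
  ends <- frames[c(br, length(frames))]
  cz <- scale(dff)  # cell-wise z-score over all frames
  res <- list(frames = frames, z = t(z),
              blocks = data.frame(start = starts, end = ends),
              pop_z = rowMeans(cz))
  class(res) <- "cell_event_frames"
  res
}

#' Pairwise cellular correlations over event frames
#'
#' Pearson correlation between every pair of cells' frame-wise z-scored
#' activity across event frames. Zero-variance cells yield NA rows/columns.
#'
#' @param evframes a [detect_cell_event_frames()] result with >= 2 frames.
#' @return `n_cells x n_cells` symmetric correlation matrix, unit diagonal.
#' @export
pairwise_cell_correlations <- function(evframes) {
  stopifnot(inherits(evframes, "cell_event_frames"))
  if (length(evframes$frames) < 2) stop("need at least 2 event frames")
  X <- t(evframes$z)  # frames x cells
  sds <- apply(X, 2, sd)
  M <- suppressWarnings(cor(X))
  M[sds == 0, ] <- NA_real_
  M[, sds == 0] <- NA_real_
  diag(M)[sds > 0] <- 1
  M
}

#' Pairwise correlation versus distance by cell-type pair
#'
#' Bins pairwise correlations by inter-cell distance, separately for the
#' unordered type pairs E-E, I-I and E-I; self-pairs excluded.
#'
#' @param corrs correlation matrix from [pairwise_cell_correlations()].
#' @param positions `n x 2` matrix of cell positions (um).
#' @param types character vector of "E"/"I" labels.
#' @param bins_um distance bin edges (um).
#' @return data frame: `pair` ("EE"/"II"/"EI"), `bin_lo_um`, `bin_hi_um`,
#'   `mean_corr`, `sem`, `n` (0-count bins reported with NA mean).
#' @export
correlation_vs_distance <- function(corrs, positions, types,
                                    bins_um = seq(0, 600, by = 50)) {
  n <- nrow(corrs)
  stopifnot(nrow(positions) == n, length(types) == n)
  ut <- which(upper.tri(corrs), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  d <- sqrt((positions[i, 1] - positions[j, 1])^2 +
            (positions[i, 2] - positions[j, 2])^2)
  r <- corrs[ut]
  pair <- ifelse(types[i] == types[j],
                 ifelse(types[i] == "E", "EE", "II"), "EI")
  keep <- is.finite(r)
  d <- d[keep]; r <- r[keep]; pair <- pair[keep]
  bin <- cut(d, bins_um, right = FALSE)
  out <- expand.grid(pair = c("EE", "II", "EI"),
                     b = seq_len(length(bins_um) - 1))
  out$bin_lo_um <- bins_um[out$b]
  out$bin_hi_um <- bins_um[out$b + 1]
  stats_for <- function(pp, bb) {
    sel <- which(pair == pp & !is.na(bin) & as.integer(bin) == bb)
    v <- r[sel]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
  }
  st <- t(mapply(stats_for, as.character(out$pair), out$b))
  out$mean_corr <- st[, "mean"]; out$sem <- st[, "sem"]; out$n <- st[, "n"]
  out$b <- NULL
  out
}

#' Spatially matched E/I correlation-pattern similarity with shuffle test
#'
#' Each inhibitory cell is matched to its nearest excitatory cell within
#' `match_um` (unmatched I cells dropped). For every seed cell, two
#' correlation vectors are formed: versus the matched inhibitory cells and
#' versus their matched excitatory partners, restricted to target pairs
#' farther than `exclusion_um` from the seed; similarity is the Pearson
#' correlation between the two vectors. The null shuffles the I-E pairing
#' before computing similarity; p is the add-one bootstrap estimate for
#' the median over seeds.
#'
#' @param corrs correlation matrix.
#' @param positions `n x 2` positions (um).
#' @param types "E"/"I" labels.
#' @param match_um matching radius (default 50).
#' @param exclusion_um seed exclusion radius (default 200).
#' @param n_shuffles shuffle count (default 100).
#' @param seed RNG seed.
#' @param min_targets minimum admissible target pairs per seed.
#' @return list: `per_seed` data frame (`cell`, `similarity`, `n_targets`),
#'   `median`, `shuffle` (null medians), `p`, `matches` (I index, E index).
#' @export
matched_set_similarity <- function(corrs, positions, types, match_um = 50,
                                   exclusion_um = 200, n_shuffles = 100,
                                   seed = 1, min_targets = 5) {
  n <- nrow(corrs)
  stopifnot(nrow(positions) == n, length(types) == n)
  icells <- which(types == "I"); ecells <- which(types == "E")
  if (!length(icells) || !length(ecells))
    stop("no spatially matched pairs: need both cell types")
  dmat <- as.matrix(dist(positions))
  m_i <- integer(0); m_e <- integer(0)
  for (ic in icells) {
    dd <- dmat[ic, ecells]
    j <- which.min(dd)
    if (dd[j] <= match_um) { m_i <- c(m_i, ic); m_e <- c(m_e, ecells[j]) }
  }
  if (!length(m_i)) stop("no spatially matched pairs")
  sim_for_pairing <- function(e_perm) {
    sims <- rep(NA_real_, n); ntg <- integer(n)
    for (s in seq_len(n)) {
      keep <- dmat[s, m_i] > exclusion_um & m_i != s & e_perm != s
      vi <- corrs[s, m_i[keep]]
      ve <- corrs[s, e_perm[keep]]
      ok <- is.finite(vi) & is.finite(ve)
      if (sum(ok) < min_targets) next
      if (sd(vi[ok]) == 0 || sd(ve[ok]) == 0) next
      sims[s] <- cor(vi[ok], ve[ok])
      ntg[s] <- sum(ok)
    }
    list(sims = sims, ntg = ntg)
  }
  obs <- sim_for_pairing(m_e)
  med <- median(obs$sims, na.rm = TRUE)
  null <- with_rng_seed(seed, vapply(seq_len(n_shuffles), function(k) {
    median(sim_for_pairing(sample(m_e))$sims, na.rm = TRUE)
  }, numeric(1)))
  null <- null[is.finite(null)]
  p <- (sum(null >= med) + 1) / (length(null) + 1)
  list(per_seed = data.frame(cell = seq_len(n), similarity = obs$sims,
                             n_targets = obs$ntg),
       median = med, shuffle = null, p = p,
       matches = data.frame(i_cell = m_i, e_cell = m_e))
}

#' Local E/I event-amplitude coupling
#'
#' Traces are median-filtered (3 samples) and z-scored across all frames.
#' For every cell and every population event, the mean z-scored amplitude
#' of excitatory and of inhibitory cells within `radius_um` of that cell
#' is taken at the event's maximally active frame (the frame of maximal
#' population-mean z within the qualifying block); the seed cell is
#' excluded from its own type's neighbourhood average. Returns the paired
#' local amplitudes and their Pearson correlation.
#'
#' @param dff `T x n_cells` Delta-F/F matrix.
#' @param evframes a [detect_cell_event_frames()] result with blocks.
#' @param positions `n x 2` positions (um).
#' @param types "E"/"I" labels.
#' @param radius_um neighbourhood radius (default 75).
#' @return list: `pairs` data frame (`cell`, `event`, `e_mean`, `i_mean`),
#'   `r` (Pearson correlation across pairs).
#' @export
local_event_amplitude <- function(dff, evframes, positions, types,
                                  radius_um = 75) {
  stopifnot(inherits(evframes, "cell_event_frames"))
  n <- ncol(dff)
  sm <- apply(dff, 2, function(v) runmed(v, 3, endrule = "median"))
  z <- scale(sm)
  blocks <- evframes$blocks
  if (!nrow(blocks)) stop("no events detected")
  pz <- rowMeans(z)
  maxf <- mapply(function(s, e) { fr <- s:e; fr[which.max(pz[fr])] },
                 blocks$start, blocks$end)
  dmat <- as.matrix(dist(positions))
  rows <- list()
  for (ci in seq_len(n)) {
    nb <- which(dmat[ci, ] <= radius_um)
    eset <- setdiff(nb[types[nb] == "E"], if (types[ci] == "E") ci else integer(0))
    iset <- setdiff(nb[types[nb] == "I"], if (types[ci] == "I") ci else integer(0))
    if (!length(eset) || !length(iset)) next
    em <- rowMeans(z[maxf, eset, drop = FALSE])
    im <- rowMeans(z[maxf, iset, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      cell = ci, event = seq_along(maxf), e_mean = em, i_mean = im)
  }
  if (!length(rows)) stop("no cell has neighbours of both types")
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, r = cor(pairs$e_mean, pairs$i_mean))
}
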