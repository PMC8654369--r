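# Shared internal helpers: seeded RNG scopes, masked Gaussian filtering,
# grid geometry, connected components, skeletonization.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed, staying within 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

odd_window <- function(n) {
  n <- max(1L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

# Pixel-centre coordinates in micrometers for an h x w grid (row = y, col = x).
grid_coords_um <- function(h, w, pixel_size_um) {
  list(
    y = matrix(rep(seq_len(h), w), h, w) * pixel_size_um,
    x = matrix(rep(seq_len(w), each = h), h, w) * pixel_size_um
  )
}

gaussian_kernel_1d <- function(sigma_px, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma_px))
  u <- seq(-radius, radius)
  k <- exp(-u^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian blur with NA-aware normalized convolution. Pixels where
# `mask` is FALSE (or the image is NA) do not contribute; output is NA there.
# Boundaries are handled by the same normalization (truncated kernel mass).
gaussian_blur_masked <- function(img, sigma_px, mask = NULL) {
  if (sigma_px <= 0) return(img)
  if (is.null(mask)) mask <- !is.na(img)
  x <- img
  x[!mask | is.na(x)] <- 0
  m <- matrix(0, nrow(img), ncol(img))
  m[mask & !is.na(img)] <- 1
  k <- gaussian_kernel_1d(sigma_px)
  conv_sep <- function(a) {
    a1 <- apply(a, 2, function(col) conv_same(col, k))
    t(apply(a1, 1, function(row) conv_same(row, k)))
  }
  num <- conv_sep(x)
  den <- conv_sep(m)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out[!mask] <- NA_real_
  out
}

# 1D convolution returning a vector of the same length (zero padding).
conv_same <- function(v, k) {
  n <- length(v)
  r <- (length(k) - 1L) %/% 2L
  full <- stats::convolve(v, rev(k), type = "open")
  full[(r + 1L):(r + n)]
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  h <- nrow(lab); w <- ncol(lab)
  for (dd in list(c(1L, 1L), c(1L, -1L))) {
    dr <- dd[1]; dc <- dd[2]
    rows <- seq_len(h - 1L)
    cols <- if (dc > 0) seq_len(w - 1L) else 2:w
    a <- lab[rows, cols, drop = FALSE]
    b <- lab[rows + dr, cols + dc, drop = FALSE]
    hit <- which(a > 0L & b > 0L & a != b)
    if (length(hit)) {
      pa <- a[hit]; pb <- b[hit]
      for (i in seq_along(pa)) union(pa[i], pb[i])
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Zhang-Suen morphological thinning to a one-pixel-wide skeleton.
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  img[is.na(img)] <- 0L
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3) return(img > 0)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- img
  nbr <- function(p) {
    # neighbours P2..P9 clockwise from north, as matrices over interior
    list(
      p2 = p[1:h, 2:(w + 1L)],       p3 = p[1:h, 3:(w + 2L)],
      p4 = p[2:(h + 1L), 3:(w + 2L)], p5 = p[3:(h + 2L), 3:(w + 2L)],
      p6 = p[3:(h + 2L), 2:(w + 1L)], p7 = p[3:(h + 2L), 1:w],
      p8 = p[2:(h + 1L), 1:w],        p9 = p[1:h, 1:w]
    )
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      n <- nbr(pad)
      ctr <- pad[2:(h + 1L), 2:(w + 1L)]
      B <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqs <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      A <- matrix(0L, h, w)
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (step == 1) {
        c1 <- n$p2 * n$p4 * n$p6
        c2 <- n$p4 * n$p6 * n$p8
      } else {
        c1 <- n$p2 * n$p4 * n$p8
        c2 <- n$p2 * n$p6 * n$p8
      }
      del <- ctr == 1L & B >= 2L & B <= 6L & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        changed <- TRUE
        ctr[del] <- 0L
        pad[2:(h + 1L), 2:(w + 1L)] <- ctr
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1L), 2:(w + 1L)] > 0L
}

# Strict local maxima of a 2D map over the 8-neighborhood; NA treated as -Inf.
local_maxima_2d <- function(map) {
  h <- nrow(map); w <- ncol(map)
  z <- map
  z[is.na(z)] <- -Inf
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- z
  ctr <- z
  ok <- is.finite(ctr)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    ok <- ok & (ctr > nb)
  }
  ok
}

# Mean values of `v` in radial bins of width `bin` over distances `d`.
radial_profile <- function(d, v, bin) {
  keep <- is.finite(d) & is.finite(v)
  d <- d[keep]; v <- v[keep]
  idx <- floor(d / bin)
  s <- tapply(v, idx, mean)
  r <- (as.numeric(names(s)) + 0.5) * bin
  list(r = as.numeric(r), value = as.numeric(s),
       n = as.numeric(tapply(v, idx, length)))
}

# Even-odd rule point-in-polygon test.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    j <- i
  }
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a
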