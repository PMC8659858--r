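# independent brute-force oracles and small fixture builders, used across
# the test files

# GLCM oracle: per-pixel window co-occurrence by direct enumeration over a
# quantized matrix; returns the mean of each feature over full-window pixels
oracle_glcm <- function(band, levels = 64, window = 3, dx = 1, dy = 1) {
  rng <- range(band)
  q <- if (rng[2] > rng[1]) {
    pmin(floor((band - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1)
  } else band * 0
  nr <- nrow(q); nc <- ncol(q)
  feats <- NULL
  for (r0 in seq_len(nr - window + 1)) {
    for (c0 in seq_len(nc - window + 1)) {
      w <- q[r0:(r0 + window - 1), c0:(c0 + window - 1)]
      P <- matrix(0, levels, levels)
      for (i in seq_len(window - dy)) {
        for (j in seq_len(window - dx)) {
          a <- w[i, j] + 1; b <- w[i + dy, j + dx] + 1
          P[a, b] <- P[a, b] + 1
          P[b, a] <- P[b, a] + 1
        }
      }
      P <- P / sum(P)
      lev <- 0:(levels - 1)
      pi_ <- rowSums(P)
      mu <- sum(lev * pi_)
      va <- sum((lev - mu)^2 * pi_)
      II <- matrix(lev, levels, levels)
      JJ <- t(II)
      nz <- P > 0
      feats <- rbind(feats, c(
        mean = mu,
        variance = va,
        homogeneity = sum(P / (1 + (II - JJ)^2)),
        contrast = sum(P * (II - JJ)^2),
        heterogeneity = sum(P * abs(II - JJ)),
        entropy = -sum(P[nz] * log(P[nz])),
        second_moment = sum(P^2),
        correlation = if (va > 0)
          sum(P * (II - mu) * (JJ - mu)) / va else 0))
    }
  }
  colMeans(feats)
}

# Pearson r and two-sided p by the raw sum formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# hand-assembled ordinary kriging solve for small n
oracle_ok <- function(model, locs, vals, target) {
  n <- nrow(locs)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt(sum((locs[i, ] - locs[j, ])^2))
    A[i, j] <- model_gamma(model, d)
  }
  A[n + 1, seq_len(n)] <- 1; A[seq_len(n), n + 1] <- 1
  b <- c(vapply(seq_len(n), function(i)
    model_gamma(model, sqrt(sum((locs[i, ] - target)^2))), numeric(1)), 1)
  lam <- solve(A, b)[seq_len(n)]
  sum(lam * vals)
}

# small cloud fixture: flat ground plus a block of canopy points at given
# heights/intensities
toy_cloud <- function(z_canopy, intensity = NULL, ground_z = 0) {
  nc <- length(z_canopy)
  if (is.null(intensity)) intensity <- rep(100, nc)
  ng <- max(nc, 4)
  g <- expand.grid(x = seq(0, 9, length.out = ceiling(sqrt(ng))),
                   y = seq(0, 9, length.out = ceiling(sqrt(ng))))
  rbind(
    data.frame(x = g$x, y = g$y, z = ground_z, intensity = 20,
               is_ground = TRUE),
    data.frame(x = runif(nc, 0, 9), y = runif(nc, 0, 9),
               z = ground_z + z_canopy, intensity = intensity,
               is_ground = FALSE))
}

# compact landscape configuration for fast tests
small_config <- function(seed = 1L, ...) {
  landscape_config(
    n_plots = 12L,
    species_mix = c(larix = 10L, koraiensis = 1L, sylvestris = 1L),
    extent_m = 4000, dem_pixel_m = 40, seed = seed, ...)
}
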