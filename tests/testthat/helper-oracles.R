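# Independent oracles, coded from the mathematical definitions with
# different primitives than the package implementation.

# Direct evaluation of a Gaussian band mixture on a grid.
oracle_band_sum <- function(wl, centers, sigmas, amps) {
  rowSums(sapply(seq_along(centers), function(i)
    amps[i] * exp(-(wl - centers[i])^2 / (2 * sigmas[i]^2))))
}

# The normalized PSI statistic computed by direct evaluation: band sum on
# the grid, centered inclusive running mean (explicit per-point window
# search), 798-802 nm baseline mean, PSII-window normalization, PSI-window
# maximum. Mirrors the definitions, not the package code (which uses
# cumulative sums and provenance-tracked objects).
oracle_psi_from_bands <- function(wl, centers, sigmas, amps,
                                  offset = 0, window_nm = 4) {
  y <- oracle_band_sum(wl, centers, sigmas, amps) + offset
  half <- window_nm / 2 + 1e-9
  sm <- vapply(seq_along(wl), function(i)
    mean(y[abs(wl - wl[i]) <= half]), numeric(1))
  base <- mean(sm[wl >= 798 & wl <= min(802, max(wl))])
  z <- sm - base
  z <- z / max(z[wl >= 680 & wl <= 690])
  max(z[wl >= 710 & wl <= 730])
}

# Textbook pooled-variance two-sample t statistic and two-sided p-value.
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# Dunn's z statistics computed straight from the definition: global ranks,
# per-pair z with tie correction, Holm adjustment through an explicit
# step-down loop rather than p.adjust().
oracle_dunn <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  lev <- levels(groups)
  tie_tbl <- table(values)
  C <- sum(tie_tbl^3 - tie_tbl) / (12 * (N - 1))
  res <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    gi <- rk[groups == lev[i]]; gj <- rk[groups == lev[j]]
    z <- (mean(gi) - mean(gj)) /
      sqrt((N * (N + 1) / 12 - C) * (1 / length(gi) + 1 / length(gj)))
    res[[length(res) + 1L]] <- data.frame(
      comparison = paste(lev[i], lev[j], sep = "-"), z = z,
      p = 2 * (1 - pnorm(abs(z))))
  }
  df <- do.call(rbind, res)
  o <- order(df$p)
  m <- nrow(df)
  holm <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * df$p[o[k]])
    holm[o[k]] <- min(1, running)
  }
  df$p_holm <- holm
  df
}

# Rasterized shapes for measurement tests (pixel-center-inside convention,
# matching the generator).
raster_disk <- function(r, pad = 10, off = c(0, 0)) {
  n <- 2 * r + 2 * pad + 1
  cx <- (n + 1) / 2 + off[1]; cy <- (n + 1) / 2 + off[2]
  outer(1:n, 1:n, function(i, j) as.integer((i - cx)^2 + (j - cy)^2 <= r^2))
}

raster_ellipse <- function(a, b, pad = 10) {
  n <- 2 * ceiling(a) + 2 * pad + 1
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j)
    as.integer(((i - c0) / a)^2 + ((j - c0) / b)^2 <= 1))
}

raster_square <- function(side, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(0L, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- 1L
  m
}

# Axis-ratio samplers for the two morphologies contrasted in the shape
# pipeline: irregular ovoid chloroplasts in algae vs near-spherical
# kleptoplasts in sea slugs.
alga_ratio_sampler <- function(n) 2 + rnorm(n, sd = 0.15)
slug_ratio_sampler <- function(n) 1.05 + abs(rnorm(n, sd = 0.03))
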