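# Small phantom fixtures built in code; kept modest so the suite stays fast.

small_spec <- function(snr = Inf, seed = 1L, curvature_per_m = 4.4,
                       width_mm = 6, thickness_mm = 2,
                       pixel_spacing_mm = 0.2, ...) {
  phantom_spec(width_mm = width_mm, thickness_mm = thickness_mm,
               curvature_per_m = curvature_per_m,
               pixel_spacing_mm = pixel_spacing_mm,
               snr = snr, seed = seed, ...)
}

flat_spec <- function(thickness_mm = 2, pixel_spacing_mm = 0.1, ...) {
  small_spec(curvature_per_m = 0, thickness_mm = thickness_mm,
             pixel_spacing_mm = pixel_spacing_mm, ...)
}

# brute-force midrank Pearson: independent of the package implementation
# (midranks by counting, Pearson from raw sums)
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# brute-force nearest-point distance to a polyline, scalar loop over
# segments (independent of the vectorized implementation)
oracle_dist_to_curve <- function(p, curve) {
  best <- Inf
  for (j in seq_len(nrow(curve) - 1)) {
    a <- c(curve$x[j], curve$y[j])
    b <- c(curve$x[j + 1], curve$y[j + 1])
    v <- b - a
    vv <- sum(v^2)
    t <- if (vv > 0) sum((p - a) * v) / vv else 0
    t <- min(max(t, 0), 1)
    q <- a + t * v
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}
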