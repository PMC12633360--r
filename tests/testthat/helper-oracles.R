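# brute-force taper-weighted Pearson correlation of one window
oracle_weighted_pearson <- function(x, y, w) {
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  vx <- sum(wn * (x - mx)^2); vy <- sum(wn * (y - my)^2)
  if (vx < 1e-12 || vy < 1e-12) return(0)
  sum(wn * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# independent sliding-window correlation: plain loops over windows
oracle_windowed_corr <- function(x, y, width, stride, w) {
  N <- (length(x) - width) %/% stride + 1L
  vapply(seq_len(N), function(k) {
    idx <- ((k - 1L) * stride + 1L):((k - 1L) * stride + width)
    oracle_weighted_pearson(x[idx], y[idx], w)
  }, numeric(1))
}

# straight random polyline between two points
random_streamline <- function(lo, hi, n = 5L) {
  p0 <- runif(3, lo, hi); p1 <- runif(3, lo, hi)
  tt <- seq(0, 1, length.out = n)
  outer(1 - tt, p0) + outer(tt, p1)
}

# small phantom configuration reused by the heavier tests
small_phantom_cfg <- function(...) {
  phantom_config(streamlines_per_subregion = 30L, T = 150L, ...)
}
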