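#' Sliding-window specification
#'
#' @param width Window width in timepoints (>= 2). The default 85 volumes at
#'   TR = 0.72 s corresponds to a 61.2 s window.
#' @param stride Window step in timepoints (>= 1); with stride 1 a series of
#'   length T yields `T - width + 1` windows.
#' @param taper `"hamming"` (default) or `"rectangular"`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 85L, stride = 1L, taper = c("hamming", "rectangular")) {
  taper <- match.arg(taper)
  width <- as.integer(width); stride <- as.integer(stride)
  if (is.na(width) || width < 2L) stop("width must be at least 2 timepoints")
  if (is.na(stride) || stride < 1L) stop("stride must be at least 1")
  structure(list(width = width, stride = stride, taper = taper),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("window_spec: width", x$width, "TP, stride", x$stride, ",", x$taper, "taper\n")
  invisible(x)
}

#' Number of sliding windows for a series of length `T`
#' @param spec A [window_spec()].
#' @param T Series length in timepoints.
#' @return Integer window count `floor((T - width)/stride) + 1`.
#' @export
n_windows <- function(spec, T) {
  if (T < spec$width) stop("series shorter than window width")
  as.integer((T - spec$width) %/% spec$stride + 1L)
}

#' Window duration in seconds
#' @inheritParams n_windows
#' @param tr Seconds per volume.
#' @return `width * tr` seconds.
#' @export
window_duration <- function(spec, tr) spec$width * tr

#' Hamming taper
#'
#' The periodic-endpoint Hamming weights
#' `w_n = 0.54 - 0.46 cos(2 pi n / (W - 1))`, `n = 0..W-1`, so the end
#' weights are 0.08 and the centre weight is 1 for odd `W`.
#'
#' @param W Window width, >= 2.
#' @return Numeric vector of length `W`.
#' @export
hamming_taper <- function(W) {
  W <- as.integer(W)
  if (is.na(W) || W < 2L) stop("W must be at least 2")
  n <- 0:(W - 1)
  0.54 - 0.46 * cos(2 * pi * n / (W - 1))
}

taper_weights <- function(spec) {
  switch(spec$taper,
         hamming = hamming_taper(spec$width),
         rectangular = rep(1, spec$width))
}

# taper-weighted Pearson correlations for all windows, vectorised over
# streamline pairs: X, Y are S x T matrices. Returns list(values = S x N,
# n_degenerate = count of zero-variance windows set to 0).
windowed_corr_matrix <- function(X, Y, spec) {
  T <- ncol(X)
  N <- n_windows(spec, T)
  W <- spec$width
  w <- taper_weights(spec)
  wn <- w / sum(w)
  S <- nrow(X)
  out <- matrix(NA_real_, S, N)
  n_degen <- 0L
  wnm <- matrix(wn, S, W, byrow = TRUE)
  for (k in seq_len(N)) {
    cols <- ((k - 1L) * spec$stride + 1L):((k - 1L) * spec$stride + W)
    Xw <- X[, cols, drop = FALSE]
    Yw <- Y[, cols, drop = FALSE]
    # rowSums (not BLAS gemv) keeps each row's accumulation order fixed, so
    # results are bit-identical under streamline permutation
    mx <- rowSums(Xw * wnm); my <- rowSums(Yw * wnm)
    Xc <- Xw - mx; Yc <- Yw - my
    vx <- rowSums(Xc * Xc * wnm)
    vy <- rowSums(Yc * Yc * wnm)
    cxy <- rowSums(Xc * Yc * wnm)
    degen <- vx < 1e-12 | vy < 1e-12
    r <- numeric(S)
    ok <- !degen
    r[ok] <- cxy[ok] / sqrt(vx[ok] * vy[ok])
    n_degen <- n_degen + sum(degen)
    out[, k] <- pmin(1, pmax(-1, r))
  }
  list(values = out, n_degenerate = n_degen)
}

#' Sliding-window correlation of two series
#'
#' For window `k` starting at `t0 = k * stride` (0-based), computes the
#' taper-weighted Pearson correlation of `x[t0..t0+W-1]` and `y[...]`:
#' weighted means, variances and covariance all use the taper weights.
#' Values are clipped to `[-1, 1]`; a window in which either weighted
#' variance falls below `1e-12` yields 0 and increments the degenerate-window
#' count returned in the `"n_degenerate"` attribute.
#'
#' @param x,y Numeric series of equal length `T >= width`.
#' @param spec A [window_spec()].
#' @return Numeric vector of `n_windows(spec, T)` correlations with attribute
#'   `n_degenerate`.
#' @export
windowed_corr <- function(x, y, spec = window_spec()) {
  if (length(x) != length(y)) stop("series length mismatch")
  res <- windowed_corr_matrix(rbind(x), rbind(y), spec)
  structure(drop(res$values), n_degenerate = res$n_degenerate)
}

#' Extract endpoint BOLD series for an endpoint table
#'
#' Nearest-voxel sampling: each table row yields the series stored at its
#' seed and distal endpoint voxels. Rows whose seed or distal voxel carries
#' an all-zero signal are flagged.
#'
#' @param b A [bold_series()].
#' @param tab Endpoint table from [extract_seed_tractogram()].
#' @return List with `seed` and `distal` (rows x T matrices) and `flagged`
#'   (logical: all-zero signal at either endpoint).
#' @export
endpoint_series <- function(b, tab) {
  stopifnot(inherits(b, "bold_series"))
  d <- dim(b$data)
  mat <- matrix(b$data, nrow = prod(d[1:3]), ncol = d[4])
  lin_seed <- voxel_linear(as.matrix(tab[, c("seed_i", "seed_j", "seed_k")]), b$grid)
  lin_dist <- voxel_linear(as.matrix(tab[, c("distal_i", "distal_j", "distal_k")]), b$grid)
  seed <- mat[lin_seed, , drop = FALSE]
  distal <- mat[lin_dist, , drop = FALSE]
  flagged <- rowSums(seed != 0) == 0L | rowSums(distal != 0) == 0L
  list(seed = seed, distal = distal, flagged = flagged)
}

#' Rasterize a streamline onto a voxel grid
#'
#' Resamples the polyline by arc length at `step_mm` (default: half the
#' smallest voxel size), maps every sample through [world_to_voxel()], drops
#' out-of-FOV samples and duplicates. Both endpoint voxels are always
#' included when in-FOV; a zero-length streamline yields its single voxel.
#'
#' @param s Numeric n x 3 matrix of world-mm vertices.
#' @param grid A [volume_grid()].
#' @param step_mm Positive resampling step in mm.
#' @return Integer m x 3 matrix of unique 0-based voxel indices.
#' @export
rasterize_streamline <- function(s, grid, step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- min(grid$voxel_sizes) / 2
  if (step_mm <= 0) stop("step_mm must be positive")
  seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 0)   # drop duplicate consecutive vertices
  s2 <- s[keep, , drop = FALSE]
  if (nrow(s2) < 2L) {
    v <- world_to_voxel(s[1, , drop = FALSE], grid)
    return(v$ijk[v$in_fov, , drop = FALSE])
  }
  cl <- c(0, cumsum(seg[seg > 0]))
  at <- unique(c(seq(0, cl[length(cl)], by = step_mm), cl[length(cl)]))
  pts <- vapply(1:3, function(c) stats::approx(cl, s2[, c], xout = at)$y,
                numeric(length(at)))
  pts <- rbind(pts, s[1, ], s[nrow(s), ])   # guarantee endpoints
  v <- world_to_voxel(pts, grid)
  ijk <- v$ijk[v$in_fov, , drop = FALSE]
  unique(ijk)
}

#' TW-dFC map container
#'
#' 4D array (grid dims x windows): voxel value at window `w` is the mean
#' dynamic weighting of the streamlines traversing it; voxels traversed by no
#' streamline are `NaN`.
#'
#' @param data 4D array.
#' @param grid A [volume_grid()].
#' @param spec The [window_spec()] the map was computed with.
#' @param provenance Named list of computation parameters and counters.
#' @return An object of class `twdfc_map`.
#' @export
twdfc_map <- function(data, grid, spec, provenance = list()) {
  d <- dim(data)
  if (length(d) != 4L || !all(d[1:3] == grid$dims))
    stop("data must be 4D on the given grid")
  structure(list(data = data, grid = grid, spec = spec,
                 provenance = provenance),
            class = "twdfc_map")
}

#' @export
print.twdfc_map <- function(x, ...) {
  d <- dim(x$data)
  cat("twdfc_map:", paste(d[1:3], collapse = " x "), "voxels,", d[4],
      "windows;", sum(is.finite(x$data[, , , 1])), "traversed voxels\n")
  invisible(x)
}

#' Project streamline dynamic weights onto traversed voxels
#'
#' For voxel `v` and window `w` the map value is
#' `sum_s omega_s FC_s(w) / sum_s omega_s` over the streamlines `s`
#' traversing `v`, with `omega_s = 1` by default or the streamline weight
#' when `use_weights`. A streamline contributes once per voxel per window no
#' matter how many resampled points fell inside; untraversed voxels are NaN.
#'
#' @param dyn Streamline-by-window matrix of dynamic FC values.
#' @param voxel_sets List (per streamline) of 0-based voxel index matrices,
#'   e.g. from [rasterize_streamline()].
#' @param grid A [volume_grid()].
#' @param spec The [window_spec()] used to compute `dyn`.
#' @param streamline_weights Optional per-streamline weights.
#' @param use_weights Use `streamline_weights` in the average.
#' @param provenance Extra provenance entries to record.
#' @return A [twdfc_map()].
#' @export
project_twdfc <- function(dyn, voxel_sets, grid, spec,
                          streamline_weights = NULL, use_weights = FALSE,
                          provenance = list()) {
  S <- nrow(dyn)
  if (length(voxel_sets) != S) stop("dyn rows must align with voxel_sets")
  if (use_weights && is.null(streamline_weights))
    stop("use_weights = TRUE but no streamline weights supplied")
  omega <- if (use_weights) streamline_weights else rep(1, S)
  N <- ncol(dyn)
  V <- prod(grid$dims)
  num <- matrix(0, V, N)
  den <- numeric(V)
  # canonical accumulation order (by dynamic-weight rows, then omega) makes
  # the map bit-identical under any permutation of the input streamlines
  ord <- do.call(order, c(lapply(seq_len(N), function(j) dyn[, j]),
                          list(omega)))
  for (s in ord) {
    ij <- voxel_sets[[s]]
    if (is.null(ij) || nrow(ij) == 0L) next
    lin <- voxel_linear(ij, grid)
    num[lin, ] <- num[lin, , drop = FALSE] +
      omega[s] * matrix(dyn[s, ], nrow = length(lin), ncol = N, byrow = TRUE)
    den[lin] <- den[lin] + omega[s]
  }
  traversed <- den > 0
  out <- matrix(NaN, V, N)
  out[traversed, ] <- num[traversed, , drop = FALSE] / den[traversed]
  dim(out) <- c(grid$dims, N)
  twdfc_map(out, grid, spec,
            provenance = c(list(use_weights = use_weights), provenance))
}

#' Compute a track-weighted dynamic functional connectivity map
#'
#' Assigns each streamline a dynamic functional weighting — the
#' sliding-window taper-weighted Pearson correlation between the BOLD series
#' at its two endpoints — and maps it onto every voxel the streamline
#' traverses, averaging across streamlines per voxel and window. The result
#' is a 4D map with one frame per window; frame `k` corresponds to the
#' window starting at volume `k * stride` (0-based).
#'
#' @param b A [bold_series()].
#' @param t The seed [tractogram()] (from [extract_seed_tractogram()]).
#' @param tab The matching endpoint table.
#' @param spec A [window_spec()]; the default is an 85-volume Hamming window
#'   with stride 1.
#' @param step_mm Rasterization step (default half the smallest voxel size).
#' @param use_weights Average with the per-streamline weights instead of
#'   uniformly.
#' @return A [twdfc_map()] with provenance recording window parameters,
#'   `step_mm`, weighting mode, and degenerate-window / flagged-endpoint
#'   counts.
#' @export
compute_twdfc <- function(b, t, tab, spec = window_spec(), step_mm = NULL,
                          use_weights = FALSE) {
  stopifnot(inherits(b, "bold_series"), inherits(t, "tractogram"))
  if (nrow(tab) == 0L) stop("endpoint table is empty")
  if (is.null(step_mm)) step_mm <- min(b$grid$voxel_sizes) / 2
  series <- endpoint_series(b, tab)
  wc <- windowed_corr_matrix(series$seed, series$distal, spec)
  ids <- tab$streamline_id
  voxel_sets <- lapply(t$streamlines[ids], rasterize_streamline,
                       grid = b$grid, step_mm = step_mm)
  weights <- if (is.null(t$weights)) NULL else t$weights[ids]
  project_twdfc(wc$values, voxel_sets, b$grid, spec,
                streamline_weights = weights, use_weights = use_weights,
                provenance = list(
                  width = spec$width, stride = spec$stride, taper = spec$taper,
                  step_mm = step_mm,
                  n_streamlines = length(ids),
                  n_degenerate_windows = wc$n_degenerate,
                  n_flagged_endpoints = sum(series$flagged)))
}
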