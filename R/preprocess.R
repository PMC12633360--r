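#' BOLD series container
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param tr Repetition time in seconds per volume.
#' @param grid A [volume_grid()] matching the spatial dimensions.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, grid) {
  d <- dim(data)
  if (length(d) != 4L || d[4] < 2L)
    stop("data must be a 4D array with at least 2 timepoints")
  if (!all(d[1:3] == grid$dims)) stop("data dimensions do not match grid")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive")
  structure(list(data = data, tr = tr, grid = grid), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat("bold_series:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "volumes, TR =", x$tr, "s\n")
  invisible(x)
}

n_timepoints <- function(b) dim(b$data)[4]

# symmetric (edge-inclusive) reflection of 1-based indices onto 1..L;
# this padding makes a normalised symmetric kernel mass-preserving
reflect_index <- function(i, L) {
  repeat {
    below <- i < 1L
    i[below] <- 1L - i[below]
    above <- i > L
    i[above] <- 2L * L + 1L - i[above]
    if (!any(i < 1L | i > L)) return(i)
  }
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve an array along one margin with a 1D kernel, reflect padding
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  L <- dp[1]
  xm <- matrix(x, nrow = L)
  out <- matrix(0, nrow = L, ncol = ncol(xm))
  r <- (length(kernel) - 1L) %/% 2L
  for (j in -r:r) {
    idx <- reflect_index(seq_len(L) + j, L)
    out <- out + kernel[j + r + 1L] * xm[idx, , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

smooth_volume_3d <- function(vol, sigma_vox) {
  for (axis in 1:3)
    if (sigma_vox[axis] > 0)
      vol <- conv_axis(vol, gaussian_kernel_1d(sigma_vox[axis]), axis)
  vol
}

#' Volumetric Gaussian smoothing
#'
#' Smooths each volume of a BOLD series with an isotropic Gaussian of the
#' given full-width at half-maximum, `sigma = fwhm / (2 sqrt(2 ln 2))` mm per
#' axis, converted to voxel units through the grid's voxel sizes. Separable
#' 1D convolutions with symmetric (edge-reflecting) padding are used, which
#' preserves the volume mean exactly for the normalised kernel. When a mask
#' is given, smoothing is mask-renormalised: `data * mask` and `mask` are
#' convolved separately and divided, so signal does not bleed across the mask
#' boundary; voxels outside the mask are zeroed.
#'
#' @param b A [bold_series()].
#' @param fwhm_mm Kernel FWHM in millimetres; 0 returns the input unchanged.
#' @param mask Optional binary 3D array on the same grid.
#' @return A smoothed [bold_series()].
#' @export
gaussian_smooth <- function(b, fwhm_mm, mask = NULL) {
  stopifnot(inherits(b, "bold_series"))
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(b)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / b$grid$voxel_sizes
  T <- n_timepoints(b)
  out <- b$data
  if (is.null(mask)) {
    for (t in seq_len(T))
      out[, , , t] <- smooth_volume_3d(b$data[, , , t], sigma_vox)
  } else {
    mask <- array(as.numeric(mask != 0), dim = b$grid$dims)
    sm_mask <- smooth_volume_3d(mask, sigma_vox)
    inside <- mask > 0
    for (t in seq_len(T)) {
      v <- smooth_volume_3d(b$data[, , , t] * mask, sigma_vox)
      v <- ifelse(sm_mask > 0, v / sm_mask, 0)
      v[!inside] <- 0
      out[, , , t] <- v
    }
  }
  bold_series(out, b$tr, b$grid)
}

#' Temporal bandpass filter
#'
#' Zero-phase per-voxel bandpass retaining `[low_hz, high_hz]`. The default
#' `fft` mode zeroes all DFT bins whose frequency magnitude falls outside the
#' band (exact band edges, ideal zero-phase response); `butterworth` applies
#' an order-2 Butterworth forward-backward via [signal::filtfilt()]. The DC
#' bin is removed whenever `low_hz > 0`.
#'
#' @param b A [bold_series()].
#' @param low_hz,high_hz Band edges in Hz; `0 <= low_hz < high_hz <= 1/(2 tr)`.
#' @param mode `"fft"` (default) or `"butterworth"`.
#' @return A filtered [bold_series()].
#' @export
bandpass <- function(b, low_hz, high_hz, mode = c("fft", "butterworth")) {
  stopifnot(inherits(b, "bold_series"))
  mode <- match.arg(mode)
  nyq <- 1 / (2 * b$tr)
  if (low_hz < 0 || low_hz >= high_hz || high_hz > nyq + 1e-12)
    stop("band must satisfy 0 <= low < high <= Nyquist (", signif(nyq, 4), " Hz)")
  T <- n_timepoints(b)
  d <- dim(b$data)
  x <- matrix(b$data, nrow = prod(d[1:3]), ncol = T)
  if (mode == "fft") {
    k <- 0:(T - 1)
    f <- pmin(k, T - k) / (T * b$tr)
    keep <- f >= low_hz - 1e-12 & f <= high_hz + 1e-12
    if (low_hz > 0) keep[1] <- FALSE
    X <- stats::mvfft(t(x))
    X[!keep, ] <- 0
    xt <- Re(stats::mvfft(X, inverse = TRUE)) / T
    out <- t(xt)
  } else {
    W <- c(max(low_hz, 1e-6), high_hz) / nyq
    bf <- signal::butter(2, W, type = "pass")
    xt <- t(x)
    xt <- xt - rep(colMeans(xt), each = T)
    out <- t(apply(xt, 2, function(col) signal::filtfilt(bf, col)))
  }
  dim(out) <- d
  bold_series(out, b$tr, b$grid)
}
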