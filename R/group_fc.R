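#' Mean time series of a merged cluster
#'
#' Unweighted mean over all voxels carrying the merged cluster id, per
#' timepoint.
#'
#' @param b A [bold_series()].
#' @param p A [merge_bilateral()] (or any) parcellation on the same grid.
#' @param merged_id Integer cluster id in `p$labels`.
#' @return Numeric series of length `T`.
#' @export
cluster_timeseries <- function(b, p, merged_id) {
  stopifnot(inherits(b, "bold_series"))
  lin <- which(as.vector(p$labels) == merged_id)
  if (length(lin) == 0L) stop("cluster ", merged_id, " is empty")
  d <- dim(b$data)
  mat <- matrix(b$data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(mat[lin, , drop = FALSE])
}

#' Seed-based functional connectivity map
#'
#' Voxel-wise Pearson correlation between a seed series and every in-mask
#' voxel's series, with the Fisher z transform (`atanh`, with `|r|` capped at
#' `1 - 1e-7` to keep z finite). Zero-variance voxels get r = 0 and are
#' flagged.
#'
#' @param b A [bold_series()].
#' @param series Seed series of length `T` (e.g. [cluster_timeseries()]).
#' @param brain_mask Optional logical 3D array (default: all voxels).
#' @return Object of class `seed_fc`: `r`, `z` (vectors over the mask),
#'   `voxel_index`, `flagged` (zero-variance voxels), `n_timepoints`, `grid`.
#' @export
seed_fc <- function(b, series, brain_mask = NULL) {
  stopifnot(inherits(b, "bold_series"))
  T <- n_timepoints(b)
  if (length(series) != T) stop("series length must equal the number of volumes")
  if (stats::sd(series) < 1e-12) stop("seed series is constant")
  d <- dim(b$data)
  lin <- if (is.null(brain_mask)) seq_len(prod(d[1:3])) else
    which(as.vector(brain_mask != 0))
  mat <- matrix(b$data, nrow = prod(d[1:3]), ncol = T)[lin, , drop = FALSE]
  mu <- rowMeans(mat)
  cen <- mat - mu
  ssq <- rowSums(cen^2)
  sc <- series - mean(series)
  r <- as.vector(cen %*% sc) / sqrt(ssq * sum(sc^2))
  flagged <- ssq < 1e-24
  r[flagged] <- 0
  r <- pmin(1, pmax(-1, r))
  cap <- 1 - 1e-7
  z <- atanh(pmin(cap, pmax(-cap, r)))
  structure(list(r = r, z = z, voxel_index = lin, flagged = flagged,
                 n_timepoints = T, grid = b$grid),
            class = "seed_fc")
}

#' Directional contrast between two sets of subject FC maps
#'
#' Per voxel, a one-tailed t-test of `X > Y`. The default paired form tests
#' `d_i = z_X,i - z_Y,i` across the `n` subjects:
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`; the unpaired form is a
#' pooled two-sample t with `df = 2n - 2`. One-tailed p-values are
#' Benjamini-Hochberg corrected across the in-mask voxels of this contrast
#' (each contrast is its own FDR family), converted to z by
#' `qnorm(1 - q)` capped at +/- 8.2, and thresholded at `z_threshold`.
#' Voxels with zero variance of `d` get p = 0.5 and are flagged.
#'
#' @param fc_x,fc_y Subjects x voxels matrices of Fisher-z FC values for the
#'   two conditions (same subjects, same voxel order).
#' @param tail Direction label, e.g. `"A>B"` (metadata only).
#' @param paired Paired (default) or pooled two-sample t.
#' @param z_threshold Suprathreshold cut-off on the z map; the default
#'   `qnorm(0.95)` is the one-tailed 5 percent normal quantile, 1.645.
#' @return Object of class `contrast_result`: `contrast`, `t`, `p`, `q`,
#'   `z`, `suprathreshold` (logical), `df`, `n`, `flagged`, `z_threshold`.
#' @export
contrast <- function(fc_x, fc_y, tail = "X>Y", paired = TRUE,
                     z_threshold = stats::qnorm(0.95)) {
  fc_x <- as.matrix(fc_x); fc_y <- as.matrix(fc_y)
  if (!all(dim(fc_x) == dim(fc_y)))
    stop("fc_x and fc_y must hold the same subjects and voxels")
  n <- nrow(fc_x)
  if (n < 3L) stop("need at least 3 subjects")
  if (paired) {
    d <- fc_x - fc_y
    m <- colMeans(d)
    s <- sqrt(colSums((d - rep(m, each = n))^2) / (n - 1))
    df <- n - 1
    tt <- ifelse(s > 0, m / (s / sqrt(n)), 0)
    flagged <- s == 0
  } else {
    mx <- colMeans(fc_x); my <- colMeans(fc_y)
    vx <- colSums((fc_x - rep(mx, each = n))^2) / (n - 1)
    vy <- colSums((fc_y - rep(my, each = n))^2) / (n - 1)
    sp <- sqrt((vx + vy) / 2) * sqrt(2 / n)
    df <- 2 * n - 2
    tt <- ifelse(sp > 0, (mx - my) / sp, 0)
    flagged <- sp == 0
  }
  p <- stats::pt(tt, df = df, lower.tail = FALSE)
  p[flagged] <- 0.5
  q <- stats::p.adjust(p, method = "BH")
  z <- stats::qnorm(1 - q)
  z <- pmin(8.2, pmax(-8.2, z))
  structure(list(contrast = tail, t = tt, p = p, q = q, z = z,
                 suprathreshold = z >= z_threshold, df = df, n = n,
                 flagged = flagged, z_threshold = z_threshold),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("contrast", x$contrast, ": n =", x$n, ", df =", x$df, ";",
      sum(x$suprathreshold), "/", length(x$z),
      "voxels above z =", signif(x$z_threshold, 4), "\n")
  invisible(x)
}

#' All directional cluster contrasts
#'
#' Runs [contrast()] for every ordered pair of clusters — 3 clusters give
#' the six directional contrasts A>B, B>A, A>C, C>A, B>C, C>B — each with
#' its own FDR family.
#'
#' @param fc_maps Named list (one entry per cluster, e.g. `A`, `B`, `C`) of
#'   subjects x voxels Fisher-z matrices.
#' @param ... Passed to [contrast()].
#' @return Named list of `contrast_result`s, one per ordered pair.
#' @export
run_all_contrasts <- function(fc_maps, ...) {
  nm <- names(fc_maps)
  if (is.null(nm) || any(!nzchar(nm))) stop("fc_maps must be a named list")
  if (length(fc_maps) < 2L) stop("need at least 2 clusters")
  out <- list()
  for (a in nm) for (b in nm) {
    if (a == b) next
    lab <- paste0(a, ">", b)
    out[[lab]] <- contrast(fc_maps[[a]], fc_maps[[b]], tail = lab, ...)
  }
  out
}

#' Per-subject cluster FC maps for a cohort
#'
#' Convenience wrapper: for each subject's BOLD series and each merged
#' cluster, computes the cluster mean series and its seed-based FC map, and
#' stacks the Fisher-z maps into subjects x voxels matrices keyed by cluster
#' letter.
#'
#' @param bolds List of [bold_series()], one per subject.
#' @param p A merged [parcellation()].
#' @param brain_mask Optional logical 3D array.
#' @return Named list of subjects x voxels Fisher-z matrices, suitable for
#'   [run_all_contrasts()].
#' @export
cohort_cluster_fc <- function(bolds, p, brain_mask = NULL) {
  letters_used <- if (!is.null(p$letters)) p$letters else as.character(seq_len(p$k))
  out <- stats::setNames(vector("list", p$k), letters_used)
  for (j in seq_len(p$k)) {
    zs <- lapply(bolds, function(b) {
      fc <- seed_fc(b, cluster_timeseries(b, p, j), brain_mask)
      fc$z
    })
    out[[j]] <- do.call(rbind, zs)
  }
  out
}
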