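#' Temporally concatenate TW-dFC maps
#'
#' Stacks the window frames of several subjects' maps into one
#' frames x voxels matrix over the analysis mask (voxels finite in at least
#' one frame of at least one subject). Within each subject block every
#' voxel's finite frames are mean-centred (NaN-aware) and remaining NaN
#' frames are imputed as 0; subject boundaries are recorded.
#'
#' @param maps List of [twdfc_map()] objects on a shared grid.
#' @param analysis_mask Optional logical 3D array restricting the voxel set.
#' @return An object of class `twdfc_concat`: `X` (total frames x voxels),
#'   `voxel_index` (1-based linear indices into the grid), `blocks` (per
#'   subject frame ranges), `grid`.
#' @export
concatenate_maps <- function(maps, analysis_mask = NULL) {
  stopifnot(length(maps) >= 1L)
  grid <- maps[[1]]$grid
  for (m in maps)
    if (!all(m$grid$dims == grid$dims) ||
        max(abs(m$grid$affine - grid$affine)) > 1e-6)
      stop("all maps must share the same grid")
  V <- prod(grid$dims)
  finite_any <- rep(FALSE, V)
  for (m in maps) {
    flat <- matrix(m$data, nrow = V)
    finite_any <- finite_any | rowSums(is.finite(flat)) > 0
  }
  if (!is.null(analysis_mask))
    finite_any <- finite_any & as.vector(analysis_mask != 0)
  voxel_index <- which(finite_any)
  if (length(voxel_index) == 0L) stop("analysis mask is empty")
  blocks <- list()
  pieces <- vector("list", length(maps))
  at <- 0L
  for (i in seq_along(maps)) {
    flat <- matrix(maps[[i]]$data, nrow = V)[voxel_index, , drop = FALSE]
    mu <- rowMeans(flat, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    flat <- flat - mu
    flat[!is.finite(flat)] <- 0
    Nf <- ncol(flat)
    blocks[[i]] <- c(at + 1L, at + Nf)
    at <- at + Nf
    pieces[[i]] <- t(flat)
  }
  structure(list(X = do.call(rbind, pieces), voxel_index = voxel_index,
                 blocks = blocks, grid = grid),
            class = "twdfc_concat")
}

#' @export
print.twdfc_concat <- function(x, ...) {
  cat("twdfc_concat:", nrow(x$X), "frames x", ncol(x$X), "voxels,",
      length(x$blocks), "subject block(s)\n")
  invisible(x)
}

#' Decompose concatenated TW-dFC data into spatial components
#'
#' PCA-whitens the frames x voxels matrix to `n_components` dimensions (auto
#' mode: the smallest count whose cumulative eigenvalue fraction reaches
#' `var_threshold`), then runs fixed-point ICA on the whitened spatial data.
#' Each spatial map is standardised to a z-score map (zero mean, unit SD over
#' voxels). Deterministic given `seed`; on non-convergence the ICA is retried
#' under new random rotations, and if the fixed point is still rotating after
#' all retries (typical when residual components are Gaussian noise) the
#' final rotation is returned with a warning.
#'
#' @param data A `twdfc_concat` or a frames x voxels matrix.
#' @param n_components Component count, or `"auto"`.
#' @param var_threshold Cumulative variance fraction for auto mode.
#' @param seed RNG seed for the ICA initial rotation.
#' @param maxit,tol Fixed-point iteration controls.
#' @return An object of class `component_set`: `spatial_maps`
#'   (components x voxels, z-scored), `mixing` (frames x components) and
#'   `frame_offsets` (reconstruction is `mixing %*% spatial_maps +
#'   frame_offsets`), `variance_explained`, `n_components`, `eig_fractions`,
#'   `voxel_index`, `grid` (the latter two when available from the input).
#' @export
decompose <- function(data, n_components = "auto", var_threshold = 0.98,
                      seed = 1L, maxit = 200L, tol = 1e-6) {
  voxel_index <- NULL; grid <- NULL
  if (inherits(data, "twdfc_concat")) {
    voxel_index <- data$voxel_index; grid <- data$grid
    X <- data$X
  } else X <- as.matrix(data)
  sv <- svd(X)
  ev <- sv$d^2
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  frac <- cumsum(ev) / sum(ev)
  if (identical(n_components, "auto")) {
    n <- which(frac >= var_threshold - 1e-12)[1]
    if (is.na(n)) n <- rank
  } else {
    n <- as.integer(n_components)
    if (n > min(dim(X))) stop("n_components exceeds min(frames, voxels)")
  }
  n <- min(n, rank)
  V <- ncol(X)
  # whitened spatial data: rows unit variance over voxels
  Z <- (t(sv$u[, 1:n, drop = FALSE]) %*% X) / sv$d[1:n] * sqrt(V)
  S <- ica_fixed_point(Z, seed = seed, maxit = maxit, tol = tol)
  mu <- rowMeans(S); sd <- apply(S, 1, stats::sd)
  maps <- (S - mu) / sd
  # least-squares mixing with a per-frame offset (z-scoring removed the map
  # means); reconstruction is mixing %*% maps + frame_offsets
  A <- rbind(maps, 1)
  coefs <- X %*% t(A) %*% solve(tcrossprod(A))
  mixing <- coefs[, seq_len(n), drop = FALSE]
  frame_offsets <- coefs[, n + 1L]
  structure(list(spatial_maps = maps, mixing = mixing,
                 frame_offsets = frame_offsets,
                 variance_explained = frac[n], n_components = n,
                 eig_fractions = frac, voxel_index = voxel_index, grid = grid),
            class = "component_set")
}

# Symmetric fixed-point ICA (logcosh contrast) on whitened data Z
# (components x samples), retried under fresh random rotations. Residual
# Gaussian subspaces have no stable rotation, so a run that is still
# rotating at maxit after all retries is returned with a warning rather
# than discarded (any rotation of that subspace is an equally valid basis).
ica_fixed_point <- function(Z, seed, maxit, tol, retries = 3L) {
  n <- nrow(Z)
  if (n == 1L) return(Z)
  last <- NULL
  for (attempt in seq_len(retries)) {
    fit <- with_seed(seed + attempt - 1L, {
      R0 <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
      ica::icafast(t(Z), nc = n, center = FALSE, maxit = maxit, tol = tol,
                   Rmat = R0, alg = "par", fun = "logcosh")
    })
    ok <- length(fit$vafs) == n && all(is.finite(fit$S))
    converged <- ok && (is.null(fit$iter) || fit$iter < maxit)
    if (converged) return(t(fit$S))
    if (ok) last <- fit
  }
  if (is.null(last)) stop("ICA failed: no restart produced a finite unmixing")
  warning("fixed-point ICA did not reach tol within ", maxit,
          " iterations after ", retries,
          " restarts; returning the final rotation")
  t(last$S)
}

#' @export
print.component_set <- function(x, ...) {
  cat("component_set:", x$n_components, "components over",
      ncol(x$spatial_maps), "voxels; variance explained",
      sprintf("%.1f%%", 100 * x$variance_explained), "\n")
  invisible(x)
}

#' Threshold component z-score maps
#'
#' `mixture` mode (default) fits a Gaussian mixture to each component's z
#' values, selecting between one and two classes by BIC: with a single class
#' the component is treated as pure noise and fully zeroed; with two, voxels
#' whose posterior probability of the signal class exceeds 0.5 are kept. The
#' signal class is the higher-variance class (tie within 10 percent: larger
#' absolute mean). `zabs` mode keeps voxels with `|z| > z_cut`. Kept voxels
#' retain their z value; all others are set exactly to 0. A degenerate
#' mixture fit falls back to `zabs` with a warning.
#'
#' @param comp A `component_set` from [decompose()].
#' @param mode `"mixture"` or `"zabs"`.
#' @param z_cut Cut-off for `zabs` mode (default `qnorm(0.95)`).
#' @return `comp` with `spatial_maps` replaced by the thresholded maps and a
#'   `threshold_mode` character vector recording the mode used per component.
#' @export
threshold_zmaps <- function(comp, mode = c("mixture", "zabs"),
                            z_cut = stats::qnorm(0.95)) {
  mode <- match.arg(mode)
  maps <- comp$spatial_maps
  used <- character(nrow(maps))
  for (i in seq_len(nrow(maps))) {
    z <- maps[i, ]
    if (mode == "zabs") {
      keep <- abs(z) > z_cut
      used[i] <- "zabs"
    } else {
      keep <- tryCatch(mixture_keep(z), error = function(e) NULL)
      if (is.null(keep)) {
        warning("mixture fit degenerate for component ", i,
                "; falling back to |z| threshold")
        keep <- abs(z) > z_cut
        used[i] <- "zabs_fallback"
      } else used[i] <- "mixture"
    }
    z[!keep] <- 0
    maps[i, ] <- z
  }
  comp$spatial_maps <- maps
  comp$threshold_mode <- used
  comp
}

mixture_keep <- function(z) {
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(z, G = 1:2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mclust returned NULL")
  if (fit$G == 1L) return(rep(FALSE, length(z)))
  vars <- fit$parameters$variance$sigmasq
  means <- fit$parameters$mean
  signal <- if (abs(diff(vars)) / max(vars) < 0.10)
    which.max(abs(means)) else which.max(vars)
  fit$z[, signal] > 0.5
}

#' Build the per-voxel feature matrix inside the seed mask
#'
#' One row per seed voxel (rows ordered by linear voxel index, which is
#' lexicographic in (i, j, k) with i fastest), one column per component,
#' holding that voxel's thresholded z-scores. Seed voxels absent from the
#' analysis domain get a zero row and are counted in the `n_outside`
#' attribute (with a warning).
#'
#' @param comp A (thresholded) `component_set` carrying `voxel_index`.
#' @param seed_mask Logical 3D array.
#' @return Object of class `feature_matrix`: `features` (voxels x
#'   components), `voxel_index` (linear indices of the seed voxels), `grid`.
#' @export
build_features <- function(comp, seed_mask) {
  if (is.null(comp$voxel_index))
    stop("component set carries no voxel index; decompose a twdfc_concat")
  seed_lin <- which(as.vector(seed_mask != 0))
  pos <- match(seed_lin, comp$voxel_index)
  features <- matrix(0, length(seed_lin), nrow(comp$spatial_maps))
  inside <- !is.na(pos)
  features[inside, ] <- t(comp$spatial_maps[, pos[inside], drop = FALSE])
  n_outside <- sum(!inside)
  if (n_outside > 0)
    warning(n_outside, " seed voxel(s) outside the analysis domain; ",
            "zero feature rows assigned")
  structure(list(features = features, voxel_index = seed_lin,
                 grid = comp$grid, n_outside = n_outside),
            class = "feature_matrix")
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    probs <- d2 / sum(d2)
    centers[j, ] <- x[sample(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' k-means parcellation of the seed region
#'
#' k-means++ initialisation with `n_init` restarts; the solution with the
#' lowest within-cluster sum of squares is kept. Clusters are relabelled
#' 1..k by descending size, ties broken by the lexicographically smaller
#' feature centroid. Deterministic given `seed`.
#'
#' @param f A `feature_matrix` from [build_features()].
#' @param k Number of clusters (>= 2).
#' @param seed RNG seed.
#' @param n_init Number of k-means++ restarts.
#' @return An object of class `parcellation`: `labels` (integer array over
#'   the grid, 0 outside the seed), `k`, `voxel_index`, `cluster` (label per
#'   seed voxel), `centroids_mm` (k x 3 world-mm cluster centroids),
#'   `sizes`, `inertia`, `grid`, `bilateral_map` (NULL until
#'   [merge_bilateral()]).
#' @export
kmeans_parcellate <- function(f, k, seed = 1L, n_init = 10L) {
  stopifnot(inherits(f, "feature_matrix"))
  x <- f$features
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(unique(x)) < k) stop("k exceeds the number of distinct feature rows")
  best <- NULL
  with_seed(seed, {
    tries <- 0L
    done <- 0L
    while (done < n_init && tries < n_init * 4L) {
      tries <- tries + 1L
      fit <- tryCatch(
        stats::kmeans(x, centers = kmeanspp_init(x, k), iter.max = 100L),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || length(unique(fit$cluster)) < k) next  # empty cluster: restart
      done <- done + 1L
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed: no restart produced k non-empty clusters")
  # relabel by descending size; ties by lexicographically smaller centroid
  sizes <- tabulate(best$cluster, k)
  ord <- order(-sizes, apply(best$centers, 1, function(r) paste(
    formatC(r, format = "e", digits = 10), collapse = ",")))
  relab <- integer(k); relab[ord] <- seq_len(k)
  cluster <- relab[best$cluster]
  labels <- array(0L, dim = f$grid$dims)
  labels[f$voxel_index] <- cluster
  centroids <- t(vapply(seq_len(k), function(j) {
    ij <- linear_voxel(f$voxel_index[cluster == j], f$grid)
    colMeans(voxel_to_world(ij, f$grid))
  }, numeric(3)))
  structure(list(labels = labels, k = k, voxel_index = f$voxel_index,
                 cluster = cluster, centroids_mm = centroids,
                 sizes = tabulate(cluster, k), inertia = best$tot.withinss,
                 grid = f$grid, bilateral_map = NULL),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation: k =", x$k, "; sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.null(x$bilateral_map)) {
    cat("bilateral merge:",
        paste(names(x$bilateral_map), x$bilateral_map, sep = "->", collapse = " "), "\n")
  }
  invisible(x)
}

#' Merge hemispherically symmetric clusters
#'
#' Splits clusters by the world-x side of their centroid relative to
#' `midline_x`, then pairs each left cluster with the right cluster whose
#' mirrored centroid (x -> 2 midline_x - x) is closest, through an optimal
#' one-to-one assignment. Merged clusters are lettered A, B, C, ... by
#' anterior-to-posterior (descending world y) order of their merged
#' centroid. An explicit `override` mapping (named vector, cluster id ->
#' letter) bypasses the geometric matching.
#'
#' @param p A [kmeans_parcellate()] parcellation.
#' @param midline_x World-mm x coordinate of the midline (default 0).
#' @param override Optional named character vector, e.g.
#'   `c("1"="A","4"="A","2"="B","6"="B","3"="C","5"="C")`.
#' @return A `parcellation` whose `labels`/`cluster` carry merged ids
#'   1..n_merged, with `letters` (merged id -> letter) and `bilateral_map`
#'   (source cluster id -> letter).
#' @export
merge_bilateral <- function(p, midline_x = 0, override = NULL) {
  stopifnot(inherits(p, "parcellation"))
  if (!is.null(override)) {
    src <- as.integer(names(override))
    if (!setequal(src, seq_len(p$k))) stop("override must map every cluster")
    letters_used <- sort(unique(unname(override)))
    merged_of <- match(unname(override)[match(seq_len(p$k), src)], letters_used)
    bil <- unname(override)[match(seq_len(p$k), src)]
  } else {
    side <- ifelse(p$centroids_mm[, 1] < midline_x, "L", "R")
    lefts <- which(side == "L"); rights <- which(side == "R")
    if (length(lefts) != length(rights))
      stop("unequal cluster counts per side (", length(lefts), " left, ",
           length(rights), " right); supply an explicit override mapping")
    mirrored <- p$centroids_mm[rights, , drop = FALSE]
    mirrored[, 1] <- 2 * midline_x - mirrored[, 1]
    cost <- as.matrix(stats::dist(rbind(p$centroids_mm[lefts, , drop = FALSE],
                                        mirrored)))[seq_along(lefts),
                                                    length(lefts) + seq_along(rights),
                                                    drop = FALSE]
    assign <- as.integer(clue::solve_LSAP(cost))
    pair_y <- (p$centroids_mm[lefts, 2] + p$centroids_mm[rights[assign], 2]) / 2
    ord <- order(-pair_y)   # anterior (larger y) first
    merged_of <- integer(p$k)
    for (m in seq_along(ord)) {
      merged_of[lefts[ord[m]]] <- m
      merged_of[rights[assign[ord[m]]]] <- m
    }
    letters_used <- LETTERS[seq_along(ord)]
    bil <- letters_used[merged_of]
  }
  names(bil) <- as.character(seq_len(p$k))
  n_merged <- length(letters_used)
  cluster <- merged_of[p$cluster]
  labels <- array(0L, dim = p$grid$dims)
  labels[p$voxel_index] <- cluster
  centroids <- t(vapply(seq_len(n_merged), function(j) {
    ij <- linear_voxel(p$voxel_index[cluster == j], p$grid)
    colMeans(voxel_to_world(ij, p$grid))
  }, numeric(3)))
  structure(list(labels = labels, k = n_merged, voxel_index = p$voxel_index,
                 cluster = cluster, centroids_mm = centroids,
                 sizes = tabulate(cluster, n_merged), inertia = p$inertia,
                 grid = p$grid, bilateral_map = bil, letters = letters_used,
                 source = p),
            class = "parcellation")
}

#' Build a parcellation from an integer label volume
#'
#' Wraps an existing label volume (e.g. planted ground-truth subregions) in
#' the `parcellation` container so it can drive [cluster_timeseries()] and
#' [cohort_cluster_fc()].
#'
#' @param labels Integer 3D array, 0 = background, 1..k cluster ids.
#' @param grid The matching [volume_grid()].
#' @param letters Optional letter names for the clusters.
#' @return A `parcellation`.
#' @export
as_parcellation <- function(labels, grid, letters = NULL) {
  labels <- array(as.integer(labels), dim = grid$dims)
  k <- max(labels)
  if (k < 1L) stop("labels contain no clusters")
  voxel_index <- which(as.vector(labels) > 0L)
  cluster <- as.vector(labels)[voxel_index]
  centroids <- t(vapply(seq_len(k), function(j) {
    ij <- linear_voxel(voxel_index[cluster == j], grid)
    colMeans(voxel_to_world(ij, grid))
  }, numeric(3)))
  structure(list(labels = labels, k = k, voxel_index = voxel_index,
                 cluster = cluster, centroids_mm = centroids,
                 sizes = tabulate(cluster, k), inertia = NA_real_,
                 grid = grid, bilateral_map = NULL, letters = letters),
            class = "parcellation")
}
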