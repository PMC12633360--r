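#' Classify streamline endpoints against a seed mask
#'
#' The endpoints of a streamline are its first and last polyline vertices,
#' mapped to voxels with [world_to_voxel()]. Each streamline is labelled
#' `none_in_seed`, `one_in_seed`, `both_in_seed`, or `endpoint_out_of_fov`
#' (when either endpoint falls outside the grid).
#'
#' @param t A [tractogram()].
#' @param seed Binary 3D array on `grid` (non-zero = seed).
#' @param grid A [volume_grid()].
#' @return Character vector, one category per streamline.
#' @export
classify_endpoints <- function(t, seed, grid) {
  stopifnot(inherits(t, "tractogram"))
  if (length(t) == 0L) stop("tractogram is empty")
  ep <- endpoint_voxels(t, grid)
  seed_flat <- as.vector(seed != 0)
  categorize <- function(first_in, last_in, fov_ok) {
    if (!fov_ok) return("endpoint_out_of_fov")
    n <- first_in + last_in
    c("none_in_seed", "one_in_seed", "both_in_seed")[n + 1L]
  }
  first_in <- rep(FALSE, length(t)); last_in <- rep(FALSE, length(t))
  fov_ok <- ep$first$in_fov & ep$last$in_fov
  first_in[ep$first$in_fov] <-
    seed_flat[voxel_linear(ep$first$ijk[ep$first$in_fov, , drop = FALSE], grid)]
  last_in[ep$last$in_fov] <-
    seed_flat[voxel_linear(ep$last$ijk[ep$last$in_fov, , drop = FALSE], grid)]
  mapply(categorize, first_in, last_in, fov_ok)
}

endpoint_voxels <- function(t, grid) {
  firsts <- do.call(rbind, lapply(t$streamlines, function(s) s[1, ]))
  lasts <- do.call(rbind, lapply(t$streamlines, function(s) s[nrow(s), ]))
  list(first = world_to_voxel(firsts, grid), last = world_to_voxel(lasts, grid))
}

#' Extract the seed tractogram and its endpoint table
#'
#' Keeps streamlines whose endpoint classification matches the policy
#' (default: exactly one endpoint in the seed; `"both"` additionally keeps
#' streamlines with both endpoints inside). Weights are subset in the same
#' order. Each kept streamline contributes one endpoint-table row oriented so
#' `seed_voxel` is the in-seed endpoint (for both-in-seed streamlines the
#' first vertex is taken as the seed endpoint). Streamlines with an
#' out-of-FOV endpoint are dropped and counted.
#'
#' @inheritParams classify_endpoints
#' @param categories Optional precomputed [classify_endpoints()] output.
#' @param policy `"one"` (default) or `"both"`.
#' @return List with `tractogram` (the kept subset) and `table`, a data frame
#'   with columns `streamline_id` (index into the *returned* tractogram),
#'   `source_id` (index into the input), `seed_i/j/k`, `distal_i/j/k`
#'   (0-based voxel indices) and `weight` (1 when the input is unweighted).
#' @export
extract_seed_tractogram <- function(t, seed, grid, categories = NULL,
                                    policy = c("one", "both")) {
  policy <- match.arg(policy)
  if (is.null(categories)) categories <- classify_endpoints(t, seed, grid)
  wanted <- if (policy == "one") "one_in_seed" else c("one_in_seed", "both_in_seed")
  keep <- which(categories %in% wanted)
  n_oof <- sum(categories == "endpoint_out_of_fov")
  if (n_oof > 0)
    message(n_oof, " streamline(s) with an out-of-FOV endpoint dropped")
  if (length(keep) == 0L) {
    warning("no streamlines matched the seed policy; result is empty")
    tab <- data.frame(streamline_id = integer(), source_id = integer(),
                      seed_i = integer(), seed_j = integer(), seed_k = integer(),
                      distal_i = integer(), distal_j = integer(),
                      distal_k = integer(), weight = numeric())
    return(list(tractogram = tractogram(list(), header = t$header), table = tab))
  }
  ep <- endpoint_voxels(t, grid)
  seed_flat <- as.vector(seed != 0)
  first_in <- seed_flat[voxel_linear(ep$first$ijk, grid)]
  # orient: seed endpoint first; both-in-seed keeps the first vertex as seed
  seed_ijk <- ep$first$ijk[keep, , drop = FALSE]
  distal_ijk <- ep$last$ijk[keep, , drop = FALSE]
  flip <- !first_in[keep]
  if (any(flip)) {
    tmp <- seed_ijk[flip, , drop = FALSE]
    seed_ijk[flip, ] <- distal_ijk[flip, , drop = FALSE]
    distal_ijk[flip, ] <- tmp
  }
  w <- if (is.null(t$weights)) rep(1, length(keep)) else t$weights[keep]
  tab <- data.frame(
    streamline_id = seq_along(keep), source_id = keep,
    seed_i = seed_ijk[, 1], seed_j = seed_ijk[, 2], seed_k = seed_ijk[, 3],
    distal_i = distal_ijk[, 1], distal_j = distal_ijk[, 2],
    distal_k = distal_ijk[, 3], weight = w)
  sub <- tractogram(t$streamlines[keep],
                    weights = if (is.null(t$weights)) NULL else t$weights[keep],
                    header = t$header)
  list(tractogram = sub, table = tab)
}

#' Endpoint-density map
#'
#' Counts (or weight-sums) streamline endpoints per voxel. The map total
#' equals the number of table rows (or the total weight) exactly.
#'
#' @param tab Endpoint table from [extract_seed_tractogram()].
#' @param grid A [volume_grid()].
#' @param which `"seed"` or `"distal"` endpoints.
#' @param weighted Sum the `weight` column instead of counting.
#' @return 3D numeric array over the grid.
#' @export
endpoint_density_map <- function(tab, grid, which = c("seed", "distal"),
                                 weighted = FALSE) {
  which <- match.arg(which)
  if (nrow(tab) == 0L) stop("endpoint table is empty")
  cols <- paste0(which, c("_i", "_j", "_k"))
  ijk <- as.matrix(tab[, cols])
  lin <- voxel_linear(ijk, grid)
  vals <- if (weighted) tab$weight else rep(1, nrow(tab))
  flat <- numeric(prod(grid$dims))
  acc <- rowsum(vals, lin)
  flat[as.integer(rownames(acc))] <- acc[, 1]
  array(flat, dim = grid$dims)
}
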