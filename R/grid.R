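#' Volume grid
#'
#' A `volume_grid` couples the array dimensions of a volume with the 4x4
#' affine transform mapping 0-based voxel indices to world coordinates in
#' millimetres (the NIfTI sform convention, also the frame TCK streamline
#' vertices live in).
#'
#' @param dims Integer vector of length 3, voxels per axis.
#' @param affine 4x4 matrix, voxel index (0-based) to world mm. Defaults to a
#'   scaling by `voxel_sizes` with the origin at voxel (0,0,0).
#' @param voxel_sizes Numeric length 3, mm per voxel along each axis. Derived
#'   from `affine` column norms when an affine is supplied.
#' @return An object of class `volume_grid` with fields `dims`, `affine`,
#'   `voxel_sizes`.
#' @examples
#' g <- volume_grid(c(10, 10, 10), voxel_sizes = c(2, 2, 2))
#' world_to_voxel(c(2, 2, 2), g)
#' @export
volume_grid <- function(dims, affine = NULL, voxel_sizes = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be 3 positive integers")
  if (is.null(affine)) {
    if (is.null(voxel_sizes)) voxel_sizes <- c(1, 1, 1)
    if (length(voxel_sizes) == 1L) voxel_sizes <- rep(voxel_sizes, 3)
    affine <- diag(c(voxel_sizes, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  if (!all(is.finite(affine))) stop("affine must be finite")
  det3 <- det(affine[1:3, 1:3])
  if (abs(det3) < .Machine$double.eps) stop("affine must be invertible")
  if (det3 < 0)
    warning("left-handed affine: TCK vertices are assumed to share this ",
            "world frame; no re-orientation is applied")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be positive")
  structure(list(dims = dims, affine = affine, voxel_sizes = vs),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$dims, collapse = " x "),
      "voxels,", paste(signif(x$voxel_sizes, 4), collapse = " x "), "mm\n")
  invisible(x)
}

# round half away from zero, the documented voxel-assignment tie-break
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3L) stop("points must be n x 3")
  points
}

#' Map world coordinates to voxel indices
#'
#' Applies the inverse affine and rounds to the nearest voxel index
#' (half-away-from-zero, so a point exactly on a voxel-face boundary belongs
#' to the higher-index voxel). Points falling outside `[0, dims)` are flagged,
#' never clamped.
#'
#' @param points Numeric vector of length 3 or an n x 3 matrix of world-mm
#'   coordinates.
#' @param grid A [volume_grid()].
#' @return List with `ijk` (n x 3 integer matrix of 0-based indices) and
#'   `in_fov` (logical vector).
#' @export
world_to_voxel <- function(points, grid) {
  points <- as_points(points)
  inv <- solve(grid$affine)
  cont <- cbind(points, 1) %*% t(inv)
  ijk <- round_half_away(cont[, 1:3, drop = FALSE])
  in_fov <- ijk[, 1] >= 0 & ijk[, 1] < grid$dims[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$dims[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$dims[3]
  storage.mode(ijk) <- "integer"
  list(ijk = ijk, in_fov = as.vector(in_fov))
}

#' Map voxel indices to world coordinates of voxel centres
#'
#' @param ijk Integer vector of length 3 or n x 3 matrix of 0-based indices.
#' @inheritParams world_to_voxel
#' @return n x 3 matrix of world-mm coordinates.
#' @export
voxel_to_world <- function(ijk, grid) {
  ijk <- as_points(ijk)
  out <- cbind(ijk, 1) %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

# 0-based ijk matrix -> 1-based linear index into an array of grid$dims
voxel_linear <- function(ijk, grid) {
  d <- grid$dims
  as.integer(ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3]) + 1L)
}

# inverse of voxel_linear
linear_voxel <- function(lin, grid) {
  d <- grid$dims
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i = i, j = j, k = k)
}

#' Read a NIfTI volume
#'
#' Thin wrapper over [RNifti::readNifti()] splitting the result into the data
#' array and a [volume_grid()] built from the image xform.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (array, 3D or 4D) and `grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(RNifti::xform(img), 4, 4)
  dm <- dim(img)
  grid <- volume_grid(dm[1:3], affine = aff)
  list(data = as.array(img), grid = grid)
}

#' Write a NIfTI volume
#'
#' @param data 3D or 4D array whose first three dimensions match `grid$dims`.
#' @param grid A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  if (!all(dim(data)[1:3] == grid$dims))
    stop("data dimensions do not match grid")
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
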