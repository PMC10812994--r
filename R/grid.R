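#' Spatial sampling grid of a brain volume
#'
#' A `volume_grid` couples the voxel lattice of a 3D image with the affine
#' transform that maps 0-based voxel indices to world coordinates in mm
#' (an MNI-like frame for the synthetic data shipped with the package).
#'
#' @param shape Integer vector of length 3: voxels along each axis.
#' @param voxel_size Numeric vector of length 3: voxel edge lengths in mm.
#'   Must be strictly positive.
#' @param affine Optional 4x4 affine matrix mapping 0-based voxel indices to
#'   world mm. Defaults to a diagonal affine with the grid centred on the
#'   world origin.
#' @return An object of class `volume_grid` with fields `shape`,
#'   `voxel_size` and `affine`.
#' @export
volume_grid <- function(shape, voxel_size = c(3, 3, 3), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(is.finite(voxel_size)),
            all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    # centre of the grid at world (0,0,0)
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("volume_grid: affine must be invertible")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

grids_compatible <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Map 0-based voxel indices to world mm coordinates
#'
#' @param grid A [volume_grid()].
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices (a vector of
#'   length 3 is treated as one voxel).
#' @return Numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  xyz <- cbind(ijk, 1) %*% t(grid$affine[1:3, , drop = FALSE])
  unname(xyz)
}

#' Map world mm coordinates to (fractional) 0-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz Numeric matrix (n x 3) of world coordinates in mm.
#' @return Numeric matrix (n x 3) of 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind2mat(xyz)
  inv <- solve(grid$affine)
  ijk <- cbind(xyz, 1) %*% t(inv[1:3, , drop = FALSE])
  unname(ijk)
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else
    matrix(as.numeric(x), nrow = nrow(x))
}

#' Binary analysis mask over a grid
#'
#' @param grid A [volume_grid()].
#' @param inside Logical array with dimensions `grid$shape`; `TRUE` marks
#'   voxels inside the analysis mask. At least one voxel must be inside.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, inside) {
  stopifnot(inherits(grid, "volume_grid"))
  inside <- array(as.logical(inside), dim = dim(inside))
  stopifnot(identical(dim(inside), as.integer(grid$shape)))
  if (!any(inside)) stop("binary_mask: mask is empty")
  structure(list(grid = grid, inside = inside), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d / %d voxels inside\n",
              sum(x$inside), prod(x$grid$shape)))
  invisible(x)
}

#' Number of in-mask voxels
#' @param mask A [binary_mask()].
#' @return Integer count of voxels inside the mask.
#' @export
mask_size <- function(mask) sum(mask$inside)

#' 0-based voxel indices of in-mask voxels
#' @param mask A [binary_mask()].
#' @return Integer matrix (n x 3), rows ordered by linear array index.
#' @export
mask_voxels <- function(mask) {
  which(mask$inside, arr.ind = TRUE) - 1L
}

#' 4D resting-state time-series image
#'
#' @param grid A [volume_grid()].
#' @param data Numeric 4D array `[x, y, z, t]` with `t >= 2`; values must be
#'   finite inside the mask.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param mask A [binary_mask()] on the same grid.
#' @return An object of class `time_series_image`.
#' @export
time_series_image <- function(grid, data, tr_seconds, mask) {
  stopifnot(inherits(grid, "volume_grid"), inherits(mask, "binary_mask"))
  stopifnot(length(dim(data)) == 4L,
            identical(dim(data)[1:3], as.integer(grid$shape)),
            dim(data)[4] >= 2L)
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  if (!grids_compatible(grid, mask$grid))
    stop("time_series_image: mask grid does not match data grid")
  nt <- dim(data)[4]
  flat <- matrix(data, ncol = nt)
  if (!all(is.finite(flat[as.vector(mask$inside), ])))
    stop("time_series_image: non-finite values inside mask")
  structure(list(grid = grid, data = data, tr_seconds = tr_seconds,
                 mask = mask), class = "time_series_image")
}

#' 3D map of voxel-wise statistics
#'
#' Holds voxel t-values together with the degrees of freedom of the fit and
#' the mask on which they are defined. Positive values mean case > control
#' under the package's contrast coding. Out-of-mask voxels are `NA`.
#'
#' @param grid A [volume_grid()].
#' @param values Numeric 3D array of statistics; finite inside the mask.
#' @param dof Degrees of freedom (>= 1).
#' @param mask A [binary_mask()] on the same grid.
#' @param tail One of `"two_sided"`, `"positive"`, `"negative"`.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(grid, values, dof, mask, tail = "two_sided") {
  stopifnot(inherits(grid, "volume_grid"), inherits(mask, "binary_mask"))
  stopifnot(identical(dim(values), as.integer(grid$shape)))
  dof <- as.integer(dof)
  stopifnot(dof >= 1L)
  tail <- match.arg(tail, c("two_sided", "positive", "negative"))
  if (!all(is.finite(values[mask$inside])))
    stop("stat_map: non-finite statistic inside mask")
  values[!mask$inside] <- NA_real_
  structure(list(grid = grid, values = values, dof = dof, mask = mask,
                 tail = tail), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$mask$inside]
  cat(sprintf("stat_map (%s, dof=%d): range [%.3f, %.3f] over %d voxels\n",
              x$tail, x$dof, min(v), max(v), length(v)))
  invisible(x)
}
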