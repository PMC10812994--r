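# Separable 3D Gaussian smoothing implemented as one banded operator per
# axis. Grids here are small (tens of voxels per axis), so a dense n x n
# convolution matrix per axis is cheaper and simpler than FFT padding.

gauss_kernel_matrix <- function(n, voxel_mm, fwhm_mm, normalize = TRUE) {
  if (fwhm_mm <= 0) return(diag(n))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * voxel_mm)
  k <- exp(-d^2 / (2 * sigma^2))
  radius <- 4 * sigma / voxel_mm
  k[abs(d / voxel_mm) > radius] <- 0
  if (normalize) k / rowSums(k) else k
}

# Apply an axis operator: A acts on dimension `axis` of 3D array x.
apply_axis <- function(x, A, axis) {
  d <- dim(x)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  y <- A %*% matrix(xp, nrow = dp[1])
  y <- array(y, dim = dp)
  aperm(y, order(perm))
}

smooth_3d_plain <- function(arr, voxel_size, fwhm_mm, normalize = TRUE) {
  if (all(fwhm_mm <= 0)) return(arr)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    A <- gauss_kernel_matrix(d[ax], voxel_size[ax], fwhm_mm[ax], normalize)
    arr <- apply_axis(arr, A, ax)
  }
  arr
}

#' Mask-aware Gaussian smoothing of a 3D map
#'
#' Smooths with a separable Gaussian kernel of the given full width at half
#' maximum (mm), renormalizing at mask edges: the kernel-weighted average is
#' taken over in-mask voxels only, so a constant map stays constant inside
#' the mask and no signal bleeds in from outside.
#'
#' @param values Numeric 3D array.
#' @param mask A [binary_mask()] (also supplies the voxel size).
#' @param fwhm_mm Kernel FWHM in mm (scalar or per-axis); `0` is the
#'   identity.
#' @return Smoothed 3D array; out-of-mask voxels are `NA`.
#' @export
smooth_gaussian <- function(values, mask, fwhm_mm) {
  stopifnot(inherits(mask, "binary_mask"), all(fwhm_mm >= 0))
  vs <- mask$grid$voxel_size
  m <- array(as.numeric(mask$inside), dim = dim(mask$inside))
  v <- values
  v[!mask$inside] <- 0
  if (all(fwhm_mm <= 0)) {
    v[!mask$inside] <- NA_real_
    return(v)
  }
  num <- smooth_3d_plain(v, vs, fwhm_mm, normalize = FALSE)
  den <- smooth_3d_plain(m, vs, fwhm_mm, normalize = FALSE)
  out <- num / den
  out[!mask$inside] <- NA_real_
  out
}
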