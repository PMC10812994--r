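# Shared small fixtures, built in code at test time.

small_mask <- function(shape = c(10, 10, 10), voxel = 3) {
  make_mask(shape, voxel, seed = 1)
}

full_mask <- function(shape = c(8, 8, 8), voxel = 3) {
  binary_mask(volume_grid(shape, voxel), array(TRUE, shape))
}

# single-voxel-series 4D image where every in-mask voxel carries `series`
uniform_ts <- function(series, mask, tr = 2) {
  nt <- length(series)
  d <- dim(mask$inside)
  arr <- array(rep(series, each = prod(d)), dim = c(d, nt))
  time_series_image(mask$grid, arr, tr, mask)
}

# list of per-subject smoothed-noise 3D maps
noise_maps <- function(n, mask, fwhm = 6, sd = 1) {
  d <- dim(mask$inside)
  lapply(seq_len(n), function(i) {
    x <- array(stats::rnorm(prod(d), sd = sd), d)
    if (fwhm > 0) x <- neurotx:::smooth_3d_plain(x, mask$grid$voxel_size,
                                                 fwhm)
    x
  })
}

# a t-map-like reference field: estimated null two-sample t-map from
# smoothed-noise subjects (used as the spatial target of gene coupling)
reference_tmap_values <- function(mask, n_per_group = 15, seed = 7) {
  set.seed(seed)
  des <- generate_design(n_per_group, n_per_group, seed = seed)
  dm <- build_design_matrix(des, covariates = character(0))
  maps <- noise_maps(2 * n_per_group, mask)
  fit <- fit_two_sample_glm(maps, dm, mask)
  v <- fit$tmap$values
  v[is.na(v)] <- 0
  v
}

as_volume3d <- function(values, mask) {
  structure(list(grid = mask$grid, values = values, mask = mask),
            class = "volume3d")
}
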