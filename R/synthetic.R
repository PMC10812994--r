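# Synthetic ground-truth generators for the whole pipeline: a brain-like
# mask, two-group 4D time series with band-limited amplitude effects in
# known clusters, two-group GMV maps with additive effects, and donor-
# tagged probe-level expression samples whose true genes track a supplied
# effect map. All generators are pure functions of (parameters, seed).

#' Generate an ellipsoidal brain-like mask
#'
#' A single connected ellipsoid centred in the grid, occupying roughly
#' 30-50% of the voxels.
#'
#' @param shape Grid shape (default `c(24, 28, 24)`).
#' @param voxel_size Voxel size in mm (default 3).
#' @param seed Integer seed (the default mask is deterministic; the seed
#'   perturbs the ellipsoid semi-axes slightly).
#' @param jitter Relative semi-axis jitter (default 0.05).
#' @return A [binary_mask()].
#' @export
make_mask <- function(shape = c(24, 28, 24), voxel_size = c(3, 3, 3),
                      seed = 1L, jitter = 0.05) {
  shape <- as.integer(shape)
  if (any(shape < 4L)) stop("make_mask: degenerate shape")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  grid <- volume_grid(shape, voxel_size)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  semi <- (shape / 2 - 1.5) * (1 + jitter * stats::runif(3, -1, 1))
  ctr <- (shape - 1) / 2
  i <- (seq_len(shape[1]) - 1 - ctr[1]) / semi[1]
  j <- (seq_len(shape[2]) - 1 - ctr[2]) / semi[2]
  k <- (seq_len(shape[3]) - 1 - ctr[3]) / semi[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  binary_mask(grid, r2 <= 1)
}

#' Specify seeded group-difference clusters
#'
#' @param cluster_centers Matrix (k x 3) of 0-based voxel coordinates.
#' @param cluster_radius_mm Sphere radius in mm (> 0).
#' @param amplitude_effect Fractional increase of band-limited signal
#'   amplitude for cases in positive clusters (divided for negative).
#' @param gmv_effect Additive case-minus-control GMV difference.
#' @param signs `+1` / `-1` per cluster.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(cluster_centers, cluster_radius_mm = 7.5,
                        amplitude_effect = 0.5, gmv_effect = 0.15,
                        signs = NULL) {
  cluster_centers <- rbind2mat(cluster_centers)
  if (is.null(signs)) signs <- rep(1, nrow(cluster_centers))
  stopifnot(cluster_radius_mm > 0,
            length(signs) == nrow(cluster_centers),
            all(signs %in% c(-1, 1)))
  structure(list(cluster_centers = cluster_centers,
                 cluster_radius_mm = cluster_radius_mm,
                 amplitude_effect = amplitude_effect,
                 gmv_effect = gmv_effect, signs = signs),
            class = "effect_spec")
}

#' Default two-cluster effect specification for a mask
#'
#' One positive and one negative spherical cluster placed inside the mask,
#' offset from the centre along the longest axis.
#'
#' @param mask A [binary_mask()].
#' @param ... Passed to [effect_spec()].
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(mask, ...) {
  vox <- mask_voxels(mask)
  ctr <- round(colMeans(vox))
  span <- apply(vox, 2, function(v) diff(range(v)))
  ax <- which.max(span)
  off <- round(span[ax] / 4)
  c1 <- ctr; c1[ax] <- ctr[ax] + off
  c2 <- ctr; c2[ax] <- ctr[ax] - off
  effect_spec(rbind(c1, c2), signs = c(1, -1), ...)
}

# signed indicator (+1 / -1 / 0) of effect clusters over the grid
effect_indicator <- function(mask, effect) {
  d <- dim(mask$inside)
  ind <- array(0, dim = d)
  centers_world <- voxel_to_world(mask$grid, effect$cluster_centers)
  vox <- mask_voxels(mask)
  world <- voxel_to_world(mask$grid, vox)
  lin <- which(mask$inside)
  for (k in seq_len(nrow(centers_world))) {
    dist <- sqrt(rowSums((world - matrix(centers_world[k, ],
                                         nrow(world), 3,
                                         byrow = TRUE))^2))
    hit <- dist <= effect$cluster_radius_mm
    if (!any(hit))
      stop("effect_indicator: cluster ", k, " lies outside the mask")
    ind[lin[hit]] <- effect$signs[k]
  }
  ctr_in <- mask$inside[matrix(effect$cluster_centers + 1L, ncol = 3)]
  if (!all(ctr_in))
    stop("effect_indicator: cluster centre(s) outside the mask")
  ind
}

# band-limited noise: V voxels x T timepoints, unit variance per series
band_limited_noise <- function(n_voxel, n_time, tr, low_hz, high_hz) {
  bins <- band_bins(n_time, tr, low_hz, high_hz)
  bins <- bins[bins > 0]
  X <- matrix(0 + 0i, n_time, n_voxel)
  re <- matrix(stats::rnorm(length(bins) * n_voxel), length(bins))
  im <- matrix(stats::rnorm(length(bins) * n_voxel), length(bins))
  X[bins + 1L, ] <- complex(real = re, imaginary = im)
  X[n_time - bins + 1L, ] <- Conj(X[bins + 1L, ])
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n_time
  # closed-form unit-variance scaling: var(x_t) = 4 B / N^2
  x / (2 * sqrt(length(bins)) / n_time)
}

#' Generate two-group 4D resting-state time series
#'
#' Per subject: a smooth spatial baseline plus a band-limited (default
#' 0.01-0.08 Hz) stochastic signal whose amplitude inside positive-effect
#' clusters is multiplied by `1 + amplitude_effect` for cases (divided for
#' negative clusters), plus white noise. The group difference lives purely
#' in the band-limited amplitude, i.e. in ALFF.
#'
#' @param design Data.frame with columns `subject_id`, `group`.
#' @param mask A [binary_mask()].
#' @param effect An [effect_spec()].
#' @param tr Repetition time in seconds (default 2).
#' @param n_timepoints Time points per subject (default 200, minimum 64).
#' @param seed Integer seed.
#' @param band Pass-band of the stochastic signal (default
#'   `c(0.01, 0.08)` Hz).
#' @param signal_sd,noise_sd Standard deviations of the band-limited signal
#'   and the white noise (defaults 1 and 0.5).
#' @param amp_heterogeneity Relative spatial variation of the band-limited
#'   amplitude across the brain (smooth field, default 0.3), emulating the
#'   regional ALFF topography of real resting-state data; without it the
#'   standardized ALFF map is flat and a one-sample masking step would
#'   retain almost nothing.
#' @param baseline Mean signal level (default 100).
#' @param apply_fn Optional function applied to each subject's
#'   [time_series_image()] as it is generated; the list then holds the
#'   results instead of the raw 4D images (keeps memory flat when only a
#'   per-subject summary map is needed).
#' @return Named list of [time_series_image()] (or of `apply_fn` results),
#'   one per design row.
#' @export
generate_group_fmri <- function(design, mask, effect, tr = 2,
                                n_timepoints = 200L, seed = 1L,
                                band = c(0.01, 0.08), signal_sd = 1,
                                noise_sd = 0.5, amp_heterogeneity = 0.3,
                                baseline = 100, apply_fn = NULL) {
  stopifnot(n_timepoints >= 64L)
  ind <- effect_indicator(mask, effect)
  d <- dim(mask$inside)
  inside <- mask$inside
  nv <- sum(inside)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  base_field <- baseline +
    10 * smooth_3d_plain(array(stats::rnorm(prod(d)), d),
                         mask$grid$voxel_size, 12)
  amp_field <- smooth_3d_plain(array(stats::rnorm(prod(d)), d),
                               mask$grid$voxel_size, 12)
  amp_field <- amp_field / stats::sd(amp_field[inside])
  amp <- signal_sd * pmax(0.2, 1 + amp_heterogeneity * amp_field[inside])
  gain_case <- ifelse(ind[inside] > 0, 1 + effect$amplitude_effect,
                      ifelse(ind[inside] < 0,
                             1 / (1 + effect$amplitude_effect), 1))
  out <- vector("list", nrow(design))
  names(out) <- design$subject_id
  for (s in seq_len(nrow(design))) {
    sig <- band_limited_noise(nv, n_timepoints, tr, band[1], band[2]) *
      matrix(amp, n_timepoints, nv, byrow = TRUE)
    if (design$group[s] == "case")
      sig <- sig * matrix(gain_case, n_timepoints, nv, byrow = TRUE)
    wn <- matrix(stats::rnorm(n_timepoints * nv, sd = noise_sd),
                 n_timepoints)
    series <- sig + wn +
      matrix(base_field[inside], n_timepoints, nv, byrow = TRUE)
    arr <- array(0, dim = c(d, n_timepoints))
    flat <- matrix(arr, ncol = n_timepoints)
    flat[inside, ] <- t(series)
    arr <- array(flat, dim = c(d, n_timepoints))
    tsi <- time_series_image(mask$grid, arr, tr, mask)
    out[[s]] <- if (is.null(apply_fn)) tsi else apply_fn(tsi)
  }
  out
}

#' Generate two-group gray-matter-volume maps
#'
#' Per subject: smooth template + additive group effect (`gmv_effect`
#' times the signed cluster indicator for cases) + smoothed subject noise.
#'
#' @param design Data.frame with `subject_id`, `group`.
#' @param mask A [binary_mask()].
#' @param effect An [effect_spec()] (`gmv_effect`, `signs` used).
#' @param smoothing_fwhm Noise smoothing FWHM in mm (default 8).
#' @param seed Integer seed.
#' @param noise_sd Pre-smoothing noise SD (default 0.35; smoothing shrinks
#'   it substantially).
#' @param template_mean Baseline GMV level (default 0.6).
#' @return Named list of `volume3d` objects, one per design row.
#' @export
generate_group_gmv <- function(design, mask, effect, smoothing_fwhm = 8,
                               seed = 1L, noise_sd = 0.35,
                               template_mean = 0.6) {
  ind <- effect_indicator(mask, effect)
  d <- dim(mask$inside)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  template <- template_mean +
    0.05 * smooth_3d_plain(array(stats::rnorm(prod(d)), d),
                           mask$grid$voxel_size, 12)
  out <- vector("list", nrow(design))
  names(out) <- design$subject_id
  for (s in seq_len(nrow(design))) {
    noise <- array(stats::rnorm(prod(d), sd = noise_sd), d)
    if (smoothing_fwhm > 0)
      noise <- smooth_3d_plain(noise, mask$grid$voxel_size, smoothing_fwhm)
    vals <- template + noise
    if (design$group[s] == "case") vals <- vals + effect$gmv_effect * ind
    vals[!mask$inside] <- NA_real_
    out[[s]] <- structure(list(grid = mask$grid, values = vals,
                               mask = mask), class = "volume3d")
  }
  out
}

#' Generate a synthetic subject design table
#'
#' @param n_case,n_control Group sizes (defaults 31 and 31).
#' @param seed Integer seed.
#' @return Data.frame with the design-table columns.
#' @export
generate_design <- function(n_case = 31L, n_control = 31L, seed = 1L) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  n <- n_case + n_control
  data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    age = round(stats::rnorm(n, 42, 9), 1),
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(0.8, 0.2)),
    education = round(stats::runif(n, 6, 19)),
    bmi = round(stats::rnorm(n, 26, 3), 1),
    stringsAsFactors = FALSE)
}

#' Ground-truth parameters for the expression generator
#'
#' @param n_genes Total genes (default 2000).
#' @param n_true Number of genes coupled to the effect map (default 50).
#' @param coupling_r Target Pearson correlation between a true gene's
#'   spatial profile and the effect map (default 0.5; must be in (0,1)).
#' @param noise_sd Residual spread of the gene profiles (default 1).
#' @param n_donors Donor count (default 3).
#' @param probes_per_gene Probes per gene (default 2).
#' @param frac_low_intensity Fraction of probes planted below background
#'   (default 0.1).
#' @param frac_stale Fraction of probes with an outdated annotation symbol
#'   (default 0.1).
#' @param frac_unmappable Fraction of probes absent from the current
#'   annotation map (default 0.02).
#' @param pattern_fwhm_mm Spatial correlation length (FWHM) of a null
#'   gene's intrinsic expression pattern (default 8 mm).
#' @param pattern_smooth_frac Variance fraction of a null gene's pattern
#'   at that structure scale, the rest being sample-level white variation
#'   (default 0.5). Genes whose patterns have little structure-scale
#'   variance are unstable across donors and are mostly removed by the
#'   stability filter, as in real probe-level expression data.
#' @param true_pattern_fwhm_mm,true_pattern_smooth_frac Same two
#'   parameters for the intrinsic (non-coupled) component of the true
#'   genes (defaults 18 mm and 0.75): disease-associated genes are drawn
#'   from the strongly patterned, donor-reproducible portion of the
#'   transcriptome so they survive preprocessing.
#' @return An object of class `expression_truth` (includes
#'   `true_gene_ids`).
#' @export
expression_truth <- function(n_genes = 2000L, n_true = 50L,
                             coupling_r = 0.5, noise_sd = 1,
                             n_donors = 3L, probes_per_gene = 2L,
                             frac_low_intensity = 0.1, frac_stale = 0.1,
                             frac_unmappable = 0.02,
                             pattern_fwhm_mm = 8,
                             pattern_smooth_frac = 0.5,
                             true_pattern_fwhm_mm = 18,
                             true_pattern_smooth_frac = 0.75) {
  stopifnot(coupling_r > 0, coupling_r < 1, n_donors >= 1L,
            n_true <= n_genes, pattern_smooth_frac >= 0,
            pattern_smooth_frac <= 1, true_pattern_smooth_frac >= 0,
            true_pattern_smooth_frac <= 1)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  structure(list(n_genes = as.integer(n_genes),
                 gene_ids = genes,
                 true_gene_ids = genes[seq_len(n_true)],
                 coupling_r = coupling_r, noise_sd = noise_sd,
                 n_donors = as.integer(n_donors),
                 probes_per_gene = as.integer(probes_per_gene),
                 frac_low_intensity = frac_low_intensity,
                 frac_stale = frac_stale,
                 frac_unmappable = frac_unmappable,
                 pattern_fwhm_mm = pattern_fwhm_mm,
                 pattern_smooth_frac = pattern_smooth_frac,
                 true_pattern_fwhm_mm = true_pattern_fwhm_mm,
                 true_pattern_smooth_frac = true_pattern_smooth_frac),
            class = "expression_truth")
}

#' Generate donor-tagged probe-level expression samples
#'
#' Samples are placed at distinct in-mask voxel centres (with sub-voxel
#' jitter), assigned round-robin to donors, and tagged with a coarse
#' structure label (block partition of the mask) shared across donors.
#' Each true gene's per-sample profile is `r * z(effect) +
#' sqrt(1 - r^2) * noise`, so its correlation with the effect map is
#' `coupling_r` in expectation; null genes are weakly smooth spatial noise.
#' Genes are carried by `probes_per_gene` probes with per-probe offsets and
#' per-donor affine intensity distortions; configurable fractions of
#' probes are planted below background intensity or given stale / missing
#' annotations.
#'
#' @param mask A [binary_mask()].
#' @param truth An [expression_truth()].
#' @param effect_map A [stat_map()] (or `volume3d`) whose in-mask values
#'   define the spatial pattern true genes follow.
#' @param n_samples Number of samples (default 300; must not exceed the
#'   in-mask voxel count, minimum 2).
#' @param seed Integer seed.
#' @return An object of class `expression_sample_set` with fields
#'   `samples` (data.frame: sample_id, donor, x, y, z, structure, voxel
#'   linear index), `intensity` (probes x samples), `background`
#'   (per-probe), `annotation` (data.frame: probe_id, gene_symbol),
#'   `current_map` (data.frame: probe_id, gene_symbol), and `truth`.
#' @export
generate_expression_samples <- function(mask, truth, effect_map,
                                        n_samples = 300L, seed = 1L) {
  stopifnot(inherits(truth, "expression_truth"))
  if (n_samples < 2L) stop("generate_expression_samples: n_samples < 2")
  nv <- mask_size(mask)
  if (n_samples > nv)
    stop("generate_expression_samples: more samples than in-mask voxels")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  lin_inside <- which(mask$inside)
  pick <- sort(sample(lin_inside, n_samples))
  ijk <- arrayInd(pick, dim(mask$inside)) - 1L
  xyz <- voxel_to_world(mask$grid, ijk) +
    matrix(stats::runif(3 * n_samples, -1, 1), ncol = 3)
  donors <- sprintf("donor%d", ((seq_len(n_samples) - 1L) %%
                                  truth$n_donors) + 1L)
  structure_tag <- structure_labels(mask)[pick]
  eff <- if (inherits(effect_map, "stat_map")) effect_map$values else
    effect_map$values
  z_eff <- as.numeric(scale(eff[pick]))
  ng <- truth$n_genes
  r <- truth$coupling_r
  # Every gene owns a fixed spatial pattern: a smooth (structure-scale)
  # component -- reproducible across donors, which is what differential
  # stability measures -- plus sample-level white variation. Smooth
  # patterns live in shared low-rank bases of smooth random fields; true
  # genes draw their intrinsic component from a longer-range basis.
  d <- dim(mask$inside)
  make_basis <- function(fwhm) {
    nbasis <- 80L
    basis <- matrix(0, n_samples, nbasis)
    for (b in seq_len(nbasis)) {
      f <- smooth_3d_plain(array(stats::rnorm(prod(d)), d),
                           mask$grid$voxel_size, fwhm)
      basis[, b] <- f[pick]
    }
    scale(basis)
  }
  gene_patterns <- function(n, basis, v_smooth) {
    nbasis <- ncol(basis)
    sp <- tcrossprod(matrix(stats::rnorm(n * nbasis) / sqrt(nbasis), n),
                     basis)
    sp <- sp / stats::sd(as.numeric(sp))
    sqrt(v_smooth) * sp +
      sqrt(1 - v_smooth) * matrix(stats::rnorm(n * n_samples), nrow = n)
  }
  expr <- gene_patterns(ng, make_basis(truth$pattern_fwhm_mm),
                        truth$pattern_smooth_frac) * truth$noise_sd
  is_true <- truth$gene_ids %in% truth$true_gene_ids
  nt <- sum(is_true)
  if (nt > 0) {
    eta <- gene_patterns(nt, make_basis(truth$true_pattern_fwhm_mm),
                         truth$true_pattern_smooth_frac)
    expr[is_true, ] <- r * matrix(z_eff, nt, n_samples, byrow = TRUE) +
      sqrt(1 - r^2) * eta
  }
  # probe level
  ppg <- truth$probes_per_gene
  probe_id <- sprintf("P%04d_%d", rep(seq_len(ng), each = ppg),
                      rep(seq_len(ppg), ng))
  probe_gene <- rep(truth$gene_ids, each = ppg)
  np <- length(probe_id)
  donor_scale <- stats::runif(truth$n_donors, 0.7, 1.3)
  donor_offset <- stats::runif(truth$n_donors, -10, 10)
  dix <- ((seq_len(n_samples) - 1L) %% truth$n_donors) + 1L
  probe_offset <- stats::rnorm(np, sd = 4)
  gene_row <- rep(seq_len(ng), each = ppg)
  intensity <- 120 + 15 * expr[gene_row, , drop = FALSE]
  intensity <- intensity *
    matrix(donor_scale[dix], np, n_samples, byrow = TRUE) +
    matrix(donor_offset[dix], np, n_samples, byrow = TRUE) +
    matrix(probe_offset, np, n_samples) +
    matrix(stats::rnorm(np * n_samples, sd = 2), np)
  background <- rep(40, np)
  # plant low-intensity probes: at most one probe per gene so no gene dies
  n_low <- round(truth$frac_low_intensity * np)
  cand <- which(rep(seq_len(ppg), ng) == ppg & ppg > 1L)
  if (ppg == 1L) cand <- seq_len(np)
  low <- sort(sample(cand, min(n_low, length(cand))))
  intensity[low, ] <- matrix(stats::runif(length(low) * n_samples, 5, 35),
                             length(low))
  # annotations: stale symbols and unmappable probes (first probes only,
  # so every gene keeps a mappable probe when ppg > 1)
  ann_symbol <- probe_gene
  n_stale <- round(truth$frac_stale * np)
  stale_cand <- if (ppg > 1L) which(rep(seq_len(ppg), ng) == 1L) else
    seq_len(np)
  stale <- sort(sample(stale_cand, min(n_stale, length(stale_cand))))
  ann_symbol[stale] <- paste0(probe_gene[stale], "_OLD")
  unmap_cand <- setdiff(stale_cand, stale)
  n_unmap <- round(truth$frac_unmappable * np)
  unmap <- sort(sample(unmap_cand, min(n_unmap, length(unmap_cand))))
  current_map <- data.frame(probe_id = probe_id[-unmap],
                            gene_symbol = probe_gene[-unmap],
                            stringsAsFactors = FALSE)
  if (!length(unmap)) current_map <- data.frame(
    probe_id = probe_id, gene_symbol = probe_gene,
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    donor = donors, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    structure = structure_tag, voxel = pick,
    stringsAsFactors = FALSE)
  rownames(intensity) <- probe_id
  colnames(intensity) <- samples$sample_id
  structure(list(samples = samples, intensity = intensity,
                 background = stats::setNames(background, probe_id),
                 annotation = data.frame(probe_id = probe_id,
                                         gene_symbol = ann_symbol,
                                         stringsAsFactors = FALSE),
                 current_map = current_map,
                 truth = truth,
                 planted_low = probe_id[low]),
            class = "expression_sample_set")
}

# coarse contiguous structure labels: 3x3x3 block partition of the mask
structure_labels <- function(mask, blocks = c(3L, 3L, 3L)) {
  d <- dim(mask$inside)
  cuts <- lapply(1:3, function(ax)
    pmin(blocks[ax], 1L + ((seq_len(d[ax]) - 1L) * blocks[ax]) %/% d[ax]))
  lab <- array("", dim = d)
  bi <- cuts[[1]][slice.index(lab, 1)]
  bj <- cuts[[2]][slice.index(lab, 2)]
  bk <- cuts[[3]][slice.index(lab, 3)]
  array(sprintf("B%d%d%d", bi, bj, bk), dim = d)
}

#' Generate a synthetic clinical table
#'
#' Sleep-severity-like and cognition-like measures with realistic group
#' separation: cases have a high apnea-hypopnea-index-like measure and
#' lower cognition scores. One cognition measure is coupled to the
#' supplied per-subject imaging score so the downstream Spearman stage has
#' a planted association.
#'
#' @param design Subject design data.frame.
#' @param imaging_score Optional numeric vector (one value per subject) a
#'   cognition measure is linearly coupled to.
#' @param seed Integer seed.
#' @return Data.frame with `subject_id`, `ahi`, `ess`, `moca`,
#'   `stroop_word`, `smoker`.
#' @export
generate_clinical_table <- function(design, imaging_score = NULL,
                                    seed = 1L) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  n <- nrow(design)
  case <- design$group == "case"
  ahi <- ifelse(case, stats::rgamma(n, shape = 6, scale = 6) + 15,
                stats::rgamma(n, shape = 2, scale = 1.5))
  ess <- round(ifelse(case, stats::rnorm(n, 12, 4),
                      stats::rnorm(n, 5, 3)))
  moca <- round(pmin(30, ifelse(case, stats::rnorm(n, 24, 2.5),
                                stats::rnorm(n, 27, 1.5))))
  stroop <- stats::rnorm(n, 80, 10)
  if (!is.null(imaging_score))
    stroop <- stroop - 8 * as.numeric(scale(imaging_score))
  smoker <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.3, 0.7))
  data.frame(subject_id = design$subject_id, ahi = round(ahi, 1),
             ess = pmax(0, ess), moca = moca,
             stroop_word = round(stroop, 1), smoker = smoker,
             stringsAsFactors = FALSE)
}
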