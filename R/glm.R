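#' Build the two-group design matrix
#'
#' Columns: intercept, group contrast (case = +1, control = 0, so a
#' positive group effect means case > control), age, sex (male = 1),
#' education, bmi. The contrast vector selects the group column.
#'
#' @param design Data.frame as returned by [read_design_table()].
#' @param covariates Character vector of covariate columns to include
#'   (default `c("age", "sex", "education", "bmi")`; use `character(0)` for
#'   a group-only design).
#' @return List with `X` (n x p matrix), `contrast` (length-p vector) and
#'   `groups` (factor).
#' @export
build_design_matrix <- function(design,
                                covariates = c("age", "sex", "education",
                                               "bmi")) {
  stopifnot(all(design$group %in% c("case", "control")))
  if (length(unique(design$group)) != 2L ||
      any(table(design$group) < 2L))
    stop("build_design_matrix: need >= 2 subjects in each group")
  X <- cbind(intercept = 1, group = as.numeric(design$group == "case"))
  for (cv in covariates) {
    col <- if (cv == "sex") as.numeric(design$sex == "male") else
      as.numeric(design[[cv]])
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X))
    stop("build_design_matrix: design matrix is rank deficient")
  contrast <- as.numeric(colnames(X) == "group")
  list(X = X, contrast = contrast, groups = factor(design$group))
}

stack_maps <- function(maps, mask) {
  inside <- as.vector(mask$inside)
  do.call(rbind, lapply(maps, function(m) {
    arr <- if (is.list(m) && !is.null(m$values)) m$values else
      if (inherits(m, "alff_map")) m$standardized_alff else m
    as.numeric(arr)[inside]
  }))
}

#' One-sample t masking of standardized maps
#'
#' Voxel-wise one-sample t-test of each group's maps against a null value
#' (1 for mALFF maps), keeping the union of voxels where either group is
#' significant at `alpha` (two-sided, uncorrected). Used to restrict the
#' two-sample comparison to voxels with reliable signal in at least one
#' group, mirroring the common two-step ALFF analysis.
#'
#' @param maps List of per-subject 3D arrays (or `alff_map` /`volume3d`
#'   objects).
#' @param groups Factor/character vector (`case` / `control`) per map.
#' @param mask A [binary_mask()]; the test runs inside it.
#' @param null_value Value tested against (default 1, the mALFF mean).
#' @param alpha Two-sided uncorrected significance level (default 0.05).
#' @return A [binary_mask()] of significant voxels. Zero-variance voxels
#'   are excluded (count logged).
#' @export
one_sample_mask <- function(maps, groups, mask, null_value = 1,
                            alpha = 0.05) {
  groups <- as.character(groups)
  Y <- stack_maps(maps, mask)
  keep <- rep(FALSE, ncol(Y))
  n_zero <- 0L
  for (g in unique(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    n <- nrow(Yg)
    stopifnot(n >= 2L)
    m <- colMeans(Yg)
    s <- sqrt(colSums((Yg - matrix(m, n, ncol(Yg), byrow = TRUE))^2) /
                (n - 1))
    zero <- s == 0
    n_zero <- n_zero + sum(zero)
    tt <- rep(0, length(m))
    tt[!zero] <- (m[!zero] - null_value) / (s[!zero] / sqrt(n))
    p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
    keep <- keep | (!zero & p < alpha)
  }
  stage_log("one_sample_mask", "kept %d voxels (%d zero-variance excluded)",
            sum(keep), n_zero)
  inside <- array(FALSE, dim = dim(mask$inside))
  inside[mask$inside] <- keep
  if (!any(inside)) stop("one_sample_mask: no significant voxels")
  binary_mask(mask$grid, inside)
}

#' Fit the voxel-wise two-group GLM
#'
#' Ordinary least squares at every in-mask voxel with the group contrast
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)`, dof = n - rank(X). Positive t
#' means case > control after covariate adjustment.
#'
#' @param maps List of per-subject 3D arrays (or map objects), one per
#'   design row, in design order.
#' @param design_matrix Result of [build_design_matrix()].
#' @param mask A [binary_mask()] restricting the fit.
#' @return A list of class `glm_fit`: `tmap` (a [stat_map()]), `residuals`
#'   (n_subject x n_voxel matrix of residuals, for smoothness estimation),
#'   and `n_undefined` (zero-residual-variance voxels, flagged `NA`).
#' @export
fit_two_sample_glm <- function(maps, design_matrix, mask) {
  X <- design_matrix$X
  cvec <- design_matrix$contrast
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(maps) == n, n > p + 1)
  Y <- stack_maps(maps, mask)
  qrX <- qr(X)
  stopifnot(qrX$rank == p)
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  dof <- n - p
  sigma2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  cxc <- drop(t(cvec) %*% XtXinv %*% cvec)
  eff <- drop(crossprod(cvec, beta))
  tt <- eff / sqrt(sigma2 * cxc)
  undef <- sigma2 <= .Machine$double.eps * max(sigma2, 1)
  tt[undef] <- NA_real_
  vals <- array(NA_real_, dim = dim(mask$inside))
  vals[mask$inside] <- tt
  # stat_map requires finite values inside the mask; shrink it at
  # undefined voxels
  inside <- mask$inside
  if (any(undef)) {
    inside[mask$inside][undef] <- FALSE
    vals[!inside] <- NA_real_
  }
  m2 <- binary_mask(mask$grid, inside)
  structure(list(tmap = stat_map(mask$grid, vals, dof, m2),
                 residuals = res, mask = m2,
                 n_undefined = sum(undef)),
            class = "glm_fit")
}

#' Estimate residual smoothness by the gradient-variance method
#'
#' Each voxel's residual vector across maps is normalized to unit norm;
#' per-axis smoothness follows from the ratio of the variance of spatial
#' first differences to the variance of the (normalized) residuals:
#' `FWHM_axis = voxel_size * sqrt(4*log(2) / ratio_axis)`. The resel count
#' is the mask volume divided by the product of per-axis FWHMs.
#'
#' @param residuals n_maps x n_voxel matrix of residuals over in-mask
#'   voxels (as from [fit_two_sample_glm()]), or a list of 3D residual
#'   arrays.
#' @param mask A [binary_mask()].
#' @param dof Degrees of freedom of the fit that produced the residuals.
#' @return List of class `smoothness_estimate`: `fwhm_mm` (length 3),
#'   `fwhm_voxels`, `resels`, `dof`.
#' @export
estimate_smoothness <- function(residuals, mask, dof) {
  if (is.list(residuals)) residuals <- stack_maps(residuals, mask)
  stopifnot(nrow(residuals) >= 2L)
  d <- dim(mask$inside)
  inside <- mask$inside
  # voxel-wise normalization to unit norm across maps
  norms <- sqrt(colSums(residuals^2))
  norms[norms == 0] <- 1
  U <- residuals / matrix(norms, nrow(residuals), ncol(residuals),
                          byrow = TRUE)
  ssq_grad <- c(0, 0, 0)
  n_grad <- c(0L, 0L, 0L)
  full <- array(NA_real_, dim = d)
  for (i in seq_len(nrow(U))) {
    full[inside] <- U[i, ]
    for (ax in 1:3) {
      idx_lo <- slice_index(d, ax, 1L, d[ax] - 1L)
      idx_hi <- slice_index(d, ax, 2L, d[ax])
      both <- inside[idx_lo] & inside[idx_hi]
      g <- full[idx_hi][both] - full[idx_lo][both]
      ssq_grad[ax] <- ssq_grad[ax] + sum(g^2)
      if (i == 1L) n_grad[ax] <- sum(both)
    }
  }
  n_maps <- nrow(U)
  # unit-norm residuals: mean squared value per voxel over maps is 1/n_maps
  var_res <- 1 / n_maps
  var_grad <- ssq_grad / (n_grad * n_maps)
  ratio <- var_grad / var_res
  if (any(ratio <= 0))
    stop("estimate_smoothness: zero gradient variance (infinite smoothness)")
  fwhm_vox <- sqrt(4 * log(2) / ratio)
  fwhm_mm <- fwhm_vox * mask$grid$voxel_size
  resels <- mask_size(mask) / prod(fwhm_vox)
  structure(list(fwhm_mm = fwhm_mm, fwhm_voxels = fwhm_vox,
                 resels = resels,
                 resel_counts = resel_counts(mask, fwhm_vox),
                 dof = dof),
            class = "smoothness_estimate")
}

# logical index extracting slices lo..hi along axis `ax` of a d-dim array
slice_index <- function(d, ax, lo, hi) {
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[ax]] <- lo:hi
  arr <- array(FALSE, dim = d)
  arr[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  arr
}

# --- Gaussian random field cluster-level inference ------------------------

# Euler-characteristic densities of a t-field (dimensions 0..3, per resel)
ec_density_t <- function(t, dof) {
  a <- 4 * log(2)
  shape <- (1 + t^2 / dof)^(-(dof - 1) / 2)
  b <- exp(lgamma((dof + 1) / 2) - lgamma(dof / 2))
  c(stats::pt(t, df = dof, lower.tail = FALSE),
    sqrt(a) / (2 * pi) * shape,
    a / (2 * pi)^(3 / 2) * shape * t * b / sqrt(dof / 2),
    a^(3 / 2) / (2 * pi)^2 * shape * ((dof - 1) * t^2 / dof - 1))
}

# Lattice resel counts of a mask (Worsley-style voxel/edge/face/cube
# counting) at smoothness fwhm_vox (per-axis FWHM in voxel units).
resel_counts <- function(mask, fwhm_vox) {
  m <- mask$inside
  d <- dim(m)
  P <- sum(m)
  pair <- function(ax) {
    lo <- slice_index(d, ax, 1L, d[ax] - 1L)
    hi <- slice_index(d, ax, 2L, d[ax])
    sum(m[lo] & m[hi])
  }
  Ex <- pair(1); Ey <- pair(2); Ez <- pair(3)
  # shift_down(a, ax)[i] = a[i+1] along ax (FALSE past the border)
  shift_down <- function(a, ax) {
    out <- array(FALSE, d)
    keep <- lapply(d, seq_len); keep[[ax]] <- seq_len(d[ax] - 1L)
    src <- lapply(d, seq_len); src[[ax]] <- 2:d[ax]
    out[keep[[1]], keep[[2]], keep[[3]]] <-
      a[src[[1]], src[[2]], src[[3]]]
    out
  }
  face <- function(ax1, ax2) {
    s1 <- shift_down(m, ax1)
    sum(m & s1 & shift_down(m & s1, ax2))
  }
  Fxy <- face(1, 2); Fxz <- face(1, 3); Fyz <- face(2, 3)
  cube <- {
    a <- m & shift_down(m, 1)
    b <- a & shift_down(a, 2)
    sum(b & shift_down(b, 3))
  }
  r <- 1 / fwhm_vox
  c(R0 = P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - cube,
    R1 = (Ex - Fxy - Fxz + cube) * r[1] + (Ey - Fxy - Fyz + cube) * r[2] +
         (Ez - Fxz - Fyz + cube) * r[3],
    R2 = (Fxy - cube) * r[1] * r[2] + (Fxz - cube) * r[1] * r[3] +
         (Fyz - cube) * r[2] * r[3],
    R3 = cube * r[1] * r[2] * r[3])
}

# Cluster-level corrected p for a cluster of `extent` voxels above
# threshold `tthr`: expected cluster count from the full EC sum over the
# mask's resel counts, extent distribution per the standard 3D
# cluster-size approximation (one tail).
grf_cluster_p <- function(extent, tthr, resels, nvox, dof) {
  phi <- stats::pt(tthr, df = dof, lower.tail = FALSE)
  ec <- ec_density_t(tthr, dof)
  Em <- if (length(resels) == 4L) sum(resels * ec) else resels * ec[4]
  Em <- max(Em, .Machine$double.xmin)
  EN <- nvox * phi                              # expected suprathreshold voxels
  En <- EN / Em                                 # expected cluster extent
  beta <- (gamma(5 / 2) / En)^(2 / 3)
  p_ext <- exp(-beta * extent^(2 / 3))          # P(extent >= k)
  1 - exp(-Em * p_ext)
}

#' Cluster-level correction by Gaussian random field theory
#'
#' Thresholds the t-map voxel-wise (each tail at `voxel_p / 2` when
#' two-tailed), labels suprathreshold clusters per tail, and assigns each
#' cluster a corrected p-value from the expected Euler characteristic of a
#' 3D t-field and the standard cluster-extent distribution. Clusters with
#' corrected p below `cluster_p` are returned.
#'
#' @param tmap A [stat_map()].
#' @param smoothness A `smoothness_estimate` from [estimate_smoothness()]
#'   on the same mask.
#' @param voxel_p Voxel-level threshold (two-tailed total; default 0.001).
#' @param cluster_p Cluster-level corrected threshold (total across both
#'   tails; default 0.05). In a two-tailed analysis each tail is tested at
#'   `voxel_p / 2` and `cluster_p / 2`, so the family-wise error over
#'   increases and decreases together is controlled at `cluster_p`.
#' @param two_tailed Test both tails (default `TRUE`).
#' @param connectivity Cluster connectivity (default 26).
#' @return Data.frame of cluster records sorted by decreasing |peak t|:
#'   `label`, `sign` (`increase`/`decrease`), `peak_x/y/z` (world mm),
#'   `extent` (voxels), `peak_t`, `p_corrected`.
#' @export
grf_cluster_correction <- function(tmap, smoothness, voxel_p = 0.001,
                                   cluster_p = 0.05, two_tailed = TRUE,
                                   connectivity = 26L) {
  stopifnot(inherits(tmap, "stat_map"),
            inherits(smoothness, "smoothness_estimate"))
  if (smoothness$resels < 1)
    warning("grf_cluster_correction: fewer than 1 resel; ",
            "correction unreliable")
  if (any(smoothness$fwhm_voxels < 2))
    warning("grf_cluster_correction: smoothness below 2 voxels FWHM; ",
            "GRF approximation may be inaccurate")
  p_tail <- if (two_tailed) voxel_p / 2 else voxel_p
  cluster_p_tail <- if (two_tailed) cluster_p / 2 else cluster_p
  tthr <- stats::qt(p_tail, df = tmap$dof, lower.tail = FALSE)
  nvox <- mask_size(tmap$mask)
  tails <- if (two_tailed) c(1, -1) else
    if (tmap$tail == "negative") -1 else 1
  rows <- list()
  vox_list <- list()
  for (sgn in tails) {
    v <- tmap$values * sgn
    flag <- !is.na(v) & v > tthr
    if (!any(flag)) next
    lab <- label_clusters(flag, connectivity)
    sizes <- attr(lab, "sizes")
    rc <- smoothness$resel_counts %||% smoothness$resels
    for (k in seq_along(sizes)) {
      idx <- which(lab == k)
      pcorr <- grf_cluster_p(sizes[k], tthr, rc, nvox, tmap$dof)
      peak_lin <- idx[which.max(v[idx])]
      ijk <- arrayInd(peak_lin, dim(v)) - 1L
      xyz <- voxel_to_world(tmap$grid, ijk)
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "increase" else "decrease",
        peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
        extent = sizes[k],
        peak_t = tmap$values[peak_lin],
        p_corrected = pcorr)
      vox_list[[length(vox_list) + 1L]] <- idx
    }
  }
  finalize_cluster_records(rows, vox_list,
                           keep = function(df)
                             df$p_corrected < cluster_p_tail)
}

finalize_cluster_records <- function(rows, vox_list, keep) {
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0),
               extent = integer(0), peak_t = numeric(0),
               p_corrected = numeric(0))
  sel <- if (nrow(out)) which(keep(out)) else integer(0)
  out <- out[sel, , drop = FALSE]
  vox_list <- vox_list[sel]
  ord <- order(-abs(out$peak_t))
  out <- out[ord, , drop = FALSE]
  vox_list <- vox_list[ord]
  out <- cbind(label = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, voxels = vox_list)
}

#' Cluster records from a Monte-Carlo extent threshold
#'
#' Thresholds the t-map two-tailed at `voxel_p`, labels clusters per tail
#' and keeps those with extent at least the Monte-Carlo minimum from
#' [monte_carlo_cluster_threshold()].
#'
#' @param tmap A [stat_map()].
#' @param extent_threshold Minimum significant extent (voxels).
#' @param voxel_p Two-tailed voxel threshold (default 0.001).
#' @param two_tailed Test both tails (default `TRUE`).
#' @param connectivity Cluster connectivity (default 26).
#' @return Cluster records data.frame as in [grf_cluster_correction()]
#'   (without `p_corrected`).
#' @export
mc_cluster_records <- function(tmap, extent_threshold, voxel_p = 0.001,
                               two_tailed = TRUE, connectivity = 26L) {
  p_tail <- if (two_tailed) voxel_p / 2 else voxel_p
  tthr <- stats::qt(p_tail, df = tmap$dof, lower.tail = FALSE)
  tails <- if (two_tailed) c(1, -1) else 1
  rows <- list()
  vox_list <- list()
  for (sgn in tails) {
    v <- tmap$values * sgn
    flag <- !is.na(v) & v > tthr
    if (!any(flag)) next
    lab <- label_clusters(flag, connectivity)
    sizes <- attr(lab, "sizes")
    for (k in seq_along(sizes)) {
      idx <- which(lab == k)
      peak_lin <- idx[which.max(v[idx])]
      ijk <- arrayInd(peak_lin, dim(v)) - 1L
      xyz <- voxel_to_world(tmap$grid, ijk)
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "increase" else "decrease",
        peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
        extent = sizes[k],
        peak_t = tmap$values[peak_lin],
        p_corrected = NA_real_)
      vox_list[[length(vox_list) + 1L]] <- idx
    }
  }
  out <- finalize_cluster_records(rows, vox_list,
                                  keep = function(df)
                                    df$extent >= extent_threshold)
  out$p_corrected <- NULL
  out
}

#' Monte-Carlo cluster-extent threshold
#'
#' AlphaSim-style simulation: Gaussian noise on the mask, smoothed to the
#' given FWHM, standardized to unit variance, thresholded two-tailed at
#' `voxel_p`; the maximum cluster extent is recorded per iteration. The
#' returned threshold is the smallest extent `k` such that the fraction of
#' iterations with a maximum extent of at least `k` does not exceed
#' `cluster_p`; clusters at least this large are reported significant.
#'
#' @param mask A [binary_mask()].
#' @param fwhm_mm Smoothness to simulate (scalar or per-axis, mm); pass a
#'   `smoothness_estimate` to use its `fwhm_mm`.
#' @param voxel_p Voxel-level two-tailed threshold (default 0.001).
#' @param cluster_p Cluster-level threshold (default 0.05).
#' @param n_iter Number of simulations (default 1000, minimum 100).
#' @param seed Integer seed for reproducibility.
#' @param connectivity Cluster connectivity (default 26).
#' @return Integer minimum cluster extent, with attribute `max_extents`
#'   (the simulated distribution).
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm_mm, voxel_p = 0.001,
                                          cluster_p = 0.05, n_iter = 1000L,
                                          seed = 1L, connectivity = 26L) {
  stopifnot(n_iter >= 100L)
  if (inherits(fwhm_mm, "smoothness_estimate")) fwhm_mm <- fwhm_mm$fwhm_mm
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  d <- dim(mask$inside)
  inside <- mask$inside
  zthr <- stats::qnorm(voxel_p / 2, lower.tail = FALSE)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  maxext <- integer(n_iter)
  smooth_any <- any(fwhm_mm > 0)
  for (i in seq_len(n_iter)) {
    noise <- array(stats::rnorm(prod(d)), dim = d)
    if (smooth_any)
      noise <- smooth_3d_plain(noise, mask$grid$voxel_size, fwhm_mm)
    v <- noise[inside]
    z <- (v - mean(v)) / stats::sd(v)
    flag <- array(FALSE, dim = d)
    flag[inside] <- abs(z) > zthr
    maxext[i] <- max_cluster_extent(flag, connectivity)
  }
  k <- 1L
  while (mean(maxext >= k) > cluster_p) k <- k + 1L
  structure(as.integer(k), max_extents = maxext)
}

#' Render a Table-2-style cluster table
#'
#' @param records Cluster data.frame from [grf_cluster_correction()] (or a
#'   compatible frame from the Monte-Carlo path).
#' @param path Optional output TSV path; when given the table is written
#'   and the path returned invisibly.
#' @param atlas_labels Optional function mapping a world-mm coordinate
#'   (length-3 numeric) to a region label.
#' @return Data.frame with columns `index`, `region`, `side`, `peak_x`,
#'   `peak_y`, `peak_z`, `extent`, `peak_t`, `sign` (and `p_corrected`
#'   when present).
#' @export
make_cluster_table <- function(records, path = NULL, atlas_labels = NULL) {
  n <- nrow(records)
  region <- rep("unlabelled", n)
  if (!is.null(atlas_labels) && n > 0)
    region <- vapply(seq_len(n), function(i)
      atlas_labels(c(records$peak_x[i], records$peak_y[i],
                     records$peak_z[i])), "")
  side <- if (n > 0) ifelse(records$peak_x < 0, "L", "R") else character(0)
  out <- data.frame(index = seq_len(n), region = region, side = side,
                    peak_x = records$peak_x, peak_y = records$peak_y,
                    peak_z = records$peak_z, extent = records$extent,
                    peak_t = records$peak_t,
                    sign = if (n > 0)
                      ifelse(records$peak_t < 0, "decrease", "increase")
                    else character(0))
  if ("p_corrected" %in% names(records))
    out$p_corrected <- records$p_corrected
  if (!is.null(path)) {
    write_tsv(out, path)
    return(invisible(path))
  }
  out
}

# seed handling: run a block under a local RNG state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
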