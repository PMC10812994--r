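test_that("one-sample masking keeps offset regions and drops null ones", {
  mask <- full_mask(c(8, 8, 8))
  d <- dim(mask$inside)
  set.seed(1)
  # all maps at the null value -> empty mask (error by contract)
  flat <- lapply(1:10, function(i) array(1, d))
  groups <- rep(c("case", "control"), each = 5)
  expect_error(one_sample_mask(flat, groups, mask), "no significant")
  # a strong offset region is included
  maps <- lapply(1:10, function(i) {
    m <- array(1 + rnorm(prod(d), sd = 0.05), d)
    m[1:4, , ] <- m[1:4, , ] + 1
    m
  })
  osm <- one_sample_mask(maps, groups, mask)
  expect_true(all(osm$inside[1:4, , ]))
  # closed-form one-sample t at a voxel
  v <- sapply(maps[1:5], function(m) m[1, 1, 1])
  t_manual <- (mean(v) - 1) / (sd(v) / sqrt(5))
  expect_true(abs(t_manual) > qt(0.975, 4))  # so it must be in the mask
})

test_that("covariate-free GLM equals the pooled-variance two-sample t", {
  mask <- full_mask(c(10, 10, 10))
  des <- generate_design(14, 17, seed = 2)
  dm <- build_design_matrix(des, covariates = character(0))
  set.seed(3)
  maps <- noise_maps(31, mask, fwhm = 0)
  fit <- fit_two_sample_glm(maps, dm, mask)
  Y <- t(sapply(maps, function(m) m[mask$inside]))
  idx <- sample(ncol(Y), 1000)
  tref <- vapply(idx, function(j)
    oracle_pooled_t(Y[des$group == "case", j],
                    Y[des$group == "control", j]), 0)
  tgot <- fit$tmap$values[mask$inside][idx]
  expect_lt(max(abs(tgot - tref) / abs(tref)), 1e-10)
  expect_equal(fit$tmap$dof, 29L)
})

test_that("GLM with covariates matches the normal-equations oracle and
           is invariant to covariate rescaling", {
  mask <- full_mask(c(6, 6, 6))
  des <- generate_design(14, 17, seed = 4)
  dm <- build_design_matrix(des)
  set.seed(5)
  maps <- noise_maps(31, mask, fwhm = 0)
  fit <- fit_two_sample_glm(maps, dm, mask)
  Y <- t(sapply(maps, function(m) m[mask$inside]))
  for (j in c(1, 50, 200)) {
    expect_equal(fit$tmap$values[mask$inside][j],
                 oracle_glm_t(dm$X, Y[, j], dm$contrast),
                 tolerance = 1e-10)
  }
  # affine rescaling of a covariate leaves t unchanged
  des2 <- des; des2$bmi <- 10 * des2$bmi - 100
  fit2 <- fit_two_sample_glm(maps, build_design_matrix(des2), mask)
  expect_equal(fit2$tmap$values[mask$inside],
               fit$tmap$values[mask$inside], tolerance = 1e-8)
  # swapping group labels flips the sign exactly
  des3 <- des
  des3$group <- ifelse(des$group == "case", "control", "case")
  fit3 <- fit_two_sample_glm(maps, build_design_matrix(des3), mask)
  expect_equal(fit3$tmap$values[mask$inside],
               -fit$tmap$values[mask$inside], tolerance = 1e-10)
  # covariate collinear with group is rejected
  des4 <- des; des4$age <- as.numeric(des4$group == "case")
  expect_error(build_design_matrix(des4), "rank deficient")
})

test_that("smoothness estimator matches its analytic independent-noise
           limit and scales with voxel size", {
  mask <- full_mask(c(12, 12, 12))
  set.seed(6)
  res <- noise_maps(100, mask, fwhm = 0)
  sm <- estimate_smoothness(res, mask, 99)
  expect_equal(unname(sm$fwhm_mm), rep(3 * sqrt(4 * log(2) / 2), 3),
               tolerance = 0.1 * 3.53)
  # doubling voxel size doubles FWHM for identical voxel data
  mask6 <- binary_mask(volume_grid(c(12, 12, 12), 6),
                       array(TRUE, c(12, 12, 12)))
  sm6 <- estimate_smoothness(res, mask6, 99)
  expect_equal(sm6$fwhm_mm, 2 * sm$fwhm_mm, tolerance = 1e-10)
  expect_error(estimate_smoothness(lapply(1:3, function(i)
    array(1, c(12, 12, 12))), mask, 2), "gradient variance")
})

test_that("GRF cluster p agrees with an independent RFT oracle", {
  mask <- small_mask()
  set.seed(7)
  res <- noise_maps(40, mask, fwhm = 6)
  sm <- estimate_smoothness(res, mask, 39)
  rc <- sm$resel_counts
  nvox <- mask_size(mask)
  for (case in list(c(10, 3.5, 30), c(41, 3.66, 29), c(100, 4.0, 60))) {
    got <- neurotx:::grf_cluster_p(case[1], case[2], rc, nvox, case[3])
    ref <- oracle_grf_cluster_p(case[1], case[2], rc, nvox, case[3])
    expect_equal(got, ref, tolerance = 1e-6)
  }
  # all-zero t-map -> no clusters
  z <- stat_map(mask$grid, array(0, dim(mask$inside)) +
                  ifelse(mask$inside, 0, NA), 29, mask)
  expect_equal(nrow(suppressWarnings(grf_cluster_correction(z, sm))), 0L)
})

test_that("cluster labeling is deterministic and respects connectivity", {
  d <- c(6, 6, 6)
  flag <- array(FALSE, d)
  flag[1:2, 1, 1] <- TRUE          # one face-connected pair
  flag[4, 4, 4] <- TRUE            # isolated voxel
  flag[5, 5, 5] <- TRUE            # corner-adjacent to (4,4,4)
  lab26 <- label_clusters(flag, 26)
  expect_equal(sort(attr(lab26, "sizes")), c(2L, 2L))
  lab6 <- label_clusters(flag, 6)
  expect_equal(sort(attr(lab6, "sizes")), c(1L, 1L, 2L))
  # voxel order independence: permuted construction gives same labels
  expect_identical(as.vector(label_clusters(flag, 26)),
                   as.vector(label_clusters(flag[, , ], 26)))
})

test_that("Monte-Carlo extent threshold is deterministic and monotone in
           smoothness", {
  mask <- make_mask()
  k1 <- monte_carlo_cluster_threshold(mask, 6, n_iter = 300, seed = 5)
  k2 <- monte_carlo_cluster_threshold(mask, 6, n_iter = 300, seed = 5)
  expect_identical(as.integer(k1), as.integer(k2))
  k12 <- monte_carlo_cluster_threshold(mask, 12, n_iter = 300, seed = 5)
  expect_gte(as.integer(k12), as.integer(k1))
  expect_error(monte_carlo_cluster_threshold(mask, 6, n_iter = 50),
               "n_iter")
})

test_that("cluster tables mirror the reporting layout", {
  rec <- data.frame(label = 1:2, sign = c("increase", "decrease"),
                    peak_x = c(-15, 4.5), peak_y = c(-33, -19.5),
                    peak_z = c(-3, 1.5), extent = c(41L, 12L),
                    peak_t = c(5.294, -4.1),
                    p_corrected = c(0.001, 0.02))
  tab <- make_cluster_table(rec)
  expect_equal(tab$peak_x[1], -15)
  expect_equal(tab$peak_y[1], -33)
  expect_equal(tab$peak_z[1], -3)
  expect_equal(tab$extent[1], 41L)
  expect_equal(tab$peak_t[1], 5.294)
  expect_equal(tab$side, c("L", "R"))
  expect_equal(tab$sign, c("increase", "decrease"))
  f <- tempfile(fileext = ".tsv")
  make_cluster_table(rec[0, ], f)
  expect_equal(nrow(utils::read.delim(f)), 0L)
})

test_that("GRF and Monte-Carlo paths recover seeded clusters and agree", {
  mask <- make_mask(c(12, 14, 12))
  des <- generate_design(12, 12, seed = 8)
  dm <- build_design_matrix(des, covariates = character(0))
  eff <- default_effect_spec(mask, cluster_radius_mm = 6,
                             amplitude_effect = 0.5)
  ind <- neurotx:::effect_indicator(mask, eff)
  seeded <- which(ind != 0)
  nrep <- 10
  agree <- power_hits <- 0
  for (r in seq_len(nrep)) {
    alffs <- generate_group_fmri(
      des, mask, eff, n_timepoints = 100, seed = 3000 + r,
      apply_fn = function(ts) {
        am <- compute_alff(ts)
        smooth_gaussian(am$standardized_alff, ts$mask, 6)
      })
    fit <- fit_two_sample_glm(alffs, dm, mask)
    sm <- estimate_smoothness(fit$residuals, fit$mask, fit$tmap$dof)
    rec_grf <- suppressWarnings(grf_cluster_correction(fit$tmap, sm))
    kmin <- monte_carlo_cluster_threshold(fit$mask, sm, n_iter = 200,
                                          seed = 4000 + r)
    rec_mc <- mc_cluster_records(fit$tmap, kmin)
    overlap_seeded <- function(rec) {
      v <- attr(rec, "voxels")
      length(v) > 0 && any(vapply(v, function(x)
        length(intersect(x, seeded)) > 0, TRUE))
    }
    hit_grf <- overlap_seeded(rec_grf)
    hit_mc <- overlap_seeded(rec_mc)
    if (hit_grf == hit_mc) agree <- agree + 1
    if (hit_grf) power_hits <- power_hits + 1
  }
  expect_gte(agree / nrep, 0.9)
  expect_gte(power_hits / nrep, 0.8)
})
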