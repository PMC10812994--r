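test_that("mask generator yields one connected brain-like component", {
  mask <- make_mask()
  lab <- label_clusters(mask$inside, 26)
  expect_length(attr(lab, "sizes"), 1L)
  frac <- mask_size(mask) / prod(mask$grid$shape)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.5)
  # determinism and affine scale
  expect_identical(mask$inside, make_mask()$inside)
  expect_equal(abs(diag(mask$grid$affine)[1:3]), c(3, 3, 3))
  expect_error(make_mask(c(2, 2, 2)), "degenerate")
})

test_that("generators are pure functions of parameters and seed", {
  mask <- make_mask(c(8, 10, 8))
  des <- generate_design(3, 3, seed = 2)
  eff <- default_effect_spec(mask, cluster_radius_mm = 4)
  a <- generate_group_fmri(des, mask, eff, n_timepoints = 64, seed = 11)
  b <- generate_group_fmri(des, mask, eff, n_timepoints = 64, seed = 11)
  expect_identical(a[[1]]$data, b[[1]]$data)
  g1 <- generate_group_gmv(des, mask, eff, seed = 12)
  g2 <- generate_group_gmv(des, mask, eff, seed = 12)
  expect_identical(g1[[2]]$values, g2[[2]]$values)
  truth <- expression_truth(n_genes = 30, n_true = 5)
  em <- as_volume3d(array(rnorm(prod(mask$grid$shape)),
                          mask$grid$shape), mask)
  e1 <- generate_expression_samples(mask, truth, em, 24, seed = 13)
  e2 <- generate_expression_samples(mask, truth, em, 24, seed = 13)
  expect_identical(e1$intensity, e2$intensity)
  expect_identical(e1$samples, e2$samples)
})

test_that("fMRI generator respects effect signs and band-limitedness", {
  mask <- make_mask(c(10, 12, 10))
  des <- generate_design(8, 8, seed = 4)
  eff <- default_effect_spec(mask, cluster_radius_mm = 5,
                             amplitude_effect = 0.5)
  alffs <- generate_group_fmri(
    des, mask, eff, n_timepoints = 96, seed = 21,
    apply_fn = function(ts) compute_alff(ts))
  dm <- build_design_matrix(des, covariates = character(0))
  fit <- fit_two_sample_glm(alffs, dm, mask)
  ind <- neurotx:::effect_indicator(mask, eff)
  tin <- fit$tmap$values[ind > 0 & fit$mask$inside]
  tneg <- fit$tmap$values[ind < 0 & fit$mask$inside]
  tout <- fit$tmap$values[ind == 0 & fit$mask$inside]
  # mean in-cluster t exceeds out-of-cluster t, with the configured signs
  expect_gt(mean(tin), mean(tout))
  expect_lt(mean(tneg), mean(tout))
  expect_gt(mean(tin), 2)
  expect_lt(mean(tneg), -2)

  # band-limitedness: >= 90% of noise-free signal variance inside the band
  sig <- neurotx:::band_limited_noise(50, 96, 2, 0.01, 0.08)
  spec_mass <- function(x) {
    X <- stats::mvfft(x)
    P <- Mod(X)^2
    bins <- neurotx:::band_bins(96, 2, 0.01, 0.08)
    keep <- unique(c(bins, (96 - bins) %% 96)) + 1
    sum(P[keep, ]) / sum(P)
  }
  expect_gte(spec_mass(sig), 0.9)
  # unit variance closed-form scaling
  expect_equal(mean(apply(sig, 2, var)), 1, tolerance = 0.1)
})

test_that("GMV generator plants additive signed effects", {
  mask <- make_mask(c(10, 12, 10))
  des <- generate_design(10, 10, seed = 4)
  eff <- default_effect_spec(mask, cluster_radius_mm = 5,
                             gmv_effect = 0.2)
  maps <- generate_group_gmv(des, mask, eff, seed = 3)
  ind <- neurotx:::effect_indicator(mask, eff)
  case_mean <- Reduce(`+`, lapply(which(des$group == "case"),
                                  function(i) maps[[i]]$values)) /
    sum(des$group == "case")
  ctrl_mean <- Reduce(`+`, lapply(which(des$group == "control"),
                                  function(i) maps[[i]]$values)) /
    sum(des$group == "control")
  dpos <- mean(case_mean[ind > 0]) - mean(ctrl_mean[ind > 0])
  dneg <- mean(case_mean[ind < 0]) - mean(ctrl_mean[ind < 0])
  expect_gt(dpos, 0.1)
  expect_lt(dneg, -0.1)
  # effect clusters outside the mask are rejected
  bad <- effect_spec(matrix(c(0L, 0L, 0L), 1), cluster_radius_mm = 2)
  expect_error(generate_group_gmv(des, mask, bad, seed = 1), "outside")
})

test_that("GMV residual smoothness reflects the applied kernel", {
  mask <- make_mask()
  des <- generate_design(15, 15, seed = 6)
  eff <- default_effect_spec(mask, gmv_effect = 0)
  maps <- generate_group_gmv(des, mask, eff, smoothing_fwhm = 8, seed = 9)
  dm <- build_design_matrix(des, covariates = character(0))
  fit <- fit_two_sample_glm(maps, dm, mask)
  sm <- estimate_smoothness(fit$residuals, fit$mask, fit$tmap$dof)
  # estimated smoothness of residual maps within 20% of the 8 mm kernel
  expect_true(all(sm$fwhm_mm > 8 * 0.8 & sm$fwhm_mm < 8 * 1.2))
})

test_that("null fMRI effect gives a calibrated voxel-wise type-I rate", {
  mask <- make_mask(c(10, 12, 10))
  des <- generate_design(10, 10, seed = 8)
  eff <- default_effect_spec(mask, cluster_radius_mm = 5,
                             amplitude_effect = 0)
  dm <- build_design_matrix(des, covariates = character(0))
  nrep <- 200
  rates <- numeric(nrep)
  for (r in seq_len(nrep)) {
    alffs <- generate_group_fmri(
      des, mask, eff, n_timepoints = 96, seed = 1000 + r,
      apply_fn = function(ts) compute_alff(ts))
    fit <- fit_two_sample_glm(alffs, dm, mask)
    tt <- fit$tmap$values[fit$mask$inside]
    p <- 2 * stats::pt(abs(tt), df = fit$tmap$dof, lower.tail = FALSE)
    rates[r] <- mean(p < 0.001)
  }
  rate <- mean(rates)
  se <- stats::sd(rates) / sqrt(nrep)
  expect_lt(abs(rate - 0.001), 3 * se + 1e-12)
})

test_that("expression coupling construction hits its target correlation", {
  mask <- make_mask()
  eff_vals <- reference_tmap_values(mask)
  effmap <- as_volume3d(eff_vals, mask)
  # true genes kept sparse (5%): a dense planted fraction would bleed
  # into the per-sample normalization statistics and attenuate coupling
  truth <- expression_truth(n_genes = 500, n_true = 25)
  eset <- generate_expression_samples(mask, truth, effmap, 300, seed = 31)
  prep <- prep_expression(eset, mask)
  tv <- eff_vals[prep$matrix$features$voxel]
  a <- mass_correlation(prep$matrix$matrix, tv)
  rt <- a$r[a$gene %in% truth$true_gene_ids]
  # empirical r within [0.35, 0.65] for >= 90% of surviving true genes
  expect_gte(mean(rt >= 0.35 & rt <= 0.65), 0.9)
  expect_error(generate_expression_samples(mask, truth, effmap, 1,
                                           seed = 1), "n_samples")
})
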