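test_that("linear detrending removes exact trends and is idempotent", {
  t_ <- 0:199
  expect_equal(detrend_linear(2 * t_ + 5), rep(0, 200), tolerance = 1e-10)
  s <- sin(2 * pi * 0.05 * t_)
  ds <- detrend_linear(s)
  expect_lt(max(abs(ds - (s - mean(s) -
    coef(lm(s ~ t_))[2] * (t_ - mean(t_))))), 1e-12)
  # the removed component is exactly the fitted line, which for a
  # whole-period sinusoid is small relative to the amplitude
  expect_lt(max(abs(ds - s)), 0.1)
  expect_equal(detrend_linear(ds), ds, tolerance = 1e-12)
})

test_that("nuisance regression orthogonalizes against its regressors", {
  set.seed(2)
  n <- 120
  nuis <- matrix(rnorm(n * 5), n)
  y <- rnorm(n)
  res <- regress_nuisance(y, nuis)
  expect_lt(max(abs(crossprod(cbind(1, nuis), res))), 1e-9)
  # residuals match the normal-equations oracle
  X <- cbind(1, nuis)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res, drop(y - X %*% beta), tolerance = 1e-10)
  # series equal to a regressor -> zero residuals
  expect_lt(max(abs(regress_nuisance(nuis[, 3], nuis))), 1e-10)
  # empty nuisance set -> mean centering
  expect_equal(regress_nuisance(y, NULL), y - mean(y))
  # collinear columns rejected with a rank error
  expect_error(regress_nuisance(y, cbind(nuis, nuis[, 1])),
               "rank-deficient")
})

test_that("ideal bandpass passes on-bin in-band and kills out-of-band", {
  nt <- 200; tr <- 2
  t_ <- (0:(nt - 1)) * tr
  inband <- sin(2 * pi * 0.05 * t_)     # bin 40/400
  expect_lt(max(abs(bandpass_filter(inband, tr) - inband)), 1e-8)
  out <- sin(2 * pi * 0.2 * t_)         # 0.2 Hz, outside band
  expect_lt(max(abs(bandpass_filter(out, tr))), 1e-8)
  # Parseval: output variance equals in-band periodogram mass
  set.seed(3)
  w <- rnorm(nt)
  filt <- bandpass_filter(w, tr)
  X <- fft(w)
  bins <- neurotx:::band_bins(nt, tr, 0.01, 0.08)
  keep <- unique(c(bins, (nt - bins) %% nt)) + 1
  expect_equal(sum(filt^2), sum(Mod(X[keep])^2) / nt, tolerance = 1e-10)
  expect_error(bandpass_filter(w, tr, 0.1, 0.05), "inverted")
  expect_error(bandpass_filter(w, tr, 0.01, 0.3), "Nyquist")
})

test_that("ALFF equals the closed-form single-bin amplitude", {
  mask <- full_mask()
  nt <- 200; tr <- 2
  A <- 3
  series <- A * sin(2 * pi * 0.04 * (0:(nt - 1)) * tr)  # exact bin 16
  ts <- uniform_ts(series, mask, tr)
  am <- compute_alff(ts, NULL, detrend = FALSE)
  bins <- neurotx:::band_bins(nt, tr, 0.01, 0.08)
  raw <- am$raw_alff[mask$inside][1]
  expect_equal(raw, A / length(bins), tolerance = 1e-6)
  # brute-force DFT oracle at the signal bin
  expect_equal(oracle_dft_amplitude(series, 16), A, tolerance = 1e-8)
  # constant series has zero ALFF (and standardization must fail)
  expect_error(compute_alff(uniform_ts(rep(1, nt), mask, tr)),
               "standardize")
})

test_that("ALFF scale equivariance and standardization invariants hold", {
  mask <- full_mask()
  set.seed(4)
  d <- dim(mask$inside)
  nt <- 128
  arr <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  ts1 <- time_series_image(mask$grid, arr, 2, mask)
  ts2 <- time_series_image(mask$grid, 2 * arr, 2, mask)
  a1 <- compute_alff(ts1); a2 <- compute_alff(ts2)
  expect_equal(a2$raw_alff[mask$inside], 2 * a1$raw_alff[mask$inside],
               tolerance = 1e-10)
  expect_equal(a2$standardized_alff[mask$inside],
               a1$standardized_alff[mask$inside], tolerance = 1e-10)
  expect_equal(mean(a1$standardized_alff[mask$inside]), 1,
               tolerance = 1e-10)
  # invariance to mean and linear trend of the input series
  tr_ <- array(rep(0:(nt - 1), each = prod(d)), dim = c(d, nt))
  ts3 <- time_series_image(mask$grid, arr + 5 + 0.03 * tr_, 2, mask)
  a3 <- compute_alff(ts3)
  expect_equal(a3$raw_alff[mask$inside], a1$raw_alff[mask$inside],
               tolerance = 1e-8)
})

test_that("raw ALFF scales linearly with white-noise amplitude", {
  mask <- full_mask(c(6, 6, 6))
  set.seed(5)
  d <- dim(mask$inside)
  nt <- 200
  base <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  a1 <- compute_alff(time_series_image(mask$grid, base, 2, mask))
  a2 <- compute_alff(time_series_image(mask$grid, 3 * base, 2, mask))
  ratio <- mean(a2$raw_alff[mask$inside] / a1$raw_alff[mask$inside])
  expect_equal(ratio, 3, tolerance = 0.05 * 3)
})

test_that("mask-aware Gaussian smoothing conserves mass and constants", {
  mask <- full_mask(c(15, 15, 15))
  d <- dim(mask$inside)
  delta <- array(0, d); delta[8, 8, 8] <- 1
  sm <- smooth_gaussian(delta, mask, 6)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # constants stay constant inside an irregular mask (edge renorm)
  irr <- small_mask()
  cst <- array(2.5, dim(irr$inside))
  smc <- smooth_gaussian(cst, irr, 8)
  expect_equal(range(smc[irr$inside]), c(2.5, 2.5), tolerance = 1e-10)
  # fwhm 0 is the identity
  set.seed(6)
  x <- array(rnorm(prod(d)), d)
  expect_equal(smooth_gaussian(x, mask, 0)[mask$inside], x[mask$inside])
})
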