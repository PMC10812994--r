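#' Remove the least-squares linear trend (and mean) from time series
#'
#' @param series Numeric vector, or a matrix with time in rows (each column
#'   detrended independently).
#' @return Detrended series of the same shape: zero mean and zero fitted
#'   linear slope.
#' @export
detrend_linear <- function(series) {
  x <- as.matrix(series)
  n <- nrow(x)
  stopifnot(n >= 3L)
  t0 <- seq_len(n) - (n + 1) / 2          # centred time, orthogonal to 1
  denom <- sum(t0^2)
  slope <- crossprod(t0, x) / denom        # 1 x p
  out <- x - matrix(colMeans(x), n, ncol(x), byrow = TRUE) -
    outer(t0, drop(slope))
  if (is.null(dim(series))) drop(out) else out
}

#' Regress nuisance signals out of time series
#'
#' Ordinary least squares of each series on an intercept plus the supplied
#' regressors; returns the residuals, which are orthogonal to every
#' regressor.
#'
#' @param series Numeric vector or matrix (time in rows).
#' @param nuisance Numeric matrix of regressors (time in rows), or `NULL` /
#'   zero columns for mean-centering only.
#' @return Residual series of the same shape as `series`.
#' @export
regress_nuisance <- function(series, nuisance = NULL) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (is.null(nuisance) || NCOL(nuisance) == 0L) {
    out <- x - matrix(colMeans(x), n, ncol(x), byrow = TRUE)
  } else {
    nuis <- as.matrix(nuisance)
    stopifnot(nrow(nuis) == n)
    X <- cbind(intercept = 1, nuis)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("regress_nuisance: rank-deficient regressor matrix; collinear: ",
           paste(dropped, collapse = ", "))
    }
    out <- qr.resid(qrX, x)
  }
  if (is.null(dim(series))) drop(out) else out
}

band_bins <- function(n, tr, low_hz, high_hz) {
  # 0-based DFT bin frequencies k/(n*tr); one-sided bins 0..floor(n/2).
  k <- 0:(n %/% 2)
  f <- k / (n * tr)
  k[f >= low_hz & f <= high_hz]
}

#' Ideal band-pass filter via the discrete Fourier transform
#'
#' Zeroes every DFT coefficient whose bin-centre frequency lies outside
#' `[low_hz, high_hz]` (inclusive on both edges) and inverse-transforms.
#'
#' @param series Numeric vector or matrix (time in rows).
#' @param tr Sampling interval in seconds.
#' @param low_hz,high_hz Pass-band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1/(2*tr)`.
#' @return Filtered series of the same shape.
#' @export
bandpass_filter <- function(series, tr, low_hz = 0.01, high_hz = 0.08) {
  if (low_hz > high_hz) stop("bandpass_filter: band edges inverted")
  if (high_hz >= 1 / (2 * tr) + 1e-12)
    stop("bandpass_filter: high_hz must be below Nyquist 1/(2*tr)")
  x <- as.matrix(series)
  n <- nrow(x)
  keep1 <- band_bins(n, tr, low_hz, high_hz)        # one-sided 0-based bins
  keep <- unique(c(keep1, (n - keep1) %% n))        # mirror negatives
  X <- stats::mvfft(x)
  zero <- setdiff(0:(n - 1), keep)
  X[zero + 1L, ] <- 0
  out <- Re(stats::mvfft(X, inverse = TRUE)) / n
  if (is.null(dim(series))) drop(out) else out
}

#' Build a nuisance regressor set
#'
#' Container for per-subject nuisance signals: motion-derived regressors,
#' tissue means (white matter, cerebrospinal fluid) and the optional global
#' mean signal.
#'
#' @param motion,tissue Numeric matrices (time in rows), or `NULL`.
#' @param global_signal Numeric vector or `NULL`.
#' @param use_global Include the global signal (default `TRUE`; the
#'   corresponding field toggle).
#' @return An object of class `nuisance_set`; its `matrix` field is the
#'   assembled regressor matrix (possibly with zero columns).
#' @export
nuisance_set <- function(motion = NULL, tissue = NULL, global_signal = NULL,
                         use_global = TRUE) {
  mats <- list()
  if (!is.null(motion)) mats$motion <- as.matrix(motion)
  if (!is.null(tissue)) mats$tissue <- as.matrix(tissue)
  if (!is.null(global_signal) && use_global)
    mats$global <- matrix(as.numeric(global_signal), ncol = 1)
  X <- if (length(mats)) do.call(cbind, mats) else
    matrix(numeric(0), nrow = 0, ncol = 0)
  if (ncol(X) > 0) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("nuisance_set: constant regressor column(s)")
  }
  structure(list(matrix = X, use_global = use_global),
            class = "nuisance_set")
}

#' Compute an ALFF map from a 4D time-series image
#'
#' Pipeline per voxel: optional discard of initial volumes, linear
#' detrending, nuisance regression, ideal band-pass filtering, then the
#' one-sided amplitude spectrum `a_k = 2|X_k|/N`. Raw ALFF is the mean of
#' `a_k` over bins whose centre frequency lies in the band (inclusive);
#' standardized ALFF (mALFF) is raw ALFF divided by its in-mask mean.
#'
#' @param ts A [time_series_image()].
#' @param nuisance A [nuisance_set()] or `NULL`.
#' @param low_hz,high_hz Band edges in Hz (defaults 0.01 and 0.08).
#' @param detrend Apply linear detrending first (default `TRUE`).
#' @param drop_initial Number of initial volumes discarded before any
#'   computation (default 0; study-style pipelines drop 10).
#' @return An object of class `alff_map` with fields `grid`, `mask`,
#'   `raw_alff` and `standardized_alff` (3D arrays, `NA` outside the mask).
#' @export
compute_alff <- function(ts, nuisance = NULL, low_hz = 0.01, high_hz = 0.08,
                         detrend = TRUE, drop_initial = 0L) {
  stopifnot(inherits(ts, "time_series_image"))
  d <- dim(ts$data)
  nt0 <- d[4]
  keep_t <- (drop_initial + 1L):nt0
  stopifnot(length(keep_t) >= 8L)
  inside <- as.vector(ts$mask$inside)
  x <- t(matrix(ts$data, ncol = nt0)[inside, keep_t, drop = FALSE])
  if (detrend) x <- detrend_linear(x)
  nmat <- if (inherits(nuisance, "nuisance_set")) nuisance$matrix else
    nuisance
  if (!is.null(nmat) && NCOL(nmat) > 0) {
    nmat <- as.matrix(nmat)[keep_t, , drop = FALSE]
    if (detrend) nmat <- detrend_linear(nmat)
    x <- regress_nuisance(x, nmat)
  }
  x <- bandpass_filter(x, ts$tr_seconds, low_hz, high_hz)
  n <- nrow(x)
  bins <- band_bins(n, ts$tr_seconds, low_hz, high_hz)
  if (!length(bins)) stop("compute_alff: no DFT bins inside the band")
  X <- stats::mvfft(x)
  amp <- 2 * Mod(X[bins + 1L, , drop = FALSE]) / n
  raw_vec <- colMeans(amp)
  raw <- array(NA_real_, dim = d[1:3])
  raw[inside] <- raw_vec
  mean_raw <- mean(raw_vec)
  if (mean_raw <= .Machine$double.eps)
    stop("compute_alff: in-mask mean ALFF is zero; cannot standardize")
  std <- raw / mean_raw
  structure(list(grid = ts$grid, mask = ts$mask, raw_alff = raw,
                 standardized_alff = std,
                 band = c(low_hz, high_hz),
                 standardization = "mALFF (division by in-mask mean)"),
            class = "alff_map")
}

#' @export
print.alff_map <- function(x, ...) {
  v <- x$raw_alff[x$mask$inside]
  cat(sprintf("alff_map: band %.3f-%.3f Hz, raw ALFF mean %.4g over %d voxels\n",
              x$band[1], x$band[2], mean(v), length(v)))
  invisible(x)
}
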