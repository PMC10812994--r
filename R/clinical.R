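#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. For small samples (both groups at
#' most `exact_max`) the two-sided p-value is computed by exact
#' enumeration of all group assignments of the pooled values (so ties are
#' handled exactly); otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param values_a,values_b Numeric vectors.
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return List: `U` (statistic of the first sample), `p` (two-sided),
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(values_a, values_b, exact_max = 8L) {
  na <- length(values_a); nb <- length(values_b)
  stopifnot(na >= 1L, nb >= 1L)
  pooled <- c(values_a, values_b)
  rk <- rank(pooled)                       # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    combs <- utils::combn(na + nb, na)
    Us <- apply(combs, 2, function(idx)
      sum(rk[idx]) - na * (na + 1) / 2)
    mu <- na * nb / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    n <- na + nb
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    list(U = U, p = p, method = "normal_approx")
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value from the conditional hypergeometric distribution:
#' the sum of probabilities of all tables (with the observed margins) at
#' most as probable as the observed one. The odds ratio reported is the
#' sample odds ratio `(a*d)/(b*c)`.
#'
#' @param counts 2x2 integer matrix (or a length-4 vector, filled
#'   column-wise).
#' @return List: `odds_ratio`, `p` (two-sided).
#' @export
fisher_exact <- function(counts) {
  m <- matrix(as.numeric(counts), 2, 2)
  if (any(m < 0) || any(m != round(m)))
    stop("fisher_exact: counts must be non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  or <- (a * d) / (b * c_)
  r1 <- a + b; c1 <- a + c_; n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n)
    return(list(odds_ratio = or, p = 1))
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}

#' Spearman correlations with FDR control
#'
#' Midrank Spearman rho for every (imaging, clinical) pair, two-sided
#' p-values from the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`,
#' and Benjamini-Hochberg q-values across the whole tested family.
#'
#' @param imaging Data.frame / matrix of per-subject imaging summaries
#'   (e.g. mean standardized ALFF per significant cluster), one column per
#'   index.
#' @param clinical Data.frame of per-subject numeric clinical measures.
#' @return Data.frame: `imaging_index`, `clinical_measure`, `rho`, `p`,
#'   `q`, sorted by q then p.
#' @export
spearman_with_fdr <- function(imaging, clinical) {
  imaging <- as.data.frame(imaging)
  clinical <- as.data.frame(clinical)
  num <- vapply(clinical, is.numeric, TRUE)
  clinical <- clinical[, num, drop = FALSE]
  stopifnot(nrow(imaging) == nrow(clinical), ncol(imaging) >= 1L,
            ncol(clinical) >= 1L)
  n <- nrow(imaging)
  rows <- list()
  for (ii in names(imaging)) for (cc in names(clinical)) {
    x <- imaging[[ii]]; y <- clinical[[cc]]
    ok <- is.finite(x) & is.finite(y)
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    m <- sum(ok)
    p <- if (is.na(rho) || abs(rho) >= 1) {
      if (is.na(rho)) NA_real_ else 0
    } else {
      tt <- rho * sqrt((m - 2) / (1 - rho^2))
      2 * stats::pt(abs(tt), df = m - 2, lower.tail = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      imaging_index = ii, clinical_measure = cc, rho = rho, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subject cluster summaries for imaging-clinical correlation
#'
#' Mean (default) or peak-voxel value of each subject's map within each
#' significant cluster.
#'
#' @param maps List of per-subject 3D arrays / map objects.
#' @param records Cluster table from [grf_cluster_correction()] or
#'   [mc_cluster_records()] (its `voxels` attribute supplies cluster
#'   membership).
#' @param mask A [binary_mask()].
#' @param summary `"mean"` (default) or `"peak"`.
#' @return Matrix subjects x clusters of summary values.
#' @export
cluster_subject_summaries <- function(maps, records, mask,
                                      summary = c("mean", "peak")) {
  summary <- match.arg(summary)
  vox_list <- attr(records, "voxels")
  stopifnot(!is.null(vox_list), length(vox_list) == nrow(records))
  Y <- stack_maps(maps, mask)
  lin_inside <- which(mask$inside)
  out <- matrix(NA_real_, nrow(Y), nrow(records))
  for (k in seq_len(nrow(records))) {
    vox <- vox_list[[k]]
    cols <- match(vox, lin_inside)
    cols <- cols[!is.na(cols)]
    sub <- Y[, cols, drop = FALSE]
    out[, k] <- if (summary == "mean") rowMeans(sub) else
      apply(sub, 1, function(v) v[which.max(abs(v))])
  }
  colnames(out) <- paste0("cluster", records$label)
  out
}
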