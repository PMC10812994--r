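# Independent oracles used across the suite. Each reimplements the
# quantity under test from first principles (closed forms, enumeration,
# or a different algorithm) and must stay independent of the package's
# own code paths.

# normal-equations least squares: beta = (X'X)^-1 X'y, t for contrast c
oracle_glm_t <- function(X, y, cvec) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dof
  drop(t(cvec) %*% beta) / sqrt(s2 * drop(t(cvec) %*% solve(XtX, cvec)))
}

# pooled-variance two-sample t (case minus control)
oracle_pooled_t <- function(ya, yb) {
  na <- length(ya); nb <- length(yb)
  sp2 <- ((na - 1) * stats::var(ya) + (nb - 1) * stats::var(yb)) /
    (na + nb - 2)
  (mean(ya) - mean(yb)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# brute-force one-voxel DFT amplitude spectrum, a_k = 2|X_k|/N
oracle_dft_amplitude <- function(x, k) {
  n <- length(x)
  t_ <- 0:(n - 1)
  Xk <- sum(x * exp(-2i * pi * k * t_ / n))
  2 * Mod(Xk) / n
}

# RFT cluster-level p recomputed with numerically integrated tail
# probability and independently coded EC densities / extent distribution
oracle_grf_cluster_p <- function(extent, tthr, rc, nvox, dof) {
  phi <- stats::integrate(function(x) stats::dt(x, dof), tthr, Inf,
                          rel.tol = 1e-12)$value
  u <- tthr
  f <- (1 + u^2 / dof)^(-(dof - 1) / 2)
  lg <- exp(lgamma((dof + 1) / 2) - lgamma(dof / 2))
  rho <- c(phi,
           sqrt(4 * log(2)) / (2 * pi) * f,
           (4 * log(2)) / (2 * pi)^1.5 * f * u * lg / sqrt(dof / 2),
           (4 * log(2))^1.5 / (4 * pi^2) * f *
             ((dof - 1) / dof * u^2 - 1))
  Em <- sum(rc * rho)
  En <- nvox * phi / Em
  beta <- (gamma(2.5) / En)^(2 / 3)
  1 - exp(-Em * exp(-beta * extent^(2 / 3)))
}

# Monte-Carlo max-extent threshold by an independent vectorized
# simulation: pairwise-merge component labeling, column-standardized noise
oracle_mc_threshold <- function(d, n_iter, voxel_p = 0.001,
                                cluster_p = 0.05, seed = 99L) {
  set.seed(seed)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  n <- prod(d)
  maxext <- integer(0)
  chunk <- 1000L
  done <- 0L
  while (done < n_iter) {
    m <- min(chunk, n_iter - done)
    Z <- matrix(stats::rnorm(n * m), n)
    Z <- scale(Z)
    supra <- abs(Z) > zthr
    me <- integer(m)
    for (i in which(colSums(supra) > 0)) {
      w <- which(supra[, i])
      if (length(w) == 1L) { me[i] <- 1L; next }
      co <- arrayInd(w, d)
      nw <- length(w)
      comp <- seq_len(nw)
      repeat {
        changed <- FALSE
        for (a in 1:(nw - 1)) for (b in (a + 1):nw) {
          if (comp[a] != comp[b] && all(abs(co[a, ] - co[b, ]) <= 1)) {
            comp[comp == comp[b]] <- comp[a]; changed <- TRUE
          }
        }
        if (!changed) break
      }
      me[i] <- max(table(comp))
    }
    maxext <- c(maxext, me)
    done <- done + m
  }
  k <- 1L
  while (mean(maxext >= k) > cluster_p) k <- k + 1L
  k
}

# hypergeometric upper tail by direct summation of choose() products
oracle_hyper_p <- function(overlap, set_size, query_size, universe) {
  ks <- overlap:min(set_size, query_size)
  terms <- vapply(ks, function(k)
    choose(set_size, k) * choose(universe - set_size, query_size - k) /
      choose(universe, query_size), 0)
  sum(terms)
}

# hand Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# exact two-sided Fisher p by explicit factorial enumeration
oracle_fisher_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d; n <- sum(m)
  lp <- function(x) lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
    lfactorial(c2) - lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
    lfactorial(c1 - x) - lfactorial(r2 - c1 + x)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(ks, lp, 0))
  p_obs <- exp(lp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney: exact two-sided p by enumerating group assignments and
# computing U by pair counting (greater + half-ties)
oracle_mw <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U_obs <- u_of(a, b)
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  Us <- apply(combs, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  list(U = U_obs,
       p = mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9))
}

# Spearman rho as rank-then-Pearson
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# scaled robust sigmoid + min-max, direct recomputation
oracle_srs <- function(x) {
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  y <- 1 / (1 + exp(-(x - med) / (iqr / 1.349)))
  (y - min(y)) / (max(y) - min(y))
}
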