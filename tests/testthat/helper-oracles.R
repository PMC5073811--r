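# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they validate.

# Dense 2-D Simpson quadrature of the shells likelihood over the prior box.
shells_grid_logz <- function(cfg, n_grid = 1201L) {
  stopifnot(cfg$dim == 2L)
  b <- cfg$prior_halfwidth
  g <- seq(-b, b, length.out = n_grid)
  h <- g[2] - g[1]
  sw <- c(1, rep(c(4, 2), length.out = n_grid - 2), 1)
  sw[n_grid] <- 1
  ll <- outer(g, g, function(x, y)
    shells_loglik(cfg, cbind(as.vector(x), as.vector(y))))
  lw <- log(sw * h / 3)
  m <- max(ll)
  # integral of L over the box, then divide by the box volume (2b)^2
  log(sum(exp(ll - m) * exp(outer(lw, lw, "+")))) + m - 2 * log(2 * b)
}

# Sheather-Jones solve-the-equation bandwidth by dense grid search on the
# fixed-point equation (Sheather & Jones 1991 formulation).
sj_bandwidth_grid <- function(x, n_grid = 4000L) {
  n <- length(x)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * stats::dnorm(u)
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * stats::dnorm(u)
  pair_sum <- function(f, h) {
    D <- outer(x, x, "-") / h
    sum(f(D))
  }
  lambda <- min(stats::sd(x), stats::IQR(x) / 1.349)
  a <- 1.24 * lambda * n^(-1 / 7)
  b <- 1.23 * lambda * n^(-1 / 9)
  TD <- -pair_sum(phi6, b) / (n * (n - 1) * b^7)
  SD <- pair_sum(phi4, a) / (n * (n - 1) * a^5)
  RK <- 1 / (2 * sqrt(pi))
  fcn <- function(h) {
    alpha2 <- 1.357 * (SD / TD)^(1 / 7) * h^(5 / 7)
    SDa <- pair_sum(phi4, alpha2) / (n * (n - 1) * alpha2^5)
    (RK / (n * SDa))^(1 / 5) - h
  }
  hs <- seq(0.05 * lambda, 2 * lambda, length.out = n_grid)
  vals <- vapply(hs, fcn, 0)
  sgn <- which(diff(sign(vals)) != 0)[1]
  if (is.na(sgn)) stop("no sign change found for the SJ equation")
  # linear interpolation of the root between the bracketing grid points
  h0 <- hs[sgn]; h1 <- hs[sgn + 1]
  v0 <- vals[sgn]; v1 <- vals[sgn + 1]
  h0 - v0 * (h1 - h0) / (v1 - v0)
}

# Brute-force uniform sampling from the union of ellipsoids by rejection
# from an enclosing box.
union_rejection_sample <- function(es, n, lo, hi) {
  d <- length(es[[1]]$center)
  out <- matrix(NA_real_, 0, d)
  while (nrow(out) < n) {
    X <- matrix(stats::runif(4 * n * d, rep(lo, each = 4 * n),
                             rep(hi, each = 4 * n)), 4 * n, d)
    keep <- rep(FALSE, nrow(X))
    for (e in es) keep <- keep | ellipsoid_contains(e, X)
    out <- rbind(out, X[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Exact Metropolis-Hastings transition matrix for a discrete target with
# nearest-neighbour proposals, and its stationary distribution by
# eigen-analysis.
discrete_mh_stationary <- function(p) {
  K <- length(p)
  P <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in c(i - 1, i + 1)) {
      if (j >= 1 && j <= K)
        P[i, j] <- 0.5 * min(1, p[j] / p[i])
    }
    P[i, i] <- 1 - sum(P[i, ])
  }
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  v / sum(v)
}

# Small prior fixtures reused across tests.
box_prior_2d <- function(b = 6) {
  prior_spec(parameter_spec("x1", "uniform", lower = -b, upper = b),
             parameter_spec("x2", "uniform", lower = -b, upper = b))
}
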