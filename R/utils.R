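# Internal numeric helpers shared by the sampler families.

# log(sum(exp(x))) guarded against overflow; returns -Inf for an all--Inf input.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Weighted column means / covariance; w need not be normalized.
weighted_mean_cov <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * w, Xc) / (1 - sum(w^2))
  list(mean = mu, cov = (S + t(S)) / 2)
}

# Draw n points from N(mu, Sigma) given the upper Cholesky factor R (R'R = Sigma).
rmvnorm_chol <- function(n, mu, R) {
  d <- length(mu)
  Z <- matrix(stats::rnorm(n * d), n, d)
  sweep(Z %*% R, 2, mu, "+")
}

# Log density of rows of X under N(mu, Sigma), Sigma given by upper Cholesky R.
dmvnorm_chol <- function(X, mu, R) {
  d <- length(mu)
  Xc <- sweep(X, 2, mu)
  Z <- t(backsolve(R, t(Xc), transpose = TRUE))
  -0.5 * rowSums(Z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

# Cholesky with a diagonal jitter fallback for near-singular covariances.
safe_chol <- function(S, eps = 1e-6) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) R <- chol(S + diag(eps, nrow(S)))
  R
}

`%||%` <- function(a, b) if (is.null(a)) b else a
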