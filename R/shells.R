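#' Gaussian shells benchmark configuration
#'
#' A multimodal, ridge-shaped test likelihood: the sum of two thin Gaussian
#' shells of radius `radius` and width `width` centred at `centers`, under a
#' uniform box prior of half-width `prior_halfwidth` per dimension. The shells
#' are narrow and well separated, which makes the problem a demanding test of
#' mode-hopping and evidence estimation while its marginal likelihood remains
#' available in closed form ([shells_analytic_logz()]).
#'
#' @param dim Dimension `n >= 2`.
#' @param radius Shell radius (default 2).
#' @param width Shell width (default 0.1).
#' @param centers Two-row matrix of shell centres; defaults to
#'   `(+/-3.5, 0, ..., 0)`.
#' @param prior_halfwidth Half-width of the uniform prior box (default 6).
#' @return Object of class `shells_config`.
#' @export
shells_config <- function(dim = 2L, radius = 2, width = 0.1,
                          centers = NULL, prior_halfwidth = 6) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L, radius > 0, width > 0, prior_halfwidth > 0)
  if (is.null(centers)) {
    centers <- matrix(0, 2, dim)
    centers[1, 1] <- 3.5
    centers[2, 1] <- -3.5
  }
  stopifnot(nrow(centers) == 2, ncol(centers) == dim)
  if (all(centers[1, ] == centers[2, ])) stop("shell centres must be distinct")
  structure(list(dim = dim, radius = radius, width = width,
                 centers = centers, prior_halfwidth = prior_halfwidth),
            class = "shells_config")
}

#' Gaussian shells log likelihood
#'
#' \deqn{L(\theta) = \sum_{i=1}^{2} \frac{1}{\sqrt{2\pi w^2}}
#'   \exp\left(-\frac{(|\theta - c_i| - r)^2}{2 w^2}\right)}
#' evaluated stably on the log scale via log-sum-exp.
#'
#' @param cfg A [shells_config()].
#' @param theta Parameter vector of length `cfg$dim`, or a matrix with one
#'   point per row.
#' @return Log likelihood value(s).
#' @export
#' @examples
#' cfg <- shells_config(dim = 2)
#' shells_loglik(cfg, c(5.5, 0))   # on the first shell: -log(0.1 * sqrt(2*pi))
shells_loglik <- function(cfg, theta) {
  stopifnot(inherits(cfg, "shells_config"))
  if (is.matrix(theta)) {
    if (ncol(theta) != cfg$dim)
      stop(sprintf("theta has %d columns, expected %d", ncol(theta), cfg$dim))
    Theta <- theta
  } else {
    if (length(theta) != cfg$dim)
      stop(sprintf("theta has length %d, expected %d", length(theta), cfg$dim))
    Theta <- matrix(theta, nrow = 1)
  }
  lognorm <- -log(cfg$width) - 0.5 * log(2 * pi)
  t1 <- lognorm - (sqrt(rowSums(sweep(Theta, 2, cfg$centers[1, ])^2)) -
                     cfg$radius)^2 / (2 * cfg$width^2)
  t2 <- lognorm - (sqrt(rowSums(sweep(Theta, 2, cfg$centers[2, ])^2)) -
                     cfg$radius)^2 / (2 * cfg$width^2)
  m <- pmax(t1, t2)
  out <- m + log(exp(t1 - m) + exp(t2 - m))
  if (is.matrix(theta)) out else out[1]
}

#' Analytic log evidence of the Gaussian shells problem
#'
#' Reduces the n-dimensional integral of one shell over the uniform box prior
#' to a 1-D radial integral against the hypersphere surface area,
#' \deqn{Z = \frac{2}{(2b)^n}\int_0^\infty S_{n-1}(\rho)\,
#'       \mathcal{N}(\rho; r, w^2)\, d\rho,}
#' computed by Simpson quadrature on the log scale (stable up to dimension 100
#' and beyond). Both shells are assumed to lie inside the prior box up to
#' negligible (many-sigma) truncation.
#'
#' @param cfg A [shells_config()].
#' @return Log marginal likelihood (a single number).
#' @export
#' @examples
#' shells_analytic_logz(shells_config(dim = 2))   # log(8 * pi / 144)
shells_analytic_logz <- function(cfg) {
  stopifnot(inherits(cfg, "shells_config"))
  n <- cfg$dim; r <- cfg$radius; w <- cfg$width; b <- cfg$prior_halfwidth
  if (max(abs(cfg$centers)) + r + 3 * w > b)
    stop("shell truncated by the prior box; analytic reduction invalid")
  lo <- max(r - 12 * w, w * 1e-6)
  hi <- r + 12 * w
  m <- 4001L                                # odd count for Simpson's rule
  rho <- seq(lo, hi, length.out = m)
  h <- rho[2] - rho[1]
  # log integrand: hypersphere area S_{n-1}(rho) times N(rho; r, w^2)
  g <- log(2) + (n / 2) * log(pi) - lgamma(n / 2) + (n - 1) * log(rho) +
    stats::dnorm(rho, r, w, log = TRUE)
  sw <- c(1, rep(c(4, 2), length.out = m - 2), 1)
  sw[m] <- 1
  logI <- logsumexp(g + log(sw * h / 3))
  if (!is.finite(logI)) stop("radial quadrature did not converge")
  log(2) + logI - n * log(2 * b)
}

# Tempered target for the shells benchmark (vectorized likelihood).
shells_target <- function(cfg) {
  specs <- lapply(seq_len(cfg$dim), function(j)
    parameter_spec(paste0("x", j), "uniform",
                   lower = -cfg$prior_halfwidth, upper = cfg$prior_halfwidth))
  make_target(prior_spec(specs),
              function(Theta) shells_loglik(cfg, Theta), vectorized = TRUE)
}

#' Built-in shells benchmark target
#'
#' Convenience wrapper returning the [make_target()] object for the shells
#' problem with its uniform box prior, ready to pass to any of
#' [run_ptmcmc()], [run_smc()] or [run_nested()].
#'
#' @param dim Problem dimension.
#' @param ... Further arguments to [shells_config()].
#' @return A `tempered_target`.
#' @export
shells_benchmark_target <- function(dim = 2L, ...) {
  shells_target(shells_config(dim = dim, ...))
}

#' Conjugate normal-normal benchmark with closed-form evidence
#'
#' A fixed synthetic inference problem used as the toolkit-wide cross-check:
#' prior \eqn{\theta \sim N(0, 1)}, likelihood a product of `n_obs` terms
#' \eqn{N(x_i; \theta, \sigma^2)} over data generated once from
#' \eqn{\theta = 0.5}. The marginal likelihood has the closed form of a
#' Gaussian integral, so every sampler family can be checked against it,
#' including its own reported error bound.
#'
#' @param n_obs Number of observations (default 10).
#' @param sigma Observation noise standard deviation (default 1).
#' @param seed Seed for the fixed synthetic data set.
#' @return List with the `target`, data `x`, closed-form `log_z`, and the
#'   exact posterior `mean` and `sd`.
#' @export
conjugate_normal_problem <- function(n_obs = 10L, sigma = 1, seed = 42L) {
  set.seed(seed)
  x <- stats::rnorm(n_obs, mean = 0.5, sd = sigma)
  prior <- prior_spec(parameter_spec("theta", "normal", mean = 0, sd = 1))
  target <- make_target(prior, function(Theta)
    vapply(Theta[, 1], function(th)
      sum(stats::dnorm(x, th, sigma, log = TRUE)), 0),
    vectorized = TRUE)
  prec <- 1 + n_obs / sigma^2
  sx <- sum(x); s2 <- sum(x^2)
  log_z <- -0.5 * n_obs * log(2 * pi * sigma^2) - 0.5 * log(prec) -
    0.5 * (s2 / sigma^2 - (sx / sigma^2)^2 / prec)
  list(target = target, x = x, sigma = sigma, log_z = log_z,
       mean = (sx / sigma^2) / prec, sd = sqrt(1 / prec))
}
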