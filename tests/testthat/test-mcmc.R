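test_that("mh_update leaves a standard normal target invariant", {
  pr <- prior_spec(parameter_spec("x", "uniform", lower = -20, upper = 20))
  tg <- make_target(pr, function(theta) dnorm(theta[1], log = TRUE))
  set.seed(101)
  st <- chain_state(0, tg, beta = 1, cov = matrix(5.66), scale = 1)
  n <- 1e5
  draws <- numeric(n)
  for (i in seq_len(n)) {
    st <- mh_update(st, tg)
    draws[i] <- st$theta
  }
  expect_lt(abs(mean(draws)), 0.05)
  expect_gt(var(draws), 0.9)
  expect_lt(var(draws), 1.1)
  expect_equal(st$n_prop, n)
  expect_gt(st$n_acc / st$n_prop, 0.1)
  expect_lt(st$n_acc / st$n_prop, 0.9)
  # cached densities stay consistent with re-evaluation
  expect_equal(st$log_lik, dnorm(st$theta, log = TRUE))
})

test_that("mh_update rejects proposals outside the prior support", {
  pr <- prior_spec(parameter_spec("x", "uniform", lower = 0, upper = 1))
  tg <- make_target(pr, function(theta) 0)
  set.seed(7)
  # enormous steps: essentially every proposal leaves [0, 1]
  st <- chain_state(0.5, tg, beta = 1, cov = matrix(1e6))
  for (i in 1:200) st <- mh_update(st, tg)
  expect_true(st$theta >= 0 && st$theta <= 1)
  expect_true(is.finite(st$log_prior))
})

test_that("mh_update occupancy matches the eigen-analysis stationary law on a binned target", {
  # piecewise-constant density over 5 unit bins; the exact MH kernel for the
  # discrete nearest-neighbour analogue has this as its eigen-stationary law
  p <- c(0.05, 0.2, 0.5, 0.15, 0.1)
  stat <- discrete_mh_stationary(p)
  expect_equal(stat, p, tolerance = 1e-10)   # brute-force oracle agrees

  pr <- prior_spec(parameter_spec("x", "uniform", lower = 0, upper = 5))
  tg <- make_target(pr, function(theta) log(p[ceiling(max(theta[1], 1e-9))]))
  set.seed(42)
  st <- chain_state(2.5, tg, beta = 1, cov = matrix(1), scale = 1)
  n <- 4e4
  bins <- integer(n)
  for (i in seq_len(n)) {
    st <- mh_update(st, tg)
    bins[i] <- ceiling(st$theta)
  }
  occ <- tabulate(bins, 5) / n
  expect_lt(max(abs(occ - stat)), 0.02)
})

test_that("adaptive proposal covariance follows the 2.38^2/d scaling rule", {
  set.seed(1)
  h <- matrix(rnorm(500, sd = 1), ncol = 1)
  ap <- adapt_proposal(h)
  expect_equal(ap$cov[1, 1], 2.38^2 * var(h[, 1]) + 1e-6, tolerance = 1e-12)
  expect_equal(adapt_proposal(matrix(1, 50, 1))$cov[1, 1], 1e-6)

  H <- matrix(rnorm(300), ncol = 3)
  C <- adapt_proposal(H)$cov
  expect_true(isSymmetric(C))
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(adapt_proposal(matrix(rnorm(4), 2, 2)), "history")
})

test_that("replica-exchange acceptance follows the tempered swap ratio", {
  expect_equal(swap_log_alpha(0.3, 0.3, -5, -2), 0)
  expect_equal(swap_log_alpha(0.2, 0.9, -4, -4), 0)
  expect_equal(swap_log_alpha(0.5, 1.0, -2, -1), -0.5)
  # swapping a zero-likelihood state into a beta > 0 rung is impossible
  expect_equal(swap_log_alpha(0.5, 1.0, -2, -Inf), -Inf)

  pr <- prior_spec(parameter_spec("x", "uniform", lower = -1, upper = 1))
  tg <- make_target(pr, function(theta) -theta[1]^2)
  set.seed(8)
  a <- chain_state(0.5, tg, beta = 0.4)
  b <- chain_state(-0.1, tg, beta = 0.8)
  sw <- temper_swap(a, b)
  if (sw$swapped) {
    expect_equal(sw$state_i$theta, -0.1)
    expect_equal(sw$state_j$theta, 0.5)
  } else {
    expect_equal(sw$state_i$theta, 0.5)
  }
})

test_that("ladder feedback optimization is a fixed point on linear flow and preserves invariants", {
  betas <- init_ladder(8, 2)
  f_lin <- seq(0, 1, length.out = 8)
  expect_equal(optimize_ladder(f_lin, betas), betas, tolerance = 1e-8)
  expect_equal(optimize_ladder(rep(0.5, 8), betas), betas)

  set.seed(11)
  for (i in 1:20) {
    f <- sort(runif(8))
    nb <- optimize_ladder(f, betas)
    expect_equal(length(nb), 8)
    expect_equal(nb[1], 0)
    expect_equal(nb[8], 1)
    expect_false(is.unsorted(nb, strictly = TRUE))
  }
  # non-monotone flow is monotonized, output still a valid ladder
  nb <- optimize_ladder(c(0, 0.3, 0.2, 0.5, 0.4, 0.7, 0.6, 1), betas)
  expect_false(is.unsorted(nb, strictly = TRUE))
})

test_that("parameter blocking clusters by absolute correlation", {
  expect_equal(infer_blocks(diag(3)), list(1L, 2L, 3L))
  C <- matrix(c(1, 0.99, 0.99, 1), 2, 2)
  expect_equal(infer_blocks(C), list(c(1L, 2L)))
  # negative correlation counts through |rho|
  C[1, 2] <- C[2, 1] <- -0.8
  expect_equal(infer_blocks(C), list(c(1L, 2L)))

  set.seed(3)
  for (i in 1:10) {
    X <- matrix(rnorm(200), ncol = 4)
    blocks <- infer_blocks(cor(X), threshold = runif(1, 0.2, 0.9))
    expect_setequal(unlist(blocks), 1:4)
    expect_equal(length(unlist(blocks)), 4L)
  }
  expect_error(infer_blocks(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("thermodynamic integration reproduces trapezoid arithmetic and error propagation", {
  expect_equal(ti_evidence(c(0, 0.25, 0.6, 1), rep(3.5, 4))$log_z, 3.5)
  est <- ti_evidence(c(0, 0.5, 1), c(0, 2, 4))
  expect_equal(est$log_z, 2)
  expect_equal(est$error, 0)
  est2 <- ti_evidence(c(0, 0.5, 1), c(0, 2, 4), se_loglik = c(1, 2, 1))
  expect_equal(est2$error, sqrt(0.25^2 + 1 + 0.25^2))
  expect_error(ti_evidence(1, 3), "ladder")
  expect_error(ti_evidence(c(0, 0.5, 1), c(1, 2)), "per rung")
})

test_that("swap moves preserve per-rung marginals on a product-form target", {
  # prior N(0,1), likelihood N(0, 1) density: at rung beta the tempered
  # marginal is N(0, 1/(1+beta)) -- exactly known at every rung
  pr <- prior_spec(parameter_spec("x", "normal", mean = 0, sd = 1))
  tg <- make_target(pr, function(Theta) dnorm(Theta[, 1], log = TRUE),
                    vectorized = TRUE)
  r <- run_ptmcmc(tg, list(rungs = 5, burnin = 1000, sweeps = 4000,
                           samples = 2000), seed = 13)
  # cold chain (beta = 1) must have variance 1/2
  v <- var(r$samples$x)
  expect_gt(v, 0.42)
  expect_lt(v, 0.58)
  expect_gt(r$diagnostics$swap_rate, 0.2)
})

test_that("ptmcmc run contracts: ladder invariants, config validation, reproducibility", {
  cz <- conjugate_normal_problem()
  expect_error(run_ptmcmc(cz$target, list(sweeps = 0)), "sweep")
  expect_error(run_ptmcmc(cz$target, list(bogus_key = 1)), "unknown")

  r1 <- run_ptmcmc(cz$target, list(rungs = 6, burnin = 500, sweeps = 500,
                                   samples = 100), seed = 5)
  r2 <- run_ptmcmc(cz$target, list(rungs = 6, burnin = 500, sweeps = 500,
                                   samples = 100), seed = 5)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$evidence$log_z, r2$evidence$log_z)

  b <- r1$diagnostics$betas
  expect_equal(b[1], 0)
  expect_equal(b[length(b)], 1)
  expect_false(is.unsorted(b, strictly = TRUE))
  expect_equal(length(b), 6L)
  # ladder history never changes the rung count or the endpoints
  for (h in r1$diagnostics$ladder_history) {
    expect_equal(length(h), 6L)
    expect_equal(h[c(1, 6)], c(0, 1))
  }
})

test_that("automated blocking groups the correlated pair on a correlated target", {
  pr <- prior_spec(parameter_spec("a", "uniform", lower = -10, upper = 10),
                   parameter_spec("b", "uniform", lower = -10, upper = 10),
                   parameter_spec("c", "uniform", lower = -10, upper = 10))
  # strongly correlated (a, b), independent c
  S <- matrix(c(1, 0.95, 0, 0.95, 1, 0, 0, 0, 1), 3, 3)
  Sinv <- solve(S)
  tg <- make_target(pr, function(Theta)
    -0.5 * rowSums((Theta %*% Sinv) * Theta), vectorized = TRUE)
  r <- run_ptmcmc(tg, list(rungs = 4, burnin = 3000, sweeps = 1000,
                           samples = 200, blocking = TRUE), seed = 2)
  blocks <- r$diagnostics$blocks
  sizes <- sort(lengths(blocks))
  expect_equal(sizes, c(1L, 2L))
  expect_setequal(unlist(blocks), 1:3)
})
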