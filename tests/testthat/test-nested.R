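test_that("nested-sampling quadrature handles degenerate and telescoping cases", {
  # deterministic volumes telescope: sum_i dX_i = 1 - exp(-k/N)
  N <- 50; k <- 120
  log_dX <- -(seq_len(k) - 1) / N + log1p(-exp(-1 / N))
  expect_equal(sum(exp(log_dX)), 1 - exp(-k / N), tolerance = 1e-12)

  # constant likelihood: log Z = log c, H = 0, error 0
  est <- ns_quadrature(rep(log(3), 200), n_live = 50,
                       log_lik_live = rep(log(3), 50))
  expect_equal(est$log_z, log(3), tolerance = 1e-12)
  expect_equal(est$error, 0, tolerance = 1e-6)
  # dead points carry all posterior mass except the live remainder e^{-k/N}
  expect_equal(sum(exp(attr(est, "log_weights"))), 1 - exp(-200 / 50),
               tolerance = 1e-6)

  expect_error(ns_quadrature(numeric(0), 10), "empty")
  expect_error(ns_quadrature(c(1, 0.5), 10), "non-decreasing")
})

test_that("nested sampling recovers the 1-D analytic evidence Z = 1 - exp(-1)", {
  pr <- prior_spec(parameter_spec("x", "uniform", lower = 0, upper = 1))
  tg <- make_target(pr, function(Theta) -Theta[, 1], vectorized = TRUE)
  r <- run_nested(tg, list(live_points = 500, variant = "ellipsoid",
                           samples = 500), seed = 11)
  true_lz <- log(1 - exp(-1))
  expect_lt(abs(r$evidence$log_z - true_lz),
            3 * r$evidence$error + 0.01)
  # dead-point likelihood sequence is non-decreasing by construction
  expect_false(is.unsorted(r$diagnostics$dead_loglik))
  # posterior mean matches the truncated-exponential closed form
  post_mean <- (1 - 2 * exp(-1)) / (1 - exp(-1))
  expect_lt(abs(mean(r$samples$x) - post_mean), 0.03)
})

test_that("likelihood-constrained walks respect the threshold and stay uniform", {
  pr <- box_prior_2d(b = 1)
  tg <- make_target(pr, function(Theta) rep(0, nrow(Theta)), vectorized = TRUE)
  set.seed(5)
  live <- sample_prior(tg$prior, 100)
  # vacuous constraint: reduces to a prior-constrained walk
  out <- replace_mcmc(live, -Inf, tg, n_steps = 10)
  expect_true(is.finite(out$log_prior))
  expect_gte(out$n_accepted, 1)

  # uniformity oracle: replacements from clustered starts spread to uniform
  clustered <- matrix(runif(200, -0.05, 0.05), ncol = 2)
  xs <- t(vapply(1:400, function(i)
    replace_mcmc(clustered, -Inf, tg, n_steps = 40)$theta, c(0, 0)))
  for (j in 1:2) {
    cnt <- table(cut(xs[, j], breaks = seq(-1, 1, length.out = 6)))
    expect_gt(chisq.test(cnt)$p.value, 1e-4)
  }

  # threshold contract on a nontrivial likelihood
  cfg <- shells_config(2)
  tgs <- shells_benchmark_target(2)
  set.seed(6)
  ang <- runif(60, 0, 2 * pi)
  ring <- cbind(3.5 + 2 * cos(ang), 2 * sin(ang)) +
    matrix(rnorm(120, sd = 0.05), ncol = 2)
  lstar <- stats::median(shells_loglik(cfg, ring))
  live <- ring[shells_loglik(cfg, ring) > lstar, , drop = FALSE]
  for (i in 1:10) {
    res <- replace_mcmc(live, lstar, tgs, n_steps = 15)
    expect_gt(res$log_lik, lstar)
  }
})

test_that("constrained walk errors on an unreachable plateau", {
  pr <- prior_spec(parameter_spec("x", "uniform", lower = 0, upper = 1))
  tg <- make_target(pr, function(Theta) rep(0, nrow(Theta)), vectorized = TRUE)
  set.seed(2)
  live <- sample_prior(pr, 20)
  expect_error(replace_mcmc(live, lstar = 5, tg, n_steps = 5, max_tries = 200),
               "stuck")
})

test_that("bounding ellipsoids scale the covariance to contain all points", {
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  e <- bounding_ellipsoid(pts, enlargement = 1)
  expect_equal(e$center, c(0, 0))
  expect_equal(e$shape, diag(2), tolerance = 1e-9)   # the unit disk
  expect_equal(e$log_volume, log(pi), tolerance = 1e-9)

  set.seed(12)
  for (i in 1:10) {
    P <- matrix(rnorm(60), ncol = 3) %*% matrix(rnorm(9), 3, 3)
    e <- bounding_ellipsoid(P)
    expect_true(all(ellipsoid_contains(e, P)))
  }
  # volume scales as enlargement^dim
  e1 <- bounding_ellipsoid(pts, enlargement = 1)
  e2 <- bounding_ellipsoid(pts, enlargement = 1.3)
  expect_equal(e2$log_volume - e1$log_volume, 2 * log(1.3), tolerance = 1e-9)
  expect_error(bounding_ellipsoid(matrix(rnorm(4), 2, 2)), "more points")
})

test_that("ellipsoid sampling is uniform: radius law, containment, symmetry", {
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  e <- bounding_ellipsoid(pts, enlargement = 1)
  set.seed(14)
  X <- sample_ellipsoid(e, 1e4)
  r <- sqrt(rowSums(X^2))
  expect_true(all(r <= 1 + 1e-9))
  expect_lt(abs(mean(r < 0.5) - 0.25), 0.02)              # area ratio
  expect_lt(max(abs(colMeans(X))), 0.02)                  # mean -> centre

  ee <- bounding_ellipsoid(pts, enlargement = 1.2)
  Xe <- sample_ellipsoid(ee, 2000)
  expect_true(all(ellipsoid_contains(ee, Xe)))
})

test_that("multi-ellipsoid partition separates distant clusters and covers all points", {
  set.seed(15)
  A <- matrix(rnorm(160, sd = 0.3), ncol = 2); A[, 1] <- A[, 1] + 10
  B <- matrix(rnorm(160, sd = 0.3), ncol = 2); B[, 1] <- B[, 1] - 10
  pts <- rbind(A, B)
  es <- multinest_partition(pts)
  expect_gte(length(es), 2L)
  union_vol <- evidencer:::logsumexp(vapply(es, `[[`, 0, "log_volume"))
  single <- bounding_ellipsoid(pts)
  expect_lt(union_vol, single$log_volume)
  expect_true(all(evidencer:::ellipsoid_set_membership(es, pts) >= 1))

  # one spherical cloud: the split is rejected
  C <- matrix(rnorm(300), ncol = 2)
  es1 <- multinest_partition(C)
  expect_equal(length(es1), 1L)
})

test_that("overlap-corrected union sampling matches brute-force rejection from the union", {
  set.seed(16)
  # two genuinely overlapping, differently shaped ellipsoids
  e1 <- bounding_ellipsoid(cbind(runif(40, -2, 2), runif(40, -0.5, 0.5)))
  e2 <- bounding_ellipsoid(cbind(runif(40, -0.5, 0.5), runif(40, -2, 2)))
  es <- structure(list(e1, e2), class = "ellipsoid_set")
  X <- matrix(NA_real_, 0, 2)
  while (nrow(X) < 3000) X <- rbind(X, evidencer:::sample_union_batch(es, 3000))
  X <- X[1:3000, ]
  Y <- union_rejection_sample(es, 3000, lo = c(-4, -4), hi = c(4, 4))
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(X[, j], Y[, j]))
    expect_gt(ks$p.value, 1e-3)
  }

  # two *identical* ellipsoids: correction halves acceptance, law unchanged
  es2 <- structure(list(e1, e1), class = "ellipsoid_set")
  X2 <- matrix(NA_real_, 0, 2)
  while (nrow(X2) < 2000) X2 <- rbind(X2, evidencer:::sample_union_batch(es2, 2000))
  X1 <- sample_ellipsoid(e1, 5000)
  ks <- suppressWarnings(stats::ks.test(X2[1:2000, 1], X1[, 1]))
  expect_gt(ks$p.value, 1e-3)
})

test_that("constrained draws from an ellipsoid set satisfy the likelihood threshold", {
  tg <- shells_benchmark_target(2)
  cfg <- shells_config(2)
  set.seed(18)
  ang <- runif(300, 0, 2 * pi)
  ring <- cbind(3.5 + 2 * cos(ang), 2 * sin(ang)) +
    matrix(rnorm(600, sd = 0.05), ncol = 2)
  es <- multinest_partition(ring, target_volume = 2 * pi * 2 * 0.3)
  lstar <- quantile(shells_loglik(cfg, ring), 0.3)
  for (i in 1:10) {
    res <- sample_ellipsoid_set(es, lstar, tg)
    expect_gt(res$log_lik, lstar)
    expect_true(is.finite(res$log_prior))
  }
  # a single-ellipsoid set reduces to plain ellipsoid sampling + constraint
  es1 <- structure(list(bounding_ellipsoid(ring)), class = "ellipsoid_set")
  res <- sample_ellipsoid_set(es1, -Inf, tg)
  expect_true(ellipsoid_contains(es1[[1]], matrix(res$theta, 1)))
})

test_that("collapsed acceptance is reported as an error, not a hang", {
  tg <- shells_benchmark_target(2)
  set.seed(19)
  far <- matrix(rnorm(60, sd = 0.01), ncol = 2)   # tiny cloud at the origin
  es <- structure(list(bounding_ellipsoid(far)), class = "ellipsoid_set")
  # no point near the origin can beat a threshold above the global maximum
  expect_error(sample_ellipsoid_set(es, lstar = 10, tg, max_tries = 640),
               "acceptance rate")
})

test_that("nested runs validate configuration and reproduce under a fixed seed", {
  cz <- conjugate_normal_problem()
  expect_error(run_nested(cz$target, list(whatever = 1)), "unknown")
  r1 <- run_nested(cz$target, list(live_points = 100, variant = "ellipsoid",
                                   samples = 100), seed = 4)
  r2 <- run_nested(cz$target, list(live_points = 100, variant = "ellipsoid",
                                   samples = 100), seed = 4)
  expect_identical(r1$samples, r2$samples)
  expect_false(is.unsorted(r1$diagnostics$dead_loglik))
  # posterior weights of dead points sum to one after normalization
  r3 <- run_nested(cz$target, list(live_points = 150, variant = "multinest",
                                   samples = 100), seed = 4)
  lw <- attr(r3$evidence, "log_weights")
  expect_lt(sum(exp(lw)), 1 + 1e-6)
  expect_gt(sum(exp(lw)), 0.9)   # live remainder is small at termination
})
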