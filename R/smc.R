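#' Create a particle population
#'
#' Container for the sequential Monte Carlo state: particle positions, cached
#' log densities, unnormalized log weights, the current inverse temperature,
#' an island (batch) label per particle, and the accumulated log-evidence —
#' globally and per island, the latter giving the batch-based error bound.
#'
#' @param Theta `N x d` matrix of particle positions.
#' @param log_priors,log_liks Cached log densities per particle.
#' @param beta Current inverse temperature.
#' @param n_islands Number of near-equal-size islands.
#' @return Object of class `particle_population`.
#' @export
particle_population <- function(Theta, log_priors, log_liks, beta = 0,
                                n_islands = 8L) {
  N <- nrow(Theta)
  if (N < 2) stop("a population needs at least 2 particles")
  n_islands <- max(1L, min(as.integer(n_islands), N %/% 2L))
  structure(list(Theta = Theta, log_priors = log_priors, log_liks = log_liks,
                 log_weights = rep(0, N), beta = beta,
                 island = rep_len(seq_len(n_islands), N),
                 logz = 0, logz_islands = rep(0, n_islands),
                 diag = list(acc = numeric(0), betas = beta)),
            class = "particle_population")
}

#' Effective sample size of a set of log weights
#'
#' `(sum w)^2 / sum(w^2)` on the normalized weights; ranges from 1 (all mass
#' on one particle) to `N` (uniform weights).
#'
#' @param log_weights Numeric vector of (unnormalized) log weights.
#' @return ESS in `[1, N]`.
#' @export
#' @examples
#' ess(rep(0, 100))                 # 100
#' ess(log(c(2/3, 1/3)))            # 1.8
ess <- function(log_weights) {
  lse <- logsumexp(log_weights)
  if (!is.finite(lse)) stop("population death: all weights are zero")
  exp(-logsumexp(2 * (log_weights - lse)))
}

#' Automated temperature schedule: choose the next inverse temperature
#'
#' Finds, by bisection, the largest `beta' > beta` such that the effective
#' sample size of the incremental weights `L^(beta' - beta)` is still at
#' least `alpha` times the current ESS — retaining a controlled fraction of
#' particle diversity per tempering step. Returns 1 when the full step to the
#' posterior satisfies the constraint.
#'
#' @param pop A [particle_population()] with `beta < 1`.
#' @param alpha Retention fraction in (0, 1), default 0.8.
#' @param tol Bisection tolerance on beta (default `1e-8`).
#' @return The next inverse temperature in `(beta, 1]`.
#' @export
next_temperature <- function(pop, alpha = 0.8, tol = 1e-8) {
  if (pop$beta >= 1) stop("population already at beta = 1")
  target_ess <- alpha * ess(pop$log_weights)
  g <- function(b)
    ess(pop$log_weights + (b - pop$beta) * pop$log_liks) - target_ess
  if (g(1) >= 0) return(1)
  lo <- pop$beta; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) lo <- mid else hi <- mid
  }
  max(lo, pop$beta + tol)
}

#' Reweight a population to a higher temperature
#'
#' Multiplies each particle weight by `L^(new_beta - beta)` and accumulates
#' the sequential evidence increment
#' `log sum(normalized old weights * exp(increment))`, both globally and per
#' island (island-normalized), so the final `logz` is the product-of-weights
#' evidence estimate and the island accumulators provide its error bound.
#'
#' @param pop A [particle_population()].
#' @param new_beta New inverse temperature `> pop$beta` (equal allowed as an
#'   identity step).
#' @return The updated population.
#' @export
reweight <- function(pop, new_beta) {
  if (new_beta < pop$beta) stop("new_beta must be >= current beta")
  inc <- (new_beta - pop$beta) * pop$log_liks
  lw <- pop$log_weights - logsumexp(pop$log_weights)
  pop$logz <- pop$logz + logsumexp(lw + inc)
  for (j in seq_along(pop$logz_islands)) {
    i <- pop$island == j
    lwj <- pop$log_weights[i] - logsumexp(pop$log_weights[i])
    pop$logz_islands[j] <- pop$logz_islands[j] + logsumexp(lwj + inc[i])
  }
  pop$log_weights <- pop$log_weights + inc
  pop$beta <- new_beta
  pop$diag$betas <- c(pop$diag$betas, new_beta)
  pop
}

# Systematic resampling indices for normalized weights w (one uniform offset).
systematic_indices <- function(w) {
  n <- length(w)
  pos <- (seq_len(n) - 1 + stats::runif(1)) / n
  findInterval(pos, cumsum(w)) + 1L
}

#' Systematic resampling within islands
#'
#' Replaces the weighted population by an equal-weight one, resampling
#' independently within each island with island-normalized weights so that
#' island sizes are preserved and the per-island evidence estimates stay
#' independent. With exactly uniform weights every particle is copied exactly
#' once.
#'
#' @param pop A [particle_population()].
#' @return The resampled, equal-weight population.
#' @export
resample <- function(pop) {
  if (!is.finite(logsumexp(pop$log_weights)))
    stop("population death: all weights are zero")
  idx <- integer(nrow(pop$Theta))
  for (j in seq_along(pop$logz_islands)) {
    i <- which(pop$island == j)
    lw <- pop$log_weights[i]
    w <- exp(lw - logsumexp(lw))
    idx[i] <- i[systematic_indices(w / sum(w))]
  }
  pop$Theta <- pop$Theta[idx, , drop = FALSE]
  pop$log_priors <- pop$log_priors[idx]
  pop$log_liks <- pop$log_liks[idx]
  pop$log_weights <- rep(0, length(idx))
  pop
}

#' Kernel-density-estimate independence proposal
#'
#' Gaussian mixture centred at the particles with kernel covariance
#' `h^2 * WeightedCov`, using the multivariate Silverman-type bandwidth
#' `h = (4 / (N (d + 2)))^(1 / (d + 4))`. The returned object can both draw
#' (`rdraw(n)`) and evaluate (`logdens(Theta)`), the latter enabling the
#' Metropolis-Hastings correction of the independence kernel.
#'
#' @param pop A [particle_population()].
#' @return List with `rdraw`, `logdens`, `h` and the kernel Cholesky factor.
#' @export
kde_proposal <- function(pop) {
  N <- nrow(pop$Theta); d <- ncol(pop$Theta)
  if (N <= d + 1) stop("need more particles than dimensions for a KDE")
  lw <- pop$log_weights - logsumexp(pop$log_weights)
  w <- exp(lw)
  wc <- weighted_mean_cov(pop$Theta, w)
  h <- (4 / (N * (d + 2)))^(1 / (d + 4))
  R <- safe_chol(h^2 * wc$cov)
  Theta <- pop$Theta
  list(
    h = h, R = R,
    rdraw = function(n) {
      i <- sample.int(N, n, replace = TRUE, prob = w)
      Theta[i, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d) %*% R
    },
    logdens = function(X) {
      if (!is.matrix(X)) X <- matrix(X, ncol = d)
      vapply(seq_len(nrow(X)), function(i) {
        logsumexp(lw + dmvnorm_chol(
          matrix(X[i, ], N, d, byrow = TRUE) - Theta,
          mu = rep(0, d), R = R))
      }, 0)
    })
}

#' Move particles with an MCMC kernel targeting the current tempered density
#'
#' Each particle is advanced by `n_steps` Metropolis-Hastings updates
#' targeting `pi_beta`, leaving the tempered distribution invariant. The
#' `"mcmc"` kernel is a Gaussian random walk with covariance
#' `(2.38^2 / d) * WeightedCov(particles)`; the `"kde"` kernel proposes
#' independently from [kde_proposal()] with the full independence-MH
#' correction. Weights are untouched (moves are applied to equal-weight,
#' post-resampling populations).
#'
#' @param pop A [particle_population()].
#' @param target A [make_target()] object.
#' @param kernel `"mcmc"` or `"kde"`.
#' @param n_steps Number of MH updates per particle (default 5).
#' @return The moved population; acceptance rates appended to `pop$diag$acc`.
#' @export
move <- function(pop, target, kernel = c("mcmc", "kde"), n_steps = 5L) {
  kernel <- match.arg(kernel)
  if (n_steps < 1) return(pop)
  N <- nrow(pop$Theta); d <- ncol(pop$Theta)
  lw <- exp(pop$log_weights - logsumexp(pop$log_weights))
  if (kernel == "mcmc") {
    wc <- weighted_mean_cov(pop$Theta, lw)
    R <- safe_chol((2.38^2 / d) * wc$cov + diag(1e-10, d))
  } else {
    q <- kde_proposal(pop)
    cur_q <- q$logdens(pop$Theta)
  }
  cur <- tempered_logdens(pop$log_priors, pop$log_liks, pop$beta)
  acc_tot <- 0
  for (s in seq_len(n_steps)) {
    if (kernel == "mcmc") {
      Prop <- pop$Theta + matrix(stats::rnorm(N * d), N, d) %*% R
    } else {
      Prop <- q$rdraw(N)
    }
    pe <- target_eval_matrix(target, Prop)
    new <- tempered_logdens(pe$log_prior, pe$log_lik, pop$beta)
    logr <- new - cur
    if (kernel == "kde") {
      prop_q <- q$logdens(Prop)
      logr <- logr + cur_q - prop_q
    }
    acc <- log(stats::runif(N)) < logr
    acc[is.na(acc)] <- FALSE
    pop$Theta[acc, ] <- Prop[acc, , drop = FALSE]
    pop$log_priors[acc] <- pe$log_prior[acc]
    pop$log_liks[acc] <- pe$log_lik[acc]
    cur[acc] <- new[acc]
    if (kernel == "kde") cur_q[acc] <- prop_q[acc]
    acc_tot <- acc_tot + mean(acc)
  }
  pop$diag$acc <- c(pop$diag$acc, acc_tot / n_steps)
  pop
}

smc_defaults <- function() {
  list(particles = 2000L, alpha = 0.8, kernel = "mcmc", move_steps = 5L,
       islands = 8L, samples = 1000L, workers = 1L)
}

#' Sequential Monte Carlo run over the tempered path
#'
#' Iterates `next_temperature` -> `reweight` -> (systematic `resample` and
#' MCMC/KDE `move` when ESS drops below N/2) from the prior (`beta = 0`) to
#' the posterior (`beta = 1`). The evidence estimate is the accumulated
#' product of incremental weight sums; its error bound is the standard error
#' of the per-island evidence estimates across islands. Posterior samples are
#' obtained by a final resampling pass.
#'
#' @param target A [make_target()] object.
#' @param cfg Named list overriding any of: `particles`, `alpha`, `kernel`
#'   (`"mcmc"` or `"kde"`), `move_steps`, `islands`, `samples`, `workers`.
#' @param seed Integer seed.
#' @return A `run_result`.
#' @export
run_smc <- function(target, cfg = list(), seed = 1L) {
  cfg <- merge_config(cfg, smc_defaults(), "smc")
  set.seed(seed)
  N <- as.integer(cfg$particles)
  Theta <- sample_prior(target$prior, N)
  ev <- target_eval_matrix(target, Theta)
  pop <- particle_population(Theta, ev$log_prior, ev$log_lik, beta = 0,
                             n_islands = cfg$islands)
  if (all(!is.finite(pop$log_liks)))
    stop("population death at initialization; increase the particle count")

  it <- 0L
  while (pop$beta < 1) {
    it <- it + 1L
    if (it > 10000L) stop("temperature schedule failed to reach beta = 1")
    nb <- next_temperature(pop, cfg$alpha)
    pop <- reweight(pop, nb)
    if (ess(pop$log_weights) < N / 2) {
      pop <- tryCatch(resample(pop), error = function(e)
        stop("population death: all weights zero; increase the particle count"))
      pop <- move(pop, target, cfg$kernel, cfg$move_steps)
    }
  }

  err <- if (length(pop$logz_islands) > 1)
    stats::sd(pop$logz_islands) / sqrt(length(pop$logz_islands))
  else NA_real_   # a single island carries no replication for an error bound
  evidence <- evidence_estimate(pop$logz, err, "smc", eval_count(target))

  lw <- exp(pop$log_weights - logsumexp(pop$log_weights))
  idx <- systematic_indices(lw / sum(lw))
  idx <- idx[seq_len(min(cfg$samples, length(idx)))]
  smp <- pop$Theta[idx, , drop = FALSE]
  colnames(smp) <- target$prior$names
  samples <- as.data.frame(apply_transforms(target$prior, smp))
  samples$log_prior <- pop$log_priors[idx]
  samples$log_lik <- pop$log_liks[idx]

  run_result(samples = samples, evidence = evidence,
             settings = c(list(algorithm = "smc", seed = seed), cfg),
             diagnostics = list(betas = pop$diag$betas,
                                acceptance = pop$diag$acc,
                                logz_islands = pop$logz_islands,
                                n_steps = it))
}
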