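#' Initial inverse-temperature ladder
#'
#' Power-law schedule `beta_i = (i / (K - 1))^power` with endpoints exactly 0
#' and 1. The default cubic power concentrates rungs near `beta = 0`, where
#' the thermodynamic-integration integrand typically has the largest
#' curvature; the feedback optimization ([optimize_ladder()]) then refines
#' rung placement during burn-in.
#'
#' @param K Number of rungs (default 12).
#' @param power Exponent of the schedule (default 3).
#' @return Strictly increasing numeric vector of length `K` from 0 to 1.
#' @export
init_ladder <- function(K = 12L, power = 3) {
  K <- as.integer(K)
  if (K < 2) stop("a ladder needs at least 2 rungs")
  ((seq_len(K) - 1) / (K - 1))^power
}

check_ladder <- function(betas) {
  if (length(betas) < 2 || is.unsorted(betas, strictly = TRUE) ||
      betas[1] != 0 || betas[length(betas)] != 1)
    stop("ladder must be strictly increasing from 0 to 1")
  invisible(betas)
}

#' Create a single MCMC chain state
#'
#' @param theta Initial parameter vector (must have positive prior density).
#' @param target A [make_target()] object.
#' @param beta Inverse temperature of the chain.
#' @param cov Proposal covariance (defaults to the identity).
#' @param scale Scalar multiplier on the proposal covariance.
#' @return Object of class `chain_state` carrying cached densities and
#'   proposal bookkeeping.
#' @export
chain_state <- function(theta, target, beta = 1, cov = NULL, scale = 1) {
  ev <- target_eval(target, theta)
  if (!is.finite(ev$log_prior)) stop("initial theta outside prior support")
  d <- length(theta)
  cov <- cov %||% diag(1, d)
  structure(list(theta = theta, log_prior = ev$log_prior,
                 log_lik = ev$log_lik, beta = beta,
                 cov_R = safe_chol(cov), scale = scale,
                 n_prop = 0L, n_acc = 0L),
            class = "chain_state")
}

#' One Metropolis-Hastings update on a parameter block
#'
#' Gaussian random-walk proposal on the block coordinates, accepted with
#' probability `min(1, exp(delta log pi_beta))` where
#' `log pi_beta = log prior + beta * log lik`. Proposals outside the prior
#' support (density `-Inf`) are rejected without invoking the likelihood;
#' non-finite proposal densities auto-reject, never crash.
#'
#' @param state A [chain_state()].
#' @param target A [make_target()] object.
#' @param block Integer indices of the coordinates to update (default: all).
#' @return The updated `chain_state` (cached densities valid, counters
#'   incremented).
#' @export
mh_update <- function(state, target, block = seq_along(state$theta)) {
  d_b <- length(block)
  step <- state$scale * drop(stats::rnorm(d_b) %*%
                               state$cov_R[block, block, drop = FALSE])
  prop <- state$theta
  prop[block] <- prop[block] + step
  state$n_prop <- state$n_prop + 1L
  lp_new <- log_prior(target$prior, prop)
  if (is.finite(lp_new)) {
    ev <- target_eval(target, prop)
    ll_new <- ev$log_lik
    logr <- tempered_logdens(lp_new, ll_new, state$beta) -
      tempered_logdens(state$log_prior, state$log_lik, state$beta)
    if (is.nan(logr)) logr <- -Inf
    if (log(stats::runif(1)) < logr) {
      state$theta <- prop
      state$log_prior <- lp_new
      state$log_lik <- ll_new
      state$n_acc <- state$n_acc + 1L
    }
  }
  state
}

#' Adaptive-Metropolis proposal covariance from chain history
#'
#' Classic adaptive scaling: `(2.38^2 / d) * SampleCov(history) + eps * I`.
#' A degenerate (zero-variance) history falls back to `eps * I`. The returned
#' `scale` starts at 1 and is tuned separately toward the 0.234 target
#' acceptance rate by the running sampler.
#'
#' @param history Matrix of recent chain states (rows) for the block
#'   coordinates (columns).
#' @param eps Diagonal jitter (default `1e-6`).
#' @return List with `cov` (symmetric positive definite) and `scale`.
#' @export
adapt_proposal <- function(history, eps = 1e-6) {
  history <- as.matrix(history)
  d <- ncol(history)
  if (nrow(history) < d + 2)
    stop("need at least dim + 2 history states to adapt")
  S <- stats::cov(history)
  if (!all(is.finite(S)) || all(S == 0)) S <- matrix(0, d, d)
  list(cov = (2.38^2 / d) * S + diag(eps, d), scale = 1)
}

#' Replica-exchange (parallel tempering) swap
#'
#' Proposes exchanging the states of two chains at adjacent rungs and accepts
#' with probability
#' `min(1, exp((beta_i - beta_j) * (loglik_j - loglik_i)))`.
#'
#' @param state_i,state_j Two [chain_state()] objects.
#' @return List with the (possibly exchanged) states and `swapped`.
#' @export
temper_swap <- function(state_i, state_j) {
  la <- swap_log_alpha(state_i$beta, state_j$beta,
                       state_i$log_lik, state_j$log_lik)
  swapped <- log(stats::runif(1)) < la
  if (swapped) {
    for (f in c("theta", "log_prior", "log_lik")) {
      tmp <- state_i[[f]]; state_i[[f]] <- state_j[[f]]; state_j[[f]] <- tmp
    }
  }
  list(state_i = state_i, state_j = state_j, swapped = swapped)
}

#' @rdname temper_swap
#' @param beta_i,beta_j Rung temperatures.
#' @param ll_i,ll_j Cached log likelihoods.
#' @return `swap_log_alpha`: the log acceptance probability (capped at 0 by
#'   the caller's comparison with `log(runif(1))`).
#' @export
swap_log_alpha <- function(beta_i, beta_j, ll_i, ll_j) {
  f <- function(b, ll) if (b == 0) 0 else b * ll
  la <- (f(beta_i, ll_j) + f(beta_j, ll_i)) -
    (f(beta_i, ll_i) + f(beta_j, ll_j))
  if (is.nan(la)) -Inf else la
}

#' Feedback optimization of a temperature ladder
#'
#' Takes the fraction `f` of visits at each rung made by replicas whose last
#' endpoint visit was the cold end (`beta = 1`), monotonizes it by isotonic
#' regression, and repositions the interior rungs so that the monotonized
#' fraction becomes linear in rung index — equalizing the round-trip flow of
#' replicas between the two ends. Endpoints stay exactly at 0 and 1 and the
#' rung count never changes. A flat `f` (no round trips observed yet) returns
#' the ladder unchanged.
#'
#' @param f Numeric vector: cold-visit fraction per rung.
#' @param betas Current ladder (strictly increasing, endpoints 0 and 1).
#' @return The new ladder.
#' @export
optimize_ladder <- function(f, betas) {
  check_ladder(betas)
  K <- length(betas)
  if (length(f) != K) stop("f must have one entry per rung")
  if (diff(range(f)) < 1e-10) return(betas)
  fm <- stats::isoreg(seq_len(K), f)$yf
  if (fm[K] - fm[1] < 1e-10) return(betas)
  targets <- seq(fm[1], fm[K], length.out = K)
  new_betas <- stats::approx(fm, betas, xout = targets,
                             ties = "ordered", rule = 2)$y
  new_betas[1] <- 0
  new_betas[K] <- 1
  # enforce strict monotonicity against interpolation ties
  for (k in 2:(K - 1))
    new_betas[k] <- min(max(new_betas[k], new_betas[k - 1] + 1e-10),
                        1 - (K - k) * 1e-10)
  check_ladder(new_betas)
}

#' Automated parameter blocking from a posterior correlation matrix
#'
#' Average-linkage hierarchical clustering on the distance `1 - |rho|`, with
#' the tree cut at height `1 - threshold`: parameters whose absolute
#' correlation exceeds `threshold` end up in the same proposal block.
#' Singleton blocks are allowed; the blocks partition the parameter indices.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param threshold Absolute-correlation threshold (default 0.5).
#' @return List of integer index vectors (one per block).
#' @export
infer_blocks <- function(corr, threshold = 0.5) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  d <- nrow(corr)
  if (d == 1) return(list(1L))
  hc <- stats::hclust(stats::as.dist(1 - abs(corr)), method = "average")
  memb <- stats::cutree(hc, h = 1 - threshold)
  unname(split(seq_len(d), memb))
}

#' Thermodynamic-integration evidence estimate
#'
#' Trapezoid rule over the ladder of the per-rung posterior means of the log
#' likelihood: `log Z = integral over beta of E_beta[log L]`. The error bound
#' propagates the per-rung standard errors through the trapezoid weights,
#' `error = sqrt(sum(w_k^2 se_k^2))`, treating rungs as independent.
#'
#' @param betas Ladder (strictly increasing, from 0 to 1).
#' @param mean_loglik Per-rung posterior mean of the log likelihood
#'   (including the `beta = 0` rung).
#' @param se_loglik Per-rung standard errors (default 0).
#' @return An [evidence_estimate()] with method `"ti"`.
#' @export
#' @examples
#' ti_evidence(c(0, 0.5, 1), c(0, 2, 4))   # log Z = 2
ti_evidence <- function(betas, mean_loglik, se_loglik = 0) {
  check_ladder(betas)
  K <- length(betas)
  if (length(mean_loglik) != K) stop("one mean log-likelihood per rung required")
  se_loglik <- rep_len(se_loglik, K)
  w <- trapezoid_weights(betas)
  evidence_estimate(log_z = sum(w * mean_loglik),
                    error = sqrt(sum(w^2 * se_loglik^2)),
                    method = "ti")
}

trapezoid_weights <- function(betas) {
  K <- length(betas)
  w <- numeric(K)
  w[1] <- (betas[2] - betas[1]) / 2
  w[K] <- (betas[K] - betas[K - 1]) / 2
  if (K > 2) w[2:(K - 1)] <- (betas[3:K] - betas[1:(K - 2)]) / 2
  w
}

ptmcmc_defaults <- function() {
  list(rungs = 12L, samples = 1000L, burnin = 5000L, sweeps = 5000L,
       adapt_interval = 200L, ladder_update_interval = 1000L,
       blocking = FALSE, blocking_threshold = 0.5, ladder_power = 3,
       workers = 1L)
}

merge_config <- function(cfg, defaults, what) {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s config key(s): %s", what,
                 paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, cfg)
}

#' Feedback-optimized parallel-tempered MCMC run
#'
#' Runs `rungs` coupled chains at inverse temperatures from 0 (prior) to 1
#' (posterior). Each sweep performs one Metropolis-Hastings update per
#' parameter block on every chain, followed by replica-exchange swaps between
#' alternating even/odd adjacent rung pairs. During burn-in the proposal
#' covariances adapt to the per-rung sample covariance (with scale tuned
#' toward 0.234 acceptance), the ladder is re-optimized from replica-flow
#' statistics ([optimize_ladder()]), and (optionally) correlated parameters
#' are grouped into proposal blocks ([infer_blocks()]). After burn-in the
#' kernel is fixed. Posterior samples are the thinned post-burn-in `beta = 1`
#' chain; the evidence comes from thermodynamic integration over the per-rung
#' mean log likelihoods with effective-sample-size-corrected standard errors.
#'
#' @param target A [make_target()] object.
#' @param cfg Named list overriding any of: `rungs`, `samples`, `burnin`,
#'   `sweeps` (post-burn-in), `adapt_interval`, `ladder_update_interval`,
#'   `blocking`, `blocking_threshold`, `ladder_power`, `workers`. Unknown
#'   keys are rejected.
#' @param seed Integer seed; a fixed seed reproduces the run exactly.
#' @return A `run_result`: posterior `samples` (data frame), `evidence`
#'   ([evidence_estimate()]), `settings`, and `diagnostics` (final ladder,
#'   ladder history, per-rung acceptance and swap rates, blocks).
#' @export
run_ptmcmc <- function(target, cfg = list(), seed = 1L) {
  cfg <- merge_config(cfg, ptmcmc_defaults(), "mcmc")
  if (cfg$sweeps < 1) stop("post-burn-in sweep count must be >= 1")
  if (cfg$samples < 1) stop("requested sample count must be >= 1")
  set.seed(seed)
  K <- as.integer(cfg$rungs)
  d <- target$prior$dimension
  betas <- init_ladder(K, cfg$ladder_power)

  Theta <- sample_prior(target$prior, K)
  ev <- target_eval_matrix(target, Theta)
  lp <- ev$log_prior; ll <- ev$log_lik
  if (all(!is.finite(lp)))
    stop("initialization failed: no prior draw has finite density")

  blocks <- list(seq_len(d))
  # per-rung, per-block proposal state seeded from a prior sample
  seed_cov <- function(blks) {
    ps <- sample_prior(target$prior, max(50, d + 5))
    lapply(seq_len(K), function(k)
      lapply(blks, function(idx) {
        ap <- adapt_proposal(ps[, idx, drop = FALSE])
        list(R = safe_chol(ap$cov), scale = 1,
             n_prop = 0L, n_acc = 0L)
      }))
  }
  prop <- seed_cov(blocks)

  labels <- rep("none", K)
  cold_counts <- lab_counts <- numeric(K)
  W <- max(cfg$adapt_interval, d + 3)
  Hist <- array(NA_real_, dim = c(W, K, d))
  cold_hist <- matrix(NA_real_, cfg$burnin, d)
  ladder_history <- list(betas)
  swap_acc <- swap_try <- 0L

  total <- cfg$burnin + cfg$sweeps
  post_theta <- matrix(NA_real_, cfg$sweeps, d)
  post_ll <- matrix(NA_real_, cfg$sweeps, K)
  post_cold_lp <- post_cold_ll <- numeric(cfg$sweeps)

  for (t in seq_len(total)) {
    in_burn <- t <= cfg$burnin
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]; d_b <- length(idx)
      Prop <- Theta
      for (k in seq_len(K)) {
        st <- prop[[k]][[b]]
        Prop[k, idx] <- Theta[k, idx] +
          st$scale * drop(stats::rnorm(d_b) %*% st$R)
      }
      pe <- target_eval_matrix(target, Prop)
      logr <- tempered_rows(pe$log_prior, pe$log_lik, betas) -
        tempered_rows(lp, ll, betas)
      acc <- log(stats::runif(K)) < logr
      acc[is.na(acc)] <- FALSE
      if (any(acc)) {
        Theta[acc, idx] <- Prop[acc, idx, drop = FALSE]
        lp[acc] <- pe$log_prior[acc]
        ll[acc] <- pe$log_lik[acc]
      }
      for (k in seq_len(K)) {
        prop[[k]][[b]]$n_prop <- prop[[k]][[b]]$n_prop + 1L
        prop[[k]][[b]]$n_acc <- prop[[k]][[b]]$n_acc + acc[k]
      }
    }

    # replica exchange on alternating adjacent pairs
    pairs <- seq.int(if (t %% 2 == 1) 1L else 2L, K - 1L, by = 2L)
    for (i in pairs) {
      la <- swap_log_alpha(betas[i], betas[i + 1], ll[i], ll[i + 1])
      swap_try <- swap_try + 1L
      if (log(stats::runif(1)) < la) {
        swap_acc <- swap_acc + 1L
        Theta[c(i, i + 1), ] <- Theta[c(i + 1, i), , drop = FALSE]
        lp[c(i, i + 1)] <- lp[c(i + 1, i)]
        ll[c(i, i + 1)] <- ll[c(i + 1, i)]
        labels[c(i, i + 1)] <- labels[c(i + 1, i)]
      }
    }
    labels[1] <- "hot"; labels[K] <- "cold"
    tagged <- labels != "none"
    cold_counts <- cold_counts + (labels == "cold")
    lab_counts <- lab_counts + tagged

    Hist[(t - 1L) %% W + 1L, , ] <- Theta
    if (in_burn) {
      cold_hist[t, ] <- Theta[K, ]

      if (cfg$blocking && t == floor(cfg$burnin / 2) && d > 1) {
        ch <- cold_hist[seq_len(t), , drop = FALSE]
        sds <- apply(ch, 2, stats::sd)
        if (all(sds > 0)) {
          blocks <- infer_blocks(stats::cor(ch), cfg$blocking_threshold)
          prop <- seed_cov(blocks)
          for (k in seq_len(K)) for (b in seq_along(blocks)) {
            ap <- adapt_proposal(ch[, blocks[[b]], drop = FALSE])
            prop[[k]][[b]]$R <- safe_chol(ap$cov)
          }
        }
      }

      if (t %% cfg$adapt_interval == 0 && t >= W) {
        for (k in seq_len(K)) for (b in seq_along(blocks)) {
          st <- prop[[k]][[b]]
          h <- Hist[, k, blocks[[b]], drop = FALSE]
          dim(h) <- c(W, length(blocks[[b]]))
          ap <- tryCatch(adapt_proposal(h), error = function(e) NULL)
          if (!is.null(ap)) st$R <- safe_chol(ap$cov)
          rate <- st$n_acc / max(st$n_prop, 1L)
          st$scale <- min(max(st$scale * exp(rate - 0.234), 1e-3), 1e3)
          st$n_prop <- st$n_acc <- 0L
          prop[[k]][[b]] <- st
        }
      }

      if (t %% cfg$ladder_update_interval == 0 && any(lab_counts > 0)) {
        f <- ifelse(lab_counts > 0, cold_counts / lab_counts, NA)
        if (!anyNA(f)) {
          betas <- optimize_ladder(f, betas)
          ladder_history[[length(ladder_history) + 1L]] <- betas
        }
        cold_counts[] <- 0; lab_counts[] <- 0
      }
    } else {
      s <- t - cfg$burnin
      post_theta[s, ] <- Theta[K, ]
      post_ll[s, ] <- ll
      post_cold_lp[s] <- lp[K]; post_cold_ll[s] <- ll[K]
    }
  }

  mean_ll <- colMeans(post_ll)
  se_ll <- vapply(seq_len(K), function(k) {
    x <- post_ll[, k]
    if (stats::sd(x) == 0) return(0)
    stats::sd(x) / sqrt(effective_sample_size(x))
  }, 0)
  evidence <- ti_evidence(betas, mean_ll, se_ll)
  # Replica exchange correlates the log-likelihood series across rungs, so
  # the independent-rung propagation is optimistic; report instead the
  # ESS-corrected standard error of the per-sweep quadrature series
  # y_t = sum_k w_k loglik_{t,k}, whose mean is the same TI estimate.
  y <- drop(post_ll %*% trapezoid_weights(betas))
  if (stats::sd(y) > 0)
    evidence$error <- stats::sd(y) / sqrt(effective_sample_size(y))
  evidence$n_evals <- eval_count(target)

  keep <- unique(round(seq(1, cfg$sweeps, length.out = min(cfg$samples,
                                                           cfg$sweeps))))
  smp <- post_theta[keep, , drop = FALSE]
  colnames(smp) <- target$prior$names
  samples <- as.data.frame(apply_transforms(target$prior, smp))
  samples$log_prior <- post_cold_lp[keep]
  samples$log_lik <- post_cold_ll[keep]

  acc_rates <- vapply(seq_len(K), function(k)
    mean(vapply(prop[[k]], function(st)
      st$n_acc / max(st$n_prop, 1L), 0)), 0)

  run_result(samples = samples, evidence = evidence,
             settings = c(list(algorithm = "mcmc", seed = seed), cfg),
             diagnostics = list(betas = betas,
                                ladder_history = ladder_history,
                                acceptance = acc_rates,
                                swap_rate = swap_acc / max(swap_try, 1L),
                                blocks = blocks,
                                mean_loglik = mean_ll, se_loglik = se_ll))
}

# Tempered log density per row with a per-row beta vector.
tempered_rows <- function(lp, ll, betas) {
  out <- lp + ifelse(betas > 0, betas * ll, 0)
  out[is.nan(out)] <- -Inf
  out
}
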