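#' Nested-sampling evidence quadrature
#'
#' Deterministic prior-volume shrinkage: the i-th discarded (dead) point is
#' assigned volume `X_i = exp(-i / N)` and shell width
#' `dX_i = X_{i-1} - X_i`, giving
#' `Z = sum(L_i dX_i) + mean(live L) * X_k` with the live-point remainder.
#' The information `H = sum(p_i log(L_i / Z))` (posterior weights
#' `p_i = L_i dX_i / Z`) sets the error bound `sqrt(H / N)`.
#'
#' @param log_lik_dead Log likelihoods of the dead points in non-decreasing
#'   order (the order in which nested sampling discards them).
#' @param n_live Number of live points `N` used during the run.
#' @param log_lik_live Optional log likelihoods of the final live set, used
#'   for the remainder term.
#' @return An [evidence_estimate()] (method `"ns"`) with attributes
#'   `log_weights` (normalized posterior log weights of the dead points) and
#'   `H`.
#' @export
ns_quadrature <- function(log_lik_dead, n_live, log_lik_live = NULL) {
  k <- length(log_lik_dead)
  if (k == 0) stop("empty dead-point set")
  if (is.unsorted(log_lik_dead))
    stop("dead-point log likelihoods must be non-decreasing")
  N <- as.integer(n_live)
  i <- seq_len(k)
  # log dX_i = log(e^{-(i-1)/N} - e^{-i/N}) = -(i-1)/N + log(1 - e^{-1/N})
  log_dX <- -(i - 1) / N + log1p(-exp(-1 / N))
  terms <- log_lik_dead + log_dX
  if (!is.null(log_lik_live) && length(log_lik_live)) {
    log_rem <- logsumexp(log_lik_live) - log(length(log_lik_live)) - k / N
    terms_all <- c(terms, log_rem)
  } else {
    terms_all <- terms
  }
  log_z <- logsumexp(terms_all)
  p <- exp(terms_all - log_z)
  ll_all <- c(log_lik_dead,
              if (!is.null(log_lik_live) && length(log_lik_live))
                logsumexp(log_lik_live) - log(length(log_lik_live)))
  H <- sum(ifelse(p > 0, p * (ll_all - log_z), 0))
  H <- max(H, 0)
  est <- evidence_estimate(log_z, sqrt(H / N), "ns")
  attr(est, "log_weights") <- terms - log_z
  attr(est, "H") <- H
  est
}

#' Likelihood-constrained MCMC replacement
#'
#' Draws a new point distributed as the prior truncated to
#' `log L > lstar` by a Gaussian random walk started from a uniformly chosen
#' live point: proposals are accepted with the prior-density MH ratio and
#' additionally required to satisfy the likelihood constraint. The step size
#' adapts multiplicatively toward roughly 50% acceptance.
#'
#' @param live Matrix of live-point positions (rows).
#' @param lstar Likelihood threshold (use `-Inf` for an unconstrained
#'   prior walk).
#' @param target A [make_target()] object.
#' @param n_steps Number of walk steps (default 20).
#' @param max_tries Total proposal budget before declaring a stuck plateau.
#' @return List with `theta`, `log_lik`, `log_prior`, `n_accepted`.
#' @export
replace_mcmc <- function(live, lstar, target, n_steps = 20L,
                         max_tries = 100L * n_steps) {
  N <- nrow(live); d <- ncol(live)
  S <- stats::cov(live)
  if (!all(is.finite(S))) S <- diag(1, d)
  R <- safe_chol((2.38^2 / d) * S + diag(1e-10, d))
  i0 <- sample.int(N, 1)
  theta <- live[i0, ]
  ev <- target_eval(target, theta)
  lp <- ev$log_prior; ll <- ev$log_lik
  scale <- 1
  n_acc <- 0L; tries <- 0L
  repeat {
    if (tries >= n_steps && n_acc > 0L) break
    if (tries >= max_tries)
      stop("constrained walk stuck: no acceptances within the proposal budget")
    tries <- tries + 1L
    prop <- theta + scale * drop(stats::rnorm(d) %*% R)
    lp_new <- log_prior(target$prior, prop)
    ok <- FALSE
    if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
      pe <- target_eval(target, prop)
      if (pe$log_lik > lstar) {
        theta <- prop; lp <- lp_new; ll <- pe$log_lik
        n_acc <- n_acc + 1L
        ok <- TRUE
      }
    }
    scale <- scale * if (ok) 1.1 else 0.95
    scale <- min(max(scale, 1e-4), 10)
  }
  list(theta = theta, log_lik = ll, log_prior = lp, n_accepted = n_acc)
}

#' Bounding ellipsoid of a point set
#'
#' Centre = sample mean; shape = sample covariance rescaled so that the
#' largest Mahalanobis distance equals 1, i.e. the smallest covariance-shaped
#' ellipsoid containing every point. The `enlargement` factor expands the
#' linear dimensions (volume scales as `enlargement^dim`).
#'
#' @param points Matrix of points (rows); needs more rows than columns.
#' @param enlargement Linear enlargement factor (default 1.1).
#' @return Object of class `ellipsoid` with fields `center`, `shape`,
#'   `enlargement`, `R` (upper Cholesky of `shape`) and `log_volume`.
#' @export
bounding_ellipsoid <- function(points, enlargement = 1.1) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n <= d) stop("need more points than dimensions")
  ctr <- colMeans(points)
  S <- stats::cov(points)
  R0 <- safe_chol(S, eps = max(1e-12, 1e-8 * mean(diag(S))))
  Z <- t(backsolve(R0, t(sweep(points, 2, ctr)), transpose = TRUE))
  max_d2 <- max(rowSums(Z^2))
  if (max_d2 == 0) max_d2 <- 1e-12
  shape <- crossprod(R0) * max_d2
  R <- R0 * sqrt(max_d2)
  log_ball <- (d / 2) * log(pi) - lgamma(d / 2 + 1)
  structure(list(center = ctr, shape = shape, enlargement = enlargement,
                 R = R,
                 log_volume = log_ball + sum(log(diag(R))) +
                   d * log(enlargement)),
            class = "ellipsoid")
}

# Squared Mahalanobis distance of rows of X to the ellipsoid shape.
ellipsoid_d2 <- function(e, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  Z <- t(backsolve(e$R, t(sweep(X, 2, e$center)), transpose = TRUE))
  rowSums(Z^2)
}

#' Does an ellipsoid contain the given point(s)?
#' @param e An [bounding_ellipsoid()] object.
#' @param X Point or matrix of points (rows).
#' @param tol Containment slack on the squared radius.
#' @return Logical vector.
#' @export
ellipsoid_contains <- function(e, X, tol = 1e-9) {
  ellipsoid_d2(e, X) <= e$enlargement^2 * (1 + tol)
}

#' Uniform draws from an ellipsoid
#'
#' Uniform direction times radius `U^(1/d)`, mapped through the shape
#' Cholesky factor and the enlargement.
#'
#' @param e An [bounding_ellipsoid()] object.
#' @param n Number of draws.
#' @return `n x d` matrix.
#' @export
sample_ellipsoid <- function(e, n = 1L) {
  d <- length(e$center)
  Z <- matrix(stats::rnorm(n * d), n, d)
  Z <- Z / sqrt(rowSums(Z^2)) * stats::runif(n)^(1 / d)
  sweep(e$enlargement * (Z %*% e$R), 2, e$center, "+")
}

#' Recursive multi-ellipsoid decomposition of the live set
#'
#' MultiNest-style partition. Points are split by 2-means followed by a few
#' rounds of Mahalanobis reassignment between the two child ellipsoids. A
#' split is kept when the children's total bounding-ellipsoid volume beats
#' the parent's (each volume floored at the cluster's share of
#' `target_volume / efficiency`), *or* — when a prior-volume estimate is
#' supplied — when the parent ellipsoid is more than twice its share of the
#' expected prior volume, which forces curved or elongated regions (e.g. the
#' shells' rings) to be approximated by chains of small ellipsoids even
#' though a single split barely reduces the volume. Recursion is
#' depth-capped, clusters below `d + 2` points are never split, and the
#' union always covers every point.
#'
#' @param points Matrix of live points (rows); needs at least `2 (d + 1)`.
#' @param target_volume Estimate of the *absolute* volume of the likelihood-
#'   constrained region (current prior-volume fraction `X` times the prior
#'   volume). Optional; enables the volume floor and forced splits.
#' @param efficiency Sampling-efficiency parameter (default 0.3).
#' @param enlargement Per-ellipsoid enlargement (default 1.1).
#' @param max_depth Recursion cap (default 10).
#' @return Object of class `ellipsoid_set`: a list of ellipsoids.
#' @export
multinest_partition <- function(points, target_volume = NULL,
                                efficiency = 0.3, enlargement = 1.1,
                                max_depth = 10L) {
  points <- as.matrix(points)
  d <- ncol(points)
  n_total <- nrow(points)
  if (n_total < 2 * (d + 1)) stop("too few points for a partition")

  log_share <- function(n_pts) {
    if (is.null(target_volume)) -Inf
    else log(target_volume * n_pts / n_total)
  }
  floored_volume <- function(e, n_pts)
    max(e$log_volume, log_share(n_pts) - log(efficiency))

  split_once <- function(pts) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(pts, centers = 2, nstart = 3)),
      error = function(e) NULL)
    if (is.null(km) || min(km$size) < d + 2) return(NULL)
    cl <- km$cluster
    for (iter in 1:3) {   # Mahalanobis reassignment refines curved clusters
      ch <- lapply(1:2, function(g) {
        p <- pts[cl == g, , drop = FALSE]
        if (nrow(p) < d + 2) NULL else bounding_ellipsoid(p, enlargement)
      })
      if (any(vapply(ch, is.null, TRUE))) return(NULL)
      d2 <- cbind(ellipsoid_d2(ch[[1]], pts), ellipsoid_d2(ch[[2]], pts))
      new_cl <- max.col(-d2)
      if (all(new_cl == cl)) break
      if (min(tabulate(new_cl, 2)) < d + 2) break
      cl <- new_cl
    }
    ch <- lapply(1:2, function(g)
      bounding_ellipsoid(pts[cl == g, , drop = FALSE], enlargement))
    list(cluster = cl, ellipsoids = ch, sizes = tabulate(cl, 2))
  }

  recurse <- function(pts, depth) {
    parent <- bounding_ellipsoid(pts, enlargement)
    if (depth >= max_depth || nrow(pts) < 2 * (d + 2))
      return(list(parent))
    sp <- split_once(pts)
    if (is.null(sp)) return(list(parent))
    v_children <- logsumexp(c(floored_volume(sp$ellipsoids[[1]], sp$sizes[1]),
                              floored_volume(sp$ellipsoids[[2]], sp$sizes[2])))
    improved <- v_children < floored_volume(parent, nrow(pts))
    forced <- !is.null(target_volume) &&
      parent$log_volume > log(2) + log_share(nrow(pts))
    if (improved || forced) {
      c(recurse(pts[sp$cluster == 1, , drop = FALSE], depth + 1L),
        recurse(pts[sp$cluster == 2, , drop = FALSE], depth + 1L))
    } else {
      list(parent)
    }
  }

  leaves <- recurse(points, 0L)
  # Inflate each leaf to at least its share of the expected prior volume:
  # point-fitted ellipsoids underestimate the true constrained region, and
  # sampling from an under-covering union biases the evidence upward.
  if (!is.null(target_volume)) {
    leaves <- lapply(leaves, function(e) {
      n_pts <- sum(ellipsoid_contains(e, points))
      want <- log_share(max(n_pts, d + 2L))
      if (e$log_volume < want) {
        e$enlargement <- e$enlargement * exp((want - e$log_volume) / d)
        e$log_volume <- want
      }
      e
    })
  }
  structure(leaves, class = "ellipsoid_set")
}

# Count, for each row of X, how many ellipsoids of the set contain it.
ellipsoid_set_membership <- function(es, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  counts <- integer(nrow(X))
  for (e in es) counts <- counts + ellipsoid_contains(e, X)
  counts
}

# Draw n candidate points uniformly from the union of an ellipsoid set:
# volume-weighted ellipsoid choice + 1/n_membership overlap correction.
# Returns the accepted candidate positions (may be fewer than n).
sample_union_batch <- function(es, n) {
  lv <- vapply(es, `[[`, 0, "log_volume")
  pv <- exp(lv - logsumexp(lv))
  which_e <- sample.int(length(es), n, replace = TRUE, prob = pv)
  d <- length(es[[1]]$center)
  X <- matrix(NA_real_, n, d)
  for (j in unique(which_e)) {
    rows <- which(which_e == j)
    X[rows, ] <- sample_ellipsoid(es[[j]], length(rows))
  }
  m <- ellipsoid_set_membership(es, X)
  X[stats::runif(n) < 1 / m, , drop = FALSE]
}

#' Draw a constrained replacement from a multi-ellipsoid decomposition
#'
#' Picks an ellipsoid with probability proportional to its volume, draws
#' uniformly inside it, accepts against the overlap with probability
#' `1 / (number of ellipsoids containing the draw)` — which makes the
#' accepted draws uniform on the union — and finally requires prior support
#' and `log L > lstar`. Exhausting the budget signals a collapsed acceptance
#' rate.
#'
#' @param es An [multinest_partition()] result.
#' @param lstar Likelihood threshold.
#' @param target A [make_target()] object.
#' @param max_tries Proposal budget (default 10000).
#' @return List with `theta`, `log_lik`, `log_prior`, `n_tries`.
#' @export
sample_ellipsoid_set <- function(es, lstar, target, max_tries = 10000L) {
  if (!length(es)) stop("empty ellipsoid set")
  tries <- 0L
  while (tries < max_tries) {
    X <- sample_union_batch(es, 32L)
    tries <- tries + 32L
    if (!nrow(X)) next
    ev <- target_eval_matrix(target, X)
    hit <- which(is.finite(ev$log_prior) & ev$log_lik > lstar)
    if (length(hit)) {
      i <- hit[1]
      return(list(theta = X[i, ], log_lik = ev$log_lik[i],
                  log_prior = ev$log_prior[i], n_tries = tries))
    }
  }
  stop("multi-ellipsoid sampling acceptance rate dropped to essentially zero")
}

nested_defaults <- function() {
  list(live_points = 1000L, variant = "multinest", termination_frac = 1e-3,
       efficiency = 0.3, enlargement = 1.1, steps = 20L, samples = 1000L,
       batch = 512L, workers = 1L)
}

#' Nested sampling run
#'
#' Initializes `live_points` draws from the prior, then repeatedly removes
#' the worst live point (recording it as a dead point with deterministic
#' prior-volume shell) and replaces it by a draw from the prior constrained
#' to exceed the removed likelihood, using one of three strategies:
#' `"mcmc"` ([replace_mcmc()]), `"ellipsoid"` (rejection from a single
#' bounding ellipsoid) or `"multinest"` (a multi-ellipsoid decomposition,
#' [multinest_partition()], rebuilt every `N/5` iterations or when the
#' acceptance rate halves). For the ellipsoid variants, candidate
#' replacements are generated in batches and unused candidates are cached
#' and re-validated against the current likelihood threshold in later
#' iterations. Terminates when the maximum possible remaining contribution
#' `max(live L) * X_k` falls below `termination_frac` times the accumulated
#' evidence. Evidence and error come from [ns_quadrature()]; posterior
#' samples are drawn from the dead points with weights `L_i dX_i / Z`.
#'
#' @param target A [make_target()] object.
#' @param cfg Named list overriding any of: `live_points`, `variant`
#'   (`"mcmc"`, `"ellipsoid"`, `"multinest"`), `termination_frac`,
#'   `efficiency`, `enlargement`, `steps` (MCMC variant), `samples`,
#'   `batch`, `workers`.
#' @param seed Integer seed.
#' @return A `run_result`.
#' @export
run_nested <- function(target, cfg = list(), seed = 1L) {
  cfg <- merge_config(cfg, nested_defaults(), "nested")
  variant <- match.arg(cfg$variant, c("mcmc", "ellipsoid", "multinest"))
  set.seed(seed)
  N <- as.integer(cfg$live_points)
  d <- target$prior$dimension
  Theta <- sample_prior(target$prior, N)
  ev <- target_eval_matrix(target, Theta)
  ll <- ev$log_lik; lp <- ev$log_prior
  if (all(!is.finite(ll)))
    stop("initialization failed: all live points have zero likelihood")

  max_iter <- 200L * N
  dead_ll <- dead_lp <- numeric(max_iter)
  dead_theta <- matrix(NA_real_, max_iter, d)
  cache <- NULL       # cached candidates: list(Theta, ll, lp)
  es <- NULL
  last_build <- -Inf
  draws_since_hit <- 0L
  cur_batch <- as.integer(cfg$batch)
  rebuild_every <- max(1L, N %/% 5L)
  # absolute constrained-region volume estimate for the partition floor,
  # available when every marginal prior is uniform (box prior)
  lpv <- prior_log_volume(target$prior)
  tv_abs <- function(it) if (is.na(lpv)) NULL else exp(-it / N + lpv)
  it <- 0L
  log_z <- -Inf

  repeat {
    it <- it + 1L
    if (it > max_iter) stop("nested sampling failed to terminate")
    w <- which.min(ll)
    lstar <- ll[w]
    log_dX <- -(it - 1) / N + log1p(-exp(-1 / N))
    log_z <- logsumexp(c(log_z, lstar + log_dX))
    dead_ll[it] <- lstar
    dead_lp[it] <- lp[w]
    dead_theta[it, ] <- Theta[w, ]

    # termination: largest possible remaining contribution is negligible
    if (max(ll) - it / N <= log(cfg$termination_frac) + log_z) break

    if (variant == "mcmc") {
      live_sub <- Theta[-w, , drop = FALSE]
      rep_pt <- replace_mcmc(live_sub, lstar, target, cfg$steps)
    } else {
      # drop cached candidates that no longer beat the threshold
      if (!is.null(cache)) {
        keep <- cache$ll > lstar
        cache <- if (any(keep))
          list(Theta = cache$Theta[keep, , drop = FALSE],
               ll = cache$ll[keep], lp = cache$lp[keep]) else NULL
      }
      rebuild <- is.null(es) || (it - last_build) >= rebuild_every ||
        draws_since_hit > 20L * cfg$batch
      if (rebuild) {
        es <- if (variant == "ellipsoid") {
          structure(list(bounding_ellipsoid(Theta, cfg$enlargement)),
                    class = "ellipsoid_set")
        } else {
          multinest_partition(Theta, target_volume = tv_abs(it),
                              efficiency = cfg$efficiency,
                              enlargement = cfg$enlargement)
        }
        last_build <- it
        draws_since_hit <- 0L
      }
      budget <- 0L
      while (is.null(cache) || !length(cache$ll)) {
        X <- sample_union_batch(es, cur_batch)
        budget <- budget + cur_batch
        draws_since_hit <- draws_since_hit + cur_batch
        if (budget > 500000L)
          stop(paste("replacement acceptance rate dropped to essentially",
                     "zero; the ellipsoidal decomposition cannot track the",
                     "constrained region at this dimensionality"))
        if (!nrow(X)) next
        cev <- target_eval_matrix(target, X)
        ok <- is.finite(cev$log_prior) & cev$log_lik > lstar
        if (any(ok)) {
          cache <- list(Theta = X[ok, , drop = FALSE],
                        ll = cev$log_lik[ok], lp = cev$log_prior[ok])
          draws_since_hit <- 0L
          # batch size tracks the acceptance rate so low-acceptance regimes
          # amortize the union-sampling overhead over many iterations
          cur_batch <- min(max(as.integer(cfg$batch),
                               as.integer(4 * cur_batch / max(sum(ok), 1))),
                           16384L)
        } else {
          cur_batch <- min(2L * cur_batch, 16384L)
        }
      }
      rep_pt <- list(theta = cache$Theta[1, ], log_lik = cache$ll[1],
                     log_prior = cache$lp[1])
      cache <- if (length(cache$ll) > 1)
        list(Theta = cache$Theta[-1, , drop = FALSE],
             ll = cache$ll[-1], lp = cache$lp[-1]) else NULL
    }

    Theta[w, ] <- rep_pt$theta
    ll[w] <- rep_pt$log_lik
    lp[w] <- rep_pt$log_prior
  }

  dead_ll <- dead_ll[seq_len(it)]
  dead_lp <- dead_lp[seq_len(it)]
  dead_theta <- dead_theta[seq_len(it), , drop = FALSE]

  est <- ns_quadrature(dead_ll, N, log_lik_live = ll)
  est$n_evals <- eval_count(target)

  lw <- attr(est, "log_weights")
  n_out <- min(cfg$samples, 10L * length(dead_ll))
  idx <- sample.int(length(dead_ll), n_out, replace = TRUE, prob = exp(lw))
  smp <- dead_theta[idx, , drop = FALSE]
  colnames(smp) <- target$prior$names
  samples <- as.data.frame(apply_transforms(target$prior, smp))
  samples$log_prior <- dead_lp[idx]
  samples$log_lik <- dead_ll[idx]

  run_result(samples = samples, evidence = est,
             settings = c(list(algorithm = "nested", seed = seed), cfg),
             diagnostics = list(iterations = it, H = attr(est, "H"),
                                dead_loglik = dead_ll,
                                n_ellipsoids = if (!is.null(es)) length(es)
                                               else NA_integer_))
}
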