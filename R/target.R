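#' Build a tempered posterior target from a prior and a likelihood plugin
#'
#' A target couples a [prior_spec()] with a user-supplied log-likelihood and
#' exposes the tempered log density
#' \deqn{\log \pi_\beta(\theta) = \log P(\theta) + \beta \log L(\theta),}
#' the contract shared by all three sampler families: \eqn{\beta = 0} is the
#' prior, \eqn{\beta = 1} the posterior. The data live inside the likelihood
#' closure.
#'
#' Evaluation order is guaranteed: the log prior is computed first and the
#' likelihood is *not* invoked outside the prior support. The target keeps a
#' monotone counter of likelihood evaluations, readable with [eval_count()].
#'
#' @param prior A [prior_spec()].
#' @param log_likelihood Function mapping a parameter vector to a finite
#'   number or `-Inf`. If `vectorized = TRUE` it must instead accept an
#'   `n x dimension` matrix and return `n` values, which the samplers exploit
#'   to evaluate whole populations in one call.
#' @param vectorized Does `log_likelihood` accept a matrix of parameter rows?
#' @param simulate Optional function `simulate(theta, times)` returning
#'   predicted observables, used for posterior predictive checks.
#' @return An object of class `tempered_target`.
#' @export
#' @examples
#' pr <- prior_spec(parameter_spec("x", "uniform", lower = 0, upper = 1))
#' tg <- make_target(pr, function(theta) 0)   # flat likelihood
#' target_eval(tg, 0.5)
make_target <- function(prior, log_likelihood, vectorized = FALSE,
                        simulate = NULL) {
  stopifnot(inherits(prior, "prior_spec"), is.function(log_likelihood))
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  structure(list(prior = prior, loglik = log_likelihood,
                 vectorized = isTRUE(vectorized), simulate = simulate,
                 counter = counter),
            class = "tempered_target")
}

#' Number of likelihood evaluations performed by a target
#' @param target A [make_target()] object.
#' @return Integer count; never decreases.
#' @export
eval_count <- function(target) target$counter$n

# Validate raw plugin output; NaN/NA/+Inf are plugin bugs, -Inf is a valid
# zero-likelihood sentinel.
check_loglik_values <- function(ll, Theta) {
  if (!is.numeric(ll) || length(ll) != nrow(Theta))
    stop("likelihood plugin returned a non-numeric or wrongly sized result")
  bad <- is.na(ll) | ll == Inf
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("likelihood plugin returned %s at theta = (%s)",
                 format(ll[i]),
                 paste(format(Theta[i, ], digits = 6), collapse = ", ")))
  }
  ll
}

#' Evaluate log prior and log likelihood at one parameter vector
#'
#' @param target A [make_target()] object.
#' @param theta Parameter vector.
#' @return List with `log_prior` and `log_lik`; `log_lik` is `-Inf` (and the
#'   likelihood plugin is not called) when `theta` is outside the prior
#'   support.
#' @export
target_eval <- function(target, theta) {
  ev <- target_eval_matrix(target, matrix(theta, nrow = 1))
  list(log_prior = ev$log_prior[1], log_lik = ev$log_lik[1])
}

# Population version: rows of Theta; likelihood called only on supported rows.
target_eval_matrix <- function(target, Theta) {
  lp <- log_prior_matrix(target$prior, Theta)
  ll <- rep(-Inf, nrow(Theta))
  ok <- is.finite(lp)
  if (any(ok)) {
    sub <- Theta[ok, , drop = FALSE]
    if (target$vectorized) {
      ll[ok] <- check_loglik_values(target$loglik(sub), sub)
    } else {
      vals <- vapply(seq_len(nrow(sub)), function(i) {
        v <- target$loglik(sub[i, ])
        if (!is.numeric(v) || length(v) != 1L) v <- NaN
        v
      }, 0)
      ll[ok] <- check_loglik_values(vals, sub)
    }
    target$counter$n <- target$counter$n + sum(ok)
  }
  list(log_prior = lp, log_lik = ll)
}

#' Tempered log density from cached components
#'
#' Combines cached log-prior and log-likelihood values at inverse temperature
#' `beta`, with the convention that `beta = 0` returns the log prior even when
#' the log likelihood is `-Inf` (so prior-only chains never see `NaN`).
#'
#' @param log_prior,log_lik Numeric vectors (may contain `-Inf`).
#' @param beta Inverse temperature in `[0, 1]`.
#' @return Vector of tempered log densities.
#' @export
tempered_logdens <- function(log_prior, log_lik, beta) {
  if (beta == 0) return(log_prior)
  out <- log_prior + beta * log_lik
  out[is.nan(out)] <- -Inf
  out
}

#' Evidence estimate container
#'
#' @param log_z Log marginal likelihood estimate.
#' @param error Symmetric error bound (`>= 0`).
#' @param method Short tag naming the estimator.
#' @param n_evals Number of likelihood evaluations spent.
#' @return Object of class `evidence_estimate`.
#' @export
evidence_estimate <- function(log_z, error, method, n_evals = NA_integer_) {
  stopifnot(is.numeric(log_z), length(log_z) == 1L)
  if (!is.na(error) && error < 0) stop("error bound must be >= 0")
  structure(list(log_z = log_z, error = error, method = method,
                 n_evals = n_evals),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("log Z = %.4f +/- %.4f  [%s, %s likelihood evaluations]\n",
              x$log_z, x$error, x$method,
              if (is.na(x$n_evals)) "?" else format(x$n_evals)))
  invisible(x)
}
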