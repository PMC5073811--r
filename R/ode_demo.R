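#' Define a kinetic ODE observation model
#'
#' A thin harness around a user right-hand side suitable for Bayesian
#' inference: states, rate-parameter names, initial conditions, and a map from
#' simulated states to observed quantities. Stiff or failing solves are
#' reported as failures (and mapped to zero likelihood by callers), never as
#' silent `NaN` trajectories.
#'
#' @param state_names Character vector of state names.
#' @param rate_names Character vector of rate-parameter names.
#' @param rhs Function `rhs(t, y, p)` returning `dy/dt` (deSolve convention:
#'   a list whose first element is the derivative vector).
#' @param y0 Named initial state.
#' @param observables Function mapping a state matrix (times x states) to an
#'   observable matrix (times x observables).
#' @param obs_names Names of the observables.
#' @return Object of class `ode_model`.
#' @export
ode_model <- function(state_names, rate_names, rhs, y0, observables,
                      obs_names) {
  stopifnot(is.function(rhs), is.function(observables),
            length(y0) == length(state_names))
  structure(list(state_names = state_names, rate_names = rate_names,
                 rhs = rhs, y0 = stats::setNames(y0, state_names),
                 observables = observables, obs_names = obs_names),
            class = "ode_model")
}

#' Simulate an ODE model over a time grid
#'
#' Integrates with [deSolve::ode()] (lsoda, switching automatically between
#' stiff and non-stiff methods). A failed or non-finite solve is returned as a
#' flagged result rather than an error, because stiff systems routinely fail
#' at extreme prior draws and a sampler must treat that draw as having zero
#' likelihood, not abort the run.
#'
#' @param model An [ode_model()].
#' @param theta Named rate-parameter vector.
#' @param times Strictly increasing time grid starting at 0.
#' @param y0 Optional initial-state override.
#' @param rtol,atol Solver tolerances.
#' @return List with `failed` (logical), `times`, `states` (times x states)
#'   and `observed` (times x observables; `NULL` when failed).
#' @export
#' @examples
#' m <- ode_model("x", "k", function(t, y, p) list(-p[["k"]] * y),
#'                y0 = 1, observables = function(Y) Y, obs_names = "x")
#' simulate_ode(m, c(k = 0.5), c(0, 1))$states[2, "x"]   # exp(-0.5)
simulate_ode <- function(model, theta, times, y0 = NULL,
                         rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(model, "ode_model"))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and start at 0")
  y0 <- y0 %||% model$y0
  out <- tryCatch(
    suppressWarnings(deSolve::ode(y = y0, times = times, parms = theta,
                                  func = model$rhs, rtol = rtol, atol = atol)),
    error = function(e) NULL)
  failed <- is.null(out) || nrow(out) < length(times) ||
    !all(is.finite(out[, -1, drop = FALSE]))
  if (failed)
    return(list(failed = TRUE, times = times, states = NULL, observed = NULL))
  states <- out[, -1, drop = FALSE]
  colnames(states) <- model$state_names
  obs <- model$observables(states)
  colnames(obs) <- model$obs_names
  list(failed = FALSE, times = times, states = states, observed = obs)
}

#' Bundled two-species reversible-conversion demo model
#'
#' A deliberately small kinetic system, A <-> B with forward rate `k1` and
#' backward rate `k2`, starting from `A = 1, B = 0`. Both species are
#' observed. The total `A + B` is conserved, which tests use as a solver
#' invariant. Rates are passed on the log10 scale (`lk1`, `lk2`), matching
#' the convention of order-of-magnitude uniform priors for kinetic constants.
#'
#' @return An [ode_model()].
#' @export
demo_ode_model <- function() {
  ode_model(
    state_names = c("A", "B"),
    rate_names = c("lk1", "lk2"),
    rhs = function(t, y, p) {
      k1 <- 10^p[["lk1"]]; k2 <- 10^p[["lk2"]]
      dA <- -k1 * y[1] + k2 * y[2]
      list(c(dA, -dA))
    },
    y0 = c(1, 0),
    observables = function(Y) Y,
    obs_names = c("A", "B"))
}

#' Data-generating settings of the bundled demo
#'
#' `demo_truth()` returns the log10 rates used to generate synthetic data
#' (`k1 = 1`, `k2 = 0.5`); `demo_times()` the six default observation times.
#' @return Named numeric vector / numeric vector.
#' @export
demo_truth <- function() c(lk1 = 0, lk2 = log10(0.5))

#' @rdname demo_truth
#' @export
demo_times <- function() c(0.25, 0.5, 1, 1.5, 2.5, 4)

#' Order-of-magnitude prior for the demo model
#'
#' Uniform priors on the log10 rates spanning one order of magnitude on
#' either side of the data-generating values.
#' @return A [prior_spec()].
#' @export
demo_prior <- function() {
  tr <- demo_truth()
  prior_spec(
    parameter_spec("lk1", "uniform", lower = tr[["lk1"]] - 1,
                   upper = tr[["lk1"]] + 1),
    parameter_spec("lk2", "uniform", lower = tr[["lk2"]] - 1,
                   upper = tr[["lk2"]] + 1))
}

#' Create an observation set
#'
#' Container for (possibly replicated) time-course observations with Gaussian
#' measurement noise of known standard deviation.
#'
#' @param times Observation times.
#' @param obs_names Observable names.
#' @param replicates Number of replicates.
#' @param values Numeric array `times x observables x replicates`.
#' @param noise_sd Measurement noise standard deviation.
#' @return Object of class `observation_set`.
#' @export
observation_set <- function(times, obs_names, replicates, values,
                            noise_sd = 0.05) {
  values <- array(values, dim = c(length(times), length(obs_names), replicates),
                  dimnames = list(NULL, obs_names, NULL))
  stopifnot(length(values) == length(times) * length(obs_names) * replicates,
            noise_sd >= 0)
  structure(list(times = times, obs_names = obs_names,
                 replicates = replicates, values = values,
                 noise_sd = noise_sd),
            class = "observation_set")
}

#' Generate a synthetic noisy time course from an ODE model
#'
#' Simulates the model at `theta_true`, samples every observable at each
#' observation time with the requested number of replicates, and adds i.i.d.
#' Gaussian noise. Defaults emulate a typical small biological data set: six
#' time points, two observables, three replicates (36 points), noise sd 0.05.
#'
#' @param model An [ode_model()] (default: the bundled demo).
#' @param theta_true Data-generating parameters (default: the demo truth).
#' @param seed Integer seed; fixed seed gives an identical data set.
#' @param times Observation times (6 by default).
#' @param replicates Replicates per time/observable (default 3).
#' @param noise_sd Noise standard deviation (default 0.05).
#' @return An [observation_set()].
#' @export
generate_timecourse <- function(model = demo_ode_model(),
                                theta_true = demo_truth(), seed = 1L,
                                times = demo_times(), replicates = 3L,
                                noise_sd = 0.05) {
  sim <- simulate_ode(model, theta_true, c(0, times))
  if (sim$failed) stop("simulation failed at theta_true")
  pred <- sim$observed[-1, , drop = FALSE]   # drop t = 0
  set.seed(seed)
  n_obs <- length(model$obs_names)
  vals <- array(rep(pred, replicates) +
                  stats::rnorm(length(times) * n_obs * replicates, 0, noise_sd),
                dim = c(length(times), n_obs, replicates))
  observation_set(times, model$obs_names, replicates, vals, noise_sd)
}

#' Gaussian observation log likelihood
#'
#' Sum over all data points of the log normal density of the observed value
#' around the simulated prediction with the observation-set noise sd.
#'
#' @param sim A non-failed result of [simulate_ode()] covering all
#'   observation times and observables.
#' @param obs An [observation_set()].
#' @return Log likelihood (a single number).
#' @export
gaussian_obs_loglik <- function(sim, obs) {
  stopifnot(inherits(obs, "observation_set"))
  if (sim$failed) stop("cannot score a failed simulation")
  idx <- match(obs$times, sim$times)
  if (anyNA(idx)) stop("simulation does not cover all observation times")
  jdx <- match(obs$obs_names, colnames(sim$observed))
  if (anyNA(jdx)) stop("simulation does not cover all observables")
  pred <- sim$observed[idx, jdx, drop = FALSE]
  sum(stats::dnorm(obs$values, mean = array(rep(pred, obs$replicates),
                                            dim = dim(obs$values)),
                   sd = obs$noise_sd, log = TRUE))
}

#' Tempered target for the bundled ODE demo
#'
#' Couples [demo_prior()] with the Gaussian observation likelihood of the
#' two-species demo. Failed solves map to log likelihood `-Inf` (the draw is
#' auto-rejected), never to an aborted run. The target carries a `simulate`
#' hook for posterior predictive checks.
#'
#' @param obs An [observation_set()], e.g. from [generate_timecourse()].
#' @return A [make_target()] object.
#' @export
demo_target <- function(obs) {
  model <- demo_ode_model()
  sim_times <- c(0, obs$times)
  make_target(
    demo_prior(),
    function(theta) {
      names(theta) <- model$rate_names
      sim <- simulate_ode(model, theta, sim_times)
      if (sim$failed) return(-Inf)
      gaussian_obs_loglik(sim, obs)
    },
    simulate = function(theta, times = sim_times) {
      names(theta) <- model$rate_names
      sim <- simulate_ode(model, theta, times)
      if (sim$failed) NULL else sim$observed
    })
}

#' Write / read observation sets as tab-delimited text
#'
#' Long format with columns `time`, `observable`, `replicate`, `value`, plus
#' a `# noise_sd` header line, so user data can replace synthetic data.
#'
#' @param obs An [observation_set()].
#' @param path File path.
#' @return `write_observations`: `path` invisibly; `read_observations`: an
#'   [observation_set()].
#' @export
write_observations <- function(obs, path) {
  df <- data.frame(
    time = rep(obs$times, times = length(obs$obs_names) * obs$replicates),
    observable = rep(rep(obs$obs_names, each = length(obs$times)),
                     times = obs$replicates),
    replicate = rep(seq_len(obs$replicates),
                    each = length(obs$times) * length(obs$obs_names)),
    value = as.vector(obs$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# noise_sd\t%.17g", obs$noise_sd), con)
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# noise_sd"))
    stop("missing '# noise_sd' header in ", path)
  noise_sd <- as.numeric(strsplit(hdr, "\t")[[1]][2])
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE)
  times <- sort(unique(df$time))
  obs_names <- unique(df$observable)
  reps <- max(df$replicate)
  vals <- array(NA_real_, dim = c(length(times), length(obs_names), reps))
  vals[cbind(match(df$time, times), match(df$observable, obs_names),
             df$replicate)] <- df$value
  if (anyNA(vals)) stop("incomplete observation table in ", path)
  observation_set(times, obs_names, reps, vals, noise_sd)
}
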