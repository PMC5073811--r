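#' Run result container
#'
#' Every sampler returns one of these: a posterior sample table (one column
#' per parameter on its reporting scale, plus `log_prior`, `log_lik` and an
#' optional `weight` column), an [evidence_estimate()], the settings used,
#' and per-algorithm diagnostics.
#'
#' @param samples Data frame of posterior samples.
#' @param evidence An [evidence_estimate()].
#' @param settings Named list echoing the run configuration.
#' @param diagnostics Named list of algorithm-specific diagnostics.
#' @return Object of class `run_result`.
#' @export
run_result <- function(samples, evidence, settings, diagnostics = list()) {
  stopifnot(is.data.frame(samples), inherits(evidence, "evidence_estimate"))
  if (!is.null(samples$weight)) {
    if (any(samples$weight < 0)) stop("weights must be >= 0")
    samples$weight <- samples$weight / sum(samples$weight)
  }
  structure(list(samples = samples, evidence = evidence,
                 settings = settings, diagnostics = diagnostics),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Run result: %d posterior samples, %d parameters\n",
              nrow(x$samples),
              ncol(x$samples) - sum(c("log_prior", "log_lik", "weight") %in%
                                      names(x$samples))))
  print(x$evidence)
  invisible(x)
}

#' Write / read a run result
#'
#' `write_run` stores the sample table as tab-delimited UTF-8 text
#' (`samples.tsv`, full `%.17g` precision so values round-trip bit-for-bit)
#' and a structured `summary.json` with the evidence estimate, settings and
#' scalar diagnostics. `read_run` inverts it.
#'
#' @param result A [run_result()].
#' @param dir Run directory (created if needed).
#' @return `write_run`: `dir` invisibly; `read_run`: a [run_result()].
#' @export
write_run <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- result$samples
  fmt <- vapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col),
    character(nrow(df)))
  utils::write.table(as.data.frame(fmt, stringsAsFactors = FALSE),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  keep_diag <- Filter(function(v) is.numeric(v) && length(v) < 1000,
                      result$diagnostics)
  jsonlite::write_json(
    list(evidence = list(log_z = result$evidence$log_z,
                         error = result$evidence$error,
                         method = result$evidence$method,
                         n_evals = result$evidence$n_evals),
         settings = result$settings, diagnostics = keep_diag),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  sf <- file.path(dir, "samples.tsv")
  jf <- file.path(dir, "summary.json")
  if (!file.exists(sf)) stop("missing sample table: ", sf)
  if (!file.exists(jf)) stop("missing summary file: ", jf)
  samples <- utils::read.table(sf, sep = "\t", header = TRUE,
                               colClasses = "numeric", check.names = FALSE)
  js <- jsonlite::read_json(jf, simplifyVector = TRUE)
  ev <- evidence_estimate(js$evidence$log_z, js$evidence$error,
                          js$evidence$method,
                          js$evidence$n_evals %||% NA_integer_)
  run_result(samples, ev, as.list(js$settings),
             as.list(js$diagnostics %||% list()))
}

#' Kernel density estimate with Sheather-Jones bandwidth
#'
#' Gaussian-kernel density on a regular grid with the Sheather-Jones
#' solve-the-equation bandwidth ([stats::bw.SJ()] with `method = "ste"`).
#' Weighted samples are supported through the `weights` argument of
#' [stats::density()] (the bandwidth is selected on the unweighted values).
#'
#' @param x Numeric sample (at least 10 distinct values).
#' @param weights Optional non-negative weights (normalized internally).
#' @param n Grid size (default 512).
#' @return List with `x` (grid), `y` (density, integrating to 1 within
#'   `1e-3`) and `bw`.
#' @export
kde_density <- function(x, weights = NULL, n = 512L) {
  if (length(unique(x)) < 10)
    stop("fewer than 10 distinct values; posterior looks degenerate")
  bw <- stats::bw.SJ(x, method = "ste")
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be >= 0")
    weights <- weights / sum(weights)
  }
  den <- stats::density(x, bw = bw, n = n, weights = weights, cut = 4)
  list(x = den$x, y = den$y, bw = bw)
}

#' Autocorrelation function of a chain
#'
#' Biased (divide-by-n) estimator, so `acf(0) = 1` exactly and the sequence
#' is positive semi-definite.
#'
#' @param chain Numeric vector; must be longer than `max_lag` and
#'   non-constant.
#' @param max_lag Largest lag.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorrelation <- function(chain, max_lag) {
  n <- length(chain)
  if (n <= max_lag) stop("chain shorter than max_lag")
  if (stats::sd(chain) == 0) stop("constant chain has undefined autocorrelation")
  drop(stats::acf(chain, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
}

#' Effective sample size from autocorrelation
#'
#' `n / (1 + 2 * sum(rho_k))`, truncating the sum at the first non-positive
#' autocorrelation (initial-positive-sequence rule), clamped to `[1, n]`.
#'
#' @param chain Numeric vector (non-constant).
#' @return Effective sample size.
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  rho <- autocorrelation(chain, max_lag = min(n - 1, max(50, floor(10 * sqrt(n)))))[-1]
  np <- which(rho <= 0)
  if (length(np)) rho <- rho[seq_len(np[1] - 1)]
  min(max(n / (1 + 2 * sum(rho)), 1), n)
}

#' Posterior predictive quantile bands
#'
#' Simulates (a subsample of) the posterior draws through the plugin's
#' `simulate` hook and reports per-time, per-observable weighted quantile
#' bands (2.5%, 50%, 97.5%) of the predicted observables. Simulation
#' failures are skipped and counted; if every simulation fails the call
#' errors.
#'
#' @param samples Posterior sample data frame (parameter columns first, as
#'   produced by the samplers); an optional `weight` column is honoured.
#' @param simulate Function `simulate(theta, times)` returning a
#'   `times x observables` matrix or `NULL` on failure.
#' @param times Time grid passed to `simulate`.
#' @param n_max Maximum number of draws to simulate (default 200).
#' @return List with `times`, one `lower`/`median`/`upper` matrix each
#'   (times x observables), and `n_failed`.
#' @export
posterior_predictive <- function(samples, simulate, times, n_max = 200L) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0, is.function(simulate))
  par_cols <- setdiff(names(samples), c("log_prior", "log_lik", "weight"))
  w <- samples$weight %||% rep(1 / nrow(samples), nrow(samples))
  idx <- if (nrow(samples) > n_max)
    sample.int(nrow(samples), n_max, replace = TRUE, prob = w)
  else seq_len(nrow(samples))
  sims <- list(); n_failed <- 0L
  for (i in idx) {
    out <- simulate(as.numeric(samples[i, par_cols]), times)
    if (is.null(out)) n_failed <- n_failed + 1L else sims[[length(sims) + 1]] <- out
  }
  if (!length(sims)) stop("all posterior simulations failed")
  arr <- array(unlist(sims), dim = c(nrow(sims[[1]]), ncol(sims[[1]]),
                                     length(sims)))   # times x obs x draws
  qs <- apply(arr, c(1, 2), stats::quantile, probs = c(0.025, 0.5, 0.975))
  list(times = times,
       lower = qs[1, , , drop = TRUE],
       median = qs[2, , , drop = TRUE],
       upper = qs[3, , , drop = TRUE],
       n_failed = n_failed)
}
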