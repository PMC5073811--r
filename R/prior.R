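#' Declare a single model parameter and its prior
#'
#' A parameter is described by its name, a marginal prior distribution and,
#' optionally, a reporting transform. The joint prior of a model is the
#' product of independent marginals (see [prior_spec()]).
#'
#' Supported distributions and their parameters:
#' \describe{
#'   \item{`uniform`}{`lower`, `upper` with `lower < upper`}
#'   \item{`normal`}{`mean`, `sd` with `sd > 0`}
#'   \item{`exponential`}{`rate > 0`}
#'   \item{`beta`}{`a`, `b`, both `> 0`}
#' }
#'
#' @param name Parameter name (unique within a [prior_spec()]).
#' @param distribution One of `"uniform"`, `"normal"`, `"exponential"`, `"beta"`.
#' @param ... Numeric distribution parameters, named as above.
#' @param transform `"none"` or `"log10"`; affects how samples are reported,
#'   never how the prior density is evaluated.
#' @return An object of class `parameter_spec`.
#' @export
#' @examples
#' parameter_spec("k1", "uniform", lower = -6, upper = 6)
parameter_spec <- function(name, distribution, ..., transform = "none") {
  params <- c(...)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("parameter name must be a non-empty string")
  distribution <- match.arg(distribution,
                            c("uniform", "normal", "exponential", "beta"))
  transform <- match.arg(transform, c("none", "log10"))
  required <- switch(distribution,
    uniform     = c("lower", "upper"),
    normal      = c("mean", "sd"),
    exponential = "rate",
    beta        = c("a", "b"))
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop(sprintf("parameter '%s': missing %s for %s prior",
                 name, paste(missing, collapse = ", "), distribution))
  params <- params[required]
  if (anyNA(params) || !all(is.finite(params)))
    stop(sprintf("parameter '%s': non-finite distribution parameters", name))
  ok <- switch(distribution,
    uniform     = params[["lower"]] < params[["upper"]],
    normal      = params[["sd"]] > 0,
    exponential = params[["rate"]] > 0,
    beta        = params[["a"]] > 0 && params[["b"]] > 0)
  if (!ok)
    stop(sprintf("parameter '%s': invalid parameters for %s prior",
                 name, distribution))
  structure(list(name = name, distribution = distribution,
                 params = params, transform = transform),
            class = "parameter_spec")
}

#' Joint prior specification
#'
#' Bundles an ordered list of [parameter_spec()] objects into the joint prior
#' of a model. The joint density is the product of the independent marginals;
#' parameter order defines the layout of every parameter vector seen by the
#' samplers.
#'
#' @param parameters List of `parameter_spec` objects (or several passed
#'   directly as `...`).
#' @return An object of class `prior_spec` with fields `parameters`,
#'   `dimension` and `names`.
#' @export
prior_spec <- function(parameters, ...) {
  if (inherits(parameters, "parameter_spec")) parameters <- list(parameters, ...)
  if (!length(parameters)) stop("a prior needs at least one parameter")
  if (!all(vapply(parameters, inherits, TRUE, "parameter_spec")))
    stop("all elements must be parameter_spec objects")
  nms <- vapply(parameters, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate parameter names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(list(parameters = parameters, dimension = length(parameters),
                 names = nms),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Prior over %d parameter(s):\n", x$dimension))
  for (p in x$parameters)
    cat(sprintf("  %-12s %s(%s)%s\n", p$name, p$distribution,
                paste(sprintf("%s=%g", names(p$params), p$params),
                      collapse = ", "),
                if (p$transform != "none") paste0(" [", p$transform, "]") else ""))
  invisible(x)
}

#' Read a prior specification from XML
#'
#' The file format is one `<parameter>` element per model parameter under any
#' root element, e.g.
#' \preformatted{
#' <prior>
#'   <parameter name="x1" distribution="uniform" lower="-6" upper="6"/>
#'   <parameter name="mu" distribution="normal" mean="0" sd="1" transform="log10"/>
#' </prior>
#' }
#' Distribution parameter attributes follow [parameter_spec()]. Document order
#' defines parameter order. Unknown distribution names and invalid parameters
#' are rejected with an error naming the offending parameter.
#'
#' @param path Path to an XML file.
#' @return A [prior_spec()].
#' @seealso [write_prior_xml()] for the inverse.
#' @export
parse_prior_xml <- function(path) {
  if (!file.exists(path)) stop("prior file not found: ", path)
  doc <- xml2::read_xml(path)   # malformed XML -> xml2 error naming the line
  nodes <- xml2::xml_find_all(doc, ".//parameter")
  if (!length(nodes)) stop("no <parameter> elements in ", path)
  specs <- lapply(nodes, function(nd) {
    at <- as.list(xml2::xml_attrs(nd))
    nm <- at$name %||% stop("a <parameter> element is missing its name attribute")
    dist <- at$distribution %||%
      stop(sprintf("parameter '%s': missing distribution attribute", nm))
    if (!dist %in% c("uniform", "normal", "exponential", "beta"))
      stop(sprintf("parameter '%s': unknown distribution '%s'", nm, dist))
    num <- at[setdiff(names(at), c("name", "distribution", "transform"))]
    vals <- suppressWarnings(vapply(num, as.numeric, 0))
    if (anyNA(vals))
      stop(sprintf("parameter '%s': non-numeric distribution attribute", nm))
    do.call(parameter_spec,
            c(list(name = nm, distribution = dist),
              as.list(vals), list(transform = at$transform %||% "none")))
  })
  prior_spec(specs)
}

#' Write a prior specification to XML
#'
#' Inverse of [parse_prior_xml()]: the written file parses back to an equal
#' `prior_spec`.
#'
#' @param prior A [prior_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prior_xml <- function(prior, path) {
  stopifnot(inherits(prior, "prior_spec"))
  doc <- xml2::xml_new_root("prior")
  for (p in prior$parameters) {
    attrs <- c(list(name = p$name, distribution = p$distribution),
               as.list(format(p$params, digits = 17)))
    if (p$transform != "none") attrs$transform <- p$transform
    do.call(xml2::xml_add_child, c(list(doc, "parameter"), attrs))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Joint log prior density
#'
#' Sum of the independent marginal log densities; `-Inf` outside the support.
#' `-Inf` (never `NaN`) is the package-wide sentinel for zero density, which
#' every sampler treats as an automatic rejection.
#'
#' @param prior A [prior_spec()].
#' @param theta Numeric parameter vector of length `prior$dimension`.
#' @return A single number, possibly `-Inf`.
#' @export
#' @examples
#' pr <- prior_spec(parameter_spec("x", "uniform", lower = -6, upper = 6),
#'                  parameter_spec("y", "uniform", lower = -6, upper = 6))
#' log_prior(pr, c(0, 0))   # -log(144)
log_prior <- function(prior, theta) {
  stopifnot(inherits(prior, "prior_spec"))
  if (length(theta) != prior$dimension)
    stop(sprintf("theta has length %d but the prior has dimension %d",
                 length(theta), prior$dimension))
  drop(log_prior_matrix(prior, matrix(theta, nrow = 1)))
}

# Vectorized joint log prior over rows of Theta (n x dimension).
log_prior_matrix <- function(prior, Theta) {
  stopifnot(ncol(Theta) == prior$dimension)
  lp <- numeric(nrow(Theta))
  for (j in seq_len(prior$dimension)) {
    p <- prior$parameters[[j]]
    x <- Theta[, j]
    lp <- lp + switch(p$distribution,
      uniform     = stats::dunif(x, p$params[["lower"]], p$params[["upper"]], log = TRUE),
      normal      = stats::dnorm(x, p$params[["mean"]], p$params[["sd"]], log = TRUE),
      exponential = stats::dexp(x, p$params[["rate"]], log = TRUE),
      beta        = stats::dbeta(x, p$params[["a"]], p$params[["b"]], log = TRUE))
  }
  lp[is.nan(lp)] <- -Inf
  lp
}

#' Draw i.i.d. samples from the joint prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x dimension` matrix with parameter names as column names.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  Theta <- matrix(0, n, prior$dimension,
                  dimnames = list(NULL, prior$names))
  for (j in seq_len(prior$dimension)) {
    p <- prior$parameters[[j]]
    Theta[, j] <- switch(p$distribution,
      uniform     = stats::runif(n, p$params[["lower"]], p$params[["upper"]]),
      normal      = stats::rnorm(n, p$params[["mean"]], p$params[["sd"]]),
      exponential = stats::rexp(n, p$params[["rate"]]),
      beta        = stats::rbeta(n, p$params[["a"]], p$params[["b"]]))
  }
  Theta
}

# Log volume of the prior support box; NA unless every marginal is uniform.
prior_log_volume <- function(prior) {
  if (!all(vapply(prior$parameters, `[[`, "", "distribution") == "uniform"))
    return(NA_real_)
  sum(vapply(prior$parameters, function(p)
    log(p$params[["upper"]] - p$params[["lower"]]), 0))
}

# Apply reporting transforms to a sample matrix (log10 columns renamed).
apply_transforms <- function(prior, Theta) {
  for (j in seq_len(prior$dimension)) {
    p <- prior$parameters[[j]]
    if (p$transform == "log10") {
      Theta[, j] <- log10(Theta[, j])
      colnames(Theta)[j] <- paste0("log10_", p$name)
    }
  }
  Theta
}
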