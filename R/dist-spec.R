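#' Declarative univariate distribution specification
#'
#' A `dist_spec` describes a prior distribution for a single model quantity.
#' Five families cover all elicited priors used in the investment model:
#' degenerate point masses, uniform intervals (the usual encoding of expert
#' bounds), Normal (e.g. targeted-beneficiary pools), Beta with an optional
#' linear rescaling of its support (adoption fractions), and finite discrete
#' distributions.
#'
#' @param family One of `"point"`, `"uniform"`, `"normal"`, `"beta"`,
#'   `"discrete"`.
#' @param ... Family parameters: `value` (point); `low`, `high` (uniform);
#'   `mean`, `sd` (normal); `alpha`, `beta` and optionally `low`, `high`
#'   (beta, rescaled from `[0, 1]` to `[low, high]`); `values`, `probs`
#'   (discrete).
#' @param units Free-text unit tag (e.g. `"USD"`, `"fraction"`,
#'   `"t CO2-eq"`). Informational only.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("normal", mean = 224000, sd = 24071, units = "persons")
#' dist_spec("uniform", low = 0.2, high = 1, units = "fraction")
#' @export
dist_spec <- function(family = c("point", "uniform", "normal", "beta", "discrete"),
                      ..., units = "") {
  family <- match.arg(family)
  params <- list(...)
  d <- structure(list(family = family, params = params, units = units),
                 class = "dist_spec")
  bad <- validate_dist_spec(d)
  if (length(bad) > 0L)
    stop("invalid dist_spec: ", paste(bad, collapse = "; "), call. = FALSE)
  d
}

#' @rdname dist_spec
#' @param x Object to test or print.
#' @export
is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Validate a distribution specification
#'
#' Checks the family invariants: `sd > 0` (normal), `low < high` (uniform and
#' rescaled beta), `alpha, beta > 0` (beta), discrete probabilities in
#' `[0, 1]` summing to 1 within `1e-9`.
#'
#' @param d A [dist_spec()].
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_dist_spec <- function(d) {
  p <- d$params
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  out <- character()
  switch(d$family,
    point = {
      if (!num1(p$value)) out <- c(out, "point: 'value' must be a finite number")
    },
    uniform = {
      if (!num1(p$low) || !num1(p$high)) out <- c(out, "uniform: 'low' and 'high' must be finite numbers")
      else if (!(p$low < p$high)) out <- c(out, "uniform: requires low < high")
    },
    normal = {
      if (!num1(p$mean) || !num1(p$sd)) out <- c(out, "normal: 'mean' and 'sd' must be finite numbers")
      else if (!(p$sd > 0)) out <- c(out, "normal: requires sd > 0")
    },
    beta = {
      if (!num1(p$alpha) || !num1(p$beta)) out <- c(out, "beta: 'alpha' and 'beta' must be finite numbers")
      else if (!(p$alpha > 0 && p$beta > 0)) out <- c(out, "beta: requires alpha > 0 and beta > 0")
      if (!is.null(p$low) || !is.null(p$high)) {
        if (!num1(p$low) || !num1(p$high)) out <- c(out, "beta: scale bounds 'low'/'high' must both be finite numbers")
        else if (!(p$low < p$high)) out <- c(out, "beta: requires scale low < high")
      }
    },
    discrete = {
      v <- p$values; pr <- p$probs
      if (!is.numeric(v) || length(v) == 0L || !is.numeric(pr) || length(pr) != length(v)) {
        out <- c(out, "discrete: 'values' and 'probs' must be numeric vectors of equal positive length")
      } else {
        if (any(pr < 0 | pr > 1)) out <- c(out, "discrete: probabilities must lie in [0, 1]")
        if (abs(sum(pr) - 1) > 1e-9) out <- c(out, "discrete: probabilities must sum to 1 within 1e-9")
      }
    }
  )
  out
}

#' Draw from a distribution specification
#'
#' Samples `n` independent values using the current R random-number stream.
#'
#' @param d A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(d, n = 1L) {
  p <- d$params
  switch(d$family,
    point = rep.int(p$value, n),
    uniform = stats::runif(n, p$low, p$high),
    normal = stats::rnorm(n, p$mean, p$sd),
    beta = {
      x <- stats::rbeta(n, p$alpha, p$beta)
      if (!is.null(p$low)) p$low + (p$high - p$low) * x else x
    },
    discrete = p$values[sample.int(length(p$values), n, replace = TRUE, prob = p$probs)]
  )
}

#' Expectation of a distribution specification
#'
#' @param d A [dist_spec()].
#' @return The mean of the distribution.
#' @export
dist_mean <- function(d) {
  p <- d$params
  switch(d$family,
    point = p$value,
    uniform = (p$low + p$high) / 2,
    normal = p$mean,
    beta = {
      m <- p$alpha / (p$alpha + p$beta)
      if (!is.null(p$low)) p$low + (p$high - p$low) * m else m
    },
    discrete = sum(p$values * p$probs)
  )
}

#' Support bounds of a distribution specification
#'
#' @param d A [dist_spec()].
#' @return Numeric `c(lower, upper)`; infinite for the Normal family.
#' @export
dist_support <- function(d) {
  p <- d$params
  switch(d$family,
    point = c(p$value, p$value),
    uniform = c(p$low, p$high),
    normal = c(-Inf, Inf),
    beta = if (!is.null(p$low)) c(p$low, p$high) else c(0, 1),
    discrete = range(p$values)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- x$params
  desc <- switch(x$family,
    point = sprintf("point(%g)", p$value),
    uniform = sprintf("uniform(%g, %g)", p$low, p$high),
    normal = sprintf("normal(mean = %g, sd = %g)", p$mean, p$sd),
    beta = if (!is.null(p$low))
      sprintf("beta(%g, %g) scaled to [%g, %g]", p$alpha, p$beta, p$low, p$high)
    else sprintf("beta(%g, %g)", p$alpha, p$beta),
    discrete = sprintf("discrete(%s)", paste(sprintf("%g:%g", p$values, p$probs), collapse = ", "))
  )
  cat("<dist_spec> ", desc, if (nzchar(x$units)) paste0(" [", x$units, "]"), "\n", sep = "")
  invisible(x)
}

# equality helper used by round-trip checks (numeric fields compared exactly
# up to double formatting; 1e-12 relative tolerance)
dist_equal <- function(a, b, tol = 1e-12) {
  if (!is_dist_spec(a) || !is_dist_spec(b)) return(FALSE)
  if (a$family != b$family || !identical(a$units, b$units)) return(FALSE)
  na <- sort(names(a$params)); nb <- sort(names(b$params))
  if (!identical(na, nb)) return(FALSE)
  for (k in na) {
    if (!isTRUE(all.equal(a$params[[k]], b$params[[k]], tolerance = tol))) return(FALSE)
  }
  TRUE
}
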