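#' Fit a Normal prior from two elicited percentiles
#'
#' Expert elicitation often yields a pessimistic and an optimistic estimate
#' interpreted as low and high percentiles (typically the 1st and 99th) of
#' the quantity. The two conditions `P(X <= low_value) = p_low` and
#' `P(X <= high_value) = p_high` identify a Normal distribution in closed
#' form.
#'
#' @param low_value,high_value The elicited values, `low_value < high_value`.
#' @param p_low,p_high The percentile levels, `0 < p_low < p_high < 1`.
#' @param units Optional unit tag for the returned spec.
#' @return A Normal [dist_spec()] whose CDF passes through both
#'   (value, probability) pairs to machine precision.
#' @examples
#' # a beneficiary pool with 1st/99th percentiles 168,000 / 280,000:
#' fit_normal_from_percentiles(168000, 280000, 0.01, 0.99)
#' @export
fit_normal_from_percentiles <- function(low_value, high_value, p_low = 0.01,
                                        p_high = 0.99, units = "") {
  if (!(low_value < high_value))
    stop("low_value must be strictly less than high_value", call. = FALSE)
  if (!(p_low > 0 && p_high < 1 && p_low < p_high))
    stop("percentile levels must satisfy 0 < p_low < p_high < 1", call. = FALSE)
  z1 <- stats::qnorm(p_low)
  z2 <- stats::qnorm(p_high)
  sd <- (high_value - low_value) / (z2 - z1)
  mean <- low_value - z1 * sd
  dist_spec("normal", mean = mean, sd = sd, units = units)
}

#' Fit a Beta prior from two elicited percentiles
#'
#' Identifies shape parameters `alpha`, `beta` such that the Beta CDF passes
#' through `(low_value, p_low)` and `(high_value, p_high)`. The two-equation
#' system has no closed form; it is solved numerically (BFGS on log-shape
#' parameters from a moment-matched Normal start) to a residual below
#' `1e-6` in probability.
#'
#' @inheritParams fit_normal_from_percentiles
#' @param low_value,high_value Elicited fractions,
#'   `0 <= low_value < high_value <= 1`.
#' @return A Beta [dist_spec()].
#' @examples
#' fit_beta_from_percentiles(0.05, 0.15, 0.01, 0.99)
#' @export
fit_beta_from_percentiles <- function(low_value, high_value, p_low = 0.01,
                                      p_high = 0.99, units = "") {
  if (!(low_value >= 0 && high_value <= 1 && low_value < high_value))
    stop("values must satisfy 0 <= low_value < high_value <= 1", call. = FALSE)
  if (!(p_low > 0 && p_high < 1 && p_low < p_high))
    stop("percentile levels must satisfy 0 < p_low < p_high < 1", call. = FALSE)
  target <- c(p_low, p_high)
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    r <- stats::pbeta(c(low_value, high_value), a, b) - target
    sum(r^2)
  }
  # moment-matched start: treat the percentile pair as a Normal, convert to
  # Beta shapes; fall back to a flat start when outside the feasible region
  z1 <- stats::qnorm(p_low); z2 <- stats::qnorm(p_high)
  s <- (high_value - low_value) / (z2 - z1)
  m <- min(max(low_value - z1 * s, 1e-4), 1 - 1e-4)
  v <- s^2
  k <- m * (1 - m) / v - 1
  start <- if (is.finite(k) && k > 0) log(c(m * k, (1 - m) * k)) else c(0, 0)
  resid <- function(par)
    stats::pbeta(c(low_value, high_value), exp(par[1]), exp(par[2])) - target
  newton_polish <- function(par) {
    for (it in 1:40) {
      r <- resid(par)
      if (max(abs(r)) < 1e-12) break
      h <- 1e-6
      J <- cbind((resid(par + c(h, 0)) - r) / h,
                 (resid(par + c(0, h)) - r) / h)
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      # damped update; keeps log-parameters finite
      step <- pmin(pmax(step, -2), 2)
      par <- par - step
    }
    par
  }
  best <- NULL
  for (st in list(start, c(0, 0), c(2, 2))) {
    fit <- tryCatch(stats::optim(st, obj, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-16)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    par <- newton_polish(fit$par)
    val <- max(abs(resid(par)))
    if (is.null(best) || val < best$val) best <- list(par = par, val = val)
  }
  if (is.null(best) || best$val > 1e-6) {
    res <- if (is.null(best)) NA_real_ else resid(best$par)
    stop("beta percentile fit did not converge; residuals: ",
         paste(format(res, digits = 4), collapse = ", "), call. = FALSE)
  }
  dist_spec("beta", alpha = exp(best$par[1]), beta = exp(best$par[2]), units = units)
}

#' Annual event probability from a historical frequency
#'
#' Converts an observed count of events over a span of years to an annual
#' occurrence probability, `min(count / years, 1)`. This is the rule used
#' for hazard likelihoods derived from historical records (e.g. one drought
#' per decade gives a 10% annual chance).
#'
#' @param event_count Number of events observed (non-negative).
#' @param span_years Length of the observation window in years (positive).
#' @return A probability in `[0, 1]`.
#' @examples
#' annual_prob_from_frequency(1, 10)  # 0.1
#' annual_prob_from_frequency(5, 100) # 0.05
#' @export
annual_prob_from_frequency <- function(event_count, span_years) {
  if (!is.numeric(event_count) || event_count < 0)
    stop("event_count must be non-negative", call. = FALSE)
  if (!is.numeric(span_years) || span_years <= 0)
    stop("span_years must be positive", call. = FALSE)
  min(event_count / span_years, 1)
}

#' Linear indicator scale
#'
#' Governance-style indicator scores (e.g. political stability or social
#' conflict indices) are converted to event probabilities by a linear scale
#' anchored at a score mapped to certainty (probability 1) and a score
#' mapped to impossibility (probability 0).
#'
#' @param score_at_certain Score mapped to probability 1.
#' @param score_at_impossible Score mapped to probability 0 (must differ).
#' @return An object of class `indicator_scale`.
#' @export
indicator_scale <- function(score_at_certain, score_at_impossible) {
  if (score_at_certain == score_at_impossible)
    stop("indicator scale anchors must differ", call. = FALSE)
  structure(list(score_at_certain = score_at_certain,
                 score_at_impossible = score_at_impossible),
            class = "indicator_scale")
}

#' Convert an indicator score to an event probability
#'
#' Applies the linear scale to a score summary: the mean maps affinely
#' between the anchors and is clamped to `[0, 1]` (scores can fall outside
#' the anchor range); the standard deviation maps by the absolute slope of
#' the scale.
#'
#' @param score_mean Mean indicator score.
#' @param score_sd Standard deviation of the score (`>= 0`); use 0 for a
#'   single score.
#' @param scale An [indicator_scale()].
#' @return A list with elements `mean` (clamped probability) and `sd`.
#' @examples
#' # a political-stability score of -3 on a scale where -3 is certain
#' # instability and 2 is none:
#' prob_from_indicator_scale(-3, 0, indicator_scale(-3, 2))
#' @export
prob_from_indicator_scale <- function(score_mean, score_sd = 0, scale) {
  if (!inherits(scale, "indicator_scale"))
    stop("'scale' must be an indicator_scale", call. = FALSE)
  if (score_sd < 0) stop("score_sd must be >= 0", call. = FALSE)
  span <- scale$score_at_impossible - scale$score_at_certain
  p <- (scale$score_at_impossible - score_mean) / span
  list(mean = min(max(p, 0), 1), sd = score_sd * abs(1 / span))
}

#' Count drought events in a monthly rainfall series
#'
#' Computes rolling 12-month rainfall totals, standardizes them against
#' their own long-term mean and standard deviation (a z-score reading of
#' the 12-month standardized precipitation index), and counts drought
#' events. An event opens in a month where the index falls below -1 and
#' closes when the index returns to at least 0 (average conditions);
#' consecutive months below the threshold belong to the same event, and an
#' event still open at the end of the series counts once.
#'
#' Note this is a z-score index, not the gamma-distribution-fitted SPI of
#' the climatological literature; it identifies periods more than one
#' standard deviation drier than the long-term average.
#'
#' @param monthly_rainfall Ordered numeric vector of monthly rainfall
#'   totals, length at least 24.
#' @return Integer count of drought events.
#' @export
count_drought_events <- function(monthly_rainfall) {
  x <- as.numeric(monthly_rainfall)
  if (length(x) < 24L)
    stop("need at least 24 months of rainfall to compute a 12-month index", call. = FALSE)
  if (anyNA(x)) stop("rainfall series contains missing values", call. = FALSE)
  r12 <- stats::filter(x, rep(1, 12), sides = 1)
  r12 <- as.numeric(r12[!is.na(r12)])
  s <- stats::sd(r12)
  if (!is.finite(s) || s == 0)
    stop("rainfall series has zero variance; index undefined", call. = FALSE)
  z <- (r12 - mean(r12)) / s
  events <- 0L
  open <- FALSE
  for (zi in z) {
    if (!open && zi < -1) {
      open <- TRUE
      events <- events + 1L
    } else if (open && zi >= 0) {
      open <- FALSE
    }
  }
  events
}

#' Combine several likelihood estimates into one prior
#'
#' When independent lines of evidence give different annual probabilities
#' for the same hazard (e.g. a long-run historical rate and a recent-period
#' rate), they can be combined either as their arithmetic mean (a point
#' prior) or as a uniform distribution spanning their range (retaining the
#' disagreement as uncertainty; its expectation is the midpoint).
#'
#' @param values Numeric vector of probabilities in `[0, 1]`.
#' @param method `"mean"` or `"uniform_interval"`.
#' @return A [dist_spec()]: a point mass for `"mean"` (and for a single or
#'   constant input), otherwise a uniform over `[min, max]`.
#' @examples
#' combine_likelihood_estimates(c(0.05, 0.25), "mean")             # point at 0.15
#' combine_likelihood_estimates(c(0.05, 0.25), "uniform_interval") # uniform(0.05, 0.25)
#' @export
combine_likelihood_estimates <- function(values, method = c("mean", "uniform_interval")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("no likelihood estimates given", call. = FALSE)
  if (any(values < 0 | values > 1)) stop("likelihoods must lie in [0, 1]", call. = FALSE)
  if (method == "mean" || min(values) == max(values))
    dist_spec("point", value = mean(values), units = "probability")
  else
    dist_spec("uniform", low = min(values), high = max(values), units = "probability")
}

#' Effect estimate with uncertainty
#'
#' A published or elicited effect size (e.g. percent yield change of a
#' practice) together with the standard error of the estimate.
#'
#' @param mean Effect estimate.
#' @param sd Standard error of the estimate (`> 0`).
#' @param label Free-text label (practice, crop, source).
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(mean, sd, label = "") {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  structure(list(mean = mean, sd = sd, label = label), class = "effect_estimate")
}

#' Pool effect estimates by meta-analysis
#'
#' Combines several [effect_estimate()]s into one by inverse-variance
#' weighting: `"fixed"` uses the fixed-effect model, `"random"` (the
#' default, appropriate when estimates are heterogeneous) adds the
#' DerSimonian-Laird moment estimate of between-study variance to the
#' weights. The computation is delegated to [metafor::rma()].
#'
#' @param estimates List of [effect_estimate()]s (at least one).
#' @param model `"random"` or `"fixed"`.
#' @return An [effect_estimate()] with the pooled mean and pooled standard
#'   error.
#' @export
pool_effect_estimates <- function(estimates, model = c("random", "fixed")) {
  model <- match.arg(model)
  if (length(estimates) == 0L) stop("no effect estimates given", call. = FALSE)
  if (!all(vapply(estimates, inherits, logical(1), "effect_estimate")))
    stop("estimates must be effect_estimate objects", call. = FALSE)
  if (length(estimates) == 1L) return(estimates[[1]])
  yi <- vapply(estimates, function(e) e$mean, numeric(1))
  sei <- vapply(estimates, function(e) e$sd, numeric(1))
  fit <- metafor::rma(yi = yi, sei = sei,
                      method = if (model == "fixed") "FE" else "DL")
  effect_estimate(mean = as.numeric(fit$b), sd = fit$se,
                  label = sprintf("pooled (%s-effects, k = %d)", model, length(estimates)))
}

#' Derive absolute adopter income from a relative impact
#'
#' When evidence gives the relative income impact of a project (a
#' dimensionless multiplier) rather than an absolute post-adoption income,
#' the adopter income is realized at simulation time as the product of
#' independent draws of the baseline income and the multiplier. This helper
#' returns the descriptor that instructs the engine to do so; for
#' independent inputs the expectation of the product is the product of the
#' expectations.
#'
#' @param baseline [dist_spec()] of the baseline income.
#' @param relative_impact [dist_spec()] of the dimensionless multiplier.
#' @return An object of class `income_product` with a `mean` field and a
#'   draw function; [impact_spec()] with `relative_impact` set uses exactly
#'   this realization.
#' @export
relative_to_absolute_income <- function(baseline, relative_impact) {
  for (d in list(baseline, relative_impact)) {
    if (!is_dist_spec(d) || length(validate_dist_spec(d)) > 0L)
      stop("both inputs must be valid dist_spec objects", call. = FALSE)
  }
  structure(list(baseline = baseline, relative = relative_impact,
                 mean = dist_mean(baseline) * dist_mean(relative_impact),
                 sample = function(n = 1L)
                   dist_sample(baseline, n) * dist_sample(relative_impact, n)),
            class = "income_product")
}

#' @export
print.income_product <- function(x, ...) {
  cat("<income_product> baseline x relative impact; mean", x$mean, "\n")
  invisible(x)
}
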