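## weighted summary helpers --------------------------------------------------

# normalized weights for a simulation result (NULL means uniform)
sim_weights <- function(result) {
  if (is.null(result$weights)) rep(1 / result$n, result$n)
  else result$weights / sum(result$weights)
}

wmean <- function(x, w, na.rm = FALSE) {
  if (na.rm) {
    ok <- !is.na(x)
    x <- x[ok]; w <- w[ok] / sum(w[ok])
  }
  sum(w * x)
}

# weighted sample SD with a Bessel-type correction; reduces to sd() for
# uniform weights, NA for a single draw
wsd <- function(x, w, na.rm = FALSE) {
  if (na.rm) {
    ok <- !is.na(x)
    x <- x[ok]; w <- w[ok]
  }
  if (length(x) < 2L) return(NA_real_)
  w <- w / sum(w)
  mu <- sum(w * x)
  v2 <- sum(w^2)
  sqrt(sum(w * (x - mu)^2) / (1 - v2))
}

# weighted lower quantile (inverse of the weighted empirical CDF); equals
# type-1 quantiles for uniform weights
wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

## summary -------------------------------------------------------------------

#' Summarize a simulation result
#'
#' Computes the scenario-level report: weighted mean and sample standard
#' deviation of NPV and ROI, the probability of a positive NPV, and NPV
#' quantiles. With a single draw the standard deviations are reported as
#' `NA`. Draws with undefined ROI (zero cost denominator) are excluded from
#' the ROI statistics.
#'
#' @param object An `ebis_sim` from [simulate_project()].
#' @param quantile_levels Quantile levels for the NPV distribution.
#' @param ... Unused.
#' @return An object of class `ebis_summary` with fields `scenario_name`,
#'   `npv_mean`, `npv_sd`, `roi_mean`, `roi_sd`, `prob_positive_npv`,
#'   `quantiles`, `n`, `seed`.
#' @export
summary.ebis_sim <- function(object,
                             quantile_levels = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99),
                             ...) {
  w <- sim_weights(object)
  npv <- object$draws$npv
  roi <- object$draws$roi
  q <- wquantile(npv, w, quantile_levels)
  names(q) <- as.character(quantile_levels)
  structure(list(
    scenario_name = object$scenario_name,
    npv_mean = wmean(npv, w),
    npv_sd = wsd(npv, w),
    roi_mean = wmean(roi, w, na.rm = TRUE),
    roi_sd = wsd(roi, w, na.rm = TRUE),
    prob_positive_npv = sum(w[npv > 0]),
    quantiles = q,
    n = object$n, seed = object$seed
  ), class = "ebis_summary")
}

#' @export
print.ebis_summary <- function(x, ...) {
  fmt_m <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v / 1e6)
  cat("Scenario: ", x$scenario_name, "  (n = ", x$n, ", seed = ", x$seed, ")\n", sep = "")
  cat("  NPV  (m$): ", fmt_m(x$npv_mean), " +/- ", fmt_m(x$npv_sd), "\n", sep = "")
  cat("  ROI   (%): ",
      if (is.na(x$roi_mean)) "NA" else sprintf("%.0f", 100 * x$roi_mean), " +/- ",
      if (is.na(x$roi_sd)) "NA" else sprintf("%.0f", 100 * x$roi_sd), "\n", sep = "")
  cat("  P(NPV > 0): ", sprintf("%.2f", x$prob_positive_npv), "\n", sep = "")
  invisible(x)
}

#' @export
print.ebis_sim <- function(x, ...) {
  cat("<ebis_sim> ", x$n, " draws, scenario '", x$scenario_name,
      "', seed ", x$seed, "\n", sep = "")
  if (x$n_clamped > 0)
    cat("  note: ", x$n_clamped, " negative sample(s) clamped to zero\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' @export
quantile.ebis_sim <- function(x, probs = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99), ...) {
  q <- wquantile(x$draws$npv, sim_weights(x), probs)
  names(q) <- as.character(probs)
  q
}

#' @export
as.data.frame.ebis_sim <- function(x, ...) x$draws

#' Histogram of the simulated NPV or ROI distribution
#'
#' @param x An `ebis_sim`.
#' @param what `"npv"` or `"roi"`.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments to [graphics::hist()].
#' @return The histogram object, invisibly.
#' @export
plot.ebis_sim <- function(x, what = c("npv", "roi"), breaks = 50, ...) {
  what <- match.arg(what)
  v <- x$draws[[what]]
  v <- v[!is.na(v)]
  h <- graphics::hist(v, breaks = breaks,
                      main = sprintf("%s - %s", x$scenario_name, toupper(what)),
                      xlab = if (what == "npv") "NPV (USD)" else "ROI (fraction)", ...)
  invisible(h)
}

## scenario comparison -------------------------------------------------------

#' Compare a project under several risk scenarios
#'
#' Runs the simulation once per scenario, each with a seed derived
#' deterministically from the root seed, and returns one summary per
#' scenario in input order.
#'
#' @param spec A valid [project_spec()].
#' @param scenarios List of [scenario_spec()]s; defaults to
#'   [standard_scenarios()].
#' @param n Draws per scenario.
#' @param seed Root seed.
#' @param quantile_levels Passed to [summary.ebis_sim()].
#' @param keep_draws Keep the full `ebis_sim` objects in the result
#'   (attribute `"sims"`)?
#' @return A list of `ebis_summary` objects, classed `ebis_comparison`.
#' @export
compare_scenarios <- function(spec, scenarios = standard_scenarios(),
                              n = 10000L, seed = 1L,
                              quantile_levels = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99),
                              keep_draws = FALSE) {
  if (length(scenarios) == 0L) stop("no scenarios given", call. = FALSE)
  sims <- lapply(seq_along(scenarios), function(j)
    run_monte_carlo(spec, scenarios[[j]], n, derive_seed(seed, j)))
  reports <- lapply(sims, summary, quantile_levels = quantile_levels)
  out <- structure(reports, class = "ebis_comparison")
  if (keep_draws) attr(out, "sims") <- sims
  out
}

#' @export
print.ebis_comparison <- function(x, ...) {
  df <- comparison_table(x)
  df$npv_mean <- sprintf("%.1f", df$npv_mean / 1e6)
  df$npv_sd <- sprintf("%.1f", df$npv_sd / 1e6)
  df$roi_mean <- sprintf("%.0f", 100 * df$roi_mean)
  df$roi_sd <- sprintf("%.0f", 100 * df$roi_sd)
  df$prob_positive_npv <- sprintf("%.2f", df$prob_positive_npv)
  names(df)[names(df) == "npv_mean"] <- "NPV (m$)"
  names(df)[names(df) == "npv_sd"] <- "NPV SD (m$)"
  names(df)[names(df) == "roi_mean"] <- "ROI (%)"
  names(df)[names(df) == "roi_sd"] <- "ROI SD (%)"
  names(df)[names(df) == "prob_positive_npv"] <- "P(NPV>0)"
  print(df[, c("scenario", "NPV (m$)", "NPV SD (m$)", "ROI (%)", "ROI SD (%)", "P(NPV>0)")],
        row.names = FALSE)
  invisible(x)
}

# reports (list of ebis_summary) -> one data frame row per scenario
comparison_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    df <- data.frame(scenario = r$scenario_name, n = r$n, seed = r$seed,
                     npv_mean = r$npv_mean, npv_sd = r$npv_sd,
                     roi_mean = r$roi_mean, roi_sd = r$roi_sd,
                     prob_positive_npv = r$prob_positive_npv,
                     stringsAsFactors = FALSE)
    for (i in seq_along(r$quantiles))
      df[[paste0("npv_q", names(r$quantiles)[i])]] <- r$quantiles[i]
    df
  }))
}

## export --------------------------------------------------------------------

#' Export scenario summaries (and optionally draws) to disk
#'
#' Writes a scenario-comparison table — one row per summary with NPV/ROI
#' moments, probability of positive NPV and NPV quantiles — as CSV or JSON.
#' Numbers are written at full double precision so a re-import with
#' [read_report()] reproduces the values exactly, and re-export of
#' identical inputs is byte-identical. When a simulation result is also
#' given, a companion `<path-stem>_draws.csv` with one row per draw (NPV,
#' ROI, risk states, weight) is written for histogramming.
#'
#' @param reports A list of `ebis_summary` objects (e.g. from
#'   [compare_scenarios()]), or a single one.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default follows the file extension.
#' @param result Optional `ebis_sim` whose draws are exported alongside.
#' @return Character vector of the files written, invisibly.
#' @export
export_report <- function(reports, path, format = NULL, result = NULL) {
  if (inherits(reports, "ebis_summary")) reports <- list(reports)
  if (length(reports) == 0L) stop("no reports to export", call. = FALSE)
  if (!all(vapply(reports, inherits, logical(1), "ebis_summary")))
    stop("reports must be ebis_summary objects", call. = FALSE)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  files <- path
  df <- comparison_table(reports)
  wrt <- function(expr) tryCatch(expr, error = function(e)
    stop("cannot write report to '", path, "': ", conditionMessage(e), call. = FALSE))
  if (format == "json") {
    wrt(jsonlite::write_json(df, path, dataframe = "rows", digits = NA, auto_unbox = TRUE))
  } else {
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    wrt(utils::write.csv(out, path, row.names = FALSE, quote = TRUE))
  }
  if (!is.null(result)) {
    stopifnot(inherits(result, "ebis_sim"))
    dpath <- sub("\\.[A-Za-z]+$", "", path)
    dpath <- paste0(dpath, "_draws.csv")
    dd <- result$draws
    dd$weight <- sim_weights(result)
    num <- vapply(dd, is.numeric, logical(1))
    dd[num] <- lapply(dd[num], function(v) sprintf("%.17g", v))
    wrt(utils::write.csv(dd, dpath, row.names = FALSE, quote = TRUE))
    files <- c(files, dpath)
  }
  invisible(files)
}

#' Re-import an exported scenario report
#'
#' @param path A file written by [export_report()].
#' @return A data frame with one row per scenario; numeric columns restored
#'   to full precision.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df
}
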