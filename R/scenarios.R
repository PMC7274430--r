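#' What-if risk scenario
#'
#' A scenario switches whole risk categories on or off and can override the
#' probabilities of individual named factors. Deactivating a category sets
#' every factor probability in it to zero, so the category's "none" state is
#' certain.
#'
#' @param name Scenario label.
#' @param natural_active,adoption_active,financial_active Logical flags:
#'   is the category allowed to occur?
#' @param overrides Optional named numeric vector mapping factor names to
#'   replacement probabilities (applied after the flags, for single-factor
#'   what-ifs).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, natural_active = TRUE, adoption_active = TRUE,
                          financial_active = TRUE, overrides = NULL) {
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named numeric vector", call. = FALSE)
    if (any(overrides < 0 | overrides > 1))
      stop("override probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name,
                 natural_active = isTRUE(natural_active),
                 adoption_active = isTRUE(adoption_active),
                 financial_active = isTRUE(financial_active),
                 overrides = overrides),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  onoff <- function(b) if (b) "on" else "off"
  cat("<scenario_spec> ", x$name, ": natural ", onoff(x$natural_active),
      ", adoption ", onoff(x$adoption_active),
      ", financial ", onoff(x$financial_active), "\n", sep = "")
  if (!is.null(x$overrides))
    cat("  overrides:", paste(names(x$overrides), "=", x$overrides, collapse = ", "), "\n")
  invisible(x)
}

#' The four standard risk scenarios
#'
#' Returns the canonical scenario set used for project comparison: no risks
#' at all; natural risks only; adoption and financial (socio-political)
#' risks only; and all risks active.
#'
#' @return A list of four [scenario_spec()]s.
#' @export
standard_scenarios <- function() {
  list(
    scenario_spec("No Risks", FALSE, FALSE, FALSE),
    scenario_spec("Natural Risks Only", TRUE, FALSE, FALSE),
    scenario_spec("Adoption and Financial Risks Only", FALSE, TRUE, TRUE),
    scenario_spec("All Risks", TRUE, TRUE, TRUE)
  )
}

#' Apply a scenario to a project specification
#'
#' Returns a new specification in which deactivated risk categories have
#' all factor probabilities set to zero and any named overrides are applied
#' last. The input specification is not modified; applying the same
#' scenario twice gives the same result as applying it once.
#'
#' @param spec A [project_spec()].
#' @param scenario A [scenario_spec()], or `NULL` for the identity.
#' @return A [project_spec()].
#' @export
apply_scenario <- function(spec, scenario) {
  if (is.null(scenario)) return(spec)
  if (!inherits(scenario, "scenario_spec")) stop("not a scenario_spec", call. = FALSE)
  out <- spec
  if (!scenario$natural_active)
    out$natural_risks <- lapply(out$natural_risks, function(rf) { rf$annual_probability <- 0; rf })
  if (!scenario$adoption_active)
    out$adoption_risks <- lapply(out$adoption_risks, function(rf) { rf$probability <- 0; rf })
  if (!scenario$financial_active)
    out$financial_risks <- lapply(out$financial_risks, function(rf) { rf$probability <- 0; rf })
  if (!is.null(scenario$overrides)) {
    all_names <- c(vapply(out$natural_risks, `[[`, character(1), "name"),
                   vapply(out$adoption_risks, `[[`, character(1), "name"),
                   vapply(out$financial_risks, `[[`, character(1), "name"))
    missing <- setdiff(names(scenario$overrides), all_names)
    if (length(missing) > 0L)
      stop("scenario overrides name unknown risk factors: ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (nm in names(scenario$overrides)) {
      p <- unname(scenario$overrides[[nm]])
      out$natural_risks <- lapply(out$natural_risks, function(rf) {
        if (rf$name == nm) rf$annual_probability <- p
        rf
      })
      out$adoption_risks <- lapply(out$adoption_risks, function(rf) {
        if (rf$name == nm) rf$probability <- p
        rf
      })
      out$financial_risks <- lapply(out$financial_risks, function(rf) {
        if (rf$name == nm) rf$probability <- p
        rf
      })
    }
  }
  out
}
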