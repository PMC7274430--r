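#' Risk-effect descriptor
#'
#' Risk factors act on a baseline quantity through one of three channels:
#' `"multiplier"` (a distribution whose draw multiplies the baseline draw —
#' the usual encoding of elicited effects such as "a 15--25% decrease"),
#' `"replace"` (a full conditional distribution replacing the baseline, e.g.
#' the budget available under a financial risk), or `"per_year"` (a list of
#' conditional distributions, one per evaluation year, replacing the yearly
#' adoption rates).
#'
#' @param kind One of `"multiplier"`, `"replace"`, `"per_year"`.
#' @param dist A [dist_spec()] (for `"multiplier"` and `"replace"`).
#' @param dists A list of [dist_spec()]s of length equal to the evaluation
#'   period (for `"per_year"`).
#' @return An object of class `risk_effect`.
#' @export
risk_effect <- function(kind = c("multiplier", "replace", "per_year"),
                        dist = NULL, dists = NULL) {
  kind <- match.arg(kind)
  if (kind == "per_year") {
    if (is.null(dists) || !all(vapply(dists, is_dist_spec, logical(1))))
      stop("per_year risk_effect requires a list of dist_spec in 'dists'", call. = FALSE)
  } else {
    if (!is_dist_spec(dist))
      stop(kind, " risk_effect requires a dist_spec in 'dist'", call. = FALSE)
  }
  structure(list(kind = kind, dist = dist, dists = dists), class = "risk_effect")
}

#' Natural risk factor (e.g. drought, flood, pest outbreak)
#'
#' Natural hazards are drawn independently every year as a multinomial state
#' (at most one hazard per year; the residual probability is the implicit
#' "none" state). A hazard year replaces the unit income multipliers of
#' beneficiaries and non-adopters by draws from the retained-income
#' distributions given here: the fraction of a farmer's yearly income kept
#' when the hazard strikes.
#'
#' @param name Factor label.
#' @param annual_probability Probability the hazard occurs in any given year.
#' @param beneficiary_income_multiplier [dist_spec()] of the retained-income
#'   fraction for project beneficiaries under this hazard.
#' @param baseline_income_multiplier [dist_spec()] of the retained-income
#'   fraction for non-adopters.
#' @return An object of class `natural_risk_factor`.
#' @export
natural_risk_factor <- function(name, annual_probability,
                                beneficiary_income_multiplier,
                                baseline_income_multiplier) {
  structure(list(name = name,
                 annual_probability = annual_probability,
                 beneficiary_income_multiplier = beneficiary_income_multiplier,
                 baseline_income_multiplier = baseline_income_multiplier),
            class = "natural_risk_factor")
}

#' Adoption (socio-political) risk factor
#'
#' Adoption risks — political crisis, community conflict, poor governance —
#' are drawn once per project lifetime and act on project reach: the yearly
#' adoption rates, the targeted beneficiary pool, and (in Bass mode) the
#' innovation/imitation rates. At least one effect channel must be given.
#'
#' @param name Factor label.
#' @param probability Probability the factor is active over the project.
#' @param adoption_rate_effect Optional [risk_effect()]: `"multiplier"` on
#'   the baseline yearly rates or `"per_year"` conditional rate
#'   distributions.
#' @param beneficiary_pool_effect Optional [risk_effect()]: `"multiplier"`
#'   on, or `"replace"` distribution of, the target pool.
#' @param bass_innovation_effect,bass_imitation_effect Optional
#'   [dist_spec()]s for the Bass innovation/imitation rates under this
#'   factor.
#' @return An object of class `adoption_risk_factor`.
#' @export
adoption_risk_factor <- function(name, probability,
                                 adoption_rate_effect = NULL,
                                 beneficiary_pool_effect = NULL,
                                 bass_innovation_effect = NULL,
                                 bass_imitation_effect = NULL) {
  structure(list(name = name, probability = probability,
                 adoption_rate_effect = adoption_rate_effect,
                 beneficiary_pool_effect = beneficiary_pool_effect,
                 bass_innovation_effect = bass_innovation_effect,
                 bass_imitation_effect = bass_imitation_effect),
            class = "adoption_risk_factor")
}

#' Financial risk factor
#'
#' Financial risks (e.g. donor withdrawal, ineffective management) are drawn
#' once per project and change the available budget.
#'
#' @param name Factor label.
#' @param probability Probability the factor is active over the project.
#' @param budget_under_risk [risk_effect()]: `"replace"` distribution of the
#'   budget under the risk, or `"multiplier"` on the baseline budget.
#' @return An object of class `financial_risk_factor`.
#' @export
financial_risk_factor <- function(name, probability, budget_under_risk) {
  structure(list(name = name, probability = probability,
                 budget_under_risk = budget_under_risk),
            class = "financial_risk_factor")
}

#' Adoption component of a project specification
#'
#' @param mode `"direct"` (yearly cumulative adoption-fraction priors) or
#'   `"bass"` (two-parameter Bass diffusion curve).
#' @param target_pool [dist_spec()] of the total targeted pool: persons
#'   (`scope_basis = "beneficiaries"`) or hectares (`scope_basis = "area"`).
#' @param scope_basis `"beneficiaries"` or `"area"`. Area scope is the same
#'   model with the pool read as target area and yearly uptake as area under
#'   implementation.
#' @param yearly_rates List of [dist_spec()]s, one per evaluation year, of
#'   the cumulative adoption fraction (direct mode; supports must lie in
#'   `[0, 1]`).
#' @param innovation_rate,imitation_rate [dist_spec()]s of the Bass
#'   innovation and imitation rates (bass mode).
#' @return An object of class `adoption_spec`.
#' @export
adoption_spec <- function(mode = c("direct", "bass"), target_pool,
                          scope_basis = c("beneficiaries", "area"),
                          yearly_rates = NULL,
                          innovation_rate = NULL, imitation_rate = NULL) {
  mode <- match.arg(mode)
  scope_basis <- match.arg(scope_basis)
  structure(list(mode = mode, scope_basis = scope_basis,
                 target_pool = target_pool, yearly_rates = yearly_rates,
                 innovation_rate = innovation_rate,
                 imitation_rate = imitation_rate),
            class = "adoption_spec")
}

#' Impact component of a project specification
#'
#' Productivity impact is the income difference between an adopter and a
#' non-adopter; climate impact is the monetized greenhouse-gas balance.
#' Exactly one of `adopter_income` (absolute income after adoption) or
#' `relative_impact` (a dimensionless multiplier applied to the baseline
#' income) must be supplied.
#'
#' @param baseline_income [dist_spec()], USD per beneficiary per year before
#'   adoption.
#' @param adopter_income Optional [dist_spec()], USD per beneficiary per
#'   year after adoption.
#' @param relative_impact Optional [dist_spec()], dimensionless multiplier;
#'   income after adoption is realized as the product of independent draws
#'   of the baseline income and this multiplier.
#' @param ghg_balance [dist_spec()], t CO2-eq per beneficiary per year (may
#'   be negative for net emissions).
#' @param ghg_cost [dist_spec()], USD per t CO2-eq.
#' @return An object of class `impact_spec`.
#' @export
impact_spec <- function(baseline_income, adopter_income = NULL,
                        relative_impact = NULL, ghg_balance, ghg_cost) {
  structure(list(baseline_income = baseline_income,
                 adopter_income = adopter_income,
                 relative_impact = relative_impact,
                 ghg_balance = ghg_balance, ghg_cost = ghg_cost),
            class = "impact_spec")
}

#' Finance component of a project specification
#'
#' @param budget [dist_spec()] of the total project budget (USD).
#' @param yearly_costs List of [dist_spec()]s, one per evaluation year
#'   (USD; supports must be non-negative).
#' @param discount_rate Yearly discount rate `d >= 0`.
#' @param reduction_rate Fraction of yearly impact retained once cumulative
#'   costs exceed the budget. Defaults to 0.5 with a warning when not given
#'   explicitly, as it must normally be an elicited quantity.
#' @param roi_denominator `"undiscounted"` (ROI = NPV / total cost) or
#'   `"discounted"` (ROI = NPV / total discounted cost).
#' @return An object of class `finance_spec`.
#' @export
finance_spec <- function(budget, yearly_costs, discount_rate,
                         reduction_rate = NULL,
                         roi_denominator = c("undiscounted", "discounted")) {
  roi_denominator <- match.arg(roi_denominator)
  if (is.null(reduction_rate)) {
    warning("reduction_rate not supplied; defaulting to 0.5", call. = FALSE)
    reduction_rate <- 0.5
  }
  structure(list(budget = budget, yearly_costs = yearly_costs,
                 discount_rate = discount_rate,
                 reduction_rate = reduction_rate,
                 roi_denominator = roi_denominator),
            class = "finance_spec")
}

#' Full project specification
#'
#' Collects the finance, adoption, impact and risk-factor components that
#' parameterize the per-year network fragment. Each risk category is a
#' multinomial: the listed factor probabilities must sum to at most 1, the
#' remainder being the implicit "none" state (never listed explicitly).
#'
#' @param name Project label.
#' @param evaluation_period Number of evaluation years `m`.
#' @param finance A [finance_spec()].
#' @param adoption An [adoption_spec()].
#' @param impact An [impact_spec()].
#' @param natural_risks List of [natural_risk_factor()]s.
#' @param adoption_risks List of [adoption_risk_factor()]s.
#' @param financial_risks List of [financial_risk_factor()]s.
#' @return An object of class `project_spec`.
#' @seealso [validate_project_spec()], [load_project_spec()],
#'   [simulate_project()]
#' @export
project_spec <- function(name, evaluation_period, finance, adoption, impact,
                         natural_risks = list(), adoption_risks = list(),
                         financial_risks = list()) {
  structure(list(name = name, evaluation_period = as.integer(evaluation_period),
                 finance = finance, adoption = adoption, impact = impact,
                 natural_risks = natural_risks,
                 adoption_risks = adoption_risks,
                 financial_risks = financial_risks),
            class = "project_spec")
}

#' @export
print.project_spec <- function(x, ...) {
  cat("<project_spec> ", x$name, "\n", sep = "")
  cat("  evaluation period: ", x$evaluation_period, " years; adoption mode: ",
      x$adoption$mode, " (", x$adoption$scope_basis, ")\n", sep = "")
  cat("  discount rate: ", x$finance$discount_rate,
      "; ROI denominator: ", x$finance$roi_denominator, "\n", sep = "")
  cat("  risk factors: ", length(x$natural_risks), " natural, ",
      length(x$adoption_risks), " adoption, ",
      length(x$financial_risks), " financial\n", sep = "")
  v <- validate_project_spec(x)
  if (nrow(v) > 0L) cat("  NOTE:", nrow(v), "validation violation(s); see validate_project_spec()\n")
  invisible(x)
}

violation <- function(field, rule, message) {
  data.frame(field = field, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(field = character(), rule = character(), message = character(),
             stringsAsFactors = FALSE)
}

check_dist <- function(d, field) {
  if (!is_dist_spec(d))
    return(violation(field, "type", "expected a dist_spec"))
  bad <- validate_dist_spec(d)
  if (length(bad) == 0L) return(no_violations())
  do.call(rbind, lapply(bad, function(b) violation(field, "distribution", b)))
}

check_prob <- function(p, field) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    violation(field, "probability_range", "probability must lie in [0, 1]")
  else no_violations()
}

check_support_nonneg <- function(d, field) {
  if (!is_dist_spec(d) || length(validate_dist_spec(d)) > 0L) return(no_violations())
  if (dist_support(d)[1] < 0)
    violation(field, "support_nonnegative", "distribution support must be non-negative")
  else no_violations()
}

check_support_unit <- function(d, field) {
  if (!is_dist_spec(d) || length(validate_dist_spec(d)) > 0L) return(no_violations())
  s <- dist_support(d)
  if (s[1] < 0 || s[2] > 1)
    violation(field, "support_unit_interval", "distribution support must lie in [0, 1]")
  else no_violations()
}

check_effect <- function(e, field, m) {
  if (is.null(e)) return(no_violations())
  if (!inherits(e, "risk_effect"))
    return(violation(field, "type", "expected a risk_effect"))
  if (e$kind == "per_year") {
    out <- no_violations()
    if (length(e$dists) != m)
      out <- rbind(out, violation(field, "length", sprintf("per_year effect must have %d yearly distributions", m)))
    for (i in seq_along(e$dists))
      out <- rbind(out, check_dist(e$dists[[i]], sprintf("%s[%d]", field, i)))
    out
  } else {
    check_dist(e$dist, field)
  }
}

#' Validate a project specification
#'
#' Checks every structural invariant of the model: distribution-family
#' parameter constraints, probability ranges, category probability sums
#' (each risk category plus its implicit "none" state must form a
#' distribution), component list lengths against the evaluation period,
#' support constraints (costs and risk multipliers non-negative, adoption
#' fractions within `[0, 1]`), and the exactly-one-of rule for absolute vs
#' relative adopter income.
#'
#' Violations are returned as data, not raised as errors, so a
#' specification can be inspected and repaired interactively.
#'
#' @param spec A [project_spec()].
#' @return A data frame with columns `field`, `rule`, `message`; zero rows
#'   when the specification is valid.
#' @export
validate_project_spec <- function(spec) {
  out <- no_violations()
  m <- spec$evaluation_period
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != round(m))
    return(rbind(out, violation("evaluation_period", "positive_integer",
                                "evaluation_period must be a positive integer")))
  m <- as.integer(m)

  ## finance
  fin <- spec$finance
  out <- rbind(out, check_dist(fin$budget, "finance.budget"))
  if (length(fin$yearly_costs) != m) {
    out <- rbind(out, violation("finance.yearly_costs", "length",
                                sprintf("yearly_costs has %d entries but evaluation_period is %d",
                                        length(fin$yearly_costs), m)))
  }
  for (i in seq_along(fin$yearly_costs)) {
    f <- sprintf("finance.yearly_costs[%d]", i)
    out <- rbind(out, check_dist(fin$yearly_costs[[i]], f),
                 check_support_nonneg(fin$yearly_costs[[i]], f))
  }
  if (!is.numeric(fin$discount_rate) || fin$discount_rate < 0)
    out <- rbind(out, violation("finance.discount_rate", "nonnegative", "discount_rate must be >= 0"))
  if (!is.numeric(fin$reduction_rate) || fin$reduction_rate < 0 || fin$reduction_rate > 1)
    out <- rbind(out, violation("finance.reduction_rate", "range", "reduction_rate must lie in [0, 1]"))
  if (!fin$roi_denominator %in% c("undiscounted", "discounted"))
    out <- rbind(out, violation("finance.roi_denominator", "enum", "roi_denominator must be 'undiscounted' or 'discounted'"))

  ## adoption
  ad <- spec$adoption
  out <- rbind(out, check_dist(ad$target_pool, "adoption.target_pool"))
  if (identical(ad$mode, "direct")) {
    if (length(ad$yearly_rates) != m) {
      out <- rbind(out, violation("adoption.yearly_rates", "length",
                                  sprintf("direct mode requires %d yearly_rates, got %d",
                                          m, length(ad$yearly_rates))))
    }
    for (i in seq_along(ad$yearly_rates)) {
      f <- sprintf("adoption.yearly_rates[%d]", i)
      out <- rbind(out, check_dist(ad$yearly_rates[[i]], f),
                   check_support_unit(ad$yearly_rates[[i]], f))
    }
  } else if (identical(ad$mode, "bass")) {
    if (!is_dist_spec(ad$innovation_rate))
      out <- rbind(out, violation("adoption.innovation_rate", "required", "bass mode requires innovation_rate"))
    else out <- rbind(out, check_dist(ad$innovation_rate, "adoption.innovation_rate"))
    if (!is_dist_spec(ad$imitation_rate))
      out <- rbind(out, violation("adoption.imitation_rate", "required", "bass mode requires imitation_rate"))
    else out <- rbind(out, check_dist(ad$imitation_rate, "adoption.imitation_rate"))
  } else {
    out <- rbind(out, violation("adoption.mode", "enum", "mode must be 'direct' or 'bass'"))
  }
  if (!ad$scope_basis %in% c("beneficiaries", "area"))
    out <- rbind(out, violation("adoption.scope_basis", "enum", "scope_basis must be 'beneficiaries' or 'area'"))

  ## impact
  im <- spec$impact
  out <- rbind(out, check_dist(im$baseline_income, "impact.baseline_income"))
  has_ip <- is_dist_spec(im$adopter_income)
  has_ri <- is_dist_spec(im$relative_impact)
  if (has_ip + has_ri != 1L)
    out <- rbind(out, violation("impact", "exactly_one",
                                "exactly one of adopter_income or relative_impact must be given"))
  if (has_ip) out <- rbind(out, check_dist(im$adopter_income, "impact.adopter_income"))
  if (has_ri) out <- rbind(out, check_dist(im$relative_impact, "impact.relative_impact"))
  out <- rbind(out, check_dist(im$ghg_balance, "impact.ghg_balance"),
               check_dist(im$ghg_cost, "impact.ghg_cost"))

  ## risk factors
  psum <- function(ps, field) {
    if (length(ps) > 0L && sum(ps) > 1 + 1e-9)
      violation(field, "category_probability_sum",
                sprintf("category probability sum %.6g > 1", sum(ps)))
    else no_violations()
  }
  for (i in seq_along(spec$natural_risks)) {
    rf <- spec$natural_risks[[i]]
    f <- sprintf("natural_risks[%s]", rf$name)
    out <- rbind(out,
                 check_prob(rf$annual_probability, paste0(f, ".annual_probability")),
                 check_dist(rf$beneficiary_income_multiplier, paste0(f, ".beneficiary_income_multiplier")),
                 check_support_nonneg(rf$beneficiary_income_multiplier, paste0(f, ".beneficiary_income_multiplier")),
                 check_dist(rf$baseline_income_multiplier, paste0(f, ".baseline_income_multiplier")),
                 check_support_nonneg(rf$baseline_income_multiplier, paste0(f, ".baseline_income_multiplier")))
  }
  out <- rbind(out, psum(vapply(spec$natural_risks, function(r) r$annual_probability, numeric(1)),
                         "natural_risks"))
  for (i in seq_along(spec$adoption_risks)) {
    rf <- spec$adoption_risks[[i]]
    f <- sprintf("adoption_risks[%s]", rf$name)
    out <- rbind(out, check_prob(rf$probability, paste0(f, ".probability")))
    channels <- (!is.null(rf$adoption_rate_effect)) + (!is.null(rf$beneficiary_pool_effect)) +
      is_dist_spec(rf$bass_innovation_effect) + is_dist_spec(rf$bass_imitation_effect)
    if (channels == 0L)
      out <- rbind(out, violation(f, "effect_channel", "at least one effect channel must be defined"))
    out <- rbind(out,
                 check_effect(rf$adoption_rate_effect, paste0(f, ".adoption_rate_effect"), m),
                 check_effect(rf$beneficiary_pool_effect, paste0(f, ".beneficiary_pool_effect"), m))
    if (is_dist_spec(rf$bass_innovation_effect))
      out <- rbind(out, check_dist(rf$bass_innovation_effect, paste0(f, ".bass_innovation_effect")))
    if (is_dist_spec(rf$bass_imitation_effect))
      out <- rbind(out, check_dist(rf$bass_imitation_effect, paste0(f, ".bass_imitation_effect")))
  }
  out <- rbind(out, psum(vapply(spec$adoption_risks, function(r) r$probability, numeric(1)),
                         "adoption_risks"))
  for (i in seq_along(spec$financial_risks)) {
    rf <- spec$financial_risks[[i]]
    f <- sprintf("financial_risks[%s]", rf$name)
    out <- rbind(out, check_prob(rf$probability, paste0(f, ".probability")),
                 check_effect(rf$budget_under_risk, paste0(f, ".budget_under_risk"), m))
  }
  out <- rbind(out, psum(vapply(spec$financial_risks, function(r) r$probability, numeric(1)),
                         "financial_risks"))
  out
}

# stop with an aggregated report unless the spec is valid
assert_valid_spec <- function(spec) {
  if (!inherits(spec, "project_spec")) stop("not a project_spec", call. = FALSE)
  v <- validate_project_spec(spec)
  if (nrow(v) > 0L) {
    stop("invalid project spec:\n",
         paste(sprintf("  - %s [%s]: %s", v$field, v$rule, v$message), collapse = "\n"),
         call. = FALSE)
  }
  invisible(spec)
}

# canonical leaf paths of a spec, used by fixture provenance bookkeeping
spec_field_paths <- function(spec) {
  paths <- c("name", "evaluation_period",
             "finance.budget", "finance.yearly_costs", "finance.discount_rate",
             "finance.reduction_rate", "finance.roi_denominator",
             "adoption.mode", "adoption.scope_basis", "adoption.target_pool")
  if (identical(spec$adoption$mode, "direct")) paths <- c(paths, "adoption.yearly_rates")
  else paths <- c(paths, "adoption.innovation_rate", "adoption.imitation_rate")
  paths <- c(paths, "impact.baseline_income",
             if (is_dist_spec(spec$impact$adopter_income)) "impact.adopter_income"
             else "impact.relative_impact",
             "impact.ghg_balance", "impact.ghg_cost")
  for (rf in spec$natural_risks) {
    f <- sprintf("natural_risks[%s]", rf$name)
    paths <- c(paths, paste0(f, c(".annual_probability", ".beneficiary_income_multiplier",
                                  ".baseline_income_multiplier")))
  }
  for (rf in spec$adoption_risks) {
    f <- sprintf("adoption_risks[%s]", rf$name)
    paths <- c(paths, paste0(f, ".probability"))
    if (!is.null(rf$adoption_rate_effect)) paths <- c(paths, paste0(f, ".adoption_rate_effect"))
    if (!is.null(rf$beneficiary_pool_effect)) paths <- c(paths, paste0(f, ".beneficiary_pool_effect"))
    if (is_dist_spec(rf$bass_innovation_effect)) paths <- c(paths, paste0(f, ".bass_innovation_effect"))
    if (is_dist_spec(rf$bass_imitation_effect)) paths <- c(paths, paste0(f, ".bass_imitation_effect"))
  }
  for (rf in spec$financial_risks) {
    f <- sprintf("financial_risks[%s]", rf$name)
    paths <- c(paths, paste0(f, c(".probability", ".budget_under_risk")))
  }
  paths
}

# field-by-field equality of two specs (numeric tolerance for text round-trips)
spec_equal <- function(a, b, tol = 1e-12) {
  eq <- function(x, y) {
    if (is_dist_spec(x) || is_dist_spec(y)) return(dist_equal(x, y, tol))
    if (inherits(x, "risk_effect") || inherits(y, "risk_effect")) {
      if (!inherits(x, "risk_effect") || !inherits(y, "risk_effect")) return(FALSE)
      if (!identical(x$kind, y$kind)) return(FALSE)
      if (x$kind == "per_year") {
        if (length(x$dists) != length(y$dists)) return(FALSE)
        return(all(mapply(dist_equal, x$dists, y$dists, MoreArgs = list(tol = tol))))
      }
      return(dist_equal(x$dist, y$dist, tol))
    }
    if (is.list(x) && is.list(y)) {
      if (length(x) != length(y)) return(FALSE)
      return(all(vapply(seq_along(x), function(i) eq(x[[i]], y[[i]]), logical(1))))
    }
    if (is.null(x) && is.null(y)) return(TRUE)
    if (is.numeric(x) && is.numeric(y)) return(isTRUE(all.equal(x, y, tolerance = tol)))
    identical(x, y)
  }
  eq(unclass(a), unclass(b))
}
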