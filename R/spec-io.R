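#' @title Project specification files
#' @description Project specifications are stored as human-editable YAML (or
#'   JSON) documents with a versioned `schema_version` key. The document
#'   mirrors the [project_spec()] structure; distributions are flat mappings
#'   (`family` plus the family's parameters and an optional `units` tag),
#'   risk effects carry a `kind` key. Monetary amounts are plain USD
#'   numbers; probabilities are fractions in `[0, 1]`, never percentages.
#'   Risk categories never list their "none" state: its probability is the
#'   residual `1 - sum(p)`.
#' @name spec-io
NULL

SCHEMA_VERSION <- 1L

dist_to_plain <- function(d) {
  out <- c(list(family = d$family), d$params)
  if (nzchar(d$units)) out$units <- d$units
  out
}

plain_to_dist <- function(x, key) {
  if (!is.list(x) || is.null(x$family))
    stop("schema error at '", key, "': expected a distribution mapping with a 'family' key",
         call. = FALSE)
  units <- if (is.null(x$units)) "" else as.character(x$units)
  params <- x[setdiff(names(x), c("family", "units", "kind"))]
  params <- lapply(params, function(v) as.numeric(unlist(v)))
  d <- structure(list(family = as.character(x$family), params = params, units = units),
                 class = "dist_spec")
  if (!d$family %in% c("point", "uniform", "normal", "beta", "discrete"))
    stop("schema error at '", key, "': unknown distribution family '", d$family, "'",
         call. = FALSE)
  d
}

effect_to_plain <- function(e) {
  if (is.null(e)) return(NULL)
  if (e$kind == "per_year")
    list(kind = "per_year", dists = lapply(e$dists, dist_to_plain))
  else
    list(kind = e$kind, dist = dist_to_plain(e$dist))
}

plain_to_effect <- function(x, key) {
  if (is.null(x)) return(NULL)
  if (!is.list(x) || is.null(x$kind))
    stop("schema error at '", key, "': expected a risk-effect mapping with a 'kind' key",
         call. = FALSE)
  kind <- as.character(x$kind)
  if (kind == "per_year") {
    risk_effect("per_year",
                dists = lapply(seq_along(x$dists), function(i)
                  plain_to_dist(x$dists[[i]], sprintf("%s.dists[%d]", key, i))))
  } else if (kind %in% c("multiplier", "replace")) {
    risk_effect(kind, dist = plain_to_dist(x$dist, paste0(key, ".dist")))
  } else {
    stop("schema error at '", key, "': unknown effect kind '", kind, "'", call. = FALSE)
  }
}

spec_to_plain <- function(spec) {
  ad <- spec$adoption
  im <- spec$impact
  fin <- spec$finance
  list(
    schema_version = SCHEMA_VERSION,
    name = spec$name,
    evaluation_period = spec$evaluation_period,
    finance = list(
      budget = dist_to_plain(fin$budget),
      yearly_costs = lapply(fin$yearly_costs, dist_to_plain),
      discount_rate = fin$discount_rate,
      reduction_rate = fin$reduction_rate,
      roi_denominator = fin$roi_denominator
    ),
    adoption = Filter(Negate(is.null), list(
      mode = ad$mode,
      scope_basis = ad$scope_basis,
      target_pool = dist_to_plain(ad$target_pool),
      yearly_rates = if (!is.null(ad$yearly_rates)) lapply(ad$yearly_rates, dist_to_plain),
      innovation_rate = if (is_dist_spec(ad$innovation_rate)) dist_to_plain(ad$innovation_rate),
      imitation_rate = if (is_dist_spec(ad$imitation_rate)) dist_to_plain(ad$imitation_rate)
    )),
    impact = Filter(Negate(is.null), list(
      baseline_income = dist_to_plain(im$baseline_income),
      adopter_income = if (is_dist_spec(im$adopter_income)) dist_to_plain(im$adopter_income),
      relative_impact = if (is_dist_spec(im$relative_impact)) dist_to_plain(im$relative_impact),
      ghg_balance = dist_to_plain(im$ghg_balance),
      ghg_cost = dist_to_plain(im$ghg_cost)
    )),
    natural_risks = lapply(spec$natural_risks, function(rf) list(
      name = rf$name,
      annual_probability = rf$annual_probability,
      beneficiary_income_multiplier = dist_to_plain(rf$beneficiary_income_multiplier),
      baseline_income_multiplier = dist_to_plain(rf$baseline_income_multiplier)
    )),
    adoption_risks = lapply(spec$adoption_risks, function(rf) Filter(Negate(is.null), list(
      name = rf$name,
      probability = rf$probability,
      adoption_rate_effect = effect_to_plain(rf$adoption_rate_effect),
      beneficiary_pool_effect = effect_to_plain(rf$beneficiary_pool_effect),
      bass_innovation_effect = if (is_dist_spec(rf$bass_innovation_effect)) dist_to_plain(rf$bass_innovation_effect),
      bass_imitation_effect = if (is_dist_spec(rf$bass_imitation_effect)) dist_to_plain(rf$bass_imitation_effect)
    ))),
    financial_risks = lapply(spec$financial_risks, function(rf) list(
      name = rf$name,
      probability = rf$probability,
      budget_under_risk = effect_to_plain(rf$budget_under_risk)
    ))
  )
}

need <- function(x, key, parent) {
  if (is.null(x[[key]]))
    stop("schema error: missing key '", paste0(parent, key), "'", call. = FALSE)
  x[[key]]
}

plain_to_spec <- function(pl) {
  if (!is.list(pl)) stop("schema error: document root must be a mapping", call. = FALSE)
  fin <- need(pl, "finance", "")
  ad <- need(pl, "adoption", "")
  im <- need(pl, "impact", "")
  finance <- structure(list(
    budget = plain_to_dist(need(fin, "budget", "finance."), "finance.budget"),
    yearly_costs = lapply(seq_along(need(fin, "yearly_costs", "finance.")), function(i)
      plain_to_dist(fin$yearly_costs[[i]], sprintf("finance.yearly_costs[%d]", i))),
    discount_rate = as.numeric(need(fin, "discount_rate", "finance.")),
    reduction_rate = if (is.null(fin$reduction_rate)) {
      warning("reduction_rate not present in file; defaulting to 0.5", call. = FALSE)
      0.5
    } else as.numeric(fin$reduction_rate),
    roi_denominator = if (is.null(fin$roi_denominator)) "undiscounted"
      else as.character(fin$roi_denominator)
  ), class = "finance_spec")
  adoption <- structure(list(
    mode = as.character(need(ad, "mode", "adoption.")),
    scope_basis = if (is.null(ad$scope_basis)) "beneficiaries" else as.character(ad$scope_basis),
    target_pool = plain_to_dist(need(ad, "target_pool", "adoption."), "adoption.target_pool"),
    yearly_rates = if (!is.null(ad$yearly_rates))
      lapply(seq_along(ad$yearly_rates), function(i)
        plain_to_dist(ad$yearly_rates[[i]], sprintf("adoption.yearly_rates[%d]", i))),
    innovation_rate = if (!is.null(ad$innovation_rate))
      plain_to_dist(ad$innovation_rate, "adoption.innovation_rate"),
    imitation_rate = if (!is.null(ad$imitation_rate))
      plain_to_dist(ad$imitation_rate, "adoption.imitation_rate")
  ), class = "adoption_spec")
  impact <- structure(list(
    baseline_income = plain_to_dist(need(im, "baseline_income", "impact."), "impact.baseline_income"),
    adopter_income = if (!is.null(im$adopter_income))
      plain_to_dist(im$adopter_income, "impact.adopter_income"),
    relative_impact = if (!is.null(im$relative_impact))
      plain_to_dist(im$relative_impact, "impact.relative_impact"),
    ghg_balance = plain_to_dist(need(im, "ghg_balance", "impact."), "impact.ghg_balance"),
    ghg_cost = plain_to_dist(need(im, "ghg_cost", "impact."), "impact.ghg_cost")
  ), class = "impact_spec")
  nr <- lapply(pl$natural_risks, function(x) natural_risk_factor(
    name = as.character(need(x, "name", "natural_risks.")),
    annual_probability = as.numeric(need(x, "annual_probability", "natural_risks.")),
    beneficiary_income_multiplier = plain_to_dist(
      need(x, "beneficiary_income_multiplier", "natural_risks."),
      "natural_risks.beneficiary_income_multiplier"),
    baseline_income_multiplier = plain_to_dist(
      need(x, "baseline_income_multiplier", "natural_risks."),
      "natural_risks.baseline_income_multiplier")))
  ar <- lapply(pl$adoption_risks, function(x) adoption_risk_factor(
    name = as.character(need(x, "name", "adoption_risks.")),
    probability = as.numeric(need(x, "probability", "adoption_risks.")),
    adoption_rate_effect = plain_to_effect(x$adoption_rate_effect, "adoption_risks.adoption_rate_effect"),
    beneficiary_pool_effect = plain_to_effect(x$beneficiary_pool_effect, "adoption_risks.beneficiary_pool_effect"),
    bass_innovation_effect = if (!is.null(x$bass_innovation_effect))
      plain_to_dist(x$bass_innovation_effect, "adoption_risks.bass_innovation_effect"),
    bass_imitation_effect = if (!is.null(x$bass_imitation_effect))
      plain_to_dist(x$bass_imitation_effect, "adoption_risks.bass_imitation_effect")))
  fr <- lapply(pl$financial_risks, function(x) financial_risk_factor(
    name = as.character(need(x, "name", "financial_risks.")),
    probability = as.numeric(need(x, "probability", "financial_risks.")),
    budget_under_risk = plain_to_effect(need(x, "budget_under_risk", "financial_risks."),
                                        "financial_risks.budget_under_risk")))
  project_spec(
    name = as.character(need(pl, "name", "")),
    evaluation_period = as.numeric(need(pl, "evaluation_period", "")),
    finance = finance, adoption = adoption, impact = impact,
    natural_risks = nr, adoption_risks = ar, financial_risks = fr
  )
}

#' Read a project specification from a YAML or JSON file
#'
#' The file format is chosen by extension: `.json` is parsed as JSON,
#' anything else as YAML. The parsed document is converted to a
#' [project_spec()] and validated; a specification with violations is
#' rejected with an aggregated report.
#'
#' @param path Path to a specification file.
#' @return A validated [project_spec()].
#' @seealso [save_project_spec()], [validate_project_spec()]
#' @export
load_project_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  pl <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("schema error: cannot parse '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  sv <- pl$schema_version
  if (!is.null(sv) && as.integer(sv) > SCHEMA_VERSION)
    warning("spec file declares schema_version ", sv, " > supported ", SCHEMA_VERSION,
            call. = FALSE)
  spec <- plain_to_spec(pl)
  assert_valid_spec(spec)
  spec
}

#' Write a project specification to a YAML or JSON file
#'
#' Numbers are written with enough precision that [load_project_spec()]
#' inverts the file to a value-identical specification.
#'
#' @param spec A valid [project_spec()].
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
save_project_spec <- function(spec, path) {
  assert_valid_spec(spec)
  pl <- spec_to_plain(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(pl, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    txt <- yaml::as.yaml(pl, precision = 15)
    ok <- tryCatch({ writeLines(txt, path); TRUE },
                   error = function(e) stop("cannot write spec to '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
  }
  invisible(path)
}
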