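#' Bass diffusion cumulative adoption fraction
#'
#' Closed-form cumulative adoption at time `year` for the two-parameter
#' diffusion model with innovation rate `P > 0` and imitation rate
#' `Q >= 0`:
#' \deqn{AR_t = \frac{1 - e^{-(P+Q)t}}{1 + (Q/P) e^{-(P+Q)t}}}
#' The curve starts at 0, is non-decreasing, and approaches 1.
#'
#' @param innovation Innovation rate `P` (strictly positive).
#' @param imitation Imitation rate `Q` (non-negative).
#' @param year Time in years (non-negative; vectorized).
#' @return Adoption fraction(s) in `[0, 1)`.
#' @export
adoption_rate_bass <- function(innovation, imitation, year) {
  if (!is.numeric(innovation) || any(innovation <= 0))
    stop("innovation rate must be strictly positive", call. = FALSE)
  if (any(imitation < 0)) stop("imitation rate must be non-negative", call. = FALSE)
  if (any(year < 0)) stop("year must be non-negative", call. = FALSE)
  e <- exp(-(innovation + imitation) * year)
  (1 - e) / (1 + (imitation / innovation) * e)
}

# sample one multinomial state: returns an index into p, or 0L for the
# implicit "none" state with probability 1 - sum(p)
sample_state <- function(p) {
  k <- length(p)
  if (k == 0L) return(0L)
  u <- stats::runif(1)
  cs <- cumsum(p)
  i <- sum(u > cs) + 1L
  if (i > k) 0L else i
}

#' Sample the risk states of one Monte-Carlo draw
#'
#' The adoption and financial states are drawn once per project lifetime;
#' the natural state is drawn independently for every year (at most one
#' natural hazard per year; the residual probability in each category is
#' the implicit "none" state). Categories deactivated by the scenario
#' always yield "none".
#'
#' @param spec A valid [project_spec()].
#' @param scenario Optional [scenario_spec()] applied before sampling.
#' @return A list of class `risk_realization` with `adoption_state`,
#'   `financial_state` (factor index or 0 for none) and `natural_states`
#'   (integer vector of length `evaluation_period`).
#' @export
sample_risk_realization <- function(spec, scenario = NULL) {
  spec <- apply_scenario(spec, scenario)
  p_nat <- vapply(spec$natural_risks, function(r) r$annual_probability, numeric(1))
  p_ad <- vapply(spec$adoption_risks, function(r) r$probability, numeric(1))
  p_fin <- vapply(spec$financial_risks, function(r) r$probability, numeric(1))
  m <- spec$evaluation_period
  structure(list(
    adoption_state = sample_state(p_ad),
    financial_state = sample_state(p_fin),
    natural_states = vapply(seq_len(m), function(t) sample_state(p_nat), integer(1))
  ), class = "risk_realization")
}

# draw one value and clamp at zero, incrementing the shared clamp counter
draw_nonneg <- function(d, counter) {
  x <- dist_sample(d, 1L)
  if (x < 0) {
    counter$n <- counter$n + 1L
    x <- 0
  }
  x
}

#' Simulate one draw of the per-year network fragment
#'
#' Samples a risk realization, the lifetime quantities (target pool,
#' incomes, GHG terms, budget and — in Bass mode — the diffusion rates,
#' each switched to its risk-conditional distribution when the relevant
#' risk state is active), then rolls the fragment forward year by year:
#' adoption fraction and adopters, retained-income multipliers under the
#' year's natural hazard, productivity and climate impact, cost, the
#' budget-exceedance flag, adjusted impact and discounted benefit, ending
#' in NPV and ROI. Negative sampled incomes, prices, pools, budgets or
#' costs are clamped at zero and counted.
#'
#' @param spec A valid [project_spec()].
#' @param scenario Optional [scenario_spec()].
#' @return A list of class `draw_trajectory`; see the field list in the
#'   package vignette. `roi` is `NA` when the cost denominator is zero.
#' @export
simulate_draw <- function(spec, scenario = NULL) {
  spec <- apply_scenario(spec, scenario)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  risk <- sample_risk_realization(spec)
  tr <- simulate_draw_prepared(spec, risk, counter)
  tr$risk <- risk
  tr$n_clamped <- counter$n
  tr
}

# the draw body, assuming the scenario is already applied and the risk
# states are given; `counter` accumulates negative-value clamps
simulate_draw_prepared <- function(spec, risk, counter) {
  m <- spec$evaluation_period
  fin <- spec$finance
  ad <- spec$adoption
  im <- spec$impact
  a_state <- risk$adoption_state
  f_state <- risk$financial_state
  arf <- if (a_state > 0L) spec$adoption_risks[[a_state]] else NULL

  ## lifetime quantities
  tb <- draw_nonneg(ad$target_pool, counter)
  if (!is.null(arf) && !is.null(arf$beneficiary_pool_effect)) {
    eff <- arf$beneficiary_pool_effect
    tb <- if (eff$kind == "replace") draw_nonneg(eff$dist, counter)
          else tb * draw_nonneg(eff$dist, counter)
  }
  ib <- draw_nonneg(im$baseline_income, counter)
  ip <- if (is_dist_spec(im$adopter_income)) draw_nonneg(im$adopter_income, counter)
        else ib * draw_nonneg(im$relative_impact, counter)
  ghgb <- dist_sample(im$ghg_balance, 1L)  # a balance: legitimately signed
  ghgc <- draw_nonneg(im$ghg_cost, counter)
  cl <- ghgb * ghgc
  bd <- draw_nonneg(fin$budget, counter)
  if (f_state > 0L) {
    eff <- spec$financial_risks[[f_state]]$budget_under_risk
    bd <- if (eff$kind == "replace") draw_nonneg(eff$dist, counter)
          else bd * draw_nonneg(eff$dist, counter)
  }

  ## adoption-rate machinery
  rate_mult <- 1
  rate_dists <- NULL
  if (identical(ad$mode, "bass")) {
    p_dist <- ad$innovation_rate
    q_dist <- ad$imitation_rate
    if (!is.null(arf)) {
      if (is_dist_spec(arf$bass_innovation_effect)) p_dist <- arf$bass_innovation_effect
      if (is_dist_spec(arf$bass_imitation_effect)) q_dist <- arf$bass_imitation_effect
    }
    bass_p <- max(dist_sample(p_dist, 1L), 1e-12)
    bass_q <- max(dist_sample(q_dist, 1L), 0)
  } else {
    rate_dists <- ad$yearly_rates
    if (!is.null(arf) && !is.null(arf$adoption_rate_effect)) {
      eff <- arf$adoption_rate_effect
      if (eff$kind == "per_year") rate_dists <- eff$dists
      else rate_mult <- draw_nonneg(eff$dist, counter)
    }
  }

  ## per-year roll-forward
  ar <- numeric(m); ep <- rep(1, m); eb <- rep(1, m); cost <- numeric(m)
  for (t in seq_len(m)) {
    if (identical(ad$mode, "bass")) {
      ar[t] <- adoption_rate_bass(bass_p, bass_q, t)
    } else {
      ar[t] <- min(max(dist_sample(rate_dists[[t]], 1L) * rate_mult, 0), 1)
    }
    cost[t] <- draw_nonneg(fin$yearly_costs[[t]], counter)
    i <- risk$natural_states[t]
    if (i > 0L) {
      nrf <- spec$natural_risks[[i]]
      ep[t] <- draw_nonneg(nrf$beneficiary_income_multiplier, counter)
      eb[t] <- draw_nonneg(nrf$baseline_income_multiplier, counter)
    }
  }
  adopters <- ar * tb
  prod_impact <- ip * ep - ib * eb
  impact <- adopters * (prod_impact + cl)
  over_budget <- as.numeric(cumsum(cost) - bd > 0)
  adj_impact <- over_budget * impact * fin$reduction_rate + (1 - over_budget) * impact
  disc <- (1 + fin$discount_rate)^seq_len(m)
  benefit <- (adj_impact - cost) / disc
  npv <- sum(benefit)
  denom <- if (identical(fin$roi_denominator, "discounted")) sum(cost / disc) else sum(cost)
  roi <- if (denom == 0) NA_real_ else npv / denom

  structure(list(
    adoption_fraction = ar, adopters = adopters,
    beneficiary_multiplier = ep, baseline_multiplier = eb,
    productivity_impact = prod_impact, impact = impact, cost = cost,
    over_budget_flag = over_budget, adjusted_impact = adj_impact,
    discounted_benefit = benefit,
    climate_impact = cl, realized_pool = tb, realized_budget = bd,
    npv = npv, roi = roi
  ), class = "draw_trajectory")
}

# deterministic seed derivation for scenario sub-runs; stays below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 + as.double(k) * 1000003) %% 2147483646 + 1)
}

#' Run the Monte-Carlo simulation
#'
#' Draws `n` independent trajectories of the project model under a
#' scenario. Each draw uses its own random-number stream derived
#' deterministically from the root seed (L'Ecuyer-CMRG substreams), so
#' results are bit-identical for identical `(spec, scenario, n, seed)` and
#' the first `k` draws do not change when `n` is increased.
#'
#' @param spec A valid [project_spec()].
#' @param scenario Optional [scenario_spec()]; `NULL` leaves all risk
#'   categories active as specified.
#' @param n Number of draws (at least 1).
#' @param seed Integer root seed.
#' @return An object of class `ebis_sim`: a list with `draws` (data frame
#'   with one row per draw: `npv`, `roi`, risk states, realized pool and
#'   budget, climate impact), `years` (per-year matrices, one row per
#'   draw), `natural_states` (character matrix), `n`, `seed`,
#'   `scenario_name`, `weights` (`NULL` for uniform) and `n_clamped` (count
#'   of negative samples clamped to zero).
#' @seealso [summary.ebis_sim()], [condition_result()], [compare_scenarios()]
#' @export
run_monte_carlo <- function(spec, scenario = NULL, n = 10000L, seed = 1L) {
  assert_valid_spec(spec)
  if (!is.numeric(n) || n < 1) stop("n must be at least 1", call. = FALSE)
  n <- as.integer(n)
  spec <- apply_scenario(spec, scenario)
  assert_valid_spec(spec)
  m <- spec$evaluation_period

  p_nat <- vapply(spec$natural_risks, function(r) r$annual_probability, numeric(1))
  p_ad <- vapply(spec$adoption_risks, function(r) r$probability, numeric(1))
  p_fin <- vapply(spec$financial_risks, function(r) r$probability, numeric(1))
  nat_names <- vapply(spec$natural_risks, `[[`, character(1), "name")
  ad_names <- vapply(spec$adoption_risks, `[[`, character(1), "name")
  fin_names <- vapply(spec$financial_risks, `[[`, character(1), "name")

  year_fields <- c("adoption_fraction", "adopters", "beneficiary_multiplier",
                   "baseline_multiplier", "productivity_impact", "impact",
                   "cost", "over_budget_flag", "adjusted_impact",
                   "discounted_benefit")
  years <- lapply(year_fields, function(f) matrix(NA_real_, n, m))
  names(years) <- year_fields
  npv <- numeric(n); roi <- numeric(n)
  cl <- numeric(n); tb <- numeric(n); bd <- numeric(n)
  a_state <- integer(n); f_state <- integer(n)
  nat_state <- matrix(0L, n, m)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L

  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = .GlobalEnv)

  for (k in seq_len(n)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = .GlobalEnv)
    risk <- structure(list(
      adoption_state = sample_state(p_ad),
      financial_state = sample_state(p_fin),
      natural_states = vapply(seq_len(m), function(t) sample_state(p_nat), integer(1))
    ), class = "risk_realization")
    tr <- simulate_draw_prepared(spec, risk, counter)
    for (f in year_fields) years[[f]][k, ] <- tr[[f]]
    npv[k] <- tr$npv; roi[k] <- tr$roi
    cl[k] <- tr$climate_impact; tb[k] <- tr$realized_pool; bd[k] <- tr$realized_budget
    a_state[k] <- risk$adoption_state; f_state[k] <- risk$financial_state
    nat_state[k, ] <- risk$natural_states
  }

  state_name <- function(idx, nms) ifelse(idx == 0L, "none", nms[pmax(idx, 1L)])
  draws <- data.frame(
    npv = npv, roi = roi,
    adoption_state = state_name(a_state, ad_names),
    financial_state = state_name(f_state, fin_names),
    realized_pool = tb, realized_budget = bd, climate_impact = cl,
    stringsAsFactors = FALSE
  )
  nat_chr <- matrix(state_name(nat_state, nat_names), n, m)
  structure(list(draws = draws, years = years, natural_states = nat_chr,
                 n = n, seed = as.integer(seed),
                 scenario_name = if (is.null(scenario)) "(as specified)" else scenario$name,
                 weights = NULL, n_clamped = counter$n, spec = spec),
            class = "ebis_sim")
}

#' Simulate a project under a risk scenario
#'
#' The main entry point of the package: applies a scenario to a project
#' specification and runs the seeded Monte-Carlo simulation of the per-year
#' network fragment. Equivalent to [run_monte_carlo()]; provided under the
#' name users of the modelling interface expect.
#'
#' @inheritParams run_monte_carlo
#' @return An object of class `ebis_sim`; see [run_monte_carlo()].
#' @examples
#' fx <- make_point_mass_fixture()
#' sim <- simulate_project(fx$spec, n = 10, seed = 1)
#' summary(sim)
#' @export
simulate_project <- function(spec, scenario = NULL, n = 10000L, seed = 1L) {
  run_monte_carlo(spec, scenario, n, seed)
}

#' Condition a simulation on a draw-level event
#'
#' Backward queries ("what does the risk landscape look like given a
#' negative NPV?") are answered by a-posteriori filtering of the forward
#' draws: the sub-population satisfying a predicate is retained and its
#' weights renormalized.
#'
#' @param result An `ebis_sim`.
#' @param predicate Function taking the `draws` data frame and returning a
#'   logical vector, e.g. `function(d) d$npv < 0`.
#' @return An `ebis_sim` containing only the matching draws, with
#'   renormalized weights.
#' @examples
#' fx <- make_point_mass_fixture()
#' sim <- simulate_project(fx$spec, n = 50, seed = 1)
#' pos <- condition_result(sim, function(d) d$npv > 0)
#' pos$n
#' @export
condition_result <- function(result, predicate) {
  if (!inherits(result, "ebis_sim")) stop("not an ebis_sim", call. = FALSE)
  keep <- predicate(result$draws)
  if (!is.logical(keep) || length(keep) != result$n)
    stop("predicate must return one logical per draw", call. = FALSE)
  keep <- which(keep)
  if (length(keep) == 0L)
    stop("no draws satisfy the predicate; increase n or relax the condition",
         call. = FALSE)
  w <- if (is.null(result$weights)) rep(1, result$n) else result$weights
  w <- w[keep] / sum(w[keep])
  out <- result
  out$draws <- result$draws[keep, , drop = FALSE]
  rownames(out$draws) <- NULL
  out$years <- lapply(result$years, function(mat) mat[keep, , drop = FALSE])
  out$natural_states <- result$natural_states[keep, , drop = FALSE]
  out$n <- length(keep)
  out$weights <- w
  out
}
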