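test_that("Bass adoption curve matches its closed form and limits", {
  expect_equal(adoption_rate_bass(0.05, 0.4, 0), 0)
  expect_equal(adoption_rate_bass(0.03, 0.38, 1e6), 1, tolerance = 1e-12)
  # independent algebraic rearrangement as oracle:
  # AR_t = P (e^{(P+Q)t} - 1) / (P e^{(P+Q)t} + Q)
  bass_oracle <- function(p, q, t) {
    g <- exp((p + q) * t)
    p * (g - 1) / (p * g + q)
  }
  for (case in list(c(0.01, 0.50, 5), c(0.03, 0.38, 2), c(0.2, 0, 7))) {
    expect_equal(adoption_rate_bass(case[1], case[2], case[3]),
                 bass_oracle(case[1], case[2], case[3]), tolerance = 1e-12)
  }
  # non-decreasing in t, bounded in [0, 1)
  t <- seq(0, 50, by = 0.5)
  ar <- adoption_rate_bass(0.02, 0.45, t)
  expect_true(all(diff(ar) >= 0))
  expect_true(all(ar >= 0 & ar < 1))
  expect_error(adoption_rate_bass(0, 0.4, 1), "positive")
})

test_that("the point-mass toy reproduces hand arithmetic exactly", {
  base <- make_point_mass_fixture()
  sim <- simulate_project(base$spec, n = 3, seed = 11)
  expect_identical(sim$draws$npv, rep(45000, 3))
  expect_identical(sim$draws$roi, rep(1.5, 3))
  # per-year chain of the first draw, against the recorded arithmetic
  expect_equal(sim$years$adopters[1, ], c(500, 1000))
  expect_equal(sim$years$impact[1, ], c(25000, 50000))
  expect_equal(sim$years$over_budget_flag[1, ], c(0, 0))
  expect_equal(sim$years$discounted_benefit[1, ], c(5000, 40000))

  over <- make_point_mass_fixture(budget = 15000)
  sim <- simulate_project(over$spec, n = 2, seed = 11)
  expect_identical(sim$draws$npv, rep(7500, 2))
  expect_equal(sim$years$over_budget_flag[1, ], c(1, 1))
  expect_equal(sim$years$adjusted_impact[1, ], c(12500, 25000))

  disc <- make_point_mass_fixture(discount_rate = 0.1)
  sim <- simulate_project(disc$spec, n = 1, seed = 11)
  expect_equal(sim$draws$npv, 5000 / 1.1 + 40000 / 1.21, tolerance = 1e-12)
})

test_that("simulation is seed-deterministic and draw streams are stable in n", {
  spec <- make_random_fixture(5)$spec
  a <- simulate_project(spec, n = 200, seed = 42)
  b <- simulate_project(spec, n = 200, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$years, b$years)
  # extending the run leaves earlier draws bit-identical
  c_ <- simulate_project(spec, n = 300, seed = 42)
  expect_identical(c_$draws[1:200, ], a$draws)
  d <- simulate_project(spec, n = 200, seed = 43)
  expect_false(identical(a$draws$npv, d$draws$npv))
})

test_that("risk states occur at their specified category frequencies", {
  fx <- make_point_mass_fixture()
  spec <- fx$spec
  spec$natural_risks <- list(
    natural_risk_factor("A", 0.3, pt(0.5), pt(0.5)),
    natural_risk_factor("B", 0.2, pt(0.5), pt(0.5))
  )
  n <- 100000
  set.seed(99)
  states <- vapply(seq_len(n), function(i)
    sample_risk_realization(spec)$natural_states[1], integer(1))
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(states == 1L) - 0.3), 3 * se)
  expect_lt(abs(mean(states == 2L) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(mean(states == 0L) - 0.5), 3 * sqrt(0.25 / n))

  # a scenario deactivating the category forces the none state always
  off <- scenario_spec("off", natural_active = FALSE)
  set.seed(99)
  states <- vapply(seq_len(500), function(i)
    sample_risk_realization(spec, off)$natural_states[1], integer(1))
  expect_true(all(states == 0L))
})

test_that("Monte-Carlo mean NPV matches the closed-form expectation of a linear spec", {
  spec <- make_linear_spec(m = 3, d = 0.05)
  sim <- simulate_project(spec, n = 20000, seed = 7)
  expected <- linear_spec_enpv(spec)
  se <- sd(sim$draws$npv) / sqrt(sim$n)
  expect_lt(abs(mean(sim$draws$npv) - expected), 3 * se)
})

test_that("risk-conditioned NPV obeys the mixture law over adoption states", {
  spec <- make_point_mass_fixture()$spec
  spec$adoption_risks <- list(
    adoption_risk_factor("shock", 0.4,
                         adoption_rate_effect = risk_effect("multiplier",
                           dist_spec("uniform", low = 0.6, high = 0.8)))
  )
  n <- 20000
  sim <- simulate_project(spec, n = n, seed = 3)
  # E[NPV] = p E[NPV | shock] + (1-p) E[NPV | none]; conditional means are
  # exact because all other quantities are point masses
  e_none <- 45000
  e_shock <- 0.7 * (25000 + 50000) - 30000  # multiplier mean 0.7 on adoption
  mixture <- 0.4 * e_shock + 0.6 * e_none
  se <- sd(sim$draws$npv) / sqrt(n)
  expect_lt(abs(mean(sim$draws$npv) - mixture), 3 * se)
})

test_that("budget-exceedance flags are monotone and the ROI identity holds per draw", {
  for (seed in c(2, 9, 17)) {
    spec <- make_random_fixture(seed)$spec
    sim <- simulate_project(spec, n = 400, seed = 5)
    flags <- sim$years$over_budget_flag
    expect_true(all(apply(flags, 1, function(r) all(diff(r) >= 0))))
    denom <- if (spec$finance$roi_denominator == "discounted") {
      disc <- (1 + spec$finance$discount_rate)^seq_len(spec$evaluation_period)
      as.numeric(sim$years$cost %*% (1 / disc))
    } else rowSums(sim$years$cost)
    ok <- denom > 0
    expect_equal(sim$draws$roi[ok] * denom[ok], sim$draws$npv[ok], tolerance = 1e-12)
  }
})

test_that("Bass-mode adoption fractions rise monotonically in every draw", {
  fx <- make_point_mass_fixture()
  spec <- fx$spec
  spec$evaluation_period <- 4L
  spec$finance$yearly_costs <- rep(list(pt(5000)), 4)
  spec$adoption <- adoption_spec("bass", target_pool = pt(1000),
                                 innovation_rate = dist_spec("uniform", low = 0.01, high = 0.05),
                                 imitation_rate = dist_spec("uniform", low = 0.1, high = 0.5))
  sim <- simulate_project(spec, n = 300, seed = 8)
  ar <- sim$years$adoption_fraction
  expect_true(all(apply(ar, 1, function(r) all(diff(r) > 0))))
  expect_true(all(ar > 0 & ar < 1))
})

test_that("conditioning on a risk state agrees with forcing that state", {
  spec <- make_point_mass_fixture()$spec
  spec$adoption$target_pool <- dist_spec("normal", mean = 1000, sd = 100)
  spec$adoption_risks <- list(
    adoption_risk_factor("unrest", 0.4,
                         adoption_rate_effect = risk_effect("multiplier",
                           dist_spec("uniform", low = 0.6, high = 0.9)))
  )
  n <- 30000
  sim <- simulate_project(spec, n = n, seed = 21)
  cond <- condition_result(sim, function(d) d$adoption_state == "unrest")
  forced <- simulate_project(spec, scenario_spec("forced", overrides = c(unrest = 1)),
                             n = n, seed = 22)
  se <- sqrt(sd(cond$draws$npv)^2 / cond$n + sd(forced$draws$npv)^2 / forced$n)
  expect_lt(abs(mean(cond$draws$npv) - mean(forced$draws$npv)), 3 * se)
})

test_that("conditioning filters, renormalizes and errors on empty events", {
  spec <- make_random_fixture(31)$spec
  sim <- simulate_project(spec, n = 500, seed = 2)
  same <- condition_result(sim, function(d) rep(TRUE, nrow(d)))
  expect_identical(same$draws, sim$draws)
  expect_equal(sum(same$weights), 1)

  neg <- tryCatch(condition_result(sim, function(d) d$npv < median(d$npv)),
                  error = function(e) NULL)
  if (!is.null(neg)) expect_lt(neg$n, sim$n)

  toy <- simulate_project(make_point_mass_fixture()$spec, n = 20, seed = 1)
  expect_error(condition_result(toy, function(d) d$npv < 0), "no draws satisfy")
})

test_that("negative samples are clamped at zero and counted", {
  spec <- make_point_mass_fixture()$spec
  spec$impact$baseline_income <- dist_spec("normal", mean = 0, sd = 10)
  sim <- simulate_project(spec, n = 200, seed = 13)
  expect_gt(sim$n_clamped, 0)
  expect_true(all(sim$years$baseline_multiplier >= 0))
})

test_that("undefined ROI is flagged, not raised", {
  spec <- make_point_mass_fixture()$spec
  spec$finance$yearly_costs <- list(pt(0), pt(0))
  sim <- simulate_project(spec, n = 3, seed = 1)
  expect_true(all(is.na(sim$draws$roi)))
  expect_false(anyNA(sim$draws$npv))
})
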