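test_that("summary statistics are exact on degenerate draw sets", {
  sim <- simulate_project(make_point_mass_fixture()$spec, n = 25, seed = 1)
  s <- summary(sim)
  expect_equal(s$npv_mean, 45000)
  expect_equal(s$npv_sd, 0)
  expect_equal(s$roi_mean, 1.5)
  expect_equal(s$prob_positive_npv, 1)
  expect_true(all(s$quantiles == 45000))
  expect_true(all(diff(s$quantiles) >= 0))

  # single draw: dispersion undefined
  s1 <- summary(simulate_project(make_point_mass_fixture()$spec, n = 1, seed = 1))
  expect_true(is.na(s1$npv_sd))
})

test_that("summaries respect weights and are invariant to draw permutation", {
  sim <- simulate_project(make_random_fixture(12)$spec, n = 400, seed = 3)
  s <- summary(sim)

  # uniform weights equal the unweighted path
  wsim <- sim
  wsim$weights <- rep(2.5, sim$n)  # non-normalized uniform
  sw <- summary(wsim)
  expect_equal(sw$npv_mean, s$npv_mean)
  expect_equal(sw$npv_sd, s$npv_sd)
  expect_equal(sw$quantiles, s$quantiles)

  # permutation invariance
  perm <- sample(sim$n)
  psim <- sim
  psim$draws <- sim$draws[perm, ]
  psim$years <- lapply(sim$years, function(m) m[perm, , drop = FALSE])
  sp <- summary(psim)
  expect_equal(sp$npv_mean, s$npv_mean)
  expect_equal(sp$npv_sd, s$npv_sd)
  expect_equal(sp$quantiles, s$quantiles)

  # half-negative, half-positive: P(NPV > 0) = 1/2 by construction
  hsim <- sim
  hsim$draws$npv <- rep(c(-1, 1), length.out = sim$n)
  sh <- summary(hsim)
  expect_equal(sh$npv_mean, 0)
  expect_equal(sh$prob_positive_npv, 0.5)
})

test_that("probability of positive NPV matches a known generator", {
  sim <- simulate_project(make_point_mass_fixture()$spec, n = 4, seed = 1)
  n <- 50000
  set.seed(123)
  sim$draws <- data.frame(npv = rnorm(n), roi = rnorm(n),
                          adoption_state = "none", financial_state = "none",
                          realized_pool = 0, realized_budget = 0, climate_impact = 0)
  sim$n <- n
  s <- summary(sim)
  expect_lt(abs(s$prob_positive_npv - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(s$quantiles[["0.5"]] - 0), 0.02)
})

test_that("scenario comparison is ordered, reproducible and degenerate-safe", {
  spec <- make_point_mass_fixture()$spec  # no risk factors at all
  cmp <- compare_scenarios(spec, n = 30, seed = 4)
  expect_length(cmp, 4)
  expect_identical(vapply(cmp, `[[`, character(1), "scenario_name"),
                   vapply(standard_scenarios(), `[[`, character(1), "name"))
  # without risk factors all four scenarios are the same model
  expect_true(all(vapply(cmp, `[[`, numeric(1), "npv_mean") == 45000))

  spec2 <- make_case_like_fixture()$spec
  a <- compare_scenarios(spec2, n = 150, seed = 5)
  b <- compare_scenarios(spec2, n = 150, seed = 5)
  expect_equal(a, b)
})

test_that("report export round-trips values at full precision", {
  spec <- make_random_fixture(44)$spec
  sim <- simulate_project(spec, n = 120, seed = 6)
  reports <- list(summary(sim))

  for (ext in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    export_report(reports, path)
    df <- read_report(path)
    expect_identical(nrow(df), 1L)
    expect_equal(df$npv_mean, reports[[1]]$npv_mean, tolerance = 1e-15)
    expect_equal(df$npv_sd, reports[[1]]$npv_sd, tolerance = 1e-15)
    expect_equal(df$prob_positive_npv, reports[[1]]$prob_positive_npv, tolerance = 1e-15)
    expect_equal(df[["npv_q0.5"]], unname(reports[[1]]$quantiles["0.5"]), tolerance = 1e-15)
  }

  # re-export is byte-identical; draws file is written alongside
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  export_report(reports, p1, result = sim)
  export_report(reports, p2, result = sim)
  expect_identical(readLines(p1), readLines(p2))
  draws_file <- sub("\\.csv$", "_draws.csv", p1)
  expect_true(file.exists(draws_file))
  dd <- utils::read.csv(draws_file)
  expect_identical(nrow(dd), sim$n)
  expect_equal(dd$npv, sim$draws$npv, tolerance = 1e-15)

  expect_error(export_report(list(), tempfile()), "no reports")
})
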