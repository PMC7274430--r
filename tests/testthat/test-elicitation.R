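test_that("normal percentile fit reproduces the elicited percentiles exactly", {
  d <- fit_normal_from_percentiles(168000, 280000, 0.01, 0.99)
  expect_equal(d$params$mean, 224000)
  # independent closed form: half-range over the 99th-percentile z-score
  expect_equal(d$params$sd, 56000 / qnorm(0.99), tolerance = 1e-12)
  resid <- pnorm(c(168000, 280000), d$params$mean, d$params$sd) - c(0.01, 0.99)
  expect_lt(max(abs(resid)), 1e-9)

  # symmetry: symmetric values and levels give mean zero
  for (a in c(1, 3.7, 1e5)) {
    d <- fit_normal_from_percentiles(-a, a, 0.05, 0.95)
    expect_equal(d$params$mean, 0, tolerance = 1e-9 * a)
  }
  expect_error(fit_normal_from_percentiles(5, 2, 0.01, 0.99), "less than")
  expect_error(fit_normal_from_percentiles(1, 2, 0.99, 0.01), "p_low < p_high")
})

test_that("beta percentile fit reproduces the elicited percentiles", {
  cases <- list(c(0.05, 0.15, 0.01, 0.99), c(0.2, 0.4, 0.01, 0.99),
                c(0.8, 0.98, 0.01, 0.99), c(0.1, 0.6, 0.05, 0.95))
  for (cs in cases) {
    d <- fit_beta_from_percentiles(cs[1], cs[2], cs[3], cs[4])
    resid <- pbeta(cs[1:2], d$params$alpha, d$params$beta) - cs[3:4]
    expect_lt(max(abs(resid)), 1e-6)
  }
  # symmetric percentiles about 1/2 with complementary levels: alpha = beta
  d <- fit_beta_from_percentiles(0.3, 0.7, 0.05, 0.95)
  expect_equal(d$params$alpha, d$params$beta, tolerance = 1e-6)
  expect_error(fit_beta_from_percentiles(0.3, 0.2, 0.01, 0.99), "low_value < high_value")
})

test_that("annual probability from frequency follows the counting rule", {
  expect_equal(annual_prob_from_frequency(1, 10), 0.10)
  expect_equal(annual_prob_from_frequency(5, 100), 0.05)
  expect_equal(annual_prob_from_frequency(0, 20), 0)
  expect_equal(annual_prob_from_frequency(30, 20), 1)  # capped
  # homogeneity in the observation window
  for (k in c(0.5, 2, 7)) {
    expect_equal(annual_prob_from_frequency(3 * k, 40 * k),
                 annual_prob_from_frequency(3, 40))
  }
  expect_error(annual_prob_from_frequency(-1, 10), "non-negative")
  expect_error(annual_prob_from_frequency(1, 0), "positive")
})

test_that("indicator scales map scores to probabilities affinely with clamping", {
  psav <- indicator_scale(-3, 2)
  expect_equal(prob_from_indicator_scale(-3, 0, psav)$mean, 1)
  expect_equal(prob_from_indicator_scale(2, 0, psav)$mean, 0)
  expect_equal(prob_from_indicator_scale(-0.5, 0, psav)$mean, 0.5)
  conflict <- indicator_scale(0, 4)
  expect_equal(prob_from_indicator_scale(4, 0, conflict)$mean, 0)
  expect_equal(prob_from_indicator_scale(0, 0, conflict)$mean, 1)
  # clamped outside the anchors
  expect_equal(prob_from_indicator_scale(-5, 0, psav)$mean, 1)
  expect_equal(prob_from_indicator_scale(3, 0, psav)$mean, 0)
  # sd maps by the absolute slope and is shift-invariant
  expect_equal(prob_from_indicator_scale(0, 0.5, psav)$sd, 0.1)
  shifted <- indicator_scale(-3 + 10, 2 + 10)
  expect_equal(prob_from_indicator_scale(7, 0.5, shifted)$sd,
               prob_from_indicator_scale(0, 0.5, psav)$sd)
  expect_error(indicator_scale(1, 1), "differ")
})

test_that("drought events are counted from the standardized 12-month index", {
  # variance without any deficit: no event
  expect_identical(count_drought_events(rainfall_quiet(120)), 0L)
  # one engineered 12-month deficit: one event
  expect_identical(count_drought_events(rainfall_with_excursions(120, 40)), 1L)
  # two disjoint deficits: two events
  x2 <- rainfall_with_excursions(240, c(60, 150))
  expect_identical(count_drought_events(x2), 2L)
  # an excursion still open at the end of the series counts once
  x_open <- rainfall_with_excursions(120, 109)
  expect_identical(count_drought_events(x_open), 1L)
  # scale invariance: z-scores unchanged under positive rescaling
  for (k in c(0.25, 3)) {
    expect_identical(count_drought_events(k * x2), 2L)
  }
  expect_error(count_drought_events(rep(100, 23)), "24 months")
  expect_error(count_drought_events(rep(100, 48)), "zero variance")
})

test_that("likelihood estimates combine as mean point or spanning uniform", {
  d <- combine_likelihood_estimates(c(0.05, 0.25), "mean")
  expect_identical(d$family, "point")
  expect_equal(d$params$value, 0.15)
  d <- combine_likelihood_estimates(c(0.05, 0.25), "uniform_interval")
  expect_identical(d$family, "uniform")
  expect_equal(unname(unlist(d$params[c("low", "high")])), c(0.05, 0.25))
  expect_equal(dist_mean(d), 0.15)
  for (m in c("mean", "uniform_interval")) {
    d <- combine_likelihood_estimates(0.1, m)
    expect_identical(d$family, "point")
    expect_equal(d$params$value, 0.1)
  }
  expect_error(combine_likelihood_estimates(numeric(0), "mean"), "no likelihood")
  expect_error(combine_likelihood_estimates(c(0.5, 1.2), "mean"), "\\[0, 1\\]")
})

test_that("effect pooling matches independent inverse-variance oracles", {
  e1 <- effect_estimate(40, 10, "practice A")
  expect_identical(pool_effect_estimates(list(e1), "random"), e1)

  # equal weights: fixed-effect pooled mean is the arithmetic mean and the
  # pooled se shrinks by sqrt(k)
  p <- pool_effect_estimates(list(effect_estimate(40, 10), effect_estimate(60, 10)), "fixed")
  expect_equal(p$mean, 50)
  expect_equal(p$sd, 10 / sqrt(2))

  # random-effects vs a step-by-step DerSimonian-Laird computation
  means <- c(40, 55, 70); sds <- c(10, 5, 20)
  est <- Map(effect_estimate, means, sds)
  o <- dl_pool_oracle(means, sds)
  p <- pool_effect_estimates(est, "random")
  expect_equal(p$mean, unname(o["mean"]), tolerance = 1e-10)
  expect_equal(p$sd, unname(o["se"]), tolerance = 1e-10)

  # fixed-effect pooled se never exceeds the most precise input
  p <- pool_effect_estimates(est, "fixed")
  expect_lte(p$sd, min(sds))
  expect_error(pool_effect_estimates(list()), "no effect")
})

test_that("relative impact converts to absolute adopter income multiplicatively", {
  ib <- dist_spec("point", value = 100)
  ri <- dist_spec("point", value = 1.463)
  prod <- relative_to_absolute_income(ib, ri)
  expect_equal(prod$mean, 146.3)
  expect_equal(prod$sample(3), rep(146.3, 3))

  # identity multiplier: distributed exactly as the baseline
  set.seed(1)
  x <- relative_to_absolute_income(dist_spec("normal", mean = 50, sd = 4),
                                   dist_spec("point", value = 1))$sample(5000)
  expect_equal(mean(x), 50, tolerance = 3 * 4 / sqrt(5000) / 50)
  expect_equal(sd(x), 4, tolerance = 0.05)

  # product mean is the product of means for independent draws
  set.seed(2)
  x <- relative_to_absolute_income(dist_spec("normal", mean = 200, sd = 20),
                                   dist_spec("point", value = 1.3))$sample(20000)
  expect_lt(abs(mean(x) - 260), 3 * sd(x) / sqrt(20000))
})
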