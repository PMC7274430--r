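# shared fixtures and independent oracles for the test suite

pt <- function(v, units = "") dist_spec("point", value = v, units = units)

# a stochastic spec with no risks and a budget that can never be exceeded,
# so NPV is linear in the sampled quantities and its expectation has the
# closed form sum_t (E[AR_t] E[TB] (E[IP] - E[IB] + E[CL]) - E[C_t]) / (1+d)^t
make_linear_spec <- function(m = 3, d = 0.05) {
  project_spec(
    name = "linear no-exceedance spec",
    evaluation_period = m,
    finance = finance_spec(
      budget = pt(1e12),
      yearly_costs = lapply(seq_len(m), function(t)
        dist_spec("uniform", low = 900 * t, high = 1100 * t)),
      discount_rate = d,
      reduction_rate = 0.5
    ),
    adoption = adoption_spec(
      mode = "direct",
      target_pool = dist_spec("normal", mean = 1000, sd = 50),
      yearly_rates = lapply(seq_len(m), function(t)
        dist_spec("beta", alpha = 4 * t, beta = 4 * (m + 1 - t)))
    ),
    impact = impact_spec(
      baseline_income = dist_spec("normal", mean = 100, sd = 5),
      adopter_income = dist_spec("normal", mean = 140, sd = 10),
      ghg_balance = pt(0.2),
      ghg_cost = dist_spec("uniform", low = 5, high = 15)
    )
  )
}

# closed-form expectation of NPV for make_linear_spec output
linear_spec_enpv <- function(spec) {
  m <- spec$evaluation_period
  d <- spec$finance$discount_rate
  e_tb <- dist_mean(spec$adoption$target_pool)
  e_gap <- dist_mean(spec$impact$adopter_income) - dist_mean(spec$impact$baseline_income) +
    dist_mean(spec$impact$ghg_balance) * dist_mean(spec$impact$ghg_cost)
  sum(vapply(seq_len(m), function(t) {
    (dist_mean(spec$adoption$yearly_rates[[t]]) * e_tb * e_gap -
       dist_mean(spec$finance$yearly_costs[[t]])) / (1 + d)^t
  }, numeric(1)))
}

# step-by-step DerSimonian-Laird pooling, independent of metafor
dl_pool_oracle <- function(means, sds) {
  w <- 1 / sds^2
  mu_fe <- sum(w * means) / sum(w)
  q <- sum(w * (means - mu_fe)^2)
  df <- length(means) - 1
  c_const <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / c_const)
  w_re <- 1 / (sds^2 + tau2)
  c(mean = sum(w_re * means) / sum(w_re), se = sqrt(1 / sum(w_re)))
}

# drought-free series: constant rainfall with a few wet spikes, so the
# rolling totals have variance but their z-score never goes below -1
# (the dry tail is shallow; only the wet tail is long)
rainfall_quiet <- function(n_months, base = 100) {
  x <- rep(base, n_months)
  x[c(30, 60)] <- base + 100
  x
}

# monthly rainfall series with engineered 12-month deficit excursions:
# baseline `base` everywhere, each excursion replaces 12 consecutive months
# by a deep deficit so the rolling-total z-score dives below -1 and then
# recovers past 0
rainfall_with_excursions <- function(n_months, excursion_starts, base = 100,
                                     deficit = 20) {
  x <- rep(base, n_months)
  # mild 7-month wiggle so the rolling totals have nonzero variance
  # outside excursions (a 12-divisible period would cancel in the sums)
  x <- x + 3 * sin(2 * pi * seq_len(n_months) / 7)
  for (s in excursion_starts) x[s:(s + 11)] <- deficit
  x
}

expect_spec_equal <- function(a, b) {
  expect_true(ebis:::spec_equal(a, b))
}
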