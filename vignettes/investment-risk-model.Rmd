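---
title: "Evaluating agricultural investments under risk: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating agricultural investments under risk: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebis)
```

## The problem and the model

Ex-ante evaluation of agricultural development projects has to work with
scarce data, strong expert involvement, and risks that act through
qualitatively different pathways. `ebis` encodes a per-year generative
model — a dynamic Bayesian-network fragment — whose prior distributions are
small enough to elicit one by one, and answers every question by seeded
Monte-Carlo simulation.

One draw of the model proceeds as follows. Lifetime quantities are sampled
once: the target pool `TB`, baseline and adopter incomes `IB` and `IP`
(or `IP = IB * RI` when the evidence is a relative impact), greenhouse-gas
balance and price (`CL = GHGB * GHGC`), the budget `BD`, and — in Bass
mode — the diffusion rates `P` and `Q`. The socio-political adoption state
and the financial state are also drawn once: these describe conditions
(political crisis, governance quality, donor behaviour) that persist over
a project's life. Natural-hazard states are drawn independently every
year, because droughts, floods and pest outbreaks are yearly events. Then,
per year `t`:

* adoption fraction `AR_t` (direct priors or the Bass closed form),
  adopters `B_t = AR_t * TB`;
* retained-income fractions `EP_t` (beneficiaries) and `EB_t`
  (non-adopters) drawn from the hazard's multipliers, both 1 in
  hazard-free years;
* productivity impact `PR_t = IP * EP_t - IB * EB_t`, total impact
  `I_t = B_t * (PR_t + CL)`;
* cost `C_t`; the budget-exceedance flag `REB_t = 1` once cumulative costs
  pass `BD` (necessarily monotone in `t`), after which impact is scaled by
  the reduction rate `RR`: `IA_t = REB_t * I_t * RR + (1 - REB_t) * I_t`;
* discounted benefit `R_t = (IA_t - C_t) / (1 + d)^t`.

`NPV` is the sum of `R_t`; `ROI = NPV / sum(C_i)`.

Modelling assumptions worth stating explicitly:

* **At most one natural hazard per year.** Each risk category is a single
  multinomial variable with an implicit "none" state (probability one
  minus the listed factor probabilities). An independent-hazards mode is
  deliberately not offered; compound events should be modelled as their
  own factor.
* **Adoption fractions are cumulative.** `AR_t` is the fraction of the
  pool adopting *by* year `t`, consistent with the Bass curve and with how
  adoption milestones ("10 % by year 2, 30 % by year 3") are usually
  elicited. Nothing forces elicited priors to be monotone across years;
  that is the analyst's responsibility in direct mode.
* **Costs continue after budget exhaustion.** Exceeding the budget
  penalizes impact (via `RR`) but does not stop spending; this follows the
  adjusted-impact formula literally and matches projects that limp on
  under-funded rather than stopping.
* **Natural risks can raise measured impact.** Because
  `PR_t = IP * EP_t - IB * EB_t`, a hazard that hits non-adopters harder
  than beneficiaries can *increase* the income difference. This is a
  property of the model, not a bug: the promoted practices are
  climate-resilient, and the impact metric is relative to the
  counterfactual.

## Parameters

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `evaluation_period` (m) | years | — | length of every yearly list |
| `discount_rate` (d) | 1/yr | — | must be elicited; ≥ 0 |
| `reduction_rate` (RR) | fraction | 0.5 with warning | impact retained once over budget; should be elicited |
| `roi_denominator` | — | `"undiscounted"` | see below |
| risk probabilities | fraction | — | per category, sum ≤ 1 |
| retained-income multipliers | fraction | — | non-negative support; usually Uniform bounds |
| `target_pool`, incomes, costs, budget | persons/USD | — | any supported family |
| `ghg_balance`, `ghg_cost` | t CO2-eq/benef/yr, USD/t | — | balance may be negative |

**ROI denominator.** The printed definition of ROI in the source material
divides NPV by the plain sum of costs, while the accompanying prose says
"total discounted cost". Both readings are implemented
(`roi_denominator = "undiscounted"` or `"discounted"`); the default
follows the formula, and neither is asserted to be the original intent.

**Distribution families.** Point, Uniform, Normal, Beta (optionally
rescaled to an interval) and finite discrete. These cover every prior the
elicitation procedures produce: Uniforms for expert bounds, Normals for
large pools and pooled effects, Betas for fractions.

## Elicitation procedures

* `fit_normal_from_percentiles()` / `fit_beta_from_percentiles()` invert
  elicited percentile pairs (typically pessimistic/optimistic read as
  1st/99th). The Normal fit is closed-form; the Beta fit is a numerical
  solve (BFGS on log-shapes from a moment-matched start, polished by
  damped Newton on the two CDF equations) accepted only if both CDF
  residuals are below 1e-6, and in practice reaching ~1e-12.
* `annual_prob_from_frequency()` is the historical counting rule
  (events / years, capped at 1).
* `count_drought_events()` standardizes rolling 12-month rainfall totals
  against their own mean and SD and counts excursions that open strictly
  below −1 and close on returning to ≥ 0; consecutive sub-threshold months
  are one event, and an event still open at the series end counts once.
  This is the z-score reading of the 12-month standardized precipitation
  index, *not* the gamma-fitted SPI of the climatological literature; the
  two differ for skewed rainfall climatologies. A strictly constant series
  has an undefined index and is rejected rather than reported as zero
  events.
* `prob_from_indicator_scale()` maps governance-style scores affinely
  between two anchors and clamps to [0, 1]; score SDs map by the absolute
  slope. Clamping matters because real indicator series exceed their
  nominal anchor range.
* `pool_effect_estimates()` pools published effect sizes by
  inverse-variance weighting via `metafor::rma`. The default is
  DerSimonian–Laird random effects because agricultural effect-size
  tables are typically very heterogeneous (printed dispersions of 40–90
  percentage points); fixed-effect pooling is available for homogeneous
  inputs. How any particular published table was pooled is usually not
  reproducible from the table itself, so pooled cells of such tables are
  treated as data, not as targets.
* Where two likelihood estimates disagree (e.g. a 5 % long-run rate and a
  25 % recent-period rate for pest outbreaks),
  `combine_likelihood_estimates()` offers the arithmetic mean (point
  prior) or a spanning uniform; the original combination method is
  unstated, so both are exposed and the case fixture uses the mean.

## Numerical and reproducibility choices

* **RNG.** One root seed; every draw runs on its own L'Ecuyer-CMRG
  substream (`parallel::nextRNGStream`), so results are bit-identical for
  identical inputs and the first `k` draws do not change when `n` grows.
  Scenario comparisons derive one sub-seed per scenario from the root seed.
* **Clamping.** Negative samples of incomes, prices, pools, budgets or
  costs (possible under Normal priors) are clamped to zero and counted;
  the count is reported on the result object. The greenhouse-gas balance
  is legitimately signed and never clamped.
* **Degenerate inputs.** A zero cost denominator flags ROI as `NA` in that
  draw instead of raising; single-draw summaries report `NA` dispersion;
  an empty conditional (no draws satisfy a predicate) is an error advising
  a larger `n`.
* **Weighted summaries.** Conditioned results carry renormalized weights;
  means, SDs (with a Bessel-type correction that reduces to `sd()` under
  uniform weights) and lower quantiles of the weighted empirical CDF are
  used throughout, so weighted and unweighted paths agree exactly on
  uniform weights.
* **Spec files.** YAML (or JSON) with numbers written at 15 significant
  digits; save/load round-trips are value-identical at 1e-12 relative
  tolerance.

## The fixtures: what they emulate and what they do not

`make_point_mass_fixture()` is the arithmetic oracle: every distribution a
point mass, so the whole chain is hand-checkable (NPV 45,000 / ROI 1.5;
NPV 7,500 in the over-budget variant; NPV 37,603.31 at a 10 % discount
rate). `make_random_fixture()` generates valid random specs for fuzzing
and distributional property checks (round-trips, mixture law,
budget-flag monotonicity).

`make_case_like_fixture()` mirrors a published five-year flood-plain
investment evaluation. Published inputs are used verbatim (budget, cost
schedule, pool percentiles, two adoption milestones, pooled relative
income impact, hazard multiplier bounds, the drought and pest likelihood
examples, the 15–25 % socio-political decrease). The unpublished inputs
are stand-ins chosen once, before any simulation was run, by
order-of-magnitude reasoning and field experience, and tagged `stand_in`
in the manifest:

* baseline income Normal(600, 120) USD/yr — a smallholder farm income at
  which central discounted benefits are commensurate with the 89 M$
  budget, as they must be for a project shortlisted for funding;
* discount rate 0.05/yr, reduction rate 0.5;
* adoption-rate percentile bands centred on 2 %, 10 %, 30 %, 60 %, 90 %
  across the five years (years 2–3 published, the rest interpolated to
  near-full uptake of the *elicited pool*, which itself counts adopters
  by year 5);
* socio-political risk probabilities 0.25 / 0.25 / 0.20 — "relatively
  high", as the source characterizes them, while keeping a 30 % none
  state; flood probability 0.10, matching the drought rate (both derive
  from decade-scale disaster records); GHG balance Normal(0.3, 0.15)
  t CO2-eq/beneficiary/yr and price Uniform(5, 30) USD/t, spanning the
  voluntary-market prices of the period.

Consequently the fixture's headline numbers are demonstrative. What *is*
reproducible — and what the test suite asserts — is the qualitative
pattern: natural risks alone cause a mild decrease in expected NPV,
socio-political risks a large one, and all risks together the lowest
value. Passing tests on this fixture show the machinery propagates risk
the way the published analysis describes; they do not validate the
stand-in values against the original elicitation.

## Problem sizes used by the test suite

Deterministic oracles run at trivial sizes. The distributional checks use
100,000 draws for the closed-form mean comparison (3 standard errors),
20,000 draws per scenario for the case-like pattern, and a sweep of 100
random fixtures (2,000 overall + 1,000 per forced state) for the mixture
law `E[NPV] = sum_s p_s E[NPV | state s]`. These sizes keep every
statistical assertion at the 3-standard-error level while the whole suite
completes in about two minutes on one core.

## Known limitations

* Forward sampling only: posterior queries are answered by filtering
  draws, which degrades for rare events (the empty-conditional error is
  the guard rail). There is no exact hybrid-BN inference.
* No decision nodes, portfolio optimization or value-of-information
  analysis; scenarios are compared, not optimized over.
* Natural hazards are mutually exclusive within a year by construction.
* Direct-mode adoption priors are not constrained to be monotone over
  years.
* The drought index is the z-score variant; results will differ from
  gamma-fitted SPI tooling on skewed climatologies.
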