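Package: ebis
Title: Evidence-Based Investment Selection for Agricultural Development
    Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic evaluation of agricultural development
    investments under natural, socio-political (adoption) and financial
    risk. A dynamic Bayesian-network fragment linking adoption, income
    impact, greenhouse-gas value, costs and budget is rolled forward by
    seeded Monte-Carlo simulation to produce net-present-value and
    return-on-investment distributions under what-if risk scenarios.
    Includes elicitation utilities that turn published evidence into
    prior distributions: percentile-based Normal and Beta fits,
    drought-event counting from monthly rainfall, linear governance
    indicator-to-probability scales, and meta-analytic pooling of effect
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    metafor,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
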