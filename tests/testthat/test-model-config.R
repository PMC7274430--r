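test_that("a well-formed spec validates cleanly and structural errors are caught", {
  fx <- make_case_like_fixture()
  expect_identical(nrow(validate_project_spec(fx$spec)), 0L)
  expect_identical(fx$spec$evaluation_period, 5L)
  expect_length(fx$spec$finance$yearly_costs, 5)

  # category probabilities plus the implicit none-state must be a distribution
  bad <- fx$spec
  bad$natural_risks[[1]]$annual_probability <- 0.7
  bad$natural_risks[[2]]$annual_probability <- 0.5
  v <- validate_project_spec(bad)
  expect_true(any(v$rule == "category_probability_sum" & v$field == "natural_risks"))

  # wrong yearly cost count is named
  bad <- fx$spec
  bad$finance$yearly_costs <- bad$finance$yearly_costs[1:4]
  v <- validate_project_spec(bad)
  expect_true(any(grepl("yearly_costs", v$field) & v$rule == "length"))

  # corrupted distribution parameters are reported as data, not raised
  bad <- fx$spec
  bad$adoption$yearly_rates[[2]]$params$alpha <- -1
  v <- validate_project_spec(bad)
  expect_true(any(grepl("yearly_rates\\[2\\]", v$field)))
})

test_that("single-field corruptions of a valid spec are each flagged", {
  fx <- make_point_mass_fixture()
  corruptions <- list(
    function(s) { s$finance$discount_rate <- -0.1; s },
    function(s) { s$finance$reduction_rate <- 1.4; s },
    function(s) { s$finance$roi_denominator <- "nominal"; s },
    function(s) { s$evaluation_period <- 2.5; s },
    function(s) { s$adoption$mode <- "magic"; s },
    function(s) { s$adoption$yearly_rates[[1]]$params$value <- 1.7; s },
    function(s) { s$finance$yearly_costs[[1]]$params$value <- -5; s },
    function(s) { s$impact$adopter_income <- NULL; s }
  )
  for (corrupt in corruptions) {
    v <- validate_project_spec(corrupt(fx$spec))
    expect_gt(nrow(v), 0)
  }
})

test_that("save/load round-trips are value-identical across formats and families", {
  fx <- make_case_like_fixture()
  spec <- fx$spec
  # exercise discrete distributions and area scope too
  spec$impact$ghg_cost <- dist_spec("discrete", values = c(5, 10, 30),
                                    probs = c(0.25, 0.5, 0.25), units = "USD per t CO2-eq")
  spec$adoption$scope_basis <- "area"
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    save_project_spec(spec, path)
    expect_spec_equal(load_project_spec(path), spec)
  }
})

test_that("fuzzed random specs round-trip through the file format", {
  for (seed in c(11, 23, 37, 58, 71)) {
    spec <- make_random_fixture(seed)$spec
    expect_identical(nrow(validate_project_spec(spec)), 0L)
    path <- tempfile(fileext = ".yaml")
    save_project_spec(spec, path)
    expect_spec_equal(load_project_spec(path), spec)
  }
})

test_that("loading rejects files that violate the schema or the invariants", {
  fx <- make_point_mass_fixture()
  path <- tempfile(fileext = ".yaml")
  save_project_spec(fx$spec, path)

  txt <- readLines(path)
  writeLines(txt[!grepl("^name:", txt)], path)
  expect_error(load_project_spec(path), "name")

  path2 <- tempfile(fileext = ".yaml")
  save_project_spec(fx$spec, path2)
  txt <- readLines(path2)
  writeLines(sub("evaluation_period: 2", "evaluation_period: 3", txt), path2)
  expect_error(load_project_spec(path2), "yearly_costs")

  expect_error(load_project_spec(tempfile(fileext = ".yaml")), "not found")
})
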