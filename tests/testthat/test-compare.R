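comparison_fixture <- local({
  st <- tiny_study(seed = 23)
  cfg <- st$config
  sch <- cfg$scheme
  spec_full <- model_spec(names(sch$factors), "pct_poverty")
  spec_nocov <- model_spec(names(sch$factors))
  raked <- rake_all_areas(sch, st$margins)
  fit_once <- function(spec) {
    fit <- fit_multilevel_logistic(st$survey, st$covariates, spec, sch,
                                   se = FALSE)
    est <- poststratify(
      predict_cell_probabilities(fit, st$covariates, st$margins$areas),
      raked)
    list(fit = fit, est = est)
  }
  list(st = st, full = fit_once(spec_full), nocov = fit_once(spec_nocov))
})

test_that("identical specifications give identical estimates", {
  fx <- comparison_fixture
  again <- local({
    st <- fx$st; sch <- st$config$scheme
    fit <- fit_multilevel_logistic(st$survey, st$covariates,
                                   model_spec(names(sch$factors),
                                              "pct_poverty"),
                                   sch, se = FALSE)
    poststratify(
      predict_cell_probabilities(fit, st$covariates, st$margins$areas),
      rake_all_areas(sch, st$margins))
  })
  expect_identical(fx$full$est$estimate, again$estimate)
})

test_that("comparison reports per-model ranges in percent notation", {
  fx <- comparison_fixture
  cmp <- compare_models(list(full = fx$full$fit, reduced = fx$nocov$fit),
                        list(full = fx$full$est, reduced = fx$nocov$est))
  expect_match(cmp$ranges[["full"]], "^[0-9]+\\.[0-9]–[0-9]+\\.[0-9]%$")
  expect_equal(nrow(cmp$table), length(fx$st$margins$areas))
  expect_true(all(c("full", "reduced") %in% names(cmp$table)))
})

test_that("models fitted to different surveys cannot be compared", {
  fx <- comparison_fixture
  other <- tiny_study(seed = 24)
  sch <- other$config$scheme
  fit_other <- fit_multilevel_logistic(other$survey, other$covariates,
                                       model_spec(names(sch$factors),
                                                  "pct_poverty"),
                                       sch, se = FALSE)
  expect_error(compare_models(list(a = fx$full$fit, b = fit_other),
                              list(a = fx$full$est, b = fx$full$est)),
               "different surveys")
  expect_error(compare_models(list(a = fx$full$fit),
                              list(a = fx$full$est)),
               "at least 2")
})

test_that("direct benchmarks attach error metrics to the comparison", {
  fx <- comparison_fixture
  tr <- fx$st$truth
  direct <- stats::setNames(tr$prevalence, tr$area_id)
  cmp <- compare_models(list(full = fx$full$fit, reduced = fx$nocov$fit),
                        list(full = fx$full$est, reduced = fx$nocov$est),
                        direct_est = direct)
  expect_named(cmp$metrics, c("full", "reduced"))
  expect_gte(cmp$metrics$full$mse, 0)
  # metrics are on the percentage scale
  expect_lt(cmp$metrics$full$mad, 100)
})
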