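# fast shared fixture: moderate random-effect SD, most areas sampled so
# sigma_mu is interior
fit_fixture <- local({
  cfg <- tiny_generator_config(seed = 3, sigma_mu = 0.5, n_areas = 8,
                               areas_sampled = 6,
                               sample_sizes = c(400L, 350L, 300L, 300L,
                                                250L, 200L))
  st <- simulate_study(cfg)
  list(cfg = cfg, st = st)
})

test_that("the adaptive-quadrature fit matches an independent GLMM fitter", {
  skip_if_not_installed("lme4")
  cfg <- fit_fixture$cfg; st <- fit_fixture$st
  fit <- fit_multilevel_logistic(st$survey, st$covariates, st$spec,
                                 cfg$scheme)
  d <- merge(st$survey, st$covariates, by = "area_id")
  for (f in names(cfg$scheme$factors))
    d[[f]] <- factor(d[[f]], levels = cfg$scheme$factors[[f]])
  ref <- lme4::glmer(y ~ age + sex + education + pct_poverty +
                       (1 | area_id),
                     data = d, family = binomial, nAGQ = 15)
  expect_lt(max(abs(coef(fit) - lme4::fixef(ref))), 1e-3)
  expect_lt(abs(fit$sigma_mu -
                  sqrt(unlist(lme4::VarCorr(ref))[1])), 1e-3)
  expect_lt(abs(fit$logLik - as.numeric(logLik(ref))), 1e-4)
  expect_lt(max(abs(fit$mu - lme4::ranef(ref)$area_id[[1]])), 1e-3)
})

test_that("zero random-effect data collapses to ordinary logistic regression", {
  cfg <- tiny_generator_config(seed = 5, sigma_mu = 0)
  st <- simulate_study(cfg)
  fit <- fit_multilevel_logistic(st$survey, st$covariates, st$spec,
                                 cfg$scheme)
  expect_lt(fit$sigma_mu, 0.05)
  d <- merge(st$survey, st$covariates, by = "area_id")
  for (f in names(cfg$scheme$factors))
    d[[f]] <- factor(d[[f]], levels = cfg$scheme$factors[[f]])
  ref <- glm(y ~ age + sex + education + pct_poverty, data = d,
             family = binomial)
  expect_lt(max(abs(coef(fit) - coef(ref))), 1e-3)
})

test_that("degenerate and malformed inputs raise fitting errors", {
  cfg <- tiny_generator_config(seed = 5)
  st <- simulate_study(cfg)
  sv <- st$survey
  sv$y <- 1L
  expect_error(fit_multilevel_logistic(sv, st$covariates, st$spec,
                                       cfg$scheme),
               "separation|degenerate")
  expect_error(fit_multilevel_logistic(st$survey, NULL, st$spec,
                                       cfg$scheme),
               "covariates")
  expect_error(fit_multilevel_logistic(
    st$survey, st$covariates,
    model_spec(c("age", "nope"), "pct_poverty"), cfg$scheme),
    "nope")
  wsv <- st$survey; wsv$weight <- 2
  expect_warning(fit_multilevel_logistic(wsv, st$covariates, st$spec,
                                         cfg$scheme),
                 "unweighted")
})

test_that("fit is stable in the number of quadrature nodes", {
  cfg <- fit_fixture$cfg; st <- fit_fixture$st
  f7 <- fit_multilevel_logistic(st$survey, st$covariates, st$spec,
                                cfg$scheme, quadrature_points = 7, se = FALSE)
  f25 <- fit_multilevel_logistic(st$survey, st$covariates, st$spec,
                                 cfg$scheme, quadrature_points = 25,
                                 se = FALSE)
  expect_lt(max(abs(coef(f7) - coef(f25))), 1e-4)
})

test_that("marginal likelihood at the optimum dominates the truth", {
  cfg <- fit_fixture$cfg; st <- fit_fixture$st
  fit <- fit_multilevel_logistic(st$survey, st$covariates, st$spec,
                                 cfg$scheme, se = FALSE)
  ll_true <- marginal_loglik(fit, st$survey, st$covariates, cfg$scheme,
                             coefficients = c(cfg$beta, cfg$eta),
                             sigma_mu = cfg$sigma_mu)
  expect_gte(fit$logLik, ll_true - 1e-6)
})

test_that("cell predictions follow the inverse-logit closed form", {
  sch <- strat_scheme(g = c("a", "b"))
  sv <- data.frame(area_id = rep(c("A", "B"), each = 12),
                   y = rep(c(0L, 1L, 1L, 0L), 6),
                   g = rep(c("a", "b"), 12))
  cov <- data.frame(area_id = c("A", "B", "C"), z = c(0.3, 0.1, 0.3))
  fit <- fit_multilevel_logistic(sv, cov, model_spec("g", "z"), sch,
                                 se = FALSE)
  # overwrite the fitted parameters with known values
  fit$coefficients[] <- c(0, 0, 1)   # intercept, g=b, z
  fit$eta[] <- 1
  fit$mu[] <- c(0.2, 0)
  fit$sigma_mu <- 0.4
  pr <- predict_cell_probabilities(fit, cov, "A",
                                   re_policy = "conditional_blup")
  # lin = 0 + 1*0.3 + mu 0.2 = 0.5
  expect_equal(pr$p, rep(1 / (1 + exp(-0.5)), 2), tolerance = 1e-12)
  expect_equal(pr$p[1], 0.62246, tolerance = 1e-4)

  # all coefficients zero, mu* = 0 -> every probability one half
  fit0 <- fit
  fit0$coefficients[] <- 0
  pr0 <- predict_cell_probabilities(fit0, cov, c("A", "C"),
                                    re_policy = "conditional_zero")
  expect_true(all(pr0$p == 0.5))

  # sigma ~ 0: marginal equals conditional_zero for unsampled areas
  fitz <- fit
  fitz$sigma_mu <- 0
  pz <- predict_cell_probabilities(fitz, cov, "C",
                                   re_policy = "conditional_zero")
  pm <- predict_cell_probabilities(fitz, cov, "C", re_policy = "marginal")
  expect_equal(pz$p, pm$p, tolerance = 1e-12)

  # marginal with positive sigma shrinks toward one half
  pmar <- predict_cell_probabilities(fit, cov, "C", re_policy = "marginal")
  pcz <- predict_cell_probabilities(fit, cov, "C",
                                    re_policy = "conditional_zero")
  expect_true(all(abs(pmar$p - 0.5) < abs(pcz$p - 0.5)))
  expect_error(predict_cell_probabilities(fit, cov, "D"), "area")
})

test_that("fixed-effect variant matches a near-zero-sigma multilevel fit", {
  # large per-area samples: the free area dummies of the fixed-effect fit
  # approach zero only at the rate of their sampling error
  cfg <- tiny_generator_config(seed = 9, sigma_mu = 0,
                               eta = stats::setNames(numeric(0),
                                                     character(0)),
                               sample_sizes = c(9000L, 8000L, 7000L),
                               pop_meanlog = log(1e5),
                               pop_range = c(5e4, 3e5))
  st <- simulate_study(cfg)
  spec_ri <- model_spec(names(cfg$scheme$factors), random_intercept = TRUE)
  spec_fx <- model_spec(names(cfg$scheme$factors), random_intercept = FALSE)
  f_ri <- fit_multilevel_logistic(st$survey, NULL, spec_ri, cfg$scheme,
                                  se = FALSE)
  f_fx <- fit_multilevel_logistic(st$survey, NULL, spec_fx, cfg$scheme)
  expect_identical(f_fx$type, "fixed")
  sampled <- f_ri$areas_sampled
  p_ri <- predict_cell_probabilities(f_ri, NULL, sampled,
                                     re_policy = "conditional_blup")
  p_fx <- predict_cell_probabilities(f_fx, NULL, sampled)
  expect_lt(max(abs(p_ri$p - p_fx$p)), 0.01)
  expect_error(predict_cell_probabilities(f_fx, NULL, "area99"),
               "unsampled")
})
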