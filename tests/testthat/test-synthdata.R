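test_that("the generator is deterministic in its master seed", {
  cfg <- tiny_generator_config(seed = 21)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$population$population, s2$population$population)
  expect_identical(s1$survey, s2$survey)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(tiny_generator_config(seed = 22))
  expect_false(identical(s1$survey, s3$survey))
})

test_that("zero dependence gives independent factors, up to sampling error", {
  cfg <- tiny_generator_config(seed = 8, dependence = 0,
                               pop_meanlog = log(2e5), pop_sdlog = 0.01,
                               pop_range = c(1e5, 4e5))
  pop <- generate_population(cfg)
  a <- pop$truth$area_id[1]
  sub <- pop$population[pop$population$area_id == a, ]
  N <- sum(sub$count)
  pj <- sub$count / N
  marg <- lapply(names(cfg$scheme$factors), function(f)
    tapply(sub$count, sub[[f]], sum) / N)
  names(marg) <- names(cfg$scheme$factors)
  prod_p <- Reduce(`*`, lapply(names(marg), function(f)
    marg[[f]][sub[[f]]]))
  expect_lt(max(abs(pj - prod_p)), 5e-3)
})

test_that("a flat outcome model gives prevalence one half everywhere", {
  cfg <- tiny_generator_config(seed = 6, sigma_mu = 0,
                               eta = c(pct_poverty = 0))
  cfg$beta[] <- 0
  pop <- generate_population(cfg)
  expect_equal(pop$truth$prevalence, rep(0.5, cfg$n_areas))
})

test_that("derived margins are exact sums and compose associatively", {
  sch <- strat_scheme(a = c("x", "y"), b = c("u", "v"))
  joint <- data.frame(area_id = "A", cell = 0:3,
                      a = c("x", "x", "y", "y"),
                      b = c("u", "v", "u", "v"),
                      count = c(1, 2, 3, 4))
  ms <- derive_margins(joint, sch, list("a", "b"))
  expect_equal(as.numeric(ms$targets[[1]]["A", ]), c(3, 7))
  expect_equal(as.numeric(ms$targets[[2]]["A", ]), c(4, 6))
  # full joint as one margin reproduces the joint
  msj <- derive_margins(joint, sch, list(c("a", "b")))
  expect_equal(as.numeric(msj$targets[[1]]["A", ]), c(1, 2, 3, 4))
  expect_error(derive_margins(joint, sch, list("a", "q")), "unknown")

  # margins of margins: {a} from the population equals {a} from {a,b}
  st <- tiny_study(seed = 13)
  popdf <- st$population$population
  sch3 <- st$config$scheme
  direct_a <- derive_margins(popdf, sch3, list("age", c("sex", "education")))
  ab <- stats::aggregate(popdf["count"],
                         popdf[c("area_id", "age", "sex")], sum)
  from_ab <- stats::aggregate(ab["count"], ab[c("area_id", "age")], sum)
  tgt <- direct_a$targets[[1]]
  for (ar in rownames(tgt)) {
    v <- from_ab$count[from_ab$area_id == ar][
      match(sch3$factors$age, from_ab$age[from_ab$area_id == ar])]
    expect_equal(as.numeric(tgt[ar, ]), v)
  }
})

test_that("raking error against the true joint shrinks with dependence", {
  one_mae <- function(dep, s) {
    cfg <- tiny_generator_config(seed = s, dependence = dep,
                                 pop_meanlog = log(5e4),
                                 pop_range = c(2e4, 1e5))
    pop <- generate_population(cfg)
    rk <- rake_all_areas(cfg$scheme, derive_margins(pop))
    key <- paste(rk$area_id, rk$cell)
    tru <- pop$population
    mean(abs(rk$count -
               tru$count[match(key, paste(tru$area_id, tru$cell))]) /
           pop$truth$N[match(rk$area_id, pop$truth$area_id)])
  }
  # average over replicate populations: a single draw of the log-linear
  # interaction terms is too noisy to order nearby dependence levels
  maes <- vapply(c(0.8, 0.4, 0), function(dep)
    mean(vapply(1:12, function(s) one_mae(dep, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(maes) < 0))
})

test_that("survey draws respect sampling design constraints", {
  cfg <- tiny_generator_config(seed = 14)
  pop <- generate_population(cfg)
  a <- pop$truth$area_id[which.min(pop$truth$N)]
  N_a <- pop$truth$N[pop$truth$area_id == a]

  # census case: full enumeration reproduces the joint exactly
  sv <- draw_survey(pop, sample_sizes = stats::setNames(N_a, a))
  tab <- table(factor(cell_index(cfg$scheme,
                                 sv[names(cfg$scheme$factors)]),
                      levels = 0:(cfg$scheme$n_cells - 1)))
  truth <- pop$population$count[pop$population$area_id == a]
  expect_equal(as.numeric(tab), truth)

  expect_error(draw_survey(pop, sample_sizes = stats::setNames(N_a + 1, a)),
               "sampling rate > 1")
  expect_error(draw_survey(pop, sample_sizes = stats::setNames(10, "zz")),
               "unknown area")

  # realized factor-level counts concentrate around expectation
  b <- pop$truth$area_id[which.max(pop$truth$N)]
  n_b <- 2000L
  svb <- draw_survey(pop, sample_sizes = stats::setNames(n_b, b), seed = 77)
  subpop <- pop$population[pop$population$area_id == b, ]
  p_lvl <- tapply(subpop$count, subpop$education, sum) / sum(subpop$count)
  obs <- table(factor(svb$education, levels = names(p_lvl)))
  expect_true(all(abs(as.numeric(obs) - n_b * p_lvl) <=
                    3 * sqrt(n_b * p_lvl * (1 - p_lvl)) + 1))
})
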