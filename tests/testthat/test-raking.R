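test_that("uniform seed converges to the independence table on 2x2", {
  sch <- strat_scheme(r = c("r1", "r2"), c = c("c1", "c2"))
  ms <- margin_set(sch, list(
    r = data.frame(area_id = "A", r = c("r1", "r2"), count = c(3, 1)),
    c = data.frame(area_id = "A", c = c("c1", "c2"), count = c(2, 2))))
  rk <- rake(sch, ms, "A")
  expect_equal(rk$count, c(1.5, 1.5, 0.5, 0.5))
  expect_true(raking_metadata(rk)$converged)
})

test_that("a seed already satisfying the margins is a fixed point", {
  sch <- strat_scheme(r = c("r1", "r2"), c = c("c1", "c2"))
  seed <- c(1.2, 1.8, 0.8, 0.2)  # rows (3,1), cols (2,2)
  ms <- margin_set(sch, list(
    r = data.frame(area_id = "A", r = c("r1", "r2"), count = c(3, 1)),
    c = data.frame(area_id = "A", c = c("c1", "c2"), count = c(2, 2))))
  rk <- rake(sch, ms, "A", seed = seed)
  expect_equal(rk$count, seed, tolerance = 1e-12)
})

test_that("raked tables match the brute-force IPF oracle", {
  sch <- strat_scheme(r = c("r1", "r2"), c = c("c1", "c2"))
  ms <- margin_set(sch, list(
    r = data.frame(area_id = "A", r = c("r1", "r2"), count = c(4, 2)),
    c = data.frame(area_id = "A", c = c("c1", "c2"), count = c(3, 3))))
  rk <- rake(sch, ms, "A", seed = c(2, 1, 1, 2), tol = 1e-12)
  W <- bf_ipf(array(c(2, 1, 1, 2), c(2, 2)),  # array is column-major
              list(list(dims = 1, target = c(4, 2)),
                   list(dims = 2, target = c(3, 3))))
  expect_equal(rk$count, canon_order(W), tolerance = 1e-8)

  for (s in 0:9) {
    fx <- random_rake_fixture(seed = s)
    ms <- margin_set(fx$scheme, fx$margins_pkg)
    rk <- rake(fx$scheme, ms, "A",
               seed = canon_order(fx$seed_arr), tol = 1e-13)
    W <- bf_ipf(fx$seed_arr, fx$margins_bf)
    expect_equal(rk$count, canon_order(W), tolerance = 1e-8,
                 label = paste("fixture seed", s))
  }
})

test_that("raking preserves totals, nonnegativity and structural zeros", {
  fx <- random_rake_fixture(seed = 42, n_factors = 3)
  ms <- margin_set(fx$scheme, fx$margins_pkg)
  rk <- rake(fx$scheme, ms, "A", tol = 1e-10)
  N <- sum(fx$joint)
  expect_equal(sum(rk$count), N, tolerance = 1e-9 * N)
  expect_true(all(rk$count >= 0))

  # zero out one margin slice -> those cells must be exactly 0
  mp <- fx$margins_pkg
  lvl0 <- mp[[length(mp)]][1, 2]
  zeroed <- mp
  drop_n <- zeroed[[length(mp)]]$count[zeroed[[length(mp)]][, 2] == lvl0]
  zeroed[[length(mp)]]$count[zeroed[[length(mp)]][, 2] == lvl0] <- 0
  # rescale other margins so totals still agree
  fac <- (N - sum(drop_n)) / N
  for (k in seq_len(length(zeroed) - 1L))
    zeroed[[k]]$count <- zeroed[[k]]$count * fac
  ms0 <- margin_set(fx$scheme, zeroed)
  rk0 <- rake(fx$scheme, ms0, "A", tol = 1e-10)
  fcol <- names(zeroed[[length(mp)]])[2]
  in_slice <- rk0[[fcol]] == lvl0
  expect_true(all(rk0$count[in_slice] == 0))
  expect_true(all(rk0$count[!in_slice] > 0))
})

test_that("margin order does not change the converged table materially", {
  fx <- random_rake_fixture(seed = 7, n_factors = 3)
  tol <- 1e-10
  ms1 <- margin_set(fx$scheme, fx$margins_pkg)
  ms2 <- margin_set(fx$scheme, rev(fx$margins_pkg))
  r1 <- rake(fx$scheme, ms1, "A", tol = tol)
  r2 <- rake(fx$scheme, ms2, "A", tol = tol)
  N <- sum(fx$joint)
  expect_lt(max(abs(r1$count - r2$count)), 10 * tol * N)
})

test_that("max margin deviation is non-increasing across cycles", {
  for (s in c(3, 11, 19)) {
    fx <- random_rake_fixture(seed = s, n_factors = 3)
    ms <- margin_set(fx$scheme, fx$margins_pkg)
    rk <- rake(fx$scheme, ms, "A", seed = canon_order(fx$seed_arr),
               tol = 1e-12)
    trace <- attr(rk, "dev_trace")
    if (length(trace) > 1L)
      expect_true(all(diff(trace) <= 1e-9 * sum(fx$joint)))
  }
})

test_that("supplying the full joint as the single margin copies it", {
  sch <- strat_scheme(a = c("x", "y"), b = c("u", "v"))
  joint <- data.frame(area_id = "A",
                      a = c("x", "x", "y", "y"), b = c("u", "v", "u", "v"),
                      count = c(10, 20, 30, 40))
  ms <- margin_set(sch, list(joint = joint))
  rk <- rake(sch, ms, "A")
  expect_equal(rk$count, c(10, 20, 30, 40))
  expect_equal(raking_metadata(rk)$iterations, 1L)
})

test_that("seed policies cover cells without sampled respondents", {
  st <- tiny_study(seed = 4)
  sch <- st$config$scheme
  sv <- validate_survey(st$survey, sch)
  rk_u <- rake_all_areas(sch, st$margins, seed_policy = "uniform")
  rk_s <- rake_all_areas(sch, st$margins,
                         seed_policy = "sample_counts_plus_epsilon",
                         survey = sv)
  expect_true(all(rk_u$count > 0))
  expect_true(all(rk_s$count > 0))
  # both satisfy every margin
  for (rk in list(rk_u, rk_s)) {
    md <- raking_metadata(rk)
    expect_true(all(md$converged))
  }
  expect_error(rake_all_areas(sch, st$margins,
                              seed_policy = "sample_counts_plus_epsilon"),
               "needs a survey")
  expect_error(rake_all_areas(sch, st$margins, areas = "nowhere"),
               "nowhere")
})

test_that("state-scale raking (58 areas x 240 cells) runs in seconds", {
  cfg <- generator_config(seed = 3)
  pop <- generate_population(cfg)
  mar <- derive_margins(pop)
  t0 <- proc.time()
  rk <- rake_all_areas(cfg$scheme, mar, tol = 1e-8)
  elapsed <- (proc.time() - t0)[3]
  expect_lt(elapsed, 5)
  md <- raking_metadata(rk)
  expect_true(all(md$converged))
  # fitted two-way age x sex margin matches its target within tol * N
  tm <- mar$targets[[1]]
  map <- mrpraking:::margin_cell_map(cfg$scheme, c("age", "sex")) + 1L
  for (a in utils::head(mar$areas, 3)) {
    w <- rk$count[rk$area_id == a]
    fitted <- as.numeric(rowsum(w, map))
    expect_lt(max(abs(fitted - tm[a, ])), 1e-8 * mar$N[a] + 1e-9)
  }
})
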