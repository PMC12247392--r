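#' Configure the synthetic study generator
#'
#' The generator emulates the structure the estimation method assumes: a
#' multi-county population whose stratification factors are dependent
#' (pairwise log-linear interactions, so the joint is not the product of
#' its margins), a logistic outcome model with county random effects and a
#' continuous county covariate, and a survey that observes only a few
#' (large, metro-like) areas while estimates are produced for all areas.
#'
#' The default configuration mirrors a state-scale study: 58 areas of which
#' the 5 largest are surveyed with sample sizes (3400, 830, 1512, 882, 533),
#' a 6x2x4x5 = 240-cell scheme, census margins = joint age x sex plus
#' one-way education and race, poverty percentage as the area covariate
#' with a strong effect (eta = -0.05 per point), and a modest residual
#' county random-effect SD (sigma_mu = 0.15 on the logit scale).
#'
#' @param n_areas number of areas in the population.
#' @param areas_sampled how many areas the survey observes (the largest by
#'   population, mimicking metro-area surveillance samples).
#' @param scheme the [strat_scheme()] of stratification factors.
#' @param sample_sizes per-sampled-area respondent counts (length
#'   `areas_sampled`).
#' @param margin_subsets list of factor subsets defining which margins the
#'   "census" releases.
#' @param beta named true fixed-effect vector (built by
#'   [default_true_beta()] when NULL).
#' @param eta named true area-covariate coefficients.
#' @param sigma_mu true random-intercept SD (logit scale).
#' @param dependence strength of the pairwise log-linear factor
#'   interactions in the population composition (0 = independent factors).
#' @param pop_meanlog,pop_sdlog,pop_range lognormal population-size
#'   distribution and clipping range.
#' @param covariate_mean,covariate_sd,covariate_range distribution of the
#'   area covariate (percent below poverty).
#' @param oversample optional unequal-probability sampling tilt: a list
#'   `list(factor = , weights = )` with one weight per level of that
#'   factor.
#' @param seed master seed; every generator function derives its
#'   randomness from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_areas = 58L,
                             areas_sampled = 5L,
                             scheme = default_scheme(),
                             sample_sizes = c(3400L, 830L, 1512L, 882L,
                                              533L),
                             margin_subsets = NULL,
                             beta = NULL,
                             eta = c(pct_poverty = -0.05),
                             sigma_mu = 0.15,
                             dependence = 0.3,
                             pop_meanlog = log(3e4), pop_sdlog = 1,
                             pop_range = c(3000, 3e5),
                             covariate_mean = 14, covariate_sd = 6,
                             covariate_range = c(3, 30),
                             oversample = list(
                               factor = "education",
                               weights = c(no_hs = 0.7, hs = 0.95,
                                           some_college = 1.1,
                                           college_grad = 1.3)),
                             seed = 1L) {
  stopifnot(inherits(scheme, "strat_scheme"),
            areas_sampled <= n_areas,
            length(sample_sizes) == areas_sampled)
  if (is.null(beta)) beta <- default_true_beta(scheme)
  if (is.null(margin_subsets)) {
    fn <- names(scheme$factors)
    if (all(c("age", "sex") %in% fn))
      margin_subsets <- c(list(c("age", "sex")),
                          as.list(setdiff(fn, c("age", "sex"))))
    else margin_subsets <- as.list(fn)
  }
  if (!is.null(oversample)) {
    if (!oversample$factor %in% names(scheme$factors))
      stop("oversample factor '", oversample$factor,
           "' not in the scheme", call. = FALSE)
    lv <- scheme$factors[[oversample$factor]]
    if (!setequal(names(oversample$weights), lv))
      stop("oversample weights must name every level of '",
           oversample$factor, "'", call. = FALSE)
  }
  structure(list(n_areas = as.integer(n_areas),
                 areas_sampled = as.integer(areas_sampled),
                 scheme = scheme, sample_sizes = as.integer(sample_sizes),
                 margin_subsets = margin_subsets,
                 beta = beta, eta = eta, sigma_mu = sigma_mu,
                 dependence = dependence,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 pop_range = pop_range,
                 covariate_mean = covariate_mean,
                 covariate_sd = covariate_sd,
                 covariate_range = covariate_range,
                 oversample = oversample,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Tiny generator profile for fast unit tests
#'
#' 6 areas (3 surveyed with sample sizes 150/120/100), a 2x2x2 scheme,
#' margins = joint age x sex plus one-way education; same outcome-model
#' shape as the default profile.
#'
#' @param seed master seed.
#' @param ... overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
tiny_generator_config <- function(seed = 1L, ...) {
  scheme <- strat_scheme(age = c("18-44", "45+"),
                         sex = c("male", "female"),
                         education = c("hs_or_less", "college"))
  args <- list(n_areas = 6L, areas_sampled = 3L, scheme = scheme,
               sample_sizes = c(150L, 120L, 100L),
               margin_subsets = list(c("age", "sex"), "education"),
               pop_meanlog = log(5000), pop_sdlog = 0.5,
               pop_range = c(1500, 2e4),
               oversample = NULL, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(generator_config, args)
}

#' Default true fixed effects for a scheme
#'
#' Intercept 0.4 (baseline utilization ~60%); within each factor the
#' non-reference levels get evenly spaced coefficients from -0.3 to 0.3 on
#' the logit scale (a single non-reference level gets 0.3), giving
#' realistic moderate demographic gradients.
#'
#' @param scheme a [strat_scheme()].
#' @return Named coefficient vector matching the fitter's dummy coding.
#' @export
default_true_beta <- function(scheme) {
  beta <- c("(Intercept)" = 0.4)
  for (f in names(scheme$factors)) {
    lv <- scheme$factors[[f]]
    k <- length(lv) - 1L
    vals <- if (k == 1L) 0.3 else seq(-0.3, 0.3, length.out = k)
    names(vals) <- paste0(f, "=", lv[-1L])
    beta <- c(beta, vals)
  }
  beta
}

implied_model_spec <- function(config)
  model_spec(fixed = names(config$scheme$factors),
             area_covariates = names(config$eta),
             random_intercept = TRUE)

#' Generate a synthetic multi-area population
#'
#' Per-area joint cell counts are drawn multinomially from a log-linear
#' composition model with area-specific main effects and shared pairwise
#' interactions of strength `dependence`; true cell outcome probabilities
#' come from the logistic model with true coefficients, the area covariate
#' and a N(0, sigma_mu^2) area random effect. True area prevalence is the
#' count-weighted mean of the true cell probabilities.
#'
#' @param config a [generator_config()].
#' @param seed seed (default: the config's master seed).
#' @return list of class `synth_population`: `population` (area x cell
#'   counts and true probabilities), `covariates`, `truth` (per-area N,
#'   random effect, true prevalence), `sampled_areas` (the largest areas),
#'   `params`, `config`.
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  scheme <- config$scheme
  fn <- names(scheme$factors)
  areas <- sprintf("area%02d", seq_len(config$n_areas))

  N <- round(pmin(pmax(stats::rlnorm(config$n_areas, config$pop_meanlog,
                                     config$pop_sdlog),
                       config$pop_range[1]), config$pop_range[2]))
  z <- pmin(pmax(stats::rnorm(config$n_areas, config$covariate_mean,
                              config$covariate_sd),
                 config$covariate_range[1]), config$covariate_range[2])
  mu <- stats::rnorm(config$n_areas, 0, config$sigma_mu)

  grid <- cell_grid(scheme)
  # shared pairwise interactions + per-area main effects
  theta_pair <- numeric(scheme$n_cells)
  if (length(fn) > 1L && config$dependence != 0) {
    for (a in seq_along(fn)[-length(fn)]) for (b in (a + 1L):length(fn)) {
      la <- scheme$factors[[fn[a]]]; lb <- scheme$factors[[fn[b]]]
      G <- matrix(stats::rnorm(length(la) * length(lb), 0, 1),
                  length(la), length(lb)) * config$dependence
      theta_pair <- theta_pair +
        G[cbind(match(grid[[fn[a]]], la), match(grid[[fn[b]]], lb))]
    }
  }
  main_base <- lapply(fn, function(f)
    stats::rnorm(length(scheme$factors[[f]]), 0, 0.4))
  names(main_base) <- fn

  spec <- implied_model_spec(config)
  covariates <- data.frame(area_id = areas, stringsAsFactors = FALSE)
  for (v in names(config$eta)) covariates[[v]] <- z

  gdf <- grid
  for (v in names(config$eta)) gdf[[v]] <- covariates[[v]][1L]
  Xg <- build_design(gdf, spec, scheme)
  coefs <- c(config$beta, config$eta)
  miss <- setdiff(colnames(Xg), names(coefs))
  if (length(miss))
    stop("true coefficients missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  beta_part <- as.numeric(
    Xg[, setdiff(colnames(Xg), names(config$eta)), drop = FALSE] %*%
      config$beta[setdiff(colnames(Xg), names(config$eta))])

  pieces <- vector("list", config$n_areas)
  prevalence <- numeric(config$n_areas)
  for (i in seq_len(config$n_areas)) {
    theta <- theta_pair
    for (f in fn) {
      jit <- main_base[[f]] + stats::rnorm(length(scheme$factors[[f]]),
                                           0, 0.15)
      theta <- theta + jit[match(grid[[f]], scheme$factors[[f]])]
    }
    if (any(!is.finite(theta)))
      stop("infeasible composition model (non-finite log-linear terms)",
           call. = FALSE)
    prob <- exp(theta - max(theta)); prob <- prob / sum(prob)
    counts <- as.numeric(stats::rmultinom(1L, N[i], prob))
    lin <- beta_part + sum(config$eta * 0) +
      as.numeric(as.matrix(covariates[i, names(config$eta),
                                      drop = FALSE]) %*% config$eta) + mu[i]
    p_cell <- stats::plogis(lin)
    prevalence[i] <- sum(counts * p_cell) / N[i]
    df <- grid
    df$area_id <- areas[i]
    df$count <- counts
    df$p <- p_cell
    pieces[[i]] <- df[c("area_id", names(grid), "count", "p")]
  }
  population <- do.call(rbind, pieces)
  truth <- data.frame(area_id = areas, N = N, mu = mu,
                      prevalence = prevalence, stringsAsFactors = FALSE)
  sampled <- areas[order(N, decreasing = TRUE)][seq_len(config$areas_sampled)]
  structure(list(population = population, covariates = covariates,
                 truth = truth, sampled_areas = sort(sampled),
                 params = list(beta = config$beta, eta = config$eta,
                               sigma_mu = config$sigma_mu),
                 config = config),
            class = "synth_population")
}

#' Derive census-style margins from a true joint distribution
#'
#' Exact sums of the per-area joint counts over the complementary factors
#' of each requested subset.
#'
#' @param population a `synth_population` or a data.frame with columns
#'   `area_id`, `cell`, `count`.
#' @param scheme the scheme (taken from the population object when given).
#' @param subsets list of character vectors of factor names; together they
#'   must cover every scheme factor.
#' @param ... passed to [margin_set()] (e.g. `tol`, `rescale`).
#' @return A [margin_set()].
#' @export
derive_margins <- function(population, scheme = NULL, subsets = NULL, ...) {
  if (inherits(population, "synth_population")) {
    if (is.null(scheme)) scheme <- population$config$scheme
    if (is.null(subsets)) subsets <- population$config$margin_subsets
    population <- population$population
  }
  stopifnot(inherits(scheme, "strat_scheme"), is.list(subsets))
  fn <- names(scheme$factors)
  unknown <- setdiff(unlist(subsets), fn)
  if (length(unknown))
    stop("margin subset references unknown factor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tables <- lapply(subsets, function(sub) {
    sub <- fn[fn %in% sub]
    agg <- stats::aggregate(population["count"],
                            population[c("area_id", sub)], sum)
    agg
  })
  names(tables) <- vapply(subsets, function(s) paste(s, collapse = "_"), "")
  margin_set(scheme, tables, ...)
}

#' Draw a survey from a synthetic population
#'
#' Respondents in each surveyed area are drawn across cells proportionally
#' to the true cell counts, optionally tilted by the configured
#' unequal-probability factor (emulating a telephone-survey education
#' skew); outcomes are Bernoulli draws from the true cell probabilities.
#' When an area's sample size equals its population the survey is the full
#' census of that area (cell counts reproduced exactly); sample sizes
#' above the population are an error.
#'
#' @param population a `synth_population`.
#' @param sample_sizes named vector (names = area ids) of respondent
#'   counts; default: the config's sizes assigned to the sampled areas in
#'   decreasing population order.
#' @param seed seed (default: master seed + 1).
#' @return Survey data.frame: `area_id`, `y`, one column per factor.
#' @export
draw_survey <- function(population, sample_sizes = NULL,
                        seed = population$config$seed + 1L) {
  stopifnot(inherits(population, "synth_population"))
  config <- population$config
  scheme <- config$scheme
  if (is.null(sample_sizes)) {
    ord <- population$truth$area_id[order(population$truth$N,
                                          decreasing = TRUE)]
    sample_sizes <- stats::setNames(config$sample_sizes,
                                    ord[seq_len(config$areas_sampled)])
  }
  if (is.null(names(sample_sizes)))
    stop("sample_sizes must be named by area_id", call. = FALSE)
  unknown <- setdiff(names(sample_sizes), population$truth$area_id)
  if (length(unknown))
    stop("sample_sizes name unknown area(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  set.seed(seed)
  fn <- names(scheme$factors)
  pieces <- list()
  for (a in sort(names(sample_sizes))) {
    sub <- population$population[population$population$area_id == a, ,
                                 drop = FALSE]
    N_a <- sum(sub$count)
    n_a <- sample_sizes[[a]]
    if (n_a > N_a)
      stop("sampling rate > 1 for area '", a, "' (n = ", n_a,
           " > N = ", N_a, ")", call. = FALSE)
    if (n_a == N_a) {
      cell_n <- sub$count
    } else {
      w <- sub$count
      if (!is.null(config$oversample)) {
        tilt <- config$oversample$weights[sub[[config$oversample$factor]]]
        w <- w * as.numeric(tilt)
      }
      cell_n <- as.numeric(stats::rmultinom(1L, n_a, w / sum(w)))
    }
    keep <- cell_n > 0
    y <- stats::rbinom(sum(cell_n), 1L, rep(sub$p[keep], cell_n[keep]))
    df <- sub[rep(which(keep), cell_n[keep]), c("area_id", fn),
              drop = FALSE]
    rownames(df) <- NULL
    df <- cbind(df[, "area_id", drop = FALSE], y = y,
                df[, fn, drop = FALSE])
    pieces[[a]] <- df
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Population, census margins, area covariates and survey in one call, all
#' derived deterministically from one master seed.
#'
#' @param config a [generator_config()].
#' @param seed master seed override.
#' @return list: `population`, `margins`, `survey`, `covariates`, `truth`,
#'   `sampled_areas`, `spec` (the generator-matched [model_spec()]),
#'   `config`.
#' @export
simulate_study <- function(config, seed = config$seed) {
  pop <- generate_population(config, seed = seed)
  margins <- derive_margins(pop)
  survey <- draw_survey(pop, seed = seed + 1L)
  list(population = pop, margins = margins, survey = survey,
       covariates = pop$covariates, truth = pop$truth,
       sampled_areas = pop$sampled_areas,
       spec = implied_model_spec(config),
       config = config)
}
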