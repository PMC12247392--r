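#' Bootstrap percentile confidence intervals for area estimates
#'
#' Case-resampling bootstrap stratified by area: respondents are resampled
#' with replacement within each sampled area (area sample sizes fixed), the
#' multilevel model is refitted, cell probabilities re-predicted, and
#' post-stratification repeated against the FIXED raked counts (census
#' margins are treated as known and not resampled). The interval is the
#' percentile interval of the replicate estimates; results are
#' deterministic given `(seed, B)`. Replicates whose refit fails are
#' dropped and counted; more than 10% failures is an error unless
#' `allow_unstable = TRUE`.
#'
#' @param survey survey microdata.
#' @param covariates area-level covariates.
#' @param spec a [model_spec()].
#' @param scheme the [strat_scheme()].
#' @param margins a [margin_set()] (ignored if `raked` is supplied).
#' @param B number of bootstrap resamples (the conventional choice is
#'   1000).
#' @param seed integer seed; spawns one sub-seed per replicate.
#' @param level confidence level (default 0.95).
#' @param target_areas areas to estimate (default: all areas with margins).
#' @param re_policy random-effect policy for prediction, see
#'   [predict_cell_probabilities()].
#' @param raked optionally a precomputed `raked_table` to post-stratify
#'   against.
#' @param quadrature_points passed to the fitter.
#' @param allow_unstable tolerate >10% failed replicates (with a warning).
#' @return An `area_estimates` data.frame with columns `area_id`,
#'   `estimate` (point estimate from the original data), `ci_lower`,
#'   `ci_upper`, `N`; attribute `bootstrap` records `B`, effective
#'   replicates, failures, seed and level.
#' @export
bootstrap_ci <- function(survey, covariates = NULL, spec, scheme, margins,
                         B = 1000L, seed = 1L, level = 0.95,
                         target_areas = NULL,
                         re_policy = "conditional_blup",
                         raked = NULL, quadrature_points = 15L,
                         allow_unstable = FALSE) {
  stopifnot(B >= 2L, level > 0, level < 1)
  survey <- validate_survey(survey, scheme)
  if (is.null(raked)) {
    if (is.null(target_areas)) target_areas <- margins$areas
    raked <- rake_all_areas(scheme, margins, areas = target_areas)
  } else if (is.null(target_areas)) {
    target_areas <- unique(raked$area_id)
  }

  run_once <- function(dat, start = NULL) {
    fit <- fit_multilevel_logistic(dat, covariates, spec, scheme,
                                   quadrature_points = quadrature_points,
                                   se = FALSE, start = start)
    preds <- predict_cell_probabilities(fit, covariates, target_areas,
                                        re_policy = re_policy)
    list(fit = fit, est = poststratify(preds, raked))
  }

  base <- run_once(survey)
  point <- base$est[match(target_areas, base$est$area_id), , drop = FALSE]
  warm <- if (base$fit$type == "glmm")
    c(base$fit$coefficients, log(max(base$fit$sigma_mu, 1e-3))) else NULL

  idx_by_area <- split(seq_len(nrow(survey)), survey$area_id)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)
  est <- matrix(NA_real_, nrow = B, ncol = length(target_areas),
                dimnames = list(NULL, target_areas))
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    take <- unlist(lapply(idx_by_area, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    res <- tryCatch(
      suppressWarnings(run_once(survey[take, , drop = FALSE],
                                start = warm)$est),
      error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    est[b, ] <- res$estimate[match(target_areas, res$area_id)]
  }
  if (failed > 0.1 * B) {
    msg <- paste0(failed, " of ", B, " bootstrap replicates failed to ",
                  "converge")
    if (allow_unstable) warning(msg, call. = FALSE)
    else stop(msg, "; rerun with allow_unstable = TRUE to accept",
              call. = FALSE)
  }
  ok <- stats::complete.cases(est)
  alpha <- (1 - level) / 2
  ci <- apply(est[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- data.frame(area_id = target_areas,
                    estimate = point$estimate,
                    ci_lower = ci[1L, ],
                    ci_upper = ci[2L, ],
                    N = point$N,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("area_estimates", "data.frame")
  attr(out, "bootstrap") <- list(B = B, B_effective = sum(ok),
                                 failed = failed, seed = seed,
                                 level = level,
                                 replicate_seeds = rep_seeds)
  out
}
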