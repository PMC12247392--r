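#' Read survey microdata from CSV
#'
#' Expected columns: `area_id`, `y`, one column per scheme factor (levels
#' as strings). Malformed rows are reported with their line number.
#'
#' @param path CSV file.
#' @param scheme a [strat_scheme()].
#' @return Validated survey data.frame (see [validate_survey()]).
#' @export
read_survey <- function(path, scheme) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"y" %in% names(df))
    stop(path, ": missing 'y' column", call. = FALSE)
  y <- suppressWarnings(as.integer(df$y))
  bad <- which(is.na(y) | !(y %in% c(0L, 1L)))
  if (length(bad))
    stop(path, " line ", bad[1L] + 1L, ": invalid outcome '",
         df$y[bad[1L]], "'", call. = FALSE)
  df$y <- y
  tryCatch(validate_survey(df, scheme),
           error = function(e)
             stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' Read per-area margins from long-format CSV
#'
#' Expected columns: `area_id`, `margin_id`, one column per scheme factor
#' (empty for factors outside a given margin), `count`. All rows sharing a
#' `margin_id` must use the same factor columns.
#'
#' @param path CSV file.
#' @param scheme a [strat_scheme()].
#' @param tol relative tolerance for margin-total agreement.
#' @param rescale rescale disagreeing margins instead of erroring
#'   (the `--rescale-margins` behavior).
#' @return A [margin_set()].
#' @export
read_margins <- function(path, scheme, tol = 1e-6, rescale = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- setdiff(c("area_id", "margin_id", "count"), names(df))
  if (length(need))
    stop(path, ": missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt))
  if (length(bad))
    stop(path, " line ", bad[1L] + 1L, ": invalid count '",
         df$count[bad[1L]], "'", call. = FALSE)
  df$count <- cnt
  fn <- intersect(names(scheme$factors), names(df))
  tables <- lapply(split(df, df$margin_id), function(sub) {
    used <- fn[vapply(fn, function(f)
      any(!is.na(sub[[f]]) & sub[[f]] != ""), TRUE)]
    if (length(used) == 0L)
      stop(path, ": margin '", sub$margin_id[1L],
           "' uses no factor column", call. = FALSE)
    for (f in used)
      if (any(is.na(sub[[f]]) | sub[[f]] == ""))
        stop(path, ": margin '", sub$margin_id[1L],
             "' has empty '", f, "' entries", call. = FALSE)
    sub[c("area_id", used, "count")]
  })
  tryCatch(margin_set(scheme, tables, tol = tol, rescale = rescale),
           error = function(e)
             stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' Read area-level covariates from CSV
#'
#' Expected columns: `area_id` plus one numeric column per covariate.
#'
#' @param path CSV file.
#' @return Validated covariates data.frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_covariates(df)
}

#' Write area estimates to CSV
#'
#' Columns `area_id,estimate,ci_lower,ci_upper,N`. With `percent = TRUE`
#' estimates and CI bounds are written as percentages with one decimal
#' (the conventional reporting format); the default writes full-precision
#' proportions so that write/read round-trips losslessly.
#'
#' @param estimates an `area_estimates` data.frame.
#' @param path output CSV file.
#' @param percent write one-decimal percentages instead of proportions.
#' @export
write_estimates <- function(estimates, path, percent = FALSE) {
  out <- as.data.frame(estimates)
  for (col in c("ci_lower", "ci_upper"))
    if (!col %in% names(out)) out[[col]] <- NA_real_
  out <- out[c("area_id", "estimate", "ci_lower", "ci_upper", "N")]
  if (percent)
    for (col in c("estimate", "ci_lower", "ci_upper"))
      out[[col]] <- round(100 * out[[col]], 1)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read area estimates written by [write_estimates()]
#' @param path CSV file.
#' @return An `area_estimates` data.frame (proportions as written).
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$area_id <- as.character(df$area_id)
  class(df) <- c("area_estimates", "data.frame")
  df
}

#' Write a margin set to long-format CSV
#' @param margins a [margin_set()].
#' @param path output CSV file.
#' @export
write_margins <- function(margins, path) {
  stopifnot(inherits(margins, "margin_set"))
  fn <- names(margins$scheme$factors)
  pieces <- lapply(names(margins$margins), function(m) {
    mg <- margin_grid(margins$scheme, margins$margins[[m]]$factors)
    tm <- margins$targets[[m]]
    df <- data.frame(area_id = rep(rownames(tm), each = nrow(mg)),
                     margin_id = m, stringsAsFactors = FALSE)
    for (f in fn)
      df[[f]] <- if (f %in% names(mg))
        rep(mg[[f]], times = nrow(tm)) else ""
    df$count <- as.numeric(t(tm))
    df
  })
  utils::write.csv(do.call(rbind, pieces), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a stratification scheme from YAML
#'
#' The YAML maps factor names to level lists, in declared order.
#'
#' @param path YAML file.
#' @return A [strat_scheme()].
#' @export
read_scheme <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(strat_scheme, lapply(lst, as.character))
}

#' MMSA dental-visit benchmark table
#'
#' The five-metro internal-validation table shipped with the package:
#' model-based and direct survey estimates (percent, with 95% CIs) of the
#' share of adults with a dental visit in the past year, 2018, for five
#' California metropolitan areas.
#'
#' @return data.frame with columns `area_id`, `model_est`, `model_lower`,
#'   `model_upper`, `direct_est`, `direct_lower`, `direct_upper`.
#' @export
mmsa_benchmark <- function() {
  utils::read.csv(system.file("extdata", "mmsa_dental_2018.csv",
                              package = "mrpraking"),
                  stringsAsFactors = FALSE)
}

#' Run the full estimation pipeline from a config
#'
#' Stages: read inputs, fit the multilevel model, predict cell
#' probabilities, rake margins, post-stratify, optional bootstrap CIs,
#' optional validation against direct estimates. Any stage failure aborts
#' with the stage name. A machine-readable manifest (inputs, seeds,
#' tolerances, convergence) is written alongside the estimates when
#' `out_dir` is set.
#'
#' @param config a YAML file path or an equivalent nested list. Keys:
#'   `scheme` (factor -> levels, or omit to use objects passed in
#'   `inputs`), `survey`/`margins`/`covariates` (CSV paths),
#'   `model` (`fixed`, `area_covariates`, `random_intercept`),
#'   `raking` (`seed_policy`, `tol`, `max_iter`, `rescale_margins`),
#'   `predict` (`re_policy`), `target_areas`, `bootstrap` (`B`, `seed`,
#'   `level`), `direct` (CSV with `area_id,estimate[,lower,upper]`),
#'   `out_dir`.
#' @param inputs optional list of in-memory objects (`survey`, `margins`,
#'   `covariates`, `scheme`) overriding file paths.
#' @return list: `estimates`, `fit`, `raked`, `predictions`, `validation`
#'   (NULL unless direct estimates given), `manifest`.
#' @export
run_pipeline <- function(config, inputs = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  scheme <- stage("inputs", {
    if (!is.null(inputs$scheme)) inputs$scheme
    else if (!is.null(config$scheme))
      do.call(strat_scheme, lapply(config$scheme, as.character))
    else stop("no scheme supplied")
  })
  rk <- config$raking
  rescale <- isTRUE(rk$rescale_margins)
  survey <- stage("inputs",
    if (!is.null(inputs$survey)) validate_survey(inputs$survey, scheme)
    else read_survey(config$survey, scheme))
  margins <- stage("inputs",
    if (!is.null(inputs$margins)) inputs$margins
    else read_margins(config$margins, scheme, rescale = rescale))
  covariates <- NULL
  if (!is.null(inputs$covariates)) covariates <- inputs$covariates
  else if (!is.null(config$covariates))
    covariates <- stage("inputs", read_covariates(config$covariates))

  mc <- config$model
  if (is.null(mc$fixed)) mc$fixed <- names(scheme$factors)
  spec <- model_spec(fixed = as.character(mc$fixed),
                     area_covariates =
                       as.character(mc$area_covariates %||% character(0)),
                     random_intercept = !isFALSE(mc$random_intercept))
  qp <- mc$quadrature_points %||% 15L

  target_areas <- as.character(config$target_areas %||% margins$areas)

  fit <- stage("fit",
    fit_multilevel_logistic(survey, covariates, spec, scheme,
                            quadrature_points = qp))
  raked <- stage("rake",
    rake_all_areas(scheme, margins,
                   seed_policy = rk$seed_policy %||% "uniform",
                   survey = survey, areas = target_areas,
                   tol = rk$tol %||% 1e-8,
                   max_iter = rk$max_iter %||% 1000L))
  re_policy <- config$predict$re_policy %||% "conditional_blup"
  preds <- stage("predict",
    predict_cell_probabilities(fit, covariates, target_areas,
                               re_policy = re_policy))
  estimates <- stage("poststratify", poststratify(preds, raked))

  boot_meta <- NULL
  if (!is.null(config$bootstrap)) {
    bc <- config$bootstrap
    estimates <- stage("bootstrap",
      bootstrap_ci(survey, covariates, spec, scheme, margins,
                   B = bc$B %||% 1000L, seed = bc$seed %||% 1L,
                   level = bc$level %||% 0.95,
                   target_areas = target_areas, re_policy = re_policy,
                   raked = raked, quadrature_points = qp,
                   allow_unstable = isTRUE(bc$allow_unstable)))
    boot_meta <- attr(estimates, "bootstrap")
    boot_meta$replicate_seeds <- NULL
  }

  validation <- NULL
  if (!is.null(config$direct)) {
    validation <- stage("validate", {
      direct <- utils::read.csv(config$direct, stringsAsFactors = FALSE)
      direct$area_id <- as.character(direct$area_id)
      ci <- if (all(c("lower", "upper") %in% names(direct)))
        direct[c("area_id", "lower", "upper")] else NULL
      compare_estimates(
        stats::setNames(100 * estimates$estimate, estimates$area_id),
        stats::setNames(direct$estimate, direct$area_id),
        direct_ci = ci)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrpraking")),
    scheme = scheme$factors,
    n_respondents = nrow(survey),
    areas_sampled = fit$areas_sampled,
    target_areas = target_areas,
    model = list(fixed = spec$fixed,
                 area_covariates = spec$area_covariates,
                 random_intercept = spec$random_intercept,
                 quadrature_points = qp,
                 sigma_mu = fit$sigma_mu, logLik = fit$logLik,
                 iterations = fit$iterations),
    raking = list(seed_policy = rk$seed_policy %||% "uniform",
                  tol = rk$tol %||% 1e-8,
                  max_iter = rk$max_iter %||% 1000L,
                  rescale_margins = rescale,
                  converged = all(raking_metadata(raked)$converged)),
    re_policy = re_policy,
    bootstrap = boot_meta)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_estimates(estimates, file.path(config$out_dir, "estimates.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(estimates = estimates, fit = fit, raked = raked,
       predictions = preds, validation = validation, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
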