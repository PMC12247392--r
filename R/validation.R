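#' Compare model-based and direct estimates
#'
#' Computes, over the areas common to both series (at least two required):
#' mean squared error MSE = mean((m_i - d_i)^2), mean absolute difference
#' MAD = mean(|m_i - d_i|), Pearson and Spearman correlations (average
#' ranks for ties), and a five-number-plus-IQR summary of each series.
#' When either series has zero variance the correlations are reported as
#' undefined (`NA` with `correlation_defined = FALSE`), not as 0. Metrics
#' are computed on whatever scale the inputs are on; use the percentage
#' scale to match conventional reporting.
#'
#' @param model_est named numeric vector (names = area ids) or data.frame
#'   with columns `area_id`, `estimate`.
#' @param direct_est same format as `model_est`.
#' @param direct_ci optional data.frame with columns `area_id`, `lower`,
#'   `upper`: the direct estimates' 95% CIs, enabling a containment count.
#' @return An object of class `validation_report`.
#' @export
compare_estimates <- function(model_est, direct_est, direct_ci = NULL) {
  m <- as_named_estimates(model_est, "model_est")
  d <- as_named_estimates(direct_est, "direct_est")
  common <- intersect(names(m), names(d))
  if (length(common) < 2L)
    stop("need at least 2 common areas; got ", length(common), call. = FALSE)
  m <- m[common]; d <- d[common]
  defined <- stats::sd(m) > 0 && stats::sd(d) > 0
  rep <- list(
    areas = common,
    n = length(common),
    model = m,
    direct = d,
    mse = mean((m - d)^2),
    mad = mean(abs(m - d)),
    pearson = if (defined) stats::cor(m, d) else NA_real_,
    spearman = if (defined) stats::cor(m, d, method = "spearman")
               else NA_real_,
    correlation_defined = defined,
    model_summary = summarize_series(m),
    direct_summary = summarize_series(d)
  )
  if (!is.null(direct_ci)) {
    cc <- containment_check(model_est, direct_est, direct_ci)
    rep$containment <- cc
  }
  structure(rep, class = "validation_report")
}

as_named_estimates <- function(x, what) {
  if (is.data.frame(x)) {
    need <- setdiff(c("area_id", "estimate"), names(x))
    if (length(need))
      stop(what, " missing column(s): ", paste(need, collapse = ", "),
           call. = FALSE)
    out <- stats::setNames(as.numeric(x$estimate), as.character(x$area_id))
  } else {
    if (is.null(names(x)))
      stop(what, " must be a named vector or a data.frame", call. = FALSE)
    out <- x
  }
  if (anyDuplicated(names(out)))
    stop("duplicate area ids in ", what, call. = FALSE)
  if (any(!is.finite(out)))
    stop("non-finite values in ", what, call. = FALSE)
  out
}

#' Five-number summary plus IQR and range
#'
#' Quartiles use the linear-interpolation convention between order
#' statistics (`stats::quantile` type 7).
#'
#' @param values numeric vector with at least one finite value.
#' @return Named vector: `min`, `q1`, `median`, `q3`, `max`, `iqr`, `range`.
#' @export
summarize_series <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("values must be nonempty and finite", call. = FALSE)
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                       type = 7)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    iqr = q[4] - q[2], range = q[5] - q[1])
}

#' Check containment of estimates in confidence intervals
#'
#' Flags, for each common area, whether the model-based estimate lies
#' inside the direct estimate's confidence interval (closed on both ends).
#' When `model_ci` is supplied the symmetric check (direct estimate inside
#' the model CI) is reported too.
#'
#' @param model_est,direct_est named vectors or data.frames with `area_id`,
#'   `estimate`.
#' @param direct_ci data.frame with columns `area_id`, `lower`, `upper`.
#' @param model_ci optional data.frame in the same format.
#' @return list with per-area logical `contained`, the count `n_contained`,
#'   `n`, and (when `model_ci` given) `direct_in_model_ci`.
#' @export
containment_check <- function(model_est, direct_est, direct_ci,
                              model_ci = NULL) {
  m <- as_named_estimates(model_est, "model_est")
  d <- as_named_estimates(direct_est, "direct_est")
  ci <- validate_ci(direct_ci, "direct_ci")
  common <- Reduce(intersect, list(names(m), names(d), names(ci$lower)))
  if (length(common) == 0L) stop("no common areas", call. = FALSE)
  contained <- m[common] >= ci$lower[common] & m[common] <= ci$upper[common]
  out <- list(contained = contained,
              n_contained = sum(contained),
              n = length(common))
  if (!is.null(model_ci)) {
    mc <- validate_ci(model_ci, "model_ci")
    ok <- intersect(common, names(mc$lower))
    out$direct_in_model_ci <- d[ok] >= mc$lower[ok] & d[ok] <= mc$upper[ok]
  }
  out
}

validate_ci <- function(ci, what) {
  stopifnot(is.data.frame(ci))
  need <- setdiff(c("area_id", "lower", "upper"), names(ci))
  if (length(need))
    stop(what, " missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(ci$lower > ci$upper))
    stop("malformed CI in ", what, ": lower > upper for area(s) ",
         paste(ci$area_id[ci$lower > ci$upper], collapse = ", "),
         call. = FALSE)
  list(lower = stats::setNames(ci$lower, as.character(ci$area_id)),
       upper = stats::setNames(ci$upper, as.character(ci$area_id)))
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat("Validation over", x$n, "areas\n")
  cat(sprintf("  MSE %.1f  MAD %.1f\n", x$mse, x$mad))
  if (x$correlation_defined)
    cat(sprintf("  Pearson %.3f  Spearman %.3f\n", x$pearson, x$spearman))
  else cat("  correlations undefined (zero variance)\n")
  tab <- rbind(model = x$model_summary, direct = x$direct_summary)
  colnames(tab) <- c("Min", "25%", "Median", "75%", "Max", "IQR", "Range")
  print(round(tab, 1))
  cat(sprintf("  model range %s, direct range %s\n",
              range_string(x$model), range_string(x$direct)))
  if (!is.null(x$containment))
    cat("  model estimates inside direct CI:", x$containment$n_contained,
        "of", x$containment$n, "\n")
  invisible(x)
}

range_string <- function(v) sprintf("%.1f–%.1f%%", min(v), max(v))
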