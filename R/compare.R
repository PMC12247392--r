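#' Compare area estimates from competing model specifications
#'
#' Given two or more fits of different specifications to the same survey
#' and their area estimates, reports each model's cross-area estimate
#' range (printed as e.g. "52.5–73.1%"), a per-area estimate table, and —
#' when direct estimates are supplied — MSE/MAD and correlations against
#' them on the percentage scale.
#'
#' @param fits named list of `glmm_fit` objects (>= 2), all fitted to the
#'   same survey.
#' @param estimates named list of `area_estimates` (same names as `fits`),
#'   estimates as proportions in [0, 1].
#' @param direct_est optional direct estimates (proportions): named vector
#'   or data.frame with `area_id`, `estimate`.
#' @param direct_ci optional data.frame `area_id`, `lower`, `upper`
#'   (proportions) for containment counting.
#' @return An object of class `model_comparison`: `table` (per-area wide
#'   table of estimates), `ranges` (named "min–max%" strings), `metrics`
#'   (per-model [compare_estimates()] reports, when direct estimates
#'   given).
#' @export
compare_models <- function(fits, estimates, direct_est = NULL,
                           direct_ci = NULL) {
  stopifnot(is.list(fits), is.list(estimates))
  if (length(fits) < 2L)
    stop("need at least 2 fitted specifications", call. = FALSE)
  if (is.null(names(fits)) || !setequal(names(fits), names(estimates)))
    stop("fits and estimates must be named lists with matching names",
         call. = FALSE)
  fp <- lapply(fits, function(f) f$fingerprint)
  for (k in seq_along(fp)[-1L])
    if (!identical(fp[[1L]], fp[[k]]))
      stop("models were fitted on different surveys ('", names(fp)[1L],
           "' vs '", names(fp)[k], "')", call. = FALSE)

  areas <- sort(Reduce(union, lapply(estimates, function(e) e$area_id)))
  tab <- data.frame(area_id = areas, stringsAsFactors = FALSE)
  for (nm in names(estimates)) {
    e <- estimates[[nm]]
    tab[[nm]] <- e$estimate[match(areas, e$area_id)]
  }
  ranges <- vapply(names(estimates), function(nm)
    range_string(100 * estimates[[nm]]$estimate), "")

  metrics <- NULL
  if (!is.null(direct_est)) {
    d <- as_named_estimates(direct_est, "direct_est")
    ci <- NULL
    if (!is.null(direct_ci)) {
      ci <- direct_ci
      ci$lower <- 100 * ci$lower; ci$upper <- 100 * ci$upper
    }
    metrics <- lapply(names(estimates), function(nm) {
      e <- estimates[[nm]]
      compare_estimates(
        stats::setNames(100 * e$estimate, e$area_id), 100 * d,
        direct_ci = ci)
    })
    names(metrics) <- names(estimates)
  }
  structure(list(table = tab, ranges = ranges, metrics = metrics),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison over", nrow(x$table), "areas\n")
  for (nm in names(x$ranges)) {
    cat(sprintf("  %s: range %s", nm, x$ranges[[nm]]))
    if (!is.null(x$metrics))
      cat(sprintf("  MSE %.1f  MAD %.1f", x$metrics[[nm]]$mse,
                  x$metrics[[nm]]$mad))
    cat("\n")
  }
  invisible(x)
}
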