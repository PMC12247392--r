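#' Predict per-cell outcome probabilities for target areas
#'
#' For each target area and each scheme cell, computes
#' p = inverse-logit(x'beta + z'eta + mu*), where the random-effect term
#' mu* depends on `re_policy`:
#' \describe{
#'   \item{conditional_blup}{the area's posterior-mode random effect if the
#'     area was sampled, 0 otherwise (the conventional prediction for an
#'     unobserved group).}
#'   \item{conditional_zero}{always 0.}
#'   \item{marginal}{for unsampled areas, the population-averaged
#'     probability obtained by integrating the inverse-logit over
#'     N(0, sigma_mu^2) by quadrature; sampled areas still use their
#'     posterior mode.}
#' }
#' For a fixed-effect fit (area dummies), predictions are only defined for
#' sampled areas and `re_policy` is ignored.
#'
#' @param fit a `glmm_fit` from [fit_multilevel_logistic()].
#' @param covariates area-level covariates covering all target areas (when
#'   the model uses any).
#' @param target_areas character vector of areas to predict for.
#' @param re_policy random-effect policy, see above.
#' @param n_nodes quadrature nodes for the `marginal` policy.
#' @return data.frame (class `cell_predictions`) with columns `area_id`,
#'   `cell`, the factor level columns, and `p`.
#' @export
predict_cell_probabilities <- function(fit, covariates = NULL, target_areas,
                                       re_policy = c("conditional_blup",
                                                     "conditional_zero",
                                                     "marginal"),
                                       n_nodes = 21L) {
  stopifnot(inherits(fit, "glmm_fit"))
  re_policy <- match.arg(re_policy)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  target_areas <- as.character(target_areas)
  scheme <- fit$scheme
  spec <- fit$spec

  if (fit$type == "fixed") {
    unsampled <- setdiff(target_areas, fit$areas_sampled)
    if (length(unsampled))
      stop("fixed-effect fit cannot predict for unsampled area(s): ",
           paste(unsampled, collapse = ", "), call. = FALSE)
  }

  grid <- cell_grid(scheme)
  nd <- grid[rep(seq_len(nrow(grid)), times = length(target_areas)), ,
             drop = FALSE]
  nd$area_id <- rep(target_areas, each = nrow(grid))
  if (length(spec$area_covariates)) {
    covariates <- validate_covariates(covariates,
                                      required = spec$area_covariates,
                                      areas = target_areas)
    nd <- merge(nd, covariates[c("area_id", spec$area_covariates)],
                by = "area_id", sort = FALSE)
    nd <- nd[order(match(nd$area_id, target_areas), nd$cell), , drop = FALSE]
  }

  X <- build_design(nd, spec, scheme,
                    area_levels = if (fit$type == "fixed")
                      fit$areas_sampled else NULL)
  if (fit$type == "fixed") {
    # area dummy columns in X are 0/1 on nd$area_id already
    lin <- as.numeric(X %*% fit$coefficients)
    p <- stats::plogis(lin)
  } else {
    lin <- as.numeric(X %*% fit$coefficients)
    sampled <- nd$area_id %in% fit$areas_sampled
    mu_star <- numeric(nrow(nd))
    if (re_policy %in% c("conditional_blup", "marginal"))
      mu_star[sampled] <- fit$mu[nd$area_id[sampled]]
    p <- stats::plogis(lin + mu_star)
    if (re_policy == "marginal" && any(!sampled))
      p[!sampled] <- logistic_normal_mean(lin[!sampled], fit$sigma_mu,
                                          n_nodes = n_nodes)
  }
  out <- data.frame(area_id = nd$area_id, nd[names(grid)], p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cell_predictions", "data.frame")
  out
}
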