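#' Specify the regression model
#'
#' @param fixed character vector of scheme factors used as individual-level
#'   fixed effects (dummy-coded; the first declared level of each factor is
#'   the reference).
#' @param area_covariates character vector of continuous area-level
#'   covariate names (e.g. percent of population below poverty).
#' @param random_intercept if TRUE (default) an area-level random intercept
#'   is fitted; if FALSE the model instead includes fixed area indicator
#'   dummies (the fixed-effect variant), in which case area-level
#'   covariates are dropped as collinear with the dummies.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed, area_covariates = character(0),
                       random_intercept = TRUE) {
  stopifnot(is.character(fixed), length(fixed) >= 1L)
  structure(list(fixed = fixed,
                 area_covariates = as.character(area_covariates),
                 random_intercept = isTRUE(random_intercept)),
            class = "model_spec")
}

# deterministic dummy-coded design matrix shared by fitting and prediction
build_design <- function(df, spec, scheme, area_levels = NULL) {
  n <- nrow(df)
  cols <- list("(Intercept)" = rep.int(1, n))
  for (f in spec$fixed) {
    lv <- scheme$factors[[f]]
    for (l in lv[-1L])
      cols[[paste0(f, "=", l)]] <- as.numeric(df[[f]] == l)
  }
  for (v in spec$area_covariates)
    cols[[v]] <- as.numeric(df[[v]])
  if (!is.null(area_levels))
    for (a in area_levels[-1L])
      cols[[paste0("area=", a)]] <- as.numeric(df$area_id == a)
  do.call(cbind, cols)
}

log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x < 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit the random-intercept multilevel logistic regression
#'
#' Maximizes the exact marginal likelihood of the random-intercept logistic
#' model logit(p_ij) = x_ij' beta + z_i' eta + mu_i, mu_i ~ N(0, sigma_mu^2),
#' with the one-dimensional per-area integral evaluated by adaptive
#' Gauss-Hermite quadrature (nodes centered and scaled at each area's
#' posterior mode). The fit is unweighted: every respondent counts once; a
#' `weight` column in the survey, if present, is ignored with a warning.
#'
#' @param survey survey microdata (validated against `scheme`).
#' @param covariates area-level covariates data.frame (needed when the spec
#'   names any; may be NULL otherwise).
#' @param spec a [model_spec()].
#' @param scheme the [strat_scheme()] the factors belong to.
#' @param quadrature_points number of Gauss-Hermite nodes (default 15).
#' @param tol relative convergence tolerance of the optimizer.
#' @param max_iter optimizer iteration cap.
#' @param se compute observed-information standard errors (skip for speed
#'   inside resampling loops).
#' @param start optional warm-start vector `c(coefficients, log(sigma_mu))`.
#' @return An object of class `glmm_fit`: fixed effects `beta`, area-level
#'   coefficients `eta`, random-intercept SD `sigma_mu`, per-sampled-area
#'   posterior modes `mu`, `logLik`, standard errors and convergence
#'   metadata. With `random_intercept = FALSE` the returned fit is the
#'   fixed-effect variant (area dummies; `sigma_mu` is NA).
#' @export
fit_multilevel_logistic <- function(survey, covariates = NULL, spec, scheme,
                                    quadrature_points = 15L, tol = 1e-10,
                                    max_iter = 500L, se = TRUE,
                                    start = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(scheme, "strat_scheme"))
  unknown <- setdiff(spec$fixed, names(scheme$factors))
  if (length(unknown))
    stop("model_spec names factor(s) not in the scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  survey <- validate_survey(survey, scheme)
  if ("weight" %in% names(survey))
    warning("survey weights present but ignored: the model is fitted ",
            "unweighted", call. = FALSE)
  sampled <- sort(unique(survey$area_id))
  spec_use <- spec
  if (!spec$random_intercept && length(spec$area_covariates)) {
    warning("area-level covariates are collinear with area dummies in the ",
            "fixed-effect variant; dropping: ",
            paste(spec$area_covariates, collapse = ", "), call. = FALSE)
    spec_use$area_covariates <- character(0)
  }
  if (length(spec_use$area_covariates)) {
    covariates <- validate_covariates(covariates,
                                      required = spec_use$area_covariates,
                                      areas = sampled)
    survey <- merge(survey,
                    covariates[c("area_id", spec_use$area_covariates)],
                    by = "area_id", sort = FALSE)
  }

  fingerprint <- list(n = nrow(survey), y_sum = sum(survey$y),
                      area_n = table(survey$area_id))

  if (!spec$random_intercept) {
    X <- build_design(survey, spec_use, scheme, area_levels = sampled)
    fit0 <- suppressWarnings(
      stats::glm.fit(X, survey$y, family = stats::binomial()))
    theta <- stats::coef(fit0)
    if (any(!is.finite(theta)) || max(abs(theta)) > 15)
      stop("fixed-effect fit did not converge (possible separation); ",
           "max |coef| = ", signif(max(abs(theta)), 3), call. = FALSE)
    area_cols <- grep("^area=", names(theta))
    mu <- c(0, theta[area_cols])
    names(mu) <- sampled
    p_cols <- setdiff(seq_along(theta), area_cols)
    se <- rep(NA_real_, length(theta))
    return(structure(list(type = "fixed",
                          coefficients = theta,
                          beta = theta[p_cols],
                          eta = stats::setNames(numeric(0), character(0)),
                          sigma_mu = NA_real_,
                          mu = mu,
                          logLik = -fit0$deviance / 2,
                          se = se,
                          converged = fit0$converged,
                          iterations = fit0$iter,
                          quadrature_points = NA_integer_,
                          spec = spec_use, scheme = scheme,
                          areas_sampled = sampled,
                          fingerprint = fingerprint),
                     class = "glmm_fit"))
  }

  X <- build_design(survey, spec_use, scheme)
  xnames <- colnames(X)
  # scale columns to O(1) so continuous covariates do not dominate the
  # curvature; coefficients are mapped back afterwards
  col_scale <- apply(abs(X), 2L, max)
  col_scale[col_scale == 0] <- 1
  X <- sweep(X, 2L, col_scale, "/")
  y <- survey$y
  p <- ncol(X)
  idx_by_area <- split(seq_len(nrow(X)), survey$area_id)
  gh <- gauss_hermite(quadrature_points)
  log_w <- log(gh$weights)
  xk <- gh$nodes
  sqrt2 <- sqrt(2)

  area_mode <- function(o, yi, sig2, u0 = 0) {
    u <- u0
    for (it in 1:50) {
      pr <- stats::plogis(o + u)
      g <- sum(yi - pr) - u / sig2
      H <- -sum(pr * (1 - pr)) - 1 / sig2
      step <- g / H
      u <- u - step
      if (abs(step) < 1e-11) break
    }
    pr <- stats::plogis(o + u)
    list(u = u, s = 1 / sqrt(sum(pr * (1 - pr)) + 1 / sig2))
  }

  eval_ll <- function(par, want_grad = TRUE) {
    theta <- par[seq_len(p)]
    zeta <- par[p + 1L]
    sig <- exp(zeta)
    sig2 <- sig^2
    o_all <- as.numeric(X %*% theta)
    ll <- 0
    gtheta <- numeric(p)
    gzeta <- 0
    modes <- numeric(length(idx_by_area))
    for (i in seq_along(idx_by_area)) {
      idx <- idx_by_area[[i]]
      o <- o_all[idx]; yi <- y[idx]
      md <- area_mode(o, yi, sig2)
      modes[i] <- md$u
      uk <- md$u + sqrt2 * md$s * xk
      LP <- outer(o, uk, "+")
      llk <- colSums(yi * LP - log1pexp(LP))
      lognorm <- -0.5 * log(2 * pi) - zeta - uk^2 / (2 * sig2)
      terms <- log_w + xk^2 + llk + lognorm
      ll <- ll + log(sqrt2 * md$s) + log_sum_exp(terms)
      if (want_grad) {
        om <- exp(terms - max(terms)); om <- om / sum(om)
        P <- stats::plogis(LP)
        gtheta <- gtheta + as.numeric(crossprod(X[idx, , drop = FALSE],
                                                yi - as.numeric(P %*% om)))
        gzeta <- gzeta + sum(om * (uk^2 / sig2 - 1))
      }
    }
    list(ll = ll, grad = c(gtheta, gzeta), modes = modes)
  }

  if (is.null(start)) {
    theta0 <- suppressWarnings(
      stats::coef(stats::glm.fit(X, y, family = stats::binomial())))
    theta0[!is.finite(theta0)] <- 0
    start <- c(theta0, log(0.5))
  } else {
    stopifnot(length(start) == p + 1L)
    start <- as.numeric(start)
    start[seq_len(p)] <- start[seq_len(p)] * col_scale
  }
  lower <- c(rep(-Inf, p), log(1e-4))
  upper <- c(rep(Inf, p), log(20))

  cache <- new.env(parent = emptyenv())
  get_eval <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- eval_ll(par)
      cache$key <- key
    }
    cache$val
  }
  obj <- function(par) -get_eval(par)$ll
  gr <- function(par) -get_eval(par)$grad

  run_opt <- function(par0) {
    opt <- stats::nlminb(par0, obj, gr, lower = lower, upper = upper,
                         control = list(iter.max = max_iter,
                                        eval.max = 4L * max_iter,
                                        rel.tol = tol))
    final <- eval_ll(opt$par)
    # the likelihood is flat in log(sigma) when sigma is effectively zero;
    # exclude that coordinate from the stationarity check there
    grad_chk <- final$grad
    if (exp(opt$par[p + 1L]) < 1e-2) grad_chk <- grad_chk[seq_len(p)]
    list(opt = opt, final = final, gnorm = max(abs(grad_chk)))
  }
  # stationarity tolerance scales with n: the score is a sum of n terms
  gtol <- max(1e-3, 1e-4 * length(y))
  res <- run_opt(start)
  if (res$opt$convergence != 0 && res$gnorm > gtol) {
    # cold restart from an ordinary logistic fit
    theta0 <- suppressWarnings(
      stats::coef(stats::glm.fit(X, y, family = stats::binomial())))
    theta0[!is.finite(theta0)] <- 0
    res2 <- run_opt(c(theta0, log(0.5)))
    if (res2$opt$objective < res$opt$objective || res2$gnorm < res$gnorm)
      res <- res2
  }
  opt <- res$opt
  final <- res$final
  if (opt$convergence != 0 && res$gnorm > gtol)
    stop("multilevel fit did not converge: nlminb code ", opt$convergence,
         " (", opt$message, "), max |gradient| = ", signif(res$gnorm, 3),
         call. = FALSE)
  theta <- opt$par[seq_len(p)] / col_scale
  if (max(abs(opt$par[seq_len(p)])) > 15)
    stop("fitted coefficients diverged (max |coef| = ",
         signif(max(abs(theta)), 3), "): possible complete separation",
         call. = FALSE)
  names(theta) <- xnames
  sigma_mu <- exp(opt$par[p + 1L])

  # observed-information SEs from a central-difference Jacobian of the
  # analytic gradient
  want_se <- isTRUE(se)
  se <- rep(NA_real_, p + 1L)
  hess <- if (!want_se) NULL else tryCatch({
    np <- p + 1L
    H <- matrix(0, np, np)
    h <- 1e-5 * pmax(1, abs(opt$par))
    for (j in seq_len(np)) {
      pp <- opt$par; pp[j] <- pp[j] + h[j]
      pm <- opt$par; pm[j] <- pm[j] - h[j]
      H[, j] <- (eval_ll(pp)$grad - eval_ll(pm)$grad) / (2 * h[j])
    }
    -(H + t(H)) / 2
  }, error = function(e) NULL)
  if (!is.null(hess)) {
    v <- tryCatch(diag(solve(hess)), error = function(e) rep(NA_real_, p + 1L))
    se <- ifelse(v > 0, sqrt(v), NA_real_) / c(col_scale, 1)
  }

  cov_cols <- match(spec_use$area_covariates, xnames)
  beta_cols <- setdiff(seq_len(p), cov_cols)
  mu <- stats::setNames(final$modes, names(idx_by_area))

  structure(list(type = "glmm",
                 coefficients = theta,
                 beta = theta[beta_cols],
                 eta = theta[cov_cols],
                 sigma_mu = sigma_mu,
                 mu = mu,
                 logLik = final$ll,
                 se = stats::setNames(se, c(xnames, "log_sigma_mu")),
                 converged = TRUE,
                 iterations = opt$iterations,
                 quadrature_points = as.integer(quadrature_points),
                 spec = spec_use, scheme = scheme,
                 areas_sampled = sampled,
                 fingerprint = fingerprint),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(if (x$type == "glmm") "Random-intercept" else "Fixed-effect",
      "logistic model:", length(x$coefficients), "coefficients,",
      length(x$areas_sampled), "sampled areas\n")
  if (x$type == "glmm")
    cat("  sigma_mu =", signif(x$sigma_mu, 4),
        " logLik =", signif(x$logLik, 8), "\n")
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...) object$coefficients

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) +
              as.integer(object$type == "glmm"), class = "logLik")
}

#' Marginal log-likelihood of a fitted model at given parameters
#'
#' Re-evaluates the adaptive-quadrature marginal log-likelihood of the data
#' used in `fit` at user-supplied parameter values (useful for optimizer
#' sanity checks).
#'
#' @param fit a `glmm_fit` of type "glmm".
#' @param survey,covariates,scheme the data the model was fitted to.
#' @param coefficients named vector matching `coef(fit)`.
#' @param sigma_mu random-intercept SD.
#' @return log marginal likelihood (numeric scalar).
#' @export
marginal_loglik <- function(fit, survey, covariates = NULL, scheme,
                            coefficients, sigma_mu) {
  stopifnot(inherits(fit, "glmm_fit"), fit$type == "glmm")
  refit <- fit_loglik_only(survey, covariates, fit$spec, scheme,
                           fit$quadrature_points, coefficients, sigma_mu)
  refit
}

fit_loglik_only <- function(survey, covariates, spec, scheme, q,
                            coefficients, sigma_mu) {
  survey <- validate_survey(survey, scheme)
  if (length(spec$area_covariates)) {
    covariates <- validate_covariates(covariates,
                                      required = spec$area_covariates)
    survey <- merge(survey, covariates[c("area_id", spec$area_covariates)],
                    by = "area_id", sort = FALSE)
  }
  X <- build_design(survey, spec, scheme)
  y <- survey$y
  idx_by_area <- split(seq_len(nrow(X)), survey$area_id)
  gh <- gauss_hermite(q)
  sqrt2 <- sqrt(2)
  sig2 <- sigma_mu^2
  o_all <- as.numeric(X %*% coefficients[colnames(X)])
  ll <- 0
  for (idx in idx_by_area) {
    o <- o_all[idx]; yi <- y[idx]
    u <- 0
    for (it in 1:50) {
      pr <- stats::plogis(o + u)
      g <- sum(yi - pr) - u / sig2
      H <- -sum(pr * (1 - pr)) - 1 / sig2
      step <- g / H; u <- u - step
      if (abs(step) < 1e-11) break
    }
    pr <- stats::plogis(o + u)
    s <- 1 / sqrt(sum(pr * (1 - pr)) + 1 / sig2)
    uk <- u + sqrt2 * s * gh$nodes
    LP <- outer(o, uk, "+")
    llk <- colSums(yi * LP - log1pexp(LP))
    lognorm <- -0.5 * log(2 * pi) - log(sigma_mu) - uk^2 / (2 * sig2)
    ll <- ll + log(sqrt2 * s) +
      log_sum_exp(log(gh$weights) + gh$nodes^2 + llk + lognorm)
  }
  ll
}
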