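#' Validate survey microdata against a scheme
#'
#' Survey microdata has one row per respondent: an `area_id`, a binary
#' outcome `y`, and one column per scheme factor holding that respondent's
#' level. Records with levels outside the scheme are rejected (not imputed).
#'
#' @param survey data.frame with columns `area_id`, `y`, and one column per
#'   scheme factor.
#' @param scheme a [strat_scheme()].
#' @return The validated data.frame (factor columns as character), with a
#'   `cell` column giving each respondent's canonical cell id.
#' @export
validate_survey <- function(survey, scheme) {
  stopifnot(is.data.frame(survey), inherits(scheme, "strat_scheme"))
  fnames <- names(scheme$factors)
  missing <- setdiff(c("area_id", "y", fnames), names(survey))
  if (length(missing))
    stop("survey is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  survey <- as.data.frame(survey)
  survey$area_id <- as.character(survey$area_id)
  if (!all(survey$y %in% c(0L, 1L)))
    stop("outcome y must be 0/1", call. = FALSE)
  survey$y <- as.integer(survey$y)
  if (nrow(survey) == 0L) stop("survey has no records", call. = FALSE)
  if (all(survey$y == 0L) || all(survey$y == 1L))
    stop("degenerate outcome: all y are ", survey$y[1L],
         " (complete separation)", call. = FALSE)
  for (f in fnames) {
    v <- as.character(survey[[f]])
    bad <- which(!(v %in% scheme$factors[[f]]))
    if (length(bad))
      stop("unknown level '", v[bad[1L]], "' for factor '", f,
           "' at survey row ", bad[1L], call. = FALSE)
    survey[[f]] <- v
  }
  survey$cell <- cell_index(scheme, survey[fnames])
  survey
}

#' Area-level covariates
#'
#' @param covariates data.frame with an `area_id` column and one numeric
#'   column per covariate.
#' @param required character vector of covariate names that must be present
#'   and complete (default: all non-id columns).
#' @param areas optional character vector of areas that must have complete
#'   rows.
#' @return The validated data.frame with character `area_id`.
#' @export
validate_covariates <- function(covariates, required = NULL, areas = NULL) {
  if (is.null(covariates))
    stop("area-level covariates are required but none were supplied",
         call. = FALSE)
  stopifnot(is.data.frame(covariates))
  if (!"area_id" %in% names(covariates))
    stop("covariates need an 'area_id' column", call. = FALSE)
  covariates <- as.data.frame(covariates)
  covariates$area_id <- as.character(covariates$area_id)
  if (anyDuplicated(covariates$area_id))
    stop("duplicate area_id in covariates", call. = FALSE)
  if (is.null(required)) required <- setdiff(names(covariates), "area_id")
  missing <- setdiff(required, names(covariates))
  if (length(missing))
    stop("covariates missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(areas)) {
    absent <- setdiff(areas, covariates$area_id)
    if (length(absent))
      stop("no covariate row for area(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    sub <- covariates[match(areas, covariates$area_id), required, drop = FALSE]
    if (anyNA(sub))
      stop("missing covariate values for required areas", call. = FALSE)
  }
  for (v in required)
    if (!is.numeric(covariates[[v]]))
      stop("covariate '", v, "' is not numeric", call. = FALSE)
  covariates
}

# canonical margin-cell index (0-based, row-major over `factors` in scheme
# order) for every full cell of the scheme
margin_cell_map <- function(scheme, factors) {
  fnames <- names(scheme$factors)
  unknown <- setdiff(factors, fnames)
  if (length(unknown))
    stop("margin references unknown factor(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  factors <- fnames[fnames %in% factors]   # scheme order
  grid <- cell_levels(scheme, seq_len(scheme$n_cells) - 1L)
  idx <- rep.int(0L, scheme$n_cells)
  for (f in factors) {
    lv <- scheme$factors[[f]]
    idx <- idx * length(lv) + (match(grid[[f]], lv) - 1L)
  }
  idx
}

# level combinations of a margin in its canonical order
margin_grid <- function(scheme, factors) {
  fnames <- names(scheme$factors)
  factors <- fnames[fnames %in% factors]
  sub <- strat_scheme_subset(scheme, factors)
  cell_levels(sub, seq_len(sub$n_cells) - 1L)
}

strat_scheme_subset <- function(scheme, factors) {
  structure(list(factors = scheme$factors[factors],
                 n_cells = prod(lengths(scheme$factors[factors]))),
            class = "strat_scheme")
}

#' Build a set of per-area population margins
#'
#' A margin set holds, for every area, known population count tables on
#' subsets of the stratification factors (e.g. a joint age x sex table plus
#' one-way education and race tables). These are the raking targets.
#'
#' All margins of one area must sum to the same area total `N_i` (within
#' relative tolerance `tol`, since independently rounded census margins
#' rarely agree exactly); set `rescale = TRUE` to proportionally rescale
#' each margin to the mean total instead of erroring.
#'
#' @param scheme a [strat_scheme()].
#' @param margins named list; each element is a data.frame with columns
#'   `area_id`, one column per factor in that margin, and `count`.
#' @param tol relative tolerance for agreement of margin totals.
#' @param rescale if TRUE, rescale disagreeing margins to the mean total.
#' @return An object of class `margin_set`: per-margin target matrices
#'   (areas x margin cells), factor subsets, and area totals `N`.
#' @export
margin_set <- function(scheme, margins, tol = 1e-6, rescale = FALSE) {
  stopifnot(inherits(scheme, "strat_scheme"), is.list(margins))
  if (length(margins) == 0L) stop("no margins supplied", call. = FALSE)
  if (is.null(names(margins)) || any(names(margins) == ""))
    names(margins) <- paste0("margin", seq_along(margins))
  fnames <- names(scheme$factors)

  parsed <- list()
  areas <- character(0)
  for (m in names(margins)) {
    df <- as.data.frame(margins[[m]])
    mf <- intersect(fnames, names(df))
    if (length(mf) == 0L)
      stop("margin '", m, "' contains no scheme factor column", call. = FALSE)
    need <- setdiff(c("area_id", "count"), names(df))
    if (length(need))
      stop("margin '", m, "' missing column(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    if (!is.numeric(df$count) || any(!is.finite(df$count)))
      stop("margin '", m, "' has non-finite counts", call. = FALSE)
    if (any(df$count < 0))
      stop("margin '", m, "' has negative counts", call. = FALSE)
    df$area_id <- as.character(df$area_id)
    sub <- strat_scheme_subset(scheme, fnames[fnames %in% mf])
    mcell <- cell_index(sub, df[names(sub$factors)])
    if (anyDuplicated(paste(df$area_id, mcell)))
      stop("margin '", m, "' has duplicate (area, cell) rows", call. = FALSE)
    parsed[[m]] <- list(factors = names(sub$factors), n = sub$n_cells,
                        df = data.frame(area_id = df$area_id, mcell = mcell,
                                        count = df$count))
    areas <- union(areas, df$area_id)
  }
  covered <- unique(unlist(lapply(parsed, `[[`, "factors")))
  uncovered <- setdiff(fnames, covered)
  if (length(uncovered))
    stop("factor(s) not covered by any margin: ",
         paste(uncovered, collapse = ", "), call. = FALSE)

  areas <- sort(areas)
  targets <- lapply(parsed, function(p) {
    tm <- matrix(0, nrow = length(areas), ncol = p$n,
                 dimnames = list(areas, NULL))
    tm[cbind(match(p$df$area_id, areas), p$df$mcell + 1L)] <- p$df$count
    tm
  })

  totals <- vapply(targets, rowSums, numeric(length(areas)))
  if (length(areas) == 1L) totals <- matrix(totals, nrow = 1L)
  N <- rowMeans(totals)
  rel_dev <- abs(totals - N) / pmax(N, .Machine$double.eps)
  if (any(rel_dev > tol)) {
    if (rescale) {
      for (m in seq_along(targets)) {
        fac <- ifelse(totals[, m] > 0, N / totals[, m], 1)
        targets[[m]] <- targets[[m]] * fac
      }
      message("margin totals rescaled to the mean area total (max relative ",
              "deviation ", signif(max(rel_dev), 3), ")")
    } else {
      bad <- areas[which(apply(rel_dev, 1L, max) > tol)[1L]]
      stop("margin totals disagree for area '", bad,
           "' (max relative deviation ", signif(max(rel_dev), 3),
           "); use rescale = TRUE to rescale", call. = FALSE)
    }
  }
  names(N) <- areas
  structure(list(scheme = scheme,
                 margins = lapply(parsed, function(p)
                   list(factors = p$factors, n = p$n)),
                 targets = targets,
                 areas = areas,
                 N = N),
            class = "margin_set")
}

#' @export
print.margin_set <- function(x, ...) {
  cat("Margin set:", length(x$areas), "areas;",
      paste(vapply(x$margins, function(m)
        paste(m$factors, collapse = "x"), ""), collapse = ", "), "\n")
  invisible(x)
}
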