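#' Define a post-stratification scheme
#'
#' A stratification scheme is an ordered set of categorical factors whose
#' level combinations define the post-stratification cells within each area
#' (e.g. age x sex x education x race/ethnicity). All tables in the package
#' (raked counts, cell predictions) share one canonical cell ordering:
#' row-major over the declared factor order, i.e. the last declared factor
#' varies fastest.
#'
#' @param ... named character vectors, one per factor, giving the ordered
#'   levels of that factor. At least one factor; every factor needs >= 2
#'   levels; factor names must be unique and level names unique within a
#'   factor.
#' @return An object of class `strat_scheme` with elements `factors` (named
#'   list of level vectors) and `n_cells`.
#' @examples
#' sch <- strat_scheme(sex = c("male", "female"),
#'                     edu = c("no_hs", "hs", "college", "postgrad"))
#' sch$n_cells # 8
#' @export
strat_scheme <- function(...) {
  factors <- list(...)
  if (length(factors) == 0L)
    stop("a stratification scheme needs at least one factor", call. = FALSE)
  nm <- names(factors)
  if (is.null(nm) || any(nm == ""))
    stop("every factor must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate factor names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  for (f in nm) {
    lv <- factors[[f]]
    if (!is.character(lv)) lv <- as.character(lv)
    if (length(lv) < 2L)
      stop("factor '", f, "' must have at least 2 levels", call. = FALSE)
    if (anyDuplicated(lv))
      stop("duplicate levels in factor '", f, "'", call. = FALSE)
    factors[[f]] <- lv
  }
  structure(list(factors = factors,
                 n_cells = prod(lengths(factors))),
            class = "strat_scheme")
}

#' @export
print.strat_scheme <- function(x, ...) {
  cat("Stratification scheme:",
      paste(sprintf("%s(%d)", names(x$factors), lengths(x$factors)),
            collapse = " x "),
      "=", x$n_cells, "cells\n")
  invisible(x)
}

#' Default 240-cell scheme
#'
#' Age (6) x sex (2) x education (4) x race/ethnicity (5): the 240
#' socio-demographic groups used for county-level dental-visit estimation.
#'
#' @return A `strat_scheme`.
#' @export
default_scheme <- function() {
  strat_scheme(
    age  = c("18-24", "25-34", "35-44", "45-54", "55-64", "65+"),
    sex  = c("male", "female"),
    education = c("no_hs", "hs", "some_college", "college_grad"),
    race = c("white", "black", "hispanic", "asian", "other")
  )
}

#' Map level combinations to canonical cell ids
#'
#' Cell ids are 0-based and row-major over the declared factor order (the
#' last factor varies fastest); `cell_levels()` is the inverse map.
#'
#' @param scheme a [strat_scheme()].
#' @param levels a named list or character vector with one level per scheme
#'   factor (names matching the factor names), or a data.frame with one
#'   column per factor (one row per combination).
#' @return Integer cell id(s) in `0:(n_cells-1)`.
#' @export
cell_index <- function(scheme, levels) {
  stopifnot(inherits(scheme, "strat_scheme"))
  fnames <- names(scheme$factors)
  if (is.data.frame(levels)) {
    missing <- setdiff(fnames, names(levels))
    if (length(missing))
      stop("missing factor column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    idx <- rep.int(0L, nrow(levels))
    for (f in fnames) {
      lv <- scheme$factors[[f]]
      pos <- match(as.character(levels[[f]]), lv)
      if (anyNA(pos)) {
        bad <- unique(as.character(levels[[f]])[is.na(pos)])
        stop("unknown level(s) for factor '", f, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      idx <- idx * length(lv) + (pos - 1L)
    }
    return(idx)
  }
  levels <- as.list(levels)
  if (is.null(names(levels)) || any(names(levels) == "")) {
    if (length(levels) != length(fnames))
      stop("expected one level per factor (", length(fnames), ")",
           call. = FALSE)
    names(levels) <- fnames
  }
  unknown <- setdiff(names(levels), fnames)
  if (length(unknown))
    stop("unknown factor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cell_index(scheme, as.data.frame(levels, stringsAsFactors = FALSE))
}

#' @rdname cell_index
#' @param cell integer cell id(s), 0-based.
#' @return `cell_levels()`: a data.frame with one factor column per scheme
#'   factor and one row per supplied cell id.
#' @export
cell_levels <- function(scheme, cell) {
  stopifnot(inherits(scheme, "strat_scheme"))
  cell <- as.integer(cell)
  if (any(cell < 0L) || any(cell >= scheme$n_cells))
    stop("cell id out of range 0..", scheme$n_cells - 1L, call. = FALSE)
  fnames <- rev(names(scheme$factors))
  out <- vector("list", length(fnames))
  names(out) <- fnames
  rem <- cell
  for (f in fnames) {          # peel factors off from fastest-varying
    k <- length(scheme$factors[[f]])
    out[[f]] <- scheme$factors[[f]][rem %% k + 1L]
    rem <- rem %/% k
  }
  as.data.frame(out[rev(fnames)], stringsAsFactors = FALSE)
}

#' All cells of a scheme in canonical order
#'
#' @param scheme a [strat_scheme()].
#' @return data.frame with columns `cell` (0-based id) and one column per
#'   factor, rows in canonical (row-major) order.
#' @export
cell_grid <- function(scheme) {
  stopifnot(inherits(scheme, "strat_scheme"))
  ids <- seq_len(scheme$n_cells) - 1L
  cbind(cell = ids, cell_levels(scheme, ids))
}
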