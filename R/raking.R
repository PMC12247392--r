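#' Rake a single area's joint cell counts to its margins
#'
#' Iterative proportional fitting: starting from a seed table over the full
#' cell grid, cyclically rescale so that each margin (defined on an
#' arbitrary subset of the scheme's factors) matches its target, until the
#' maximum absolute deviation of every fitted margin from its target falls
#' below `tol * N_i` or `max_iter` cycles elapse. Cells lying in a
#' zero-count margin slice (structural zeros) are fixed at exactly 0 before
#' iterating.
#'
#' @param scheme a [strat_scheme()].
#' @param margins a [margin_set()] containing the area.
#' @param area_id which area of the margin set to rake.
#' @param seed `"uniform"` (all non-structural-zero cells start at 1) or a
#'   nonnegative numeric vector of length `n_cells` in canonical cell order.
#' @param tol convergence tolerance, relative to the area total `N_i`.
#' @param max_iter maximum number of full cycles over the margins.
#' @return data.frame (class `raked_table`) with columns `area_id`, `cell`,
#'   the factor level columns, and `count`; attribute `metadata` records
#'   convergence, iterations and the final maximum margin deviation.
#' @export
rake <- function(scheme, margins, area_id, seed = "uniform",
                 tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(scheme, "strat_scheme"), inherits(margins, "margin_set"))
  if (!area_id %in% margins$areas)
    stop("no margins for area '", area_id, "'", call. = FALSE)
  maps <- lapply(margins$margins, function(m)
    margin_cell_map(scheme, m$factors) + 1L)
  targets <- lapply(margins$targets, function(tm) tm[area_id, ])
  res <- ipf_core(scheme$n_cells, maps, targets, seed, tol, max_iter)
  out <- cbind(area_id = area_id, cell_grid(scheme), count = res$w)
  meta <- data.frame(area_id = area_id, converged = res$converged,
                     iterations = res$iterations,
                     max_margin_dev = res$max_dev,
                     stringsAsFactors = FALSE)
  if (!res$converged)
    warning("raking did not converge for area '", area_id,
            "' (max margin deviation ", signif(res$max_dev, 4), ")",
            call. = FALSE)
  structure(out, metadata = meta, dev_trace = res$dev_trace,
            class = c("raked_table", "data.frame"))
}

# maps: per margin, 1-based margin-cell index for each full cell
# targets: per margin, target counts in margin-cell order
ipf_core <- function(n_cells, maps, targets, seed, tol, max_iter) {
  N <- sum(targets[[1L]])
  if (identical(seed, "uniform")) {
    w <- rep.int(1, n_cells)
  } else {
    w <- as.numeric(seed)
    if (length(w) != n_cells)
      stop("seed must have length n_cells = ", n_cells, call. = FALSE)
    if (any(!is.finite(w)) || any(w < 0))
      stop("seed must be nonnegative and finite", call. = FALSE)
  }
  # structural zeros: any containing margin slice with zero target
  zero <- rep.int(FALSE, n_cells)
  for (m in seq_along(maps))
    zero <- zero | (targets[[m]][maps[[m]]] == 0)
  w[zero] <- 0
  for (m in seq_along(maps)) {
    need <- targets[[m]][maps[[m]]] > 0
    slice_pos <- rowsum_by(w, maps[[m]], length(targets[[m]]))
    if (any(targets[[m]] > 0 & slice_pos == 0))
      stop("seed is zero on a margin slice with positive target; ",
           "use a strictly positive seed there", call. = FALSE)
  }
  if (N == 0 || all(w == 0)) {
    if (N > 0) stop("all-zero seed with positive margins", call. = FALSE)
    return(list(w = rep.int(0, n_cells), converged = TRUE,
                iterations = 0L, max_dev = 0, dev_trace = numeric(0)))
  }

  max_dev <- Inf
  iter <- 0L
  dev_trace <- numeric(0)
  thresh <- tol * N
  while (iter < max_iter) {
    iter <- iter + 1L
    for (m in seq_along(maps)) {
      fitted <- rowsum_by(w, maps[[m]], length(targets[[m]]))
      ratio <- ifelse(fitted > 0, targets[[m]] / fitted, 0)
      w <- w * ratio[maps[[m]]]
    }
    max_dev <- 0
    for (m in seq_along(maps)) {
      fitted <- rowsum_by(w, maps[[m]], length(targets[[m]]))
      max_dev <- max(max_dev, max(abs(fitted - targets[[m]])))
    }
    dev_trace <- c(dev_trace, max_dev)
    if (max_dev < thresh) break
  }
  list(w = w, converged = max_dev < thresh, iterations = iter,
       max_dev = max_dev, dev_trace = dev_trace)
}

rowsum_by <- function(w, map, n_out) {
  out <- rowsum(w, map)
  full <- numeric(n_out)
  full[as.integer(rownames(out))] <- out[, 1L]
  full
}

#' Rake every area of a margin set
#'
#' Applies [rake()] per area. The seed policy is either `"uniform"` (every
#' non-structurally-zero cell starts at 1, so cells with no sampled
#' respondents still receive mass) or `"sample_counts_plus_epsilon"` (seed
#' with the area's observed survey cell counts plus `epsilon`).
#'
#' @param scheme a [strat_scheme()].
#' @param margins a [margin_set()].
#' @param seed_policy `"uniform"` or `"sample_counts_plus_epsilon"`.
#' @param survey validated survey data.frame (required by the
#'   sample-count policy).
#' @param epsilon mass added to every cell under the sample-count policy.
#' @param areas areas to rake (default: all areas of the margin set).
#' @inheritParams rake
#' @return A `raked_table` data.frame covering all requested areas, with a
#'   per-area `metadata` attribute.
#' @export
rake_all_areas <- function(scheme, margins,
                           seed_policy = c("uniform",
                                           "sample_counts_plus_epsilon"),
                           survey = NULL, epsilon = 0.5, areas = NULL,
                           tol = 1e-8, max_iter = 1000L) {
  seed_policy <- match.arg(seed_policy)
  if (is.null(areas)) areas <- margins$areas
  missing <- setdiff(areas, margins$areas)
  if (length(missing))
    stop("no margins for area(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (seed_policy == "sample_counts_plus_epsilon" && is.null(survey))
    stop("seed_policy 'sample_counts_plus_epsilon' needs a survey",
         call. = FALSE)
  pieces <- vector("list", length(areas))
  metas <- vector("list", length(areas))
  for (k in seq_along(areas)) {
    a <- areas[k]
    seed <- "uniform"
    if (seed_policy == "sample_counts_plus_epsilon") {
      cnt <- numeric(scheme$n_cells)
      sub <- survey[survey$area_id == a, , drop = FALSE]
      if (nrow(sub)) {
        tab <- table(factor(sub$cell, levels = 0:(scheme$n_cells - 1L)))
        cnt <- as.numeric(tab)
      }
      seed <- cnt + epsilon
    }
    r <- rake(scheme, margins, a, seed = seed, tol = tol,
              max_iter = max_iter)
    pieces[[k]] <- as.data.frame(r)
    metas[[k]] <- attr(r, "metadata")
  }
  structure(do.call(rbind, pieces),
            metadata = do.call(rbind, metas),
            class = c("raked_table", "data.frame"))
}

#' Convergence metadata of a raked table
#' @param raked a `raked_table`.
#' @return data.frame with one row per area: `converged`, `iterations`,
#'   `max_margin_dev`.
#' @export
raking_metadata <- function(raked) attr(raked, "metadata")
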