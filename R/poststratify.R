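#' Post-stratify cell predictions with raked population counts
#'
#' Area prevalence is the count-weighted mean of the per-cell predicted
#' probabilities: p_i = (1/N_i) * sum_cells N_i(cell) * p_i(cell).
#'
#' @param preds a `cell_predictions` data.frame (columns `area_id`, `cell`,
#'   `p`).
#' @param raked a `raked_table` data.frame (columns `area_id`, `cell`,
#'   `count`) covering exactly the same (area, cell) set.
#' @return data.frame (class `area_estimates`) with columns `area_id`,
#'   `estimate`, `N`.
#' @export
poststratify <- function(preds, raked) {
  stopifnot(is.data.frame(preds), is.data.frame(raked))
  key_p <- paste(preds$area_id, preds$cell)
  key_r <- paste(raked$area_id, raked$cell)
  only_p <- setdiff(key_p, key_r)
  only_r <- setdiff(key_r, key_p)
  if (length(only_p) || length(only_r))
    stop("predictions and raked counts cover different (area, cell) sets; ",
         "only in predictions: {",
         paste(utils::head(only_p, 5L), collapse = "; "),
         "}; only in raked: {",
         paste(utils::head(only_r, 5L), collapse = "; "), "}",
         call. = FALSE)
  if (any(preds$p < 0 | preds$p > 1 | !is.finite(preds$p)))
    stop("cell probabilities must be finite and in [0, 1]", call. = FALSE)
  cnt <- raked$count[match(key_p, key_r)]
  num <- rowsum(cnt * preds$p, preds$area_id)
  den <- rowsum(cnt, preds$area_id)
  if (any(den[, 1L] <= 0))
    stop("area(s) with zero total population: ",
         paste(rownames(den)[den[, 1L] <= 0], collapse = ", "),
         call. = FALSE)
  out <- data.frame(area_id = rownames(den),
                    estimate = num[, 1L] / den[, 1L],
                    N = den[, 1L],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("area_estimates", "data.frame")
  out
}

#' Aggregate area estimates to larger units
#'
#' Population-weighted aggregation: the unit estimate is
#' sum(N_i * p_i) / sum(N_i) over member areas, with weights taken from the
#' (census-derived) area totals carried in the estimates.
#'
#' @param estimates an `area_estimates` data.frame with columns `area_id`,
#'   `estimate`, `N` (and optionally CI columns, which are not aggregated).
#' @param grouping data.frame with columns `area_id`, `unit_id` mapping each
#'   area to exactly one unit.
#' @return data.frame (class `area_estimates`) keyed by `area_id` = unit id.
#' @export
aggregate_areas <- function(estimates, grouping) {
  stopifnot(is.data.frame(estimates), is.data.frame(grouping))
  need <- setdiff(c("area_id", "unit_id"), names(grouping))
  if (length(need))
    stop("grouping missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  grouping$area_id <- as.character(grouping$area_id)
  if (anyDuplicated(grouping$area_id))
    stop("area(s) mapped to multiple units: ",
         paste(unique(grouping$area_id[duplicated(grouping$area_id)]),
               collapse = ", "), call. = FALSE)
  m <- match(grouping$area_id, estimates$area_id)
  if (anyNA(m))
    stop("no estimate for grouped area(s): ",
         paste(grouping$area_id[is.na(m)], collapse = ", "), call. = FALSE)
  est <- estimates[m, , drop = FALSE]
  unit <- as.character(grouping$unit_id)
  num <- rowsum(est$N * est$estimate, unit)
  den <- rowsum(est$N, unit)
  out <- data.frame(area_id = rownames(den),
                    estimate = num[, 1L] / den[, 1L],
                    N = den[, 1L],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("area_estimates", "data.frame")
  out
}
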