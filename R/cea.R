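# Pairwise cost-effectiveness comparison: incremental cost, incremental
# QALYs, ICER with dominance handling, net monetary benefit and the
# willingness-to-pay decision rule.

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes `delta = reference - comparator` for cost and QALYs and
#' summarizes cost-effectiveness at a willingness-to-pay threshold.  The
#' ICER is only reported as a ratio in the interpretable quadrant (more
#' costly and more effective); otherwise a dominance flag replaces it:
#' `"dominant"` (cheaper and at least as effective), `"dominated"`
#' (costlier and no more effective), or `"infinite"` when the QALY
#' difference is zero but costs differ.  The net monetary benefit is
#' `wtp * delta_qaly - delta_cost`; the reference strategy is
#' cost-effective when it dominates or its ICER is at or below `wtp`.
#'
#' @param reference,comparator `strategy_outcome` objects (see
#'   [run_cohort()]), or any lists with `total_cost`, `total_qaly` and
#'   optionally `salvage_rate`.
#' @param wtp Willingness-to-pay threshold in CNY per QALY.
#' @return A `cea_result` with per-strategy cost/QALY, `delta_cost`,
#'   `delta_qaly`, `icer` (number or `NA` under a dominance flag),
#'   `dominance` (`"ratio"`, `"dominant"`, `"dominated"`, `"infinite"`),
#'   `nmb_at_wtp`, `salvage_reduction` (when both salvage rates are
#'   available) and `cost_effective`.
#' @examples
#' p <- default_parameters()
#' icer(run_cohort("navigated", p), run_cohort("traditional", p))
#' @export
icer <- function(reference, comparator, wtp = 140000) {
  dc <- reference$total_cost - comparator$total_cost
  dq <- reference$total_qaly - comparator$total_qaly
  nmb <- wtp * dq - dc

  if (dq == 0 && dc == 0) {
    dominance <- "infinite"; ratio <- NA_real_; ce <- FALSE
  } else if (dq == 0) {
    dominance <- "infinite"; ratio <- NA_real_; ce <- dc < 0
  } else if (dc <= 0 && dq > 0) {
    dominance <- "dominant"; ratio <- NA_real_; ce <- TRUE
  } else if (dc >= 0 && dq < 0) {
    dominance <- "dominated"; ratio <- NA_real_; ce <- FALSE
  } else {
    dominance <- "ratio"; ratio <- dc / dq
    ce <- if (dq > 0) ratio <= wtp else FALSE
    if (dq < 0 && dc < 0) {  # cheaper but worse: ratio sign is misleading
      dominance <- "cheaper_less_effective"; ratio <- NA_real_
      ce <- nmb > 0
    }
  }

  salv_red <- if (!is.null(reference$salvage_rate) &&
                  !is.null(comparator$salvage_rate) &&
                  comparator$salvage_rate > 0)
    salvage_reduction(reference, comparator) else NA_real_

  structure(list(
    reference = list(strategy = reference$strategy,
                     cost = reference$total_cost, qaly = reference$total_qaly),
    comparator = list(strategy = comparator$strategy,
                      cost = comparator$total_cost, qaly = comparator$total_qaly),
    delta_cost = dc, delta_qaly = dq, icer = ratio, dominance = dominance,
    wtp = wtp, nmb_at_wtp = nmb, salvage_reduction = salv_red,
    cost_effective = ce), class = "cea_result")
}

#' @rdname icer
#' @export
compare_strategies <- icer

#' Relative reduction in salvage procedures
#'
#' `(comparator - reference) / comparator` on the cumulative salvage
#' incidence: the fraction of salvage procedures avoided by the reference
#' strategy.
#'
#' @inheritParams icer
#' @return A fraction (0.234 means a 23.4% reduction).
#' @export
salvage_reduction <- function(reference, comparator) {
  if (is.null(comparator$salvage_rate) || comparator$salvage_rate <= 0)
    stop("comparator salvage rate must be positive", call. = FALSE)
  (comparator$salvage_rate - reference$salvage_rate) / comparator$salvage_rate
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$reference$strategy, x$comparator$strategy))
  cat(sprintf("  cost: %s vs %s (delta %s)\n",
              format(round(x$reference$cost), big.mark = ","),
              format(round(x$comparator$cost), big.mark = ","),
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  QALY: %.3f vs %.3f (delta %.4f)\n",
              x$reference$qaly, x$comparator$qaly, x$delta_qaly))
  if (x$dominance == "ratio")
    cat(sprintf("  ICER: %s per QALY\n", format(round(x$icer, 1), big.mark = ",")))
  else cat(sprintf("  ICER: %s\n", x$dominance))
  if (!is.na(x$salvage_reduction))
    cat(sprintf("  salvage reduction: %.1f%%\n", 100 * x$salvage_reduction))
  cat(sprintf("  NMB at WTP %s: %s; cost-effective: %s\n",
              format(x$wtp, big.mark = ","),
              format(round(x$nmb_at_wtp), big.mark = ","), x$cost_effective))
  invisible(x)
}

#' Serialize a comparison to JSON
#'
#' @param x A `cea_result`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
cea_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cea_result"))
  obj <- unclass(x)
  if (is.null(path)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  else { jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
         invisible(path) }
}
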