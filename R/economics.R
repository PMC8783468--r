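#' Discount factor
#'
#' @param t Time in whole years from model start (>= 0).
#' @param rate Annual discount rate (base case 0.035; 0.015 in scenario
#'   analysis).
#' @return `(1 + rate)^-t`.
#' @export
discount_factor <- function(t, rate) {
  stopifnot(all(t >= 0), rate >= 0)
  (1 + rate)^-t
}

#' Aggregate one arm's total cost and QALYs
#'
#' Sums the component results for an arm: intervention outlay (zero in the
#' standard-care arm), acute infant condition costs, infant death costs,
#' lifetime QALYs of infants saved from death, and the women's breast-cancer
#' model cost and QALYs.
#'
#' @param intervention_cost_total Total intervention cost for the arm (GBP).
#' @param acute_cost Total acute-condition cost for the arm.
#' @param death_cost Total infant death cost for the arm.
#' @param infant_qalys Infant lifetime QALYs attributed to the arm.
#' @param bc_cost,bc_qalys Women's breast-cancer model totals for the arm.
#' @return Named vector `c(cost = , qalys = )`.
#' @export
aggregate_arm <- function(intervention_cost_total = 0, acute_cost = 0,
                          death_cost = 0, infant_qalys = 0,
                          bc_cost = 0, bc_qalys = 0) {
  c(cost = intervention_cost_total + acute_cost + death_cost + bc_cost,
    qalys = infant_qalys + bc_qalys)
}

#' Incremental cost-effectiveness comparison
#'
#' Computes the incremental cost and QALYs of the intervention arm versus
#' standard care, the ICER (when defined), dominance flags, and a
#' classification against the willingness-to-pay thresholds.
#'
#' @param sc,int_arm Named vectors `c(cost = , qalys = )` as returned by
#'   [aggregate_arm()].
#' @param thresholds Lower and upper cost-effectiveness thresholds in
#'   GBP/QALY (default 20,000 and 30,000).
#' @return An object of class `bfcea_comparison`: `delta_cost`,
#'   `delta_qaly`, `icer` (`NA` when undefined), and `classification`, one
#'   of `"dominant"`, `"cost_effective_20k"`, `"cost_effective_30k"`,
#'   `"not_cost_effective"`, `"dominated"`.
#' @export
compare_arms <- function(sc, int_arm, thresholds = c(20000, 30000)) {
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
  dc <- unname(int_arm[["cost"]] - sc[["cost"]])
  de <- unname(int_arm[["qalys"]] - sc[["qalys"]])
  icer <- NA_real_
  if (dc < 0 && de > 0) {
    cls <- "dominant"
  } else if (dc > 0 && de < 0) {
    cls <- "dominated"
  } else if (de == 0) {
    # no division: equal effectiveness decided on cost alone
    cls <- if (dc > 0) "dominated" else if (dc < 0) "dominant"
           else "cost_effective_20k"
  } else if (dc <= 0 && de < 0) {
    # cheaper and less effective: ICER of forgoing; report ratio, classify
    # against thresholds from the south-west quadrant
    icer <- dc / de
    cls <- if (icer >= thresholds[2]) "cost_effective_20k"
           else "not_cost_effective"
  } else {
    icer <- dc / de
    cls <- if (icer <= thresholds[1]) "cost_effective_20k"
           else if (icer <= thresholds[2]) "cost_effective_30k"
           else "not_cost_effective"
  }
  structure(list(delta_cost = dc, delta_qaly = de, icer = icer,
                 classification = cls, thresholds = thresholds),
            class = "bfcea_comparison")
}

#' @export
print.bfcea_comparison <- function(x, ...) {
  cat(sprintf("Incremental cost: %s GBP; incremental QALYs: %.4f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (x$classification == "dominant") {
    cat("Intervention dominant (cheaper and more effective)\n")
  } else if (is.na(x$icer)) {
    cat("ICER undefined;", x$classification, "\n")
  } else {
    cat(sprintf("ICER: %s GBP/QALY (%s)\n",
                format(round(x$icer), big.mark = ","), x$classification))
  }
  invisible(x)
}

#' Label a comparison for report cells
#'
#' @param cmp A `bfcea_comparison`.
#' @return `"dominant"`, `"dominated"` or the ICER rounded to whole GBP as a
#'   string, matching the layout of published two-way grids.
#' @export
comparison_label <- function(cmp) {
  if (cmp$classification == "dominant") "dominant"
  else if (cmp$classification == "dominated") "dominated"
  else if (is.na(cmp$icer)) cmp$classification
  else as.character(round(cmp$icer))
}
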