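#' Relative effect estimate with 95\% confidence interval
#'
#' Container for a ratio-scale effect (risk ratio or odds ratio) with its
#' 95\% confidence interval, as used for the intervention effect on
#' breastfeeding rates and for the protective effects of breastfeeding and
#' parity on clinical outcomes.
#'
#' @param point Point estimate (ratio scale, > 0).
#' @param ci_lower,ci_upper 95\% confidence limits; must satisfy
#'   `0 < ci_lower <= point <= ci_upper`.
#' @param measure `"risk_ratio"` or `"odds_ratio"`.
#' @return An object of class `bfcea_effect`.
#' @examples
#' effect_estimate(1.19, 1.10, 1.30)
#' effect_estimate(0.67, 0.62, 0.72, measure = "odds_ratio")
#' @export
effect_estimate <- function(point, ci_lower = point, ci_upper = point,
                            measure = c("risk_ratio", "odds_ratio")) {
  measure <- match.arg(measure)
  stopifnot(is.numeric(point), length(point) == 1L, is.finite(point))
  if (!(ci_lower > 0 && ci_lower <= point && point <= ci_upper))
    stop("effect estimate must satisfy 0 < ci_lower <= point <= ci_upper")
  structure(list(point = point, ci_lower = ci_lower, ci_upper = ci_upper,
                 measure = measure),
            class = "bfcea_effect")
}

#' @export
print.bfcea_effect <- function(x, ...) {
  cat(sprintf("%s %.3g (95%% CI %.3g to %.3g)\n",
              if (x$measure == "risk_ratio") "RR" else "OR",
              x$point, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Breastfeeding prevalence schedule
#'
#' Population prevalence of any breastfeeding at 4 and 6 months after birth.
#'
#' @param p_bf_4m,p_bf_6m Probabilities with `0 <= p_bf_6m <= p_bf_4m <= 1`
#'   (prevalence cannot rise as babies age).
#' @return An object of class `bfcea_schedule`.
#' @export
bf_schedule <- function(p_bf_4m, p_bf_6m) {
  stopifnot(is.numeric(p_bf_4m), is.numeric(p_bf_6m))
  if (!(p_bf_6m >= 0 && p_bf_6m <= p_bf_4m && p_bf_4m <= 1))
    stop("need 0 <= p_bf_6m <= p_bf_4m <= 1")
  structure(list(p_bf_4m = p_bf_4m, p_bf_6m = p_bf_6m),
            class = "bfcea_schedule")
}

#' Cohort specification
#'
#' @param n_women Number of women in the cohort (>= 1).
#' @param start_age_mother_years Age of the mothers at model start; national
#'   mean age at delivery is 30, varied to 25/35 in scenarios.
#' @param babies_per_delivery Mean liveborn babies per delivery (1.016).
#' @param births_per_woman_scenario Total fertility rate used by the
#'   retained-effect scenario (1.70 births per woman).
#' @param proportion_male_infants Proportion of males among live babies.
#' @return An object of class `bfcea_cohort`.
#' @export
cohort_spec <- function(n_women = 1000,
                        start_age_mother_years = 30,
                        babies_per_delivery = 1.016,
                        births_per_woman_scenario = 1.70,
                        proportion_male_infants = 0.513) {
  stopifnot(n_women >= 1, babies_per_delivery >= 1,
            births_per_woman_scenario > 0,
            proportion_male_infants >= 0, proportion_male_infants <= 1,
            start_age_mother_years > 0)
  structure(list(n_women = n_women,
                 start_age_mother_years = start_age_mother_years,
                 babies_per_delivery = babies_per_delivery,
                 births_per_woman_scenario = births_per_woman_scenario,
                 proportion_male_infants = proportion_male_infants),
            class = "bfcea_cohort")
}

#' Back-calculate breastfeeding prevalence at 4 and 6 months
#'
#' Recent national statistics report the prevalence of any breastfeeding only
#' at 6--8 weeks after birth; the most recent 4- and 6-month figures are
#' older (2010). Assuming an exponential decline in breastfeeding prevalence,
#' the 2010 data define instantaneous weekly decline rates for the segments
#' 6 to 16 weeks and 16 to 26 weeks; applying those rates to the recent
#' 6--8-week figure yields up-to-date 4- and 6-month estimates.
#'
#' @param p_ref_2019 Recent prevalence of any breastfeeding at the reference
#'   week (probability in (0, 1)).
#' @param ref_week Week after birth at which `p_ref_2019` was measured; the
#'   default 7 is the midpoint of the 6--8-week reporting window and must be
#'   below 16.
#' @param anchors_2010 List with elements `p_6wk`, `p_16wk`, `p_26wk`: the
#'   2010 prevalences at 6 weeks, 4 months and 6 months (0.57, 0.44, 0.36).
#' @return A [bf_schedule()] with the unrounded 4- and 6-month estimates.
#' @examples
#' sched <- estimate_bf_prevalence(0.53)
#' percent_display(c(sched$p_bf_4m, sched$p_bf_6m))  # 42, 34
#' @seealso [percent_display()] for whole-percent display values.
#' @export
estimate_bf_prevalence <- function(p_ref_2019, ref_week = 7,
                                   anchors_2010 = list(p_6wk = 0.57,
                                                       p_16wk = 0.44,
                                                       p_26wk = 0.36)) {
  a <- anchors_2010
  stopifnot(all(c("p_6wk", "p_16wk", "p_26wk") %in% names(a)))
  if (!all(vapply(a, function(p) p > 0 && p < 1, logical(1))))
    stop("2010 anchor prevalences must lie in (0, 1)")
  if (!(a$p_6wk >= a$p_16wk && a$p_16wk >= a$p_26wk))
    stop("anchor prevalences must be nonincreasing: p_6wk >= p_16wk >= p_26wk")
  if (!(p_ref_2019 > 0 && p_ref_2019 < 1))
    stop("p_ref_2019 must lie in (0, 1)")
  if (!(ref_week > 0 && ref_week < 16))
    stop("ref_week must lie before week 16")
  # instantaneous weekly decline rates from the 2010 segments
  lambda_early <- log(a$p_16wk / a$p_6wk) / (16 - 6)
  lambda_late  <- log(a$p_26wk / a$p_16wk) / (26 - 16)
  p4 <- p_ref_2019 * exp((16 - ref_week) * lambda_early)
  p6 <- p4 * exp((26 - 16) * lambda_late)
  bf_schedule(p4, p6)
}

#' Display rounding helpers
#'
#' Reported tables round prevalences to whole percent, per-1000 counts to two
#' decimals and money to whole GBP; all internal arithmetic is unrounded.
#'
#' @param p Probability (or vector of probabilities).
#' @return `percent_display()`: whole-percent integer values.
#' @export
percent_display <- function(p) round(100 * p)

#' @rdname percent_display
#' @param x Count per 1000 (or vector).
#' @return `per1000_display()`: values rounded to 2 decimal places.
#' @export
per1000_display <- function(x) round(x, 2)

#' @rdname percent_display
#' @param gbp Money value in GBP.
#' @return `gbp_display()`: whole-pound values.
#' @export
gbp_display <- function(gbp) round(gbp)

#' Partition an overall incidence into exposed and unexposed strata
#'
#' The observed (baseline) incidence of a condition reflects the current mix
#' of exposed (breastfed / parous) and unexposed individuals. Given the
#' exposure prevalence and the relative effect of exposure, the stratum
#' incidences consistent with the overall figure are
#' \deqn{I_{unexp} = \frac{I_{overall}}{p \cdot RR + 1 - p}, \qquad
#'       I_{exp} = RR \cdot I_{unexp}}
#' so that the exposure-prevalence-weighted mixture reproduces the overall
#' incidence exactly. When the effect is an odds ratio it is used in place of
#' the risk ratio; this is accurate for rare events, and a warning is issued
#' if the overall incidence is 10\% or more.
#'
#' @param overall Overall incidence (rate or probability, >= 0).
#' @param p_exposed Prevalence of the exposure in the population, in [0, 1].
#' @param effect An [effect_estimate()].
#' @return Named numeric vector `c(unexposed = , exposed = )`.
#' @examples
#' partition_incidence(0.04682, 0.42, effect_estimate(0.46, 0.28, 0.78))
#' @export
partition_incidence <- function(overall, p_exposed, effect) {
  stopifnot(inherits(effect, "bfcea_effect"))
  if (!is.numeric(overall) || overall < 0) stop("overall incidence must be >= 0")
  if (!(p_exposed >= 0 && p_exposed <= 1)) stop("p_exposed must lie in [0, 1]")
  if (effect$measure == "odds_ratio" && overall >= 0.10)
    warning("odds ratio used as risk ratio with baseline incidence >= 10%; ",
            "the rare-event approximation may be inaccurate")
  unexposed <- overall / (p_exposed * effect$point + 1 - p_exposed)
  exposed <- effect$point * unexposed
  c(unexposed = unexposed, exposed = exposed)
}

#' Mix stratum incidences at a given exposure prevalence
#'
#' @param strata Output of [partition_incidence()].
#' @param p_exposed Exposure prevalence at which to recombine.
#' @return The mixture incidence.
#' @export
mix_incidence <- function(strata, p_exposed) {
  p_exposed * strata[["exposed"]] + (1 - p_exposed) * strata[["unexposed"]]
}

#' Apply the intervention effect to a breastfeeding prevalence
#'
#' Multiplicative uplift of a baseline prevalence by the intervention risk
#' ratio, capped at 1 (needed for sensitivity values up to RR 2.0). The same
#' uplift is applied to the 4-month and 6-month prevalences, both of which
#' lie inside the 16--26-week window over which the effect was measured.
#'
#' @param p_bf Baseline prevalence in [0, 1].
#' @param rr Intervention risk ratio (> 0).
#' @return `min(1, p_bf * rr)`.
#' @examples
#' apply_intervention(0.42, 1.19)  # 0.4998
#' @export
apply_intervention <- function(p_bf, rr) {
  stopifnot(p_bf >= 0, p_bf <= 1, rr > 0)
  pmin(1, p_bf * rr)
}

#' Intervention session cost component
#'
#' @param n_sessions Number of sessions of this type.
#' @param duration_minutes Duration of each session in minutes.
#' @param unit_cost_per_hour Cost per patient-related hour (GBP, 2018).
#' @param group_size Women sharing each session (1 = individual).
#' @return A cost-component list.
#' @export
session_component <- function(n_sessions, duration_minutes,
                              unit_cost_per_hour, group_size = 1) {
  stopifnot(n_sessions >= 0, duration_minutes >= 0,
            unit_cost_per_hour >= 0, group_size >= 1)
  list(n_sessions = n_sessions, duration_minutes = duration_minutes,
       unit_cost_per_hour = unit_cost_per_hour, group_size = group_size)
}

#' Per-woman intervention cost from its session components
#'
#' Each component contributes
#' `n_sessions * duration_hours * unit_cost_per_hour / group_size`.
#' The base-case composition (two individual 30-minute sessions by a Band-5
#' health professional at 59 GBP/h, two individual 30-minute sessions by a
#' trained peer supporter at 20 GBP/h, and two 45-minute group sessions at
#' 20 GBP/h shared by 6 women) costs 84 GBP per woman.
#'
#' @param components List of [session_component()]s (may be empty).
#' @return Cost per woman in GBP.
#' @examples
#' intervention_cost(base_intervention_components())  # 84
#' @export
intervention_cost <- function(components) {
  if (length(components) == 0) return(0)
  sum(vapply(components, function(cmp) {
    if (cmp$duration_minutes < 0 || cmp$unit_cost_per_hour < 0)
      stop("negative session duration or unit cost")
    cmp$n_sessions * (cmp$duration_minutes / 60) *
      cmp$unit_cost_per_hour / cmp$group_size
  }, numeric(1)))
}

#' Base-case intervention composition
#'
#' @return The session components whose total cost is 84 GBP per woman.
#' @export
base_intervention_components <- function() {
  list(session_component(2, 30, 59),
       session_component(2, 30, 20),
       session_component(2, 45, 20, group_size = 6))
}

#' Cost per extra woman breastfeeding
#'
#' Back-of-envelope value of the intervention: per 100 women, the number of
#' extra women breastfeeding is the prevalence uplift rounded to whole women,
#' and the cost per extra breastfeeding woman is the total intervention
#' outlay for those 100 women divided by that count.
#'
#' @param p_bf Baseline prevalence of breastfeeding.
#' @param rr Intervention risk ratio.
#' @param cost_per_woman Intervention cost per woman receiving it.
#' @return List with `extra_per_100` (whole women) and
#'   `cost_per_extra_breastfeeder` (GBP).
#' @examples
#' cost_per_extra_breastfeeder(0.42, 1.19, 84)  # 8 women; 1050 GBP
#' @export
cost_per_extra_breastfeeder <- function(p_bf, rr, cost_per_woman) {
  uplift <- apply_intervention(p_bf, rr) - p_bf
  extra <- round(100 * uplift)
  list(extra_per_100 = extra,
       cost_per_extra_breastfeeder = 100 * cost_per_woman / extra)
}
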