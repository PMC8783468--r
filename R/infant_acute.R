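#' Parameters for one acute infant condition
#'
#' Baseline event rates, breastfeeding effects and NHS unit costs for one of
#' the acute infant conditions modelled over the first year of life:
#' gastrointestinal infection (GI), lower respiratory tract infection (RTI)
#' or acute otitis media (AOM). GP-consultation and hospital-admission
#' processes are separate baseline streams; AOM has no admission stream.
#'
#' @param name Condition label.
#' @param baseline_gp_rate GP consultations per infant-year (overall
#'   population rate).
#' @param effect_incidence [effect_estimate()] of breastfeeding on incidence.
#' @param gp_unit_cost Cost per GP consultation (GBP).
#' @param baseline_hosp_rate Hospital admissions per infant-year, or `NULL`
#'   for conditions without an admission stream.
#' @param effect_hosp [effect_estimate()] on hospitalisation, or `NULL`.
#' @param hosp_unit_cost Cost per admission (GBP), or `NULL`.
#' @return An object of class `bfcea_acute_params`.
#' @export
acute_condition_params <- function(name, baseline_gp_rate, effect_incidence,
                                   gp_unit_cost, baseline_hosp_rate = NULL,
                                   effect_hosp = NULL, hosp_unit_cost = NULL) {
  stopifnot(baseline_gp_rate >= 0, baseline_gp_rate <= 1, gp_unit_cost >= 0,
            inherits(effect_incidence, "bfcea_effect"))
  has_hosp <- !is.null(baseline_hosp_rate)
  if (has_hosp && (is.null(effect_hosp) || is.null(hosp_unit_cost)))
    stop(sprintf("condition '%s' defines a hospitalisation rate but is %s",
                 name, "missing effect_hosp or hosp_unit_cost"))
  if (has_hosp)
    stopifnot(baseline_hosp_rate >= 0, baseline_hosp_rate <= 1,
              inherits(effect_hosp, "bfcea_effect"), hosp_unit_cost >= 0)
  structure(list(name = name, baseline_gp_rate = baseline_gp_rate,
                 effect_incidence = effect_incidence,
                 gp_unit_cost = gp_unit_cost,
                 baseline_hosp_rate = baseline_hosp_rate,
                 effect_hosp = effect_hosp, hosp_unit_cost = hosp_unit_cost),
            class = "bfcea_acute_params")
}

#' Parameters for one infant mortality cause
#'
#' @param cause `"infectious_disease"` or `"sids"`.
#' @param baseline_rate Deaths per live birth (in [0, 0.01]).
#' @param effect [effect_estimate()] of breastfeeding on the death rate.
#' @param death_unit_cost Cost per death (GBP; emergency attendance).
#' @param postmortem_cost Post-mortem examination cost added per death when
#'   the scenario flag is on (GBP).
#' @return An object of class `bfcea_mortality_params`.
#' @export
infant_mortality_params <- function(cause = c("infectious_disease", "sids"),
                                    baseline_rate, effect, death_unit_cost,
                                    postmortem_cost = 8000) {
  cause <- match.arg(cause)
  stopifnot(baseline_rate >= 0, baseline_rate <= 0.01,
            inherits(effect, "bfcea_effect"),
            death_unit_cost >= 0, postmortem_cost >= 0)
  structure(list(cause = cause, baseline_rate = baseline_rate,
                 effect = effect, death_unit_cost = death_unit_cost,
                 postmortem_cost = postmortem_cost),
            class = "bfcea_mortality_params")
}

# expected events per arm for one baseline stream: partition at the current
# (standard-care) 4-month prevalence, then recombine at each arm's prevalence
arm_expected <- function(n_babies, baseline, effect, p_bf_baseline,
                         p_bf_sc, p_bf_int) {
  strata <- partition_incidence(baseline, p_bf_baseline, effect)
  c(sc = n_babies * mix_incidence(strata, p_bf_sc),
    int = n_babies * mix_incidence(strata, p_bf_int))
}

#' One-year decision tree for an acute infant condition
#'
#' Babies either develop the condition or not; each case corresponds to one
#' GP contact, and (for GI and RTI) an independent admission stream sends a
#' number of babies to hospital. Stratum incidences are fixed by partitioning
#' the baseline rates at the current (standard-care) 4-month breastfeeding
#' prevalence; the two arms differ only in the breastfed/non-breastfed mix.
#'
#' @param cohort A [cohort_spec()].
#' @param params An [acute_condition_params()].
#' @param p_bf_sc,p_bf_int 4-month breastfeeding prevalence in the
#'   standard-care and intervention arms.
#' @param p_bf_baseline Prevalence at which the baseline rates were observed;
#'   defaults to `p_bf_sc`.
#' @param n_babies Babies in the cohort; defaults to
#'   `n_women * babies_per_delivery`.
#' @return Data frame with one row per arm (`sc`, `int`): expected `cases`,
#'   `hospitalisations` and `cost` for the whole cohort.
#' @export
acute_condition_outcomes <- function(cohort, params, p_bf_sc, p_bf_int,
                                     p_bf_baseline = p_bf_sc,
                                     n_babies = NULL) {
  stopifnot(inherits(cohort, "bfcea_cohort"),
            inherits(params, "bfcea_acute_params"))
  if (is.null(n_babies))
    n_babies <- cohort$n_women * cohort$babies_per_delivery
  cases <- arm_expected(n_babies, params$baseline_gp_rate,
                        params$effect_incidence, p_bf_baseline,
                        p_bf_sc, p_bf_int)
  hosp <- c(sc = 0, int = 0)
  if (!is.null(params$baseline_hosp_rate))
    hosp <- arm_expected(n_babies, params$baseline_hosp_rate,
                         params$effect_hosp, p_bf_baseline,
                         p_bf_sc, p_bf_int)
  cost <- cases * params$gp_unit_cost +
    hosp * (if (is.null(params$hosp_unit_cost)) 0 else params$hosp_unit_cost)
  data.frame(condition = params$name, arm = c("sc", "int"),
             cases = c(cases[["sc"]], cases[["int"]]),
             hospitalisations = c(hosp[["sc"]], hosp[["int"]]),
             cost = c(cost[["sc"]], cost[["int"]]),
             row.names = NULL)
}

#' Expected infant deaths and death costs per arm
#'
#' @inheritParams acute_condition_outcomes
#' @param params An [infant_mortality_params()].
#' @param include_postmortem Add the post-mortem examination cost per death
#'   (scenario analysis)?
#' @return List with the per-arm data frame (`deaths`, `cost`) and
#'   `deaths_prevented` (= standard-care deaths minus intervention deaths).
#' @export
infant_death_outcomes <- function(cohort, params, p_bf_sc, p_bf_int,
                                  p_bf_baseline = p_bf_sc, n_babies = NULL,
                                  include_postmortem = FALSE) {
  stopifnot(inherits(cohort, "bfcea_cohort"),
            inherits(params, "bfcea_mortality_params"))
  if (is.null(n_babies))
    n_babies <- cohort$n_women * cohort$babies_per_delivery
  deaths <- arm_expected(n_babies, params$baseline_rate, params$effect,
                         p_bf_baseline, p_bf_sc, p_bf_int)
  unit <- params$death_unit_cost +
    if (include_postmortem) params$postmortem_cost else 0
  list(arms = data.frame(cause = params$cause, arm = c("sc", "int"),
                         deaths = c(deaths[["sc"]], deaths[["int"]]),
                         cost = unit * c(deaths[["sc"]], deaths[["int"]]),
                         row.names = NULL),
       deaths_prevented = deaths[["sc"]] - deaths[["int"]])
}

#' Total acute-condition cost per arm
#'
#' @param results List of per-condition data frames as returned by
#'   [acute_condition_outcomes()].
#' @return Named numeric vector `c(sc = , int = )` of summed costs.
#' @export
acute_total <- function(results) {
  if (length(results) == 0) stop("need at least one condition result")
  tab <- do.call(rbind, results)
  with(tab, c(sc = sum(cost[arm == "sc"]), int = sum(cost[arm == "int"])))
}
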