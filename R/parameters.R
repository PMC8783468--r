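#' Base-case model parameter set
#'
#' Returns the full deterministic parameter set of the base-case analysis
#' together with the probability distributions assigned for probabilistic
#' sensitivity analysis: intervention effect RR 1.19 (log-normal from its
#' 95\% CI) and cost 84 GBP (normal, SE 10\% of the mean, truncated at 0);
#' 4- and 6-month breastfeeding prevalences 0.42 / 0.34 (beta from counts);
#' per-condition baseline rates, breastfeeding effects and unit costs for
#' GI, RTI and AOM; infant mortality baselines and effects; breast-cancer
#' effects (breastfeeding OR 0.86, parity OR 0.84), breast-cancer utility
#' 0.67; and the 3.5\% annual discount rate.
#'
#' The GP unit cost defaults to 37.40 GBP, the unrounded per-consultation
#' cost from the national unit-cost source (displayed as 37 GBP when rounded
#' to whole pounds). The GI admission baseline is 15.3 per 1000 live births.
#'
#' @return Nested parameter list with components `cohort`, `intervention`,
#'   `breastfeeding`, `conditions` (`gi`, `rti`, `aom`), `mortality`,
#'   `bc`, `costs`, `discount_rate`, `thresholds`, `max_age` and
#'   `distributions` (named [dist_spec()]s for the PSA).
#' @export
base_case_parameters <- function() {
  list(
    cohort = cohort_spec(),
    intervention = list(
      effect = effect_estimate(1.19, 1.10, 1.30),
      cost_per_woman = 84),
    breastfeeding = list(p_bf_4m = 0.42, p_bf_6m = 0.34),
    conditions = list(
      gi = list(baseline_gp_rate = 0.04682,
                effect_incidence = effect_estimate(0.46, 0.28, 0.78),
                baseline_hosp_rate = 0.0153,
                effect_hosp = effect_estimate(0.28, 0.16, 0.50),
                hosp_unit_cost = 756),
      rti = list(baseline_gp_rate = 0.23433,
                 effect_incidence = effect_estimate(0.68, 0.60, 0.77),
                 baseline_hosp_rate = 0.1154,
                 effect_hosp = effect_estimate(0.43, 0.33, 0.55),
                 hosp_unit_cost = 1094),
      aom = list(baseline_gp_rate = 0.13556,
                 effect_incidence = effect_estimate(0.67, 0.62, 0.72,
                                                    "odds_ratio"),
                 baseline_hosp_rate = NULL, effect_hosp = NULL,
                 hosp_unit_cost = NULL)),
    mortality = list(
      infectious = list(baseline_rate = 0.00012,
                        effect = effect_estimate(0.48, 0.30, 0.60,
                                                 "odds_ratio")),
      sids = list(baseline_rate = 0.00025,
                  effect = effect_estimate(0.38, 0.27, 0.54)),
      death_unit_cost = 204, postmortem_cost = 8000),
    bc = list(
      bf_effect = effect_estimate(0.86, 0.82, 0.91, "odds_ratio"),
      parity = parity_params(),
      utility_bc_y1_5 = 0.67),
    costs = list(gp_unit_cost = 37.40),
    discount_rate = 0.035,
    discount_rate_scenario = 0.015,
    thresholds = c(20000, 30000),
    max_age = 100,
    distributions = list(
      intervention_effect = dist_spec("lognormal_from_ci", point = 1.19,
                                      ci_lower = 1.10, ci_upper = 1.30),
      intervention_cost = dist_spec("normal_rel_se", mean = 84,
                                    rel_se = 0.10),
      p_bf_4m = dist_spec("beta_counts", alpha = 418, beta = 582),
      p_bf_6m = dist_spec("beta_counts", alpha = 342, beta = 658),
      gi_effect_incidence = dist_spec("lognormal_from_ci", point = 0.46,
                                      ci_lower = 0.28, ci_upper = 0.78),
      gi_effect_hosp = dist_spec("lognormal_from_ci", point = 0.28,
                                 ci_lower = 0.16, ci_upper = 0.50),
      gi_gp_rate = dist_spec("beta_counts", alpha = 47, beta = 953),
      rti_effect_incidence = dist_spec("lognormal_from_ci", point = 0.68,
                                       ci_lower = 0.60, ci_upper = 0.77),
      rti_effect_hosp = dist_spec("lognormal_from_ci", point = 0.43,
                                  ci_lower = 0.33, ci_upper = 0.55),
      rti_gp_rate = dist_spec("beta_counts", alpha = 234, beta = 766),
      aom_effect_incidence = dist_spec("lognormal_from_ci", point = 0.67,
                                       ci_lower = 0.62, ci_upper = 0.72),
      aom_gp_rate = dist_spec("beta_counts", alpha = 136, beta = 864),
      mort_infectious_effect = dist_spec("lognormal_from_ci", point = 0.48,
                                         ci_lower = 0.30, ci_upper = 0.60),
      mort_sids_effect = dist_spec("lognormal_from_ci", point = 0.38,
                                   ci_lower = 0.27, ci_upper = 0.54),
      bc_bf_effect = dist_spec("lognormal_from_ci", point = 0.86,
                               ci_lower = 0.82, ci_upper = 0.91),
      parity_effect = dist_spec("lognormal_from_ci", point = 0.84,
                                ci_lower = 0.80, ci_upper = 0.89),
      utility_bc = dist_spec("beta_counts", alpha = 67.46, beta = 32.54),
      gp_unit_cost = dist_spec("normal_rel_se", mean = 37.40, rel_se = 0.10),
      cost_hosp_gi = dist_spec("gamma_rel_se", mean = 756, rel_se = 0.10),
      cost_hosp_rti = dist_spec("gamma_rel_se", mean = 1094, rel_se = 0.10),
      cost_death = dist_spec("gamma_rel_se", mean = 204, rel_se = 0.10),
      bc_cost_scale = dist_spec("gamma_rel_se", mean = 1, rel_se = 0.10)))
}

# strip S3 classes recursively so yaml can serialise the parameter list
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write or read a parameter configuration file
#'
#' Parameters are stored as YAML mirroring the structure of
#' [base_case_parameters()]. Reading restores the typed objects (effect
#' estimates, cohort, parity, distribution specs).
#'
#' @param params Parameter list as from [base_case_parameters()].
#' @param path YAML file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: the
#'   parameter list.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(strip_classes(params), path)
  invisible(path)
}

restore_effect <- function(x)
  effect_estimate(x$point, x$ci_lower, x$ci_upper, x$measure)

#' @rdname write_config
#' @export
read_config <- function(path) {
  p <- yaml::read_yaml(path)
  p$cohort <- do.call(cohort_spec, p$cohort)
  p$intervention$effect <- restore_effect(p$intervention$effect)
  for (cn in names(p$conditions)) {
    p$conditions[[cn]]$effect_incidence <-
      restore_effect(p$conditions[[cn]]$effect_incidence)
    if (!is.null(p$conditions[[cn]]$effect_hosp))
      p$conditions[[cn]]$effect_hosp <-
        restore_effect(p$conditions[[cn]]$effect_hosp)
  }
  for (mc in c("infectious", "sids"))
    p$mortality[[mc]]$effect <- restore_effect(p$mortality[[mc]]$effect)
  p$bc$bf_effect <- restore_effect(p$bc$bf_effect)
  pp <- p$bc$parity
  p$bc$parity <- parity_params(
    stats::setNames(unlist(pp$props), pp$step_ages),
    restore_effect(pp$parity_effect), pp$mean_children)
  p$thresholds <- unlist(p$thresholds)
  p$distributions <- lapply(p$distributions, function(d)
    do.call(dist_spec, c(list(family = d$family),
                         d[setdiff(names(d), "family")])))
  p
}
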