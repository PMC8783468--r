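#' Run the full deterministic cost-effectiveness model
#'
#' Executes the complete pipeline for both arms: intervention uplift of the
#' breastfeeding prevalences, one-year decision trees for GI, RTI and AOM,
#' infant mortality with lifetime QALYs for infants saved from death, the
#' women's breast-cancer Markov model, arm aggregation and the incremental
#' comparison. Results are reported for the whole cohort (`n_women` women
#' and their babies).
#'
#' Infant outcomes use the 4-month breastfeeding prevalence, the women's
#' breast-cancer model the 6-month prevalence; stratum incidences are
#' anchored at the standard-care prevalences in both arms. Lifetime QALYs
#' of infants saved from a first-year death accrue from age 0. The QALY gain
#' from prevented deaths is credited to the intervention arm.
#'
#' @param params Parameter list as from [base_case_parameters()].
#' @param bundle A [fixture_bundle()] supplying life, utility and
#'   breast-cancer tables.
#' @param include_postmortem Add the post-mortem examination cost to each
#'   infant death (scenario analysis)?
#' @param discount_rate Override of the annual discount rate.
#' @param start_age_mother Override of the mothers' starting age.
#' @param babies_per_woman Override of babies per woman for the infant
#'   components (scenario: effect retained over all births, 1.70); default
#'   uses babies per delivery (1.016).
#' @return List with `condition_table` (per-condition counts and costs per
#'   arm with differences), `sc` and `int` aggregate `c(cost, qalys)`,
#'   `comparison` (a `bfcea_comparison`), `deaths_prevented`,
#'   `infant_qalys_gained` and `bc` (the breast-cancer arm table).
#' @examples
#' \donttest{
#' res <- run_model(base_case_parameters(), default_bundle(1))
#' res$comparison
#' }
#' @export
run_model <- function(params, bundle,
                      include_postmortem = FALSE,
                      discount_rate = NULL,
                      start_age_mother = NULL,
                      babies_per_woman = NULL) {
  stopifnot(inherits(bundle, "bfcea_bundle"))
  cohort <- params$cohort
  r <- if (is.null(discount_rate)) params$discount_rate else discount_rate
  start_age <- if (is.null(start_age_mother)) cohort$start_age_mother_years
               else start_age_mother
  bpw <- if (is.null(babies_per_woman)) cohort$babies_per_delivery
         else babies_per_woman
  n_babies <- cohort$n_women * bpw
  rr <- params$intervention$effect$point

  p4_sc <- params$breastfeeding$p_bf_4m
  p6_sc <- params$breastfeeding$p_bf_6m
  p4_int <- apply_intervention(p4_sc, rr)
  p6_int <- apply_intervention(p6_sc, rr)

  gp_cost <- params$costs$gp_unit_cost
  acute <- lapply(names(params$conditions), function(cn) {
    cp <- params$conditions[[cn]]
    ap <- acute_condition_params(cn, cp$baseline_gp_rate,
                                 cp$effect_incidence, gp_cost,
                                 cp$baseline_hosp_rate, cp$effect_hosp,
                                 cp$hosp_unit_cost)
    acute_condition_outcomes(cohort, ap, p4_sc, p4_int,
                             p_bf_baseline = p4_sc, n_babies = n_babies)
  })
  acute_costs <- acute_total(acute)

  deaths <- lapply(c("infectious", "sids"), function(mc) {
    mp <- params$mortality[[mc]]
    ip <- infant_mortality_params(
      if (mc == "infectious") "infectious_disease" else "sids",
      mp$baseline_rate, mp$effect, params$mortality$death_unit_cost,
      params$mortality$postmortem_cost)
    infant_death_outcomes(cohort, ip, p4_sc, p4_int,
                          p_bf_baseline = p4_sc, n_babies = n_babies,
                          include_postmortem = include_postmortem)
  })
  deaths_prevented <- sum(vapply(deaths, `[[`, numeric(1),
                                 "deaths_prevented"))
  death_tab <- do.call(rbind, lapply(deaths, `[[`, "arms"))
  death_costs <- with(death_tab, c(sc = sum(cost[arm == "sc"]),
                                   int = sum(cost[arm == "int"])))

  qalys_pp <- lifetime_discounted_qalys(
    0, cohort$proportion_male_infants, bundle$life_table,
    bundle$utility_table, r, params$max_age)
  infant_qalys_gained <- qalys_from_prevented_deaths(deaths_prevented,
                                                     qalys_pp)

  bc_tab <- bundle$bc
  bc_tab$utility_bc_y1_5 <- params$bc$utility_bc_y1_5
  bc <- bc_arm_comparison(p6_sc, p6_int, cohort, bc_tab, params$bc$parity,
                          params$bc$bf_effect, bundle$utility_table,
                          discount_rate = r, max_age = params$max_age,
                          start_age = start_age)

  int_cost_total <- cohort$n_women * params$intervention$cost_per_woman
  sc_tot <- aggregate_arm(0, acute_costs[["sc"]], death_costs[["sc"]],
                          0, bc$cost[bc$arm == "sc"],
                          bc$qalys[bc$arm == "sc"])
  int_tot <- aggregate_arm(int_cost_total, acute_costs[["int"]],
                           death_costs[["int"]], infant_qalys_gained,
                           bc$cost[bc$arm == "int"],
                           bc$qalys[bc$arm == "int"])
  cmp <- compare_arms(sc_tot, int_tot, params$thresholds)

  list(condition_table = build_condition_table(acute, death_tab,
                                               infant_qalys_gained,
                                               int_cost_total, bc, cmp),
       acute = acute, deaths = death_tab,
       deaths_prevented = deaths_prevented,
       infant_qalys_per_person = qalys_pp,
       infant_qalys_gained = infant_qalys_gained,
       bc = bc, sc = sc_tot, int = int_tot, comparison = cmp)
}

# long-format per-condition report table (one row per quantity), with
# intervention, standard-care and difference columns
build_condition_table <- function(acute, death_tab, infant_qalys_gained,
                                  int_cost_total, bc, cmp) {
  row <- function(group, quantity, int, sc)
    data.frame(group = group, quantity = quantity,
               intervention = int, sc = sc, difference = int - sc)
  rows <- list(row("intervention", "cost", int_cost_total, 0))
  for (tab in acute) {
    g <- tab$condition[1]
    gv <- function(col, arm) tab[[col]][tab$arm == arm]
    rows <- c(rows, list(
      row(g, "infections", gv("cases", "int"), gv("cases", "sc"))))
    if (any(tab$hospitalisations > 0))
      rows <- c(rows, list(row(g, "hospitalisations",
                               gv("hospitalisations", "int"),
                               gv("hospitalisations", "sc"))))
    rows <- c(rows, list(row(g, "cost", gv("cost", "int"), gv("cost", "sc"))))
  }
  for (cause in unique(death_tab$cause)) {
    sub <- death_tab[death_tab$cause == cause, ]
    rows <- c(rows, list(row("infant mortality", paste("deaths,", cause),
                             sub$deaths[sub$arm == "int"],
                             sub$deaths[sub$arm == "sc"])))
  }
  rows <- c(rows, list(
    row("infant mortality", "cost",
        sum(death_tab$cost[death_tab$arm == "int"]),
        sum(death_tab$cost[death_tab$arm == "sc"])),
    row("infant mortality", "QALYs gained", infant_qalys_gained, 0),
    row("breast cancer", "new cases", bc$cases[bc$arm == "int"],
        bc$cases[bc$arm == "sc"]),
    row("breast cancer", "QALYs", bc$qalys[bc$arm == "int"],
        bc$qalys[bc$arm == "sc"]),
    row("breast cancer", "cost", bc$cost[bc$arm == "int"],
        bc$cost[bc$arm == "sc"]),
    data.frame(group = "total", quantity = c("QALY difference",
                                             "cost difference",
                                             "ICER"),
               intervention = NA, sc = NA,
               difference = c(cmp$delta_qaly, cmp$delta_cost, cmp$icer))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
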