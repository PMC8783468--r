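#' Parity parameters for the women's breast-cancer model
#'
#' Proportion of nulliparous women by age (a step function: 48\% at 30,
#' 27\% at 35, 19\% at 40, 18\% at 45 and above), the protective effect of
#' parity on breast-cancer incidence (odds ratio for parous women with two
#' live births versus nulliparous women), and the mean number of children
#' per parous woman.
#'
#' @param prop_nulliparous_by_age Named numeric vector: step start ages
#'   (ascending) mapped to nulliparous proportions.
#' @param parity_effect An [effect_estimate()]; default OR 0.84 (0.80-0.89).
#' @param mean_children Mean children per parous woman (about 2).
#' @return An object of class `bfcea_parity`.
#' @export
parity_params <- function(prop_nulliparous_by_age = c("30" = 0.48,
                                                      "35" = 0.27,
                                                      "40" = 0.19,
                                                      "45" = 0.18),
                          parity_effect = effect_estimate(0.84, 0.80, 0.89,
                                                          "odds_ratio"),
                          mean_children = 2) {
  ages <- as.numeric(names(prop_nulliparous_by_age))
  stopifnot(!anyNA(ages), !is.unsorted(ages, strictly = TRUE),
            all(prop_nulliparous_by_age >= 0),
            all(prop_nulliparous_by_age <= 1),
            inherits(parity_effect, "bfcea_effect"))
  structure(list(step_ages = ages,
                 props = unname(prop_nulliparous_by_age),
                 parity_effect = parity_effect,
                 mean_children = mean_children),
            class = "bfcea_parity")
}

#' Proportion of nulliparous women at a given age
#'
#' @param parity A [parity_params()].
#' @param age Vector of ages; ages below the first step age take the first
#'   step's value (needed for starting-age scenarios below 30).
#' @return Nulliparous proportions (step function, half-open bands).
#' @export
prop_nulliparous <- function(parity, age) {
  idx <- pmax(findInterval(age, parity$step_ages), 1L)
  parity$props[idx]
}

#' Bundle of age-indexed breast-cancer model tables
#'
#' @param incidence_general Data frame `(age, rate)`: breast-cancer incidence
#'   in the general female population (new cases per woman-year).
#' @param mortality_general Data frame `(age, q)`: all-cause annual death
#'   probability for women.
#' @param mortality_bc_general Data frame `(age, rate)`: breast-cancer death
#'   rate in the general female population (used only by the optional
#'   background-mortality subtraction).
#' @param net_survival Data frame `(year, survival)`: cumulative age-adjusted
#'   net survival 1-10 years after diagnosis, nonincreasing, in (0, 1].
#' @param cost_no_bc Data frame `(age, cost)`: annual healthcare cost of
#'   women without breast cancer.
#' @param cost_bc Data frame `(year, cost)`: annual healthcare cost by year
#'   since diagnosis (front-loaded).
#' @param utility_bc_y1_5 Utility in breast-cancer years 1-5 (default 0.67).
#'   In years 6-10 the model uses the average of this value and the
#'   age-specific general-population utility.
#' @param bc_duration_years Duration of the breast-cancer state (10 years of
#'   tunnel states, after which survivors return to 'no breast cancer').
#' @return An object of class `bfcea_bc_tables`.
#' @export
bc_tables <- function(incidence_general, mortality_general,
                      mortality_bc_general, net_survival,
                      cost_no_bc, cost_bc,
                      utility_bc_y1_5 = 0.67, bc_duration_years = 10) {
  stopifnot(all(c("age", "rate") %in% names(incidence_general)),
            all(c("age", "q") %in% names(mortality_general)),
            all(c("age", "rate") %in% names(mortality_bc_general)),
            all(c("year", "survival") %in% names(net_survival)),
            all(c("age", "cost") %in% names(cost_no_bc)),
            all(c("year", "cost") %in% names(cost_bc)))
  ns <- net_survival$survival[order(net_survival$year)]
  if (length(ns) != bc_duration_years)
    stop("net_survival must cover years 1..", bc_duration_years)
  if (any(diff(ns) > 0)) stop("net survival must be nonincreasing")
  if (any(ns <= 0 | ns > 1)) stop("net survival must lie in (0, 1]")
  stopifnot(all(incidence_general$rate >= 0 & incidence_general$rate <= 1),
            all(mortality_general$q > 0 & mortality_general$q < 1),
            all(cost_no_bc$cost >= 0), all(cost_bc$cost >= 0),
            utility_bc_y1_5 >= 0, utility_bc_y1_5 <= 1)
  structure(list(incidence_general = incidence_general,
                 mortality_general = mortality_general,
                 mortality_bc_general = mortality_bc_general,
                 net_survival = net_survival[order(net_survival$year), ],
                 cost_no_bc = cost_no_bc, cost_bc = cost_bc,
                 utility_bc_y1_5 = utility_bc_y1_5,
                 bc_duration_years = bc_duration_years),
            class = "bfcea_bc_tables")
}

lookup_col <- function(tab, key_col, val_col, keys, what) {
  idx <- match(keys, tab[[key_col]])
  if (anyNA(idx))
    stop(what, " table missing ", key_col, " ",
         paste(unique(keys[is.na(idx)]), collapse = ", "))
  tab[[val_col]][idx]
}

#' Breast-cancer incidence in parous women
#'
#' Partitions the general-population incidence at a given age into parous
#' and nulliparous strata, using the age-specific nulliparous proportion and
#' the protective effect of parity, and returns the parous (exposed) stratum.
#'
#' @param age Integer age (>= the first parity step age, i.e. 30).
#' @param tables A [bc_tables()].
#' @param parity A [parity_params()].
#' @return Annual breast-cancer incidence among parous women.
#' @export
parous_incidence <- function(age, tables, parity) {
  overall <- lookup_col(tables$incidence_general, "age", "rate", age,
                        "incidence")
  vapply(seq_along(age), function(i) {
    partition_incidence(overall[i], 1 - prop_nulliparous(parity, age[i]),
                        parity$parity_effect)[["exposed"]]
  }, numeric(1))
}

#' Breast-cancer incidence by breastfeeding status among parous women
#'
#' Second-level partition: the parous incidence is split into women who
#' breastfed for at least 6 months and those who did not, at the current
#' standard-care 6-month prevalence, using the protective effect of
#' breastfeeding on breast cancer (OR 0.86, any versus no breastfeeding for
#' 6 months).
#'
#' @inheritParams parous_incidence
#' @param p_bf_6m Current 6-month breastfeeding prevalence used to anchor the
#'   partition.
#' @param bf_effect An [effect_estimate()] (OR 0.86, 0.82-0.91).
#' @return Named vector `c(bf = , non_bf = )` of stratum incidences.
#' @export
bf_stratified_incidence <- function(age, tables, parity, p_bf_6m, bf_effect) {
  parous <- parous_incidence(age, tables, parity)
  bf <- non_bf <- numeric(length(age))
  for (i in seq_along(age)) {
    s <- partition_incidence(parous[i], p_bf_6m, bf_effect)
    bf[i] <- s[["exposed"]]
    non_bf[i] <- s[["unexposed"]]
  }
  if (length(age) == 1L) c(bf = bf, non_bf = non_bf)
  else list(bf = bf, non_bf = non_bf)
}

#' Annual mortality in the breast-cancer state
#'
#' Combines general all-cause mortality with a duration-dependent excess
#' derived from cumulative net survival: with conditional net survival
#' `c(k) = S_net(k) / S_net(k - 1)` (and `S_net(0) = 1`), the annual death
#' probability `k` years after diagnosis at a given age is
#' `q_bc = 1 - (1 - q_general) * c(k)`, floored at `q_general` and capped at
#' 1. This conditional-survival construction is this package's documented
#' derivation of excess breast-cancer mortality and is isolated here so it
#' can be swapped.
#'
#' @inheritParams parous_incidence
#' @param years_since_dx Year lived with breast cancer, in 1..10.
#' @return Annual death probability in the breast-cancer tunnel state.
#' @export
bc_annual_mortality <- function(age, years_since_dx, tables) {
  k <- years_since_dx
  if (any(k < 1 | k > tables$bc_duration_years))
    stop("years_since_dx must lie in 1..", tables$bc_duration_years)
  q_gen <- lookup_col(tables$mortality_general, "age", "q", age, "mortality")
  ns <- c(1, tables$net_survival$survival)
  cond <- ns[k + 1] / ns[k]
  pmin(1, pmax(q_gen, 1 - (1 - q_gen) * cond))
}

# cycle-by-cycle cohort run for one homogeneous stratum with incidence
# vector inc (one entry per cycle). States: 1 = noBC, 2..(D+1) = tunnel
# years 1..D, D+2 = dead. Incident cases arise among women surviving the
# cycle's background mortality.
bc_stratum_run <- function(inc, start_age, tables, utilities, discount_rate,
                           max_age, subtract_bc_mortality = FALSE) {
  D <- tables$bc_duration_years
  n_states <- D + 2
  ages <- start_age:(max_age - 1)
  T <- length(ages)
  stopifnot(length(inc) == T)
  q_gen <- lookup_col(tables$mortality_general, "age", "q", ages, "mortality")
  if (subtract_bc_mortality) {
    q_bcg <- lookup_col(tables$mortality_bc_general, "age", "rate", ages,
                        "breast-cancer mortality")
    q_gen <- pmax(q_gen - q_bcg, 1e-8)
  }
  ns <- c(1, tables$net_survival$survival)
  cond <- ns[2:(D + 1)] / ns[1:D]
  # q_bc[t, k]: death probability at cycle t in tunnel year k
  q_bc <- sapply(seq_len(D), function(k)
    pmin(1, pmax(q_gen, 1 - (1 - q_gen) * cond[k])))
  u_gen <- lookup_utility(utilities, ages, "female")
  u_bc <- tables$utility_bc_y1_5
  u_states <- cbind(u_gen,
                    matrix(u_bc, T, min(5, D)),
                    if (D > 5) (u_bc + u_gen) %o% rep(0.5, D - 5),
                    0)
  c_no <- lookup_col(tables$cost_no_bc, "age", "cost", ages, "cost")
  c_bc <- lookup_col(tables$cost_bc, "year", "cost", seq_len(D), "cost")
  c_states <- cbind(c_no, matrix(c_bc, T, D, byrow = TRUE), 0)

  occ <- matrix(0, T + 1, n_states)
  occ[1, 1] <- 1
  new_cases <- numeric(T)
  for (t in seq_len(T)) {
    cur <- occ[t, ]
    nxt <- numeric(n_states)
    p_inc <- inc[t] * (1 - q_gen[t])
    tunnel_surv <- cur[2:(D + 1)] * (1 - q_bc[t, ])
    # final-tunnel-year survivors recover into 'no breast cancer'
    nxt[1] <- cur[1] * (1 - q_gen[t] - p_inc) + tunnel_surv[D]
    nxt[2] <- cur[1] * p_inc
    nxt[3:(D + 1)] <- tunnel_surv[seq_len(D - 1)]
    nxt[n_states] <- cur[n_states] + cur[1] * q_gen[t] +
      sum(cur[2:(D + 1)] * q_bc[t, ])
    new_cases[t] <- cur[1] * p_inc
    occ[t + 1, ] <- nxt
  }
  drift <- max(abs(rowSums(occ) - 1))
  if (drift > 1e-10)
    stop("occupancy drifted from 1 by ", format(drift), "; internal failure")
  w <- (occ[seq_len(T), , drop = FALSE] + occ[-1, , drop = FALSE]) / 2
  v <- (1 + discount_rate)^-(seq_len(T) - 1)
  list(trace = occ, new_cases = new_cases,
       qalys = sum(v * rowSums(w * u_states)),
       cost = sum(v * rowSums(w * c_states)),
       cases = sum(new_cases),
       qalys_start = sum(v * rowSums(occ[seq_len(T), , drop = FALSE] * u_states)),
       qalys_end = sum(v * rowSums(occ[-1, , drop = FALSE] * u_states)))
}

#' Lifetime breast-cancer Markov model for one arm
#'
#' Three-state annual-cycle cohort model ('no breast cancer', 'breast
#' cancer' as 10 tunnel states, 'death') for women entering cancer-free at
#' `start_age`. The arm is modelled as two lifelong homogeneous sub-cohorts
#' -- women who breastfeed for 6 months and women who do not -- whose
#' age-specific incidences come from [bf_stratified_incidence()] anchored at
#' the current standard-care prevalence, mixed at the arm's prevalence.
#' Women surviving 10 years with breast cancer return to 'no breast cancer'
#' and are again at risk, so recurrent primaries count as new cases. QALYs
#' and costs use half-cycle correction (trapezoidal state membership) and
#' are discounted at `(1 + r)^-t`.
#'
#' @param p_bf_6m Arm's 6-month breastfeeding prevalence.
#' @param start_age Age of women at entry (base case 30).
#' @param tables A [bc_tables()].
#' @param parity A [parity_params()].
#' @param bf_effect Breastfeeding effect on breast cancer
#'   ([effect_estimate()], OR 0.86).
#' @param utilities Utility table (see [lookup_utility()]).
#' @param discount_rate Annual discount rate (default 0.035).
#' @param max_age Age at which the model stops (default 100).
#' @param p_bf_baseline Prevalence anchoring the stratum partition; defaults
#'   to `p_bf_6m` (i.e. the standard-care arm).
#' @param subtract_bc_mortality Subtract general-population breast-cancer
#'   mortality from the background rate in the 'no breast cancer' state?
#'   Off by default (the double count is small).
#' @return List: `trace` (mixed occupancy matrix, cycles x states),
#'   `qalys`, `cost`, `cases` (per woman), `new_cases` (per-cycle incident
#'   flow), plus undiscounted bookkeeping fields used by diagnostics.
#' @export
run_bc_markov <- function(p_bf_6m, start_age, tables, parity, bf_effect,
                          utilities, discount_rate = 0.035, max_age = 100,
                          p_bf_baseline = p_bf_6m,
                          subtract_bc_mortality = FALSE) {
  stopifnot(p_bf_6m >= 0, p_bf_6m <= 1)
  ages <- start_age:(max_age - 1)
  strata <- bf_stratified_incidence(ages, tables, parity, p_bf_baseline,
                                    bf_effect)
  res_bf <- bc_stratum_run(strata$bf, start_age, tables, utilities,
                           discount_rate, max_age, subtract_bc_mortality)
  res_nb <- bc_stratum_run(strata$non_bf, start_age, tables, utilities,
                           discount_rate, max_age, subtract_bc_mortality)
  mix <- function(f) p_bf_6m * res_bf[[f]] + (1 - p_bf_6m) * res_nb[[f]]
  list(trace = mix("trace"), new_cases = mix("new_cases"),
       qalys = mix("qalys"), cost = mix("cost"), cases = mix("cases"),
       qalys_start = mix("qalys_start"), qalys_end = mix("qalys_end"))
}

#' Compare the breast-cancer model between the two arms
#'
#' Runs [run_bc_markov()] for the standard-care and intervention arms (the
#' stratum partition is anchored at the standard-care prevalence in both)
#' and scales per-woman results by the cohort size.
#'
#' @param p_bf_sc,p_bf_int 6-month breastfeeding prevalence per arm.
#' @param cohort A [cohort_spec()].
#' @inheritParams run_bc_markov
#' @return Data frame with one row per arm (`sc`, `int`) and a `diff` row
#'   (intervention minus standard care): `cases`, `qalys`, `cost` per
#'   `n_women` women.
#' @export
bc_arm_comparison <- function(p_bf_sc, p_bf_int, cohort, tables, parity,
                              bf_effect, utilities, discount_rate = 0.035,
                              max_age = 100, start_age = NULL,
                              subtract_bc_mortality = FALSE) {
  stopifnot(inherits(cohort, "bfcea_cohort"))
  if (is.null(start_age)) start_age <- cohort$start_age_mother_years
  n <- cohort$n_women
  sc <- run_bc_markov(p_bf_sc, start_age, tables, parity, bf_effect,
                      utilities, discount_rate, max_age,
                      p_bf_baseline = p_bf_sc,
                      subtract_bc_mortality = subtract_bc_mortality)
  it <- run_bc_markov(p_bf_int, start_age, tables, parity, bf_effect,
                      utilities, discount_rate, max_age,
                      p_bf_baseline = p_bf_sc,
                      subtract_bc_mortality = subtract_bc_mortality)
  data.frame(arm = c("sc", "int", "diff"),
             cases = n * c(sc$cases, it$cases, it$cases - sc$cases),
             qalys = n * c(sc$qalys, it$qalys, it$qalys - sc$qalys),
             cost = n * c(sc$cost, it$cost, it$cost - sc$cost),
             row.names = NULL)
}
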