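# Monte-Carlo and closed-form oracles, independent of the cohort-expectation
# implementations they check.

test_bundle <- function(seed = 2021) default_bundle(seed)

# per-baby microsimulation of one acute-condition stream: Bernoulli
# breastfeeding status, then Bernoulli event at the stratum incidence
microsim_acute_rate <- function(n, strata, p_bf) {
  bf <- stats::runif(n) < p_bf
  rate <- ifelse(bf, strata[["exposed"]], strata[["unexposed"]])
  events <- stats::runif(n) < rate
  list(mean = mean(events), se = stats::sd(events) / sqrt(n))
}

# per-person microsimulation of the two-state (alive/dead) lifetime model
microsim_lifetime_qalys <- function(n, start_age, sex_mix, life_table,
                                    utilities, discount_rate, max_age) {
  male <- stats::runif(n) < sex_mix
  ages <- start_age:(max_age - 1)
  T <- length(ages)
  q <- list(male = bfcea:::life_table_q(life_table, "male", start_age,
                                        max_age),
            female = bfcea:::life_table_q(life_table, "female", start_age,
                                          max_age))
  u <- list(male = lookup_utility(utilities, ages, "male"),
            female = lookup_utility(utilities, ages, "female"))
  v <- (1 + discount_rate)^-(seq_len(T) - 1)
  alive <- rep(TRUE, n)
  qaly <- numeric(n)
  for (t in seq_len(T)) {
    ut <- ifelse(male, u$male[t], u$female[t])
    qaly <- qaly + alive * ut * v[t]          # start-of-cycle accrual
    qt <- ifelse(male, q$male[t], q$female[t])
    alive <- alive & (stats::runif(n) >= qt)
  }
  list(mean = mean(qaly), se = stats::sd(qaly) / sqrt(n))
}

# per-woman microsimulation of the breast-cancer tunnel-state model, using
# the same transition probabilities, utilities, costs, half-cycle accrual
# and discounting as the cohort model, but simulated person by person
microsim_bc <- function(n, p_bf, start_age, tables, parity, bf_effect,
                        utilities, discount_rate, max_age) {
  D <- tables$bc_duration_years
  dead_state <- D + 2L
  ages <- start_age:(max_age - 1)
  T <- length(ages)
  strata <- bf_stratified_incidence(ages, tables, parity, p_bf, bf_effect)
  q_gen <- bfcea:::lookup_col(tables$mortality_general, "age", "q", ages,
                              "mortality")
  ns <- c(1, tables$net_survival$survival)
  cond <- ns[2:(D + 1)] / ns[1:D]
  q_bc <- sapply(seq_len(D), function(k)
    pmin(1, pmax(q_gen, 1 - (1 - q_gen) * cond[k])))
  u_gen <- lookup_utility(utilities, ages, "female")
  u_tab <- cbind(u_gen, matrix(tables$utility_bc_y1_5, T, 5),
                 (tables$utility_bc_y1_5 + u_gen) %o% rep(0.5, D - 5), 0)
  c_no <- bfcea:::lookup_col(tables$cost_no_bc, "age", "cost", ages, "cost")
  c_bc <- bfcea:::lookup_col(tables$cost_bc, "year", "cost", seq_len(D),
                             "cost")
  c_tab <- cbind(c_no, matrix(c_bc, T, D, byrow = TRUE), 0)
  v <- (1 + discount_rate)^-(seq_len(T) - 1)

  bf <- stats::runif(n) < p_bf
  state <- rep(1L, n)
  qaly <- cost <- cases <- numeric(n)
  for (t in seq_len(T)) {
    before_u <- u_tab[t, state]
    before_c <- c_tab[t, state]
    u1 <- stats::runif(n)
    inc_t <- ifelse(bf, strata$bf[t], strata$non_bf[t]) * (1 - q_gen[t])
    new_state <- state
    in_no <- state == 1L
    new_state[in_no & u1 < q_gen[t]] <- dead_state
    to_bc <- in_no & u1 >= q_gen[t] & u1 < q_gen[t] + inc_t
    new_state[to_bc] <- 2L
    cases <- cases + to_bc
    in_tun <- state >= 2L & state <= D + 1L
    if (any(in_tun)) {
      k <- state[in_tun] - 1L
      die <- u1[in_tun] < q_bc[cbind(t, k)]
      adv <- ifelse(k == D, 1L, state[in_tun] + 1L)
      new_state[in_tun] <- ifelse(die, dead_state, adv)
    }
    qaly <- qaly + v[t] * 0.5 * (before_u + u_tab[t, new_state])
    cost <- cost + v[t] * 0.5 * (before_c + c_tab[t, new_state])
    state <- new_state
  }
  list(qalys = mean(qaly), qalys_se = stats::sd(qaly) / sqrt(n),
       cost = mean(cost), cost_se = stats::sd(cost) / sqrt(n),
       cases = mean(cases), cases_se = stats::sd(cases) / sqrt(n))
}
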