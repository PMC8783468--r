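bc_fixture <- function(seed = 2021) {
  b <- test_bundle(seed)
  list(tables = b$bc, utilities = b$utility_table,
       parity = parity_params(),
       bf_effect = effect_estimate(0.86, 0.82, 0.91, "odds_ratio"))
}

test_that("the nulliparous proportion is a half-open step function", {
  par <- parity_params()
  expect_equal(prop_nulliparous(par, c(30, 34, 35, 37, 40, 44, 45, 90)),
               c(0.48, 0.48, 0.27, 0.27, 0.19, 0.19, 0.18, 0.18))
  # ages below the first step take the first step's value (age-25 scenario)
  expect_equal(prop_nulliparous(par, 25), 0.48)
})

test_that("parous incidence satisfies the mixture identity", {
  fx <- bc_fixture()
  # a unit parity effect leaves incidence unchanged
  par1 <- parity_params(parity_effect = effect_estimate(1, 1, 1,
                                                        "odds_ratio"))
  general <- fx$tables$incidence_general
  g50 <- general$rate[general$age == 50]
  expect_equal(parous_incidence(50, fx$tables, par1), g50)
  # mixture of parous and nulliparous strata reproduces the overall rate
  par <- parity_params()
  p_parous <- 1 - prop_nulliparous(par, 50)
  parous <- parous_incidence(50, fx$tables, par)
  nulli <- parous / par$parity_effect$point
  expect_equal(p_parous * parous + (1 - p_parous) * nulli, g50,
               tolerance = 1e-12)
})

test_that("breastfeeding stratification recovers the parous incidence", {
  fx <- bc_fixture()
  eff1 <- effect_estimate(1, 1, 1, "odds_ratio")
  s1 <- bf_stratified_incidence(55, fx$tables, fx$parity, 0.34, eff1)
  parous <- parous_incidence(55, fx$tables, fx$parity)
  expect_equal(unname(s1[["bf"]]), parous)
  expect_equal(unname(s1[["non_bf"]]), parous)
  s <- bf_stratified_incidence(55, fx$tables, fx$parity, 0.34, fx$bf_effect)
  expect_equal(0.34 * s[["bf"]] + 0.66 * s[["non_bf"]], parous,
               tolerance = 1e-12)
  expect_lt(s[["bf"]], s[["non_bf"]])
})

test_that("tunnel-state mortality combines background and excess hazards", {
  fx <- bc_fixture()
  flat <- fx$tables
  flat$net_survival$survival <- rep(1, 10)
  q_gen <- flat$mortality_general$q[flat$mortality_general$age == 60]
  expect_equal(bc_annual_mortality(60, 3, flat), q_gen)
  # hand-checkable case: net survival 0.95 in year 1, background 0.01
  one <- fx$tables
  one$mortality_general$q[] <- 0.01
  one$net_survival$survival <- 0.95^(1:10)
  expect_equal(bc_annual_mortality(40, 1, one), 1 - 0.99 * 0.95)
  # improving conditional survival makes q_bc nonincreasing in duration
  qk <- vapply(1:10, function(k) bc_annual_mortality(60, k, fx$tables),
               numeric(1))
  expect_true(all(diff(qk) <= 1e-12))
  expect_true(all(qk >= fx$tables$mortality_general$q[
    fx$tables$mortality_general$age == 60]))
  expect_error(bc_annual_mortality(60, 11, fx$tables), "1..10")
  expect_error(bc_annual_mortality(60, 0, fx$tables), "1..10")
})

test_that("zero incidence collapses the model to alive/dead", {
  fx <- bc_fixture()
  t0 <- fx$tables
  t0$incidence_general$rate[] <- 0
  res <- run_bc_markov(0.34, 30, t0, fx$parity, fx$bf_effect, fx$utilities)
  expect_equal(res$cases, 0)
  # the half-cycle-corrected total lies inside the start/end bracket, and
  # the start-of-cycle accrual equals the two-state lifetime model
  mg <- fx$tables$mortality_general
  lt <- rbind(data.frame(age = mg$age, sex = "female", q = mg$q),
              data.frame(age = mg$age, sex = "male", q = mg$q))
  two_state <- lifetime_discounted_qalys(30, 0, lt, fx$utilities, 0.035, 100)
  expect_equal(res$qalys_start, two_state, tolerance = 1e-10)
  expect_gte(res$qalys, min(res$qalys_start, res$qalys_end))
  expect_lte(res$qalys, max(res$qalys_start, res$qalys_end))
})

test_that("occupancy is conserved at every cycle", {
  fx <- bc_fixture()
  res <- run_bc_markov(0.34, 30, fx$tables, fx$parity, fx$bf_effect,
                       fx$utilities)
  expect_lt(max(abs(rowSums(res$trace) - 1)), 1e-10)
  expect_true(all(res$trace >= 0))
  expect_equal(nrow(res$trace), 71)  # 70 cycles plus the initial state
})

test_that("equal prevalences and unit effects give identical arms", {
  fx <- bc_fixture()
  cohort <- cohort_spec()
  eff1 <- effect_estimate(1, 1, 1, "odds_ratio")
  cmp1 <- bc_arm_comparison(0.34, 0.4046, cohort, fx$tables, fx$parity,
                            eff1, fx$utilities)
  expect_equal(cmp1[cmp1$arm == "diff", c("cases", "qalys", "cost")],
               data.frame(cases = 0, qalys = 0, cost = 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  cmp2 <- bc_arm_comparison(0.34, 0.34, cohort, fx$tables, fx$parity,
                            fx$bf_effect, fx$utilities)
  expect_equal(unlist(cmp2[cmp2$arm == "diff", -1]), c(0, 0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("more breastfeeding means fewer cases, more QALYs, lower cost", {
  fx <- bc_fixture()
  cmp <- bc_arm_comparison(0.34, 0.4046, cohort_spec(), fx$tables,
                           fx$parity, fx$bf_effect, fx$utilities)
  d <- cmp[cmp$arm == "diff", ]
  expect_lt(d$cases, 0)
  expect_gt(d$qalys, 0)
  expect_lt(d$cost, 0)
  # order of magnitude on the synthetic tables
  sc <- cmp[cmp$arm == "sc", ]
  expect_gt(sc$cases, 60); expect_lt(sc$cases, 180)
  expect_gt(sc$qalys / 1000, 18); expect_lt(sc$qalys / 1000, 23)
})

test_that("duration-dependent inputs are exercised by the tunnel states", {
  fx <- bc_fixture()
  res <- run_bc_markov(0.34, 30, fx$tables, fx$parity, fx$bf_effect,
                       fx$utilities)
  flat <- fx$tables
  flat$net_survival$survival <- rep(fx$tables$net_survival$survival[1], 10)
  flat$cost_bc$cost <- rep(fx$tables$cost_bc$cost[1], 10)
  res_flat <- run_bc_markov(0.34, 30, flat, fx$parity, fx$bf_effect,
                            fx$utilities)
  expect_false(isTRUE(all.equal(res$qalys, res_flat$qalys)))
  expect_false(isTRUE(all.equal(res$cost, res_flat$cost)))
  expect_gt(res_flat$cost, res$cost)   # year-1 costs applied to all years
})

test_that("background-mortality subtraction lowers deaths without cancer", {
  fx <- bc_fixture()
  res <- run_bc_markov(0.34, 30, fx$tables, fx$parity, fx$bf_effect,
                       fx$utilities)
  res_sub <- run_bc_markov(0.34, 30, fx$tables, fx$parity, fx$bf_effect,
                           fx$utilities, subtract_bc_mortality = TRUE)
  expect_gt(res_sub$qalys, res$qalys)
})
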