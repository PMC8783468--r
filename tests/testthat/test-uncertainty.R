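test_that("samplers match their analytic moments and quantiles", {
  set.seed(101)
  beta <- build_sampler(dist_spec("beta_counts", alpha = 418, beta = 582))
  draws <- beta(1e5)
  expect_lt(abs(mean(draws) - 418 / 1000), 0.005)
  ln <- build_sampler(dist_spec("lognormal_from_ci", point = 1.19,
                                ci_lower = 1.10, ci_upper = 1.30))
  qs <- quantile(ln(1e5), c(0.025, 0.975))
  # exp(log 1.19 -/+ 1.96 * sigma), sigma = log(1.30/1.10) / (2 * 1.96)
  expect_lt(abs(qs[[1]] - 1.19 * exp(-log(1.30 / 1.10) / 2)), 0.01)
  expect_lt(abs(qs[[2]] - 1.19 * exp(log(1.30 / 1.10) / 2)), 0.01)
  gam <- build_sampler(dist_spec("gamma_rel_se", mean = 756, rel_se = 0.1))
  g <- gam(1e5)
  expect_lt(abs(mean(g) - 756) / 756, 0.01)
  expect_lt(abs(sd(g) - 75.6) / 75.6, 0.05)
  nrm <- build_sampler(dist_spec("normal_rel_se", mean = 84, rel_se = 0.1))
  expect_true(all(nrm(1e4) >= 0))
  fx <- build_sampler(dist_spec("fixed", value = 0.42))
  expect_equal(fx(5), rep(0.42, 5))
})

test_that("invalid distribution parameters are rejected", {
  expect_error(dist_spec("beta_counts", alpha = -1, beta = 2), "> 0")
  expect_error(dist_spec("lognormal_from_ci", point = 1, ci_lower = 2,
                         ci_upper = 1), "ordered")
  expect_error(dist_spec("gamma_rel_se", mean = 10), "rel_se")
  expect_error(dist_spec("nope"), "arg")
})

degenerate_inputs <- function(seed = 2021) {
  p <- base_case_parameters()
  point_of <- function(d)
    switch(d$family,
           lognormal_from_ci = d$point,
           beta_counts = d$alpha / (d$alpha + d$beta),
           gamma_rel_se = , normal_rel_se = d$mean,
           fixed = d$value)
  p$distributions <- lapply(p$distributions, function(d)
    dist_spec("fixed", value = point_of(d)))
  # align the deterministic points with the degenerate draws
  p$intervention$effect <- effect_estimate(1.19, 1.10, 1.30)
  p$breastfeeding$p_bf_4m <- 0.418
  p$breastfeeding$p_bf_6m <- 0.342
  p$conditions$gi$baseline_gp_rate <- 0.047
  p$conditions$rti$baseline_gp_rate <- 0.234
  p$conditions$aom$baseline_gp_rate <- 0.136
  p$bc$utility_bc_y1_5 <- 67.46 / 100
  b <- default_bundle(seed)
  b$utility_table$se <- 0
  list(params = p, bundle = b)
}

test_that("a degenerate PSA reproduces the deterministic run exactly", {
  di <- degenerate_inputs()
  det <- suppressWarnings(run_model(di$params, di$bundle))
  psa <- run_psa(di$params, di$bundle, n_iterations = 5, seed = 9)
  expect_equal(psa$mean_cost[["sc"]], det$sc[["cost"]], tolerance = 1e-12)
  expect_equal(psa$mean_qalys[["int"]], det$int[["qalys"]],
               tolerance = 1e-12)
  expect_equal(psa$icer, det$comparison$icer, tolerance = 1e-12)
})

test_that("the PSA is bit-reproducible for a given seed", {
  p <- base_case_parameters()
  b <- default_bundle(2021)
  a <- run_psa(p, b, n_iterations = 30, seed = 5, keep_draws = TRUE)
  bb <- run_psa(p, b, n_iterations = 30, seed = 5, keep_draws = TRUE)
  expect_identical(a, bb)
  cc <- run_psa(p, b, n_iterations = 30, seed = 6)
  expect_false(identical(a$icer, cc$icer))
})

test_that("parameter draws respect structural constraints", {
  p <- base_case_parameters()
  b <- default_bundle(2021)
  set.seed(77)
  for (i in 1:25) {
    d <- draw_parameter_set(p, b)
    expect_lte(d$params$breastfeeding$p_bf_6m,
               d$params$breastfeeding$p_bf_4m)
    expect_gte(d$params$intervention$cost_per_woman, 0)
    expect_true(all(d$bundle$utility_table$utility >= 0 &
                      d$bundle$utility_table$utility <= 1))
    expect_equal(d$params$conditions$aom$effect_incidence$measure,
                 "odds_ratio")
    expect_true(all(d$bundle$bc$cost_bc$cost > 0))
  }
})

test_that("the two-way grid is monotone with a staircase dominance frontier", {
  p <- base_case_parameters()
  b <- default_bundle(2021)
  rr <- c(1.05, 1.19, 1.40, 1.70, 2.00)
  cost <- c(20, 40, 60, 84, 100)
  g <- two_way_grid(p, b, rr_values = rr, cost_values = cost)
  expect_equal(dim(g$labels), c(5, 5))
  # base-case cell equals the standalone comparison
  base <- suppressWarnings(run_model(p, b))$comparison
  expect_equal(g$icer["1.19", "84"], base$icer)
  dominant <- g$labels == "dominant"
  for (i in seq_along(rr)) {
    row <- g$icer[i, ]
    def <- !is.na(row)
    expect_true(all(diff(row[def]) >= -1e-9))        # ICER rises with cost
    # once dominant at a cost, dominant at every lower cost
    if (any(dominant[i, ]))
      expect_true(all(dominant[i, seq_len(max(which(dominant[i, ])))]))
  }
  for (j in seq_along(cost)) {
    col <- g$icer[, j]
    def <- !is.na(col)
    expect_true(all(diff(col[def]) <= 1e-9))         # ICER falls with effect
    if (any(dominant[, j]))
      expect_true(all(dominant[min(which(dominant[, j])):length(rr), j]))
  }
  expect_equal(g$labels["2", "20"], "dominant")
  expect_warning(two_way_grid(p, b, rr_values = c(1.19, 2.5),
                              cost_values = 84), "outside")
})

test_that("scenario analyses move the ICER in the expected directions", {
  p <- base_case_parameters()
  b <- default_bundle(2021)
  scen <- run_scenarios(p, b)
  expect_setequal(scen$scenario,
                  c("base_case", "postmortem_cost",
                    "effect_retained_future_births", "discount_1.5pc",
                    "start_age_25", "start_age_35"))
  icer <- function(s) scen$icer[scen$scenario == s]
  expect_lt(abs(icer("postmortem_cost") - icer("base_case")) /
              icer("base_case"), 0.005)
  expect_lt(icer("discount_1.5pc"), icer("base_case"))
  expect_lt(icer("start_age_35"), icer("start_age_25"))
  expect_lt(icer("effect_retained_future_births"), icer("base_case"))
})
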