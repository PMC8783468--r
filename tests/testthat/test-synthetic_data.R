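test_that("generation is bit-reproducible per seed and varies across seeds", {
  expect_identical(generate_life_table(7), generate_life_table(7))
  expect_false(identical(generate_life_table(7), generate_life_table(8)))
  b1 <- default_bundle(7); b2 <- default_bundle(7)
  expect_identical(b1, b2)
  expect_false(identical(b1$bc$incidence_general,
                         default_bundle(8)$bc$incidence_general))
})

test_that("life tables are monotone, sex-ordered and demographically sane", {
  lt <- generate_life_table(2021)
  for (s in c("male", "female")) {
    q <- lt$q[lt$sex == s][order(lt$age[lt$sex == s])]
    expect_true(all(diff(q[-1]) >= 0))        # monotone from age 1
    expect_gt(q[1], q[2])                     # elevated infant mortality
  }
  qf <- lt$q[lt$sex == "female"]; qm <- lt$q[lt$sex == "male"]
  expect_true(all(qm >= qf))
  le_f <- sum(cumprod(1 - qf))
  expect_gt(le_f, 78); expect_lt(le_f, 86)
  expect_lt(sum(cumprod(1 - qm)), le_f + 1e-9)
  expect_error(generate_life_table(1, gompertz_params =
    list(a_female = 2, a_male = 2, b = 1, infant_q = 0.004,
         jitter_sd = 0)), "outside")
})

test_that("the synthetic incidence curve has the registry shape", {
  bc <- generate_bc_tables(2021)
  inc <- bc$incidence_general
  expect_true(all(inc$rate[inc$age < 25] < 1e-4))
  peak_age <- inc$age[which.max(inc$rate)]
  expect_gte(peak_age, 60); expect_lte(peak_age, 75)
  expect_gt(max(inc$rate), 0.002); expect_lt(max(inc$rate), 0.004)
  # rises sharply after 40: rate at least triples between 40 and 55
  expect_gt(inc$rate[inc$age == 55], 3 * inc$rate[inc$age == 40])
  cum <- 1 - prod(1 - inc$rate)
  expect_gt(cum, 1 / 9); expect_lt(cum, 1 / 6)
})

test_that("net survival declines and cancer costs are front-loaded", {
  bc <- generate_bc_tables(2021)
  expect_true(all(diff(bc$net_survival$survival) < 0))
  expect_gt(bc$net_survival$survival[1], 0.90)
  expect_gt(bc$net_survival$survival[10], 0.70)
  expect_equal(which.max(bc$cost_bc$cost), 1)
  expect_true(all(diff(bc$cost_bc$cost) < 0))
  expect_true(all(diff(bc$cost_no_bc$cost) > 0))
  expect_equal(bc$utility_bc_y1_5, 0.67)
})

test_that("the utility table matches the published population norms", {
  ut <- default_utility_table()
  u <- function(age, sex) lookup_utility(ut, age, sex)
  expect_equal(u(10, "male"), 0.94)
  expect_equal(u(30, "female"), 0.93)
  expect_equal(u(50, "male"), 0.84)
  expect_equal(u(50, "female"), 0.85)
  expect_equal(u(60, "female"), 0.81)
  expect_equal(u(80, "female"), 0.71)
  expect_error(u(101, "female"), "outside")
})

test_that("bundles round-trip losslessly through CSV", {
  b <- default_bundle(5)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$life_table, b$life_table)
  expect_equal(b2$utility_table, b$utility_table)
  expect_equal(b2$bc$incidence_general, b$bc$incidence_general)
  expect_equal(b2$bc$net_survival, b$bc$net_survival)
  expect_equal(b2$bc$cost_bc$cost, b$bc$cost_bc$cost)
  expect_equal(b2$bc$cost_no_bc$cost, b$bc$cost_no_bc$cost)
  expect_equal(b2$bc$utility_bc_y1_5, b$bc$utility_bc_y1_5)
  expect_equal(b2$provenance$label, "synthetic")
  expect_equal(b2$provenance$seed, 5)
})

test_that("schema violations are reported with the missing column", {
  b <- default_bundle(5)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  lt <- utils::read.csv(file.path(dir, "life_table.csv"))
  utils::write.csv(lt[, c("age", "sex")], file.path(dir, "life_table.csv"),
                   row.names = FALSE)
  expect_error(read_bundle(dir), "missing column.*q")
  dir2 <- withr::local_tempdir()
  write_bundle(b, dir2)
  unlink(file.path(dir2, "bc_incidence.csv"))
  expect_error(read_bundle(dir2), "bundle file missing")
})

test_that("the packaged parameter set carries the published inputs", {
  p <- base_case_parameters()
  expect_equal(p$intervention$effect$point, 1.19)
  expect_equal(p$intervention$cost_per_woman, 84)
  expect_equal(p$breastfeeding$p_bf_4m, 0.42)
  expect_equal(p$breastfeeding$p_bf_6m, 0.34)
  expect_equal(gbp_display(p$costs$gp_unit_cost), 37)
  expect_equal(p$conditions$gi$baseline_gp_rate, 0.04682)
  expect_equal(p$conditions$rti$baseline_gp_rate, 0.23433)
  expect_equal(p$conditions$aom$baseline_gp_rate, 0.13556)
  expect_equal(p$conditions$aom$effect_incidence$measure, "odds_ratio")
  expect_equal(p$mortality$sids$effect$point, 0.38)
  expect_equal(p$mortality$sids$effect$ci_lower, 0.27)
  expect_equal(p$mortality$infectious$baseline_rate, 0.00012)
  expect_equal(p$bc$bf_effect$point, 0.86)
  expect_equal(p$bc$parity$parity_effect$point, 0.84)
  expect_equal(p$discount_rate, 0.035)
  expect_equal(p$thresholds, c(20000, 30000))
  expect_equal(p$distributions$p_bf_4m$alpha, 418)
  expect_equal(p$distributions$p_bf_4m$beta, 582)
})

test_that("parameter configs round-trip through YAML", {
  p <- base_case_parameters()
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(p, path)
  p2 <- read_config(path)
  expect_equal(p2$intervention$effect, p$intervention$effect)
  expect_equal(p2$conditions$gi, p$conditions$gi)
  expect_equal(p2$bc$parity$props, p$bc$parity$props)
  expect_equal(p2$thresholds, p$thresholds)
  expect_equal(p2$distributions$bc_cost_scale, p$distributions$bc_cost_scale)
  b <- default_bundle(3)
  r1 <- suppressWarnings(run_model(p, b))
  r2 <- suppressWarnings(run_model(p2, b))
  expect_equal(r2$comparison$icer, r1$comparison$icer)
})
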