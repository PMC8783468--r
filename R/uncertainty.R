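#' Distribution specification for probabilistic sensitivity analysis
#'
#' @param family One of `"lognormal_from_ci"` (location `ln(point)`, scale
#'   `(ln(ci_upper) - ln(ci_lower)) / (2 * 1.96)`), `"beta_counts"`
#'   (`Beta(alpha, beta)`), `"gamma_rel_se"` (shape `1 / rel_se^2`, scale
#'   `mean * rel_se^2`), `"normal_rel_se"` (`Normal(mean, rel_se * mean)`
#'   truncated at 0, for cost parameters) or `"fixed"`.
#' @param ... Family parameters: `point`, `ci_lower`, `ci_upper`; or
#'   `alpha`, `beta`; or `mean`, `rel_se`; or `value`.
#' @return An object of class `bfcea_dist`.
#' @examples
#' dist_spec("beta_counts", alpha = 418, beta = 582)
#' dist_spec("lognormal_from_ci", point = 1.19, ci_lower = 1.10,
#'           ci_upper = 1.30)
#' @export
dist_spec <- function(family = c("lognormal_from_ci", "beta_counts",
                                 "gamma_rel_se", "normal_rel_se", "fixed"),
                      ...) {
  family <- match.arg(family)
  args <- list(...)
  chk <- function(need) {
    missing <- setdiff(need, names(args))
    if (length(missing))
      stop(family, " needs parameter(s): ", paste(missing, collapse = ", "))
  }
  switch(family,
    lognormal_from_ci = {
      chk(c("point", "ci_lower", "ci_upper"))
      if (!(args$ci_lower > 0 && args$ci_lower <= args$ci_upper))
        stop("confidence limits must be positive and ordered")
    },
    beta_counts = {
      chk(c("alpha", "beta"))
      if (args$alpha <= 0 || args$beta <= 0) stop("alpha and beta must be > 0")
    },
    gamma_rel_se = , normal_rel_se = {
      chk(c("mean", "rel_se"))
      if (args$rel_se <= 0) stop("relative SE must be > 0")
    },
    fixed = chk("value"))
  structure(c(list(family = family), args), class = "bfcea_dist")
}

#' Build a sampling function from a distribution spec
#'
#' @param spec A [dist_spec()].
#' @return A function of `n` returning `n` draws from the current R random
#'   stream (seed the stream with `set.seed()` for reproducibility).
#' @examples
#' set.seed(1)
#' s <- build_sampler(dist_spec("beta_counts", alpha = 418, beta = 582))
#' mean(s(1000))
#' @export
build_sampler <- function(spec) {
  stopifnot(inherits(spec, "bfcea_dist"))
  switch(spec$family,
    lognormal_from_ci = {
      mu <- log(spec$point)
      sigma <- (log(spec$ci_upper) - log(spec$ci_lower)) / (2 * 1.96)
      function(n) stats::rlnorm(n, mu, sigma)
    },
    beta_counts = function(n) stats::rbeta(n, spec$alpha, spec$beta),
    gamma_rel_se = {
      shape <- 1 / spec$rel_se^2
      scale <- spec$mean * spec$rel_se^2
      function(n) stats::rgamma(n, shape = shape, scale = scale)
    },
    normal_rel_se = function(n)
      pmax(0, stats::rnorm(n, spec$mean, spec$rel_se * spec$mean)),
    fixed = function(n) rep(spec$value, n))
}

draw1 <- function(distributions, name) build_sampler(distributions[[name]])(1)

replace_point <- function(effect, new_point) {
  # a sampled effect keeps its measure; the CI of the draw is degenerate
  effect_estimate(new_point, min(effect$ci_lower, new_point),
                  max(effect$ci_upper, new_point), effect$measure)
}

#' Draw one probabilistic parameter vector
#'
#' Draws every parameter that has an assigned distribution and substitutes
#' it into copies of the parameter list and fixture bundle: effects
#' (log-normal from CIs), prevalences and baseline GP rates (beta),
#' breast-cancer utility (beta), unit costs (gamma or truncated normal),
#' general-population utilities (normal per age band, clamped to [0, 1]),
#' and a single gamma scale factor applied to both breast-cancer cost
#' schedules. Parameters without distributions (admission and mortality
#' baselines, cohort structure, discount rate) stay at their point values.
#'
#' @param params Parameter list as from [base_case_parameters()].
#' @param bundle A [fixture_bundle()].
#' @return List with drawn `params` and `bundle`.
#' @export
draw_parameter_set <- function(params, bundle) {
  d <- params$distributions
  p <- params
  p$intervention$effect <- replace_point(params$intervention$effect,
                                         draw1(d, "intervention_effect"))
  p$intervention$cost_per_woman <- draw1(d, "intervention_cost")
  p4 <- draw1(d, "p_bf_4m")
  p6 <- draw1(d, "p_bf_6m")
  # preserve the schedule invariant p_bf_6m <= p_bf_4m
  p$breastfeeding$p_bf_4m <- max(p4, p6)
  p$breastfeeding$p_bf_6m <- min(p4, p6)
  for (cn in names(p$conditions)) {
    p$conditions[[cn]]$baseline_gp_rate <- draw1(d, paste0(cn, "_gp_rate"))
    p$conditions[[cn]]$effect_incidence <-
      replace_point(params$conditions[[cn]]$effect_incidence,
                    draw1(d, paste0(cn, "_effect_incidence")))
    if (!is.null(p$conditions[[cn]]$effect_hosp))
      p$conditions[[cn]]$effect_hosp <-
        replace_point(params$conditions[[cn]]$effect_hosp,
                      draw1(d, paste0(cn, "_effect_hosp")))
  }
  p$mortality$infectious$effect <-
    replace_point(params$mortality$infectious$effect,
                  draw1(d, "mort_infectious_effect"))
  p$mortality$sids$effect <- replace_point(params$mortality$sids$effect,
                                           draw1(d, "mort_sids_effect"))
  p$bc$bf_effect <- replace_point(params$bc$bf_effect,
                                  draw1(d, "bc_bf_effect"))
  p$bc$parity$parity_effect <-
    replace_point(params$bc$parity$parity_effect, draw1(d, "parity_effect"))
  p$bc$utility_bc_y1_5 <- draw1(d, "utility_bc")
  p$costs$gp_unit_cost <- draw1(d, "gp_unit_cost")
  p$conditions$gi$hosp_unit_cost <- draw1(d, "cost_hosp_gi")
  p$conditions$rti$hosp_unit_cost <- draw1(d, "cost_hosp_rti")
  p$mortality$death_unit_cost <- draw1(d, "cost_death")

  b <- bundle
  ut <- b$utility_table
  ut$utility <- pmin(1, pmax(0, stats::rnorm(nrow(ut), ut$utility, ut$se)))
  b$utility_table <- ut
  scale <- draw1(d, "bc_cost_scale")
  b$bc$cost_no_bc$cost <- b$bc$cost_no_bc$cost * scale
  b$bc$cost_bc$cost <- b$bc$cost_bc$cost * scale
  list(params = p, bundle = b)
}

#' Probabilistic sensitivity analysis
#'
#' Runs the full deterministic pipeline once per iteration with one drawn
#' parameter vector applied to both arms (common random numbers across
#' arms). Mean per-arm costs and QALYs are averages over the iterations;
#' the probabilistic ICER is the ratio of mean incremental cost to mean
#' incremental QALYs. Identical seeds give bit-identical results.
#'
#' @param params Parameter list.
#' @param bundle A [fixture_bundle()].
#' @param n_iterations Number of iterations (default 10,000).
#' @param seed Integer seed.
#' @param keep_draws Retain the per-iteration arm totals?
#' @return An object of class `bfcea_psa`: `n_iterations`, `seed`, per-arm
#'   `mean_cost` and `mean_qalys`, `delta_cost`, `delta_qaly`, `icer`, and
#'   optionally `draws` (data frame of per-iteration totals).
#' @export
run_psa <- function(params, bundle, n_iterations = 10000, seed = 1,
                    keep_draws = FALSE) {
  stopifnot(n_iterations >= 1)
  set.seed(seed)
  cost_sc <- cost_int <- qaly_sc <- qaly_int <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    drawn <- tryCatch(draw_parameter_set(params, bundle),
                      error = function(e)
                        stop("sampler failure at iteration ", i, ": ",
                             conditionMessage(e)))
    # the rare-event odds-ratio warning is assessed once on the point
    # estimates, not re-raised for each of the 10,000 draws
    res <- suppressWarnings(run_model(drawn$params, drawn$bundle))
    cost_sc[i] <- res$sc[["cost"]]; qaly_sc[i] <- res$sc[["qalys"]]
    cost_int[i] <- res$int[["cost"]]; qaly_int[i] <- res$int[["qalys"]]
  }
  dc <- mean(cost_int) - mean(cost_sc)
  de <- mean(qaly_int) - mean(qaly_sc)
  structure(list(n_iterations = n_iterations, seed = seed,
                 mean_cost = c(sc = mean(cost_sc), int = mean(cost_int)),
                 mean_qalys = c(sc = mean(qaly_sc), int = mean(qaly_int)),
                 delta_cost = dc, delta_qaly = de,
                 icer = if (de != 0) dc / de else NA_real_,
                 draws = if (keep_draws)
                   data.frame(cost_sc, cost_int, qaly_sc, qaly_int)),
            class = "bfcea_psa")
}

#' @export
print.bfcea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d)\n", x$n_iterations, x$seed))
  cat(sprintf("Mean incremental cost %.0f GBP, QALYs %.4f, ICER %s GBP/QALY\n",
              x$delta_cost, x$delta_qaly,
              format(round(x$icer), big.mark = ",")))
  invisible(x)
}

#' Two-way deterministic sensitivity grid
#'
#' Re-runs the deterministic model at every combination of intervention
#' effect (RR) and intervention cost, holding all other parameters at their
#' point values, and labels each cell with the ICER (whole GBP) or
#' `"dominant"`.
#'
#' @param params Parameter list.
#' @param bundle A [fixture_bundle()].
#' @param rr_values Intervention effects to test; default 1.05 to 2.00 by
#'   0.05 plus the base-case 1.19.
#' @param cost_values Intervention costs to test; default 20 to 100 GBP by
#'   5 plus the base-case 84.
#' @return List with `labels` (character matrix, effects in rows), `icer`
#'   (numeric matrix, `NA` where dominant) and the value vectors. Values
#'   outside the tested publication ranges trigger a warning but run.
#' @export
two_way_grid <- function(params, bundle,
                         rr_values = sort(unique(c(seq(1.05, 2.00, by = 0.05),
                                                   1.19))),
                         cost_values = sort(unique(c(seq(20, 100, by = 5),
                                                     84)))) {
  if (any(rr_values < 1.05 | rr_values > 2.00))
    warning("intervention effects outside the tested range 1.05-2.00")
  if (any(cost_values < 20 | cost_values > 100))
    warning("intervention costs outside the tested range 20-100 GBP")
  labels <- matrix("", length(rr_values), length(cost_values),
                   dimnames = list(effect = as.character(rr_values),
                                   cost = as.character(cost_values)))
  icers <- matrix(NA_real_, length(rr_values), length(cost_values),
                  dimnames = dimnames(labels))
  for (i in seq_along(rr_values)) {
    p <- params
    p$intervention$effect <- replace_point(params$intervention$effect,
                                           rr_values[i])
    for (j in seq_along(cost_values)) {
      p$intervention$cost_per_woman <- cost_values[j]
      # the rare-event OR warning concerns the inputs, not the grid; it is
      # not re-raised for each of the cells
      cmp <- suppressWarnings(run_model(p, bundle))$comparison
      labels[i, j] <- comparison_label(cmp)
      icers[i, j] <- cmp$icer
    }
  }
  list(labels = labels, icer = icers,
       rr_values = rr_values, cost_values = cost_values)
}

#' One-way scenario analyses
#'
#' Re-runs the model under the four alternative scenarios: (a) a post-mortem
#' examination cost of 8000 GBP attached to each infant death; (b) the
#' intervention effect retained over all future births, scaling infant
#' benefits to the total fertility rate of 1.70 babies per woman (the
#' 6-month breast-cancer effect is unchanged, as the protective effect is
#' the same for 6- and 12-month breastfeeding durations); (c) a 1.5\% annual
#' discount rate for costs and outcomes; (d) mothers' starting age 25 and
#' 35 years.
#'
#' @param params Parameter list.
#' @param bundle A [fixture_bundle()].
#' @return Data frame with `scenario`, `icer` and `label` (ICER string or
#'   dominance), base case first.
#' @export
run_scenarios <- function(params, bundle) {
  run <- function(...) suppressWarnings(run_model(params, bundle, ...))
  runs <- list(
    base_case = run(),
    postmortem_cost = run(include_postmortem = TRUE),
    effect_retained_future_births =
      run(babies_per_woman = params$cohort$births_per_woman_scenario),
    discount_1.5pc = run(discount_rate = params$discount_rate_scenario),
    start_age_25 = run(start_age_mother = 25),
    start_age_35 = run(start_age_mother = 35))
  data.frame(scenario = names(runs),
             icer = vapply(runs, function(r) r$comparison$icer, numeric(1)),
             label = vapply(runs, function(r) comparison_label(r$comparison),
                            character(1)),
             row.names = NULL)
}
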