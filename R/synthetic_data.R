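# Synthetic stand-ins for the age-indexed national-statistics tables the
# model consumes (general-population life tables, breast-cancer incidence,
# net survival, breast-cancer healthcare costs). They reproduce the
# qualitative structure the analysis relies on -- incidence rising sharply
# after age 40, net survival declining with years since diagnosis, mortality
# increasing with age, front-loaded cancer costs -- but are NOT official
# estimates; every bundle carries a "synthetic" provenance label.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic period life table
#'
#' Annual death probabilities follow a Gompertz hazard
#' `q(age) = 1 - exp(-a * exp(b * age))` with a sex-specific level `a`
#' (male above female), plus an elevated infant value at age 0. A single
#' seeded multiplicative jitter on each sex's level makes distinct seeds
#' give distinct but structurally identical tables.
#'
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param max_age Oldest age included (default 100).
#' @param gompertz_params List with `a_female`, `a_male` (baseline hazard
#'   levels), `b` (log-hazard slope per year), `infant_q` (age-0 death
#'   probability) and `jitter_sd` (sd of the seeded log-level jitter).
#' @return Life table data frame `(age, sex, q)`, ages 0..`max_age`.
#' @export
generate_life_table <- function(seed = 2021, max_age = 100,
                                gompertz_params = list(a_female = 2.6e-5,
                                                       a_male = 4.2e-5,
                                                       b = 0.094,
                                                       infant_q = 0.004,
                                                       jitter_sd = 0.02)) {
  gp <- gompertz_params
  stopifnot(gp$a_female > 0, gp$a_male > 0, gp$b > 0,
            gp$infant_q > 0, gp$infant_q < 1)
  with_seed(seed, {
    jit <- exp(stats::rnorm(2, 0, gp$jitter_sd))
    ages <- 0:max_age
    mk <- function(a, sex, jitter) {
      q <- 1 - exp(-a * jitter * exp(gp$b * ages))
      q[1] <- max(gp$infant_q, q[1])
      if (any(q <= 0) || any(q >= 1 - 1e-12))
        stop("Gompertz parameters yield death probabilities outside (0, 1)")
      data.frame(age = ages, sex = sex, q = q)
    }
    tab <- rbind(mk(gp$a_female, "female", jit[1]),
                 mk(gp$a_male, "male", jit[2]))
    # enforce q(male) >= q(female) at every age
    qf <- tab$q[tab$sex == "female"]
    tab$q[tab$sex == "male"] <- pmax(tab$q[tab$sex == "male"], qf)
    validate_life_table(tab)
    tab
  })
}

#' General-population utility table (EQ-5D norms)
#'
#' Age- and sex-specific population utility means and standard errors over
#' half-open age bands, as used for people without the modelled conditions.
#'
#' @return Data frame `(age_lo, age_hi, sex, utility, se)`.
#' @export
default_utility_table <- function() {
  lo <- c(0, 25, 35, 45, 55, 65, 75)
  hi <- c(25, 35, 45, 55, 65, 75, 101)
  male <- c(0.94, 0.93, 0.91, 0.84, 0.78, 0.78, 0.75)
  male_se <- c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02, 0.03)
  female <- c(0.94, 0.93, 0.91, 0.85, 0.81, 0.78, 0.71)
  female_se <- c(0.01, 0.01, 0.01, 0.01, 0.02, 0.02, 0.02)
  rbind(data.frame(age_lo = lo, age_hi = hi, sex = "male",
                   utility = male, se = male_se),
        data.frame(age_lo = lo, age_hi = hi, sex = "female",
                   utility = female, se = female_se))
}

#' Generate synthetic breast-cancer model tables
#'
#' Builds a [bc_tables()] bundle with the qualitative structure of the
#' national data the women's model needs:
#' \itemize{
#'   \item incidence near zero before age 25, rising sharply after 40 to a
#'     peak between 60 and 75, then declining only gently (incidence stays
#'     high into old age, as in registry data);
#'   \item strictly decreasing cumulative net survival over years 1--10
#'     after diagnosis, built from a geometrically declining excess hazard
#'     (so conditional net survival improves with time since diagnosis);
#'   \item front-loaded annual breast-cancer costs (year 1 maximal);
#'   \item small, gently increasing annual costs for women without breast
#'     cancer.
#' }
#' All-cause female mortality is taken from the supplied life table.
#'
#' @param seed Integer seed (deterministic generation).
#' @param life_table Life table supplying female all-cause mortality;
#'   defaults to [generate_life_table()] with the same seed.
#' @param params Shape parameters: `inc_midpoint_age` and `inc_rise_width`
#'   (logistic rise of the age-incidence curve), `inc_peak_rate` (annual
#'   incidence at the peak age), `inc_late_decline` (fractional decline from
#'   the peak by the oldest age), `excess_h1` (first-year excess hazard),
#'   `excess_decay` (annual decay of the excess hazard), `cost_bc_year1`,
#'   `cost_bc_floor`, `cost_bc_decay`, `cost_no_bc_30`, `cost_no_bc_growth`,
#'   `jitter_sd`.
#' @param max_age Oldest age included.
#' @return A [bc_tables()] object.
#' @export
generate_bc_tables <- function(seed = 2021, life_table = NULL,
                               params = list(inc_midpoint_age = 48,
                                             inc_rise_width = 7,
                                             inc_peak_rate = 0.0033,
                                             inc_late_decline = 0.15,
                                             excess_h1 = 0.05,
                                             excess_decay = 0.85,
                                             cost_bc_year1 = 12000,
                                             cost_bc_floor = 1800,
                                             cost_bc_decay = 0.62,
                                             cost_no_bc_30 = 260,
                                             cost_no_bc_growth = 0.013,
                                             jitter_sd = 0.03),
                               max_age = 100) {
  p <- params
  if (is.null(life_table)) life_table <- generate_life_table(seed, max_age)
  with_seed(seed + 1L, {
    jit <- exp(stats::rnorm(3, 0, p$jitter_sd))
    ages <- 0:max_age
    # logistic rise with a gentle late decline: near zero before 25, sharp
    # increase after 40, peak in the 60s-70s, still high in old age; the
    # age-25 logistic level is subtracted so the young tail vanishes
    rise <- stats::plogis(ages, location = p$inc_midpoint_age,
                          scale = p$inc_rise_width)
    rise <- pmax(rise - stats::plogis(25, location = p$inc_midpoint_age,
                                      scale = p$inc_rise_width), 0)
    late <- 1 - p$inc_late_decline *
      pmax(0, ages - (p$inc_midpoint_age + 18)) /
        (max_age - p$inc_midpoint_age - 18)
    shape_curve <- rise * late
    inc <- p$inc_peak_rate * jit[1] * shape_curve / max(shape_curve)
    inc[ages < 20] <- 0
    incidence <- data.frame(age = ages, rate = inc)

    h1 <- p$excess_h1 * jit[2]
    excess <- h1 * p$excess_decay^(0:9)
    net_surv <- data.frame(year = 1:10, survival = exp(-cumsum(excess)))
    if (any(diff(net_surv$survival) >= 0))
      stop("generated net survival is not strictly decreasing")

    cost_bc <- data.frame(
      year = 1:10,
      cost = jit[3] * (p$cost_bc_floor +
                         (p$cost_bc_year1 - p$cost_bc_floor) *
                           p$cost_bc_decay^(0:9)))
    cost_no <- data.frame(
      age = ages,
      cost = p$cost_no_bc_30 * exp(p$cost_no_bc_growth * (ages - 30)))

    mort_fem <- life_table[life_table$sex == "female", c("age", "q")]
    # crude case-fatality proxy for the optional background subtraction
    mort_bc <- data.frame(age = ages, rate = 0.30 * inc)

    bc_tables(incidence_general = incidence,
              mortality_general = mort_fem,
              mortality_bc_general = mort_bc,
              net_survival = net_surv,
              cost_no_bc = cost_no, cost_bc = cost_bc)
  })
}

#' Assemble a fixture bundle
#'
#' @param life_table,utility_table,bc Component tables.
#' @param provenance List of provenance metadata; must contain `label`.
#' @return An object of class `bfcea_bundle`.
#' @export
fixture_bundle <- function(life_table, utility_table, bc, provenance) {
  stopifnot(is.list(provenance), !is.null(provenance$label),
            inherits(bc, "bfcea_bc_tables"))
  validate_life_table(life_table)
  structure(list(life_table = life_table, utility_table = utility_table,
                 bc = bc, provenance = provenance),
            class = "bfcea_bundle")
}

#' Default synthetic bundle
#'
#' @param seed Integer seed.
#' @param max_age Oldest age included.
#' @return A [fixture_bundle()] with synthetic provenance.
#' @export
default_bundle <- function(seed = 2021, max_age = 100) {
  lt <- generate_life_table(seed, max_age)
  fixture_bundle(
    life_table = lt,
    utility_table = default_utility_table(),
    bc = generate_bc_tables(seed, lt, max_age = max_age),
    provenance = list(label = "synthetic",
                      note = paste("synthetic stand-in tables; not official",
                                   "population statistics"),
                      seed = seed, max_age = max_age))
}

bundle_schemas <- list(
  life_table = c("age", "sex", "q"),
  utility_table = c("age_lo", "age_hi", "sex", "utility", "se"),
  bc_incidence = c("age", "rate"),
  bc_mortality_general = c("age", "rate"),
  bc_net_survival = c("year", "survival"),
  bc_costs = c("key", "value"))

#' Write or read a fixture bundle as plain CSV files
#'
#' The bundle is serialised as `life_table.csv`, `utility_table.csv`,
#' `bc_incidence.csv`, `bc_mortality_general.csv`, `bc_net_survival.csv`,
#' `bc_costs.csv` (long key/value form holding both cost schedules, the
#' breast-cancer utility and the tunnel duration) and `provenance.yml`.
#' The round trip is lossless.
#'
#' @param bundle A [fixture_bundle()].
#' @param dir Directory to write to (created if absent).
#' @return `write_bundle()`: `dir`, invisibly. `read_bundle()`: the bundle.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bfcea_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(bundle$life_table, "life_table")
  wr(bundle$utility_table, "utility_table")
  wr(bundle$bc$incidence_general, "bc_incidence")
  wr(bundle$bc$mortality_bc_general, "bc_mortality_general")
  wr(bundle$bc$net_survival, "bc_net_survival")
  costs <- rbind(
    data.frame(key = sprintf("cost_no_bc_age_%d", bundle$bc$cost_no_bc$age),
               value = bundle$bc$cost_no_bc$cost),
    data.frame(key = sprintf("cost_bc_year_%d", bundle$bc$cost_bc$year),
               value = bundle$bc$cost_bc$cost),
    data.frame(key = c("utility_bc_y1_5", "bc_duration_years"),
               value = c(bundle$bc$utility_bc_y1_5,
                         bundle$bc$bc_duration_years)))
  wr(costs, "bc_costs")
  yaml::write_yaml(bundle$provenance, file.path(dir, "provenance.yml"))
  invisible(dir)
}

read_bundle_csv <- function(dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) stop("bundle file missing: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(bundle_schemas[[name]], names(df))
  if (length(missing))
    stop(sprintf("bundle file %s.csv missing column(s): %s",
                 name, paste(missing, collapse = ", ")))
  df
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  lt <- read_bundle_csv(dir, "life_table")
  ut <- read_bundle_csv(dir, "utility_table")
  inc <- read_bundle_csv(dir, "bc_incidence")
  mbc <- read_bundle_csv(dir, "bc_mortality_general")
  ns <- read_bundle_csv(dir, "bc_net_survival")
  costs <- read_bundle_csv(dir, "bc_costs")
  pick <- function(pattern, key_name) {
    sub <- costs[grepl(pattern, costs$key), ]
    key <- as.integer(sub("^.*_", "", sub$key))
    out <- data.frame(key = key, value = sub$value)
    out <- out[order(out$key), ]
    names(out) <- c(key_name, "cost")
    rownames(out) <- NULL
    out
  }
  scalar <- function(key) {
    v <- costs$value[costs$key == key]
    if (length(v) != 1) stop("bc_costs.csv missing scalar key: ", key)
    v
  }
  prov_path <- file.path(dir, "provenance.yml")
  if (!file.exists(prov_path)) stop("bundle file missing: ", prov_path)
  bc <- bc_tables(incidence_general = inc,
                  mortality_general = lt[lt$sex == "female", c("age", "q")],
                  mortality_bc_general = mbc,
                  net_survival = ns,
                  cost_no_bc = pick("^cost_no_bc_age_", "age"),
                  cost_bc = pick("^cost_bc_year_", "year"),
                  utility_bc_y1_5 = scalar("utility_bc_y1_5"),
                  bc_duration_years = as.integer(scalar("bc_duration_years")))
  fixture_bundle(lt, ut, bc, yaml::read_yaml(prov_path))
}
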