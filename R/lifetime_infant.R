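#' Validate a life table
#'
#' A life table is a data frame with columns `age` (integer years), `sex`
#' (`"male"`/`"female"`) and `q` (annual probability of death in (0, 1)),
#' with contiguous ages for both sexes.
#'
#' @param life_table Data frame to validate.
#' @return The life table, invisibly, if valid; otherwise an error.
#' @export
validate_life_table <- function(life_table) {
  stopifnot(is.data.frame(life_table),
            all(c("age", "sex", "q") %in% names(life_table)))
  if (!all(life_table$q > 0 & life_table$q < 1))
    stop("life-table q values must lie in (0, 1)")
  for (s in c("male", "female")) {
    ages <- sort(life_table$age[life_table$sex == s])
    if (length(ages) == 0) stop("life table missing sex: ", s)
    if (!identical(ages, seq(min(ages), max(ages))))
      stop("life-table ages must be contiguous for sex: ", s)
  }
  invisible(life_table)
}

# annual death probabilities for one sex over [start_age, max_age - 1]
life_table_q <- function(life_table, sex, start_age, max_age) {
  sub <- life_table[life_table$sex == sex, ]
  ages <- start_age:(max_age - 1)
  idx <- match(ages, sub$age)
  if (anyNA(idx))
    stop("life table missing ages ", paste(ages[is.na(idx)], collapse = ", "),
         " for sex ", sex)
  sub$q[idx]
}

#' Age- and sex-specific utility lookup
#'
#' Utility tables hold EQ-5D population norms over half-open age bands
#' `[age_lo, age_hi)` per sex, with standard errors for the probabilistic
#' analysis.
#'
#' @param utilities Data frame with columns `age_lo`, `age_hi`, `sex`,
#'   `utility`, `se`.
#' @param age Vector of ages (years).
#' @param sex `"male"` or `"female"`.
#' @return Vector of utilities, one per age.
#' @export
lookup_utility <- function(utilities, age, sex) {
  stopifnot(all(c("age_lo", "age_hi", "sex", "utility") %in% names(utilities)))
  sub <- utilities[utilities$sex == sex, ]
  sub <- sub[order(sub$age_lo), ]
  idx <- findInterval(age, sub$age_lo)
  if (any(idx == 0) || any(age >= sub$age_hi[idx]))
    stop("age outside the bands of the utility table")
  sub$utility[idx]
}

#' Discounted lifetime QALYs from a two-state (alive/dead) Markov model
#'
#' Annual-cycle cohort model: a person enters alive at `start_age`; each
#' cycle they die with the life-table probability for their current age and
#' sex. QALYs accrue at the start-of-cycle survival probability weighted by
#' the age-band utility, discounted at `(1 + r)^-t` with `t = 0` at entry.
#' Results for the two sexes are mixed with weight `sex_mix`.
#'
#' @param start_age Integer age at entry (years).
#' @param sex_mix Proportion male.
#' @param life_table A life table (see [validate_life_table()]).
#' @param utilities A utility table (see [lookup_utility()]).
#' @param discount_rate Annual discount rate in [0, 1).
#' @param max_age Age at which accrual stops (default 100).
#' @return Discounted QALYs per person.
#' @export
lifetime_discounted_qalys <- function(start_age, sex_mix, life_table,
                                      utilities, discount_rate = 0.035,
                                      max_age = 100) {
  stopifnot(discount_rate >= 0, discount_rate < 1, start_age < max_age,
            sex_mix >= 0, sex_mix <= 1)
  per_sex <- vapply(c("male", "female"), function(s) {
    q <- life_table_q(life_table, s, start_age, max_age)
    n <- length(q)
    surv <- cumprod(c(1, 1 - q))[seq_len(n)]   # survival to start of cycle t
    ages <- start_age + seq_len(n) - 1
    u <- lookup_utility(utilities, ages, s)
    v <- (1 + discount_rate)^-(seq_len(n) - 1)
    sum(surv * u * v)
  }, numeric(1))
  sex_mix * per_sex[["male"]] + (1 - sex_mix) * per_sex[["female"]]
}

#' QALYs gained from prevented infant deaths
#'
#' @param deaths_prevented Expected number of deaths averted in year 1.
#' @param qalys_per_person Discounted lifetime QALYs per saved infant.
#' @return QALYs gained for the cohort (simple product).
#' @export
qalys_from_prevented_deaths <- function(deaths_prevented, qalys_per_person) {
  stopifnot(deaths_prevented >= 0, qalys_per_person >= 0)
  deaths_prevented * qalys_per_person
}
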