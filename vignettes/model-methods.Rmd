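---
title: "Methods: a decision-analytic model of breastfeeding support"
author: "bfcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-analytic model of breastfeeding support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfcea)
```

## The question and the model

`bfcea` implements a cohort cost-effectiveness model for a breastfeeding
education and support intervention offered to women around birth, compared
with standard care alone, from a health-service and personal-social-services
perspective (costs in 2018 GBP, outcomes in QALYs). The intervention's only
direct effect is a multiplicative uplift (risk ratio, default 1.19) of the
prevalence of *any* breastfeeding at 16–26 weeks after birth; everything
downstream flows from the changed mix of breastfed and non-breastfed babies
and of breastfeeding and non-breastfeeding mothers.

The model has four linked components:

1. **Acute infant infections** (gastrointestinal infection, lower
   respiratory tract infection, acute otitis media): one-year decision
   trees. Each case corresponds to one GP consultation; GI and RTI also
   have independent hospital-admission streams.
2. **Infant mortality** (infectious disease, SIDS): the same decision-tree
   construction on first-year death rates.
3. **Infants saved from death** enter a two-state (alive/dead) annual-cycle
   Markov model accruing age- and sex-specific utility over a lifetime.
4. **Mothers' breast cancer**: a three-state annual-cycle Markov model
   ('no breast cancer', 'breast cancer' as ten tunnel states, 'death') from
   age 30 over a lifetime, with half-cycle correction.

## The incidence partition

Observed population rates reflect the current breastfeeding mix. Given an
overall incidence $I$, exposure prevalence $p$ and relative effect $RR$,
the stratum incidences are

$$I_{nonBF} = \frac{I}{p \cdot RR + 1 - p}, \qquad I_{BF} = RR \cdot I_{nonBF},$$

which conserve the mixture exactly: $p I_{BF} + (1-p) I_{nonBF} = I$.
`partition_incidence()` enforces this identity to $10^{-12}$ relative
error. Stratum incidences are anchored at the *standard-care* prevalence in
both arms; only the mixing weights differ between arms. Where the
literature reports an odds ratio, it is substituted for the risk ratio;
this rare-event approximation is accurate below roughly 10% baseline
incidence, and a warning (not an error) is raised above that (the AOM
baseline of 13.6% triggers it once per deterministic run; the grid, PSA and
scenario loops do not repeat it).

Infant outcomes use the 4-month prevalence (benefits anchor at 4 months);
breast cancer uses the 6-month prevalence (protective effect established
from 6 months of breastfeeding). The intervention uplift is applied
multiplicatively to both, capped at 1 so that grid effects up to RR 2.0
remain probabilities.

## Breastfeeding prevalence back-calculation

Recent statistics report any-breastfeeding prevalence only at 6–8 weeks
(53% in 2019); 4- and 6-month figures exist for 2010 (57% at 6 weeks, 44%
at 16 weeks, 36% at 26 weeks). Assuming exponential decline with
segment-specific instantaneous weekly rates estimated from 2010,
`estimate_bf_prevalence()` carries the 2019 figure forward from its anchor
week. The anchor defaults to week 7, the midpoint of the 6–8-week
reporting window; it is the only whole-week anchor that reproduces the
published 42%/34% display values, and it is exposed as `ref_week` rather
than hard-coded. Internal arithmetic is unrounded; `percent_display()`,
`per1000_display()` and `gbp_display()` produce the whole-percent, 2-dp and
whole-GBP values used in report tables.

## The infant models

Expected counts are cohort expectations, not simulations: for each
condition and arm, `n_babies × mixture(stratum incidences, arm prevalence)`
with `n_babies = n_women × 1.016` liveborn babies per delivery. GP and
admission streams are *independent* expected-count processes, not nested
conditional probabilities — this mirrors the source model's structure and
is what reproduces its published per-1000 cells. The one-year horizon means
infection costs are undiscounted year-0 costs. Nonfatal infections carry no
QALY loss (consistent with the source analysis), so infants contribute
QALYs only through averted deaths.

Infants saved from a first-year death accrue discounted lifetime QALYs from
age 0, with year 0 undiscounted; the averted death is treated as occurring
at the start of year 1. The anchor age is a documented choice (the source
does not state it) and is configurable through `lifetime_discounted_qalys()`.
This sub-model uses start-of-cycle (survival-weighted) accrual without
half-cycle correction, since the source applies half-cycle correction only
to the breast-cancer model. The GP unit cost defaults to £37.40 — the
unrounded per-consultation national unit cost, which whole-pound display
rounds to £37 and which reconstructs the published condition cost cells
within 0.2%.

The GI admission baseline is 15.3 per 1000 live births and RTI 115.4 per
1000, the values stated in the text of the source (its summary input table
rounds the former to 0.015).

## The breast-cancer model

Women enter cancer-free at age 30 (25/35 in scenarios). Each arm is
modelled as two lifelong homogeneous sub-cohorts — women who breastfeed for
six months and women who do not — mixed at the arm's prevalence. Treating
breastfeeding status as a lifelong attribute matches the
partition-then-mix construction: the protective effect (OR 0.86) is a
property of the exposure, not of a model year.

Age-specific incidence in these strata comes from a two-level partition of
general-population incidence: first by parity (nulliparous proportion 48% /
27% / 19% / 18% at ages 30 / 35 / 40 / 45+, half-open bands; parity OR
0.84), then by breastfeeding status among parous women. Ages below 30 (the
age-25 scenario) use the first band's value.

Transitions each cycle, at current age $a$ and background mortality
$q(a)$:

* no BC → death with $q(a)$; no BC → first tunnel year with
  $i(a)\,(1 - q(a))$ (incident cases arise among the year's survivors —
  the ordering is a documented tie-break, matched exactly by the
  microsimulation oracle);
* tunnel year $k$ → death with $q_{bc}(a, k)$, otherwise to year $k+1$;
* tunnel year 10 survivors return to 'no breast cancer' and are again at
  risk, so second primaries count as new cases.

Duration-dependent mortality is derived from cumulative net survival
$S_{net}(k)$ by conditional-survival multiplication:

$$q_{bc}(a, k) = 1 - (1 - q(a)) \cdot \frac{S_{net}(k)}{S_{net}(k-1)},$$

floored at $q(a)$ and capped at 1. The national source's exact
excess-mortality assumptions are in unpublished supplementary detail, so
this derivation is this package's own specification; it is isolated in
`bc_annual_mortality()` so it can be swapped. The 'no breast cancer' state
uses all-cause female mortality; the small double count of breast-cancer
deaths can be removed with `subtract_bc_mortality = TRUE` (off by default —
the correction is second-order).

Utilities: general population norms by age band outside cancer; 0.67 in
tunnel years 1–5; the mean of 0.67 and the age-specific norm in years
6–10. Costs: an age-indexed schedule outside cancer and a front-loaded
year-since-diagnosis schedule inside it. QALYs and costs use trapezoidal
half-cycle correction (mean of start- and end-of-cycle occupancy) and
discounting at $(1+r)^{-t}$ with $t = 0$ in the entry year. Occupancy must
sum to 1 within $10^{-10}$ at every cycle or the run aborts.

## Economics

Arm totals sum the intervention outlay (£84/woman × 1000 women in the
intervention arm), infection and death costs, infant QALYs gained and the
breast-cancer totals. The ICER is $\Delta C / \Delta E$ on unrounded
increments; cells are classified against the £20,000/£30,000 per QALY
thresholds, with explicit `dominant` (cheaper, more effective) and
`dominated` flags and no division when $\Delta E = 0$. The south-west
quadrant (cheaper, less effective) is handled explicitly although the base
case cannot reach it.

## Uncertainty analyses

The PSA draws one parameter vector per iteration, applies it to both arms
and re-runs the whole pipeline; means are taken over 10,000 iterations and
the probabilistic ICER is the ratio of mean increments. Distribution
families follow the published input table: log-normal effects with
location $\ln(\text{point})$ and scale
$(\ln CI_u - \ln CI_l)/(2 \times 1.96)$ (published CIs are mildly
asymmetric, so they cannot be reproduced exactly — the symmetric-on-log
choice is the standard one and is documented rather than hidden); beta
prevalences and rates from printed counts (whose means, e.g. 418/1000 =
0.418, sit a fraction off the deterministic points — the printed counts are
used verbatim); gamma unit costs with SE 10% of the mean
(shape $1/0.1^2$); the intervention cost as a normal truncated at zero;
general-population utilities as normals with the published band SEs,
clamped to $[0,1]$; and a single gamma multiplier (mean 1, SE 0.1) scaling
both breast-cancer cost schedules. A drawn 6-month prevalence above the
drawn 4-month prevalence is reordered to preserve the schedule invariant.
Baselines published without distributions (admissions, infant mortality,
cohort structure, discount rate) stay fixed.

The two-way grid re-runs the deterministic model over effects 1.05–2.00
(step 0.05, plus 1.19) and costs £20–£100 (step £5, plus £84). Scenario
analyses: post-mortem cost of £8000 per infant death; intervention effect
retained over all births (infant streams scaled to 1.70 babies per woman;
the breast-cancer effect unchanged, as the protective effect is the same
for 6- and 12-month durations); 1.5% discounting; starting ages 25 and 35.

## Synthetic tables

The model needs age-indexed inputs that the source takes from national
statistics and does not print: life tables, breast-cancer incidence, net
survival after diagnosis, and healthcare costs with and without breast
cancer. `generate_life_table()` and `generate_bc_tables()` produce
synthetic stand-ins with the qualitative structure the analysis relies on —
Gompertz mortality (female life expectancy ~78–86 years, male above female
at every age, an elevated infant value), incidence near zero before 25
rising sharply after 40 to a peak of 0.002–0.004/woman-year between ages 60
and 75 with only a gentle late decline (lifetime cumulative risk between
1-in-9 and 1-in-6), strictly decreasing net survival from ~0.95 (year 1)
built from a geometrically fading excess hazard, and front-loaded cancer
costs. Generation is bit-reproducible per seed, and every bundle carries a
`synthetic` provenance label: these are **not** official estimates and the
package's breast-cancer magnitudes (per-1000 cases, QALYs, costs, and hence
the ICER) are fixture-dependent. Passing tests therefore demonstrate
internal correctness — conservation, monotonicity, oracle agreement,
reproduction of the desk-scale published cells — not agreement with the
published lifetime ICER, which would require the real national tables.
Realized lifetime cases per 1000 women land somewhat below the published
count at these defaults; pushing them higher would push the generated
lifetime risk above the 1-in-6 bound, and the lifetime-risk constraint was
kept binding.

## Verification choices and problem sizes

Cohort expectations are cross-checked against independent per-person
microsimulations that share only the transition probabilities: $10^6$
babies for the decision trees, $10^5$ lifetimes for the two-state model and
$10^5$ women for the tunnel-state model, each required to agree within
three Monte-Carlo standard errors. The PSA-versus-deterministic agreement
check runs the full 10,000 iterations. These sizes keep the complete suite
at a few minutes on one CPU while leaving the Monte-Carlo bands tight
enough to catch indexing errors (a one-year shift in tunnel utilities or
costs fails the oracle and the flattened-tunnel regression test).

## Known limitations

Exclusive (as opposed to any) breastfeeding, infections beyond the first
year, morbidity QALY losses from nonfatal infections,
antimicrobial-resistance effects, ovarian cancer, diabetes, obesity,
cognitive outcomes, breast-cancer staging and treatment pathways, net
monetary benefit and acceptability curves are all out of scope, matching
the source analysis. The breast-cancer magnitudes depend on synthetic
tables as described above.
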