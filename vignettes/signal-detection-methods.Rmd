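---
title: "Disproportionality signal detection: models, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
voluntarily submitted case reports linking drugs to suspected adverse
events coded as MedDRA preferred terms (PTs). There is no denominator of
exposed patients, so incidence cannot be estimated; instead, signal
detection asks whether a drug–event pair is reported *disproportionately*
often relative to the rest of the database. A signal is a statistical
flag, not a causal claim: reporting bias, confounding by indication and
duplicate reports all distort it, which is why this package combines five
screening algorithms with different operating characteristics and makes
every cleaning step auditable.

## Report cleaning

FAERS ships one row per report *version*. Deduplication keeps, per case
identifier, the version with the latest receipt date (`FDA_DT`), breaking
ties by the larger report key — the rule FDA's data documentation
recommends — and optionally removes caseids named in deleted-case lists
(published only from 2019Q1 on, so their absence is not an error). The
audit identity `input = kept + dropped_duplicate + dropped_deleted` is
enforced by tests, and deduplication is idempotent.

A report enters the analysis if its receipt year falls in the study
window and it carries at least one reaction PT after per-report
deduplication (a report listing the same PT twice contributes one
mention; a report with none can contribute to no contingency cell).
Seriousness follows the outcome codes: a report is serious when any of
DE/LT/HO/DS/CA/RI is present; OT ("other") alone leaves it non-serious.
Ages are converted to years from the unit code (decades ×10, months /12,
weeks /52.1429, days /365.25, hours /8766); implausible results outside
0–130 years become missing with a warning rather than an error, because
malformed demographic fields are routine in this data and must never
abort an ingest.

Target selection keeps reports with at least one primary-suspect (PS)
drug entry whose `DRUGNAME` *or* `PROD_AI` contains any target pattern as
a case-insensitive substring — brand and generic names both match, which
is why the default patterns are `rivaroxaban` and `xarelto`. Reports
where the drug appears only as secondary suspect, concomitant or
interacting are background, never target, and no report is in both arms.

## The counting unit

All 2×2 cells count distinct (report, term) **combinations**, not
reports: a report naming three distinct PTs contributes three
combinations. This matches how large published analyses reconcile
"77,384 reports" with "177,465 combinations". At the SOC level each
report contributes one combination per distinct system organ class its
PTs map to, under a user-supplied single-assignment PT→SOC map (MedDRA is
licensed and multi-axial; the package takes one primary SOC per PT and
counts unmapped PTs under an explicit `"unmapped"` bucket rather than
dropping them silently).

## The five statistics

With cells $(a, b, c, d)$, $n = a+b+c+d$:

**ROR** $= ad/bc$ with $\mathrm{se} = \sqrt{1/a + 1/b + 1/c + 1/d}$ and
95% bounds $\exp(\ln \mathrm{ROR} \pm 1.96\,\mathrm{se})$.
**PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with
$\mathrm{se} = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$.
Both intervals are geometrically symmetric about the estimate
($\mathrm{lo}\cdot\mathrm{hi} = \mathrm{est}^2$), a property tests verify
to $10^{-9}$, and the algebraic identity ROR > PRR ⟺ ROR > 1 holds on
every table. When any cell is zero the Haldane–Anscombe 0.5 is added to
all four cells (flagged per row) — only for ROR/PRR/χ²; the Bayesian
statistics need no correction. With the correction disabled, zero
denominators yield undefined-flagged rows, never crashes.

**MHRA χ²** uses the classical
$\chi^2 = n(|ad-bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))$ with the Yates
continuity term applied by default (the MHRA convention) and the inner
difference floored at zero; an uncorrected variant is available and both
are exercised in tests, since published reports rarely state which was
used.

**BCPNN.** The information component is computed from the closed-form
posterior moments of the Bayesian confidence propagation neural network
model with hyperparameters $(\alpha_1 = \beta_1 = 1,\ \alpha = \beta = 2,
\ \gamma_{11} = 1)$ and $\gamma$ chosen per table so the *prior* IC
expectation is exactly zero — hence the all-zero table scores IC = 0, a
property asserted directly. The screening bound is IC − 2SD (the
conventional "IC-2SD"), with tiers −/+/++/+++ at 0, 1.5 and 3; exported
tables additionally carry ±1.96 SD bounds because published tables print
an "IC 95% CI" column and it is not knowable which multiplier a given
paper used, so both are emitted. The closed form is validated against a
Monte-Carlo oracle that samples the three conjugate Beta posteriors
($10^5$ draws) and estimates the same functional, with batch-mean
standard errors; agreement within 3 MC standard errors is required on
100 random tables.

**MGPS.** The DuMouchel gamma-Poisson shrinker assumes the relative
reporting rate $\lambda$ of each cell is drawn from a two-component gamma
mixture $w\,\mathrm{Ga}(\alpha_1, \beta_1) + (1-w)\,
\mathrm{Ga}(\alpha_2, \beta_2)$; the observed count is Poisson with mean
$\lambda E$, $E = (a+b)(a+c)/n$. The prior is fitted by maximising the
marginal negative-binomial mixture likelihood over all drug–event cells
(at least 50), on a log/logit scale so constraints hold by construction,
from five deterministic starts including the canonical
$(0.2, 0.1, 2, 4, 1/3)$; the best solution wins and components are
relabelled so component 1 has the larger prior mean, making the fit
label-switch-proof. The fit is unstratified by default, as published
analyses of this kind describe no stratification. The posterior for a
cell is again a gamma mixture; EBGM is its geometric mean (digamma
closed form) and EB05/EB95 are found by vectorised bisection on the
mixture CDF to absolute tolerance $10^{-6}$, validated against a
grid-quadrature oracle to $10^{-4}$. Parameter recovery on 50,000
simulated cells (w within ±0.05, shapes within ±20%) is part of the
acceptance suite.

### Screening criteria

ROR and PRR are positive when $a \ge 3$ and the 95% lower bound exceeds
1 (PRR positivity is CI-based, matching the convention that its
screening rule "is the same as ROR's"); MHRA when PRR > 2, χ² > 4 and
$a > 3$ — note the *strict* count gate, kept deliberately distinct from
the $a \ge 3$ gate rather than harmonised, since both appear verbatim in
the literature; BCPNN when IC − 2SD > 0; MGPS when EB05 > 2. Undefined
statistics evaluate as negative, and terms with $a = 0$ are excluded
from decision tables entirely so negative rows are not inflated.
Important-medical-event flagging is case-insensitive exact PT membership
in a user-supplied list (the EMA's IME list is the intended input; it is
licensed content, so the package ships only a synthetic stand-in).

## Time trends

`ic_time_series()` recomputes the BCPNN IC per receipt year, either from
each year's reports alone (`per_year`, the default) or cumulatively.
Both modes are genuinely useful and published figures are often
ambiguous between them: a very wide final-period interval indicates
per-period data (a partial year has few reports), while "accumulating"
IC curves with narrowing intervals indicate cumulative analysis. The
cumulative series ends exactly at the pooled analysis and per-year cells
sum to the pooled cells — both identities are tested, as is the
localisation of an injected change-point to within a year.

## The synthetic generator

`sim_config()` defines the generative model the validation suite runs
on. Defaults were chosen once to emulate the marginals of a large
published oral-anticoagulant report population: receipt-year weights,
sex (46.2% F / 47.7% M / 6.0% missing), reporter occupation (53.8%
consumer), country (74.4% US), route (98.7% oral), 86.2% serious, age
centred on a median of 72 with SD 14 years (IQR ≈ 61–80) and 20.8%
missing, indication shares led by atrial fibrillation (33.45%), and
about 2.3 combinations per report. Reports draw a suspect drug from a
Zipf marginal over 25 drugs and $1 + \mathrm{Poisson}(\mu)$ reaction
mentions (so every report survives cleaning) from a Zipf marginal over
120 events; designated signal pairs multiply the event probability by
$\rho \ge 1$ with renormalisation. Five percent of cases gain later
duplicate versions with perturbed fields, and the version dedup must
keep is recorded as ground truth.

`expected_tables()` gives closed-form cell expectations: with
$K = 1 + \mathrm{Poisson}(\mu)$ draws and per-event probability $p$, the
presence probability is $1 - (1-p)e^{-\mu p}$ (the +1 draw times the
Poisson generating function), accounting exactly for the $\rho$
renormalisation. These expectations are verified by hand arithmetic on a
toy configuration and by Monte-Carlo means over 200 replicates.

What the generator does *not* emulate: real MedDRA vocabulary and
term co-occurrence structure, drug co-reporting (concomitant entries are
independent noise), reporting-rate drift within a year, and
country-specific coding habits. Passing tests therefore demonstrate that
the pipeline's algebra, cleaning rules and decision logic are correct
under a known model — not that any particular real-data signal is
causal, nor that real FAERS signal counts will be reproduced (those
depend on the full database).

## Numerical and design choices

- Percentages print with half-up rounding to two decimals, the
  convention of published report tables (`round_half_up()` exists
  because R's `round()` goes to even at ties).
- The exact published formula supplements for the five algorithms are
  often unavailable; the canonical literature forms (Evans PRR, van
  Puijenbroek ROR, Bate BCPNN moments, DuMouchel MGPS) are implemented
  and every hyperparameter is recorded in output metadata so variants
  are auditable.
- Indication subgroup analyses rebuild *both* arms from reports carrying
  the indication (indication-restricted background). The alternative — a
  global background — answers a different question; the restricted form
  mirrors per-indication tables whose background is the indication
  population.
- MGPS quantile bisection brackets with the component-wise
  $10^{-6}$-quantile upper bound plus one, and terminates at absolute
  width $10^{-6}$; BCPNN needs no iteration at all.
- Volcano exports floor p-values at the smallest positive double before
  taking $-\ln p$, and carry both the raw IC − 2SD and its log2 (the
  latter mirrors how some published volcano plots label their x axis;
  non-positive bounds yield NA there).
- Problem sizes in the validation suite: oracle comparisons use 100
  random tables, contingency enumeration 1,000 reports, prior recovery
  50,000 cells, and pipeline signal recovery and null calibration 20
  seeds of 50,000 reports each — large enough for the binomial bands the
  tests assert, small enough to run routinely.

## Worked example

```{r example}
cfg <- sim_config(
  n_reports = 5000,
  signal_pairs = tibble::tibble(drug = "rivaroxaban",
                                event = "pt_010", rho = 5),
  seed = 11
)
sim <- simulate_reports(cfg)
reports <- clean_reports(deduplicate_cases(sim$tables))
target <- filter_primary_suspect(reports)
background <- anti_join(reports, target, by = "primaryid")

stats <- dispro_stats(
  contingency_tables(count_combinations(target, background)),
  prior = fit_mgps_prior(drug_event_cells(reports))
)
filter(stats, term == "pt_010") |>
  select(a, ror, ror_lo, prr, chi2, ic025, ebgm, eb05)

evaluate_signals(stats) |> filter(term == "pt_010")
```

```{r trend, fig.width = 6, fig.height = 3.5}
autoplot(ic_time_series(target, background, "pt_010"))
```

## Limitations

Disproportionality quantifies reporting, not risk: no denominators, no
confounding adjustment, no causality. The package deliberately excludes
drug–drug interaction analysis and regression-based adjustment. SOC
aggregation uses a single primary SOC per PT, so multi-axial MedDRA
assignments are approximated. Published full-database signal counts are
not reproducible from code alone and are out of scope for the test
suite; what is reproduced are the self-contained printed quantities
(descriptive ratios, ROR→PRR identities, CI symmetry) and the behaviour
of every algorithm under a fully known generative model.
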