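---
title: "Simulating career-long clinician exposure to rare diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating career-long clinician exposure to rare diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careersim)
```

## The model

People are poor intuitive judges of small probabilities, and students (and
some of their teachers) systematically underestimate how often a working
clinician meets patients with rare diseases. The point of this package is a
simple, transparent stochastic model that makes the arithmetic vivid: although
each rare condition is individually unlikely, there are very many of them, so
career-long encounters with *some* rare condition are essentially certain.

The model world is deliberately minimal:

* **A disease list.** `n_conditions` theoretical conditions (default 462),
  each identified by a 1-based Condition Code Number (CCN). Prevalence decays
  exponentially in the code,
  $$p(c) = p_{\max}\, e^{-k (c - 1)}, \qquad
    k = \frac{\ln(p_{\max}/p_{\min})}{n-1},$$
  anchored at $p(1) = 0.641$ and $p(462) = 10^{-6}$. With these defaults,
  code 200 lands at $2\times10^{-3}$ — the EU rare-disease threshold of
  1/2000 — so codes above 200 are "rare"; codes 303 and 382 land at
  $10^{-4}$ and $10^{-5}$. The single-rate form is the only free modelling
  choice here; it reproduces every interior anchor to within 2% relative,
  i.e. within the precision to which the anchors themselves are quoted.
* **Two acquisition classes.** A fixed number of conditions (default 73 of
  462) are *congenital/persistent*: carried life-long, so a clinician can
  only meet such a patient when the patient is **new** to the panel. The rest
  are *spontaneous*: they arise afresh in the standing panel each year.
  Class labels are assigned uniformly at random without replacement — an
  exact count, not a per-condition coin flip, because the split is stated as
  an exact count.
* **A panel and a career.** Each clinician serves a fixed panel
  (`panel_size`, ~2000 medical, default 1500 dental) for `years` years
  (default 30). The panel is entirely new in year 1 and whenever the
  clinician starts at a new practice; the number of practice changes is
  uniform on `[min_job_changes, max_job_changes]` (default 2–10) with change
  years drawn uniformly without replacement from years 2..`years`. In any
  other year, a fraction `attrition_rate` of the panel is replaced by new
  patients.
* **Local variation.** Real prevalence varies with geography and
  demographics. Each (clinician, condition) pair gets one multiplicative
  jitter $p' = p(1+u)$, $u \sim U(-0.15, +0.15)$ by default, drawn once and
  held for the whole career — a clinician's locality does not change under
  them every year.

Given the jittered prevalence, yearly case counts are sampled per clinician
and condition:

* spontaneous: `cases ~ Binomial(panel_size, p')` each year, independently;
* congenital: `new cases ~ Binomial(new patients that year, p')`; the active
  caseload accumulates these, resets at every practice change (the clinician
  leaves those patients behind), and is otherwise never reduced under the
  default `congenital_loss = "job_change_only"`.

Prevalence is used directly as a per-year encounter probability for
spontaneous conditions. That conflates prevalence with incidence; it is the
convention of the back-of-envelope arithmetic the simulator illustrates
(a 2000-patient panel "should" meet one case per year of a 1/2000 condition),
and we inherit it rather than introduce a latent incidence model the anchors
could not constrain.

## The analytic oracle

Because everything is linear, expectations are closed-form:

| quantity | formula | headline value |
|---|---|---|
| annual, per clinician | $p \times \text{panel}$ | $1/2000 \times 2000 = 1$ |
| career, per clinician | $p \times \text{panel} \times \text{years}$ | $1/60000 \times 2000 \times 30 = 1$ |
| cohort | $p \times \text{panel} \times \text{years} \times C$ | $10^{-6} \times 2000 \times 30 \times 200 = 12$ |

`expected_annual_cases()`, `expected_career_cases()` and
`expected_cohort_cases()` compute these. They are not a convenience: they are
the *oracle* the test suite holds the simulator to. For any spontaneous
condition with jitter off, the cohort total is exactly
Binomial($C \cdot Y \cdot$ panel, $p$), so replicate means must sit within
3 Monte Carlo standard errors of the oracle — and the tests check that they
do across a prevalence grid, in both sampling modes.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `p_max`, `p_min`, `n_conditions` | 0.641, 1e-6, 462 | proportion / count | the stated anchor values of the disease list |
| `n_congenital` | 73 | count | stated split of the 462 conditions |
| `n_clinicians` | 97 | count | reference cohort scenario |
| `years` | 30 | years | reference career length |
| `panel_size` | 1500 | patients | dental panel; use 2000 for medical |
| `min/max_job_changes` | 2 / 10 | count | reference scenario range |
| `attrition_rate` | 0.10 | fraction/year | **not stated anywhere in the source scenario**, though attrition is integral to the congenital logic; 10%/year is a plausible primary-care panel turnover. Every headline quantity (year-1 totals, all spontaneous arithmetic) is insensitive to it. |
| `jitter_fraction` | 0.15 | fraction | stated bound on local prevalence variation |
| `sampling_mode` | `"binomial"` | — | exact patient-level model; `"expected_branch"` reproduces the original expected-cases-below-1 branching (floor of $\lambda$ plus Bernoulli($\lambda - \lfloor\lambda\rfloor$)), same mean |
| `congenital_loss` | `"job_change_only"` | — | persistence until practice change, as the career tables display it; `"attrition_also"` erodes caseloads with panel turnover for users who want conservation |

## Numerical and design choices

* **Seeding.** `simulate_cohort()` derives an independent L'Ecuyer-CMRG
  substream per clinician from the master seed (`parallel::nextRNGStream`),
  so output is bit-reproducible and enlarging the cohort extends rather than
  reshuffles a smaller run. The engine snapshots and restores the caller's
  full RNG state, including the generator kind.
* **Expected-branch semantics.** The exact branch taken by the original
  implementation when the expected case number is below 1 is not printed;
  our `"expected_branch"` mode is a reconstruction with the correct mean
  (and is not the default).
* **Attrition rounding.** The yearly replacement intake is
  `round(attrition_rate * panel_size)` with half-away-from-zero rounding.
* **Caseload cap.** A congenital caseload cannot exceed `panel_size` (a
  panel only holds that many patients); the cap can only bind at prevalence
  values far above any realistic congenital condition.
* **Counting convention.** Congenital patient-years (`counts`) and unique
  patient entries (`new_counts`) are both kept. Cohort and first-year totals
  default to `new_counts` so a patient carried for a decade is not counted
  ten times; career tables default to `counts` because persistence is
  exactly what those tables are meant to show. Whether the original
  figure totals count patient-years or unique patients is not decidable from
  the source; both are exported.
* **Degenerate inputs.** A single-condition list, zero prevalence (allowed
  in user-supplied lists; the generated curve is strictly positive), zero
  job changes, `years = 1`, and `jitter_fraction = 0` are all valid and
  tested; `max_job_changes` must leave year 1 free.
* **Colour bins.** Only the scattergram extremes are fixed by the stated
  legend (1 case = black, ≥300 = magenta). Interior edges
  (2–4, 5–14, 15–49, 50–149, 150–299) are geometric and purely cosmetic.

## The survey module

The companion analysis for the in-class before/after surveys is a grouped
Pearson chi-squared test: the ordered response categories are collapsed into
a 2×2 table (low group vs high group, before vs after) and tested with
$\sum (O-E)^2/E$ on 1 degree of freedom. The continuity correction is off by
default — the source does not state one, and for the bundled response table
both the corrected and uncorrected statistics satisfy the printed p-bound —
with `yates = TRUE` available. The bundled fixture
(`inst/extdata/table1.csv`) is the response table for "how many first-year
cases of a 1/10,000 condition will your class see?": grouping answers 0–9
vs 10–25 gives $\chi^2 = 28.47$, $p \approx 9.5\times10^{-8} < 10^{-4}$. A paired
analysis is impossible (responses were anonymous, 89 then 77 respondents);
the unpaired test inherits that limitation. Per-prevalence-level tests are
repeated calls of `survey_chi2()` over a list of tables.

## What the generator does and does not emulate

The synthetic world reproduces the *stated* conditions: the anchored
prevalence curve, the exact congenital split, panel sizes, career lengths,
job-change ranges and jitter bound above. It does not emulate: conditions
that arise spontaneously but then persist; specialists with high patient
turnover; variable panel sizes, career interruptions or part-time work;
correlated prevalences (comorbidity); or real disease lists with curated
prevalence values (supported as input via `read_disease_list()`, but no
curation is attempted — unambiguous prevalence values are unavailable for
surprisingly many conditions). A green test therefore establishes that the
implementation is faithful to this stated world and consistent with its own
analytic expectations — not that the world is an accurate demographic model
of any particular health system.

## Known limitations

* The prevalence/incidence conflation above means spontaneous "cases per
  year" are better read as "patients in the panel afflicted during that
  year" than as diagnosed incident cases.
* With `congenital_loss = "job_change_only"`, total congenital patient-years
  grow with career length between changes; use `new_counts` (the default for
  totals) when unique patients are the quantity of interest.
* The chi-squared test is asymptotic; for small expected cell counts
  (< 5) prefer `yates = TRUE` or an exact test from elsewhere.
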