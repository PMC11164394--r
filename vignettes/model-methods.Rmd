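---
title: "Model methods: G-CSF prophylaxis of febrile neutropenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: G-CSF prophylaxis of febrile neutropenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncea)
```

## Scope and structure

`fncea` evaluates granulocyte colony-stimulating factor (G-CSF) prophylaxis
of chemotherapy-induced febrile neutropenia (FN) in a cohort of women aged
56 with early-stage breast cancer receiving a high-risk regimen: six
chemotherapy cycles of 21 days, followed for life. Strategies combine a
prophylaxis mode — none, primary (drug every cycle), secondary (drug in
cycles after a first FN event) — with a drug (filgrastim, lenograstim,
pegfilgrastim, or a filgrastim/pegfilgrastim biosimilar differing only in
price). The perspective is a single payer; all costs are New Taiwan Dollars
and fall within the first year, so only health outcomes are discounted.

The model is deliberately two engines, not one:

* a **chemotherapy-phase engine** (`run_chemo_phase()`) that computes exact
  expectations over the per-cycle event tree — at most one FN event per
  cycle, each fatal with probability `p_fn_death`, survivors carrying FN
  history forward;
* a **post-chemotherapy engine** (`run_post_chemo()`) that depletes the
  surviving cohort in annual cycles, stratified by relative dose intensity
  (RDI), to a terminal age.

`fn_cea()` composes the two and builds the cost-effectiveness frontier.

## Parameters

All inputs live in one validated object, `fn_params()`; the base-case
values, uncertainty ranges and probabilistic families ship as the package
defaults and as `inst/extdata/params_basecase.yaml`. The parameters that
drive results most:

| parameter | default | units / note |
|---|---|---|
| `p_fn_cycle1` | 0.364 | FN probability, cycle 1, no prophylaxis |
| `rr_cycle2plus` | 0.46 | RR of FN, cycles 2+ vs cycle 1 |
| `rr_history` | 2.4 | RR of FN with vs without FN history |
| `p_fn_death` | 0.036 | case fatality per FN event |
| drug RRs | 0.640/0.575, 0.452/0.609, 0.334 | cycles 1–2 / 3+ (single RR for pegfilgrastim) |
| `cost_fn_event` | NT$8,287 | per FN event, fatal or not |
| prices | 1,673 / 1,674 / 16,626 (14,457, 1,559 biosim.) | NTD per injection; 4/cycle short-acting, 1/cycle pegfilgrastim |
| `hr_rdi_low` | 1.73 | long-term mortality HR, RDI < 85% |
| `discount_rate` | 0.03 | per annum, health outcomes only |
| `wtp` | NT$976,914/QALY | one 2022 GDP per capita |

Drug efficacy enters through a per-drug RR multiplying the FN probability;
the history multiplier and the drug RR apply jointly and multiplicatively,
and the product is capped at 1 (the cap never binds at base case; it can at
one-way-analysis extremes). Biosimilars carry an `efficacy_source` pointer
and always mirror their reference product's RR — in the probabilistic
analysis a reference-drug draw propagates to its biosimilar, so the pair
differs only in price there too.

## Numerical and structural choices

These were genuinely open design points; the package resolves them as
follows.

* **Events resolve at cycle end.** A patient dying of FN in cycle *k*
  accrues that cycle's drug cost, the FN event cost (fatal events are
  assumed to incur the full NT$8,287), the cycle's chemotherapy QALY minus
  the FN decrement, and nothing afterwards. This reconciles
  primary-prophylaxis drug totals (slightly below six full cycles of drug,
  because of FN-death attrition) with the FN-cost totals.
* **Cycle-tier RRs are indexed by chemotherapy cycle number** (1–2 vs 3+),
  not by time on drug; secondary prophylaxis, once triggered, continues in
  all remaining cycles.
* **Chemotherapy-phase QALYs are undiscounted** by default (the phase ends
  within 18 weeks); `discount_chemo_qalys = TRUE` switches per-cycle
  discounting on. Year length is 365.25 days throughout.
* **Hazard-scale application of the RDI hazard ratio**:
  `q' = 1 − (1 − q)^hr` rather than `q × hr`, which is the correct
  transform for a hazard ratio and keeps `q'` a probability even at the
  upper range end (`q × hr` can exceed 1).
* **Half-cycle correction** in the annual phase (person-years are the mean
  of start- and end-of-year survivors); none in the 3-week phase, where the
  correction is negligible.
* **The 2.02% annual excess mortality applies to the RDI ≥ 85% stratum**
  for post-chemotherapy years 1–10, with the HR layered onto the RDI < 85%
  stratum; scenario 1 applies baseline mortality to everyone. The discount
  clock starts at the end of chemotherapy; attained age in post-chemotherapy
  year *t* is `start_age + t` (the 18-week chemotherapy duration is ignored
  for age indexing). Survivor utility "years 1–5" is indexed from the end
  of chemotherapy.
* **Terminal age 110** with `qx = 1` forces full absorption in finite time.
* **Frontier construction** sorts by cost, removes strong dominance, then
  iteratively removes the interior strategy wherever the incremental ICER
  sequence fails to increase (extended dominance). All comparisons use
  unrounded values; rounding (integer NTD, two-decimal QALYs) happens only
  in `cea_table()`. Exact cost/QALY ties are both retained, ordered by
  input order.
* **Threshold search** is plain bisection on the ICER, stopping at
  `|ICER − target| < tol` (default NT$1/QALY) or a 1e-12 bracket width; it
  refuses brackets without a sign change rather than extrapolating.

## Probabilistic sensitivity analysis

No fitting method from mean-plus-range is prescribed by convention, so the
package declares one: beta and gamma parameters by method of moments with
mean at the base value and `SE = (high − low)/3.92` (the range read as a
95% interval), and log-normal with `meanlog = log(base)`,
`sdlog = (log high − log low)/3.92`. Probabilities and utilities (including
the FN utility decrement) are beta; relative risks, the odds ratio and the
hazard ratio log-normal; costs and length of stay gamma; drug prices and
the discount rate fixed. Parameters are drawn independently — no
correlation structure is available to inform anything richer. Infeasible
beta moments (`SE² ≥ p(1−p)`) raise an error naming the parameter rather
than silently truncating.

One-way analysis ranges follow the same table, with two conventions: FN
cost ±20%, and drug prices −20% to 0% (reimbursement prices only move
downwards). The discount rate has no published range; the package uses
0–5%, a standard span in health-technology assessment, and keeps the rate
fixed in the probabilistic analysis.

The default willingness-to-pay grid runs from 0 to 1.5× the threshold in
NT$10,000 steps. With 10,000 iterations (`run_psa(n_iter = 10000)`) the
acceptability curves are stable to about one percentage point; the test
suite uses 1,000 iterations for the qualitative shape checks to keep
runtimes modest.

## Synthetic data: what it emulates, what it does not

Two inputs cannot ship with the package and are generated instead.

**Life table.** `make_life_table()` builds a female life table on a
Gompertz schedule `qx = min(1, a·e^{b(x−56)})`, slope `b = 0.095`, with the
level `a` calibrated by bisection so that remaining life expectancy at 56
equals 29.0 years — a realistic value for a Taiwanese woman of that age.
The packaged CSV (`inst/extdata/life_table_synthetic.csv`) is exactly this
table. It reproduces the *level* of survivorship but not the precise shape
of the official national table, so absolute QALY totals and therefore
ICERs shift by a few percent against published figures that used the real
table; the test suite accordingly holds QALYs to a band (13.0–14.2), the
published effectiveness ordering, and increasing frontier ICERs rather
than to exact values. Dropping in the real table via `read_life_table()`
restores exact reproduction.

**Cohort records.** `simulate_cohort()` draws per-patient per-cycle
records (exposure, FN event, FN death) from the model's own probabilities —
a generative twin of the expectation engine, used three ways: as an
independent Monte-Carlo oracle for the engine, as the substrate for
parameter-recovery studies of `estimate_rr()`, and as a demonstration of
the per-cycle effectiveness analysis that produced the short-acting drug
RRs. It does not emulate claims realism: no diagnosis codes, no antibiotic
exclusions (only a uniform record-drop fraction), no regimen
heterogeneity.

`estimate_rr()` is the Mantel–Haenszel common risk ratio over
(cycle × FN-history) strata within a cycle tier. A crude ratio of pooled
incidence proportions would be confounded — exposure under secondary
prophylaxis exists only in FN-history cycles, and arms accumulate history
at different rates — and is biased by about −0.03 for lenograstim in
cycles 1–2; the stratified estimator removes this. Its confidence interval
uses a cluster-robust variance with patients as the sampling unit, because
a patient's cycles are correlated (an early FN event moves later cycles
into the history stratum): the naive stratum-count variance undercovers by
several points for the short-acting drugs. At ~100,000 simulated cycles
the estimator recovers all five drug RRs with |bias| < 0.01 and 93–99%
interval coverage over 100 replicates.

## Problem sizes

The shipped tests evaluate the full event-tree enumeration (all strategies),
a 10⁶-patient microsimulation check of the chemotherapy engine, 100
parameter-recovery replicates of ~16,800 patients each, and a 1,000-
iteration PSA; together they run in about a minute on one CPU. These sizes
were chosen so that Monte-Carlo checks operate at three standard errors
without being flaky.

## Known limitations

* No breast-cancer recurrence or progression states; post-chemotherapy
  mortality is a single excess-rate window plus general-population rates.
* At most one FN event per cycle; no dose-delay dynamics beyond the binary
  RDI split; no chemotherapy drug or administration costs (only G-CSF and
  FN costs differ across strategies, so shared costs cancel from ICERs).
* Independence of all sampled parameters in the PSA.
* The synthetic life table is a two-parameter Gompertz: adequate for
  frontier structure and sensitivity rankings, not for reproducing
  published absolute QALYs to the last decimal.
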