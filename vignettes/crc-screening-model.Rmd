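---
title: "The multistate screening-colonoscopy model: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multistate screening-colonoscopy model: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`crcscreen` simulates the natural history of colorectal cancer (CRC)
through the adenoma–carcinoma sequence as an annual-cycle Markov cohort
model. A closed cohort of `cohort_size` persons (default 100,000 men or
women) enters at age 45 and is followed to age 85; outcomes accumulate
over ages 45–84.

Living, undiagnosed persons occupy one of four health states:

* no lesion,
* non-advanced adenoma,
* advanced adenoma,
* preclinical (asymptomatic, colonoscopy-detectable) CRC,

and progress along the chain with age- and sex-specific **annual
transition probabilities** $r_{0\to NA}(a)$, $r_{NA\to Adv}(a)$,
$r_{Adv\to Pre}(a)$, $r_{Pre\to Clin}(a)$, stored per 5-year age group
(45–49 … 80+; ages ≥ 85 use the open-ended 80+ group). At most one
forward step is taken per year — the standard annual-cycle convention,
consistent with probabilities that are themselves annual. Preclinical
cancer that progresses becomes a clinically detected incident case.

Diagnosed persons are tracked by detection mode (screen-detected vs
clinically detected) and year since diagnosis (1…10, then an open-ended
"beyond" stratum), each cell carrying its own annual CRC death
probability. Screen-detected disease carries lower mortality,
representing the stage shift at asymptomatic detection. Other-cause
mortality $q(a)$ from a population life table applies to every living
state. Two absorbing states (death from CRC, death from other causes)
complete the model; total occupancy is conserved exactly (checked to
1e-9 relative each cycle — observed defects are at machine precision,
~1e-15).

### Event order within a year

The within-year sequence is not dictated by the annual data and had to be
fixed by design:

1. any scheduled colonoscopy,
2. other-cause death on all living states,
3. lesion progression on survivors,
4. CRC death on diagnosed states, then the year-since-diagnosis and
   surveillance clocks advance.

An exam at the scheduled birthday thus protects the year it opens, which
matches the intuition that a clean exam at age $a$ covers $[a, a+1)$. The
sequence is isolated in a single internal function (`advance_core`) so
alternatives can be tested; the individual-level stochastic engine uses
the identical order, which is what makes the deterministic/stochastic
agreement check meaningful. Newly diagnosed persons face other-cause
death in the diagnosis year but enter the CRC survival schedule at year 1
the following year.

## Screening and surveillance

A scenario offers **at most two lifetime screening colonoscopies**: the
first at `first_age`, the second at `second_age` and only to persons
whose first exam detected nothing. Detection uses sensitivity 75% for
non-advanced adenomas and 95% for advanced neoplasms (advanced adenomas
and preclinical CRC), with perfect specificity — the tandem-colonoscopy
miss-rate consensus. Detected adenomas are removed (polypectomy, return
to the lesion-free state) and the person enters **surveillance**: exams
every 3 years after an advanced finding, every 10 years after a
non-advanced finding, unlimited in number, never at or after the age
limit of 85. Detected preclinical cancer becomes a screen-detected
incident case. Three design points deserve note:

* A **missed lesion at a screening exam schedules as a negative exam**:
  the person proceeds to the second screening colonoscopy. Scheduling is
  conditioned on what was detected, not on the truth.
* A non-advanced finding at the *first* screening exam moves the person
  onto the 10-year surveillance track, which **replaces** the second
  screening exam rather than supplementing it (when the interval is 10
  years the timing coincides; the exam is booked as surveillance).
* A surveillance exam resets the clock; on detection the stratum is
  reassigned by the class of the detected lesion, and cancers found at
  surveillance use the screen-detected survival schedule.

The default grid is the nine two-exam strategies with intervals of 10
years (first exam at 45/50/55/60), 15 years (45/50/55) and 20 years
(45/50), compared against a no-screening cohort and summarised relative
to a reference strategy (men: exams at 50 and 60; women: 55 and 65 — the
earliest use of a typical statutory two-exam offer).

## Outcomes

Over ages 45–84 the package accumulates incident CRC cases, CRC deaths,
and:

* **YPLL** $= \sum_a d(a)\, e(a)$ — CRC deaths at age $a$ times residual
  life expectancy at the integer age of death (no interpolation, matching
  the granularity of the formula).
* **YLD** $= \sum_p \mathrm{PY}_p w_p$ — diagnosed person-years by phase
  times disability weights. The first year after diagnosis is the
  diagnosis/treatment phase, later diagnosed years are remission, and the
  year of CRC death is the metastatic/terminal phase — the standard
  burden-of-disease phase convention. Default weights (0.288, 0.049,
  0.451) are GBD-style placeholders and configurable; analyses tied to a
  specific published valuation should substitute its weights.
* **DALYs** $=$ YPLL $+$ YLD. No discounting and no age-weighting.

Person-years are counted on start-of-year occupancy with no half-cycle
correction — a deliberate simplification at annual granularity, shared by
the death accounting.

Strategy comparisons report signed integer percent changes versus the
reference, rounded half away from zero (`relative_change()`), computed as
$100\,(x - x_\mathrm{ref})/x_\mathrm{ref}$ so that integer inputs produce
exact halves. The shipped table of published two-exam strategy results
(`published_burden_tables()`) regression-tests this arithmetic cell by
cell; one cell of that source table is internally inconsistent with its
own printed absolutes (documented in the test), the other 71 reproduce
exactly.

## Synthetic parameters and calibration

Registry-derived inputs for this model family have a characteristic
structure, which `generate_parameters()` emulates so every module is
testable without access to any proprietary table:

* one base value per transition drawn from a documented uniform range,
  perturbed by at most 10% across the observed age groups (55–59 … 80+) —
  transition rates in screening registries are strikingly constant across
  age;
* the unobserved 45–49 and 50–54 bands copied from 55–59;
* a Gompertz life table ($q(a) = q_{45} e^{b(a-45)}$, residual life
  expectancy computed from the table itself);
* a geometrically decaying post-diagnosis mortality schedule with a
  screen-detected hazard multiplier below one;
* age-45 starting prevalences **calibrated** so that an
  interventions-free forward simulation reproduces target prevalences at
  age 55, the youngest age screening registries observe.

Default ranges and targets (see `?synthetic_spec`, `?prevalence_target`)
are epidemiologically plausible constants — deliberately *not* the
estimates of any specific registry — chosen so the default bundles
produce a lifetime burden of the right order of magnitude and the
characteristic several-fold case reduction of two-exam screening. The
female factor 0.75 on all transition draws mirrors the ~5-year lag of
female age-specific incidence.

### Calibration algorithm

The paper trail for models of this kind says only that starting
prevalences were found "iteratively". We use a damped fixed point on the
prevalence residual,

$$s_{k+1} = \mathrm{clip}\big(s_k + \lambda_k\,(t - F(s_k)),\ 0,\ 1\big),$$

updating all three compartments simultaneously (they interact through the
flows). The 45→55 map $F$ is monotone and near-affine with contraction
factor well below 1 for the adenoma compartments, so the iteration
converges linearly; $\lambda_k$ is halved whenever the residual norm
grows (an oscillation guard) and relaxed back toward 1 while it shrinks.
Convergence tolerance defaults to 1e-8 on the maximum absolute prevalence
residual, typically reached in 100–200 iterations. Infeasible targets —
a compartment pinned at a zero start while the flows alone overshoot its
target — are detected and reported as errors rather than silently
returned.

### The self-consistent preclinical target

The preclinical compartment empties at ~0.22–0.25 per year, so its age-45
start is almost entirely washed out by age 55: its age-55 prevalence is
pinned by the adenoma flows, not by its start. A fixed preclinical target
is therefore either infeasible (below the flow-determined floor) or
forces an unrealistically large age-45 start (the surplus is divided by
the ~0.09 survival factor of the start). By default the generator
resolves this by first calibrating the two adenoma compartments with a
zero preclinical start, measuring the flow-determined preclinical
prevalence at 55, and targeting 5% above it. This keeps the calibrated
age-45 preclinical start small (typically 0.3–0.9%), as it is in real
populations. An explicit numeric target can always be supplied instead.

### What the generator does and does not emulate

It reproduces the *structure* of registry inputs: near-constant rates,
copied-down young-age bands, calibrated starts, sex differences,
detection-mode-specific survival. It does not reproduce their *values*,
nor adenoma multiplicity, anatomical location, serrated-pathway lesions,
stage at diagnosis, or cohort (birth-year) effects. Passing tests
therefore demonstrate that the machinery is correct and internally
consistent — conservation, oracle equivalence, calibration round trips,
monotone screening benefit — not that any particular published number is
reproduced. Reproducing published headline burdens requires transcribing
the source parameter tables into a bundle
(`inst/extdata/registry-bundle-<sex>/`), for which an integration test is
provided.

## Validation strategy and problem sizes

The test suite checks, among others:

* engine = explicit 5×5 matrix-power oracle (interventions and mortality
  disabled) to 1e-12 relative over 40 years, on 100 random bundles;
* exact mass conservation (≤1e-9 relative, observed ~1e-15) at every age,
  with and without screening;
* calibration round trips on 50 random feasible targets to 1e-6;
* agreement of the deterministic engine with the mean of 200 stochastic
  replicates of 10,000 individuals within 3 Monte-Carlo standard errors;
* monotone benefit: each of the nine strategies yields no more cases than
  no screening, on 20 random bundles;
* closed-form checks (geometric lesion accrual, life-table survival,
  dot-product YPLL/YLD oracles) and the cell-by-cell regression of the
  comparison arithmetic against the published strategy tables.

These sizes (100/50/200×10,000/20) are the package's validation design:
large enough that systematic event-order or bookkeeping errors on the
order of one percent would be detected, small enough to run routinely.

## Known limitations

* Full adherence only; no participation, no fecal-test alternative, no
  colonoscopy complications, no costs.
* One lesion class per person (the most advanced); no multiplicity or
  location.
* Survival depends on detection mode and time since diagnosis, not stage.
* Annual cycles without half-cycle correction.
* Default disability weights are placeholder valuations.

## A worked run

```{r example}
library(crcscreen)

bundles <- list(
  male = generate_parameters(synthetic_spec("male", seed = 1)),
  female = generate_parameters(synthetic_spec("female", seed = 2))
)
exp <- run_experiment(bundles)
render_change_table(exp, style = "paper")
ggplot2::autoplot(exp)
```
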