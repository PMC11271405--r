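---
title: "Models, rules and design choices in pgtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, rules and design choices in pgtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtkit)
```

# The analysis problem

Precision-medicine cohort studies in high-risk (often pediatric) cancer
follow a common skeleton: patients are enrolled, profiled, and discussed at
a molecular tumor board (MTB) that issues therapeutic recommendations graded
by strength of evidence (tier 1, clinical evidence in the same cancer, down
to tier 5, consensus opinion). Some patients then receive the matched
therapy (PGT), others a standard-of-care regimen (SOC) or a new agent chosen
without molecular guidance (UGT). The analysis must demonstrate, from serial
disease assessments, whether guided treatment changed outcomes — response
rate, durable disease control, progression-free survival (PFS), overall
survival (OS) — and which patient features predict benefit.

`pgtkit` implements that chain as five composable modules: a typed cohort
data model, modality-specific response adjudication, endpoint derivation
with auditable filters, a self-contained inference kernel, and a synthetic
cohort generator that makes the whole pipeline testable without patient
data.

# Time and units

All times are integer day offsets from study start. Week-based protocol
constants translate exactly: 4 weeks = 28 days (evaluability and the
PFS-ratio gain threshold), 6 weeks = 42 days (minimum interval for a
countable stable-disease finding), 24 weeks = 168 days (durable-benefit
clock), 2 years = 730 days (survival read-out). The data cutoff is a
configuration parameter (`pgt_config(cutoff_day = ...)`); every censoring
time is `min(cutoff_day, last_followup_day)`. Reported percentages round
half away from zero (42.97 → 43, 54.64 → 55), matching clinical-report
conventions rather than banker's rounding.

# Response adjudication

Imaging modalities are operationalized as percent-change bands on the
target-lesion diameter sum (or the SUV-derived quantity when PET is the only
imaging): with change $c = (\text{current} - \text{baseline}) /
\text{baseline}$,

* $c \ge +25\%$ → PD (progression); configurable to RECIST 1.1's $+20\%$
  for RECIST/PERCIST courses via `thresholds = "recist11"`;
* $c \le -50\%$ (CNS tumors, RANO-style) or $c \le -30\%$
  (RECIST/PERCIST-style) → PR;
* $c = -100\%$ → CR;
* otherwise SD. Both boundaries are inclusive toward the more extreme
  category; new lesions force PD regardless of $c$.

Non-measurable disease supports only CR (disappearance), PD (unequivocal
progression or new lesions) and non-CR/non-PD (persistence); a PR cannot be
determined. Acute leukemia uses blast counts: CR requires marrow < 5%
blasts with no circulating blasts or extramedullary disease; PR is marrow
5–25%, or a > 50% relative reduction with ≥ 10-point absolute reduction,
again with clean blood and no extramedullary disease; PD is a > 25%
relative rise in absolute circulating blasts (any appearance when the
baseline count is zero — a relative rise over zero is undefined, and
treating appearance as progression keeps the rule monotone), or a marrow
rise of > 25 points after PR or > 5 points after CR. The rise is measured
from the marrow nadir; when the nadir is unknown it defaults to the
achieved category's cap (5 after CR, 25 after PR), the most conservative
value consistent with the category.

The best response over a course takes the optimum under
CR > PR > SD > PD, with one clock rule: SD (or non-CR/non-PD) counts only
when achieved at ≥ 42 days after treatment start, anchored to the start
because the protocol phrase is "after commencing a treatment". No
confirmation scan is required for CR/PR. A course with no qualifying
post-baseline assessment is NE (not evaluable) — a value, not an error.
The same 42-day clock is applied to non-CR/non-PD; the source protocol does
not state this case and we chose symmetry with SD.

# Endpoints

**Evaluability.** A course enters the analysis set when its duration is
≥ 28 days, no progression occurred before day 28, and at least one response
evaluation exists (a disease-free course needs none). Every exclusion
carries a reason code, and `audit_filters()` asserts conservation:
`n_input = n_evaluable + Σ exclusions`.

**PFS** runs from the start of the specific course to the first progression
on it or death from any cause; otherwise it is censored at the cutoff. OS
grouping assigns each patient to the category of the first new treatment
started on or after the MTB day (patients who never started one are
excluded); for patients whose first post-MTB treatment is guided, the
origin is the first guided course.

**Objective clinical benefit** (OCB) is CR/PR/SD sustained ≥ 168 days
(measurable), CR or non-CR/non-PD sustained ≥ 168 days (non-measurable),
or a disease-free interval ≥ 168 days (no evidence of disease at start).
"Sustained" is measured from course start to the first progression or the
treatment stop, whichever ends observation — a response continuing off-drug
does not extend the clock (the protocol is silent; stopping the clock is
the conservative reading). A course whose best response is SD but which
stopped before 168 days while still in SD is NE and excluded from the OCB
denominator. A CR/PR course stopped early without progression returns NO,
not NE: the protocol's NE carve-out names SD only.

**PFS ratio.** For a guided course, PFS2 is compared with PFS1 of the most
recent prior treatment on which the patient progressed. Eligibility needs
all five of: no progression in the first 28 days of the guided course; if
the guided course is censored, its duration must be at least the
comparator's (the ratio is then computed on the censored duration — a
conservative under-estimate); the comparator ended in progression *before
the guided course started*; the comparator was given for relapsed or
refractory disease; and both treatment durations were ≥ 28 days. Benefit is
PFS2/PFS1 > 1.3 **and** PFS2 − PFS1 ≥ 28 days.

**Favorable factors** count tier-1 evidence, a fusion/structural-variant
target, and treatment before any post-enrollment progression (0–3);
undefined for hematologic malignancies, which the source analysis excluded
for small numbers.

# Statistical kernel

The kernel is deliberately written from first principles so the test suite
can check it against independent oracles (hand-computed product-limit
values, brute-force O−E tables, binomial tail-sum inversion, and the
`survival` package, which is never used in the production path).

* **Kaplan–Meier**: $\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ with
  censored-at-event-time subjects counted at risk; survival-at-$t$ reads
  the step function last-value-carried-forward; the median is the smallest
  time with $\hat S \le 0.5$.
* **Log-rank**: at each event time the observed group-wise event counts are
  compared with their multivariate hypergeometric expectation and
  covariance; the quadratic form over $k-1$ groups is referred to
  $\chi^2_{k-1}$. Two-sided throughout.
* **Cox regression**: Newton–Raphson on the partial likelihood, Efron tie
  correction by default (day-resolution data are heavily tied; Breslow is
  available for cross-checks), convergence when the log partial likelihood
  changes by < 1e−9 (max 100 iterations, step-halving), standard errors
  from the inverse observed information. Non-convergence and suspected
  monotone likelihood (complete separation, flagged at |coef| > 15 or a
  singular information matrix) are reported, never silent.
* **Proportions**: Pearson chi-squared without continuity correction;
  exact binomial CIs are Clopper–Pearson via beta quantiles, with the
  degenerate bounds 0 (k = 0) and 1 (k = n).
* No multiplicity correction is applied anywhere, matching the source
  analysis; intra-patient correlation of per-course PFS is acknowledged but
  not modeled (no frailty/cluster variance) — a stated non-goal.

# The synthetic cohort generator

`simulate_cohort()` emulates the structure of the real data: 385 tumors
split 146/183/56 across CNS / non-CNS solid / hematologic groups;
recommendation probabilities 0.73 / 0.62 by group as published, with the
hematologic rate set to 0.64 so the expected overall recommendation rate
reproduces the published 67% (the group-specific value is unpublished);
uptake 0.43; tier probabilities (0.20, 0.33, 0.28, 0.15, 0.04) consistent
with the published margins (53% tier 1–2, 43% tier 3–4); aberration-class
and therapy-type frequencies from the published course-level tables; and
per-stratum response probabilities whose CR/PR mass reproduces the
published response rates by tier group (39% / 18% / 31%). Joint
distributions are unpublished, so independence is assumed; every
probability is a `sim_config()` field and can be overridden.

Progression times are exponential (Weibull optional, for
proportional-hazards stress tests) with hazard
$\lambda = \lambda_0 \exp(\beta^\top x)$ over four binary covariates —
tier-1 evidence, fusion target, no progression before start,
non-hematologic malignancy — with default log hazard ratios
$\ln(0.43), \ln(0.42), \ln(0.50), \ln(0.21)$. The baseline
$\lambda_0 = 0.0174$/day places the all-covariates-absent stratum near the
published single-digit 2-year PFS. Times are rounded to whole days
(creating realistic ties), and death follows observed progression after an
exponential lag with median 270 days.

The generator draws each course's best-response category *first*, then
constructs a trajectory realizing it. When the drawn category cannot be
realized against the drawn progression day (SD needs a qualifying scan at
day ≥ 42 before progression; any response needs a pre-progression
assessment; progression beyond the censoring window is unobservable), the
category is resolved deterministically — to PD, or to SD when progression
cannot be observed — and the *resolved* category is what the generator
reports as truth. The consistency invariant (adjudication reproduces
generated truth on 100% of courses) therefore tests the adjudicator against
an exactly realizable specification, not against a distribution. Each
patient consumes an independent sub-stream of the master seed, so growing
`n_patients` never perturbs existing rows.

What the generator does **not** emulate: assessment-schedule irregularity,
measurement noise in lesion sums, inter-assessment dependence, competing
risks, loss to follow-up (censoring is purely administrative), multiple
recommendations per patient, and any genomic content (aberration classes
are sampled labels). A green pipeline test therefore establishes rule-set
correctness and filter accounting, not robustness to messy real-world
assessment data.

The hand-built `printed_counts` fixture is the complement: a fully scripted
385-patient cohort whose adjudication lands exactly on the published
course-level accounting (117 guided courses → 99 evaluable; 70 measurable
with 6/19/24/21 CR/PR/SD/PD; 20 non-measurable with 2/10/8; 9 disease-free
at start; 97 benefit-assessable with 53 benefits; 31 ratio-assessable with
13 benefits; 110 treated of 256 recommended). Every acceptance figure is
recomputed by running the pipeline on it, never asserted.

# Numerical and degenerate-input choices

* Percent-change classification requires a strictly positive baseline sum;
  a zero baseline is a hard error (the data dictionary requires a baseline
  sum for measurable courses).
* `km_fit` rejects non-positive durations; derived PFS of 0 days cannot
  occur for evaluable courses (≥ 28 by construction) but reporting code
  clamps at 0.5 days defensively before fitting.
* The k-group log-rank covariance can be singular with empty risk sets; a
  Moore–Penrose fallback keeps the statistic defined.
* Greenwood/log-log confidence intervals for survival-at-730-days are a
  convention choice (the source does not state its CI method) and are
  returned as NA at $\hat S \in \{0, 1\}$ where the transform degenerates.
* The stable-disease clock threshold (42 days), evaluability window
  (28 days), benefit clock (168 days) and cutoff are all `pgt_config()`
  parameters with the protocol values as defaults.

# Known limitations

* Per-course PFS treats a patient's multiple courses as independent; no
  clustering correction (matches the source analysis; flagged, not fixed).
* The PERCIST arm is a percent-change operationalization of the published
  figure bands; full SUL arithmetic is out of scope.
* The RANO implementation covers the percent bands only — no T2/FLAIR or
  corticosteroid clauses.
* OS machinery is exercised by the generator and grouping functions, but
  the published OS comparisons are not reproducible at desk scale because
  patient-level survival times are not printed; the acceptance suite
  substitutes oracle-agreement, calibration, and parameter-recovery
  properties for them.
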