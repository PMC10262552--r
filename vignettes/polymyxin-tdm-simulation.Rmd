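---
title: "Simulating TDM-guided polymyxin B dosing: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TDM-guided polymyxin B dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytdm)
```

`polytdm` simulates a therapeutic-drug-monitoring (TDM) strategy for
intravenous polymyxin B in sepsis caused by carbapenem-resistant
Gram-negative bacteria, and provides the statistical toolkit of a
two-arm randomized dosing trial built on that strategy. This vignette is
the package's own account of its models: the assumptions, the tunable
parameters and their defaults, the calibration of the synthetic cohort,
and the design decisions taken where the design was genuinely open.

## Pharmacokinetic model

Disposition is a linear two-compartment model with zero-order
(constant-rate) infusion input. Every dose contributes an independent
closed-form term (superposition), with disposition exponents
$\alpha \ge \beta > 0$ derived from clearance CL, central volume $V_1$,
intercompartmental clearance $Q$ and peripheral volume $V_2$. The model
is evaluated analytically both for concentrations and for AUCs
(term-by-term exponential integration), so AUC is exactly additive over
adjacent windows and total single-dose AUC equals dose/CL (mass
balance). With $Q = 0$ the implementation switches to the
one-compartment closed form, avoiding the $\beta \to 0$ singularity.

A two-compartment structure was chosen because published population
models of polymyxin B in critically ill adults are two-compartment, and
because the limited-sampling strategy below uses a trough plus an early
post-infusion sample — a design that only makes sense when distribution
and elimination phases are distinct.

Defaults (all configurable via `pk_parameters()`): CL = 2 L/h, $V_1$ =
12 L, $Q$ = 8 L/h, $V_2$ = 18 L. These are *illustrative,
literature-typical* values, not estimates from any particular study; no
parameter values are printed in the trial protocol this package
re-implements. The infusion duration is likewise unstated there; the
package default is 1 h. Under q12h dosing these defaults put a 150
mg/day patient at a true steady-state ssAUC₀–₂₄ of ~75 mg·h/L — the
centre of the therapeutic window.

Two covariates act on clearance: serum creatinine, as
$\mathrm{CL} \propto (\mathrm{Scr}/\mathrm{Scr_{ref}})^{-\theta}$
(default $\theta = 0.35$, $\mathrm{Scr_{ref}} = 80$ µmol/L), so that
higher creatinine means lower clearance and higher exposure — the
direction observed clinically; and continuous hemofiltration, as a
multiplicative clearance increase (default ×1.4), because convective
renal replacement removes polymyxin B.

## Limited-sampling AUC estimation

The steady-state 24-h AUC is estimated from a trough (C0h, immediately
before an infusion) and a sample 2 h after the *start* of that infusion
(C2h — with the default 1-h infusion this is 1 h after the end):

$$\widehat{\mathrm{ssAUC}}_{0\text{–}24} = 2\,(-0.673 + 6.084\,C_{0h} + 6.230\,C_{2h}).$$

The coefficients are published constants and are treated as given; the
Bayesian/population workflow that produced them is out of scope. Because
of the negative intercept the estimate can be non-positive at very low
concentrations; such estimates are *flagged* (`valid = FALSE`) rather
than raised as errors, and the titration layer treats them as below
target.

Numerical choices isolated in `classify_auc()`: both window bounds are
inclusive (the protocol maintains the dose once the estimate "reaches"
50–100 mg·h/L; nothing in that wording is strict), and the three
categories partition the real line.

The estimator was derived from a different population model than the
simulator's, so the package asserts only *rank* fidelity (Spearman
correlation > 0.95 between estimated and true 7th-dose ssAUC on
noise-free virtual patients) and reports, without asserting, the mean
relative bias — about +3% at the default parameter set, which sits
deliberately in the concentration regime where the two-sample design is
sensible.

## The titration protocol

* Initial regimens: HD 150 mg loading + 75 mg q12h; LD 100 mg + 50 mg
  q12h. The loading dose is never adjusted.
* Sampling at the 2nd dose (informational) and the 7th dose (steady
  state, day 4 — the decision point). A configuration flag can enable
  early adjustment on the 2nd-dose sample, but the default follows the
  7th-dose-decision reading.
* Below window: +25 mg to the maintenance dose; above: −25 mg; within:
  stop titrating (`on_target`). After each accepted step the
  concentration is rechecked four administrations later; the new dose
  takes effect at the next scheduled administration.
* Dose bounds: "exceeding 50–200 mg/day" is read as *leaving the closed
  interval* — 50 and 200 mg/day themselves are legal. This reading is
  forced by usability: the LD arm must be able to step from 50 mg q12h
  down to 25 mg q12h (= 50 mg/day). An adjustment that would leave the
  interval is not applied and the course stops
  (`stopped_dose_bounds`).
* The adjustment cap defaults to 2 (second adjustments were rare in
  practice). Two terminal statuses beyond the obvious ones were added
  because real courses end these ways: `stopped_max_adjustments` and
  `not_rechecked` (a scheduled recheck that never happens, Bernoulli
  with default probability 0.32 — the observed recheck completion
  fraction 48/150). Dropout (death, discharge, transfer) is an
  exponential off-study process with default hazard 0.05/day, which
  reproduces roughly the observed ~17% loss before the 7th-dose sample.

Under noise-free linear PK each accepted ±25 mg step moves the true
ssAUC strictly toward the window (dose proportionality), which the test
suite asserts over a clearance grid, along with dose-bound safety and
termination over 10,000 random courses.

## Synthetic cohort and outcome models

`generate_cohort()` draws independent virtual patients: sex (74% male),
age truncated-normal in the 18–75 inclusion range, lognormal weight by
sex (male median 70 kg, female 57 kg), septic shock (17%), continuous
renal replacement (12.5%), primary infection site (mostly pulmonary,
with a 21% chance of one additional site), pathogen (CRAB/CRE dominant),
MIC ≤ 2 mg/L by construction, rounded-normal SOFA (median ~7–8), and
lognormal serum creatinine (median 60 µmol/L, shifted ×1.35 in shock —
shock patients run higher creatinine, which is also why their exposures,
and their target-attainment rates, are higher). Between-subject PK
variability is lognormal with $\omega_{CL} = 0.35$ and $\omega = 0.30$
on the volumes and $Q$.

The creatinine *unit* deserves a note: the source table labels Scr
"mg/dL" but prints values (median ≈ 60, IQR ≈ 40–100) that are only
plausible in µmol/L. The package fixes µmol/L repo-wide; KDIGO absolute
thresholds are therefore 26.5 and 353.6 µmol/L.

Outcome models are deliberately simple, because the trial specifies
none; every coefficient lives in `cohort_config()`:

* **AKI** is Bernoulli with probability
  $\mathrm{logit}^{-1}(a + b \log \mathrm{AUC})$. The two coefficients
  are solved by least squares on the logits of the three observed
  category rates (15/107, 35/132, 7/19) at anchor exposures 35, 75 and
  120 mg·h/L. On the *log*-exposure scale those three logits are almost
  exactly collinear, so the fitted curve passes through all three
  anchors to better than 0.001 — a linear-in-AUC logistic cannot do
  this (residuals up to ~0.009), which is why the model is linear in
  log AUC. Given AKI, a KDIGO stage is targeted (62/30/8%), a
  creatinine trajectory consistent with that stage is generated, and
  the recorded stage is *re-derived* from the trajectory through the
  staging rules, so the classifier and generator cannot drift apart.
* **Survival** is Weibull (shape 0.648, scale 108.7 days — matching
  ~34% mortality at day 28 and ~75% at day 180) with multiplicative
  hazards: ×1.6 for septic shock and ×0.85 for in-window exposure. The
  severity effect deliberately exceeds the exposure effect: disease
  severity, not attained AUC, dominates outcome.
* **Response components** among day-14 survivors: SOFA criterion passes
  with probability 0.88, shock resolves with 0.80, P/F improves with
  0.93, blood cultures clear with 0.85. The composite response is then
  *classified*, not drawn, via `classify_response()`.

### What a green test does and does not establish

The generator emulates marginal covariate distributions, an
exposure–AKI gradient, and plausible mortality; it does **not** emulate
covariate correlations beyond the few modelled ones (creatinine–shock,
creatinine–clearance), informative censoring, site-level clustering
across 26 hospitals, assay failure, or any causal exposure–mortality
structure. Passing tests establish that the machinery is faithful to
the protocol and calibrated where calibration was specified — not that
the defaults describe any real population.

## Outcome classifiers

The composite 14-day response requires survival AND the SOFA criterion
(≥ 30% improvement when baseline ≥ 3, inclusive at exactly 30%;
unchanged-or-better when baseline < 3) AND every applicable
syndrome-specific criterion: hemodynamic stability without vasopressors
in baseline shock (MAP > 65 mmHg), improved-or-stable P/F in pneumonia
(day-14 ≥ baseline, no tolerance band by default), and a negative day-14
blood culture in bacteremia. Criteria for absent syndromes are vacuously
true. AND over applicable criteria is the strict reading of the
protocol's list; an OR variant exists behind an explicit flag and is
labelled non-protocol. Microbiological cure applies to bacteremia only.
KDIGO staging uses the creatinine and RRT criteria only — synthetic
courses carry no urine output.

## Trial statistics

Interval methods follow what the printed tables actually contain, which
is subtler than the methods sentence suggests: all relative-risk
intervals are log-Wald; the primary-response risk difference carries a
plain Wald interval; every other printed risk-difference interval
matches the Newcombe hybrid Wilson-score construction. The
table-regeneration layer therefore applies Wald to the primary-response
row and Newcombe elsewhere, and both constructions are exported. The
Pearson chi-square is uncorrected (no Yates continuity correction) —
this reproduces the printed p = 0.005 for the final-attainment row; a
few sparse-cell p-values in the source correspond to the Fisher exact
test instead, which the package also provides.

Sample size uses the classic two-proportion normal approximation with
pooled and unpooled variance terms; for control rate 0.58, RR 1.26,
α = 0.05, power 0.80 it returns 155/arm (total 310). The published total
of 311 implies a rounding convention that cannot be recovered from the
closed form (~154.7/arm); the package documents a ±2 band rather than
tuning to 311. Power is available three ways: closed form, *exact*
enumeration of the joint binomial distribution
(`exact_power_two_proportions()`, the deterministic oracle), and Monte
Carlo (`empirical_power()`). At the realized arm sizes 152/159 the exact
rejection probability is just above 0.80; a 10,000-replication Monte
Carlo estimate has a standard error of ~0.4 percentage points, so the
acceptance suite asserts the deterministic exact value against the 0.80
claim and checks the Monte-Carlo estimator against the exact value
within the same ±1.5-point tolerance the suite uses for its null
calibration check.

Survival machinery (Kaplan–Meier, log-rank, Cox with Efron ties) wraps
the `survival` package behind the module's interface; hand-computed
product-limit and observed-minus-expected oracles in the test suite keep
the wrapping honest. The published 180-day hazard ratio cannot be
recomputed without patient-level data, so the Cox route is validated by
parameter recovery on simulated exponential survival instead.

## Table regeneration and known misprints

`regenerate_paper_tables()` recomputes every printed RR/RD point
estimate (and chi-square p) from the printed counts shipped in
`inst/extdata/trial_table_counts.csv`. Three printed cells are
arithmetically inconsistent with their own counts (a disposition-row RR,
an adverse-event RR, and one risk-difference sign), and three more
differ by one unit in the last printed digit; all are flagged in the
fixture's `misprint` column and asserted against the independent
recomputation instead. The adverse-event table prints its risk ratios in
the low-dose/high-dose direction; the fixture records the direction per
row.

## Randomization and pipeline

Randomization is stratified permuted blocks of size 6 ("A" = high dose),
stratified by age and infection site. The source states no age cutoffs
and no site granularity; the package defaults to two age strata at
< 60 / ≥ 60 years (near the cohort median) and collapses sites to
pulmonary / bloodstream / other to avoid sparse strata — both
configurable. Lost-to-follow-up primary endpoints count as
non-response (intention-to-treat); the per-protocol population is
survivors beyond 72 h. `run_trial()` is reproducible byte-for-byte from
`(config, seed)`, and `write_trial_result()` emits plain-CSV outputs
plus a small JSON manifest.

## Known limitations

* PK is linear; no saturable binding, no polymyxin B1/B2 split (the
  assay sums them), no renal-function dose adjustment (the protocol
  explicitly forbids it).
* Outcome models are marginal and intentionally coarse; they support
  protocol-level questions (attainment, titration behaviour, AKI
  gradient), not causal or prognostic inference.
* The limited-sampling coefficients are treated as exact constants;
  re-deriving them from the simulator's own population model would be a
  different (and circular) exercise.
* Default calibrations were chosen once from the stated inputs and are
  not fitted to reproduce any table beyond the calibrations described
  above.
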