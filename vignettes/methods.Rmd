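---
title: "Methods: a partitioned-survival cost-utility model for maintenance therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned-survival cost-utility model for maintenance therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceamaint)
```

## The decision problem

Patients with newly diagnosed metastatic nasopharyngeal carcinoma who achieve
disease control after platinum-based induction chemotherapy can either stop
active treatment (best supportive care, BSC) or continue with low-dose oral
capecitabine maintenance plus BSC. Maintenance roughly quadruples median
progression-free survival in the underlying trial, at the price of two years
of drug cost and some grade 3–4 toxicity. The question for a payer is whether
the QALY gain is worth the extra cost at a willingness-to-pay (WTP) threshold
of $36,007 per QALY (three times GDP per capita).

This vignette documents the modelling choices, their rationale, and the
limits of what the test suite establishes.

## Survival model and time scale

All survival is modelled in 21-day cycles. Five parametric families are
supported; the reference analysis uses the log-logistic in the form

$$S(t) = \frac{1}{1 + \lambda t^{\gamma}}, \qquad t \text{ in cycles}.$$

The published parameter tables give $(\lambda, \gamma)$ per curve without
stating the time unit or functional form. We adopted the cycle-based unit and
the $1/(1+\lambda t^\gamma)$ form because, with the published control-arm PFS
parameters, the implied median is 14.2 cycles ($\approx$ 9.8 months against
the trial's 8.2) and the treated-arm PFS median is 54.8 cycles
($\approx$ 37.8 months against the trial's 35.9). Month- or week-based units,
or the $(\lambda t)^\gamma$ form, miss these medians by large factors. This
reconstruction is validated *only* against those medians; it is the main
reason absolute cost/QALY totals are not expected to reproduce the source
table (see "What the tests establish").

Fitting uses right-censored maximum likelihood on pseudo individual patient
data (time, event), the standard representation when curves are digitized
from publications. Model choice is by AIC, with BIC and then a conventional
family order as tie-breaks. The optimizer works on log-transformed parameters
(identity for parameters with full real support), Nelder–Mead followed by a
BFGS polish; survival is floored at $10^{-12}$ before any ratio. The
independent cross-check in the test suite fits the same data with
`survival::survreg` and matches log-likelihoods and back-transformed
parameters.

## Cohort engine

The trace is built by the partitioned-survival construction rather than by
separately estimated transition intensities: only PFS and OS curves are
published, and they under-determine the individual PFS→PD and PFS→death
rates. Progressed-disease occupancy is $S_{os} - S_{pfs}$ (both multiplied by
background survival), clamped at zero where the extrapolated curves cross —
under the published parameters the control-arm curves do cross, around cycle
266, and the engine reports the affected cycles. The source text describes
the model as memoryless; per-cycle probabilities derived from log-logistic
curves are necessarily time-varying, and we use the time-varying form.

Background mortality comes from a life table as the annual probability
$q_x$, converted per cycle as $1-(1-q_x)^{21/365.25}$ and applied
multiplicatively to both curves; disease curves are treated as net of
background risk, defensible because the cohort is young relative to
background mortality. The bundled life table is a Gompertz–Makeham synthetic
stand-in ($q_x = 1 - e^{-(a + b e^{cx})}$, $a = 5\times10^{-4}$,
$b = 3\times10^{-5}$, $c = 0.09$, absorbing at 100) approximating modern
East-Asian adult mortality; the national table used by the source lives in an
unavailable supplement.

Key engine settings, all configurable:

| setting | default | why |
|---|---|---|
| cycle length | 21 days | the treatment cycle |
| discount rate | 3%/year (range 0–8%) | guideline value |
| half-cycle correction | on (trapezoid) | transitions mid-cycle on average |
| start age | 45 years | typical mNPC presentation; not stated in source |
| horizon | min(1000 cycles, life-table max age, cohort death > $1-10^{-6}$) | "lifetime" |

The adverse-event sub-state holds a fixed fraction
$1-\prod_i(1-\text{incidence}_i)$ of the progression-free compartment. AEs
carry a one-off expected management cost (incidence × unit cost, charged at
cycle 1) and zero disutility by default — the source costs AEs exactly this
way and publishes no AE durations or disutilities; both are config keys.

## Costs

All amounts are 2022 US$ (already converted upstream; no currency logic).
Recurrence schedules are not stated in the source, so each is an explicit
assumption key:

- **Maintenance drug**: 1000 mg/m² twice daily, days 1–14 of each cycle,
  500 mg tablets rounded up per administration, stopped after 35 cycles
  (the two-year cap) or progression. At the baseline BSA of 1.72 m² this is
  112 tablets/cycle.
- **BSC and laboratory costs**: every cycle, all alive states.
- **Imaging/surveillance**: every 3 cycles ($\approx$ 9-week restaging),
  amortized to cost/3 per cycle so pulsed charges compose cleanly with the
  trapezoidal correction (identical in expectation).
- **Concomitant therapy**: locoregional radiotherapy as a one-off
  proportion-weighted course at entry; bisphosphonates proportion-weighted
  per cycle.
- **Subsequent therapy in PD**: a proportion-weighted per-cycle cost over
  chemotherapy (gemcitabine 1000 mg/m² ×2 + cisplatin 75 mg/m²),
  immunotherapy (camrelizumab 200 mg flat) and a radiotherapy course
  amortized over the cap, charged as a lump of (cap × per-cycle cost) to each
  new PD entrant, discounted at the entry cycle. The default cap is 6 cycles.
  A memoryless cohort cannot represent "first $k$ cycles after progression"
  exactly; the entrant-lump is its expectation-level equivalent and slightly
  overcharges patients who die within the cap. Entrants are estimated by
  attributing cohort deaths preferentially to the PD compartment, which is
  clinically conservative for metastatic disease.
- **Death costs**: named by the source but given no values; default 0.
- **BSA**: the source prints both 1.72 and 1.79 m²; we use 1.72 (the
  parameter-table value), configurable.

Utilities: PFS 0.760, PD 0.350, death 0; QALYs accrue as utility × occupancy
× cycle length in years, discounted and half-cycle corrected identically to
costs. Monetary results are rounded to whole dollars only at the reporting
layer.

## Sensitivity analysis

**One-way**: every distributed parameter varied ±20% (the discount rate over
its 0–8% range), full model re-run at each extreme, parameters ranked by ICUR
spread.

**Probabilistic**: each parameter draws independently from its published
distribution — gamma (shape, rate) for costs and body measures, beta for
proportions, incidences and utilities. Two fidelity decisions:

1. *Rounded gamma rates.* Several published rates are rounded to two
   decimals, which shifts the implied mean off its baseline by up to 49%
   (e.g. the anemia management cost, printed Gamma(96.04, 0.01) against a
   baseline of $6,434). Whenever the printed rate's implied mean deviates
   from the baseline by more than 1%, the fixture keeps the printed shape
   (which fixes the coefficient of variation, $\approx$ 10%) and re-derives
   rate = shape/baseline, recording the printed rate and an `adjusted` flag.
   A load-time audit then enforces mean-vs-baseline agreement within 1%.
2. *Published pseudo-count betas.* Distributions such as Beta(0.528, 0.472)
   have the right mean but extreme, U-shaped spread. They are used exactly as
   printed, for fidelity; an analyst can re-parameterize through the config.
   The discount rate's Beta(0.03, 0.97) has support (0, 1), wider than the
   admissible 0–8%; draws are clamped to that range (bounds stored on the
   PSA entry) rather than excluding a large fraction of draws.

Survival parameters carry no published distributions and are held fixed in
the PSA. The CEAC reports, per WTP value, the fraction of draws with positive
incremental net monetary benefit.

**Subgroups**: only PFS hazard ratios are available, so the treated arm's
subgroup PFS is reconstructed as $S_{control}(t)^{HR}$ — leaving the
parametric family, which is accepted since the HR mechanism is all that is
specified — with OS and all economics unchanged. INHB is monotone
non-increasing in HR, and interval endpoints bracket the point estimate by
construction. The numeric HRs behind the published subgroup figure are not
printed; the fixture carries the trial-level HR 0.44 (0.26–0.74) plus a
clearly-labelled synthetic grid.

## Synthetic data

`simulate_ipd()` draws event times by inverse-CDF from a known model and
censors at the minimum of an administrative cutoff and an exponential
censoring time. The "20% censoring" world used in the recovery tests is
realized by exponential censoring at 0.0016/cycle (calibrated once,
empirically 21% censored). The generator emulates the *size and censoring
structure* of reconstructed trial data; it does not emulate digitization
error, at-risk-table constraints, or covariate structure — so a green
recovery test establishes correctness of the fitting machinery, not the
fidelity of any digitization workflow.

## What the tests establish — and what they do not

The suite verifies closed-form evaluations, telescoping of per-cycle
probabilities back to $S(t)$ ($10^{-12}$), conservation and absorbing-death
invariants, the geometric-series oracle for discounted person-time
($10^{-8}$), dual-route fitting against `survreg`, parameter recovery within
10% median relative error, monotonicity of the economics in utilities, unit
costs, discount rate and hazard ratio, the exact published worked example for
ICUR/ICER/INMB/INHB, the ±20% ranges, the distribution-mean audit, and the
qualitative base-case conclusion (positive ΔQALYs, ICUR below threshold,
CEAC above one half at the threshold).

Absolute per-strategy totals are *not* reproduced: the source
under-specifies the survival time unit and form, start age, horizon
operationalization, cost recurrence, and death costs. Each of those levers is
an exposed configuration key, so closer calibration is possible when those
inputs become available; with the defaults stated here the model lands in the
same decision region (ICUR $\approx$ \$16k/QALY vs the published \$8.4k, both
far below \$36k) with larger absolute increments, driven mainly by the
heavy-tailed treated-arm OS extrapolation ($\gamma$ barely above 1) over a
lifetime horizon.

## Numerical notes

- Survival floored at $10^{-12}$ before ratios; per-cycle event probability
  returns 1 with a warning once survival is exhausted.
- Trace truncation at cohort death $> 1-10^{-6}$.
- AIC ties broken by BIC within $10^{-9}$, then family order.
- All randomness flows through one seed per run; the PSA parameter matrix is
  drawn column-wise before evaluation, so sample sets are reproducible
  bitwise under a fixed seed regardless of per-draw failures.
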