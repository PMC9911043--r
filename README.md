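# ceamaint

Trial-based cost-utility analysis of low-dose maintenance chemotherapy versus
best supportive care (BSC) alone, built as a reusable, tested R pipeline. The
motivating application is oral capecitabine maintenance after induction
chemotherapy in newly diagnosed metastatic nasopharyngeal carcinoma, evaluated
from a payer perspective against a willingness-to-pay (WTP) threshold of
three times GDP per capita ($36,007/QALY).

The package is aimed at health-economics and HTA analysts who need the whole
chain — survival extrapolation, cohort simulation, cost/utility accrual,
incremental economics, and sensitivity analysis — reproducible from a single
configuration file, rather than locked inside a point-and-click decision-tree
tool.

## The model

**States.** A four-state cohort model: progression-free survival without
adverse events (AEs), progression-free survival with AEs, progressed disease
(PD), and death. Cycle length is 21 days (one treatment cycle); the horizon is
lifetime. Costs and effects are discounted at 3%/year and accrued with
trapezoidal half-cycle correction.

**Occupancy** follows the partitioned-survival construction. With
progression-free survival S_pfs(t) and overall survival S_os(t), both
multiplied by background survival B(t) from a life table,

    alive(t) = S_os(t) B(t),   pfs(t) = min(S_pfs(t) B(t), alive(t)),
    pd(t)    = alive(t) − pfs(t),   death(t) = 1 − alive(t).

Survival curves are log-logistic, S(t) = 1 / (1 + λ t^γ) with t in cycles;
the package also fits exponential, Weibull, lognormal and Gompertz laws to
right-censored pseudo individual patient data by maximum likelihood and
selects among them by AIC (BIC as tie-break).

**Economics.** For treated (1) versus control (0) strategies with discounted
totals C (cost), U (QALYs) and E (life-years):

    ICUR = ΔC/ΔU    ICER = ΔC/ΔE
    INMB = ΔU·WTP − ΔC    INHB = ΔU − ΔC/WTP

One-way sensitivity analysis varies each parameter ±20% (tornado ranking by
ICUR spread); probabilistic sensitivity analysis samples beta/gamma
distributions per parameter over Monte Carlo replicates and summarizes them as
a cost-effectiveness acceptability curve (CEAC). Subgroups are modelled by
applying a published PFS hazard ratio to the control-arm curve,
S_control(t)^HR.

## Worked example

```r
library(ceamaint)

cfg  <- baseline_fixture()          # full published parameter set + defaults
base <- run_base_case(cfg)
base$comparison
#> <comparison_result>
#>   delta cost  : $46127
#>   delta QALYs : 2.817
#>   delta LYs   : 4.128
#>   ICUR        : $16373/QALY
#>   ICER        : $11174/LY
#>   INMB        : $55314
#>   INHB        : 1.536 QALYs (WTP $36007/QALY)

psa <- run_psa(cfg, n = 2000, seed = 1)
ceac(psa, 36007)
#>     wtp prob_treated prob_control
#> 1 36007        0.873        0.127
```

Maintenance therapy costs more ($46k extra over the disease course) but adds
2.8 discounted QALYs, so the cost per QALY gained ($16,373) sits well below
the $36,007 threshold, the incremental net monetary benefit is positive, and
87% of probabilistic draws are cost-effective at that threshold — the same
qualitative conclusion as the reference analysis. Absolute totals are
sensitive to levers the source under-specifies (start age, cost recurrence
schedules, horizon); every such lever is an explicit configuration key (see
the methods vignette).

Survival fitting from simulated pseudo-IPD:

```r
truth <- parametric_survival("loglogistic", lambda = 0.0346, gamma = 0.84)
ipd   <- simulate_ipd(simulation_spec(truth, n = 500, censor_rate = 0.0016,
                                      seed = 1))
select_model(fit_all_families(ipd$time, ipd$event))
#> <surv_fit> loglogistic  loglik = -2208.9 ...
```

## Command line

```sh
Rscript inst/cli/ceamaint.R simulate --out fixtures/          # config + IPD
Rscript inst/cli/ceamaint.R run  --config fixtures/config.json --out results/
Rscript inst/cli/ceamaint.R owsa --config fixtures/config.json --out results/
Rscript inst/cli/ceamaint.R psa  --config fixtures/config.json --out results/ \
        --draws 10000 --seed 20220801
Rscript inst/cli/ceamaint.R subgroups --config fixtures/config.json --out results/
```

Each run writes a `manifest.json` (config MD5, seed, package version, files);
identical config + seed give byte-identical CSV/JSON outputs.

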