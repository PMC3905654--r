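# bpdcua

Cost-utility model of atypical antipsychotics in bipolar disorder:
a one-year decision tree (extrapyramidal symptoms, treatment switching,
significant ≥7% weight gain) chained to a time-dependent Markov cohort
model of long-term metabolic complications (diabetes, hypertension,
coronary heart disease, stroke, absorbing death), comparing asenapine
against olanzapine from Ministry-of-Health and societal perspectives.

The package is written for health-economics analysts who want a fully
scriptable, testable implementation of this class of model: every input is
a plain-text parameter (YAML + CSV), every modelling convention is an
explicit option, and an independent individual-level microsimulation
cross-validates the cohort engine.

## The model in brief

Year 1 resolves three events per arm: EPS (probability `p_eps`), a switch
to a third antipsychotic given EPS (`p_switch|eps`), and weight gain
(`p_wg`), independent of EPS. The resulting strata enter a 37-state Markov
model run in yearly cycles: within a cycle, suicide-adjusted background
mortality acts first,

```
q(a, sex, state) = [ q_all(a) − q_suicide(a) + 15.5 · q_suicide(a) ] · Π_c RR_c ,
```

then surviving mass faces at most one incident complication (sequential
competing events), with incidence for weight-gained strata adjusted on the
odds scale, `p' = OR·p/(1−p) / (1 + OR·p/(1−p))`. Incident CHD/stroke
split into fatal and non-fatal parts. QALYs apply the
most-debilitating-complication rule (`u = 0.800 − 0.066·I(wg) − max_c du_c`
in the base case); costs tier CHD/stroke into event-year / later-year /
fatal components, with productivity losses and stroke informal care added
under the societal perspective. Costs and QALYs are discounted at 5%/year
(year 1 undiscounted) and reported per 1,000 patients; the incremental
cost-utility ratio is classified as dominant / dominated / equivalent or
reported as Δcost/ΔQALY.

Because the national life table and the complication-incidence annex
behind the original analysis are not redistributable, the package ships
*synthetic* stand-ins (`inst/extdata/*_synthetic.csv`) generated by
`generate_life_table()` / `generate_epidemiology()`; real tables can be
dropped in as CSVs with the same schema.

## Worked example

```r
library(bpdcua)
p <- base_case_parameters()   # published inputs + synthetic epidemiology
res <- run_model(p)           # both arms, both perspectives, 5 years
print(res)
#> <cua_result> horizon 5 years
#> -- moh perspective --
#>          arm     cost incremental_cost    qaly incremental_qaly     icur
#> 1  asenapine  6380253         -3765065 3449.03          48.0409 dominant
#> 2 olanzapine 10145318               NA 3400.99               NA     <NA>
#> -- societal perspective --
#>          arm     cost incremental_cost    qaly incremental_qaly     icur
#> 1  asenapine  7349599         -3778034 3449.03          48.0409 dominant
#> 2 olanzapine 11127633               NA 3400.99               NA     <NA>
```

Read: per 1,000 patients over five years, asenapine accrues $6.38M in
discounted Ministry-of-Health costs against olanzapine's $10.15M — a
$3.77M saving, driven mostly by the drug-price difference — while gaining
48 discounted QALYs, mostly through less weight gain and fewer downstream
metabolic complications. Lower cost with more QALYs makes asenapine
*dominant*; no ratio is reported for a dominant strategy.

Sensitivity analyses:

```r
dsa <- run_dsa(p)                            # one-way, every bound
all(dsa$label == "dominant")
#> [1] TRUE
psa <- run_psa(p, n_reps = 500, seed = 42)   # Monte Carlo
print(psa)
#> <psa_result> 500 replications (seed 42)
#>   fraction dominant: MoH 0.976, societal 0.976
```

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bpdcua.R", package = "bpdcua"))')" \
  run --horizon 5 --perspective both --out out/
```

## Package layout

| Component | Where |
|---|---|
| Parameter store, bounds, config I/O | `R/params.R`, `inst/extdata/base_case.yaml` |
| Year-1 decision tree | `R/decision_tree.R` |
| Markov cohort engine | `R/markov.R` |
| Accrual, discounting, ICUR | `R/outcomes.R` |
| DSA / PSA / CEAC | `R/sensitivity.R` |
| Microsimulation oracle | `R/microsim.R` |
| Synthetic life table / epidemiology | `R/synthetic.R` |
| Reporting + CLI | `R/report.R`, `inst/cli/bpdcua.R` |

The methods vignette (`vignettes/cost-utility-model.Rmd`) documents the
modelling conventions, the decisions taken where the evidence base is
silent, the PSA distribution calibration, and what the synthetic inputs do
and do not establish.
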