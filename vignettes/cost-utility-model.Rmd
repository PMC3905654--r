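---
title: "A decision-tree/Markov cost-utility model of atypical antipsychotics in bipolar disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree/Markov cost-utility model of atypical antipsychotics in bipolar disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpdcua)
```

## The model

`bpdcua` implements a cost-utility analysis comparing two atypical
antipsychotics — asenapine (intervention) and olanzapine (comparator) — as
monotherapy for bipolar disorder, with the analysis centred on treatment-
induced *metabolic* harm rather than on mood-episode control (the two drugs
are taken as comparably effective). The structure is a one-year decision
tree chained to a time-dependent Markov cohort model:

1. **Year 1 (decision tree).** Three stochastic events: an EPS
   (extrapyramidal symptom) episode with arm-specific probability; a
   treatment switch (to a metabolically neutral third drug) conditional on
   EPS; and significant weight gain, defined as a ≥ 7% increase over
   baseline body weight, with arm-specific probability. Weight gain and EPS
   are treated as independent — nothing in the source evidence links them —
   and switching requires EPS, so six of the eight weight-gain × EPS ×
   switch combinations are reachable. The tree emits the year-1 cost and
   QALY accruals and the stratified cohort entering the Markov model.
2. **Years 2..horizon (Markov cohort).** States are combinations of four
   metabolic complications — diabetes, hypertension, coronary heart disease
   (CHD) and stroke — with CHD and stroke carrying a three-level status
   (none / event year / post-event), plus an absorbing death state:
   2·2·3·3 = 36 alive states + 1. Diabetes and hypertension are chronic
   from onset; CHD and stroke are punctual events with chronic
   consequences and a fatal variant. Complications never remit.

Weight gain is the causal gateway: the weight-gained strata face
complication incidence adjusted by published odds ratios (applied on the
odds scale, `p' = OR·odds(p) back-transformed`; a relative-risk
interpretation is available as `options$or_scale = "rr"` for sensitivity).
Because the intervention causes less weight gain (39.2% vs 55.1%) and costs
less per year, it is expected to dominate, and the analyses here reproduce
that qualitative finding.

### Within-cycle event logic

The evidence base states that at most one complication can occur per
patient per year, but not the mechanism. We resolve a cycle as:

* **Death first.** Annual all-cause mortality is the life-table value with
  the general-population suicide component removed and replaced by the
  bipolar-disorder rate (15.5× the general rate), then multiplied by the
  mortality risk ratio of every complication present. Ratios combine
  multiplicatively across concomitant complications — "all risks included"
  — with `options$mortality_combine = "max"` available as the conservative
  alternative; the product is clipped to [0, 1].
* **Sequential competing complications.** Surviving mass faces candidate
  incidences in a fixed order (diabetes, hypertension, CHD, stroke by
  default; `options$complication_order` permutes it), each candidate
  thinned by the no-prior-event products, which guarantees the
  at-most-one-per-year constraint. At realistic incidences (≤ 3%/year) the
  ordering effect is third-order small; the permutation is exposed
  precisely so a user can verify this.
* **Fatal splits and tier advancement.** Incident CHD/stroke split into a
  fatal part (straight to death, charging the one-time fatal-event cost)
  and a non-fatal part entering the event-year tier; event-year states
  advance to the cheaper post tier in the next cycle. Background mortality
  does not double-count fatal events: fatal CHD/stroke flow only through
  the conditional fatality probabilities.

### Accrual conventions

The state occupied at the *end* of a cycle carries that cycle's cost and
utility: a complication incident in year *t* is charged its event-year cost
and disutility in year *t*. Mass dying in a cycle accrues nothing for that
cycle beyond the fatal-event charge. Costs and QALYs are discounted at 5%
per year with year 1 undiscounted (the standard first-cycle convention for
annual-cycle analyses; the alternative is `options$discount_year1`). No
half-cycle correction is applied, matching the source analysis, which never
mentions one.

Utility in a cycle is the bipolar-disorder baseline (0.800) minus the
permanent weight-gain disutility (0.066) where applicable, minus the
complication disutility under the *most debilitating complication* rule:
only the largest disutility among complications present counts in full,
the others weighted by `w_additional` (0 in the base case; 0.5 and 1.0 are
the sensitivity scenarios). Utilities are floored at zero. EPS contributes
a transient disutility (0.074 for three months) in year 1 only.

Costs under the Ministry-of-Health (MoH) perspective cover drugs, EPS
management (one physician visit) and the direct costs of complications,
tiered for CHD/stroke (event year vs subsequent years vs fatal). The
societal perspective adds per-complication productivity losses and, for
stroke only, informal care. All currency is CAD-2011; no inflation
adjustment is performed.

### Decisions taken where the source is silent

* **Switch timing and cost.** EPS arises early in treatment, but no exact
  timing is given: switchers pay half a year of each drug in year 1 and
  the switch drug thereafter. The switch probability given EPS (0.20) and
  the switch drug's annual cost (set equal to the comparator's) have no
  published values; both are explicit, documented config fields, and
  conclusions that depend on them are tested by property, not by value.
* **Year-1 weight-gain exposure.** The disutility is "permanent" from
  acquisition with no ramp given, so the full first year is counted
  (`options$wg_exposure_y1 = 1`; 0.5 models mid-year acquisition).
* **Entry prevalence.** Patients enter the Markov model already carrying
  complications per their population prevalence, treated as independent
  across complications; prevalent CHD/stroke enter the post tier, since no
  in-model event year was observed.
* **Fatal-event fractions.** The claims-derived fatality proportions are
  unpublished; synthetic defaults of 0.10 (CHD) and 0.15 (stroke) are
  flagged as such in the packaged configuration.

## Parameters

Every input lives in a YAML configuration (schema: the packaged
`base_case.yaml`); `parameter_bounds()` lists each scalar with its
deterministic-sensitivity bounds — published confidence limits where they
exist, otherwise ±25% with probabilities clipped to [0, 1]. Two quirks of
the published table are handled explicitly: disutility bounds are stored as
sorted magnitudes (the EPS row prints low/high in utility space, not
magnitude space), and the additional-disutility weight has scenario values
(0.5, 1.0) that do not bracket its base (0) — it is varied in the DSA and
held fixed in the PSA.

```{r}
p <- base_case_parameters()
head(parameter_bounds(p)[, c("id", "base", "lower", "upper")], 8)
```

## Synthetic external inputs

The life table, suicide mortality and baseline complication epidemiology
used by the original analysis are not redistributable (national life
tables and an unpublished incidence annex). The `generate_life_table()`
and `generate_epidemiology()` generators emulate their statistical
structure — and nothing more:

* **Life table.** Gompertz hazard `q(a) = 1 − exp(−b·e^{ca})` with
  `b = 5×10⁻⁵` (men) / `3.5×10⁻⁵` (women), `c = 0.09`: monotone in age,
  ~0.18%/0.13% annual mortality at 40, under 2% cumulative over five
  years — the right order for a general-population table. Suicide
  mortality is age-flat (1.8×10⁻⁴ men, 5.4×10⁻⁵ women, the order of
  national suicide statistics), so the SMR-style adjustment (subtract,
  re-add ×15.5) has realistic leverage.
* **Epidemiology.** Entry prevalences of 1–15% and annual incidences of
  0.1–3% growing ~3%/year of age, with a small seeded lognormal jitter so
  distinct fixtures are structurally identical but numerically distinct.

What passing tests on these inputs demonstrate is that the *model
machinery* is correct (conservation, competing-event logic, accrual,
dominance direction, engine cross-validation) — not that the package
reproduces the original dollar figures, which depend on the unpublished
inputs. With the synthetic inputs the intervention's QALY gain
(~48/1,000 patients at five years) sits below the published ~85/1,000,
consistent with a lighter synthetic complication burden; the cost saving
(~$3.8M/1,000) is dominated by the drug-price difference and lands close
to the published figure. Users holding the real life table and incidence
annex can drop them in as CSVs — the schemas are identical.

## Sensitivity analyses

`run_dsa()` varies one parameter at a time to each bound (all others at
base) and records the incremental results under both perspectives. On the
packaged inputs, dominance holds at every bound, matching the published
qualitative finding.

`run_psa()` re-samples all Table-type parameters jointly and
independently: beta for probabilities, utilities and disutility
magnitudes; gamma for costs; lognormal for odds ratios, risk ratios and
the suicide multiplier. Distributions are calibrated by moment matching to
the bounds read as 95% intervals (mean = base, sd = span/3.92; lognormals
match the median and log-scale span), which reproduces the printed bounds
as 2.5/97.5% quantiles to within plotting accuracy for the mildly skewed
parameters in play. Structural quantities (entry age, sex mix, discount
rate, horizon, `w_additional`) and the synthetic life table/epidemiology
stay fixed — the published analysis lists only clinical, resource and cost
parameters as sampled — as does the intervention's drug price, whose
uncertainty the source explicitly declines to quantify ("N/A" bounds).
One master seed drives per-replication substreams, so results are
reproducible and independent of evaluation order. The headline PSA output
is the fraction of replications in which the intervention is dominant
(cheaper, more QALYs), plus the CEAC.

```{r, eval = FALSE}
psa <- run_psa(p, n_reps = 10000, seed = 1)
psa$fraction_dominant
plot_ceac(psa)
```

## Validation design

Two independent engines implement the identical event logic:

* the **cohort engine** (`run_model()`): deterministic propagation of
  probability mass through 37-state transition matrices; and
* the **microsimulation oracle** (`simulate_cohort()`): per-patient
  sampling of the same decisions in the same order (death draw, then
  sequential complication draws with fatal sub-draws), sharing parameter
  structures but no numerical machinery.

The acceptance suite requires agreement within three Monte Carlo standard
errors at 50,000 patients on discounted cost (both perspectives) and QALYs,
for five fixtures spanning the base case, a zero-risk annuity case (where
the cohort totals are closed-form: `0.800·Σ_{t=1..5} 1.05^{−(t−1)} =
3.6368` QALYs/person), symmetric arms (all increments exactly zero),
and low/high-incidence stress cases. Test problem sizes (50,000-patient
microsimulations, a 1,000-replication PSA in the acceptance suite,
10,000 replications in the reporting script) were chosen so Monte Carlo
error is far below every tolerance asserted.

## Known limitations

* Adherence, persistence, dose reduction and repeat switching are out of
  scope, as in the source analysis; so are comorbidity interactions
  (complication risks act separately) and remission of complications.
* The competing-event mechanism and the multiplicative mortality
  combination are modelling choices where the source states only the
  constraint; both are config-switchable and their alternatives leave the
  qualitative results unchanged.
* Synthetic epidemiology reproduces structure, not national values; all
  absolute dollar/QALY outputs on the packaged inputs should be read as
  order-of-magnitude faithful only.
* Parameters are sampled independently in the PSA; no correlation
  structure is available to impose.
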