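# Base-case parameterisation: published clinical and cost inputs for the
# asenapine-vs-olanzapine bipolar-disorder cost-utility model, combined with
# synthetic life-table and epidemiology tables (*_synthetic.csv) standing in
# for the national life table and complication-incidence annex, which are
# not redistributable. Currency: CAD-2011. Fields marked "assumption" have
# no published value.
arms:
  asenapine:
    annual_drug_cost: 1030.00
    p_weight_gain_y1: 0.392
    p_eps_y1: 0.107
    p_switch_given_eps: 0.20          # assumption: schizophrenia-trial switch rate, unpublished
    switch_drug_annual_cost: 1871.00  # assumption: aripiprazole priced at the comparator's cost
  olanzapine:
    annual_drug_cost: 1871.00
    p_weight_gain_y1: 0.551
    p_eps_y1: 0.095
    p_switch_given_eps: 0.20          # assumption (as above)
    switch_drug_annual_cost: 1871.00  # assumption (as above)
risks:
  odds_ratio:          # weight gain -> complication incidence, odds scale
    diabetes:     {male: 2.69, female: 1.90}
    hypertension: {male: 1.68, female: 1.56}
    chd:          {male: 1.68, female: 1.25}
    stroke:       {male: 1.02, female: 1.02}
  mortality_rr:        # complication present -> all-cause mortality
    diabetes:     {male: 1.88, female: 1.88}
    hypertension: {male: 1.44, female: 1.34}
    chd:          {male: 2.20, female: 1.60}
    stroke:       {male: 2.37, female: 2.37}
utilities:
  u_bpd: 0.800
  du_weight_gain: 0.066       # permanent from acquisition
  du_eps: 0.074               # transient
  eps_duration_years: 0.25    # three months
  w_additional: 0.0           # weight of non-worst concurrent complication disutilities
  du_complication:            # magnitudes (decrements)
    diabetes:     {male: 0.06, female: 0.05}
    hypertension: {male: 0.02, female: 0.00}
    chd:          {male: 0.07, female: 0.06}
    stroke:       {male: 0.17, female: 0.18}
costs:
  eps_management: 60.00
  direct:
    diabetes: 3834.77
    hypertension: 571.00
    chd_y1: 2481.24
    chd_y2plus: 1146.11
    chd_fatal: 7093.20
    stroke_y1: 4034.86
    stroke_y2plus: 1867.59
    stroke_fatal: 30776.93
  productivity:
    diabetes: 528.00
    hypertension: 119.00
    chd: 3109.00
    stroke: 4322.00
  informal_care_stroke: 3770.00
epidemiology:
  p_fatal_given_chd_event: 0.10     # synthetic default (claims-derived value unpublished)
  p_fatal_given_stroke_event: 0.15  # synthetic default (claims-derived value unpublished)
  prevalence_csv: prevalence_synthetic.csv
  incidence_csv: incidence_synthetic.csv
mortality:
  bpd_suicide_multiplier: 15.50
  life_table_csv: life_table_synthetic.csv
  suicide_csv: suicide_synthetic.csv
run:
  horizon_years: 5
  discount_rate: 0.05
  entry_age: 40
  sex_mix: 0.50            # assumption: even split, varied in sensitivity analyses
  cohort_size_report: 1000
options:
  wg_exposure_y1: 1.0      # weight-gain disutility counts for the full first year
  or_scale: odds
  mortality_combine: multiplicative
  complication_order: [diabetes, hypertension, chd, stroke]
  discount_year1: false    # year 1 undiscounted (factor 1)
bounds:
  # published confidence limits; parameters absent here use base x 0.75/1.25
  arms.asenapine.p_weight_gain_y1: [0.294, 0.490]
  arms.olanzapine.p_weight_gain_y1: [0.413, 0.689]
  arms.asenapine.p_eps_y1: [0.072, 0.149]
  arms.olanzapine.p_eps_y1: [0.068, 0.131]
  arms.olanzapine.annual_drug_cost: [1316.00, 2426.00]
  risks.odds_ratio.diabetes.male: [2.17, 3.34]
  risks.odds_ratio.diabetes.female: [1.50, 2.30]
  risks.odds_ratio.hypertension.male: [1.45, 1.94]
  risks.odds_ratio.hypertension.female: [1.48, 1.64]
  risks.odds_ratio.chd.male: [1.13, 2.50]
  risks.odds_ratio.chd.female: [1.01, 1.55]
  risks.odds_ratio.stroke.male: [1.01, 1.03]
  risks.odds_ratio.stroke.female: [1.01, 1.03]
  risks.mortality_rr.diabetes.male: [1.55, 2.27]
  risks.mortality_rr.diabetes.female: [1.55, 2.27]
  risks.mortality_rr.hypertension.male: [1.00, 2.88]
  risks.mortality_rr.hypertension.female: [1.00, 2.68]
  risks.mortality_rr.chd.male: [2.00, 2.40]
  risks.mortality_rr.chd.female: [1.20, 2.10]
  risks.mortality_rr.stroke.male: [2.11, 2.64]
  risks.mortality_rr.stroke.female: [2.07, 2.70]
  utilities.u_bpd: [0.580, 1.000]
  utilities.du_weight_gain: [0.050, 0.083]
  utilities.du_eps: [0.053, 0.090]    # printed low/high swapped once stored as magnitudes
  utilities.w_additional: [0.5, 1.0]  # scenario values; base 0 lies outside
  utilities.du_complication.diabetes.male: [0.03, 0.08]
  utilities.du_complication.diabetes.female: [0.03, 0.08]
  utilities.du_complication.hypertension.male: [0.00, 0.03]
  utilities.du_complication.hypertension.female: [0.00, 0.02]
  utilities.du_complication.chd.male: [0.05, 0.09]
  utilities.du_complication.chd.female: [0.03, 0.08]
  utilities.du_complication.stroke.male: [0.12, 0.23]
  utilities.du_complication.stroke.female: [0.10, 0.25]
  costs.eps_management: [0.00, null]
  costs.direct.diabetes: [1215.00, 17072.00]
  costs.direct.hypertension: [233.00, 827.00]
  costs.direct.chd_fatal: [775.00, 52617.00]
  costs.direct.chd_y1: [818.00, 8819.00]
  costs.direct.chd_y2plus: [360.00, 5795.00]
  costs.direct.stroke_fatal: [7362.00, 34165.00]
  costs.direct.stroke_y1: [1395.00, 10560.00]
  costs.direct.stroke_y2plus: [452.00, 8692.00]
  costs.productivity.diabetes: [396.00, 660.00]
  costs.productivity.hypertension: [89.25, 148.75]
  costs.productivity.chd: [2331.75, 3886.25]
  costs.productivity.stroke: [3241.50, 5402.50]
  costs.informal_care_stroke: [2827.50, 4712.50]
  mortality.bpd_suicide_multiplier: [12.25, 18.44]
  run.entry_age: [20, null]
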