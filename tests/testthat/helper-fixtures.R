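# Hand-buildable parameterisation with flat (age-constant) tables, so that
# transition arithmetic can be checked against pencil-and-paper values.
make_toy_params <- function(life = 0.003, suicide = 0.0002, multiplier = 15.5,
                            inc = c(diabetes = 0, hypertension = 0,
                                    chd = 0, stroke = 0),
                            prev = c(diabetes = 0, hypertension = 0,
                                     chd = 0, stroke = 0),
                            or = 1, mortality_rr = 1,
                            p_fatal_chd = 0, p_fatal_stroke = 0,
                            p_wg = 0, p_eps = 0, p_switch = 0.2,
                            horizon = 5, discount = 0.05, ages = 18:62) {
  # named complication vector -> nested {complication: {male, female}} list
  cs <- function(v) {
    if (length(v) == 1) v <- stats::setNames(rep(v, 4), names(inc))
    lapply(stats::setNames(names(v), names(v)),
           function(cc) list(male = v[[cc]], female = v[[cc]]))
  }
  long <- function(val) {
    do.call(rbind, lapply(c("male", "female"), function(s) {
      data.frame(sex = s, age = ages, value = val)
    }))
  }
  inc_df <- do.call(rbind, lapply(names(inc), function(cc) {
    do.call(rbind, lapply(c("male", "female"), function(s) {
      data.frame(sex = s, age = ages, complication = cc, value = inc[[cc]])
    }))
  }))
  prev_df <- expand.grid(complication = names(prev), sex = c("male", "female"),
                         stringsAsFactors = FALSE)
  prev_df$value <- prev[prev_df$complication]

  arm <- list(annual_drug_cost = 1000, p_weight_gain_y1 = p_wg,
              p_eps_y1 = p_eps, p_switch_given_eps = p_switch,
              switch_drug_annual_cost = 1500)
  cfg <- list(
    arms = list(asenapine = arm, olanzapine = arm),
    risks = list(odds_ratio = cs(or),
                 mortality_rr = cs(mortality_rr)),
    utilities = list(u_bpd = 0.8, du_weight_gain = 0.066, du_eps = 0.074,
                     eps_duration_years = 0.25, w_additional = 0,
                     du_complication = cs(c(diabetes = 0.06, hypertension = 0.02,
                                            chd = 0.07, stroke = 0.17))),
    costs = list(eps_management = 60,
                 direct = list(diabetes = 100, hypertension = 50,
                               chd_y1 = 200, chd_y2plus = 120, chd_fatal = 700,
                               stroke_y1 = 400, stroke_y2plus = 180,
                               stroke_fatal = 3000),
                 productivity = list(diabetes = 10, hypertension = 5,
                                     chd = 30, stroke = 40),
                 informal_care_stroke = 35),
    epidemiology = list(p_fatal_given_chd_event = p_fatal_chd,
                        p_fatal_given_stroke_event = p_fatal_stroke,
                        prevalence = prev_df, incidence = inc_df),
    mortality = list(bpd_suicide_multiplier = multiplier,
                     life_table = long(life), suicide = long(suicide)),
    run = list(horizon_years = horizon, discount_rate = discount,
               entry_age = 40, sex_mix = 0.5, cohort_size_report = 1000),
    options = list(),
    bounds = list()
  )
  as_cua_params(cfg)
}

# alive-state lookup in the canonical ordering
toy_state <- function(diab = FALSE, htn = FALSE, chd = "none", stroke = "none",
                      dead = FALSE) {
  list(has_diabetes = diab, has_hypertension = htn, chd_status = chd,
       stroke_status = stroke, dead = dead)
}

total_cohort_mass <- function(cohort) sum(cohort$mass)
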