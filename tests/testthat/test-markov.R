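test_that("state space enumerates 36 alive combinations plus death", {
  st <- enumerate_states()
  expect_equal(nrow(st), 37)
  expect_equal(sum(st$dead), 1)
  expect_true(any(!st$has_diabetes & !st$has_hypertension &
                    st$chd_status == "none" & st$stroke_status == "none" &
                    !st$dead))
  expect_true(any(st$has_diabetes & st$has_hypertension &
                    st$chd_status == "post" & st$stroke_status == "post"))
  # combinations are unique
  expect_equal(nrow(unique(st)), 37)
})

test_that("odds ratios act on the odds scale", {
  expect_equal(adjusted_probability(0.10, 1.0), 0.10)
  expect_equal(adjusted_probability(0.0, 5.0), 0.0)
  odds <- 2.69 * 0.1 / 0.9
  expect_equal(adjusted_probability(0.10, 2.69), odds / (1 + odds))
  expect_equal(adjusted_probability(0.10, 2.69), 0.2301112, tolerance = 1e-6)
  expect_error(adjusted_probability(1.0, 2.0), "odds")
  # relative-risk sensitivity option
  expect_equal(adjusted_probability(0.10, 2.69, scale = "rr"), 0.269)
})

test_that("mortality combines suicide re-weighting and complication risks", {
  p <- make_toy_params(life = 0.0030, suicide = 0.0002, multiplier = 15.5,
                       mortality_rr = c(diabetes = 1.88, hypertension = 1,
                                        chd = 1, stroke = 1))
  none <- toy_state()
  # 0.0030 - 0.0002 + 15.5 * 0.0002 = 0.0059
  expect_equal(adjusted_mortality(p$mortality, none, "male", 45, p$risks),
               0.0059)
  diab <- toy_state(diab = TRUE)
  expect_equal(adjusted_mortality(p$mortality, diab, "male", 45, p$risks),
               0.0059 * 1.88)
  expect_equal(0.0059 * 1.88, 0.011092)

  # multiplier 1 recovers the life table exactly
  p1 <- make_toy_params(life = 0.0030, suicide = 0.0002, multiplier = 1)
  expect_equal(adjusted_mortality(p1$mortality, none, "female", 50, p1$risks),
               0.0030)
  # concomitant complications multiply; "max" option takes the largest
  p2 <- make_toy_params(mortality_rr = c(diabetes = 1.88, hypertension = 1.44,
                                         chd = 2.2, stroke = 2.37))
  both <- toy_state(diab = TRUE, htn = TRUE)
  q0 <- adjusted_mortality(p2$mortality, toy_state(), "male", 45, p2$risks)
  expect_equal(adjusted_mortality(p2$mortality, both, "male", 45, p2$risks),
               q0 * 1.88 * 1.44)
  expect_equal(adjusted_mortality(p2$mortality, both, "male", 45, p2$risks,
                                  combine = "max"), q0 * 1.88)
  expect_error(adjusted_mortality(p$mortality, none, "male", 200, p$risks),
               "life-table")
})

test_that("transition rows follow the death-first sequential event rule", {
  zero <- make_toy_params(life = 0, suicide = 0, multiplier = 1)
  row <- build_transitions(toy_state(), FALSE, "male", 45, zero)
  expect_equal(sum(row), 1)
  expect_equal(unname(row[1]), 1) # identity when nothing can happen

  # only diabetes at 0.05, death at 0.01: death resolved first
  p <- make_toy_params(life = 0.01, suicide = 0, multiplier = 1,
                       inc = c(diabetes = 0.05, hypertension = 0,
                               chd = 0, stroke = 0))
  row <- build_transitions(toy_state(), FALSE, "male", 45, p)
  st <- enumerate_states()
  i_diab <- which(st$has_diabetes & !st$has_hypertension &
                    st$chd_status == "none" & st$stroke_status == "none")
  expect_equal(unname(row[i_diab]), 0.05 * 0.99)
  expect_equal(unname(row[37]), 0.01)
  expect_equal(unname(row[1]), 0.99 * 0.95)

  # two candidates 0.03/0.04, no mortality: second thinned by the first
  p2 <- make_toy_params(life = 0, suicide = 0, multiplier = 1,
                        inc = c(diabetes = 0.03, hypertension = 0.04,
                                chd = 0, stroke = 0))
  row2 <- build_transitions(toy_state(), FALSE, "male", 45, p2)
  i_htn <- which(!st$has_diabetes & st$has_hypertension &
                   st$chd_status == "none" & st$stroke_status == "none")
  expect_equal(unname(row2[i_diab]), 0.03)
  expect_equal(unname(row2[i_htn]), 0.04 * 0.97)
  expect_equal(unname(row2[1]), 0.97 * 0.96)
  expect_equal(sum(row2), 1)

  # incident stroke splits into fatal and event-year parts
  p3 <- make_toy_params(life = 0, suicide = 0, multiplier = 1,
                        inc = c(diabetes = 0, hypertension = 0,
                                chd = 0, stroke = 0.1),
                        p_fatal_stroke = 0.15)
  row3 <- build_transitions(toy_state(), FALSE, "female", 45, p3)
  i_ev <- which(!st$has_diabetes & !st$has_hypertension &
                  st$chd_status == "none" & st$stroke_status == "event_year")
  expect_equal(unname(row3[i_ev]), 0.1 * 0.85)
  expect_equal(unname(row3[37]), 0.1 * 0.15)
  expect_equal(attr(row3, "fatal_stroke"), 0.015)

  # event-year states advance to post; existing complications cannot recur
  row4 <- build_transitions(toy_state(stroke = "event_year"), FALSE,
                            "female", 45, p3)
  i_post <- which(!st$has_diabetes & !st$has_hypertension &
                    st$chd_status == "none" & st$stroke_status == "post")
  expect_equal(unname(row4[i_post]), 1)
  # dead is absorbing
  row5 <- build_transitions(toy_state(dead = TRUE), FALSE, "male", 45, p3)
  expect_equal(unname(row5[37]), 1)
})

test_that("initial cohort follows the entry-prevalence product measure", {
  p <- make_toy_params(prev = c(diabetes = 0.05, hypertension = 0.10,
                                chd = 0, stroke = 0))
  sd <- run_year_one(p$arms$asenapine, p$utilities, p$costs, p$options)
  cohort <- initialize_cohort(sd, p$epidemiology, p$run)
  expect_equal(total_cohort_mass(cohort), 1, tolerance = 1e-12)

  st <- enumerate_states()
  pick <- function(d, h) {
    which(st$has_diabetes == d & st$has_hypertension == h &
            st$chd_status == "none" & st$stroke_status == "none" & !st$dead)
  }
  mass_at <- function(i) sum(cohort$mass[i, , ])
  expect_equal(mass_at(pick(TRUE, TRUE)), 0.05 * 0.10)
  expect_equal(mass_at(pick(TRUE, FALSE)), 0.05 * 0.90)
  expect_equal(mass_at(pick(FALSE, FALSE)), 0.95 * 0.90)

  # prevalent CHD/stroke enter the post tier, never the event year
  p2 <- make_toy_params(prev = c(diabetes = 0, hypertension = 0,
                                 chd = 0.08, stroke = 0))
  cohort2 <- initialize_cohort(run_year_one(p2$arms$asenapine, p2$utilities,
                                            p2$costs, p2$options),
                               p2$epidemiology, p2$run)
  ev <- which(st$chd_status == "event_year")
  post <- which(st$chd_status == "post" & !st$has_diabetes &
                  !st$has_hypertension & st$stroke_status == "none")
  expect_equal(sum(cohort2$mass[ev, , ]), 0)
  expect_equal(sum(cohort2$mass[post, , ]), 0.08)
})

test_that("cohort advancement conserves mass and never loses complications", {
  p <- base_case_parameters()
  sd <- run_year_one(p$arms$olanzapine, p$utilities, p$costs, p$options)
  cohort <- initialize_cohort(sd, p$epidemiology, p$run)
  st <- enumerate_states()
  flagged <- which(st$has_diabetes[1:36])
  prev_diab <- 0
  prev_dead <- 0
  for (t in 2:10) {
    step <- advance(cohort, p)
    cohort <- step$cohort
    expect_equal(total_cohort_mass(cohort), 1, tolerance = 1e-10)
    expect_true(all(cohort$mass >= -1e-15))
    dead <- sum(cohort$mass[37, , ])
    diab <- sum(cohort$mass[flagged, , ])
    expect_gte(dead, prev_dead)              # death absorbing
    expect_gte(diab + dead, prev_diab - 1e-12) # flags cannot be lost
    prev_dead <- dead
    prev_diab <- diab + dead
  }
})

test_that("weight-gain strata dominate non-gained strata; equal under OR = 1", {
  p <- base_case_parameters()
  sd <- run_year_one(p$arms$olanzapine, p$utilities, p$costs, p$options)
  cohort <- initialize_cohort(sd, p$epidemiology, p$run)
  strata <- cohort$strata
  k_wg <- which(strata$weight_gained & !strata$had_eps)
  k_no <- which(!strata$weight_gained & !strata$had_eps)
  st <- enumerate_states()
  any_comp <- which(st$has_diabetes | st$has_hypertension |
                      st$chd_status != "none" | st$stroke_status != "none")
  any_comp <- setdiff(any_comp, 37)
  for (t in 2:6) {
    cohort <- advance(cohort, p)$cohort
    frac_wg <- sum(cohort$mass[any_comp, k_wg, ]) / sum(cohort$mass[1:36, k_wg, ])
    frac_no <- sum(cohort$mass[any_comp, k_no, ]) / sum(cohort$mass[1:36, k_no, ])
    expect_gte(frac_wg, frac_no)
  }

  p1 <- p
  p1$risks$odds_ratio[] <- 1
  cohort <- initialize_cohort(sd, p1$epidemiology, p1$run)
  for (t in 2:4) cohort <- advance(cohort, p1)$cohort
  a <- cohort$mass[, k_wg, ] / sum(strata$mass[k_wg])
  b <- cohort$mass[, k_no, ] / sum(strata$mass[k_no])
  expect_equal(a, b, tolerance = 1e-12)
})
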