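test_that("cycle utility applies the most-debilitating-complication rule", {
  p <- base_case_parameters()
  u <- p$utilities
  none <- toy_state()
  expect_equal(cycle_utility(none, list(weight_gained = FALSE), u, "male"), 0.800)

  both <- toy_state(diab = TRUE, stroke = "post")
  # w = 0: only the worst (stroke, 0.17) counts
  expect_equal(cycle_utility(both, list(weight_gained = FALSE), u, "male"),
               0.800 - 0.17)
  u1 <- u
  u1$w_additional <- 1
  expect_equal(cycle_utility(both, list(weight_gained = FALSE), u1, "male"),
               0.800 - 0.17 - 0.06)
  u5 <- u
  u5$w_additional <- 0.5
  expect_equal(cycle_utility(both, list(weight_gained = FALSE), u5, "male"),
               0.800 - 0.17 - 0.5 * 0.06)
  # weight gain subtracts on top; dead contributes nothing
  expect_equal(cycle_utility(both, list(weight_gained = TRUE), u, "male"),
               0.800 - 0.066 - 0.17)
  expect_equal(cycle_utility(toy_state(dead = TRUE),
                             list(weight_gained = TRUE), u, "male"), 0)
  # never negative
  u2 <- u
  u2$du_complication["stroke", "male"] <- 0.9
  expect_equal(cycle_utility(both, list(weight_gained = FALSE), u2, "male"), 0)
})

test_that("cycle costs tier complications and add societal components", {
  p <- base_case_parameters()
  arm <- p$arms$asenapine
  none <- toy_state()
  expect_equal(cycle_cost(none, list(switched = FALSE), arm, p$costs, "moh"),
               1030)
  expect_equal(cycle_cost(none, list(switched = TRUE), arm, p$costs, "moh"),
               1871)

  post_stroke <- toy_state(stroke = "post")
  expect_equal(cycle_cost(post_stroke, list(switched = FALSE), arm, p$costs,
                          "moh"), 1030 + 1867.59)
  expect_equal(cycle_cost(post_stroke, list(switched = FALSE), arm, p$costs,
                          "societal"), 1030 + 1867.59 + 4322.00 + 3770.00)
  ev_chd <- toy_state(chd = "event_year", htn = TRUE)
  expect_equal(cycle_cost(ev_chd, list(switched = FALSE), arm, p$costs, "moh"),
               1030 + 2481.24 + 571.00)
  expect_equal(cycle_cost(toy_state(dead = TRUE), list(switched = FALSE),
                          arm, p$costs, "societal"), 0)
})

test_that("fatal events charge their one-time cost in the cycle of death", {
  # certain stroke in year 2, always fatal: the cohort pays exactly the
  # fatal-stroke cost discounted one year, and accrues no year-2 QALY
  p <- make_toy_params(life = 0, suicide = 0, multiplier = 1,
                       inc = c(diabetes = 0, hypertension = 0, chd = 0,
                               stroke = 1 - 1e-12),
                       p_fatal_stroke = 1, horizon = 2)
  res <- run_model(p)
  o <- res$arms$asenapine$moh
  drug <- p$arms$asenapine$annual_drug_cost
  expect_equal(o$total_cost / 1000, drug + 3000 / 1.05, tolerance = 1e-6)
  expect_equal(o$total_qaly / 1000, 0.8, tolerance = 1e-6)
})

test_that("discounting follows the year-1-undiscounted convention", {
  expect_equal(discount(100, 1, 0.05), 100)
  expect_equal(discount(100, 2, 0.05), 100 / 1.05)
  expect_equal(discount(100, 2, 0.05), 95.2381, tolerance = 1e-6)
  expect_equal(discount(100, 3, 0), 100)
  expect_error(discount(100, 0, 0.05))
})

test_that("zero-risk cohort reduces to a closed-form annuity", {
  fx <- make_fixture_suite()
  zero <- fx$zero_risk
  res <- run_model(zero)
  annuity <- sum(1 / 1.05^(0:4)) # 4.5459505
  for (pp in c("moh", "societal")) {
    expect_equal(res$arms$asenapine[[pp]]$total_qaly / 1000, 0.8 * annuity,
                 tolerance = 1e-12)
    expect_equal(res$arms$asenapine[[pp]]$total_cost / 1000, 1030 * annuity,
                 tolerance = 1e-12)
    expect_equal(res$arms$olanzapine[[pp]]$total_cost / 1000, 1871 * annuity,
                 tolerance = 1e-12)
  }
  # horizon 1 degenerates to the decision tree
  sd <- run_year_one(zero$arms$asenapine, zero$utilities, zero$costs,
                     zero$options)
  res1 <- run_model(zero, horizon = 1)
  expect_equal(res1$arms$asenapine$moh$total_cost / 1000, sd$year1_cost)
  expect_equal(res1$arms$asenapine$moh$total_qaly / 1000, sd$year1_qaly)
})

test_that("totals equal per-cycle sums; discounting and perspectives order", {
  p <- base_case_parameters()
  res <- run_model(p)
  for (a in names(res$arms)) {
    for (pp in c("moh", "societal")) {
      o <- res$arms[[a]][[pp]]
      expect_equal(o$total_cost, sum(o$per_cycle$dcost))
      expect_equal(o$total_qaly, sum(o$per_cycle$dqaly))
      expect_true(all(o$per_cycle$dcost <= o$per_cycle$cost + 1e-9))
      expect_lte(o$total_qaly / 1000, p$utilities$u_bpd * res$horizon)
    }
    expect_gte(res$arms[[a]]$societal$total_cost, res$arms[[a]]$moh$total_cost)
  }
  p0 <- p
  p0$run$discount_rate <- 0
  res0 <- run_model(p0)
  expect_gte(res0$arms$asenapine$moh$total_cost,
             res$arms$asenapine$moh$total_cost)
  expect_gte(res0$arms$asenapine$moh$total_qaly,
             res$arms$asenapine$moh$total_qaly)
})

test_that("ICUR classification covers dominance, equivalence and ratios", {
  mk <- function(cost, qaly) {
    structure(list(arm = "x", perspective = "moh", horizon = 5,
                   total_cost = cost, total_qaly = qaly),
              class = "arm_outcome")
  }
  # published 5-year base-case magnitudes
  ic <- compute_icur(mk(5881858, 3386), mk(9729158, 3301))
  expect_equal(ic$delta_cost, -3847300)
  expect_equal(ic$delta_qaly, 85)
  expect_equal(ic$label, "dominant")

  expect_equal(compute_icur(mk(100, 1), mk(0, 0))$label, "ratio")
  expect_equal(compute_icur(mk(100, 1), mk(0, 0))$icur, 100)
  expect_equal(compute_icur(mk(5, 5), mk(5, 5))$label, "equivalent")
  expect_equal(compute_icur(mk(10, 1), mk(0, 2))$label, "dominated")

  bad <- mk(1, 1)
  bad$perspective <- "societal"
  expect_error(compute_icur(mk(1, 1), bad), "perspective")
})

test_that("identical arms produce exactly zero incremental results", {
  fx <- make_fixture_suite()
  res <- run_model(fx$symmetric_arms)
  for (pp in c("moh", "societal")) {
    expect_identical(res$icur[[pp]]$delta_cost, 0)
    expect_identical(res$icur[[pp]]$delta_qaly, 0)
    expect_equal(res$icur[[pp]]$label, "equivalent")
  }
})
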