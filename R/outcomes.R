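# Cost/QALY accrual, discounting, arm totals and ICUR classification.
#
# Accrual convention: the state occupied at the end of a cycle (i.e. after
# that year's events, with incident CHD/stroke in their event-year tier)
# carries that year's cost and utility. Mass dying during a cycle accrues
# nothing for that cycle beyond the one-time fatal-event cost. Year 1 is
# undiscounted (factor 1) by default.

#' Utility of a health state for one cycle
#'
#' Baseline bipolar-disorder utility minus the permanent weight-gain
#' disutility (if the stratum gained weight), minus the complication
#' disutility under the most-debilitating rule: only the largest disutility
#' among complications present counts in full, the others are weighted by
#' `w_additional` (0 in the base case). Floored at 0; the dead state
#' contributes 0.
#'
#' @param state One row of [enumerate_states()].
#' @param stratum List or row with a `weight_gained` flag.
#' @param utils The `utilities` block of a `cua_params` object.
#' @param sex `"male"` or `"female"`.
#' @return Utility value in \[0, 1\].
#' @export
cycle_utility <- function(state, stratum, utils, sex) {
  if (isTRUE(state$dead)) return(0)
  present <- c(
    diabetes = isTRUE(state$has_diabetes),
    hypertension = isTRUE(state$has_hypertension),
    chd = state$chd_status != "none",
    stroke = state$stroke_status != "none"
  )
  du <- utils$du_complication[names(present)[present], sex]
  comp <- if (length(du)) max(du) + utils$w_additional * (sum(du) - max(du)) else 0
  u <- utils$u_bpd -
    utils$du_weight_gain * isTRUE(stratum$weight_gained) - comp
  max(u, 0)
}

#' Annual cost of occupying a health state
#'
#' Drug cost for the stratum's current drug (the switch drug for switched
#' strata) plus the tier-appropriate direct cost of every complication
#' present (event-year vs subsequent-year tiers for CHD and stroke). Under
#' the societal perspective, adds per-complication productivity losses and
#' informal care for stroke. Fatal-event costs are not part of this
#' occupancy cost; they are charged once on the fatal transition.
#'
#' @param state One row of [enumerate_states()].
#' @param stratum List or row with a `switched` flag.
#' @param arm One element of `params$arms`.
#' @param costs The `costs` block of a `cua_params` object.
#' @param perspective `"moh"` or `"societal"`.
#' @return Annual cost (CAD-2011).
#' @export
cycle_cost <- function(state, stratum, arm, costs, perspective = "moh") {
  if (isTRUE(state$dead)) return(0)
  drug <- if (isTRUE(stratum$switched)) arm$switch_drug_annual_cost else arm$annual_drug_cost
  d <- costs$direct
  total <- drug
  if (isTRUE(state$has_diabetes)) total <- total + d$diabetes
  if (isTRUE(state$has_hypertension)) total <- total + d$hypertension
  if (state$chd_status == "event_year") total <- total + d$chd_y1
  if (state$chd_status == "post") total <- total + d$chd_y2plus
  if (state$stroke_status == "event_year") total <- total + d$stroke_y1
  if (state$stroke_status == "post") total <- total + d$stroke_y2plus
  if (identical(perspective, "societal")) {
    pr <- costs$productivity
    if (isTRUE(state$has_diabetes)) total <- total + pr$diabetes
    if (isTRUE(state$has_hypertension)) total <- total + pr$hypertension
    if (state$chd_status != "none") total <- total + pr$chd
    if (state$stroke_status != "none") {
      total <- total + pr$stroke + costs$informal_care_stroke
    }
  }
  total
}

#' Discount an amount accrued in a given model year
#'
#' Year 1 is undiscounted; year `t` is divided by `(1 + rate)^(t - 1)`.
#'
#' @param amount Numeric amount.
#' @param year_index Model year (1-based).
#' @param rate Annual discount rate (e.g. 0.05).
#' @return Discounted amount.
#' @export
#' @examples
#' discount(100, 2, 0.05) # 95.2381
discount <- function(amount, year_index, rate) {
  stopifnot(year_index >= 1)
  amount / (1 + rate)^(year_index - 1)
}

# 36-vector of per-state utilities for a (weight-gain, sex) combination
utility_vector <- function(params, wg, sex) {
  geo <- state_geometry()
  u <- params$utilities
  du <- u$du_complication[, sex]
  dumat <- geo$present * rep(du, each = 36)
  maxdu <- apply(dumat, 1, max)
  extra <- rowSums(dumat) - maxdu
  pmax(u$u_bpd - u$du_weight_gain * wg - (maxdu + u$w_additional * extra), 0)
}

# 36-vector of per-state annual costs for (arm, switched, perspective)
cost_vector <- function(params, arm, switched, perspective) {
  geo <- state_geometry()
  d <- params$costs$direct
  drug <- if (switched) arm$switch_drug_annual_cost else arm$annual_drug_cost
  total <- rep(drug, 36) +
    geo$present[, "diabetes"] * d$diabetes +
    geo$present[, "hypertension"] * d$hypertension +
    (geo$c == STATUS_EVENT) * d$chd_y1 + (geo$c == STATUS_POST) * d$chd_y2plus +
    (geo$s == STATUS_EVENT) * d$stroke_y1 + (geo$s == STATUS_POST) * d$stroke_y2plus
  if (identical(perspective, "societal")) {
    pr <- params$costs$productivity
    total <- total +
      geo$present[, "diabetes"] * pr$diabetes +
      geo$present[, "hypertension"] * pr$hypertension +
      geo$present[, "chd"] * pr$chd +
      geo$present[, "stroke"] * (pr$stroke + params$costs$informal_care_stroke)
  }
  total
}

#' Run the full model for both arms and both perspectives
#'
#' Chains the year-1 decision tree with the Markov cohort model over years
#' 2..horizon, accruing discounted costs and QALYs under the
#' Ministry-of-Health and societal perspectives for each arm. Transition
#' matrices are shared across arms (they depend only on weight-gain status,
#' sex and age), so this is the fast path used by the sensitivity analyses.
#'
#' @param params A `cua_params` object.
#' @param horizon Optional horizon override (years); defaults to
#'   `params$run$horizon_years`.
#' @return A `cua_result`: list with `horizon`, `arms` (per arm, per
#'   perspective, an `arm_outcome`), and `icur` (per perspective, the
#'   first-vs-second-arm [compute_icur()] result).
#' @export
#' @examples
#' res <- run_model(base_case_parameters())
#' res$icur$moh$label
run_model <- function(params, horizon = NULL) {
  spec <- params$run
  if (!is.null(horizon)) spec$horizon_years <- horizon
  h <- spec$horizon_years
  r <- spec$discount_rate
  scale <- spec$cohort_size_report
  arm_names <- names(params$arms)

  uvec <- list()
  for (ss in SEXES) {
    for (wg in c(FALSE, TRUE)) {
      uvec[[paste(wg, ss)]] <- utility_vector(params, wg, ss)
    }
  }

  state <- list()
  for (a in arm_names) {
    sd <- run_year_one(params$arms[[a]], params$utilities, params$costs,
                       params$options)
    cohort <- initialize_cohort(sd, params$epidemiology, spec)
    cvec <- list()
    for (sw in c(FALSE, TRUE)) {
      for (pp in PERSPECTIVES) {
        cvec[[paste(sw, pp)]] <- cost_vector(params, params$arms[[a]], sw, pp)
      }
    }
    y1_factor <- if (isTRUE(params$options$discount_year1)) 1 / (1 + r) else 1
    per_cycle <- data.frame(year = 1L, cost_moh = sd$year1_cost,
                            cost_societal = sd$year1_cost, qaly = sd$year1_qaly)
    per_cycle$dcost_moh <- per_cycle$cost_moh * y1_factor
    per_cycle$dcost_societal <- per_cycle$cost_societal * y1_factor
    per_cycle$dqaly <- per_cycle$qaly * y1_factor
    state[[a]] <- list(tree = sd, cohort = cohort, cvec = cvec,
                       per_cycle = per_cycle)
  }

  if (h >= 2) {
    for (t in 2:h) {
      age <- spec$entry_age + (t - 1)
      tms <- list()
      for (ss in SEXES) {
        rr_mult <- rr_multiplier_vec(params$risks, ss,
                                     params$options$mortality_combine)
        for (wg in c(FALSE, TRUE)) {
          tms[[paste(wg, ss)]] <-
            build_transition_matrix(params, wg, ss, age, rr_mult)
        }
      }
      dfac <- discount(1, t, r) * (if (isTRUE(params$options$discount_year1)) 1 / (1 + r) else 1)
      for (a in arm_names) {
        st <- state[[a]]
        strata <- st$cohort$strata
        cost <- c(moh = 0, societal = 0)
        qaly <- 0
        new_mass <- st$cohort$mass
        for (ss in SEXES) {
          for (k in seq_len(nrow(strata))) {
            tm <- tms[[paste(strata$weight_gained[k], ss)]]
            v <- st$cohort$mass[, k, ss]
            nv <- as.vector(v %*% tm$P)
            new_mass[, k, ss] <- nv
            fatal_cost <-
              sum(v[1:36] * tm$fatal_chd) * params$costs$direct$chd_fatal +
              sum(v[1:36] * tm$fatal_stroke) * params$costs$direct$stroke_fatal
            alive <- nv[1:36]
            for (pp in PERSPECTIVES) {
              cost[[pp]] <- cost[[pp]] + fatal_cost +
                sum(alive * st$cvec[[paste(strata$switched[k], pp)]])
            }
            qaly <- qaly + sum(alive * uvec[[paste(strata$weight_gained[k], ss)]])
          }
        }
        st$cohort$mass <- new_mass
        st$cohort$age <- st$cohort$age + 1
        st$cohort$cycle_index <- st$cohort$cycle_index + 1L
        st$per_cycle <- rbind(st$per_cycle, data.frame(
          year = t, cost_moh = cost[["moh"]], cost_societal = cost[["societal"]],
          qaly = qaly, dcost_moh = cost[["moh"]] * dfac,
          dcost_societal = cost[["societal"]] * dfac, dqaly = qaly * dfac))
        state[[a]] <- st
      }
    }
  }

  arms <- list()
  for (a in arm_names) {
    pc <- state[[a]]$per_cycle
    arms[[a]] <- list()
    for (pp in PERSPECTIVES) {
      dcost <- pc[[paste0("dcost_", pp)]]
      arms[[a]][[pp]] <- structure(list(
        arm = a, perspective = pp, horizon = h,
        total_cost = sum(dcost) * scale,
        total_qaly = sum(pc$dqaly) * scale,
        per_cycle = data.frame(year = pc$year,
                               cost = pc[[paste0("cost_", pp)]] * scale,
                               qaly = pc$qaly * scale,
                               dcost = dcost * scale,
                               dqaly = pc$dqaly * scale)
      ), class = "arm_outcome")
    }
  }

  icur <- list()
  if (length(arm_names) >= 2) {
    for (pp in PERSPECTIVES) {
      icur[[pp]] <- compute_icur(arms[[arm_names[1]]][[pp]],
                                 arms[[arm_names[2]]][[pp]])
    }
  }
  structure(list(horizon = h, arms = arms, icur = icur,
                 final_cohorts = lapply(state, `[[`, "cohort")),
            class = "cua_result")
}

#' Discounted totals for a single arm and perspective
#'
#' Convenience wrapper around [run_model()] extracting one arm/perspective.
#'
#' @param params A `cua_params` object.
#' @param arm Arm name (e.g. `"asenapine"`).
#' @param perspective `"moh"` or `"societal"`.
#' @param horizon Optional horizon override (years).
#' @return An `arm_outcome` (totals per `run$cohort_size_report` persons).
#' @export
run_arm <- function(params, arm, perspective = "moh", horizon = NULL) {
  res <- run_model(params, horizon = horizon)
  out <- res$arms[[arm]][[perspective]]
  if (is.null(out)) stop("unknown arm: ", arm)
  out
}

#' Incremental cost-utility ratio and dominance verdict
#'
#' Differences `a - b` in discounted cost and QALYs. Classification:
#' `"dominant"` when the intervention costs less and yields more QALYs,
#' `"dominated"` for the reverse, `"equivalent"` when both differences are
#' zero (to numerical tolerance), otherwise `"ratio"` with
#' `icur = delta_cost / delta_qaly`.
#'
#' @param a `arm_outcome` of the intervention.
#' @param b `arm_outcome` of the comparator (same perspective and horizon).
#' @param tol Numerical tolerance for zero differences.
#' @return An `icur_result`: list with `delta_cost`, `delta_qaly`, `icur`
#'   (NA unless a ratio), `label`.
#' @export
compute_icur <- function(a, b, tol = 1e-9) {
  if (!identical(a$perspective, b$perspective) || !identical(a$horizon, b$horizon)) {
    stop("compute_icur: outcomes differ in perspective or horizon")
  }
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qaly - b$total_qaly
  if (abs(dc) <= tol && abs(dq) <= tol) {
    label <- "equivalent"; icur <- NA_real_
  } else if (dc < 0 && dq > 0) {
    label <- "dominant"; icur <- NA_real_
  } else if (dc > 0 && dq < 0) {
    label <- "dominated"; icur <- NA_real_
  } else {
    label <- "ratio"; icur <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icur = icur, label = label,
                 perspective = a$perspective, horizon = a$horizon),
            class = "icur_result")
}

#' @export
print.icur_result <- function(x, ...) {
  cat(sprintf("<icur_result> [%s, %dy] dCost %.0f, dQALY %.2f: %s%s\n",
              x$perspective, x$horizon, x$delta_cost, x$delta_qaly, x$label,
              if (x$label == "ratio") sprintf(" (%.0f $/QALY)", x$icur) else ""))
  invisible(x)
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> %s [%s, %dy]: cost %.0f, QALY %.1f (per cohort)\n",
              x$arm, x$perspective, x$horizon, x$total_cost, x$total_qaly))
  invisible(x)
}

#' Cost-utility summary table
#'
#' Formats a [run_model()] result as the familiar per-1,000-patients
#' cost-utility layout: one row per arm with discounted costs, incremental
#' costs, QALYs, incremental QALYs and the ICUR/dominance verdict (the
#' first arm is the intervention).
#'
#' @param result A `cua_result` from [run_model()].
#' @param perspective `"moh"` or `"societal"`.
#' @return A data frame.
#' @export
icur_table <- function(result, perspective = "moh") {
  arms <- names(result$arms)
  ic <- result$icur[[perspective]]
  verdict <- if (ic$label == "ratio") sprintf("%.0f", ic$icur) else ic$label
  df <- data.frame(
    arm = arms,
    cost = vapply(arms, function(a) result$arms[[a]][[perspective]]$total_cost, 0.0),
    incremental_cost = c(ic$delta_cost, NA),
    qaly = vapply(arms, function(a) result$arms[[a]][[perspective]]$total_qaly, 0.0),
    incremental_qaly = c(ic$delta_qaly, NA),
    icur = c(verdict, NA)
  )
  rownames(df) <- NULL
  df
}

#' @export
print.cua_result <- function(x, ...) {
  cat(sprintf("<cua_result> horizon %d years\n", x$horizon))
  for (pp in names(x$icur)) {
    cat(sprintf("-- %s perspective --\n", pp))
    print(icur_table(x, pp), digits = 6)
  }
  invisible(x)
}
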