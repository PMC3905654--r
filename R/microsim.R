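# Individual-level Monte Carlo re-implementation of the identical event
# logic, used as an independent brute-force oracle for the cohort engine.
# Transitions are realised by sampling per patient (death draw first, then
# sequential complication draws in the configured order, with fatal
# sub-draws for incident CHD/stroke), not by matrix algebra.

#' Microsimulation of one treatment arm
#'
#' Simulates `n` individual patients through the year-1 decision tree
#' (weight gain, EPS, switch draws) and the annual Markov event logic for
#' years 2..horizon, accruing discounted costs (both perspectives) and
#' QALYs per patient. Sample means and standard errors are directly
#' comparable with the cohort engine's per-person expectations.
#'
#' @param params A `cua_params` object.
#' @param arm Arm name (e.g. `"asenapine"`).
#' @param n Number of simulated patients.
#' @param seed RNG seed.
#' @param horizon Optional horizon override (years).
#' @return List with `n`, per-person means `mean_cost_moh`,
#'   `mean_cost_societal`, `mean_qaly` and their standard errors `se_*`.
#' @export
simulate_cohort <- function(params, arm, n, seed = 1, horizon = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  spec <- params$run
  h <- if (is.null(horizon)) spec$horizon_years else horizon
  A <- params$arms[[arm]]
  if (is.null(A)) stop("unknown arm: ", arm)
  u <- params$utilities
  cs <- params$costs
  r <- spec$discount_rate
  y1f <- if (isTRUE(params$options$discount_year1)) 1 / (1 + r) else 1
  dfac <- y1f / (1 + r)^(seq_len(max(h, 1)) - 1)

  sex <- ifelse(stats::runif(n) < spec$sex_mix, "male", "female")
  is_m <- sex == "male"
  wg <- stats::runif(n) < A$p_weight_gain_y1
  eps <- stats::runif(n) < A$p_eps_y1
  sw <- eps & (stats::runif(n) < A$p_switch_given_eps)

  f_wg <- params$options$wg_exposure_y1
  cost_moh <- ifelse(sw, 0.5 * A$annual_drug_cost + 0.5 * A$switch_drug_annual_cost,
                     A$annual_drug_cost) + eps * cs$eps_management
  qaly <- u$u_bpd - u$du_weight_gain * f_wg * wg -
    u$du_eps * u$eps_duration_years * eps
  cost_moh <- cost_moh * dfac[1]
  cost_soc <- cost_moh
  qaly <- qaly * dfac[1]

  if (h >= 2) {
    # complication status: 0 none, 1 event year, 2 post (diab/htn use 0/2)
    st <- matrix(0L, n, 4, dimnames = list(NULL, COMPLICATIONS))
    for (cc in COMPLICATIONS) {
      prev <- ifelse(is_m, params$epidemiology$prevalence[cc, "male"],
                     params$epidemiology$prevalence[cc, "female"])
      st[stats::runif(n) < prev, cc] <- 2L
    }
    alive <- rep(TRUE, n)
    rr <- params$risks$mortality_rr
    or <- params$risks$odds_ratio
    inc <- params$epidemiology$incidence
    du <- u$du_complication
    drug <- ifelse(sw, A$switch_drug_annual_cost, A$annual_drug_cost)
    combine_max <- identical(params$options$mortality_combine, "max")

    for (t in 2:h) {
      age <- as.character(spec$entry_age + (t - 1))
      live <- which(alive)
      if (!length(live)) break
      sx <- ifelse(is_m[live], 1L, 2L)

      qb <- base_mortality(params$mortality, "male", as.integer(age))
      qf <- base_mortality(params$mortality, "female", as.integer(age))
      q <- ifelse(is_m[live], qb, qf)
      pres <- st[live, , drop = FALSE] > 0
      if (combine_max) {
        mult <- rep(1, length(live))
        for (cc in COMPLICATIONS) {
          mult <- pmax(mult, ifelse(pres[, cc], rr[cc, ][sx], 1))
        }
      } else {
        mult <- rep(1, length(live))
        for (cc in COMPLICATIONS) {
          mult <- mult * ifelse(pres[, cc], rr[cc, ][sx], 1)
        }
      }
      q <- pmin(pmax(q * mult, 0), 1)
      died <- stats::runif(length(live)) < q
      alive[live[died]] <- FALSE
      surv <- live[!died]
      if (length(surv)) {
        # event-year states age into the post tier before new events
        ev <- st[surv, , drop = FALSE]
        ev[ev == 1L] <- 2L
        st[surv, ] <- ev
        sxs <- ifelse(is_m[surv], 1L, 2L)
        had_event <- rep(FALSE, length(surv))
        fatal_cost_now <- rep(0, length(surv))
        for (cc in params$options$complication_order) {
          base_p <- inc[cc, , age][sxs]
          p <- ifelse(wg[surv],
                      adjusted_probability(base_p, or[cc, ][sxs],
                                           scale = params$options$or_scale),
                      base_p)
          hit <- !had_event & st[surv, cc] == 0L &
            stats::runif(length(surv)) < p
          had_event <- had_event | hit
          if (cc == "chd") {
            fatal <- hit & stats::runif(length(surv)) <
              params$epidemiology$p_fatal_given_chd_event
            st[surv[hit & !fatal], cc] <- 1L
            fatal_cost_now[fatal] <- fatal_cost_now[fatal] + cs$direct$chd_fatal
            alive[surv[fatal]] <- FALSE
          } else if (cc == "stroke") {
            fatal <- hit & stats::runif(length(surv)) <
              params$epidemiology$p_fatal_given_stroke_event
            st[surv[hit & !fatal], cc] <- 1L
            fatal_cost_now[fatal] <- fatal_cost_now[fatal] + cs$direct$stroke_fatal
            alive[surv[fatal]] <- FALSE
          } else {
            st[surv[hit], cc] <- 2L
          }
        }
        cost_moh[surv] <- cost_moh[surv] + fatal_cost_now * dfac[t]
        cost_soc[surv] <- cost_soc[surv] + fatal_cost_now * dfac[t]

        acc <- surv[alive[surv]]
        if (length(acc)) {
          sa <- st[acc, , drop = FALSE]
          sxa <- ifelse(is_m[acc], 1L, 2L)
          cost <- drug[acc] +
            (sa[, "diabetes"] > 0) * cs$direct$diabetes +
            (sa[, "hypertension"] > 0) * cs$direct$hypertension +
            (sa[, "chd"] == 1L) * cs$direct$chd_y1 +
            (sa[, "chd"] == 2L) * cs$direct$chd_y2plus +
            (sa[, "stroke"] == 1L) * cs$direct$stroke_y1 +
            (sa[, "stroke"] == 2L) * cs$direct$stroke_y2plus
          soc <- cost +
            (sa[, "diabetes"] > 0) * cs$productivity$diabetes +
            (sa[, "hypertension"] > 0) * cs$productivity$hypertension +
            (sa[, "chd"] > 0) * cs$productivity$chd +
            (sa[, "stroke"] > 0) * (cs$productivity$stroke + cs$informal_care_stroke)

          dumat <- cbind(
            (sa[, "diabetes"] > 0) * du["diabetes", ][sxa],
            (sa[, "hypertension"] > 0) * du["hypertension", ][sxa],
            (sa[, "chd"] > 0) * du["chd", ][sxa],
            (sa[, "stroke"] > 0) * du["stroke", ][sxa]
          )
          dmax <- pmax(dumat[, 1], dumat[, 2], dumat[, 3], dumat[, 4])
          dcomp <- dmax + u$w_additional * (rowSums(dumat) - dmax)
          uy <- pmax(u$u_bpd - u$du_weight_gain * wg[acc] - dcomp, 0)

          cost_moh[acc] <- cost_moh[acc] + cost * dfac[t]
          cost_soc[acc] <- cost_soc[acc] + soc * dfac[t]
          qaly[acc] <- qaly[acc] + uy * dfac[t]
        }
      }
    }
  }

  list(
    n = n,
    mean_cost_moh = mean(cost_moh), se_cost_moh = stats::sd(cost_moh) / sqrt(n),
    mean_cost_societal = mean(cost_soc),
    se_cost_societal = stats::sd(cost_soc) / sqrt(n),
    mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n)
  )
}
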