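# Year-1 decision tree: EPS occurrence, switch-on-EPS, >=7% weight gain.
# Weight gain and EPS are modelled as independent events; a switch can only
# follow EPS, so the 2 x 2 x 2 grid collapses to six reachable strata.

#' One-year decision tree for a treatment arm
#'
#' Computes the probability mass over the six reachable year-1 strata
#' (weight gained x EPS x switched, with switching conditional on EPS) and
#' the expected year-1 cost and QALY accruals for one treatment arm.
#'
#' Year-1 cost is the annual drug cost (switchers pay half a year of the
#' initial drug plus half a year of the switch drug, since EPS arises early
#' in treatment) plus the EPS management cost weighted by the EPS
#' probability. Year-1 QALY starts from the bipolar-disorder baseline
#' utility; weight gain subtracts its permanent disutility for the fraction
#' `options$wg_exposure_y1` of the year (1 by default), and EPS subtracts
#' its transient disutility for `eps_duration_years` (three months).
#'
#' @param arm One element of `params$arms` (e.g. `params$arms$asenapine`).
#' @param utils The `utilities` block of a `cua_params` object.
#' @param costs The `costs` block of a `cua_params` object.
#' @param options The `options` block (year-1 weight-gain exposure fraction).
#' @return A `stratum_distribution`: list with `arm`, `strata` (data frame
#'   with columns `weight_gained`, `had_eps`, `switched`, `mass`),
#'   `year1_cost` and `year1_qaly` (per person).
#' @export
#' @examples
#' p <- base_case_parameters()
#' run_year_one(p$arms$asenapine, p$utilities, p$costs, p$options)
run_year_one <- function(arm, utils, costs, options = list(wg_exposure_y1 = 1)) {
  p_wg <- arm$p_weight_gain_y1
  p_eps <- arm$p_eps_y1
  p_sw <- arm$p_switch_given_eps
  f_wg <- if (is.null(options$wg_exposure_y1)) 1 else options$wg_exposure_y1

  eps_branch <- data.frame(
    had_eps  = c(FALSE, TRUE, TRUE),
    switched = c(FALSE, FALSE, TRUE),
    mass     = c(1 - p_eps, p_eps * (1 - p_sw), p_eps * p_sw)
  )
  strata <- merge(data.frame(weight_gained = c(FALSE, TRUE),
                             wg_mass = c(1 - p_wg, p_wg)),
                  eps_branch)
  strata$mass <- strata$wg_mass * strata$mass
  strata$wg_mass <- NULL
  strata <- strata[order(strata$weight_gained, strata$had_eps, strata$switched), ]
  rownames(strata) <- NULL

  drug <- ifelse(strata$switched,
                 0.5 * arm$annual_drug_cost + 0.5 * arm$switch_drug_annual_cost,
                 arm$annual_drug_cost)
  year1_cost <- sum(strata$mass * drug) + costs$eps_management * p_eps
  year1_qaly <- utils$u_bpd -
    utils$du_weight_gain * f_wg * p_wg -
    utils$du_eps * utils$eps_duration_years * p_eps

  structure(list(arm = arm$name, strata = strata,
                 year1_cost = year1_cost, year1_qaly = year1_qaly),
            class = "stratum_distribution")
}

#' @export
print.stratum_distribution <- function(x, ...) {
  cat(sprintf("<stratum_distribution> arm %s: year-1 cost %.2f, QALY %.4f\n",
              x$arm, x$year1_cost, x$year1_qaly))
  print(x$strata)
  invisible(x)
}
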