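# Synthetic generators for every external-looking input: a Gompertz life
# table, an age-flat suicide mortality component, and baseline
# prevalence/incidence tables for the four metabolic complications. These
# emulate the statistical structure the model assumes (monotone-in-age
# mortality, small baseline prevalences around age 40, small mildly
# age-increasing incidences) without reproducing any actual national
# statistics; packaged files built from them carry a `_synthetic` label.

#' Synthetic life table and suicide mortality
#'
#' Annual all-cause mortality follows a Gompertz hazard,
#' `q(a) = 1 - exp(-b * exp(c * a))`, monotone increasing in age for
#' `c > 0`; suicide mortality is an age-flat per-sex probability (it must
#' be subtractable from `q` at every age, since the model replaces the
#' general-population suicide component with the bipolar-disorder rate).
#'
#' @param gompertz Per-sex list of Gompertz parameters `b` (baseline
#'   hazard, > 0) and `c` (log-hazard slope per year of age, >= 0).
#' @param ages Integer age range to tabulate.
#' @param suicide Named per-sex annual suicide mortality probabilities.
#' @return List with `life_table` and `suicide`, each a long data frame
#'   `(sex, age, value)` as read by [load_parameters()].
#' @export
#' @examples
#' lt <- generate_life_table()
#' subset(lt$life_table, age == 40)
generate_life_table <- function(gompertz = list(
                                  male = list(b = 5e-5, c = 0.09),
                                  female = list(b = 3.5e-5, c = 0.09)),
                                ages = 18:75,
                                suicide = c(male = 1.8e-4, female = 5.4e-5)) {
  rows <- lapply(SEXES, function(ss) {
    b <- gompertz[[ss]]$b
    cc <- gompertz[[ss]]$c
    if (b <= 0 || cc < 0) stop("Gompertz parameters must satisfy b > 0, c >= 0")
    q <- 1 - exp(-b * exp(cc * ages))
    if (any(q < 0 | q > 1)) stop("life-table probabilities outside [0, 1]")
    if (any(q <= suicide[[ss]])) {
      stop("suicide mortality exceeds all-cause mortality at some age")
    }
    data.frame(sex = ss, age = ages, value = q)
  })
  sui <- lapply(SEXES, function(ss) {
    data.frame(sex = ss, age = ages, value = suicide[[ss]])
  })
  list(life_table = do.call(rbind, rows), suicide = do.call(rbind, sui))
}

#' Synthetic baseline epidemiology of metabolic complications
#'
#' Generates entry prevalences and annual incidences for diabetes,
#' hypertension, CHD and stroke with realistic orders of magnitude for a
#' general adult population around age 40: prevalences at entry in
#' \[0.01, 0.15\], annual incidences in \[0.001, 0.03\] growing about 3%
#' per year of age. A per-(complication, sex) lognormal jitter (5% on the
#' log scale) makes distinct seeds produce distinct but structurally
#' identical tables; the function is a pure function of its arguments.
#'
#' @param seed Integer seed for the jitter.
#' @param scale `"realistic"` (default), `"low"` (all incidences <= 0.005)
#'   or `"high"` (doubled incidences, capped at 0.03).
#' @param ages Integer age range for the incidence table.
#' @return List with `prevalence` (`sex, complication, value`) and
#'   `incidence` (`sex, age, complication, value`) data frames.
#' @export
generate_epidemiology <- function(seed = 1, scale = "realistic", ages = 18:75) {
  scale <- match.arg(scale, c("realistic", "low", "high"))
  prev40 <- matrix(c(0.060, 0.050,
                     0.145, 0.135,
                     0.030, 0.020,
                     0.014, 0.010),
                   4, 2, byrow = TRUE,
                   dimnames = list(COMPLICATIONS, SEXES))
  inc40 <- matrix(c(0.0065, 0.0055,
                    0.0200, 0.0180,
                    0.0045, 0.0028,
                    0.0016, 0.0013),
                  4, 2, byrow = TRUE,
                  dimnames = list(COMPLICATIONS, SEXES))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  jit <- matrix(exp(stats::rnorm(8, 0, 0.05)), 4, 2,
                dimnames = list(COMPLICATIONS, SEXES))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  prev <- prev40 * jit
  inc40 <- inc40 * jit
  fac <- switch(scale, realistic = 1, low = 0.25, high = 2)
  inc_cap <- switch(scale, realistic = 0.03, low = 0.005, high = 0.03)
  prev <- pmin(pmax(prev * (if (scale == "low") 0.5 else if (scale == "high") 1.5 else 1),
                    0.01), 0.15)

  prevalence <- expand.grid(complication = COMPLICATIONS, sex = SEXES,
                            stringsAsFactors = FALSE)
  prevalence$value <- prev[cbind(prevalence$complication, prevalence$sex)]

  incidence <- expand.grid(complication = COMPLICATIONS, sex = SEXES,
                           age = ages, stringsAsFactors = FALSE)
  incidence$value <- pmin(pmax(
    inc40[cbind(incidence$complication, incidence$sex)] * fac *
      1.03^(incidence$age - 40),
    0.001), inc_cap)
  list(prevalence = prevalence[, c("sex", "complication", "value")],
       incidence = incidence[, c("sex", "age", "complication", "value")])
}

#' Named suite of model parameterisations for testing and validation
#'
#' Builds a family of full parameterisations used throughout the test
#' suite and the cohort-vs-microsimulation cross-validation:
#' \describe{
#'   \item{tables12_base}{the packaged base case: published clinical/cost
#'     inputs with synthetic life table and epidemiology.}
#'   \item{zero_risk}{no mortality, no complications, no adverse events,
#'     drug cost only — admits closed-form annuity totals.}
#'   \item{symmetric_arms}{both arms given the intervention's parameters,
#'     so every incremental quantity is exactly zero.}
#'   \item{high_incidence}{doubled complication incidences (stress case).}
#'   \item{low_incidence}{quartered complication incidences
#'     (all below 0.005).}
#' }
#'
#' @param seed Seed forwarded to [generate_epidemiology()] for the
#'   incidence variants.
#' @return Named list of `cua_params` objects.
#' @export
make_fixture_suite <- function(seed = 421) {
  base <- base_case_parameters()

  zero <- base
  zero$arms <- lapply(zero$arms, function(a) {
    a$p_weight_gain_y1 <- 0; a$p_eps_y1 <- 0; a
  })
  zero$mortality$life_table[] <- 0
  zero$mortality$suicide[] <- 0
  zero$epidemiology$prevalence[] <- 0
  zero$epidemiology$incidence[] <- 0
  zero$costs$eps_management <- 0
  zero$costs$direct <- lapply(zero$costs$direct, function(x) 0)
  zero$costs$productivity <- lapply(zero$costs$productivity, function(x) 0)
  zero$costs$informal_care_stroke <- 0
  validate_parameters(zero)

  sym <- base
  sym$arms$olanzapine <- sym$arms$asenapine
  sym$arms$olanzapine$name <- "olanzapine"
  validate_parameters(sym)

  with_epi <- function(p, scale) {
    epi <- generate_epidemiology(seed = seed, scale = scale)
    p$epidemiology$prevalence <- as_prevalence_matrix(epi$prevalence)
    p$epidemiology$incidence <- as_incidence_array(epi$incidence)
    validate_parameters(p)
    p
  }

  list(tables12_base = base,
       zero_risk = zero,
       symmetric_arms = sym,
       high_incidence = with_epi(base, "high"),
       low_incidence = with_epi(base, "low"))
}
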