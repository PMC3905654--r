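# Markov cohort engine over metabolic-complication states.
#
# State space: diabetes (absent/present) x hypertension (absent/present) x
# CHD (none / event year / post) x stroke (none / event year / post), plus
# an absorbing dead state: 2*2*3*3 = 36 alive states + 1 = 37.
#
# Within a yearly cycle, death (all-cause, suicide-adjusted, multiplied by
# the mortality risks of complications already present) is resolved first;
# the surviving mass then faces at most one incident complication, resolved
# as sequential competing events in a fixed order, each candidate thinned by
# the no-prior-event products. Incident CHD/stroke split into fatal and
# non-fatal parts; event-year states advance to their post tier.

STATUS_NONE <- 0L
STATUS_EVENT <- 1L
STATUS_POST <- 2L
N_STATES <- 37L
DEAD <- 37L

state_index <- function(d, h, c, s) d * 18L + h * 9L + c * 3L + s + 1L

#' Enumerate the Markov health states
#'
#' Returns the canonical state table: 36 alive combinations of diabetes,
#' hypertension, CHD status (none / event year / post) and stroke status,
#' followed by the absorbing dead state. Row order is the engine's canonical
#' state indexing.
#'
#' @return A data frame with columns `has_diabetes`, `has_hypertension`,
#'   `chd_status`, `stroke_status` (each status in `c("none", "event_year",
#'   "post")`), `dead`.
#' @export
enumerate_states <- function() {
  grid <- expand.grid(stroke = 0:2, chd = 0:2, htn = 0:1, diab = 0:1)
  lab <- c("none", "event_year", "post")
  df <- data.frame(
    has_diabetes = as.logical(grid$diab),
    has_hypertension = as.logical(grid$htn),
    chd_status = lab[grid$chd + 1],
    stroke_status = lab[grid$stroke + 1],
    dead = FALSE
  )
  df <- df[order(state_index(grid$diab, grid$htn, grid$chd, grid$stroke)), ]
  rownames(df) <- NULL
  rbind(df, data.frame(has_diabetes = FALSE, has_hypertension = FALSE,
                       chd_status = "none", stroke_status = "none", dead = TRUE))
}

# integer-coded alive-state table and destination indices, computed once
state_geometry <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- expand.grid(s = 0:2, c = 0:2, h = 0:1, d = 0:1)
    g <- g[order(state_index(g$d, g$h, g$c, g$s)), ]
    d <- g$d; h <- g$h; cc <- g$c; ss <- g$s
    cadv <- ifelse(cc == STATUS_EVENT, STATUS_POST, cc)
    sadv <- ifelse(ss == STATUS_EVENT, STATUS_POST, ss)
    stay <- state_index(d, h, cadv, sadv)
    elig <- cbind(diabetes = d == 0, hypertension = h == 0,
                  chd = cc == 0, stroke = ss == 0)
    dest <- cbind(
      diabetes = ifelse(elig[, 1], state_index(1L, h, cadv, sadv), stay),
      hypertension = ifelse(elig[, 2], state_index(d, 1L, cadv, sadv), stay),
      chd = ifelse(elig[, 3], state_index(d, h, STATUS_EVENT, sadv), stay),
      stroke = ifelse(elig[, 4], state_index(d, h, cadv, STATUS_EVENT), stay)
    )
    present <- cbind(diabetes = d == 1, hypertension = h == 1,
                     chd = cc > 0, stroke = ss > 0)
    cache <<- list(d = d, h = h, c = cc, s = ss, stay = stay,
                   elig = elig, dest = dest, present = present)
    cache
  }
})

#' Apply an odds ratio to a baseline probability
#'
#' Converts the baseline annual probability to odds, multiplies by the odds
#' ratio, and back-transforms. With `scale = "rr"` the ratio is instead
#' applied multiplicatively to the probability (capped at 1), a sensitivity
#' option for when published ratios are treated as relative risks.
#'
#' @param p_base Baseline probability in \[0, 1).
#' @param or_value Ratio (> 0).
#' @param scale `"odds"` (default) or `"rr"`.
#' @return Adjusted probability.
#' @export
#' @examples
#' adjusted_probability(0.10, 2.69)
adjusted_probability <- function(p_base, or_value, scale = "odds") {
  stopifnot(all(or_value > 0))
  if (any(p_base < 0) || any(p_base >= 1)) {
    if (any(p_base == 1)) stop("adjusted_probability: p_base = 1 has no odds")
    stop("adjusted_probability: p_base must lie in [0, 1)")
  }
  if (identical(scale, "rr")) return(pmin(p_base * or_value, 1))
  odds <- or_value * p_base / (1 - p_base)
  odds / (1 + odds)
}

# suicide-adjusted background mortality before complication risk ratios
base_mortality <- function(mort, sex, age) {
  lt <- mort$life_table
  a <- as.character(age)
  if (!a %in% rownames(lt)) stop("age ", age, " outside life-table range")
  q_all <- lt[a, sex]
  q_sui <- mort$suicide[a, sex]
  q_all - q_sui + mort$bpd_suicide_multiplier * q_sui
}

#' Annual all-cause mortality for a health state
#'
#' General-population mortality with the suicide component replaced by the
#' bipolar-disorder rate (general suicide mortality subtracted, then added
#' back multiplied by the suicide-rate ratio), then multiplied by the
#' mortality risk ratio of every complication present in the state
#' (multiplicatively by default, or the maximum single ratio with
#' `combine = "max"`), clipped to \[0, 1\].
#'
#' @param mort The `mortality` block of a `cua_params` object.
#' @param state One row of [enumerate_states()] (or a list with the same
#'   fields).
#' @param sex `"male"` or `"female"`.
#' @param age Integer age within the life-table range.
#' @param risks The `risks` block (for `mortality_rr`).
#' @param combine `"multiplicative"` (default) or `"max"`.
#' @return Annual death probability.
#' @export
adjusted_mortality <- function(mort, state, sex, age, risks,
                               combine = "multiplicative") {
  q <- base_mortality(mort, sex, age)
  present <- c(
    diabetes = isTRUE(state$has_diabetes),
    hypertension = isTRUE(state$has_hypertension),
    chd = state$chd_status != "none",
    stroke = state$stroke_status != "none"
  )
  rr <- risks$mortality_rr[names(present)[present], sex]
  if (length(rr)) {
    q <- if (identical(combine, "max")) q * max(rr) else q * prod(rr)
  }
  min(max(q, 0), 1)
}

# per-sex multiplier vector over the 36 alive states
rr_multiplier_vec <- function(risks, sex, combine) {
  geo <- state_geometry()
  logrr <- log(risks$mortality_rr[, sex])
  if (identical(combine, "max")) {
    apply(geo$present, 1, function(pr) if (any(pr)) max(exp(logrr[pr])) else 1)
  } else {
    exp(as.vector(geo$present %*% logrr))
  }
}

# candidate incidence per complication for (wg, sex, age)
candidate_incidence <- function(params, wg, sex, age) {
  inc <- params$epidemiology$incidence
  a <- as.character(age)
  if (!a %in% dimnames(inc)[[3]]) stop("age ", age, " outside incidence table")
  cand <- inc[, sex, a]
  if (wg) {
    cand <- adjusted_probability(cand, params$risks$odds_ratio[, sex],
                                 scale = params$options$or_scale)
  }
  cand
}

# Full 37 x 37 transition matrix for one (weight-gain flag, sex, age), plus
# the per-source fatal CHD/stroke flows (needed for one-time fatal costs).
build_transition_matrix <- function(params, wg, sex, age, rr_mult = NULL) {
  geo <- state_geometry()
  if (is.null(rr_mult)) {
    rr_mult <- rr_multiplier_vec(params$risks, sex,
                                 params$options$mortality_combine)
  }
  q <- pmin(pmax(base_mortality(params$mortality, sex, age) * rr_mult, 0), 1)
  cand <- candidate_incidence(params, wg, sex, age)
  survive <- 1 - q

  rem <- rep(1, 36)
  p_eff <- matrix(0, 36, 4, dimnames = list(NULL, COMPLICATIONS))
  for (cc in params$options$complication_order) {
    ce <- cand[[cc]] * geo$elig[, cc]
    p_eff[, cc] <- ce * rem
    rem <- rem * (1 - ce)
  }

  pf_chd <- params$epidemiology$p_fatal_given_chd_event
  pf_str <- params$epidemiology$p_fatal_given_stroke_event
  m <- p_eff * survive
  fatal_chd <- m[, "chd"] * pf_chd
  fatal_stroke <- m[, "stroke"] * pf_str
  m[, "chd"] <- m[, "chd"] * (1 - pf_chd)
  m[, "stroke"] <- m[, "stroke"] * (1 - pf_str)
  stay <- survive * rem

  P <- matrix(0, N_STATES, N_STATES)
  rows <- 1:36
  P[cbind(rows, geo$stay)] <- stay
  for (cc in COMPLICATIONS) {
    cells <- cbind(rows, geo$dest[, cc])
    P[cells] <- P[cells] + m[, cc]
  }
  P[rows, DEAD] <- P[rows, DEAD] + q + fatal_chd + fatal_stroke
  P[DEAD, DEAD] <- 1
  list(P = P, fatal_chd = fatal_chd, fatal_stroke = fatal_stroke)
}

#' One transition row of the Markov model
#'
#' Destination probability masses for a single source state under the annual
#' event logic: death first, then at most one incident complication
#' (sequential competing events with odds-ratio-adjusted incidence for the
#' weight-gained stratum), fatal splits for incident CHD/stroke, and
#' event-year to post advancement.
#'
#' @param state One row of [enumerate_states()].
#' @param weight_gained Logical; does the stratum carry the elevated
#'   (odds-ratio-adjusted) complication risks?
#' @param sex `"male"` or `"female"`.
#' @param age Integer age during the cycle.
#' @param params A `cua_params` object.
#' @return Named numeric vector of length 37 summing to 1 over the canonical
#'   state order, with attributes `fatal_chd` and `fatal_stroke` (the fatal
#'   shares of the flow into death).
#' @export
build_transitions <- function(state, weight_gained, sex, age, params) {
  if (isTRUE(state$dead)) {
    row <- numeric(N_STATES); row[DEAD] <- 1
    return(structure(row, fatal_chd = 0, fatal_stroke = 0))
  }
  lab <- c(none = 0L, event_year = 1L, post = 2L)
  i <- state_index(as.integer(state$has_diabetes),
                   as.integer(state$has_hypertension),
                   lab[[state$chd_status]], lab[[state$stroke_status]])
  tm <- build_transition_matrix(params, weight_gained, sex, age)
  structure(tm$P[i, ], fatal_chd = tm$fatal_chd[i],
            fatal_stroke = tm$fatal_stroke[i])
}

#' Initial cohort entering the Markov model
#'
#' Distributes each year-1 stratum's mass over the alive states according to
#' the baseline prevalence of each complication at model entry, treated as
#' independent across complications; prevalent CHD/stroke enter the post
#' (not event-year) tier. Mass is crossed with the male/female split.
#'
#' @param strata A `stratum_distribution` from [run_year_one()].
#' @param epi The `epidemiology` block of a `cua_params` object.
#' @param spec The `run` block (for `sex_mix` and `entry_age`).
#' @return A `cohort_vector`: list with `mass` (array states x strata x
#'   sex), `age` (age during the upcoming cycle), `cycle_index`, `strata`.
#' @export
initialize_cohort <- function(strata, epi, spec) {
  geo <- state_geometry()
  ns <- nrow(strata$strata)
  mass <- array(0, dim = c(N_STATES, ns, 2),
                dimnames = list(NULL, NULL, SEXES))
  sex_share <- c(male = spec$sex_mix, female = 1 - spec$sex_mix)
  for (ss in SEXES) {
    prev <- epi$prevalence[, ss]
    # product measure; prevalent CHD/stroke sit in the post tier
    pm <- ifelse(geo$present[, "diabetes"], prev["diabetes"], 1 - prev["diabetes"]) *
      ifelse(geo$present[, "hypertension"], prev["hypertension"], 1 - prev["hypertension"]) *
      ifelse(geo$c == STATUS_POST, prev["chd"], ifelse(geo$c == STATUS_NONE, 1 - prev["chd"], 0)) *
      ifelse(geo$s == STATUS_POST, prev["stroke"], ifelse(geo$s == STATUS_NONE, 1 - prev["stroke"], 0))
    for (k in seq_len(ns)) {
      mass[1:36, k, ss] <- strata$strata$mass[k] * sex_share[[ss]] * pm
    }
  }
  structure(list(mass = mass, age = spec$entry_age + 1, cycle_index = 2L,
                 strata = strata$strata),
            class = "cohort_vector")
}

#' Advance the cohort by one yearly cycle
#'
#' Applies the age-, sex- and stratum-specific transition matrices to every
#' slice of the cohort, increments age and cycle index, and records the
#' expected mass undergoing fatal CHD/stroke events (for one-time fatal
#' costs).
#'
#' @param cohort A `cohort_vector`.
#' @param params A `cua_params` object.
#' @return List with `cohort` (the advanced `cohort_vector`), `fatal_chd`
#'   and `fatal_stroke` (strata x sex matrices of expected fatal-event
#'   mass during the cycle).
#' @export
advance <- function(cohort, params) {
  ns <- dim(cohort$mass)[2]
  new_mass <- cohort$mass
  fatal_chd <- matrix(0, ns, 2, dimnames = list(NULL, SEXES))
  fatal_stroke <- matrix(0, ns, 2, dimnames = list(NULL, SEXES))
  for (ss in SEXES) {
    rr_mult <- rr_multiplier_vec(params$risks, ss,
                                 params$options$mortality_combine)
    for (wg in c(FALSE, TRUE)) {
      ks <- which(cohort$strata$weight_gained == wg)
      if (!length(ks)) next
      tm <- build_transition_matrix(params, wg, ss, cohort$age, rr_mult)
      for (k in ks) {
        v <- cohort$mass[, k, ss]
        new_mass[, k, ss] <- as.vector(v %*% tm$P)
        fatal_chd[k, ss] <- sum(v[1:36] * tm$fatal_chd)
        fatal_stroke[k, ss] <- sum(v[1:36] * tm$fatal_stroke)
      }
    }
  }
  cohort$mass <- new_mass
  cohort$age <- cohort$age + 1
  cohort$cycle_index <- cohort$cycle_index + 1L
  list(cohort = cohort, fatal_chd = fatal_chd, fatal_stroke = fatal_stroke)
}
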