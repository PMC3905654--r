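#' @keywords internal
"_PACKAGE"

# Model-wide vocabulary. Complication order here is the default resolution
# order for the at-most-one-event-per-year rule (configurable in `options`).
COMPLICATIONS <- c("diabetes", "hypertension", "chd", "stroke")
SEXES <- c("male", "female")
ARMS <- c("asenapine", "olanzapine")
PERSPECTIVES <- c("moh", "societal")

#' Load and validate a full model parameterisation
#'
#' Reads a YAML configuration plus the CSV tables it references (life table,
#' suicide mortality, baseline prevalence and annual incidence of the four
#' metabolic complications) and returns a validated `cua_params` object
#' holding every model input: per-arm drug costs and year-1 adverse-event
#' probabilities, weight-gain odds ratios and mortality risk ratios per
#' complication and sex, utilities/disutilities, direct and societal costs,
#' epidemiology, mortality, and run settings (horizon, discount rate, entry
#' age, sex mix).
#'
#' CSV tables are resolved relative to the directory containing the YAML
#' file. Life table and suicide CSVs have columns `sex, age, value`;
#' incidence has `sex, age, complication, value`; prevalence has
#' `sex, complication, value`.
#'
#' @param config_path Path to a YAML configuration. The packaged base case
#'   (Table 1/2 values with synthetic epidemiology) is at
#'   `system.file("extdata", "base_case.yaml", package = "bpdcua")`.
#' @return A `cua_params` object (a validated nested list).
#' @seealso [base_case_parameters()], [write_parameters()],
#'   [parameter_bounds()]
#' @export
#' @examples
#' p <- base_case_parameters()
#' p$arms$asenapine$p_weight_gain_y1
load_parameters <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path)
  }
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(normalizePath(config_path))

  read_tbl <- function(rel) {
    path <- if (file.exists(rel)) rel else file.path(dir, rel)
    if (!file.exists(path)) stop("referenced CSV not found: ", rel)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }

  cfg$mortality$life_table <- read_tbl(cfg$mortality$life_table_csv)
  cfg$mortality$suicide <- read_tbl(cfg$mortality$suicide_csv)
  cfg$epidemiology$prevalence <- read_tbl(cfg$epidemiology$prevalence_csv)
  cfg$epidemiology$incidence <- read_tbl(cfg$epidemiology$incidence_csv)

  as_cua_params(cfg)
}

#' Construct a cua_params object from a nested list
#'
#' Lower-level constructor behind [load_parameters()]: takes an already
#' assembled nested list (the YAML layout, with the four epidemiology /
#' mortality data frames in place of CSV references) and returns the
#' validated object with fast lookup arrays attached.
#'
#' @param cfg Nested list following the configuration schema.
#' @return A `cua_params` object.
#' @export
as_cua_params <- function(cfg) {
  p <- cfg
  for (a in names(p$arms)) {
    if (is.null(p$arms[[a]]$name)) p$arms[[a]]$name <- a
  }
  p$risks$odds_ratio <- as_cs_matrix(p$risks$odds_ratio, "risks.odds_ratio")
  p$risks$mortality_rr <- as_cs_matrix(p$risks$mortality_rr, "risks.mortality_rr")
  p$utilities$du_complication <-
    as_cs_matrix(p$utilities$du_complication, "utilities.du_complication")
  p$mortality$life_table <- as_sex_age_table(p$mortality$life_table, "life_table")
  p$mortality$suicide <- as_sex_age_table(p$mortality$suicide, "suicide")
  p$epidemiology$incidence <-
    as_incidence_array(p$epidemiology$incidence)
  p$epidemiology$prevalence <-
    as_prevalence_matrix(p$epidemiology$prevalence)
  if (is.null(p$bounds)) p$bounds <- list()
  if (is.null(p$options)) p$options <- list()
  opt_defaults <- list(
    wg_exposure_y1 = 1.0,
    or_scale = "odds",
    mortality_combine = "multiplicative",
    complication_order = COMPLICATIONS,
    discount_year1 = FALSE
  )
  for (nm in names(opt_defaults)) {
    if (is.null(p$options[[nm]])) p$options[[nm]] <- opt_defaults[[nm]]
  }
  p$options$complication_order <- unlist(p$options$complication_order)
  class(p) <- "cua_params"
  validate_parameters(p)
  p
}

# complication x sex named matrix from nested list (or pass-through)
as_cs_matrix <- function(x, what) {
  if (is.matrix(x)) {
    stopifnot(identical(rownames(x), COMPLICATIONS), identical(colnames(x), SEXES))
    return(x)
  }
  m <- matrix(NA_real_, length(COMPLICATIONS), length(SEXES),
              dimnames = list(COMPLICATIONS, SEXES))
  for (cc in COMPLICATIONS) {
    for (ss in SEXES) {
      v <- x[[cc]][[ss]]
      if (is.null(v)) stop("missing field: ", what, ".", cc, ".", ss)
      m[cc, ss] <- as.numeric(v)
    }
  }
  m
}

# long (sex, age, value) -> age x sex matrix with contiguous integer ages
as_sex_age_table <- function(df, what) {
  if (is.matrix(df)) return(df)
  stopifnot(all(c("sex", "age", "value") %in% names(df)))
  ages <- sort(unique(df$age))
  if (!identical(ages, seq(min(ages), max(ages)))) {
    stop(what, ": ages must be contiguous integers")
  }
  m <- matrix(NA_real_, length(ages), length(SEXES),
              dimnames = list(as.character(ages), SEXES))
  for (ss in SEXES) {
    sub <- df[df$sex == ss, ]
    if (nrow(sub) != length(ages)) stop(what, ": incomplete coverage for sex ", ss)
    m[as.character(sub$age), ss] <- sub$value
  }
  attr(m, "age_min") <- min(ages)
  m
}

# long (sex, age, complication, value) -> array [complication, sex, age]
as_incidence_array <- function(df) {
  if (is.array(df) && length(dim(df)) == 3) return(df)
  stopifnot(all(c("sex", "age", "complication", "value") %in% names(df)))
  ages <- sort(unique(df$age))
  arr <- array(NA_real_, c(length(COMPLICATIONS), length(SEXES), length(ages)),
               dimnames = list(COMPLICATIONS, SEXES, as.character(ages)))
  idx <- cbind(match(df$complication, COMPLICATIONS), match(df$sex, SEXES),
               match(df$age, ages))
  if (anyNA(idx)) stop("incidence: unknown complication or sex label")
  arr[idx] <- df$value
  if (anyNA(arr)) stop("incidence: incomplete (complication x sex x age) coverage")
  attr(arr, "age_min") <- min(ages)
  arr
}

as_prevalence_matrix <- function(df) {
  if (is.matrix(df)) return(df)
  stopifnot(all(c("sex", "complication", "value") %in% names(df)))
  m <- matrix(NA_real_, length(COMPLICATIONS), length(SEXES),
              dimnames = list(COMPLICATIONS, SEXES))
  m[cbind(match(df$complication, COMPLICATIONS), match(df$sex, SEXES))] <- df$value
  if (anyNA(m)) stop("prevalence: incomplete (complication x sex) coverage")
  m
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("validation error: ", field, " must be a probability in [0, 1] (got ",
         paste(signif(x, 4), collapse = ", "), ")")
  }
}
check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("validation error: ", field, " must be >= 0")
  }
}
check_pos <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop("validation error: ", field, " must be > 0")
  }
}

#' Validate a cua_params object
#'
#' Checks every structural invariant: probabilities in \[0, 1\], costs
#' non-negative, odds/risk ratios positive, life-table and suicide mortality
#' in \[0, 1\] at every age, disutilities stored as non-negative magnitudes,
#' and run settings sane. Errors name the offending field.
#'
#' @param p A `cua_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_parameters <- function(p) {
  for (a in names(p$arms)) {
    arm <- p$arms[[a]]
    for (f in c("annual_drug_cost", "switch_drug_annual_cost")) {
      check_nonneg(arm[[f]], paste0("arms.", a, ".", f))
    }
    for (f in c("p_weight_gain_y1", "p_eps_y1", "p_switch_given_eps")) {
      if (is.null(arm[[f]])) stop("missing field: arms.", a, ".", f)
      check_prob(arm[[f]], paste0("arms.", a, ".", f))
    }
  }
  check_pos(p$risks$odds_ratio, "risks.odds_ratio")
  check_pos(p$risks$mortality_rr, "risks.mortality_rr")
  u <- p$utilities
  check_prob(u$u_bpd, "utilities.u_bpd")
  check_nonneg(u$du_weight_gain, "utilities.du_weight_gain")
  check_nonneg(u$du_eps, "utilities.du_eps")
  check_prob(u$eps_duration_years, "utilities.eps_duration_years")
  check_prob(u$w_additional, "utilities.w_additional")
  check_nonneg(u$du_complication, "utilities.du_complication")
  check_nonneg(p$costs$eps_management, "costs.eps_management")
  check_nonneg(unlist(p$costs$direct), "costs.direct")
  check_nonneg(unlist(p$costs$productivity), "costs.productivity")
  check_nonneg(p$costs$informal_care_stroke, "costs.informal_care_stroke")
  check_prob(p$epidemiology$p_fatal_given_chd_event,
             "epidemiology.p_fatal_given_chd_event")
  check_prob(p$epidemiology$p_fatal_given_stroke_event,
             "epidemiology.p_fatal_given_stroke_event")
  check_prob(p$epidemiology$prevalence, "epidemiology.prevalence")
  check_prob(p$epidemiology$incidence, "epidemiology.incidence")
  check_prob(p$mortality$life_table, "mortality.life_table")
  check_prob(p$mortality$suicide, "mortality.suicide")
  check_pos(p$mortality$bpd_suicide_multiplier, "mortality.bpd_suicide_multiplier")
  r <- p$run
  if (r$horizon_years < 1) stop("validation error: run.horizon_years must be >= 1")
  check_nonneg(r$discount_rate, "run.discount_rate")
  check_prob(r$sex_mix, "run.sex_mix")
  if (!setequal(p$options$complication_order, COMPLICATIONS)) {
    stop("validation error: options.complication_order must permute the four complications")
  }
  invisible(p)
}

#' Packaged base-case parameterisation
#'
#' Convenience wrapper loading the packaged base case: the published clinical
#' and cost inputs (adverse-event incidences, odds ratios, mortality risks,
#' utilities, drug and complication costs, suicide-rate multiplier) combined
#' with synthetic life-table and epidemiology tables (files labelled
#' `*_synthetic.csv`), since the original Canadian life table and baseline
#' incidence annex are not distributable.
#'
#' @return A `cua_params` object.
#' @export
base_case_parameters <- function() {
  load_parameters(system.file("extdata", "base_case.yaml", package = "bpdcua"))
}

#' Write a parameterisation back to disk
#'
#' Inverse of [load_parameters()]: writes the YAML configuration and the four
#' CSV tables into `dir` so that `load_parameters(file.path(dir,
#' "config.yaml"))` round-trips to an identical object.
#'
#' @param p A `cua_params` object.
#' @param dir Output directory (created if needed).
#' @return The path of the written YAML, invisibly.
#' @export
write_parameters <- function(p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(p)

  mat_to_nested <- function(m) {
    res <- list()
    for (cc in rownames(m)) res[[cc]] <- as.list(stats::setNames(m[cc, ], colnames(m)))
    res
  }
  sex_age_long <- function(m) {
    ages <- as.integer(rownames(m))
    do.call(rbind, lapply(SEXES, function(ss) {
      data.frame(sex = ss, age = ages, value = m[, ss])
    }))
  }

  out$risks$odds_ratio <- mat_to_nested(p$risks$odds_ratio)
  out$risks$mortality_rr <- mat_to_nested(p$risks$mortality_rr)
  out$utilities$du_complication <- mat_to_nested(p$utilities$du_complication)

  utils::write.csv(sex_age_long(p$mortality$life_table),
                   file.path(dir, "life_table.csv"), row.names = FALSE)
  utils::write.csv(sex_age_long(p$mortality$suicide),
                   file.path(dir, "suicide.csv"), row.names = FALSE)
  prev <- expand.grid(complication = COMPLICATIONS, sex = SEXES,
                      stringsAsFactors = FALSE)
  prev$value <- p$epidemiology$prevalence[cbind(prev$complication, prev$sex)]
  utils::write.csv(prev, file.path(dir, "prevalence.csv"), row.names = FALSE)
  inc_arr <- p$epidemiology$incidence
  ages <- as.integer(dimnames(inc_arr)[[3]])
  inc <- expand.grid(complication = COMPLICATIONS, sex = SEXES, age = ages,
                     stringsAsFactors = FALSE)
  inc$value <- inc_arr[cbind(inc$complication, inc$sex, as.character(inc$age))]
  utils::write.csv(inc, file.path(dir, "incidence.csv"), row.names = FALSE)

  out$mortality$life_table <- NULL
  out$mortality$suicide <- NULL
  out$epidemiology$prevalence <- NULL
  out$epidemiology$incidence <- NULL
  out$mortality$life_table_csv <- "life_table.csv"
  out$mortality$suicide_csv <- "suicide.csv"
  out$epidemiology$prevalence_csv <- "prevalence.csv"
  out$epidemiology$incidence_csv <- "incidence.csv"
  out$options$complication_order <- as.list(p$options$complication_order)

  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Get / set a scalar parameter by dotted identifier
#'
#' Parameters are addressed by dotted paths matching the configuration
#' layout, e.g. `"arms.asenapine.p_weight_gain_y1"`,
#' `"risks.odds_ratio.diabetes.male"`, `"utilities.u_bpd"`,
#' `"costs.direct.stroke_fatal"`, `"run.discount_rate"`. Matrix-valued
#' inputs take their row and column labels as the final two path segments.
#'
#' @param p A `cua_params` object.
#' @param id Dotted parameter identifier.
#' @param value Replacement value (for `set_param`).
#' @return `get_param` the scalar value; `set_param` the modified object
#'   (re-validated).
#' @export
get_param <- function(p, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  node <- p
  for (i in seq_along(parts)) {
    if (is.matrix(node)) {
      return(node[parts[i], parts[i + 1]])
    }
    node <- node[[parts[i]]]
    if (is.null(node)) stop("unknown parameter: ", id)
  }
  node
}

#' @rdname get_param
#' @export
set_param <- function(p, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  assign_rec <- function(node, parts) {
    if (is.matrix(node)) {
      stopifnot(length(parts) == 2)
      node[parts[1], parts[2]] <- value
      return(node)
    }
    if (length(parts) == 1) {
      if (is.null(node[[parts]])) stop("unknown parameter: ", id)
      node[[parts]] <- value
      return(node)
    }
    if (is.null(node[[parts[1]]])) stop("unknown parameter: ", id)
    node[[parts[1]]] <- assign_rec(node[[parts[1]]], parts[-1])
    node
  }
  cls <- class(p)
  p <- assign_rec(unclass(p), parts)
  class(p) <- cls
  validate_parameters(p)
  p
}

# ---- parameter registry: ids, bounds, distribution families --------------

# Enumerates every scalar model input varied in sensitivity analyses.
# kind drives both bound defaulting (probabilities are clipped to [0,1])
# and the PSA family: probability/utility -> beta, cost -> gamma,
# ratio -> lognormal, structural -> DSA only.
registry_ids <- function() {
  ids <- list()
  add <- function(id, kind, psa = TRUE) {
    ids[[length(ids) + 1]] <<- data.frame(id = id, kind = kind, psa = psa,
                                          stringsAsFactors = FALSE)
  }
  for (a in ARMS) {
    add(paste0("arms.", a, ".annual_drug_cost"), "cost",
        psa = (a != "asenapine")) # asenapine price has no published bounds
    add(paste0("arms.", a, ".switch_drug_annual_cost"), "cost")
    add(paste0("arms.", a, ".p_weight_gain_y1"), "probability")
    add(paste0("arms.", a, ".p_eps_y1"), "probability")
    add(paste0("arms.", a, ".p_switch_given_eps"), "probability")
  }
  for (cc in COMPLICATIONS) {
    for (ss in SEXES) {
      add(paste0("risks.odds_ratio.", cc, ".", ss), "ratio")
      add(paste0("risks.mortality_rr.", cc, ".", ss), "ratio")
      add(paste0("utilities.du_complication.", cc, ".", ss), "utility")
    }
  }
  add("utilities.u_bpd", "utility")
  add("utilities.du_weight_gain", "utility")
  add("utilities.du_eps", "utility")
  add("utilities.w_additional", "structural", psa = FALSE)
  add("costs.eps_management", "cost")
  for (f in names_direct_costs()) add(paste0("costs.direct.", f), "cost")
  for (cc in COMPLICATIONS) add(paste0("costs.productivity.", cc), "cost")
  add("costs.informal_care_stroke", "cost")
  add("epidemiology.p_fatal_given_chd_event", "probability")
  add("epidemiology.p_fatal_given_stroke_event", "probability")
  add("mortality.bpd_suicide_multiplier", "ratio")
  add("run.sex_mix", "structural", psa = FALSE)
  add("run.entry_age", "structural", psa = FALSE)
  add("run.discount_rate", "structural", psa = FALSE)
  do.call(rbind, ids)
}

names_direct_costs <- function() {
  c("diabetes", "hypertension", "chd_y1", "chd_y2plus", "chd_fatal",
    "stroke_y1", "stroke_y2plus", "stroke_fatal")
}

#' Sensitivity bounds for every model parameter
#'
#' Returns one row per scalar parameter with its base value and the lower /
#' upper bounds used in sensitivity analyses. Parameters with published
#' confidence bounds (carried in the configuration's `bounds` table) use
#' them; all others default to base x 0.75 / base x 1.25, with probabilities
#' clipped to \[0, 1\].
#'
#' @param p A `cua_params` object.
#' @return A data frame with columns `id`, `kind`, `psa`, `base`, `lower`,
#'   `upper`.
#' @export
parameter_bounds <- function(p) {
  reg <- registry_ids()
  reg$base <- vapply(reg$id, function(id) as.numeric(get_param(p, id)), 0.0)
  reg$lower <- NA_real_
  reg$upper <- NA_real_
  for (i in seq_len(nrow(reg))) {
    b <- p$bounds[[reg$id[i]]]
    if (!is.null(b)) {
      b <- vapply(b, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                  0.0)
      lo <- b[1]; hi <- b[2]
      if (is.na(lo)) lo <- reg$base[i] * 0.75
      if (is.na(hi)) hi <- reg$base[i] * 1.25
    } else {
      lo <- reg$base[i] * 0.75
      hi <- reg$base[i] * 1.25
    }
    if (reg$kind[i] %in% c("probability", "utility")) {
      lo <- min(max(lo, 0), 1)
      hi <- min(max(hi, 0), 1)
    }
    reg$lower[i] <- min(lo, hi)
    reg$upper[i] <- max(lo, hi)
  }
  rownames(reg) <- NULL
  reg
}

#' @export
print.cua_params <- function(x, ...) {
  cat("<cua_params>\n")
  cat("  arms:", paste(names(x$arms), collapse = ", "), "\n")
  cat(sprintf("  horizon %d y, discount %.1f%%, entry age %d, sex mix %.2f\n",
              x$run$horizon_years, 100 * x$run$discount_rate,
              x$run$entry_age, x$run$sex_mix))
  lt <- x$mortality$life_table
  cat(sprintf("  life table ages %s-%s; u_bpd %.3f\n",
              rownames(lt)[1], rownames(lt)[nrow(lt)], x$utilities$u_bpd))
  invisible(x)
}
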