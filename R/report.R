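# Result rendering and thin command-style entry points used by the
# inst/cli/bpdcua.R script.

#' Write base-case results to disk
#'
#' Runs the model and writes, under `out_dir`: `arm_outcomes.csv` (per-arm
#' per-perspective discounted totals), `per_cycle_<arm>_<perspective>.csv`
#' breakdowns, `icur.json`, and `report.txt`, a per-1,000-patients
#' cost-utility table per perspective. Every file is stamped with a hash of
#' the resolved parameter values for provenance.
#'
#' @param params A `cua_params` object (e.g. from [load_parameters()]).
#' @param out_dir Output directory (created if needed).
#' @param horizon Optional horizon override (years).
#' @param perspective `"moh"`, `"societal"` or `"both"`.
#' @return The `cua_result`, invisibly.
#' @export
cua_run <- function(params, out_dir, horizon = NULL, perspective = "both") {
  pers <- if (perspective == "both") PERSPECTIVES else perspective
  stopifnot(all(pers %in% PERSPECTIVES))
  res <- run_model(params, horizon = horizon)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- params_digest(params)

  rows <- list()
  for (a in names(res$arms)) {
    for (pp in pers) {
      o <- res$arms[[a]][[pp]]
      rows[[paste(a, pp)]] <- data.frame(
        arm = a, perspective = pp, horizon = o$horizon,
        total_cost = o$total_cost, total_qaly = o$total_qaly)
      utils::write.csv(o$per_cycle,
                       file.path(out_dir, sprintf("per_cycle_%s_%s.csv", a, pp)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "arm_outcomes.csv"), row.names = FALSE)

  icur <- lapply(res$icur[pers], function(ic) {
    list(delta_cost = ic$delta_cost, delta_qaly = ic$delta_qaly,
         icur = if (is.na(ic$icur)) NULL else ic$icur, label = ic$label)
  })
  jsonlite::write_json(list(config_hash = tag, horizon = res$horizon,
                            icur = icur),
                       file.path(out_dir, "icur.json"), auto_unbox = TRUE,
                       digits = NA)

  txt <- c(sprintf("Cost-utility results per %d patients (horizon %d years)",
                   params$run$cohort_size_report, res$horizon),
           sprintf("config hash: %s", tag), "")
  for (pp in pers) {
    txt <- c(txt, sprintf("== %s perspective ==", toupper(pp)),
             utils::capture.output(print(icur_table(res, pp), digits = 6)), "")
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(res)
}

#' Write one-way sensitivity results to disk
#'
#' Runs the deterministic sensitivity analysis and writes `dsa.csv`,
#' tornado-ordered (largest swing in incremental cost first within each
#' perspective).
#'
#' @inheritParams cua_run
#' @return The `dsa_result` data frame, invisibly.
#' @export
cua_dsa <- function(params, out_dir, horizon = NULL) {
  dsa <- run_dsa(params, horizon = horizon)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  swing <- stats::aggregate(delta_cost ~ id + perspective, data = dsa,
                            FUN = function(x) diff(range(x)))
  names(swing)[3] <- "swing"
  out <- merge(dsa, swing, by = c("id", "perspective"))
  out <- out[order(out$perspective, -out$swing, out$id, out$bound), ]
  out$config_hash <- params_digest(params)
  utils::write.csv(out, file.path(out_dir, "dsa.csv"), row.names = FALSE)
  invisible(dsa)
}

#' Run the probabilistic sensitivity analysis and write its outputs
#'
#' Writes `psa_draws.csv` (per-replication incremental cost/QALY pairs,
#' the cost-effectiveness plane), `ceac.csv`, and `psa_summary.json`
#' (fraction of replications with the intervention dominant, per
#' perspective).
#'
#' @inheritParams cua_run
#' @param n_reps Number of Monte Carlo replications.
#' @param seed Master seed.
#' @return The `psa_result`, invisibly.
#' @export
cua_psa <- function(params, out_dir, n_reps = 10000, seed = 1, horizon = NULL) {
  psa <- run_psa(params, n_reps = n_reps, seed = seed, horizon = horizon)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(psa$draws, file.path(out_dir, "psa_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(psa$ceac, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = params_digest(params), n_reps = psa$n_reps,
         seed = psa$seed,
         fraction_dominant = as.list(psa$fraction_dominant)),
    file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(psa)
}

# short content hash of the resolved parameter values (provenance stamp)
params_digest <- function(params) {
  reg <- parameter_bounds(params)
  payload <- paste(reg$id, signif(reg$base, 12), collapse = ";")
  # small FNV-1a style rolling hash; avoids a digest dependency
  h <- 216613626
  for (b in utf8ToInt(payload)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}
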