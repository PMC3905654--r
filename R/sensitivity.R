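# One-way deterministic sensitivity analysis over parameter bounds, and
# Monte Carlo probabilistic sensitivity analysis with CEAC output.

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full model once per parameter per bound (all other
#' parameters at base case) and records the incremental cost, incremental
#' QALYs and dominance verdict under both perspectives. Bounds come from
#' [parameter_bounds()]: published confidence limits where available,
#' otherwise +/-25%.
#'
#' @param params A `cua_params` object (base case).
#' @param horizon Optional horizon override (years).
#' @return A `dsa_result` data frame with columns `id`, `bound`
#'   (`"base"`, `"lower"`, `"upper"`), `value`, `perspective`,
#'   `delta_cost`, `delta_qaly`, `icur`, `label`.
#' @export
run_dsa <- function(params, horizon = NULL) {
  bounds <- parameter_bounds(params)
  rows <- list()
  push <- function(id, bound, value, res) {
    for (pp in PERSPECTIVES) {
      ic <- res$icur[[pp]]
      rows[[length(rows) + 1]] <<- data.frame(
        id = id, bound = bound, value = value, perspective = pp,
        delta_cost = ic$delta_cost, delta_qaly = ic$delta_qaly,
        icur = ic$icur, label = ic$label, stringsAsFactors = FALSE)
    }
  }
  push("(base case)", "base", NA_real_, run_model(params, horizon = horizon))
  for (i in seq_len(nrow(bounds))) {
    for (bd in c("lower", "upper")) {
      val <- bounds[[bd]][i]
      if (isTRUE(all.equal(val, bounds$base[i]))) {
        res <- run_model(params, horizon = horizon)
      } else {
        res <- run_model(set_param(params, bounds$id[i], val),
                         horizon = horizon)
      }
      push(bounds$id[i], bd, val, res)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dsa_result", class(out))
  out
}

#' Probability distributions for the probabilistic sensitivity analysis
#'
#' Assigns a sampling distribution to every parameter varied in the PSA,
#' calibrated by moment matching to the deterministic bounds interpreted as
#' a 95% interval: probabilities, utilities and disutility magnitudes get a
#' beta distribution (mean = base, sd = (upper - lower)/3.92); costs a
#' gamma distribution likewise; ratios (odds ratios, mortality risk ratios,
#' the suicide-rate multiplier) a lognormal with median = base and
#' `sdlog = (log(upper) - log(lower))/3.92`. Degenerate bounds (or base
#' values of exactly 0 or 1, where the families collapse) yield a point
#' mass. Structural parameters and parameters without published uncertainty
#' by design (the intervention drug price) are excluded.
#'
#' @param params A `cua_params` object.
#' @return A data frame with columns `id`, `family` (`"beta"`, `"gamma"`,
#'   `"lognormal"`, `"point"`), `base`, and the family parameters
#'   `par1`/`par2` (shape1/shape2, shape/rate, meanlog/sdlog).
#' @export
assign_distributions <- function(params) {
  b <- parameter_bounds(params)
  b <- b[b$psa, ]
  if (any(b$lower > b$upper)) stop("infeasible bounds: lower > upper")
  out <- data.frame(id = b$id, family = "point", base = b$base,
                    par1 = NA_real_, par2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(b))) {
    m <- b$base[i]
    s <- (b$upper[i] - b$lower[i]) / (2 * stats::qnorm(0.975))
    if (s <= 0) next
    if (b$kind[i] %in% c("probability", "utility")) {
      if (m <= 0 || m >= 1) next
      v <- min(s^2, 0.95 * m * (1 - m)) # keep beta parameters positive
      nu <- m * (1 - m) / v - 1
      out$family[i] <- "beta"
      out$par1[i] <- m * nu
      out$par2[i] <- (1 - m) * nu
    } else if (b$kind[i] == "cost") {
      if (m <= 0) next
      out$family[i] <- "gamma"
      out$par1[i] <- m^2 / s^2   # shape
      out$par2[i] <- m / s^2     # rate
    } else if (b$kind[i] == "ratio") {
      if (m <= 0 || b$lower[i] <= 0) next
      out$family[i] <- "lognormal"
      out$par1[i] <- log(m)
      out$par2[i] <- (log(b$upper[i]) - log(b$lower[i])) / (2 * stats::qnorm(0.975))
    }
  }
  out
}

# one joint draw from the assigned distributions (uses the current RNG state)
draw_parameter_set <- function(dists) {
  n <- nrow(dists)
  vals <- dists$base
  for (i in seq_len(n)) {
    vals[i] <- switch(dists$family[i],
      point = dists$base[i],
      beta = stats::rbeta(1, dists$par1[i], dists$par2[i]),
      gamma = stats::rgamma(1, shape = dists$par1[i], rate = dists$par2[i]),
      lognormal = stats::rlnorm(1, dists$par1[i], dists$par2[i])
    )
  }
  stats::setNames(vals, dists$id)
}

# assign many scalar values without re-validating after each one
apply_draws <- function(params, values) {
  cls <- class(params)
  p <- unclass(params)
  for (id in names(values)) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    p <- assign_path(p, parts, values[[id]])
  }
  class(p) <- cls
  validate_parameters(p)
  p
}

assign_path <- function(node, parts, value) {
  if (is.matrix(node)) {
    node[parts[1], parts[2]] <- value
    return(node)
  }
  if (length(parts) == 1) {
    node[[parts]] <- value
    return(node)
  }
  node[[parts[1]]] <- assign_path(node[[parts[1]]], parts[-1], value)
  node
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Jointly re-samples every PSA parameter from its assigned distribution
#' (independently across parameters), runs the full model per replication,
#' and records the incremental cost and QALY pair under both perspectives.
#' Reports the fraction of replications in which the intervention is
#' dominant (cheaper and more effective) and the cost-effectiveness
#' acceptability curve. Per-replication RNG substreams are derived
#' deterministically from the master seed, so results do not depend on
#' evaluation order.
#'
#' @param params A `cua_params` object (base case).
#' @param n_reps Number of Monte Carlo replications (>= 1).
#' @param seed Master seed (integer).
#' @param horizon Optional horizon override (years).
#' @param thresholds Willingness-to-pay grid ($/QALY) for the CEAC.
#' @return A `psa_result`: list with `n_reps`, `seed`, `draws` (data frame
#'   of per-replication deltas), `fraction_dominant` (named by
#'   perspective), `ceac` (long data frame of threshold x perspective x
#'   probability cost-effective).
#' @export
run_psa <- function(params, n_reps = 10000, seed = 1, horizon = NULL,
                    thresholds = seq(0, 100000, by = 5000)) {
  if (n_reps < 1) stop("run_psa: n_reps must be >= 1")
  dists <- assign_distributions(params)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)

  draws <- matrix(NA_real_, n_reps, 4,
                  dimnames = list(NULL, c("delta_cost_moh", "delta_qaly_moh",
                                          "delta_cost_societal",
                                          "delta_qaly_societal")))
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    vals <- draw_parameter_set(dists)
    res <- run_model(apply_draws(params, vals), horizon = horizon)
    draws[i, ] <- c(res$icur$moh$delta_cost, res$icur$moh$delta_qaly,
                    res$icur$societal$delta_cost, res$icur$societal$delta_qaly)
  }
  draws <- as.data.frame(draws)

  frac_dom <- c(
    moh = mean(draws$delta_cost_moh < 0 & draws$delta_qaly_moh > 0),
    societal = mean(draws$delta_cost_societal < 0 & draws$delta_qaly_societal > 0)
  )
  ceac <- do.call(rbind, lapply(PERSPECTIVES, function(pp) {
    dc <- draws[[paste0("delta_cost_", pp)]]
    dq <- draws[[paste0("delta_qaly_", pp)]]
    data.frame(perspective = pp, threshold = thresholds,
               p_cost_effective = vapply(thresholds, function(l) {
                 mean(l * dq - dc > 0)
               }, 0.0))
  }))

  structure(list(n_reps = n_reps, seed = seed, draws = draws,
                 fraction_dominant = frac_dom, ceac = ceac),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d replications (seed %d)\n", x$n_reps, x$seed))
  cat(sprintf("  fraction dominant: MoH %.3f, societal %.3f\n",
              x$fraction_dominant[["moh"]], x$fraction_dominant[["societal"]]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param psa A `psa_result` from [run_psa()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ceac <- function(psa) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ceac requires ggplot2")
  }
  ggplot2::ggplot(psa$ceac,
                  ggplot2::aes(x = .data$threshold, y = .data$p_cost_effective,
                               colour = .data$perspective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "P(cost-effective)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
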