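# Model-driven selection of flow rates and module volumes under
# physiologic-concentration and response-time constraints.

#' Design constraints for flow/volume selection
#'
#' @param analyte analyte whose peak concentration is constrained.
#' @param window numeric `c(low, high)` pg/ml applied to the peak simulated
#'   concentration in `module` over the 28-day run.
#' @param module module id the window applies to.
#' @param response_time_bound_h optional upper bound (hours) on the
#'   acceptor 90% step-response time.
#' @param objective `"min_response_time"` or `"min_lag"`.
#' @return a `design_constraints` list.
#' @export
design_constraints <- function(analyte, window, module,
                               response_time_bound_h = NULL,
                               objective = c("min_response_time", "min_lag")) {
  objective <- match.arg(objective)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!is.null(response_time_bound_h)) stopifnot(response_time_bound_h > 0)
  structure(list(analyte = analyte, window = window, module = module,
                 response_time_bound_h = response_time_bound_h,
                 objective = objective),
            class = "design_constraints")
}

rebuild_candidate <- function(template, volume, through, recirc_mult) {
  if (is.null(template$preset)) {
    stop("design search needs a preset-derived template (make_platform)",
         call. = FALSE)
  }
  make_platform(template$preset, tissue_volume = volume,
                through_flow = through,
                recirc_flow = if (template$preset == "quintet")
                  recirc_mult * through else NULL)
}

evaluate_candidate <- function(config, secretion, constraints, t_grid,
                               need_lag = FALSE) {
  traj <- simulate_platform(config, secretion, t_grid)
  peak <- max(trajectory_series(traj, constraints$module,
                                constraints$analyte))
  resp <- step_response_time(config, config$acceptor_id, fraction = 0.90)
  max_lag <- NA_real_
  if (need_lag) {
    lp <- lag_profile(config)
    max_lag <- if (nrow(lp)) max(lp$lag_h) else 0
  }
  list(peak = peak, response_time_h = resp, max_lag_h = max_lag)
}

#' Exhaustive grid search for a feasible flow/volume configuration
#'
#' Evaluates every combination of tissue-module volume, through-system
#' flow and recirculation multiplier (deterministic order: volumes
#' ascending, flows ascending, multipliers ascending). Each candidate is
#' simulated over the 28-day horizon under the given secretion; a
#' candidate is feasible when the named module's peak concentration falls
#' in the window (and, if given, the acceptor 90% response time is within
#' its bound). Among feasible candidates, the stated objective is
#' minimized; ties go to the smaller total system volume, then the smaller
#' through-flow.
#'
#' @param template a preset-derived [platform_config()] (used as the
#'   topology to rebuild at each grid point).
#' @param secretion a [secretion_spec()] naming modules of the template.
#' @param constraints a [design_constraints()].
#' @param volumes tissue-module volumes to try (ml).
#' @param flows through-system flows to try (ml/h).
#' @param recirc_mults recirculation multipliers (Q_R = mult * Q_D);
#'   ignored for presets without a recirculation loop.
#' @param t_grid simulation grid in hours (default hourly over 28 days).
#' @return a `design_result` with the selected config, achieved metrics,
#'   feasibility flag and grid size.
#' @export
find_flow_config <- function(template, secretion, constraints,
                             volumes = c(0.1, 0.2, 0.4, 0.7),
                             flows = seq(0.02, 0.2, by = 0.02),
                             recirc_mults = c(0, 1, 10),
                             t_grid = seq(0, 28 * 24, by = 1)) {
  stopifnot(inherits(template, "platform_config"),
            inherits(constraints, "design_constraints"),
            length(volumes) > 0, length(flows) > 0)
  if (is.null(template$preset) || template$preset != "quintet") {
    recirc_mults <- 0
  }
  need_lag <- constraints$objective == "min_lag"
  best <- NULL
  best_violation <- NULL
  n_grid <- 0L
  for (v in sort(volumes)) for (q in sort(flows)) for (m in sort(recirc_mults)) {
    n_grid <- n_grid + 1L
    cand <- rebuild_candidate(template, v, q, m)
    met <- evaluate_candidate(cand, secretion, constraints, t_grid,
                              need_lag = need_lag)
    ok <- met$peak >= constraints$window[1] &&
      met$peak <= constraints$window[2]
    if (!is.null(constraints$response_time_bound_h)) {
      ok <- ok && met$response_time_h <= constraints$response_time_bound_h
    }
    score <- if (need_lag) met$max_lag_h else met$response_time_h
    total_v <- sum(cand$modules$volume_ml)
    key <- c(score, total_v, q)
    if (ok) {
      if (is.null(best) || lexico_less(key, best$key)) {
        best <- list(config = cand, metrics = met, key = key,
                     volume = v, flow = q, mult = m)
      }
    } else if (is.null(best)) {
      # distance to the window, to report the best-violating candidate
      viol <- max(constraints$window[1] - met$peak,
                  met$peak - constraints$window[2], 0)
      if (is.null(best_violation) || viol < best_violation$viol) {
        best_violation <- list(config = cand, metrics = met, viol = viol)
      }
    }
  }
  feasible <- !is.null(best)
  chosen <- if (feasible) best else best_violation
  structure(list(
    config = chosen$config,
    feasible = feasible,
    response_time_h = chosen$metrics$response_time_h,
    peak_pg_per_ml = chosen$metrics$peak,
    max_lag_h = chosen$metrics$max_lag_h,
    n_grid = n_grid,
    objective = constraints$objective),
    class = "design_result")
}

lexico_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", if (x$feasible) "feasible" else "INFEASIBLE",
      " (grid size ", x$n_grid, ")\n", sep = "")
  cat("  acceptor 90% response time: ", round(x$response_time_h, 2), " h (",
      round(x$response_time_h / 24, 3), " days)\n", sep = "")
  cat("  peak concentration: ", signif(x$peak_pg_per_ml, 4), " pg/ml\n",
      sep = "")
  if (!is.na(x$max_lag_h)) {
    cat("  max intermodule lag: ", round(x$max_lag_h, 2), " h\n", sep = "")
  }
  invisible(x)
}

#' Lag between consecutive modules under a donor step
#'
#' Simulates a unit donor concentration step and reports the 50%-crossing
#' lag for each consecutive pair of modules in [transit_order()].
#'
#' @param config a flow-balanced [platform_config()].
#' @param fraction crossing fraction (default 0.50).
#' @return data frame with columns `from`, `to`, `lag_h`; zero rows when
#'   the transit order has fewer than two modules.
#' @export
lag_profile <- function(config, fraction = 0.50) {
  ord <- transit_order(config)
  if (length(ord) < 2) {
    return(data.frame(from = character(0), to = character(0),
                      lag_h = numeric(0)))
  }
  fr <- flow_rates(config)
  active_out <- fr$outflow[fr$outflow > 0]
  horizon <- 40 * sum(config$modules$volume_ml) / min(active_out)
  grid <- seq(0, horizon, length.out = 4000L)
  traj <- simulate_platform(config, secretion_spec(list()), grid,
                            donor_forcing = list(step = function(t) 1))
  pairs <- data.frame(from = ord[-length(ord)], to = ord[-1],
                      stringsAsFactors = FALSE)
  pairs$lag_h <- vapply(seq_len(nrow(pairs)), function(i) {
    intermodule_lag(traj, pairs$from[i], pairs$to[i], fraction = fraction,
                    analyte = "step")
  }, numeric(1))
  pairs
}
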