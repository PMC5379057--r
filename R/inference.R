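# Recovery of secretion parameters from noisy, left-censored effluent
# series, and the comparative statistics used across platforms.

#' Estimate a constant secretion rate from effluent measurements
#'
#' Inverts the steady-state balance of the platform: for a single
#' secreting module, the measured module's steady concentration is
#' proportional to the production rate, `C = s * R`, where the
#' sensitivity `s` (pg/ml per pg/h) comes from solving the balance system
#' with unit production. For a plain donor-tissue-acceptor cascade
#' `s = 1/Q`, recovering the familiar `R = Q * C`. The estimate is the
#' least-squares fit of a constant to the uncensored measurements in the
#' declared steady window; censored records are excluded (conservative).
#'
#' @param meas a `measurement_series` (one analyte).
#' @param config the flow-balanced [platform_config()] the series came
#'   from.
#' @param window numeric `c(first_day, last_day)` of the caller-declared
#'   steady-state window.
#' @param secreting_module id of the producing module (default: the first
#'   tissue module).
#' @param measured_module id of the sampled module (default: the series'
#'   `module` attribute, else the acceptor).
#' @return a `rate_estimate` list: `module`, `analyte`, `rate_pg_per_h`,
#'   `se`, `n_days`, `method`.
#' @export
estimate_secretion_rates <- function(meas, config, window,
                                     secreting_module = NULL,
                                     measured_module = NULL) {
  stopifnot(inherits(config, "platform_config"), length(window) == 2)
  if (is.null(secreting_module)) {
    secreting_module <- config$modules$id[config$modules$role == "tissue"][1L]
  }
  if (is.null(measured_module)) {
    measured_module <- attr(meas, "module")
    if (is.null(measured_module)) measured_module <- config$acceptor_id
  }
  analyte <- unique(meas$analyte)
  if (length(analyte) != 1L) {
    stop("measurement series must contain exactly one analyte", call. = FALSE)
  }
  inwin <- meas$day >= window[1] & meas$day <= window[2]
  usable <- inwin & !meas$censored
  if (!any(usable)) {
    stop("all-censored window: no uncensored measurements between days ",
         window[1], " and ", window[2], call. = FALSE)
  }
  if (sum(usable) < 3) {
    stop("need at least 3 uncensored measurements in the window",
         call. = FALSE)
  }
  unit_spec <- secretion_spec(secreting(secreting_module, analyte,
                                        production = 1))
  s <- steady_state(config, unit_spec)[[analyte]][[measured_module]]
  if (!is.finite(s) || s <= 0) {
    stop("measured module '", measured_module,
         "' receives nothing from '", secreting_module, "'", call. = FALSE)
  }
  y <- meas$value[usable]
  n <- length(y)
  cbar <- mean(y)
  se_c <- stats::sd(y) / sqrt(n)
  structure(list(module = secreting_module, analyte = analyte,
                 rate_pg_per_h = cbar / s, se = se_c / s, n_days = n,
                 method = "steady_state_least_squares"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> ", x$analyte, " in ", x$module, ": ",
      signif(x$rate_pg_per_h, 4), " pg/h (se ", signif(x$se, 3),
      ", n = ", x$n_days, ")\n", sep = "")
  invisible(x)
}

#' Normalize effluent concentrations to per-tissue-unit daily production
#'
#' Converts a measured effluent concentration into a production rate per
#' biological unit and day: `value * flow * 24 / n_units` (pg per unit per
#' day). Censoring flags are propagated.
#'
#' @param meas a `measurement_series`.
#' @param flow_ml_h through-system flow in ml/h (> 0).
#' @param n_units number of tissue units (e.g. follicles per bead; >= 1).
#' @return data frame `day`, `analyte`, `rate_pg_per_unit_per_day`,
#'   `censored`.
#' @export
per_tissue_rate <- function(meas, flow_ml_h, n_units) {
  if (!is.numeric(flow_ml_h) || flow_ml_h <= 0) {
    stop("flow must be positive", call. = FALSE)
  }
  if (!is.numeric(n_units) || n_units < 1) {
    stop("n_units must be >= 1", call. = FALSE)
  }
  data.frame(day = meas$day, analyte = meas$analyte,
             rate_pg_per_unit_per_day = meas$value * flow_ml_h * 24 / n_units,
             censored = meas$censored, stringsAsFactors = FALSE)
}

series_statistic <- function(meas, statistic) {
  ok <- !meas$censored
  if (!any(ok)) stop("no uncensored records", call. = FALSE)
  if (statistic == "peak") {
    max(meas$value[ok])
  } else {
    d <- meas$day[ok]; v <- meas$value[ok]
    o <- order(d)
    d <- d[o]; v <- v[o]
    if (length(d) < 2) stop("AUC needs >= 2 uncensored records",
                            call. = FALSE)
    sum(diff(d) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  }
}

#' Fold change between two measurement series
#'
#' Compares like-for-like summary statistics of two effluent series:
#' the uncensored peak, or the trapezoid area under the curve over days.
#'
#' @param series_a,series_b `measurement_series` for the same analyte.
#' @param statistic `"peak"` or `"auc"`.
#' @return a `fold_change_record` list: `analyte`, `statistic`, `value_a`,
#'   `value_b`, `fold` (= a/b).
#' @examples
#' # peaks 6000 vs 100 give a 60-fold difference
#' @export
fold_change <- function(series_a, series_b, statistic = c("peak", "auc")) {
  statistic <- match.arg(statistic)
  an_a <- unique(series_a$analyte); an_b <- unique(series_b$analyte)
  if (length(an_a) != 1L || length(an_b) != 1L || an_a != an_b) {
    stop("both series must carry the same single analyte", call. = FALSE)
  }
  a <- series_statistic(series_a, statistic)
  b <- series_statistic(series_b, statistic)
  if (b == 0) stop("zero denominator statistic", call. = FALSE)
  structure(list(analyte = an_a, statistic = statistic,
                 value_a = a, value_b = b, fold = a / b),
            class = "fold_change_record")
}

#' @export
print.fold_change_record <- function(x, ...) {
  cat("<fold_change> ", x$analyte, " ", x$statistic, ": ",
      signif(x$value_a, 4), " / ", signif(x$value_b, 4), " = ",
      signif(x$fold, 4), "\n", sep = "")
  invisible(x)
}
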