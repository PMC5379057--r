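# Seven-compartment (general n-compartment) well-mixed mass balance:
#   V_i dC_i/dt = sum_in Q_in C_src - sum_out Q_out C_i + R_i(t) - k_i V_i C_i
# Donor draws fresh media (concentration 0) at its net outflow rate; the
# acceptor discharges collected media at its inflow rate, so all volumes are
# constant. Concentrations are pg/ml, rates pg/h, flows ml/h, time hours.

CULTURE_START_DAY <- -14 # t = 0 h is culture day -14; the hCG surge is day 0

#' Convert hours since culture start to cycle day
#'
#' The 28-day culture starts at day −14; the ovulatory (hCG) surge is day 0,
#' splitting the follicular (−14..0) and luteal (0..14) phases.
#'
#' @param t_h hours since culture start.
#' @return culture day relative to the surge.
#' @export
hours_to_day <- function(t_h) t_h / 24 + CULTURE_START_DAY

#' @rdname hours_to_day
#' @param day culture day relative to the surge.
#' @export
day_to_hours <- function(day) (day - CULTURE_START_DAY) * 24

#' Describe production and elimination of analytes in platform modules
#'
#' A secretion specification lists, per module and analyte, a zero-order
#' production rate (pg/h; a constant or a function of time in hours) and an
#' optional first-order elimination constant (per hour, e.g. tissue
#' consumption). Modules without an entry default to no production and no
#' elimination.
#'
#' @param ... entries created by [secreting()].
#' @return an object of class `secretion_spec`.
#' @examples
#' spec <- secretion_spec(secreting("tissue", "E2", production = 4))
#' @export
secretion_spec <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) &&
      !inherits(entries[[1L]], "secretion_entry")) {
    entries <- entries[[1L]]
  }
  for (e in entries) {
    if (!inherits(e, "secretion_entry")) {
      stop("secretion_spec() takes entries built with secreting()",
           call. = FALSE)
    }
  }
  structure(list(entries = entries), class = "secretion_spec")
}

#' @rdname secretion_spec
#' @param module module id.
#' @param analyte analyte name.
#' @param production zero-order rate in pg/h: a nonnegative constant or a
#'   function of time (hours) returning pg/h.
#' @param elimination first-order constant in 1/h (>= 0).
#' @export
secreting <- function(module, analyte, production = 0, elimination = 0) {
  if (is.numeric(production) && production < 0) {
    stop("production rate must be >= 0", call. = FALSE)
  }
  if (elimination < 0) stop("elimination must be >= 0", call. = FALSE)
  structure(list(module = module, analyte = analyte, production = production,
                 elimination = elimination),
            class = "secretion_entry")
}

spec_analytes <- function(secretion) {
  unique(vapply(secretion$entries, `[[`, "", "analyte"))
}

spec_entry <- function(secretion, module, analyte) {
  for (e in secretion$entries) {
    if (e$module == module && e$analyte == analyte) return(e)
  }
  NULL
}

# production as a vectorised function of hours, regardless of how given
production_fun <- function(entry) {
  if (is.null(entry)) return(function(t) rep(0, length(t)))
  p <- entry$production
  if (is.function(p)) p else function(t) rep(p, length(t))
}

spec_is_constant <- function(secretion) {
  all(vapply(secretion$entries, function(e) is.numeric(e$production),
             logical(1)))
}

# --- system assembly -------------------------------------------------------

# Flow rate matrix Q[i, j]: flow from module j into module i (ml/h), plus
# per-module total outflow including the acceptor's implicit discharge.
flow_rates <- function(config) {
  ids <- config$modules$id
  n <- length(ids)
  Qin <- matrix(0, n, n, dimnames = list(ids, ids))
  outflow <- stats::setNames(numeric(n), ids)
  p <- config$paths
  for (i in seq_len(nrow(p))) {
    Qin[p$dst[i], p$src[i]] <- Qin[p$dst[i], p$src[i]] + p$rate_ml_h[i]
    outflow[p$src[i]] <- outflow[p$src[i]] + p$rate_ml_h[i]
  }
  # acceptor discharges what it receives (daily media collection)
  acc <- config$acceptor_id
  outflow[acc] <- outflow[acc] + sum(Qin[acc, ])
  list(Qin = Qin, outflow = outflow)
}

# Linear system dC/dt = A C + b(t) for one analyte. When the donor
# concentration is externally forced (Dirichlet), the donor state is dropped
# and its contribution enters b(t).
assemble_system <- function(config, secretion, analyte, donor_forced = FALSE) {
  ids <- config$modules$id
  V <- stats::setNames(config$modules$volume_ml, ids)
  fr <- flow_rates(config)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  k <- stats::setNames(numeric(n), ids)
  prod_funs <- vector("list", n); names(prod_funs) <- ids
  for (id in ids) {
    e <- spec_entry(secretion, id, analyte)
    k[id] <- if (is.null(e)) 0 else e$elimination
    prod_funs[[id]] <- production_fun(e)
  }
  for (i in ids) {
    A[i, i] <- -(fr$outflow[i] / V[i]) - k[i]
    for (j in ids) if (i != j && fr$Qin[i, j] > 0) {
      A[i, j] <- A[i, j] + fr$Qin[i, j] / V[i]
    }
  }
  donor <- config$donor_id
  if (donor_forced) {
    keep <- setdiff(ids, donor)
    donor_in <- A[keep, donor, drop = TRUE] # 1/h per unit donor conc
    A <- A[keep, keep, drop = FALSE]
    list(ids = keep, A = A, V = V[keep], prod_funs = prod_funs[keep],
         donor_in = donor_in, donor = donor)
  } else {
    list(ids = ids, A = A, V = V, prod_funs = prod_funs,
         donor_in = NULL, donor = donor)
  }
}

DEFAULT_SOLVER_OPTS <- list(rtol = 1e-8, atol = 1e-12, method = "lsoda")

# --- trajectory container --------------------------------------------------

new_trajectory <- function(time_h, conc) {
  # conc: list analyte -> matrix [time x module]
  stopifnot(length(time_h) >= 1, all(diff(time_h) > 0))
  structure(list(time_h = time_h, day = hours_to_day(time_h), conc = conc),
            class = "mfp_trajectory")
}

#' @export
print.mfp_trajectory <- function(x, ...) {
  cat("<mfp_trajectory> ", length(x$time_h), " time points, ",
      "day ", round(min(x$day), 2), " to ", round(max(x$day), 2), "\n",
      "  analytes: ", paste(names(x$conc), collapse = ", "), "\n",
      "  modules:  ", paste(colnames(x$conc[[1]]), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Extract one concentration series from a trajectory
#'
#' @param traj an `mfp_trajectory` from [simulate_platform()].
#' @param module module id.
#' @param analyte analyte name.
#' @return numeric vector of pg/ml aligned with `traj$time_h`.
#' @export
trajectory_series <- function(traj, module, analyte) {
  stopifnot(inherits(traj, "mfp_trajectory"))
  if (!analyte %in% names(traj$conc)) {
    stop("analyte '", analyte, "' not in trajectory", call. = FALSE)
  }
  m <- traj$conc[[analyte]]
  if (!module %in% colnames(m)) {
    stop("module '", module, "' not in trajectory", call. = FALSE)
  }
  m[, module]
}

#' Convert a trajectory to a long data frame
#'
#' @param traj an `mfp_trajectory`.
#' @return data frame with columns `time_h`, `day`, `module_id`, `analyte`,
#'   `concentration_pg_per_ml`.
#' @export
as_trajectory_df <- function(traj) {
  stopifnot(inherits(traj, "mfp_trajectory"))
  out <- do.call(rbind, lapply(names(traj$conc), function(an) {
    m <- traj$conc[[an]]
    do.call(rbind, lapply(colnames(m), function(mod) {
      data.frame(time_h = traj$time_h, day = traj$day, module_id = mod,
                 analyte = an, concentration_pg_per_ml = m[, mod],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# --- simulation ------------------------------------------------------------

#' Simulate hormone distribution through a platform
#'
#' Integrates the well-mixed mass balance for every module and analyte.
#' Each analyte is independent, so the system is solved per analyte with a
#' stiff-capable solver and fixed tolerances for deterministic output.
#'
#' @param config a flow-balanced [platform_config()].
#' @param secretion a [secretion_spec()].
#' @param t_grid strictly increasing time grid in hours since culture start.
#' @param init optional initial state: named list `analyte -> named vector
#'   of pg/ml by module id`; missing entries start at 0.
#' @param donor_forcing optional named list `analyte -> function(t_h)` that
#'   prescribes the donor concentration externally (spike or step
#'   experiments); the donor then no longer obeys its own balance.
#' @param solver_opts list with `rtol`, `atol`, `method` (defaults
#'   `1e-8`, `1e-12`, `"lsoda"`).
#' @return an `mfp_trajectory`.
#' @examples
#' solo <- make_platform("solo")
#' spec <- secretion_spec(secreting("tissue", "E2", production = 4))
#' traj <- simulate_platform(solo, spec, t_grid = seq(0, 240, by = 1))
#' max(trajectory_series(traj, "acceptor", "E2")) # approaches 4/0.04 = 100
#' @export
simulate_platform <- function(config, secretion, t_grid, init = NULL,
                              donor_forcing = NULL, solver_opts = list()) {
  stopifnot(inherits(config, "platform_config"),
            inherits(secretion, "secretion_spec"))
  bal <- validate_flow_balance(config)
  if (nrow(bal) > 0) {
    stop("platform is not flow-balanced (module(s): ",
         paste(bal$module_id, collapse = ", "), ")", call. = FALSE)
  }
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing with >= 2 points", call. = FALSE)
  }
  opts <- utils::modifyList(DEFAULT_SOLVER_OPTS, solver_opts)
  analytes <- unique(c(spec_analytes(secretion), names(donor_forcing)))
  if (!length(analytes)) {
    stop("no analytes: supply secretion entries or donor forcing",
         call. = FALSE)
  }
  ids <- config$modules$id
  conc <- vector("list", length(analytes)); names(conc) <- analytes

  for (an in analytes) {
    forced <- !is.null(donor_forcing[[an]])
    sys <- assemble_system(config, secretion, an, donor_forced = forced)
    y0 <- stats::setNames(numeric(length(sys$ids)), sys$ids)
    if (!is.null(init[[an]])) {
      given <- init[[an]]
      if (any(given < 0)) stop("initial concentrations must be >= 0",
                               call. = FALSE)
      common <- intersect(names(given), sys$ids)
      y0[common] <- given[common]
    }
    prod_per_vol <- sys$prod_funs
    Vinv <- 1 / sys$V
    cd_fun <- if (forced) donor_forcing[[an]] else NULL
    deriv <- function(t, y, parms) {
      b <- vapply(seq_along(sys$ids),
                  function(i) prod_per_vol[[i]](t) * Vinv[i], numeric(1))
      if (forced) b <- b + sys$donor_in * cd_fun(t)
      list(as.vector(sys$A %*% y) + b)
    }
    sol <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = NULL,
                        method = opts$method, rtol = opts$rtol,
                        atol = opts$atol,
                        jacfunc = function(t, y, parms) sys$A,
                        jactype = "fullusr")
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE solver failed for analyte '", an, "' near t = ",
           max(sol[, 1L]), " h", call. = FALSE)
    }
    m <- sol[, sys$ids, drop = FALSE]
    # clamp solver jitter; anything more negative is a real failure
    low <- min(m)
    if (low < -1e-9) {
      stop("negative concentration (", signif(low, 3),
           ") produced for analyte '", an, "'", call. = FALSE)
    }
    m[m < 0] <- 0
    if (forced) {
      m <- cbind(m, vapply(t_grid, cd_fun, numeric(1)))
      colnames(m)[ncol(m)] <- sys$donor
      m <- m[, ids, drop = FALSE]
    }
    conc[[an]] <- m
  }
  new_trajectory(t_grid, conc)
}

#' Steady-state concentrations under constant secretion
#'
#' Solves the linear balance system directly for `dC/dt = 0`. Modules with
#' no flow, no elimination and no production are inert and sit at zero;
#' an inert module *with* production has no sink and no steady state.
#'
#' @param config a flow-balanced [platform_config()].
#' @param secretion a [secretion_spec()] with constant (numeric) rates.
#' @return named list `analyte -> named vector of pg/ml by module id`.
#' @examples
#' solo <- make_platform("solo")
#' spec <- secretion_spec(secreting("tissue", "E2", production = 4))
#' steady_state(solo, spec)$E2[["acceptor"]] # 100 = R/Q
#' @export
steady_state <- function(config, secretion) {
  stopifnot(inherits(config, "platform_config"),
            inherits(secretion, "secretion_spec"))
  if (!spec_is_constant(secretion)) {
    stop("steady_state() needs constant production rates", call. = FALSE)
  }
  bal <- validate_flow_balance(config)
  if (nrow(bal) > 0) stop("platform is not flow-balanced", call. = FALSE)
  ids <- config$modules$id
  out <- list()
  for (an in spec_analytes(secretion)) {
    sys <- assemble_system(config, secretion, an)
    b <- vapply(seq_along(sys$ids),
                function(i) sys$prod_funs[[i]](0) / sys$V[i], numeric(1))
    active <- abs(diag(sys$A)) > 0 | abs(b) > 0
    # inert modules (zero row and zero production) are dropped at C = 0
    inert <- !active & colSums(abs(sys$A)) == abs(diag(sys$A))
    drop_ids <- sys$ids[inert & b == 0]
    if (any(inert & b != 0)) {
      stop("singular balance matrix: module with production but no outflow",
           call. = FALSE)
    }
    keep <- setdiff(sys$ids, drop_ids)
    Ak <- sys$A[keep, keep, drop = FALSE]
    cs <- tryCatch(solve(Ak, -b[match(keep, sys$ids)]),
                   error = function(e) {
                     stop("singular balance matrix: ", conditionMessage(e),
                          call. = FALSE)
                   })
    full <- stats::setNames(numeric(length(ids)), ids)
    full[keep] <- cs
    out[[an]] <- full
  }
  out
}

# Steady state of the donor-forced subsystem under unit donor concentration.
forced_steady <- function(sys) {
  solve(sys$A, -sys$donor_in)
}

#' Step-response time of a module to a donor concentration step
#'
#' Applies a unit step in donor concentration at `t = 0` from an all-zero
#' state (no secretion) and returns the first time the observed module
#' reaches `fraction` of its new steady value, reported to 0.01 h.
#'
#' @param config a flow-balanced [platform_config()].
#' @param observed_module module id to monitor.
#' @param fraction fraction of the new steady value (0 < fraction < 1),
#'   default 0.90.
#' @param solver_opts passed to [simulate_platform()].
#' @return time in hours.
#' @examples
#' solo1 <- make_platform("solo")
#' # a single 0.7 ml module at 0.04 ml/h charges with tau = V/Q = 17.5 h:
#' step_response_time(solo1, "tissue", fraction = 0.9) # (V/Q) ln 10 = 40.30
#' @export
step_response_time <- function(config, observed_module, fraction = 0.90,
                               solver_opts = list()) {
  stopifnot(fraction > 0, fraction < 1)
  if (!observed_module %in% config$modules$id) {
    stop("unknown module '", observed_module, "'", call. = FALSE)
  }
  empty <- secretion_spec(list())
  sys <- assemble_system(config, empty, "step", donor_forced = TRUE)
  if (observed_module == config$donor_id) return(0)
  # unwired modules have an all-zero balance row; drop them so the forced
  # subsystem is nonsingular
  active <- sys$ids[abs(diag(sys$A)) > 0]
  if (!observed_module %in% active) {
    stop("module '", observed_module,
         "' is unreachable from the donor and never responds", call. = FALSE)
  }
  sub <- sys
  sub$A <- sys$A[active, active, drop = FALSE]
  sub$donor_in <- sys$donor_in[active]
  sub$ids <- active
  target_inf <- tryCatch(unname(forced_steady(sub)[observed_module]),
                         error = function(e) NA_real_)
  if (!is.finite(target_inf) || target_inf <= 0) {
    stop("module '", observed_module,
         "' is unreachable from the donor and never responds", call. = FALSE)
  }
  target <- fraction * target_inf
  forcing <- list(step = function(t) 1)

  # coarse pass over an expanding horizon, then a fine pass over the bracket
  fr <- flow_rates(config)
  active <- names(fr$outflow)[fr$outflow > 0]
  horizon <- 10 * sum(config$modules$volume_ml[config$modules$id %in% active]) /
    min(fr$outflow[fr$outflow > 0])
  for (tries in 1:6) {
    grid <- seq(0, horizon, length.out = 600L)
    traj <- simulate_platform(config, empty, grid, donor_forcing = forcing,
                              solver_opts = solver_opts)
    ser <- trajectory_series(traj, observed_module, "step")
    hit <- which(ser >= target)
    if (length(hit)) break
    horizon <- horizon * 4
  }
  if (!length(hit)) {
    stop("module '", observed_module, "' did not reach ", fraction,
         " of steady state within ", signif(horizon, 3), " h", call. = FALSE)
  }
  i <- hit[1L]
  lo <- if (i == 1L) 0 else grid[i - 1L]
  hi <- grid[i]
  fine <- seq(lo, hi, length.out = 2001L)
  if (fine[1L] > 0) fine <- c(0, fine)
  traj <- simulate_platform(config, empty, fine, donor_forcing = forcing,
                            solver_opts = solver_opts)
  ser <- trajectory_series(traj, observed_module, "step")
  j <- which(ser >= target)[1L]
  t_cross <- if (j == 1L) fine[1L] else {
    # linear interpolation inside one fine step
    t0 <- fine[j - 1L]; t1 <- fine[j]
    y0 <- ser[j - 1L]; y1 <- ser[j]
    t0 + (target - y0) / (y1 - y0) * (t1 - t0)
  }
  round(t_cross, 2)
}

first_crossing <- function(time_h, series, level) {
  hit <- which(series >= level)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(time_h[1L])
  t0 <- time_h[i - 1L]; t1 <- time_h[i]
  y0 <- series[i - 1L]; y1 <- series[i]
  if (y1 == y0) return(t1)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Concentration lag between two modules on a step-response trajectory
#'
#' On monotone step responses, returns the difference between the times at
#' which the downstream and upstream modules first cross `fraction` of
#' their own final values.
#'
#' @param traj an `mfp_trajectory` from a donor step experiment.
#' @param upstream,downstream module ids.
#' @param fraction crossing fraction of each series' final value
#'   (default 0.50).
#' @param analyte analyte to use (default: the trajectory's first).
#' @return lag in hours (downstream minus upstream crossing time).
#' @export
intermodule_lag <- function(traj, upstream, downstream, fraction = 0.50,
                            analyte = names(traj$conc)[1L]) {
  stopifnot(inherits(traj, "mfp_trajectory"), fraction > 0, fraction < 1)
  times <- numeric(2)
  mods <- c(upstream, downstream)
  for (i in 1:2) {
    ser <- trajectory_series(traj, mods[i], analyte)
    final <- ser[length(ser)]
    if (final <= 0) {
      stop("undefined lag: series for module '", mods[i],
           "' has nonpositive final value", call. = FALSE)
    }
    tc <- first_crossing(traj$time_h, ser, fraction * final)
    if (is.na(tc)) {
      stop("undefined lag: series for module '", mods[i],
           "' never crosses ", fraction, " of its final value",
           call. = FALSE)
    }
    times[i] <- tc
  }
  times[2] - times[1]
}

#' Write a trajectory to CSV
#'
#' Columns: `time_h, day, module_id, analyte, concentration_pg_per_ml`,
#' preceded by a `# schema_version` comment line.
#'
#' @param traj an `mfp_trajectory`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as_trajectory_df(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema_version: 1", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return data frame with the trajectory columns.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
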