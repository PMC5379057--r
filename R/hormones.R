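# Synthetic endocrine stage: pituitary forcing ("surge-purge"), 28-day
# ovarian secretion profiles, and the daily immunoassay sampling model.
# Days are cycle days (surge = day 0); rates are pg/h; concentrations pg/ml.

#' Default immunoassay specifications
#'
#' Intra-/inter-assay coefficients of variation and functional sensitivity
#' (limit of quantitation) for the hormone panel. Values below the
#' functional sensitivity are left-censored. All concentrations are kept in
#' pg/ml internally (0.15 ng/ml = 150 pg/ml for P4).
#'
#' @param analyte one of `"E2"`, `"P4"`, `"inhibinA"`, `"inhibinB"`.
#' @return an `assay_spec` list with fields `analyte`, `intra_cv`,
#'   `inter_cv`, `functional_sensitivity`, `unit`.
#' @export
default_assay <- function(analyte) {
  tab <- list(
    E2       = list(intra_cv = 0.063, inter_cv = 0.081, loq = 10),
    P4       = list(intra_cv = 0.044, inter_cv = 0.078, loq = 150),
    inhibinA = list(intra_cv = 0.051, inter_cv = 0.073, loq = 12),
    inhibinB = list(intra_cv = 0.045, inter_cv = 0.061, loq = 14))
  if (!analyte %in% names(tab)) {
    stop("no default assay for analyte '", analyte, "'", call. = FALSE)
  }
  e <- tab[[analyte]]
  assay_spec(analyte, e$intra_cv, e$inter_cv, e$loq)
}

#' @rdname default_assay
#' @param intra_cv,inter_cv coefficients of variation as fractions in
#'   (0, 1).
#' @param functional_sensitivity limit of quantitation in `unit`.
#' @param unit concentration unit (default pg/ml).
#' @export
assay_spec <- function(analyte, intra_cv, inter_cv = intra_cv,
                       functional_sensitivity, unit = "pg/ml") {
  stopifnot(intra_cv > 0, intra_cv < 1, inter_cv > 0, inter_cv < 1,
            functional_sensitivity > 0)
  structure(list(analyte = analyte, intra_cv = intra_cv,
                 inter_cv = inter_cv,
                 functional_sensitivity = functional_sensitivity,
                 unit = unit),
            class = "assay_spec")
}

# --- pituitary forcing -----------------------------------------------------

#' Pituitary forcing profile ("surge-purge")
#'
#' Piecewise-constant exogenous gonadotropin schedule over the 28-day
#' cycle. In cyclic mode FSH runs at 10 mIU/ml through the follicular
#' phase (days −14..0), an hCG surge of 1.5 IU/ml is applied for 16 h
#' starting at day 0, and hormones are then purged to baseline (0). In
#' pregnant mode the hCG surge is sustained at 1.5 IU/ml and prolactin is
#' added at 25 ng/ml through the luteal phase (days 0..14), emulating
#' rescue of the corpus luteum.
#'
#' @param mode `"cyclic"` or `"pregnant"`.
#' @return a `forcing_profile`: per-analyte piecewise-constant segments
#'   with units FSH mIU/ml, hCG IU/ml, prolactin ng/ml.
#' @examples
#' f <- make_pituitary_forcing("cyclic")
#' forcing_at(f, "FSH", -7) # 10
#' forcing_at(f, "hCG", -1) # 0 (pre-surge baseline)
#' @export
make_pituitary_forcing <- function(mode = c("cyclic", "pregnant")) {
  mode <- match.arg(mode)
  seg <- function(from, to, value) {
    data.frame(from_day = from, to_day = to, value = value)
  }
  prof <- list(
    FSH = list(unit = "mIU/ml", segments = seg(-14, 0, 10)),
    hCG = list(unit = "IU/ml",
               segments = if (mode == "cyclic") seg(0, 16 / 24, 1.5)
                          else seg(0, 14, 1.5)),
    prolactin = list(unit = "ng/ml",
                     segments = if (mode == "cyclic") seg(0, 0, 0)[0, ]
                                else seg(0, 14, 25)))
  structure(list(mode = mode, analytes = prof, horizon = c(-14, 14)),
            class = "forcing_profile")
}

#' Evaluate a forcing profile
#'
#' @param profile a `forcing_profile`.
#' @param analyte `"FSH"`, `"hCG"` or `"prolactin"`.
#' @param day cycle day(s), surge = day 0.
#' @return concentration(s) in the analyte's unit; 0 outside all segments.
#' @export
forcing_at <- function(profile, analyte, day) {
  stopifnot(inherits(profile, "forcing_profile"))
  p <- profile$analytes[[analyte]]
  if (is.null(p)) stop("unknown forcing analyte '", analyte, "'",
                       call. = FALSE)
  out <- numeric(length(day))
  s <- p$segments
  for (i in seq_len(nrow(s))) {
    # half-open [from, to): a segment ending at day 0 is pre-surge only
    inside <- day >= s$from_day[i] - 1e-9 & day < s$to_day[i] - 1e-9
    out[inside] <- s$value[i]
  }
  out
}

# --- ovarian secretion profiles --------------------------------------------

# Smooth nonnegative lognormal-shaped bump: 0 at/before onset, maximum 1 at
# peak_day, width on the log-time axis.
lognormal_bump <- function(day, onset, peak_day, width) {
  stopifnot(peak_day > onset, width > 0)
  out <- numeric(length(day))
  pos <- day > onset
  x <- (day[pos] - onset) / (peak_day - onset)
  out[pos] <- exp(-(log(x))^2 / (2 * width^2))
  out
}

# Calibrated defaults: timing parameters are fixed once so that daily
# noiseless sampling of the Solo acceptor reproduces the reported effluent
# peak days (E2 day 0, P4 day +2, inhibin B day -2) after the two-stage
# V/Q washout lag of the tissue and acceptor modules (~35 h at 0.04 ml/h).
CYCLE_DEFAULTS <- list(
  E2       = list(onset = -14, peak_day = -1.6, width = 0.35,
                  peak_rate = 10, baseline = 0),
  inhibinA = list(onset = -14, peak_day = -1.6, width = 0.35,
                  peak_rate = 4, baseline = 0),
  inhibinB = list(onset = -14, peak_day = -3.6, width = 0.28,
                  peak_rate = 6, baseline = 0),
  P4       = list(onset = -0.5, peak_day = 0.5, width = 0.9,
                  peak_rate = 400, baseline = 4))

#' Reference 28-day ovarian secretion profile
#'
#' Smooth piecewise secretion-rate curves (pg/h as a function of cycle day)
#' for E2, P4, inhibin A and inhibin B, built from lognormal-shaped bumps:
#' E2 rises through the follicular phase to a maximum near follicle
#' maturation and declines through the luteal phase; inhibin A tracks E2;
#' inhibin B peaks in the late follicular phase before E2 and then stays
#' low; P4 is low before the surge and rises steeply after it to an
#' early-luteal maximum. In pregnant mode the P4 rate is held at its
#' maximum through the luteal phase (sustained corpus luteum) instead of
#' declining; it dominates the cyclic rate pointwise on days 0..14.
#'
#' @param mode `"cyclic"` or `"pregnant"`.
#' @param scale_overrides optional named nonnegative vector of peak rates
#'   (pg/h) by analyte, replacing the defaults.
#' @return a `cycle_profile`.
#' @examples
#' prof <- make_cycle_secretion("cyclic")
#' secretion_rate(prof, "E2", 0) < secretion_rate(prof, "E2", -1.6) # TRUE
#' @export
make_cycle_secretion <- function(mode = c("cyclic", "pregnant"),
                                 scale_overrides = NULL) {
  mode <- match.arg(mode)
  params <- CYCLE_DEFAULTS
  if (!is.null(scale_overrides)) {
    if (any(scale_overrides < 0)) {
      stop("scale overrides must be nonnegative", call. = FALSE)
    }
    unknown <- setdiff(names(scale_overrides), names(params))
    if (length(unknown)) {
      stop("unknown analyte(s) in scale overrides: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (an in names(scale_overrides)) {
      params[[an]]$peak_rate <- as.numeric(scale_overrides[[an]])
      if (an == "P4") {
        # keep the follicular baseline a fixed 1% of the peak rate
        params[[an]]$baseline <- 0.01 * params[[an]]$peak_rate
      }
    }
  }
  structure(list(mode = mode, params = params), class = "cycle_profile")
}

#' Evaluate a secretion profile
#'
#' @param profile a `cycle_profile` from [make_cycle_secretion()].
#' @param analyte one of `"E2"`, `"P4"`, `"inhibinA"`, `"inhibinB"`.
#' @param day cycle day(s).
#' @return secretion rate(s) in pg/h.
#' @export
secretion_rate <- function(profile, analyte, day) {
  stopifnot(inherits(profile, "cycle_profile"))
  p <- profile$params[[analyte]]
  if (is.null(p)) stop("unknown analyte '", analyte, "'", call. = FALSE)
  bump <- lognormal_bump(day, p$onset, p$peak_day, p$width)
  if (profile$mode == "pregnant" && analyte == "P4") {
    # sustained corpus luteum: hold the peak rate once reached, through
    # the luteal phase
    bump[day >= p$peak_day] <- 1
  }
  p$baseline + p$peak_rate * bump
}

#' Build a secretion specification from a cycle profile
#'
#' Attaches the profile's time-varying rates (converted from cycle day to
#' hours since culture start) to one secreting module, ready for
#' [simulate_platform()].
#'
#' @param profile a `cycle_profile`.
#' @param module id of the secreting (ovarian) module.
#' @param analytes analytes to include (default: all four).
#' @return a [secretion_spec()].
#' @export
cycle_secretion_spec <- function(profile, module,
                                 analytes = names(profile$params)) {
  stopifnot(inherits(profile, "cycle_profile"))
  entries <- lapply(analytes, function(an) {
    force(an)
    secreting(module, an,
              production = function(t_h) {
                secretion_rate(profile, an, hours_to_day(t_h))
              })
  })
  secretion_spec(entries)
}

#' Write a secretion profile's parameters to a structured text file
#'
#' Per-analyte blocks with `peak_day`, `width_days` and
#' `peak_rate_pg_per_h` (plus `onset_day` and `baseline_pg_per_h`).
#'
#' @param profile a `cycle_profile`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cycle_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cycle_profile"))
  doc <- list(mode = profile$mode,
              analytes = lapply(profile$params, function(p) {
                list(onset_day = p$onset, peak_day = p$peak_day,
                     width_days = p$width, peak_rate_pg_per_h = p$peak_rate,
                     baseline_pg_per_h = p$baseline)
              }))
  writeLines(c("# schema_version: 1", yaml::as.yaml(doc)), path)
  invisible(path)
}

#' Read a secretion profile parameter file
#'
#' @param path file written by [write_cycle_profile()].
#' @return a `cycle_profile`.
#' @export
read_cycle_profile <- function(path) {
  doc <- yaml::read_yaml(path)
  params <- lapply(doc$analytes, function(p) {
    list(onset = p$onset_day, peak_day = p$peak_day, width = p$width_days,
         peak_rate = p$peak_rate_pg_per_h, baseline = p$baseline_pg_per_h)
  })
  structure(list(mode = doc$mode, params = params), class = "cycle_profile")
}

# --- assay sampling --------------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a trajectory the way the daily effluent assay would
#'
#' Takes the simulated concentration at each sampling time (default every
#' 24 h, emulating daily media collection), multiplies by lognormal noise
#' with the assay's intra-assay coefficient of variation, and left-censors
#' values below the functional sensitivity: censored records carry the LOQ
#' as value and a censoring flag. The multiplier is mean-one
#' (`exp(rnorm(0, sigma) - sigma^2/2)` with `sigma^2 = log(1 + cv^2)`), so
#' noise does not bias the mean. Bit-reproducible for a fixed seed.
#'
#' @param traj an `mfp_trajectory`.
#' @param module module id to sample (normally the acceptor).
#' @param analyte analyte name.
#' @param assay an [assay_spec()]; default [default_assay()] for the
#'   analyte. Set `noise_cv = 0` to disable noise.
#' @param interval_h sampling interval in hours (default 24).
#' @param seed integer seed (required when noise is on).
#' @param noise_cv override for the noise CV; `NULL` uses the assay's
#'   intra-assay CV, `0` disables noise.
#' @return a `measurement_series` data frame with columns `day`, `analyte`,
#'   `value`, `unit`, `censored`.
#' @export
sample_assay <- function(traj, module, analyte, assay = default_assay(analyte),
                         interval_h = 24, seed = NULL, noise_cv = NULL) {
  stopifnot(inherits(traj, "mfp_trajectory"), inherits(assay, "assay_spec"))
  ser <- trajectory_series(traj, module, analyte)
  t0 <- traj$time_h[1L]
  t1 <- traj$time_h[length(traj$time_h)]
  times <- seq(t0, t1, by = interval_h)
  span <- t1 - t0
  if (abs(span / interval_h - round(span / interval_h)) > 1e-9) {
    warning("sampling interval does not divide the trajectory span; ",
            "series truncated at ", max(times), " h")
  }
  true_vals <- stats::approx(traj$time_h, ser, xout = times)$y
  cv <- if (is.null(noise_cv)) assay$intra_cv else noise_cv
  vals <- if (cv > 0) {
    if (is.null(seed)) {
      stop("a seed is required when assay noise is enabled", call. = FALSE)
    }
    sigma <- sqrt(log(1 + cv^2))
    with_seed(seed,
              true_vals * exp(stats::rnorm(length(times), 0, sigma) -
                                sigma^2 / 2))
  } else true_vals
  censored <- vals < assay$functional_sensitivity
  vals[censored] <- assay$functional_sensitivity
  out <- data.frame(day = hours_to_day(times), analyte = analyte,
                    value = vals, unit = assay$unit, censored = censored,
                    stringsAsFactors = FALSE)
  attr(out, "module") <- module
  attr(out, "interval_h") <- interval_h
  class(out) <- c("measurement_series", class(out))
  out
}

#' Write a measurement series to CSV
#'
#' Columns `day, analyte, value, unit, censored` (`censored` written as
#' 0/1), preceded by a `# schema_version` comment line.
#'
#' @param meas a `measurement_series` (or compatible data frame).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(meas, path) {
  df <- as.data.frame(meas)
  df$censored <- as.integer(df$censored)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema_version: 1", con)
  utils::write.csv(df[, c("day", "analyte", "value", "unit", "censored")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements_csv()]
#'
#' @param path file path.
#' @return a `measurement_series` data frame (`censored` as logical).
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$censored <- as.logical(df$censored)
  class(df) <- c("measurement_series", class(df))
  df
}
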