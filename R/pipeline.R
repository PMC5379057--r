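# End-to-end reproducible pipeline: forcing -> secretion -> simulation ->
# daily assay sampling -> rate recovery -> fold comparison, with a run
# manifest. A thin command-line wrapper lives in inst/scripts/.

#' Derive a stage seed from the global run seed
#'
#' A single global seed fans out deterministically to per-stage child
#' seeds so each stage is independently reproducible.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 1).
#' @return integer child seed below 2^31.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9973) %%
               2147483647)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (block in c("platform", "mode")) {
    if (is.null(config[[block]])) {
      stop("pipeline config is missing the '", block, "' block",
           call. = FALSE)
    }
  }
  if (is.null(config$analytes)) {
    config$analytes <- c("E2", "P4", "inhibinA", "inhibinB")
  }
  if (is.null(config$noise)) config$noise <- TRUE
  config
}

pipeline_platform <- function(spec) {
  if (spec %in% c("solo", "duet", "quintet")) make_platform(spec)
  else read_platform_config(spec)
}

#' Run the full synthetic-cycle pipeline
#'
#' Executes, in order: pituitary forcing and ovarian secretion profile
#' generation, 28-day platform simulation, daily acceptor assay sampling,
#' secretion-rate recovery over a declared steady window, and (in
#' pregnant mode) a P4 fold comparison against the cyclic counterpart.
#' Writes `trajectory.csv`, `measurements.csv`, `rates.csv`, `folds.csv`
#' and `manifest.json` into `out_dir`. Numeric outputs are byte-identical
#' across runs with the same config and seed.
#'
#' @param config path to a YAML pipeline config (blocks `platform`,
#'   `mode`, optional `analytes`, `noise`) or an equivalent list.
#' @param seed integer global seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, seed, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  outputs <- c(forcing = file.path(out_dir, "forcing.csv"),
               trajectory = file.path(out_dir, "trajectory.csv"),
               measurements = file.path(out_dir, "measurements.csv"),
               rates = file.path(out_dir, "rates.csv"),
               folds = file.path(out_dir, "folds.csv"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)

  platform <- pipeline_platform(cfg$platform)
  tissue <- platform$modules$id[platform$modules$role == "tissue"][1L]
  forcing <- make_pituitary_forcing(cfg$mode)
  fdays <- seq(-14, 14, by = 1 / 24)
  fdf <- do.call(rbind, lapply(names(forcing$analytes), function(an) {
    data.frame(day = fdays, analyte = an,
               value = forcing_at(forcing, an, fdays),
               unit = forcing$analytes[[an]]$unit, stringsAsFactors = FALSE)
  }))
  con <- file(outputs[["forcing"]], "w")
  writeLines("# schema_version: 1", con)
  utils::write.csv(fdf, con, row.names = FALSE, quote = FALSE)
  close(con)

  profile <- make_cycle_secretion(cfg$mode)
  t_grid <- seq(0, 28 * 24, by = 1)

  traj <- simulate_platform(platform,
                            cycle_secretion_spec(profile, tissue,
                                                 cfg$analytes),
                            t_grid)
  write_trajectory_csv(traj, outputs[["trajectory"]])

  meas <- lapply(seq_along(cfg$analytes), function(i) {
    an <- cfg$analytes[i]
    sample_assay(traj, platform$acceptor_id, an,
                 seed = child_seed(seed, i),
                 noise_cv = if (isTRUE(cfg$noise)) NULL else 0)
  })
  names(meas) <- cfg$analytes
  write_measurements_csv(do.call(rbind, lapply(meas, as.data.frame)),
                         outputs[["measurements"]])

  # rate recovery over a late-follicular window declared steady
  window <- c(-4, 0)
  rates <- do.call(rbind, lapply(cfg$analytes, function(an) {
    est <- tryCatch(
      estimate_secretion_rates(meas[[an]], platform, window,
                               secreting_module = tissue),
      error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(module = est$module, analyte = an,
               rate_pg_per_h = est$rate_pg_per_h, se = est$se,
               n_days = est$n_days, method = est$method,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rates)) {
    rates <- data.frame(module = character(0), analyte = character(0),
                        rate_pg_per_h = numeric(0), se = numeric(0),
                        n_days = integer(0), method = character(0))
  }
  con <- file(outputs[["rates"]], "w")
  writeLines("# schema_version: 1", con)
  utils::write.csv(rates, con, row.names = FALSE, quote = FALSE)
  close(con)

  folds <- data.frame(analyte = character(0), statistic = character(0),
                      value_a = numeric(0), value_b = numeric(0),
                      fold = numeric(0))
  if (cfg$mode == "pregnant" && "P4" %in% cfg$analytes) {
    cyc_traj <- simulate_platform(
      platform, cycle_secretion_spec(make_cycle_secretion("cyclic"),
                                     tissue, "P4"), t_grid)
    cyc_meas <- sample_assay(cyc_traj, platform$acceptor_id, "P4",
                             seed = child_seed(seed, 100L),
                             noise_cv = if (isTRUE(cfg$noise)) NULL else 0)
    luteal <- function(m) m[m$day >= 0 & m$day <= 14, ]
    fc <- fold_change(luteal(meas[["P4"]]), luteal(cyc_meas), "auc")
    folds <- data.frame(analyte = fc$analyte, statistic = fc$statistic,
                        value_a = fc$value_a, value_b = fc$value_b,
                        fold = fc$fold, stringsAsFactors = FALSE)
  }
  con <- file(outputs[["folds"]], "w")
  writeLines("# schema_version: 1", con)
  utils::write.csv(folds, con, row.names = FALSE, quote = FALSE)
  close(con)

  manifest <- list(
    command = "pipeline",
    config = cfg[c("platform", "mode", "analytes", "noise")],
    seed = seed,
    package_version = as.character(utils::packageVersion("organflow")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
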