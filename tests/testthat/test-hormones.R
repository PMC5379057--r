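test_that("surge-purge forcing reproduces the gonadotropin schedule", {
  f <- make_pituitary_forcing("cyclic")
  expect_equal(forcing_at(f, "FSH", -7), 10)   # follicular FSH, mIU/ml
  expect_equal(forcing_at(f, "FSH", 7), 0)     # withdrawn after the surge
  expect_equal(forcing_at(f, "hCG", -1), 0)    # pre-surge baseline
  expect_equal(forcing_at(f, "hCG", 8 / 24), 1.5) # inside the 16 h surge
  expect_equal(forcing_at(f, "hCG", 1), 0)     # purged to baseline
  expect_equal(forcing_at(f, "prolactin", 7), 0)

  p <- make_pituitary_forcing("pregnant")
  expect_equal(forcing_at(p, "prolactin", 7), 25) # ng/ml, luteal rescue
  expect_equal(forcing_at(p, "hCG", 7), 1.5)      # sustained hCG
  expect_equal(forcing_at(p, "FSH", -7), 10)
  expect_error(make_pituitary_forcing("lunar"))
})

test_that("cyclic secretion profile has the reference phase structure", {
  prof <- make_cycle_secretion("cyclic")
  days <- seq(-14, 14, by = 0.05)
  e2 <- secretion_rate(prof, "E2", days)
  peak_day <- days[which.max(e2)]
  # E2 rises through the follicular phase to its maximum, then declines
  rising <- days <= peak_day
  expect_true(all(diff(e2[rising]) >= 0))
  expect_true(all(diff(e2[!rising]) <= 0))
  # P4 in the follicular phase sits below its luteal maximum
  p4 <- secretion_rate(prof, "P4", days)
  expect_lt(max(p4[days < 0]), max(p4[days >= 0]))
  expect_gt(days[which.max(p4)], 0)
  # inhibin A tracks E2; inhibin B peaks earlier, in the late follicular phase
  inha <- secretion_rate(prof, "inhibinA", days)
  expect_equal(days[which.max(inha)], peak_day)
  expect_gt(stats::cor(inha, e2), 0.999)
  inhb <- secretion_rate(prof, "inhibinB", days)
  expect_lt(days[which.max(inhb)], peak_day)
  expect_lt(mean(inhb[days > 7]), 0.05 * max(inhb)) # low late-luteal tail
  expect_true(all(c(e2, p4, inha, inhb) >= 0))
})

test_that("pregnancy-like mode sustains P4 above the cyclic rate", {
  cyc <- make_cycle_secretion("cyclic")
  preg <- make_cycle_secretion("pregnant")
  days <- seq(0, 14, by = 0.1)
  expect_true(all(secretion_rate(preg, "P4", days) >=
                    secretion_rate(cyc, "P4", days) - 1e-12))
  # integrated luteal production is strictly higher
  expect_gt(sum(secretion_rate(preg, "P4", days)),
            sum(secretion_rate(cyc, "P4", days)))
})

test_that("scale overrides rescale peaks and zero them out entirely", {
  zero <- make_cycle_secretion("cyclic",
                               scale_overrides = c(E2 = 0, P4 = 0,
                                                   inhibinA = 0, inhibinB = 0))
  days <- seq(-14, 14, by = 0.5)
  for (an in c("E2", "P4", "inhibinA", "inhibinB")) {
    expect_true(all(secretion_rate(zero, an, days) == 0))
  }
  dbl <- make_cycle_secretion("cyclic", scale_overrides = c(E2 = 20))
  base <- make_cycle_secretion("cyclic")
  expect_equal(secretion_rate(dbl, "E2", days),
               2 * secretion_rate(base, "E2", days))
  expect_error(make_cycle_secretion("cyclic", scale_overrides = c(E2 = -1)),
               "nonnegative")
})

test_that("profile parameter files round-trip", {
  prof <- make_cycle_secretion("cyclic")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cycle_profile(prof, path)
  back <- read_cycle_profile(path)
  days <- seq(-14, 14, by = 0.25)
  for (an in c("E2", "P4", "inhibinA", "inhibinB")) {
    expect_equal(secretion_rate(back, an, days),
                 secretion_rate(prof, an, days))
  }
})

test_that("noiseless sampling returns the trajectory values", {
  solo <- make_platform("solo")
  spec <- secretion_spec(secreting("tissue", "E2", production = 4))
  init <- list(E2 = c(donor = 0, tissue = 50, acceptor = 50))
  traj <- simulate_platform(solo, spec, seq(0, 96, by = 1), init = init)
  m <- sample_assay(traj, "acceptor", "E2", noise_cv = 0)
  expect_equal(m$value, trajectory_series(traj, "acceptor", "E2")[
    traj$time_h %% 24 == 0], tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(any(m$censored))
  expect_equal(m$day, seq(-14, -10))
})

test_that("values below functional sensitivity are left-censored at LOQ", {
  solo <- make_platform("solo")
  # constant 5 pg/ml, below the E2 functional sensitivity of 10 pg/ml
  spec <- secretion_spec(secreting("tissue", "E2", production = 0.2))
  init <- list(E2 = c(donor = 0, tissue = 5, acceptor = 5))
  traj <- simulate_platform(solo, spec, seq(0, 96, by = 1), init = init)
  m <- sample_assay(traj, "acceptor", "E2", noise_cv = 0)
  expect_true(all(m$censored))
  expect_true(all(m$value == 10))
})

test_that("lognormal noise reproduces the intra-assay CV and is seeded", {
  solo <- make_platform("solo")
  spec <- secretion_spec(secreting("tissue", "E2", production = 4))
  init <- list(E2 = c(donor = 0, tissue = 100, acceptor = 100))
  # steady trajectory, 10,000 daily draws of a true value of 100 pg/ml
  traj <- simulate_platform(solo, spec, seq(0, 10000 * 24, by = 2400),
                            init = init)
  m <- sample_assay(traj, "acceptor", "E2", seed = 4242)
  expect_equal(nrow(m), 10001L)
  cv_hat <- stats::sd(m$value) / mean(m$value)
  expect_lt(abs(cv_hat - 0.063), 0.005)
  expect_lt(abs(mean(m$value) - 100), 1) # mean-one noise multiplier
  # bit-reproducible for a fixed seed, different for another
  m2 <- sample_assay(traj, "acceptor", "E2", seed = 4242)
  expect_identical(m$value, m2$value)
  m3 <- sample_assay(traj, "acceptor", "E2", seed = 4243)
  expect_false(identical(m$value, m3$value))
  # sampling leaves the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(5)
  set.seed(1); invisible(sample_assay(traj, "acceptor", "E2", seed = 9))
  expect_identical(stats::runif(5), before)
})

test_that("censoring fraction decreases as the true level rises", {
  solo <- make_platform("solo")
  frac <- vapply(c(6, 9, 12, 20, 60), function(level) {
    spec <- secretion_spec(secreting("tissue", "E2",
                                     production = level * 0.04))
    init <- list(E2 = c(donor = 0, tissue = level, acceptor = level))
    traj <- simulate_platform(solo, spec, seq(0, 500 * 24, by = 2400),
                              init = init)
    mean(sample_assay(traj, "acceptor", "E2", seed = 77)$censored)
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
  expect_gt(frac[1], 0.9)
  expect_equal(frac[5], 0)
})

test_that("a non-dividing sampling interval truncates with a warning", {
  solo <- make_platform("solo")
  spec <- secretion_spec(secreting("tissue", "E2", production = 4))
  traj <- simulate_platform(solo, spec, seq(0, 100, by = 1))
  expect_warning(m <- sample_assay(traj, "acceptor", "E2", noise_cv = 0),
                 "truncated")
  expect_equal(nrow(m), 5L) # samples at 0, 24, 48, 72, 96 h
})

test_that("solo end-to-end series orders the E2 and P4 peaks correctly", {
  prof <- make_cycle_secretion("cyclic")
  e2 <- solo_daily_series(prof, "E2")
  p4 <- solo_daily_series(prof, "P4")
  # exactly one global maximum each, P4 peaking after E2
  expect_equal(sum(e2$value == max(e2$value)), 1L)
  expect_equal(sum(p4$value == max(p4$value)), 1L)
  expect_gt(p4$day[which.max(p4$value)], e2$day[which.max(e2$value)])
})

test_that("measurement CSV round-trips with 0/1 censoring flags", {
  df <- data.frame(day = -2:2, analyte = "E2",
                   value = c(10, 55.5, 123.456, 10, 88),
                   unit = "pg/ml",
                   censored = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  class(df) <- c("measurement_series", class(df))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(df, path)
  expect_equal(readLines(path, n = 2)[2], "day,analyte,value,unit,censored")
  back <- read_measurements_csv(path)
  expect_equal(back$value, df$value)
  expect_identical(back$censored, df$censored)
})

test_that("default assay table carries the published CVs and LOQs", {
  e2 <- default_assay("E2")
  expect_equal(c(e2$intra_cv, e2$inter_cv, e2$functional_sensitivity),
               c(0.063, 0.081, 10))
  expect_equal(default_assay("P4")$functional_sensitivity, 150) # 0.15 ng/ml
  expect_equal(default_assay("inhibinA")$functional_sensitivity, 12)
  expect_equal(default_assay("inhibinB")$intra_cv, 0.045)
  expect_error(default_assay("activinZ"), "no default assay")
  expect_error(assay_spec("E2", intra_cv = 1.2, functional_sensitivity = 10))
})
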