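iso <- ac225()
one <- single_alpha_isotope(half_life_s = 86400)

test_that("decay weight matches half-life intuition and a quadrature oracle", {
  expect_equal(decay_weight(acquisition_schedule(cbind(0, Inf)), iso), 1)
  expect_equal(decay_weight(acquisition_schedule(cbind(0, iso$half_life_s)),
                            iso), 0.5)
  win <- rbind(c(0, 86400), c(2 * 86400, 3 * 86400))
  expect_equal(decay_weight(acquisition_schedule(win), iso),
               oracle_decay_weight(win, iso$lambda), tolerance = 1e-9)
  expect_error(decay_weight(acquisition_schedule(cbind(0, 1))[0, ], iso),
               "empty")
})

test_that("splitting a window into contiguous sub-windows leaves W unchanged", {
  whole <- decay_weight(acquisition_schedule(cbind(0, 7 * 86400)), iso)
  cuts <- c(0, 1.3, 2.2, 5.05, 7) * 86400
  split <- decay_weight(acquisition_schedule(cbind(cuts[-5], cuts[-1])), iso)
  expect_equal(split, whole, tolerance = 1e-12)
})

test_that("activity conversion inverts the forward counting model exactly", {
  # counts constructed from the forward model with N0 = 1e6 atoms
  n0 <- 1e6; f <- 1.77; T <- 60 * 3600
  sch <- acquisition_schedule(cbind(0, T))
  counts <- f * n0 * (1 - exp(-iso$lambda * T))
  a0 <- activity_at_reference(counts, f, iso, sch)
  expect_equal(a0, iso$lambda * n0, tolerance = 1e-12)

  # limiting form: f = 1, full decay -> A0 = lambda * counts
  expect_equal(activity_at_reference(1000, 1, iso,
                                     acquisition_schedule(cbind(0, Inf))),
               iso$lambda * 1000)
  expect_equal(activity_at_reference(0, 1.77, iso, sch), 0)
  # linear in counts, inverse in f
  expect_equal(activity_at_reference(500, 2, iso, sch),
               5 * activity_at_reference(200, 4, iso, sch))
  expect_error(activity_at_reference(10, 1.77, single_alpha_isotope(1),
                                     acquisition_schedule(cbind(1e6, 1e6 + 1))),
               "numerically zero")
})

test_that("constant-activity approximation error matches the quadrature oracle", {
  # oracle: mean of endpoint activities vs exact exponential time average
  oracle <- function(dur, lambda) {
    exact <- stats::integrate(function(t) exp(-lambda * t), 0, dur)$value / dur
    (1 + exp(-lambda * dur)) / 2 / exact - 1
  }
  for (dur in c(3600, 60 * 3600, 7 * 86400, 14 * 86400)) {
    expect_equal(constant_activity_error(dur, iso), oracle(dur, iso$lambda),
                 tolerance = 1e-10)
  }
  # tends to zero for short acquisitions, strictly increasing
  durs <- c(1, 10, 1e3, 1e5, 1e6, 5e6)
  errs <- constant_activity_error(durs, iso)
  expect_lt(errs[1], 1e-12)
  expect_true(all(diff(errs) > 0))
  expect_error(constant_activity_error(0, iso), "duration")
})

test_that("detector efficiency follows the one-sided 2-pi geometry rule", {
  expect_equal(detector_efficiency(1.77, 4), 0.885)
  expect_equal(detector_efficiency(2.0, 4), 1.0)
  expect_equal(detector_efficiency(0.5, 1), 1.0)
  expect_error(detector_efficiency(-1, 4), "f")
})

test_that("sensitivity fit recovers f from a noiseless dilution series", {
  sch <- acquisition_schedule(cbind(0, 82 * 3600))
  W <- decay_weight(sch, iso)
  truth <- 1.77
  samples <- lapply(c(0.001, 0.01, 0.1, 1, 10), function(a)
    list(known_activity_bq = a, counts = truth * (a / iso$lambda) * W,
         schedule = sch))
  fit <- fit_sensitivity(samples, iso)
  expect_s3_class(fit, "sensitivity_fit")
  expect_equal(fit$f, truth, tolerance = 1e-9)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-9)
  expect_equal(fit$detector_efficiency, truth / 2, tolerance = 1e-9)
  expect_gt(fit$r_squared, 0.999999)
  # recovered activity sits on the identity line
  expect_equal(fit$samples$recovered_activity_bq,
               fit$samples$known_activity_bq, tolerance = 1e-9)
  # predict() reproduces the fitted counts
  expect_equal(predict(fit), fit$samples$fitted_counts)

  # one-point ratio
  f1 <- fit_sensitivity(samples[3], iso)
  expect_equal(f1$f, truth, tolerance = 1e-9)
  expect_true(f1$low_confidence)
})

test_that("sensitivity fit on Poisson-noised counts stays within 3 SE", {
  set.seed(9)
  sch <- acquisition_schedule(cbind(0, 82 * 3600))
  W <- decay_weight(sch, iso)
  truth <- 1.77
  samples <- lapply(c(0.002, 0.02, 0.2, 2), function(a)
    list(known_activity_bq = a,
         counts = rpois(1, truth * (a / iso$lambda) * W),
         schedule = sch))
  fit <- fit_sensitivity(samples, iso)
  expect_lt(abs(fit$f - truth), 3 * fit$se)
  expect_error(fit_sensitivity(lapply(samples, function(s) {
    s$counts <- 0; s
  }), iso), "zero")
})

test_that("simulated list mode inverts back to the input activity map", {
  sch <- acquisition_schedule(cbind(0, 60 * 3600))
  W <- decay_weight(sch, iso)
  f <- 1.77
  a0 <- 1.2e4 * iso$lambda / (f * W)  # ~1.2e4 expected counts per pixel
  A <- activity_image(matrix(a0, 12, 12), pixel_spacing = 26.5)
  ev <- simulate_listmode(A, iso, f, sch, seed = 21)
  ci <- bin_events(ev, 26.5, grid_shape = c(12, 12))
  Ahat <- activity_at_reference(ci, f, iso)
  rel <- abs(unclass(Ahat) - a0) / a0
  expect_gte(mean(rel < 3 / sqrt(unclass(ci))), 0.99)
  expect_equal(attr(ci, "dropped"), 0L)
})

test_that("calibration tables read into decay-corrected samples", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,known_activity_bq,ref_time_s,counts,window_start_s,window_end_s",
    "a,1.0,0,5000,0,3600",
    "b,2.0,3600,9000,0,1800",
    "b,2.0,3600,9000,7200,9000"), path)
  smp <- read_calibration_table(path, iso)
  expect_length(smp, 2L)
  expect_equal(smp$a$known_activity_bq, 1.0)
  # activity stated 1 h after reference is larger at reference time
  expect_equal(smp$b$known_activity_bq, 2 * exp(iso$lambda * 3600))
  expect_equal(nrow(smp$b$schedule), 2L)
})
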