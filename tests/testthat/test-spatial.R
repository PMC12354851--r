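test_that("distance maps are exact Euclidean distances", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  d <- distance_map(m, pixel_spacing = 2)
  g <- alphamap:::pixel_grid(9, 9)
  expect_equal(d, 2 * sqrt((g$x - 5)^2 + (g$y - 5)^2), tolerance = 1e-6)

  # all-foreground: all zeros
  expect_equal(distance_map(matrix(TRUE, 6, 6)), matrix(0, 6, 6))

  # random 64x64 mask vs brute-force nearest-foreground search
  set.seed(11)
  rm <- matrix(runif(64 * 64) < 0.01, 64, 64)
  rm[1, 1] <- TRUE  # ensure nonempty
  expect_equal(distance_map(rm, pixel_spacing = 3),
               oracle_distance_map(rm, spacing = 3), tolerance = 1e-6)

  expect_error(distance_map(matrix(FALSE, 4, 4)), "empty")
})

test_that("uptake profiles are normalized and locate constructed enrichment", {
  kp <- generate_kidney_phantom(
    enrichment = list(reference = "glomeruli", annulus_um = c(50, 100),
                      amplitude = 2), seed = 3)
  sp <- 6.625
  dm <- distance_map(kp$masks$glomeruli, sp)

  # uniform activity: profile flat at 1 in every populated bin
  flat <- matrix(1, nrow(kp$anatomy), ncol(kp$anatomy))
  pf <- uptake_vs_distance(flat, dm, kp$masks$tissue, bin_width_um = 5)
  expect_true(all(abs(pf$mean_relative_uptake[pf$n_pixels > 0] - 1) < 1e-9))

  # 2x annular enrichment peaked at 75 um: peak bin within one bin of 75
  pr <- uptake_vs_distance(kp$activity_fine, dm, kp$masks$tissue,
                           bin_width_um = 5,
                           exclude_mask = kp$masks$glomeruli)
  peak_mid <- (pr$bin_lo_um + pr$bin_hi_um)[which.max(pr$mean_relative_uptake)] / 2
  expect_lte(abs(peak_mid - 75), 5)

  # pixel-count-weighted profile mean is exactly 1
  ok <- pr$n_pixels > 0
  wm <- sum(pr$mean_relative_uptake[ok] * pr$n_pixels[ok]) / sum(pr$n_pixels)
  expect_equal(wm, 1, tolerance = 1e-6)

  # the same holds after resampling the coarse autoradiography activity
  up <- resample_to_grid(kp$activity, dim(kp$anatomy), sp)
  pr2 <- uptake_vs_distance(up, dm, kp$masks$tissue, bin_width_um = 5,
                            exclude_mask = kp$masks$glomeruli)
  peak2 <- (pr2$bin_lo_um + pr2$bin_hi_um)[which.max(pr2$mean_relative_uptake)] / 2
  expect_lte(abs(peak2 - 75), 10)

  expect_error(uptake_vs_distance(flat * 0, dm, kp$masks$tissue, 5), "zero")
})

test_that("replicate aggregation reproduces the closed-form t interval", {
  mk_profile <- function(vals) {
    structure(data.frame(bin_lo_um = (seq_along(vals) - 1) * 5,
                         bin_hi_um = seq_along(vals) * 5,
                         mean_relative_uptake = vals,
                         n_pixels = rep(100L, length(vals))),
              class = c("distance_profile", "data.frame"))
  }
  a <- list(mk_profile(c(1.0, 1.1, 0.9)), mk_profile(c(1.2, 1.0, 0.8)))
  ens <- aggregate_and_test(list(x = a, y = a))
  mu <- c(1.1, 1.05, 0.85)
  half <- qt(0.975, 1) * apply(rbind(c(1, 1.1, 0.9), c(1.2, 1, 0.8)), 2, sd) /
    sqrt(2)
  expect_equal(ens$mean_x, mu)
  expect_equal(ens$ci_lo_x, mu - half)
  expect_equal(ens$ci_hi_x, mu + half)
  # identical conditions: no significance anywhere
  expect_false(any(ens$significant))
})

test_that("a constructed shift larger than the CI flags all populated bins", {
  set.seed(8)
  mk <- function(base) {
    vals <- base + rnorm(10, 0, 0.01)
    structure(data.frame(bin_lo_um = 0:9 * 5, bin_hi_um = 1:10 * 5,
                         mean_relative_uptake = vals,
                         n_pixels = rep(50L, 10)),
              class = c("distance_profile", "data.frame"))
  }
  a <- replicate(5, mk(1.0), simplify = FALSE)
  b <- replicate(5, mk(1.5), simplify = FALSE)
  ens <- aggregate_and_test(list(early = a, late = b))
  expect_true(all(ens$significant))
  expect_true(all(ens$ci_lo_early <= ens$mean_early))
  expect_true(all(ens$mean_early <= ens$ci_hi_early))

  # single replicate: CIs undefined, flagged by warning
  expect_warning(aggregate_and_test(list(early = a[1], late = b)),
                 "single replicate")

  # bootstrap CIs cover the same story
  ens2 <- aggregate_and_test(list(early = a, late = b), method = "bootstrap",
                             seed = 2)
  expect_true(all(ens2$significant))
})

test_that("null phantom comparisons stay below the 10% false-flag budget", {
  # two conditions drawn from the same flat-uptake phantom: the fraction of
  # bins flagged significant estimates the per-bin false-positive rate of
  # the interval-exceedance rule
  set.seed(42)
  kp <- generate_kidney_phantom(seed = 3)
  sp <- 6.625
  dm <- distance_map(kp$masks$glomeruli, sp)
  truth_coarse <- unclass(kp$activity)
  noise <- 200
  mk <- function() {
    a <- matrix(rpois(length(truth_coarse), truth_coarse * noise) / noise,
                nrow(truth_coarse))
    au <- resample_to_grid(structure(a, pixel_spacing = 26.5,
                                     origin = c(0, 0)),
                           dim(kp$anatomy), sp)
    uptake_vs_distance(au, dm, kp$masks$tissue, bin_width_um = 15,
                       exclude_mask = kp$masks$glomeruli,
                       max_distance_um = 300)
  }
  fp <- replicate(100, {
    ens <- aggregate_and_test(list(a = replicate(9, mk(), simplify = FALSE),
                                   b = replicate(9, mk(), simplify = FALSE)))
    mean(ens$significant, na.rm = TRUE)
  })
  expect_lte(mean(fp), 0.10)
})

test_that("profile ensembles export to the documented CSV layout", {
  mk <- function(vals)
    structure(data.frame(bin_lo_um = (seq_along(vals) - 1) * 5,
                         bin_hi_um = seq_along(vals) * 5,
                         mean_relative_uptake = vals,
                         n_pixels = rep(10L, length(vals))),
              class = c("distance_profile", "data.frame"))
  ens <- aggregate_and_test(list(a = list(mk(c(1, 1.2)), mk(c(1.1, 1.0))),
                                 b = list(mk(c(0.9, 1.4)), mk(c(1.0, 1.3)))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(ens, path)
  back <- read.csv(path)
  expect_true(all(c("bin_lo_um", "bin_hi_um", "mean_a", "ci_lo_a", "ci_hi_a",
                    "significant") %in% names(back)))
  expect_equal(nrow(back), 2L)
})
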