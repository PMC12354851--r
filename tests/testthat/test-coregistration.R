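test_that("landmark rigid fit is exact on constructed rigid motions", {
  set.seed(2)
  f <- cbind(runif(6, 0, 2000), runif(6, 0, 2000))
  # identity
  tr0 <- landmark_rigid_fit(f, f)
  expect_equal(tr0$rotation, 0, tolerance = 1e-12)
  expect_equal(attr(tr0, "rms_residual_um"), 0, tolerance = 1e-9)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m <- t(R %*% t(f)) + matrix(c(5, -3), 6, 2, byrow = TRUE)
  tr <- landmark_rigid_fit(f, m)
  expect_equal(max(abs(apply_rigid2d(tr, f) - m)), 0, tolerance = 1e-9)
  expect_equal(tr$rotation, th, tolerance = 1e-12)
  # pure rotation + translation: linear part has unit determinant
  ct <- cos(tr$rotation); st <- sin(tr$rotation)
  expect_equal(ct^2 + st^2, 1)

  expect_error(landmark_rigid_fit(cbind(1:3, 2 * (1:3)), cbind(1:3, 2 * (1:3))),
               "collinear|degenerate")
  expect_error(landmark_rigid_fit(f[1:2, ], f[1:2, ]), "3")
})

test_that("rigid MI registration recovers known shifts and rotations", {
  set.seed(3)
  stk <- generate_tumor_stack(seed = 5)
  ana <- stk$sections[[2]]$anatomy
  sp <- stk$pixel_spacing_um
  # moving = fixed: identity within tolerance
  tr0 <- register_histology_to_autoradiography(ana, ana, sp)
  expect_lt(max(abs(tr0$translation)) / sp, 0.5)
  expect_lt(abs(tr0$rotation) * 180 / pi, 0.5)

  # anatomy-derived synthetic "activity" (blurred, noised), shifted 5 px
  act <- as.array(EBImage::gblur(EBImage::Image(ana), sigma = 2))
  moved <- alphamap:::resample_moving(
    act, rigid2d(translation = c(5 * sp, 0)), dim(act), sp)
  moved <- pmax(moved + matrix(rnorm(length(moved), 0, 0.02), nrow(moved)), 0)
  tr <- register_histology_to_autoradiography(ana, moved, sp)
  expect_lt(abs(tr$translation[1] / sp + 5), 0.5)
  expect_lt(abs(tr$translation[2] / sp), 0.5)
  expect_false(is.null(attr(tr, "report")$trace))

  # known 10 degree rotation recovered within 0.5 degrees
  rot <- alphamap:::resample_moving(
    ana, rigid2d(rotation = 10 * pi / 180, center = dim(ana) / 2 * sp),
    dim(ana), sp)
  tr2 <- register_histology_to_autoradiography(ana, rot, sp)
  expect_lt(abs(tr2$rotation * 180 / pi + 10), 0.5)
})

test_that("3-section slide groups resolve rotations that single sections cannot", {
  # near-symmetric section: a disk with faint texture has an almost
  # rotation-invariant MI landscape; three of them at fixed relative
  # positions pin the rotation down
  sp <- 26.5
  nx <- 180; ny <- 72
  g <- alphamap:::pixel_grid(nx, ny)
  mk_disk <- function(cx, cy, r, tex_seed) {
    set.seed(tex_seed)
    d2 <- (g$x - cx)^2 + (g$y - cy)^2
    base <- ifelse(d2 <= r^2, 0.6, 0.03)
    tex <- as.array(EBImage::gblur(
      EBImage::Image(matrix(runif(nx * ny), nx, ny)), sigma = 4))
    base + 0.06 * tex * (d2 <= r^2)
  }
  slide <- mk_disk(30, 36, 22, 1) + mk_disk(90, 36, 22, 2) +
    mk_disk(150, 36, 22, 3)
  true_deg <- 6
  errs <- sapply(1:3, function(s) {
    set.seed(s)
    tr_true <- rigid2d(rotation = true_deg * pi / 180,
                       center = c(nx, ny) / 2 * sp)
    moved <- alphamap:::resample_moving(slide, tr_true, dim(slide), sp)
    moved <- pmax(moved + matrix(rnorm(nx * ny, 0, 0.03), nx), 0)
    # group: register the whole slide; single: just the central section
    tr_g <- register_histology_to_autoradiography(slide, moved, sp)
    sub <- 61:120
    tr_s <- register_histology_to_autoradiography(slide[sub, ], moved[sub, ],
                                                  sp)
    c(group = abs(abs(tr_g$rotation) * 180 / pi - true_deg),
      single = abs(abs(tr_s$rotation) * 180 / pi - true_deg))
  })
  expect_lt(median(errs["group", ]), median(errs["single", ]))
})

test_that("Dice coefficient matches hand counts and conventions", {
  a <- matrix(FALSE, 20, 20); b <- a
  a[1:10, 1:10] <- TRUE
  expect_equal(dice(a, a), 1.0)
  b[11:20, 11:20] <- TRUE
  expect_equal(dice(a, b), 0.0)
  # two 10x10 squares overlapping in a 5x10 strip
  c2 <- matrix(FALSE, 20, 20); c2[6:15, 1:10] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  # both empty: defined as perfect agreement
  e <- matrix(FALSE, 5, 5)
  expect_equal(dice(e, e), 1.0)
  expect_error(dice(a, e), "mismatch")
})

test_that("stacking recovers known transforms and preserves mask areas", {
  stk <- generate_tumor_stack(seed = 7, max_rotation_deg = 0, max_shift_um = 0)
  sp <- stk$pixel_spacing_um
  # rotate one section by 10 degrees
  secs <- stk$truth$sections0
  tr_true <- rigid2d(rotation = 10 * pi / 180, center = dim(secs[[1]]$anatomy) / 2 * sp)
  ti <- alphamap:::invert_rigid2d(tr_true)
  secs[[3]]$anatomy <- alphamap:::resample_moving(secs[[3]]$anatomy, ti,
                                                  dim(secs[[3]]$anatomy), sp)
  secs[[3]]$activity <- alphamap:::resample_moving(secs[[3]]$activity, ti,
                                                   dim(secs[[3]]$activity), sp)
  st <- stack_sections(secs, method = "activity_only", pixel_spacing = sp)
  expect_lt(abs(st$transforms[[3]]$rotation * 180 / pi - 10), 0.5)
  # similarity stage stayed close to unit scale on a rigid-only problem
  expect_lt(abs(st$transforms[[3]]$scale - 1), 0.02)

  # rigid resampling preserves mask areas within 0.5%
  msk <- segment_tissue(secs[[3]]$anatomy, pixel_spacing = sp,
                        min_area_um2 = 1e4)
  w <- alphamap:::resample_moving(msk * 1, tr_true, dim(msk), sp,
                                  bilinear = FALSE)
  expect_lt(abs(sum(w) - sum(msk)) / sum(msk), 0.005)
})

test_that("perfectly aligned stacks register to the identity", {
  stk <- generate_tumor_stack(seed = 3, max_rotation_deg = 0,
                              max_shift_um = 0)
  sp <- stk$pixel_spacing_um
  st <- stack_sections(stk$sections, method = "anatomy_guided",
                       pixel_spacing = sp)
  for (tr in st$transforms) {
    expect_lt(max(abs(tr$translation)) / sp, 0.5)
    expect_lt(abs(tr$rotation) * 180 / pi, 0.5)
  }
  seg <- function(img) segment_tissue(img, pixel_spacing = sp,
                                      min_area_um2 = 1e4)
  d_before <- dice(seg(stk$sections[[1]]$anatomy),
                   seg(stk$sections[[2]]$anatomy))
  d_after <- dice(seg(st$anatomy[, , 1]), seg(st$anatomy[, , 2]))
  expect_gt(d_after, d_before - 0.02)
})

test_that("landmark fit agrees with the MI optimizer on exact rigid motion", {
  stk <- generate_tumor_stack(seed = 13)
  ana <- stk$sections[[2]]$anatomy
  sp <- stk$pixel_spacing_um
  tr_true <- rigid2d(rotation = 3 * pi / 180, translation = c(2 * sp, -sp),
                     center = dim(ana) / 2 * sp)
  moved <- alphamap:::resample_moving(ana, tr_true, dim(ana), sp)
  # a feature at fixed coords q appears in `moved` at inv(tr_true)(q)
  inv <- alphamap:::invert_rigid2d(tr_true)
  pts <- cbind(c(400, 1200, 700), c(500, 900, 1300))
  tr_lm <- landmark_rigid_fit(pts, apply_rigid2d(inv, pts))
  tr_mi <- register_histology_to_autoradiography(ana, moved, sp,
                                                 fixed_landmarks = pts,
                                                 moving_landmarks =
                                                   apply_rigid2d(inv, pts))
  p <- cbind(c(500, 1000), c(500, 1000))
  expect_lt(max(abs(apply_rigid2d(tr_lm, p) - apply_rigid2d(tr_mi, p))) / sp,
            0.5)
})

test_that("paired stacking comparison matches the closed-form t statistic", {
  a <- c(0.80, 0.82, 0.78, 0.85, 0.81)
  b <- a + c(0.05, 0.03, 0.06, 0.02, 0.04)
  cmp <- compare_stacking(a, b)
  d <- b - a
  t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$t_statistic, t_closed, tolerance = 1e-12)
  expect_equal(cmp$p_value,
               2 * pt(-abs(t_closed), length(d) - 1), tolerance = 1e-12)
  expect_equal(cmp$relative_improvement,
               (mean(b) - mean(a)) / mean(a), tolerance = 1e-12)

  # uniformly 10% higher
  cmp2 <- compare_stacking(a, a * 1.1)
  expect_equal(cmp2$relative_improvement, 0.1, tolerance = 1e-12)

  # identical pairs: degenerate p reported as undefined
  cmp3 <- compare_stacking(a, a)
  expect_true(cmp3$degenerate)
  expect_true(is.na(cmp3$p_value))
  expect_equal(cmp3$relative_improvement, 0)

  expect_error(compare_stacking(a, b[-1]), "equal length")
  expect_error(compare_stacking(c(0.5, 1.2), c(0.5, 0.6)), "\\[0, 1\\]")
})
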