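test_that("rendered phantoms put elements exactly on the lattice", {
  sp <- phantom_spec("dots", element_size = 400, spacing = 520,
                     grid_rows = 5, grid_cols = 7,
                     image_shape = c(160, 120), pixel_spacing = 26.5)
  img <- render_phantom(sp)
  expect_setequal(unique(as.vector(img)), c(0, 1))
  cents <- phantom_centroids(img)
  expect_equal(nrow(cents), 35L)
  # adjacent centroid distance equals the spec pitch within half a pixel
  expect_lt(abs(alphamap:::lattice_pitch(cents) - 520), 26.5 / 2)
  # independent center-of-mass oracle: mean pixel coordinates per component
  bw <- EBImage::bwlabel(unclass(img) > 0.5)
  oracle <- t(sapply(seq_len(max(bw)), function(l) {
    w <- which(as.array(bw) == l, arr.ind = TRUE)
    (colMeans(w) - 0.5) * 26.5
  }))
  nn <- apply(sp$centroids_um, 1, function(p)
    min(sqrt((oracle[, 1] - p[1])^2 + (oracle[, 2] - p[2])^2)))
  expect_lt(max(nn) / 26.5, 0.1)
  # elements larger than the frame are rejected
  expect_error(phantom_spec("dots", 300, 500, 50, 50, c(40, 40), 26.5),
               "bounds")
})

test_that("isotropic scale estimation is accurate and rotation-invariant", {
  sp <- test_dot_spec()
  img <- render_phantom(sp)
  expect_equal(estimate_isotropic_scale(img, img), 1.0)

  ph <- generate_distorted_phantom(sp, scale = 1.016)
  expect_equal(estimate_isotropic_scale(ph$distorted, ph$ideal), 1.016,
               tolerance = 0.001)

  rot <- alphamap:::resample_moving(
    img, rigid2d(rotation = 5 * pi / 180, center = c(80, 65) * 26.5),
    dim(img), 26.5)
  attr(rot, "pixel_spacing") <- 26.5
  expect_equal(estimate_isotropic_scale(rot, img), 1.0, tolerance = 0.001)
})

test_that("warp field estimation recovers a known barrel distortion", {
  sp <- test_dot_spec()
  ph <- generate_distorted_phantom(sp, scale = 1, k1 = 0.04, seed = 2)
  fld <- estimate_warp_field(ph$distorted, ph$ideal)
  expect_s3_class(fld, "deformation_field")
  expect_gt(min(fld$jacobian_det), 0)
  ci <- attr(ph$ideal, "spec")$centroids_um
  idx <- px_index(ci, 26.5, dim(ph$ideal))
  rms_px <- sqrt(mean((fld$dx[idx] - ph$field$dx[idx])^2 +
                      (fld$dy[idx] - ph$field$dy[idx])^2)) / 26.5
  expect_lt(rms_px, 0.5)
  rep <- attr(fld, "fit_report")
  expect_true(rep$converged)
  expect_equal(rep$n_elements, 48L)

  # identity: measured = ideal gives a (numerically) zero field
  img <- render_phantom(sp)
  fld0 <- estimate_warp_field(img, img)
  expect_lt(max(displacement_magnitude_map(fld0)) / 26.5, 0.25)
})

test_that("Jacobian-corrected resampling preserves intensity", {
  sp <- test_dot_spec()
  img <- render_phantom(sp)
  # identity field leaves the image unchanged
  z <- matrix(0, nrow(img), ncol(img))
  fid <- deformation_field(z, z, 26.5)
  expect_equal(unclass(apply_correction(img, fid)), unclass(img),
               ignore_attr = TRUE)

  # uniform areal expansion by 2: corrected-to-raw map compresses by sqrt(2),
  # Jacobian 1/2 halves every intensity
  g <- alphamap:::pixel_grid(nrow(img), ncol(img))
  ctr <- dim(img) / 2 * 26.5
  px <- (g$x - 0.5) * 26.5; py <- (g$y - 0.5) * 26.5
  fac <- 1 / sqrt(2) - 1
  fexp <- deformation_field(fac * (px - ctr[1]), fac * (py - ctr[2]), 26.5)
  expect_equal(unique(as.vector(round(fexp$jacobian_det, 10))), 0.5)
  flat <- matrix(3, nrow(img), ncol(img))
  out <- apply_correction(flat, fexp)
  interior <- out[20:140, 20:110]
  expect_equal(unname(as.vector(interior)), rep(1.5, length(interior)),
               tolerance = 1e-9)

  # smooth random seeded field conserves the total within 0.5%
  ph <- generate_distorted_phantom(sp, scale = 1, k1 = 0.015, n_bumps = 4,
                                   bump_amp_um = 20, bump_sigma_um = 700,
                                   seed = 5)
  corr <- apply_correction(ph$distorted, ph$field)
  expect_lt(abs(sum(corr) - sum(ph$distorted)) / sum(ph$distorted), 0.005)

  expect_error(apply_correction(img[1:10, 1:10], fid), "mismatch")
})

test_that("displacement magnitude maps behave geometrically", {
  z <- matrix(0, 30, 20)
  expect_equal(displacement_magnitude_map(deformation_field(z, z, 26.5)),
               z)
  tr <- deformation_field(z + 10, z, 26.5)
  expect_equal(displacement_magnitude_map(tr), z + 10)
  # barrel truth field peaks in the corners
  sp <- test_dot_spec()
  ph <- generate_distorted_phantom(sp, scale = 1, k1 = 0.05)
  mag <- displacement_magnitude_map(ph$field)
  corners <- c(1, nrow(mag), (ncol(mag) - 1) * nrow(mag) + 1,
               nrow(mag) * ncol(mag))
  expect_true(which.max(mag) %in% corners)
})

test_that("correcting a distorted phantom restores the lattice", {
  sp <- test_dot_spec()
  ph <- generate_distorted_phantom(sp, scale = 1, k1 = 0.03, n_bumps = 3,
                                   bump_amp_um = 15, seed = 8)
  fld <- estimate_warp_field(ph$distorted, ph$ideal)
  corr <- structure(apply_correction(ph$distorted, fld),
                    pixel_spacing = 26.5)
  cc <- phantom_centroids(corr)
  ci <- attr(ph$ideal, "spec")$centroids_um
  nn <- apply(ci, 1, function(p)
    min(sqrt((cc[, 1] - p[1])^2 + (cc[, 2] - p[2])^2)))
  expect_lt(sqrt(mean(nn^2)) / 26.5, 1)
})

test_that("deformation fields serialize with stage metadata", {
  z <- matrix(0, 16, 12)
  fld <- deformation_field(z + 5, z - 3, 26.5, provenance = c("rigid", "ffd"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_deformation_field(fld, path)
  back <- read_image_tiff(path)
  expect_equal(back$img[, , 1], z + 5, tolerance = 1e-5)
  expect_equal(back$img[, , 2], z - 3, tolerance = 1e-5)
  expect_equal(back$meta$provenance, c("rigid", "ffd"))
})
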