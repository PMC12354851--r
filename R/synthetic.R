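#' Simulate list-mode detection events from a known activity map
#'
#' Forward model of the camera: for each pixel and acquisition window the
#' expected number of detected events is
#' `f * (A0 / lambda) * (exp(-lambda t1) - exp(-lambda t2))`; realized counts
#' are Poisson, event positions uniform within the pixel, and timestamps
#' drawn from the exponential decay density truncated to the window. Fully
#' reproducible given the seed.
#'
#' @param activity An [activity_image()] (Bq per pixel at reference time 0).
#' @param isotope An [isotope()] or `"Ac-225"`.
#' @param f Camera sensitivity factor.
#' @param schedule An [acquisition_schedule()].
#' @param seed RNG seed.
#' @return An [event_list()] carrying `schedule`.
#' @export
simulate_listmode <- function(activity, isotope, f, schedule, seed = 1L) {
  iso <- as_isotope(isotope)
  if (f <= 0) stop("'f' must be > 0")
  sp <- attr(activity, "pixel_spacing")
  org <- attr(activity, "origin"); if (is.null(org)) org <- c(0, 0)
  a <- unclass(activity)
  set.seed(seed)
  xs <- ys <- ts <- numeric(); win <- integer()
  n0 <- a / iso$lambda  # atoms per pixel at reference time
  for (i in seq_len(nrow(schedule))) {
    t1 <- schedule$t_start[i]; t2 <- schedule$t_end[i]
    e1 <- exp(-iso$lambda * t1); e2 <- exp(-iso$lambda * t2)
    mu <- f * n0 * (e1 - e2)
    cnt <- stats::rpois(length(mu), as.vector(mu))
    tot <- sum(cnt)
    if (tot == 0L) next
    pix <- rep(seq_along(cnt), cnt)
    ix <- ((pix - 1) %% nrow(a)) + 1
    iy <- ((pix - 1) %/% nrow(a)) + 1
    xs <- c(xs, org[1] + (ix - 1 + stats::runif(tot)) * sp)
    ys <- c(ys, org[2] + (iy - 1 + stats::runif(tot)) * sp)
    u <- stats::runif(tot)
    tabs <- -log(e1 - u * (e1 - e2)) / iso$lambda  # absolute decay times
    ts <- c(ts, tabs - t1)
    win <- c(win, rep(i, tot))
  }
  event_list(xs, ys, ts, window = win, schedule = schedule)
}

#' Generate a distorted calibration phantom with known true field
#'
#' Renders the ideal phantom and a geometrically distorted copy under a known
#' feature mapping `m`: isotropic scale `s` plus radial (barrel-type)
#' distortion `r' = r (1 + k1 rho^2)` about the image center (`rho` = radius
#' in units of the image half-diagonal), plus optional smooth Gaussian
#' displacement bumps. A feature at ideal position `x` appears in the
#' distorted image at `m(x)`; the returned truth field `u = m - id` is
#' exactly the corrected-to-raw displacement that [apply_correction()]
#' expects, evaluated on the pixel grid.
#'
#' @param spec A [phantom_spec()].
#' @param scale Isotropic scale factor (e.g. 1.016 for +1.6%).
#' @param k1 Radial distortion coefficient (0 = none).
#' @param n_bumps,bump_amp_um,bump_sigma_um Smooth random Gaussian
#'   displacement bumps (seeded).
#' @param seed RNG seed for the bumps.
#' @return List: `ideal` and `distorted` images, `field` (the true
#'   [deformation_field()]), and `truth` (list with `scale`, `k1`, bump
#'   table).
#' @export
generate_distorted_phantom <- function(spec, scale = 1, k1 = 0, n_bumps = 0L,
                                       bump_amp_um = 0, bump_sigma_um = 500,
                                       seed = 1L) {
  ideal <- render_phantom(spec)
  nx <- spec$image_shape[1]; ny <- spec$image_shape[2]
  sp <- spec$pixel_spacing
  ctr <- c(nx, ny) * sp / 2
  halfdiag <- sqrt(sum((c(nx, ny) * sp / 2)^2))
  set.seed(seed)
  bumps <- if (n_bumps > 0)
    data.frame(x = stats::runif(n_bumps, 0.2, 0.8) * nx * sp,
               y = stats::runif(n_bumps, 0.2, 0.8) * ny * sp,
               ax = stats::runif(n_bumps, -1, 1) * bump_amp_um,
               ay = stats::runif(n_bumps, -1, 1) * bump_amp_um)
  else NULL
  fwd <- function(px, py) {   # feature map m: ideal -> distorted coords
    rx <- px - ctr[1]; ry <- py - ctr[2]
    rho2 <- (rx^2 + ry^2) / halfdiag^2
    fac <- scale * (1 + k1 * rho2)
    ox <- ctr[1] + fac * rx; oy <- ctr[2] + fac * ry
    if (!is.null(bumps)) for (b in seq_len(nrow(bumps))) {
      g <- exp(-((px - bumps$x[b])^2 + (py - bumps$y[b])^2) /
                 (2 * bump_sigma_um^2))
      ox <- ox + bumps$ax[b] * g; oy <- oy + bumps$ay[b] * g
    }
    list(x = ox, y = oy)
  }
  g <- pixel_grid(nx, ny)
  px <- (g$x - 0.5) * sp; py <- (g$y - 0.5) * sp
  # truth displacement field (corrected -> raw)
  f <- fwd(px, py)
  ux <- f$x - px; uy <- f$y - py
  # render distorted image: distorted(p) = ideal(m^{-1}(p)), inverse by
  # fixed-point iteration q <- p - u(q)
  qx <- px; qy <- py
  for (it in 1:40) {
    fq <- fwd(qx, qy)
    qx <- qx - (fq$x - px) * 0.8
    qy <- qy - (fq$y - py) * 0.8
  }
  distorted <- matrix(bilinear_sample(unclass(ideal), qx / sp + 0.5,
                                      qy / sp + 0.5), nx, ny)
  distorted <- structure(distorted, pixel_spacing = sp, origin = c(0, 0))
  fld <- deformation_field(ux, uy, sp, provenance = "synthetic_truth")
  list(ideal = ideal, distorted = distorted, field = fld,
       truth = list(scale = scale, k1 = k1, bumps = bumps))
}

#' Generate a kidney-like phantom with distance-structured uptake
#'
#' Builds a stained-section-like anatomy image (bright tissue ellipse with
#' texture, dark round glomeruli restricted to a cortical band, dark
#' elongated vessels), the matching ground-truth compartment masks, and an
#' activity map with a configurable enrichment profile: a raised-cosine
#' annular bump (peaking at the annulus center) of given amplitude around a
#' chosen reference structure, plus an optional blood-pool term in the
#' vessels. The activity is emitted both on the fine anatomy grid (truth) and
#' binned/averaged to the coarser autoradiography grid.
#'
#' @param shape Anatomy grid `c(nx, ny)` (default `c(360, 280)`).
#' @param pixel_spacing_um Anatomy pixel, micrometres (default 6.625 = one
#'   quarter of the 26.5 um autoradiography pixel).
#' @param activity_ratio Anatomy:autoradiography resolution ratio (default
#'   4).
#' @param cortex_width_um Cortical band measured inward from the tissue edge.
#' @param n_glomeruli,glom_diameter_um Glomeruli count and diameter band.
#' @param n_vessels,vessel_width_um,vessel_length_um Vessel geometry.
#' @param enrichment List `list(reference = "edge"|"glomeruli"|"vessels",
#'   annulus_um = c(lo, hi), amplitude = x)`; `amplitude` is the peak uptake
#'   in multiples of the tissue baseline (1 = no enrichment).
#' @param blood_pool Activity multiple inside vessels (default 1).
#' @param noise `"poisson"` scale (expected events per autoradiography pixel
#'   at baseline; 0 for noiseless).
#' @param seed RNG seed.
#' @return List: `anatomy` (matrix, spacing attr), `masks` (a
#'   `"compartment_masks"`-style list of truth masks), `activity_fine`
#'   (anatomy grid), `activity` (autoradiography grid [activity_image()]),
#'   and `truth` (spec echo).
#' @export
generate_kidney_phantom <- function(shape = c(360, 280),
                                    pixel_spacing_um = 6.625,
                                    activity_ratio = 4L,
                                    cortex_width_um = 400,
                                    n_glomeruli = 20L,
                                    glom_diameter_um = c(60, 120),
                                    n_vessels = 3L,
                                    vessel_width_um = 180,
                                    vessel_length_um = 900,
                                    enrichment = list(reference = "glomeruli",
                                                      annulus_um = c(50, 100),
                                                      amplitude = 1),
                                    blood_pool = 1,
                                    noise = 0,
                                    seed = 1L) {
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]; sp <- pixel_spacing_um
  g <- pixel_grid(nx, ny)
  px <- (g$x - 0.5) * sp; py <- (g$y - 0.5) * sp
  ctr <- c(nx, ny) * sp / 2
  ax <- 0.44 * nx * sp; by <- 0.44 * ny * sp
  tissue <- ((px - ctr[1]) / ax)^2 + ((py - ctr[2]) / by)^2 <= 1
  # distance from the outer tissue edge (inside the tissue)
  edge_dist <- distance_map(!tissue, sp)
  cortex <- tissue & edge_dist <= cortex_width_um & edge_dist > 0
  glomeruli <- matrix(FALSE, nx, ny)
  vessels <- matrix(FALSE, nx, ny)
  # elongated vessels placed in the interior
  placed_v <- 0L; tries <- 0L
  while (placed_v < n_vessels && tries < 200L) {
    tries <- tries + 1L
    cx <- stats::runif(1, 0.3, 0.7) * nx * sp
    cy <- stats::runif(1, 0.3, 0.7) * ny * sp
    th <- stats::runif(1, 0, pi)
    ux <- cos(th); uy <- sin(th)
    lon <- (px - cx) * ux + (py - cy) * uy
    lat <- -(px - cx) * uy + (py - cy) * ux
    v <- abs(lon) <= vessel_length_um / 2 & abs(lat) <= vessel_width_um / 2
    v <- v & tissue & edge_dist > cortex_width_um / 2
    if (!any(v) || any(v & (vessels | glomeruli))) next
    vessels <- vessels | v
    placed_v <- placed_v + 1L
  }
  # glomeruli in the cortex band, non-overlapping, away from vessels
  placed_g <- 0L; tries <- 0L
  while (placed_g < n_glomeruli && tries < 4000L) {
    tries <- tries + 1L
    i <- sample(which(cortex & edge_dist > glom_diameter_um[2]), 1L)
    cx <- px[i]; cy <- py[i]
    dia <- stats::runif(1, glom_diameter_um[1], glom_diameter_um[2])
    d2 <- (px - cx)^2 + (py - cy)^2
    gm <- d2 <= (dia / 2)^2
    near <- d2 <= (dia / 2 + 2 * sp)^2
    if (any(near & (glomeruli | vessels)) || any(gm & !tissue)) next
    glomeruli <- glomeruli | gm
    placed_g <- placed_g + 1L
  }
  if (placed_g < n_glomeruli)
    stop("could not place all glomeruli; relax the phantom spec")
  # stain-like anatomy: bright tissue, dark lumina, mild texture
  anatomy <- matrix(0.03, nx, ny)
  anatomy[tissue] <- 0.65
  anatomy <- anatomy + matrix(stats::rnorm(nx * ny, 0, 0.02), nx, ny)
  anatomy[glomeruli] <- 0.12
  anatomy[vessels] <- 0.10
  anatomy <- pmin(pmax(anatomy, 0), 1)
  anatomy <- structure(anatomy, pixel_spacing = sp)
  # activity: baseline + raised-cosine annular enrichment + blood pool
  act <- matrix(0, nx, ny); act[tissue] <- 1
  ref_mask <- switch(enrichment$reference,
                     edge = !tissue, glomeruli = glomeruli, vessels = vessels)
  if (enrichment$amplitude != 1 && any(ref_mask)) {
    dm <- distance_map(ref_mask, sp)
    lo <- enrichment$annulus_um[1]; hi <- enrichment$annulus_um[2]
    mid <- (lo + hi) / 2; halfw <- (hi - lo) / 2
    w <- ifelse(abs(dm - mid) <= halfw,
                0.5 * (1 + cos(pi * (dm - mid) / halfw)), 0)
    act <- act + (enrichment$amplitude - 1) * w * (act > 0)
  }
  act[vessels] <- blood_pool
  act_fine <- structure(act, pixel_spacing = sp)
  # average to the autoradiography grid
  r <- as.integer(activity_ratio)
  cnx <- nx %/% r; cny <- ny %/% r
  coarse <- matrix(0, cnx, cny)
  sub <- act[seq_len(cnx * r), seq_len(cny * r)]
  coarse <- .block_mean(sub, r)
  if (noise > 0) {
    lam <- coarse * noise
    coarse <- stats::rpois(length(lam), as.vector(lam)) / noise
    coarse <- matrix(coarse, cnx, cny)
  }
  masks <- structure(list(tissue = tissue, vessels = vessels,
                          glomeruli = glomeruli, features = NULL,
                          rules = NULL, pixel_spacing = sp),
                     class = "compartment_masks")
  list(anatomy = anatomy, masks = masks, activity_fine = act_fine,
       activity = activity_image(coarse, pixel_spacing = sp * r),
       truth = list(enrichment = enrichment, blood_pool = blood_pool,
                    cortex_width_um = cortex_width_um, seed = seed))
}

.block_mean <- function(m, r) {
  nx <- nrow(m) %/% r; ny <- ncol(m) %/% r
  a <- array(m[seq_len(nx * r), seq_len(ny * r)], c(r, nx, r, ny))
  apply(a, c(2, 4), mean)
}

# smooth 3D blob texture via random Gaussians
.blob_field <- function(nx, ny, n, sigma_px, seed_offset = 0) {
  f <- matrix(0, nx, ny)
  g <- pixel_grid(nx, ny)
  for (i in seq_len(n)) {
    cx <- stats::runif(1, 0.15, 0.85) * nx
    cy <- stats::runif(1, 0.15, 0.85) * ny
    s <- stats::runif(1, 0.6, 1.4) * sigma_px
    f <- f + exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * s^2))
  }
  f
}

#' Generate a serial-section tumor stack with known misalignments
#'
#' Slices a synthetic 3D tumor (lobed boundary, rich internal anatomy
#' texture; sparse hot-spot activity as is typical for antibody-mediated
#' alpha therapy) into `n_sections` sections, then applies a known random
#' rigid perturbation (and optionally a smooth warp) per section to both
#' modalities consistently — emulating sectioning artifacts. The truth
#' transforms allow registration methods to be scored exactly.
#'
#' @param n_sections Number of sections (default 3).
#' @param shape Anatomy grid per section (default `c(128, 128)`).
#' @param pixel_spacing_um Anatomy pixel (default 13.25).
#' @param z_spacing_um Section spacing (default 28).
#' @param n_hotspots,hotspot_sigma_um Sparse activity texture parameters.
#' @param max_rotation_deg,max_shift_um Per-section rigid perturbation
#'   ranges (uniform, the reference middle section is never perturbed).
#' @param warp_amp_um Amplitude of an additional smooth warp (0 = none).
#' @param seed RNG seed.
#' @return List: `sections` (each with `anatomy`, `activity`, perturbed),
#'   `truth` (per-section [rigid2d()] transforms applied, unperturbed
#'   `sections0`, `tissue_masks0`), `pixel_spacing_um`, `z_spacing_um`.
#' @export
generate_tumor_stack <- function(n_sections = 3L, shape = c(128L, 128L),
                                 pixel_spacing_um = 13.25, z_spacing_um = 28,
                                 n_hotspots = 5L, hotspot_sigma_um = 60,
                                 max_rotation_deg = 4, max_shift_um = 120,
                                 warp_amp_um = 0, seed = 1L) {
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]; sp <- pixel_spacing_um
  g <- pixel_grid(nx, ny)
  ctr <- c(nx, ny) / 2
  # lobed tumor boundary, slowly varying across z
  ang <- atan2(g$y - ctr[2], g$x - ctr[1])
  nlobe <- sample(3:5, 1)
  ph <- stats::runif(1, 0, 2 * pi)
  lobe_amp <- stats::runif(1, 0.08, 0.16)
  base_r <- 0.36 * min(nx, ny)
  # internal texture shared across z with per-section derivative
  tex <- .blob_field(nx, ny, 25L, 6)
  hot_x <- stats::runif(n_hotspots, 0.3, 0.7) * nx
  hot_y <- stats::runif(n_hotspots, 0.3, 0.7) * ny
  hot_a <- stats::runif(n_hotspots, 0.5, 1)
  sections0 <- vector("list", n_sections)
  tissue0 <- vector("list", n_sections)
  for (k in seq_len(n_sections)) {
    zfac <- 1 - 0.03 * abs(k - (n_sections + 1) / 2)
    rad <- base_r * zfac * (1 + lobe_amp * cos(nlobe * ang + ph))
    rr <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
    tis <- rr <= rad
    ana <- matrix(0.04, nx, ny)
    ana[tis] <- 0.55
    ana <- ana + 0.35 * tex * tis / max(tex)
    ana <- ana + matrix(stats::rnorm(nx * ny, 0, 0.015), nx, ny)
    ana <- pmin(pmax(ana, 0), 1)
    act <- matrix(0, nx, ny)
    for (h in seq_len(n_hotspots)) {
      act <- act + hot_a[h] *
        exp(-((g$x - hot_x[h])^2 + (g$y - hot_y[h])^2) /
              (2 * (hotspot_sigma_um / sp)^2)) * zfac
    }
    act <- act * tis
    sections0[[k]] <- list(anatomy = ana, activity = act)
    tissue0[[k]] <- tis
  }
  ref <- (n_sections + 1L) %/% 2L
  truth <- vector("list", n_sections)
  sections <- vector("list", n_sections)
  ctr_um <- ctr * sp
  for (k in seq_len(n_sections)) {
    if (k == ref) {
      tr <- rigid2d(center = ctr_um)
    } else {
      tr <- rigid2d(rotation = stats::runif(1, -1, 1) * max_rotation_deg * pi / 180,
                    translation = stats::runif(2, -1, 1) * max_shift_um,
                    center = ctr_um)
    }
    truth[[k]] <- tr
    # the observed section is the true section seen under the perturbation:
    # observed(p) = true(T^{-1}(p)); resampling with transform T^{-1}
    ti <- invert_rigid2d(tr)
    if (k == ref) {
      sections[[k]] <- sections0[[k]]
    } else {
      ana_p <- resample_moving(sections0[[k]]$anatomy, ti, c(nx, ny), sp)
      act_p <- resample_moving(sections0[[k]]$activity, ti, c(nx, ny), sp)
      if (warp_amp_um > 0) {
        wx <- .blob_field(nx, ny, 4L, nx / 3) ; wx <- wx - mean(wx)
        wy <- .blob_field(nx, ny, 4L, nx / 3) ; wy <- wy - mean(wy)
        wx <- wx / max(abs(wx)) * warp_amp_um / sp
        wy <- wy / max(abs(wy)) * warp_amp_um / sp
        ana_p <- matrix(bilinear_sample(ana_p, g$x + wx, g$y + wy), nx)
        act_p <- matrix(bilinear_sample(act_p, g$x + wx, g$y + wy), nx)
      }
      sections[[k]] <- list(anatomy = ana_p, activity = act_p)
    }
  }
  list(sections = sections, truth = list(transforms = truth,
                                         sections0 = sections0,
                                         tissue_masks0 = tissue0,
                                         reference = ref),
       pixel_spacing_um = sp, z_spacing_um = z_spacing_um)
}
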