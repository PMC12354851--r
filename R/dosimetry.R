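# Bragg-Kleeman range-energy coefficient for alpha particles in liquid water,
# k in um/MeV^p with p = 1.75, calibrated so that R(8.375 MeV) ~ 85 um
# (consistent with tabulated CSDA ranges: ~47 um at 5.8 MeV, ~85-90 um at
# 8.4 MeV).
.bk_exponent <- 1.75
.bk_k_um <- 85 / 8.375^1.75

#' Alpha-particle CSDA range and stopping power in water
#'
#' Bragg-Kleeman parametrization `R(E) = k E^p` (p = 1.75) of the
#' continuous-slowing-down range of alpha particles in liquid water, with `k`
#' calibrated against tabulated CSDA ranges (about 85 um at 8.375 MeV, the
#' most energetic Ac-225 chain alpha — hence the "under 80-90 um" action
#' radius of the chain). `alpha_stopping_power()` is the corresponding
#' `dE/dx = E^(1-p) / (k p)`.
#'
#' @param energy_mev Alpha energy, MeV (0 to 10).
#' @return Range in micrometres (strictly increasing, `R(0) = 0`), or
#'   stopping power in MeV/um.
#' @examples
#' alpha_range(8.375)   # ~85 um
#' alpha_range(5.830)   # ~45 um
#' @export
alpha_range <- function(energy_mev) {
  if (any(energy_mev < 0)) stop("energy must be >= 0")
  if (any(energy_mev > 10)) stop("parametrization calibrated for E <= 10 MeV")
  .bk_k_um * energy_mev^.bk_exponent
}

#' @rdname alpha_range
#' @export
alpha_stopping_power <- function(energy_mev) {
  if (any(energy_mev <= 0)) stop("energy must be > 0")
  energy_mev^(1 - .bk_exponent) / (.bk_k_um * .bk_exponent)
}

# Energy remaining after path length s for a particle of initial range R0:
# E(s) = ((R0 - s)/k)^(1/p), zero beyond the range.
energy_at_path <- function(R0, s) {
  r <- pmax(R0 - s, 0)
  (r / .bk_k_um)^(1 / .bk_exponent)
}

MEV_TO_J <- 1.602176634e-13

#' Generate an alpha dose-voxel kernel by Monte-Carlo CSDA transport
#'
#' Simulates `n_primaries` primary decays uniformly distributed inside the
#' central voxel of a 3D voxel grid. Each primary emits the isotope's chain
#' alphas isotropically; each alpha travels in a straight line
#' (continuous-slowing-down approximation in water, Bragg-Kleeman
#' range-energy relation) depositing its energy step by step into the voxels
#' it traverses. The kernel is the mean absorbed dose per primary decay in
#' each voxel (Gy), assuming unit-density water. Energy straggling, delta
#' rays, scattering and non-alpha emissions are neglected.
#'
#' @param isotope An [isotope()] or `"Ac-225"`.
#' @param voxel_um `c(dx, dy, dz)` voxel dimensions, micrometres (default
#'   `c(26.5, 26.5, 14)`: camera pixel spacing and section thickness).
#' @param kernel_extent Half-width of the kernel in voxels per axis
#'   (`2*extent+1` voxels); default covers the maximum alpha range. An error
#'   lists the required extent if too small.
#' @param n_primaries Number of simulated primary decays.
#' @param seed RNG seed.
#' @param step_um Deposition step (default `min(voxel_um)/4` capped at 1 um).
#' @return Object of class `"dose_voxel_kernel"`: 3D array of Gy per primary
#'   decay with odd dimensions and the source voxel at the center, plus
#'   attributes `voxel_um`, `n_primaries`, `seed`, `isotope`,
#'   `alphas_emitted` (simulation log: total alphas emitted),
#'   `energy_deposited_mev` (total inside the grid).
#' @export
generate_dvk <- function(isotope = "Ac-225", voxel_um = c(26.5, 26.5, 14),
                         kernel_extent = NULL, n_primaries = 1e5L, seed = 7L,
                         step_um = NULL) {
  iso <- as_isotope(isotope)
  if (n_primaries < 1) stop("'n_primaries' must be >= 1")
  rmax <- alpha_range(max(iso$alpha_energies_mev))
  need <- ceiling((rmax + max(voxel_um) / 2) / voxel_um)
  if (is.null(kernel_extent)) kernel_extent <- need
  kernel_extent <- rep(as.integer(kernel_extent), length.out = 3L)
  if (any(kernel_extent < need))
    stop(sprintf("kernel_extent too small: need at least c(%d, %d, %d) voxels",
                 need[1], need[2], need[3]))
  if (is.null(step_um)) step_um <- min(min(voxel_um) / 4, 1)
  dims <- 2L * kernel_extent + 1L
  nvox <- prod(dims)
  edep <- numeric(nvox)  # MeV accumulated per voxel
  set.seed(seed)
  # precompute per-line path discretization (identical for every track)
  lines <- lapply(iso$alpha_energies_mev, function(E) {
    R0 <- alpha_range(E)
    ns <- max(1L, ceiling(R0 / step_um))
    sb <- seq(0, R0, length.out = ns + 1L)
    list(mid = (sb[-1L] + sb[-(ns + 1L)]) / 2,
         de = energy_at_path(R0, sb[-(ns + 1L)]) - energy_at_path(R0, sb[-1L]))
  })
  chunk <- 5000L
  done <- 0L
  alphas_emitted <- 0L
  while (done < n_primaries) {
    m <- min(chunk, n_primaries - done)
    # decay positions uniform in the central voxel (um, kernel center at 0)
    px <- (stats::runif(m) - 0.5) * voxel_um[1]
    py <- (stats::runif(m) - 0.5) * voxel_um[2]
    pz <- (stats::runif(m) - 0.5) * voxel_um[3]
    for (ln in lines) {
      # one isotropic direction per primary per chain alpha
      cz <- stats::runif(m, -1, 1)
      phi <- stats::runif(m, 0, 2 * pi)
      sz <- sqrt(pmax(1 - cz^2, 0))
      dx <- sz * cos(phi); dy <- sz * sin(phi); dz <- cz
      alphas_emitted <- alphas_emitted + m
      # outer products: track x step midpoints
      X <- outer(dx, ln$mid) + px
      Y <- outer(dy, ln$mid) + py
      Z <- outer(dz, ln$mid) + pz
      ix <- floor(X / voxel_um[1] + 0.5) + kernel_extent[1] + 1L
      iy <- floor(Y / voxel_um[2] + 0.5) + kernel_extent[2] + 1L
      iz <- floor(Z / voxel_um[3] + 0.5) + kernel_extent[3] + 1L
      ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
            iz >= 1 & iz <= dims[3]
      idx <- (iz - 1L) * (dims[1] * dims[2]) + (iy - 1L) * dims[1] + ix
      w <- matrix(ln$de, m, length(ln$de), byrow = TRUE)
      add <- rowsum(w[ok], idx[ok])
      ii <- as.integer(rownames(add))
      edep[ii] <- edep[ii] + add[, 1]
    }
    done <- done + m
  }
  mass_kg <- prod(voxel_um) * 1e-12 * 1e-3  # um^3 -> cm^3 -> kg at 1 g/cm^3
  kern <- array(edep * MEV_TO_J / mass_kg / n_primaries, dims)
  structure(kern, voxel_um = voxel_um, n_primaries = n_primaries, seed = seed,
            isotope = iso, step_um = step_um,
            alphas_emitted = alphas_emitted,
            energy_deposited_mev = sum(edep),
            class = c("dose_voxel_kernel", "array"))
}

#' @export
print.dose_voxel_kernel <- function(x, ...) {
  d <- dim(x); v <- attr(x, "voxel_um")
  cat(sprintf(
    "<dose_voxel_kernel> %dx%dx%d voxels of %.3gx%.3gx%.3g um, %s, %g primaries\n",
    d[1], d[2], d[3], v[1], v[2], v[3], attr(x, "isotope")$name,
    attr(x, "n_primaries")))
  cat(sprintf("  central-voxel dose %.4g Gy/decay; energy in grid %.4g MeV/primary\n",
              x[(d[1] + 1) / 2, (d[2] + 1) / 2, (d[3] + 1) / 2],
              attr(x, "energy_deposited_mev") / attr(x, "n_primaries")))
  invisible(x)
}

#' Assemble a 3D activity volume from aligned sections
#'
#' Stacks aligned 2D activity maps at strictly increasing z positions with
#' constant spacing; each measured section's activity is taken as
#' representative of its slab.
#'
#' @param slices List of activity matrices (common in-plane grid) or a 3D
#'   array.
#' @param pixel_spacing In-plane pixel spacing, micrometres.
#' @param z_spacing Slab thickness / section spacing, micrometres.
#' @return Object of class `"activity_volume"`: 3D array with geometry
#'   attributes.
#' @export
activity_volume <- function(slices, pixel_spacing, z_spacing = 28) {
  if (is.list(slices)) {
    d <- dim(slices[[1]])
    arr <- array(0, c(d, length(slices)))
    for (k in seq_along(slices)) {
      if (!all(dim(slices[[k]]) == d)) stop("slices must share a common grid")
      arr[, , k] <- unclass(slices[[k]])
    }
  } else arr <- unclass(slices)
  if (any(arr < 0)) stop("activity must be >= 0")
  structure(arr, pixel_spacing = pixel_spacing, z_spacing = z_spacing,
            class = c("activity_volume", "array"))
}

#' Dose-rate map by kernel convolution
#'
#' Convolves the activity volume (Bq per voxel, converted to decays per hour)
#' with the dose-voxel kernel (Gy per decay), yielding a dose-rate map in
#' Gy/h at the activity reference time. Voxel geometries of kernel and
#' volume must match exactly; no silent resampling. When the kernel extends
#' beyond the stack in z, out-of-stack planes contribute no activity and the
#' function warns about the edge truncation.
#'
#' @param volume An [activity_volume()] (or 3D array with matching
#'   attributes).
#' @param kernel A [generate_dvk()] kernel with identical `voxel_um`.
#' @return Object of class `"dose_rate_map"`: 3D array, Gy/h.
#' @export
dose_rate_map <- function(volume, kernel) {
  vu <- attr(kernel, "voxel_um")
  sp <- attr(volume, "pixel_spacing"); zs <- attr(volume, "z_spacing")
  if (is.null(sp) || is.null(zs))
    stop("volume lacks pixel_spacing/z_spacing attributes")
  if (!isTRUE(all.equal(c(sp, sp, zs), as.numeric(vu), tolerance = 1e-6)))
    stop(sprintf(
      "voxel grid mismatch: volume %.6gx%.6gx%.6g um vs kernel %.6gx%.6gx%.6g um",
      sp, sp, zs, vu[1], vu[2], vu[3]))
  a <- unclass(volume); k <- unclass(kernel)
  da <- dim(a); dk <- dim(k)
  hz <- (dk[3] - 1) / 2
  if (hz > 0 && da[3] < dk[3])
    warning(sprintf(
      "kernel z-extent (+/-%d planes) exceeds the stack (%d planes): dose at the outer sections is edge-truncated",
      hz, da[3]))
  decays_per_h <- a * 3600
  out <- array(0, da)
  ctr <- (dk + 1) / 2
  for (k3 in seq_len(dk[3])) for (k2 in seq_len(dk[2])) for (k1 in seq_len(dk[1])) {
    kv <- k[k1, k2, k3]
    if (kv == 0) next
    o1 <- k1 - ctr[1]; o2 <- k2 - ctr[2]; o3 <- k3 - ctr[3]
    if (max(1, 1 + o1) > min(da[1], da[1] + o1) ||
        max(1, 1 + o2) > min(da[2], da[2] + o2) ||
        max(1, 1 + o3) > min(da[3], da[3] + o3)) next
    s1 <- max(1, 1 + o1):min(da[1], da[1] + o1)
    s2 <- max(1, 1 + o2):min(da[2], da[2] + o2)
    s3 <- max(1, 1 + o3):min(da[3], da[3] + o3)
    out[s1, s2, s3] <- out[s1, s2, s3] +
      kv * decays_per_h[s1 - o1, s2 - o2, s3 - o3]
  }
  structure(out, pixel_spacing = sp, z_spacing = zs,
            class = c("dose_rate_map", "array"))
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the masked volume receiving at least each threshold dose rate,
#' on a uniform threshold grid from 0 to the masked maximum (plus one closing
#' point just above the maximum, where the fraction is 0). Starts at 1,
#' monotone non-increasing.
#'
#' @param map A [dose_rate_map()] or numeric array.
#' @param mask Logical array of valid (tissue) voxels, nonempty; default all.
#' @param n_thresholds Number of thresholds between 0 and the maximum.
#' @return Object of class `"dvh_curve"`: data.frame with `threshold`
#'   (Gy/h) and `fraction`.
#' @export
cumulative_dvh <- function(map, mask = NULL, n_thresholds = 100L) {
  a <- unclass(map)
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  if (!any(mask)) stop("empty mask")
  v <- a[as.logical(mask)]
  mx <- max(v)
  thr <- if (mx > 0) seq(0, mx, length.out = n_thresholds) else c(0, 1)
  thr <- c(thr, if (mx > 0) mx * (1 + 1e-9) else 2)
  frac <- vapply(thr, function(t) mean(v >= t), numeric(1))
  structure(data.frame(threshold = thr, fraction = frac),
            class = c("dvh_curve", "data.frame"))
}

#' @export
plot.dvh_curve <- function(x, ...) {
  graphics::plot(x$threshold, x$fraction, type = "s", xlab = "dose rate (Gy/h)",
                 ylab = "volume fraction >= threshold", ylim = c(0, 1), ...)
  invisible(x)
}
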