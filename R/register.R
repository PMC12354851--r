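#' 2D rigid (and similarity) transforms
#'
#' A rigid transform maps fixed-frame coordinates to moving-frame
#' coordinates: `p' = s * R(theta) %*% (p - center) + center + t`, with
#' `s = 1` for a pure rigid transform (the determinant of the linear part is
#' then exactly 1: no scaling).
#'
#' @param rotation Rotation angle, radians.
#' @param translation `c(tx, ty)`, micrometres.
#' @param center Rotation center `c(x, y)`, micrometres.
#' @param scale Isotropic scale (1 for rigid; similarity transforms allow
#'   other values).
#' @return Object of class `"rigid2d"`.
#' @export
rigid2d <- function(rotation = 0, translation = c(0, 0), center = c(0, 0),
                    scale = 1) {
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 center = as.numeric(center), scale = scale),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> rot %.4g deg, t (%.4g, %.4g) um%s\n",
              x$rotation * 180 / pi, x$translation[1], x$translation[2],
              if (x$scale != 1) sprintf(", scale %.5g", x$scale) else ""))
  invisible(x)
}

#' @rdname rigid2d
#' @param transform A `rigid2d`.
#' @param points n x 2 matrix of coordinates (micrometres).
#' @export
apply_rigid2d <- function(transform, points) {
  points <- rbind(points)  # accept a single point as a vector
  ct <- cos(transform$rotation); st <- sin(transform$rotation)
  px <- points[, 1] - transform$center[1]
  py <- points[, 2] - transform$center[2]
  s <- transform$scale
  cbind(s * (ct * px - st * py) + transform$center[1] + transform$translation[1],
        s * (st * px + ct * py) + transform$center[2] + transform$translation[2])
}

invert_rigid2d <- function(tr) {
  # inverse of p' = sR(p-c)+c+t is p = (1/s)R(-theta)(p'-c)+c - (1/s)R(-theta)t
  ct <- cos(tr$rotation); st <- sin(tr$rotation); s <- tr$scale
  t_inv <- -c(ct * tr$translation[1] + st * tr$translation[2],
              -st * tr$translation[1] + ct * tr$translation[2]) / s
  rigid2d(rotation = -tr$rotation, translation = t_inv,
          center = tr$center, scale = 1 / s)
}

#' Least-squares rigid fit to paired landmarks
#'
#' Direct (closed-form) least-squares estimation of the rigid transform that
#' maps the fixed points onto the moving points, via the SVD of the
#' cross-covariance matrix (no scaling). Requires at least 3 non-collinear
#' point pairs.
#'
#' @param fixed_points,moving_points n x 2 matrices of paired landmark
#'   coordinates, micrometres.
#' @return A [rigid2d()] (center at the fixed centroid) with attribute
#'   `rms_residual_um`.
#' @export
landmark_rigid_fit <- function(fixed_points, moving_points) {
  f <- as.matrix(fixed_points); m <- as.matrix(moving_points)
  if (nrow(f) < 3L || nrow(m) != nrow(f))
    stop("need >= 3 paired landmarks")
  fc <- colMeans(f); mc <- colMeans(m)
  fcen <- sweep(f, 2, fc); mcen <- sweep(m, 2, mc)
  if (min(svd(fcen)$d) < 1e-9 * max(svd(fcen)$d, 1e-12))
    stop("degenerate landmark configuration (collinear points)")
  H <- t(mcen) %*% fcen
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  theta <- atan2(R[2, 1], R[1, 1])
  tr <- rigid2d(rotation = theta, translation = mc - fc, center = fc)
  pred <- apply_rigid2d(tr, f)
  attr(tr, "rms_residual_um") <- sqrt(mean(rowSums((pred - m)^2)))
  tr
}

# --- intensity metrics -------------------------------------------------------

normalize01 <- function(img) {
  lo <- min(img); hi <- max(img)
  if (hi > lo) (img - lo) / (hi - lo) else img * 0
}

#' Mutual information between two images
#'
#' Histogram-based mutual information (default 32 bins) on min-max
#' intensity-normalized images, the similarity metric driving the rigid
#' registration stages. Optionally restricted to a pixel mask.
#'
#' @param a,b Same-shape numeric matrices.
#' @param bins Number of histogram bins per axis.
#' @param mask Optional logical matrix of pixels to include.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(a, b, bins = 32L, mask = NULL) {
  av <- as.vector(normalize01(a)); bv <- as.vector(normalize01(b))
  if (!is.null(mask)) { av <- av[mask]; bv <- bv[mask] }
  ia <- pmin(floor(av * bins) + 1L, bins)
  ib <- pmin(floor(bv * bins) + 1L, bins)
  jo <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins) / length(ia)
  pj <- matrix(jo, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

# Resample moving image into the fixed frame under a rigid2d mapping
# fixed -> moving, both images sharing pixel spacing `sp` (um/px).
resample_moving <- function(moving, transform, shape, sp, bilinear = TRUE) {
  g <- pixel_grid(shape[1], shape[2])
  pts <- cbind((as.vector(g$x) - 0.5) * sp, (as.vector(g$y) - 0.5) * sp)
  q <- apply_rigid2d(transform, pts)
  xs <- q[, 1] / sp + 0.5; ys <- q[, 2] / sp + 0.5
  f <- if (bilinear) bilinear_sample else nn_sample
  matrix(f(unclass(moving), xs, ys), shape[1], shape[2])
}

# Generic rigid / similarity registration by maximizing mutual information
# with Nelder-Mead; parameters (theta_deg, tx_um, ty_um[, log_scale]).
register_rigid_mi <- function(fixed, moving, sp, init = rigid2d(),
                              similarity = FALSE, maxit = 400L, bins = 32L,
                              coarse_search = TRUE) {
  center <- c(nrow(fixed), ncol(fixed)) / 2 * sp
  shape <- dim(fixed)
  trace_env <- new.env(); trace_env$vals <- numeric()
  obj <- function(p) {
    tr <- rigid2d(rotation = p[1] * pi / 180,
                  translation = c(p[2], p[3]), center = center,
                  scale = if (similarity) exp(p[4]) else 1)
    w <- resample_moving(moving, tr, shape, sp)
    v <- -mutual_information(fixed, w, bins = bins)
    trace_env$vals <- c(trace_env$vals, v)
    v
  }
  # express the initial transform about our center
  p0c <- apply_rigid2d(init, rbind(center))
  init_t <- as.numeric(p0c) - center
  p0 <- c(init$rotation * 180 / pi, init_t,
          if (similarity) log(init$scale))
  if (coarse_search && !similarity) {
    # coarse MI sweep around the initialization to escape flat/ambiguous
    # starts (sub-capture-range shifts, weak rotation signal)
    best <- p0; bestv <- obj(p0)
    for (dr in seq(-12, 12, by = 4)) for (du in seq(-8, 8, by = 4))
      for (dv in seq(-8, 8, by = 4)) {
        p <- p0 + c(dr, du * sp, dv * sp)
        v <- obj(p)
        if (v < bestv) { bestv <- v; best <- p }
      }
    p0 <- best
  }
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9,
                                     parscale = c(1, sp, sp,
                                                  if (similarity) 0.05)))
  tr <- rigid2d(rotation = opt$par[1] * pi / 180,
                translation = c(opt$par[2], opt$par[3]), center = center,
                scale = if (similarity) exp(opt$par[4]) else 1)
  tv <- trace_env$vals
  tail_n <- max(2L, ceiling(length(tv) * 0.1))
  tail_v <- tv[(length(tv) - tail_n + 1):length(tv)]
  plateau <- (max(tail_v) - min(tail_v)) <=
    1e-6 * max(abs(stats::median(tail_v)), 1e-12)
  structure(tr, report = list(metric = -opt$value, trace = tv,
                              converged = plateau, evaluations = length(tv)))
}

#' Register stained-section histology to autoradiography
#'
#' Two-step procedure: landmark initialization (3+ points per modality,
#' closed-form least squares) followed by a rigid transformation optimized
#' against mutual information. When a slide carries several sections imaged
#' together, their relative positions are physically fixed, so a single rigid
#' transform is fitted for the whole slide group — this extra geometric
#' constraint resolves rotations that a single (possibly near-symmetric)
#' section cannot. No scaling is permitted: the autoradiography grid is
#' already physically calibrated by the warp correction.
#'
#' @param fixed Autoradiography (warp-corrected) image of the whole slide.
#' @param moving Anatomy image of the whole slide, same grid.
#' @param pixel_spacing Shared pixel spacing, micrometres.
#' @param fixed_landmarks,moving_landmarks Optional >= 3 paired points
#'   (micrometres) for initialization.
#' @param maxit Optimizer iteration cap.
#' @return A [rigid2d()] mapping fixed to moving coordinates, with attribute
#'   `report` (final metric, objective trace, plateau convergence flag).
#' @export
register_histology_to_autoradiography <- function(fixed, moving, pixel_spacing,
                                                  fixed_landmarks = NULL,
                                                  moving_landmarks = NULL,
                                                  maxit = 400L) {
  init <- if (!is.null(fixed_landmarks))
    landmark_rigid_fit(fixed_landmarks, moving_landmarks) else rigid2d()
  register_rigid_mi(fixed, moving, pixel_spacing, init = init,
                    similarity = FALSE, maxit = maxit)
}

# --- free-form stage: block matching + penalized B-spline field -------------

# Estimate a smooth displacement field moving -> fixed by local normalized
# cross-correlation block matching, then penalized B-spline smoothing.
block_match_field <- function(fixed, moving, sp, block = 16L, stride = 12L,
                              search = 5L, min_sd = 0.02, k = c(6L, 6L)) {
  nx <- nrow(fixed); ny <- ncol(fixed)
  fx <- normalize01(fixed); mv <- normalize01(moving)
  xs <- seq(1L, nx - block + 1L, by = stride)
  ys <- seq(1L, ny - block + 1L, by = stride)
  pos <- NULL; dsp <- NULL
  for (x0 in xs) for (y0 in ys) {
    bl <- fx[x0:(x0 + block - 1L), y0:(y0 + block - 1L)]
    if (stats::sd(bl) < min_sd) next
    best <- c(0, 0); bestv <- -Inf
    for (du in -search:search) for (dv in -search:search) {
      u0 <- x0 + du; v0 <- y0 + dv
      if (u0 < 1L || v0 < 1L || u0 + block - 1L > nx || v0 + block - 1L > ny)
        next
      fb <- mv[u0:(u0 + block - 1L), v0:(v0 + block - 1L)]
      if (stats::sd(fb) < 1e-8) next
      v <- stats::cor(as.vector(bl), as.vector(fb))
      if (is.finite(v) && v > bestv) { bestv <- v; best <- c(du, dv) }
    }
    if (bestv > 0.3) {
      ctr <- c(x0 + (block - 1) / 2, y0 + (block - 1) / 2)
      pos <- rbind(pos, (ctr - 0.5) * sp)
      dsp <- rbind(dsp, best * sp)
    }
  }
  if (is.null(pos) || nrow(pos) < 8L) return(NULL)
  fit_displacement_field(pos, dsp, c(nx, ny), sp, k = k)
}

#' Stack serial sections into an aligned 3D set
#'
#' Aligns an ordered set of serial sections (each with an activity map and an
#' anatomy image on a common grid) to the middle reference section, by one of
#' two strategies:
#' \describe{
#' \item{`"activity_only"`}{rigid then similarity transform fitted on the
#'   activity maps (mutual information); the resulting transforms are applied
#'   to the anatomy images for evaluation.}
#' \item{`"anatomy_guided"`}{rigid transform fitted on the anatomy images,
#'   followed by a free-form stage (local block matching + penalized B-spline
#'   displacement field, bending-energy regularized); the identical
#'   transforms are applied to the activity maps.}
#' }
#' Landmark initialization is used when landmarks are provided. Free-form
#' fields that fold (Jacobian determinant <= 0) are rejected.
#'
#' @param sections List of sections, each a list with `activity` and
#'   `anatomy` matrices on a common grid.
#' @param method `"anatomy_guided"` or `"activity_only"`.
#' @param pixel_spacing Grid spacing, micrometres.
#' @param z_spacing Section spacing, micrometres (default 28).
#' @param landmarks Optional list (per section) of >= 3 landmark points
#'   matched to the same points on the reference section.
#' @param maxit Optimizer iteration cap per stage.
#' @return Object of class `"section_stack"`: list with `method`, `z_um`,
#'   per-section `transforms` (and `fields` for the free-form stage),
#'   `activity` and `anatomy` 3D arrays aligned to the reference section's
#'   frame, and `reference` (index of the middle section).
#' @export
stack_sections <- function(sections,
                           method = c("anatomy_guided", "activity_only"),
                           pixel_spacing, z_spacing = 28,
                           landmarks = NULL, maxit = 300L) {
  method <- match.arg(method)
  n <- length(sections)
  if (n < 2L) stop("need at least 2 sections to stack")
  ref <- (n + 1L) %/% 2L
  shape <- dim(sections[[ref]]$anatomy)
  sp <- pixel_spacing
  transforms <- vector("list", n); fields <- vector("list", n)
  act <- array(0, c(shape, n)); ana <- array(0, c(shape, n))
  act[, , ref] <- sections[[ref]]$activity
  ana[, , ref] <- sections[[ref]]$anatomy
  transforms[[ref]] <- rigid2d()
  for (i in seq_len(n)[-ref]) {
    fixed_img <- if (method == "anatomy_guided") sections[[ref]]$anatomy
                 else sections[[ref]]$activity
    mov_img <- if (method == "anatomy_guided") sections[[i]]$anatomy
               else sections[[i]]$activity
    init <- if (!is.null(landmarks))
      landmark_rigid_fit(landmarks[[ref]], landmarks[[i]]) else rigid2d()
    tr <- register_rigid_mi(fixed_img, mov_img, sp, init = init,
                            similarity = FALSE, maxit = maxit)
    if (method == "activity_only") {
      tr <- register_rigid_mi(fixed_img, mov_img, sp, init = tr,
                              similarity = TRUE, maxit = maxit)
    }
    transforms[[i]] <- tr
    ana_w <- resample_moving(sections[[i]]$anatomy, tr, shape, sp)
    act_w <- resample_moving(sections[[i]]$activity, tr, shape, sp)
    if (method == "anatomy_guided") {
      ff <- block_match_field(sections[[ref]]$anatomy, ana_w, sp)
      if (!is.null(ff)) {
        jd <- jacobian_determinant(ff$dx, ff$dy, sp)
        if (min(jd) > 0) {   # reject folding fields
          fld <- deformation_field(ff$dx, ff$dy, sp,
                                   provenance = c("blockmatch_bspline"))
          # displacement maps reference coords to warped-moving coords
          g <- pixel_grid(shape[1], shape[2])
          xs <- g$x + fld$dx / sp; ys <- g$y + fld$dy / sp
          ana_w <- matrix(bilinear_sample(ana_w, xs, ys), shape[1])
          act_w <- matrix(bilinear_sample(act_w, xs, ys), shape[1])
          fields[[i]] <- fld
        }
      }
    }
    ana[, , i] <- ana_w
    act[, , i] <- act_w
  }
  structure(list(method = method, z_um = (seq_len(n) - 1) * z_spacing,
                 z_spacing = z_spacing, pixel_spacing = sp,
                 transforms = transforms, fields = fields,
                 activity = act, anatomy = ana, reference = ref),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d sections (%s), z spacing %.3g um, ref %d\n",
              dim(x$activity)[3], x$method, x$z_spacing, x$reference))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two same-shape binary masks. Two
#' empty masks are defined to agree perfectly (DSC 1, a documented
#' convention).
#'
#' @param mask_a,mask_b Logical or 0/1 matrices of equal shape.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shape mismatch")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1.0)
  2 * sum(a & b) / denom
}

#' Compare stacking strategies by paired Dice coefficients
#'
#' Computes the mean relative improvement of the anatomy-guided over the
#' activity-only stacking, `(mean_anat - mean_act) / mean_act`, and a paired
#' two-sided t-test on the per-set DSC differences.
#'
#' @param dsc_activity,dsc_anatomy Equal-length numeric vectors of per-set
#'   DSCs for the two methods (paired by set).
#' @return Object of class `"stacking_comparison"`: list with `n`,
#'   `mean_activity`, `mean_anatomy`, `relative_improvement`, `t_statistic`,
#'   `p_value` (NA with a `degenerate` flag if the differences have zero
#'   variance).
#' @export
compare_stacking <- function(dsc_activity, dsc_anatomy) {
  if (length(dsc_activity) != length(dsc_anatomy))
    stop("paired DSC lists must have equal length")
  n <- length(dsc_activity)
  if (n < 2L) stop("need n >= 2 pairs")
  if (any(dsc_activity < 0 | dsc_activity > 1 |
          dsc_anatomy < 0 | dsc_anatomy > 1))
    stop("DSC values must lie in [0, 1]")
  d <- dsc_anatomy - dsc_activity
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    ht <- stats::t.test(dsc_anatomy, dsc_activity, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(list(n = n,
                 mean_activity = mean(dsc_activity),
                 mean_anatomy = mean(dsc_anatomy),
                 relative_improvement =
                   (mean(dsc_anatomy) - mean(dsc_activity)) /
                   mean(dsc_activity),
                 t_statistic = tt$statistic, p_value = tt$p.value,
                 degenerate = degenerate),
            class = "stacking_comparison")
}

#' @export
print.stacking_comparison <- function(x, ...) {
  cat(sprintf("Stacking comparison over %d paired sets\n", x$n))
  cat(sprintf("  mean DSC: activity-only %.4f, anatomy-guided %.4f (%+.1f%%)\n",
              x$mean_activity, x$mean_anatomy,
              100 * x$relative_improvement))
  if (x$degenerate)
    cat("  paired t-test undefined (zero-variance differences)\n")
  else
    cat(sprintf("  paired t = %.3f, two-sided p = %.3g\n",
                x$t_statistic, x$p_value))
  invisible(x)
}
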