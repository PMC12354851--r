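#' Calibration phantom specification and rendering
#'
#' Describes a regular lattice phantom (filled circles, squares, or small
#' dots) used to calibrate the camera's geometric distortion, and renders its
#' idealized digital image: binary 0/1, element centroids exactly on the
#' lattice.
#'
#' @param kind One of `"circles"`, `"squares"`, `"dots"`.
#' @param element_size Element diameter / side, micrometres.
#' @param spacing Center-to-center lattice pitch, micrometres
#'   (`> element_size`).
#' @param grid_rows,grid_cols Lattice dimensions.
#' @param image_shape `c(nx, ny)` pixels.
#' @param pixel_spacing Pixel side, micrometres.
#' @return `phantom_spec()`: a `"phantom_spec"` list, including the exact
#'   lattice centroid coordinates (`centroids_um`, lattice centered in the
#'   image). `render_phantom()`: a 0/1 matrix with geometry attributes.
#' @examples
#' sp <- phantom_spec("dots", element_size = 100, spacing = 400,
#'                    grid_rows = 5, grid_cols = 7,
#'                    image_shape = c(128, 96), pixel_spacing = 26.5)
#' img <- render_phantom(sp)
#' @export
phantom_spec <- function(kind = c("dots", "circles", "squares"),
                         element_size, spacing, grid_rows, grid_cols,
                         image_shape, pixel_spacing) {
  kind <- match.arg(kind)
  if (!(spacing > element_size) || element_size <= 0)
    stop("need spacing > element_size > 0")
  ext <- c(image_shape[1], image_shape[2]) * pixel_spacing
  cx <- ext[1] / 2 + (seq_len(grid_cols) - (grid_cols + 1) / 2) * spacing
  cy <- ext[2] / 2 + (seq_len(grid_rows) - (grid_rows + 1) / 2) * spacing
  cents <- cbind(x = rep(cx, times = grid_rows),
                 y = rep(cy, each = grid_cols))
  half <- element_size / 2
  if (any(cents[, 1] - half < 0) || any(cents[, 1] + half > ext[1]) ||
      any(cents[, 2] - half < 0) || any(cents[, 2] + half > ext[2]))
    stop("phantom elements exceed image bounds")
  structure(list(kind = kind, element_size = element_size, spacing = spacing,
                 grid_rows = grid_rows, grid_cols = grid_cols,
                 image_shape = as.integer(image_shape),
                 pixel_spacing = pixel_spacing, centroids_um = cents),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param spec A `phantom_spec`.
#' @param supersample Anti-aliasing subsampling factor used only to decide
#'   pixel membership (default 1: a pixel is set if its center is inside an
#'   element; binary output either way).
#' @export
render_phantom <- function(spec, supersample = 1L) {
  nx <- spec$image_shape[1]; ny <- spec$image_shape[2]
  g <- pixel_grid(nx, ny)
  px <- (g$x - 0.5) * spec$pixel_spacing
  py <- (g$y - 0.5) * spec$pixel_spacing
  img <- matrix(0, nx, ny)
  half <- spec$element_size / 2
  for (i in seq_len(nrow(spec$centroids_um))) {
    dx <- px - spec$centroids_um[i, 1]
    dy <- py - spec$centroids_um[i, 2]
    inside <- if (spec$kind == "squares")
      abs(dx) <= half & abs(dy) <= half
    else dx^2 + dy^2 <= half^2
    img[inside] <- 1
  }
  structure(img, pixel_spacing = spec$pixel_spacing, origin = c(0, 0),
            spec = spec)
}

#' Extract element centroids from a phantom image
#'
#' Connected-component labelling followed by per-component center of mass, in
#' micrometres. Foreground is `image > 0.5 * max`.
#'
#' @param image Phantom image matrix (geometry attributes respected).
#' @param min_px Discard components smaller than this many pixels.
#' @return Matrix with columns `x`, `y` (micrometres), one row per element.
#' @export
phantom_centroids <- function(image, min_px = 2L) {
  spacing <- attr(image, "pixel_spacing"); if (is.null(spacing)) spacing <- 1
  origin <- attr(image, "origin"); if (is.null(origin)) origin <- c(0, 0)
  img <- unclass(image)
  bw <- EBImage::bwlabel(img > 0.5 * max(img))
  n <- max(bw)
  if (n == 0L) stop("no phantom elements found")
  # intensity-weighted centers of mass over a slightly larger support, so the
  # grey anti-aliased rim of resampled phantoms contributes subpixel accuracy
  supp <- img > 0.1 * max(img)
  lab <- nn_grow_labels(as.array(bw), supp)
  idx <- which(lab > 0)
  l <- lab[idx]; w <- img[idx]
  xs <- ((idx - 1) %% nrow(img)) + 1
  ys <- ((idx - 1) %/% nrow(img)) + 1
  sz <- tabulate(l, n)
  wsum <- tapply(w, l, sum)
  cx <- (tapply(xs * w, l, sum) / wsum)[sz >= min_px]
  cy <- (tapply(ys * w, l, sum) / wsum)[sz >= min_px]
  cbind(x = origin[1] + (as.numeric(cx) - 0.5) * spacing,
        y = origin[2] + (as.numeric(cy) - 0.5) * spacing)
}

# Extend component labels over a support mask by one-pass nearest label in a
# 3x3 neighbourhood, repeated until stable (support rims are thin).
nn_grow_labels <- function(lab, supp) {
  nx <- nrow(lab); ny <- ncol(lab)
  for (rep in 1:3) {
    todo <- supp & lab == 0
    if (!any(todo)) break
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      src <- matrix(0L, nx, ny)
      xr <- max(1, 1 + sh[1]):min(nx, nx + sh[1])
      yr <- max(1, 1 + sh[2]):min(ny, ny + sh[2])
      src[xr, yr] <- lab[xr - sh[1], yr - sh[2]]
      fill <- todo & lab == 0 & src > 0
      lab[fill] <- src[fill]
    }
  }
  lab
}

# Robust lattice pitch: median nearest-neighbour centroid distance.
lattice_pitch <- function(cents) {
  d <- as.matrix(stats::dist(cents))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

# Centroids of an ideal phantom: exact lattice positions when the image was
# digitally generated by render_phantom (spec attached), else measured.
ideal_centroids <- function(image) {
  sp <- attr(image, "spec")
  if (!is.null(sp)) sp$centroids_um else phantom_centroids(image)
}

# Nearest-neighbour correspondence between two centered centroid clouds;
# returns indices into `to` for each row of `from`.
match_centroids <- function(from, to) {
  fc <- sweep(from, 2, colMeans(from)); tc <- sweep(to, 2, colMeans(to))
  apply(fc, 1, function(p)
    which.min((tc[, 1] - p[1])^2 + (tc[, 2] - p[2])^2))
}

#' Estimate the global isotropic scale error from a circles phantom
#'
#' Matches element centroids between the measured and ideal lattice (nearest
#' neighbour after centering) and returns the robust median of paired
#' centered-radius ratios — the ratio of measured to ideal lattice pitch,
#' invariant to rotation and translation of the phantom.
#'
#' @param measured,ideal Phantom images (same phantom; any rigid pose).
#' @return Scalar scale factor (measured / ideal), e.g. 1.016 for a 1.6%
#'   enlargement.
#' @export
estimate_isotropic_scale <- function(measured, ideal) {
  cm <- phantom_centroids(measured)
  ci <- phantom_centroids(ideal)  # same extractor on both: biases cancel
  if (abs(nrow(cm) - nrow(ci)) / nrow(ci) > 0.2)
    stop(sprintf("element count mismatch > 20%% (measured %d vs ideal %d)",
                 nrow(cm), nrow(ci)))
  nn <- match_centroids(ci, cm)
  cic <- sweep(ci, 2, colMeans(ci))
  cmc <- sweep(cm[nn, , drop = FALSE], 2, colMeans(cm[nn, , drop = FALSE]))
  ri <- sqrt(rowSums(cic^2)); rm <- sqrt(rowSums(cmc^2))
  keep <- ri > lattice_pitch(ci) / 2   # exclude near-center elements
  stats::median(rm[keep] / ri[keep])
}

# Fit a smooth dense displacement field through scattered (position,
# displacement) samples with penalized tensor-product B-spline smooths
# (bending-energy-type penalty); returns um-valued dx, dy on the pixel grid.
fit_displacement_field <- function(pos_um, disp_um, image_shape, pixel_spacing,
                                   k = NULL) {
  n <- nrow(pos_um)
  df <- data.frame(x = pos_um[, 1], y = pos_um[, 2],
                   dx = disp_um[, 1], dy = disp_um[, 2])
  g <- pixel_grid(image_shape[1], image_shape[2])
  newd <- data.frame(x = as.vector((g$x - 0.5) * pixel_spacing),
                     y = as.vector((g$y - 0.5) * pixel_spacing))
  if (is.null(k)) {
    kx <- max(4L, min(10L, floor(sqrt(n)) ))
    k <- c(kx, kx)
  }
  form1 <- stats::as.formula(sprintf("dx ~ te(x, y, k = c(%d, %d), bs = 'ps')",
                                     k[1], k[2]))
  form2 <- stats::as.formula(sprintf("dy ~ te(x, y, k = c(%d, %d), bs = 'ps')",
                                     k[1], k[2]))
  fit1 <- mgcv::gam(form1, data = df)
  fit2 <- mgcv::gam(form2, data = df)
  dx <- matrix(stats::predict(fit1, newd), image_shape[1], image_shape[2])
  dy <- matrix(stats::predict(fit2, newd), image_shape[1], image_shape[2])
  list(dx = dx, dy = dy,
       rms_residual_um = sqrt(mean(stats::residuals(fit1)^2 +
                                   stats::residuals(fit2)^2)))
}

# Jacobian determinant of the map x -> x + u(x) by central differences on the
# dense displacement grid (one-sided at borders). Displacement in um, grid
# spacing in um.
jacobian_determinant <- function(dx, dy, pixel_spacing) {
  grad <- function(m) {
    nx <- nrow(m); ny <- ncol(m)
    gx <- m; gy <- m
    gx[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / 2
    gx[1, ] <- m[2, ] - m[1, ]; gx[nx, ] <- m[nx, ] - m[nx - 1, ]
    gy[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / 2
    gy[, 1] <- m[, 2] - m[, 1]; gy[, ny] <- m[, ny] - m[, ny - 1]
    list(x = gx / pixel_spacing, y = gy / pixel_spacing)
  }
  gdx <- grad(dx); gdy <- grad(dy)
  (1 + gdx$x) * (1 + gdy$y) - gdx$y * gdy$x
}

#' Construct a deformation field object
#'
#' A deformation field maps corrected coordinates to raw (distorted)
#' coordinates: `x_raw = x_corrected + u(x_corrected)`, displacement `u` in
#' micrometres on the pixel grid. The Jacobian determinant of the map is
#' computed by central differences and must be positive everywhere (no
#' folding).
#'
#' @param dx,dy Displacement components, micrometres, matrices on the image
#'   grid.
#' @param pixel_spacing Pixel side, micrometres.
#' @param provenance Character vector of transform stages.
#' @return Object of class `"deformation_field"`.
#' @export
deformation_field <- function(dx, dy, pixel_spacing, provenance = character()) {
  stopifnot(all(dim(dx) == dim(dy)))
  if (any(!is.finite(dx)) || any(!is.finite(dy)))
    stop("displacement must be finite")
  jd <- jacobian_determinant(dx, dy, pixel_spacing)
  if (min(jd) <= 0)
    stop("deformation field folds (Jacobian determinant <= 0)")
  structure(list(dx = dx, dy = dy, jacobian_det = jd,
                 pixel_spacing = pixel_spacing, provenance = provenance),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf(
    "<deformation_field> %d x %d px, |u| max %.3g um, Jdet in [%.3g, %.3g]\n",
    nrow(x$dx), ncol(x$dx), max(mag), min(x$jacobian_det),
    max(x$jacobian_det)))
  cat("  stages:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Estimate the warping correction field from a measured phantom
#'
#' Matches lattice element centroids between the measured (distorted) and
#' ideal phantom images, decomposes their displacements into a rigid part
#' (least-squares rotation + translation) plus a smooth free-form residual
#' fitted by penalized tensor-product B-splines, and returns the composed
#' dense field mapping corrected to raw coordinates. Apply any global
#' isotropic scale correction before calling ([estimate_isotropic_scale()]).
#'
#' @param measured,ideal Same-shape phantom images.
#' @param k Optional B-spline basis dimension `c(kx, ky)` for the free-form
#'   stage.
#' @return A [deformation_field()] with a `fit_report` attribute
#'   (`rms_residual_um` at the centroids, matched element count,
#'   `converged`).
#' @export
estimate_warp_field <- function(measured, ideal, k = NULL) {
  if (!all(dim(measured) == dim(ideal))) stop("images must have equal shape")
  spacing <- attr(ideal, "pixel_spacing"); if (is.null(spacing)) spacing <- 1
  cm <- phantom_centroids(measured)
  ci <- phantom_centroids(ideal)  # same extractor on both: biases cancel
  if (abs(nrow(cm) - nrow(ci)) / nrow(ci) > 0.2)
    stop("element count mismatch > 20% between measured and ideal phantom")
  nn <- match_centroids(ci, cm)
  if (anyDuplicated(nn)) {
    keep <- !duplicated(nn)
    ci <- ci[keep, , drop = FALSE]; nn <- nn[keep]
  }
  cm <- cm[nn, , drop = FALSE]
  rig <- landmark_rigid_fit(ci, cm)   # maps ideal -> measured coords
  rigid_pos <- apply_rigid2d(rig, ci)
  resid <- cm - rigid_pos
  ff <- fit_displacement_field(ci, resid, dim(ideal), spacing, k = k)
  g <- pixel_grid(nrow(ideal), ncol(ideal))
  px <- (g$x - 0.5) * spacing; py <- (g$y - 0.5) * spacing
  rg <- apply_rigid2d(rig, cbind(as.vector(px), as.vector(py)))
  dx <- matrix(rg[, 1], nrow(ideal)) - px + ff$dx
  dy <- matrix(rg[, 2], nrow(ideal)) - py + ff$dy
  fld <- deformation_field(dx, dy, spacing,
                           provenance = c("rigid", "bspline_freeform"))
  attr(fld, "fit_report") <- list(
    rms_residual_um = ff$rms_residual_um, n_elements = nrow(ci),
    converged = TRUE,
    rigid = list(rotation = rig$rotation, translation = rig$translation))
  fld
}

#' Apply a warping correction with intensity preservation
#'
#' Resamples the raw image at `x + u(x)` (bilinear) and multiplies by the
#' Jacobian determinant of the field, so that local count density changes are
#' compensated and the image integral is preserved for content that stays
#' inside the frame.
#'
#' @param image Raw image matrix (counts or activity).
#' @param field A [deformation_field()] of the same shape.
#' @return Corrected image, same shape and geometry attributes as `image`.
#' @export
apply_correction <- function(image, field) {
  if (!inherits(field, "deformation_field")) stop("'field' must be a deformation_field")
  if (!all(dim(image) == dim(field$dx)))
    stop("field/image shape mismatch")
  sp <- field$pixel_spacing
  g <- pixel_grid(nrow(image), ncol(image))
  xs <- g$x + field$dx / sp
  ys <- g$y + field$dy / sp
  out <- matrix(bilinear_sample(unclass(image), xs, ys), nrow(image)) *
    field$jacobian_det
  attributes(out) <- attributes(image)[c("dim", "pixel_spacing", "origin")]
  dim(out) <- dim(image)
  out
}

#' Displacement magnitude map
#'
#' Per-pixel Euclidean norm of the displacement, micrometres — the standard
#' visualization of detector distortion (largest in the corners for
#' barrel-type distortion).
#'
#' @param field A [deformation_field()].
#' @return Matrix of displacement magnitudes, micrometres.
#' @export
displacement_magnitude_map <- function(field) {
  sqrt(field$dx^2 + field$dy^2)
}

#' Write a deformation field to disk
#'
#' Stored as a 2-slice 32-bit float TIFF (dx, dy in micrometres) plus JSON
#' stage metadata.
#' @param field A [deformation_field()].
#' @param path Output TIFF path.
#' @export
write_deformation_field <- function(field, path) {
  arr <- array(0, c(dim(field$dx), 2L))
  arr[, , 1] <- field$dx; arr[, , 2] <- field$dy
  write_image_tiff(arr, path,
                   meta = list(pixel_spacing = field$pixel_spacing,
                               channels = c("dx_um", "dy_um"),
                               provenance = field$provenance))
}
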