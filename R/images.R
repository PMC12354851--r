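#' Activity image container
#'
#' A calibrated 2D activity map: Bq per pixel at reference time 0. Stored as a
#' numeric matrix indexed `[ix, iy]` (x along the first dimension, matching
#' EBImage convention), with physical metadata in attributes.
#'
#' @param activity Numeric matrix, Bq per pixel, all finite and >= 0.
#' @param pixel_spacing Pixel side, micrometres.
#' @param origin `c(x, y)` of the low corner of pixel (1,1), micrometres.
#' @param isotope An [isotope()] or `NULL`.
#' @param reference_time_label Free text describing reference time 0.
#' @return Object of class `"activity_image"`.
#' @export
activity_image <- function(activity, pixel_spacing, origin = c(0, 0),
                           isotope = NULL, reference_time_label = "t0") {
  activity <- as.matrix(activity)
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activity values must be finite and >= 0")
  structure(activity, pixel_spacing = pixel_spacing,
            origin = as.numeric(origin), isotope = isotope,
            reference_time_label = reference_time_label,
            class = c("activity_image", "matrix", "array"))
}

#' @export
print.activity_image <- function(x, ...) {
  cat(sprintf(
    "<activity_image> %d x %d px @ %.3g um, total %.4g Bq at '%s'\n",
    nrow(x), ncol(x), attr(x, "pixel_spacing"), sum(x),
    attr(x, "reference_time_label")))
  invisible(x)
}

#' Write / read an image as 32-bit float TIFF with JSON metadata
#'
#' Images (counts, activity, masks, kernels) are stored as 32-bit float TIFF;
#' physical metadata (pixel spacing, origin, isotope, any extra fields) go to
#' a sidecar `<file>.json`. 3D arrays are written as multi-slice TIFFs.
#'
#' @param img Numeric matrix or 3D array.
#' @param path Output TIFF path.
#' @param meta Named list of metadata to store alongside.
#' @return `write_image_tiff()`: `path` invisibly. `read_image_tiff()`: list
#'   with `img` (matrix/array) and `meta` (list, possibly empty).
#' @export
write_image_tiff <- function(img, path, meta = list()) {
  a <- unclass(img)
  for (at in c("pixel_spacing", "origin", "reference_time_label", "dropped"))
    if (!is.null(attr(img, at)) && is.null(meta[[at]])) meta[[at]] <- attr(img, at)
  # TIFF samples live in [0,1]; store an affine intensity transform in the
  # sidecar so arbitrary physical ranges round-trip.
  lo <- min(a); hi <- max(a)
  scale <- if (hi > lo) hi - lo else 1
  meta$intensity_offset <- lo
  meta$intensity_scale <- scale
  a <- (a - lo) / scale
  if (length(dim(a)) == 2L) {
    tiff::writeTIFF(t(a), path, bits.per.sample = 32)
  } else {
    sl <- lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]))
    tiff::writeTIFF(sl, path, bits.per.sample = 32)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE)
  img <- if (length(x) == 1L) t(x[[1]])
         else {
           arr <- array(0, c(ncol(x[[1]]), nrow(x[[1]]), length(x)))
           for (k in seq_along(x)) arr[, , k] <- t(x[[k]])
           arr
         }
  mp <- paste0(path, ".json")
  meta <- if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE)
          else list()
  if (!is.null(meta$intensity_scale))
    img <- img * meta$intensity_scale + meta$intensity_offset
  list(img = img, meta = meta)
}

# Bilinear sampling of a matrix at continuous pixel coordinates (1-based,
# pixel centers at integers). Points outside the support return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x >= 1 & x <= nx & y >= 1 & y <= ny
  x0c <- pmin(pmax(x0, 1L), nx); x1c <- pmin(x0c + 1L, nx)
  y0c <- pmin(pmax(y0, 1L), ny); y1c <- pmin(y0c + 1L, ny)
  # clamp fractional parts where clipping occurred
  fx <- ifelse(x0 < 1, 0, ifelse(x0 >= nx, 0, fx))
  fy <- ifelse(y0 < 1, 0, ifelse(y0 >= ny, 0, fy))
  i00 <- (y0c - 1) * nx + x0c; i10 <- (y0c - 1) * nx + x1c
  i01 <- (y1c - 1) * nx + x0c; i11 <- (y1c - 1) * nx + x1c
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i10] +
       (1 - fx) * fy * img[i01] + fx * fy * img[i11]
  v[!inside] <- fill
  v
}

# Nearest-neighbour sampling (mask-safe).
nn_sample <- function(img, x, y, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  xi <- round(x); yi <- round(y)
  inside <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  xi <- pmin(pmax(xi, 1L), nx); yi <- pmin(pmax(yi, 1L), ny)
  v <- img[(yi - 1) * nx + xi]
  v[!inside] <- fill
  v
}

# Pixel-center coordinate grids for an nx x ny image.
pixel_grid <- function(nx, ny) {
  list(x = matrix(rep(seq_len(nx), ny), nx, ny),
       y = matrix(rep(seq_len(ny), each = nx), nx, ny))
}

#' Resample an image onto a finer or coarser grid (bilinear)
#'
#' Maps between two grids that share physical coordinates: pixel centers at
#' `origin + (i - 0.5) * spacing`. Used to move autoradiography activity onto
#' the finer anatomy grid for spatial profiling.
#'
#' @param img Matrix with attributes `pixel_spacing` and `origin`, or plain
#'   matrix plus explicit `spacing`/`origin` arguments.
#' @param target_shape `c(nx, ny)` of the target grid.
#' @param target_spacing Target pixel spacing, micrometres.
#' @param target_origin Target origin (default same as source).
#' @param spacing,origin Source geometry overrides.
#' @return Matrix of size `target_shape` with updated geometry attributes.
#' @export
resample_to_grid <- function(img, target_shape, target_spacing,
                             target_origin = NULL,
                             spacing = attr(img, "pixel_spacing"),
                             origin = attr(img, "origin")) {
  if (is.null(origin)) origin <- c(0, 0)
  if (is.null(target_origin)) target_origin <- origin
  g <- pixel_grid(target_shape[1], target_shape[2])
  xs <- (target_origin[1] + (g$x - 0.5) * target_spacing - origin[1]) / spacing + 0.5
  ys <- (target_origin[2] + (g$y - 0.5) * target_spacing - origin[2]) / spacing + 0.5
  out <- matrix(bilinear_sample(unclass(img), xs, ys), target_shape[1],
                target_shape[2])
  structure(out, pixel_spacing = target_spacing,
            origin = as.numeric(target_origin))
}
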