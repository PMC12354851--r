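#' Otsu threshold
#'
#' Threshold maximizing the between-class variance on a 256-bin histogram of
#' the intensity range (computed by EBImage's implementation of Otsu's
#' method).
#'
#' @param image Numeric matrix with at least two distinct values.
#' @return Threshold on the intensity scale of `image`; pixels strictly above
#'   it are foreground.
#' @export
otsu_threshold <- function(image) {
  img <- unclass(as.matrix(image))
  lo <- min(img); hi <- max(img)
  if (hi <= lo) stop("constant image: Otsu threshold undefined")
  EBImage::otsu(EBImage::Image((img - lo) / (hi - lo)), range = c(0, 1),
                levels = 256) * (hi - lo) + lo
}

#' Segment whole tissue from a stained-section image
#'
#' Otsu foreground, hole filling, then removal of connected components below
#' a minimum area. The stain (e.g. phalloidin) renders tissue bright on a
#' dark background; internal unstained cavities are filled so that the tissue
#' mask is simply connected.
#'
#' @param anatomy Intensity matrix; attribute `pixel_spacing` (micrometres)
#'   used for the area cut, else supply `pixel_spacing`.
#' @param min_area_um2 Minimum component area retained (default 0.05 mm^2 =
#'   5e4 um^2).
#' @param pixel_spacing Pixel side in micrometres.
#' @return Logical tissue mask (same shape); warns and returns an empty mask
#'   when no foreground survives.
#' @export
segment_tissue <- function(anatomy, min_area_um2 = 5e4,
                           pixel_spacing = attr(anatomy, "pixel_spacing")) {
  if (is.null(pixel_spacing)) pixel_spacing <- 1
  img <- unclass(as.matrix(anatomy))
  thr <- otsu_threshold(img)
  fg <- img > thr
  if (!any(fg)) {
    warning("empty foreground after thresholding")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(fg * 1)))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes * pixel_spacing^2 >= min_area_um2)
  if (length(keep) == 0L) {
    warning("no component reaches the minimum tissue area")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  mask <- matrix(as.array(lab) %in% keep, nrow(img), ncol(img))
  structure(mask, pixel_spacing = pixel_spacing)
}

#' Shape features of labelled components
#'
#' Area, perimeter, bounding box and circularity (`4 pi A / P^2`) of each
#' connected component, in physical units.
#'
#' @param label_image Integer label matrix (0 background), e.g. from
#'   `EBImage::bwlabel`.
#' @param pixel_spacing Pixel side, micrometres.
#' @return data.frame with one row per component: `label`, `area_um2`,
#'   `perimeter_um`, `bbox_w_um`, `bbox_h_um`, `equiv_diameter_um`,
#'   `aspect_ratio`, `circularity`, centroid `cx_um`, `cy_um`.
#' @export
component_features <- function(label_image, pixel_spacing = 1) {
  lab <- unclass(label_image)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), bbox_w_um = numeric(),
                      bbox_h_um = numeric(), equiv_diameter_um = numeric(),
                      aspect_ratio = numeric(), circularity = numeric(),
                      cx_um = numeric(), cy_um = numeric()))
  fs <- EBImage::computeFeatures.shape(lab)
  idx <- which(lab > 0); l <- lab[idx]
  xs <- ((idx - 1) %% nrow(lab)) + 1
  ys <- ((idx - 1) %/% nrow(lab)) + 1
  bw <- (tapply(xs, l, max) - tapply(xs, l, min) + 1) * pixel_spacing
  bh <- (tapply(ys, l, max) - tapply(ys, l, min) + 1) * pixel_spacing
  area <- fs[, "s.area"] * pixel_spacing^2
  per <- pmax(fs[, "s.perimeter"], 1) * pixel_spacing
  data.frame(label = seq_len(n),
             area_um2 = area, perimeter_um = per,
             bbox_w_um = as.numeric(bw), bbox_h_um = as.numeric(bh),
             equiv_diameter_um = 2 * sqrt(area / pi),
             aspect_ratio = pmax(bw, bh) / pmax(pmin(bw, bh), pixel_spacing),
             circularity = 4 * pi * area / per^2,
             cx_um = as.numeric(tapply(xs, l, mean) - 0.5) * pixel_spacing,
             cy_um = as.numeric(tapply(ys, l, mean) - 0.5) * pixel_spacing)
}

#' Default compartment classification rules
#'
#' Shape-statistic bands distinguishing glomeruli from larger blood vessels
#' among low-intensity candidate structures inside the tissue. Defaults match
#' murine renal microanatomy: glomeruli are near-circular with equivalent
#' diameters of roughly 50-150 um; vessels are larger and/or elongated.
#'
#' @param glomerulus_diameter_um Length-2 band of equivalent diameters.
#' @param glomerulus_min_circularity Minimum circularity for a glomerulus.
#' @param vessel_min_diameter_um Equivalent diameter above which a candidate
#'   is a vessel.
#' @param vessel_min_aspect Bounding-box aspect ratio above which a candidate
#'   is a vessel regardless of size.
#' @return A named list of rule parameters.
#' @export
compartment_rules <- function(glomerulus_diameter_um = c(50, 150),
                              glomerulus_min_circularity = 0.7,
                              vessel_min_diameter_um = 150,
                              vessel_min_aspect = 3) {
  list(glomerulus_diameter_um = glomerulus_diameter_um,
       glomerulus_min_circularity = glomerulus_min_circularity,
       vessel_min_diameter_um = vessel_min_diameter_um,
       vessel_min_aspect = vessel_min_aspect)
}

#' Classify tissue compartments
#'
#' Detects candidate structures as low-intensity lumina inside the tissue
#' mask (inverted Otsu restricted to tissue), labels them, and assigns each
#' component to glomeruli (near-circular, diameter within the configured
#' band), blood vessels (large and/or elongated) or discards it, using
#' connected-component shape statistics. The returned masks satisfy
#' `vessels`, `glomeruli` subset of `tissue` and `vessels` disjoint from
#' `glomeruli`.
#'
#' @param anatomy Stained-section intensity matrix.
#' @param tissue_mask Logical tissue mask from [segment_tissue()].
#' @param rules Rule bands from [compartment_rules()].
#' @param pixel_spacing Pixel side, micrometres.
#' @return Object of class `"compartment_masks"`: list with logical matrices
#'   `tissue`, `vessels`, `glomeruli`, plus `features` (per-candidate
#'   data.frame with an assigned `class` column) and the `rules` used.
#' @export
classify_compartments <- function(anatomy, tissue_mask,
                                  rules = compartment_rules(),
                                  pixel_spacing = attr(anatomy, "pixel_spacing")) {
  if (is.null(pixel_spacing)) pixel_spacing <- 1
  img <- unclass(as.matrix(anatomy))
  vessels <- glomeruli <- matrix(FALSE, nrow(img), ncol(img))
  feats <- NULL
  if (any(tissue_mask)) {
    vals <- img[tissue_mask]
    if (length(unique(vals)) > 1L) {
      thr <- otsu_threshold(matrix(vals))
      cand <- tissue_mask & (img < thr)
      if (any(cand)) {
        lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
        feats <- component_features(as.array(lab), pixel_spacing)
        cls <- rep("discard", nrow(feats))
        is_vessel <- feats$equiv_diameter_um > rules$vessel_min_diameter_um |
          feats$aspect_ratio > rules$vessel_min_aspect
        is_glom <- !is_vessel &
          feats$equiv_diameter_um >= rules$glomerulus_diameter_um[1] &
          feats$equiv_diameter_um <= rules$glomerulus_diameter_um[2] &
          feats$circularity >= rules$glomerulus_min_circularity
        cls[is_vessel] <- "vessel"; cls[is_glom] <- "glomerulus"
        feats$class <- cls
        la <- as.array(lab)
        vessels <- matrix(la %in% feats$label[is_vessel], nrow(img))
        glomeruli <- matrix(la %in% feats$label[is_glom], nrow(img))
      }
    }
  }
  structure(list(tissue = matrix(as.logical(tissue_mask), nrow(img)),
                 vessels = vessels, glomeruli = glomeruli,
                 features = feats, rules = rules,
                 pixel_spacing = pixel_spacing),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf(
    "<compartment_masks> tissue %d px, vessels %d px (%d), glomeruli %d px (%d)\n",
    sum(x$tissue), sum(x$vessels),
    if (is.null(x$features)) 0L else sum(x$features$class == "vessel"),
    sum(x$glomeruli),
    if (is.null(x$features)) 0L else sum(x$features$class == "glomerulus")))
  invisible(x)
}
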