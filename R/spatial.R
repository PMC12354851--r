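#' Euclidean distance map to a reference mask
#'
#' Per-pixel Euclidean distance (micrometres) to the nearest pixel of the
#' reference mask; zero on the mask itself. Computed with EBImage's exact
#' Euclidean distance transform applied to the mask complement.
#'
#' @param reference_mask Logical/0-1 matrix, nonempty.
#' @param pixel_spacing Pixel side, micrometres.
#' @return Numeric matrix of distances, micrometres.
#' @export
distance_map <- function(reference_mask,
                         pixel_spacing = attr(reference_mask, "pixel_spacing")) {
  if (is.null(pixel_spacing)) pixel_spacing <- 1
  m <- unclass(reference_mask) > 0
  if (!any(m)) stop("empty reference mask")
  d <- as.array(EBImage::distmap(EBImage::Image((!m) * 1))) * pixel_spacing
  matrix(d, nrow(m), ncol(m))
}

#' Relative uptake versus distance from a reference structure
#'
#' Bins tissue pixels by their distance to the reference structure and
#' reports, per bin, the mean activity relative to the mean over all profiled
#' pixels (so the pixel-count-weighted mean of the profile is exactly 1).
#' Pixels inside `exclude_mask` (e.g. the vessel lumen itself when profiling
#' distance from vessels) are left out of both the bins and the normalizing
#' mean; the zero-distance reference band can thereby be reported separately.
#' Empty bins are reported as missing (`NA`), not zero.
#'
#' @param activity Activity matrix on the anatomy grid (resample first with
#'   [resample_to_grid()] if needed).
#' @param dmap Distance map from [distance_map()], micrometres.
#' @param tissue_mask Logical mask of profiled tissue.
#' @param bin_width_um Distance bin width (default 5).
#' @param exclude_mask Optional logical mask of pixels excluded from the
#'   profile.
#' @param max_distance_um Optional cap; default covers the largest observed
#'   distance.
#' @return Object of class `"distance_profile"`: data.frame with
#'   `bin_lo_um`, `bin_hi_um`, `mean_relative_uptake`, `n_pixels`, and
#'   attribute `tissue_mean` (absolute units).
#' @export
uptake_vs_distance <- function(activity, dmap, tissue_mask, bin_width_um = 5,
                               exclude_mask = NULL, max_distance_um = NULL) {
  if (bin_width_um <= 0) stop("'bin_width_um' must be > 0")
  sel <- as.logical(tissue_mask)
  if (!is.null(exclude_mask)) sel <- sel & !as.logical(exclude_mask)
  a <- unclass(activity)[sel]
  d <- unclass(dmap)[sel]
  if (length(a) == 0L) stop("no pixels to profile")
  m <- mean(a)
  if (m == 0) stop("tissue mean activity is zero")
  if (is.null(max_distance_um)) max_distance_um <- max(d)
  nb <- max(1L, ceiling(max_distance_um / bin_width_um))
  bin <- pmin(floor(d / bin_width_um) + 1L, nb)
  cnt <- tabulate(bin, nbins = nb)
  s <- rep(NA_real_, nb)
  sums <- tapply(a, factor(bin, levels = seq_len(nb)), sum)
  nz <- cnt > 0
  s[nz] <- as.numeric(sums[nz]) / cnt[nz] / m
  out <- data.frame(bin_lo_um = (seq_len(nb) - 1) * bin_width_um,
                    bin_hi_um = seq_len(nb) * bin_width_um,
                    mean_relative_uptake = s,
                    n_pixels = cnt)
  structure(out, tissue_mean = m, bin_width_um = bin_width_um,
            class = c("distance_profile", "data.frame"))
}

#' Aggregate replicate profiles and flag significant differences
#'
#' Combines replicate distance profiles (e.g. 3 sections from each of 3
#' kidneys) per condition: per-bin mean over replicates and a 95% confidence
#' interval (mean +/- t-quantile * SEM by default, or a seeded percentile
#' bootstrap). Conditions are compared with the interval-exceedance rule: a
#' direction flag is raised wherever the other condition's mean lies outside
#' this condition's CI, and a bin is reported `significant` when the flags
#' are raised in both directions (each mean outside the other's interval).
#' The per-direction flags are also returned; all flags are per-bin and
#' unadjusted for multiple comparisons.
#'
#' @param profiles_by_condition Named list (one entry per condition) of lists
#'   of [uptake_vs_distance()] profiles sharing a common bin grid; at least 2
#'   replicates per condition.
#' @param conf Confidence level (default 0.95).
#' @param method `"t"` (default) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap resamples and seed (method `"bootstrap"`).
#' @param rule `"both"` (default) or `"either"`: how the two per-direction
#'   exceedance flags combine into `significant`.
#' @return Object of class `"profile_ensemble"`: data.frame with per-bin
#'   per-condition `mean`, `ci_lo`, `ci_hi`, `n_pixels`, the per-direction
#'   exceedance flags, and `significant`.
#' @export
aggregate_and_test <- function(profiles_by_condition, conf = 0.95,
                               method = c("t", "bootstrap"), n_boot = 1000L,
                               seed = 1L, rule = c("both", "either")) {
  method <- match.arg(method); rule <- match.arg(rule)
  conds <- names(profiles_by_condition)
  if (is.null(conds) || length(conds) < 1L)
    stop("'profiles_by_condition' must be a named list")
  first <- profiles_by_condition[[1]][[1]]
  nb <- nrow(first)
  for (cn in conds) for (p in profiles_by_condition[[cn]])
    if (nrow(p) != nb || any(p$bin_lo_um != first$bin_lo_um))
      stop("profiles must share a common bin grid")
  stats_per_cond <- lapply(conds, function(cn) {
    ps <- profiles_by_condition[[cn]]
    if (length(ps) < 2L)
      warning("condition '", cn, "' has a single replicate; CI undefined")
    mat <- sapply(ps, function(p) p$mean_relative_uptake)
    mat <- matrix(mat, nrow = nb)
    n <- rowSums(!is.na(mat))
    mu <- rowMeans(mat, na.rm = TRUE)
    if (method == "t") {
      sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
      tq <- stats::qt(1 - (1 - conf) / 2, pmax(n - 1, 1))
      half <- ifelse(n >= 2, tq * sdv / sqrt(n), NA_real_)
      lo <- mu - half; hi <- mu + half
    } else {
      set.seed(seed)
      qs <- t(apply(mat, 1, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2L) return(c(NA_real_, NA_real_))
        bm <- replicate(n_boot, mean(sample(v, replace = TRUE)))
        stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2))
      }))
      lo <- qs[, 1]; hi <- qs[, 2]
    }
    npx <- rowSums(sapply(ps, function(p) p$n_pixels))
    list(mean = mu, ci_lo = lo, ci_hi = hi, n_replicates = n, n_pixels = npx)
  })
  names(stats_per_cond) <- conds
  out <- data.frame(bin_lo_um = first$bin_lo_um, bin_hi_um = first$bin_hi_um)
  for (cn in conds) {
    s <- stats_per_cond[[cn]]
    out[[paste0("mean_", cn)]] <- s$mean
    out[[paste0("ci_lo_", cn)]] <- s$ci_lo
    out[[paste0("ci_hi_", cn)]] <- s$ci_hi
    out[[paste0("n_pixels_", cn)]] <- s$n_pixels
  }
  if (length(conds) == 2L) {
    a <- stats_per_cond[[1]]; b <- stats_per_cond[[2]]
    ex_ab <- !is.na(b$mean) & !is.na(a$ci_lo) &
      (b$mean < a$ci_lo | b$mean > a$ci_hi)
    ex_ba <- !is.na(a$mean) & !is.na(b$ci_lo) &
      (a$mean < b$ci_lo | a$mean > b$ci_hi)
    out[[paste0("exceeds_ci_of_", conds[1])]] <- ex_ab
    out[[paste0("exceeds_ci_of_", conds[2])]] <- ex_ba
    out$significant <- if (rule == "both") ex_ab & ex_ba else ex_ab | ex_ba
  }
  structure(out, conf = conf, method = method, rule = rule,
            class = c("profile_ensemble", "data.frame"))
}

#' Export a profile ensemble to CSV
#'
#' Writes the per-bin means, confidence bounds, pixel counts and significance
#' flags in a flat CSV.
#' @param ensemble A `"profile_ensemble"` from [aggregate_and_test()].
#' @param path Output CSV path.
#' @export
write_profile_csv <- function(ensemble, path) {
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.profile_ensemble <- function(x, ...) {
  conds <- sub("^mean_", "", grep("^mean_", names(x), value = TRUE))
  cols <- c("#1b6ca8", "#c1403d", "#3a8f5f")
  ylim <- range(unlist(x[grep("^(mean|ci)_", names(x))]), na.rm = TRUE)
  mid <- (x$bin_lo_um + x$bin_hi_um) / 2
  graphics::plot(NA, xlim = range(mid), ylim = ylim,
                 xlab = "distance (um)", ylab = "relative uptake", ...)
  for (i in seq_along(conds)) {
    cn <- conds[i]
    lo <- x[[paste0("ci_lo_", cn)]]; hi <- x[[paste0("ci_hi_", cn)]]
    ok <- !is.na(lo)
    graphics::polygon(c(mid[ok], rev(mid[ok])), c(lo[ok], rev(hi[ok])),
                      border = NA,
                      col = grDevices::adjustcolor(cols[i], alpha.f = 0.25))
    graphics::lines(mid, x[[paste0("mean_", cn)]], col = cols[i], lwd = 2)
  }
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", legend = conds, col = cols[seq_along(conds)],
                   lwd = 2, bty = "n")
  invisible(x)
}
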