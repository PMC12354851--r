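#' Acquisition schedule
#'
#' An acquisition schedule is the ordered set of time windows during which the
#' camera was recording, expressed in seconds on a common reference-time axis
#' (reference time 0 is the time the activity map refers to). Windows must be
#' non-overlapping and sorted.
#'
#' @param windows Numeric matrix or 2-column data.frame with one row per
#'   window, columns `t_start`, `t_end` (seconds), or a list of length-2
#'   vectors.
#' @param reference_time_label Free-text label of what time 0 means.
#' @return Object of class `"acquisition_schedule"`: a data.frame with columns
#'   `t_start`, `t_end` and attribute `reference_time_label`.
#' @examples
#' acquisition_schedule(rbind(c(0, 3600), c(7200, 10800)))
#' @export
acquisition_schedule <- function(windows, reference_time_label = "t0") {
  if (is.list(windows) && !is.data.frame(windows))
    windows <- do.call(rbind, windows)
  windows <- as.matrix(windows)
  if (ncol(windows) != 2L) stop("'windows' must have two columns (t_start, t_end)")
  if (nrow(windows) < 1L) stop("schedule must contain at least one window")
  w <- data.frame(t_start = as.numeric(windows[, 1]),
                  t_end   = as.numeric(windows[, 2]))
  if (any(!is.finite(w$t_start)) || any(w$t_end != Inf & !is.finite(w$t_end)))
    stop("window times must be finite (t_end may be Inf)")
  if (any(w$t_start < 0)) stop("window start times must be >= 0")
  if (any(w$t_end <= w$t_start)) stop("each window must satisfy t_start < t_end")
  o <- order(w$t_start)
  w <- w[o, , drop = FALSE]
  if (nrow(w) > 1L && any(w$t_start[-1L] < w$t_end[-nrow(w)]))
    stop("acquisition windows overlap")
  rownames(w) <- NULL
  structure(w, reference_time_label = reference_time_label,
            class = c("acquisition_schedule", "data.frame"))
}

#' List-mode event list
#'
#' Container for list-mode detection events: per-event detector position
#' (micrometres) and timestamp. Timestamps are stored relative to the start of
#' the acquisition window the event belongs to, so that
#' `t_start[window] + t_s` is the event's absolute time on the reference axis.
#'
#' @param x_um,y_um Numeric event centroid positions, micrometres.
#' @param t_s Numeric timestamps, seconds since the start of the event's
#'   window (>= 0).
#' @param window Integer index of the acquisition window of each event
#'   (default 1).
#' @param schedule An [acquisition_schedule()]; default is a single window
#'   covering all events.
#' @return Object of class `"event_list"`: data.frame with columns `x_um`,
#'   `y_um`, `t_s`, `window` and attribute `schedule`.
#' @export
event_list <- function(x_um = numeric(), y_um = numeric(), t_s = numeric(),
                       window = rep(1L, length(x_um)), schedule = NULL) {
  n <- length(x_um)
  if (length(y_um) != n || length(t_s) != n)
    stop("x_um, y_um and t_s must have the same length")
  if (any(!is.finite(x_um)) || any(!is.finite(y_um)))
    stop("event positions must be finite")
  if (any(t_s < 0)) stop("event timestamps must be >= 0")
  if (is.null(schedule)) {
    t_max <- if (n) max(t_s) else 1
    schedule <- acquisition_schedule(cbind(0, t_max + 1))
  }
  window <- as.integer(window)
  if (n && (any(window < 1L) || any(window > nrow(schedule))))
    stop("event window index outside schedule")
  if (n) {
    tt <- schedule$t_start[window] + t_s
    bad <- tt < schedule$t_start[window] - 1e-9 | tt > schedule$t_end[window] + 1e-9
    if (any(bad))
      stop(sum(bad), " event(s) fall outside their acquisition window")
  }
  structure(data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                       t_s = as.numeric(t_s), window = window),
            schedule = schedule, class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  s <- attr(x, "schedule")
  cat(sprintf("<event_list> %d events over %d acquisition window(s)\n",
              nrow(x), nrow(s)))
  invisible(x)
}

#' Read / write list-mode event files
#'
#' The on-disk dialect is a plain CSV with header `x_um,y_um,t_s` (one event
#' per row, timestamps in seconds relative to the window start) plus an
#' optional sidecar JSON (`<file>.schedule.json`) containing
#' `{"windows": [[t_start_s, t_end_s], ...]}` and optionally a per-event
#' `window` column in the CSV. Without a sidecar a single window covering the
#' events is assumed.
#'
#' @param path Path to the CSV file.
#' @param schedule_path Optional explicit sidecar path; default
#'   `paste0(path, ".schedule.json")` if that file exists.
#' @return [read_listmode()]: an [event_list()]. [write_listmode()]: `path`,
#'   invisibly.
#' @export
read_listmode <- function(path, schedule_path = NULL) {
  if (!file.exists(path)) stop("list-mode file does not exist: ", path)
  df <- utils::read.csv(path)
  need <- c("x_um", "y_um", "t_s")
  if (!all(need %in% names(df)))
    stop("list-mode CSV must have header x_um,y_um,t_s; got: ",
         paste(names(df), collapse = ","))
  if (nrow(df) > 0L) for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("malformed value in column '%s' at data line %d of %s",
                   cn, if (is.na(bad)) NA_integer_ else bad, path))
    }
  }
  if (any(df$t_s < 0))
    stop("negative timestamp at data line ", which(df$t_s < 0)[1], " of ", path)
  if (is.null(schedule_path)) {
    cand <- paste0(path, ".schedule.json")
    if (file.exists(cand)) schedule_path <- cand
  }
  schedule <- NULL
  if (!is.null(schedule_path)) {
    js <- jsonlite::read_json(schedule_path, simplifyVector = TRUE)
    schedule <- acquisition_schedule(js$windows,
      reference_time_label = if (!is.null(js$reference_time_label))
        js$reference_time_label else "t0")
  }
  window <- if ("window" %in% names(df)) df$window else rep(1L, nrow(df))
  event_list(df$x_um, df$y_um, df$t_s, window = window, schedule = schedule)
}

#' @rdname read_listmode
#' @param events An [event_list()] to write.
#' @export
write_listmode <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  s <- attr(events, "schedule")
  jsonlite::write_json(
    list(windows = unname(as.matrix(s)),
         reference_time_label = attr(s, "reference_time_label")),
    paste0(path, ".schedule.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bin list-mode events to a pixel grid
#'
#' Events are binned into square pixels of side `pixel_spacing`, exactly as a
#' 2D histogram. Bins are half-open `[edge, edge + spacing)`; events on the
#' top/right outer edge, or outside the grid, are dropped and counted in the
#' `dropped` attribute.
#'
#' @param events An [event_list()].
#' @param pixel_spacing Pixel side, micrometres (default 26.5, the camera
#'   grid).
#' @param grid_shape Integer `c(nx, ny)` number of pixels; default covers the
#'   event extent.
#' @param origin Numeric `c(x, y)` of the low corner of pixel (1,1), in
#'   micrometres (default `c(0, 0)`).
#' @return Object of class `"counts_image"`: an integer matrix indexed
#'   `[ix, iy]` with attributes `pixel_spacing`, `origin`, `schedule`,
#'   `dropped`.
#' @examples
#' ev <- event_list(c(13, 40), c(13, 40), c(0, 1))
#' ci <- bin_events(ev, 26.5, grid_shape = c(2, 2))
#' sum(ci)  # 2
#' @export
bin_events <- function(events, pixel_spacing = 26.5, grid_shape = NULL,
                       origin = c(0, 0)) {
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("'pixel_spacing' must be > 0")
  n <- nrow(events)
  if (is.null(grid_shape)) {
    if (n == 0L) grid_shape <- c(1L, 1L)
    else grid_shape <- c(
      max(1L, floor((max(events$x_um) - origin[1]) / pixel_spacing) + 1L),
      max(1L, floor((max(events$y_um) - origin[2]) / pixel_spacing) + 1L))
  }
  grid_shape <- as.integer(grid_shape)
  counts <- matrix(0L, grid_shape[1], grid_shape[2])
  dropped <- 0L
  if (n > 0L) {
    ix <- floor((events$x_um - origin[1]) / pixel_spacing) + 1
    iy <- floor((events$y_um - origin[2]) / pixel_spacing) + 1
    ok <- ix >= 1 & ix <= grid_shape[1] & iy >= 1 & iy <= grid_shape[2]
    dropped <- sum(!ok)
    if (any(ok)) {
      idx <- (iy[ok] - 1) * grid_shape[1] + ix[ok]
      tab <- tabulate(idx, nbins = prod(grid_shape))
      counts <- matrix(as.integer(tab), grid_shape[1], grid_shape[2])
    }
  }
  structure(counts, pixel_spacing = pixel_spacing, origin = as.numeric(origin),
            schedule = attr(events, "schedule"), dropped = as.integer(dropped),
            class = c("counts_image", "matrix", "array"))
}

#' Merge list-mode sessions onto a common reference axis
#'
#' Splices several recordings of the same sample into one event list. Each
#' session's schedule is shifted by its offset onto the common reference axis;
#' the merged schedule must remain non-overlapping.
#'
#' @param lists List of [event_list()] objects.
#' @param session_offsets Numeric vector, seconds to add to each session's
#'   window times to place it on the common axis.
#' @return A merged [event_list()] with one window per input window, sorted.
#' @export
merge_sessions <- function(lists, session_offsets = rep(0, length(lists))) {
  stopifnot(length(lists) >= 1L, length(session_offsets) == length(lists))
  wins <- NULL
  x <- y <- t <- numeric(); win <- integer()
  wcount <- 0L
  for (i in seq_along(lists)) {
    ev <- lists[[i]]
    s <- attr(ev, "schedule")
    sw <- cbind(s$t_start + session_offsets[i], s$t_end + session_offsets[i])
    wins <- rbind(wins, sw)
    x <- c(x, ev$x_um); y <- c(y, ev$y_um); t <- c(t, ev$t_s)
    win <- c(win, ev$window + wcount)
    wcount <- wcount + nrow(s)
  }
  if (any(wins[, 1] < 0))
    stop("offsets place a window before reference time 0")
  o <- order(wins[, 1])
  sched <- acquisition_schedule(wins[o, , drop = FALSE])  # errors on overlap
  remap <- match(seq_len(nrow(wins)), o)
  event_list(x, y, t, window = remap[win], schedule = sched)
}
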