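# Spatiotemporal Ca2+ event detection in x-y-t movies and per-event metrics.

#' Detect per-pixel calcium transients
#'
#' For every pixel, a rolling-percentile baseline F0 is computed over a
#' centred window; samples whose excess over F0 exceeds `k_sigma` times the
#' per-movie noise sd (estimated from dark frames when present, else from
#' the movie's rolling residual) are marked active. Active runs lasting
#' `min_duration` seconds or less are erased — only transients strictly
#' longer than the filter survive, which is what separates astrocytic from
#' neuronal activity here.
#'
#' @param movie a [ca_movie]
#' @param k_sigma detection threshold in noise sds
#' @param min_duration erase active runs of this duration (s) or shorter
#' @param baseline_window rolling-baseline window, s
#' @param baseline_prob rolling percentile used as F0
#' @return logical array `[y, x, t]` of active samples, with the noise sd in
#'   attribute `noise_sigma`
#' @export
detect_pixel_transients <- function(movie, k_sigma = 3, min_duration = 4,
                                    baseline_window = 121,
                                    baseline_prob = 0.2) {
  stopifnot(inherits(movie, "ca_movie"))
  dm <- dim(movie$frames)
  nt <- dm[3]
  win_frames <- round(baseline_window / movie$frame_interval)
  if (nt < win_frames)
    stop(sprintf("movie (%d frames) shorter than the baseline window (%d)",
                 nt, win_frames))
  min_frames <- round(min_duration / movie$frame_interval)
  if (nt <= min_frames) stop("movie shorter than the minimum event duration")
  x <- matrix(aperm(movie$frames, c(3, 1, 2)), nrow = nt)   # t x pixels
  f0 <- cpp_rolling_quantile(x, as.integer(win_frames), baseline_prob)
  resid <- x - f0
  sigma <- if (!is.null(movie$dark_frames)) {
    v <- as.numeric(movie$dark_frames)
    mad(v, center = median(v))
  } else {
    mad(as.numeric(resid))
  }
  if (sigma <= 0) stop("estimated noise sigma is not positive")
  # the low-percentile F0 sits below the noise median by qnorm(prob) sigmas;
  # add that quantile offset back so the threshold is k_sigma above baseline
  act <- resid > (k_sigma - stats::qnorm(baseline_prob)) * sigma
  # erase runs <= min_duration (strictly longer survives)
  for (p in seq_len(ncol(act))) {
    col <- act[, p]
    if (!any(col)) next
    r <- rle(col)
    short <- r$values & r$lengths <= min_frames
    if (any(short)) {
      r$values[short] <- FALSE
      act[, p] <- inverse.rle(r)
    }
  }
  out <- aperm(array(act, c(nt, dm[1], dm[2])), c(2, 3, 1))
  attr(out, "noise_sigma") <- sigma
  out
}

#' Combine active pixels into spatiotemporal events
#'
#' 26-connected components in (y, x, t); components below `min_voxels`
#' space-time voxels are discarded.
#'
#' @param mask logical array `[y, x, t]` from [detect_pixel_transients()]
#' @param movie the source [ca_movie] (for intensities and scales)
#' @param min_voxels minimal component size (x-y-t voxels)
#' @return object of class `ca_event_set`: list of events, each holding its
#'   voxel support
#' @export
label_events <- function(mask, movie, min_voxels = 10) {
  stopifnot(inherits(movie, "ca_movie"))
  dm <- dim(mask)
  lab <- cpp_label_3d(as.logical(mask), as.integer(dm))
  nlab <- max(lab)
  if (nlab == 0L)
    return(structure(list(events = list(), pixel_size = movie$pixel_size,
                          frame_interval = movie$frame_interval,
                          fov_px = dm[1:2]), class = "ca_event_set"))
  sizes <- tabulate(lab, nbins = nlab)
  keep <- which(sizes >= min_voxels)
  idx <- which(lab > 0L)
  ai <- arrayInd(idx, dm)
  lv <- lab[idx]
  events <- list()
  for (k in keep) {
    sel <- lv == k
    events[[length(events) + 1L]] <-
      list(voxels = ai[sel, , drop = FALSE])
  }
  structure(list(events = events, pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval,
                 movie = movie, fov_px = dm[1:2]),
            class = "ca_event_set")
}

#' @export
print.ca_event_set <- function(x, ...) {
  cat(sprintf("<ca_event_set> %d events\n", length(x$events)))
  invisible(x)
}

#' Per-event metrics: duration, projection area, volume, initiation pixel
#'
#' Duration is `(last - first frame + 1) * frame_interval`; area is the count
#' of distinct (y, x) pixels times the pixel area (the maximal projection
#' along time); volume is the space-time voxel count times pixel area and
#' frame interval; the initiation pixel is the intensity-weighted centroid of
#' the event's active pixels in its first frame, rounded to the nearest
#' pixel.
#'
#' @param eventset a `ca_event_set` from [label_events()]
#' @return data.frame of class `ca_event_table`, one row per event:
#'   `id`, `onset_frame`, `duration`, `area`, `volume`, `init_y`, `init_x`
#' @export
event_metrics <- function(eventset) {
  stopifnot(inherits(eventset, "ca_event_set"))
  px2 <- eventset$pixel_size^2
  dt <- eventset$frame_interval
  movie <- eventset$movie
  rows <- lapply(seq_along(eventset$events), function(i) {
    v <- eventset$events[[i]]$voxels
    t0 <- min(v[, 3]); t1 <- max(v[, 3])
    area_px <- nrow(unique(v[, 1:2, drop = FALSE]))
    first <- v[v[, 3] == t0, , drop = FALSE]
    w <- if (!is.null(movie)) movie$frames[first] else rep(1, nrow(first))
    w <- pmax(w - min(w) + 1e-9, 1e-9)
    init <- round(c(sum(first[, 1] * w), sum(first[, 2] * w)) / sum(w))
    data.frame(id = i, onset_frame = t0,
               duration = (t1 - t0 + 1) * dt,
               area = area_px * px2,
               volume = nrow(v) * px2 * dt,
               init_y = init[1], init_x = init[2])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = integer(0), onset_frame = integer(0),
                                      duration = numeric(0), area = numeric(0),
                                      volume = numeric(0), init_y = integer(0),
                                      init_x = integer(0))
  class(out) <- c("ca_event_table", "data.frame")
  out
}

#' Event frequency density
#'
#' Number of events per unit area and unit time.
#'
#' @param events a `ca_event_table` (or anything with one row per event)
#' @param fov_area field of view, um^2
#' @param record_duration recording duration, s
#' @return events per (s * um^2)
#' @export
frequency_density <- function(events, fov_area, record_duration) {
  stopifnot(fov_area > 0, record_duration > 0)
  NROW(events) / (fov_area * record_duration)
}

#' Initiation-spot statistics
#'
#' Counts events initiated in each (optionally binned) pixel and histograms
#' events-per-spot. The sum of the per-spot counts always equals the number
#' of events.
#'
#' @param events a `ca_event_table`
#' @param bin spatial bin size in pixels (default 2 x 2)
#' @return list of class `initiation_map`: `counts` (named per-spot counts),
#'   `histogram` (table: events-per-spot -> number of spots), `bin`
#' @export
initiation_statistics <- function(events, bin = 2) {
  stopifnot(inherits(events, "data.frame"), bin >= 1)
  if (nrow(events) == 0L)
    return(structure(list(counts = integer(0), histogram = table(integer(0)),
                          bin = bin), class = "initiation_map"))
  by <- floor((events$init_y - 1) / bin)
  bx <- floor((events$init_x - 1) / bin)
  key <- paste(by, bx, sep = ",")
  counts <- table(key)
  structure(list(counts = counts, histogram = table(as.integer(counts)),
                 bin = bin), class = "initiation_map")
}

#' @export
print.initiation_map <- function(x, ...) {
  cat(sprintf("<initiation_map> %d spots, %d events (bin %dx%d)\n",
              length(x$counts), sum(x$counts), x$bin, x$bin))
  invisible(x)
}

#' Full event detection chain for one movie
#'
#' Convenience wrapper: [detect_pixel_transients()] then [label_events()]
#' then [event_metrics()].
#'
#' @inheritParams detect_pixel_transients
#' @inheritParams label_events
#' @return a `ca_event_table`
#' @export
detect_ca_events <- function(movie, k_sigma = 3, min_duration = 4,
                             baseline_window = 121, baseline_prob = 0.2,
                             min_voxels = 10) {
  act <- detect_pixel_transients(movie, k_sigma, min_duration,
                                 baseline_window, baseline_prob)
  event_metrics(label_events(act, movie, min_voxels))
}
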