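# Volume fraction of optically unresolved astrocytic processes from
# soma-normalized fluorescence cross sections.

#' Select the soma-containing plane of a stack
#'
#' Returns the z-plane with the greatest integrated soma intensity and checks
#' that the soma is not saturated.
#'
#' @param stack an [image_stack]
#' @param soma optional result of [find_soma()] (computed if missing)
#' @param sat_level detector ceiling (intensity units); `Inf` disables the
#'   saturation check
#' @param max_sat_frac maximal tolerated fraction of soma pixels at the
#'   ceiling
#' @return list: `image` ([image2d] of the selected plane), `z_index`,
#'   `soma` (the descriptor used)
#' @export
select_soma_plane <- function(stack, soma = NULL, sat_level = Inf,
                              max_sat_frac = 0.01) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(soma)) soma <- find_soma(stack)
  sm <- soma$mask$mask
  per_plane <- vapply(seq_len(dim(stack$voxels)[3]), function(k) {
    m <- sm[, , k]
    if (!any(m)) return(0)
    sum(stack$voxels[, , k][m])
  }, numeric(1))
  z <- which.max(per_plane)
  if (is.finite(sat_level)) {
    m <- sm[, , z]
    if (any(m)) {
      frac <- mean(stack$voxels[, , z][m] >= sat_level)
      if (frac > max_sat_frac)
        stop(sprintf("soma saturated: %.1f%% of soma pixels at the ceiling",
                     100 * frac))
    }
  }
  list(image = image2d(stack$voxels[, , z], stack$spacing[2]),
       z_index = z, soma = soma)
}

# bilinear sampling of a matrix at fractional (row, col) positions (1-based)
.bilinear <- function(m, ry, rx) {
  dm <- dim(m)
  y0 <- floor(ry); x0 <- floor(rx)
  ok <- y0 >= 1 & x0 >= 1 & y0 + 1 <= dm[1] & x0 + 1 <= dm[2]
  out <- rep(NA_real_, length(ry))
  if (!any(ok)) return(out)
  fy <- ry[ok] - y0[ok]; fx <- rx[ok] - x0[ok]
  i00 <- cbind(y0[ok], x0[ok]); i10 <- cbind(y0[ok] + 1, x0[ok])
  i01 <- cbind(y0[ok], x0[ok] + 1); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
  out[ok] <- m[i00] * (1 - fy) * (1 - fx) + m[i10] * fy * (1 - fx) +
    m[i01] * (1 - fy) * fx + m[i11] * fy * fx
  out
}

#' Cast radial fluorescence profiles through the soma centre
#'
#' Samples `n_lines` full cross sections through the soma centre at equal
#' angular spacing (72 degrees for the default five lines), splits each at
#' the centre into two half-profiles, and normalizes fluorescence to the
#' maximal soma fluorescence (= 100%). The soma reference is the maximum of
#' a lightly smoothed copy of the plane, which keeps single-pixel noise
#' excursions from deflating the normalization.
#'
#' @param image an [image2d] (the selected soma plane, photon units)
#' @param center soma centre in um, c(y, x)
#' @param n_lines number of cross sections
#' @param step_um sampling step along each line, um
#' @param smooth_px sd (pixels) of the smoothing used for the soma reference
#' @param linewidth_um transverse width of each sampling line, um; the
#'   fluorescence is averaged across this width (a finite-width line profile,
#'   as in standard line-scan tools), which suppresses single-pixel noise
#'   without biasing the mean
#' @param n_across number of parallel sample lines across the width
#' @return list of `radial_profile` data.frames (columns `distance`, um, and
#'   `fluorescence`, % of soma peak) with attributes `angle` and `side`
#' @export
cast_profiles <- function(image, center, n_lines = 5, step_um = 0.1,
                          smooth_px = 4, linewidth_um = 1.6, n_across = 7) {
  stopifnot(inherits(image, "image2d"))
  px <- image$pixel_size
  m <- image$pixels
  ref <- max(EBImage::gblur(m, sigma = smooth_px))
  if (ref <= 0) stop("non-positive soma reference intensity")
  dm <- dim(m)
  max_r <- min(center[1], center[2],
               (dm[1] - 1) * px - center[1], (dm[2] - 1) * px - center[2])
  dists <- seq(0, max_r, by = step_um)
  angles <- (seq_len(n_lines) - 1) * 180 / n_lines   # full lines: 0..180
  offs <- if (n_across > 1)
    seq(-linewidth_um / 2, linewidth_um / 2, length.out = n_across) else 0
  out <- list()
  for (a in angles) {
    th <- a * pi / 180
    dir <- c(sin(th), cos(th))
    perp <- c(-cos(th), sin(th))
    for (side in c(1, -1)) {
      f <- 0
      for (o in offs) {
        ry <- (center[1] + side * dists * dir[1] + o * perp[1]) / px + 1
        rx <- (center[2] + side * dists * dir[2] + o * perp[2]) / px + 1
        f <- f + .bilinear(m, ry, rx)
      }
      f <- f / length(offs) / ref * 100
      pr <- data.frame(distance = dists, fluorescence = f)
      pr <- pr[!is.na(pr$fluorescence), ]
      attr(pr, "angle") <- a
      attr(pr, "side") <- if (side > 0) "pos" else "neg"
      class(pr) <- c("radial_profile", "data.frame")
      out[[length(out) + 1L]] <- pr
    }
  }
  out
}

#' Excise branch/branchlet peaks from a radial profile
#'
#' Removes contiguous runs where the fluorescence exceeds a running-median
#' local baseline by more than `amp_thresh` (percentage points of the soma
#' peak) over a width greater than `width_thresh` micrometres. Excised
#' samples are dropped (a gap is left), not interpolated.
#'
#' A qualifying run is excised over its full extent: the cut is widened
#' outward from the supra-threshold core to where the excess falls below
#' `low_frac * amp_thresh`, so the shoulders of a branch cross-section do
#' not leak into the volume-fraction average.
#'
#' @param profile a `radial_profile`
#' @param amp_thresh amplitude threshold, percentage points of soma peak
#' @param width_thresh minimal run width to excise, um
#' @param baseline_window running-median window, um
#' @param low_frac fraction of `amp_thresh` down to which an excised run is
#'   extended
#' @return the profile with excised samples removed; excised intervals (um)
#'   in attribute `excised`
#' @export
excise_branch_peaks <- function(profile, amp_thresh = 10, width_thresh = 0.5,
                                baseline_window = 12, low_frac = 0.18) {
  stopifnot(inherits(profile, "radial_profile"))
  f <- profile$fluorescence
  d <- profile$distance
  n <- length(f)
  if (n == 0L) stop("profile fully excised: no samples remain")
  step <- if (n > 1) stats::median(diff(d)) else 1
  k <- max(3L, round(baseline_window / step))
  if (k %% 2 == 0) k <- k + 1L
  base <- stats::runmed(f, k = min(k, if (n %% 2 == 0) n - 1 else n),
                        endrule = "median")
  excess <- f - base
  # a branch fluctuation is coherent over ~1 um, single-sample noise is not:
  # detect runs on a boxcar-smoothed excess at that scale
  ks <- max(1L, round(1 / step))
  excess_s <- as.numeric(stats::filter(excess, rep(1 / ks, ks), sides = 2))
  excess_s[is.na(excess_s)] <- excess[is.na(excess_s)]
  above <- excess_s > amp_thresh
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  low <- excess_s > low_frac * amp_thresh
  drop <- rep(FALSE, n)
  excised <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    width <- d[ends[i]] - d[starts[i]] + step
    if (width > width_thresh) {
      a <- starts[i]; b <- ends[i]
      while (a > 1L && low[a - 1L]) a <- a - 1L
      while (b < n && low[b + 1L]) b <- b + 1L
      # fixed margin: the sub-threshold optical tail of a branch extends a
      # little beyond the detected run
      mar <- max(1L, round(0.4 / step))
      a <- max(1L, a - mar); b <- min(n, b + mar)
      drop[a:b] <- TRUE
      excised[[length(excised) + 1L]] <- c(d[a], d[b])
    }
  }
  out <- profile[!drop, ]
  if (nrow(out) == 0L) stop("profile fully excised: no samples remain")
  attr(out, "angle") <- attr(profile, "angle")
  attr(out, "side") <- attr(profile, "side")
  attr(out, "excised") <- excised
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Soma border radius from the radially averaged profile
#'
#' The soma border is the first distance at which the profile averaged over
#' all half-profiles falls below `frac` of the soma peak (100%).
#'
#' @param profiles list of `radial_profile`s (before excision is fine)
#' @param frac fraction of the soma peak defining the border; the default
#'   0.3 places the border at the foot of the PSF-blurred soma edge rather
#'   than halfway down its flank
#' @return border radius, um
#' @export
soma_border_radius <- function(profiles, frac = 0.3) {
  dmax <- max(vapply(profiles, function(p) max(p$distance), numeric(1)))
  step <- stats::median(diff(profiles[[1]]$distance))
  grid <- seq(0, dmax, by = step)
  acc <- matrix(NA_real_, length(profiles), length(grid))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    acc[i, ] <- approx(p$distance, p$fluorescence, xout = grid, rule = 1)$y
  }
  avg <- colMeans(acc, na.rm = TRUE)
  below <- which(avg < 100 * frac)
  if (length(below) == 0L) stop("profile never falls below the border level")
  grid[below[1L]]
}

#' Volume fraction from an excised half-profile
#'
#' Mean of the surviving normalized fluorescence at distances within
#' `window` micrometres beyond the soma border.
#'
#' @param profile an excised `radial_profile`
#' @param border soma border radius, um
#' @param window distance window beyond the border, um (default 10-20)
#' @return VF in % of soma peak, or `NA` (with a warning) if the window is
#'   empty after excision
#' @export
vf_from_profile <- function(profile, border, window = c(10, 20)) {
  sel <- profile$distance >= border + window[1] &
         profile$distance <= border + window[2]
  if (!any(sel)) {
    warning("VF window empty after excision; half-profile dropped")
    return(NA_real_)
  }
  mean(profile$fluorescence[sel])
}

#' Full volume-fraction estimate for one astrocyte stack
#'
#' Chains the calibration (optional), soma-plane selection, profile casting,
#' branch-peak excision and windowed averaging: photon conversion without
#' zero-clipping (so faint-haze means are unbiased), five cross sections at
#' 72 degrees, ten half-profiles, excision of fluctuations > `amp_thresh`
#' and wider than `width_thresh`, VF window 10-20 um beyond the soma border.
#'
#' @param stack an [image_stack] of raw intensities
#' @param cal optional [pmt_calibration]; estimated from the stack if absent
#' @param n_lines number of cross sections
#' @param window VF window beyond the soma border, um
#' @param amp_thresh,width_thresh excision thresholds (see
#'   [excise_branch_peaks()])
#' @param border_frac soma-border definition (see [soma_border_radius()])
#' @param sat_level detector ceiling forwarded to [select_soma_plane()]
#' @return list of class `vf_result`: `vf_cell` (%), `vf_half_profiles`
#'   (10 values, %), `soma_border_radius` (um), `excised` intervals,
#'   `z_index`
#' @export
estimate_vf <- function(stack, cal = NULL, n_lines = 5, window = c(10, 20),
                        amp_thresh = 10, width_thresh = 0.5,
                        border_frac = 0.3, sat_level = Inf) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(cal)) {
    gain <- tryCatch(estimate_pmt_gain_offset(stack)$gain,
                     error = function(e) 1)
    # offset from a signal-free region: the variance-mean intercept is
    # biased by the read noise, and the normalization cancels the gain
    cal <- pmt_calibration(gain, estimate_offset_background(stack))
  }
  cstack <- to_photon_counts(stack, cal, clip = FALSE)
  # soma detection on the clipped copy (mask needs non-negative intensities)
  soma <- find_soma(to_photon_counts(stack, cal, clip = TRUE))
  sel <- select_soma_plane(cstack, soma = soma, sat_level = sat_level)
  center <- soma$center[1:2]
  profiles <- cast_profiles(sel$image, center, n_lines = n_lines)
  border <- soma_border_radius(profiles, frac = border_frac)
  exc <- lapply(profiles, excise_branch_peaks,
                amp_thresh = amp_thresh, width_thresh = width_thresh)
  vfs <- vapply(exc, vf_from_profile, numeric(1), border = border,
                window = window)
  structure(list(vf_cell = mean(vfs, na.rm = TRUE),
                 vf_half_profiles = vfs,
                 soma_border_radius = border,
                 excised = lapply(exc, attr, "excised"),
                 z_index = sel$z_index),
            class = "vf_result")
}

#' @export
print.vf_result <- function(x, ...) {
  cat(sprintf("<vf_result> VF %.2f%% (border %.1f um, %d half-profiles)\n",
              x$vf_cell, x$soma_border_radius,
              sum(is.finite(x$vf_half_profiles))))
  invisible(x)
}
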