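# Photon-count calibration, noise estimation, tubular enhancement and
# binarization shared by all image-based stages.

#' Estimate PMT gain and offset from the photon-transfer relation
#'
#' Randomly samples small cubic patches from the stack and fits the per-patch
#' sample variance against the sample mean by ordinary least squares. Under
#' Poisson photon statistics scaled by the detector, variance =
#' gain * (mean - offset), so the slope is the PMT gain and the x-axis
#' intercept the PMT offset.
#'
#' Patches whose variance is dominated by structure (edges of the soma or of
#' branches) would bias the slope upward, so patches are screened for
#' homogeneity first: for pure noise the variance of first differences is
#' twice the sample variance, whereas structure inflates the sample variance
#' relative to the differences. Only patches whose ratio stays below
#' `homog_max` enter the fit, with a final one-sided trim as a safety net.
#'
#' @param stack an [image_stack] of raw detector intensities
#' @param n_patches number of random patches (>= 10)
#' @param patch_size cube edge in voxels
#' @param seed integer seed for patch sampling
#' @param homog_max maximal variance / difference-variance ratio accepted
#' @return a [pmt_calibration] with fit diagnostics
#' @export
estimate_pmt_gain_offset <- function(stack, n_patches = 1500, patch_size = 5,
                                     seed = 1, homog_max = 1.6) {
  stopifnot(inherits(stack, "image_stack"), n_patches >= 10)
  dm <- dim(stack$voxels)
  if (any(dm < patch_size)) stop("patches do not fit in the stack")
  withr::with_seed(seed, {
    mu <- va <- vd <- numeric(n_patches)
    for (i in seq_len(n_patches)) {
      o <- c(sample.int(dm[1] - patch_size + 1L, 1),
             sample.int(dm[2] - patch_size + 1L, 1),
             sample.int(dm[3] - patch_size + 1L, 1))
      p <- stack$voxels[o[1]:(o[1] + patch_size - 1L),
                        o[2]:(o[2] + patch_size - 1L),
                        o[3]:(o[3] + patch_size - 1L)]
      mu[i] <- mean(p); va[i] <- stats::var(as.numeric(p))
      d <- c(apply(p, c(2, 3), diff), apply(p, c(1, 3), diff),
             apply(p, c(1, 2), diff))
      vd[i] <- stats::var(d) / 2          # = noise variance for iid noise
    }
    if (stats::var(mu) == 0 || all(va == 0))
      stop("calibration failed: variance does not increase with mean ",
           "(structure-dominated or constant stack)")
    keep <- vd > 0 & va / vd < homog_max
    if (sum(keep) < 10 || stats::var(mu[keep]) == 0)
      stop("calibration failed: too few homogeneous patches")
    fit <- NULL
    for (it in 1:5) {
      if (sum(keep) < 10 || stats::var(mu[keep]) == 0)
        stop("calibration failed: too few homogeneous patches")
      fit <- lm(va[keep] ~ mu[keep])
      res <- va - (coef(fit)[[1]] + coef(fit)[[2]] * mu)
      s <- mad(res[keep])
      if (s == 0) break
      new_keep <- keep & res < 4 * s      # structure only inflates variance
      if (all(new_keep == keep)) break
      keep <- new_keep
    }
    slope <- coef(fit)[[2]]; intercept <- coef(fit)[[1]]
    if (!is.finite(slope) || slope <= 0)
      stop("calibration failed: variance does not increase with mean ",
           "(structure-dominated or constant stack)")
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
    pmt_calibration(gain = slope, offset = -intercept / slope,
                    diagnostics = list(slope_se = se[[2]],
                                       intercept_se = se[[1]],
                                       n_patches = n_patches,
                                       n_used = sum(keep),
                                       patch_size = patch_size,
                                       r_squared = summary(fit)$r.squared))
  })
}

#' Convert detector intensities to photon-count estimates
#'
#' Applies `(value - offset) / gain`. Negative estimates are clipped at zero
#' by default; pass `clip = FALSE` where the *mean* of a faint signal matters
#' (clipping biases means upward when the signal is comparable to the read
#' noise), as in the volume-fraction profiles.
#'
#' @param stack an [image_stack] of raw intensities
#' @param cal a [pmt_calibration]
#' @param clip clip negative photon estimates at zero
#' @return an [image_stack] of photon counts with the calibration recorded
#' @export
to_photon_counts <- function(stack, cal, clip = TRUE) {
  stopifnot(inherits(stack, "image_stack"), inherits(cal, "pmt_calibration"))
  if (cal$gain <= 0) stop("gain must be > 0")
  v <- (stack$voxels - cal$offset) / cal$gain
  if (clip) v <- pmax(v, 0)
  out <- image_stack(v, stack$spacing)
  out$calibration <- cal
  out
}

#' Robust noise sigma from dark frames or a background region
#'
#' Median-absolute-deviation estimate (scaled to the Gaussian sd) of the
#' detector noise. Dark frames are preferred when supplied; otherwise a
#' background box of the stack is used. Never estimated from the whole
#' stack, since structure inflates the estimate.
#'
#' @param stack an [image_stack] (or numeric array) used as fallback source
#' @param dark_frames optional array of dark-noise frames
#' @param background_box optional list(y=, x=, z=) of index ranges naming the
#'   background region; defaults to the stack's corner octant
#' @return noise sd, intensity units, with the method in attribute `method`
#' @export
estimate_noise_sigma <- function(stack = NULL, dark_frames = NULL,
                                 background_box = NULL) {
  if (!is.null(dark_frames)) {
    s <- mad(as.numeric(dark_frames), center = median(as.numeric(dark_frames)))
    return(structure(s, method = "dark_frames"))
  }
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (is.null(v)) stop("either a stack or dark frames must be given")
  dm <- dim(v)
  if (is.null(background_box)) background_box <- .default_bg_box(dm)
  bg <- v[background_box$y, background_box$x, background_box$z]
  structure(mad(as.numeric(bg), center = median(as.numeric(bg))),
            method = "background_box")
}

# lateral corner (structure-free in the generator's geometry), full z range
.default_bg_box <- function(dm) {
  n <- pmax(2L, floor(dm[1:2] / 6))
  list(y = 1:n[1], x = 1:n[2], z = seq_len(dm[3]))
}

#' Detector offset from a signal-free background region
#'
#' The mean intensity of a region receiving no photons equals the PMT offset
#' regardless of the read noise, whereas the x-axis intercept of the
#' variance-mean line is displaced by `-read_noise_sd^2 / gain`. Quantities
#' that depend on absolute photon levels near the noise floor (the
#' volume-fraction profiles) therefore take their offset from here.
#'
#' @param stack an [image_stack] of raw intensities
#' @param background_box list(y=, x=, z=) index ranges; defaults to a
#'   lateral corner over the full z range
#' @return offset estimate, intensity units
#' @export
estimate_offset_background <- function(stack, background_box = NULL) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (is.null(background_box)) background_box <- .default_bg_box(dim(v))
  median(as.numeric(v[background_box$y, background_box$x, background_box$z]))
}

#' Coherence-enhancing diffusion, plane-wise along all three axes
#'
#' Runs 2D structure-tensor-steered (Weickert-type) coherence-enhancing
#' diffusion on every plane along z, then y, then x, and averages the three
#' filtered volumes voxel-wise. Elongated structures (processes) are smoothed
#' along their orientation and gain contrast against the noise.
#'
#' @param stack an [image_stack]
#' @param iters diffusion iterations per plane
#' @param tau explicit time step (stability requires tau <= 0.2)
#' @param sigma gradient pre-smoothing sd, px
#' @param rho structure-tensor integration sd, px
#' @param alpha isotropic diffusivity floor in (0, 1)
#' @param cpar coherence contrast parameter; `<= 0` selects it per plane
#'   from the coherence distribution
#' @return an [image_stack] of the averaged filtered volume
#' @export
enhance_tubular <- function(stack, iters = 10, tau = 0.15, sigma = 1,
                            rho = 4, alpha = 0.25, cpar = -1) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (any(!is.finite(v))) stop("stack contains non-finite voxels")
  dm <- dim(v)
  if (any(dm < 3)) stop("need at least 3 planes per axis")
  acc <- array(0, dm)
  for (k in seq_len(dm[3]))                       # planes along z: [y, x]
    acc[, , k] <- acc[, , k] + cpp_ced2d(v[, , k], iters, tau, sigma, rho,
                                         alpha, cpar)
  for (j in seq_len(dm[2]))                       # planes along x: [y, z]
    acc[, j, ] <- acc[, j, ] + cpp_ced2d(v[, j, ], iters, tau, sigma, rho,
                                         alpha, cpar)
  for (i in seq_len(dm[1]))                       # planes along y: [x, z]
    acc[i, , ] <- acc[i, , ] + cpp_ced2d(v[i, , ], iters, tau, sigma, rho,
                                         alpha, cpar)
  out <- image_stack(acc / 3, stack$spacing)
  out$calibration <- stack$calibration
  out
}

#' Hysteresis binarization at multiples of the noise sigma
#'
#' Voxels at or above `high_k * sigma` seed regions which are grown through
#' all 26-connected voxels at or above `low_k * sigma`.
#'
#' @param stack an [image_stack] (typically diffusion-filtered)
#' @param noise_sigma noise sd in the same units as the stack
#' @param low_k,high_k low/high thresholds in units of sigma
#' @return a [binary_mask]
#' @export
binarize_hysteresis <- function(stack, noise_sigma, low_k = 1, high_k = 3) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.finite(noise_sigma) || noise_sigma <= 0)
    stop("noise sigma must be > 0")
  dm <- dim(stack$voxels)
  m <- cpp_hysteresis_3d(as.numeric(stack$voxels), as.integer(dm),
                         low_k * noise_sigma, high_k * noise_sigma)
  binary_mask(array(m, dm), stack$spacing)
}

#' Remove small connected components from a mask
#'
#' 26-connected components with fewer than `min_voxels` voxels are removed
#' (a component of exactly `min_voxels` is kept). Idempotent.
#'
#' @param mask a [binary_mask]
#' @param min_voxels minimum component size to keep
#' @return a [binary_mask]
#' @export
prune_small <- function(mask, min_voxels = 100) {
  stopifnot(inherits(mask, "binary_mask"))
  dm <- dim(mask$mask)
  lab <- cpp_label_3d(as.logical(mask$mask), as.integer(dm))
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab)
  keep <- sizes >= min_voxels
  out <- array(lab > 0L & keep[pmax(lab, 1L)], dm)
  binary_mask(out, mask$spacing)
}
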