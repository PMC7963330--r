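#' Calibrated 3D image stack
#'
#' Container for a voxel grid with physical spacing. Arrays are indexed
#' `[y, x, z]` (plane-major, matching R's matrix convention per z-plane);
#' `spacing` gives the voxel pitch in micrometres along y, x and z.
#'
#' @param voxels numeric 3D array `[y, x, z]`, intensity units or photon counts
#' @param spacing numeric length-3, micrometres per voxel along (y, x, z);
#'   all strictly positive
#' @param calibration optional [pmt_calibration] recorded after photon
#'   conversion
#' @return an object of class `image_stack`
#' @export
image_stack <- function(voxels, spacing, calibration = NULL) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array [y, x, z]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (y, x, z) in um")
  if (!is.null(calibration) && any(voxels < 0, na.rm = TRUE))
    stop("calibrated stacks must be non-negative")
  structure(list(voxels = voxels, spacing = spacing, calibration = calibration),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.null(x$calibration)) "" else " (photon-calibrated)"))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' 2D image with physical pixel size
#'
#' @param pixels numeric matrix `[y, x]`
#' @param pixel_size micrometres per pixel (isotropic)
#' @return an object of class `image2d`
#' @export
image2d <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), is.numeric(pixel_size), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size), class = "image2d")
}

#' Binary 3D mask with inherited spacing
#'
#' @param mask logical 3D array, same shape as its source stack
#' @param spacing voxel pitch (y, x, z) in micrometres
#' @return an object of class `binary_mask`
#' @export
binary_mask <- function(mask, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(mask = mask, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Time-lapse calcium movie
#'
#' @param frames numeric 3D array `[y, x, t]`
#' @param pixel_size micrometres per pixel
#' @param frame_interval seconds per frame (default 1 s)
#' @param dark_frames optional array `[y, x, t]` of detector-noise frames
#' @return an object of class `ca_movie`
#' @export
ca_movie <- function(frames, pixel_size, frame_interval = 1, dark_frames = NULL) {
  stopifnot(length(dim(frames)) == 3L, pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, dark_frames = dark_frames),
            class = "ca_movie")
}

#' Set of electrophysiological sweeps
#'
#' Current (or voltage) traces on a uniform time base with stimulus
#' annotations.
#'
#' @param time numeric vector, seconds
#' @param sweeps named list or matrix (one column per sweep), pA or mV
#' @param sampling_rate Hz
#' @param stim_times named list: per-sweep stimulus times (s)
#' @param holding_mv holding potential, mV
#' @param units character, `"pA"` or `"mV"`
#' @param meta optional list of free-form annotations
#' @return an object of class `sweep_set`
#' @export
sweep_set <- function(time, sweeps, sampling_rate, stim_times = list(),
                      holding_mv = -80, units = "pA", meta = list()) {
  if (is.matrix(sweeps)) sweeps <- as.data.frame(sweeps)
  stopifnot(all(vapply(sweeps, length, 1L) == length(time)))
  for (st in stim_times)
    if (length(st) && (min(st) < min(time) || max(st) > max(time)))
      stop("stimulus annotations fall outside the trace span")
  structure(list(time = time, sweeps = sweeps, sampling_rate = sampling_rate,
                 stim_times = stim_times, holding_mv = holding_mv,
                 units = units, meta = meta),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g Hz (%s)\n",
              length(x$sweeps), length(x$time), x$sampling_rate, x$units))
  invisible(x)
}

#' fEPSP amplitude timecourse
#'
#' @param time_min minutes relative to HFS (HFS at t = 0)
#' @param amplitude fEPSP amplitudes, mV
#' @return an object of class `fepsp_timecourse`
#' @export
fepsp_timecourse <- function(time_min, amplitude) {
  stopifnot(length(time_min) == length(amplitude))
  if (!any(time_min <= 0)) stop("baseline period (t <= 0) is empty")
  structure(list(time_min = time_min, amplitude = amplitude),
            class = "fepsp_timecourse")
}

#' PMT calibration (gain/offset from the photon-transfer relation)
#'
#' @param gain intensity units per photon (must be > 0)
#' @param offset intensity units at zero photons
#' @param diagnostics list: slope/intercept standard errors, number of patches
#' @return an object of class `pmt_calibration`
#' @export
pmt_calibration <- function(gain, offset, diagnostics = list()) {
  if (!is.finite(gain) || gain <= 0)
    stop("calibration failed: gain must be > 0")
  structure(list(gain = gain, offset = offset, diagnostics = diagnostics),
            class = "pmt_calibration")
}

#' @export
print.pmt_calibration <- function(x, ...) {
  cat(sprintf("<pmt_calibration> gain %.4g intensity/photon, offset %.4g\n",
              x$gain, x$offset))
  invisible(x)
}

# internal: x/y/z voxel-centre coordinates (um) of an array dim = (ny, nx, nz)
.grid_coords <- function(dm, spacing) {
  list(y = (seq_len(dm[1]) - 1) * spacing[1],
       x = (seq_len(dm[2]) - 1) * spacing[2],
       z = (seq_len(dm[3]) - 1) * spacing[3])
}
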