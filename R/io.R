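# File interchange: TIFF stacks/movies with JSON sidecars, tabular sweep
# sets, SWC morphology export, ground-truth JSON.

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 32-bit float TIFF pages (one per z-plane);
#' physical spacing and calibration go to `<path>.json`.
#'
#' @param stack an [image_stack]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  # TIFF float pages take [0, 1]; store the affine range in the sidecar
  rng <- range(v)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  vn <- (v - rng[1]) / scale
  pages <- lapply(seq_len(dim(vn)[3]), function(k) vn[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(spacing_um = stack$spacing,
                  axes = c("y", "x", "z"),
                  value_offset = rng[1], value_scale = scale,
                  calibration = if (!is.null(stack$calibration))
                    list(gain = stack$calibration$gain,
                         offset = stack$calibration$offset))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist)
#' @return an [image_stack]
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) v[, , k] <- pages[[k]]
  if (!is.null(sc$value_scale))
    v <- v * sc$value_scale + sc$value_offset
  image_stack(v, sc$spacing_um)
}

#' Write a sweep set as plain-text table with a JSON sidecar
#'
#' One header line; columns: time then one column per sweep. Sampling rate,
#' stimulus annotations and holding potential go to `<path>.json`.
#'
#' @param sweeps a [sweep_set]
#' @param path output path (tab-separated text)
#' @return `path`, invisibly
#' @export
write_sweep_set <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  tab <- cbind(data.frame(time = sweeps$time), as.data.frame(sweeps$sweeps))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate = sweeps$sampling_rate,
         stim_times = sweeps$stim_times,
         holding_mv = sweeps$holding_mv, units = sweeps$units,
         meta = sweeps$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a sweep set written by [write_sweep_set()]
#'
#' @param path tabular path (sidecar `<path>.json` must exist)
#' @return a [sweep_set]
#' @export
read_sweep_set <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sweep_set(tab$time, as.list(tab[-1]), sc$sampling_rate,
            stim_times = as.list(sc$stim_times),
            holding_mv = sc$holding_mv, units = sc$units,
            meta = as.list(sc$meta))
}

#' Write ground truth as JSON
#'
#' @param gt a `ground_truth` record emitted by a generator
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Export a branch graph as SWC-style text
#'
#' Writes point records `id type x y z radius parent` (type 1 = soma,
#' 3 = branch/branchlet point). Each polyline is written root-to-tip; the
#' soma centre is the common root.
#'
#' @param graph a `branch_graph`
#' @param path output path
#' @param radius point radius written for branch points, um
#' @return `path`, invisibly
#' @export
write_swc <- function(graph, path, radius = 0.5) {
  stopifnot(inherits(graph, "branch_graph"))
  lines <- sprintf("%d %d %.3f %.3f %.3f %.3f %d", 1L, 1L,
                   graph$soma_center[2], graph$soma_center[1],
                   graph$soma_center[3], 2.5, -1L)
  id <- 1L
  for (pl in graph$polylines) {
    parent <- 1L
    for (r in seq_len(nrow(pl))) {
      id <- id + 1L
      lines <- c(lines, sprintf("%d %d %.3f %.3f %.3f %.3f %d", id, 3L,
                                pl[r, 2], pl[r, 1], pl[r, 3], radius, parent))
      parent <- id
    }
  }
  writeLines(c("# SWC export: id type x y z radius parent", lines), path)
  invisible(path)
}
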