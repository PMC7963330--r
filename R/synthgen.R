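# Synthetic-data generators. Every generator is a pure function of
# (preset, seed): all randomness flows through one seeded RNG per call and the
# planted parameters are echoed in a machine-readable ground-truth record so
# downstream recovery tests need no other information.

.unit <- function(v) v / sqrt(sum(v^2))

# well-spread unit directions: golden-spiral points, randomly rotated about z
.primary_directions <- function(n, z_compress) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i + runif(1, 0, 2 * pi)
  d <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  d[, 3] <- d[, 3] * z_compress
  d <- d + matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
  t(apply(d, 1, .unit))
}

# occupancy grid for self-avoiding growth (1 um cells, coords in [-50, 50]);
# cells store the id of the branch that claimed them so a daughter may pass
# near its own parent but not through unrelated processes
.occ_new <- function() array(0L, c(101L, 101L, 101L))

.occ_idx <- function(p) pmin(pmax(round(p) + 51L, 1L), 101L)

.occ_mark <- function(occ, pts, id, radius = 0.6) {
  r <- ceiling(radius)
  offs <- expand.grid(-r:r, -r:r, -r:r)
  offs <- offs[rowSums(offs^2) <= radius^2 + 1e-9, ]
  ctr <- unique(matrix(.occ_idx(c(pts)), ncol = 3))
  for (o in seq_len(nrow(offs))) {
    idx <- sweep(ctr, 2, as.numeric(offs[o, ]), `+`)
    idx <- pmin(pmax(idx, 1L), 101L)
    occ[idx] <- id
  }
  occ
}

.occ_blocked <- function(occ, p, radius, allow = 0L) {
  r <- ceiling(radius)
  offs <- expand.grid(-r:r, -r:r, -r:r)
  offs <- offs[rowSums(offs^2) <= radius^2 + 1e-9, ]
  idx <- sweep(as.matrix(offs), 2, as.numeric(.occ_idx(p)), `+`)
  idx <- pmin(pmax(idx, 1L), 101L)
  v <- occ[idx]
  any(v != 0L & !(v %in% allow))
}

# grow one branch as a persistent random walk inside the territory ellipsoid
# (x-y radius R, z half-extent C); steps that would exit reflect off the
# boundary, and off the soma sphere. Growth is self-avoiding: steps heading
# into already-occupied territory are deflected and, failing that, the
# branch terminates early (astrocyte processes tile rather than touch).
.grow_branch <- function(start, dir, len, step, persistence_sd, R, C, soma_r,
                         radial_bias = 0, occ = NULL, avoid_radius = 0,
                         allow_id = 0L) {
  n_steps <- max(2L, round(len / step))
  pts <- matrix(NA_real_, n_steps + 1L, 3L)
  pts[1L, ] <- start
  pos <- start
  n_done <- 0L
  for (k in seq_len(n_steps)) {
    dir <- .unit(dir + rnorm(3, sd = persistence_sd))
    if (radial_bias > 0) {
      rhat <- c(pos[1], pos[2], 0)
      rn <- sqrt(sum(rhat^2))
      if (rn > 1e-6) dir <- .unit(dir + radial_bias * rhat / rn)
    }
    reflect <- function(d, nrm) .unit(d - 2 * sum(d * nrm) * nrm)
    propose <- function(d) {
      nxt <- pos + d * step
      if ((nxt[1]^2 + nxt[2]^2) / R^2 + nxt[3]^2 / C^2 > 1) {
        nrm <- .unit(c(2 * pos[1] / R^2, 2 * pos[2] / R^2,
                       2 * pos[3] / C^2))
        if (sum(d * nrm) > 0) {         # only fold genuinely outbound steps
          d <- reflect(d, nrm)
          nxt <- pos + d * step
        }
      }
      if (sum(nxt^2) < (soma_r + 0.5)^2) {
        nrm <- .unit(pos)
        if (sum(d * nrm) < 0) {         # only fold genuinely inbound steps
          d <- reflect(d, nrm)
          nxt <- pos + d * step
        }
      }
      list(d = d, nxt = nxt)
    }
    pr <- propose(dir)
    blocked <- FALSE
    clear_of_start <- sqrt(sum((pos - start)^2)) > avoid_radius + 0.6
    if (!is.null(occ) && avoid_radius > 0 && clear_of_start &&
        .occ_blocked(occ, pr$nxt, avoid_radius, allow_id)) {
      ok <- FALSE
      a <- .unit(rnorm(3)); a <- .unit(a - sum(a * dir) * dir)
      for (ang in c(0.6, -0.6, 1.2, -1.2, 1.8, -1.8)) {
        cand <- .unit(cos(ang) * dir + sin(ang) * a)
        pc <- propose(cand)
        if (!.occ_blocked(occ, pc$nxt, avoid_radius, allow_id)) {
          pr <- pc; ok <- TRUE; break
        }
      }
      if (!ok) blocked <- TRUE   # walled in: terminate early
    }
    if (blocked) break
    dir <- pr$d
    pos <- pr$nxt
    pts[k + 1L, ] <- pos
    n_done <- k
  }
  list(points = pts[seq_len(max(n_done, 1L) + 1L), , drop = FALSE], dir = dir,
       terminated = n_done < n_steps)
}

.polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# recursive persistent-random-walk tree; branches either bifurcate or
# terminate at their distal end (no single-child continuation, so planted
# segments correspond one-to-one with junction-to-junction skeleton edges)
.grow_tree <- function(preset) {
  R <- preset$domain_radius; C <- preset$z_half
  segs <- list()
  dirs <- .primary_directions(preset$n_primary, C / R)
  queue <- lapply(seq_len(preset$n_primary), function(i)
    list(start = dirs[i, ] * preset$soma_radius, dir = dirs[i, ],
         depth = 1L, parent = 0L))
  occ <- if (preset$avoid_radius > 0) .occ_new() else NULL
  sib_of <- list()    # per parent id: seg ids of its grown daughters
  guard <- 0L
  while (length(queue) > 0L && guard < 2000L) {
    guard <- guard + 1L
    job <- queue[[1L]]; queue <- queue[-1L]
    # draw slightly long: boundary reflection and tiling termination shave
    # realised arc length, and this scale is calibrated so the realised
    # mean equals branch_length_mean
    len <- rgamma(1, shape = 9,
                  scale = preset$branch_length_mean *
                    preset$length_draw_scale / 9)
    # a branch may pass near its parent and its already-grown siblings
    sibs <- if (job$parent > 0L && job$parent <= length(sib_of))
      sib_of[[job$parent]] else integer(0)
    allow <- c(0L, job$parent, sibs)
    br <- .grow_branch(job$start, job$dir, len, preset$step_um,
                       preset$persistence_sd, R, C, preset$soma_radius,
                       radial_bias = preset$radial_bias,
                       occ = occ, avoid_radius = preset$avoid_radius,
                       allow_id = allow)
    # a daughter walled in before reaching a resolvable length leaves no
    # recoverable branch (thinning retracts tips by about a tube radius and
    # spur pruning removes what remains): discard it on both sides of the
    # ledger so ground truth and image stay consistent
    if (job$depth > 1L &&
        .polyline_length(br$points) < preset$min_branch_um) next
    id <- length(segs) + 1L
    segs[[id]] <- list(points = br$points, depth = job$depth,
                       parent = job$parent,
                       length = .polyline_length(br$points))
    if (job$parent > 0L)
      sib_of[[job$parent]] <- c(if (job$parent <= length(sib_of))
        sib_of[[job$parent]] else integer(0), id)
    if (!is.null(occ)) occ <- .occ_mark(occ, br$points, id)
    if (job$depth < preset$branch_order_depth && !isTRUE(br$terminated) &&
        runif(1) < preset$bifurcation_prob) {
      a <- .unit(rnorm(3)); a <- .unit(a - sum(a * br$dir) * br$dir)
      ang <- preset$split_angle * runif(2, 0.8, 1.2)
      tip <- br$points[nrow(br$points), ]
      rhat <- c(tip[1], tip[2], 0)
      rhat <- if (sqrt(sum(rhat^2)) > 1e-6) .unit(rhat) else c(1, 0, 0)
      for (s in c(1, -1)) {
        nd <- .unit(cos(ang[(3 - s) / 2]) * br$dir +
                    s * sin(ang[(3 - s) / 2]) * a)
        # centrifugal growth: inward-heading daughters are usually folded
        # outward (radial component reflected), preserving tangential spread
        rc <- sum(nd * rhat)
        if (rc < 0 && runif(1) < preset$outward_prob)
          nd <- .unit(nd - 2 * rc * rhat)
        queue <- c(queue, list(list(start = tip, dir = nd,
                                    depth = job$depth + 1L, parent = id)))
      }
    }
  }
  # when one daughter of a bifurcation was discarded, the survivor simply
  # continues its parent: no branch point exists, so parent and survivor
  # are one branch -- merge them so planted segments match what a tracer
  # (or the skeleton) can actually see
  repeat {
    parents <- vapply(segs, `[[`, 0L, "parent")
    counts <- tabulate(parents + 1L, nbins = length(segs) + 1L)[-1L]
    single <- which(counts == 1L)
    if (length(single) == 0L) break
    pid <- single[1L]
    cid <- which(parents == pid)[1L]
    segs[[pid]]$points <- rbind(segs[[pid]]$points,
                                segs[[cid]]$points[-1L, , drop = FALSE])
    segs[[pid]]$length <- segs[[pid]]$length + segs[[cid]]$length
    for (k in seq_along(segs))
      if (segs[[k]]$parent == cid) segs[[k]]$parent <- pid
      else if (segs[[k]]$parent > cid) segs[[k]]$parent <- segs[[k]]$parent - 1L
    segs <- segs[-cid]
  }
  segs
}

# paint tube voxels: for each polyline sample point, stamp an ellipsoidal
# cross-section (in-plane radius may differ from the axial radius)
.paint_branches <- function(rate, segs, center_vox, spacing, radius_um, value,
                            radius_z_um = radius_um) {
  dm <- dim(rate)
  rr <- expand.grid(dy = -3:3, dx = -3:3, dz = -1:1)
  keep <- ((rr$dy * spacing[1])^2 + (rr$dx * spacing[2])^2) / radius_um^2 +
          (rr$dz * spacing[3])^2 / radius_z_um^2 <= 1 + 1e-9
  offs <- rr[keep, , drop = FALSE]
  pts <- do.call(rbind, lapply(segs, `[[`, "points"))
  iy <- round(pts[, 2] / spacing[1] + center_vox[1])
  ix <- round(pts[, 1] / spacing[2] + center_vox[2])
  iz <- round(pts[, 3] / spacing[3] + center_vox[3])
  for (o in seq_len(nrow(offs))) {
    y <- iy + offs$dy[o]; x <- ix + offs$dx[o]; z <- iz + offs$dz[o]
    ok <- y >= 1 & y <= dm[1] & x >= 1 & x <= dm[2] & z >= 1 & z <= dm[3]
    if (any(ok)) {
      idx <- cbind(y[ok], x[ok], z[ok])
      rate[idx] <- pmax(rate[idx], value)
    }
  }
  rate
}

#' Generate a dye-filled astrocyte image stack with ground truth
#'
#' Builds a noiseless photon-rate volume containing a spherical soma, a
#' recursively bifurcating branch tree (persistent random walk confined to the
#' territory ellipsoid) and an isotropic sub-resolution "leaflet" haze at
#' `leaflet_vf` times the soma intensity, blurs it with an anisotropic
#' Gaussian PSF, then converts to detector intensities through Poisson photon
#' noise, PMT gain/offset and Gaussian read noise.
#'
#' @param preset an [astrocyte_preset()]
#' @param seed integer; fixes all randomness
#' @return list with elements `stack` (an [image_stack] of detector
#'   intensities), `noiseless` (an [image_stack] of PSF-blurred photon rates),
#'   and `ground_truth`: planted primary count, realised branch polylines and
#'   segment lengths, true projected domain area (from the noiseless
#'   structure mask), true volume fraction, soma centre and PMT parameters.
#' @export
gen_astrocyte_stack <- function(preset, seed) {
  stopifnot(inherits(preset, "astro_preset"))
  half_fov <- preset$fov_px * preset$pixel_size / 2
  if (preset$domain_radius + 1 > half_fov)
    stop("domain_radius exceeds the field of view (preset field `domain_radius`)")
  if (preset$haze_radius + 0.5 > half_fov)
    stop("haze_radius exceeds the field of view (preset field `haze_radius`)")
  withr::with_seed(seed, {
    dm <- c(preset$fov_px, preset$fov_px, preset$nz)
    spacing <- c(preset$pixel_size, preset$pixel_size, preset$z_step)
    center_vox <- (dm + 1) / 2
    co <- .grid_coords(dm, spacing)
    cy <- (center_vox[1] - 1) * spacing[1]
    cx <- (center_vox[2] - 1) * spacing[2]
    cz <- (center_vox[3] - 1) * spacing[3]

    segs <- .grow_tree(preset)
    structure_rate <- array(0, dm)
    # soma ball
    d2 <- outer(outer((co$y - cy)^2, (co$x - cx)^2, `+`), (co$z - cz)^2, `+`)
    structure_rate[d2 <= preset$soma_radius^2] <- preset$photon_rate_soma
    rz <- if (!is.null(preset$branch_radius_z)) preset$branch_radius_z
          else preset$branch_radius
    structure_rate <- .paint_branches(
      structure_rate, segs, center_vox, spacing, preset$branch_radius,
      preset$branch_photon_frac * preset$photon_rate_soma, rz)

    # projected domain footprint of the noiseless structure, thresholded at
    # one nominal noise sd after PSF blur -- the same segmentation physics
    # the hysteresis pipeline applies, so recovery is compared like for like
    # effective resolution of the segmentation pipeline: optical PSF plus
    # the diffusion filter's averaging, so ground truth and measurement
    # share the same footprint physics
    ced_xy <- 0.87 * spacing[2]; ced_z <- 0.87 * spacing[3]
    sr_blur <- array(cpp_gauss3d(
      as.numeric(structure_rate), as.integer(dm),
      sqrt(preset$psf_sigma_xy^2 + ced_xy^2) / spacing[1],
      sqrt(preset$psf_sigma_xy^2 + ced_xy^2) / spacing[2],
      sqrt(preset$psf_sigma_z^2 + ced_z^2) / spacing[3]), dm)
    thr <- preset$read_noise_sd / preset$pmt_gain
    true_area <- .domain_footprint(apply(sr_blur >= thr, c(1, 2), any),
                                   preset$pixel_size)

    haze <- outer(outer((co$y - cy)^2, (co$x - cx)^2, `+`) /
                    preset$haze_radius^2,
                  (co$z - cz)^2 / preset$haze_z_half^2, `+`) <= 1
    rate <- structure_rate
    rate[structure_rate == 0 & haze] <-
      preset$leaflet_vf * preset$photon_rate_soma

    rate <- array(cpp_gauss3d(as.numeric(rate), as.integer(dm),
                              preset$psf_sigma_xy / spacing[1],
                              preset$psf_sigma_xy / spacing[2],
                              preset$psf_sigma_z / spacing[3]), dm)

    photons <- array(rpois(length(rate), rate), dm)
    intensity <- preset$pmt_gain * photons + preset$pmt_offset +
      rnorm(length(photons), sd = preset$read_noise_sd)
    if (is.finite(preset$sat_level))
      intensity <- pmin(intensity, preset$sat_level)

    gt <- list(
      generator = "gen_astrocyte_stack", seed = seed, age = preset$age,
      n_primary = preset$n_primary,
      n_segments = length(segs),
      segment_lengths = vapply(segs, `[[`, 1, "length"),
      mean_segment_length = mean(vapply(segs, `[[`, 1, "length")),
      polylines = lapply(segs, `[[`, "points"),
      domain_area = true_area,
      vf = preset$leaflet_vf,
      soma_center = c(cy, cx, cz), soma_radius = preset$soma_radius,
      pmt_gain = preset$pmt_gain, pmt_offset = preset$pmt_offset,
      read_noise_sd = preset$read_noise_sd,
      photon_rate_soma = preset$photon_rate_soma)
    list(stack = image_stack(intensity, spacing),
         noiseless = image_stack(rate, spacing),
         ground_truth = structure(gt, class = "ground_truth"))
  })
}

#' Generate an SR101-stained field of astrocyte somata
#'
#' Places Gaussian somata by Poisson-disc (dart-throwing) sampling on a noisy
#' background. The placed count is the expected count for the requested
#' density with its fractional part stochastically rounded.
#'
#' @param density somata per 100 x 100 um^2
#' @param fov field of view, um (length-2)
#' @param seed integer seed
#' @param pixel_size um per pixel
#' @param min_spacing minimum centre-to-centre distance, um
#' @param soma_sigma Gaussian soma radius parameter, um
#' @param peak_snr soma peak amplitude in units of background noise sigma
#' @param noise_sigma background noise sd, intensity units
#' @return list(`image` = [image2d], `ground_truth` = coordinates and count)
#' @export
gen_sr101_field <- function(density, fov = c(300, 300), seed,
                            pixel_size = 1, min_spacing = 15,
                            soma_sigma = 3, peak_snr = 8, noise_sigma = 1) {
  stopifnot(density >= 0, all(fov > 0))
  expected <- density * prod(fov) / 1e4
  max_pack <- 0.5 * prod(fov) / (pi * (min_spacing / 2)^2)
  if (expected > max_pack)
    stop(sprintf("requested %.1f somata infeasible at min spacing %g um",
                 expected, min_spacing))
  withr::with_seed(seed, {
    n <- floor(expected) + rbinom(1, 1, expected - floor(expected))
    margin <- 3 * soma_sigma
    coords <- matrix(NA_real_, 0, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:500) {
        p <- c(runif(1, margin, fov[1] - margin),
               runif(1, margin, fov[2] - margin))
        if (nrow(coords) == 0 ||
            min(sqrt(rowSums(sweep(coords, 2, p)^2))) >= min_spacing) {
          coords <- rbind(coords, p); placed <- TRUE; break
        }
      }
      if (!placed)
        stop(sprintf("could not place %d somata at min spacing %g um",
                     n, min_spacing))
    }
    npx <- round(fov / pixel_size)
    img <- matrix(rnorm(prod(npx), sd = noise_sigma), npx[1], npx[2])
    img <- img + .stamp_gaussians(npx, coords / pixel_size,
                                  soma_sigma / pixel_size,
                                  peak_snr * noise_sigma)
    gt <- list(generator = "gen_sr101_field", seed = seed,
               density = density, count = nrow(coords),
               coordinates = coords, fov = fov)
    list(image = image2d(img, pixel_size),
         ground_truth = structure(gt, class = "ground_truth"))
  })
}

# sum of 2D Gaussians; coords in pixel units (y, x), may be a vector of peaks
.stamp_gaussians <- function(npx, coords_px, sigma_px, amp) {
  img <- matrix(0, npx[1], npx[2])
  if (NROW(coords_px) == 0) return(img)
  amp <- rep_len(amp, NROW(coords_px))
  r <- ceiling(4 * sigma_px)
  for (i in seq_len(NROW(coords_px))) {
    cyx <- coords_px[i, ]
    ys <- max(1, floor(cyx[1] - r)):min(npx[1], ceiling(cyx[1] + r))
    xs <- max(1, floor(cyx[2] - r)):min(npx[2], ceiling(cyx[2] + r))
    g <- amp[i] * exp(-outer((ys - 1 - cyx[1])^2, (xs - 1 - cyx[2])^2, `+`) /
                        (2 * sigma_px^2))
    img[ys, xs] <- img[ys, xs] + g
  }
  img
}

#' Generate a gap-junction dye-coupling image
#'
#' One bright (patched) soma plus `n_coupled` dimmer somata, all above the
#' stated detectability contrast.
#'
#' @param n_coupled number of coupled neighbours (>= 0)
#' @param seed integer seed
#' @param fov field of view, um
#' @param pixel_size um per pixel
#' @param min_spacing minimum soma spacing, um
#' @param soma_sigma soma Gaussian sigma, um
#' @param coupled_snr peak amplitude of coupled somata over noise sigma
#' @param patched_snr peak amplitude of the patched soma over noise sigma
#' @param noise_sigma background noise sd
#' @return list(`image` = [image2d], `ground_truth`)
#' @export
gen_coupling_image <- function(n_coupled, seed, fov = c(200, 200),
                               pixel_size = 1, min_spacing = 18,
                               soma_sigma = 3, coupled_snr = 8,
                               patched_snr = 24, noise_sigma = 1) {
  if (n_coupled < 0) stop("n_coupled must be >= 0")
  withr::with_seed(seed, {
    margin <- 3 * soma_sigma
    coords <- matrix(fov / 2, 1, 2)          # patched soma at the centre
    for (i in seq_len(n_coupled)) {
      for (try in 1:1000) {
        p <- c(runif(1, margin, fov[1] - margin),
               runif(1, margin, fov[2] - margin))
        if (min(sqrt(rowSums(sweep(coords, 2, p)^2))) >= min_spacing) {
          coords <- rbind(coords, p); break
        }
        if (try == 1000)
          stop("could not place coupled somata at the requested spacing")
      }
    }
    npx <- round(fov / pixel_size)
    amps <- c(patched_snr, rep(coupled_snr, n_coupled)) * noise_sigma
    img <- matrix(rnorm(prod(npx), sd = noise_sigma), npx[1], npx[2]) +
      .stamp_gaussians(npx, coords / pixel_size, soma_sigma / pixel_size, amps)
    gt <- list(generator = "gen_coupling_image", seed = seed,
               n_coupled = n_coupled, coordinates = coords,
               patched_index = 1L)
    list(image = image2d(img, pixel_size),
         ground_truth = structure(gt, class = "ground_truth"))
  })
}

# quasi-disc of exactly npix pixels around an integer centre
.disc_pixels <- function(center, npix, dm) {
  r <- ceiling(sqrt(npix / pi)) + 2L
  gy <- (center[1] - r):(center[1] + r)
  gx <- (center[2] - r):(center[2] + r)
  gr <- expand.grid(y = gy, x = gx)
  d2 <- (gr$y - center[1])^2 + (gr$x - center[2])^2
  ord <- order(d2, gr$y, gr$x)
  px <- as.matrix(gr[ord[seq_len(npix)], ])
  px[px[, 1] >= 1 & px[, 1] <= dm[1] & px[, 2] >= 1 & px[, 2] <= dm[2], ,
     drop = FALSE]
}

#' Generate a calcium movie with planted x-y-t events
#'
#' Events are constant-footprint discs with a trapezoidal temporal envelope
#' (soft first/last frame), planted at high SNR with known voxel support.
#' `reuse_prob` controls re-initiation at a previously used spot. Thirty dark
#' frames carrying only the noise model accompany the movie. Planted events
#' that could not be placed without touching an existing event (26-adjacency
#' in x-y-t) are flagged `merge_expected` in the ground truth rather than
#' silently dropped.
#'
#' @param preset a [ca_movie_preset()]
#' @param seed integer seed
#' @return list(`movie` = [ca_movie] (with dark frames attached),
#'   `ground_truth` = per-event spots, onsets, durations, areas, volumes,
#'   pixel supports)
#' @export
gen_ca_movie <- function(preset, seed) {
  stopifnot(inherits(preset, "ca_preset"))
  withr::with_seed(seed, {
    dmf <- c(preset$fov_px, preset$fov_px, preset$n_frames)
    frames <- array(0, dmf)
    margin <- 8L
    spots <- list()
    events <- list()
    intervals_at <- list()   # per spot: matrix of (onset, end)
    for (i in seq_len(preset$n_events)) {
      dur <- max(preset$min_frames,
                 round(rlnorm(1, preset$duration_meanlog,
                              preset$duration_sdlog) / preset$frame_interval))
      dur <- min(dur, preset$n_frames - 2L)
      npix <- max(4L, round(rlnorm(1, preset$area_meanlog, preset$area_sdlog) /
                              preset$pixel_size^2))
      reuse <- length(spots) > 0 && runif(1) < preset$reuse_prob
      spot_id <- if (reuse) sample.int(length(spots), 1) else {
        spots[[length(spots) + 1L]] <-
          c(sample(margin:(dmf[1] - margin), 1),
            sample(margin:(dmf[2] - margin), 1))
        intervals_at[[length(spots)]] <- matrix(numeric(0), 0, 2)
        length(spots)
      }
      center <- spots[[spot_id]]
      px <- .disc_pixels(center, npix, dmf[1:2])
      merge_expected <- FALSE
      onset <- NA_integer_
      for (try in 1:80) {
        cand <- sample.int(dmf[3] - dur, 1)
        iv <- intervals_at[[spot_id]]
        ok <- nrow(iv) == 0 ||
          all(cand > iv[, 2] + 2 | cand + dur - 1 < iv[, 1] - 2)
        # spatial adjacency to events at other spots overlapping in time
        if (ok && length(events)) {
          for (ev in events) {
            if (ev$spot_id == spot_id) next
            if (cand > ev$onset + ev$dur | cand + dur < ev$onset) next
            if (min(abs(outer(px[, 1], ev$pixels[, 1], `-`))) <= 1 &&
                min(abs(outer(px[, 2], ev$pixels[, 2], `-`))) <= 1 &&
                min(.cross_dist2(px, ev$pixels)) <= 2) { ok <- FALSE; break }
          }
        }
        if (ok) { onset <- cand; break }
      }
      if (is.na(onset)) { onset <- sample.int(dmf[3] - dur, 1); merge_expected <- TRUE }
      intervals_at[[spot_id]] <- rbind(intervals_at[[spot_id]],
                                       c(onset, onset + dur - 1L))
      env <- rep(1, dur)
      if (dur >= 3) { env[1] <- 0.7; env[dur] <- 0.7 }
      for (k in seq_len(dur))
        frames[cbind(px[, 1], px[, 2], onset + k - 1L)] <-
          frames[cbind(px[, 1], px[, 2], onset + k - 1L)] +
          preset$amplitude * env[k]
      events[[i]] <- list(
        id = i, spot_id = spot_id, spot = center,
        initiation_pixel = center,
        onset = onset, dur = dur,
        duration_s = dur * preset$frame_interval,
        area_um2 = nrow(px) * preset$pixel_size^2,
        volume = nrow(px) * dur * preset$pixel_size^2 * preset$frame_interval,
        pixels = px, merge_expected = merge_expected)
    }
    movie <- preset$baseline + frames +
      array(rnorm(prod(dmf), sd = preset$noise_sigma), dmf)
    dark <- array(rnorm(preset$fov_px^2 * preset$n_dark,
                        sd = preset$noise_sigma),
                  c(preset$fov_px, preset$fov_px, preset$n_dark))
    gt <- list(generator = "gen_ca_movie", seed = seed, age = preset$age,
               n_events = preset$n_events, events = events,
               noise_sigma = preset$noise_sigma,
               frame_interval = preset$frame_interval,
               pixel_size = preset$pixel_size)
    list(movie = ca_movie(movie, preset$pixel_size, preset$frame_interval,
                          dark_frames = dark),
         ground_truth = structure(gt, class = "ground_truth"))
  })
}

.cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
}

#' Generate voltage-clamp step sweeps (I-V protocol)
#'
#' Ohmic current responses `dI = 1000 * dV / r_input` (pA from mV and MOhm)
#' with a capacitive transient at the step edges and Gaussian noise.
#'
#' @param preset an [ephys_preset()]
#' @param protocol_mv absolute step potentials, mV
#' @param seed integer seed
#' @param holding_mv holding potential, mV
#' @return list(`sweeps` = [sweep_set] (baseline-subtracted, pA),
#'   `ground_truth` = planted `r_input` and per-step plateau currents)
#' @export
gen_vclamp_sweeps <- function(preset, protocol_mv = seq(-140, 80, by = 20),
                              seed, holding_mv = -80) {
  stopifnot(inherits(preset, "ephys_preset"))
  if (!is.finite(preset$r_input) || preset$r_input <= 0)
    stop("r_input must be finite and positive")
  withr::with_seed(seed, {
    fs <- preset$sampling_rate
    t <- seq(0, 0.8, by = 1 / fs)
    on <- 0.1; off <- 0.6
    mk <- function(v) {
      dV <- v - holding_mv
      dI <- 1000 * dV / preset$r_input
      y <- ifelse(t >= on & t < off, dI, 0)
      y <- y + preset$cap_scale * dI *
        (exp(-pmax(t - on, 0) * 1000 / preset$cap_tau) * (t >= on) -
         exp(-pmax(t - off, 0) * 1000 / preset$cap_tau) * (t >= off))
      y + rnorm(length(t), sd = preset$noise_sigma)
    }
    sw <- lapply(protocol_mv, mk)
    names(sw) <- sprintf("V%+d", protocol_mv)
    gt <- list(generator = "gen_vclamp_sweeps", seed = seed,
               r_input = preset$r_input, protocol_mv = protocol_mv,
               holding_mv = holding_mv,
               plateau_pA = 1000 * (protocol_mv - holding_mv) / preset$r_input)
    list(sweeps = sweep_set(t, sw, fs,
                            stim_times = list(step = c(on, off)),
                            holding_mv = holding_mv, units = "pA",
                            meta = list(step_on = on, step_off = off,
                                        protocol_mv = protocol_mv)),
         ground_truth = structure(gt, class = "ground_truth"))
  })
}

# unit-peak fast transporter transient (difference of exponentials)
.glut_shape <- function(t, t0, tau_ms, rise_ms) {
  u <- t - t0
  y <- ifelse(u > 0, exp(-u * 1000 / tau_ms) - exp(-u * 1000 / rise_ms), 0)
  pk <- {
    tpk <- log(tau_ms / rise_ms) / (1000 / rise_ms - 1000 / tau_ms)
    exp(-tpk * 1000 / tau_ms) - exp(-tpk * 1000 / rise_ms)
  }
  y / pk
}

# slow K+ envelope; amplitude defined at t_last + 200 ms
.ik_shape <- function(t, t0, t_last, amp200, tau_ms, rise_ms) {
  s <- function(u) ifelse(u > 0,
                          (1 - exp(-u * 1000 / rise_ms)) *
                            exp(-u * 1000 / tau_ms), 0)
  amp200 / s(t_last + 0.2 - t0) * s(t - t0)
}

#' Generate synaptic-stimulation sweeps for current decomposition
#'
#' Emits baseline-subtracted astrocytic current sweeps for 1, 4 and 5 stimuli
#' at 50 Hz as sums of fast glutamate-transporter transients (one per
#' stimulus) and a slow K+ uptake envelope, plus a transporter-block
#' ("TBOA") sweep containing only `residual_ik_scale` times the K+ envelope.
#' By construction the noiseless 5-stimulus sweep minus the 4-stimulus sweep
#' equals the planted fifth-stimulus component. Currents are inward
#' (negative); preset amplitudes are magnitudes in pA.
#'
#' @param preset an [ephys_preset()]
#' @param seed integer seed
#' @return list(`sweeps` = [sweep_set] with sweeps `s1`, `s4`, `s5`, `tboa`,
#'   `ground_truth` = all planted component amplitudes and taus)
#' @export
gen_synaptic_sweeps <- function(preset, seed) {
  stopifnot(inherits(preset, "ephys_preset"))
  withr::with_seed(seed, {
    fs <- preset$sampling_rate
    t <- seq(0, 1.48, by = 1 / fs)
    st <- 0.1 + (0:4) / 50
    glut <- function(t0, amp, tau)
      -amp * .glut_shape(t, t0, tau, preset$iglut_tau_rise)
    ik <- function(t0, tl, amp, tau)
      -.ik_shape(t, t0, tl, amp, tau, preset$ik_tau_rise)
    g_amp <- seq(preset$iglut_amp_1, preset$iglut_amp_5, length.out = 5)
    g_tau <- seq(preset$iglut_tau_1, preset$iglut_tau_5, length.out = 5)
    ik4_amp <- 2.5 * preset$ik_amp_1
    ik4_tau <- (preset$ik_tau_1 + preset$ik_tau_5) / 2

    s1 <- ik(st[1], st[1], preset$ik_amp_1, preset$ik_tau_1) +
      glut(st[1], preset$iglut_amp_1, preset$iglut_tau_1)
    ik4 <- ik(st[1], st[4], ik4_amp, ik4_tau)
    s4 <- ik4 + Reduce(`+`, lapply(1:4, function(k)
      glut(st[k], g_amp[k], g_tau[k])))
    fifth <- ik(st[5], st[5], preset$ik_amp_5, preset$ik_tau_5) +
      glut(st[5], preset$iglut_amp_5, preset$iglut_tau_5)
    s5 <- s4 + fifth
    ik5_total <- ik4 + ik(st[5], st[5], preset$ik_amp_5, preset$ik_tau_5)
    # transporter block at the end of the experiment: the residual K+
    # current is re-recorded for each stimulus protocol
    rs <- preset$residual_ik_scale
    tboa1 <- rs * ik(st[1], st[1], preset$ik_amp_1, preset$ik_tau_1)
    tboa4 <- rs * ik4
    tboa5 <- rs * ik5_total

    noisy <- lapply(list(s1 = s1, s4 = s4, s5 = s5, tboa_s1 = tboa1,
                         tboa_s4 = tboa4, tboa_s5 = tboa5),
                    function(y) y + rnorm(length(t), sd = preset$noise_sigma))
    gt <- list(generator = "gen_synaptic_sweeps", seed = seed,
               age = preset$age,
               ik_amp_1 = preset$ik_amp_1, ik_amp_5 = preset$ik_amp_5,
               ik_tau_1 = preset$ik_tau_1, ik_tau_5 = preset$ik_tau_5,
               iglut_amp_1 = preset$iglut_amp_1,
               iglut_amp_5 = preset$iglut_amp_5,
               iglut_tau_1 = preset$iglut_tau_1,
               iglut_tau_5 = preset$iglut_tau_5,
               residual_ik_scale = preset$residual_ik_scale,
               stim_times = st,
               fifth_component = fifth, ik5_total = ik5_total,
               iglut5_component = glut(st[5], preset$iglut_amp_5,
                                       preset$iglut_tau_5))
    list(sweeps = sweep_set(t, noisy, fs,
                            stim_times = list(s1 = st[1], s4 = st[1:4],
                                              s5 = st, tboa_s1 = st[1],
                                              tboa_s4 = st[1:4],
                                              tboa_s5 = st),
                            units = "pA",
                            meta = list(noise_sigma = preset$noise_sigma)),
         ground_truth = structure(gt, class = "ground_truth"))
  })
}

#' Generate a pre/post-HFS fEPSP amplitude timecourse
#'
#' Amplitudes at fixed stimulus intervals; the pre-HFS mean equals
#' `baseline_amp` and the post-HFS plateau approaches
#' `potentiation_factor * baseline_amp` with an exponential rise, under
#' multiplicative noise of coefficient of variation `noise_cv`.
#'
#' @param preset an [ltp_preset()]
#' @param seed integer seed
#' @return list(`timecourse` = [fepsp_timecourse], `ground_truth`)
#' @export
gen_fepsp_timecourse <- function(preset, seed) {
  stopifnot(inherits(preset, "ltp_preset"))
  withr::with_seed(seed, {
    dt <- preset$inter_stimulus / 60
    tt <- seq(-preset$baseline_duration, preset$post_duration, by = dt)
    f <- preset$potentiation_factor
    mean_amp <- preset$baseline_amp *
      ifelse(tt <= 0, 1, 1 + (f - 1) * (1 - exp(-tt / preset$rise_tau)))
    amp <- mean_amp * (1 + preset$noise_cv * rnorm(length(tt)))
    gt <- list(generator = "gen_fepsp_timecourse", seed = seed,
               age = preset$age, tboa = preset$tboa,
               potentiation_factor = f, baseline_amp = preset$baseline_amp)
    list(timecourse = fepsp_timecourse(tt, amp),
         ground_truth = structure(gt, class = "ground_truth"))
  })
}
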