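# Small fixtures shared across the suite. Everything is generated in code;
# reduced fields of view keep the voxel work fast while leaving the physics
# (PSF, noise model, thresholds) identical to the full-size presets.

# compact astrocyte preset: small territory in a small stack
tiny_astro_preset <- function(n_primary = 5L, domain_radius = 14,
                              haze_radius = 17, leaflet_vf = 0.045, ...) {
  astrocyte_preset("adult",
                   fov_px = 96L, nz = 25L,
                   domain_radius = domain_radius, haze_radius = haze_radius,
                   leaflet_vf = leaflet_vf, soma_radius = 4,
                   n_primary = n_primary, branch_order_depth = 3L,
                   bifurcation_prob = 0.6, branch_length_mean = 6,
                   length_draw_scale = 1.05,
                   ...)
}

# clean, well-separated planted cell for topology recovery checks
sparse_astro_preset <- function(n_primary = 7L, ...) {
  # a large soma spreads the primaries apart where they cross the
  # soma-complex sphere, so they stay optically separate
  astrocyte_preset("adult",
                   n_primary = n_primary, branch_order_depth = 2L,
                   bifurcation_prob = 0.5, branch_length_mean = 12,
                   soma_radius = 7, persistence_sd = 0.05,
                   avoid_radius = 1.5,
                   leaflet_vf = 0.01, read_noise_sd = 20,
                   ...)
}

short_ca_preset <- function(n_events = 6L, n_frames = 200L, ...) {
  ca_movie_preset("adult", fov_px = 32L, n_frames = n_frames,
                  n_events = n_events, ...)
}

# brute-force Mann-Whitney U (count pairs a > b, ties 1/2)
bf_mann_whitney_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# flood-fill hysteresis oracle on a 3D array using igraph components
oracle_hysteresis <- function(img, lo, hi) {
  dm <- dim(img)
  idx <- which(img >= lo)
  if (length(idx) == 0) return(array(FALSE, dm))
  ai <- arrayInd(idx, dm)
  id_of <- integer(prod(dm)); id_of[idx] <- seq_along(idx)
  edges <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ai, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    lin <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1) + dm[1] * dm[2] * (nb[ok, 3] - 1)
    j <- id_of[lin]
    keep <- j > 0
    if (any(keep))
      edges <- rbind(edges, cbind(which(ok)[keep], j[keep]))
  }
  g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  seeds <- which(img[idx] >= hi)
  keep_comp <- unique(comp[seeds])
  out <- array(FALSE, dm)
  out[idx[comp %in% keep_comp]] <- TRUE
  out
}

# voxel-shell Sholl oracle: 26-connected clusters of mask voxels in the
# spherical shell [r - 0.5, r + 0.5] um
oracle_sholl_shell <- function(mask, spacing, center, radii) {
  dm <- dim(mask)
  co <- list(y = (seq_len(dm[1]) - 1) * spacing[1],
             x = (seq_len(dm[2]) - 1) * spacing[2],
             z = (seq_len(dm[3]) - 1) * spacing[3])
  d <- sqrt(outer(outer((co$y - center[1])^2, (co$x - center[2])^2, `+`),
                  (co$z - center[3])^2, `+`))
  vapply(radii, function(r) {
    shell <- mask & d >= r - 0.5 & d <= r + 0.5
    if (!any(shell)) return(0L)
    lab <- astroage:::cpp_label_3d(as.logical(shell), as.integer(dm))
    max(lab)
  }, integer(1))
}

# rasterize polylines into a voxel mask (for Sholl cross-checks)
rasterize_polylines <- function(polylines, dm, spacing, radius_vox = 1L) {
  m <- array(FALSE, dm)
  for (pl in polylines) {
    iy <- round(pl[, 1] / spacing[1]) + 1
    ix <- round(pl[, 2] / spacing[2]) + 1
    iz <- round(pl[, 3] / spacing[3]) + 1
    ok <- iy >= 1 & iy <= dm[1] & ix >= 1 & ix <= dm[2] & iz >= 1 & iz <= dm[3]
    m[cbind(iy[ok], ix[ok], iz[ok])] <- TRUE
  }
  m
}
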