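# Branch-graph extraction, 3D Sholl analysis, domain area, soma density and
# gap-junction coupling counts.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3D dilation by one voxel (26-neighbourhood), plain shifts
.dilate26 <- function(a) {
  dm <- dim(a); out <- a
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dz == 0 && dx == 0 && dy == 0) next
    ys <- pmin(pmax(seq_len(dm[1]) + dy, 1L), dm[1])
    xs <- pmin(pmax(seq_len(dm[2]) + dx, 1L), dm[2])
    zs <- pmin(pmax(seq_len(dm[3]) + dz, 1L), dm[3])
    out <- out | a[ys, xs, zs]
  }
  out
}

#' Locate the astrocyte soma in a stack
#'
#' The soma mask is the largest connected component above a stated fraction
#' of the (smoothed) peak intensity, dilated by one voxel; the soma centre is
#' the intensity-weighted centroid of that component.
#'
#' @param stack an [image_stack] (photon-calibrated recommended)
#' @param peak_frac fraction of the smoothed peak intensity defining the
#'   soma core; branches are dimmer than the dye-filled soma, so a value
#'   above the branch/soma intensity ratio isolates the soma
#' @return list with `mask` (a [binary_mask]), `center` (um, c(y, x, z)),
#'   `radius` (um, volume-equivalent sphere radius)
#' @export
find_soma <- function(stack, peak_frac = 0.8) {
  stopifnot(inherits(stack, "image_stack"))
  dm <- dim(stack$voxels)
  sm <- array(cpp_gauss3d(as.numeric(stack$voxels), as.integer(dm), 1, 1, 0.5),
              dm)
  thr <- peak_frac * max(sm)
  m <- sm >= thr
  lab <- cpp_label_3d(as.logical(m), as.integer(dm))
  if (max(lab) == 0L) stop("no soma candidate above the intensity quantile")
  big <- which.max(tabulate(lab))
  core <- array(lab == big, dm)
  idx <- which(core, arr.ind = TRUE)
  w <- sm[core]
  sp <- stack$spacing
  center <- c(sum((idx[, 1] - 1) * w), sum((idx[, 2] - 1) * w),
              sum((idx[, 3] - 1) * w)) / sum(w) * sp
  vol <- sum(core) * prod(sp)
  list(mask = binary_mask(.dilate26(core), sp),
       center = center, radius = (3 * vol / (4 * pi))^(1 / 3))
}

# adjacency list of skeleton voxels (26-connectivity); indices follow the
# order of which(skel): column-major, matching cpp_flag_edges
.skel_adjacency <- function(skel, dm) {
  n <- sum(skel)
  ed <- cpp_flag_edges(as.logical(skel), as.integer(dm))
  adj <- vector("list", n)
  if (nrow(ed)) {
    sp1 <- split(ed[, 2], factor(ed[, 1], levels = seq_len(n)))
    sp2 <- split(ed[, 1], factor(ed[, 2], levels = seq_len(n)))
    for (i in seq_len(n)) adj[[i]] <- c(sp1[[i]], sp2[[i]])
  }
  adj
}

# trace junction-to-junction paths through an adjacency list
.trace_paths <- function(adj, anchors) {
  deg <- lengths(adj)
  nodes <- which(deg != 2L)
  nodes <- union(nodes, anchors)
  is_node <- rep(FALSE, length(adj)); is_node[nodes] <- TRUE
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  paths <- list()
  for (v in nodes) {
    for (w in adj[[v]]) {
      if (!is.null(get0(ekey(v, w), envir = used))) next
      path <- c(v, w)
      assign(ekey(v, w), TRUE, envir = used)
      prev <- v; cur <- w
      while (!is_node[cur]) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0L) break
        nxt <- nxt[1L]
        assign(ekey(cur, nxt), TRUE, envir = used)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  paths
}

# light smoothing of a polyline (running mean of 3, endpoints kept)
.smooth_polyline <- function(p) {
  n <- nrow(p)
  if (n < 5) return(p)
  q <- p
  q[2:(n - 1), ] <- (p[1:(n - 2), ] + p[2:(n - 1), ] + p[3:n, ]) / 3
  q
}

#' Extract a soma-rooted branch graph from a binary mask
#'
#' The mask minus the soma interior is reduced to a medial-axis curve
#' skeleton (topology-preserving 3D thinning), converted to a geometric
#' graph, and spurs shorter than `spur_um` are pruned. Every retained branch
#' is connected to the soma surface.
#'
#' @param mask a [binary_mask] of the segmented cell
#' @param soma a soma descriptor from [find_soma()] (or a [binary_mask])
#' @param spur_um prune terminal spurs shorter than this arc length (um)
#' @param soma_pad_um the proximal region within this distance of the soma
#'   surface is treated as part of the soma complex: at optical resolution
#'   the crowded proximal processes merge into one body there, and thinning
#'   a merged body yields lattice artefacts rather than branches
#' @return an object of class `branch_graph`: per-edge arc lengths and
#'   polylines (um coordinates), primary flags (edges leaving the soma
#'   surface), plus `soma_center` and `soma_mask`
#' @export
extract_branch_graph <- function(mask, soma, spur_um = 1.5, soma_pad_um = 3,
                                 reg_sigma = 1.2, reg_thresh = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  soma_mask <- if (inherits(soma, "binary_mask")) soma$mask else soma$mask$mask
  soma_center <- if (is.list(soma) && !is.null(soma$center)) soma$center
                 else NULL
  if (!any(mask$mask)) stop("mask is empty: cell not segmented")
  dm <- dim(mask$mask)
  sp <- mask$spacing
  if (is.null(soma_center)) {
    idx <- which(soma_mask, arr.ind = TRUE)
    soma_center <- (colMeans(idx) - 1) * sp
  }
  soma_r <- if (is.list(soma) && !is.null(soma$radius)) soma$radius
            else (3 * sum(soma_mask) * prod(sp) / (4 * pi))^(1 / 3)
  co <- .grid_coords(dm, sp)
  d2 <- outer(outer((co$y - soma_center[1])^2,
                    (co$x - soma_center[2])^2, `+`),
              (co$z - soma_center[3])^2, `+`)
  soma_ball <- d2 <= (soma_r + soma_pad_um)^2 | soma_mask
  work <- mask$mask & !soma_ball
  # regularize before thinning: surface noise bumps form tiny handles whose
  # loops a topology-preserving thinning must keep, shattering the skeleton
  # into short cycle edges; a sub-voxel smooth + re-threshold removes them
  sm <- array(cpp_gauss3d(as.numeric(work), as.integer(dm),
                          reg_sigma, reg_sigma, reg_sigma / 2), dm)
  regularized <- sm > reg_thresh
  # very thin masks can dissolve entirely; fall back to the raw mask then
  work <- if (any(regularized)) regularized else work
  skel <- array(cpp_skeletonize_3d(as.logical(work), as.integer(dm)), dm)
  # anchor shell: thinning retracts an entering stub's proximal face by up
  # to the tube radius, so the capture zone extends a couple of micrometres
  # beyond the soma-complex surface
  soma_halo <- d2 <= (soma_r + soma_pad_um + 2.2)^2

  # one anchor per branch entering the soma complex: cluster the skeleton
  # voxels lying in the halo shell spatially (a wide cut face can leave two
  # nearby stubs for one branch) and keep the innermost of each cluster
  pick_anchors <- function(vox, adj, merge_um = 3.5) {
    cand <- which(soma_halo[vox])
    if (length(cand) == 0L) return(integer(0))
    pts <- sweep(vox[cand, , drop = FALSE] - 1, 2, sp, `*`)
    cl <- if (length(cand) == 1L) 1L else
      stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                    h = merge_um)
    vapply(split(seq_along(cand), cl), function(ii) {
      d <- rowSums(sweep(pts[ii, , drop = FALSE], 2, soma_center)^2)
      cand[ii][which.min(d)]
    }, integer(1))
  }

  for (pass in 1:3) {
    vox <- which(skel, arr.ind = TRUE)
    if (nrow(vox) == 0L) stop("no skeleton voxel adjacent to soma: ",
                              "cell not segmented")
    adj <- .skel_adjacency(skel, dm)
    anchor <- pick_anchors(vox, adj)
    if (length(anchor) == 0L) stop("no skeleton voxel adjacent to soma: ",
                                   "cell not segmented")
    is_anchor <- rep(FALSE, nrow(vox))
    is_anchor[which(soma_halo[vox])] <- TRUE   # protect all entering voxels
    paths <- .trace_paths(adj, anchor)
    if (length(paths) == 0L) stop("skeleton yielded no traceable branches")
    plen <- vapply(paths, function(p)
      .polyline_length(sweep(vox[p, , drop = FALSE] - 1, 2, sp, `*`)),
      numeric(1))
    deg <- lengths(adj)
    spur <- vapply(paths, function(p) {
      a <- p[1]; b <- p[length(p)]
      tip <- (deg[a] == 1L & !is_anchor[a]) | (deg[b] == 1L & !is_anchor[b])
      tip
    }, logical(1)) & plen < spur_um
    if (!any(spur)) break
    drop_vox <- unique(unlist(lapply(paths[spur], function(p)
      p[-c(1L, length(p))])))
    # also drop the free tip voxel itself
    tips <- unlist(lapply(paths[spur], function(p) {
      ends <- c(p[1], p[length(p)])
      ends[deg[ends] == 1L & !is_anchor[ends]]
    }))
    drop_vox <- unique(c(drop_vox, tips))
    if (length(drop_vox) == 0L) break
    skel[vox[drop_vox, , drop = FALSE]] <- FALSE
  }

  # keep only components connected to the soma
  lab <- cpp_label_3d(as.logical(skel), as.integer(dm))
  keep_lab <- unique(lab[which(skel & soma_halo)])
  keep_lab <- keep_lab[keep_lab > 0L]
  skel <- array(lab > 0L & array(lab, dm) %in% keep_lab, dm)

  vox <- which(skel, arr.ind = TRUE)
  adj <- .skel_adjacency(skel, dm)
  anchor <- pick_anchors(vox, adj)
  paths <- .trace_paths(adj, anchor)

  # graph surgery: the raw skeleton carries sub-resolution artefacts --
  # short bridges between junction doublets, residual spurs -- which are
  # contracted/pruned before edges are reported
  el <- lapply(paths, function(p)
    list(a = p[1], b = p[length(p)],
         pl = sweep(vox[p, , drop = FALSE] - 1, 2, sp, `*`)))
  anchors <- unique(anchor)
  el <- .graph_surgery(el, anchors, spur_um = spur_um, merge_um = 2)
  if (length(el) == 0L) stop("skeleton yielded no traceable branches")

  # complete terminal tips: thinning retracts ends by about the tube
  # radius, so extend each free tip along its final direction while still
  # inside the (regularized) mask
  deg <- table(unlist(lapply(el, function(e) c(e$a, e$b))))
  for (i in seq_along(el)) {
    e <- el[[i]]
    for (endn in c("a", "b")) {
      key <- as.character(e[[endn]])
      if (deg[key] != 1L || e[[endn]] %in% anchors) next
      pl <- if (endn == "a") e$pl[rev(seq_len(nrow(e$pl))), , drop = FALSE]
            else e$pl
      n <- nrow(pl)
      if (n < 3) next
      d <- .unit(pl[n, ] - pl[max(1, n - 4), ])
      tip <- pl[n, ]
      for (s in 1:3) {
        cand <- tip + d * 0.4
        ci <- round(cand / sp) + 1
        if (any(ci < 1) || any(ci > dm) || !work[ci[1], ci[2], ci[3]]) break
        tip <- cand
      }
      if (sum((tip - pl[n, ])^2) > 0) {
        add <- matrix(tip, 1, 3)
        el[[i]]$pl <- if (endn == "a") rbind(add, e$pl) else rbind(e$pl, add)
      }
    }
  }

  # root primary edges at the soma surface: the padded exclusion ball cut
  # them short, so prepend the run from the entry point back to the soma
  for (i in seq_along(el)) {
    e <- el[[i]]
    for (endn in c("a", "b")) {
      if (!(e[[endn]] %in% anchors)) next
      pl <- el[[i]]$pl
      pt <- if (endn == "a") pl[1, ] else pl[nrow(pl), ]
      v <- pt - soma_center
      vr <- sqrt(sum(v^2))
      if (vr <= soma_r) next
      surf <- soma_center + v / vr * soma_r
      add <- matrix(surf, 1, 3)
      el[[i]]$pl <- if (endn == "a") rbind(add, pl) else rbind(pl, add)
    }
  }

  # light smoothing removes the voxel staircase before arc lengths are read
  polylines <- lapply(el, function(e) .smooth_polyline(e$pl))
  lens <- vapply(polylines, .polyline_length, numeric(1))
  primary <- vapply(el, function(e)
    (e$a %in% anchors) || (e$b %in% anchors), logical(1))
  keep <- lens > 0
  edges <- data.frame(id = seq_len(sum(keep)), length = lens[keep],
                      primary = primary[keep],
                      n_vox = vapply(el[keep], function(e) nrow(e$pl),
                                     integer(1)))
  structure(list(edges = edges, polylines = polylines[keep],
                 soma_center = soma_center, soma_mask = soma_mask,
                 soma_radius = soma_r, soma_pad = soma_pad_um,
                 spacing = sp, n_skeleton_voxels = nrow(vox)),
            class = "branch_graph")
}

# iterative cleanup of an edge list: drop spur tips, contract short
# junction-junction bridges, splice degree-2 nodes back into single edges
.graph_surgery <- function(el, anchors, spur_um, merge_um, max_iter = 500) {
  elen <- function(e) .polyline_length(e$pl)
  for (it in seq_len(max_iter)) {
    if (length(el) == 0L) break
    keys <- unlist(lapply(el, function(e) c(e$a, e$b)))
    deg <- table(keys)
    dg <- function(k) as.integer(deg[as.character(k)])
    changed <- FALSE
    # 1. prune spurs: short edges ending in a free tip
    drop <- vapply(el, function(e) {
      tip_a <- dg(e$a) == 1L && !(e$a %in% anchors)
      tip_b <- dg(e$b) == 1L && !(e$b %in% anchors)
      (tip_a || tip_b) && elen(e) < spur_um
    }, logical(1))
    if (any(drop)) { el <- el[!drop]; changed <- TRUE; next }
    # 2. contract short bridges between two junctions (junction doublets)
    keys <- unlist(lapply(el, function(e) c(e$a, e$b)))
    deg <- table(keys)
    short <- which(vapply(el, function(e)
      elen(e) < merge_um && dg(e$a) >= 3L && dg(e$b) >= 3L && e$a != e$b,
      logical(1)))
    if (length(short)) {
      e <- el[[short[1]]]
      from <- e$b; to <- e$a
      el <- el[-short[1]]
      el <- lapply(el, function(x) {
        if (x$a == from) x$a <- to
        if (x$b == from) x$b <- to
        x
      })
      if (from %in% anchors) anchors <- unique(c(anchors, to))
      changed <- TRUE
      next
    }
    # 3. splice degree-2 nodes (not anchors) back into one edge
    keys <- unlist(lapply(el, function(e) c(e$a, e$b)))
    deg <- table(keys)
    two <- as.numeric(names(deg)[deg == 2])
    two <- setdiff(two, anchors)
    spliced <- FALSE
    for (nk in two) {
      inc <- which(vapply(el, function(e) e$a == nk || e$b == nk, logical(1)))
      if (length(inc) != 2L) next
      e1 <- el[[inc[1]]]; e2 <- el[[inc[2]]]
      if (e1$a == e1$b || e2$a == e2$b) next
      p1 <- if (e1$b == nk) e1$pl else e1$pl[rev(seq_len(nrow(e1$pl))), ,
                                             drop = FALSE]
      a1 <- if (e1$b == nk) e1$a else e1$b
      p2 <- if (e2$a == nk) e2$pl else e2$pl[rev(seq_len(nrow(e2$pl))), ,
                                             drop = FALSE]
      b2 <- if (e2$a == nk) e2$b else e2$a
      newe <- list(a = a1, b = b2, pl = rbind(p1, p2[-1, , drop = FALSE]))
      el <- c(el[-inc], list(newe))
      spliced <- TRUE
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  el
}

#' @export
print.branch_graph <- function(x, ...) {
  cat(sprintf("<branch_graph> %d edges (%d primary), mean length %.2f um\n",
              nrow(x$edges), sum(x$edges$primary), mean(x$edges$length)))
  invisible(x)
}

#' 3D Sholl profile of a branch graph
#'
#' Counts transversal crossings of the graph polylines with concentric
#' spheres about the soma centre: a polyline step whose endpoint distances
#' straddle a radius contributes one crossing (tangency counts once).
#'
#' @param graph a `branch_graph`
#' @param radii sphere radii, um (default 5..50 step 1)
#' @return data.frame of class `sholl_profile` with columns `radius`,
#'   `intersections`
#' @export
sholl_3d <- function(graph, radii = 5:50) {
  stopifnot(inherits(graph, "branch_graph"))
  if (length(radii) == 0L) stop("radius list is empty")
  counts <- integer(length(radii))
  for (pl in graph$polylines) {
    d <- sqrt(rowSums(sweep(pl, 2, graph$soma_center)^2))
    for (k in seq_along(radii)) {
      s <- sign(d - radii[k])
      s[s == 0] <- 1e-9      # tangency: count the touch once, not twice
      counts[k] <- counts[k] + sum(abs(diff(s > 0)) > 0)
    }
  }
  structure(data.frame(radius = radii, intersections = counts),
            class = c("sholl_profile", "data.frame"))
}

# projected footprint area: morphological closing then hole filling
.domain_footprint <- function(proj, pixel_size, closing_um = 3) {
  if (!any(proj)) return(0)
  r <- max(1L, round(closing_um / pixel_size))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  img <- EBImage::Image(proj * 1)
  cl <- EBImage::closing(img, brush)
  filled <- EBImage::fillHull(cl)
  sum(filled > 0.5) * pixel_size^2
}

#' Morphometry summary of one cell
#'
#' @param graph a `branch_graph`
#' @param profile a `sholl_profile`
#' @param mask the cell's [binary_mask] (for the projected domain area)
#' @param closing_um closing radius applied to the z maximum projection
#'   before hole filling
#' @param min_edge_um edges shorter than this are junction artefacts of the
#'   skeleton lattice and are excluded from the mean branch length
#' @return list of class `morphometry_summary`: `n_primary` (edges leaving
#'   the soma surface), `max_intersections`, `mean_branch_length` (um),
#'   `domain_area` (um^2)
#' @export
summarize_morphometry <- function(graph, profile, mask, closing_um = 3,
                                  min_edge_um = 2) {
  stopifnot(inherits(graph, "branch_graph"),
            inherits(mask, "binary_mask"))
  proj <- apply(mask$mask, c(1, 2), any)
  area <- .domain_footprint(proj, mask$spacing[2], closing_um)
  len <- graph$edges$length
  len <- len[len >= min_edge_um]
  if (length(len) == 0L) len <- graph$edges$length
  # primaries counted geometrically: edges crossing the soma-complex sphere
  # (robust to how the skeleton fragments inside the proximal merge zone)
  n_prim <- sum(graph$edges$primary)
  if (!is.null(graph$soma_radius)) {
    rc <- graph$soma_radius + (graph$soma_pad %||% 3) + 0.5
    cross <- vapply(graph$polylines, function(pl) {
      dd <- sqrt(rowSums(sweep(pl, 2, graph$soma_center)^2))
      min(dd) < rc && max(dd) > rc
    }, logical(1))
    if (any(cross)) n_prim <- sum(cross)
  }
  structure(list(
    n_primary = n_prim,
    max_intersections = if (nrow(profile)) max(profile$intersections) else 0L,
    mean_branch_length = mean(len),
    domain_area = area), class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_summary> %d primaries, max intersections ",
                     "%d, mean branch length %.2f um, domain area %.0f um^2\n"),
              x$n_primary, x$max_intersections, x$mean_branch_length,
              x$domain_area))
  invisible(x)
}

# band-pass (difference-of-Gaussians) blob detection at soma scale
.detect_somata <- function(image, soma_sigma = 3, k = 5, min_sep = 10) {
  px <- image$pixel_size
  s <- soma_sigma / px
  m <- image$pixels
  g1 <- EBImage::gblur(m, sigma = s)
  g2 <- EBImage::gblur(m, sigma = 2 * s)
  dog <- g1 - g2
  noise <- mad(as.numeric(dog))
  r <- max(2L, round(min_sep / 2 / px))
  dil <- EBImage::dilate(EBImage::Image(dog),
                         EBImage::makeBrush(2L * r + 1L, shape = "disc"))
  peaks <- which(dog >= as.matrix(dil) - 1e-12 & dog > k * noise,
                 arr.ind = TRUE)
  if (nrow(peaks) == 0L)
    return(list(count = 0L, coords = matrix(numeric(0), 0, 2),
                intensity = numeric(0)))
  list(count = nrow(peaks), coords = (peaks - 1) * px,
       intensity = dog[peaks])
}

#' Count SR101-stained somata and report tissue density
#'
#' Difference-of-Gaussians blob detection at the soma scale with local-maximum
#' extraction above a contrast threshold set in units of the robust image
#' noise (so the result is invariant to global intensity scaling).
#'
#' @param image an [image2d]
#' @param soma_sigma expected soma Gaussian scale, um
#' @param k contrast threshold in units of the band-pass noise sd
#' @param min_sep minimum peak separation, um
#' @return list of class `soma_count`: `count`, `density`
#'   (somata per 100 x 100 um^2), `coords` (um)
#' @export
count_somata <- function(image, soma_sigma = 3, k = 5, min_sep = 10) {
  stopifnot(inherits(image, "image2d"))
  det <- .detect_somata(image, soma_sigma, k, min_sep)
  fov_area <- prod(dim(image$pixels)) * image$pixel_size^2
  structure(list(count = det$count,
                 density = det$count * 1e4 / fov_area,
                 coords = det$coords), class = "soma_count")
}

#' Count dye-coupled astrocytes
#'
#' Detects somata as in [count_somata()] and excludes the brightest detection
#' (the patched cell); the remaining detections are the coupled neighbours.
#'
#' @inheritParams count_somata
#' @return integer count of coupled cells
#' @export
count_coupled <- function(image, soma_sigma = 3, k = 5, min_sep = 10) {
  det <- .detect_somata(image, soma_sigma, k, min_sep)
  if (det$count == 0L) return(0L)
  det$count - 1L
}
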