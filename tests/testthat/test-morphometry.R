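# Branch-graph extraction, Sholl analysis, domain area, soma counting.

# build a mask containing a soma ball plus straight tubes, in code
tube_mask <- function(dm = c(128L, 128L, 21L), sp = c(0.4, 0.4, 1),
                      soma_r = 3, tubes = list(list(dir = c(0, 1, 0),
                                                    len = 16))) {
  ctr <- (dm + 1) / 2
  ctr_um <- (ctr - 1) * sp
  co <- astroage:::.grid_coords(dm, sp)
  d2 <- outer(outer((co$y - ctr_um[1])^2, (co$x - ctr_um[2])^2, `+`),
              (co$z - ctr_um[3])^2, `+`)
  m <- d2 <= soma_r^2
  for (tb in tubes) {
    for (s in seq(0, tb$len, by = 0.2)) {
      p <- ctr_um + tb$dir * (soma_r - 0.5 + s)
      iy <- round(p[1] / sp[1]) + 1; ix <- round(p[2] / sp[2]) + 1
      iz <- round(p[3] / sp[3]) + 1
      if (iy < 3 || iy > dm[1] - 2 || ix < 3 || ix > dm[2] - 2 ||
          iz < 2 || iz > dm[3] - 1) next
      for (yy in (iy - 2):(iy + 2)) for (xx in (ix - 2):(ix + 2))
        for (zz in (iz - 1):(iz + 1))
        if (((yy - 1) * sp[1] - p[1])^2 + ((xx - 1) * sp[2] - p[2])^2 +
            ((zz - 1) * sp[3] - p[3])^2 <= 1)
          m[yy, xx, zz] <- TRUE
    }
  }
  soma <- d2 <= soma_r^2
  list(mask = binary_mask(m, sp),
       soma = list(mask = binary_mask(soma, sp), center = ctr_um,
                   radius = soma_r))
}

test_that("a straight tube yields one edge of the right length", {
  fx <- tube_mask(tubes = list(list(dir = c(0, 1, 0), len = 16)))
  gr <- extract_branch_graph(fx$mask, fx$soma, soma_pad_um = 1.5)
  expect_equal(nrow(gr$edges), 1L)
  expect_true(gr$edges$primary[1])
  # tube spans soma surface to soma_r - 0.5 + 16; arc measured from surface
  expect_lt(abs(gr$edges$length[1] - 16) / 16, 0.15)
})

test_that("a Y-shaped cell yields one branch point and three edges", {
  fx <- tube_mask(dm = c(128L, 128L, 21L),
                  tubes = list(list(dir = c(0, 1, 0), len = 10)))
  # add two arms from the tube tip
  sp <- c(0.4, 0.4, 1)
  ctr_um <- ((c(128, 128, 21) + 1) / 2 - 1) * sp
  tip <- ctr_um + c(0, 2.5 - 0.5 + 10, 0)
  m <- fx$mask$mask
  for (ang in c(0.6, -0.6)) {
    d <- c(sin(ang), cos(ang), 0)
    for (s in seq(0, 8, by = 0.2)) {
      p <- tip + d * s
      iy <- round(p[1] / sp[1]) + 1; ix <- round(p[2] / sp[2]) + 1
      iz <- round(p[3] / sp[3]) + 1
      if (iy < 3 || iy > 126 || ix < 3 || ix > 126 || iz < 2 || iz > 20) next
      for (yy in (iy - 2):(iy + 2)) for (xx in (ix - 2):(ix + 2))
        for (zz in (iz - 1):(iz + 1))
          if (((yy - 1) * sp[1] - p[1])^2 + ((xx - 1) * sp[2] - p[2])^2 +
              ((zz - 1) * sp[3] - p[3])^2 <= 1)
            m[yy, xx, zz] <- TRUE
    }
  }
  gr <- extract_branch_graph(binary_mask(m, sp), fx$soma, soma_pad_um = 1.5)
  # one stem and two arms; residual junction micro-bridges sit below the
  # 2-um edge floor used throughout the analysis
  expect_equal(sum(gr$edges$length >= 2), 3L)
  expect_equal(sum(gr$edges$primary), 1L)
})

test_that("empty or detached masks raise segmentation errors", {
  fx <- tube_mask()
  empty <- binary_mask(array(FALSE, dim(fx$mask$mask)), fx$mask$spacing)
  expect_error(extract_branch_graph(empty, fx$soma), "empty")
  # mask present but nowhere near the soma
  far <- array(FALSE, dim(fx$mask$mask))
  far[2:4, 2:30, 2:4] <- TRUE
  expect_error(extract_branch_graph(binary_mask(far, fx$mask$spacing),
                                    fx$soma), "soma")
})

test_that("sholl_3d counts distance-straddling crossings", {
  mk_graph <- function(polylines) {
    n <- length(polylines)
    structure(list(polylines = polylines, soma_center = c(0, 0, 0),
                   edges = data.frame(id = seq_len(n),
                                      length = rep(1, n),
                                      primary = rep(FALSE, n))),
              class = "branch_graph")
  }
  # radial process spanning 8..30 um along +x
  pl <- cbind(0, seq(8, 30, by = 0.25), 0)
  g <- mk_graph(list(pl))
  pr <- sholl_3d(g, radii = 5:50)
  expect_equal(pr$intersections[pr$radius %in% 9:30], rep(1L, 22))
  expect_true(all(pr$intersections[pr$radius < 9 | pr$radius > 30] == 0))
  # two disjoint radial processes: counts add
  pl2 <- cbind(seq(6, 20, by = 0.25), 0, 0)
  g2 <- mk_graph(list(pl, pl2))
  pr2 <- sholl_3d(g2, radii = 5:50)
  expect_equal(sum(pr2$intersections),
               sum(pr$intersections) + sum(sholl_3d(mk_graph(list(pl2)),
                                                    5:50)$intersections))
  expect_error(sholl_3d(g, radii = integer(0)), "empty")
  # empty graph
  g0 <- mk_graph(list())
  expect_true(all(sholl_3d(g0, 5:50)$intersections == 0))
})

test_that("sholl profile agrees with the voxel-shell oracle on a tube", {
  fx <- tube_mask(dm = c(128L, 128L, 21L),
                  tubes = list(list(dir = c(0, 1, 0), len = 20)))
  gr <- extract_branch_graph(fx$mask, fx$soma, soma_pad_um = 1.5)
  pr <- sholl_3d(gr, radii = 5:20)
  oracle <- oracle_sholl_shell(fx$mask$mask, fx$mask$spacing,
                               fx$soma$center, 5:20)
  # exclude shells touching the soma ball itself
  sel <- 5:20 > fx$soma$radius + 1.5
  expect_true(all(abs(pr$intersections[sel] - oracle[sel]) <= 1))
})

test_that("sholl profile is invariant under 90-degree rotation", {
  g <- gen_astrocyte_stack(tiny_astro_preset(), seed = 3)
  an <- analyze_stack(g$stack)
  pr <- sholl_3d(an$graph)
  rot <- image_stack(aperm(g$stack$voxels[, rev(seq_len(dim(g$stack$voxels)[2])), ],
                           c(2, 1, 3)),
                     g$stack$spacing)
  an2 <- analyze_stack(rot)
  pr2 <- sholl_3d(an2$graph)
  # same cell rotated: profiles agree closely (segmentation is re-run)
  expect_lt(mean(abs(pr$intersections - pr2$intersections)), 1.01)
})

test_that("domain area of a disc footprint approximates pi r^2", {
  dm <- c(100L, 100L, 5L); sp <- c(0.4, 0.4, 1)
  co <- astroage:::.grid_coords(dm, sp)
  ctr <- (dm[1:2] - 1) / 2 * sp[1:2]
  d2 <- outer((co$y - ctr[1])^2, (co$x - ctr[2])^2, `+`)
  m <- array(FALSE, dm); m[, , 3] <- d2 <= 15.5^2
  area <- astroage:::.domain_footprint(apply(m, c(1, 2), any), sp[2])
  expect_lt(abs(area - pi * 15.5^2) / (pi * 15.5^2), 0.03)
})

test_that("morphometry summary reports planted primaries on clean cells", {
  hits <- 0L; total <- 0L
  for (s in 1:6) {
    g <- gen_astrocyte_stack(sparse_astro_preset(n_primary = 7L), seed = s)
    an <- try(analyze_stack(g$stack), silent = TRUE)
    if (inherits(an, "try-error")) next
    total <- total + 1L
    if (abs(an$summary$n_primary - 7L) <= 1L) hits <- hits + 1L
  }
  expect_gte(total, 4L)
  expect_gte(hits / total, 0.7)
})

test_that("soma density counting recovers planted fields", {
  found <- planted <- 0
  for (s in 1:6) {
    f <- gen_sr101_field(0.59, fov = c(300, 300), seed = s)
    res <- count_somata(f$image)
    found <- found + res$count
    planted <- planted + f$ground_truth$count
  }
  expect_gte(found / planted, 0.95)
  expect_lte(found / planted, 1.05)
  blank <- gen_sr101_field(0, seed = 3)
  expect_equal(count_somata(blank$image)$count, 0L)
  # density arithmetic: 5 somata in a 300x300 field
  f5 <- list(count = 5L)
  expect_equal(5 * 1e4 / (300 * 300), 0.5556, tolerance = 1e-3)
})

test_that("coupled-cell counting excludes the patched soma and is scale-free", {
  img <- gen_coupling_image(3L, seed = 4)
  expect_equal(count_coupled(img$image), 3L)
  scaled <- image2d(img$image$pixels * 12.5, img$image$pixel_size)
  expect_equal(count_coupled(scaled), 3L)
  single <- gen_coupling_image(0L, seed = 5)
  expect_equal(count_coupled(single$image), 0L)
})
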