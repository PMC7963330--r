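# Volume fraction of unresolved processes from soma-normalized profiles.

flat_profile <- function(level = 4.5, dmax = 40, step = 0.1) {
  pr <- data.frame(distance = seq(0, dmax, by = step),
                   fluorescence = level)
  class(pr) <- c("radial_profile", "data.frame")
  pr
}

test_that("soma plane selection finds the soma and flags saturation", {
  g <- gen_astrocyte_stack(tiny_astro_preset(), seed = 5)
  soma <- find_soma(g$stack)
  sel <- select_soma_plane(g$stack, soma = soma)
  zc <- round(soma$center[3] / g$stack$spacing[3]) + 1
  expect_lte(abs(sel$z_index - zc), 1)
  # clipped soma trips the saturation check
  sat <- g$stack
  lvl <- quantile(sat$voxels, 0.98)
  sat$voxels <- pmin(sat$voxels, lvl)
  expect_error(select_soma_plane(sat, soma = soma, sat_level = lvl),
               "saturated")
  # single-plane stack returns that plane
  one <- image_stack(g$stack$voxels[, , 12, drop = FALSE], g$stack$spacing)
  expect_equal(select_soma_plane(one, soma = list(
    mask = binary_mask(soma$mask$mask[, , 12, drop = FALSE],
                       g$stack$spacing),
    center = soma$center))$z_index, 1L)
})

test_that("five lines give ten half-profiles normalized to the soma peak", {
  withr::with_seed(8, {
    m <- matrix(2, 101, 101)
    d2 <- outer((-50:50)^2, (-50:50)^2, `+`)
    m[d2 <= 100] <- 100                 # bright soma disc, radius 10 px
  })
  img <- image2d(m, pixel_size = 1)
  prof <- cast_profiles(img, center = c(50, 50), n_lines = 5)
  expect_length(prof, 10L)
  # soma peak maps to 100%
  expect_equal(max(prof[[1]]$fluorescence), 100, tolerance = 2)
  # radially symmetric image: all half-profiles agree
  v <- vapply(prof, function(p) mean(p$fluorescence[p$distance > 15 &
                                                      p$distance < 30]),
              numeric(1))
  expect_lt(diff(range(v)), 1)
})

test_that("branch-peak excision follows both amplitude and width rules", {
  pr <- flat_profile(4.5)
  bump <- pr$distance >= 20 & pr$distance <= 22
  pr$fluorescence[bump] <- 4.5 + 30
  out <- excise_branch_peaks(pr)
  expect_false(any(out$distance >= 20.2 & out$distance <= 21.8))
  expect_equal(mean(out$fluorescence[out$distance > 5]), 4.5, tolerance = 0.2)
  expect_gte(length(attr(out, "excised")), 1L)

  # 8-point bump fails the amplitude rule -> kept
  pr2 <- flat_profile(4.5)
  pr2$fluorescence[pr2$distance >= 20 & pr2$distance <= 22] <- 4.5 + 8
  out2 <- excise_branch_peaks(pr2)
  expect_equal(nrow(out2), nrow(pr2))

  # narrow 0.3-um spike fails the width rule -> kept
  pr3 <- flat_profile(4.5)
  pr3$fluorescence[pr3$distance >= 20 & pr3$distance <= 20.3] <- 4.5 + 15
  out3 <- excise_branch_peaks(pr3)
  expect_equal(nrow(out3), nrow(pr3))
})

test_that("fully excised profiles raise an error", {
  pr <- flat_profile(0)
  expect_error(excise_branch_peaks(pr[0, ]), "excised")
})

test_that("windowed VF returns the planted haze level", {
  pr <- flat_profile(4.5)
  expect_equal(vf_from_profile(pr, border = 6), 4.5)
  expect_equal(vf_from_profile(flat_profile(0), border = 6), 0)
  expect_equal(vf_from_profile(flat_profile(100), border = 6), 100)
  # empty window is flagged, not fatal
  short <- flat_profile(4.5, dmax = 10)
  expect_warning(v <- vf_from_profile(short, border = 6), "empty")
  expect_true(is.na(v))
})

test_that("VF is invariant to global intensity scaling", {
  g <- gen_astrocyte_stack(tiny_astro_preset(), seed = 9)
  v1 <- estimate_vf(g$stack)$vf_cell
  scaled <- image_stack(g$stack$voxels * 3.7, g$stack$spacing)
  v2 <- estimate_vf(scaled)$vf_cell
  expect_equal(v1, v2, tolerance = 0.05)
})

test_that("VF increases monotonically with planted haze", {
  vf_at <- function(vf) {
    mean(vapply(1:3, function(s)
      estimate_vf(gen_astrocyte_stack(tiny_astro_preset(leaflet_vf = vf),
                                      seed = s)$stack)$vf_cell, numeric(1)))
  }
  lo <- vf_at(0.02); hi <- vf_at(0.06)
  expect_gt(hi, lo)
})

test_that("planted volume fractions are recovered with branches present", {
  for (vf in c(0.045, 0.021)) {
    rec <- vapply(1:5, function(s)
      estimate_vf(gen_astrocyte_stack(
        astrocyte_preset(if (vf > 0.03) "adult" else "old"),
        seed = s)$stack)$vf_cell, numeric(1))
    expect_lt(abs(mean(rec) - vf * 100) / (vf * 100), 0.20)
  }
})
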