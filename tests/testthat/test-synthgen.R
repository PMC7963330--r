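# Generators: determinism, planted-value echo, noiseless limits.

test_that("generators are pure functions of (preset, seed)", {
  p <- tiny_astro_preset()
  a <- gen_astrocyte_stack(p, seed = 11)
  b <- gen_astrocyte_stack(p, seed = 11)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$ground_truth$polylines, b$ground_truth$polylines)
  c <- gen_astrocyte_stack(p, seed = 12)
  expect_false(identical(a$stack$voxels, c$stack$voxels))

  m1 <- gen_ca_movie(short_ca_preset(), seed = 3)
  m2 <- gen_ca_movie(short_ca_preset(), seed = 3)
  expect_identical(m1$movie$frames, m2$movie$frames)

  s1 <- gen_vclamp_sweeps(ephys_preset("adult"), protocol_mv = -85, seed = 5)
  s2 <- gen_vclamp_sweeps(ephys_preset("adult"), protocol_mv = -85, seed = 5)
  expect_identical(s1$sweeps$sweeps, s2$sweeps$sweeps)

  f1 <- gen_sr101_field(0.59, seed = 7)
  f2 <- gen_sr101_field(0.59, seed = 7)
  expect_identical(f1$image$pixels, f2$image$pixels)

  t1 <- gen_fepsp_timecourse(ltp_preset("old"), seed = 9)
  t2 <- gen_fepsp_timecourse(ltp_preset("old"), seed = 9)
  expect_identical(t1$timecourse$amplitude, t2$timecourse$amplitude)
})

test_that("astrocyte ground truth echoes planted values", {
  p <- tiny_astro_preset(n_primary = 7L)
  g <- gen_astrocyte_stack(p, seed = 2)
  expect_equal(g$ground_truth$n_primary, 7L)
  expect_equal(g$ground_truth$vf, p$leaflet_vf)
  expect_equal(length(g$ground_truth$polylines), g$ground_truth$n_segments)
  expect_equal(g$ground_truth$mean_segment_length,
               mean(g$ground_truth$segment_lengths))
})

test_that("leaflet haze sits at the planted fraction of soma intensity", {
  p <- tiny_astro_preset(leaflet_vf = 0.045)
  g <- gen_astrocyte_stack(p, seed = 4)
  nl <- g$noiseless$voxels
  dm <- dim(nl)
  co <- astroage:::.grid_coords(dm, g$noiseless$spacing)
  ctr <- (dm + 1) / 2 * g$noiseless$spacing - g$noiseless$spacing
  r <- sqrt(outer(outer((co$y - ctr[1])^2, (co$x - ctr[2])^2, `+`),
                  (co$z - ctr[3])^2 * 0, `+`))
  zmid <- abs(co$z - ctr[3]) < 2
  # haze-only annulus: inside haze radius, away from soma and branches
  sel <- r > p$soma_radius + 4 & r < p$haze_radius - 2
  sel <- sel & array(rep(zmid, each = dm[1] * dm[2]), dm)
  sel <- sel & nl < 0.3 * p$photon_rate_soma   # exclude branch cores
  haze_med <- median(nl[sel & nl > 0.01])
  expect_lt(abs(haze_med / p$photon_rate_soma - 0.045), 0.015)
})

test_that("infeasible geometry is rejected with the offending field named", {
  expect_error(gen_astrocyte_stack(tiny_astro_preset(domain_radius = 40),
                                   seed = 1), "domain_radius")
  expect_error(gen_astrocyte_stack(tiny_astro_preset(haze_radius = 40),
                                   seed = 1), "haze_radius")
  expect_error(gen_coupling_image(-1, seed = 1), "n_coupled")
  expect_error(gen_sr101_field(50, fov = c(100, 100), seed = 1,
                               min_spacing = 40), "infeasible")
  expect_error(gen_vclamp_sweeps(ephys_preset("adult", r_input = Inf),
                                 seed = 1))
})

test_that("SR101 field plants the expected Poisson-rounded count", {
  f <- gen_sr101_field(0.59, fov = c(300, 300), seed = 21)
  gt <- f$ground_truth
  expect_true(gt$count %in% c(5L, 6L))   # expected 5.31, stochastic rounding
  expect_equal(nrow(gt$coordinates), gt$count)
  blank <- gen_sr101_field(0, seed = 1)
  expect_equal(blank$ground_truth$count, 0L)
})

test_that("coupling image plants one patched plus n coupled somata", {
  g <- gen_coupling_image(3L, seed = 2)
  expect_equal(g$ground_truth$n_coupled, 3L)
  expect_equal(nrow(g$ground_truth$coordinates), 4L)
  g0 <- gen_coupling_image(0L, seed = 2)
  expect_equal(nrow(g0$ground_truth$coordinates), 1L)
})

test_that("calcium movie events carry consistent planted metrics", {
  p <- short_ca_preset(n_events = 5L)
  g <- gen_ca_movie(p, seed = 6)
  ev <- g$ground_truth$events
  expect_length(ev, 5L)
  for (e in ev) {
    expect_equal(e$duration_s, e$dur * p$frame_interval)
    expect_equal(e$volume, e$area_um2 * e$duration_s)
    expect_gte(e$dur, p$min_frames)
  }
  empty <- gen_ca_movie(short_ca_preset(n_events = 0L), seed = 1)
  expect_length(empty$ground_truth$events, 0L)
  # degenerate reuse probability: all events share one initiation spot
  reuse <- gen_ca_movie(short_ca_preset(n_events = 5L, reuse_prob = 1,
                                        n_frames = 400L), seed = 8)
  spots <- unique(t(vapply(reuse$ground_truth$events, `[[`, numeric(2), "spot")))
  expect_equal(nrow(spots), 1L)
})

test_that("voltage-clamp sweeps obey Ohm's law in the noiseless limit", {
  p <- ephys_preset("adult", noise_sigma = 0, cap_scale = 0)
  g <- gen_vclamp_sweeps(p, protocol_mv = -85, seed = 1)
  t <- g$sweeps$time
  plateau <- mean(g$sweeps$sweeps[[1]][t > 0.5 & t < 0.6])
  expect_equal(plateau, 1000 * (-5) / 21.5, tolerance = 1e-6)
  expect_equal(g$ground_truth$r_input, 21.5)
})

test_that("noiseless burst subtraction returns the planted fifth component", {
  p <- ephys_preset("old", noise_sigma = 0)
  g <- gen_synaptic_sweeps(p, seed = 1)
  fifth <- isolate_fifth(g$sweeps$sweeps$s5, g$sweeps$sweeps$s4)
  expect_equal(fifth, g$ground_truth$fifth_component, tolerance = 1e-10)
  # planted amplitude ratio is echoed
  expect_equal(g$ground_truth$ik_amp_5 / g$ground_truth$ik_amp_1, 0.77)
})

test_that("fEPSP timecourse plants baseline and potentiation exactly", {
  p0 <- ltp_preset("adult", noise_cv = 0, potentiation_factor = 1)
  g0 <- gen_fepsp_timecourse(p0, seed = 1)
  expect_equal(diff(range(g0$timecourse$amplitude)), 0)
  p <- ltp_preset("adult", noise_cv = 0, potentiation_factor = 1.53,
                  rise_tau = 1e-6)
  g <- gen_fepsp_timecourse(p, seed = 1)
  tc <- g$timecourse
  expect_equal(mean(tc$amplitude[tc$time_min > 50 & tc$time_min <= 60]) /
                 mean(tc$amplitude[tc$time_min <= 0]), 1.53, tolerance = 1e-9)
})
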