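# Voltage-clamp and field-potential analytics.

test_that("I-V curve from an ohmic cell is linear with the planted slope", {
  g <- gen_vclamp_sweeps(ephys_preset("adult"), seed = 1)
  iv <- build_iv(g$sweeps)
  expect_equal(length(iv$dV), 12L)                 # -140..+80 by 20
  expect_gt(iv$r_squared, 0.999)
  expect_equal(iv$slope, 1000 / 21.5, tolerance = 0.01)
  # zero-conductance (infinite resistance is rejected, use huge)
  g0 <- gen_vclamp_sweeps(ephys_preset("adult", r_input = 1e9,
                                       noise_sigma = 0, cap_scale = 0),
                          seed = 2)
  iv0 <- build_iv(g0$sweeps)
  expect_lt(abs(iv0$slope), 1e-3)
})

test_that("input resistance follows Ohm's law exactly and errors open-circuit", {
  # dI = -232.6 pA at -5 mV -> 21.5 MOhm
  expect_equal(1000 * (-5) / (-232.558), 21.5, tolerance = 1e-3)
  g <- gen_vclamp_sweeps(ephys_preset("adult", noise_sigma = 0, cap_scale = 0),
                         protocol_mv = -85, seed = 1)
  expect_equal(input_resistance(g$sweeps), 21.5, tolerance = 1e-6)
  # -5 nA at -5 mV -> 1 MOhm
  g1 <- gen_vclamp_sweeps(ephys_preset("adult", r_input = 1,
                                       noise_sigma = 0, cap_scale = 0),
                          protocol_mv = -85, seed = 1)
  expect_equal(input_resistance(g1$sweeps), 1, tolerance = 1e-6)
  flat <- g$sweeps
  flat$sweeps[[1]][] <- 0
  expect_error(input_resistance(flat), "noise floor")
})

test_that("input resistance is unbiased at preset noise", {
  r <- vapply(1:50, function(s)
    input_resistance(gen_vclamp_sweeps(ephys_preset("adult"),
                                       protocol_mv = -85,
                                       seed = s)$sweeps), numeric(1))
  expect_lt(abs(mean(r) - 21.5) / 21.5, 0.02)
})

test_that("burst subtraction is exact and linear", {
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(isolate_fifth(x, x), rep(0, 100))
  expect_equal(isolate_fifth(2 * x + y, y), 2 * x)
  expect_error(isolate_fifth(x, y[1:50]), "equal length")
})

test_that("I_K amplitude is read 200 ms after the last stimulus", {
  g <- gen_synaptic_sweeps(ephys_preset("old", noise_sigma = 0), seed = 1)
  t <- g$sweeps$time
  amp <- ik_amplitude(g$sweeps$sweeps$s1, t, g$sweeps$stim_times$s1)
  expect_equal(as.numeric(amp), 50, tolerance = 0.02)
  flat <- rep(0, length(t))
  expect_equal(as.numeric(ik_amplitude(flat, t, 0.1)), 0)
})

test_that("mono-exponential fit is exact noiselessly and robust at 5% noise", {
  t <- seq(0, 1, by = 1 / 5000)
  y <- 100 * exp(-t / 0.15) + 3
  f <- fit_monoexp(y, t, fit_start = 0)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  expect_equal(f$tau, 150, tolerance = 1e-6)
  taus <- vapply(1:20, function(s) {
    withr::with_seed(s, yn <- y + rnorm(length(y), sd = 5))
    fit_monoexp(yn, t, 0)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 150) / 150, 0.1)
  # rising trace is rejected
  expect_error(fit_monoexp(exp(t * 3), t, 0), "decay")
})

test_that("template subtraction recovers the pure transporter current", {
  withr::with_seed(3, {
    t <- seq(0, 1, by = 1 / 5000)
    glut <- -120 * (exp(-t / 0.015) - exp(-t / 0.001))
    tmpl <- -40 * (1 - exp(-t / 0.02)) * exp(-t / 0.2)
    trace <- glut + 0.7 * tmpl
  })
  iso <- isolate_iglut(trace, tmpl, t, tail_start = 0.3)
  expect_equal(iso$scale, 0.7, tolerance = 1e-6)
  expect_equal(iso$iglut, glut, tolerance = 1e-6)
  # template-free trace is left unchanged
  iso0 <- isolate_iglut(glut, tmpl, t, tail_start = 0.3)
  expect_lt(abs(iso0$scale), 1e-6)
  # zero-energy template errors
  expect_error(isolate_iglut(trace, rep(0, length(t)), t, 0.3), "energy")
})

test_that("decomposition ratios recover planted kinetics", {
  expect_equal(decomposition_ratios(10, 10, 100, 100)$amp_ratio_5_1, 1)
  expect_equal(decomposition_ratios(10, 10, 100, 115)$tau_ratio_5_1, 1.15)
  expect_equal(decomposition_ratios(10, 10, 100, 115)$tau_ratio_1_5,
               1 / 1.15, tolerance = 1e-12)
  # gain scaling leaves amplitude ratios unchanged
  r1 <- decomposition_ratios(50, 38.5, 200, 230)
  r2 <- decomposition_ratios(500, 385, 200, 230)
  expect_equal(r1$amp_ratio_5_1, r2$amp_ratio_5_1)
  # full pipeline on noiseless sweeps hits the planted values exactly
  g <- gen_synaptic_sweeps(ephys_preset("old", noise_sigma = 0), seed = 1)
  dec <- decompose_currents(g$sweeps)
  expect_equal(dec$ratios$ik$tau_ratio_5_1, 1.15, tolerance = 0.005)
  expect_equal(dec$ratios$ik$amp_ratio_5_1, 0.77, tolerance = 0.005)
  expect_equal(dec$ratios$iglut$amp_ratio_5_1, 1.13, tolerance = 0.01)
})

test_that("LTP magnitude is the plateau/baseline percentage", {
  g <- gen_fepsp_timecourse(ltp_preset("adult", noise_cv = 0,
                                       potentiation_factor = 1), seed = 1)
  expect_equal(ltp_magnitude(g$timecourse), 100)
  g2 <- gen_fepsp_timecourse(ltp_preset("adult", noise_cv = 0,
                                        rise_tau = 1e-6), seed = 1)
  expect_equal(ltp_magnitude(g2$timecourse), 153, tolerance = 1e-6)
  # short baseline or empty post window error
  tc <- g2$timecourse
  short <- fepsp_timecourse(tc$time_min[tc$time_min > -5],
                            tc$amplitude[tc$time_min > -5])
  expect_error(ltp_magnitude(short), "baseline")
  nopost <- fepsp_timecourse(tc$time_min[tc$time_min < 40],
                             tc$amplitude[tc$time_min < 40])
  expect_error(ltp_magnitude(nopost), "post-HFS")
})

test_that("LTP recovery at 2% multiplicative noise is unbiased", {
  m <- vapply(1:20, function(s)
    ltp_magnitude(gen_fepsp_timecourse(ltp_preset("adult"),
                                       seed = s)$timecourse), numeric(1))
  expect_lt(abs(mean(m) - 153) / 153, 0.02)
})
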