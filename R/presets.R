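#' Astrocyte stack generator preset
#'
#' Parameter bundle for [gen_astrocyte_stack()]. The `"adult"`, `"old"` and
#' `"young"` factories plant the corresponding group means reported for
#' hippocampal CA1 astrocytes: branch length (8.4 / 5.4 / 6.3 um), primary
#' branch count (8 / 7 / 7), unresolved-process volume fraction (4.5% / 2.1%)
#' and a territory radius calibrated so the projected domain footprint matches
#' the group mean domain area (2206 / 757 / 1959 um^2).
#'
#' @param age one of `"adult"`, `"old"`, `"young"`
#' @param ... named overrides of any preset field
#' @return an object of class `astro_preset` with fields:
#'   `n_primary` (count), `branch_length_mean` (um), `branch_order_depth`,
#'   `bifurcation_prob`, `domain_radius` (um, territory ellipsoid, x-y),
#'   `z_half` (um, territory half-extent along z), `leaflet_vf` (fraction of
#'   soma intensity, 0-1), `haze_radius` (um, extent of the unresolved-leaflet
#'   haze), `soma_radius` (um), `photon_rate_soma` (photons/voxel),
#'   `branch_photon_frac`, `pmt_gain` (intensity/photon), `pmt_offset`
#'   (intensity), `read_noise_sd` (intensity units), `psf_sigma_xy`,
#'   `psf_sigma_z` (um), `pixel_size`, `z_step` (um), `fov_px`, `nz`.
#' @export
astrocyte_preset <- function(age = c("adult", "old", "young"), ...) {
  age <- match.arg(age)
  base <- list(
    pixel_size = 0.4, z_step = 1, fov_px = 168L, nz = 33L,
    psf_sigma_xy = 0.3, psf_sigma_z = 0.8,
    pmt_gain = 2, pmt_offset = 100, read_noise_sd = 24,
    photon_rate_soma = 140, branch_photon_frac = 1,
    z_half = 10, haze_radius = 30, haze_z_half = 12,
    step_um = 0.5, persistence_sd = 0.10, split_angle = 0.65,
    radial_bias = 0, outward_prob = 0.8, length_draw_scale = 1,
    min_branch_um = 1.5,
    sat_level = Inf)
  # branching density, tube radius and territory radius are calibrated so
  # the planted summaries reproduce the group means (branch length 8.4 um
  # for the adult; projected domain footprint 757 um^2 for the old); growth
  # is self-avoiding (avoid_radius, um) so processes tile without touching
  group <- switch(age,
    adult = list(n_primary = 8L, branch_length_mean = 8.4, branch_radius = 0.7,
                 branch_radius_z = 1.0,
                 branch_order_depth = 5L, bifurcation_prob = 0.7,
                 avoid_radius = 3.2, length_draw_scale = 0.76,
                 min_branch_um = 4.5,
                 read_noise_sd = 50,
                 domain_radius = 29, leaflet_vf = 0.045, soma_radius = 5),
    old   = list(n_primary = 7L, branch_length_mean = 5.4, branch_radius = 0.5,
                 branch_order_depth = 6L, bifurcation_prob = 0.95,
                 avoid_radius = 1.3, z_half = 12,
                 domain_radius = 14.6, leaflet_vf = 0.021, soma_radius = 4.5),
    young = list(n_primary = 7L, branch_length_mean = 6.3, branch_radius = 0.5,
                 branch_order_depth = 5L, bifurcation_prob = 0.8,
                 avoid_radius = 1.4,
                 domain_radius = 27, leaflet_vf = 0.045, soma_radius = 5))
  p <- modifyList(modifyList(base, c(group, list(age = age))), list(...))
  stopifnot(p$n_primary >= 1, p$leaflet_vf > 0, p$leaflet_vf < 1,
            p$domain_radius > p$soma_radius, p$soma_radius > 0,
            p$pmt_gain > 0, p$branch_length_mean > 0)
  structure(p, class = "astro_preset")
}

#' Calcium movie generator preset
#'
#' Planted x-y-t event statistics for [gen_ca_movie()]. The `"adult"` and
#' `"old"` factories plant the reported group medians: event duration 6 s vs
#' 7 s, projection area 20.2 vs 16.2 um^2, with more frequent initiation-spot
#' reuse in the old group. Durations and areas are lognormal; durations are
#' floored at `min_frames` so that planted events survive the > 4 s
#' astrocyte filter unless rejection is being tested deliberately.
#'
#' @param age `"adult"` or `"old"`
#' @param ... named overrides
#' @return object of class `ca_preset`: `fov_px`, `pixel_size` (um),
#'   `frame_interval` (s), `n_frames`, `n_events`, `duration_meanlog`,
#'   `duration_sdlog` (log-seconds), `min_frames`, `area_meanlog`,
#'   `area_sdlog` (log-um^2), `reuse_prob`, `amplitude` (intensity units),
#'   `noise_sigma`, `baseline`, `n_dark`
#' @export
ca_movie_preset <- function(age = c("adult", "old"), ...) {
  age <- match.arg(age)
  base <- list(fov_px = 64L, pixel_size = 1, frame_interval = 1,
               n_frames = 600L, noise_sigma = 10, baseline = 100,
               amplitude = 80, n_dark = 30L, min_frames = 5L)
  group <- switch(age,
    adult = list(n_events = 33L, duration_meanlog = log(6),
                 duration_sdlog = 0.3, area_meanlog = log(20.2),
                 area_sdlog = 0.4, reuse_prob = 0.15),
    old   = list(n_events = 41L, duration_meanlog = log(7),
                 duration_sdlog = 0.3, area_meanlog = log(16.2),
                 area_sdlog = 0.4, reuse_prob = 0.5))
  p <- modifyList(modifyList(base, c(group, list(age = age))), list(...))
  stopifnot(p$frame_interval > 0, p$n_events >= 0, p$fov_px >= 8)
  structure(p, class = "ca_preset")
}

#' Electrophysiology generator preset
#'
#' Membrane and synaptic-current parameters for [gen_vclamp_sweeps()] and
#' [gen_synaptic_sweeps()]. Factories plant the reported group values: input
#' resistance 21.5 (adult) / 35.8 (old) MOhm, I_K amplitude ratio
#' amp(5)/amp(1) 1.05 / 0.77, I_K decay-time ratio tau(5)/tau(1) 0.81 / 1.15,
#' I_GluT amplitude ratio 1.15 / 1.13 and I_GluT tau ratio 0.81 / 1.11.
#' Amplitudes are magnitudes of inward (negative) currents, in pA; I_K
#' amplitudes refer to the value 200 ms after the last stimulus.
#'
#' @param age `"adult"` or `"old"`
#' @param ... named overrides
#' @return object of class `ephys_preset`
#' @export
ephys_preset <- function(age = c("adult", "old"), ...) {
  age <- match.arg(age)
  base <- list(sampling_rate = 5000, noise_sigma = 3,
               ik_tau_rise = 20, iglut_tau_rise = 1,
               residual_ik_scale = 0.3,
               cap_tau = 3, cap_scale = 3)
  group <- switch(age,
    adult = list(r_input = 21.5,
                 ik_amp_1 = 50, ik_amp_5 = 52.5,        # ratio 1.05
                 ik_tau_1 = 200, ik_tau_5 = 162,        # ratio 0.81
                 iglut_amp_1 = 120, iglut_amp_5 = 138,  # ratio 1.15
                 iglut_tau_1 = 15, iglut_tau_5 = 12.15),# ratio 0.81
    old   = list(r_input = 35.8,
                 ik_amp_1 = 50, ik_amp_5 = 38.5,        # ratio 0.77
                 ik_tau_1 = 200, ik_tau_5 = 230,        # ratio 1.15
                 iglut_amp_1 = 120, iglut_amp_5 = 135.6,# ratio 1.13
                 iglut_tau_1 = 15, iglut_tau_5 = 16.65))# ratio 1.11
  p <- modifyList(modifyList(base, c(group, list(age = age))), list(...))
  stopifnot(is.finite(p$r_input), p$r_input > 0,
            p$ik_tau_1 > 0, p$ik_tau_5 > 0,
            p$iglut_tau_1 > 0, p$iglut_tau_5 > 0,
            p$sampling_rate > 0)
  structure(p, class = "ephys_preset")
}

#' LTP timecourse generator preset
#'
#' Plants the reported fEPSP potentiation: 153% (adult) / 128% (old) of
#' baseline, with optional transporter-block variants (129% / 124% under
#' TFB-TBOA). 15 min stable baseline sampled every 20 s, at least 60 min
#' post-HFS.
#'
#' @param age `"adult"` or `"old"`
#' @param tboa logical; plant the partial glutamate-transporter-block variant
#' @param ... named overrides
#' @return object of class `ltp_preset`: `baseline_amp` (mV),
#'   `potentiation_factor` (post-plateau / baseline), `baseline_duration`,
#'   `post_duration` (min), `inter_stimulus` (s), `noise_cv`,
#'   `rise_tau` (min)
#' @export
ltp_preset <- function(age = c("adult", "old"), tboa = FALSE, ...) {
  age <- match.arg(age)
  factor <- if (tboa) switch(age, adult = 1.29, old = 1.24)
            else      switch(age, adult = 1.53, old = 1.28)
  p <- modifyList(list(age = age, tboa = tboa,
                       baseline_amp = 0.3, potentiation_factor = factor,
                       baseline_duration = 15, post_duration = 60,
                       inter_stimulus = 20, noise_cv = 0.02, rise_tau = 4),
                  list(...))
  stopifnot(p$potentiation_factor > 0, p$post_duration >= 60,
            p$inter_stimulus > 0)
  structure(p, class = "ltp_preset")
}

#' SR101 field / dye-coupling presets
#'
#' Group values for the tissue-level generators: SR101-stained soma density
#' 0.59 (adult) / 0.61 (old) astrocytes per 100 x 100 um^2, and dye-coupled
#' neighbour count 7 (adult) / 3 (old).
#'
#' @param age `"adult"` or `"old"`
#' @return named list with `density` (somata per 100 x 100 um^2) and
#'   `n_coupled` (cells)
#' @export
tissue_preset <- function(age = c("adult", "old")) {
  age <- match.arg(age)
  switch(age,
         adult = list(age = age, density = 0.59, n_coupled = 7L),
         old   = list(age = age, density = 0.61, n_coupled = 3L))
}
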