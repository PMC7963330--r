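# Voltage-clamp and field-potential analytics: I-V and input resistance,
# burst-subtraction isolation of the fifth response, K+/glutamate-transporter
# current decomposition, LTP magnitude.

.window_mean <- function(time, y, lo, hi) {
  sel <- time >= lo & time < hi
  if (!any(sel)) stop(sprintf("no samples in window [%g, %g] s", lo, hi))
  mean(y[sel])
}

#' Current-voltage relationship from step sweeps
#'
#' The current response for each step is the plateau mean (last 100 ms of
#' the 500-ms step) minus the pre-step baseline; the slope conductance is a
#' least-squares fit and linearity is reported as R^2.
#'
#' @param sweeps a [sweep_set] from [gen_vclamp_sweeps()] (or with `step_on`
#'   / `step_off` and `protocol_mv` in `meta`)
#' @param plateau_ms plateau averaging window before step offset, ms
#' @return list of class `iv_curve`: `dV` (mV), `dI` (pA), `slope`
#'   (pA/mV = nS), `r_squared`
#' @export
build_iv <- function(sweeps, plateau_ms = 100) {
  stopifnot(inherits(sweeps, "sweep_set"))
  on <- sweeps$meta$step_on; off <- sweeps$meta$step_off
  prot <- sweeps$meta$protocol_mv
  if (is.null(on) || is.null(prot))
    stop("sweep set lacks step annotations (step_on/step_off/protocol_mv)")
  if (length(prot) != length(sweeps$sweeps))
    stop("missing steps: protocol lists ",
         paste(setdiff(sprintf("V%+d", prot), names(sweeps$sweeps)),
               collapse = ", "))
  t <- sweeps$time
  dI <- vapply(seq_along(prot), function(i) {
    y <- sweeps$sweeps[[i]]
    .window_mean(t, y, off - plateau_ms / 1000, off) -
      .window_mean(t, y, 0, on)
  }, numeric(1))
  dV <- prot - sweeps$holding_mv
  ord <- order(dV)
  dV <- dV[ord]; dI <- dI[ord]
  fit <- lm(dI ~ dV)
  structure(list(dV = dV, dI = dI, slope = coef(fit)[[2]],
                 r_squared = summary(fit)$r.squared),
            class = "iv_curve")
}

#' Input resistance from a test voltage step
#'
#' Ohm's law on the plateau-minus-baseline current response to a small
#' voltage step: `R_i = dV / dI`, reported in MOhm (dV in mV, dI in pA).
#'
#' @param sweeps a [sweep_set] containing the test-step sweep (first sweep
#'   used), or a numeric trace with attributes supplied via the other
#'   arguments
#' @param dV step magnitude, mV (default -5)
#' @param plateau_ms plateau window before step offset, ms
#' @param noise_floor minimal |dI| accepted, pA; below this the recording is
#'   treated as an open circuit
#' @return input resistance, MOhm
#' @export
input_resistance <- function(sweeps, dV = -5, plateau_ms = 100,
                             noise_floor = 1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  on <- sweeps$meta$step_on; off <- sweeps$meta$step_off
  y <- sweeps$sweeps[[1]]
  t <- sweeps$time
  dI <- .window_mean(t, y, off - plateau_ms / 1000, off) -
    .window_mean(t, y, 0, on)
  if (abs(dI) < noise_floor)
    stop("current response below the noise floor (open circuit?)")
  1000 * dV / dI
}

#' Isolate the fifth-stimulus response by burst subtraction
#'
#' Pointwise subtraction of the 4-stimulus sweep from the 5-stimulus sweep;
#' both must share the time base and be baseline-subtracted.
#'
#' @param resp5,resp4 numeric traces of equal length
#' @return numeric trace of the isolated fifth response
#' @export
isolate_fifth <- function(resp5, resp4) {
  if (length(resp5) != length(resp4))
    stop("traces must have equal length and alignment")
  resp5 - resp4
}

#' K+ current amplitude 200 ms after the last stimulus
#'
#' The slow K+ uptake current outlasts the fast transporter current by
#' hundreds of ms, so its amplitude is read at `delay` after the last
#' stimulus (short mean window), baseline-subtracted. Returns the magnitude
#' in pA (the current is inward/negative); the signed value is in attribute
#' `signed`.
#'
#' @param trace numeric baseline-subtracted current trace, pA
#' @param time time base, s
#' @param stimulus_times stimulus times, s
#' @param delay measurement time after the last stimulus, s (default 0.2)
#' @param window_ms averaging window centred on the measurement point, ms
#' @return amplitude magnitude, pA
#' @export
ik_amplitude <- function(trace, time, stimulus_times, delay = 0.2,
                         window_ms = 4) {
  tm <- max(stimulus_times) + delay
  half <- window_ms / 2000
  sel <- time >= tm - half & time <= tm + half
  if (!any(sel)) stop("measurement window outside the trace")
  v <- mean(trace[sel])
  structure(abs(v), signed = v)
}

#' Mono-exponential decay fit
#'
#' Least-squares fit of `A * exp(-(t - t0)/tau) + C` to the trace from
#' `fit_start` onward (t0 = `fit_start`). Initial values come from a
#' log-linear regression; fitting uses Levenberg-Marquardt.
#'
#' @param trace numeric trace
#' @param time time base, s
#' @param fit_start start of the decay fit, s
#' @param fit_end optional end of the fit window, s
#' @return list of class `monoexp_fit`: `amplitude` (signed, at `fit_start`),
#'   `tau` (decay constant, ms), `offset`, `fitted` residual diagnostics
#' @export
fit_monoexp <- function(trace, time, fit_start, fit_end = max(time)) {
  sel <- time >= fit_start & time <= fit_end
  if (sum(sel) < 10) stop("too few samples in the fit window")
  tt <- time[sel] - fit_start
  yy <- trace[sel]
  head_m <- mean(yy[seq_len(max(3L, round(length(yy) * 0.05)))])
  tail_m <- mean(yy[seq(round(length(yy) * 0.9), length(yy))])
  # baseline-subtracted transients decay toward zero: a segment ending
  # farther from zero than it starts is not a decay
  if (abs(tail_m) > abs(head_m) || abs(head_m - tail_m) < 1e-12)
    stop("fit failed: segment does not decay")
  sgn <- sign(head_m - tail_m)
  if (sgn == 0) sgn <- 1
  # log-linear start values on the offset-subtracted magnitude
  z <- sgn * (yy - tail_m)
  pos <- z > max(z, na.rm = TRUE) * 1e-3
  if (sum(pos) < 5) stop("fit failed: segment does not decay")
  ll <- lm(log(z[pos]) ~ tt[pos])
  tau0 <- -1 / coef(ll)[[2]]
  if (!is.finite(tau0) || tau0 <= 0)
    stop("fit failed: segment does not decay (rising or flat)")
  a0 <- sgn * exp(coef(ll)[[1]])
  fit <- minpack.lm::nlsLM(yy ~ A * exp(-tt / tau) + C,
                           start = list(A = a0, tau = tau0, C = tail_m),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  if (cf[["tau"]] <= 0) stop("fit failed: non-positive tau")
  structure(list(amplitude = cf[["A"]], tau = cf[["tau"]] * 1000,
                 offset = cf[["C"]],
                 rss = sum(stats::resid(fit)^2), n = sum(sel)),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("<monoexp_fit> A = %.3g, tau = %.3g ms, C = %.3g\n",
              x$amplitude, x$tau, x$offset))
  invisible(x)
}

#' Isolate the glutamate-transporter current by template subtraction
#'
#' The residual K+ current recorded under transporter block is scaled by
#' least squares to the tail of the mixed current (where the fast
#' transporter component has decayed) and subtracted, leaving the pure
#' transporter current.
#'
#' @param trace mixed current trace, pA
#' @param template residual K+ template recorded under transporter block
#' @param time time base, s
#' @param tail_start start of the tail matching window, s (typically last
#'   stimulus + 100 ms)
#' @param tail_end end of the window, s (default trace end)
#' @return list of class `iglut_isolation`: `iglut` (trace), `scale`
#' @export
isolate_iglut <- function(trace, template, time, tail_start,
                          tail_end = max(time)) {
  stopifnot(length(trace) == length(template), length(trace) == length(time))
  sel <- time >= tail_start & time <= tail_end
  energy <- sum(template[sel]^2)
  if (energy <= .Machine$double.eps * sum(sel))
    stop("template has no energy in the tail window")
  scale <- sum(trace[sel] * template[sel]) / energy
  structure(list(iglut = trace - scale * template, scale = scale),
            class = "iglut_isolation")
}

#' Amplitude and decay-time ratios of a current decomposition
#'
#' @param amp1,amp5 component amplitudes (pA) after one and five stimuli
#' @param tau1,tau5 decay constants (ms) after one and five stimuli
#' @return list of class `decomposition_ratios` with `amp_ratio_5_1`,
#'   `tau_ratio_5_1` and the reversed orientations `amp_ratio_1_5`,
#'   `tau_ratio_1_5` (both labelled explicitly)
#' @export
decomposition_ratios <- function(amp1, amp5, tau1, tau5) {
  stopifnot(tau1 > 0, tau5 > 0)
  out <- list(amp_ratio_5_1 = amp5 / amp1, tau_ratio_5_1 = tau5 / tau1,
              amp_ratio_1_5 = amp1 / amp5, tau_ratio_1_5 = tau1 / tau5)
  if (any(!is.finite(unlist(out)))) stop("non-finite ratio")
  structure(out, class = "decomposition_ratios")
}

#' Decompose synaptic sweeps into I_K and I_GluT components
#'
#' End-to-end decomposition of a [gen_synaptic_sweeps()]-style sweep set:
#' isolates the fifth response by burst subtraction, reads I_K amplitudes
#' 200 ms after the relevant stimulus, fits mono-exponential decays from
#' that point, and (when a transporter-block sweep is present) isolates
#' I_GluT by template subtraction.
#'
#' @param sweeps a [sweep_set] with sweeps `s1`, `s4`, `s5` and optionally
#'   `tboa`
#' @param tail_offset tail-window start after the last stimulus for template
#'   scaling, s
#' @return list of class `current_decomposition`: per-train I_K amplitude
#'   and tau, I_GluT amplitude and tau, and the `ratios`
#' @export
decompose_currents <- function(sweeps, tail_offset = 0.1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  t <- sweeps$time
  s1 <- sweeps$sweeps$s1; s4 <- sweeps$sweeps$s4; s5 <- sweeps$sweeps$s5
  st1 <- sweeps$stim_times$s1; st5 <- sweeps$stim_times$s5
  fifth <- isolate_fifth(s5, s4)
  ik1_amp <- ik_amplitude(s1, t, st1)
  ik5_amp <- ik_amplitude(fifth, t, max(st5))
  f1 <- fit_monoexp(s1, t, max(st1) + 0.2)
  f5 <- fit_monoexp(fifth, t, max(st5) + 0.2)
  out <- list(ik = list(amp_1 = as.numeric(ik1_amp), amp_5 = as.numeric(ik5_amp),
                        tau_1 = f1$tau, tau_5 = f5$tau),
              ratios = list(ik = decomposition_ratios(
                as.numeric(ik1_amp), as.numeric(ik5_amp), f1$tau, f5$tau)))
  if (!is.null(sweeps$sweeps$tboa_s1)) {
    tmpl1 <- sweeps$sweeps$tboa_s1
    # residual template for the fifth response: burst subtraction applied
    # to the transporter-block sweeps, mirroring the signal path
    tmpl5 <- isolate_fifth(sweeps$sweeps$tboa_s5, sweeps$sweeps$tboa_s4)
    g1 <- isolate_iglut(s1, tmpl1, t, max(st1) + tail_offset)
    g5 <- isolate_iglut(fifth, tmpl5, t, max(st5) + tail_offset)
    # transporter-current amplitude = negative peak after the stimulus
    win1 <- t >= st1[1] & t <= st1[1] + 0.1
    win5 <- t >= max(st5) & t <= max(st5) + 0.1
    a1 <- -min(g1$iglut[win1]); a5 <- -min(g5$iglut[win5])
    # decay fit from just after the transporter-current peak
    pk1 <- t[win1][which.min(g1$iglut[win1])]
    pk5 <- t[win5][which.min(g5$iglut[win5])]
    gf1 <- fit_monoexp(g1$iglut, t, pk1 + 0.002, max(st1) + 0.12)
    gf5 <- fit_monoexp(g5$iglut, t, pk5 + 0.002, max(st5) + 0.12)
    out$iglut <- list(amp_1 = a1, amp_5 = a5, tau_1 = gf1$tau, tau_5 = gf5$tau,
                      scale_1 = g1$scale, scale_5 = g5$scale)
    out$ratios$iglut <- decomposition_ratios(a1, a5, gf1$tau, gf5$tau)
  }
  structure(out, class = "current_decomposition")
}

#' LTP magnitude from an fEPSP amplitude timecourse
#'
#' Mean amplitude in the post window (default 50-60 min after HFS) as a
#' percentage of the mean baseline amplitude. Requires at least
#' `min_baseline` minutes of baseline whose coefficient of variation does
#' not exceed `max_baseline_cv`.
#'
#' @param tc a [fepsp_timecourse]
#' @param baseline_window minutes relative to HFS, default c(-15, 0)
#' @param post_window minutes after HFS, default c(50, 60)
#' @param min_baseline minimal baseline span, min
#' @param max_baseline_cv baseline stability criterion
#' @return LTP magnitude, % of baseline
#' @export
ltp_magnitude <- function(tc, baseline_window = c(-15, 0),
                          post_window = c(50, 60), min_baseline = 15,
                          max_baseline_cv = 0.2) {
  stopifnot(inherits(tc, "fepsp_timecourse"))
  bsel <- tc$time_min >= baseline_window[1] & tc$time_min <= 0
  if (diff(range(tc$time_min[bsel])) < min_baseline - 1e-9)
    stop(sprintf("baseline shorter than %g min", min_baseline))
  b <- tc$amplitude[bsel]
  if (sd(b) / mean(b) > max_baseline_cv)
    stop("baseline unstable (CV exceeds the stability criterion)")
  psel <- tc$time_min >= post_window[1] & tc$time_min <= post_window[2]
  if (!any(psel)) stop("no samples in the post-HFS window")
  100 * mean(tc$amplitude[psel]) / mean(b)
}
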