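# Group-level statistics and pipeline orchestration.

#' Two-sample t-test (equal variance by default)
#'
#' @param a,b numeric samples
#' @param welch use the Welch (unequal-variance) variant
#' @return list: `t`, `p` (two-tailed), `df`
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(c(a, b)) == 0) {
    # all values identical: no evidence of a difference
    return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
  }
  if (sd(a) == 0 && sd(b) == 0)
    stop("degenerate samples: both groups have zero variance")
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with tie correction; exact p-values for small
#' tie-free samples, normal approximation above `exact_max`.
#'
#' @param a,b numeric samples
#' @param exact_max maximal group size for the exact null distribution
#' @return list: `U` (number of (a, b) pairs with a > b, ties counted 1/2),
#'   `p` (two-sided)
#' @export
mann_whitney <- function(a, b, exact_max = 50) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Group summary table
#'
#' @param values named list: group label -> numeric per-cell/per-event values
#' @param metric metric name recorded in the table
#' @return data.frame: group, n, mean, sem, median
#' @export
group_table <- function(values, metric = "metric") {
  rows <- lapply(names(values), function(g) {
    v <- values[[g]]
    data.frame(metric = metric, group = g, n = length(v),
               mean = mean(v), sem = sd(v) / sqrt(length(v)),
               median = median(v))
  })
  do.call(rbind, rows)
}

#' Default pipeline configuration
#'
#' Problem sizes are deliberately modest so the demo completes in minutes on
#' one CPU; every stage still runs end to end.
#'
#' @param seed master seed; per-stage seeds are derived from it
#' @return config list for [run_pipeline()]
#' @export
default_config <- function(seed = 1) {
  list(seed = seed,
       groups = c("adult", "old"),
       n_stacks = 2, n_movies = 2, n_ephys = 3, n_ltp = 3, n_fields = 3)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates synthetic inputs per group, runs every analysis stage
#' (morphometry, volume fraction, calcium events, input resistance, current
#' decomposition, LTP, soma density, coupling), applies the group statistics
#' and writes per-figure CSV tables plus a provenance record.
#'
#' @param config list from [default_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, the list of result tables
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("astro")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed0 <- config$seed
  res <- list()
  per_group <- list()
  for (g in config$groups) {
    gi <- match(g, config$groups)
    morpho <- vf <- numeric(0)
    for (i in seq_len(config$n_stacks)) {
      sg <- gen_astrocyte_stack(astrocyte_preset(g), seed = seed0 + 100 * gi + i)
      m <- tryCatch(analyze_stack(sg$stack), error = function(e) NULL)
      if (!is.null(m)) morpho <- c(morpho, m$summary$mean_branch_length)
      vf <- c(vf, estimate_vf(sg$stack)$vf_cell)
    }
    dur <- are <- numeric(0)
    for (i in seq_len(config$n_movies)) {
      mv <- gen_ca_movie(ca_movie_preset(g), seed = seed0 + 200 * gi + i)
      ev <- detect_ca_events(mv$movie)
      dur <- c(dur, ev$duration); are <- c(are, ev$area)
    }
    ri <- vapply(seq_len(config$n_ephys), function(i) {
      sw <- gen_vclamp_sweeps(ephys_preset(g), protocol_mv = -85,
                              seed = seed0 + 300 * gi + i)
      input_resistance(sw$sweeps)
    }, numeric(1))
    tau_ratio <- vapply(seq_len(config$n_ephys), function(i) {
      sw <- gen_synaptic_sweeps(ephys_preset(g), seed = seed0 + 400 * gi + i)
      decompose_currents(sw$sweeps)$ratios$ik$tau_ratio_5_1
    }, numeric(1))
    ltp <- vapply(seq_len(config$n_ltp), function(i) {
      tc <- gen_fepsp_timecourse(ltp_preset(g), seed = seed0 + 500 * gi + i)
      ltp_magnitude(tc$timecourse)
    }, numeric(1))
    dens <- vapply(seq_len(config$n_fields), function(i) {
      fl <- gen_sr101_field(tissue_preset(g)$density, seed = seed0 + 600 * gi + i)
      count_somata(fl$image)$density
    }, numeric(1))
    coup <- count_coupled(gen_coupling_image(tissue_preset(g)$n_coupled,
                                             seed = seed0 + 700 * gi)$image)
    per_group[[g]] <- list(branch_length = morpho, vf = vf, duration = dur,
                           area = are, r_input = ri, tau_ratio = tau_ratio,
                           ltp = ltp, density = dens, coupled = coup)
  }
  metrics <- c("branch_length", "vf", "duration", "area", "r_input",
               "tau_ratio", "ltp", "density")
  tables <- lapply(metrics, function(m)
    group_table(lapply(per_group, `[[`, m), metric = m))
  summary_tab <- do.call(rbind, tables)
  stats_tab <- do.call(rbind, lapply(metrics, function(m) {
    a <- per_group[[config$groups[1]]][[m]]
    b <- per_group[[config$groups[2]]][[m]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    if (m %in% c("duration", "area")) {
      mw <- mann_whitney(a, b)
      data.frame(metric = m, test = "mann-whitney", statistic = mw$U, p = mw$p)
    } else {
      tt <- two_sample_t(a, b)
      data.frame(metric = m, test = "t", statistic = tt$t, p = tt$p)
    }
  }))
  write.csv(summary_tab, file.path(out_dir, "group_summary.csv"),
            row.names = FALSE)
  write.csv(stats_tab, file.path(out_dir, "group_tests.csv"),
            row.names = FALSE)
  coupling_tab <- data.frame(group = config$groups,
                             coupled = vapply(per_group, `[[`, 0, "coupled"))
  write.csv(coupling_tab, file.path(out_dir, "coupling.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed0, config = config[setdiff(names(config), "seed")],
         package_version = as.character(utils::packageVersion("astroage")),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary_tab, tests = stats_tab,
                 coupling = coupling_tab, per_group = per_group,
                 out_dir = out_dir))
}

#' Segment a raw stack and run the morphometry chain
#'
#' Convenience wrapper: photon calibration, tubular enhancement, hysteresis
#' binarization (1 and 3 noise sds), pruning below 100 voxels, soma
#' detection, branch-graph extraction, Sholl profile and summary.
#'
#' @param stack a raw [image_stack]
#' @param cal optional [pmt_calibration] (estimated if missing)
#' @param low_k,high_k hysteresis thresholds in noise sds
#' @param min_voxels pruning threshold
#' @return list: `mask`, `soma`, `graph`, `sholl`, `summary`
#' @export
analyze_stack <- function(stack, cal = NULL, low_k = 1, high_k = 3,
                          min_voxels = 100) {
  if (is.null(cal)) {
    gain <- tryCatch(estimate_pmt_gain_offset(stack)$gain,
                     error = function(e) 1)
    # offset from a signal-free region: under read noise the variance-mean
    # x-intercept is displaced by -read_sd^2/gain, which would shift the
    # whole photon scale and defeat the sigma-relative thresholds
    cal <- pmt_calibration(gain, estimate_offset_background(stack))
  }
  photons <- to_photon_counts(stack, cal)
  # noise sd from the raw stack (clipping at zero would deflate a MAD taken
  # on the calibrated background), rescaled to photon units
  sigma <- estimate_noise_sigma(stack) / cal$gain
  enh <- enhance_tubular(photons)
  mask <- prune_small(binarize_hysteresis(enh, sigma, low_k, high_k),
                      min_voxels)
  soma <- find_soma(photons)
  graph <- extract_branch_graph(mask, soma)
  profile <- sholl_3d(graph)
  list(mask = mask, soma = soma, graph = graph, sholl = profile,
       summary = summarize_morphometry(graph, profile, mask))
}
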