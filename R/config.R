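#' Default session configuration
#'
#' Every tunable constant of the pipeline lives here, with defaults equal to
#' the published analysis settings; later modules read their constants from
#' this list and nowhere else. Override any entry via `...`.
#'
#' Key groups:
#' \describe{
#'   \item{timing}{`sample_rate` 500 Hz; adaptation 60,000 ms on the first
#'     trial of a block, 6,000 ms otherwise; ISI 500 ms; target 1,000 ms;
#'     `response_ms` 2,000 ms of response screen separating trials (not part
#'     of any analysis period).}
#'   \item{schedule}{4 blocks of 43 trials; category proportions 65%
#'     positions of interest (split equally between top-left and
#'     bottom-right), 15% other positions, 20% catch.}
#'   \item{preprocess}{blink padding 200 ms each side; partial-blink
#'     derivative threshold 20 a.u./sample; session exclusion when more than
#'     45% of pupil samples are interpolated; 10 Hz low-pass cutoff.}
#'   \item{microsaccades}{6 candidate velocity peaks per second; PCA
#'     components kept above 5% of the largest eigenvalue; K-means with K=2
#'     and 10 restarts; physiological filters 8 ms minimum duration,
#'     amplitude 10-120 arcmin, mean velocity 3-120 deg/s; main-sequence
#'     criterion r > 0.6.}
#'   \item{decode}{10 x 10-fold stratified CV; sparsity grid of 31
#'     log-spaced values on \[1, 1000\]; 20 balanced-resampling repeats.}
#'   \item{stats}{1,000 permutations; JZS Cauchy prior scale 0.707.}
#'   \item{staircase}{0.05 log-unit steps, stop at 15 reversals or 65
#'     trials, threshold = mean of reversals excluding the first two.}
#'   \item{simulation}{observer defaults for the synthetic generator; see
#'     [simulate_session()].}
#' }
#'
#' @param ... name = value overrides for any listed entry.
#' @return a named list of class `session_config`.
#' @export
session_config <- function(...) {
  cfg <- list(
    # timing (ms)
    sample_rate = 500,
    adapt_first_ms = 60000,
    adapt_ms = 6000,
    isi_ms = 500,
    target_ms = 1000,
    response_ms = 2000,
    # schedule
    n_blocks = 4L,
    trials_per_block = 43L,
    prop_interest = 0.65,
    prop_other = 0.15,
    prop_catch = 0.20,
    # preprocessing
    blink_pad_ms = 200,
    partial_blink_delta = 20,
    exclude_interp_frac = 0.45,
    lowpass_cutoff_hz = 10,
    lowpass_order = 4,
    # microsaccade detection
    peaks_per_second = 6,
    pca_keep_frac = 0.05,
    kmeans_restarts = 10,
    min_duration_ms = 8,
    amplitude_range_arcmin = c(10, 120),
    mean_velocity_range = c(3, 120),
    delimit_floor_degs = 3,
    delimit_peak_frac = 0.2,
    accel_window_ms = 12,
    main_sequence_r = 0.6,
    # features
    gaze_deviation_deg = 0.8,
    # decoding
    cv_folds = 10L,
    cv_repeats = 10L,
    c_grid = 10 ^ seq(0, 3, length.out = 31),
    balanced_repeats = 20L,
    # statistics
    n_permutations = 1000L,
    bf_cauchy_scale = sqrt(2) / 2,
    # staircase
    staircase_step = 0.05,
    staircase_max_reversals = 15L,
    staircase_max_trials = 65L,
    # synthetic observer defaults
    sim_base_rate = 1.2,          # microsaccades per second
    sim_ms_slope = 60,            # main-sequence slope, (deg/s)/deg
    sim_ms_slope_noise = 0.1,     # multiplicative sd on peak velocity
    sim_amp_logmean = log(30),    # planted amplitude, arcmin (lognormal)
    sim_amp_logsd = 0.2,
    sim_amp_range_arcmin = c(18, 80),
    sim_drift_sd_deg = 0.1,       # OU stationary sd of fixational drift
    sim_drift_tau_s = 1,          # OU time constant
    sim_pupil_base = 2000,        # a.u.
    sim_pupil_noise_sd = 30,      # a.u., AR(1) innovations scale
    sim_pupil_noise_ar = 0.995,
    sim_pupil_dilation = 60,      # a.u., trial-locked target response
    sim_pupil_coupling_scale = 40,# a.u. per unit latent visibility
    sim_blink_rate_per_min = 2,
    sim_blink_dur_ms = 150,
    sim_p_visible = 0.5,
    sim_p_yes_visible = 0.85,
    sim_p_yes_invisible = 0.12,
    sim_p_sure = 0.6
  )
  class(cfg) <- c("session_config", "list")
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Write a configuration to a flat key-value file
#'
#' One `key = value` line per entry; vector values are comma-separated.
#'
#' @param cfg a `session_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm) {
    val <- cfg[[nm]]
    paste0(nm, " = ", paste(formatC(val, format = "g", digits = 17),
                            collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' @param path path written by [write_config()].
#' @return a `session_config` with the file's entries applied over defaults.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cfg <- session_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(cfg)) stop("unknown configuration key: ", key)
    val <- as.numeric(strsplit(trimws(kv[2]), ",", fixed = TRUE)[[1]])
    if (is.integer(cfg[[key]])) val <- as.integer(val)
    cfg[[key]] <- val
  }
  cfg
}

#' Grating drift speed from temporal and spatial frequency
#'
#' The adaptor gratings drift at the ratio of the temporal modulation
#' frequency to the spatial frequency; e.g. a 0.83 Hz triangular-wave
#' fundamental on a 1.6 cycle/deg carrier drifts at 0.52 deg/s.
#'
#' @param temporal_hz temporal fundamental frequency, Hz (cycles/s).
#' @param spatial_cpd spatial frequency, cycles/deg.
#' @return drift speed in deg/s.
#' @export
drift_speed <- function(temporal_hz, spatial_cpd) {
  stopifnot(spatial_cpd > 0)
  temporal_hz / spatial_cpd
}
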