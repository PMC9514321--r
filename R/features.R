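.feature_names <- c("sacrate_adapt", "sacrate_isi", "sacrate_target",
                    "pupil_adapt", "pupil_isi", "pupil_target")

#' Extract the six decoding features of one trial
#'
#' Microsaccade rate (events/s) and mean z-scored pupil size over each of
#' the adaptation, ISI and target periods, plus the summed blink-event
#' overlap with the trial's three periods (seconds).
#'
#' @param trial one row of a `trial_schedule`.
#' @param saccades microsaccade table from [detect_microsaccades()].
#' @param clean z-scored `clean_pupil` from [preprocess_pupil()].
#' @param blinks blink events (defaults to those attached to `clean`).
#' @return one-row data.frame with the six features and `blink_total`.
#' @export
extract_features <- function(trial, saccades, clean,
                             blinks = clean$blinks) {
  per <- trial_periods(trial)
  rates <- vapply(per, function(b) saccade_rate(saccades, b), numeric(1))
  pupils <- vapply(per, function(b) {
    idx <- period_idx(b[1], b[2], clean$sample_rate)
    mean(clean$trace[idx])
  }, numeric(1))
  span <- c(trial$adapt_on, trial$target_off)
  blink_total <- 0
  if (!is.null(blinks) && nrow(blinks)) {
    ov <- pmin(blinks$offset, span[2]) - pmax(blinks$onset, span[1])
    blink_total <- sum(pmax(0, ov)) / 1000
  }
  out <- data.frame(as.list(setNames(c(rates, pupils), .feature_names)))
  out$blink_total <- blink_total
  out
}

#' Flag trials whose gaze strays from fixation
#'
#' TRUE when any sample inside the trial's adaptation, ISI or target period
#' has a binocular-mean gaze more than `threshold` degrees from the fixation
#' point at screen center, with gaps in the gaze estimated by linear
#' interpolation first.
#'
#' @param rec an [eye_recording()].
#' @param trial one row of a `trial_schedule`.
#' @param threshold deviation threshold in deg (default 0.8).
#' @param gaze optional precomputed interpolated gaze from
#'   [interpolated_gaze()] (computed on the fly otherwise).
#' @return logical flag.
#' @export
flag_gaze_deviation <- function(rec, trial, threshold = 0.8, gaze = NULL) {
  if (is.null(gaze)) gaze <- interpolated_gaze(rec)
  per <- trial_periods(trial)
  idx <- unlist(lapply(per, function(b) {
    period_idx(b[1], b[2], rec$sample_rate)
  }))
  d <- sqrt(gaze$x[idx]^2 + gaze$y[idx]^2)
  any(d > threshold, na.rm = TRUE)
}

#' Binocular-mean gaze with gaps linearly interpolated
#'
#' @param rec an [eye_recording()].
#' @return list with `x`, `y` in deg.
#' @export
interpolated_gaze <- function(rec) {
  interp <- function(v) {
    ok <- which(!is.na(v))
    if (length(ok) == 0) return(v)
    if (length(ok) == length(v)) return(v)
    approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  x <- interp(rowMeans(cbind(rec$lx, rec$rx), na.rm = TRUE))
  y <- interp(rowMeans(cbind(rec$ly, rec$ry), na.rm = TRUE))
  x[is.nan(x)] <- NA; y[is.nan(y)] <- NA
  list(x = interp(x), y = interp(y))
}

#' Build the per-trial feature table of a session
#'
#' One row per scheduled trial (catch trials included), with the six
#' decoding features, the behavioral labels, the 0.8-deg gaze-deviation
#' flag, and total blink time.
#'
#' @param rec an [eye_recording()].
#' @param responses the schedule with `decision`/`confidence` columns (as
#'   returned in [simulate_session()]'s `responses`).
#' @param clean z-scored `clean_pupil`.
#' @param saccades microsaccade table.
#' @param cfg a [session_config()].
#' @return data.frame: `block`, `trial`, `condition`, `is_interest`,
#'   `is_catch`, the six features, `decision`, `confidence`,
#'   `gaze_deviation_flag`, `blink_total`.
#' @export
build_features <- function(rec, responses, clean, saccades,
                           cfg = session_config()) {
  gaze <- interpolated_gaze(rec)
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    tr <- responses[i, ]
    f <- extract_features(tr, saccades, clean)
    f$gaze_deviation_flag <- flag_gaze_deviation(rec, tr,
                                                 cfg$gaze_deviation_deg,
                                                 gaze = gaze)
    f
  })
  feats <- do.call(rbind, rows)
  out <- cbind(responses[, c("block", "trial", "condition", "is_interest",
                             "is_catch")],
               feats[, .feature_names],
               decision = responses$decision,
               confidence = responses$confidence,
               gaze_deviation_flag = feats$gaze_deviation_flag,
               blink_total = feats$blink_total)
  stopifnot(all(is.finite(as.matrix(out[, .feature_names]))))
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as CSV
#' @param features feature table from [build_features()].
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$gaze_deviation_flag <- as.logical(df$gaze_deviation_flag)
  df$is_interest <- as.logical(df$is_interest)
  df$is_catch <- as.logical(df$is_catch)
  df
}

#' Process one session end to end into its feature table
#'
#' Pupil preprocessing, microsaccade detection and feature extraction in
#' one call; the standard entry point after [simulate_session()] or
#' [read_recording()].
#'
#' @param rec an [eye_recording()].
#' @param responses schedule with behavioral responses.
#' @param seed seed for the clustering step.
#' @param cfg a [session_config()].
#' @return list with `features`, `saccades`, `clean`, `blinks`, `qc`
#'   (main-sequence result plus the pupil exclusion flag).
#' @export
process_session <- function(rec, responses, seed = 1L,
                            cfg = session_config()) {
  clean <- preprocess_pupil(rec, responses, cfg)
  det <- detect_microsaccades(rec, blinks = clean$blinks, seed = seed,
                              cfg = cfg)
  feats <- build_features(rec, responses, clean, det$saccades, cfg)
  qc <- main_sequence_qc(det$saccades, cfg)
  qc$pupil_excluded <- clean$excluded
  qc$cluster_failed <- det$qc_failed
  list(features = feats, saccades = det$saccades, clean = clean,
       blinks = clean$blinks, qc = qc)
}

#' Simulate and process a cohort of participants
#'
#' Convenience wrapper for power/calibration studies: draws one session per
#' participant (fresh schedule order and observer noise per participant,
#' seeds derived from `seed`) and runs [process_session()] on each.
#'
#' @param n_participants number of observers.
#' @param observer_fn function(participant index) returning
#'   [observer_params()]; defaults to a zero-coupling observer.
#' @param seed master integer seed.
#' @param n_blocks,trials_per_block schedule size (defaults from `cfg`).
#' @param cfg a [session_config()].
#' @return list of per-participant lists: `features`, `truth`, `qc`.
#' @export
simulate_participants <- function(n_participants,
                                  observer_fn = function(i) observer_params(),
                                  seed = 1L,
                                  n_blocks = NULL, trials_per_block = NULL,
                                  cfg = session_config()) {
  n_blocks <- n_blocks %||% cfg$n_blocks
  trials_per_block <- trials_per_block %||% cfg$trials_per_block
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 3 * n_participants),
                  ncol = 3)
  lapply(seq_len(n_participants), function(i) {
    sched <- make_schedule(n_blocks, trials_per_block, seed = seeds[i, 1],
                           cfg = cfg)
    sim <- simulate_session(sched, observer_fn(i), seed = seeds[i, 2],
                            cfg = cfg)
    proc <- process_session(sim$recording, sim$responses,
                            seed = seeds[i, 3], cfg = cfg)
    list(features = proc$features, truth = sim$truth, qc = proc$qc)
  })
}
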