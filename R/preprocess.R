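#' Detect full and partial blink events
#'
#' Full blinks are maximal runs where the pupil is missing in both eyes;
#' partial blinks (pupil never fully occluded) are samples where the
#' combined available pupil signal changes by more than
#' `cfg$partial_blink_delta` arbitrary units per sample. Both are padded by
#' 200 ms on each side of the detected core, and overlapping events are
#' merged; a merged event is "full" if any constituent was.
#'
#' @param rec an [eye_recording()].
#' @param cfg a [session_config()].
#' @return data.frame with columns `onset`, `offset` (ms, half-open,
#'   clamped to the recording) and `kind` ("full"/"partial"), ordered by
#'   onset.
#' @export
detect_blinks <- function(rec, cfg = session_config()) {
  n <- length(rec$time)
  step <- 1000 / rec$sample_rate
  pad <- cfg$blink_pad_ms
  runs_of <- function(flag) {
    if (!any(flag)) return(data.frame(onset = numeric(0), offset = numeric(0)))
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(onset = rec$time[starts[keep]],
               offset = rec$time[ends[keep]] + step)
  }
  full <- runs_of(!rec$lvalid & !rec$rvalid)
  comb <- combined_pupil_raw(rec)
  d <- c(0, abs(diff(comb)))
  d[is.na(d)] <- 0
  part <- runs_of(d > cfg$partial_blink_delta)
  ev <- rbind(
    if (nrow(full)) data.frame(full, kind = "full"),
    if (nrow(part)) data.frame(part, kind = "partial"))
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      kind = character(0)))
  }
  ev$onset <- pmax(0, ev$onset - pad)
  ev$offset <- pmin(rec$time[n] + step, ev$offset + pad)
  merge_blink_events(ev)
}

#' Merge overlapping blink events
#'
#' Overlapping or touching events collapse into one spanning event whose
#' kind is "full" if any constituent is full. Idempotent: merging a merged
#' list returns it unchanged.
#'
#' @param events data.frame with `onset`, `offset`, `kind`.
#' @return merged data.frame, ordered by onset.
#' @export
merge_blink_events <- function(events) {
  if (nrow(events) == 0) return(events)
  events <- events[order(events$onset), , drop = FALSE]
  out_on <- events$onset[1]; out_off <- events$offset[1]
  out_kind <- events$kind[1]
  res <- list()
  for (i in seq_len(nrow(events))[-1]) {
    if (events$onset[i] <= out_off) {
      out_off <- max(out_off, events$offset[i])
      if (events$kind[i] == "full") out_kind <- "full"
    } else {
      res[[length(res) + 1]] <- data.frame(onset = out_on, offset = out_off,
                                           kind = out_kind)
      out_on <- events$onset[i]; out_off <- events$offset[i]
      out_kind <- events$kind[i]
    }
  }
  res[[length(res) + 1]] <- data.frame(onset = out_on, offset = out_off,
                                       kind = out_kind)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# per-sample binocular pupil before any interpolation: mean where both eyes
# available, the single available eye otherwise, NA where neither
combined_pupil_raw <- function(rec) {
  lp <- ifelse(rec$lvalid, rec$lp, NA_real_)
  rp <- ifelse(rec$rvalid, rec$rp, NA_real_)
  both <- !is.na(lp) & !is.na(rp)
  comb <- ifelse(both, (lp + rp) / 2, ifelse(!is.na(lp), lp, rp))
  comb
}

#' Combine the two eyes' pupil traces and interpolate gaps
#'
#' Per sample: the mean of the two eyes where both are available, the single
#' available eye otherwise; runs with neither eye available, and all blink
#' event spans, are linearly interpolated between the nearest valid flanking
#' samples (leading/trailing gaps take the nearest valid value). Every
#' filled or blink-spanned sample is recorded in `interpolated_mask`; the
#' session is flagged `excluded` when the interpolated fraction exceeds 45%,
#' after which the pupil estimate is considered unreliable.
#'
#' @param rec an [eye_recording()].
#' @param blinks events from [detect_blinks()].
#' @param cfg a [session_config()].
#' @return an object of class `clean_pupil`: list with `trace` (a.u., later
#'   z-units), `interpolated_mask`, `interpolated_fraction`, `excluded`,
#'   `blinks`, `sample_rate`, `time`.
#' @export
combine_pupil <- function(rec, blinks, cfg = session_config()) {
  comb <- combined_pupil_raw(rec)
  n <- length(comb)
  mask <- is.na(comb)
  if (nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      mask[period_idx(blinks$onset[i], blinks$offset[i], rec$sample_rate)] <-
        TRUE
    }
  }
  good <- which(!mask & !is.na(comb))
  if (length(good) == 0) {
    stop("unrecoverable signal: no valid pupil samples in recording")
  }
  trace <- comb
  trace[mask] <- NA
  if (any(mask)) {
    trace <- approx(x = good, y = comb[good], xout = seq_len(n),
                    method = "linear", rule = 2)$y
  }
  structure(list(trace = trace,
                 interpolated_mask = mask,
                 interpolated_fraction = mean(mask),
                 excluded = mean(mask) > cfg$exclude_interp_frac,
                 blinks = blinks,
                 sample_rate = rec$sample_rate,
                 time = rec$time),
            class = "clean_pupil")
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, 4th-order design at
#' a 10 Hz cutoff by default — the standard choice for pupillometry, where
#' phase lag would misalign the trace against trial events.
#'
#' @param trace finite numeric vector sampled at `sample_rate`.
#' @param cutoff_hz cutoff frequency (default 10 Hz).
#' @param sample_rate sampling rate in Hz (default 500).
#' @param order filter order of the design (default 4).
#' @return filtered trace, same length.
#' @export
lowpass <- function(trace, cutoff_hz = 10, sample_rate = 500, order = 4) {
  if (any(!is.finite(trace))) stop("trace must be finite for filtering")
  n <- length(trace)
  if (n < 6 * (order + 1)) {
    stop("trace shorter than filter warm-up (need at least ",
         6 * (order + 1), " samples)")
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  # odd (reflected) extension at both ends suppresses the start-up
  # transient of the forward-backward pass; without it even a constant
  # trace is distorted at the edges
  pad <- min(n - 1, as.integer(10 * sample_rate / cutoff_hz))
  ext <- c(2 * trace[1] - trace[(pad + 1):2],
           trace,
           2 * trace[n] - trace[(n - 1):(n - pad)])
  out <- as.numeric(signal::filtfilt(bf, ext))
  out[(pad + 1):(pad + n)]
}

#' z-transform the pupil trace over the analysis periods
#'
#' The mean and SD are computed over the union of all adaptation, ISI and
#' target samples of the session (response screens excluded), and the whole
#' trace is replaced by `(x - mean) / sd`. Samples outside the period union
#' therefore need not have zero mean.
#'
#' @param clean a `clean_pupil`.
#' @param schedule the session's `trial_schedule`.
#' @return the `clean_pupil` with `trace` in z-units and added `z_mean`,
#'   `z_sd` fields.
#' @export
zscore_pupil <- function(clean, schedule) {
  idx <- schedule_period_idx(schedule, clean$sample_rate)
  idx <- idx[idx <= length(clean$trace)]
  if (length(idx) == 0) stop("schedule periods lie outside the recording")
  m <- mean(clean$trace[idx])
  s <- sd(clean$trace[idx])
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: zero pupil variance over the analysis periods")
  }
  clean$trace <- (clean$trace - m) / s
  clean$z_mean <- m
  clean$z_sd <- s
  clean
}

#' Full pupil preprocessing chain
#'
#' [detect_blinks()] then [combine_pupil()], [lowpass()] and
#' [zscore_pupil()], in the published order.
#'
#' @inheritParams combine_pupil
#' @param schedule the session's `trial_schedule`.
#' @return a z-scored `clean_pupil` (with its blink table attached).
#' @export
preprocess_pupil <- function(rec, schedule, cfg = session_config()) {
  blinks <- detect_blinks(rec, cfg)
  clean <- combine_pupil(rec, blinks, cfg)
  clean$trace <- lowpass(clean$trace, cfg$lowpass_cutoff_hz,
                         rec$sample_rate, cfg$lowpass_order)
  zscore_pupil(clean, schedule)
}

#' Write / read a clean pupil trace as CSV
#'
#' Columns `time_ms`, `pupil`, `interpolated` (0/1); fraction/excluded are
#' recomputed on read.
#' @param clean a `clean_pupil`.
#' @param path file path.
#' @param cfg a [session_config()] (for the exclusion rule on read).
#' @return `path` (write) or a `clean_pupil` (read).
#' @export
write_clean_pupil <- function(clean, path) {
  df <- data.frame(time_ms = clean$time,
                   pupil = formatC(clean$trace, format = "g", digits = 17),
                   interpolated = as.integer(clean$interpolated_mask))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clean_pupil
#' @export
read_clean_pupil <- function(path, cfg = session_config()) {
  df <- read.csv(path)
  step <- if (nrow(df) > 1) df$time_ms[2] - df$time_ms[1] else 2
  structure(list(trace = df$pupil,
                 interpolated_mask = df$interpolated != 0,
                 interpolated_fraction = mean(df$interpolated != 0),
                 excluded = mean(df$interpolated != 0) >
                   cfg$exclude_interp_frac,
                 blinks = NULL,
                 sample_rate = 1000 / step,
                 time = df$time_ms),
            class = "clean_pupil")
}
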