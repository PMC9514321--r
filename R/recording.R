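#' Construct a binocular eye-tracking recording
#'
#' The central raw-data container: uniformly sampled (500 Hz) binocular gaze
#' and pupil traces with per-eye validity flags. Samples where an eye's data
#' are missing (blinks, tracking loss) carry `valid = FALSE` and `NA` in that
#' eye's channels; missingness is always encoded through the flag, never
#' through a sentinel value, so that filtering stages cannot be corrupted by
#' magic numbers.
#'
#' @param time numeric vector of sample times in ms, strictly increasing with
#'   a constant 2 ms step.
#' @param lx,ly,rx,ry gaze position per eye in degrees relative to fixation.
#' @param lp,rp pupil size per eye in arbitrary units; `NA` where missing.
#' @param lvalid,rvalid logical per-sample validity flags per eye.
#' @param sample_rate sampling rate in Hz; fixed at 500 for this apparatus.
#'
#' @return An object of class `eye_recording`: a list with the above fields.
#' @export
eye_recording <- function(time, lx, ly, rx, ry, lp, rp,
                          lvalid = !is.na(lp), rvalid = !is.na(rp),
                          sample_rate = 500) {
  n <- length(time)
  chans <- list(lx = lx, ly = ly, rx = rx, ry = ry, lp = lp, rp = rp,
                lvalid = lvalid, rvalid = rvalid)
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n) {
      stop("channel '", nm, "' has length ", length(chans[[nm]]),
           " but time has length ", n)
    }
  }
  rec <- structure(
    list(time = as.numeric(time),
         lx = as.numeric(lx), ly = as.numeric(ly),
         rx = as.numeric(rx), ry = as.numeric(ry),
         lp = as.numeric(lp), rp = as.numeric(rp),
         lvalid = as.logical(lvalid), rvalid = as.logical(rvalid),
         sample_rate = sample_rate),
    class = "eye_recording")
  validate_recording(rec)
  rec
}

#' Validate an eye_recording's invariants
#'
#' Checks constant 2 ms sampling, equal channel lengths, and gaze finiteness
#' wherever the validity flag is set. Called by the constructor and the
#' reader; exported so pipelines can re-assert after manual edits.
#'
#' @param rec an `eye_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eye_recording"))
  n <- length(rec$time)
  step <- 1000 / rec$sample_rate
  if (n > 1) {
    d <- diff(rec$time)
    bad <- which(abs(d - step) > 1e-6)
    if (length(bad)) {
      stop(sprintf(
        "nonuniform sampling: interval of %g ms (expected %g ms) at t = %g ms",
        d[bad[1]], step, rec$time[bad[1]]))
    }
  }
  for (eye in c("l", "r")) {
    v <- rec[[paste0(eye, "valid")]]
    gx <- rec[[paste0(eye, "x")]]
    gy <- rec[[paste0(eye, "y")]]
    if (any(v & (!is.finite(gx) | !is.finite(gy)))) {
      stop("non-finite gaze on samples flagged valid (eye '", eye, "')")
    }
  }
  invisible(rec)
}

#' Number of samples in a recording
#' @param x an `eye_recording`.
#' @param ... unused.
#' @export
length.eye_recording <- function(x) length(x$time)

#' @export
print.eye_recording <- function(x, ...) {
  n <- length(x$time)
  dur <- if (n) (x$time[n] - x$time[1] + 1000 / x$sample_rate) / 1000 else 0
  cat(sprintf("<eye_recording> %d samples @ %g Hz (%.1f s)\n",
              n, x$sample_rate, dur))
  cat(sprintf("  pupil missing: left %.1f%%, right %.1f%%\n",
              100 * mean(!x$lvalid), 100 * mean(!x$rvalid)))
  invisible(x)
}

.rec_columns <- c("time_ms", "lx", "ly", "rx", "ry", "lp", "rp",
                  "lvalid", "rvalid")

#' Read a sample-level recording CSV
#'
#' The documented CSV dialect: comma-separated, '.' decimal, header
#' `time_ms, lx, ly, rx, ry, lp, rp, lvalid, rvalid`. Empty pupil or gaze
#' cells become `NA` with the eye's validity flag cleared; validity columns
#' hold 0/1.
#'
#' @param path path to the CSV file.
#' @return an `eye_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .rec_columns)) {
    stop("recording format error: expected columns ",
         paste(.rec_columns, collapse = ", "), " but found ",
         paste(names(df), collapse = ", "))
  }
  eye_recording(time = df$time_ms,
                lx = df$lx, ly = df$ly, rx = df$rx, ry = df$ry,
                lp = df$lp, rp = df$rp,
                lvalid = df$lvalid != 0, rvalid = df$rvalid != 0)
}

#' Write a recording to the sample CSV format
#'
#' Inverse of [read_recording()]: `read_recording(write_recording(rec, p))`
#' reproduces `rec` exactly on all fields. Missing values are written as
#' empty cells. Numbers are printed at full precision (17 significant
#' digits) so the round trip is bit-faithful.
#'
#' @param rec an `eye_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
  df <- data.frame(time_ms = fmt(rec$time),
                   lx = fmt(rec$lx), ly = fmt(rec$ly),
                   rx = fmt(rec$rx), ry = fmt(rec$ry),
                   lp = fmt(rec$lp), rp = fmt(rec$rp),
                   lvalid = as.integer(rec$lvalid),
                   rvalid = as.integer(rec$rvalid),
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write recording to ", path)
  invisible(path)
}

#' Convert a time in ms to a 0-based sample index
#'
#' All period arithmetic in the package maps half-open time intervals
#' `[start, end)` in ms to half-open 0-based sample index intervals.
#'
#' @param t_ms time(s) in ms.
#' @param sample_rate sampling rate in Hz.
#' @return 0-based sample index (integer).
#' @export
ms_to_sample <- function(t_ms, sample_rate = 500) {
  as.integer(round(t_ms * sample_rate / 1000))
}

# 1-based R index range for a half-open [start, end) ms interval
period_idx <- function(start_ms, end_ms, sample_rate = 500) {
  i0 <- ms_to_sample(start_ms, sample_rate)
  i1 <- ms_to_sample(end_ms, sample_rate)
  if (i1 <= i0) return(integer(0))
  (i0 + 1L):i1
}
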