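#' Binocular eye speed and acceleration
#'
#' Horizontal and vertical velocities are estimated per eye with the 5-point
#' smoothed central difference standard for 500 Hz fixational-eye-movement
#' data: `v[n] = (x[n+2] + x[n+1] - x[n-1] - x[n-2]) / (6 dt)`. Speed is the
#' per-eye Euclidean velocity magnitude averaged across the eyes (the single
#' available eye, with a warning, when one eye is absent); acceleration is
#' the same operator applied to the speed trace. The two edge samples on
#' each side, and samples where neither eye has valid gaze, are `NA` and
#' excluded from candidate search downstream.
#'
#' @param rec an [eye_recording()].
#' @return list with `speed` (deg/s) and `accel` (deg/s^2), per sample.
#' @export
binocular_speed <- function(rec) {
  dt <- 1 / rec$sample_rate
  deriv5 <- function(x) {
    n <- length(x)
    v <- rep(NA_real_, n)
    if (n >= 5) {
      i <- 3:(n - 2)
      v[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    }
    v
  }
  eye_speed <- function(x, y) {
    vx <- deriv5(x); vy <- deriv5(y)
    sqrt(vx^2 + vy^2)
  }
  sl <- eye_speed(rec$lx, rec$ly)
  sr <- eye_speed(rec$rx, rec$ry)
  l_absent <- all(is.na(rec$lx)); r_absent <- all(is.na(rec$rx))
  if (l_absent && r_absent) stop("no gaze data in either eye")
  if (l_absent || r_absent) {
    warning("monocular recording: speed computed from a single eye")
    speed <- if (l_absent) sr else sl
  } else {
    both <- !is.na(sl) & !is.na(sr)
    speed <- ifelse(both, (sl + sr) / 2, ifelse(!is.na(sl), sl, sr))
  }
  list(speed = speed, accel = deriv5(speed))
}

#' Select microsaccade candidates as the highest velocity peaks
#'
#' The recording is tiled into consecutive non-overlapping 1 s windows from
#' t = 0; within each window the local speed maxima (sample strictly greater
#' than its left neighbor and at least its right neighbor — the first sample
#' of a plateau) are ranked and the six highest kept, deliberately
#' over-inclusive so that no true microsaccade is missed before clustering.
#' For each candidate the peak velocity and the initial/final acceleration
#' (signed extremum of the acceleration trace in the 12 ms before/after the
#' peak) are extracted, and z-transformed copies across the whole candidate
#' set are kept alongside the raw values.
#'
#' @param speed,accel traces from [binocular_speed()].
#' @param sample_rate Hz.
#' @param exclude optional logical mask of samples to exclude from the
#'   search (invalid spans, blink pads).
#' @param cfg a [session_config()] (`peaks_per_second`, `accel_window_ms`).
#' @return data.frame of candidates: `idx` (1-based sample), `peak_time`
#'   (ms), `peak_velocity`, `initial_accel`, `final_accel`, and z-copies
#'   `z_vel`, `z_ia`, `z_fa`.
#' @export
select_candidates <- function(speed, accel, sample_rate = 500,
                              exclude = NULL, cfg = session_config()) {
  n <- length(speed)
  if (n < 3) return(empty_candidates())
  s <- speed
  if (!is.null(exclude)) s[exclude] <- NA
  i <- 2:(n - 1)
  is_peak <- c(FALSE, !is.na(s[i]) & !is.na(s[i - 1]) & !is.na(s[i + 1]) &
                 s[i] > s[i - 1] & s[i] >= s[i + 1], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) == 0) return(empty_candidates())
  win <- (peaks - 1) %/% sample_rate
  keep <- unlist(lapply(split(peaks, win), function(p) {
    p[order(s[p], decreasing = TRUE)][seq_len(min(cfg$peaks_per_second,
                                                  length(p)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  w <- ms_to_sample(cfg$accel_window_ms, sample_rate)   # samples per window
  ext <- function(idx_from, idx_to) {
    vapply(seq_along(keep), function(k) {
      lo <- max(1, idx_from[k]); hi <- min(n, idx_to[k])
      if (hi < lo) return(0)
      a <- accel[lo:hi]
      a <- a[!is.na(a)]
      if (length(a) == 0) return(0)
      a[which.max(abs(a))]
    }, numeric(1))
  }
  ia <- ext(keep - w, keep - 1)
  fa <- ext(keep + 1, keep + w)
  zt <- function(x) {
    if (length(x) >= 2 && isTRUE(sd(x) > 0)) (x - mean(x)) / sd(x) else x * 0
  }
  data.frame(idx = keep,
             peak_time = (keep - 1) * 1000 / sample_rate,
             peak_velocity = s[keep],
             initial_accel = ia, final_accel = fa,
             z_vel = zt(s[keep]), z_ia = zt(ia), z_fa = zt(fa))
}

empty_candidates <- function() {
  data.frame(idx = integer(0), peak_time = numeric(0),
             peak_velocity = numeric(0), initial_accel = numeric(0),
             final_accel = numeric(0), z_vel = numeric(0),
             z_ia = numeric(0), z_fa = numeric(0))
}

#' Separate microsaccades from noise by unsupervised clustering
#'
#' PCA on the three z-transformed candidate features; components with an
#' eigenvalue above 5% of the largest are retained; K-means (K = 2, fixed
#' seed, multiple restarts) on the retained scores; the cluster with the
#' larger mean raw peak velocity is labeled "saccade" (ties break toward the
#' smaller cluster, since saccades are rarer than noise).
#'
#' @param cands candidates from [select_candidates()].
#' @param seed integer seed for K-means.
#' @param cfg a [session_config()].
#' @return character vector of labels ("saccade"/"noise") with attribute
#'   `qc_failed`; on degenerate input (< 2 candidates or all-identical
#'   features) all labels are "noise" and `qc_failed` is `TRUE`.
#' @export
cluster_candidates <- function(cands, seed = 1L, cfg = session_config()) {
  fail <- function() {
    structure(rep("noise", nrow(cands)), qc_failed = TRUE)
  }
  if (nrow(cands) < 2) return(fail())
  Z <- as.matrix(cands[, c("z_vel", "z_ia", "z_fa")])
  if (all(apply(Z, 2, function(col) length(unique(col)) == 1))) return(fail())
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  kept <- which(ev > cfg$pca_keep_frac * max(ev))
  scores <- pc$x[, kept, drop = FALSE]
  if (nrow(unique(scores)) < 2) return(fail())
  set.seed(seed)
  km <- kmeans(scores, centers = 2, nstart = cfg$kmeans_restarts)
  mv <- tapply(cands$peak_velocity, km$cluster, mean)
  sizes <- table(km$cluster)
  sac_cluster <- if (abs(mv[["1"]] - mv[["2"]]) < 1e-12) {
    as.integer(names(which.min(sizes)))
  } else as.integer(names(which.max(mv)))
  structure(ifelse(km$cluster == sac_cluster, "saccade", "noise"),
            qc_failed = FALSE)
}

#' Delimit saccade-labeled candidates and apply physiological filters
#'
#' Each saccade-labeled velocity peak is extended backward and forward until
#' the speed drops below `max(3 deg/s, 20% of the peak)` or an invalid
#' sample is reached. Amplitude is the Euclidean displacement of the
#' binocular-mean gaze between onset and offset (arcmin); mean velocity is
#' amplitude over duration. Events failing any of duration >= 8 ms,
#' amplitude in [10, 120] arcmin, or mean velocity in [3, 120] deg/s are
#' discarded; overlapping survivors merge, keeping the higher peak.
#'
#' @param rec the [eye_recording()].
#' @param speed speed trace from [binocular_speed()].
#' @param cands candidates from [select_candidates()].
#' @param labels labels from [cluster_candidates()].
#' @param cfg a [session_config()].
#' @return data.frame of microsaccades: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `amplitude_arcmin`, `peak_velocity`, `mean_velocity`,
#'   `peak_time`.
#' @export
delimit_and_filter <- function(rec, speed, cands, labels,
                               cfg = session_config()) {
  sel <- which(labels == "saccade")
  n <- length(speed)
  step <- 1000 / rec$sample_rate
  gaze_x <- rowMeans(cbind(rec$lx, rec$rx), na.rm = TRUE)
  gaze_y <- rowMeans(cbind(rec$ly, rec$ry), na.rm = TRUE)
  out <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- cands$idx[sel[k]]
    thr <- max(cfg$delimit_floor_degs, cfg$delimit_peak_frac *
                 cands$peak_velocity[sel[k]])
    j0 <- i
    while (j0 > 1 && !is.na(speed[j0 - 1]) && speed[j0 - 1] >= thr) {
      j0 <- j0 - 1
    }
    j1 <- i
    while (j1 < n && !is.na(speed[j1 + 1]) && speed[j1 + 1] >= thr) {
      j1 <- j1 + 1
    }
    dur <- (j1 - j0 + 1) * step
    dx <- gaze_x[j1] - gaze_x[j0]
    dy <- gaze_y[j1] - gaze_y[j0]
    amp_arcmin <- 60 * sqrt(dx^2 + dy^2)
    mean_vel <- (amp_arcmin / 60) / (dur / 1000)
    out[[k]] <- data.frame(onset_ms = (j0 - 1) * step,
                           offset_ms = j1 * step,
                           duration_ms = dur,
                           amplitude_arcmin = amp_arcmin,
                           peak_velocity = cands$peak_velocity[sel[k]],
                           mean_velocity = mean_vel,
                           peak_time = cands$peak_time[sel[k]])
  }
  ms <- if (length(out)) do.call(rbind, out) else empty_saccades()
  ok <- is.finite(ms$amplitude_arcmin) &
    ms$duration_ms >= cfg$min_duration_ms &
    ms$amplitude_arcmin >= cfg$amplitude_range_arcmin[1] &
    ms$amplitude_arcmin <= cfg$amplitude_range_arcmin[2] &
    ms$mean_velocity >= cfg$mean_velocity_range[1] &
    ms$mean_velocity <= cfg$mean_velocity_range[2]
  ms <- ms[ok, , drop = FALSE]
  if (nrow(ms) > 1) {
    ms <- ms[order(ms$onset_ms), , drop = FALSE]
    keep <- rep(TRUE, nrow(ms))
    cur <- 1
    for (i in 2:nrow(ms)) {
      if (ms$onset_ms[i] < ms$offset_ms[cur]) {
        if (ms$peak_velocity[i] > ms$peak_velocity[cur]) {
          keep[cur] <- FALSE; cur <- i
        } else keep[i] <- FALSE
      } else cur <- i
    }
    ms <- ms[keep, , drop = FALSE]
  }
  rownames(ms) <- NULL
  ms
}

empty_saccades <- function() {
  data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
             duration_ms = numeric(0), amplitude_arcmin = numeric(0),
             peak_velocity = numeric(0), mean_velocity = numeric(0),
             peak_time = numeric(0))
}

#' Full microsaccade detection chain
#'
#' [binocular_speed()], candidate selection excluding invalid samples and
#' blink pads, [cluster_candidates()], [delimit_and_filter()].
#'
#' @param rec an [eye_recording()].
#' @param blinks optional blink events from [detect_blinks()] whose (already
#'   padded) spans are excluded from the candidate search.
#' @param seed integer seed for the clustering step.
#' @param cfg a [session_config()].
#' @return list with `saccades` (the filtered event table), `candidates`,
#'   `labels`, and `qc_failed`.
#' @export
detect_microsaccades <- function(rec, blinks = NULL, seed = 1L,
                                 cfg = session_config()) {
  sa <- binocular_speed(rec)
  excl <- is.na(sa$speed)
  if (!is.null(blinks) && nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      excl[period_idx(blinks$onset[i], blinks$offset[i], rec$sample_rate)] <-
        TRUE
    }
  }
  cands <- select_candidates(sa$speed, sa$accel, rec$sample_rate,
                             exclude = excl, cfg = cfg)
  labels <- cluster_candidates(cands, seed = seed, cfg = cfg)
  sacc <- if (isTRUE(attr(labels, "qc_failed"))) empty_saccades() else
    delimit_and_filter(rec, sa$speed, cands, labels, cfg)
  list(saccades = sacc, candidates = cands, labels = labels,
       qc_failed = isTRUE(attr(labels, "qc_failed")))
}

#' Main-sequence quality control
#'
#' Pearson correlation between peak velocity and amplitude over the detected
#' microsaccades; the session passes when r exceeds 0.6, the conventional
#' main-sequence criterion.
#'
#' @param saccades event table from [detect_microsaccades()].
#' @param cfg a [session_config()].
#' @return list with `r`, `pass`, `n`, and `indeterminate` (TRUE when fewer
#'   than 3 events are available, in which case `r` is `NA`).
#' @export
main_sequence_qc <- function(saccades, cfg = session_config()) {
  if (nrow(saccades) < 3) {
    return(list(r = NA_real_, pass = NA, n = nrow(saccades),
                indeterminate = TRUE))
  }
  r <- cor(saccades$peak_velocity, saccades$amplitude_arcmin)
  list(r = r, pass = r > cfg$main_sequence_r, n = nrow(saccades),
       indeterminate = FALSE)
}

#' Microsaccade rate over a period
#'
#' Number of detected microsaccades whose velocity peak falls in the
#' half-open period `[on, off)`, divided by the period duration.
#'
#' @param saccades event table.
#' @param period numeric `c(on, off)` in ms.
#' @return rate in events per second.
#' @export
saccade_rate <- function(saccades, period) {
  dur_s <- (period[2] - period[1]) / 1000
  if (dur_s <= 0) stop("zero-length period")
  cnt <- sum(saccades$peak_time >= period[1] & saccades$peak_time < period[2])
  cnt / dur_s
}

#' Write / read a microsaccade event table as CSV
#' @param saccades event table.
#' @param path file path.
#' @return `path` (write) or the event table (read).
#' @export
write_saccades <- function(saccades, path) {
  df <- saccades
  for (cl in names(df)) df[[cl]] <- formatC(df[[cl]], format = "g",
                                            digits = 15)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_saccades
#' @export
read_saccades <- function(path) {
  read.csv(path)
}
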