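# Shared fixtures, built once per test run and cached.
#
# fx_coupled(): a small (2 blocks x 12 trials) session from an observer with
# positive coupling on every feature, plus its processed outputs. Small
# enough to simulate in seconds, large enough for the detector and the
# decoders to have signal to work with.

fx_cache <- new.env(parent = emptyenv())

fx_coupled <- function() {
  if (is.null(fx_cache$coupled)) {
    sched <- make_schedule(2, 12, seed = 3)
    obs <- observer_params(coupling = c(0.8, 0.8, 0.8, 30, 30, 30))
    sim <- simulate_session(sched, obs, seed = 11)
    proc <- process_session(sim$recording, sim$responses, seed = 5)
    fx_cache$coupled <- list(schedule = sched, observer = obs, sim = sim,
                             proc = proc)
  }
  fx_cache$coupled
}

# 4 blocks x 20 trials gives 52 positions-of-interest trials, enough for
# 5-fold stratified CV with high probability under the default observer.
fx_decode_session <- function(coupling = c(0.8, 0.8, 0.8, 30, 30, 30),
                              seed = 21) {
  key <- paste0("dec_", paste(coupling, collapse = "_"), "_", seed)
  if (is.null(fx_cache[[key]])) {
    sched <- make_schedule(4, 20, seed = seed)
    sim <- simulate_session(sched, observer_params(coupling = coupling),
                            seed = seed + 1)
    proc <- process_session(sim$recording, sim$responses, seed = seed + 2)
    fx_cache[[key]] <- list(sim = sim, features = proc$features)
  }
  fx_cache[[key]]
}

# match planted and detected events by onset time within a tolerance (ms)
event_recall <- function(planted_ms, detected_ms, tol = 10) {
  if (length(planted_ms) == 0) return(NA_real_)
  mean(vapply(planted_ms,
              function(t) any(abs(detected_ms - t) <= tol), logical(1)))
}

# synthetic recording with a constant-velocity gaze ramp (both eyes)
ramp_recording <- function(n = 500, vx = 10, vy = 0, sample_rate = 500) {
  t <- (seq_len(n) - 1) * 1000 / sample_rate
  x <- vx * t / 1000
  y <- vy * t / 1000
  eye_recording(t, x, y, x, y, rep(1000, n), rep(1000, n),
                sample_rate = sample_rate)
}

# recording holding a single planted minimum-jerk saccade over a quiet
# baseline; returns the recording and the planted parameters
one_saccade_recording <- function(amp_arcmin = 60, dur_ms = 20,
                                  onset_ms = 500, total_ms = 2000,
                                  sample_rate = 500) {
  n <- as.integer(total_ms / 1000 * sample_rate)
  t <- (seq_len(n) - 1) * 1000 / sample_rate
  x <- numeric(n)
  i0 <- as.integer(onset_ms / 1000 * sample_rate) + 1L
  nd <- as.integer(dur_ms / 1000 * sample_rate)
  tau <- (0:nd) / nd
  prof <- (10 * tau^3 - 15 * tau^4 + 6 * tau^5) * amp_arcmin / 60
  x[i0:(i0 + nd)] <- prof
  if (i0 + nd < n) x[(i0 + nd + 1):n] <- amp_arcmin / 60
  eye_recording(t, x, numeric(n), x, numeric(n),
                rep(1000, n), rep(1000, n), sample_rate = sample_rate)
}
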