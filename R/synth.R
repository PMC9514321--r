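#' Default synthetic observer parameters
#'
#' An observer couples a latent per-trial target visibility (and,
#' independently, a latent confidence state) to the eye features through two
#' 6-vectors ordered as (saccade-rate adaptation, ISI, target; pupil
#' adaptation, ISI, target). Saccade-rate couplings are in events/s added
#' when the latent variable is 1; pupil couplings in arbitrary units.
#'
#' @param coupling 6-vector linking latent visibility to the per-period
#'   saccade rate and pupil offsets.
#' @param conf_coupling 6-vector linking the latent confidence state to the
#'   same offsets.
#' @param cfg a [session_config()] supplying the remaining defaults.
#' @param ... overrides for any observer field (`base_rate`, `ms_slope`,
#'   `ms_slope_noise`, `amp_logmean`, `amp_logsd`, `amp_range_arcmin`,
#'   `drift_sd_deg`, `drift_tau_s`, `pupil_base`, `pupil_noise_sd`,
#'   `pupil_noise_ar`, `pupil_dilation`, `blink_rate_per_min`,
#'   `blink_dur_ms`, `p_visible`, `p_yes_visible`, `p_yes_invisible`,
#'   `p_sure`).
#' @return a named list of observer parameters.
#' @export
observer_params <- function(coupling = rep(0, 6), conf_coupling = rep(0, 6),
                            cfg = session_config(), ...) {
  stopifnot(length(coupling) == 6, all(is.finite(coupling)),
            length(conf_coupling) == 6, all(is.finite(conf_coupling)))
  obs <- list(
    coupling = as.numeric(coupling),
    conf_coupling = as.numeric(conf_coupling),
    base_rate = cfg$sim_base_rate,
    ms_slope = cfg$sim_ms_slope,
    ms_slope_noise = cfg$sim_ms_slope_noise,
    amp_logmean = cfg$sim_amp_logmean,
    amp_logsd = cfg$sim_amp_logsd,
    amp_range_arcmin = cfg$sim_amp_range_arcmin,
    drift_sd_deg = cfg$sim_drift_sd_deg,
    drift_tau_s = cfg$sim_drift_tau_s,
    pupil_base = cfg$sim_pupil_base,
    pupil_noise_sd = cfg$sim_pupil_noise_sd,
    pupil_noise_ar = cfg$sim_pupil_noise_ar,
    pupil_dilation = cfg$sim_pupil_dilation,
    blink_rate_per_min = cfg$sim_blink_rate_per_min,
    blink_dur_ms = cfg$sim_blink_dur_ms,
    p_visible = cfg$sim_p_visible,
    p_yes_visible = cfg$sim_p_yes_visible,
    p_yes_invisible = cfg$sim_p_yes_invisible,
    p_sure = cfg$sim_p_sure)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(obs))
  if (length(unknown)) stop("unknown observer fields: ",
                            paste(unknown, collapse = ", "))
  obs[names(dots)] <- dots
  if (obs$base_rate < 0 || obs$blink_rate_per_min < 0) {
    stop("rates must be nonnegative")
  }
  obs
}

# minimum-jerk position profile on tau in [0,1]; peak velocity 1.875 A / T
minjerk_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate one recording session with known ground truth
#'
#' Generates a 500 Hz binocular recording matching a trial schedule:
#' fixational drift as a mean-reverting (Ornstein-Uhlenbeck) 2-D walk,
#' ballistic microsaccades with minimum-jerk waveforms obeying a linear main
#' sequence with multiplicative noise, slow pupil dynamics (AR(1) colored
#' noise plus a trial-locked dilation transient), and full/partial blinks.
#' Microsaccade event times follow an inhomogeneous point process whose
#' per-period rate is `base_rate` plus the observer's coupling times the
#' trial's latent visibility (and confidence state); pupil couplings enter
#' as per-period offsets. The yes/no response is drawn from the latent
#' visibility, sure/maybe from the latent confidence state, so the planted
#' feature-label association is known exactly.
#'
#' @param schedule a [make_schedule()] trial schedule.
#' @param observer an [observer_params()] list.
#' @param seed integer seed; everything stochastic derives from it.
#' @param cfg a [session_config()].
#' @return a list with elements
#'   \describe{
#'     \item{recording}{the synthetic [eye_recording()].}
#'     \item{responses}{the schedule with added columns `visibility`,
#'       `conf_state`, `decision` ("yes"/"no"), `confidence`
#'       ("sure"/"maybe").}
#'     \item{truth}{ground truth: planted saccades (onset/offset ms,
#'       amplitude arcmin, peak velocity deg/s, direction rad), planted
#'       blinks, latent states, and the coupling vectors.}
#'   }
#' @export
simulate_session <- function(schedule, observer = observer_params(),
                             seed = 1L, cfg = session_config()) {
  set.seed(seed)
  fs <- cfg$sample_rate
  dt <- 1 / fs                      # s
  dur_ms <- schedule_duration(schedule)
  n <- ms_to_sample(dur_ms, fs)
  time <- (seq_len(n) - 1) * 1000 / fs
  ntr <- nrow(schedule)

  ## latent states and responses -------------------------------------------
  vis <- ifelse(schedule$is_catch, 0L,
                rbinom(ntr, 1, observer$p_visible))
  conf <- rbinom(ntr, 1, observer$p_sure)
  p_yes <- ifelse(vis == 1, observer$p_yes_visible, observer$p_yes_invisible)
  decision <- ifelse(rbinom(ntr, 1, p_yes) == 1, "yes", "no")
  confidence <- ifelse(conf == 1, "sure", "maybe")

  ## blinks -----------------------------------------------------------------
  dur_min <- dur_ms / 60000
  draw_blinks <- function(rate_per_min, dur_ms_mean) {
    k <- rpois(1, rate_per_min * dur_min)
    if (k == 0) return(data.frame(onset = numeric(0), offset = numeric(0)))
    on <- sort(runif(k, 1000, dur_ms - 2000))
    len <- dur_ms_mean * runif(k, 0.7, 1.5)
    keep <- c(TRUE, diff(on) > 1500)
    data.frame(onset = on[keep], offset = on[keep] + len[keep])
  }
  full_bl <- draw_blinks(observer$blink_rate_per_min, observer$blink_dur_ms)
  part_bl <- draw_blinks(observer$blink_rate_per_min / 2, 40)
  truth_blinks <- rbind(
    if (nrow(full_bl)) cbind(full_bl, kind = "full"),
    if (nrow(part_bl)) cbind(part_bl, kind = "partial"))
  if (is.null(truth_blinks)) {
    truth_blinks <- data.frame(onset = numeric(0), offset = numeric(0),
                               kind = character(0))
  }

  ## planted microsaccade times --------------------------------------------
  draw_in <- function(on, off, rate) {
    len_s <- (off - on) / 1000
    k <- rpois(1, max(0, rate) * len_s)
    if (k == 0) numeric(0) else runif(k, on, off - 50)
  }
  times <- numeric(0)
  for (i in seq_len(ntr)) {
    tr <- schedule[i, ]
    lat <- c(vis = vis[i], conf = conf[i])
    for (p in 1:3) {
      rate <- observer$base_rate + observer$coupling[p] * lat[["vis"]] +
        observer$conf_coupling[p] * lat[["conf"]]
      bounds <- trial_periods(tr)[[p]]
      times <- c(times, draw_in(bounds[1], bounds[2], rate))
    }
    # response screen at base rate
    gap_end <- if (i < ntr) schedule$adapt_on[i + 1] else dur_ms
    times <- c(times, draw_in(tr$target_off, gap_end, observer$base_rate))
  }
  times <- sort(times)
  if (length(times) > 1) times <- times[c(TRUE, diff(times) > 120)]
  # keep clear of blinks (the detector masks blink pads)
  if (nrow(truth_blinks)) {
    near_blink <- vapply(times, function(tt) {
      any(tt > truth_blinks$onset - 320 & tt < truth_blinks$offset + 320)
    }, logical(1))
    times <- times[!near_blink]
  }
  nev <- length(times)

  ## saccade kinematics (main sequence) -------------------------------------
  amp_arcmin <- pmin(pmax(
    exp(rnorm(nev, observer$amp_logmean, observer$amp_logsd)),
    observer$amp_range_arcmin[1]), observer$amp_range_arcmin[2])
  amp_deg <- amp_arcmin / 60
  vpeak <- observer$ms_slope * amp_deg *
    pmax(0.3, 1 + rnorm(nev, 0, observer$ms_slope_noise))
  dur_s <- 1.875 * amp_deg / vpeak
  dur_s <- pmin(pmax(dur_s, 0.012), 0.06)

  ## directions: corrective bias keeps gaze near fixation --------------------
  theta <- numeric(nev)
  ox <- 0; oy <- 0; tprev <- 0
  decay_tau_ms <- 800
  for (k in seq_len(nev)) {
    fade <- exp(-(times[k] - tprev) / decay_tau_ms)
    ox <- ox * fade; oy <- oy * fade
    r <- sqrt(ox^2 + oy^2)
    theta[k] <- if (r > 0.3) {
      atan2(-oy, -ox) + rnorm(1, 0, 0.5)
    } else runif(1, 0, 2 * pi)
    ox <- ox + amp_deg[k] * cos(theta[k])
    oy <- oy + amp_deg[k] * sin(theta[k])
    tprev <- times[k]
  }

  ## gaze assembly -----------------------------------------------------------
  a_ou <- exp(-dt / observer$drift_tau_s)
  s_ou <- observer$drift_sd_deg * sqrt(1 - a_ou^2)
  drift_x <- as.numeric(stats::filter(rnorm(n, 0, s_ou), a_ou,
                                      method = "recursive"))
  drift_y <- as.numeric(stats::filter(rnorm(n, 0, s_ou), a_ou,
                                      method = "recursive"))
  sacc_x <- numeric(n); sacc_y <- numeric(n)
  i_on <- ms_to_sample(times, fs) + 1L     # 1-based onset sample
  n_dur <- pmax(6L, ms_to_sample(dur_s * 1000, fs))
  n_decay <- as.integer(5 * decay_tau_ms / 1000 * fs)
  for (k in seq_len(nev)) {
    i0 <- i_on[k]; nd <- n_dur[k]
    if (i0 + nd > n) next
    prof <- minjerk_pos((0:nd) / nd) * amp_deg[k]
    idx <- i0:(i0 + nd)
    sacc_x[idx] <- sacc_x[idx] + prof * cos(theta[k])
    sacc_y[idx] <- sacc_y[idx] + prof * sin(theta[k])
    # exponential return to fixation after the event
    j1 <- min(n, i0 + nd + n_decay)
    if (j1 > i0 + nd) {
      jdx <- (i0 + nd + 1L):j1
      dec <- amp_deg[k] * exp(-(seq_along(jdx)) * dt * 1000 / decay_tau_ms)
      sacc_x[jdx] <- sacc_x[jdx] + dec * cos(theta[k])
      sacc_y[jdx] <- sacc_y[jdx] + dec * sin(theta[k])
    }
  }
  gx <- drift_x + sacc_x
  gy <- drift_y + sacc_y
  meas_sd <- 0.005
  lx <- gx + rnorm(n, 0, meas_sd); ly <- gy + rnorm(n, 0, meas_sd)
  rx <- gx + rnorm(n, 0, meas_sd); ry <- gy + rnorm(n, 0, meas_sd)

  ## pupil -------------------------------------------------------------------
  ar <- observer$pupil_noise_ar
  innov_sd <- observer$pupil_noise_sd * sqrt(1 - ar^2)
  pup <- observer$pupil_base +
    as.numeric(stats::filter(rnorm(n, 0, innov_sd), ar,
                             method = "recursive"))
  # trial-locked dilation: gamma-shaped transient at target onset
  kern_t <- seq(0, 2.5, by = dt)
  kern <- (kern_t / 0.9)^2 * exp(2 - 2 * kern_t / 0.9)
  kern <- kern / max(kern)
  dilation <- numeric(n)
  per_off <- numeric(n)
  for (i in seq_len(ntr)) {
    tr <- schedule[i, ]
    i0 <- ms_to_sample(tr$target_on, fs) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    dilation[idx] <- dilation[idx] + observer$pupil_dilation *
      kern[seq_along(idx)]
    per <- trial_periods(tr)
    for (p in 1:3) {
      add <- observer$coupling[3 + p] * vis[i] +
        observer$conf_coupling[3 + p] * conf[i]
      if (add != 0) {
        pidx <- period_idx(per[[p]][1], per[[p]][2], fs)
        per_off[pidx] <- per_off[pidx] + add
      }
    }
  }
  # pupil responses are slow: ramp the per-period offsets over ~100 ms so
  # the sample-to-sample change stays far below the partial-blink criterion
  if (any(per_off != 0)) {
    k <- 51
    per_off <- as.numeric(stats::filter(c(rep(per_off[1], k), per_off,
                                          rep(per_off[n], k)),
                                        rep(1 / k, k), sides = 2))
    per_off <- per_off[(k + 1):(k + n)]
  }
  pup <- pup + dilation + per_off
  lp <- pup + rnorm(n, 0, 2)
  rp <- pup + rnorm(n, 0, 2)

  ## partial blinks: fast pupil transients ----------------------------------
  if (nrow(part_bl)) {
    for (k in seq_len(nrow(part_bl))) {
      i0 <- ms_to_sample(part_bl$onset[k], fs) + 1L
      i1 <- min(n, ms_to_sample(part_bl$offset[k], fs))
      if (i1 <= i0) next
      half <- ceiling((i1 - i0) / 2)
      bump <- c(seq(0, -35 * half, by = -35)[1:(half + 1)],
                rev(seq(0, -35 * half, by = -35)[1:(half)]))
      idx <- i0:min(i1 + 1L, i0 + length(bump) - 1L)
      lp[idx] <- lp[idx] + bump[seq_along(idx)]
      rp[idx] <- rp[idx] + bump[seq_along(idx)]
    }
  }

  ## full blinks: both eyes lost --------------------------------------------
  lvalid <- rep(TRUE, n); rvalid <- rep(TRUE, n)
  if (nrow(full_bl)) {
    for (k in seq_len(nrow(full_bl))) {
      idx <- period_idx(full_bl$onset[k], min(full_bl$offset[k], dur_ms), fs)
      lvalid[idx] <- FALSE; rvalid[idx] <- FALSE
      lp[idx] <- NA; rp[idx] <- NA
      lx[idx] <- NA; ly[idx] <- NA; rx[idx] <- NA; ry[idx] <- NA
    }
  }

  rec <- eye_recording(time, lx, ly, rx, ry, lp, rp, lvalid, rvalid,
                       sample_rate = fs)
  responses <- schedule
  responses$visibility <- vis
  responses$conf_state <- conf
  responses$decision <- decision
  responses$confidence <- confidence
  truth <- list(
    saccades = data.frame(onset_ms = times,
                          offset_ms = times + dur_s * 1000,
                          amplitude_arcmin = amp_arcmin,
                          peak_velocity = vpeak,
                          direction = theta),
    blinks = truth_blinks,
    visibility = vis,
    conf_state = conf,
    coupling = observer$coupling,
    conf_coupling = observer$conf_coupling,
    seed = seed)
  list(recording = rec, responses = responses, truth = truth)
}

#' Write / read simulation ground truth as JSON
#' @param truth the `truth` element of [simulate_session()].
#' @param path file path.
#' @return `path` (write) or the truth list (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run a 1-up-1-down staircase on a simulated observer
#'
#' Fixed-step staircase on log10 contrast: a "seen" response lowers the
#' level by one step, "unseen" raises it, which converges on the 50% point
#' of the psychometric function. Stops after `max_reversals` reversals or
#' `max_trials` trials, whichever comes first. The threshold estimate is the
#' mean of the reversal levels excluding the first two (early reversals bias
#' the estimate); if fewer than three reversals occurred, the mean of all
#' visited levels is returned with a warning flag.
#'
#' @param observer list with `threshold` (log10 contrast of the 50% point)
#'   and `slope` (logistic scale in log10 units; `slope = 0` gives a
#'   deterministic step-function observer).
#' @param start_level starting log10 contrast.
#' @param step step size in log10 units (default 0.05).
#' @param max_reversals,max_trials stopping rules (defaults 15 and 65).
#' @param seed integer seed for the observer's responses.
#' @return list with `threshold` (the estimate), `levels` (visited),
#'   `reversals` (levels at reversals), `n_trials`, and `warning` (TRUE when
#'   fewer than 3 reversals occurred).
#' @export
run_staircase <- function(observer, start_level = 0, step = 0.05,
                          max_reversals = 15L, max_trials = 65L, seed = 1L) {
  if (is.null(observer$slope) || observer$slope < 0) {
    stop("observer psychometric function must be monotone increasing ",
         "(slope >= 0)")
  }
  set.seed(seed)
  p_seen <- function(x) {
    if (observer$slope == 0) as.numeric(x >= observer$threshold)
    else 1 / (1 + exp(-(x - observer$threshold) / observer$slope))
  }
  level <- start_level
  levels <- numeric(0)
  reversals <- numeric(0)
  dir_prev <- 0L
  for (tr in seq_len(max_trials)) {
    levels <- c(levels, level)
    seen <- runif(1) < p_seen(level)
    dir <- if (seen) -1L else 1L
    if (dir_prev != 0L && dir != dir_prev) {
      reversals <- c(reversals, level)
      if (length(reversals) >= max_reversals) {
        dir_prev <- dir
        level <- level + dir * step
        break
      }
    }
    dir_prev <- dir
    level <- level + dir * step
  }
  if (length(reversals) >= 3) {
    list(threshold = mean(reversals[-(1:2)]), levels = levels,
         reversals = reversals, n_trials = length(levels), warning = FALSE)
  } else {
    list(threshold = mean(levels), levels = levels,
         reversals = reversals, n_trials = length(levels), warning = TRUE)
  }
}
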