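test_that("binocular speed recovers constant-velocity ramps", {
  rec <- ramp_recording(vx = 10, vy = 0)
  sp <- binocular_speed(rec)
  interior <- 10:490
  expect_equal(mean(sp$speed[interior]), 10, tolerance = 1e-6)
  still <- ramp_recording(vx = 0, vy = 0)
  expect_lt(max(binocular_speed(still)$speed[interior]), 1e-9)
  # ramp in one eye, stationary other: binocular mean is half
  mixed <- ramp_recording(vx = 10)
  mixed$rx <- numeric(length(mixed$time))
  expect_equal(mean(binocular_speed(mixed)$speed[interior]), 5,
               tolerance = 1e-6)
})

test_that("a monocular recording warns and uses the single eye", {
  rec <- ramp_recording(vx = 8)
  rec$rx[] <- NA; rec$ry[] <- NA; rec$rvalid[] <- FALSE
  expect_warning(sp <- binocular_speed(rec), "monocular")
  expect_equal(mean(sp$speed[10:490], na.rm = TRUE), 8, tolerance = 1e-6)
})

test_that("candidate selection keeps the six highest peaks per second", {
  # one 1-s window with 10 separated triangular peaks of distinct heights
  n <- 500
  speed <- rep(0.1, n)
  heights <- seq(2, 20, length.out = 10)
  centers <- seq(25, 475, length.out = 10)
  for (k in 1:10) {
    i <- centers[k]
    speed[(i - 2):(i + 2)] <- heights[k] * c(.3, .7, 1, .7, .3)
  }
  accel <- c(0, diff(speed)) * 500
  cands <- select_candidates(speed, accel, 500)
  expect_equal(nrow(cands), 6)
  expect_setequal(round(cands$peak_velocity), round(tail(heights, 6)))
  # window with only 3 peaks yields 3 candidates
  speed3 <- rep(0.1, n)
  for (i in c(100, 250, 400)) speed3[(i - 1):(i + 1)] <- c(3, 5, 3)
  cands3 <- select_candidates(speed3, accel, 500)
  expect_equal(nrow(cands3), 3)
  # constant trace has no local maxima
  expect_equal(nrow(select_candidates(rep(1, n), accel, 500)), 0)
})

test_that("candidate z-features are standardized across the set", {
  fx <- fx_coupled()
  cands <- fx$proc$saccades   # need raw candidates instead
  sp <- binocular_speed(fx$sim$recording)
  cands <- select_candidates(sp$speed, sp$accel, 500)
  for (col in c("z_vel", "z_ia", "z_fa")) {
    expect_lt(abs(mean(cands[[col]])), 1e-8)
    expect_equal(sd(cands[[col]]), 1, tolerance = 1e-8)
  }
  expect_true(all(cands$peak_velocity > 0))
})

test_that("clustering separates velocity clouds and flags degenerate input", {
  set.seed(7)
  n <- 200
  noise <- data.frame(peak_velocity = rnorm(n, 1, 0.2),
                      initial_accel = rnorm(n, 50, 20),
                      final_accel = rnorm(n, -50, 20))
  sacc <- data.frame(peak_velocity = rnorm(n, 25, 5),
                     initial_accel = rnorm(n, 2000, 400),
                     final_accel = rnorm(n, -2000, 400))
  cands <- rbind(noise, sacc)
  zt <- function(x) (x - mean(x)) / sd(x)
  cands$z_vel <- zt(cands$peak_velocity)
  cands$z_ia <- zt(cands$initial_accel)
  cands$z_fa <- zt(cands$final_accel)
  cands$idx <- seq_len(2 * n)
  cands$peak_time <- cands$idx * 2
  labels <- cluster_candidates(cands, seed = 3)
  truth <- rep(c("noise", "saccade"), each = n)
  expect_gte(mean(labels == truth), 0.95)
  expect_false(attr(labels, "qc_failed"))
  # variance confined to one principal direction still clusters
  cands1 <- cands
  cands1$z_ia <- cands1$z_vel * 2       # perfectly collinear
  cands1$z_fa <- cands1$z_vel * -1
  labels1 <- cluster_candidates(cands1, seed = 3)
  expect_false(attr(labels1, "qc_failed"))
  # duplicate-only candidates fail QC
  dup <- cands[rep(1, 10), ]
  expect_true(attr(cluster_candidates(dup, seed = 1), "qc_failed"))
  expect_true(attr(cluster_candidates(cands[0, ], seed = 1), "qc_failed"))
})

test_that("physiological filters reject short, huge, and slow events", {
  cfg <- session_config()
  # planted 60-arcmin, 20-ms saccade: retained, mean velocity 50 deg/s
  ok <- one_saccade_recording(amp_arcmin = 60, dur_ms = 20)
  sp <- binocular_speed(ok)
  cands <- select_candidates(sp$speed, sp$accel, 500)
  labels <- structure(rep("saccade", nrow(cands)), qc_failed = FALSE)
  ms <- delimit_and_filter(ok, sp$speed, cands, labels, cfg)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$amplitude_arcmin, 60, tolerance = 3)
  expect_equal(ms$mean_velocity,
               (ms$amplitude_arcmin / 60) / (ms$duration_ms / 1000),
               tolerance = 1e-8)
  expect_equal(ms$mean_velocity, 50, tolerance = 12)
  # 6 ms event: too short
  short <- one_saccade_recording(amp_arcmin = 60, dur_ms = 6)
  sps <- binocular_speed(short)
  cs <- select_candidates(sps$speed, sps$accel, 500)
  ls <- structure(rep("saccade", nrow(cs)), qc_failed = FALSE)
  expect_equal(nrow(delimit_and_filter(short, sps$speed, cs, ls, cfg)), 0)
  # 150 arcmin: amplitude out of range
  big <- one_saccade_recording(amp_arcmin = 150, dur_ms = 30)
  spb <- binocular_speed(big)
  cb <- select_candidates(spb$speed, spb$accel, 500)
  lb <- structure(rep("saccade", nrow(cb)), qc_failed = FALSE)
  expect_equal(nrow(delimit_and_filter(big, spb$speed, cb, lb, cfg)), 0)
})

test_that("every emitted event satisfies all three physiological bounds", {
  ms <- fx_coupled()$proc$saccades
  expect_gt(nrow(ms), 50)
  expect_true(all(ms$duration_ms >= 8))
  expect_true(all(ms$amplitude_arcmin >= 10 & ms$amplitude_arcmin <= 120))
  expect_true(all(ms$mean_velocity >= 3 & ms$mean_velocity <= 120))
  # no overlapping events after merging
  expect_true(all(diff(ms$onset_ms) > 0))
  expect_true(all(ms$onset_ms[-1] >= head(ms$offset_ms, -1)))
})

test_that("the detector recovers planted events at default noise", {
  fx <- fx_coupled()
  planted <- fx$sim$truth$saccades$onset_ms
  detected <- fx$proc$saccades$onset_ms
  expect_gte(event_recall(planted, detected), 0.95)
  expect_gte(event_recall(detected, planted), 0.95)  # precision
})

test_that("detection is deterministic given identical input and seeds", {
  fx <- fx_coupled()
  a <- detect_microsaccades(fx$sim$recording, fx$proc$blinks, seed = 5)
  b <- detect_microsaccades(fx$sim$recording, fx$proc$blinks, seed = 5)
  expect_identical(a$saccades, b$saccades)
})

test_that("main-sequence QC follows the r > 0.6 criterion", {
  qc <- fx_coupled()$proc$qc
  expect_gt(qc$r, 0.6)
  expect_true(qc$pass)
  # exactly collinear events give r = 1
  col <- data.frame(peak_velocity = c(10, 20, 30, 40),
                    amplitude_arcmin = c(10, 20, 30, 40))
  expect_equal(main_sequence_qc(col)$r, 1)
  # velocity independent of amplitude: |r| small, fails in most seeds
  fails <- vapply(1:40, function(s) {
    set.seed(s)
    ind <- data.frame(peak_velocity = runif(60, 10, 60),
                      amplitude_arcmin = runif(60, 10, 120))
    isFALSE(main_sequence_qc(ind)$pass)
  }, logical(1))
  expect_gte(mean(fails), 0.95)
  # fewer than 3 events is indeterminate
  expect_true(main_sequence_qc(col[1:2, ])$indeterminate)
})

test_that("saccade rate is count over duration and rates are additive", {
  ev <- data.frame(peak_time = c(1000, 2000, 3000, 6200, 6300))
  expect_equal(saccade_rate(ev, c(0, 6000)), 0.5)
  expect_equal(saccade_rate(ev, c(10000, 11000)), 0)
  expect_equal(saccade_rate(ev, c(6000, 6500)), 4)
  expect_error(saccade_rate(ev, c(5, 5)), "zero-length")
  # concatenation: rate over union = count-weighted average
  r1 <- saccade_rate(ev, c(0, 6000)); r2 <- saccade_rate(ev, c(6000, 6500))
  expect_equal(saccade_rate(ev, c(0, 6500)), (r1 * 6 + r2 * 0.5) / 6.5)
})

test_that("saccade tables round-trip through CSV", {
  ms <- fx_coupled()$proc$saccades
  path <- withr::local_tempfile(fileext = ".csv")
  write_saccades(ms, path)
  back <- read_saccades(path)
  expect_equal(back$onset_ms, ms$onset_ms)
  expect_equal(back$amplitude_arcmin, ms$amplitude_arcmin)
})
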