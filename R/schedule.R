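#' Target position labels
#'
#' Eight possible target positions on a ring around fixation; the top-left
#' and bottom-right diagonals are the "positions of interest" carrying 65%
#' of target presentations.
#' @name positions
#' @keywords internal
NULL

.pos_interest <- c("pos_topleft", "pos_bottomright")
.pos_other <- c("pos_top", "pos_topright", "pos_right",
                "pos_bottom", "pos_bottomleft", "pos_left")

#' Build a trial schedule
#'
#' Allocates trial categories per block by nearest-integer rounding of the
#' stated proportions, which with the defaults (43 trials/block, 65%/15%/20%)
#' gives 28 position-of-interest, 6 other-position, and 9 catch trials per
#' block, hence 36 catch and 56 + 56 interest trials per 4-block session.
#' The interest trials are split equally between top-left and bottom-right;
#' the six other positions are cycled so they stay as balanced as the
#' remainder allows. Category counts are deterministic; only trial order
#' depends on `seed`. The first trial of each block carries the long 60 s
#' adaptation; all others 6 s.
#'
#' @param n_blocks number of blocks (default 4).
#' @param trials_per_block trials per block (default 43).
#' @param proportions named numeric, `c(interest=, other=, catch=)`, summing
#'   to 1.
#' @param seed integer seed for the within-block shuffle.
#' @param cfg a [session_config()] supplying period durations.
#' @return a `trial_schedule`: data.frame with one row per trial and columns
#'   `block`, `trial` (within block), `condition`, `is_interest`, `is_catch`,
#'   `first_of_block`, and absolute period bounds in ms (`adapt_on`,
#'   `adapt_off`, `isi_on`, `isi_off`, `target_on`, `target_off`), half-open
#'   `[on, off)`.
#' @export
make_schedule <- function(n_blocks = 4L, trials_per_block = 43L,
                          proportions = c(interest = 0.65, other = 0.15,
                                          catch = 0.20),
                          seed = 1L, cfg = session_config()) {
  stopifnot(trials_per_block >= 1, n_blocks >= 1)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("category proportions must sum to 1")
  }
  n_int <- round(proportions[["interest"]] * trials_per_block)
  n_oth <- round(proportions[["other"]] * trials_per_block)
  n_cat <- round(proportions[["catch"]] * trials_per_block)
  if (n_int + n_oth + n_cat != trials_per_block) {
    stop(sprintf(paste0(
      "configuration error: nearest-integer rounding gives %d + %d + %d ",
      "trials, not the block total %d"), n_int, n_oth, n_cat,
      trials_per_block))
  }
  set.seed(seed)
  rows <- vector("list", n_blocks)
  t0 <- 0
  for (b in seq_len(n_blocks)) {
    # interest split: equal halves; an odd remainder alternates across blocks
    n_tl <- n_int %/% 2 + if (n_int %% 2 == 1 && b %% 2 == 1) 1L else 0L
    n_br <- n_int - n_tl
    oth <- if (n_oth > 0) {
      rot <- (b - 1L) %% length(.pos_other)
      .pos_other[((rot + seq_len(n_oth) - 1L) %% length(.pos_other)) + 1L]
    } else character(0)
    cond <- c(rep("pos_topleft", n_tl), rep("pos_bottomright", n_br),
              oth, rep("catch", n_cat))
    cond <- sample(cond)
    adapt_dur <- c(cfg$adapt_first_ms,
                   rep(cfg$adapt_ms, trials_per_block - 1L))
    trial_dur <- adapt_dur + cfg$isi_ms + cfg$target_ms + cfg$response_ms
    adapt_on <- t0 + cumsum(c(0, head(trial_dur, -1)))
    adapt_off <- adapt_on + adapt_dur
    rows[[b]] <- data.frame(
      block = b, trial = seq_len(trials_per_block), condition = cond,
      is_interest = cond %in% .pos_interest,
      is_catch = cond == "catch",
      first_of_block = seq_len(trials_per_block) == 1L,
      adapt_on = adapt_on, adapt_off = adapt_off,
      isi_on = adapt_off, isi_off = adapt_off + cfg$isi_ms,
      target_on = adapt_off + cfg$isi_ms,
      target_off = adapt_off + cfg$isi_ms + cfg$target_ms,
      stringsAsFactors = FALSE)
    t0 <- t0 + sum(trial_dur)
  }
  sched <- do.call(rbind, rows)
  rownames(sched) <- NULL
  class(sched) <- c("trial_schedule", "data.frame")
  attr(sched, "session_ms") <- t0
  sched
}

#' Total recording duration implied by a schedule, in ms
#' @param schedule a `trial_schedule`.
#' @return duration in ms (response screens included).
#' @export
schedule_duration <- function(schedule) {
  dur <- attr(schedule, "session_ms")
  if (is.null(dur)) dur <- max(schedule$target_off) + 2000
  dur
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial schedule (with any response columns) to JSON
#' @param schedule a `trial_schedule`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  payload <- list(session_ms = schedule_duration(schedule),
                  trials = as.data.frame(schedule))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a trial schedule from JSON
#' @param path path written by [write_schedule()].
#' @return a `trial_schedule`.
#' @export
read_schedule <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- payload$trials
  class(sched) <- c("trial_schedule", "data.frame")
  attr(sched, "session_ms") <- payload$session_ms
  sched
}

# period bounds of one trial as a named list of c(on, off) ms pairs
trial_periods <- function(trial_row) {
  list(adapt = c(trial_row$adapt_on, trial_row$adapt_off),
       isi = c(trial_row$isi_on, trial_row$isi_off),
       target = c(trial_row$target_on, trial_row$target_off))
}

# union of all analysis-period sample indices (1-based) of a schedule
schedule_period_idx <- function(schedule, sample_rate = 500) {
  idx <- lapply(seq_len(nrow(schedule)), function(i) {
    tr <- schedule[i, ]
    c(period_idx(tr$adapt_on, tr$adapt_off, sample_rate),
      period_idx(tr$isi_on, tr$isi_off, sample_rate),
      period_idx(tr$target_on, tr$target_off, sample_rate))
  })
  sort(unique(unlist(idx)))
}
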