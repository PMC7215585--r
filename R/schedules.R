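#' @include AllClasses.R constructors.R patterns.R
NULL

## internal: pack shuffled position slots into frames of dpf distinct
## positions; repair within-frame duplicates by swapping with a later slot
## whose frame stays duplicate-free. Returns NULL when repair gets stuck.
packBalancedFrames <- function(slots, nf, dpf) {
  frameOf <- rep(seq_len(nf), each = dpf)
  for (k in seq_len(nf)) {
    idx <- ((k - 1L) * dpf + 1L):(k * dpf)
    guard <- 0L
    repeat {
      fr <- slots[idx]
      dup <- which(duplicated(fr))
      if (!length(dup)) break
      guard <- guard + 1L
      if (guard > 64L) return(NULL)
      jj <- idx[dup[1]]
      later <- (k * dpf + 1L):length(slots)
      if (k == nf) return(NULL)
      ok <- !(slots[later] %in% fr)
      cand <- later[ok]
      if (!length(cand)) return(NULL)
      ## candidate's own frame must not already hold the duplicate value
      good <- FALSE
      for (cc in sample(cand, min(length(cand), 32L))) {
        cf <- frameOf[cc]
        cidx <- ((cf - 1L) * dpf + 1L):(cf * dpf)
        if (!(slots[jj] %in% slots[setdiff(cidx, cc)])) {
          tmp <- slots[jj]; slots[jj] <- slots[cc]; slots[cc] <- tmp
          good <- TRUE
          break
        }
      }
      if (!good) return(NULL)
    }
  }
  slots
}

#' Generate a balanced random-dot probing schedule
#'
#' Builds the probing movie used for connectivity mapping: every grid
#' position is stimulated exactly `n_reps` times, `dots_per_frame` distinct
#' positions per frame, frames spaced `frame_ms` apart with the light on for
#' `on_ms`. The position slots are shuffled and packed sequentially into
#' frames; within-frame duplicates are repaired by swapping with later slots,
#' so per-position balance is exact by construction.
#'
#' With the standard parameters (16 x 16 grid, 20 repetitions, 5 dots per
#' 100-ms frame) this gives 1024 frames, 5120 position-stimulation events and
#' a session of about 1.7 min.
#'
#' @param grid_shape integer(2) stimulation grid (rows, cols).
#' @param n_reps stimulations per position (default 20).
#' @param dots_per_frame simultaneously lit positions per frame (default 5).
#' @param frame_ms frame period in ms (default 100).
#' @param on_ms light-on time per frame in ms (default 40).
#' @param intensity stimulation intensity scalar.
#' @param seed integer RNG seed for reproducible schedules.
#' @return a [StimulusSchedule-class].
#' @examples
#' sch <- makeProbingSchedule(c(4, 4), n_reps = 2, dots_per_frame = 4, seed = 1)
#' nFrames(sch)  # 8
#' @export
makeProbingSchedule <- function(grid_shape = c(16L, 16L), n_reps = 20L,
                                dots_per_frame = 5L, frame_ms = 100,
                                on_ms = 40, intensity = 1, seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  g <- prod(grid_shape)
  if (dots_per_frame > g)
    stop("dots_per_frame exceeds the number of grid positions")
  if ((g * n_reps) %% dots_per_frame != 0)
    stop(sprintf("grid size x n_reps (%d) is not divisible by dots_per_frame (%d)",
                 g * n_reps, dots_per_frame))
  if (on_ms > frame_ms) stop("on_ms must not exceed frame_ms")
  if (!is.null(seed)) set.seed(seed)
  nf <- (g * n_reps) %/% dots_per_frame
  slots <- NULL
  for (try in 1:100) {
    cand <- packBalancedFrames(sample(rep(seq_len(g) - 1L, n_reps)), nf,
                               as.integer(dots_per_frame))
    if (!is.null(cand)) { slots <- cand; break }
  }
  if (is.null(slots))
    stop("could not build a duplicate-free balanced schedule; ",
         "dots_per_frame may be too close to the grid size")
  positions <- split(slots, rep(seq_len(nf), each = dots_per_frame))
  newSchedule(onset_ms = (seq_len(nf) - 1) * frame_ms, on_ms = on_ms,
              positions = positions, intensity = intensity,
              grid_shape = grid_shape,
              total_duration_ms = nf * frame_ms)
}

#' Generate a random dot movie (RDM) for burst suppression
#'
#' Each frame lights `dots_per_frame` positions drawn uniformly at random
#' from the grid; frames refresh at `frame_hz`. The standard suppression
#' movie lights 25 of 100 dots on a 10 x 10 grid for 50 ms at 10 Hz.
#'
#' @param grid_shape integer(2) RDM grid (default c(10, 10)).
#' @param dots_per_frame lit dots per frame (default 25).
#' @param frame_hz frame refresh rate (default 10).
#' @param on_ms light-on time per frame (default 50).
#' @param duration_s movie length in seconds.
#' @param intensity stimulation intensity scalar.
#' @param seed integer RNG seed.
#' @return a [StimulusSchedule-class]; empty (with a warning) when
#'   `duration_s` is shorter than one frame.
#' @export
makeRdmSchedule <- function(grid_shape = c(10L, 10L), dots_per_frame = 25L,
                            frame_hz = 10, on_ms = 50, duration_s,
                            intensity = 1, seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  g <- prod(grid_shape)
  if (dots_per_frame > g)
    stop("dots_per_frame exceeds the number of grid positions")
  if (frame_hz * on_ms > 1000)
    stop("on_ms too long for the frame rate (frame_hz * on_ms must be <= 1000)")
  nf <- floor(duration_s * frame_hz)
  if (nf < 1) {
    warning("duration shorter than one frame; returning an empty schedule")
    return(newSchedule(numeric(0), numeric(0), list(), numeric(0), grid_shape,
                       total_duration_ms = max(0, duration_s * 1000)))
  }
  if (!is.null(seed)) set.seed(seed)
  positions <- lapply(seq_len(nf), function(i) sample.int(g, dots_per_frame) - 1L)
  newSchedule(onset_ms = (seq_len(nf) - 1) * 1000 / frame_hz, on_ms = on_ms,
              positions = positions, intensity = intensity,
              grid_shape = grid_shape,
              total_duration_ms = duration_s * 1000)
}

#' Generate a high-frequency tetanus train of a full pattern
#'
#' The learning stimulus: the whole pattern is pulsed at `freq_hz` with duty
#' cycle `duty_frac` for `train_s` per trial, trials separated by
#' `trial_interval_s`. The standard protocol is 50 Hz, 50% duty (10 ms on /
#' 10 ms off), 60 trials of 1 s spaced by 9-s intervals, i.e. 50 pulses per
#' trial and 3000 pulses in total.
#'
#' @param pattern a [PatternMask-class], projected onto `grid_shape`.
#' @param grid_shape integer(2) stimulation grid addressed by the schedule.
#' @param freq_hz pulse frequency (default 50).
#' @param duty_frac on fraction of each pulse period, in (0, 1) (default 0.5).
#' @param n_trials number of trains (default 60).
#' @param trial_interval_s gap between trains in seconds (default 9).
#' @param train_s train length in seconds (default 1); `freq_hz * train_s`
#'   must be a whole number of pulses.
#' @return a [StimulusSchedule-class]; no trailing interval after the last
#'   trial.
#' @export
makeTetanusSchedule <- function(pattern, grid_shape = c(16L, 16L), freq_hz = 50,
                                duty_frac = 0.5, n_trials = 60L,
                                trial_interval_s = 9, train_s = 1) {
  stopifnot(duty_frac > 0, duty_frac < 1)
  npulse <- freq_hz * train_s
  if (abs(npulse - round(npulse)) > 1e-9)
    stop("freq_hz * train_s must be a whole number of pulses")
  npulse <- as.integer(round(npulse))
  period_ms <- 1000 / freq_hz
  on_ms <- duty_frac * period_ms
  lit <- patternToGrid(pattern, grid_shape)
  trial_base <- (seq_len(n_trials) - 1) * (train_s + trial_interval_s) * 1000
  onsets <- as.numeric(outer((seq_len(npulse) - 1) * period_ms, trial_base, "+"))
  onsets <- sort(onsets)
  ## session span: the last train runs to the end of its train_s; no
  ## trailing inter-trial interval
  newSchedule(onset_ms = onsets, on_ms = on_ms,
              positions = rep(list(lit), length(onsets)),
              intensity = pattern@intensity, grid_shape = grid_shape,
              total_duration_ms = (n_trials - 1) * (train_s + trial_interval_s) * 1000 +
                train_s * 1000)
}

#' Generate a baseline/testing pattern-presentation schedule
#'
#' Presents each pattern `n_trials_per` times in a seeded random order with
#' `interval_s` between onsets and `on_ms` of illumination (standard: 3
#' patterns x 10 trials, 10-s intervals, 100-ms stimulation).
#'
#' @param patterns list of at least two [PatternMask-class] objects (a single
#'   pattern is refused: the familiarity metric needs control patterns).
#' @param grid_shape integer(2) stimulation grid addressed by the schedule.
#' @param n_trials_per presentations per pattern (default 10).
#' @param interval_s onset-to-onset spacing in seconds (default 10).
#' @param on_ms illumination time (default 100).
#' @param seed integer RNG seed for the presentation order.
#' @return list with `schedule` (a [StimulusSchedule-class]) and `labels`
#'   (character, per-frame pattern names aligned with the frames).
#' @export
makeTestSchedule <- function(patterns, grid_shape = c(16L, 16L),
                             n_trials_per = 10L, interval_s = 10, on_ms = 100,
                             seed = NULL) {
  if (length(patterns) < 2L)
    stop("at least two patterns are required (controls for the familiarity metric)")
  names(patterns) <- vapply(patterns, function(p) p@name, character(1))
  if (!is.null(seed)) set.seed(seed)
  order_idx <- sample(rep(seq_along(patterns), n_trials_per))
  labels <- names(patterns)[order_idx]
  lit <- lapply(patterns, patternToGrid, grid_shape = grid_shape)
  n <- length(order_idx)
  sch <- newSchedule(
    onset_ms = (seq_len(n) - 1) * interval_s * 1000, on_ms = on_ms,
    positions = lit[order_idx],
    intensity = vapply(patterns, function(p) p@intensity, numeric(1))[order_idx],
    grid_shape = grid_shape,
    total_duration_ms = n * interval_s * 1000
  )
  list(schedule = sch, labels = labels)
}

#' Tally per-position stimulation counts of a schedule
#'
#' @param schedule a [StimulusSchedule-class].
#' @return integer vector of length grid size: how often each position is lit.
#' @export
positionCounts <- function(schedule) {
  g <- prod(schedule@gridShape)
  tabulate(unlist(schedule@positions) + 1L, nbins = g)
}
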