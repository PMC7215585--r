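#' @include AllClasses.R constructors.R network.R
NULL

## internal: draw SNB onset times over [0, duration_ms]; gaps are Gaussian,
## truncated below at the burst duration so bursts never overlap
drawSnbOnsets <- function(snb, duration_ms) {
  onsets <- numeric(0)
  t <- 0
  min_gap <- snb$duration_ms / 1000
  repeat {
    gap <- stats::rnorm(1, snb$ibi_mean_s, snb$ibi_sd_s)
    guard <- 0L
    while (gap <= min_gap && guard < 1000L) {
      gap <- stats::rnorm(1, snb$ibi_mean_s, snb$ibi_sd_s)
      guard <- guard + 1L
    }
    gap <- max(gap, min_gap + 1e-3)
    t <- t + gap * 1000
    if (t + snb$duration_ms > duration_ms) break
    onsets <- c(onsets, t)
  }
  onsets
}

## internal: Poisson spikes within SNB intervals for every electrode
snbSpikes <- function(net, onsets, gains) {
  ne <- nrow(net@geometry)
  dur_s <- net@snb$duration_ms / 1000
  out <- vector("list", ne)
  for (e in seq_len(ne)) {
    rate <- net@snb$within_rate_hz * net@snb$participation[e] * gains[e]
    sp <- numeric(0)
    if (rate > 0) {
      for (on in onsets) {
        n <- stats::rpois(1, rate * dur_s)
        if (n > 0) sp <- c(sp, on + stats::runif(n, 0, net@snb$duration_ms))
      }
    }
    out[[e]] <- sp
  }
  out
}

#' Simulate spontaneous network activity
#'
#' Homogeneous Poisson background per electrode, plus periodic synchronized
#' network bursts whose inter-onset gaps are Gaussian (ibi_mean_s, ibi_sd_s),
#' truncated so bursts never overlap. During a burst every electrode fires
#' Poisson at `within_rate_hz` scaled by its participation gain and, when a
#' replay pattern is armed, by the pattern's replay-bias gain.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param duration_s recording length in seconds.
#' @param seed integer RNG seed.
#' @param replay_pattern name of an armed replay pattern, or NULL.
#' @param details when TRUE, return `list(spikes, bursts)` where `bursts`
#'   holds the ground-truth burst intervals.
#' @return a [SpikeData-class] (or a list when `details`).
#' @export
simulateSpontaneous <- function(net, duration_s, seed = NULL,
                                replay_pattern = NULL, details = FALSE) {
  stopifnot(duration_s > 0)
  if (any(net@backgroundRateHz < 0) || net@snb$within_rate_hz < 0)
    stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  duration_ms <- duration_s * 1000
  ne <- nrow(net@geometry)
  gains <- rep(1, ne)
  if (!is.null(replay_pattern)) {
    if (is.null(net@replayBias[[replay_pattern]]))
      stop(sprintf("no replay bias armed for pattern '%s'", replay_pattern))
    gains <- net@replayBias[[replay_pattern]]
  }
  bg <- lapply(seq_len(ne), function(e) {
    n <- stats::rpois(1, net@backgroundRateHz[e] * duration_s)
    stats::runif(n, 0, duration_ms)
  })
  onsets <- drawSnbOnsets(net@snb, duration_ms)
  sb <- snbSpikes(net, onsets, gains)
  sp <- lapply(seq_len(ne), function(e)
    pmin(duration_ms, pmax(0, sort(c(bg[[e]], sb[[e]])))))
  sd <- spikeData(sp, duration_ms, net@geometry)
  if (!details) return(sd)
  list(spikes = sd,
       bursts = data.frame(start_ms = onsets,
                           end_ms = onsets + net@snb$duration_ms))
}

#' Simulate stimulus-evoked activity for a schedule
#'
#' For every frame and every connection whose presynaptic position is lit,
#' the postsynaptic electrode emits at most one spike with probability
#' `response_prob`, at frame onset + Normal(latency_mean_ms, latency_sd_ms).
#' Background firing (and SNBs, when `with_snbs`) is superimposed; all spikes
#' are merged and sorted per electrode.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param schedule a [StimulusSchedule-class] on the same stimulation grid.
#' @param seed integer RNG seed.
#' @param with_snbs superimpose synchronized network bursts.
#' @param replay_pattern armed replay pattern applied during SNBs, or NULL.
#' @param snb_mask when TRUE, evoked spikes inside SNB intervals are masked
#'   (dropped), modeling burst-saturated encoding failure.
#' @return a [SpikeData-class].
#' @export
simulateEvoked <- function(net, schedule, seed = NULL, with_snbs = FALSE,
                           replay_pattern = NULL, snb_mask = FALSE) {
  if (!identical(as.integer(schedule@gridShape), net@gridShape))
    stop("schedule stimulation grid does not match the network grid")
  if (!is.null(seed)) set.seed(seed)
  duration_ms <- schedule@totalDurationMs
  ne <- nrow(net@geometry)
  eidx <- match(net@connections$post, net@geometry$electrode)

  ## frame onsets (and stimulation intensities) per stimulated position;
  ## intensity scales the per-trial response probability (capped at 1),
  ## which is what luminance balancing of patterns acts on
  fp <- schedule@positions
  pos_all <- unlist(fp)
  frame_of <- rep(seq_along(fp), lengths(fp))
  onset_by_pos <- split(schedule@onsetMs[frame_of], pos_all)
  int_by_pos <- split(schedule@intensity[frame_of], pos_all)

  evoked <- vector("list", ne)
  for (e in seq_len(ne)) evoked[[e]] <- numeric(0)
  cn <- net@connections
  for (k in seq_len(nrow(cn))) {
    o <- onset_by_pos[[as.character(cn$pre[k])]]
    if (is.null(o) || !length(o)) next
    ii <- int_by_pos[[as.character(cn$pre[k])]]
    hit <- stats::runif(length(o)) < pmin(1, cn$response_prob[k] * ii)
    nh <- sum(hit)
    if (nh == 0) next
    tt <- o[hit] + stats::rnorm(nh, cn$latency_mean_ms[k], cn$latency_sd_ms[k])
    e <- eidx[k]
    evoked[[e]] <- c(evoked[[e]], tt)
  }

  duration_s <- duration_ms / 1000
  bg <- lapply(seq_len(ne), function(e) {
    n <- stats::rpois(1, net@backgroundRateHz[e] * duration_s)
    stats::runif(n, 0, duration_ms)
  })

  burst_iv <- NULL
  sb <- rep(list(numeric(0)), ne)
  if (with_snbs) {
    gains <- rep(1, ne)
    if (!is.null(replay_pattern)) {
      if (is.null(net@replayBias[[replay_pattern]]))
        stop(sprintf("no replay bias armed for pattern '%s'", replay_pattern))
      gains <- net@replayBias[[replay_pattern]]
    }
    onsets <- drawSnbOnsets(net@snb, duration_ms)
    sb <- snbSpikes(net, onsets, gains)
    burst_iv <- cbind(onsets, onsets + net@snb$duration_ms)
  }

  sp <- lapply(seq_len(ne), function(e) {
    ev <- evoked[[e]]
    if (snb_mask && !is.null(burst_iv) && length(ev) && nrow(burst_iv)) {
      inb <- vapply(ev, function(t)
        any(t >= burst_iv[, 1] & t <= burst_iv[, 2]), logical(1))
      ev <- ev[!inb]
    }
    pmin(duration_ms, pmax(0, sort(c(ev, bg[[e]], sb[[e]]))))
  })
  spikeData(sp, duration_ms, net@geometry)
}

#' Threshold spike detection on a raw voltage trace
#'
#' Detects negative-going crossings of `-multiplier * sigma`, with a
#' refractory lockout after each accepted crossing. The default multiplier of
#' 6 matches standard extracellular spike detection at 6 sigma of the
#' biological noise; when no noise estimate is supplied the median absolute
#' deviation estimator `median(|v|)/0.6745` is used.
#'
#' @param voltage_trace numeric vector of samples.
#' @param sampling_hz sampling frequency (default 20000).
#' @param multiplier threshold in noise SDs (default 6).
#' @param noise_sigma known noise SD, or NULL to estimate.
#' @param refractory_ms lockout after each detection (default 1).
#' @return numeric vector of spike times in ms.
#' @export
detectSpikesThreshold <- function(voltage_trace, sampling_hz = 20000,
                                  multiplier = 6, noise_sigma = NULL,
                                  refractory_ms = 1) {
  stopifnot(multiplier > 0)
  if (!length(voltage_trace)) return(numeric(0))
  if (any(!is.finite(voltage_trace))) stop("voltage trace must be finite")
  if (is.null(noise_sigma))
    noise_sigma <- stats::median(abs(voltage_trace)) / 0.6745
  thr <- -multiplier * noise_sigma
  below <- voltage_trace < thr
  cross <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(cross)) return(numeric(0))
  lock <- refractory_ms / 1000 * sampling_hz
  keep <- cross[1]
  last <- cross[1]
  for (i in cross[-1]) {
    if (i - last >= lock) { keep <- c(keep, i); last <- i }
  }
  (keep - 1) / sampling_hz * 1000
}
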