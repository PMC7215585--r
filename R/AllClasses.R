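#' @import methods
NULL

#' StimulusSchedule: a timed sequence of optical stimulation frames
#'
#' Each frame lights a set of positions on a stimulation grid for `onMs`
#' milliseconds starting at `onsetMs`. Positions are 0-based row-major
#' indices into `gridShape`. Frames never overlap in time.
#'
#' @slot onsetMs numeric, strictly increasing frame onsets (ms).
#' @slot onMs numeric, light-on duration per frame (ms).
#' @slot positions list of integer vectors, lit 0-based grid indices per frame.
#' @slot intensity numeric, per-frame stimulation intensity (arbitrary units).
#' @slot gridShape integer(2), (rows, cols) of the stimulation grid.
#' @slot totalDurationMs numeric(1), schedule span; at least last onset + on.
#' @exportClass StimulusSchedule
setClass("StimulusSchedule",
  representation(
    onsetMs = "numeric",
    onMs = "numeric",
    positions = "list",
    intensity = "numeric",
    gridShape = "integer",
    totalDurationMs = "numeric"
  )
)

setValidity("StimulusSchedule", function(object) {
  n <- length(object@onsetMs)
  msg <- character(0)
  if (length(object@onMs) != n || length(object@positions) != n ||
      length(object@intensity) != n)
    msg <- c(msg, "onsetMs, onMs, positions, intensity must have equal length")
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be two positive integers")
  if (n > 0) {
    if (any(diff(object@onsetMs) <= 0))
      msg <- c(msg, "frame onsets must be strictly increasing")
    if (n > 1 && any(object@onsetMs[-1] < object@onsetMs[-n] + object@onMs[-n] - 1e-9))
      msg <- c(msg, "frames must not overlap in time")
    g <- prod(object@gridShape)
    for (k in seq_len(n)) {
      p <- object@positions[[k]]
      if (length(p) == 0L) { msg <- c(msg, "each frame must light >= 1 position"); break }
      if (any(p < 0L) || any(p >= g)) { msg <- c(msg, "position index out of grid bounds"); break }
      if (anyDuplicated(p)) { msg <- c(msg, "duplicate positions within one frame"); break }
    }
    if (object@totalDurationMs < object@onsetMs[n] + object@onMs[n] - 1e-9)
      msg <- c(msg, "totalDurationMs must cover the last frame")
  }
  if (length(msg)) msg else TRUE
})

#' PatternMask: a binary stimulation pattern on its own grid
#'
#' @slot name character(1) pattern label.
#' @slot mask integer matrix of 0/1; at least one lit cell.
#' @slot intensity numeric(1) luminance scalar used to balance the baseline
#'   response elicited by different patterns.
#' @exportClass PatternMask
setClass("PatternMask",
  representation(name = "character", mask = "matrix", intensity = "numeric")
)

setValidity("PatternMask", function(object) {
  m <- object@mask
  if (!all(m %in% c(0L, 1L))) return("mask must be binary (0/1)")
  if (sum(m) < 1) return("mask must have at least one lit cell")
  if (length(object@intensity) != 1L || object@intensity <= 0)
    return("intensity must be a positive scalar")
  TRUE
})

#' SpikeData: per-electrode spike timestamps from an MEA recording
#'
#' @slot spikes list of sorted numeric timestamp vectors (ms), one per
#'   electrode, named by electrode id.
#' @slot durationMs numeric(1) recording duration.
#' @slot geometry data.frame with columns electrode, row, col, x_um, y_um.
#' @exportClass SpikeData
setClass("SpikeData",
  representation(spikes = "list", durationMs = "numeric", geometry = "data.frame")
)

setValidity("SpikeData", function(object) {
  msg <- character(0)
  need <- c("electrode", "row", "col", "x_um", "y_um")
  if (!all(need %in% names(object@geometry)))
    msg <- c(msg, sprintf("geometry needs columns: %s", paste(need, collapse = ", ")))
  if (length(object@spikes) != nrow(object@geometry))
    msg <- c(msg, "one spike vector per geometry electrode required")
  if (!identical(names(object@spikes), as.character(object@geometry$electrode)))
    msg <- c(msg, "spike list names must match geometry electrode ids")
  if (length(object@durationMs) != 1L || object@durationMs < 0)
    msg <- c(msg, "durationMs must be a single non-negative number")
  for (s in object@spikes) {
    if (length(s) == 0L) next
    if (is.unsorted(s)) { msg <- c(msg, "spike timestamps must be sorted"); break }
    if (s[1] < 0 || s[length(s)] > object@durationMs + 1e-9) {
      msg <- c(msg, "spike timestamps must lie within [0, durationMs]"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruthNetwork: simulator state for a synthetic MEA culture
#'
#' Directed (stimulus position -> electrode) connections respond to light with
#' a per-trial probability and a Gaussian latency. Background activity is
#' homogeneous Poisson; synchronized network bursts (SNBs) recur with
#' Gaussian-distributed interburst intervals, during which every electrode
#' fires at `within_rate_hz` scaled by its participation gain and, if a replay
#' pattern is armed, by the replay-bias gain for that pattern.
#'
#' @slot gridShape integer(2) stimulation grid.
#' @slot geometry electrode data.frame (electrode, row, col, x_um, y_um).
#' @slot connections data.frame: pre (grid index), post (electrode id),
#'   response_prob, latency_mean_ms, latency_sd_ms.
#' @slot backgroundRateHz numeric, per-electrode background rate (recycled).
#' @slot snb list: ibi_mean_s, ibi_sd_s, duration_ms, within_rate_hz,
#'   participation (per-electrode gain).
#' @slot replayBias list mapping pattern name to a per-electrode gain vector
#'   applied during SNBs.
#' @exportClass GroundTruthNetwork
setClass("GroundTruthNetwork",
  representation(
    gridShape = "integer",
    geometry = "data.frame",
    connections = "data.frame",
    backgroundRateHz = "numeric",
    snb = "list",
    replayBias = "list"
  )
)

setValidity("GroundTruthNetwork", function(object) {
  msg <- character(0)
  cn <- object@connections
  need <- c("pre", "post", "response_prob", "latency_mean_ms", "latency_sd_ms")
  if (!all(need %in% names(cn)))
    msg <- c(msg, sprintf("connections needs columns: %s", paste(need, collapse = ", ")))
  else if (nrow(cn) > 0) {
    if (any(cn$response_prob < 0 | cn$response_prob > 1))
      msg <- c(msg, "response_prob must be in [0, 1]")
    if (any(cn$latency_mean_ms <= 0))
      msg <- c(msg, "latency_mean_ms must be > 0")
    if (any(cn$latency_sd_ms < 0))
      msg <- c(msg, "latency_sd_ms must be >= 0")
    g <- prod(object@gridShape)
    if (any(cn$pre < 0 | cn$pre >= g))
      msg <- c(msg, "connection pre index outside the stimulation grid")
    if (!all(cn$post %in% object@geometry$electrode))
      msg <- c(msg, "connection post electrode not in geometry")
  }
  if (any(object@backgroundRateHz < 0))
    msg <- c(msg, "background rate must be non-negative")
  s <- object@snb
  sneed <- c("ibi_mean_s", "ibi_sd_s", "duration_ms", "within_rate_hz", "participation")
  if (!all(sneed %in% names(s)))
    msg <- c(msg, sprintf("snb needs fields: %s", paste(sneed, collapse = ", ")))
  else {
    if (s$ibi_mean_s <= 0) msg <- c(msg, "snb ibi_mean_s must be > 0")
    if (any(s$participation < 0)) msg <- c(msg, "snb participation gains must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Correlogram: a stimulus-response cross-correlation histogram
#'
#' Counts of coincidences cch(tau) = sum_t i(t) j(t - tau) between a binarized
#' electrode response series i and a stimulus onset series j, over a searched
#' lag window. `lambda` is the mean count over the searched lags, the null
#' rate of the Poisson peak test.
#'
#' @slot lagsMs numeric, searched lags (ms).
#' @slot counts numeric, cch value per lag.
#' @slot peakValue numeric(1), max of counts.
#' @slot peakLagMs numeric(1), lag at the (first) peak.
#' @slot lambda numeric(1), mean of counts over searched lags.
#' @exportClass Correlogram
setClass("Correlogram",
  representation(lagsMs = "numeric", counts = "numeric",
                 peakValue = "numeric", peakLagMs = "numeric", lambda = "numeric")
)

setValidity("Correlogram", function(object) {
  if (length(object@lagsMs) != length(object@counts))
    return("lags and counts must align")
  if (length(object@counts) && any(object@counts < 0))
    return("counts must be non-negative")
  if (length(object@counts) && abs(object@peakValue - max(object@counts)) > 1e-9)
    return("peakValue must equal max(counts)")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

#' ConnectivityMap: detected directed connections from one probing session
#'
#' @slot connections data.frame with one row per detected (pre, post) pair:
#'   pre, post, latency_ms, peak, peak_per100, p_value, psth_area, psth_peak,
#'   n_resp, n_trials.
#' @slot gridShape integer(2) stimulation grid of the probing schedule.
#' @slot geometry electrode data.frame.
#' @slot params list of detection parameters used.
#' @slot meta list of probing metadata.
#' @exportClass ConnectivityMap
setClass("ConnectivityMap",
  representation(connections = "data.frame", gridShape = "integer",
                 geometry = "data.frame", params = "list", meta = "list")
)

setValidity("ConnectivityMap", function(object) {
  cn <- object@connections
  need <- c("pre", "post", "latency_ms", "peak", "peak_per100", "p_value",
            "psth_area", "psth_peak", "n_resp", "n_trials")
  if (!all(need %in% names(cn)))
    return(sprintf("connections needs columns: %s", paste(need, collapse = ", ")))
  if (nrow(cn) > 0) {
    if (anyDuplicated(cn[, c("pre", "post")]))
      return("(pre, post) pairs must be unique")
    if (any(cn$p_value < 0 | cn$p_value > 1))
      return("p_value must be in [0, 1]")
    if (any(cn$n_resp < 0 | cn$n_resp > cn$n_trials))
      return("n_resp must be within [0, n_trials]")
  }
  TRUE
})

#' BurstSet: detected synchronized network burst intervals
#'
#' @slot intervals data.frame: start_ms, end_ms, n_electrodes; disjoint,
#'   ordered, end > start.
#' @exportClass BurstSet
setClass("BurstSet", representation(intervals = "data.frame"))

setValidity("BurstSet", function(object) {
  iv <- object@intervals
  need <- c("start_ms", "end_ms", "n_electrodes")
  if (!all(need %in% names(iv)))
    return(sprintf("intervals needs columns: %s", paste(need, collapse = ", ")))
  if (nrow(iv) > 0) {
    if (any(iv$end_ms <= iv$start_ms)) return("interval end must exceed start")
    if (nrow(iv) > 1 && any(iv$start_ms[-1] < iv$end_ms[-nrow(iv)]))
      return("intervals must be disjoint and ordered")
  }
  TRUE
})

#' EfficacyChangeSummary: connection-level efficacy changes between probings
#'
#' Relative PSTH-area changes for every connection of the before-map, with the
#' network-level potentiation/depression summary: P sums positive changes
#' (values above +100% counted as 101), N sums negative changes, R = P/|N|.
#'
#' @slot perConnection data.frame: pre, post, area_before, area_after,
#'   rel_change_pct, rel_change_capped, latency_before_ms, latency_after_ms,
#'   latency_delta_ms.
#' @slot P numeric(1) summed positive capped changes (percent).
#' @slot N numeric(1) summed negative changes (percent, <= 0).
#' @slot R numeric(1) P/|N|; NaN when N = 0.
#' @slot nSkipped integer(1) connections skipped for zero before-area.
#' @exportClass EfficacyChangeSummary
setClass("EfficacyChangeSummary",
  representation(perConnection = "data.frame", P = "numeric", N = "numeric",
                 R = "numeric", nSkipped = "integer")
)

setValidity("EfficacyChangeSummary", function(object) {
  if (object@N > 1e-9) return("N must be <= 0")
  if (object@P < -1e-9) return("P must be >= 0")
  pc <- object@perConnection
  if (nrow(pc) > 0 && any(pc$rel_change_capped > 101 + 1e-9))
    return("capped changes must be <= 101")
  if (!is.nan(object@R) && object@R < 0) return("R must be >= 0 or NaN")
  TRUE
})

#' TrialTensor: binned pattern-evoked responses, trials x electrodes x bins
#'
#' @slot counts numeric array [trial, electrode, time bin] of spike counts.
#' @slot labels character, per-trial pattern label.
#' @slot binMs numeric(1), bin width (ms).
#' @slot windowMs numeric(1), response window length (ms).
#' @slot electrodes integer, electrode ids in array order.
#' @slot dropped data.frame log of removed noisy trials (trial, label,
#'   onset_ms, reason).
#' @exportClass TrialTensor
setClass("TrialTensor",
  representation(counts = "array", labels = "character", binMs = "numeric",
                 windowMs = "numeric", electrodes = "integer",
                 dropped = "data.frame")
)

setValidity("TrialTensor", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L) return("counts must be a 3-d array")
  if (d[1] != length(object@labels)) return("one label per trial required")
  if (d[2] != length(object@electrodes)) return("electrode dim mismatch")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (abs(d[3] * object@binMs - object@windowMs) > 1e-6)
    return("bins * binMs must equal windowMs")
  TRUE
})

#' PatternClassifier: a trained SVM pattern decoder over 10-ms bins
#'
#' @slot model the fitted e1071/libsvm model.
#' @slot classes character, pattern labels seen in training.
#' @slot binMs numeric(1) instance bin width.
#' @slot electrodes integer, feature order.
#' @slot mode character(1), "pool_all" or "split".
#' @slot heldOut TrialTensor of held-out trials (split mode) or NULL.
#' @slot trainedLabel character(1), the familiar pattern, or NA.
#' @exportClass PatternClassifier
setClass("PatternClassifier",
  representation(model = "ANY", classes = "character", binMs = "numeric",
                 electrodes = "integer", mode = "character",
                 heldOut = "ANY", trainedLabel = "character")
)

#' ReplaySummary: SNB-bin classification ratios and the familiarity metric
#'
#' @slot ratios named numeric, per-class fraction of classified SNB bins
#'   (non-negative, sums to 1).
#' @slot nSnbBins integer(1), number of classified bins.
#' @slot delta numeric(1), familiarity metric on the ratios (NA when no
#'   trained label is known).
#' @slot trainedLabel character(1) or NA.
#' @exportClass ReplaySummary
setClass("ReplaySummary",
  representation(ratios = "numeric", nSnbBins = "integer", delta = "numeric",
                 trainedLabel = "character")
)

setValidity("ReplaySummary", function(object) {
  if (any(object@ratios < -1e-9)) return("ratios must be non-negative")
  if (abs(sum(object@ratios) - 1) > 1e-6) return("ratios must sum to 1")
  if (object@nSnbBins < 1L) return("at least one SNB bin required")
  TRUE
})

#' ExperimentResult: all outputs of one simulated learning experiment
#'
#' @slot paradigm character(1), "conventional" or "rdm".
#' @slot phases character, executed phase sequence.
#' @slot maps list of ConnectivityMap, one per probing.
#' @slot efficacy list of EfficacyChangeSummary keyed by phase.
#' @slot firingRateDelta numeric(1) familiarity metric on testing firing rates.
#' @slot replayBefore,replayAfter ReplaySummary or NULL.
#' @slot qc list from [cultureQc()].
#' @slot bi numeric(1) burstiness index of the pre-run recording.
#' @slot manifest list: seed, config, package version.
#' @exportClass ExperimentResult
setClass("ExperimentResult",
  representation(paradigm = "character", phases = "character", maps = "list",
                 efficacy = "list", firingRateDelta = "numeric",
                 replayBefore = "ANY", replayAfter = "ANY",
                 qc = "list", bi = "numeric", manifest = "list")
)
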