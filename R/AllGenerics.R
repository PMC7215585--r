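#' @include AllClasses.R
NULL

#' Accessors for meaplast objects
#'
#' Small accessor generics so user code never reaches into slots:
#' `spikes()` returns the per-electrode timestamp list, `durationMs()` the
#' recording or schedule span, `geometry()` the electrode table, `gridShape()`
#' the stimulation grid, `connections()` the edge table of a
#' [ConnectivityMap-class] or [GroundTruthNetwork-class], `nFrames()` /
#' `frameOnsets()` / `framePositions()` the frame structure of a
#' [StimulusSchedule-class], and `intervals()` / `nBursts()` the burst table
#' of a [BurstSet-class].
#'
#' @param x an object of the documented class.
#' @return the corresponding slot content (see details above).
#' @name accessors
#' @aliases spikes durationMs geometry gridShape connections nFrames
#'   frameOnsets framePositions intervals nBursts
NULL

#' @rdname accessors
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setGeneric("durationMs", function(x) standardGeneric("durationMs"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("connections", function(x) standardGeneric("connections"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameOnsets", function(x) standardGeneric("frameOnsets"))
#' @rdname accessors
#' @export
setGeneric("framePositions", function(x) standardGeneric("framePositions"))
#' @rdname accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @rdname accessors
#' @export
setGeneric("nBursts", function(x) standardGeneric("nBursts"))

#' @rdname accessors
setMethod("spikes", "SpikeData", function(x) x@spikes)
#' @rdname accessors
setMethod("durationMs", "SpikeData", function(x) x@durationMs)
#' @rdname accessors
setMethod("durationMs", "StimulusSchedule", function(x) x@totalDurationMs)
#' @rdname accessors
setMethod("geometry", "SpikeData", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "GroundTruthNetwork", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "ConnectivityMap", function(x) x@geometry)
#' @rdname accessors
setMethod("gridShape", "StimulusSchedule", function(x) x@gridShape)
#' @rdname accessors
setMethod("gridShape", "GroundTruthNetwork", function(x) x@gridShape)
#' @rdname accessors
setMethod("gridShape", "ConnectivityMap", function(x) x@gridShape)
#' @rdname accessors
setMethod("connections", "ConnectivityMap", function(x) x@connections)
#' @rdname accessors
setMethod("connections", "GroundTruthNetwork", function(x) x@connections)
#' @rdname accessors
setMethod("nFrames", "StimulusSchedule", function(x) length(x@onsetMs))
#' @rdname accessors
setMethod("frameOnsets", "StimulusSchedule", function(x) x@onsetMs)
#' @rdname accessors
setMethod("framePositions", "StimulusSchedule", function(x) x@positions)
#' @rdname accessors
setMethod("intervals", "BurstSet", function(x) x@intervals)
#' @rdname accessors
setMethod("nBursts", "BurstSet", function(x) nrow(x@intervals))

setMethod("show", "StimulusSchedule", function(object) {
  cat(sprintf("StimulusSchedule: %d frames on a %dx%d grid, %.1f s\n",
              length(object@onsetMs), object@gridShape[1], object@gridShape[2],
              object@totalDurationMs / 1000))
  if (length(object@onsetMs)) {
    cat(sprintf("  on %.0f ms / frame, %d position(s) in frame 1\n",
                object@onMs[1], length(object@positions[[1]])))
  }
  invisible(NULL)
})

setMethod("show", "PatternMask", function(object) {
  cat(sprintf("PatternMask '%s': %dx%d grid, %d lit cells, intensity %.2f\n",
              object@name, nrow(object@mask), ncol(object@mask),
              sum(object@mask), object@intensity))
  invisible(NULL)
})

setMethod("show", "SpikeData", function(object) {
  n <- sum(lengths(object@spikes))
  cat(sprintf("SpikeData: %d electrodes, %d spikes, %.1f s\n",
              length(object@spikes), n, object@durationMs / 1000))
  invisible(NULL)
})

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf(
    "GroundTruthNetwork: %dx%d stimulation grid, %d electrodes, %d connections\n",
    object@gridShape[1], object@gridShape[2], nrow(object@geometry),
    nrow(object@connections)))
  cat(sprintf("  background %.2g Hz; SNB ibi %.1f s, duration %.0f ms%s\n",
              mean(object@backgroundRateHz), object@snb$ibi_mean_s,
              object@snb$duration_ms,
              if (length(object@replayBias))
                sprintf("; replay bias armed for: %s",
                        paste(names(object@replayBias), collapse = ", "))
              else ""))
  invisible(NULL)
})

setMethod("show", "Correlogram", function(object) {
  cat(sprintf("Correlogram: peak %g at %g ms (lambda %.4g) over lags [%g, %g] ms\n",
              object@peakValue, object@peakLagMs, object@lambda,
              min(object@lagsMs), max(object@lagsMs)))
  invisible(NULL)
})

setMethod("show", "ConnectivityMap", function(object) {
  cat(sprintf("ConnectivityMap: %d connections (%dx%d grid -> %d electrodes)\n",
              nrow(object@connections), object@gridShape[1], object@gridShape[2],
              nrow(object@geometry)))
  if (nrow(object@connections)) {
    cat(sprintf("  latency %.1f +/- %.1f ms; median peak/100 trials %.0f\n",
                mean(object@connections$latency_ms),
                stats::sd(object@connections$latency_ms),
                stats::median(object@connections$peak_per100)))
  }
  invisible(NULL)
})

setMethod("show", "BurstSet", function(object) {
  iv <- object@intervals
  cat(sprintf("BurstSet: %d bursts", nrow(iv)))
  if (nrow(iv))
    cat(sprintf(", mean duration %.0f ms", mean(iv$end_ms - iv$start_ms)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "EfficacyChangeSummary", function(object) {
  cat(sprintf("EfficacyChangeSummary: %d connections, P = %.1f%%, N = %.1f%%, R = %s\n",
              nrow(object@perConnection), object@P, object@N,
              if (is.nan(object@R)) "NaN (no depression)" else sprintf("%.3g", object@R)))
  invisible(NULL)
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@counts)
  cat(sprintf("TrialTensor: %d trials x %d electrodes x %d bins of %g ms (%d dropped)\n",
              d[1], d[2], d[3], object@binMs, nrow(object@dropped)))
  invisible(NULL)
})

setMethod("show", "PatternClassifier", function(object) {
  cat(sprintf("PatternClassifier (%s): classes %s, %d features, %g-ms bins\n",
              object@mode, paste(object@classes, collapse = "/"),
              length(object@electrodes), object@binMs))
  invisible(NULL)
})

setMethod("show", "ReplaySummary", function(object) {
  cat(sprintf("ReplaySummary: %d SNB bins\n", object@nSnbBins))
  r <- object@ratios
  cat(sprintf("  %s\n", paste(sprintf("%s: %.3f", names(r), r), collapse = ", ")))
  if (!is.na(object@delta))
    cat(sprintf("  familiarity delta (familiar = %s): %.3f\n",
                object@trainedLabel, object@delta))
  invisible(NULL)
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult (%s paradigm): %d probings\n",
              object@paradigm, length(object@maps)))
  for (ph in names(object@efficacy)) {
    cat(sprintf("  R[%s] = %.3g\n", ph, object@efficacy[[ph]]@R))
  }
  cat(sprintf("  firing-rate delta = %.3f; BI = %.2f; QC pass = %s\n",
              object@firingRateDelta, object@bi, object@qc$pass))
  invisible(NULL)
})
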