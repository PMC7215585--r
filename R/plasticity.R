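#' @include AllClasses.R cch.R
NULL

#' Compare two probings: connection-level efficacy changes and P/N/R
#'
#' Anchored on the connections detected in `map_before`: for each (pre, post)
#' pair the PSTH area is recomputed on the after-session (whether or not the
#' pair is independently re-detected there), and the relative change
#' `(area_after - area_before) / area_before * 100` is taken. Positive
#' changes above 100% enter the potentiation sum P as 101; N sums the
#' negative changes; R = P/|N| summarizes the network-level outcome (R > 1:
#' LTP, R < 1: LTD). The response latency is re-estimated from the
#' after-session correlogram for a per-connection latency delta.
#'
#' @param map_before baseline [ConnectivityMap-class].
#' @param map_after optional after-map; when given, connections re-detected
#'   there are flagged in the per-connection table.
#' @param spikes_after [SpikeData-class] of the after probing session.
#' @param schedule_after probing [StimulusSchedule-class] of that session.
#' @param cap capped contribution of changes above +100% (default 101).
#' @return an [EfficacyChangeSummary-class]; R is NaN when N = 0.
#' @export
compareMaps <- function(map_before, map_after = NULL, spikes_after,
                        schedule_after, cap = 101) {
  p <- map_before@params
  if (!length(p)) p <- detectionParams()
  byPos <- onsetsByPosition(schedule_after)
  cn <- map_before@connections
  geom <- spikes_after@geometry
  nskip <- 0L
  out <- vector("list", nrow(cn))
  for (i in seq_len(nrow(cn))) {
    if (cn$psth_area[i] <= 0) { nskip <- nskip + 1L; next }
    onsets <- byPos[[as.character(cn$pre[i])]]
    if (is.null(onsets)) { nskip <- nskip + 1L; next }
    sp <- spikes_after@spikes[[match(cn$post[i], geom$electrode)]]
    psth <- computePsth(sp, onsets, p$psth_window_ms, p$bin_ms)
    cch <- cchFromTimes(sp, onsets, p$lag_range_ms, p$bin_ms)
    rel <- (psth$area - cn$psth_area[i]) / cn$psth_area[i] * 100
    out[[i]] <- data.frame(
      pre = cn$pre[i], post = cn$post[i],
      area_before = cn$psth_area[i], area_after = psth$area,
      rel_change_pct = rel,
      rel_change_capped = if (rel > 100) cap else rel,
      latency_before_ms = cn$latency_ms[i],
      latency_after_ms = cch@peakLagMs,
      latency_delta_ms = cch@peakLagMs - cn$latency_ms[i]
    )
  }
  if (nskip > 0)
    warning(sprintf("%d connection(s) skipped (zero baseline area or no after-trials)",
                    nskip))
  pc <- if (any(!vapply(out, is.null, logical(1))))
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  else
    data.frame(pre = integer(0), post = integer(0), area_before = numeric(0),
               area_after = numeric(0), rel_change_pct = numeric(0),
               rel_change_capped = numeric(0), latency_before_ms = numeric(0),
               latency_after_ms = numeric(0), latency_delta_ms = numeric(0))
  if (!is.null(map_after) && nrow(pc)) {
    key_after <- paste(map_after@connections$pre, map_after@connections$post)
    pc$redetected <- paste(pc$pre, pc$post) %in% key_after
  }
  rownames(pc) <- NULL
  P <- sum(pc$rel_change_capped[pc$rel_change_capped > 0])
  N <- sum(pc$rel_change_pct[pc$rel_change_pct < 0])
  R <- if (N == 0) NaN else P / abs(N)
  new("EfficacyChangeSummary", perConnection = pc, P = P, N = N, R = R,
      nSkipped = nskip)
}

#' Burstiness index of a recording
#'
#' Pools all electrodes' spikes into `bin_s` bins and takes the fraction `f`
#' of spikes contained in the `top_frac` most active bins; BI =
#' (f - top_frac)/(1 - top_frac), 0 for not bursting at all and 1 for
#' maximal burstiness. With the default 1-s bins and 15% top bins this
#' assumes an average interburst interval of 6.7 s (1 s / 0.15); for cultures
#' bursting faster, pass their estimated IBI via `ibi_est_s` and the top
#' fraction is raised to `bin_s / ibi_est_s`.
#'
#' @param spike_data a [SpikeData-class] with at least one spike.
#' @param bin_s bin width in seconds (default 1).
#' @param top_frac fraction of most-active bins (default 0.15).
#' @param ibi_est_s optional estimated interburst interval for the adaptive
#'   top fraction.
#' @return BI, a number <= 1.
#' @export
burstinessIndex <- function(spike_data, bin_s = 1, top_frac = 0.15,
                            ibi_est_s = NULL) {
  if (!is.null(ibi_est_s) && is.finite(ibi_est_s) && ibi_est_s > 0)
    top_frac <- min(1, max(top_frac, bin_s / ibi_est_s))
  dur_s <- spike_data@durationMs / 1000
  if (dur_s < bin_s / top_frac)
    stop("recording too short: need at least one top bin")
  all_sp <- unlist(spike_data@spikes, use.names = FALSE)
  if (!length(all_sp)) stop("no spikes in the recording")
  nbins <- ceiling(dur_s / bin_s)
  counts <- tabulate(pmin(nbins, floor(all_sp / (bin_s * 1000)) + 1L),
                     nbins = nbins)
  ntop <- max(1L, round(top_frac * nbins))
  f <- sum(sort(counts, decreasing = TRUE)[seq_len(ntop)]) / sum(counts)
  (f - top_frac) / (1 - top_frac)
}

#' Default SNB-detector parameters
#'
#' @param rate_bin_ms population-rate bin (default 10 ms).
#' @param rate_threshold_mult burst bins exceed this multiple of the median
#'   nonzero population rate (default 5).
#' @param min_electrode_frac minimum fraction of electrodes active in a burst
#'   bin (default 0.25).
#' @param min_duration_ms shortest retained burst (default 100 ms).
#' @param merge_gap_ms adjacent burst bins closer than this merge (default
#'   100 ms).
#' @return parameter list for [detectSnbs()].
#' @export
snbParams <- function(rate_bin_ms = 10, rate_threshold_mult = 5,
                      min_electrode_frac = 0.25, min_duration_ms = 100,
                      merge_gap_ms = 100) {
  list(rate_bin_ms = rate_bin_ms, rate_threshold_mult = rate_threshold_mult,
       min_electrode_frac = min_electrode_frac,
       min_duration_ms = min_duration_ms, merge_gap_ms = merge_gap_ms)
}

#' Detect synchronized network bursts
#'
#' Burst bins are those whose population firing rate exceeds
#' `rate_threshold_mult` times the median nonzero rate AND in which at least
#' `min_electrode_frac` of the electrodes are active. Burst bins separated by
#' gaps up to `merge_gap_ms` are merged into intervals; intervals shorter
#' than `min_duration_ms` are dropped.
#'
#' @param spike_data a [SpikeData-class].
#' @param params list from [snbParams()].
#' @return a [BurstSet-class] (possibly empty).
#' @export
detectSnbs <- function(spike_data, params = snbParams()) {
  p <- utils::modifyList(snbParams(), params)
  dur <- spike_data@durationMs
  stopifnot(dur > 0)
  nb <- ceiling(dur / p$rate_bin_ms)
  ne <- length(spike_data@spikes)
  counts <- integer(nb)
  active <- integer(nb)
  for (sp in spike_data@spikes) {
    if (!length(sp)) next
    idx <- pmin(nb, floor(sp / p$rate_bin_ms) + 1L)
    tb <- tabulate(idx, nbins = nb)
    counts <- counts + tb
    active <- active + (tb > 0L)
  }
  empty <- new("BurstSet", intervals = data.frame(
    start_ms = numeric(0), end_ms = numeric(0), n_electrodes = integer(0)))
  nz <- counts[counts > 0]
  if (!length(nz)) return(empty)
  thr <- p$rate_threshold_mult * stats::median(nz)
  is_burst <- counts > thr & active >= ceiling(p$min_electrode_frac * ne)
  bb <- which(is_burst)
  if (!length(bb)) return(empty)
  gap_bins <- ceiling(p$merge_gap_ms / p$rate_bin_ms)
  brk <- c(0L, which(diff(bb) > gap_bins), length(bb))
  iv <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    first <- bb[brk[i] + 1L]; last <- bb[brk[i + 1L]]
    c((first - 1L) * p$rate_bin_ms, last * p$rate_bin_ms)
  }))
  keep <- (iv[, 2] - iv[, 1]) >= p$min_duration_ms
  iv <- iv[keep, , drop = FALSE]
  if (!nrow(iv)) return(empty)
  nel <- vapply(seq_len(nrow(iv)), function(i) {
    sum(vapply(spike_data@spikes, function(sp)
      any(sp >= iv[i, 1] & sp < iv[i, 2]), logical(1)))
  }, integer(1))
  new("BurstSet", intervals = data.frame(
    start_ms = iv[, 1], end_ms = iv[, 2], n_electrodes = nel))
}

#' Mean interburst interval of a burst set
#'
#' @param bursts a [BurstSet-class].
#' @return mean onset-to-onset interval in seconds, or NA with fewer than two
#'   bursts.
#' @export
interburstInterval <- function(bursts) {
  iv <- bursts@intervals
  if (nrow(iv) < 2L) return(NA_real_)
  mean(diff(iv$start_ms)) / 1000
}

#' Culture quality control
#'
#' A culture passes when its spontaneous SNB frequency lies in
#' \[0.05, 0.2\] Hz (neither too quiet nor too active) and, when an RDM
#' suppression ratio is supplied, RDM stimulation suppressed bursting
#' effectively (R <= 0.2).
#'
#' @param bursts a [BurstSet-class] from a resting recording.
#' @param duration_s length of that recording in seconds.
#' @param rdm_R optional network efficacy ratio measured across RDM
#'   stimulation.
#' @return list with `pass` (logical), `snb_freq_hz`, and `reasons`
#'   (character, empty on pass).
#' @export
cultureQc <- function(bursts, duration_s, rdm_R = NULL) {
  stopifnot(duration_s > 0)
  freq <- nBursts(bursts) / duration_s
  reasons <- character(0)
  if (freq > 0.2) reasons <- c(reasons, sprintf("too active (SNB frequency %.3f Hz > 0.2 Hz)", freq))
  if (freq < 0.05) reasons <- c(reasons, sprintf("too quiet (SNB frequency %.3f Hz < 0.05 Hz)", freq))
  if (!is.null(rdm_R) && !is.nan(rdm_R) && rdm_R > 0.2)
    reasons <- c(reasons, sprintf("bursting not suppressed by RDMs (R = %.2f > 0.2)", rdm_R))
  list(pass = length(reasons) == 0L, snb_freq_hz = freq, reasons = reasons)
}

#' Per-electrode firing-rate map of burst-dominated activity
#'
#' For each electrode, firing rate is computed in `bin_ms` bins and the mean
#' over that electrode's `top_frac` most active bins is reported, giving a
#' within-burst rate map (default: 100-ms bins, top 15%).
#'
#' @param spike_data a [SpikeData-class].
#' @param bin_ms time bin (default 100).
#' @param top_frac fraction of top bins averaged (default 0.15).
#' @return data.frame: electrode, rate_hz.
#' @export
firingRateMap <- function(spike_data, bin_ms = 100, top_frac = 0.15) {
  dur <- spike_data@durationMs
  stopifnot(dur > 0)
  nb <- ceiling(dur / bin_ms)
  ntop <- max(1L, round(top_frac * nb))
  rate <- vapply(spike_data@spikes, function(sp) {
    if (!length(sp)) return(0)
    counts <- tabulate(pmin(nb, floor(sp / bin_ms) + 1L), nbins = nb)
    mean(sort(counts, decreasing = TRUE)[seq_len(ntop)]) / (bin_ms / 1000)
  }, numeric(1))
  data.frame(electrode = spike_data@geometry$electrode, rate_hz = unname(rate))
}
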