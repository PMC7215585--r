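#' @include AllClasses.R constructors.R
NULL

#' Binarize event times into 0/1 time bins
#'
#' One entry per `bin_ms` window over `[0, duration_ms]`; an entry is 1 when
#' at least one event falls in that bin (binary, not a count).
#'
#' @param event_times numeric event times in ms.
#' @param duration_ms series duration.
#' @param bin_ms bin width (default 1).
#' @return integer 0/1 vector of length `ceiling(duration_ms / bin_ms)`.
#' @export
binarizeEvents <- function(event_times, duration_ms, bin_ms = 1) {
  stopifnot(bin_ms > 0)
  n <- ceiling(duration_ms / bin_ms)
  if (length(event_times)) {
    if (any(event_times < 0 | event_times > duration_ms))
      stop("event times outside [0, duration_ms]")
    idx <- pmin(n, floor(event_times / bin_ms) + 1L)
    v <- integer(n)
    v[idx] <- 1L
    v
  } else integer(n)
}

#' Cross-correlation histogram between response and stimulus series
#'
#' Computes cch(tau) = sum_t i(t) j(t - tau) for each lag tau in the searched
#' window, where `i` is the binarized electrode response and `j` the
#' binarized stimulus onsets, on a common `bin_ms` binning. The peak, its lag
#' and the mean count over the searched lags (lambda, the Poisson null rate
#' of the peak test) are recorded.
#'
#' @param response integer 0/1 response series (from [binarizeEvents()]).
#' @param stimulus integer 0/1 stimulus series of the same length.
#' @param lag_range_ms numeric(2) searched lag window in ms (default 0-100).
#' @param bin_ms bin width of both series (default 1).
#' @return a [Correlogram-class].
#' @export
crossCorrelogram <- function(response, stimulus, lag_range_ms = c(0, 100),
                             bin_ms = 1) {
  if (length(response) != length(stimulus))
    stop("response and stimulus series must have the same length and binning")
  lag_bins <- seq(round(lag_range_ms[1] / bin_ms), round(lag_range_ms[2] / bin_ms))
  n <- length(response)
  o <- which(stimulus != 0)
  counts <- vapply(lag_bins, function(lag) {
    t <- o + lag
    t <- t[t >= 1 & t <= n]
    if (length(t)) sum(response[t]) else 0
  }, numeric(1))
  lags_ms <- lag_bins * bin_ms
  if (!length(counts)) stop("empty lag range")
  pk <- max(counts)
  new("Correlogram", lagsMs = lags_ms, counts = counts,
      peakValue = pk, peakLagMs = lags_ms[which.max(counts)],
      lambda = mean(counts))
}

#' Poisson probability of a correlogram peak
#'
#' The chance of observing a peak count of `k` under a Poisson null with mean
#' `lambda` (the mean correlogram count over the searched lags), evaluated as
#' the pmf `exp(-lambda) lambda^k / k!` in log space. With `upper_tail = TRUE`
#' the upper-tail probability `P(X >= k)` is returned instead.
#'
#' For `lambda = 0` the empty-null convention applies: probability 1 when
#' `k = 0`, otherwise 0.
#'
#' @param k observed peak count (non-negative integer).
#' @param lambda Poisson mean (>= 0).
#' @param upper_tail return P(X >= k) instead of the pmf.
#' @return a probability in \[0, 1\].
#' @export
poissonPeakPvalue <- function(k, lambda, upper_tail = FALSE) {
  if (any(k < 0) || any(abs(k - round(k)) > 1e-9))
    stop("k must be a non-negative integer")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  k <- round(k)
  if (upper_tail)
    stats::ppois(k - 1, lambda, lower.tail = FALSE)
  else
    stats::dpois(k, lambda)
}

#' Poststimulus time histogram and its area
#'
#' Pools postsynaptic spikes in `[onset, onset + window_ms)` over all
#' stimulation trials, bins them at `bin_ms` and normalizes by the trial
#' count. The area (total spikes per trial over the window) is the connection
#' efficacy measure; the peak is the largest normalized bin.
#'
#' @param post_spikes numeric spike times (ms) of the postsynaptic electrode.
#' @param stim_onsets numeric stimulation onset times (ms); at least one.
#' @param window_ms response window length (default 100).
#' @param bin_ms bin width (default 1).
#' @return list with `psth` (spikes/trial per bin), `bin_starts_ms`, `area`
#'   (spikes/trial) and `peak`.
#' @export
computePsth <- function(post_spikes, stim_onsets, window_ms = 100, bin_ms = 1) {
  stopifnot(window_ms > 0, bin_ms > 0)
  nt <- length(stim_onsets)
  if (nt == 0) stop("at least one stimulation trial is required")
  nb <- ceiling(window_ms / bin_ms)
  counts <- integer(nb)
  sp <- sort(post_spikes)
  for (on in stim_onsets) {
    lo <- findInterval(on, sp, left.open = TRUE) + 1L
    hi <- findInterval(on + window_ms, sp, left.open = TRUE)
    if (hi >= lo) {
      rel <- sp[lo:hi] - on
      rel <- rel[rel < window_ms]  # [onset, onset + window)
      if (length(rel)) {
        idx <- pmin(nb, floor(rel / bin_ms) + 1L)
        counts <- counts + tabulate(idx, nbins = nb)
      }
    }
  }
  psth <- counts / nt
  list(psth = psth, bin_starts_ms = (seq_len(nb) - 1) * bin_ms,
       area = sum(psth), peak = if (nb) max(psth) else 0)
}

#' Default connection-detection parameters
#'
#' @param p_threshold Poisson peak-test threshold (default 1e-6; 1e-5 admits
#'   too many connections from tonically firing channels, 1e-7 too few).
#' @param min_resp_trials responding-trial criterion; NULL means more than
#'   half, i.e. `ceiling(n_trials / 2)`.
#' @param lag_range_ms searched CCH lag window (default 0-100 ms, one frame).
#' @param resp_window_ms half-width of the trial-response window around the
#'   peak lag (default 5 ms).
#' @param psth_window_ms PSTH window for the efficacy area (default 100 ms).
#' @param bin_ms time binning (default 1 ms).
#' @param upper_tail use the upper-tail Poisson probability instead of the
#'   pmf (default FALSE).
#' @return list of parameters for [detectConnection()] and
#'   [buildConnectivityMap()].
#' @export
detectionParams <- function(p_threshold = 1e-6, min_resp_trials = NULL,
                            lag_range_ms = c(0, 100), resp_window_ms = 5,
                            psth_window_ms = 100, bin_ms = 1,
                            upper_tail = FALSE) {
  list(p_threshold = p_threshold, min_resp_trials = min_resp_trials,
       lag_range_ms = lag_range_ms, resp_window_ms = resp_window_ms,
       psth_window_ms = psth_window_ms, bin_ms = bin_ms,
       upper_tail = upper_tail)
}

## internal: CCH counts from spike times and onset times without
## materializing the full binary series; equivalent to crossCorrelogram on
## binarized series (spikes collapsing into one bin count once)
cchFromTimes <- function(post_spikes, stim_onsets, lag_range_ms, bin_ms) {
  lag_bins <- seq(round(lag_range_ms[1] / bin_ms), round(lag_range_ms[2] / bin_ms))
  sbin <- unique(floor(post_spikes / bin_ms))
  obin <- floor(stim_onsets / bin_ms)
  counts <- numeric(length(lag_bins))
  if (length(sbin) && length(obin)) {
    d <- as.vector(outer(sbin, obin, "-"))
    d <- d[d >= lag_bins[1] & d <= lag_bins[length(lag_bins)]]
    if (length(d))
      counts <- as.numeric(tabulate(d - lag_bins[1] + 1L, nbins = length(lag_bins)))
  }
  lags_ms <- lag_bins * bin_ms
  new("Correlogram", lagsMs = lags_ms, counts = counts,
      peakValue = max(counts), peakLagMs = lags_ms[which.max(counts)],
      lambda = mean(counts))
}

#' Test one (stimulus position, electrode) pair for a directed connection
#'
#' Computes the stimulus-response correlogram over the searched lag window,
#' takes the peak `k` at lag `tau_p`, evaluates the Poisson peak probability
#' against `lambda` (the mean correlogram count), and counts trials with at
#' least one spike within `tau_p` +/- `resp_window_ms`. A connection is drawn
#' when the probability falls below `p_threshold` AND the electrode responds
#' in more than half of the trials (>= `min_resp_trials`). The CCH peak is
#' also reported normalized to 100 trials.
#'
#' @param post_spikes numeric spike times (ms) of the candidate postsynaptic
#'   electrode.
#' @param stim_onsets numeric stimulation onsets (ms) of the candidate
#'   presynaptic position; at least one.
#' @param params list from [detectionParams()].
#' @return a one-row data.frame (latency_ms, peak, peak_per100, p_value,
#'   psth_area, psth_peak, n_resp, n_trials) or NULL when no connection is
#'   drawn.
#' @export
detectConnection <- function(post_spikes, stim_onsets,
                             params = detectionParams()) {
  p <- utils::modifyList(detectionParams(), params)
  nt <- length(stim_onsets)
  if (nt == 0) stop("at least one stimulus onset is required")
  min_resp <- if (is.null(p$min_resp_trials)) ceiling(nt / 2) else p$min_resp_trials

  cch <- cchFromTimes(post_spikes, stim_onsets, p$lag_range_ms, p$bin_ms)
  k <- cch@peakValue
  pval <- poissonPeakPvalue(k, cch@lambda, upper_tail = p$upper_tail)
  if (pval >= p$p_threshold) return(NULL)

  tau_p <- cch@peakLagMs
  sp <- sort(post_spikes)
  lo <- stim_onsets + tau_p - p$resp_window_ms
  hi <- stim_onsets + tau_p + p$resp_window_ms
  n_resp <- sum(findInterval(hi, sp) - findInterval(lo, sp, left.open = TRUE) >= 1)
  if (n_resp < min_resp) return(NULL)

  psth <- computePsth(sp, stim_onsets, p$psth_window_ms, p$bin_ms)
  data.frame(latency_ms = tau_p, peak = k, peak_per100 = k / nt * 100,
             p_value = pval, psth_area = psth$area, psth_peak = psth$peak,
             n_resp = n_resp, n_trials = nt)
}

## internal: stimulation onsets per grid position from a schedule
onsetsByPosition <- function(schedule) {
  fp <- schedule@positions
  pos_all <- unlist(fp)
  frame_of <- rep(seq_along(fp), lengths(fp))
  split(schedule@onsetMs[frame_of], pos_all)
}

#' Build the directed connectivity map of a probing session
#'
#' Applies [detectConnection()] to every (stimulus position, electrode) pair,
#' with each position's onset list extracted from the probing schedule.
#' Pairs are unique by construction.
#'
#' @param spike_data a [SpikeData-class] recorded during the probing session.
#' @param schedule the probing [StimulusSchedule-class]; the recording must
#'   cover it.
#' @param params list from [detectionParams()].
#' @return a [ConnectivityMap-class].
#' @examples
#' \donttest{
#' geom <- electrodeGrid(4, 4, drop_corners = FALSE)
#' net <- randomNetwork(c(4, 4), geom, 10, response_prob = 0.9, seed = 1)
#' sch <- makeProbingSchedule(c(4, 4), n_reps = 20, dots_per_frame = 4, seed = 2)
#' rec <- simulateEvoked(net, sch, seed = 3)
#' map <- buildConnectivityMap(rec, sch)
#' }
#' @export
buildConnectivityMap <- function(spike_data, schedule,
                                 params = detectionParams()) {
  p <- utils::modifyList(detectionParams(), params)
  need_ms <- if (nFrames(schedule))
    schedule@onsetMs[nFrames(schedule)] + p$lag_range_ms[2] else 0
  if (spike_data@durationMs + 1e-6 < need_ms)
    stop("recording shorter than the probing schedule (duration mismatch)")
  byPos <- onsetsByPosition(schedule)
  geom <- spike_data@geometry
  rows <- vector("list", 256L)
  nr <- 0L
  for (pos in names(byPos)) {
    onsets <- byPos[[pos]]
    min_resp <- if (is.null(p$min_resp_trials)) ceiling(length(onsets) / 2)
                else p$min_resp_trials
    for (e in seq_len(nrow(geom))) {
      sp <- spike_data@spikes[[e]]
      if (length(sp) < min_resp) next
      hit <- detectConnection(sp, onsets, p)
      if (!is.null(hit)) {
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- cbind(pre = as.integer(pos),
                            post = geom$electrode[e], hit)
      }
    }
  }
  cn <- if (nr) do.call(rbind, rows[seq_len(nr)]) else
    data.frame(pre = integer(0), post = integer(0), latency_ms = numeric(0),
               peak = numeric(0), peak_per100 = numeric(0),
               p_value = numeric(0), psth_area = numeric(0),
               psth_peak = numeric(0), n_resp = integer(0),
               n_trials = integer(0))
  rownames(cn) <- NULL
  new("ConnectivityMap", connections = cn,
      gridShape = as.integer(schedule@gridShape), geometry = geom,
      params = p,
      meta = list(n_frames = nFrames(schedule),
                  duration_ms = schedule@totalDurationMs))
}

#' Summarize a connectivity map's geometry and statistics
#'
#' Euclidean distances from each presynaptic stimulation-grid cell center to
#' its postsynaptic electrode, binned at the interelectrode pitch (200 um by
#' default); latency and CCH-peak histograms; mean +/- SD latency per
#' distance bin.
#'
#' @param map a [ConnectivityMap-class].
#' @param geometry electrode table (defaults to the map's own).
#' @param dist_bin_um distance bin width (default 200).
#' @param latency_bin_ms latency histogram bin width (default 5).
#' @return list with `distances_um`, `dist_breaks_um`, `dist_hist`,
#'   `latency_hist`, `peak_hist`, and `latency_by_dist` (data.frame:
#'   bin_start_um, n, mean_latency_ms, sd_latency_ms).
#' @export
connectivitySummary <- function(map, geometry = map@geometry,
                                dist_bin_um = 200, latency_bin_ms = 5) {
  cn <- map@connections
  sc <- stimPositionCoords(map@gridShape, geometry)
  pre_i <- match(cn$pre, sc$position)
  post_i <- match(cn$post, geometry$electrode)
  if (any(is.na(pre_i)) || any(is.na(post_i)))
    stop("geometry does not cover all connection endpoints")
  d <- sqrt((sc$x_um[pre_i] - geometry$x_um[post_i])^2 +
            (sc$y_um[pre_i] - geometry$y_um[post_i])^2)
  dmax <- if (length(d)) max(d) else 0
  dbreaks <- seq(0, (floor(dmax / dist_bin_um) + 1) * dist_bin_um,
                 by = dist_bin_um)
  dbin <- if (length(d)) findInterval(d, dbreaks, rightmost.closed = FALSE)
          else integer(0)
  dist_hist <- tabulate(dbin, nbins = length(dbreaks) - 1L)
  lmax <- if (nrow(cn)) max(cn$latency_ms) else 0
  lbreaks <- seq(0, (floor(lmax / latency_bin_ms) + 1) * latency_bin_ms,
                 by = latency_bin_ms)
  latency_hist <- tabulate(findInterval(cn$latency_ms, lbreaks),
                           nbins = length(lbreaks) - 1L)
  by_dist <- do.call(rbind, lapply(seq_len(length(dbreaks) - 1L), function(b) {
    sel <- dbin == b
    data.frame(bin_start_um = dbreaks[b], n = sum(sel),
               mean_latency_ms = if (any(sel)) mean(cn$latency_ms[sel]) else NA_real_,
               sd_latency_ms = if (sum(sel) > 1) stats::sd(cn$latency_ms[sel]) else NA_real_)
  }))
  list(distances_um = d, dist_breaks_um = dbreaks, dist_hist = dist_hist,
       latency_breaks_ms = lbreaks, latency_hist = latency_hist,
       peak_hist = if (nrow(cn)) table(round(cn$peak_per100)) else table(numeric(0)),
       latency_by_dist = by_dist)
}
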