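#' @include AllClasses.R constructors.R patterns.R
NULL

#' Construct a ground-truth synthetic network
#'
#' @param grid_shape integer(2) stimulation grid.
#' @param geometry electrode table from [electrodeGrid()].
#' @param connections data.frame with pre (0-based grid index), post
#'   (electrode id), response_prob, latency_mean_ms, latency_sd_ms.
#' @param background_rate_hz per-electrode Poisson background rate (recycled).
#' @param snb list of SNB parameters: ibi_mean_s, ibi_sd_s, duration_ms,
#'   within_rate_hz, participation (per-electrode gain, recycled).
#' @param replay_bias named list of per-electrode gain vectors applied during
#'   SNBs when the corresponding pattern is armed.
#' @return a [GroundTruthNetwork-class].
#' @export
groundTruthNetwork <- function(grid_shape, geometry, connections,
                               background_rate_hz = 0.5,
                               snb = list(), replay_bias = list()) {
  ne <- nrow(geometry)
  defaults <- list(ibi_mean_s = 6.7, ibi_sd_s = 1.5, duration_ms = 300,
                   within_rate_hz = 40, participation = rep(1, ne))
  snb <- utils::modifyList(defaults, snb)
  snb$participation <- rep_len(snb$participation, ne)
  new("GroundTruthNetwork",
      gridShape = as.integer(grid_shape), geometry = geometry,
      connections = connections,
      backgroundRateHz = rep_len(as.numeric(background_rate_hz), ne),
      snb = snb, replayBias = replay_bias)
}

#' Plant a random synthetic network
#'
#' Draws `n_connections` distinct (stimulus position, electrode) pairs with
#' response probabilities and channelrhodopsin-like evoked latencies
#' (default 30 +/- 3 ms).
#'
#' @param grid_shape,geometry as in [groundTruthNetwork()].
#' @param n_connections number of planted directed connections.
#' @param response_prob length-2 range (or scalar) of per-trial response
#'   probabilities, drawn uniformly.
#' @param latency_mean_ms,latency_sd_ms evoked latency parameters; the mean is
#'   jittered per connection by `latency_jitter_ms`. The per-trial SD defaults
#'   to 0.5 ms: optically evoked responses must be temporally precise at the
#'   1-ms correlogram binning for peak counts to approach the trial count, as
#'   observed in real probings.
#' @param latency_jitter_ms SD of the per-connection latency-mean jitter.
#' @param background_rate_hz,snb,replay_bias passed to [groundTruthNetwork()].
#' @param seed integer RNG seed.
#' @return a [GroundTruthNetwork-class].
#' @export
randomNetwork <- function(grid_shape, geometry, n_connections,
                          response_prob = c(0.6, 0.95),
                          latency_mean_ms = 30, latency_sd_ms = 0.5,
                          latency_jitter_ms = 4,
                          background_rate_hz = 0.5, snb = list(),
                          replay_bias = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- prod(grid_shape)
  ne <- nrow(geometry)
  if (n_connections > g * ne) stop("more connections requested than pairs exist")
  pair <- sample.int(g * ne, n_connections)
  pr <- range(rep_len(response_prob, 2))
  lm <- pmax(1, latency_mean_ms + stats::rnorm(n_connections, 0, latency_jitter_ms))
  cn <- data.frame(
    pre = (pair - 1L) %/% ne,
    post = geometry$electrode[(pair - 1L) %% ne + 1L],
    response_prob = stats::runif(n_connections, pr[1], pr[2]),
    latency_mean_ms = lm,
    latency_sd_ms = rep_len(latency_sd_ms, n_connections)
  )
  groundTruthNetwork(grid_shape, geometry, cn, background_rate_hz, snb,
                     replay_bias)
}

#' Apply the tetanus plasticity transform
#'
#' In the non-bursty regime, potentiation clusters on "postsynaptic hub"
#' electrodes: connections whose presynaptic position is lit by the pattern
#' and whose postsynaptic electrode receives at least `hub_threshold` lit
#' inputs have their response probability multiplied by `potentiation_gain`
#' (capped at 1). In the bursty (SNB-saturated) regime the tetanus instead
#' depresses every connection by `depression_gain`.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param pattern the tetanized [PatternMask-class].
#' @param hub_threshold minimum number of lit inputs for a hub electrode.
#' @param potentiation_gain multiplicative gain > 1 for hub connections.
#' @param depression_gain multiplicative factor < 1 used when `bursty`.
#' @param bursty logical; model the SNB-dominated depression outcome.
#' @return the modified network.
#' @export
applyTetanusPlasticity <- function(net, pattern, hub_threshold = 2L,
                                   potentiation_gain = 1.5,
                                   depression_gain = 0.8, bursty = FALSE) {
  stopifnot(potentiation_gain > 0, depression_gain > 0)
  cn <- net@connections
  if (bursty) {
    if (depression_gain >= 1)
      warning("bursty tetanus with depression_gain >= 1 does not depress")
    cn$response_prob <- pmin(1, cn$response_prob * depression_gain)
  } else {
    lit <- patternToGrid(pattern, net@gridShape)
    litIn <- cn$pre %in% lit
    nin <- table(cn$post[litIn])
    hubs <- as.numeric(names(nin))[nin >= hub_threshold]
    sel <- litIn & cn$post %in% hubs
    cn$response_prob[sel] <- pmin(1, cn$response_prob[sel] * potentiation_gain)
  }
  net@connections <- cn
  validObject(net)
  net
}

#' Apply random-dot-movie long-term depression
#'
#' Network-wide depression after prolonged RDM stimulation: every response
#' probability is multiplied by `depression_factor` and the SNB interburst
#' interval is lengthened by `ibi_factor` (burst suppression).
#'
#' @param net a [GroundTruthNetwork-class].
#' @param depression_factor multiplicative factor in (0, 1].
#' @param ibi_factor factor (>= 1) by which the mean interburst interval
#'   grows (default 3).
#' @return the modified network.
#' @export
applyRdmLtd <- function(net, depression_factor, ibi_factor = 3) {
  if (!(depression_factor > 0 && depression_factor <= 1))
    stop("depression_factor must be in (0, 1]")
  if (ibi_factor < 1) stop("ibi_factor must be >= 1")
  net@connections$response_prob <- net@connections$response_prob * depression_factor
  net@snb$ibi_mean_s <- net@snb$ibi_mean_s * ibi_factor
  validObject(net)
  net
}

#' Arm replay bias toward a stored pattern
#'
#' During SNBs, electrode firing is biased toward the engram of a stored
#' pattern: per-electrode gains proportional to the electrode's summed evoked
#' drive from the pattern's lit positions, mixed with a uniform component by
#' `strength` (0 = uniform bursting, 1 = fully engram-proportional). Gains
#' are normalized to mean 1, so the overall burst rate is unchanged.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param pattern the stored [PatternMask-class].
#' @param strength mixing weight in \[0, 1\] of the engram-proportional
#'   component.
#' @return the network with `replayBias[[pattern name]]` set.
#' @export
armReplayBias <- function(net, pattern, strength = 1) {
  stopifnot(strength >= 0, strength <= 1)
  lit <- patternToGrid(pattern, net@gridShape)
  cn <- net@connections
  sel <- cn$pre %in% lit
  drive <- rep(0, nrow(net@geometry))
  names(drive) <- as.character(net@geometry$electrode)
  if (any(sel)) {
    agg <- tapply(cn$response_prob[sel], as.character(cn$post[sel]), sum)
    drive[names(agg)] <- agg
    if (mean(drive) > 0) drive <- drive / mean(drive)
  }
  net@replayBias[[pattern@name]] <- unname((1 - strength) + strength * drive)
  net
}
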