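#' @include AllClasses.R schedules.R network.R simulate.R cch.R plasticity.R replay.R
NULL

#' Default configuration for a simulated learning experiment
#'
#' Bundles the protocol parameters of the two paradigms: probing-movie
#' parameters, pattern-presentation parameters, the 50-Hz tetanus transform,
#' the RDM depression transform, replay-bias strength and recording lengths.
#' Defaults are demonstration-scale (they probe whatever grid the network
#' declares); the stimulation protocol numbers mirror the standard ones
#' (20 probing repetitions, 10 presentations per pattern with 10-s intervals
#' and 100-ms illumination, 50-Hz/50%-duty tetanus).
#'
#' @param probe list: n_reps, dots_per_frame, frame_ms, on_ms.
#' @param test list: n_trials_per, interval_s, on_ms.
#' @param tetanus list: hub_threshold, potentiation_gain, depression_gain.
#' @param rdm list: depression_factor, ibi_factor.
#' @param replay_strength engram-proportional mixing weight armed for the
#'   trained pattern after learning in the RDM paradigm (0 disables replay;
#'   see [armReplayBias()]).
#' @param spont_s length of spontaneous recordings (pre-run QC / replay
#'   decoding), seconds.
#' @param window_ms,bin_ms trial-tensor extraction parameters.
#' @param trained_pattern name of the familiar pattern.
#' @return a config list for [runExperiment()].
#' @export
experimentConfig <- function(probe = list(n_reps = 20L, dots_per_frame = 4L,
                                          frame_ms = 100, on_ms = 40),
                             test = list(n_trials_per = 10L, interval_s = 10,
                                         on_ms = 100),
                             tetanus = list(hub_threshold = 2L,
                                            potentiation_gain = 1.6,
                                            depression_gain = 0.8),
                             rdm = list(depression_factor = 0.6,
                                        ibi_factor = 3),
                             replay_strength = 0.8,
                             spont_s = 300,
                             window_ms = 200, bin_ms = 10,
                             trained_pattern = "human") {
  list(probe = probe, test = test, tetanus = tetanus, rdm = rdm,
       replay_strength = replay_strength, spont_s = spont_s,
       window_ms = window_ms, bin_ms = bin_ms,
       trained_pattern = trained_pattern)
}

#' A demonstration-scale synthetic culture
#'
#' An 8 x 8 stimulation grid over a 6 x 6 electrode array with 90 planted
#' connections (response probabilities 0.7-0.95, latencies 30 +/- 3 ms),
#' 0.5-Hz background and SNBs every 6.7 +/- 1.5 s. Used by examples and the
#' bundled end-to-end runs.
#'
#' @param seed integer RNG seed for the planted connections.
#' @param n_connections number of planted connections (default 90).
#' @return a [GroundTruthNetwork-class].
#' @export
demoNetwork <- function(seed = 1L, n_connections = 90L) {
  geom <- electrodeGrid(6, 6, drop_corners = FALSE)
  randomNetwork(c(8L, 8L), geom, n_connections,
                response_prob = c(0.7, 0.95),
                latency_mean_ms = 30, latency_sd_ms = 0.5,
                latency_jitter_ms = 4,
                background_rate_hz = 0.5,
                snb = list(ibi_mean_s = 6.7, ibi_sd_s = 1.5,
                           duration_ms = 300, within_rate_hz = 30),
                seed = seed)
}

#' Balance pattern intensities against a network's baseline drive
#'
#' Mirrors the luminance tuning of projected patterns: each pattern's
#' intensity scalar is set so that the total evoked drive (summed response
#' probability over connections whose presynaptic position the pattern
#' lights) matches the weakest pattern's. Without this, the familiarity
#' metric would reflect pattern size rather than learning.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param patterns named list of [PatternMask-class] objects.
#' @return the pattern list with adjusted intensities.
#' @export
balancePatternIntensities <- function(net, patterns) {
  drive <- vapply(patterns, function(p) {
    lit <- patternToGrid(p, net@gridShape)
    sum(net@connections$response_prob[net@connections$pre %in% lit])
  }, numeric(1))
  if (all(drive <= 0)) return(patterns)
  target <- min(drive[drive > 0])
  for (i in seq_along(patterns))
    if (drive[i] > 0) patterns[[i]]@intensity <- target / drive[i]
  patterns
}

## internal: one probing session (schedule + evoked recording + map)
runProbe <- function(net, cfg, seed) {
  sch <- makeProbingSchedule(net@gridShape, n_reps = cfg$probe$n_reps,
                             dots_per_frame = cfg$probe$dots_per_frame,
                             frame_ms = cfg$probe$frame_ms,
                             on_ms = cfg$probe$on_ms, seed = seed)
  rec <- simulateEvoked(net, sch, seed = seed + 1L)
  list(schedule = sch, spikes = rec, map = buildConnectivityMap(rec, sch))
}

## internal: one baseline/testing session (pattern presentations + tensor)
runTestPhase <- function(net, patterns, cfg, seed) {
  ts <- makeTestSchedule(patterns, grid_shape = net@gridShape,
                         n_trials_per = cfg$test$n_trials_per,
                         interval_s = cfg$test$interval_s,
                         on_ms = cfg$test$on_ms, seed = seed)
  rec <- simulateEvoked(net, ts$schedule, seed = seed + 1L, with_snbs = TRUE)
  bursts <- detectSnbs(rec)
  tensor <- extractTrials(rec, ts$schedule, ts$labels,
                          window_ms = cfg$window_ms, bin_ms = cfg$bin_ms,
                          bursts = bursts, pre_exclusion_s = 1)
  list(schedule = ts$schedule, labels = ts$labels, spikes = rec,
       tensor = tensor)
}

#' Run one simulated learning experiment end to end
#'
#' Executes the declared paradigm against the simulator, with CCH probings
#' between phases exactly as in the protocols:
#' conventional = CCH - baseline - CCH - 50-Hz tetanus - CCH - testing - CCH;
#' rdm = CCH - baseline - CCH - RDM - CCH - 50-Hz tetanus - CCH - testing -
#' CCH. In the conventional paradigm the tetanus is applied in the bursty
#' (SNB-saturated, depressing) regime; after RDM depression it potentiates
#' hub connections of the trained pattern and the trained engram's replay
#' bias is armed. Per-phase efficacy summaries (R = P/|N|), the testing-phase
#' firing-rate familiarity metric and before/after SNB replay summaries are
#' assembled into an [ExperimentResult-class].
#'
#' The culture must pass quality control on a pre-run spontaneous recording,
#' otherwise the run aborts with the QC reasons.
#'
#' @param paradigm "conventional" or "rdm".
#' @param net a [GroundTruthNetwork-class] (e.g. [demoNetwork()]).
#' @param config list from [experimentConfig()].
#' @param seed integer master seed; all phase seeds derive from it.
#' @return an [ExperimentResult-class].
#' @export
runExperiment <- function(paradigm = c("conventional", "rdm"), net,
                          config = experimentConfig(), seed = 1L) {
  paradigm <- match.arg(paradigm)
  cfg <- config
  base <- as.integer(seed) %% 100000L
  s <- function(k) base * 1000L + k  # phase seeds, < 2^31

  patterns <- lapply(c("car", "dog", "human"), makePattern)
  names(patterns) <- c("car", "dog", "human")
  patterns <- balancePatternIntensities(net, patterns)
  trained <- cfg$trained_pattern
  if (!trained %in% names(patterns))
    stop("trained_pattern must be one of car, dog, human")

  ## pre-run spontaneous recording: QC, BI, and the before-learning replay
  pre <- simulateSpontaneous(net, cfg$spont_s, seed = s(1))
  pre_bursts <- detectSnbs(pre)
  qc <- cultureQc(pre_bursts, cfg$spont_s)
  if (!qc$pass)
    stop(sprintf("culture failed QC: %s", paste(qc$reasons, collapse = "; ")))
  bi <- burstinessIndex(pre, ibi_est_s = interburstInterval(pre_bursts))

  maps <- list()
  efficacy <- list()
  probeR <- function(before, name, probe_out) {
    cmp <- compareMaps(before$map, probe_out$map, probe_out$spikes,
                       probe_out$schedule)
    efficacy[[name]] <<- cmp
    cmp@R
  }

  p0 <- runProbe(net, cfg, s(10)); maps$probe0 <- p0$map
  baseline <- runTestPhase(net, patterns, cfg, s(20))
  p1 <- runProbe(net, cfg, s(30)); maps$probe1 <- p1$map
  probeR(p0, "baseline", p1)

  clf_base <- trainPatternClassifier(baseline$tensor, mode = "pool_all",
                                     trained_label = trained)
  replay_before <- if (nBursts(pre_bursts) > 0)
    classifySnbBins(clf_base, pre, pre_bursts) else NULL

  prev <- p1
  rdm_R <- NULL
  if (paradigm == "rdm") {
    net <- applyRdmLtd(net, cfg$rdm$depression_factor, cfg$rdm$ibi_factor)
    p2 <- runProbe(net, cfg, s(40)); maps$probe_rdm <- p2$map
    rdm_R <- probeR(prev, "rdm", p2)
    prev <- p2
  }

  ## learning: 50-Hz tetanus of the trained pattern
  net <- applyTetanusPlasticity(net, patterns[[trained]],
                                hub_threshold = cfg$tetanus$hub_threshold,
                                potentiation_gain = cfg$tetanus$potentiation_gain,
                                depression_gain = cfg$tetanus$depression_gain,
                                bursty = paradigm == "conventional")
  if (paradigm == "rdm" && cfg$replay_strength > 0)
    net <- armReplayBias(net, patterns[[trained]], cfg$replay_strength)

  ## post-learning spontaneous recording: replay decoding material
  post_sp <- simulateSpontaneous(net, cfg$spont_s, seed = s(50),
                                 replay_pattern = if (length(net@replayBias))
                                   trained else NULL)
  post_bursts <- detectSnbs(post_sp)

  p3 <- runProbe(net, cfg, s(60)); maps$probe_learning <- p3$map
  probeR(prev, "learning", p3)

  testing <- runTestPhase(net, patterns, cfg, s(70))
  p4 <- runProbe(net, cfg, s(80)); maps$probe_testing <- p4$map
  probeR(p3, "testing", p4)

  clf_test <- trainPatternClassifier(testing$tensor, mode = "pool_all",
                                     trained_label = trained)
  replay_after <- if (nBursts(post_bursts) > 0)
    classifySnbBins(clf_test, post_sp, post_bursts) else NULL

  tot <- patternResponseSummary(testing$tensor)$totals
  xf <- tot$mean_spikes[tot$pattern == trained]
  xc <- tot$mean_spikes[tot$pattern != trained]
  fr_delta <- if (length(xf) == 1 && xf > 0 && length(xc) == 2)
    familiarityDelta(xf, xc[1], xc[2]) else NA_real_

  qc$rdm_R <- if (!is.null(rdm_R)) rdm_R else NA_real_
  if (paradigm == "rdm" && !is.null(rdm_R) && !is.nan(rdm_R) && rdm_R > 0.2)
    qc$reasons <- c(qc$reasons,
                    sprintf("bursting/efficacy not suppressed by RDMs (R = %.2f > 0.2)", rdm_R))

  new("ExperimentResult",
      paradigm = paradigm,
      phases = names(efficacy),
      maps = maps, efficacy = efficacy,
      firingRateDelta = fr_delta,
      replayBefore = replay_before, replayAfter = replay_after,
      qc = qc, bi = bi,
      manifest = list(seed = as.integer(seed), config = cfg,
                      package_version = as.character(utils::packageVersion("meaplast"))))
}
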