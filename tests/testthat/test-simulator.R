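test_that("silent settings produce no spikes and outputs satisfy invariants", {
  geom <- tinyGeom(2)
  cn <- data.frame(pre = integer(0), post = integer(0),
                   response_prob = numeric(0), latency_mean_ms = numeric(0),
                   latency_sd_ms = numeric(0))
  net <- groundTruthNetwork(c(2L, 2L), geom, cn, background_rate_hz = 0,
                            snb = list(within_rate_hz = 0))
  sd0 <- simulateSpontaneous(net, 10, seed = 1)
  expect_identical(sum(lengths(spikes(sd0))), 0L)

  # invariants on a busy simulation: sorted, bounded
  net2 <- groundTruthNetwork(c(2L, 2L), geom, cn, background_rate_hz = 5)
  out <- simulateSpontaneous(net2, 30, seed = 2)
  expect_true(validObject(out))
  for (s in spikes(out)) {
    expect_false(is.unsorted(s))
    if (length(s)) expect_true(all(s >= 0 & s <= durationMs(out)))
  }
})

test_that("simulations are bit-reproducible under a fixed seed", {
  net <- demoNetwork(3)
  a <- simulateSpontaneous(net, 20, seed = 5)
  b <- simulateSpontaneous(net, 20, seed = 5)
  expect_identical(spikes(a), spikes(b))
  sch <- makeProbingSchedule(c(8L, 8L), 2L, 4L, seed = 1)
  e1 <- simulateEvoked(net, sch, seed = 6)
  e2 <- simulateEvoked(net, sch, seed = 6)
  expect_identical(spikes(e1), spikes(e2))
})

test_that("SNB counts follow the interburst-interval statistics", {
  geom <- tinyGeom(2)
  cn <- data.frame(pre = integer(0), post = integer(0),
                   response_prob = numeric(0), latency_mean_ms = numeric(0),
                   latency_sd_ms = numeric(0))
  net <- groundTruthNetwork(c(2L, 2L), geom, cn, background_rate_hz = 0.1,
                            snb = list(ibi_mean_s = 6.7, ibi_sd_s = 1.5,
                                       duration_ms = 300, within_rate_hz = 40))
  counts <- vapply(1:20, function(s)
    nrow(simulateSpontaneous(net, 300, seed = s, details = TRUE)$bursts),
    numeric(1))
  expected <- 300 / 6.7
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(20) + 1)
})

test_that("burstiness scoring separates SNB-dominant from burst-free activity", {
  geom <- electrodeGrid(4, 4, drop_corners = FALSE)
  cn <- data.frame(pre = integer(0), post = integer(0),
                   response_prob = numeric(0), latency_mean_ms = numeric(0),
                   latency_sd_ms = numeric(0))
  bursty <- groundTruthNetwork(c(4L, 4L), geom, cn, background_rate_hz = 0.05,
                               snb = list(ibi_mean_s = 6.7, ibi_sd_s = 1,
                                          duration_ms = 300,
                                          within_rate_hz = 60))
  flat <- groundTruthNetwork(c(4L, 4L), geom, cn, background_rate_hz = 2,
                             snb = list(within_rate_hz = 0))
  expect_gt(burstinessIndex(simulateSpontaneous(bursty, 120, seed = 1)), 0.8)
  expect_lt(burstinessIndex(simulateSpontaneous(flat, 120, seed = 1)), 0.2)
})

test_that("evoked responses are deterministic in the zero-jitter limit", {
  geom <- electrodeGrid(1, 1, drop_corners = FALSE)
  cn <- data.frame(pre = 0L, post = 0L, response_prob = 1,
                   latency_mean_ms = 30, latency_sd_ms = 0)
  net <- groundTruthNetwork(c(1L, 1L), geom, cn, background_rate_hz = 0,
                            snb = list(within_rate_hz = 0))
  sch <- onsetSchedule((0:9) * 100, 0L, grid_shape = c(1L, 1L),
                       duration_ms = 1100)
  rec <- simulateEvoked(net, sch, seed = 1)
  expect_equal(spikes(rec)[[1]], (0:9) * 100 + 30)
})

test_that("per-trial responses are binomial in response probability", {
  geom <- electrodeGrid(1, 1, drop_corners = FALSE)
  cn <- data.frame(pre = 0L, post = 0L, response_prob = 0.5,
                   latency_mean_ms = 30, latency_sd_ms = 0)
  net <- groundTruthNetwork(c(1L, 1L), geom, cn, background_rate_hz = 0,
                            snb = list(within_rate_hz = 0))
  sch <- onsetSchedule((0:19) * 100, 0L, grid_shape = c(1L, 1L),
                       duration_ms = 2100)
  counts <- vapply(1:40, function(s)
    length(spikes(simulateEvoked(net, sch, seed = s))[[1]]), numeric(1))
  # mean ~ n p = 10, binomial SE over 40 seeds
  se <- sqrt(20 * 0.25 / 40)
  expect_lt(abs(mean(counts) - 10), 3 * se)
})

test_that("schedule/grid mismatches are refused", {
  net <- demoNetwork(1)
  sch <- makeProbingSchedule(c(4L, 4L), 2L, 4L, seed = 1)
  expect_error(simulateEvoked(net, sch, seed = 1), "grid")
})

test_that("plasticity transforms rescale response probabilities as specified", {
  geom <- tinyGeom(2)
  pat <- makePattern("blob", mask = matrix(1L, 2, 2))  # lights everything
  cn <- data.frame(pre = c(0L, 1L, 2L), post = c(0L, 0L, 3L),
                   response_prob = c(0.5, 0.9, 0.4),
                   latency_mean_ms = 30, latency_sd_ms = 0.5)
  net <- groundTruthNetwork(c(2L, 2L), geom, cn)

  # hub potentiation: electrode 0 receives 2 lit inputs, electrode 3 only 1
  pot <- applyTetanusPlasticity(net, pat, hub_threshold = 2L,
                                potentiation_gain = 1.5)
  expect_equal(connections(pot)$response_prob, c(0.75, 1, 0.4))  # cap at 1

  # bursty regime: uniform depression
  dep <- applyTetanusPlasticity(net, pat, depression_gain = 0.8, bursty = TRUE)
  expect_equal(connections(dep)$response_prob, c(0.4, 0.72, 0.32))

  # RDM LTD: identity at factor 1, uniform scaling otherwise
  expect_equal(connections(applyRdmLtd(net, 1, ibi_factor = 1)),
               connections(net))
  ltd <- applyRdmLtd(net, 0.1)
  expect_equal(connections(ltd)$response_prob, c(0.05, 0.09, 0.04))
  expect_equal(ltd@snb$ibi_mean_s, net@snb$ibi_mean_s * 3)
  expect_error(applyRdmLtd(net, 1.2), "depression_factor")
  expect_error(applyRdmLtd(net, 0), "depression_factor")
})

test_that("threshold spike detection recovers large spikes and rejects noise", {
  set.seed(11)
  fs <- 20000
  noise <- rnorm(fs)  # 1 s of sigma = 1 noise
  expect_length(detectSpikesThreshold(noise, fs, multiplier = 6,
                                      noise_sigma = 1), 0)

  # embedded -10 sigma spikes recovered within one sample
  spike_at <- c(2000L, 7000L, 15000L)
  trace <- noise
  trace[spike_at] <- -10
  got <- detectSpikesThreshold(trace, fs, multiplier = 6, noise_sigma = 1)
  expect_length(got, 3)
  expect_true(all(abs(got - (spike_at - 1) / fs * 1000) <= 1 / fs * 1000))

  expect_length(detectSpikesThreshold(numeric(0)), 0)
  # refractory lockout merges a double crossing
  tr2 <- rep(0, 100); tr2[50:52] <- -10
  expect_length(detectSpikesThreshold(tr2, 1000, noise_sigma = 1,
                                      refractory_ms = 5), 1)
})

test_that("detected PSTH efficacy is non-decreasing in response probability", {
  geom <- electrodeGrid(1, 1, drop_corners = FALSE)
  sch <- onsetSchedule((0:19) * 100, 0L, grid_shape = c(1L, 1L),
                       duration_ms = 2100)
  area_at <- function(prob) {
    cn <- data.frame(pre = 0L, post = 0L, response_prob = prob,
                     latency_mean_ms = 30, latency_sd_ms = 0.5)
    net <- groundTruthNetwork(c(1L, 1L), geom, cn, background_rate_hz = 0,
                              snb = list(within_rate_hz = 0))
    mean(vapply(1:10, function(s) {
      rec <- simulateEvoked(net, sch, seed = s)
      computePsth(spikes(rec)[[1]], frameOnsets(sch))$area
    }, numeric(1)))
  }
  areas <- vapply(c(0.3, 0.6, 0.9), area_at, numeric(1))
  expect_true(all(diff(areas) > 0))
})
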