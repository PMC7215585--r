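test_that("identical sessions give zero change and undefined R", {
  ses <- afterSession(c(2, 3))
  map <- buildConnectivityMap(ses$spikes, ses$schedule)
  expect_identical(nrow(connections(map)), 2L)
  cmp <- compareMaps(map, map, ses$spikes, ses$schedule)
  expect_equal(cmp@perConnection$rel_change_pct, c(0, 0))
  expect_equal(cmp@P, 0)
  expect_equal(cmp@N, 0)
  expect_true(is.nan(cmp@R))
})

test_that("positive changes above 100% are capped at 101 in P", {
  before <- fakeMap(0L, 0L, area = 2, geom = electrodeGrid(1, 1, drop_corners = FALSE),
                    grid_shape = c(1L, 1L))
  after <- afterSession(7)  # area 7: raw change +250%
  cmp <- compareMaps(before, NULL, after$spikes, after$schedule)
  expect_equal(cmp@perConnection$rel_change_pct, 250)
  expect_equal(cmp@perConnection$rel_change_capped, 101)
  expect_equal(cmp@P, 101)
})

test_that("P, N and R combine changes as a signed hand sum", {
  # before areas 1, 1, 1; after areas give {+50, +30, -40}
  geom <- electrodeGrid(1, 3, drop_corners = FALSE)
  before <- new("ConnectivityMap", connections = data.frame(
    pre = 0:2, post = 0:2, latency_ms = 30, peak = 10, peak_per100 = 100,
    p_value = 1e-9, psth_area = c(2, 10, 5), psth_peak = 1, n_resp = 10L,
    n_trials = 10L), gridShape = c(1L, 3L), geometry = geom,
    params = detectionParams(), meta = list())
  after <- afterSession(c(3, 13, 3))  # 2->3 (+50), 10->13 (+30), 5->3 (-40)
  cmp <- compareMaps(before, NULL, after$spikes, after$schedule)
  expect_equal(sort(cmp@perConnection$rel_change_pct), c(-40, 30, 50))
  expect_equal(cmp@P, 80)
  expect_equal(cmp@N, -40)
  expect_equal(cmp@R, 2)
})

test_that("zero-baseline-area connections are skipped with a warning", {
  before <- fakeMap(0L, 0L, area = 0, geom = electrodeGrid(1, 1, drop_corners = FALSE),
                    grid_shape = c(1L, 1L))
  after <- afterSession(2)
  expect_warning(cmp <- compareMaps(before, NULL, after$spikes, after$schedule),
                 "skipped")
  expect_identical(nrow(cmp@perConnection), 0L)
  expect_identical(cmp@nSkipped, 1L)
})

test_that("swapping before and after flips the sign of every uncapped change", {
  sesA <- afterSession(c(2, 5, 4))
  sesB <- afterSession(c(3, 4, 6))
  mapA <- buildConnectivityMap(sesA$spikes, sesA$schedule)
  mapB <- buildConnectivityMap(sesB$spikes, sesB$schedule)
  fwd <- compareMaps(mapA, NULL, sesB$spikes, sesB$schedule)
  rev <- compareMaps(mapB, NULL, sesA$spikes, sesA$schedule)
  key <- function(pc) paste(pc$pre, pc$post)
  m <- match(key(fwd@perConnection), key(rev@perConnection))
  f <- fwd@perConnection$rel_change_pct
  r <- rev@perConnection$rel_change_pct[m]
  nonzero <- abs(f) > 1e-9
  expect_true(all(sign(f[nonzero]) == -sign(r[nonzero])))
})

test_that("burstiness index hits its boundary and worked-example values", {
  geom <- electrodeGrid(1, 1, drop_corners = FALSE)
  # all spikes inside the top 15% of bins -> BI = 1
  sp <- runif(500, 0, 10000)  # all within the first 10 of 100 one-second bins
  bi1 <- burstinessIndex(spikeData(list(sort(sp)), 100000, geom))
  expect_equal(bi1, 1)

  # perfectly uniform spikes -> BI ~ 0
  uni <- seq(0.5, 99999.5, by = 10)
  expect_lt(abs(burstinessIndex(spikeData(list(uni), 100000, geom))), 0.02)

  # constructed train with f = 0.575 -> BI = 0.5 exactly
  top <- unlist(lapply(0:14, function(b) b * 1000 + seq(1, 900, length.out = 23)))
  rest <- unlist(lapply(15:99, function(b) b * 1000 + seq(1, 900, length.out = 3)))
  stopifnot(length(top) / (length(top) + length(rest)) == 0.575)
  bi <- burstinessIndex(spikeData(list(sort(c(top, rest))), 100000, geom))
  expect_equal(bi, 0.5)

  expect_error(burstinessIndex(spikeData(list(numeric(0)), 100000, geom)),
               "no spikes")
  expect_error(burstinessIndex(spikeData(list(c(1, 2)), 3000, geom)),
               "too short")
})

test_that("BI is bounded and increases when spikes concentrate", {
  geom <- electrodeGrid(1, 1, drop_corners = FALSE)
  set.seed(3)
  for (rep in 1:5) {
    sp <- sort(runif(300, 0, 60000))
    bi <- burstinessIndex(spikeData(list(sp), 60000, geom))
    expect_gte(bi, -0.15 / 0.85 - 1e-9)
    expect_lte(bi, 1 + 1e-9)
    # move 50 spikes into the most active second: BI must increase
    counts <- tabulate(floor(sp / 1000) + 1, 60)
    hot <- which.max(counts)
    sp2 <- sort(c(sp[-(1:50)], runif(50, (hot - 1) * 1000, hot * 1000)))
    expect_gt(burstinessIndex(spikeData(list(sp2), 60000, geom)), bi)
  }
})

test_that("SNB detection recovers planted bursts and stays silent on noise", {
  geom <- electrodeGrid(4, 4, drop_corners = FALSE)
  cn <- data.frame(pre = integer(0), post = integer(0),
                   response_prob = numeric(0), latency_mean_ms = numeric(0),
                   latency_sd_ms = numeric(0))
  net <- groundTruthNetwork(c(4L, 4L), geom, cn, background_rate_hz = 1,
                            snb = list(ibi_mean_s = 6.7, ibi_sd_s = 1,
                                       duration_ms = 300, within_rate_hz = 80))
  out <- simulateSpontaneous(net, 120, seed = 7, details = TRUE)
  det <- detectSnbs(out$spikes)
  expect_gt(nBursts(det), 0)
  # mean Jaccard overlap of matched intervals >= 0.8
  jac <- vapply(seq_len(nrow(out$bursts)), function(i) {
    s <- out$bursts$start_ms[i]; e <- out$bursts$end_ms[i]
    iv <- intervals(det)
    ov <- pmax(0, pmin(e, iv$end_ms) - pmax(s, iv$start_ms))
    j <- which.max(ov)
    if (!length(j) || ov[j] <= 0) return(0)
    ov[j] / (max(e, iv$end_ms[j]) - min(s, iv$start_ms[j]))
  }, numeric(1))
  expect_gte(mean(jac), 0.8)

  # burst-free Poisson background -> empty burst set
  flat <- groundTruthNetwork(c(4L, 4L), geom, cn, background_rate_hz = 2,
                             snb = list(within_rate_hz = 0))
  expect_identical(nBursts(detectSnbs(simulateSpontaneous(flat, 120, seed = 1))),
                   0L)
})

test_that("detected burst frequency tracks the simulated interburst interval", {
  geom <- electrodeGrid(4, 4, drop_corners = FALSE)
  cn <- data.frame(pre = integer(0), post = integer(0),
                   response_prob = numeric(0), latency_mean_ms = numeric(0),
                   latency_sd_ms = numeric(0))
  net <- groundTruthNetwork(c(4L, 4L), geom, cn, background_rate_hz = 1,
                            snb = list(ibi_mean_s = 6.7, ibi_sd_s = 1,
                                       duration_ms = 300, within_rate_hz = 80))
  freqs <- vapply(1:8, function(s)
    nBursts(detectSnbs(simulateSpontaneous(net, 300, seed = s))) / 300,
    numeric(1))
  expect_lt(abs(mean(freqs) - 1 / 6.7), 3 * sd(freqs) / sqrt(8) + 0.01)
})

test_that("culture QC applies the frequency and RDM-suppression bounds", {
  mk <- function(n) new("BurstSet", intervals = data.frame(
    start_ms = seq_len(n) * 3000, end_ms = seq_len(n) * 3000 + 300,
    n_electrodes = 10L))
  too_active <- cultureQc(mk(90), 300)
  expect_false(too_active$pass)
  expect_match(too_active$reasons, "too active")
  too_quiet <- cultureQc(mk(12), 300)
  expect_false(too_quiet$pass)
  expect_match(too_quiet$reasons, "too quiet")
  ok <- cultureQc(mk(30), 300, rdm_R = 0.1)
  expect_true(ok$pass)
  bad_rdm <- cultureQc(mk(30), 300, rdm_R = 0.5)
  expect_false(bad_rdm$pass)
  expect_match(bad_rdm$reasons, "suppressed")
})

test_that("firing-rate maps average the top bins per electrode", {
  geom <- electrodeGrid(1, 3, drop_corners = FALSE)
  # electrode 0 silent; electrode 1 constant 10 Hz; electrode 2 hand-binned
  const <- seq(50, 9950, by = 100)            # one spike per 100-ms bin
  hand <- c(10, 20, 30, 150, 890)             # bins 1, 1, 1, 2, 9
  sd <- spikeData(list(numeric(0), const, hand), 10000, geom)
  frm <- firingRateMap(sd, bin_ms = 100, top_frac = 0.15)
  expect_equal(frm$rate_hz[1], 0)
  expect_equal(frm$rate_hz[2], 10)            # stationary: top-bin mean = rate
  # 100 bins -> top 15: bins with counts 3,1,1 then zeros
  expect_equal(frm$rate_hz[3], mean(c(3, 1, 1, rep(0, 12))) / 0.1)
})
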