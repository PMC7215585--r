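# a deterministic three-pattern world: patterns drive disjoint electrode sets
separableWorld <- function(n_trials_per = 6L, seed = 1L, latency_sd = 0) {
  geom <- electrodeGrid(2, 3, drop_corners = FALSE)
  pats <- list(makePattern("A", mask = matrix(c(1, 0, 0, 0), 2)),
               makePattern("B", mask = matrix(c(0, 0, 0, 1), 2)),
               makePattern("C", mask = matrix(c(0, 1, 0, 0), 2)))
  # on the 2x2 stimulation grid: A lights cell 0, B cell 3, C cell 2
  cn <- data.frame(pre = c(0L, 0L, 3L, 3L, 2L, 2L),
                   post = c(0L, 1L, 4L, 5L, 2L, 3L),
                   response_prob = 1, latency_mean_ms = 30,
                   latency_sd_ms = latency_sd)
  net <- groundTruthNetwork(c(2L, 2L), geom, cn, background_rate_hz = 0,
                            snb = list(within_rate_hz = 0))
  ts <- makeTestSchedule(pats, grid_shape = c(2L, 2L),
                         n_trials_per = n_trials_per, interval_s = 1,
                         on_ms = 100, seed = seed)
  rec <- simulateEvoked(net, ts$schedule, seed = seed + 1L)
  tensor <- extractTrials(rec, ts$schedule, ts$labels, window_ms = 200,
                          bin_ms = 10)
  list(net = net, tensor = tensor, rec = rec, schedule = ts$schedule,
       labels = ts$labels)
}

test_that("trial extraction drops burst-contaminated trials and bins exactly", {
  geom <- electrodeGrid(1, 2, drop_corners = FALSE)
  onsets <- (0:29) * 1000
  sch <- onsetSchedule(onsets, 0L, grid_shape = c(1L, 2L), on_ms = 100,
                       duration_ms = 30200)
  labels <- rep(c("a", "b", "c"), 10)
  sp <- spikeData(list(sort(c(onsets + 15, onsets + 35)), numeric(0)),
                  30200, geom)

  # no bursts: all 30 trials retained
  t0 <- extractTrials(sp, sch, labels, window_ms = 200, bin_ms = 10)
  expect_identical(dim(t0@counts)[1], 30L)

  # burst ending 0.5 s before trial 5's onset -> that trial dropped
  b <- new("BurstSet", intervals = data.frame(
    start_ms = onsets[5] - 700, end_ms = onsets[5] - 500, n_electrodes = 2L))
  t1 <- extractTrials(sp, sch, labels, window_ms = 200, bin_ms = 10,
                      bursts = b)
  expect_identical(dim(t1@counts)[1], 29L)
  expect_identical(t1@dropped$trial, 5L)

  # counts match hand binning: spikes at +15 and +35 -> bins 2 and 4
  expect_equal(t0@counts[1, 1, ], c(0, 1, 0, 1, rep(0, 16)))
  expect_equal(sum(t0@counts[, 2, ]), 0)

  # dropping every trial of one pattern errors
  ball <- new("BurstSet", intervals = data.frame(
    start_ms = onsets[labels == "a"] - 600,
    end_ms = onsets[labels == "a"] - 400,
    n_electrodes = 2L))
  expect_error(extractTrials(sp, sch, labels, bursts = ball), "'a'")
})

test_that("pattern response summaries compute means and SEMs per pattern", {
  # two identical trials of 'a', one trial of 'b'
  counts <- array(0, c(3, 2, 4))
  counts[1, 1, 2] <- 3; counts[2, 1, 2] <- 3   # identical 'a' trials
  counts[3, 2, 1] <- 5                          # single 'b' trial
  tensor <- new("TrialTensor", counts = counts, labels = c("a", "a", "b"),
                binMs = 10, windowMs = 40, electrodes = c(0L, 1L),
                dropped = data.frame())
  s <- patternResponseSummary(tensor)
  expect_equal(s$totals$mean_spikes, c(3, 5))
  expect_equal(s$totals$sem, c(0, 0))           # identical trials; n = 1
  expect_identical(s$totals$sem_defined, c(TRUE, FALSE))
  expect_equal(s$psth[, "a"], c(0, 3, 0, 0))
})

test_that("familiarity metric evaluates its closed form", {
  expect_equal(familiarityDelta(1, 1, 1), 0)
  expect_equal(familiarityDelta(2, 1, 1), 0.5)
  expect_equal(familiarityDelta(4, 2, 0), 0.75)
  expect_error(familiarityDelta(0, 1, 1), "positive")
})

test_that("the classifier separates separable classes and splits deterministically", {
  w <- separableWorld()
  clf <- trainPatternClassifier(w$tensor, mode = "pool_all")
  inst <- meaplast:::tensorInstances(w$tensor)
  acc <- mean(classifyBins(clf, inst$X) == inst$y)
  # all-zero background bins are genuinely ambiguous; response bins separate
  resp <- rowSums(inst$X) > 0
  expect_gte(mean(classifyBins(clf, inst$X[resp, , drop = FALSE]) ==
                    inst$y[resp]), 0.95)

  s1 <- trainPatternClassifier(w$tensor, mode = "split", seed = 9)
  s2 <- trainPatternClassifier(w$tensor, mode = "split", seed = 9)
  expect_identical(s1@heldOut@labels, s2@heldOut@labels)
  expect_identical(dim(s1@heldOut@counts), dim(s2@heldOut@counts))

  one_class <- new("TrialTensor", counts = w$tensor@counts,
                   labels = rep("A", length(w$tensor@labels)),
                   binMs = 10, windowMs = 200,
                   electrodes = w$tensor@electrodes, dropped = data.frame())
  expect_error(trainPatternClassifier(one_class), "two pattern classes")
})

test_that("decoding is invariant to a consistent electrode permutation", {
  w <- separableWorld()
  clf <- trainPatternClassifier(w$tensor, mode = "pool_all")
  inst <- meaplast:::tensorInstances(w$tensor)
  pred <- classifyBins(clf, inst$X)

  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  t2 <- new("TrialTensor", counts = w$tensor@counts[, perm, , drop = FALSE],
            labels = w$tensor@labels, binMs = 10, windowMs = 200,
            electrodes = w$tensor@electrodes[perm], dropped = data.frame())
  clf2 <- trainPatternClassifier(t2, mode = "pool_all")
  inst2 <- meaplast:::tensorInstances(t2)
  expect_identical(classifyBins(clf2, inst2$X), pred)
})

test_that("replay ratios are normalized and respond to burst bias", {
  w <- separableWorld(n_trials_per = 8L)
  net <- w$net
  # bursting version of the same world, biased toward pattern A's electrodes
  net@backgroundRateHz <- rep(0.2, 6)
  net@snb <- list(ibi_mean_s = 3, ibi_sd_s = 0.5, duration_ms = 300,
                  within_rate_hz = 40, participation = rep(1, 6))
  patA <- makePattern("A", mask = matrix(c(1, 0, 0, 0), 2))
  net <- armReplayBias(net, patA, strength = 1)
  clf <- trainPatternClassifier(w$tensor, mode = "pool_all",
                                trained_label = "A")
  out <- simulateSpontaneous(net, 120, seed = 3, replay_pattern = "A",
                             details = TRUE)
  sp <- out$spikes
  bursts <- new("BurstSet", intervals = data.frame(
    start_ms = out$bursts$start_ms, end_ms = out$bursts$end_ms,
    n_electrodes = 6L))
  rs <- classifySnbBins(clf, sp, bursts)
  expect_equal(sum(rs@ratios), 1)
  expect_true(all(rs@ratios >= 0))
  expect_gt(rs@ratios[["A"]], rs@ratios[["B"]])
  expect_gt(rs@ratios[["A"]], rs@ratios[["C"]])
  expect_gt(rs@delta, 0)

  empty <- new("BurstSet", intervals = data.frame(
    start_ms = numeric(0), end_ms = numeric(0), n_electrodes = integer(0)))
  expect_error(classifySnbBins(clf, sp, empty), "burst")
})

test_that("accuracy timecourse peaks after the evoked latency", {
  w <- separableWorld(n_trials_per = 10L)
  tc <- accuracyTimecourse(w$tensor, n_replicas = 5L, seed = 2)
  expect_true(all(tc$accuracy >= 0 & tc$accuracy <= 1))
  expect_equal(unique(tc$chance), 1 / 3)
  # responses arrive at 30 ms: the 30-40 ms bin must beat chance
  resp_bin <- tc$accuracy[tc$bin_start_ms == 30]
  expect_gt(resp_bin, 0.9)
})
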