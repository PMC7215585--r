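# shared fixtures: tiny geometries, toy spike data, small planted networks

tinyGeom <- function(n = 2L) electrodeGrid(n, n, drop_corners = FALSE)

# spike data with one electrode holding the given times
toySpikes <- function(times, duration_ms, n_electrodes = 1L) {
  geom <- electrodeGrid(1, n_electrodes, drop_corners = FALSE)
  sp <- c(list(times), rep(list(numeric(0)), n_electrodes - 1L))
  spikeData(sp, duration_ms, geom)
}

# brute-force CCH oracle: double loop over all time bins
bruteCch <- function(i, j, lag_bins) {
  n <- length(i)
  vapply(lag_bins, function(lag) {
    s <- 0
    for (t in seq_len(n)) {
      tj <- t - lag
      if (tj >= 1 && tj <= n) s <- s + i[t] * j[tj]
    }
    s
  }, numeric(1))
}

# fabricate a one-connection ConnectivityMap with a given PSTH area
fakeMap <- function(pre, post, area, latency = 30, geom = tinyGeom(2),
                    grid_shape = c(2L, 2L), n_trials = 10L) {
  cn <- data.frame(pre = pre, post = post, latency_ms = latency,
                   peak = n_trials, peak_per100 = 100, p_value = 1e-10,
                   psth_area = area, psth_peak = area, n_resp = n_trials,
                   n_trials = n_trials)
  new("ConnectivityMap", connections = cn, gridShape = as.integer(grid_shape),
      geometry = geom, params = detectionParams(), meta = list())
}

# an evoked session with one position per connection, each post electrode
# emitting `areas[p]` spikes per trial at ~+30 ms (PSTH area = areas[p])
afterSession <- function(areas, n_trials = 10L) {
  npos <- length(areas)
  grid <- c(1L, npos)
  geom <- electrodeGrid(1, npos, drop_corners = FALSE)
  onsets <- lapply(seq_len(npos), function(p)
    ((0:(n_trials - 1)) * npos + (p - 1)) * 200)
  all_on <- unlist(onsets)
  all_pos <- rep(seq_len(npos) - 1L, each = n_trials)
  ord <- order(all_on)
  sch <- meaplast:::newSchedule(
    onset_ms = all_on[ord], on_ms = 40,
    positions = as.list(all_pos[ord]),
    intensity = 1, grid_shape = grid,
    total_duration_ms = npos * n_trials * 200)
  sp <- lapply(seq_len(npos), function(p) {
    unlist(lapply(onsets[[p]], function(on) on + 30 + seq_len(areas[p]) * 2))
  })
  list(spikes = spikeData(sp, npos * n_trials * 200, geom), schedule = sch,
       geom = geom, grid = grid)
}

# three statistically exchangeable patterns: equal numbers of lit pixels at
# random positions, so no pattern is geometrically privileged
randomPatternSet <- function(seed, n_lit = 180L, shape = c(50L, 50L)) {
  set.seed(seed)
  setNames(lapply(c("p1", "p2", "p3"), function(nm) {
    m <- matrix(0L, shape[1], shape[2])
    m[sample.int(prod(shape), n_lit)] <- 1L
    makePattern(nm, mask = m)
  }), c("p1", "p2", "p3"))
}

# a schedule stimulating single positions, one frame per onset
onsetSchedule <- function(onsets, position, grid_shape = c(2L, 2L),
                          on_ms = 40, duration_ms = NULL) {
  meaplast:::newSchedule(onset_ms = onsets, on_ms = on_ms,
                         positions = rep(list(position), length(onsets)),
                         intensity = 1, grid_shape = grid_shape,
                         total_duration_ms = duration_ms)
}
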