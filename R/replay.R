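#' @include AllClasses.R plasticity.R
NULL

#' Extract binned pattern-evoked trials, removing burst-contaminated ones
#'
#' Per trial and electrode, spike counts in `bin_ms` bins over
#' `[onset, onset + window_ms)`. Noisy trials in which an SNB intersected the
#' `pre_exclusion_s` window before stimulus onset are removed and logged.
#'
#' @param spike_data a [SpikeData-class] of the baseline/testing recording.
#' @param schedule the pattern-presentation [StimulusSchedule-class].
#' @param labels character, per-frame pattern labels (from
#'   [makeTestSchedule()]).
#' @param window_ms response window (default 200, covering the informative
#'   30-120 ms span with margin).
#' @param bin_ms bin width (default 10).
#' @param bursts optional [BurstSet-class] used for noisy-trial removal.
#' @param pre_exclusion_s exclusion window before onset (default 1).
#' @param exclude_during also drop trials with a burst intersecting the
#'   response window itself (default TRUE): a burst riding on top of the
#'   evoked response would otherwise enter training as a pattern-labeled
#'   burst profile and corrupt replay decoding.
#' @return a [TrialTensor-class].
#' @export
extractTrials <- function(spike_data, schedule, labels, window_ms = 200,
                          bin_ms = 10, bursts = NULL, pre_exclusion_s = 1,
                          exclude_during = TRUE) {
  onsets <- frameOnsets(schedule)
  stopifnot(length(labels) == length(onsets))
  if (length(onsets) > 1 && window_ms > min(diff(onsets)))
    stop("response window longer than the inter-stimulus interval")
  drop <- rep(FALSE, length(onsets))
  if (!is.null(bursts) && nBursts(bursts) > 0) {
    iv <- intervals(bursts)
    for (t in seq_along(onsets)) {
      lo <- onsets[t] - pre_exclusion_s * 1000
      hi <- if (exclude_during) onsets[t] + window_ms else onsets[t]
      drop[t] <- any(iv$start_ms < hi & iv$end_ms > lo)
    }
  }
  for (lab in unique(labels)) {
    if (all(drop[labels == lab]))
      stop(sprintf("all trials of pattern '%s' were removed as noisy", lab))
  }
  keep <- which(!drop)
  nb <- round(window_ms / bin_ms)
  ne <- length(spike_data@spikes)
  counts <- array(0, dim = c(length(keep), ne, nb))
  for (ti in seq_along(keep)) {
    on <- onsets[keep[ti]]
    for (e in seq_len(ne)) {
      sp <- spike_data@spikes[[e]]
      rel <- sp[sp >= on & sp < on + window_ms] - on
      if (length(rel))
        counts[ti, e, ] <- tabulate(pmin(nb, floor(rel / bin_ms) + 1L),
                                    nbins = nb)
    }
  }
  dropped <- data.frame(trial = which(drop), label = labels[drop],
                        onset_ms = onsets[drop],
                        reason = rep("SNB within pre-stimulus window", sum(drop)))
  new("TrialTensor", counts = counts, labels = labels[keep],
      binMs = bin_ms, windowMs = window_ms,
      electrodes = as.integer(spike_data@geometry$electrode),
      dropped = dropped)
}

#' Per-pattern response summary: mean PSTH and spikes/trial
#'
#' @param tensor a [TrialTensor-class].
#' @return list with `psth` (matrix, time bins x patterns, mean population
#'   spikes per trial per bin) and `totals` (data.frame: pattern, n_trials,
#'   mean_spikes, sem, sem_defined).
#' @export
patternResponseSummary <- function(tensor) {
  labs <- sort(unique(tensor@labels))
  nb <- dim(tensor@counts)[3]
  psth <- matrix(0, nb, length(labs), dimnames = list(NULL, labs))
  totals <- do.call(rbind, lapply(labs, function(lab) {
    sel <- tensor@labels == lab
    ## population counts per trial per bin: sum over electrodes
    pop <- apply(tensor@counts[sel, , , drop = FALSE], c(1, 3), sum)
    psth[, lab] <<- colMeans(pop)
    per_trial <- rowSums(pop)
    n <- length(per_trial)
    data.frame(pattern = lab, n_trials = n, mean_spikes = mean(per_trial),
               sem = if (n > 1) stats::sd(per_trial) / sqrt(n) else 0,
               sem_defined = n > 1)
  }))
  rownames(totals) <- NULL
  list(psth = psth, totals = totals)
}

#' Normalized familiarity metric
#'
#' Averages the response differences between the familiar pattern and the
#' two control patterns and normalizes by the familiar-pattern response:
#' `Delta = ((x_f - x_c1) + (x_f - x_c2)) / (2 * x_f)`. Applies equally to
#' firing-rate means and to SNB replay ratios.
#'
#' @param x_f response to the familiar pattern (> 0).
#' @param x_c1,x_c2 responses to the two control patterns.
#' @return Delta; 0 when all three are equal, positive when the familiar
#'   pattern dominates.
#' @examples
#' familiarityDelta(2, 1, 1)  # 0.5
#' @export
familiarityDelta <- function(x_f, x_c1, x_c2) {
  if (any(x_f <= 0)) stop("familiar-pattern response must be positive")
  ((x_f - x_c1) + (x_f - x_c2)) / (2 * x_f)
}

## internal: flatten a TrialTensor into one instance per (trial, bin):
## the per-electrode count vector, labeled by its trial's pattern
tensorInstances <- function(tensor) {
  d <- dim(tensor@counts)
  X <- matrix(aperm(tensor@counts, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  colnames(X) <- paste0("e", tensor@electrodes)
  list(X = X, y = rep(tensor@labels, d[3]),
       trial = rep(seq_len(d[1]), d[3]),
       bin = rep(seq_len(d[3]), each = d[1]))
}

subsetTensor <- function(tensor, trials) {
  new("TrialTensor", counts = tensor@counts[trials, , , drop = FALSE],
      labels = tensor@labels[trials], binMs = tensor@binMs,
      windowMs = tensor@windowMs, electrodes = tensor@electrodes,
      dropped = tensor@dropped)
}

#' Train the SVM pattern classifier on binned responses
#'
#' Every `bin_ms` bin of every trial becomes one training instance (its
#' per-electrode spike-count vector) labeled by the trial's pattern; pooling
#' all bins of all classes into one classifier avoids the curse of
#' dimensionality. In `split` mode a stratified `split_frac` of the trials is
#' used for training and the remaining trials are returned as a held-out set
#' for validation. A linear-kernel SVM with one-vs-one multiclass (the libsvm
#' default) is used.
#'
#' @param tensor a [TrialTensor-class] with at least two classes.
#' @param mode "pool_all" (train on every bin) or "split".
#' @param split_frac fraction of trials used for training in split mode
#'   (default 0.6).
#' @param seed integer RNG seed for the split.
#' @param cost SVM cost parameter (default 1).
#' @param kernel SVM kernel (default "linear").
#' @param trained_label the familiar (tetanized) pattern, recorded so replay
#'   summaries can compute the familiarity metric; NA when unknown.
#' @return a [PatternClassifier-class].
#' @export
trainPatternClassifier <- function(tensor, mode = c("pool_all", "split"),
                                   split_frac = 0.6, seed = NULL, cost = 1,
                                   kernel = "linear",
                                   trained_label = NA_character_) {
  mode <- match.arg(mode)
  classes <- sort(unique(tensor@labels))
  if (length(classes) < 2L)
    stop("at least two pattern classes are required")
  heldOut <- NULL
  train_tensor <- tensor
  if (mode == "split") {
    if (!is.null(seed)) set.seed(seed)
    tr <- unlist(lapply(classes, function(lab) {
      idx <- which(tensor@labels == lab)
      sample(idx, max(1L, round(split_frac * length(idx))))
    }))
    tr <- sort(tr)
    te <- setdiff(seq_along(tensor@labels), tr)
    if (!length(te)) stop("split left no held-out trials")
    train_tensor <- subsetTensor(tensor, tr)
    heldOut <- subsetTensor(tensor, te)
  }
  inst <- tensorInstances(train_tensor)
  model <- e1071::svm(x = inst$X, y = factor(inst$y, levels = classes),
                      kernel = kernel, cost = cost, scale = FALSE)
  new("PatternClassifier", model = model, classes = classes,
      binMs = tensor@binMs, electrodes = tensor@electrodes, mode = mode,
      heldOut = heldOut, trainedLabel = trained_label)
}

#' Classify instances with a trained pattern classifier
#'
#' @param classifier a [PatternClassifier-class].
#' @param X numeric matrix, one per-electrode count vector per row (columns
#'   in the classifier's electrode order).
#' @return character vector of predicted pattern labels.
#' @export
classifyBins <- function(classifier, X) {
  colnames(X) <- paste0("e", classifier@electrodes)
  as.character(stats::predict(classifier@model, X))
}

#' Classify SNB bins of a continuous recording: replay decoding
#'
#' Bins the whole recording at `bin_ms` into per-electrode count vectors,
#' classifies every bin whose midpoint lies inside a detected burst interval,
#' and summarizes the per-class ratios. When the classifier knows the trained
#' (familiar) pattern, the familiarity metric is computed with that class's
#' ratio as x_f.
#'
#' @param classifier a [PatternClassifier-class].
#' @param spike_data a [SpikeData-class] continuous spontaneous recording.
#' @param bursts a [BurstSet-class] with at least one burst.
#' @param bin_ms bin width (defaults to the classifier's).
#' @return a [ReplaySummary-class].
#' @export
classifySnbBins <- function(classifier, spike_data, bursts,
                            bin_ms = classifier@binMs) {
  if (nBursts(bursts) < 1L) stop("at least one burst is required")
  dur <- spike_data@durationMs
  nb <- floor(dur / bin_ms)
  mids <- (seq_len(nb) - 0.5) * bin_ms
  iv <- intervals(bursts)
  inb <- rep(FALSE, nb)
  for (i in seq_len(nrow(iv)))
    inb <- inb | (mids >= iv$start_ms[i] & mids < iv$end_ms[i])
  sel <- which(inb)
  if (!length(sel)) stop("no recording bins fall inside burst intervals")
  ne <- length(spike_data@spikes)
  X <- matrix(0, length(sel), ne)
  binmap <- match(seq_len(nb), sel)
  for (e in seq_len(ne)) {
    sp <- spike_data@spikes[[e]]
    if (!length(sp)) next
    idx <- floor(sp / bin_ms) + 1L
    idx <- idx[idx >= 1 & idx <= nb]
    tb <- tabulate(idx, nbins = nb)
    X[, e] <- tb[sel]
  }
  pred <- classifyBins(classifier, X)
  ratios <- as.numeric(table(factor(pred, levels = classifier@classes)))
  names(ratios) <- classifier@classes
  ratios <- ratios / sum(ratios)
  delta <- NA_real_
  if (!is.na(classifier@trainedLabel) &&
      classifier@trainedLabel %in% classifier@classes) {
    xf <- ratios[[classifier@trainedLabel]]
    xc <- ratios[setdiff(classifier@classes, classifier@trainedLabel)]
    if (xf > 0 && length(xc) == 2L)
      delta <- familiarityDelta(xf, xc[[1]], xc[[2]])
  }
  new("ReplaySummary", ratios = ratios, nSnbBins = length(sel),
      delta = delta, trainedLabel = classifier@trainedLabel)
}

#' Classification-accuracy timecourse on held-out trials
#'
#' Retrains split-mode classifiers over `n_replicas` reseeded splits and
#' reports held-out classification accuracy per post-stimulus time bin with
#' its SEM, alongside the chance level (1 / number of classes). Bins during
#' and just after the stimulus carry the pattern information; pre-response
#' bins sit at chance.
#'
#' @param tensor a [TrialTensor-class].
#' @param n_replicas number of reseeded splits (default 10).
#' @param split_frac training fraction per split (default 0.6).
#' @param seed base RNG seed; replica r uses seed + r.
#' @param cost,kernel SVM parameters.
#' @return data.frame: bin_start_ms, accuracy, sem, chance.
#' @export
accuracyTimecourse <- function(tensor, n_replicas = 10L, split_frac = 0.6,
                               seed = 1L, cost = 1, kernel = "linear") {
  nb <- dim(tensor@counts)[3]
  acc <- matrix(NA_real_, n_replicas, nb)
  for (r in seq_len(n_replicas)) {
    clf <- trainPatternClassifier(tensor, mode = "split",
                                  split_frac = split_frac, seed = seed + r,
                                  cost = cost, kernel = kernel)
    ho <- clf@heldOut
    inst <- tensorInstances(ho)
    pred <- classifyBins(clf, inst$X)
    for (b in seq_len(nb)) {
      sel <- inst$bin == b
      acc[r, b] <- mean(pred[sel] == inst$y[sel])
    }
  }
  data.frame(
    bin_start_ms = (seq_len(nb) - 1) * tensor@binMs,
    accuracy = colMeans(acc),
    sem = apply(acc, 2, stats::sd) / sqrt(n_replicas),
    chance = 1 / length(unique(tensor@labels))
  )
}
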