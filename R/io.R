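#' @include AllClasses.R constructors.R
NULL

#' Write spike data to disk
#'
#' TSV format: '#'-prefixed metadata header (duration and electrode
#' geometry) followed by two columns, electrode_id and time_ms, sorted within
#' electrode. JSON format stores the same content as one object. Both round
#' trip exactly through [readSpikes()].
#'
#' @param x a [SpikeData-class].
#' @param path output file.
#' @param format "tsv" or "json".
#' @return `path`, invisibly.
#' @export
writeSpikes <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(duration_ms = x@durationMs, geometry = x@geometry,
                spikes = x@spikes)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# meaplast spikes v1",
               sprintf("# duration_ms\t%.10g", x@durationMs),
               "# geometry\telectrode\trow\tcol\tx_um\ty_um"), con)
  g <- x@geometry
  writeLines(sprintf("# g\t%d\t%d\t%d\t%.10g\t%.10g", g$electrode, g$row,
                     g$col, g$x_um, g$y_um), con)
  writeLines("electrode_id\ttime_ms", con)
  for (i in seq_along(x@spikes)) {
    sp <- x@spikes[[i]]
    if (length(sp))
      writeLines(sprintf("%s\t%.10g", names(x@spikes)[i], sp), con)
  }
  invisible(path)
}

#' Read spike data written by [writeSpikes()]
#'
#' Malformed rows, unknown electrode ids, unsorted or out-of-range
#' timestamps raise descriptive errors naming the offending line.
#'
#' @param path input file.
#' @param format "tsv" or "json"; guessed from the extension by default.
#' @return a [SpikeData-class].
#' @export
readSpikes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    geom <- as.data.frame(obj$geometry)
    sp <- lapply(obj$spikes, as.numeric)
    return(spikeData(sp[as.character(geom$electrode)], obj$duration_ms, geom))
  }
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  dur_ln <- grep("^# duration_ms\t", lines)
  if (!length(dur_ln)) stop("missing '# duration_ms' header")
  duration_ms <- as.numeric(sub("^# duration_ms\t", "", lines[dur_ln[1]]))
  g_ln <- grep("^# g\t", lines)
  if (!length(g_ln)) stop("missing '# g' geometry rows")
  gm <- do.call(rbind, strsplit(sub("^# g\t", "", lines[g_ln]), "\t"))
  geom <- data.frame(electrode = as.integer(gm[, 1]), row = as.integer(gm[, 2]),
                     col = as.integer(gm[, 3]), x_um = as.numeric(gm[, 4]),
                     y_um = as.numeric(gm[, 5]))
  body <- which(!meta)
  hdr <- body[1]
  if (lines[hdr] != "electrode_id\ttime_ms")
    stop(sprintf("line %d: expected header 'electrode_id\\ttime_ms'", hdr))
  sp <- lapply(seq_len(nrow(geom)), function(i) numeric(0))
  names(sp) <- as.character(geom$electrode)
  last_t <- stats::setNames(rep(-Inf, nrow(geom)), names(sp))
  for (ln in body[-1]) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop(sprintf("line %d: expected 2 tab-separated fields, got %d", ln, length(f)))
    id <- f[1]
    t <- suppressWarnings(as.numeric(f[2]))
    if (is.na(t)) stop(sprintf("line %d: unparseable timestamp '%s'", ln, f[2]))
    if (!(id %in% names(sp)))
      stop(sprintf("line %d: electrode id '%s' not in geometry", ln, id))
    if (t < 0 || t > duration_ms)
      stop(sprintf("line %d: timestamp %g outside [0, %g]", ln, t, duration_ms))
    if (t < last_t[[id]])
      stop(sprintf("line %d: unsorted timestamp for electrode %s", ln, id))
    last_t[[id]] <- t
    sp[[id]] <- c(sp[[id]], t)
  }
  spikeData(sp, duration_ms, geom)
}

#' Write / read a stimulus schedule as JSON
#'
#' Schema: `{grid_shape, total_duration_ms, frames: [{onset_ms, on_ms,
#' positions, intensity}]}` with 0-based row-major positions.
#'
#' @param x a [StimulusSchedule-class].
#' @param path file path.
#' @return `path` invisibly (write); a [StimulusSchedule-class] (read).
#' @export
writeSchedule <- function(x, path) {
  frames <- lapply(seq_along(x@onsetMs), function(k)
    list(onset_ms = x@onsetMs[k], on_ms = x@onMs[k],
         positions = as.integer(x@positions[[k]]), intensity = x@intensity[k]))
  jsonlite::write_json(
    list(grid_shape = x@gridShape, total_duration_ms = x@totalDurationMs,
         frames = frames),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(obj$frames)
  newSchedule(
    onset_ms = vapply(obj$frames, function(f) as.numeric(f$onset_ms), numeric(1)),
    on_ms = vapply(obj$frames, function(f) as.numeric(f$on_ms), numeric(1)),
    positions = lapply(obj$frames, function(f) as.integer(unlist(f$positions))),
    intensity = vapply(obj$frames, function(f) as.numeric(f$intensity), numeric(1)),
    grid_shape = as.integer(unlist(obj$grid_shape)),
    total_duration_ms = as.numeric(obj$total_duration_ms))
}

#' Write / read a connectivity map
#'
#' JSON keeps the full object (edge table, grid, geometry, detection
#' parameters). The TSV edge list carries one row per connection with grid
#' coordinates: pre_row, pre_col, post_row, post_col, latency_ms,
#' peak_per100, p_value, psth_area, psth_peak, n_resp, n_trials.
#'
#' @param x a [ConnectivityMap-class].
#' @param path file path.
#' @param format "json" (round-trippable) or "tsv" (edge list export).
#' @return `path` invisibly (write); a [ConnectivityMap-class] (read, JSON
#'   only).
#' @export
writeMap <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(grid_shape = x@gridShape, connections = x@connections,
           geometry = x@geometry, params = x@params, meta = x@meta),
      path, digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  cn <- x@connections
  nc <- x@gridShape[2]
  gi <- match(cn$post, x@geometry$electrode)
  out <- data.frame(
    pre_row = cn$pre %/% nc, pre_col = cn$pre %% nc,
    post_row = x@geometry$row[gi], post_col = x@geometry$col[gi],
    latency_ms = cn$latency_ms, peak_per100 = cn$peak_per100,
    p_value = cn$p_value, psth_area = cn$psth_area,
    psth_peak = cn$psth_peak, n_resp = cn$n_resp, n_trials = cn$n_trials)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMap
#' @export
readMap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- as.data.frame(obj$connections)
  if (!nrow(cn))
    cn <- data.frame(pre = integer(0), post = integer(0),
                     latency_ms = numeric(0), peak = numeric(0),
                     peak_per100 = numeric(0), p_value = numeric(0),
                     psth_area = numeric(0), psth_peak = numeric(0),
                     n_resp = integer(0), n_trials = integer(0))
  prm <- obj$params
  prm$lag_range_ms <- as.numeric(unlist(prm$lag_range_ms))
  new("ConnectivityMap", connections = cn,
      gridShape = as.integer(unlist(obj$grid_shape)),
      geometry = as.data.frame(obj$geometry),
      params = prm, meta = as.list(obj$meta))
}

#' Write a burst set as a BED-like interval table
#'
#' Three tab-separated columns: start_ms, end_ms, n_electrodes.
#'
#' @param x a [BurstSet-class].
#' @param path file path.
#' @return `path` invisibly (write); a [BurstSet-class] (read).
#' @export
writeBursts <- function(x, path) {
  utils::write.table(x@intervals, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeBursts
#' @export
readBursts <- function(path) {
  iv <- utils::read.table(path, sep = "\t", header = TRUE)
  new("BurstSet", intervals = iv)
}
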