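#' @include AllClasses.R
NULL

## internal: build a StimulusSchedule with a computed total duration
newSchedule <- function(onset_ms, on_ms, positions, intensity, grid_shape,
                        total_duration_ms = NULL) {
  n <- length(onset_ms)
  on_ms <- rep_len(on_ms, n)
  intensity <- rep_len(intensity, n)
  if (is.null(total_duration_ms))
    total_duration_ms <- if (n) onset_ms[n] + on_ms[n] else 0
  new("StimulusSchedule",
      onsetMs = as.numeric(onset_ms), onMs = as.numeric(on_ms),
      positions = unname(lapply(positions, function(p) as.integer(sort(p)))),
      intensity = as.numeric(intensity),
      gridShape = as.integer(grid_shape),
      totalDurationMs = as.numeric(total_duration_ms))
}

#' Construct an MEA electrode geometry table
#'
#' Builds a regular electrode grid at a given pitch. For the standard 16 x 16
#' layout the four grid corners carry no electrode, giving the familiar
#' 252-electrode array; smaller demonstration grids keep all positions by
#' default.
#'
#' @param nrow,ncol grid dimensions.
#' @param pitch_um interelectrode spacing in micrometers (default 200).
#' @param drop_corners drop the four corner positions (default TRUE for a
#'   16 x 16 grid, FALSE otherwise).
#' @return data.frame with columns electrode (0-based id), row, col, x_um,
#'   y_um.
#' @examples
#' g <- electrodeGrid(16, 16)
#' nrow(g)  # 252
#' @export
electrodeGrid <- function(nrow = 16L, ncol = 16L, pitch_um = 200,
                          drop_corners = (nrow == 16L && ncol == 16L)) {
  stopifnot(nrow >= 1, ncol >= 1)
  rc <- expand.grid(col = seq_len(ncol) - 1L, row = seq_len(nrow) - 1L)
  g <- data.frame(
    electrode = rc$row * ncol + rc$col,
    row = rc$row, col = rc$col,
    x_um = rc$col * pitch_um, y_um = rc$row * pitch_um
  )
  if (drop_corners && nrow >= 2 && ncol >= 2) {
    corner <- (g$row %in% c(0L, nrow - 1L)) & (g$col %in% c(0L, ncol - 1L))
    g <- g[!corner, , drop = FALSE]
  }
  rownames(g) <- NULL
  g
}

#' Construct a SpikeData object
#'
#' @param spikes list of numeric spike-time vectors in ms, one per electrode
#'   in `geometry` order (sorted automatically).
#' @param duration_ms recording duration in ms.
#' @param geometry electrode table from [electrodeGrid()].
#' @return a [SpikeData-class] object.
#' @examples
#' geom <- electrodeGrid(2, 2, drop_corners = FALSE)
#' sd <- spikeData(list(c(1, 5), numeric(0), 2.5, c(7, 8)), 10, geom)
#' @export
spikeData <- function(spikes, duration_ms, geometry) {
  spikes <- lapply(spikes, function(s) sort(as.numeric(s)))
  names(spikes) <- as.character(geometry$electrode)
  new("SpikeData", spikes = spikes, durationMs = as.numeric(duration_ms),
      geometry = geometry)
}

#' Coordinates of stimulation-grid cell centers over the electrode plane
#'
#' The optical stimulation grid covers the same area as the electrode array;
#' this maps each 0-based row-major grid index to the physical center of its
#' cell, for distance summaries of stimulus-position to electrode connections.
#'
#' @param grid_shape integer(2), (rows, cols) of the stimulation grid.
#' @param geometry electrode table defining the covered extent.
#' @return data.frame: position, row, col, x_um, y_um.
#' @export
stimPositionCoords <- function(grid_shape, geometry) {
  grid_shape <- as.integer(grid_shape)
  x0 <- min(geometry$x_um); x1 <- max(geometry$x_um)
  y0 <- min(geometry$y_um); y1 <- max(geometry$y_um)
  cw <- (x1 - x0) / grid_shape[2]
  ch <- (y1 - y0) / grid_shape[1]
  rc <- expand.grid(col = seq_len(grid_shape[2]) - 1L,
                    row = seq_len(grid_shape[1]) - 1L)
  data.frame(
    position = rc$row * grid_shape[2] + rc$col,
    row = rc$row, col = rc$col,
    x_um = x0 + (rc$col + 0.5) * cw,
    y_um = y0 + (rc$row + 0.5) * ch
  )
}
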