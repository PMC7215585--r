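#' @include AllClasses.R
NULL

## internal rasterization helpers: draw 1-px line segments / ellipse outlines
## into a binary matrix, coordinates in [0, 1] x [0, 1]
rasterLine <- function(mask, r0, c0, r1, c1) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- max(2L, ceiling(2 * max(abs(r1 - r0) * nr, abs(c1 - c0) * nc)))
  t <- seq(0, 1, length.out = n)
  rr <- pmin(nr, pmax(1, round((r0 + t * (r1 - r0)) * (nr - 1)) + 1))
  cc <- pmin(nc, pmax(1, round((c0 + t * (c1 - c0)) * (nc - 1)) + 1))
  mask[cbind(rr, cc)] <- 1L
  mask
}

rasterEllipse <- function(mask, rc, cc, rr, cr) {
  th <- seq(0, 2 * pi, length.out = 16L * max(dim(mask)))
  r <- rc + rr * sin(th)
  c <- cc + cr * cos(th)
  keep <- r >= 0 & r <= 1 & c >= 0 & c <= 1
  nr <- nrow(mask); ncn <- ncol(mask)
  ri <- pmin(nr, pmax(1, round(r[keep] * (nr - 1)) + 1))
  ci <- pmin(ncn, pmax(1, round(c[keep] * (ncn - 1)) + 1))
  mask[cbind(ri, ci)] <- 1L
  mask
}

drawCar <- function(shape) {
  m <- matrix(0L, shape[1], shape[2])
  ## body outline
  m <- rasterLine(m, 0.30, 0.08, 0.30, 0.92)
  m <- rasterLine(m, 0.30, 0.08, 0.85, 0.08)
  m <- rasterLine(m, 0.30, 0.92, 0.85, 0.92)
  m <- rasterLine(m, 0.85, 0.08, 0.85, 0.92)
  ## roof / windshield
  m <- rasterLine(m, 0.30, 0.25, 0.10, 0.35)
  m <- rasterLine(m, 0.30, 0.75, 0.10, 0.65)
  m <- rasterLine(m, 0.10, 0.35, 0.10, 0.65)
  ## headlights
  m <- rasterEllipse(m, 0.48, 0.24, 0.08, 0.08)
  m <- rasterEllipse(m, 0.48, 0.76, 0.08, 0.08)
  ## grille
  m <- rasterLine(m, 0.62, 0.35, 0.62, 0.65)
  m <- rasterLine(m, 0.70, 0.35, 0.70, 0.65)
  m <- rasterLine(m, 0.62, 0.35, 0.70, 0.35)
  m <- rasterLine(m, 0.62, 0.65, 0.70, 0.65)
  m
}

drawDog <- function(shape) {
  m <- matrix(0L, shape[1], shape[2])
  ## head
  m <- rasterEllipse(m, 0.55, 0.50, 0.32, 0.28)
  ## floppy ears
  m <- rasterLine(m, 0.28, 0.25, 0.08, 0.15)
  m <- rasterLine(m, 0.08, 0.15, 0.45, 0.08)
  m <- rasterLine(m, 0.28, 0.75, 0.08, 0.85)
  m <- rasterLine(m, 0.08, 0.85, 0.45, 0.92)
  ## eyes
  m <- rasterEllipse(m, 0.45, 0.38, 0.04, 0.04)
  m <- rasterEllipse(m, 0.45, 0.62, 0.04, 0.04)
  ## snout + nose
  m <- rasterEllipse(m, 0.68, 0.50, 0.10, 0.12)
  m <- rasterLine(m, 0.62, 0.46, 0.62, 0.54)
  m
}

drawHuman <- function(shape) {
  m <- matrix(0L, shape[1], shape[2])
  ## face oval
  m <- rasterEllipse(m, 0.50, 0.50, 0.38, 0.26)
  ## eyes
  m <- rasterLine(m, 0.40, 0.34, 0.40, 0.44)
  m <- rasterLine(m, 0.40, 0.56, 0.40, 0.66)
  ## nose
  m <- rasterLine(m, 0.42, 0.50, 0.58, 0.47)
  m <- rasterLine(m, 0.58, 0.47, 0.58, 0.53)
  ## mouth
  m <- rasterLine(m, 0.70, 0.38, 0.74, 0.50)
  m <- rasterLine(m, 0.74, 0.50, 0.70, 0.62)
  ## hair line
  m <- rasterLine(m, 0.22, 0.32, 0.16, 0.50)
  m <- rasterLine(m, 0.16, 0.50, 0.22, 0.68)
  m
}

#' Build a stimulation pattern mask
#'
#' Returns one of the three built-in sketch-like line drawings (a car front, a
#' dog face, a human face) rasterized on the pattern grid, or wraps a
#' user-supplied binary mask. The built-ins are procedurally drawn stand-ins
#' sharing only the grid size of the original projected images.
#'
#' @param name "car", "dog" or "human", or any label when `mask` is given.
#' @param pattern_grid_shape integer(2), default c(50, 50).
#' @param intensity luminance scalar stored for baseline-response balancing.
#' @param mask optional user binary matrix; overrides the built-ins.
#' @return a [PatternMask-class].
#' @examples
#' p <- makePattern("human")
#' sum(p@mask) > 0
#' @export
makePattern <- function(name, pattern_grid_shape = c(50L, 50L), intensity = 1,
                        mask = NULL) {
  if (is.null(mask)) {
    shape <- as.integer(pattern_grid_shape)
    mask <- switch(name,
      car = drawCar(shape),
      dog = drawDog(shape),
      human = drawHuman(shape),
      stop(sprintf("unknown pattern '%s' and no mask supplied; built-ins are %s",
                   name, "car, dog, human"))
    )
  } else {
    mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  }
  new("PatternMask", name = name, mask = mask, intensity = as.numeric(intensity))
}

#' Project a pattern mask onto a stimulation grid
#'
#' A stimulation-grid cell is lit when any pattern pixel inside the
#' corresponding block of the pattern grid is lit. Used to turn 50 x 50
#' line drawings into the coarser grids that schedules and the simulator
#' address.
#'
#' @param pattern a [PatternMask-class].
#' @param grid_shape integer(2) target stimulation grid.
#' @return sorted integer vector of lit 0-based row-major grid indices.
#' @export
patternToGrid <- function(pattern, grid_shape) {
  grid_shape <- as.integer(grid_shape)
  m <- pattern@mask
  lit <- which(m == 1L, arr.ind = TRUE)
  gr <- pmin(grid_shape[1] - 1L,
             floor((lit[, 1] - 1L) / nrow(m) * grid_shape[1]))
  gc <- pmin(grid_shape[2] - 1L,
             floor((lit[, 2] - 1L) / ncol(m) * grid_shape[2]))
  sort(unique(as.integer(gr * grid_shape[2] + gc)))
}
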