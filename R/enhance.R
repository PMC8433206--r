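#' Contrast-enhancement configuration
#'
#' Settings for slice-wise contrast conditioning of reconstructed volumes:
#' min-max display rescaling, contrast limited adaptive histogram
#' equalization (CLAHE) and multi-range image fusion. Tile sizes follow the
#' two-channel convention of near-infrared projection tomography
#' processing: 32 px tiles for the immunolabel channel and 16 px tiles for
#' the autofluorescence anatomy channel.
#'
#' @param clahe_tile_signal CLAHE tile size (pixels) for the signal channel.
#' @param clahe_tile_anatomy CLAHE tile size (pixels) for the anatomy
#'   channel.
#' @param clahe_clip_limit histogram clip limit as a fraction of the tile
#'   pixel count.
#' @param fusion_ranges list of three \code{c(low, high)} intensity windows
#'   (on the [0,1] scale) for low/middle/high range fusion.
#' @return A list of class \code{"EnhanceConfig"}.
#' @export
enhanceConfig <- function(clahe_tile_signal = 32L, clahe_tile_anatomy = 16L,
                          clahe_clip_limit = 0.01,
                          fusion_ranges = list(c(0, 0.35), c(0.2, 0.7),
                                               c(0.5, 1))) {
  stopifnot(clahe_tile_signal >= 2L, clahe_tile_anatomy >= 2L,
            clahe_clip_limit > 0, length(fusion_ranges) == 3L)
  for (w in fusion_ranges)
    if (length(w) != 2L || w[1] >= w[2])
      stop("fusion windows must satisfy low < high")
  structure(list(clahe_tile_signal = as.integer(clahe_tile_signal),
                 clahe_tile_anatomy = as.integer(clahe_tile_anatomy),
                 clahe_clip_limit = clahe_clip_limit,
                 fusion_ranges = fusion_ranges),
            class = "EnhanceConfig")
}

#' Rescale a volume to display minima and maxima
#'
#' Affine monotone map of the voxel values onto [0, 1]. A constant volume
#' maps to all zeros (documented degenerate case, no error).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return A \linkS4class{VoxelGrid} spanning [0, 1].
#' @examples
#' g <- VoxelGrid(array(c(10, 20, 30), c(3, 1, 1)))
#' as.vector(voxelData(rescaleMinMax(g)))
#' @export
rescaleMinMax <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  v <- grid@data
  r <- range(v)
  if (r[2] > r[1]) {
    grid@data <- (v - r[1]) / (r[2] - r[1])
  } else {
    grid@data <- array(0, dim(v))
  }
  grid
}

#' Slice-wise contrast limited adaptive histogram equalization
#'
#' Applies CLAHE independently to every z-slice: the slice is partitioned
#' into \code{tile} x \code{tile} pixel contextual regions, each region's
#' histogram is clipped at \code{clip} times the region pixel count (excess
#' redistributed uniformly), and pixels are mapped through bilinear
#' interpolation of the neighbouring region CDFs. Input is rescaled to
#' [0, 1] first; output is in [0, 1].
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param tile contextual region size in pixels (>= 2).
#' @param clip clip limit as a fraction of tile pixels.
#' @param nbins number of histogram bins.
#' @return A \linkS4class{VoxelGrid}.
#' @export
claheSlicewise <- function(grid, tile = 32L, clip = 0.01, nbins = 256L) {
  stopifnot(is(grid, "VoxelGrid"), tile >= 2L)
  d <- dim(grid@data)
  if (tile > d[1] || tile > d[2])
    stop("tile larger than slice dimensions; use global equalization ",
         "(rescaleMinMax) instead")
  g <- rescaleMinMax(grid)
  out <- g@data
  for (k in seq_len(d[3]))
    out[, , k] <- cpp_clahe_slice(out[, , k], as.integer(tile), clip,
                                  as.integer(nbins))
  g@data <- out
  g
}

#' Multi-range image fusion
#'
#' Produces three copies of the volume, each clipped and stretched to one
#' intensity window (low, middle, high range), averages them pixelwise and
#' rescales the result to [0, 1]. The combined map is monotone in the
#' input, so ranking of voxel values is preserved.
#'
#' @param grid a \linkS4class{VoxelGrid} (rescaled internally to [0, 1]).
#' @param ranges list of three \code{c(low, high)} windows on the [0, 1]
#'   scale.
#' @return A \linkS4class{VoxelGrid}.
#' @export
fuseRanges <- function(grid, ranges = enhanceConfig()$fusion_ranges) {
  stopifnot(is(grid, "VoxelGrid"), length(ranges) == 3L)
  for (w in ranges)
    if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
      stop("degenerate fusion window: need low < high")
  g <- rescaleMinMax(grid)
  v <- g@data
  acc <- array(0, dim(v))
  for (w in ranges)
    acc <- acc + (pmin(pmax(v, w[1]), w[2]) - w[1]) / (w[2] - w[1])
  g@data <- acc / 3
  rescaleMinMax(g)
}

#' Enhance one channel with the standard chain
#'
#' Convenience wrapper: min-max rescale, slice-wise CLAHE, and (for the
#' signal channel) multi-range fusion.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param channel \code{"signal"} or \code{"anatomy"}; picks the CLAHE tile
#'   size and whether fusion is applied.
#' @param cfg an \code{\link{enhanceConfig}}.
#' @return A \linkS4class{VoxelGrid} in [0, 1].
#' @export
enhanceChannel <- function(grid, channel = c("signal", "anatomy"),
                           cfg = enhanceConfig()) {
  channel <- match.arg(channel)
  tile <- if (channel == "signal") cfg$clahe_tile_signal else
    cfg$clahe_tile_anatomy
  out <- claheSlicewise(rescaleMinMax(grid), tile = tile,
                        clip = cfg$clahe_clip_limit)
  if (channel == "signal") out <- fuseRanges(out, cfg$fusion_ranges)
  out
}
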