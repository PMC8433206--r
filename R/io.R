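#' Read and write voxel volumes as multi-page TIFF
#'
#' Volumes are stored as one 32-bit float page per z-slice (rows = y,
#' columns = x). TIFF float pages hold [0, 1], so values are affinely
#' mapped into that range on write and restored on read from the
#' intensity range recorded, together with voxel size and origin, in a
#' JSON sidecar (\code{<path>.json}).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param path output TIFF path.
#' @return \code{writeVoxelGrid} returns \code{path} invisibly;
#'   \code{readVoxelGrid} returns a \linkS4class{VoxelGrid}.
#' @export
writeVoxelGrid <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid@data)
  rng <- range(grid@data)
  v <- if (rng[2] > rng[1]) (grid@data - rng[1]) / (rng[2] - rng[1])
       else array(0, d)
  pages <- lapply(seq_len(d[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size_um = grid@voxelSize,
                            origin_um = grid@origin,
                            shape_voxels = d,
                            intensity_range = rng),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVoxelGrid
#' @export
readVoxelGrid <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  a <- array(0, d)
  for (k in seq_along(pages)) a[, , k] <- t(pages[[k]])
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(m$intensity_range)) {
      rng <- m$intensity_range
      a <- a * (rng[2] - rng[1]) + rng[1]
    }
    VoxelGrid(a, m$voxel_size_um, m$origin_um)
  } else {
    VoxelGrid(a)
  }
}

#' Read and write islet catalogs as CSV
#'
#' One row per object; coordinates in micrometres, volumes in cubic
#' micrometres, areas in square micrometres.
#'
#' @param records catalog data frame (see \code{\link{objectFeatures}}).
#' @param path CSV path.
#' @export
writeCatalog <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write cuboid placement metadata as JSON
#'
#' @param meta a \linkS4class{CuboidMeta}.
#' @param path JSON path.
#' @export
writeCuboidMeta <- function(meta, path) {
  stopifnot(is(meta, "CuboidMeta"))
  jsonlite::write_json(list(schema = "cuboid-meta/1", id = meta@cuboidId,
                            grid_ijk = meta@gridIJK,
                            origin_um = meta@originUm,
                            shape_voxels = meta@shapeVoxels,
                            voxel_size_um = meta@voxelSizeUm,
                            grid_pitch_um = meta@gridPitchUm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCuboidMeta
#' @export
readCuboidMeta <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  CuboidMeta(cuboidId = m$id, gridIJK = m$grid_ijk,
             shapeVoxels = m$shape_voxels, voxelSizeUm = m$voxel_size_um,
             gridPitchUm = m$grid_pitch_um, originUm = m$origin_um)
}
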