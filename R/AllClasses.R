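#' @useDynLib isletmapper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rlnorm quantile var sd setNames dist
#' @importFrom utils write.csv read.csv
NULL

#' VoxelGrid: one channel of one tissue cuboid
#'
#' A \code{VoxelGrid} holds a single-channel 3D scalar lattice together with
#' its isotropic voxel size (micrometres) and the physical position of the
#' cuboid corner in the organ frame. Array dimensions are ordered (x, y, z)
#' and the centre of voxel \code{(i, j, k)} (1-based) sits at
#' \code{origin + (c(i, j, k) - 0.5) * voxelSize} micrometres.
#'
#' @slot data 3D numeric array, dimension (nx, ny, nz).
#' @slot voxelSize isotropic voxel edge length in micrometres.
#' @slot origin physical position (x, y, z) of the cuboid corner, micrometres.
#' @export
setClass("VoxelGrid",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be a finite numeric of length 3")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param data 3D numeric array (x, y, z).
#' @param voxelSize isotropic voxel size in micrometres (default 21, the
#'   pixel pitch of a typical near-infrared projection tomography scan).
#' @param origin physical offset of the cuboid corner in micrometres.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(array(0, c(8, 8, 8)))
#' voxelSize(g)
#' @export
VoxelGrid <- function(data, voxelSize = 21, origin = c(0, 0, 0)) {
  new("VoxelGrid", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' LabelVolume: integer object labels on a voxel lattice
#'
#' Extends \linkS4class{VoxelGrid}; \code{data} holds integer labels with 0 as
#' background and objects labelled contiguously 1..K.
#'
#' @export
setClass("LabelVolume", contains = "VoxelGrid")

setValidity("LabelVolume", function(object) {
  v <- object@data
  if (any(v < 0)) return("labels must be non-negative")
  k <- max(v)
  if (k > 0) {
    present <- unique(as.integer(v))
    if (!all(seq_len(k) %in% present))
      return("labels must be contiguous 1..K")
  }
  TRUE
})

#' Construct a LabelVolume
#'
#' @param data 3D array of integer labels (0 = background, 1..K contiguous).
#' @param voxelSize,origin as for \code{\link{VoxelGrid}}.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(data, voxelSize = 21, origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' CuboidMeta: identity and placement of a cuboid in the organ slicing grid
#'
#' Cuboids are cut on a printed slicing matrix; their grid indices and
#' physical offsets are recorded so per-cuboid data can be stitched back
#' into one organ frame. The default lateral grid pitch of 5500 x 3300
#' micrometres matches a 0.55 cm x 0.33 cm slicing matrix; the third pitch
#' component is the z block height (tall cuboids are cut into z blocks).
#'
#' @slot cuboidId character identifier, unique within an organ.
#' @slot gridIJK integer triple: position in the slicing grid (0-based).
#' @slot originUm physical offset (x, y, z) of the cuboid corner, micrometres.
#' @slot shapeVoxels integer triple: array dimensions of the cuboid volume.
#' @slot voxelSizeUm isotropic voxel size, micrometres.
#' @slot gridPitchUm numeric triple: grid pitch (x, y) and z block height.
#' @export
setClass("CuboidMeta",
  representation(cuboidId = "character", gridIJK = "integer",
                 originUm = "numeric", shapeVoxels = "integer",
                 voxelSizeUm = "numeric", gridPitchUm = "numeric"))

setValidity("CuboidMeta", function(object) {
  if (length(object@cuboidId) != 1L) return("cuboidId must be length 1")
  if (length(object@gridIJK) != 3L || any(object@gridIJK < 0))
    return("gridIJK must be 3 non-negative integers")
  if (length(object@originUm) != 3L) return("originUm must be length 3")
  if (length(object@shapeVoxels) != 3L || any(object@shapeVoxels < 1))
    return("shapeVoxels must be 3 positive integers")
  if (object@voxelSizeUm <= 0) return("voxelSizeUm must be positive")
  if (length(object@gridPitchUm) != 3L || any(object@gridPitchUm <= 0))
    return("gridPitchUm must be 3 positive numbers")
  expected <- object@gridIJK * object@gridPitchUm
  if (any(abs(expected - object@originUm) > object@voxelSizeUm))
    return("originUm must equal gridIJK * gridPitchUm within one voxel")
  TRUE
})

#' Construct a CuboidMeta
#'
#' @param cuboidId character identifier.
#' @param gridIJK integer triple, 0-based grid position.
#' @param shapeVoxels integer triple, cuboid array dimensions.
#' @param voxelSizeUm voxel size in micrometres.
#' @param gridPitchUm numeric triple, grid pitch in micrometres; defaults to
#'   the cuboid extent so adjacent cuboids abut exactly.
#' @param originUm physical corner offset; defaults to
#'   \code{gridIJK * gridPitchUm}.
#' @return A \linkS4class{CuboidMeta}.
#' @export
CuboidMeta <- function(cuboidId, gridIJK, shapeVoxels, voxelSizeUm = 21,
                       gridPitchUm = shapeVoxels * voxelSizeUm,
                       originUm = gridIJK * gridPitchUm) {
  new("CuboidMeta", cuboidId = as.character(cuboidId),
      gridIJK = as.integer(gridIJK), originUm = as.numeric(originUm),
      shapeVoxels = as.integer(shapeVoxels),
      voxelSizeUm = as.numeric(voxelSizeUm),
      gridPitchUm = as.numeric(gridPitchUm))
}

## ---- generics and accessors -------------------------------------------

#' @rdname VoxelGrid-class
#' @param object,x a \linkS4class{VoxelGrid}.
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelData", "VoxelGrid", function(object) object@data)

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelSize", "VoxelGrid", function(object) object@voxelSize)

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname VoxelGrid-class
#' @export
setMethod("gridOrigin", "VoxelGrid", function(object) object@origin)

#' @rdname VoxelGrid-class
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@data))

#' Number of labelled objects in a LabelVolume
#' @param object a \linkS4class{LabelVolume}.
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))

#' @rdname nLabels
#' @export
setMethod("nLabels", "LabelVolume", function(object) max(object@data))

#' @rdname CuboidMeta-class
#' @param object a \linkS4class{CuboidMeta}.
#' @export
setGeneric("cuboidId", function(object) standardGeneric("cuboidId"))

#' @rdname CuboidMeta-class
#' @export
setMethod("cuboidId", "CuboidMeta", function(object) object@cuboidId)

#' @rdname CuboidMeta-class
#' @export
setGeneric("cuboidOrigin", function(object) standardGeneric("cuboidOrigin"))

#' @rdname CuboidMeta-class
#' @export
setMethod("cuboidOrigin", "CuboidMeta", function(object) object@originUm)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s of %d x %d x %d voxels at %.3g um/voxel\n",
              class(object), d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  origin (um): %.1f %.1f %.1f\n", object@origin[1],
              object@origin[2], object@origin[3]))
  if (is(object, "LabelVolume")) {
    cat(sprintf("  labels: %d objects\n", max(object@data)))
  } else {
    r <- range(object@data)
    cat(sprintf("  intensity range: [%.4g, %.4g]\n", r[1], r[2]))
  }
})

setMethod("show", "CuboidMeta", function(object) {
  cat(sprintf("CuboidMeta '%s' grid (%d,%d,%d)\n", object@cuboidId,
              object@gridIJK[1], object@gridIJK[2], object@gridIJK[3]))
  cat(sprintf("  origin (um): %.1f %.1f %.1f; shape %d x %d x %d @ %.3g um\n",
              object@originUm[1], object@originUm[2], object@originUm[3],
              object@shapeVoxels[1], object@shapeVoxels[2],
              object@shapeVoxels[3], object@voxelSizeUm))
})

## ---- internal helpers --------------------------------------------------

# physical coordinates (um) of voxel centres along one axis
.axis_centers <- function(n, voxel_size, origin) {
  origin + (seq_len(n) - 0.5) * voxel_size
}

# linear index -> (i,j,k) and back, 1-based
.ind2sub <- function(ind, d) {
  ind0 <- ind - 1L
  k <- ind0 %/% (d[1] * d[2])
  r <- ind0 %% (d[1] * d[2])
  cbind(r %% d[1], r %/% d[1], k) + 1L
}

.check_same_lattice <- function(a, b) {
  if (!identical(dim(a@data), dim(b@data)))
    stop("volumes have mismatched dimensions")
  if (!isTRUE(all.equal(a@voxelSize, b@voxelSize)))
    stop("volumes have mismatched voxel sizes")
  invisible(TRUE)
}
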