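#' Per-object 3D morphometry
#'
#' Computes one catalog row per labelled object: voxel count, volume,
#' centroid (cuboid-local and, when the label volume carries a nonzero
#' origin, global micrometre coordinates), world-axis lengths, mean 3D
#' diameter, isosurface area and Wadell sphericity.
#'
#' Axis lengths are ellipsoid-equivalent lengths along the world axes:
#' \code{2 * sqrt(5 * var)} of the voxel-centre coordinates along each
#' axis (a solid ellipsoid with semi-axis a has coordinate variance
#' a^2 / 5 along that axis). The mean 3D diameter is the average of the
#' three axis lengths, matching how mean islet diameters are derived from
#' x/y/z axis lengths.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param cuboid_id identifier copied into the catalog.
#' @param compute_surface compute isosurface area and sphericity (set
#'   FALSE to skip the slower surface pass).
#' @return A data frame (one row per object) with columns \code{islet_id},
#'   \code{cuboid_id}, \code{cx_um}/\code{cy_um}/\code{cz_um} (local
#'   centroid), \code{gx_um}/\code{gy_um}/\code{gz_um} (global centroid),
#'   \code{voxel_count}, \code{volume_um3}, \code{axis_x_um},
#'   \code{axis_y_um}, \code{axis_z_um}, \code{mean_diameter_um},
#'   \code{surface_area_um2}, \code{sphericity},
#'   \code{hemorrhage_volume_um3}, \code{cluster_id},
#'   \code{size_category}, and face-contact flags \code{touch_xlo} ...
#'   \code{touch_zhi} used when merging objects cut by cuboid boundaries.
#' @examples
#' a <- array(0L, c(12, 12, 12)); a[4:8, 4:8, 4:8] <- 1L
#' objectFeatures(LabelVolume(a, 21))[, c("voxel_count", "volume_um3")]
#' @export
objectFeatures <- function(labels, cuboid_id = "cuboid",
                           compute_surface = TRUE) {
  stopifnot(is(labels, "LabelVolume"))
  d <- dim(labels@data)
  vox <- labels@voxelSize
  k <- nLabels(labels)
  empty <- data.frame(islet_id = integer(0), cuboid_id = character(0),
                      cx_um = numeric(0), cy_um = numeric(0),
                      cz_um = numeric(0), gx_um = numeric(0),
                      gy_um = numeric(0), gz_um = numeric(0),
                      voxel_count = integer(0), volume_um3 = numeric(0),
                      axis_x_um = numeric(0), axis_y_um = numeric(0),
                      axis_z_um = numeric(0), mean_diameter_um = numeric(0),
                      surface_area_um2 = numeric(0), sphericity = numeric(0),
                      hemorrhage_volume_um3 = numeric(0),
                      cluster_id = integer(0), size_category = character(0),
                      touch_xlo = logical(0), touch_xhi = logical(0),
                      touch_ylo = logical(0), touch_yhi = logical(0),
                      touch_zlo = logical(0), touch_zhi = logical(0),
                      stringsAsFactors = FALSE)
  if (k == 0L) return(empty)
  idx <- which(labels@data > 0)
  labs <- labels@data[idx]
  sub <- .ind2sub(idx, d)
  coords <- (sub - 0.5) * vox  # cuboid-local voxel centres
  counts <- tabulate(labs, nbins = k)
  sums <- rowsum(coords, labs)
  mu <- sums / counts
  sq <- rowsum(coords^2, labs)
  v <- sq / counts - mu^2  # population variance per axis
  v[v < 0] <- 0
  axis_len <- 2 * sqrt(5 * v)
  touch <- cbind(rowsum((sub[, 1] == 1) + 0, labs) > 0,
                 rowsum((sub[, 1] == d[1]) + 0, labs) > 0,
                 rowsum((sub[, 2] == 1) + 0, labs) > 0,
                 rowsum((sub[, 2] == d[2]) + 0, labs) > 0,
                 rowsum((sub[, 3] == 1) + 0, labs) > 0,
                 rowsum((sub[, 3] == d[3]) + 0, labs) > 0)
  if (compute_surface) {
    areas <- vapply(seq_len(k), function(i) surfaceArea(labels, i),
                    numeric(1))
  } else {
    areas <- rep(NA_real_, k)
  }
  vols <- counts * vox^3
  sph <- if (compute_surface) sphericity(vols, areas) else rep(NA_real_, k)
  has_origin <- any(labels@origin != 0)
  data.frame(islet_id = seq_len(k), cuboid_id = cuboid_id,
             cx_um = mu[, 1], cy_um = mu[, 2], cz_um = mu[, 3],
             gx_um = if (has_origin) mu[, 1] + labels@origin[1] else NA_real_,
             gy_um = if (has_origin) mu[, 2] + labels@origin[2] else NA_real_,
             gz_um = if (has_origin) mu[, 3] + labels@origin[3] else NA_real_,
             voxel_count = counts, volume_um3 = vols,
             axis_x_um = axis_len[, 1], axis_y_um = axis_len[, 2],
             axis_z_um = axis_len[, 3],
             mean_diameter_um = rowMeans(axis_len),
             surface_area_um2 = areas, sphericity = sph,
             hemorrhage_volume_um3 = NA_real_, cluster_id = NA_integer_,
             size_category = NA_character_,
             touch_xlo = touch[, 1], touch_xhi = touch[, 2],
             touch_ylo = touch[, 3], touch_yhi = touch[, 4],
             touch_zlo = touch[, 5], touch_zhi = touch[, 6],
             row.names = NULL, stringsAsFactors = FALSE)
}

# resample a binary voxel field onto the voxel-corner lattice: each corner
# takes the mean of its (up to) 8 incident voxels; zero-padded outside
.corner_field <- function(m) {
  d <- dim(m)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  q <- p[-1, , , drop = FALSE] + p[-(d[1] + 2L), , , drop = FALSE]
  q <- q[, -1, , drop = FALSE] + q[, -(d[2] + 2L), , drop = FALSE]
  q <- q[, , -1, drop = FALSE] + q[, , -(d[3] + 2L), drop = FALSE]
  q / 8
}

#' Isosurface area of one labelled object
#'
#' The object's binary mask (zero-padded bounding box, so objects touching
#' the volume border are closed) is resampled onto the voxel-corner
#' lattice by an 8-voxel box filter, and the 0.5-level isosurface of that
#' field is triangulated by a marching-tetrahedra traversal (six
#' tetrahedra per lattice cell, linear interpolation along edges). The
#' corner resampling keeps flat faces in place while letting the surface
#' cut voxels obliquely, which removes most of the staircase-area bias of
#' meshing the raw binary field; digitized spheres of radius 5/10/20
#' voxels come out within a few percent of the analytic area. Objects too
#' small to reach the 0.5 level on the corner lattice (about two voxels
#' and below) fall back to the raw binary field, whose area is coarse but
#' nonzero.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param islet_id label of the object.
#' @return Surface area in um^2.
#' @export
surfaceArea <- function(labels, islet_id) {
  stopifnot(is(labels, "LabelVolume"))
  idx <- which(labels@data == islet_id)
  if (length(idx) == 0L) stop("no object with label ", islet_id)
  d <- dim(labels@data)
  sub <- .ind2sub(idx, d)
  mn <- apply(sub, 2, min)
  mx <- apply(sub, 2, max)
  # crop with one voxel of zero padding on every side
  dd <- mx - mn + 3L
  field <- array(0, dd)
  field[cbind(sub[, 1] - mn[1] + 2L, sub[, 2] - mn[2] + 2L,
              sub[, 3] - mn[3] + 2L)] <- 1
  corner <- .corner_field(field)
  a <- cpp_isosurface_area(corner, dim(corner), 0.5)
  if (a == 0)  # sub-resolution object: mesh the binary field directly
    a <- cpp_isosurface_area(field, dd, 0.5)
  a * labels@voxelSize^2
}

#' Wadell sphericity
#'
#' \deqn{\Psi = \pi^{1/3} (6V)^{2/3} / A}
#' equal to 1 for a perfect sphere and decreasing with elongation.
#'
#' @param volume_um3 object volume(s), um^3.
#' @param surface_area_um2 object surface area(s), um^2.
#' @return Dimensionless sphericity value(s).
#' @examples
#' sphericity(4 / 3 * pi, 4 * pi)  # unit sphere -> 1
#' @export
sphericity <- function(volume_um3, surface_area_um2) {
  if (any(volume_um3 <= 0) || any(surface_area_um2 <= 0))
    stop("volume and surface area must be positive")
  pi^(1 / 3) * (6 * volume_um3)^(2 / 3) / surface_area_um2
}
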