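#' Specification for a synthetic tissue cuboid phantom
#'
#' Describes one synthetic cuboid: lattice shape, voxel pitch, the islet
#' population (log-normal mean 3D diameters), optional spatial islet
#' clusters, hyper-autofluorescent vessel tubes, hypointense holes (lumens,
#' fat) and intra-islet red-blood-cell blobs. The defaults emulate the
#' imaging conditions of near-infrared projection tomography of cleared
#' pancreas cuboids: 21 um isotropic voxels and a median islet mean 3D
#' diameter of 110 um.
#'
#' Intensities are arbitrary units; the signal channel carries the
#' immunolabel (islets bright over a dim tissue background), the anatomy
#' channel carries tissue autofluorescence (textured tissue, bright vessel
#' walls and red-blood-cell blobs, dark holes). Below-background holes are
#' carved out of both channels.
#'
#' @param shape_voxels integer triple, lattice dimensions (x, y, z).
#' @param voxel_size_um isotropic voxel size, micrometres.
#' @param n_islets number of non-clustered background islets.
#' @param diameter_median_um,diameter_gsd median and geometric standard
#'   deviation of the log-normal mean 3D diameter distribution (um).
#' @param diameter_min_um,diameter_max_um truncation bounds for sampled
#'   diameters; objects below about 3 voxels are unresolvable at the
#'   default pitch, so the lower bound defaults to 3 voxels.
#' @param anisotropy_max maximum ratio between ellipsoid semi-axes (>= 1).
#' @param cluster_spec optional list with \code{n_clusters},
#'   \code{islets_per_cluster}, \code{nn_distance_um} (upper bound on
#'   nearest-neighbour centre spacing inside the cluster) and
#'   \code{peripheral} (place cluster seeds at >= 80\% normalized organ
#'   radius; only meaningful through \code{\link{generateOrgan}}) and
#'   optionally \code{isolation_um} (clearance kept between clustered and
#'   background islets, default 350, so planted clusters stay separate
#'   components at the standard 300 um linkage cutoff).
#' @param vessel_spec optional list with \code{n_tubes}, \code{radius_um},
#'   \code{intensity}.
#' @param hole_spec optional list with \code{n_spherical}, \code{n_tubular},
#'   \code{sphere_diameter_um} (range), \code{tube_radius_um} (range),
#'   \code{tube_length_um} (range).
#' @param hemorrhage_fraction fraction of islets carrying an internal
#'   red-blood-cell blob in the anatomy channel.
#' @param background_level,islet_intensity,tissue_level,hole_level,
#'   outside_level,noise_sd,texture_sd intensity model parameters
#'   (arbitrary units); \code{noise_sd} is additive Gaussian noise clipped
#'   at zero, \code{texture_sd} the amplitude of the smooth tissue texture.
#'   The default islet contrast of about 2 over background is set so that
#'   the quality-1 spot-detection cutoff covers the islet diameter
#'   population: the matched-scale blob response of a solid sphere falls
#'   below half the ideal-blob response outside roughly 65-220 um.
#' @param rbc_intensity anatomy-channel intensity of red-blood-cell blobs.
#' @param margin_voxels tissue-free margin around the tissue block.
#' @param min_gap_voxels minimum surface gap enforced between planted
#'   objects, in voxels.
#' @param seed integer random seed; identical seeds give bit-identical
#'   phantoms.
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(shape_voxels = c(128L, 128L, 128L),
                        voxel_size_um = 21,
                        n_islets = 50L,
                        diameter_median_um = 110,
                        diameter_gsd = 1.35,
                        diameter_min_um = 3 * voxel_size_um,
                        diameter_max_um = 250,
                        anisotropy_max = 1.5,
                        cluster_spec = NULL,
                        vessel_spec = NULL,
                        hole_spec = NULL,
                        hemorrhage_fraction = 0,
                        background_level = 0.1,
                        islet_intensity = 2.0,
                        tissue_level = 0.35,
                        hole_level = 0.02,
                        outside_level = 0.02,
                        rbc_intensity = 1.0,
                        noise_sd = 0.03,
                        texture_sd = 0.05,
                        margin_voxels = 3L,
                        min_gap_voxels = 2,
                        seed = 1L) {
  spec <- list(shape_voxels = as.integer(shape_voxels),
               voxel_size_um = voxel_size_um, n_islets = as.integer(n_islets),
               diameter_median_um = diameter_median_um,
               diameter_gsd = diameter_gsd,
               diameter_min_um = diameter_min_um,
               diameter_max_um = diameter_max_um,
               anisotropy_max = anisotropy_max, cluster_spec = cluster_spec,
               vessel_spec = vessel_spec, hole_spec = hole_spec,
               hemorrhage_fraction = hemorrhage_fraction,
               background_level = background_level,
               islet_intensity = islet_intensity,
               tissue_level = tissue_level, hole_level = hole_level,
               outside_level = outside_level, rbc_intensity = rbc_intensity,
               noise_sd = noise_sd, texture_sd = texture_sd,
               margin_voxels = as.integer(margin_voxels),
               min_gap_voxels = min_gap_voxels, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

#' @rdname phantomSpec
#' @param spec a \code{PhantomSpec}.
#' @export
validatePhantomSpec <- function(spec) {
  stopifnot(length(spec$shape_voxels) == 3L, all(spec$shape_voxels >= 8L),
            spec$voxel_size_um > 0, spec$n_islets >= 0,
            spec$diameter_median_um > 0, spec$diameter_gsd >= 1,
            spec$diameter_min_um > 0,
            spec$diameter_max_um >= spec$diameter_min_um,
            spec$anisotropy_max >= 1,
            spec$hemorrhage_fraction >= 0, spec$hemorrhage_fraction <= 1,
            spec$noise_sd >= 0, spec$margin_voxels >= 0,
            spec$min_gap_voxels >= 0)
  if (!is.null(spec$cluster_spec))
    stopifnot(spec$cluster_spec$n_clusters >= 1,
              spec$cluster_spec$islets_per_cluster >= 1,
              spec$cluster_spec$nn_distance_um > 0)
  invisible(TRUE)
}

## ---- rasterization -----------------------------------------------------

# linear indices of voxels whose centre lies inside the ellipsoid
.ellipsoid_indices <- function(d, voxel_size, origin, center_um, semi_axes_um,
                               orientation = NULL) {
  rmax <- max(semi_axes_um)
  lo <- pmax(1L, ceiling((center_um - rmax - origin) / voxel_size + 0.5))
  hi <- pmin(d, floor((center_um + rmax - origin) / voxel_size + 0.5))
  if (any(lo > hi)) return(integer(0))
  xs <- .axis_centers(d[1], voxel_size, origin[1])[lo[1]:hi[1]] - center_um[1]
  ys <- .axis_centers(d[2], voxel_size, origin[2])[lo[2]:hi[2]] - center_um[2]
  zs <- .axis_centers(d[3], voxel_size, origin[3])[lo[3]:hi[3]] - center_um[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  cx <- rep(xs, times = ny * nz)
  cy <- rep(rep(ys, each = nx), times = nz)
  cz <- rep(zs, each = nx * ny)
  if (!is.null(orientation)) {
    rel <- cbind(cx, cy, cz) %*% orientation  # = t(R) %*% v per row
    cx <- rel[, 1]; cy <- rel[, 2]; cz <- rel[, 3]
  }
  inside <- (cx / semi_axes_um[1])^2 + (cy / semi_axes_um[2])^2 +
    (cz / semi_axes_um[3])^2 <= 1
  if (!any(inside)) return(integer(0))
  ii <- rep(lo[1]:hi[1], times = ny * nz)
  jj <- rep(rep(lo[2]:hi[2], each = nx), times = nz)
  kk <- rep(lo[3]:hi[3], each = nx * ny)
  w <- which(inside)
  (kk[w] - 1L) * (d[1] * d[2]) + (jj[w] - 1L) * d[1] + ii[w]
}

# linear indices of voxels whose centre lies within radius of segment p0-p1
.tube_indices <- function(d, voxel_size, origin, p0, p1, radius_um) {
  lo <- pmax(1L, ceiling((pmin(p0, p1) - radius_um - origin) / voxel_size + 0.5))
  hi <- pmin(d, floor((pmax(p0, p1) + radius_um - origin) / voxel_size + 0.5))
  if (any(lo > hi)) return(integer(0))
  xs <- .axis_centers(d[1], voxel_size, origin[1])[lo[1]:hi[1]]
  ys <- .axis_centers(d[2], voxel_size, origin[2])[lo[2]:hi[2]]
  zs <- .axis_centers(d[3], voxel_size, origin[3])[lo[3]:hi[3]]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  cx <- rep(xs, times = ny * nz)
  cy <- rep(rep(ys, each = nx), times = nz)
  cz <- rep(zs, each = nx * ny)
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- ((cx - p0[1]) * v[1] + (cy - p0[2]) * v[2] + (cz - p0[3]) * v[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- cx - (p0[1] + t * v[1])
  dy <- cy - (p0[2] + t * v[2])
  dz <- cz - (p0[3] + t * v[3])
  inside <- dx * dx + dy * dy + dz * dz <= radius_um^2
  if (!any(inside)) return(integer(0))
  ii <- rep(lo[1]:hi[1], times = ny * nz)
  jj <- rep(rep(lo[2]:hi[2], each = nx), times = nz)
  kk <- rep(lo[3]:hi[3], each = nx * ny)
  w <- which(inside)
  (kk[w] - 1L) * (d[1] * d[2]) + (jj[w] - 1L) * d[1] + ii[w]
}

#' Rasterize an ellipsoid into a VoxelGrid
#'
#' A voxel is set if and only if its centre lies inside the ellipsoid
#' (voxel-centre-in-solid rule); existing values are combined by maximum,
#' so re-rendering the same object is idempotent.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param center_um ellipsoid centre (x, y, z) in micrometres.
#' @param semi_axes_um positive semi-axis lengths (x, y, z) in micrometres.
#' @param orientation optional 3x3 rotation matrix mapping body axes to
#'   world axes; \code{NULL} for axis-aligned.
#' @param intensity finite voxel value for the interior.
#' @return The updated \linkS4class{VoxelGrid}. The number of voxels set is
#'   available as \code{attr(, "voxel_count")}.
#' @examples
#' g <- VoxelGrid(array(0, c(16, 16, 16)), voxelSize = 21)
#' g <- renderEllipsoid(g, center_um = c(168, 168, 168),
#'                      semi_axes_um = c(55, 55, 55), intensity = 1)
#' sum(voxelData(g) > 0)
#' @export
renderEllipsoid <- function(grid, center_um, semi_axes_um, orientation = NULL,
                            intensity = 1) {
  stopifnot(is(grid, "VoxelGrid"), all(semi_axes_um > 0),
            is.finite(intensity))
  idx <- .ellipsoid_indices(dim(grid@data), grid@voxelSize, grid@origin,
                            center_um, semi_axes_um, orientation)
  if (length(idx) == 0L) {
    ext_lo <- grid@origin
    ext_hi <- grid@origin + dim(grid@data) * grid@voxelSize
    if (any(center_um + max(semi_axes_um) < ext_lo) ||
        any(center_um - max(semi_axes_um) > ext_hi))
      warning("ellipsoid lies entirely outside the grid; nothing rendered")
  } else {
    grid@data[idx] <- pmax(grid@data[idx], intensity)
  }
  attr(grid, "voxel_count") <- length(idx)
  grid
}

## ---- object placement --------------------------------------------------

# random rotation matrix (Haar-ish via QR), deterministic under set.seed
.random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# semi-axes for a mean 3D diameter d with anisotropy bound A
.sample_semi_axes <- function(d, A) {
  if (A <= 1) return(rep(d / 2, 3))
  s <- exp(runif(3, -log(A) / 2, log(A) / 2))
  s <- s / mean(s)
  (d / 2) * s
}

.sample_diameters <- function(n, spec) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    d <- rlnorm(n, meanlog = log(spec$diameter_median_um),
                sdlog = log(spec$diameter_gsd))
    d <- d[d >= spec$diameter_min_um & d <= spec$diameter_max_um]
    out <- c(out, d)
  }
  out[seq_len(n)]
}

# preserve the caller's RNG stream around seeded generation
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# place one islet: returns center or NULL after retry cap
.try_place <- function(lo, hi, rb, placed_centers, placed_rb, gap_um,
                       max_retries = 10000L) {
  for (i in seq_len(max_retries)) {
    ctr <- runif(3, lo, hi)
    if (length(placed_rb) == 0L) return(ctr)
    dd <- sqrt(colSums((t(placed_centers) - ctr)^2))
    if (all(dd >= placed_rb + rb + gap_um)) return(ctr)
  }
  NULL
}

.empty_truth <- function() {
  data.frame(id = integer(0), kind = character(0), cx_um = numeric(0),
             cy_um = numeric(0), cz_um = numeric(0), ax_um = numeric(0),
             ay_um = numeric(0), az_um = numeric(0),
             analytic_volume_um3 = numeric(0), voxel_count = integer(0),
             parent_islet = integer(0), cluster_id = integer(0),
             truncated = logical(0), stringsAsFactors = FALSE)
}

# Shared body for cuboid- and organ-level generation. `tissue` is a logical
# array defining the tissue region; placement of object centres is
# restricted by `inside_fn(center, rb)` returning TRUE when an object of
# bounding radius rb fits the tissue.
# Shared body for cuboid- and organ-level generation. `tissue` is a logical
# array defining the tissue region; placement of object centres is
# restricted by `inside_fn(center, rb)` returning TRUE when an object of
# bounding radius rb fits the tissue. All random draws happen in the
# placement phase, so the planted geometry (truth) is identical whether or
# not the channels are rendered.
.generate_volume <- function(spec, d, tissue, inside_fn, sample_center_fn,
                             cluster_seed_fn = sample_center_fn,
                             render = TRUE) {
  vox <- spec$voxel_size_um
  gap <- spec$min_gap_voxels * vox
  n <- prod(d)

  placed_centers <- matrix(numeric(0), 0, 3)
  placed_rb <- numeric(0)
  islet_geo <- list()   # per islet: center, semi, rot, cluster
  next_islet <- 0L

  add_islet <- function(ctr, dmean, cluster_id) {
    semi <- .sample_semi_axes(dmean, spec$anisotropy_max)
    rot <- .random_rotation()
    next_islet <<- next_islet + 1L
    islet_geo[[next_islet]] <<- list(center = ctr, semi = semi, rot = rot,
                                     cluster = cluster_id)
    placed_centers <<- rbind(placed_centers, ctr)
    placed_rb <<- c(placed_rb, max(semi))
  }

  ## ---- placement phase (all RNG) --------------------------------------

  # background islets
  diams <- .sample_diameters(spec$n_islets, spec)
  for (i in seq_len(spec$n_islets)) {
    rb <- diams[i] / 2 * sqrt(spec$anisotropy_max)
    ctr <- NULL
    for (r in seq_len(10000L)) {
      cand <- sample_center_fn(rb)
      if (is.null(cand)) next
      if (!inside_fn(cand, rb)) next
      if (nrow(placed_centers) > 0L) {
        dd <- sqrt(colSums((t(placed_centers) - cand)^2))
        if (!all(dd >= placed_rb + rb + gap)) next
      }
      ctr <- cand
      break
    }
    if (is.null(ctr))
      stop("unable to place islet without overlap after bounded retries")
    add_islet(ctr, diams[i], NA_integer_)
  }
  n_background <- next_islet

  # clustered islets: sequential attachment keeps nearest-neighbour
  # spacing <= nn_distance_um, so the planted cluster is single-linkage
  # connected at that cutoff; members additionally keep isolation_um
  # clearance from the background islets so the planted cluster structure
  # is exactly recoverable from the truth centres
  if (!is.null(spec$cluster_spec)) {
    cs <- spec$cluster_spec
    isolation <- if (is.null(cs$isolation_um)) 350 else cs$isolation_um
    for (cl in seq_len(cs$n_clusters)) {
      cdiams <- .sample_diameters(cs$islets_per_cluster, spec)
      members <- integer(0)
      for (m in seq_len(cs$islets_per_cluster)) {
        rb <- cdiams[m] / 2 * sqrt(spec$anisotropy_max)
        ctr <- NULL
        for (r in seq_len(10000L)) {
          if (m == 1L) {
            cand <- cluster_seed_fn(rb)
          } else {
            pick <- if (length(members) == 1L) members else
              sample(members, 1L)
            anchor <- placed_centers[pick, ]
            anchor_rb <- placed_rb[pick]
            dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
            dmin <- min(anchor_rb + rb + gap, cs$nn_distance_um)
            dist_ <- runif(1, dmin, cs$nn_distance_um)
            cand <- anchor + dir * dist_
          }
          if (is.null(cand)) next
          if (!inside_fn(cand, rb)) next
          if (nrow(placed_centers) > 0L) {
            dd <- sqrt(colSums((t(placed_centers) - cand)^2))
            req <- placed_rb + rb + gap
            if (n_background > 0L)
              req[seq_len(n_background)] <-
                pmax(req[seq_len(n_background)], isolation)
            if (!all(dd >= req)) next
          }
          ctr <- cand
          break
        }
        if (is.null(ctr))
          stop("unable to place clustered islet after bounded retries")
        add_islet(ctr, cdiams[m], cl)
        members <- c(members, next_islet)
      }
    }
  }
  n_islets_total <- next_islet

  # vessel tubes, kept clear of islets
  vessels <- list()
  if (!is.null(spec$vessel_spec)) {
    vs <- spec$vessel_spec
    ext <- d * vox
    for (v in seq_len(vs$n_tubes)) {
      ok <- FALSE
      for (r in seq_len(10000L)) {
        p0 <- runif(3, 0.1 * ext, 0.9 * ext)
        p1 <- runif(3, 0.1 * ext, 0.9 * ext)
        if (sqrt(sum((p1 - p0)^2)) < 5 * vs$radius_um) next
        if (n_islets_total > 0L &&
            any(.point_segment_dist(placed_centers[seq_len(n_islets_total), ,
                                                   drop = FALSE], p0, p1) <
                placed_rb[seq_len(n_islets_total)] + vs$radius_um + gap))
          next
        ok <- TRUE
        break
      }
      if (!ok) stop("unable to place vessel tube after bounded retries")
      vessels[[length(vessels) + 1L]] <-
        list(p0 = p0, p1 = p1, radius = vs$radius_um,
             intensity = vs$intensity)
    }
  }

  # red-blood-cell blobs inside a random subset of islets
  rbc <- integer(0)
  if (spec$hemorrhage_fraction > 0 && n_islets_total > 0L)
    rbc <- which(runif(n_islets_total) < spec$hemorrhage_fraction)

  # hypointense holes
  holes <- list()
  if (!is.null(spec$hole_spec)) {
    hs <- spec$hole_spec
    ns <- if (is.null(hs$n_spherical)) 0L else hs$n_spherical
    nt <- if (is.null(hs$n_tubular)) 0L else hs$n_tubular
    for (h in seq_len(ns)) {
      dia <- runif(1, hs$sphere_diameter_um[1], hs$sphere_diameter_um[2])
      rb <- dia / 2
      ctr <- NULL
      for (r in seq_len(10000L)) {
        cand <- sample_center_fn(rb)
        if (is.null(cand) || !inside_fn(cand, rb)) next
        if (nrow(placed_centers) > 0L) {
          dd <- sqrt(colSums((t(placed_centers) - cand)^2))
          if (!all(dd >= placed_rb + rb + gap)) next
        }
        ctr <- cand
        break
      }
      if (is.null(ctr))
        stop("unable to place spherical hole after bounded retries")
      placed_centers <- rbind(placed_centers, ctr)
      placed_rb <- c(placed_rb, rb)
      holes[[length(holes) + 1L]] <- list(kind = "hole_sphere", center = ctr,
                                          radius = rb)
    }
    for (h in seq_len(nt)) {
      rad <- runif(1, hs$tube_radius_um[1], hs$tube_radius_um[2])
      tl <- if (is.null(hs$tube_length_um)) c(10, 30) * vox else
        hs$tube_length_um
      len <- runif(1, tl[1], tl[2])
      ok <- FALSE
      for (r in seq_len(10000L)) {
        mid <- sample_center_fn(len / 2)
        if (is.null(mid)) next
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        p0 <- mid - dir * len / 2
        p1 <- mid + dir * len / 2
        if (!inside_fn(p0, rad) || !inside_fn(p1, rad)) next
        if (nrow(placed_centers) > 0L &&
            any(.point_segment_dist(placed_centers, p0, p1) <
                placed_rb + rad + gap)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("unable to place tubular hole after bounded retries")
      holes[[length(holes) + 1L]] <- list(kind = "hole_tube", p0 = p0,
                                          p1 = p1, radius = rad, length = len)
    }
  }

  ## ---- rendering phase -------------------------------------------------

  truth <- .empty_truth()
  next_id <- 0L
  add_truth <- function(kind, ctr, semi, vol, count, parent = NA_integer_,
                        cluster = NA_integer_) {
    next_id <<- next_id + 1L
    truth <<- rbind(truth, data.frame(
      id = next_id, kind = kind, cx_um = ctr[1], cy_um = ctr[2],
      cz_um = ctr[3], ax_um = semi[1], ay_um = semi[2], az_um = semi[3],
      analytic_volume_um3 = vol, voxel_count = count, parent_islet = parent,
      cluster_id = cluster, truncated = FALSE, stringsAsFactors = FALSE))
    next_id
  }

  signal <- anatomy <- NULL
  islet_indices <- vector("list", n_islets_total)
  if (render) {
    signal <- array(spec$outside_level, d)
    signal[tissue] <- spec$background_level
    anatomy <- array(spec$outside_level, d)
    tex <- array(rnorm(n), d)
    tex <- array(cpp_gaussian3d(tex, d, 2, 2, 2), d)
    tex <- tex / max(sd(tex), 1e-12) * spec$texture_sd
    anatomy[tissue] <- spec$tissue_level + tex[tissue]
  }

  for (i in seq_len(n_islets_total)) {
    g <- islet_geo[[i]]
    count <- NA_integer_
    if (render) {
      idx <- .ellipsoid_indices(d, vox, c(0, 0, 0), g$center, g$semi, g$rot)
      islet_indices[[i]] <- idx
      signal[idx] <- pmax(signal[idx], spec$islet_intensity)
      count <- length(idx)
    }
    add_truth("islet", g$center, g$semi, 4 / 3 * pi * prod(g$semi), count,
              cluster = g$cluster)
  }

  for (v in vessels) {
    count <- NA_integer_
    if (render) {
      idx <- .tube_indices(d, vox, c(0, 0, 0), v$p0, v$p1, v$radius)
      anatomy[idx] <- pmax(anatomy[idx], v$intensity)
      count <- length(idx)
    }
    len <- sqrt(sum((v$p1 - v$p0)^2))
    add_truth("vessel", (v$p0 + v$p1) / 2, c(v$radius, v$radius, len / 2),
              pi * v$radius^2 * len, count)
  }

  for (i in rbc) {
    g <- islet_geo[[i]]
    semi <- 0.35 * g$semi
    count <- NA_integer_
    if (render) {
      idx <- .ellipsoid_indices(d, vox, c(0, 0, 0), g$center, semi, g$rot)
      anatomy[idx] <- pmax(anatomy[idx], spec$rbc_intensity)
      count <- length(idx)
    }
    add_truth("rbc_blob", g$center, semi, 4 / 3 * pi * prod(semi), count,
              parent = i)
  }

  for (h in holes) {
    count <- NA_integer_
    if (h$kind == "hole_sphere") {
      if (render) {
        idx <- .ellipsoid_indices(d, vox, c(0, 0, 0), h$center, rep(h$radius, 3))
        signal[idx] <- spec$hole_level
        anatomy[idx] <- spec$hole_level
        count <- length(idx)
      }
      add_truth("hole_sphere", h$center, rep(h$radius, 3),
                4 / 3 * pi * h$radius^3, count)
    } else {
      if (render) {
        idx <- .tube_indices(d, vox, c(0, 0, 0), h$p0, h$p1, h$radius)
        signal[idx] <- spec$hole_level
        anatomy[idx] <- spec$hole_level
        count <- length(idx)
      }
      add_truth("hole_tube", (h$p0 + h$p1) / 2,
                c(h$radius, h$radius, h$length / 2),
                pi * h$radius^2 * h$length, count)
    }
  }

  if (render && spec$noise_sd > 0) {
    signal <- pmax(signal + array(rnorm(n, 0, spec$noise_sd), d), 0)
    anatomy <- pmax(anatomy + array(rnorm(n, 0, spec$noise_sd), d), 0)
  }

  list(signal = signal, anatomy = anatomy, truth = truth,
       islet_indices = islet_indices, tissue = tissue)
}

# distance from each row of pts to segment p0-p1
.point_segment_dist <- function(pts, p0, p1) {
  v <- p1 - p0
  len2 <- sum(v^2)
  rel <- sweep(pts, 2, p0)
  t <- pmin(pmax(as.vector(rel %*% v) / len2, 0), 1)
  proj <- outer(t, v)
  sqrt(rowSums((rel - proj)^2))
}

#' Generate one synthetic cuboid with exact ground truth
#'
#' Renders the two imaging channels of one tissue cuboid from a
#' \code{\link{phantomSpec}}: an immunolabel ("signal") channel with bright
#' ellipsoidal islets over a dim background, and an autofluorescence
#' ("anatomy") channel with textured tissue, bright vessel tubes,
#' red-blood-cell blobs inside islets and dark holes. The tissue occupies
#' the cuboid minus a margin. Every planted object is listed in the ground
#' truth with analytic and rasterized volumes.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param render rasterize the two channels; with \code{render = FALSE}
#'   only the ground-truth geometry is generated (identical to the
#'   rendered one for the same seed; rasterized voxel counts are NA),
#'   which is cheap and sufficient for point-pattern analyses.
#' @return A list with elements \code{signal} and \code{anatomy}
#'   (\linkS4class{VoxelGrid}s, NULL when \code{render = FALSE}),
#'   \code{truth} (data frame of planted objects), and \code{tissue}
#'   (logical array, the planted tissue region).
#' @examples
#' ph <- generateCuboid(phantomSpec(shape_voxels = c(48, 48, 48),
#'                                  n_islets = 5, seed = 7))
#' nrow(ph$truth)
#' @export
generateCuboid <- function(spec, render = TRUE) {
  validatePhantomSpec(spec)
  d <- spec$shape_voxels
  vox <- spec$voxel_size_um
  m <- spec$margin_voxels
  .with_seed(spec$seed, {
    tissue <- array(FALSE, d)
    tissue[(m + 1):(d[1] - m), (m + 1):(d[2] - m), (m + 1):(d[3] - m)] <- TRUE
    lo <- (m + 1) * vox
    hi <- (d - m - 1) * vox
    inside_fn <- function(ctr, rb)
      all(ctr - rb >= m * vox) && all(ctr + rb <= (d - m) * vox)
    sample_center_fn <- function(rb) {
      l <- m * vox + rb
      h <- (d - m) * vox - rb
      if (any(l >= h)) return(NULL)
      runif(3, l, h)
    }
    res <- .generate_volume(spec, d, tissue, inside_fn, sample_center_fn,
                            render = render)
    list(signal = if (render) VoxelGrid(res$signal, vox) else NULL,
         anatomy = if (render) VoxelGrid(res$anatomy, vox) else NULL,
         truth = res$truth, tissue = res$tissue)
  })
}

#' Specification for a multi-cuboid synthetic organ
#'
#' An organ phantom is an ellipsoidal tissue body inscribed in a block of
#' abutting cuboids cut on a regular slicing grid, mirroring how a fixed
#' organ is partitioned on a printed slicing matrix.
#'
#' @param grid_dim integer triple: number of cuboids along x, y, z.
#' @param cuboid_shape_voxels integer triple: voxels per cuboid.
#' @param pitch_um grid pitch; must be a positive multiple of the voxel
#'   size so cuboid offsets stay voxel-aligned. Defaults to the cuboid
#'   extent so cuboids abut exactly.
#' @param organ_axis_fraction semi-axes of the organ ellipsoid as a
#'   fraction of the half-extents of the assembled block.
#' @param ... further arguments passed to \code{\link{phantomSpec}} (islet
#'   population, clusters, intensities, seed, ...).
#' @return A list of class \code{"OrganSpec"}.
#' @export
organSpec <- function(grid_dim = c(2L, 2L, 2L),
                      cuboid_shape_voxels = c(64L, 64L, 64L),
                      pitch_um = NULL, organ_axis_fraction = 0.92, ...) {
  base <- phantomSpec(shape_voxels = as.integer(grid_dim) *
                        as.integer(cuboid_shape_voxels), ...)
  if (is.null(pitch_um))
    pitch_um <- as.integer(cuboid_shape_voxels) * base$voxel_size_um
  ratio <- pitch_um / base$voxel_size_um
  if (any(pitch_um <= 0) || any(abs(ratio - round(ratio)) > 1e-9))
    stop("grid pitch must be a positive multiple of the voxel size")
  spec <- c(base, list(grid_dim = as.integer(grid_dim),
                       cuboid_shape_voxels = as.integer(cuboid_shape_voxels),
                       pitch_um = pitch_um,
                       organ_axis_fraction = organ_axis_fraction))
  class(spec) <- c("OrganSpec", "PhantomSpec")
  spec
}

#' Generate a multi-cuboid organ phantom
#'
#' Renders one organ-level phantom (ellipsoidal tissue body, islets,
#' optional peripheral clusters, vessels, holes) on the full lattice, then
#' partitions it into non-overlapping cuboids on the slicing grid. Objects
#' spanning a cut plane appear in every cuboid they intersect, flagged
#' \code{truncated}, with per-part voxel counts; the per-part counts of a
#' truncated object sum exactly to its organ-level count.
#'
#' @param ospec an \code{\link{organSpec}}.
#' @return A list with \code{cuboids} (list of per-cuboid lists with
#'   \code{signal}, \code{anatomy}, \code{meta} (\linkS4class{CuboidMeta})
#'   and \code{truth} with cuboid-local centres), \code{truth} (organ-level
#'   ground truth with global centres), \code{signal}/\code{anatomy}
#'   (organ-level \linkS4class{VoxelGrid}s, for round-trip checks), and
#'   \code{tissue}.
#' @export
generateOrgan <- function(ospec) {
  stopifnot(inherits(ospec, "OrganSpec"))
  d <- ospec$shape_voxels
  vox <- ospec$voxel_size_um
  ext <- d * vox
  ctr0 <- ext / 2
  semi_organ <- ospec$organ_axis_fraction * ext / 2

  .with_seed(ospec$seed, {
    # organ ellipsoid tissue mask
    idx <- .ellipsoid_indices(d, vox, c(0, 0, 0), ctr0, semi_organ)
    tissue <- array(FALSE, d)
    tissue[idx] <- TRUE

    norm_radius <- function(p) sqrt(sum(((p - ctr0) / semi_organ)^2))
    inside_fn <- function(ctr, rb)
      norm_radius(ctr) <= 1 - rb / min(semi_organ)
    sample_center_fn <- function(rb) {
      p <- runif(3, ctr0 - semi_organ, ctr0 + semi_organ)
      if (inside_fn(p, rb)) p else NULL
    }
    peripheral <- !is.null(ospec$cluster_spec) &&
      isTRUE(ospec$cluster_spec$peripheral)
    cluster_seed_fn <- if (peripheral) {
      function(rb) {
        # cluster seeds near the organ surface, emulating peripherally
        # enriched islet clusters
        p <- sample_center_fn(rb)
        if (!is.null(p) && norm_radius(p) >= 0.8) p else NULL
      }
    } else sample_center_fn

    res <- .generate_volume(ospec, d, tissue, inside_fn, sample_center_fn,
                            cluster_seed_fn)

    # ---- partition into cuboids ---------------------------------------
    gd <- ospec$grid_dim
    cs <- ospec$cuboid_shape_voxels
    pitch_vox <- as.integer(round(ospec$pitch_um / vox))
    # per-object cuboid membership from rasterized voxels
    obj_idx <- res$islet_indices
    all_truth <- res$truth
    # recover voxel indices of non-islet objects cheaply: only islets need
    # exact per-part counts for conservation tests; other kinds use their
    # bounding extent for membership
    cuboids <- vector("list", prod(gd))
    ci <- 0L
    for (k in seq_len(gd[3])) for (j in seq_len(gd[2])) for (i in seq_len(gd[1])) {
      ci <- ci + 1L
      ijk <- c(i, j, k) - 1L
      off_vox <- ijk * pitch_vox
      xr <- (off_vox[1] + 1):(off_vox[1] + cs[1])
      yr <- (off_vox[2] + 1):(off_vox[2] + cs[2])
      zr <- (off_vox[3] + 1):(off_vox[3] + cs[3])
      meta <- CuboidMeta(cuboidId = sprintf("c_%d_%d_%d", ijk[1], ijk[2],
                                            ijk[3]),
                         gridIJK = ijk, shapeVoxels = cs, voxelSizeUm = vox,
                         gridPitchUm = ospec$pitch_um)
      origin <- meta@originUm
      # islet membership by rasterized voxels
      loc_truth <- .empty_truth()
      loc_truth$part_voxel_count <- integer(0)
      for (o in seq_len(nrow(all_truth))) {
        row <- all_truth[o, ]
        if (row$kind == "islet") {
          sub <- .ind2sub(obj_idx[[row$id]], d)
          inside <- sub[, 1] >= xr[1] & sub[, 1] <= xr[cs[1]] &
            sub[, 2] >= yr[1] & sub[, 2] <= yr[cs[2]] &
            sub[, 3] >= zr[1] & sub[, 3] <= zr[cs[3]]
          npart <- sum(inside)
          if (npart == 0L) next
          row$truncated <- npart < row$voxel_count
          row$part_voxel_count <- npart
        } else {
          # bounding-extent membership for vessels/holes/blobs
          rb <- max(row$ax_um, row$ay_um, row$az_um)
          cmin <- c(row$cx_um, row$cy_um, row$cz_um) - rb
          cmax <- c(row$cx_um, row$cy_um, row$cz_um) + rb
          lo <- origin
          hi <- origin + cs * vox
          if (any(cmax < lo) || any(cmin > hi)) next
          row$truncated <- any(cmin < lo) || any(cmax > hi)
          row$part_voxel_count <- NA_integer_
        }
        row$cx_um <- row$cx_um - origin[1]
        row$cy_um <- row$cy_um - origin[2]
        row$cz_um <- row$cz_um - origin[3]
        loc_truth <- rbind(loc_truth, row)
      }
      cuboids[[ci]] <- list(
        signal = VoxelGrid(res$signal[xr, yr, zr, drop = FALSE], vox,
                           origin = origin),
        anatomy = VoxelGrid(res$anatomy[xr, yr, zr, drop = FALSE], vox,
                            origin = origin),
        meta = meta, truth = loc_truth)
    }
    list(cuboids = cuboids, truth = all_truth,
         signal = VoxelGrid(res$signal, vox),
         anatomy = VoxelGrid(res$anatomy, vox), tissue = res$tissue)
  })
}
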