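#' Segmentation configuration
#'
#' Parameters for islet iso-surfacing with seeded splitting of touching
#' islets, spot detection, tissue/outline masking and shape
#' classification. The defaults correspond to the standard analysis of
#' 21 um near-infrared tomography volumes of insulin-labelled pancreas:
#' a region-growing seed diameter equal to the average human islet mean
#' 3D diameter (110 um), removal of objects under 5 voxels, a spot
#' "quality" cutoff of 1 and a 15 um smoothing grain for the anatomy
#' surface.
#'
#' @param seed_diameter_um minimum separation between watershed seeds;
#'   the expected object diameter.
#' @param min_voxels objects (and hypointense regions) smaller than this
#'   voxel count are removed; objects are kept iff count >= min_voxels.
#' @param threshold_mode \code{"auto"} (Otsu over nonzero voxels) or
#'   \code{"manual"} (uses \code{threshold_value}).
#' @param threshold_value manual threshold (required when
#'   \code{threshold_mode = "manual"}).
#' @param spot_quality_min spots with normalized Laplacian-of-Gaussian
#'   quality below this are discarded.
#' @param tissue_smooth_um Gaussian smoothing sigma for the anatomy
#'   channel before tissue thresholding, micrometres.
#' @param connectivity voxel connectivity for object labelling: 6, 18 or
#'   26.
#' @param sphericity_spherical_min,sphericity_tubular_max Wadell
#'   sphericity cutoffs classifying hypointense regions as spherical
#'   (fat deposits) or tubular (vessel/duct lumens). A long thin lumen is
#'   less extreme than intuition suggests on the Wadell scale (a 40:1
#'   cylinder scores about 0.47), hence the tubular cutoff of 0.5.
#' @param outline_closing_voxels ball radius (voxels) of the
#'   morphological closing that automates the specimen outline.
#' @return A list of class \code{"SegmentConfig"}.
#' @export
segmentConfig <- function(seed_diameter_um = 110, min_voxels = 5L,
                          threshold_mode = c("auto", "manual"),
                          threshold_value = NULL, spot_quality_min = 1.0,
                          tissue_smooth_um = 15, connectivity = 26L,
                          sphericity_spherical_min = 0.7,
                          sphericity_tubular_max = 0.5,
                          outline_closing_voxels = 10L) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(seed_diameter_um > 0, min_voxels >= 1L,
            connectivity %in% c(6L, 18L, 26L),
            sphericity_tubular_max <= sphericity_spherical_min)
  if (threshold_mode == "manual" && is.null(threshold_value))
    stop("threshold_value required for manual thresholding")
  structure(list(seed_diameter_um = seed_diameter_um,
                 min_voxels = as.integer(min_voxels),
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 spot_quality_min = spot_quality_min,
                 tissue_smooth_um = tissue_smooth_um,
                 connectivity = as.integer(connectivity),
                 sphericity_spherical_min = sphericity_spherical_min,
                 sphericity_tubular_max = sphericity_tubular_max,
                 outline_closing_voxels = as.integer(outline_closing_voxels)),
            class = "SegmentConfig")
}

# Otsu threshold over the nonzero voxels of a numeric vector/array
.autoThreshold <- function(values) {
  v <- as.numeric(values[values > 0])
  if (length(v) == 0L) return(Inf)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  EBImage::otsu(matrix(v, ncol = 1L), range = r)
}

.pick_threshold <- function(values, cfg) {
  if (cfg$threshold_mode == "manual") cfg$threshold_value
  else .autoThreshold(values)
}

#' Percentile baseline subtraction
#'
#' Subtracts the given percentile of the voxel values and clips at zero:
#' \code{max(v - P_percentile, 0)}.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param percentile percentile in [0, 100).
#' @return A \linkS4class{VoxelGrid}.
#' @export
baselineSubtract <- function(grid, percentile = 50) {
  stopifnot(is(grid, "VoxelGrid"), percentile >= 0, percentile < 100)
  base <- quantile(grid@data, percentile / 100, names = FALSE)
  grid@data <- pmax(grid@data - base, 0)
  grid
}

#' Euclidean distance transform
#'
#' Distance (micrometres) from every foreground voxel to the nearest
#' background voxel.
#'
#' @param mask logical 3D array.
#' @param voxel_size_um isotropic voxel size.
#' @return Numeric 3D array of distances in micrometres (0 on background).
#' @export
distanceTransform <- function(mask, voxel_size_um = 21) {
  d <- dim(mask)
  dt <- sqrt(cpp_edt_sq(!mask, d)) * voxel_size_um
  array(dt, d)
}

#' Label connected components of a binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array of component labels (0 = background) with the
#'   component count in \code{attr(, "n_labels")}.
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), d, as.integer(connectivity))
  out <- array(lab, d)
  attr(out, "n_labels") <- attr(lab, "n_labels")
  out
}

# relabel a label array contiguously 1..K, ordered by minimum linear index
.relabel_contiguous <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0L) return(lab)
  labs <- lab[idx]
  first <- tapply(idx, labs, min)
  old <- as.integer(names(first))
  ord <- order(first)
  map <- integer(max(old))
  map[old[ord]] <- seq_along(old)
  lab[idx] <- map[labs]
  lab
}

# drop labels below min voxel count, then relabel contiguously
.filter_small <- function(lab, min_voxels) {
  k <- max(lab)
  if (k == 0L) return(lab)
  counts <- tabulate(lab[lab > 0], nbins = k)
  drop <- which(counts < min_voxels)
  if (length(drop) > 0L) lab[lab %in% drop] <- 0L
  .relabel_contiguous(lab)
}

#' Segment islets with watershed splitting of touching objects
#'
#' Foreground is obtained by thresholding (Otsu over nonzero voxels unless
#' a manual threshold is configured). Touching objects are split by a
#' seeded watershed on the Euclidean distance transform: seeds are
#' distance-transform maxima, greedily suppressed (highest first, ties by
#' lexicographic voxel index) so that accepted seeds of the same connected
#' component are at least the seed diameter apart (minus half a voxel of
#' lattice-quantization slack); every component keeps at least one seed.
#' Components below \code{min_voxels} voxels are removed and the surviving
#' labels are renumbered contiguously.
#'
#' @param signal a \linkS4class{VoxelGrid}; typically enhanced and
#'   baseline-subtracted immunolabel signal.
#' @param cfg a \code{\link{segmentConfig}}.
#' @return A \linkS4class{LabelVolume}.
#' @export
segmentIslets <- function(signal, cfg = segmentConfig()) {
  stopifnot(is(signal, "VoxelGrid"))
  d <- dim(signal@data)
  vox <- signal@voxelSize
  th <- .pick_threshold(signal@data, cfg)
  fg <- signal@data > th
  if (!any(fg)) {
    warning("empty foreground: no voxels above threshold")
    return(LabelVolume(array(0L, d), vox, signal@origin))
  }
  comp <- cpp_label_components(fg, d, cfg$connectivity)
  edt <- sqrt(cpp_edt_sq(!fg, d))  # voxel units
  cand <- cpp_local_maxima(edt, fg, d, cfg$connectivity)
  sub <- .ind2sub(cand, d)
  sep_vox <- cfg$seed_diameter_um / vox - 0.5
  keep <- cpp_min_separation_filter(sub - 0.5, edt[cand], comp[cand],
                                    sep_vox)
  seed_idx <- cand[keep]
  seeds <- integer(length(fg))
  ord <- order(seed_idx)
  seeds[seed_idx[ord]] <- seq_along(seed_idx)
  lab <- cpp_watershed_seeded(edt, seeds, fg, d, cfg$connectivity)
  lab <- array(lab, d)
  lab <- .filter_small(lab, cfg$min_voxels)
  LabelVolume(lab, vox, signal@origin)
}

# 6-neighbour discrete Laplacian with reflective boundary (voxel units)
.laplacian3d <- function(a) {
  d <- dim(a)
  lap <- -6 * a
  lap <- lap + a[c(1, seq_len(d[1] - 1)), , , drop = FALSE] +
    a[c(seq_len(d[1])[-1], d[1]), , , drop = FALSE] +
    a[, c(1, seq_len(d[2] - 1)), , drop = FALSE] +
    a[, c(seq_len(d[2])[-1], d[2]), , drop = FALSE] +
    a[, , c(1, seq_len(d[3] - 1)), drop = FALSE] +
    a[, , c(seq_len(d[3])[-1], d[3]), drop = FALSE]
  lap
}

# scale-normalized LoG response of an ideal Gaussian blob of matched size
# and unit contrast, used to normalize spot quality:
# with sigma_filter = sigma_blob, response = 3/2 * (1/2)^(3/2)
.LOG_BLOB_NORM <- 1.5 * 0.5^1.5

#' Detect islet spots by scale-matched Laplacian of Gaussian
#'
#' Blob detection at the scale of the expected islet diameter d:
#' the volume is smoothed with a Gaussian of sigma = d / (2 sqrt(3)), the
#' scale-normalized negative Laplacian is taken as the blob response, and
#' local maxima are reported as spots. The "quality" of a spot is the
#' response normalized so that an ideal isolated Gaussian blob of the
#' expected diameter and unit contrast scores 1; spots below
#' \code{spot_quality_min} are discarded. Two pruning steps keep one spot
#' per blob: maxima closer than 1.3 expected diameters are merged
#' (highest kept), which covers the antipodal ring-maxima spacing that a
#' blob of up to about 1.8 times the expected diameter produces at the
#' matched scale; and of two maxima with no intervening response valley
#' (response along the joining segment never below 70% of the lower
#' maximum) only the higher survives.
#'
#' @param signal a \linkS4class{VoxelGrid}.
#' @param cfg a \code{\link{segmentConfig}}; \code{seed_diameter_um} sets
#'   the expected diameter.
#' @return A data frame with columns \code{x_um}, \code{y_um}, \code{z_um}
#'   (spot centres, cuboid-local micrometres) and \code{quality}.
#' @export
detectSpots <- function(signal, cfg = segmentConfig()) {
  stopifnot(is(signal, "VoxelGrid"))
  d <- dim(signal@data)
  vox <- signal@voxelSize
  sigma_vox <- cfg$seed_diameter_um / (2 * sqrt(3)) / vox
  sm <- array(cpp_gaussian3d(signal@data, d, sigma_vox, sigma_vox, sigma_vox),
              d)
  resp <- -sigma_vox^2 * .laplacian3d(sm) / .LOG_BLOB_NORM
  cand <- cpp_local_maxima(resp, resp > 0, d, 26L)
  if (length(cand) == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), quality = numeric(0)))
  sub <- .ind2sub(cand, d)
  keep <- cpp_min_separation_filter((sub - 0.5) * vox, resp[cand],
                                    rep(1L, length(cand)),
                                    1.3 * cfg$seed_diameter_um)
  sel <- cand[keep]
  q <- resp[sel]
  ok <- q >= cfg$spot_quality_min
  sel <- sel[ok]
  q <- q[ok]
  sub <- .ind2sub(sel, d)
  pts <- (sub - 0.5) * vox
  # ridge merge: an oversized blob produces a ring of maxima at the
  # matched scale; two maxima with no intervening response valley belong
  # to one blob, so the lower one is dropped. Genuinely separate blobs
  # keep a deeper valley between them.
  n <- length(sel)
  if (n > 1L) {
    drop <- rep(FALSE, n)
    ord <- order(-q, sel)
    dmat <- as.matrix(dist(pts))
    for (ai in seq_len(n - 1L)) for (bi in seq((ai + 1L), n)) {
      a <- ord[ai]; b <- ord[bi]
      if (drop[a] || drop[b]) next
      if (dmat[a, b] >= 2 * cfg$seed_diameter_um) next
      ts <- seq(0, 1, length.out = 21)
      ij <- t(vapply(ts, function(t)
        pmin(pmax(round((pts[a, ] * (1 - t) + pts[b, ] * t) / vox + 0.5),
                  1), d), numeric(3)))
      valley <- min(resp[cbind(ij[, 1], ij[, 2], ij[, 3])])
      if (valley > 0.7 * q[b]) drop[b] <- TRUE
    }
    sel <- sel[!drop]
    q <- q[!drop]
    sub <- sub[!drop, , drop = FALSE]
  }
  data.frame(x_um = (sub[, 1] - 0.5) * vox, y_um = (sub[, 2] - 0.5) * vox,
             z_um = (sub[, 3] - 0.5) * vox, quality = q)
}

#' Tissue mask from the autofluorescence anatomy channel
#'
#' Gaussian smoothing (sigma = \code{tissue_smooth_um}) followed by
#' thresholding (Otsu over nonzero voxels unless manual). The largest
#' connected component is kept, together with any other component of at
#' least \code{min_voxels} voxels.
#'
#' @param anatomy a \linkS4class{VoxelGrid}.
#' @param cfg a \code{\link{segmentConfig}}.
#' @return Logical 3D array.
#' @export
tissueMask <- function(anatomy, cfg = segmentConfig()) {
  stopifnot(is(anatomy, "VoxelGrid"))
  d <- dim(anatomy@data)
  s <- cfg$tissue_smooth_um / anatomy@voxelSize
  sm <- array(cpp_gaussian3d(anatomy@data, d, s, s, s), d)
  th <- .pick_threshold(sm, cfg)
  mask <- sm > th
  if (!any(mask)) return(mask)
  lab <- labelComponents(mask, cfg$connectivity)
  counts <- tabulate(lab[lab > 0])
  keep <- unique(c(which.max(counts), which(counts >= cfg$min_voxels)))
  array(lab %in% keep, d)
}

#' Specimen outline by automated closure
#'
#' Automates the specimen outline that is traditionally traced manually:
#' morphological closing with a Euclidean ball (radius
#' \code{closing_voxels}) followed by per-slice hole filling. The result
#' always contains the tissue mask.
#'
#' @param tissue logical 3D array (from \code{\link{tissueMask}}).
#' @param closing_voxels ball radius in voxels.
#' @return Logical 3D array, a superset of \code{tissue}.
#' @export
outlineMask <- function(tissue, closing_voxels = 10L) {
  d <- dim(tissue)
  if (!any(tissue)) return(tissue)
  if (closing_voxels > 0) {
    # pad so the dilation can expand past the volume border and the
    # erosion can retract it again
    p <- as.integer(closing_voxels + 1L)
    dp <- d + 2L * p
    padded <- array(FALSE, dp)
    padded[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])] <-
      tissue
    r2 <- closing_voxels^2
    dil <- array(cpp_edt_sq(padded, dp) <= r2, dp)
    closed_p <- array(cpp_edt_sq(!dil, dp) > r2, dp)
    closed <- closed_p[(p + 1):(p + d[1]), (p + 1):(p + d[2]),
                       (p + 1):(p + d[3])]
  } else {
    closed <- tissue
  }
  filled <- EBImage::fillHull(EBImage::Image(closed * 1))
  array(EBImage::imageData(filled) > 0.5, d)
}

#' Hypointense regions inside the specimen outline
#'
#' Regions of absent or very low autofluorescence (vessel and duct lumens,
#' fat deposits) are the set difference of outline and tissue. Connected
#' components with at least \code{min_voxels} voxels are labelled and
#' classified by Wadell sphericity: spherical (fat-like) when sphericity
#' >= \code{sphericity_spherical_min}, tubular (lumen-like) when <=
#' \code{sphericity_tubular_max}, otherwise unclassified.
#'
#' @param outline,tissue logical 3D arrays with \code{outline} containing
#'   \code{tissue}.
#' @param cfg a \code{\link{segmentConfig}}.
#' @param voxel_size_um isotropic voxel size.
#' @return A list with \code{mask} (logical array, the exact complement
#'   \code{outline & !tissue}), \code{labels}
#'   (\linkS4class{LabelVolume} of regions >= \code{min_voxels}) and
#'   \code{regions} (data frame: region, voxel_count, volume_um3,
#'   surface_area_um2, sphericity, class).
#' @export
hypointenseRegions <- function(outline, tissue, cfg = segmentConfig(),
                               voxel_size_um = 21) {
  if (any(tissue & !outline))
    stop("tissue mask is not contained in the outline mask")
  d <- dim(outline)
  mask <- outline & !tissue
  lab <- labelComponents(mask, cfg$connectivity)
  lab <- .filter_small(lab, cfg$min_voxels)
  lv <- LabelVolume(lab, voxel_size_um)
  k <- max(lab)
  if (k == 0L) {
    regions <- data.frame(region = integer(0), voxel_count = integer(0),
                          volume_um3 = numeric(0),
                          surface_area_um2 = numeric(0),
                          sphericity = numeric(0), class = character(0),
                          stringsAsFactors = FALSE)
  } else {
    counts <- tabulate(lab[lab > 0], nbins = k)
    vols <- counts * voxel_size_um^3
    areas <- vapply(seq_len(k), function(i) surfaceArea(lv, i), numeric(1))
    sph <- sphericity(vols, areas)
    cls <- ifelse(sph >= cfg$sphericity_spherical_min, "spherical",
                  ifelse(sph <= cfg$sphericity_tubular_max, "tubular",
                         "unclassified"))
    regions <- data.frame(region = seq_len(k), voxel_count = counts,
                          volume_um3 = vols, surface_area_um2 = areas,
                          sphericity = sph, class = cls,
                          stringsAsFactors = FALSE)
  }
  list(mask = mask, labels = lv, regions = regions)
}

#' Intra-islet hemorrhage volumes from the anatomy channel
#'
#' The autofluorescence channel is masked onto the segmented islets and
#' thresholded; bright in-islet autofluorescence (red blood cells) is
#' summed per islet as hemorrhage volume. Voxels outside islets are never
#' counted.
#'
#' @param anatomy a \linkS4class{VoxelGrid}.
#' @param islets a \linkS4class{LabelVolume} from the same cuboid.
#' @param threshold manual intensity threshold; \code{NULL} for Otsu over
#'   the in-islet values.
#' @return Numeric vector of hemorrhage volumes (um^3), one per islet
#'   label.
#' @export
hemorrhageSegment <- function(anatomy, islets, threshold = NULL) {
  stopifnot(is(anatomy, "VoxelGrid"), is(islets, "LabelVolume"))
  .check_same_lattice(anatomy, islets)
  k <- nLabels(islets)
  if (k == 0L) return(numeric(0))
  idx <- which(islets@data > 0)
  vals <- anatomy@data[idx]
  th <- if (is.null(threshold)) .autoThreshold(vals) else threshold
  hot <- vals > th
  out <- numeric(k)
  if (any(hot)) {
    tab <- tabulate(islets@data[idx][hot], nbins = k)
    out <- tab * anatomy@voxelSize^3
  }
  out
}
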