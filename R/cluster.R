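#' Spatial clustering configuration
#'
#' Settings for single-linkage clustering of islet centroids and for
#' HIDR/LIDR (high/low islet density region) classification and ROI-based
#' density comparison. Defaults follow the standard analysis: clusters
#' join islets within 300 um of a nearest neighbour, a HIDR is a cluster
#' of strictly more than 100 islets, and ROIs are cubes of 48 voxels
#' (about 1 mm at 21 um/voxel).
#'
#' @param linkage_cutoff_um centre-to-centre linkage distance.
#' @param hidr_min_count strict threshold: HIDR iff count > this value.
#' @param roi_edge_voxels ROI cube edge in voxels.
#' @param n_random_rois number of random ROIs for the background estimate.
#' @param rng_seed seed for random ROI placement.
#' @return A list of class \code{"ClusterConfig"}.
#' @export
clusterConfig <- function(linkage_cutoff_um = 300, hidr_min_count = 100L,
                          roi_edge_voxels = 48L, n_random_rois = 10L,
                          rng_seed = 1L) {
  stopifnot(linkage_cutoff_um > 0, roi_edge_voxels >= 1L,
            n_random_rois >= 1L)
  structure(list(linkage_cutoff_um = linkage_cutoff_um,
                 hidr_min_count = as.integer(hidr_min_count),
                 roi_edge_voxels = as.integer(roi_edge_voxels),
                 n_random_rois = as.integer(n_random_rois),
                 rng_seed = as.integer(rng_seed)), class = "ClusterConfig")
}

#' Single-linkage spatial clusters at a distance cutoff
#'
#' Cluster labels are the connected components of the graph that joins
#' every pair of centroids at Euclidean distance <= cutoff (equivalently,
#' a single-linkage dendrogram cut at the cutoff). Labels are
#' deterministic: clusters are numbered by their minimum member index.
#'
#' @param centroids_um numeric matrix (n x 3) of centre coordinates in
#'   micrometres.
#' @param cutoff_um linkage distance in micrometres.
#' @return Integer vector of cluster labels (length n).
#' @examples
#' pts <- cbind(c(0, 100, 900), c(0, 0, 0), c(0, 0, 0))
#' singleLinkageClusters(pts, 300)
#' @export
singleLinkageClusters <- function(centroids_um, cutoff_um = 300) {
  centroids_um <- as.matrix(centroids_um)
  n <- nrow(centroids_um)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  stopifnot(ncol(centroids_um) == 3L, all(is.finite(centroids_um)),
            cutoff_um > 0)
  adj <- as.matrix(dist(centroids_um)) <= cutoff_um
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # renumber by minimum member index
  first <- tapply(seq_len(n), comp, min)
  map <- integer(length(first))
  map[order(first)] <- seq_along(first)
  as.integer(map[comp])
}

#' Classify clusters as high or low islet density regions
#'
#' A cluster with strictly more than \code{hidr_min_count} members is a
#' HIDR; all others (including singletons) are LIDR.
#'
#' @param cluster_labels integer labels from
#'   \code{\link{singleLinkageClusters}}.
#' @param centroids_um the clustered centroid matrix (n x 3).
#' @param cfg a \code{\link{clusterConfig}}.
#' @return Data frame with one row per cluster: \code{cluster_id},
#'   \code{count}, \code{class} ("HIDR"/"LIDR"), centroid and bounding
#'   box columns.
#' @export
classifyClusters <- function(cluster_labels, centroids_um,
                             cfg = clusterConfig()) {
  centroids_um <- as.matrix(centroids_um)
  if (length(cluster_labels) == 0L)
    return(data.frame(cluster_id = integer(0), count = integer(0),
                      class = character(0), cx_um = numeric(0),
                      cy_um = numeric(0), cz_um = numeric(0),
                      xmin_um = numeric(0), xmax_um = numeric(0),
                      ymin_um = numeric(0), ymax_um = numeric(0),
                      zmin_um = numeric(0), zmax_um = numeric(0),
                      stringsAsFactors = FALSE))
  ids <- sort(unique(cluster_labels))
  counts <- as.integer(table(factor(cluster_labels, levels = ids)))
  mu <- rowsum(centroids_um, cluster_labels) / counts
  mins <- do.call(rbind, lapply(ids, function(i)
    apply(centroids_um[cluster_labels == i, , drop = FALSE], 2, min)))
  maxs <- do.call(rbind, lapply(ids, function(i)
    apply(centroids_um[cluster_labels == i, , drop = FALSE], 2, max)))
  data.frame(cluster_id = ids, count = counts,
             class = ifelse(counts > cfg$hidr_min_count, "HIDR", "LIDR"),
             cx_um = mu[, 1], cy_um = mu[, 2], cz_um = mu[, 3],
             xmin_um = mins[, 1], xmax_um = maxs[, 1],
             ymin_um = mins[, 2], ymax_um = maxs[, 2],
             zmin_um = mins[, 3], zmax_um = maxs[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Place HIDR-centred and random ROIs
#'
#' Cubic ROIs of \code{roi_edge_voxels} voxels are centred on every HIDR
#' centroid, plus \code{n_random_rois} ROIs placed uniformly at random
#' (seeded) with the full cube inside the cuboid bounds.
#'
#' @param cluster_records output of \code{\link{classifyClusters}}.
#' @param bounds_um numeric length-3: cuboid extent (x, y, z) in
#'   micrometres.
#' @param voxel_size_um isotropic voxel size.
#' @param cfg a \code{\link{clusterConfig}}.
#' @return Data frame of ROI centres with columns \code{cx_um},
#'   \code{cy_um}, \code{cz_um}, \code{edge_um}, \code{kind}
#'   ("hidr"/"random").
#' @export
placeRois <- function(cluster_records, bounds_um, voxel_size_um = 21,
                      cfg = clusterConfig()) {
  edge <- cfg$roi_edge_voxels * voxel_size_um
  hidr <- cluster_records[cluster_records$class == "HIDR", , drop = FALSE]
  rois <- data.frame(cx_um = hidr$cx_um, cy_um = hidr$cy_um,
                     cz_um = hidr$cz_um, edge_um = edge,
                     kind = rep("hidr", nrow(hidr)),
                     stringsAsFactors = FALSE)
  rnd <- .with_seed(cfg$rng_seed, {
    t(vapply(seq_len(cfg$n_random_rois), function(i)
      runif(3, edge / 2, bounds_um - edge / 2), numeric(3)))
  })
  rbind(rois, data.frame(cx_um = rnd[, 1], cy_um = rnd[, 2],
                         cz_um = rnd[, 3], edge_um = edge,
                         kind = "random", stringsAsFactors = FALSE))
}

#' Quantify islet density inside ROIs
#'
#' An islet belongs to an ROI when its centroid lies inside the cube.
#' Densities are totals divided by the ROI volume; ROIs extending beyond
#' the cuboid bounds are clipped with a warning and their volume adjusted.
#'
#' @param records islet catalog with local centroids (\code{cx_um},
#'   \code{cy_um}, \code{cz_um}) and \code{volume_um3}.
#' @param rois data frame from \code{\link{placeRois}} (columns
#'   \code{cx_um}, \code{cy_um}, \code{cz_um}, \code{edge_um}, and
#'   optionally \code{kind}).
#' @param bounds_um optional cuboid extent for clipping.
#' @return The \code{rois} data frame with added columns \code{count},
#'   \code{islet_volume_um3}, \code{roi_volume_mm3},
#'   \code{count_per_mm3}, \code{volume_density}.
#' @export
roiQuantify <- function(records, rois, bounds_um = NULL) {
  n <- nrow(rois)
  count <- integer(n)
  volsum <- numeric(n)
  roivol <- numeric(n)
  for (i in seq_len(n)) {
    half <- rois$edge_um[i] / 2
    lo <- c(rois$cx_um[i], rois$cy_um[i], rois$cz_um[i]) - half
    hi <- lo + rois$edge_um[i]
    if (!is.null(bounds_um)) {
      clo <- pmax(lo, 0)
      chi <- pmin(hi, bounds_um)
      if (any(clo > lo) || any(chi < hi)) {
        warning("ROI ", i, " extends beyond the cuboid; clipped")
        lo <- clo
        hi <- chi
      }
    }
    inside <- records$cx_um > lo[1] & records$cx_um <= hi[1] &
      records$cy_um > lo[2] & records$cy_um <= hi[2] &
      records$cz_um > lo[3] & records$cz_um <= hi[3]
    count[i] <- sum(inside)
    volsum[i] <- sum(records$volume_um3[inside])
    roivol[i] <- prod(pmax(hi - lo, 0)) / 1e9
  }
  rois$count <- count
  rois$islet_volume_um3 <- volsum
  rois$roi_volume_mm3 <- roivol
  rois$count_per_mm3 <- count / roivol
  rois$volume_density <- volsum / (roivol * 1e9)
  rois
}

#' Fraction of the total islet count contributed by HIDRs
#'
#' @param cluster_labels labels from \code{\link{singleLinkageClusters}}.
#' @param cfg a \code{\link{clusterConfig}}.
#' @return Fraction in [0, 1]; \code{NA} when there are no islets.
#' @examples
#' hidrFraction(rep(1L, 200))  # one 200-islet cluster -> 1
#' @export
hidrFraction <- function(cluster_labels, cfg = clusterConfig()) {
  n <- length(cluster_labels)
  if (n == 0L) return(NA_real_)
  counts <- table(cluster_labels)
  sum(counts[counts > cfg$hidr_min_count]) / n
}
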