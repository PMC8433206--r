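#' Map cuboid-local centroids into the organ frame
#'
#' Adds the cuboid's physical origin to the local centroids; exactly
#' invertible.
#'
#' @param records islet catalog for one cuboid (local centroids
#'   \code{cx_um}, \code{cy_um}, \code{cz_um}).
#' @param meta the matching \linkS4class{CuboidMeta}.
#' @return The catalog with \code{gx_um}, \code{gy_um}, \code{gz_um}
#'   filled in.
#' @export
toGlobal <- function(records, meta) {
  stopifnot(is(meta, "CuboidMeta"))
  if (nrow(records) > 0 && !all(records$cuboid_id == meta@cuboidId))
    stop("records do not belong to cuboid '", meta@cuboidId, "'")
  records$gx_um <- records$cx_um + meta@originUm[1]
  records$gy_um <- records$cy_um + meta@originUm[2]
  records$gz_um <- records$cz_um + meta@originUm[3]
  records
}

# pairs of cuboids sharing a face: returns list of (i, j, axis) with j on
# the high side of i along axis
.adjacent_pairs <- function(metas) {
  out <- list()
  n <- length(metas)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    oi <- metas[[i]]@originUm
    oj <- metas[[j]]@originUm
    exti <- metas[[i]]@shapeVoxels * metas[[i]]@voxelSizeUm
    vox <- metas[[i]]@voxelSizeUm
    for (a in 1:3) {
      other <- setdiff(1:3, a)
      if (abs(oi[a] + exti[a] - oj[a]) <= vox &&
          all(abs(oi[other] - oj[other]) < exti[other]))
        out[[length(out) + 1L]] <- c(i, j, a)
    }
  }
  out
}

#' Merge per-cuboid catalogs into one organ catalog
#'
#' Concatenates the per-cuboid catalogs (mapped to global coordinates)
#' with globally unique islet ids. With \code{merge_boundary = TRUE},
#' objects in face-adjacent cuboids that both touch the shared face and
#' whose centroids are laterally within \code{lateral_tol_um} are treated
#' as parts of one object cut by the slicing plane: their volumes are
#' summed, centroids combined volume-weighted and axis lengths recombined
#' by the parallel-axis rule (surface area and sphericity of merged
#' objects are not recombined and become NA). Default off: the standard
#' analysis catalogs boundary objects separately.
#'
#' @param catalogs list of per-cuboid catalog data frames.
#' @param metas list of matching \linkS4class{CuboidMeta} objects.
#' @param merge_boundary merge objects cut by a shared face.
#' @param lateral_tol_um lateral centroid tolerance for boundary merging.
#' @return One organ-level catalog with global centroids and a
#'   \code{organ_islet_id} column.
#' @export
mergeCatalogs <- function(catalogs, metas, merge_boundary = FALSE,
                          lateral_tol_um = 55) {
  ids <- vapply(metas, cuboidId, character(1))
  if (anyDuplicated(ids)) stop("duplicate cuboid id: ",
                               ids[duplicated(ids)][1])
  vox <- vapply(metas, function(m) m@voxelSizeUm, numeric(1))
  if (length(unique(vox)) != 1L)
    stop("cuboids have inconsistent voxel sizes")
  glob <- mapply(toGlobal, catalogs, metas, SIMPLIFY = FALSE)
  cat_all <- do.call(rbind, glob)
  if (is.null(cat_all) || nrow(cat_all) == 0L) {
    cat_all <- if (is.null(cat_all)) data.frame() else cat_all
    cat_all$organ_islet_id <- integer(0)
    return(cat_all)
  }
  cat_all$organ_islet_id <- seq_len(nrow(cat_all))
  rownames(cat_all) <- NULL
  if (!merge_boundary) return(cat_all)

  # union-find over records
  parent <- seq_len(nrow(cat_all))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[min(ra, rb)] <<- parent[max(ra, rb)] <<-
        min(ra, rb)
  }
  cub_of <- match(cat_all$cuboid_id, ids)
  touch_hi <- as.matrix(cat_all[, c("touch_xhi", "touch_yhi", "touch_zhi")])
  touch_lo <- as.matrix(cat_all[, c("touch_xlo", "touch_ylo", "touch_zlo")])
  gpos <- as.matrix(cat_all[, c("gx_um", "gy_um", "gz_um")])
  for (pr in .adjacent_pairs(metas)) {
    i <- pr[1]; j <- pr[2]; a <- pr[3]
    lower <- which(cub_of == i & touch_hi[, a])
    upper <- which(cub_of == j & touch_lo[, a])
    other <- setdiff(1:3, a)
    for (u in lower) for (v in upper) {
      if (all(abs(gpos[u, other] - gpos[v, other]) <= lateral_tol_um))
        union_(u, v)
    }
  }
  roots <- vapply(seq_len(nrow(cat_all)), find, integer(1))
  groups <- split(seq_len(nrow(cat_all)), roots)
  merged <- lapply(groups, function(g) {
    if (length(g) == 1L) return(cat_all[g, , drop = FALSE])
    part <- cat_all[g, , drop = FALSE]
    w <- part$volume_um3 / sum(part$volume_um3)
    out <- part[1, , drop = FALSE]
    out$voxel_count <- sum(part$voxel_count)
    out$volume_um3 <- sum(part$volume_um3)
    for (ax in c("x", "y", "z")) {
      mu_col <- paste0("g", ax, "_um")
      len_col <- paste0("axis_", ax, "_um")
      mu <- sum(w * part[[mu_col]])
      v <- sum(w * ((part[[len_col]] / 2)^2 / 5 + (part[[mu_col]] - mu)^2))
      out[[mu_col]] <- mu
      out[[len_col]] <- 2 * sqrt(5 * v)
    }
    out$cx_um <- out$cy_um <- out$cz_um <- NA_real_
    out$mean_diameter_um <- mean(c(out$axis_x_um, out$axis_y_um,
                                   out$axis_z_um))
    out$surface_area_um2 <- NA_real_
    out$sphericity <- NA_real_
    if (!all(is.na(part$hemorrhage_volume_um3)))
      out$hemorrhage_volume_um3 <- sum(part$hemorrhage_volume_um3,
                                       na.rm = TRUE)
    out$cuboid_id <- paste(unique(part$cuboid_id), collapse = "+")
    out
  })
  out <- do.call(rbind, merged)
  out$organ_islet_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assemble per-cuboid volumes into one organ volume
#'
#' Pastes each cuboid at its voxel-aligned offset; unfilled space is 0.
#' Overlapping placements are an error (cuboids are non-overlapping by
#' construction of the slicing grid).
#'
#' @param grids list of \linkS4class{VoxelGrid}s.
#' @param metas list of matching \linkS4class{CuboidMeta} objects.
#' @return One organ-level \linkS4class{VoxelGrid}.
#' @export
assembleVolume <- function(grids, metas) {
  stopifnot(length(grids) == length(metas), length(grids) > 0)
  vox <- metas[[1]]@voxelSizeUm
  offs <- lapply(metas, function(m) {
    o <- m@originUm / vox
    if (any(abs(o - round(o)) > 1e-6))
      stop("cuboid '", m@cuboidId, "' placement is not voxel-aligned")
    as.integer(round(o))
  })
  shapes <- lapply(metas, function(m) m@shapeVoxels)
  n <- length(grids)
  for (i in seq_len(n)) {
    if (!identical(dim(grids[[i]]@data), as.integer(shapes[[i]])))
      stop("volume of cuboid '", metas[[i]]@cuboidId,
           "' does not match its metadata shape")
    for (j in seq_len(n)) {
      if (j <= i) next
      lo_i <- offs[[i]]; hi_i <- offs[[i]] + shapes[[i]]
      lo_j <- offs[[j]]; hi_j <- offs[[j]] + shapes[[j]]
      if (all(lo_i < hi_j) && all(lo_j < hi_i))
        stop("cuboids '", metas[[i]]@cuboidId, "' and '",
             metas[[j]]@cuboidId, "' overlap")
    }
  }
  dd <- Reduce(pmax, mapply(function(o, s) o + s, offs, shapes,
                            SIMPLIFY = FALSE))
  organ <- array(0, dd)
  for (i in seq_len(n)) {
    o <- offs[[i]]; s <- shapes[[i]]
    organ[(o[1] + 1):(o[1] + s[1]), (o[2] + 1):(o[2] + s[2]),
          (o[3] + 1):(o[3] + s[3])] <- grids[[i]]@data
  }
  VoxelGrid(organ, vox)
}
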