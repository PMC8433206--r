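# Brute-force single-linkage oracle: all pairwise distances + union-find.
# Clusters numbered by first occurrence (= minimum member index).
uf_single_linkage <- function(pts, cutoff) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  dmat <- as.matrix(dist(pts))
  hits <- which(dmat <= cutoff & upper.tri(dmat), arr.ind = TRUE)
  for (e in seq_len(nrow(hits))) {
    ri <- find(hits[e, 1])
    rj <- find(hits[e, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# digitized ball of radius r voxels as a LabelVolume (single object)
digit_ball <- function(r, voxel_size = 1) {
  d <- 2L * ceiling(r) + 7L
  xs <- seq_len(d) - (d + 1) / 2
  m <- outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= r^2
  LabelVolume(array(as.integer(m), rep(d, 3)), voxel_size)
}

# axis-aligned digitized ellipsoid (semi-axes in voxels) as a LabelVolume
digit_ellipsoid <- function(a, b, c, voxel_size = 1) {
  d <- 2L * ceiling(c(a, b, c)) + 7L
  xs <- seq_len(d[1]) - (d[1] + 1) / 2
  ys <- seq_len(d[2]) - (d[2] + 1) / 2
  zs <- seq_len(d[3]) - (d[3] + 1) / 2
  m <- array(FALSE, d)
  for (k in seq_len(d[3]))
    m[, , k] <- outer((xs / a)^2, (ys / b)^2, "+") + (zs[k] / c)^2 <= 1
  LabelVolume(array(as.integer(m), d), voxel_size)
}

# analytic surface area of an axis-aligned prolate spheroid (a > b = c)
prolate_area <- function(a, c) {
  e <- sqrt(1 - (c / a)^2)
  2 * pi * c^2 * (1 + (a / (c * e)) * asin(e))
}

# brute-force enumeration of voxel centres inside a sphere: the
# rasterization oracle
count_sphere_voxels <- function(center_um, radius_um, dim, voxel_size) {
  xs <- (seq_len(dim[1]) - 0.5) * voxel_size
  ys <- (seq_len(dim[2]) - 0.5) * voxel_size
  zs <- (seq_len(dim[3]) - 0.5) * voxel_size
  n <- 0L
  for (k in seq_along(zs)) {
    dz2 <- (zs[k] - center_um[3])^2
    n <- n + sum(outer((xs - center_um[1])^2, (ys - center_um[2])^2, "+") +
                   dz2 <= radius_um^2)
  }
  n
}

# match each truth row to the nearest catalog row by centroid
match_truth <- function(feat, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    which.min((feat$cx_um - truth$cx_um[i])^2 +
                (feat$cy_um - truth$cy_um[i])^2 +
                (feat$cz_um - truth$cz_um[i])^2), integer(1))
}
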