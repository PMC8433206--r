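test_that("ellipsoid rasterization follows the voxel-centre-in-solid rule", {
  d <- c(16L, 16L, 16L)
  g <- VoxelGrid(array(0, d), voxelSize = 21)
  g <- renderEllipsoid(g, center_um = c(168, 168, 168),
                       semi_axes_um = c(55, 55, 55), intensity = 1)
  # oracle: brute-force enumeration of voxel centres inside the sphere
  n_oracle <- count_sphere_voxels(c(168, 168, 168), 55, d, 21)
  expect_identical(sum(voxelData(g) > 0), n_oracle)
  expect_identical(attr(g, "voxel_count"), n_oracle)
  # max-combine idempotence
  g2 <- renderEllipsoid(g, c(168, 168, 168), c(55, 55, 55), intensity = 1)
  expect_identical(voxelData(g2), voxelData(g))
  # sub-voxel ellipsoid centred between voxel centres sets nothing
  g3 <- VoxelGrid(array(0, d), voxelSize = 21)
  g3 <- renderEllipsoid(g3, c(168, 168, 168), rep(8, 3), intensity = 1)
  expect_identical(sum(voxelData(g3)), 0)
  # entirely outside -> warning, no-op
  g4 <- VoxelGrid(array(0, d), voxelSize = 21)
  expect_warning(g4 <- renderEllipsoid(g4, c(1e5, 1e5, 1e5), rep(55, 3),
                                       intensity = 1), "outside")
  expect_identical(sum(voxelData(g4)), 0)
})

test_that("rasterized volumes of large planted objects track the analytic
           volume within the 15% discretization bound", {
  ph <- generateCuboid(phantomSpec(shape_voxels = c(96, 96, 96),
                                   n_islets = 25, seed = 2))
  isl <- ph$truth[ph$truth$kind == "islet" & ph$truth$voxel_count >= 100, ]
  expect_gt(nrow(isl), 5)
  ratio <- isl$voxel_count * 21^3 / isl$analytic_volume_um3
  expect_true(all(abs(ratio - 1) <= 0.15))
})

test_that("cuboid generation is deterministic and honours its spec", {
  spec <- phantomSpec(shape_voxels = c(48, 48, 48), n_islets = 4, seed = 7,
                      hemorrhage_fraction = 1)
  a <- generateCuboid(spec)
  b <- generateCuboid(spec)
  expect_identical(voxelData(a$signal), voxelData(b$signal))
  expect_identical(voxelData(a$anatomy), voxelData(b$anatomy))
  expect_identical(a$truth, b$truth)
  # truth-only mode reproduces the same geometry
  c <- generateCuboid(spec, render = FALSE)
  expect_null(c$signal)
  expect_equal(c$truth[, c("cx_um", "cy_um", "cz_um", "ax_um", "ay_um",
                           "az_um")],
               a$truth[, c("cx_um", "cy_um", "cz_um", "ax_um", "ay_um",
                           "az_um")])
  # empty spec: background + noise only
  e <- generateCuboid(phantomSpec(shape_voxels = c(24, 24, 24),
                                  n_islets = 0, seed = 1))
  expect_identical(nrow(e$truth), 0L)
  expect_lt(max(voxelData(e$signal)),
            0.1 + 6 * 0.03)  # background plus a few noise sd
})

test_that("planted clusters are single-linkage connected at the cutoff and
           isolated from the background", {
  spec <- phantomSpec(shape_voxels = c(192, 192, 192), n_islets = 30,
                      cluster_spec = list(n_clusters = 1,
                                          islets_per_cluster = 120,
                                          nn_distance_um = 250), seed = 4)
  ph <- generateCuboid(spec, render = FALSE)
  isl <- ph$truth[ph$truth$kind == "islet", ]
  members <- isl[!is.na(isl$cluster_id), ]
  expect_identical(nrow(members), 120L)
  pts <- as.matrix(members[, c("cx_um", "cy_um", "cz_um")])
  # brute-force: one component at 300 um linkage
  expect_identical(max(uf_single_linkage(pts, 300)), 1L)
  # every member has a neighbour within the attachment distance
  dmat <- as.matrix(dist(pts))
  diag(dmat) <- Inf
  expect_lte(max(apply(dmat, 1, min)), 250)
  # background islets stay clear of the cluster
  bg <- as.matrix(isl[is.na(isl$cluster_id), c("cx_um", "cy_um", "cz_um")])
  cross <- sqrt(outer(rowSums(pts^2), rep(1, nrow(bg))) -
                  2 * pts %*% t(bg) +
                  outer(rep(1, nrow(pts)), rowSums(bg^2)))
  expect_gt(min(cross), 300)
})

test_that("impossible packing requests fail loudly instead of overlapping", {
  spec <- phantomSpec(shape_voxels = c(24, 24, 24), n_islets = 400, seed = 1)
  expect_error(generateCuboid(spec, render = FALSE), "unable to place")
})

test_that("organ generation partitions objects exactly across cuboids", {
  os <- organSpec(grid_dim = c(2L, 2L, 2L),
                  cuboid_shape_voxels = c(48L, 48L, 48L), n_islets = 25,
                  seed = 5)
  org <- generateOrgan(os)
  expect_length(org$cuboids, 8L)
  # offsets are exact multiples of the grid pitch
  for (cb in org$cuboids) {
    m <- cb$meta
    expect_equal(cuboidOrigin(m), m@gridIJK * m@gridPitchUm)
  }
  loc <- do.call(rbind, lapply(org$cuboids, function(cb) cb$truth))
  isl <- loc[loc$kind == "islet", ]
  glob <- org$truth[org$truth$kind == "islet", ]
  # every object appears in >= 1 cuboid; truncated parts appear in >= 2
  expect_setequal(unique(isl$id), glob$id)
  parts <- table(isl$id)
  expect_true(all(parts[as.character(isl$id[isl$truncated])] >= 2))
  # conservation: per-part voxel counts sum exactly to the organ count
  agg <- tapply(isl$part_voxel_count, isl$id, sum)
  expect_equal(as.numeric(agg[as.character(glob$id)]),
               as.numeric(glob$voxel_count))
  # non-truncated objects appear in exactly one cuboid
  expect_true(all(parts[as.character(setdiff(glob$id,
                                             isl$id[isl$truncated]))] == 1))
  # pitch must stay voxel-aligned
  expect_error(organSpec(grid_dim = c(2L, 1L, 1L),
                         cuboid_shape_voxels = c(16L, 16L, 16L),
                         pitch_um = c(100, 336, 336)),
               "multiple of the voxel size")
})
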