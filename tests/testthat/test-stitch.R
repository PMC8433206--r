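test_that("global mapping adds the cuboid origin and round-trips exactly", {
  meta <- CuboidMeta("c1", c(1L, 0L, 2L), c(10L, 10L, 10L), 21)
  rec <- data.frame(cuboid_id = "c1", cx_um = c(10.5, 100.2),
                    cy_um = c(3, 4), cz_um = c(7, 8))
  g <- toGlobal(rec, meta)
  expect_equal(g$gx_um, rec$cx_um + 210)
  expect_equal(g$gz_um, rec$cz_um + 420)
  # origin zero: identity
  m0 <- CuboidMeta("c1", c(0L, 0L, 0L), c(10L, 10L, 10L), 21)
  expect_equal(toGlobal(rec, m0)$gx_um, rec$cx_um)
  # round trip recovers local coordinates
  expect_equal(g$gx_um - cuboidOrigin(meta)[1], rec$cx_um)
  expect_error(toGlobal(data.frame(cuboid_id = "other", cx_um = 1,
                                   cy_um = 1, cz_um = 1), meta),
               "do not belong")
})

test_that("volume assembly pastes cuboids exactly and rejects overlap", {
  set.seed(3)
  a <- VoxelGrid(array(runif(4^3), c(4, 4, 4)), 21)
  m1 <- CuboidMeta("a", c(0L, 0L, 0L), c(4L, 4L, 4L), 21)
  # single cuboid at the origin: identical volume
  expect_identical(voxelData(assembleVolume(list(a), list(m1))),
                   voxelData(a))
  b <- VoxelGrid(array(runif(4^3), c(4, 4, 4)), 21)
  m2 <- CuboidMeta("b", c(1L, 0L, 0L), c(4L, 4L, 4L), 21)
  organ <- assembleVolume(list(a, b), list(m1, m2))
  expect_identical(dim(organ), c(8L, 4L, 4L))
  expect_identical(organ@data[1:4, , ], a@data)
  expect_identical(organ@data[5:8, , ], b@data)
  # overlapping metas -> error naming the cuboids
  m2bad <- CuboidMeta("b", c(0L, 0L, 0L), c(4L, 4L, 4L), 21)
  expect_error(assembleVolume(list(a, b), list(m1, m2bad)), "overlap")
  expect_error(mergeCatalogs(list(data.frame(), data.frame()),
                             list(m1, m1)), "duplicate")
})

test_that("a phantom organ reassembles bit-identically and catalogs stitch
           to ground truth", {
  os <- organSpec(grid_dim = c(2L, 2L, 2L),
                  cuboid_shape_voxels = c(64L, 64L, 64L), n_islets = 40,
                  seed = 5)
  org <- generateOrgan(os)
  metas <- lapply(org$cuboids, `[[`, "meta")
  re <- assembleVolume(lapply(org$cuboids, `[[`, "signal"), metas)
  expect_identical(voxelData(re), voxelData(org$signal))

  cats <- lapply(org$cuboids, function(cb) {
    lab <- segmentIslets(cb$signal, segmentConfig())
    lab@origin <- cuboidOrigin(cb$meta)
    objectFeatures(lab, cuboid_id = cuboidId(cb$meta),
                   compute_surface = FALSE)
  })
  glob <- org$truth[org$truth$kind == "islet", ]
  loc <- do.call(rbind, lapply(org$cuboids, function(cb) cb$truth))
  truncated_ids <- unique(loc$id[loc$kind == "islet" & loc$truncated])

  # merge off: one record per part; conservation of total volume up to
  # truncated slivers below the 5-voxel filter
  organ_cat <- mergeCatalogs(cats, metas, merge_boundary = FALSE)
  kept_parts <- loc[loc$kind == "islet" & loc$part_voxel_count >= 5, ]
  expect_identical(sum(organ_cat$voxel_count),
                   as.integer(sum(kept_parts$part_voxel_count)))
  # merge on: exactly one record per planted islet, volumes within 10%
  merged <- mergeCatalogs(cats, metas, merge_boundary = TRUE)
  expect_identical(nrow(merged), nrow(glob))
  mm <- vapply(seq_len(nrow(glob)), function(i)
    which.min((merged$gx_um - glob$cx_um[i])^2 +
                (merged$gy_um - glob$cy_um[i])^2 +
                (merged$gz_um - glob$cz_um[i])^2), integer(1))
  expect_true(all(abs(merged$voxel_count[mm] - glob$voxel_count) /
                    glob$voxel_count <= 0.1))
  # bisected objects specifically: merged volume near the intact solid
  expect_gt(length(truncated_ids), 0)
  tr <- glob[glob$id %in% truncated_ids, ]
  mt <- mm[match(tr$id, glob$id)]
  expect_true(all(abs(merged$voxel_count[mt] - tr$voxel_count) /
                    tr$voxel_count <= 0.1))
  # non-truncated global centroids within one voxel of ground truth
  nt <- glob[!glob$id %in% truncated_ids, ]
  errs <- vapply(seq_len(nrow(nt)), function(i) {
    min(sqrt((organ_cat$gx_um - nt$cx_um[i])^2 +
               (organ_cat$gy_um - nt$cy_um[i])^2 +
               (organ_cat$gz_um - nt$cz_um[i])^2))
  }, numeric(1))
  expect_lt(max(errs), 21)
})

test_that("cluster labels commute with stitching for clusters inside one
           cuboid", {
  set.seed(23)
  # two point groups well inside two abutting cuboids
  g1 <- matrix(runif(30 * 3, 200, 800), ncol = 3)
  g2 <- matrix(runif(30 * 3, 200, 800), ncol = 3)
  m1 <- CuboidMeta("a", c(0L, 0L, 0L), c(48L, 48L, 48L), 21)
  m2 <- CuboidMeta("b", c(1L, 0L, 0L), c(48L, 48L, 48L), 21)
  r1 <- data.frame(cuboid_id = "a", cx_um = g1[, 1], cy_um = g1[, 2],
                   cz_um = g1[, 3])
  r2 <- data.frame(cuboid_id = "b", cx_um = g2[, 1], cy_um = g2[, 2],
                   cz_um = g2[, 3])
  allg <- rbind(toGlobal(r1, m1), toGlobal(r2, m2))
  labs <- singleLinkageClusters(as.matrix(allg[, c("gx_um", "gy_um",
                                                   "gz_um")]), 300)
  # per-cuboid clustering gives the same within-cuboid partitions
  l1 <- singleLinkageClusters(g1, 300)
  l2 <- singleLinkageClusters(g2, 300)
  expect_identical(outer(labs[1:30], labs[1:30], "=="),
                   outer(l1, l1, "=="))
  expect_identical(outer(labs[31:60], labs[31:60], "=="),
                   outer(l2, l2, "=="))
  # and the two cuboids' groups never merge across the 1 mm gap
  expect_identical(length(unique(labs[1:30])) +
                     length(unique(labs[31:60])),
                   length(unique(labs)))
})
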