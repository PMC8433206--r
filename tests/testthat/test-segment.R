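test_that("baseline subtraction clips at zero and lowers the median", {
  g <- VoxelGrid(array(0:7, c(2, 2, 2)))
  expect_equal(voxelData(baselineSubtract(g, 0)), voxelData(g))
  expect_equal(as.vector(voxelData(baselineSubtract(
    VoxelGrid(array(3, c(2, 2, 2))), 50))), rep(0, 8))
  set.seed(5)
  r <- VoxelGrid(array(runif(64), c(4, 4, 4)))
  expect_lte(median(voxelData(baselineSubtract(r, 30))),
             median(voxelData(r)))
})

test_that("watershed segmentation separates and splits touching islets", {
  vox <- 21
  d <- c(48, 48, 48)
  mk <- function(centers) {
    g <- VoxelGrid(array(0, d), vox)
    for (i in seq_len(nrow(centers)))
      g <- renderEllipsoid(g, centers[i, ], rep(55, 3), intensity = 1)
    g
  }
  cfg <- segmentConfig(threshold_mode = "manual", threshold_value = 0.5)
  # two spheres 300 um apart: two labels, volumes near analytic
  g <- mk(rbind(c(350, 500, 500), c(650, 500, 500)))
  lab <- segmentIslets(g, cfg)
  expect_identical(nLabels(lab), 2L)
  feat <- objectFeatures(lab, compute_surface = FALSE)
  n_one <- count_sphere_voxels(c(350, 500, 500), 55, d, vox)
  expect_true(all(abs(feat$voxel_count - n_one) / n_one <= 0.1))
  # two overlapping spheres, centres one diameter apart: split into two,
  # total volume matching the fused solid (brute-force union count)
  g2 <- mk(rbind(c(450, 500, 500), c(560, 500, 500)))
  lab2 <- segmentIslets(g2, cfg)
  expect_identical(nLabels(lab2), 2L)
  union_count <- sum(voxelData(g2) > 0.5)
  feat2 <- objectFeatures(lab2, compute_surface = FALSE)
  expect_equal(sum(feat2$voxel_count), union_count)
  # each half is a plausible share of the fused solid
  expect_true(all(feat2$voxel_count / union_count > 0.3))
})

test_that("the minimum-voxel filter keeps 5-voxel objects and drops 4-voxel
           ones", {
  d <- c(24, 24, 24)
  a <- array(0, d)
  a[2:5, 2, 2] <- 1          # 4-voxel speck
  a[10:14, 10, 10] <- 1      # 5-voxel speck
  g <- VoxelGrid(a, 21)
  lab <- segmentIslets(g, segmentConfig(threshold_mode = "manual",
                                        threshold_value = 0.5))
  expect_identical(nLabels(lab), 1L)
  expect_identical(sum(lab@data > 0), 5L)
  # empty foreground: warning plus valid empty labelling
  expect_warning(lab0 <- segmentIslets(VoxelGrid(array(0, d), 21),
                                       segmentConfig(threshold_mode =
                                                       "manual",
                                                     threshold_value = 1)),
                 "empty foreground")
  expect_identical(nLabels(lab0), 0L)
})

test_that("spot detection scores an ideal blob by its contrast", {
  vox <- 21
  d <- c(49, 49, 49)
  sb <- 110 / (2 * sqrt(3))
  ctr <- (25 - 0.5) * vox
  xs <- ((1:49) - 0.5) * vox - ctr
  blob <- 2 * exp(-outer(outer(xs^2, xs^2, "+"), xs^2, "+") / (2 * sb^2))
  sp <- detectSpots(VoxelGrid(array(blob, d), vox), segmentConfig())
  expect_identical(nrow(sp), 1L)
  expect_equal(sp$quality, 2, tolerance = 0.1)  # discrete-Laplacian slack
  expect_lt(max(abs(c(sp$x_um, sp$y_um, sp$z_um) - ctr)), vox)
  # empty volume -> no spots
  expect_identical(nrow(detectSpots(VoxelGrid(array(0, c(24, 24, 24)), vox),
                                    segmentConfig())), 0L)
})

test_that("spot counts track segmented object counts on a standard
           phantom", {
  ph <- generateCuboid(phantomSpec(shape_voxels = c(256, 256, 256),
                                   n_islets = 200, seed = 1))
  lab <- segmentIslets(ph$signal, segmentConfig())
  sp <- detectSpots(ph$signal, segmentConfig())
  expect_lte(abs(nrow(sp) - nLabels(lab)) / nLabels(lab), 0.05)
})

test_that("tissue and outline masks recover the planted tissue", {
  ph <- generateCuboid(phantomSpec(shape_voxels = c(64, 64, 64),
                                   n_islets = 5, seed = 3,
                                   hole_spec = list(n_spherical = 1,
                                                    n_tubular = 0,
                                                    sphere_diameter_um =
                                                      c(180, 220))))
  cfg <- segmentConfig()
  tis <- tissueMask(ph$anatomy, cfg)
  expect_lte(abs(sum(tis) - sum(ph$tissue)) / sum(ph$tissue), 0.05)
  # the dark hole is excluded from the tissue mask
  hole <- ph$truth[ph$truth$kind == "hole_sphere", ]
  hc <- round(c(hole$cx_um, hole$cy_um, hole$cz_um) / 21 + 0.5)
  expect_false(tis[hc[1], hc[2], hc[3]])
  out <- outlineMask(tis, cfg$outline_closing_voxels)
  expect_false(any(tis & !out))  # outline always contains tissue
  expect_true(out[hc[1], hc[2], hc[3]])  # hole filled back into outline
  # uniform block: mask equals the block, outline unchanged
  solid <- array(FALSE, c(24, 24, 24))
  solid[5:20, 5:20, 5:20] <- TRUE
  expect_identical(outlineMask(solid, 4L), solid)
})

test_that("outline contains tissue on randomized masks", {
  set.seed(11)
  for (i in 1:10) {
    v <- array(isletmapper:::cpp_gaussian3d(array(rnorm(24^3), rep(24, 3)),
                                            rep(24L, 3), 2, 2, 2),
               rep(24, 3))
    tis <- v > quantile(v, 0.7)
    out <- outlineMask(tis, 3L)
    expect_false(any(tis & !out))
  }
})

test_that("hypointense regions partition outline minus tissue and classify
           by shape", {
  # planted spherical hole -> one spherical region
  ph <- generateCuboid(phantomSpec(shape_voxels = c(64, 64, 64),
                                   n_islets = 0, seed = 8,
                                   noise_sd = 0,
                                   hole_spec = list(n_spherical = 1,
                                                    n_tubular = 0,
                                                    sphere_diameter_um =
                                                      c(200, 200))))
  cfg <- segmentConfig()
  tis <- tissueMask(ph$anatomy, cfg)
  out <- outlineMask(tis, cfg$outline_closing_voxels)
  hr <- hypointenseRegions(out, tis, cfg, 21)
  expect_identical(hr$mask | tis, out)        # exact set identities
  expect_false(any(hr$mask & tis))
  big <- hr$regions[hr$regions$voxel_count > 50, ]
  expect_identical(nrow(big), 1L)
  expect_identical(big$class, "spherical")
  # planted long tube -> tubular region
  ph2 <- generateCuboid(phantomSpec(shape_voxels = c(128, 128, 128),
                                    n_islets = 0, seed = 9, noise_sd = 0,
                                    hole_spec = list(n_spherical = 0,
                                                     n_tubular = 1,
                                                     tube_radius_um =
                                                       c(50, 50),
                                                     tube_length_um =
                                                       c(2000, 2000))))
  tis2 <- tissueMask(ph2$anatomy, cfg)
  out2 <- outlineMask(tis2, cfg$outline_closing_voxels)
  hr2 <- hypointenseRegions(out2, tis2, cfg, 21)
  big2 <- hr2$regions[hr2$regions$voxel_count > 100, ]
  expect_identical(nrow(big2), 1L)
  expect_identical(big2$class, "tubular")
  # tissue == outline -> no regions
  solid <- array(FALSE, c(16, 16, 16)); solid[4:12, 4:12, 4:12] <- TRUE
  hr3 <- hypointenseRegions(solid, solid, cfg, 21)
  expect_identical(nLabels(hr3$labels), 0L)
  expect_error(hypointenseRegions(array(FALSE, c(4, 4, 4)),
                                  array(TRUE, c(4, 4, 4)), cfg, 21),
               "not contained")
})

test_that("hemorrhage volumes count only bright anatomy inside islets", {
  ph <- generateCuboid(phantomSpec(shape_voxels = c(96, 96, 96),
                                   n_islets = 6, seed = 12,
                                   diameter_min_um = 150,
                                   diameter_median_um = 180,
                                   hemorrhage_fraction = 0.5))
  lab <- segmentIslets(ph$signal, segmentConfig())
  hem <- hemorrhageSegment(ph$anatomy, lab)
  feat <- objectFeatures(lab, compute_surface = FALSE)
  rbc <- ph$truth[ph$truth$kind == "rbc_blob", ]
  expect_gt(nrow(rbc), 0)
  carriers <- match_truth(feat, rbc)
  for (i in seq_len(nrow(rbc))) {
    expect_lte(abs(hem[carriers[i]] - rbc$voxel_count[i] * 21^3) /
                 (rbc$voxel_count[i] * 21^3), 0.15)
  }
  expect_true(all(hem[-carriers] == 0))
  # a bright blob outside all islets contributes nothing
  an <- ph$anatomy
  blank <- VoxelGrid(array(0, dim(an)), 21)
  blank <- renderEllipsoid(blank, c(200, 200, 200), rep(80, 3),
                           intensity = 1)
  hem2 <- hemorrhageSegment(blank, lab, threshold = 0.5)
  expect_true(all(hem2 == 0))
  # nothing above a manual threshold -> all zeros
  expect_true(all(hemorrhageSegment(ph$anatomy, lab, threshold = 10) == 0))
  expect_error(hemorrhageSegment(VoxelGrid(array(0, c(4, 4, 4)), 21), lab),
               "mismatched")
})
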