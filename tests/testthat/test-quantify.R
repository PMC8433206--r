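test_that("size categories follow left-open right-closed interval
           semantics", {
  vol <- sizeCategorySpec("volume")
  k <- assignSizeCategory(c(25000, 25001, 0, 102400000, 102400001), vol)
  labs <- attr(k, "labels")
  expect_identical(labs[k[1]], "(0,25000]")       # boundary right-closed
  expect_identical(labs[k[2]], "(25000,50000]")   # boundary + 1
  expect_true(is.na(k[3]))                        # zero is unbinned
  expect_identical(labs[k[4]], "(5.12e+07,1.024e+08]")
  expect_true(is.na(k[5]))                        # over-range unbinned
  dia <- sizeCategorySpec("diameter")
  kd <- assignSizeCategory(110, dia)
  expect_identical(attr(kd, "labels")[kd], "(109.3,140.6]")
  expect_error(assignSizeCategory(-1, vol), "non-negative")
})

test_that("every value in range falls in exactly one category for both
           printed edge sets", {
  set.seed(21)
  for (spec in list(sizeCategorySpec("volume"),
                    sizeCategorySpec("diameter"))) {
    last <- spec$edges[length(spec$edges)]
    vals <- c(runif(500, .Machine$double.eps, last), spec$edges[-1])
    k <- assignSizeCategory(vals, spec)
    expect_false(anyNA(k))
    counts <- tabulate(k, length(spec$edges) - 1)
    expect_identical(sum(counts), length(vals))
  }
})

test_that("density aggregation does the arithmetic and keeps per-category
           sums equal to totals", {
  rec <- data.frame(volume_um3 = rep(1e6, 10),
                    mean_diameter_um = rep(124, 10))
  rep_ <- aggregateDensities(rec, 10, "outline")
  expect_equal(rep_$count_per_mm3, 1)
  expect_equal(rep_$volume_density, 1e-3)
  expect_equal(sum(rep_$per_category$count), rep_$islet_count)
  expect_equal(sum(rep_$per_category$volume_um3),
               rep_$total_islet_volume_um3)
  # empty records
  rep0 <- aggregateDensities(rec[0, ], 10, "outline")
  expect_equal(rep0$count_per_mm3, 0)
  expect_equal(rep0$volume_density, 0)
  # doubling records and reference leaves densities unchanged
  rep2 <- aggregateDensities(rbind(rec, rec), 20, "outline")
  expect_equal(rep2$count_per_mm3, rep_$count_per_mm3)
  expect_equal(rep2$volume_density, rep_$volume_density)
  expect_error(aggregateDensities(rec, 0, "outline"), "positive")
})

test_that("over-range islets go to an explicit overflow row unless strict", {
  rec <- data.frame(volume_um3 = c(1e6, 2e8),
                    mean_diameter_um = c(124, 700))
  rep_ <- aggregateDensities(rec, 10, "outline")
  ov <- rep_$per_category[nrow(rep_$per_category), ]
  expect_match(ov$category, "Inf")
  expect_equal(ov$count, 1)
  expect_equal(rep_$n_overflow, 1)
  strict <- aggregateDensities(rec, 10, "outline", strict = TRUE)
  expect_false(any(grepl("Inf", strict$per_category$category)))
  # totals still include every record in both modes
  expect_equal(strict$total_islet_volume_um3, sum(rec$volume_um3))
})

test_that("reference volumes convert mask counts and enforce nesting", {
  out <- array(TRUE, c(100, 100, 100))
  rv <- referenceVolumes(out, out, 21)
  expect_equal(unname(rv["outline_mm3"]), 9.261)
  expect_equal(unname(rv["tissue_mm3"]), 9.261)
  tis <- out
  tis[seq_len(1e5)] <- FALSE
  rv2 <- referenceVolumes(out, tis, 21)
  expect_equal(unname(rv2["outline_mm3"] - rv2["tissue_mm3"]),
               1e5 * 21^3 / 1e9)
  # tissue-mode density >= outline-mode whenever holes exist
  rec <- data.frame(volume_um3 = rep(1e6, 5), mean_diameter_um = rep(124, 5))
  d_out <- aggregateDensities(rec, rv2[["outline_mm3"]], "outline")
  d_tis <- aggregateDensities(rec, rv2[["tissue_mm3"]], "tissue")
  expect_gt(d_tis$volume_density, d_out$volume_density)
  expect_error(referenceVolumes(tis, out, 21), "not contained")
  expect_error(aggregateDensities(rec, 0, "outline"), "positive")
})

test_that("sphericity summaries group correctly", {
  rec <- data.frame(volume_um3 = c(1e5, 2e5, 1e7, 2e7),
                    mean_diameter_um = c(60, 70, 270, 340),
                    sphericity = c(1, 1, 0.6, 0.8))
  g <- sphericityByGroup(rec)
  expect_identical(g$n, c(2L, 2L))
  expect_equal(g$mean_sphericity, c(1, 0.7))
  # all-equal sphericity gives identical group means
  rec$sphericity <- 1
  expect_true(all(sphericityByGroup(rec)$mean_sphericity == 1))
  # single record: own group, sd undefined
  one <- sphericityByGroup(rec[1, , drop = FALSE])
  expect_identical(one$n, c(1L, 0L))
  expect_true(is.na(one$sd_sphericity[1]))
  expect_true(is.na(one$mean_sphericity[2]))
  expect_error(sphericityByGroup(data.frame(volume_um3 = 1)), "sphericity")
})

test_that("elongated large islets depress the large-size sphericity mean", {
  # round small islets and flattened large islets
  small <- digit_ball(3, voxel_size = 21)
  large <- digit_ellipsoid(12, 6, 4, voxel_size = 21)
  fs <- objectFeatures(small)
  fl <- objectFeatures(large)
  fl$volume_um3 <- 1e7  # place in the large-volume group
  rec <- rbind(fs, fl)
  g <- sphericityByGroup(rec)
  expect_lt(g$mean_sphericity[2], g$mean_sphericity[1])
})

test_that("density reports round-trip through CSV", {
  rec <- data.frame(volume_um3 = c(2e4, 3e5, 5e6),
                    mean_diameter_um = c(50, 120, 210))
  rep_ <- aggregateDensities(rec, 4, "tissue")
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(rep_$per_category, tmp, row.names = FALSE)
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$volume_um3, rep_$per_category$volume_um3)
  expect_equal(back$count_per_mm3, rep_$per_category$count_per_mm3)
  expect_identical(back$category, rep_$per_category$category)
})
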