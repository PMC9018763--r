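# Fusion rules and the three evaluation metrics, validated against
# brute-force enumeration oracles.

test_that("fusion keeps the higher-probability branch, ties to teeth", {
  d <- c(4L, 4L, 4L)
  tl <- array(0L, d); bl <- array(0L, d)
  tp <- array(0, d); bp <- array(0, d)
  tl[1, 1, 1] <- 11L; tp[1, 1, 1] <- 0.9
  bl[1, 1, 1] <- 1L;  bp[1, 1, 1] <- 0.6   # tooth wins
  tl[2, 2, 2] <- 21L; tp[2, 2, 2] <- 0.5
  bl[2, 2, 2] <- 2L;  bp[2, 2, 2] <- 0.8   # bone wins
  tl[3, 3, 3] <- 31L; tp[3, 3, 3] <- 0.7
  bl[3, 3, 3] <- 1L;  bp[3, 3, 3] <- 0.7   # tie -> tooth
  tl[4, 4, 4] <- 41L                       # no overlap
  bl[1, 4, 4] <- 2L
  f <- fuse(volume(tl), volume(tp), volume(bl), volume(bp))
  expect_equal(f$teeth$voxels[1, 1, 1], 11L); expect_equal(f$bones$voxels[1, 1, 1], 0L)
  expect_equal(f$teeth$voxels[2, 2, 2], 0L);  expect_equal(f$bones$voxels[2, 2, 2], 2L)
  expect_equal(f$teeth$voxels[3, 3, 3], 31L); expect_equal(f$bones$voxels[3, 3, 3], 0L)
  expect_equal(f$teeth$voxels[4, 4, 4], 41L)
  expect_equal(f$bones$voxels[1, 4, 4], 2L)
  expect_equal(sum(f$teeth$voxels > 0 & f$bones$voxels > 0), 0)
  expect_error(fuse(volume(tl), volume(tp[1:2, , , drop = FALSE]),
                    volume(bl), volume(bp)),
               "misaligned")
})

test_that("no-overlap fusion returns both inputs unchanged", {
  d <- c(5L, 5L, 5L)
  tl <- array(0L, d); tl[1:2, 1, 1] <- 11L
  bl <- array(0L, d); bl[4:5, 5, 5] <- 2L
  f <- fuse(volume(tl), volume(array(0.9, d)), volume(bl), volume(array(0.9, d)))
  expect_identical(f$teeth$voxels, tl)
  expect_identical(f$bones$voxels, bl)
})

test_that("overlap metrics match hand-enumerated examples", {
  d <- c(6L, 6L, 6L)
  R <- array(FALSE, d); G <- array(FALSE, d)
  R[1:2, 1:2, 1:2] <- TRUE              # 8-voxel cube
  G[1:2, 1:2, 2:3] <- TRUE              # shifted: overlap 4
  om <- overlap_metrics(R, G)
  expect_equal(om$dice, 0.5)            # 2*4/(8+8)
  expect_equal(om$sensitivity, 0.5)

  expect_equal(overlap_metrics(G, G), list(dice = 1, sensitivity = 1))
  R2 <- array(FALSE, d); R2[6, 6, 6] <- TRUE
  expect_equal(overlap_metrics(R2, G)$dice, 0)
  expect_equal(overlap_metrics(R2, G)$sensitivity, 0)
  empty <- array(FALSE, d)
  expect_equal(overlap_metrics(empty, empty)$dice, 1)
  expect_true(is.na(overlap_metrics(R2, empty)$sensitivity))
})

test_that("ASD matches closed-form plane and identity cases", {
  d <- c(8L, 8L, 8L)
  A <- array(FALSE, d); B <- array(FALSE, d)
  A[4, , ] <- TRUE                      # 1-voxel-thick plane at z = 4
  B[5, , ] <- TRUE                      # parallel plane 1 voxel away
  expect_equal(average_surface_distance(A, B, c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(average_surface_distance(A, A, c(0.4, 0.4, 0.4)), 0)
  expect_error(average_surface_distance(A, array(FALSE, d)), "empty")
})

test_that("metrics equal brute-force enumeration on 100 random mask pairs", {
  set.seed(123)
  for (i in 1:100) {
    d <- sample(5:15, 3, replace = TRUE)
    R <- array(runif(prod(d)) < 0.25, d)
    G <- array(runif(prod(d)) < 0.25, d)
    ref <- brute_overlap(R, G)
    om <- overlap_metrics(R, G)
    expect_identical(om$dice, ref$dice)
    expect_identical(om$sensitivity, ref$sensitivity)
    if (any(R) && any(G)) {
      spacing <- sample(c(0.2, 0.4, 1.0), 3, replace = TRUE)
      expect_equal(average_surface_distance(R, G, spacing),
                   brute_asd(R, G, spacing), tolerance = 1e-9)
    }
  }
})

test_that("dice is symmetric, ASD symmetric, sensitivity directional", {
  set.seed(321)
  d <- c(10L, 10L, 10L)
  R <- array(runif(prod(d)) < 0.3, d)
  G <- array(runif(prod(d)) < 0.2, d)
  expect_equal(overlap_metrics(R, G)$dice, overlap_metrics(G, R)$dice)
  expect_equal(average_surface_distance(R, G, c(0.4, 0.4, 0.4)),
               average_surface_distance(G, R, c(0.4, 0.4, 0.4)))
  expect_false(isTRUE(all.equal(overlap_metrics(R, G)$sensitivity,
                                overlap_metrics(G, R)$sensitivity)))
})

test_that("per-label evaluation reports missing teeth without crashing", {
  ph <- fixture_phantom("small")
  gt <- ph$gt$tooth_labels
  pred <- volume(gt$voxels, gt$spacing)
  drop_fdi <- sort(unique(gt$voxels[gt$voxels > 0]))[1]
  pred$voxels[pred$voxels == drop_fdi] <- 0L   # a tooth the model missed
  rep <- evaluate_labels(pred, gt)
  expect_equal(nrow(rep), length(unique(gt$voxels[gt$voxels > 0])))
  row <- rep[rep$label == drop_fdi, ]
  expect_equal(row$dice, 0)
  expect_true(is.na(row$asd_mm))
  expect_true(all(rep$dice[rep$label != drop_fdi] == 1))
  expect_true(all(rep$asd_mm[rep$label != drop_fdi] == 0))
})

test_that("dice 1 coincides with ASD 0 on matching nonempty masks", {
  ph <- fixture_phantom("small")
  gt <- ph$gt$tooth_labels
  rep <- evaluate_labels(gt, gt)
  expect_true(all(rep$dice == 1))
  expect_true(all(rep$asd_mm == 0))
})

test_that("tooth statistics compute physical volumes and cohort curves", {
  d <- c(10L, 10L, 10L)
  lab <- array(0L, d); lab[1:10, 1:10, 1:10][1:1000] <- 11L  # 1000 voxels
  img <- array(0.7, d)
  st <- tooth_stats(volume(lab, c(0.4, 0.4, 0.4)), volume(img), age_years = 34)
  expect_equal(st$volume_mm3, 1000 * 0.4^3)   # 64 mm^3
  expect_equal(st$mean_intensity, 0.7)
  expect_equal(st$age_bin, "30-39")
  expect_error(tooth_stats(volume(lab), volume(img), age_years = -1), "non-negative")

  # synthetic cohort: radii scaled up for ages 20-49 -> volume curve peaks there
  cohort <- lapply(1:12, function(i) {
    age <- c(15, 25, 35, 45, 55, 65)[(i - 1) %% 6 + 1]
    scale <- if (age >= 20 && age < 50) 1.2 else 1.0
    ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48), teeth_per_arch = 6,
                                        tooth_scale = scale, age_years = age,
                                        seed = 500 + i))
    tooth_stats(ph$gt$tooth_labels, clip_normalize(ph$image), age_years = age)
  })
  agg <- aggregate_tooth_stats(do.call(rbind, cohort))
  vol_by_bin <- tapply(agg$volume_mm3, agg$age_bin, mean)
  peak_bins <- names(sort(vol_by_bin, decreasing = TRUE))[1:3]
  expect_setequal(peak_bins, c("20-29", "30-39", "40-49"))
})
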