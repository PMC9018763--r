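# Synthetic phantom generator and its ground-truth derivations.

test_that("identical specs produce bit-identical phantoms", {
  s <- phantom_spec(grid_shape = c(48, 48, 48), teeth_per_arch = 6,
                    missing_prob = 0.2, misalign_jitter = c(1, 5),
                    metal_count = 1, seed = 7)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$gt$tooth_labels$voxels, b$gt$tooth_labels$voxels)
  expect_identical(a$gt$bone_labels$voxels, b$gt$bone_labels$voxels)
  expect_identical(a$gt$centroids, b$gt$centroids)
})

test_that("missing_prob = 1 yields a toothless jaw with bones intact", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                      teeth_per_arch = 6, missing_prob = 1, seed = 1))
  expect_equal(sum(ph$gt$tooth_labels$voxels > 0), 0)
  expect_equal(nrow(ph$gt$centroids), 0L)
  expect_true(all(c(1L, 2L) %in% ph$gt$bone_labels$voxels))
})

test_that("a full 8-per-arch phantom has 16 singly-connected FDI labels", {
  ph <- fixture_phantom()
  labs <- ph$gt$tooth_labels$voxels
  present <- sort(unique(labs[labs > 0]))
  expect_length(present, 16L)
  expect_setequal(present, c(11:14, 21:24, 31:34, 41:44))
  d <- dim(labs)
  for (f in present) {
    cc <- dentseg:::cc3d(labs == f, d[1], d[2], d[3], 26L)
    expect_equal(max(cc), 1L)
  }
})

test_that("tooth and bone ground-truth foregrounds are disjoint", {
  ph <- fixture_phantom()
  expect_equal(sum(ph$gt$tooth_labels$voxels > 0 & ph$gt$bone_labels$voxels > 0), 0)
})

test_that("mean intensity orders teeth above bone above soft tissue", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48), teeth_per_arch = 6,
                                      noise_sigma = 0.05, seed = 5))
  img <- ph$image$voxels
  teeth <- ph$gt$tooth_labels$voxels > 0
  bone <- ph$gt$bone_labels$voxels > 0
  soft <- !teeth & !bone
  expect_gt(mean(img[teeth]), mean(img[bone]))
  expect_gt(mean(img[bone]), mean(img[soft]))
})

test_that("abnormal phantoms keep one component per present tooth", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48), teeth_per_arch = 6,
                                      missing_prob = 0.3, misalign_jitter = c(1.5, 6),
                                      metal_count = 1, seed = 11))
  labs <- ph$gt$tooth_labels$voxels
  present <- sort(unique(labs[labs > 0]))
  expect_true(length(present) < 12L)    # some slots dropped at p = 0.3 (seeded)
  d <- dim(labs)
  for (f in present) {
    cc <- dentseg:::cc3d(labs == f, d[1], d[2], d[3], 26L)
    expect_equal(max(cc), 1L)
  }
  # metal saturates beyond the clipping bound
  expect_gt(max(ph$image$voxels), 2500)
})

test_that("over-capacity tooth counts are rejected", {
  expect_error(generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                             teeth_per_arch = 16, seed = 1)),
               "capacity")
})

test_that("derive_skeleton is thin, inside the mask, and handles edge cases", {
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  expect_equal(derive_skeleton(m1), mask_coords_ref(m1))

  line <- array(FALSE, c(5, 5, 15)); line[3, 3, 3:12] <- TRUE
  sk <- derive_skeleton(line)
  expect_equal(nrow(sk), 10L)           # already thin: idempotent
  expect_true(all(line[sk]))

  expect_error(derive_skeleton(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("the skeleton of a solid bar tracks its central axis", {
  bar <- array(FALSE, c(9, 9, 24))
  bar[3:7, 3:7, 3:22] <- TRUE           # 5 x 5 x 20 bar, axis at (5, 5, x)
  sk <- derive_skeleton(bar)
  expect_true(all(bar[sk]))
  xs <- sort(unique(sk[, 3]))
  hit <- vapply(xs, function(x) {
    pts <- sk[sk[, 3] == x, , drop = FALSE]
    any(sqrt((pts[, 1] - 5)^2 + (pts[, 2] - 5)^2) <= 1)
  }, TRUE)
  expect_gte(mean(hit), 0.9)
  # thinness: no 3x3x3 neighborhood fully inside the skeleton
  vol <- array(FALSE, dim(bar)); vol[sk] <- TRUE
  expect_lt(nrow(sk), 0.15 * sum(bar))
})

test_that("boundary shell of a solid cube is its 26 outer voxels", {
  m <- array(FALSE, c(7, 7, 7)); m[3:5, 3:5, 3:5] <- TRUE
  ba <- derive_boundary_and_apex(m, arch = "lower", sigma = 1)
  shell <- m & !dentseg:::erode6(m)
  expect_equal(sum(shell), 26L)         # 27-voxel cube minus its center
  expect_equal(max(ba$boundary_map), 1)
  expect_true(all(ba$boundary_map[shell] > 0.3))
  expect_lt(ba$boundary_map[1, 1, 1], 0.05)  # support decays away from the shell
})

test_that("a single-root tooth yields exactly one apex at the root tip", {
  ph <- fixture_phantom()
  labs <- ph$gt$tooth_labels$voxels
  fdi <- 31L                            # lower arch: root points down (-z)
  m <- labs == fdi
  ba <- derive_boundary_and_apex(m, arch = "lower", sigma = 1.5)
  expect_equal(nrow(ba$apex_points), 1L)
  co <- mask_coords_ref(m)
  expect_equal(unname(ba$apex_points[1, 1]), min(co[, 1]))  # deepest root voxel
  expect_equal(max(ba$apex_map), 1)
  expect_error(derive_boundary_and_apex(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("offset targets point at centroids and skeletons", {
  ph <- fixture_phantom("small")
  gt <- ph$gt
  labs <- gt$tooth_labels$voxels

  off <- make_offset_targets(labs, "centroid", gt)
  expect_identical(dim(off$vectors), c(3L, dim(labs)))
  expect_identical(off$valid, labs > 0L)
  # vector arithmetic at two hand-picked voxels
  f <- as.integer(rownames(gt$centroids)[1])
  co <- mask_coords_ref(labs == f)
  p <- co[1, ]
  expect_equal(c(off$vectors[1, p[1], p[2], p[3]],
                 off$vectors[2, p[1], p[2], p[3]],
                 off$vectors[3, p[1], p[2], p[3]]),
               unname(gt$centroids[as.character(f), ] - p))
  # background voxels carry zero vectors
  bg <- which(labs == 0L)[1]
  expect_equal(off$vectors[1L + 3L * (bg - 1L)], 0)

  # skeleton mode: p + offset(p) lies on the tooth's skeleton, and is the
  # nearest skeleton voxel (brute force check on one tooth)
  offs <- make_offset_targets(labs, "skeleton", gt)
  sk <- gt$skeletons[[as.character(f)]]
  sk_key <- paste(sk[, 1], sk[, 2], sk[, 3])
  for (i in seq_len(min(40, nrow(co)))) {
    p <- co[i, ]
    tgt <- p + c(offs$vectors[1, p[1], p[2], p[3]],
                 offs$vectors[2, p[1], p[2], p[3]],
                 offs$vectors[3, p[1], p[2], p[3]])
    expect_true(paste(tgt[1], tgt[2], tgt[3]) %in% sk_key)
    d2 <- colSums((t(sk) - p)^2)
    expect_equal(sum((tgt - p)^2), min(d2))
  }
})

test_that("offset magnitudes stay within the tooth bounding-box diameter", {
  ph <- fixture_phantom("small")
  gt <- ph$gt
  labs <- gt$tooth_labels$voxels
  off <- make_offset_targets(labs, "centroid", gt)
  for (f in as.integer(rownames(gt$centroids))) {
    co <- mask_coords_ref(labs == f)
    diam <- sqrt(sum((apply(co, 2, max) - apply(co, 2, min) + 1)^2))
    n <- sqrt(off$vectors[cbind(1, co)]^2 + off$vectors[cbind(2, co)]^2 +
              off$vectors[cbind(3, co)]^2)
    expect_true(all(n <= diam))
  }
})

test_that("unknown labels in the volume are a consistency error", {
  ph <- fixture_phantom("small")
  labs <- ph$gt$tooth_labels$voxels
  labs[1, 1, 1] <- 18L                  # a code absent from the GT maps
  expect_error(make_offset_targets(labs, "centroid", ph$gt), "missing")
})
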