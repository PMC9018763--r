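# Tooth branch: ROI, voting, density-peaks clustering, per-tooth
# segmentation, assembly.

test_that("localize_roi contains all teeth under the oracle and dilates by margin", {
  ph <- fixture_phantom("small")
  v <- clip_normalize(ph$image)
  roi <- localize_roi(v, oracle_predictor(ph$gt, "roi"), patch = c(24, 24, 24))
  co <- mask_coords_ref(ph$gt$tooth_labels$voxels > 0)
  s <- roi$window$start; e <- s + roi$window$size - 1L
  expect_true(all(co[, 1] >= s[1] & co[, 1] <= e[1] &
                  co[, 2] >= s[2] & co[, 2] <= e[2] &
                  co[, 3] >= s[3] & co[, 3] <= e[3]))

  # hand-computed margin: a [10,20) 0-based box with margin 2 -> [8,22)
  box_pred <- function(x, window) {
    m <- array(0, c(1L, dim(x)[2:4]))
    # mask voxels 11..20 (1-based) relative to the full volume
    s <- window$start
    idx <- lapply(1:3, function(ax) {
      r <- (11:20) - s[ax] + 1L
      r[r >= 1 & r <= dim(x)[ax + 1]]
    })
    m[1, idx[[1]], idx[[2]], idx[[3]]] <- 1
    list(mask = m)
  }
  roi2 <- localize_roi(volume(array(0.5, c(64, 64, 64))), box_pred,
                       patch = c(64, 64, 64), margin = 2L)
  expect_equal(roi2$window$start, c(9L, 9L, 9L))       # 0-based 8
  expect_equal(roi2$window$start + roi2$window$size, c(23L, 23L, 23L)) # 0-based 22

  zero_pred <- function(x, window) list(mask = array(0, c(1L, dim(x)[2:4])))
  expect_error(localize_roi(v, zero_pred, patch = c(24, 24, 24)), "no dental ROI")
})

test_that("cast_votes shifts foreground voxels by their offsets", {
  d <- c(6L, 6L, 6L)
  fg <- array(FALSE, d); fg[2, 3, 4] <- TRUE; fg[5, 5, 5] <- TRUE
  vec <- array(0, c(3L, d))
  off <- structure(list(vectors = vec, valid = fg), class = "offset_field")
  vc <- cast_votes(off, fg)
  expect_equal(unname(vc$points), unname(vc$sources) + 0)

  vec[, 2, 3, 4] <- c(2, 4, 0)
  off$vectors <- vec
  vc <- cast_votes(off, fg)
  expect_equal(unname(vc$points[1, ]), c(4, 7, 4))

  empty <- cast_votes(off, array(FALSE, d))
  expect_equal(nrow(empty$points), 0L)
})

test_that("density-peaks matches the brute-force rho/delta rules point for point", {
  set.seed(5)
  mk_blob <- function(center, n, sd = 0.8) sweep(matrix(rnorm(3 * n, sd = sd), n, 3), 2, center, "+")
  for (ncl in 2:3) {
    centers <- rbind(c(10, 10, 10), c(10, 10, 50), c(40, 25, 30))[seq_len(ncl), , drop = FALSE]
    pts <- do.call(rbind, lapply(seq_len(ncl), function(i) mk_blob(centers[i, ], 50)))
    ref <- brute_dpc(pts, dc = 2, min_density = 20, min_sep = 5)
    r <- dentseg:::dpc_cluster(pts, 2, 20, 5)
    expect_equal(r$rho, ref$rho)
    expect_equal(r$delta, ref$delta, tolerance = 1e-12)
    expect_equal(sort(r$centers), sort(ref$centers))
    expect_equal(r$labels, ref$labels)

    cloud <- structure(list(points = pts, sources = round(pts)), class = "vote_cloud")
    cl <- cluster_votes(cloud)
    expect_equal(length(unique(cl$assignment)), ncl)
    truth <- rep(seq_len(ncl), each = 50)
    expect_equal(rand_index_adj(cl$assignment, truth), 1.0)  # purity 1 at 20*dc separation
  }
})

test_that("a single tight blob forms one cluster holding every point", {
  set.seed(6)
  pts <- matrix(rnorm(3 * 80, sd = 0.5), 80, 3) + 20
  cl <- cluster_votes(structure(list(points = pts, sources = round(pts)),
                                class = "vote_cloud"))
  expect_equal(nrow(cl$centroids), 1L)
  expect_true(all(cl$assignment == 1L))
})

test_that("clustering is invariant to the order of the points", {
  set.seed(7)
  pts <- rbind(matrix(rnorm(150, sd = 0.7), 50, 3) + 10,
               matrix(rnorm(150, sd = 0.7), 50, 3) + 30)
  base <- cluster_votes(structure(list(points = pts, sources = round(pts)),
                                  class = "vote_cloud"))
  part_key <- function(assignment) {
    split(seq_along(assignment), assignment)
  }
  for (rep in 1:10) {
    perm <- sample(nrow(pts))
    cl <- cluster_votes(structure(list(points = pts[perm, ], sources = round(pts[perm, ])),
                                  class = "vote_cloud"))
    # same partition after undoing the permutation
    back <- integer(nrow(pts))
    back[perm] <- cl$assignment
    expect_equal(rand_index_adj(back, base$assignment), 1.0)
  }
})

test_that("oracle votes from a full phantom recover every tooth exactly", {
  ph <- fixture_phantom()               # 16 teeth, missing_prob = 0
  gt <- ph$gt
  labs <- gt$tooth_labels$voxels
  off <- make_offset_targets(labs, "centroid", gt)
  fg <- labs > 0L
  votes <- cast_votes(off, fg)
  cl <- cluster_votes(votes)
  expect_equal(nrow(cl$centroids), 16L)
  truth <- labs[labs > 0L]
  expect_equal(rand_index_adj(cl$assignment, truth), 1.0)
})

test_that("vote noise degrades clustering monotonically on average", {
  ph <- fixture_phantom("small")
  gt <- ph$gt
  labs <- gt$tooth_labels$voxels
  off <- make_offset_targets(labs, "centroid", gt)
  fg <- labs > 0L
  votes <- cast_votes(off, fg)
  truth <- labs[labs > 0L]
  sigmas <- c(0, 1, 2.5, 4)
  ari <- sapply(sigmas, function(s) {
    mean(sapply(1:10, function(seed) {
      set.seed(seed)
      noisy <- votes
      noisy$points <- noisy$points + matrix(runif(length(noisy$points), -s, s),
                                            ncol = 3)
      cl <- try(cluster_votes(noisy), silent = TRUE)
      if (inherits(cl, "try-error")) return(0)
      rand_index_adj(cl$assignment, truth)
    }))
  })
  expect_true(all(diff(ari) <= 1e-8))
  expect_equal(ari[1], 1.0)
})

test_that("tooth input channels are (centroid heatmap, skeleton, image)", {
  ph <- fixture_phantom("small")
  v <- clip_normalize(ph$image)
  gt <- ph$gt
  f <- rownames(gt$centroids)[1]
  inst <- list(centroid = gt$centroids[f, ], skeleton_voxels = gt$skeletons[[f]])
  inp <- build_tooth_input(v, inst, patch = c(24, 24, 24))
  ctr_rel <- round(inst$centroid) - inp$window$start + 1L
  expect_equal(which.max(inp$x[1, , , ]),
               dentseg:::coords_to_index(matrix(ctr_rel, 1), c(24L, 24L, 24L)))
  # unit peak at the continuous centroid; the nearest grid sample is below 1
  expect_gt(max(inp$x[1, , , ]), 0.84)
  expect_lte(max(inp$x[1, , , ]), 1)
  expect_gt(max(inp$x[2, , , ]), 0)
  expect_equal(array(inp$x[3, , , ], c(24L, 24L, 24L)),
               dentseg:::crop_window(v$voxels, inp$window))

  # skeleton ablation zeroes channel 2 only
  inp0 <- build_tooth_input(v, inst, patch = c(24, 24, 24), use_skeleton = FALSE)
  expect_true(all(inp0$x[2, , , ] == 0))
  expect_equal(inp0$x[3, , , ], inp$x[3, , , ])

  # near-corner centroid: crop shifts inward, never out of bounds
  inst2 <- list(centroid = c(2, 2, 2), skeleton_voxels = NULL)
  inp2 <- build_tooth_input(v, inst2, patch = c(24, 24, 24))
  expect_equal(inp2$window$start, c(1L, 1L, 1L))
  expect_error(build_tooth_input(v, inst, patch = dim(v$voxels) + 2L), "larger")
})

test_that("single-tooth segmentation keeps the largest component and maps FDI", {
  two_blob <- function(x, window) {
    d <- dim(x)[2:4]
    m <- array(0, c(1L, d))
    m[1, 2:3, 2:3, 2:3] <- 0.9          # 8 voxels
    m[1, 8, 8, 8] <- 0.9                # separate single voxel
    logits <- numeric(32); logits[1] <- 5
    list(mask = m, logits = logits)
  }
  inp <- list(x = array(0, c(3, 10, 10, 10)),
              window = list(start = c(1L, 1L, 1L), size = c(10L, 10L, 10L)))
  seg <- segment_single_tooth(inp, two_blob)
  expect_equal(sum(seg$mask_crop), 8L)
  expect_false(seg$mask_crop[8, 8, 8])
  expect_equal(seg$fdi, 11L)
})

test_that("the class-FDI table is the documented row-major bijection", {
  expect_equal(class_to_fdi(1L), 11L)
  expect_equal(class_to_fdi(8L), 18L)
  expect_equal(class_to_fdi(9L), 21L)
  expect_equal(class_to_fdi(32L), 48L)
  expect_equal(fdi_to_class(class_to_fdi(1:32)), 1:32)
  expect_setequal(fdi_codes(), c(11:18, 21:28, 31:38, 41:48))
  expect_error(fdi_to_class(19L), "invalid")
})

test_that("assembly conserves disjoint masks and resolves overlaps by probability", {
  mk_inst <- function(start, val, prob, fdi) {
    m <- array(FALSE, c(4, 4, 4)); m[val] <- TRUE
    p <- array(0, c(4, 4, 4)); p[val] <- prob
    list(mask_crop = m, prob_crop = p, fdi = fdi,
         window = list(start = start, size = c(4L, 4L, 4L)))
  }
  a <- mk_inst(c(1L, 1L, 1L), 1:8, 0.9, 11L)
  b <- mk_inst(c(10L, 10L, 10L), 1:4, 0.8, 21L)
  asm <- assemble_instances(list(a, b), c(16L, 16L, 16L))
  expect_equal(sum(asm$labels$voxels == 11L), 8L)
  expect_equal(sum(asm$labels$voxels == 21L), 4L)
  expect_equal(sum(asm$labels$voxels > 0L), 12L)

  # overlapping voxel goes to the higher probability
  c1 <- mk_inst(c(1L, 1L, 1L), 1L, 0.9, 11L)
  c2 <- mk_inst(c(1L, 1L, 1L), 1L, 0.6, 21L)
  asm2 <- assemble_instances(list(c2, c1), c(8L, 8L, 8L))
  expect_equal(asm2$labels$voxels[1, 1, 1], 11L)
  # exact tie goes to the lower FDI code
  c3 <- mk_inst(c(1L, 1L, 1L), 1L, 0.9, 21L)
  asm3 <- assemble_instances(list(c3, c1), c(8L, 8L, 8L))
  expect_equal(asm3$labels$voxels[1, 1, 1], 11L)
  # duplicate FDI codes are reported, both instances kept
  asm4 <- assemble_instances(list(c1, mk_inst(c(5L, 5L, 5L), 2L, 0.7, 11L)),
                             c(12L, 12L, 12L))
  expect_equal(asm4$conflicts, 11L)
  expect_setequal(unique(asm4$instance_ids$voxels[asm4$instance_ids$voxels > 0]), c(1L, 2L))
  expect_error(assemble_instances(list(mk_inst(c(14L, 1L, 1L), 1L, 1, 11L)),
                                  c(16L, 16L, 16L)),
               "outside")
})

test_that("assembled label volumes contain only legal FDI codes and zero", {
  ph <- fixture_phantom("small")
  cfg <- pipeline_config(scale = "desk", oracle_gt = ph$gt)
  res <- run_pipeline(ph$image, cfg)
  expect_true(all(res$teeth$voxels %in% c(0L, fdi_codes())))
})
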