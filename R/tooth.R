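# Hierarchical morphology-guided tooth branch: ROI localization, offset
# voting, density-peaks clustering into instances, per-tooth multi-task
# segmentation with FDI classification, and paste-back assembly.

#' Clustering parameters for tooth instance detection
#'
#' @param dc cutoff radius (voxels) for the local density.
#' @param peak_min_density minimum local density of a cluster center.
#' @param peak_min_sep minimum distance (voxels) from a center to any denser
#'   point.
#' @export
cluster_params <- function(dc = 2, peak_min_density = 20, peak_min_sep = 5) {
  list(dc = dc, peak_min_density = peak_min_density, peak_min_sep = peak_min_sep)
}

#' Localize the dental region of interest
#'
#' Thresholds the predicted tooth-foreground probability at 0.5, keeps
#' connected components of at least `min_component_voxels`, and returns the
#' joint bounding box dilated by `margin` voxels (clamped to the volume).
#'
#' @param v preprocessed input [volume()] (values in `[0, 1]`).
#' @param predictor predictor with a sigmoid `mask` head.
#' @param patch,overlap_fraction tiling for [predict_patchwise()].
#' @param threshold probability threshold.
#' @param min_component_voxels minimum component size kept.
#' @param margin dilation of the bounding box, voxels.
#' @return `list(window, mask)`: the ROI window and the binary foreground
#'   [volume()].
#' @export
localize_roi <- function(v, predictor, patch = c(32L, 32L, 32L),
                         overlap_fraction = 0, threshold = 0.5,
                         min_component_voxels = 20L, margin = 4L) {
  pr <- predict_patchwise(predictor, v, patch, overlap_fraction)$mask
  fg <- pr >= threshold
  if (any(fg)) {
    lab <- cc3d(fg, dim(fg)[1], dim(fg)[2], dim(fg)[3], 26L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_component_voxels)
    fg <- array(lab %in% keep & lab > 0L, dim(fg))
  }
  if (!any(fg)) stopf("localize_roi(): no dental ROI found")
  co <- mask_coords(fg)
  d <- dim(fg)
  lo <- pmax(1L, apply(co, 2, min) - margin)
  hi <- pmin(d, apply(co, 2, max) + margin)
  list(window = list(start = as.integer(lo), size = as.integer(hi - lo + 1L)),
       mask = volume(fg, v$spacing, v$origin))
}

#' Cast centroid/skeleton votes from an offset field
#'
#' Each foreground voxel p casts one vote at p + offset(p).
#'
#' @param off an `offset_field` (`list(vectors, valid)`).
#' @param fg logical 3D array of voting voxels.
#' @return a `vote_cloud`: `list(points, sources)`, both n x 3 matrices of
#'   (z, y, x) positions / voxel indices.
#' @export
cast_votes <- function(off, fg) {
  if (!identical(dim(off$vectors)[2:4], dim(fg)))
    stopf("cast_votes(): shape mismatch")
  co <- mask_coords(fg)
  if (nrow(co) == 0L)
    return(structure(list(points = co, sources = co), class = "vote_cloud"))
  vec <- cbind(off$vectors[cbind(1L, co)], off$vectors[cbind(2L, co)], off$vectors[cbind(3L, co)])
  structure(list(points = co + vec, sources = co), class = "vote_cloud")
}

#' Cluster votes into tooth instances by density peaks
#'
#' Local density rho_i counts points within `dc`; delta_i is the distance to
#' the nearest denser point (density ties broken by point index; the global
#' density maximum takes its largest distance to any point). Cluster centers
#' satisfy rho >= `peak_min_density` and either delta >= `peak_min_sep` or
#' being the global density maximum — the densest point always seeds a
#' cluster, so a single tight blob yields one instance. Remaining points
#' inherit the label of their nearest denser neighbor. Instances are sorted
#' by centroid for determinism.
#'
#' @param cloud a `vote_cloud` from [cast_votes()].
#' @param params a [cluster_params()].
#' @return `list(assignment, centroids, rho, delta)`: `assignment` is an
#'   integer instance id per point (0 = unassigned), `centroids` a matrix of
#'   per-instance mean vote positions.
#' @export
cluster_votes <- function(cloud, params = cluster_params()) {
  n <- nrow(cloud$points)
  if (n == 0L) stopf("cluster_votes(): empty vote cloud")
  r <- dpc_cluster(cloud$points, params$dc, params$peak_min_density, params$peak_min_sep)
  if (length(r$centers) == 0L) stopf("cluster_votes(): no teeth detected")
  k <- max(r$labels)
  cent <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    sel <- r$labels == i
    cent[i, ] <- colMeans(cloud$points[sel, , drop = FALSE])
  }
  ord <- order(cent[, 1], cent[, 2], cent[, 3])
  remap <- integer(k); remap[ord] <- seq_len(k)
  assignment <- ifelse(r$labels > 0L, remap[pmax(r$labels, 1L)], 0L)
  list(assignment = as.integer(assignment), centroids = cent[ord, , drop = FALSE],
       rho = r$rho, delta = r$delta)
}

#' Provisional FDI assignment from arch position
#'
#' Splits detected centroids into upper/lower arches by the z midline of the
#' detections, into left/right quadrants by the volume x midline, and numbers
#' positions outward by distance from the midline. A fallback used when the
#' classifier head is disabled; the classifier overrides it otherwise.
#'
#' @param centroids matrix of instance centroids (z, y, x).
#' @param shape volume shape.
#' @return integer FDI codes, one per instance.
#' @export
assign_fdi_heuristic <- function(centroids, shape) {
  n <- nrow(centroids)
  if (n == 0L) return(integer(0))
  zmid <- mean(range(centroids[, 1]))
  upper <- centroids[, 1] > zmid
  cx <- (shape[3] + 1) / 2
  left <- centroids[, 3] >= cx           # patient's left
  fdi <- integer(n)
  for (up in c(TRUE, FALSE)) for (lf in c(TRUE, FALSE)) {
    sel <- which(upper == up & left == lf)
    if (!length(sel)) next
    quad <- if (up && !lf) 1L else if (up && lf) 2L else if (!up && lf) 3L else 4L
    pos <- rank(abs(centroids[sel, 3] - cx), ties.method = "first")
    fdi[sel] <- 10L * quad + pmin(as.integer(pos), 8L)
  }
  fdi
}

#' Build the 3-channel input patch for single-tooth segmentation
#'
#' Channels, in order: a unit-peak Gaussian at the instance centroid, the
#' instance's (smoothed) skeleton indicator, and the image intensities. The
#' crop is centered on the centroid and shifted inward at volume borders.
#'
#' @param v preprocessed image [volume()].
#' @param inst a tooth instance (`list` with `centroid`, `skeleton_voxels`).
#' @param patch cubic crop size (length-3 integer).
#' @param sigma_centroid Gaussian width of the centroid heatmap, voxels.
#' @param use_skeleton if `FALSE` (skeleton ablation) channel 2 is all zeros.
#' @return `list(x, window)`: the `(3, patch)` input array and its window.
#' @export
build_tooth_input <- function(v, inst, patch = c(24L, 24L, 24L),
                              sigma_centroid = 1.5, use_skeleton = TRUE) {
  d <- dim(v$voxels)
  patch <- as.integer(patch)
  if (any(patch > d)) stopf("build_tooth_input(): patch larger than volume")
  ctr <- round(inst$centroid)
  start <- as.integer(clampi(ctr - patch %/% 2L, 1L, d - patch + 1L))
  win <- list(start = start, size = patch)
  # channel 1: unit-peak Gaussian at the (fractional) centroid
  zi <- start[1]:(start[1] + patch[1] - 1L)
  yi <- start[2]:(start[2] + patch[2] - 1L)
  xi <- start[3]:(start[3] + patch[3] - 1L)
  g <- exp(-outer(outer((zi - inst$centroid[1])^2, (yi - inst$centroid[2])^2, "+"),
                  (xi - inst$centroid[3])^2, "+") / (2 * sigma_centroid^2))
  x <- array(0, c(3L, patch))
  x[1L, , , ] <- g
  if (use_skeleton && !is.null(inst$skeleton_voxels) && nrow(inst$skeleton_voxels) > 0L) {
    # vote-density map: repeated skeleton votes accumulate, so concentrated
    # (reliable) positions dominate after normalization and strays fade
    sk <- array(0, patch)
    rel <- sweep(round(inst$skeleton_voxels), 2, start - 1L)
    keep <- rel[, 1] >= 1 & rel[, 1] <= patch[1] &
            rel[, 2] >= 1 & rel[, 2] <= patch[2] &
            rel[, 3] >= 1 & rel[, 3] <= patch[3]
    if (any(keep)) {
      idx <- coords_to_index(rel[keep, , drop = FALSE], patch)
      cnt <- table(idx)
      sk[as.integer(names(cnt))] <- as.integer(cnt)
      sk <- gauss_smooth3(sk, 1)
      sk <- sk / max(sk)
    }
    x[2L, , , ] <- sk
  }
  x[3L, , , ] <- crop_window(v$voxels, win)
  list(x = x, window = win)
}

#' Segment one tooth from its 3-channel crop
#'
#' The sigmoid mask output is thresholded at 0.5 and restricted to its
#' largest connected component; boundary and apex maps are returned for
#' inspection; the FDI code is the argmax of the 32-class logits mapped
#' through the fixed class table (or `NA` when the predictor has no
#' classifier).
#'
#' @param input `list(x, window)` from [build_tooth_input()].
#' @param predictor tooth predictor (multi-task net or oracle).
#' @param threshold mask probability threshold.
#' @return `list(mask_crop, prob_crop, boundary_crop, apex_crop, fdi, window)`.
#' @export
segment_single_tooth <- function(input, predictor, threshold = 0.5) {
  out <- predict_patch(predictor, input$x, window = input$window)
  prob <- array(out$mask, dim(input$x)[2:4])
  mask <- largest_component(prob >= threshold)
  fdi <- NA_integer_
  if (!is.null(out$logits) && any(out$logits != 0))
    fdi <- class_to_fdi(which.max(out$logits))
  shp <- function(a) if (is.null(a)) NULL else array(a, dim(input$x)[2:4])
  list(mask_crop = mask, prob_crop = prob,
       boundary_crop = shp(out$boundary), apex_crop = shp(out$apex),
       fdi = fdi, window = input$window)
}

#' Assemble per-tooth crops into an instance label volume
#'
#' Each instance's mask is pasted at its crop window with its FDI code as the
#' voxel value. Where two instances claim a voxel, the higher per-voxel
#' probability wins; exact ties go to the lower FDI code. Duplicate FDI codes
#' across instances are kept as separate instances (disambiguated in the
#' returned instance-id volume) and reported in `conflicts`.
#'
#' @param instances list of segmented instances, each with `mask_crop`,
#'   `prob_crop`, `window` and `fdi`.
#' @param shape full volume shape.
#' @param spacing voxel spacing for the output volumes.
#' @return `list(labels, prob, instance_ids, conflicts)`.
#' @export
assemble_instances <- function(instances, shape, spacing = c(1, 1, 1)) {
  labels <- array(0L, shape)
  ids <- array(0L, shape)
  prob <- array(0, shape)
  fdis <- vapply(instances, function(i) as.integer(i$fdi %||% NA_integer_), 1L)
  conflicts <- unique(fdis[duplicated(fdis) & !is.na(fdis)])
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    win <- inst$window
    s <- win$start; e <- win$start + win$size - 1L
    if (any(s < 1L) || any(e > shape)) stopf("assemble_instances(): crop outside volume")
    sel <- which(inst$mask_crop)
    if (!length(sel)) next
    co <- mask_coords(inst$mask_crop)
    co_glob <- sweep(co, 2, s - 1L, "+")
    gi <- coords_to_index(co_glob, shape)
    p <- inst$prob_crop[sel]
    fdi <- if (is.na(fdis[i])) 0L else fdis[i]
    cur_p <- prob[gi]
    cur_l <- labels[gi]
    take <- cur_l == 0L | p > cur_p | (p == cur_p & fdi < cur_l)
    gi <- gi[take]
    labels[gi] <- fdi
    ids[gi] <- i
    prob[gi] <- p[take]
  }
  list(labels = volume(labels, spacing), prob = volume(prob, spacing),
       instance_ids = volume(ids, spacing), conflicts = conflicts)
}

#' Run the full tooth branch on a preprocessed volume
#'
#' ROI localization, centroid and skeleton offset prediction restricted to
#' the ROI, vote clustering, per-instance multi-task segmentation, and
#' assembly into an FDI-coded label volume.
#'
#' @param v preprocessed [volume()] in `[0, 1]`.
#' @param predictors `list(roi, centroid, skeleton, tooth)` predictors
#'   (skeleton may be `NULL` under the skeleton ablation).
#' @param patch tiling patch for the volume-level networks.
#' @param tooth_patch crop size for single-tooth segmentation.
#' @param params [cluster_params()].
#' @param overlap_fraction tiling overlap.
#' @param use_skeleton,use_classifier ablation switches (skeleton channel /
#'   FDI classifier vs arch-position heuristic).
#' @param threshold mask threshold.
#' @return `list(labels, prob, instance_ids, instances, conflicts, roi)`.
#' @export
#' Detect tooth instances (first-stage networks only)
#'
#' ROI localization, centroid/skeleton offset prediction and density-peaks
#' clustering — everything up to, but excluding, per-tooth segmentation.
#' Used by [run_tooth_branch()] and for stage-wise training of the
#' single-tooth network on predicted inputs.
#'
#' @inheritParams run_tooth_branch
#' @return `list(instances, roi)`: each instance has `instance_id`,
#'   `centroid`, `skeleton_voxels` (vote positions with multiplicity) and
#'   `heuristic_fdi`.
#' @export
detect_tooth_instances <- function(v, predictors, patch = c(32L, 32L, 32L),
                                   params = cluster_params(),
                                   overlap_fraction = 0, use_skeleton = TRUE,
                                   threshold = 0.5) {
  d <- dim(v$voxels)
  roi <- localize_roi(v, predictors$roi, patch, overlap_fraction, threshold)
  win <- roi$window
  sub <- volume(crop_window(v$voxels, win), v$spacing, v$origin)
  sub_fg <- crop_window(roi$mask$voxels, win)

  cen_out <- predict_patchwise(predictors$centroid, sub, patch, overlap_fraction,
                               window_offset = win$start - 1L)
  fg <- sub_fg & (cen_out$mask >= threshold)
  # the centroid net's mask exists to filter background from the offsets; if
  # it vetoes everything, fall back to the ROI foreground rather than abort
  if (!any(fg)) fg <- sub_fg
  if (!any(fg)) stopf("detect_tooth_instances(): no tooth foreground")
  off <- structure(list(vectors = cen_out$offset, valid = fg), class = "offset_field")
  votes <- cast_votes(off, fg)
  cl <- cluster_votes(votes, params)

  # skeleton votes, grouped by the centroid-cluster assignment of their source
  skel_by_inst <- vector("list", nrow(cl$centroids))
  if (use_skeleton && !is.null(predictors$skeleton)) {
    sk_out <- predict_patchwise(predictors$skeleton, sub, patch, overlap_fraction,
                                window_offset = win$start - 1L)
    sk_off <- structure(list(vectors = sk_out$offset, valid = fg), class = "offset_field")
    sk_votes <- cast_votes(sk_off, fg)
    pts <- round(sk_votes$points)
    for (i in seq_along(skel_by_inst)) {
      sel <- cl$assignment == i
      if (any(sel)) skel_by_inst[[i]] <- pts[sel, , drop = FALSE]  # keep multiplicity
    }
  }

  off0 <- win$start - 1L
  heuristic_fdi <- assign_fdi_heuristic(sweep(cl$centroids, 2, off0, "+"), d)
  instances <- list()
  for (i in seq_len(nrow(cl$centroids))) {
    instances[[i]] <- list(instance_id = i,
                           centroid = cl$centroids[i, ] + off0,
                           skeleton_voxels = if (!is.null(skel_by_inst[[i]]))
                             sweep(skel_by_inst[[i]], 2, off0, "+"),
                           heuristic_fdi = heuristic_fdi[i])
  }
  list(instances = instances, roi = roi)
}

run_tooth_branch <- function(v, predictors, patch = c(32L, 32L, 32L),
                             tooth_patch = c(24L, 24L, 24L),
                             params = cluster_params(), overlap_fraction = 0,
                             use_skeleton = TRUE, use_classifier = TRUE,
                             threshold = 0.5) {
  d <- dim(v$voxels)
  det <- detect_tooth_instances(v, predictors, patch, params, overlap_fraction,
                                use_skeleton, threshold)
  roi <- det$roi
  instances <- list()
  for (i in seq_along(det$instances)) {
    inst <- det$instances[[i]]
    inp <- build_tooth_input(v, inst, tooth_patch, use_skeleton = use_skeleton)
    seg <- segment_single_tooth(inp, predictors$tooth, threshold)
    inst$fdi <- if (use_classifier && !is.na(seg$fdi)) seg$fdi else inst$heuristic_fdi
    inst$mask_crop <- seg$mask_crop
    inst$prob_crop <- seg$prob_crop
    inst$boundary_crop <- seg$boundary_crop
    inst$apex_crop <- seg$apex_crop
    inst$window <- seg$window
    inst$crop_origin <- seg$window$start
    instances[[i]] <- inst
  }
  asm <- assemble_instances(instances, d, v$spacing)
  list(labels = asm$labels, prob = asm$prob, instance_ids = asm$instance_ids,
       instances = instances, conflicts = asm$conflicts, roi = roi)
}
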