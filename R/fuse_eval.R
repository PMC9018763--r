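# Fusion of the two branches and the evaluation metrics (Dice, sensitivity,
# average surface distance), plus tooth volume/intensity statistics.

#' Fuse tooth and bone predictions
#'
#' Voxels claimed by both branches keep the label of the branch with the
#' higher per-voxel probability; exact ties go to the tooth branch. The
#' returned foregrounds are disjoint.
#'
#' @param tooth_labels,bone_labels label [volume()]s.
#' @param tooth_prob,bone_prob per-voxel winning probabilities ([volume()] or
#'   array) of each branch.
#' @return `list(teeth, bones)` of disjoint label [volume()]s.
#' @export
fuse <- function(tooth_labels, tooth_prob, bone_labels, bone_prob) {
  tl <- if (is_volume(tooth_labels)) tooth_labels$voxels else tooth_labels
  bl <- if (is_volume(bone_labels)) bone_labels$voxels else bone_labels
  tp <- if (is_volume(tooth_prob)) tooth_prob$voxels else tooth_prob
  bp <- if (is_volume(bone_prob)) bone_prob$voxels else bone_prob
  if (!identical(dim(tl), dim(bl)) || !identical(dim(tl), dim(tp)) ||
      !identical(dim(tl), dim(bp)))
    stopf("fuse(): misaligned volumes")
  both <- tl > 0L & bl > 0L
  tooth_wins <- both & (tp >= bp)
  bl[tooth_wins] <- 0L
  tl[both & !tooth_wins] <- 0L
  sp <- if (is_volume(tooth_labels)) tooth_labels$spacing else c(1, 1, 1)
  list(teeth = volume(tl, sp), bones = volume(bl, sp))
}

#' Overlap metrics: Dice and sensitivity
#'
#' Dice = 2|R∩G| / (|R| + |G|); sensitivity = |R∩G| / |G|. Two empty masks
#' have Dice 1 by convention (needed for missing-tooth evaluation);
#' sensitivity is `NA` when G is empty.
#'
#' @param R predicted binary mask (logical array or label test).
#' @param G reference binary mask on the same grid.
#' @return `list(dice, sensitivity)`.
#' @export
overlap_metrics <- function(R, G) {
  if (!identical(dim(R), dim(G))) stopf("overlap_metrics(): grids differ")
  nR <- sum(R); nG <- sum(G)
  inter <- sum(R & G)
  dice <- if (nR + nG == 0) 1 else 2 * inter / (nR + nG)
  sens <- if (nG == 0) NA_real_ else inter / nG
  list(dice = dice, sensitivity = sens)
}

# Surface voxels: mask minus its 1-voxel (6-connectivity) erosion.
surface_voxels <- function(m) m & !erode6(m)

#' Symmetric average surface distance (mm)
#'
#' Surfaces are each mask minus its 1-voxel erosion; the ASD is the average
#' of the two directed mean distances, each surface voxel measured (in
#' physical mm, anisotropy-aware) to the nearest surface voxel of the other
#' mask.
#'
#' @param R,G nonempty binary masks on the same grid.
#' @param spacing voxel spacing (z, y, x) in mm.
#' @return ASD in mm.
#' @export
average_surface_distance <- function(R, G, spacing = c(1, 1, 1)) {
  if (!identical(dim(R), dim(G))) stopf("average_surface_distance(): grids differ")
  if (!any(R) || !any(G)) stopf("average_surface_distance(): empty mask")
  sR <- surface_voxels(R); sG <- surface_voxels(G)
  d <- dim(R)
  dtG <- edt3d(sG, d[1], d[2], d[3], as.numeric(spacing))
  dtR <- edt3d(sR, d[1], d[2], d[3], as.numeric(spacing))
  (mean(dtG[sR]) + mean(dtR[sG])) / 2
}

#' Per-label segmentation report
#'
#' One row per label present in either volume: Dice, sensitivity and ASD
#' (`NA` where a mask is empty, so missing teeth yield absent-label rows
#' rather than errors).
#'
#' @param pred,gt label [volume()]s on the same grid.
#' @param spacing voxel spacing in mm (defaults to `gt`'s).
#' @return data frame `(label, dice, sensitivity, asd_mm, n_pred, n_gt)`.
#' @export
evaluate_labels <- function(pred, gt, spacing = NULL) {
  pv <- if (is_volume(pred)) pred$voxels else pred
  gv <- if (is_volume(gt)) gt$voxels else gt
  spacing <- spacing %||% (if (is_volume(gt)) gt$spacing else c(1, 1, 1))
  labs <- sort(union(unique(pv[pv > 0L]), unique(gv[gv > 0L])))
  rows <- lapply(labs, function(l) {
    R <- pv == l; G <- gv == l
    om <- overlap_metrics(R, G)
    asd <- if (any(R) && any(G)) average_surface_distance(R, G, spacing) else NA_real_
    data.frame(label = l, dice = om$dice, sensitivity = om$sensitivity,
               asd_mm = asd, n_pred = sum(R), n_gt = sum(G))
  })
  do.call(rbind, rows)
}

#' Instance-matched mean tooth Dice
#'
#' Greedily matches predicted instances to ground-truth teeth by maximum
#' overlap and averages the per-pair Dice over all ground-truth teeth
#' (unmatched teeth count 0). Measures segmentation quality independently of
#' FDI numbering.
#'
#' @param pred_labels,gt_labels instance label [volume()]s.
#' @return mean Dice over ground-truth teeth.
#' @export
instance_matched_dice <- function(pred_labels, gt_labels) {
  pv <- if (is_volume(pred_labels)) pred_labels$voxels else pred_labels
  gv <- if (is_volume(gt_labels)) gt_labels$voxels else gt_labels
  gl <- sort(unique(gv[gv > 0L]))
  if (!length(gl)) return(NA_real_)
  pl <- sort(unique(pv[pv > 0L]))
  used <- logical(length(pl))
  dices <- numeric(length(gl))
  # overlap table
  ov <- matrix(0, length(gl), length(pl))
  for (i in seq_along(gl)) {
    sub <- pv[gv == gl[i]]
    t <- table(sub[sub > 0L])
    ov[i, match(as.integer(names(t)), pl)] <- as.integer(t)
  }
  repeat {
    if (!any(ov > 0)) break
    idx <- which(ov == max(ov), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    dices[i] <- overlap_metrics(pv == pl[j], gv == gl[i])$dice
    ov[i, ] <- -1; ov[, j] <- -1
  }
  mean(dices)
}

#' Per-tooth volume and intensity statistics
#'
#' Per FDI label: physical volume (voxel count times voxel volume, mm^3) and
#' mean image intensity inside the mask, tagged with the case's age decade.
#'
#' @param labels FDI label [volume()].
#' @param image aligned image [volume()].
#' @param spacing voxel spacing in mm (defaults to `labels`'s).
#' @param age_years non-negative case age.
#' @return data frame `(fdi, volume_mm3, mean_intensity, age_years, age_bin)`.
#' @export
tooth_stats <- function(labels, image, spacing = NULL, age_years) {
  if (age_years < 0) stopf("tooth_stats(): age must be non-negative")
  lv <- if (is_volume(labels)) labels$voxels else labels
  iv <- if (is_volume(image)) image$voxels else image
  spacing <- spacing %||% (if (is_volume(labels)) labels$spacing else c(1, 1, 1))
  vv <- prod(spacing)
  labs <- sort(unique(lv[lv > 0L]))
  decade <- (age_years %/% 10) * 10
  rows <- lapply(labs, function(l) {
    m <- lv == l
    data.frame(fdi = l, volume_mm3 = sum(m) * vv, mean_intensity = mean(iv[m]),
               age_years = age_years,
               age_bin = sprintf("%d-%d", decade, decade + 9))
  })
  do.call(rbind, rows)
}

#' Aggregate tooth statistics over a cohort
#'
#' @param stats data frame of stacked [tooth_stats()] rows.
#' @return mean volume and intensity per (FDI, age decade).
#' @export
aggregate_tooth_stats <- function(stats) {
  agg <- stats::aggregate(cbind(volume_mm3, mean_intensity) ~ fdi + age_bin,
                          data = stats, FUN = mean)
  agg[order(agg$fdi, agg$age_bin), ]
}
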