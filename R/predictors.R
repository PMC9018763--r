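# Predictor abstraction: anything that maps an input patch (plus its window
# position in the full volume) to named output maps. Two implementations: a
# trained network, and a ground-truth oracle that makes every non-network
# pipeline stage deterministically testable.

#' Apply a predictor to one patch
#'
#' @param predictor a `net_predictor` or `oracle_predictor`.
#' @param x input patch, `(C, z, y, x)` array.
#' @param window optional `list(start, size)` locating the patch in the full
#'   volume (1-based start); required by oracle predictors.
#' @return named list of output maps (`(C, z, y, x)` arrays), plus `logits`
#'   if the predictor has a classifier.
#' @export
predict_patch <- function(predictor, x, window = NULL) UseMethod("predict_patch")

#' @export
predict_patch.function <- function(predictor, x, window = NULL) {
  predictor(x, window)                  # ad-hoc predictors, mainly for tests
}

#' @export
predict_patch.net_predictor <- function(predictor, x, window = NULL) {
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  d <- dim(x)[2:4]
  div <- 2L^(predictor$cfg$levels - 1L)
  dpad <- as.integer(ceiling(d / div) * div)
  if (any(dpad != d)) {
    # zero-pad to the backbone's stride multiple, crop outputs back below
    xp <- array(0, c(dim(x)[1], dpad))
    xp[, seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    x <- xp
  }
  fwd <- net_forward(predictor, x, need_cache = FALSE)
  out <- lapply(fwd$heads, `[[`, "act")
  if (any(dpad != d))
    out <- lapply(out, function(a) a[, seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                                     drop = FALSE])
  # offset heads may be trained on scaled targets; undo the scaling here so
  # downstream voting always sees voxel units
  if (!is.null(predictor$offset_scale) && !is.null(out$offset))
    out$offset <- out$offset / predictor$offset_scale
  out$logits <- fwd$logits
  out
}

#' Ground-truth oracle predictor
#'
#' Emits network outputs derived from phantom ground truth, for a given
#' pipeline role:
#' \describe{
#'   \item{roi}{`mask` = tooth-foreground indicator.}
#'   \item{centroid}{`offset` = centroid offset targets, `mask` = foreground.}
#'   \item{skeleton}{`offset` = skeleton offset targets, `mask` = foreground.}
#'   \item{tooth}{per-crop `mask`/`boundary`/`apex` of the tooth whose GT
#'     label covers the crop center, plus one-hot FDI `logits`.}
#'   \item{bone}{`prob` = one-hot (background, midface, mandible) maps.}
#' }
#'
#' @param gt a `phantom_gt`.
#' @param role one of `"roi"`, `"centroid"`, `"skeleton"`, `"tooth"`, `"bone"`.
#' @param sigma Gaussian width for boundary/apex target maps (tooth role).
#' @return an `oracle_predictor`.
#' @export
oracle_predictor <- function(gt, role = c("roi", "centroid", "skeleton", "tooth", "bone"),
                             sigma = 1.5) {
  role <- match.arg(role)
  labels <- gt$tooth_labels$voxels
  d <- dim(labels)
  env <- new.env(parent = emptyenv())
  maps <- list()
  if (role == "roi") {
    maps$mask <- array(as.numeric(labels > 0L), c(1L, d))
  } else if (role %in% c("centroid", "skeleton")) {
    off <- make_offset_targets(labels, role, gt)
    maps$offset <- off$vectors
    maps$mask <- array(as.numeric(off$valid), c(1L, d))
  } else if (role == "bone") {
    b <- gt$bone_labels$voxels
    pr <- array(0, c(3L, d))
    pr[1L, , , ] <- b == 0L
    pr[2L, , , ] <- b == 1L
    pr[3L, , , ] <- b == 2L
    maps$prob <- pr
  }
  structure(list(gt = gt, role = role, maps = maps, sigma = sigma, cache = env),
            class = c("oracle_predictor", "dent_predictor"))
}

#' @export
predict_patch.oracle_predictor <- function(predictor, x, window = NULL) {
  if (is.null(window)) stopf("oracle predictor requires the patch window")
  if (predictor$role != "tooth")
    return(lapply(predictor$maps, crop_window, win = window))
  # tooth role: identify the instance covering the crop center
  gt <- predictor$gt
  labels <- gt$tooth_labels$voxels
  d <- dim(labels)
  ctr <- window$start + (window$size - 1L) %/% 2L
  fdi <- labels[ctr[1], ctr[2], ctr[3]]
  if (fdi == 0L) {
    # fall back to the dominant label inside the crop
    crop <- crop_window(labels, window)
    tab <- table(crop[crop > 0L])
    fdi <- if (length(tab)) as.integer(names(tab)[which.max(tab)]) else 0L
  }
  dz <- window$size
  if (fdi == 0L) {
    zero <- array(0, c(1L, dz))
    return(list(mask = zero, boundary = zero, apex = zero, logits = numeric(32L)))
  }
  key <- as.character(fdi)
  tooth <- predictor$cache[[key]]
  if (is.null(tooth)) {
    m <- labels == fdi
    arch <- if ((fdi %/% 10L) %in% c(1L, 2L)) "upper" else "lower"
    ba <- derive_boundary_and_apex(m, sigma = predictor$sigma, arch = arch)
    tooth <- list(mask = m * 1.0, boundary = ba$boundary_map, apex = ba$apex_map)
    assign(key, tooth, envir = predictor$cache)
  }
  logits <- numeric(32L)
  logits[fdi_to_class(fdi)] <- 50       # softmax-saturating one-hot
  list(mask = array(crop_window(tooth$mask, window), c(1L, dz)),
       boundary = array(crop_window(tooth$boundary, window), c(1L, dz)),
       apex = array(crop_window(tooth$apex, window), c(1L, dz)),
       logits = logits)
}

#' Whole-volume inference by sliding windows
#'
#' Tiles the volume with [sliding_windows()], applies the predictor to each
#' window and averages overlapping outputs voxelwise.
#'
#' @param predictor a predictor.
#' @param v input [volume()] (values in `[0, 1]`) or a `(C, z, y, x)` array
#'   for multi-channel input.
#' @param patch window size (length 3).
#' @param overlap_fraction window overlap in `[0, 1)`.
#' @param window_offset 0-based offset added to window starts before they are
#'   handed to the predictor, so that oracle predictors see full-volume
#'   coordinates when `v` is a cropped subvolume.
#' @return named list of output arrays aligned to `v` (channels first for
#'   multi-channel heads, 3D arrays for single-channel heads).
#' @export
predict_patchwise <- function(predictor, v, patch, overlap_fraction = 0,
                              window_offset = c(0L, 0L, 0L)) {
  arr <- if (is_volume(v)) array(v$voxels, c(1L, dim(v$voxels))) else v
  d <- dim(arr)[2:4]
  wins <- sliding_windows(d, patch, overlap_fraction)
  sums <- list()
  count <- array(0, d)
  for (win in wins) {
    xw <- crop_window(arr, win)
    gwin <- list(start = win$start + as.integer(window_offset), size = win$size)
    out <- predict_patch(predictor, xw, window = gwin)
    out$logits <- NULL
    s <- win$start; e <- win$start + win$size - 1L
    for (nm in names(out)) {
      if (is.null(sums[[nm]])) sums[[nm]] <- array(0, c(dim(out[[nm]])[1], d))
      sums[[nm]][, s[1]:e[1], s[2]:e[2], s[3]:e[3]] <-
        sums[[nm]][, s[1]:e[1], s[2]:e[2], s[3]:e[3], drop = FALSE] + out[[nm]]
    }
    count[s[1]:e[1], s[2]:e[2], s[3]:e[3]] <-
      count[s[1]:e[1], s[2]:e[2], s[3]:e[3]] + 1
  }
  lapply(sums, function(a) {
    C <- dim(a)[1]
    a <- a / array(rep(count, each = C), dim(a))
    if (C == 1L) array(a, d) else a
  })
}
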