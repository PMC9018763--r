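# Alveolar bone branch: Haar detail enhancement of bone boundaries and
# cascaded 3-class segmentation (background / midface / mandible).

#' Haar boundary enhancement
#'
#' One-level 3D Haar wavelet decomposition on 2x2x2 blocks (odd dimensions
#' padded by edge replication); the enhancement map is the sum of absolute
#' values of the seven detail subbands, upsampled (nearest) to the original
#' grid and rescaled to `[0, 1]` by its maximum (an all-constant input stays
#' zero). High response concentrates on intensity discontinuities, which is
#' what makes thin bone boundaries easier to segment.
#'
#' @param v input [volume()] with values in `[0, 1]`.
#' @return enhancement [volume()] in `[0, 1]`.
#' @export
haar_enhance <- function(v) {
  stopifnot(is_volume(v))
  a <- v$voxels
  d0 <- dim(a)
  dpad <- d0 + d0 %% 2L
  if (any(dpad != d0)) {
    b <- array(0, dpad)
    b[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- a
    if (dpad[1] > d0[1]) b[dpad[1], , ] <- b[d0[1], , ]
    if (dpad[2] > d0[2]) b[, dpad[2], ] <- b[, d0[2], ]
    if (dpad[3] > d0[3]) b[, , dpad[3]] <- b[, , d0[3]]
    a <- b
  }
  d <- dim(a)
  # one orthonormal Haar step along one axis: (lo, hi) = (e + o, e - o)/sqrt(2);
  # sequential per-axis steps give the 8 subbands with exact cancellation on
  # constants
  haar1 <- function(arr, ax) {
    n <- dim(arr)[ax]
    ev <- seq(1L, n, 2L); od <- ev + 1L
    pick <- function(idx) switch(ax,
                                 arr[idx, , , drop = FALSE],
                                 arr[, idx, , drop = FALSE],
                                 arr[, , idx, drop = FALSE])
    e <- pick(ev); o <- pick(od)
    list(lo = (e + o) / sqrt(2), hi = (e - o) / sqrt(2))
  }
  bands <- list(a)
  for (ax in 1:3) {
    nxt <- list()
    for (b in bands) {
      h <- haar1(b, ax)
      nxt <- c(nxt, list(h$lo, h$hi))
    }
    bands <- nxt
  }
  detail <- array(0, d %/% 2L)
  for (i in 2:8) detail <- detail + abs(bands[[i]])  # bands[[1]] = approximation
  # nearest upsample back to the (padded) grid, then crop to the original
  up <- upsample2(array(detail, c(1L, dim(detail))))
  up <- array(up, d)[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  mx <- max(up)
  if (mx > 0) up <- up / mx
  volume(up, v$spacing, v$origin)
}

#' Build the (original, enhanced) channel pair for bone segmentation
#'
#' @param v preprocessed [volume()] in `[0, 1]`.
#' @param use_haar if `FALSE` (Haar ablation) the enhanced channel is zeros.
#' @return `list(original, enhanced)` of aligned [volume()]s.
#' @export
enhanced_pair <- function(v, use_haar = TRUE) {
  enh <- if (use_haar) haar_enhance(v) else volume(array(0, dim(v$voxels)), v$spacing, v$origin)
  list(original = v, enhanced = enh)
}

#' Cascaded 3-class alveolar bone segmentation
#'
#' The first network consumes the 2-channel (original, enhanced) input and
#' produces coarse class probabilities; the second consumes (original,
#' enhanced, coarse probabilities) and outputs the refined softmax. The label
#' is the per-voxel argmax in {0 background, 1 midface, 2 mandible}. With a
#' single predictor the cascade collapses to one stage.
#'
#' @param pair `list(original, enhanced)` from [enhanced_pair()].
#' @param predictors one predictor or `list(coarse, fine)`; softmax head
#'   named `prob` with 3 channels.
#' @param patch,overlap_fraction tiling for [predict_patchwise()].
#' @return `list(labels, prob)`: label [volume()] and the `(3, z, y, x)`
#'   refined probability array.
#' @export
segment_bones <- function(pair, predictors, patch = c(32L, 32L, 32L),
                          overlap_fraction = 0) {
  d <- dim(pair$original$voxels)
  if (!identical(d, dim(pair$enhanced$voxels)))
    stopf("segment_bones(): channel shapes disagree")
  x2 <- array(0, c(2L, d))
  x2[1L, , , ] <- pair$original$voxels
  x2[2L, , , ] <- pair$enhanced$voxels
  if (inherits(predictors, "dent_predictor")) predictors <- list(predictors)
  coarse <- predict_patchwise(predictors[[1]], x2, patch, overlap_fraction)$prob
  if (length(predictors) > 1L) {
    x5 <- array(0, c(5L, d))
    x5[1:2, , , ] <- x2
    x5[3:5, , , ] <- coarse
    prob <- predict_patchwise(predictors[[2]], x5, patch, overlap_fraction)$prob
  } else prob <- coarse
  p0 <- prob[1L, , , ]; p1 <- prob[2L, , , ]; p2 <- prob[3L, , , ]
  lab <- array(0L, d)
  lab[p1 > p0 & p1 >= p2] <- 1L
  lab[p2 > p0 & p2 > p1] <- 2L
  list(labels = volume(lab, pair$original$spacing, pair$original$origin),
       prob = prob)
}
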