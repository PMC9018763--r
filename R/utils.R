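# Internal array helpers. All volumes use axis order (z, y, x), 1-based
# indices; multi-channel feature maps are (C, z, y, x).

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Separable Gaussian smoothing of a 3D array
#'
#' Truncated at 3 sigma; kernel normalized to sum 1. Edges use zero padding.
#' @param a 3D numeric array.
#' @param sigma standard deviation in voxels.
#' @return smoothed array of the same shape.
#' @keywords internal
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    n <- dim(a)[ax]
    for (i in seq_along(k)) {
      off <- i - r - 1L
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      if (!any(keep)) next
      dst <- seq_len(n)[keep]
      src <- src[keep]
      if (ax == 1L) out[dst, , ] <- out[dst, , ] + k[i] * a[src, , ]
      else if (ax == 2L) out[, dst, ] <- out[, dst, ] + k[i] * a[, src, ]
      else out[, , dst] <- out[, , dst] + k[i] * a[, , src]
    }
    a <- out
  }
  a
}

# 6-connectivity binary erosion (logical 3D array); out-of-volume treated as
# background, so the volume border always belongs to the shell.
erode6 <- function(m) {
  d <- dim(m)
  out <- m
  shift_and <- function(acc, ax, off) {
    n <- d[ax]
    res <- array(FALSE, d)
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    dst <- seq_len(n)[keep]
    src <- src[keep]
    if (ax == 1L) res[dst, , ] <- m[src, , ]
    else if (ax == 2L) res[, dst, ] <- m[, src, ]
    else res[, , dst] <- m[, , src]
    acc & res
  }
  for (ax in 1:3) for (off in c(-1L, 1L)) out <- shift_and(out, ax, off)
  out
}

# Voxel coordinates (1-based, rows = (z,y,x)) of TRUE entries of a 3D mask.
mask_coords <- function(m) {
  w <- which(m)
  if (length(w) == 0L) return(matrix(numeric(0), ncol = 3))
  d <- dim(m)
  z <- (w - 1L) %% d[1] + 1L
  y <- ((w - 1L) %/% d[1]) %% d[2] + 1L
  x <- (w - 1L) %/% (d[1] * d[2]) + 1L
  cbind(z = z, y = y, x = x)
}

coords_to_index <- function(coords, d) {
  (coords[, 1] - 1L) + d[1] * ((coords[, 2] - 1L) + d[2] * (coords[, 3] - 1L)) + 1L
}

clampi <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Largest 26-connected component of a logical mask (empty mask passes through).
largest_component <- function(m) {
  if (!any(m)) return(m)
  lab <- cc3d(m, dim(m)[1], dim(m)[2], dim(m)[3], 26L)
  tab <- tabulate(lab[lab > 0L])
  array(lab == which.max(tab), dim(m))
}
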