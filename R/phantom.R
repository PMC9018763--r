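# Synthetic dental phantom generator.
#
# A phantom is a CBCT-like volume holding two arch-shaped bone bands
# (midface/maxilla above, mandible below), 4-16 crown+root shaped teeth per
# arch placed along parabolic arch curves, soft-tissue background, additive
# Gaussian noise, and optionally the three abnormality classes seen in
# clinical scans: missing teeth, misaligned (jittered/tilted) teeth, and
# saturated metal inserts with radial streaks. Full ground truth (instance
# labels, centroids, skeletons, apices, bone classes) is returned alongside.

#' Parameter set for a synthetic jaw phantom
#'
#' The seed fully determines the output of [generate_phantom()].
#'
#' @param grid_shape integer length-3 (z, y, x), each >= 24.
#' @param spacing_mm isotropic voxel size in mm (default 0.4, the pipeline's
#'   working resolution).
#' @param teeth_per_arch even integer in 4..16; teeth are split half/half
#'   between the left and right quadrants of each arch.
#' @param missing_prob probability that a tooth slot is left empty.
#' @param misalign_jitter numeric length-2: max positional jitter (voxels)
#'   and max axis tilt (degrees), both uniform.
#' @param metal_count number of metal inserts (applied to random present teeth).
#' @param metal_intensity raw intensity of metal voxels; at or above the
#'   2500 clipping bound so metal saturates after normalization.
#' @param noise_sigma additive Gaussian noise scale as a fraction of the
#'   0-2500 intensity window (0.05 = 125 raw units).
#' @param tooth_scale global multiplier on tooth radii (used e.g. to emulate
#'   age-dependent tooth volume in synthetic cohorts).
#' @param age_years optional fixed age; if `NULL` an age in 10..80 is drawn
#'   from the seeded RNG.
#' @param seed integer RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing_mm = 0.4,
                         teeth_per_arch = 8, missing_prob = 0,
                         misalign_jitter = c(0, 0), metal_count = 0,
                         metal_intensity = 4000, noise_sigma = 0.02,
                         tooth_scale = 1, age_years = NULL, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 24L)) stopf("phantom_spec(): grid_shape must be >= 24 per axis")
  if (missing_prob < 0 || missing_prob > 1) stopf("phantom_spec(): missing_prob in [0,1]")
  if (teeth_per_arch < 4L || teeth_per_arch > 16L || teeth_per_arch %% 2L != 0L)
    stopf("phantom_spec(): teeth_per_arch must be an even integer in 4..16")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 teeth_per_arch = as.integer(teeth_per_arch),
                 missing_prob = missing_prob,
                 misalign_jitter = rep_len(as.numeric(misalign_jitter), 2L),
                 metal_count = as.integer(metal_count),
                 metal_intensity = metal_intensity, noise_sigma = noise_sigma,
                 tooth_scale = tooth_scale, age_years = age_years,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Run expr with a locally seeded RNG, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Raw tissue intensities (before the 0-2500 clip/normalize step).
PHANTOM_INTENSITY <- list(soft = 500, bone = 1100, tooth = 1900)

#' Generate a synthetic jaw phantom with full ground truth
#'
#' @param spec a [phantom_spec()].
#' @return `list(image, gt)`: `image` is a raw-intensity [volume()];
#'   `gt` is a `phantom_gt` list with elements `tooth_labels` (FDI-coded
#'   [volume()]), `bone_labels` ([volume()], 0 background / 1 midface /
#'   2 mandible), `centroids` (matrix, rownames = FDI), `apices` (named list
#'   of coordinate matrices), `skeletons` (named list of coordinate
#'   matrices), `meta` (per-tooth data frame), `age_years`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$grid_shape; D <- d[1]; H <- d[2]; W <- d[3]
  n_arch <- spec$teeth_per_arch
  np <- n_arch %/% 2L                      # teeth per quadrant

  # --- arch geometry (x across, y front-to-back, z vertical) ---
  cx <- (W + 1) / 2
  Rx <- 0.36 * W                           # half-span in x
  y_front <- 0.80 * H
  y_back <- 0.30 * H
  arch_xy <- function(t) cbind(y = y_front - (y_front - y_back) * t^2, x = cx + Rx * t)
  # arc length of the arch over t in [-1, 1]
  ts <- seq(-1, 1, length.out = 401)
  pts <- arch_xy(ts)
  seg <- sqrt(diff(pts[, "y"])^2 + diff(pts[, "x"])^2)
  arc_len <- sum(seg)
  cum <- c(0, cumsum(seg))
  # slot parameters: equally spaced in arc length, symmetric about the midline
  slot_arc <- (seq_len(n_arch) - 0.5) / n_arch * arc_len
  slot_t <- stats::approx(cum, ts, xout = slot_arc)$y
  spacing_arc <- arc_len / n_arch
  base_r <- 0.42 * spacing_arc
  if (base_r * spec$tooth_scale * 0.85 < 1.2)
    stopf("generate_phantom(): teeth_per_arch = %d exceeds arch capacity at grid_shape (%d,%d,%d)",
          n_arch, D, H, W)

  # --- vertical slabs ---
  slabs <- list(
    lower = list(crown_z = 0.42 * D, apex_z = 0.18 * D, bone_z = c(0.06, 0.26) * D, quadrants = c(3L, 4L)),
    upper = list(crown_z = 0.58 * D, apex_z = 0.82 * D, bone_z = c(0.74, 0.94) * D, quadrants = c(2L, 1L))
  )

  labels <- array(0L, d)
  img <- array(PHANTOM_INTENSITY$soft, d)
  meta <- list()
  tooth_geom <- list()

  for (arch in c("lower", "upper")) {
    sl <- slabs[[arch]]
    for (k in seq_len(n_arch)) {
      t <- slot_t[k]
      # FDI code: left half of the slots (t < 0) vs right; positions count
      # outward from the midline. Patient left = larger x here.
      quad <- if (t >= 0) {
        if (arch == "upper") 2L else 3L        # patient's left
      } else {
        if (arch == "upper") 1L else 4L        # patient's right
      }
      pos <- if (t >= 0) k - np else np + 1L - k
      fdi <- 10L * quad + pos
      # draw per-slot randomness in a fixed order so the seed contract holds
      u_missing <- stats::runif(1)
      jit <- stats::runif(3, -1, 1) * spec$misalign_jitter[1]
      tilt_deg <- stats::runif(1, -1, 1) * spec$misalign_jitter[2]
      tilt_dir <- stats::runif(1, 0, 2 * pi)
      if (u_missing < spec$missing_prob) next

      xy <- arch_xy(t)
      size_f <- 0.85 + 0.35 * abs(t)          # molars larger than incisors
      r <- base_r * size_f * spec$tooth_scale
      crown <- c(sl$crown_z, xy[1, "y"], xy[1, "x"]) + c(jit[1] * 0.5, jit[2], jit[3])
      apex <- c(sl$apex_z, xy[1, "y"], xy[1, "x"]) + c(jit[1] * 0.5, jit[2], jit[3])
      # tilt the crown-to-apex axis about a random horizontal direction
      axis <- apex - crown
      if (tilt_deg != 0) {
        L <- sqrt(sum(axis^2))
        th <- tilt_deg * pi / 180
        horiz <- c(0, cos(tilt_dir), sin(tilt_dir))
        axis <- axis * cos(th) + horiz * L * sin(th)
        apex <- crown + axis
      }
      vox <- render_tooth(d, crown, apex, r)
      if (length(vox) == 0L) next
      free <- vox[labels[vox] == 0L]
      labels[free] <- fdi
      img[free] <- PHANTOM_INTENSITY$tooth
      meta[[length(meta) + 1L]] <- data.frame(fdi = fdi, arch = arch, quadrant = quad,
                                              position = pos, radius = r)
      tooth_geom[[as.character(fdi)]] <- list(crown = crown, apex = apex, arch = arch)
    }
  }

  # --- bone bands: thickened arch in each bone slab, minus teeth ---
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist2d <- matrix(Inf, H, W)
  for (i in seq(1, length(ts), by = 2)) {
    dd <- (yy - pts[i, "y"])^2 + (xx - pts[i, "x"])^2
    dist2d <- pmin(dist2d, dd)
  }
  bone_halfwidth <- base_r * 1.35 + 1.2
  band2d <- dist2d <= bone_halfwidth^2
  bones <- array(0L, d)
  for (arch in c("lower", "upper")) {
    sl <- slabs[[arch]]
    zr <- round(sl$bone_z)
    zidx <- max(1L, zr[1]):min(D, zr[2])
    slab <- array(FALSE, d)
    slab[zidx, , ] <- rep(band2d, each = length(zidx))
    slab[labels > 0L] <- FALSE
    bones[slab] <- if (arch == "upper") 1L else 2L
    img[slab] <- PHANTOM_INTENSITY$bone
  }

  # --- metal artifacts: saturated crowns + radial streaks ---
  present_fdi <- sort(unique(labels[labels > 0L]))
  n_metal <- min(spec$metal_count, length(present_fdi))
  if (n_metal > 0L) {
    targets <- sample(present_fdi, n_metal)
    for (fdi in targets) {
      geom <- tooth_geom[[as.character(fdi)]]
      vox <- which(labels == fdi)
      co <- mask_coords(labels == fdi)
      axis <- geom$apex - geom$crown
      a <- as.vector((co - matrix(geom$crown, nrow(co), 3, byrow = TRUE)) %*% axis) / sum(axis^2)
      crown_vox <- vox[a <= 0.45]            # crown half gets the insert
      img[crown_vox] <- spec$metal_intensity
      ctr <- colMeans(co[a <= 0.45, , drop = FALSE])
      n_rays <- 8L
      ang0 <- stats::runif(1, 0, 2 * pi)
      for (ray in seq_len(n_rays)) {
        th <- ang0 + 2 * pi * ray / n_rays
        sgn <- if (ray %% 2L == 0L) 1 else -1
        for (rho in seq(2, 0.5 * min(H, W), by = 1)) {
          py <- round(ctr[2] + rho * cos(th)); px <- round(ctr[3] + rho * sin(th))
          if (py < 1 || py > H || px < 1 || px > W) break
          for (dz in -1:1) {
            pz <- round(ctr[1]) + dz
            if (pz < 1 || pz > D) next
            if (img[pz, py, px] < spec$metal_intensity)
              img[pz, py, px] <- img[pz, py, px] + sgn * 600 * exp(-rho / 15)
          }
        }
      }
    }
  }

  # --- noise ---
  if (spec$noise_sigma > 0)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sigma * 2500)

  age <- spec$age_years %||% sample(10:80, 1)

  # --- ground truth derivations ---
  centroids <- NULL; skeletons <- list(); apices <- list()
  for (fdi in present_fdi) {
    m <- labels == fdi
    co <- mask_coords(m)
    centroids <- rbind(centroids, colMeans(co))
    rownames(centroids)[nrow(centroids)] <- as.character(fdi)
    skeletons[[as.character(fdi)]] <- derive_skeleton(m)
    geom <- tooth_geom[[as.character(fdi)]]
    root_dir <- geom$apex - geom$crown
    root_dir <- root_dir / sqrt(sum(root_dir^2))
    apices[[as.character(fdi)]] <- find_apices(m, root_dir)
  }
  if (is.null(centroids)) centroids <- matrix(numeric(0), 0, 3)
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(fdi = integer(), arch = character(), quadrant = integer(),
               position = integer(), radius = numeric())

  sp3 <- rep(spec$spacing_mm, 3)
  gt <- structure(list(
    tooth_labels = volume(labels, sp3), bone_labels = volume(bones, sp3),
    centroids = centroids, skeletons = skeletons, apices = apices,
    meta = meta, age_years = age, tooth_geom = tooth_geom, spec = spec
  ), class = "phantom_gt")
  list(image = volume(img, sp3), gt = gt)
}

# Voxel indices of a crown+root tooth: ellipsoidal crown fused with a tapered
# root cone along the crown-to-apex axis.
render_tooth <- function(d, crown, apex, r) {
  axis <- apex - crown
  L <- sqrt(sum(axis^2))
  u <- axis / L
  pad <- r + 1
  lo <- pmax(1L, floor(pmin(crown, apex) - pad))
  hi <- pmin(d, ceiling(pmax(crown, apex) + pad))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  Z <- array(rep(zi, times = ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(yi, each = nz), times = nx), c(nz, ny, nx))
  X <- array(rep(xi, each = nz * ny), c(nz, ny, nx))
  vz <- Z - crown[1]; vy <- Y - crown[2]; vx <- X - crown[3]
  a <- vz * u[1] + vy * u[2] + vx * u[3]          # axial coordinate, voxels
  rad2 <- pmax(0, vz^2 + vy^2 + vx^2 - a^2)
  crown_in <- ((a - 0.20 * L) / (0.22 * L))^2 + rad2 / r^2 <= 1
  s <- (a - 0.30 * L) / (0.70 * L)
  root_r <- r * (0.85 - 0.60 * pmin(pmax(s, 0), 1))
  root_in <- a >= 0.30 * L & a <= L & rad2 <= root_r^2
  inside <- crown_in | root_in
  # map bbox-local TRUE voxels back to full-volume linear indices
  loc <- which(inside)
  if (length(loc) == 0L) return(integer(0))
  bz <- (loc - 1L) %% nz + 1L
  by <- ((loc - 1L) %/% nz) %% ny + 1L
  bx <- (loc - 1L) %/% (nz * ny) + 1L
  coords_to_index(cbind(zi[bz], yi[by], xi[bx]), d)
}

# Apex voxels: extremal mask voxels along the root direction; candidates
# within half a voxel of the extremum are grouped by 26-connectivity and each
# group contributes its most extremal voxel.
find_apices <- function(mask, root_dir) {
  co <- mask_coords(mask)
  proj <- as.vector(co %*% root_dir)
  cand <- proj >= max(proj) - 0.5
  sub <- array(FALSE, dim(mask))
  sub[coords_to_index(co[cand, , drop = FALSE], dim(mask))] <- TRUE
  lab <- cc3d(sub, dim(mask)[1], dim(mask)[2], dim(mask)[3], 26L)
  cc <- lab[coords_to_index(co[cand, , drop = FALSE], dim(mask))]
  out <- NULL
  for (g in sort(unique(cc))) {
    sel <- which(cand)[cc == g]
    best <- sel[which.max(proj[sel])]
    out <- rbind(out, co[best, ])
  }
  out
}

#' Skeletonize a 3D binary mask by iterative thinning
#'
#' Sequential deletion of simple border points with six directional
#' subiterations per cycle; endpoints are preserved, so the result is a thin
#' (about 1-2 voxels wide), 26-connected curve skeleton contained in the mask.
#'
#' @param mask logical 3D array, nonempty.
#' @return matrix of skeleton voxel coordinates (columns z, y, x).
#' @export
derive_skeleton <- function(mask) {
  if (is_volume(mask)) mask <- mask$voxels
  mask <- mask > 0
  if (!any(mask)) stopf("derive_skeleton(): empty mask")
  d <- dim(mask)
  thin <- thin3d(mask, d[1], d[2], d[3])
  mask_coords(array(thin, d))
}

#' Boundary and root-apex regression targets for one tooth
#'
#' The boundary shell is the mask minus its 1-voxel (6-connectivity) erosion;
#' the boundary map is its Gaussian-smoothed indicator rescaled to peak 1.
#' Apex points are the extremal mask voxels in the root direction
#' (`-occlusal_axis` for the upper arch, `+occlusal_axis` for the lower); the
#' apex map is a sum of unit-peak Gaussians at those points, clamped to [0,1].
#'
#' @param mask logical 3D array, nonempty.
#' @param occlusal_axis unit 3-vector (z, y, x) pointing from the upper jaw
#'   toward the lower jaw; default `c(-1, 0, 0)` (z increases upward).
#' @param sigma Gaussian width in voxels (default 1.5).
#' @param arch `"upper"` or `"lower"`.
#' @return `list(boundary_map, apex_map, apex_points)`.
#' @export
derive_boundary_and_apex <- function(mask, occlusal_axis = c(-1, 0, 0),
                                     sigma = 1.5, arch = c("upper", "lower")) {
  arch <- match.arg(arch)
  if (is_volume(mask)) mask <- mask$voxels
  mask <- mask > 0
  if (!any(mask)) stopf("derive_boundary_and_apex(): empty mask")
  if (sigma <= 0) stopf("derive_boundary_and_apex(): sigma must be positive")
  occ <- occlusal_axis / sqrt(sum(occlusal_axis^2))
  root_dir <- if (arch == "upper") -occ else occ
  d <- dim(mask)
  r <- ceiling(3 * sigma)
  # work on a padded bounding box; the maps are zero elsewhere
  co_all <- mask_coords(mask)
  lo <- pmax(1L, apply(co_all, 2, min) - r - 1L)
  hi <- pmin(d, apply(co_all, 2, max) + r + 1L)
  bwin <- list(start = as.integer(lo), size = as.integer(hi - lo + 1L))
  msub <- crop_window(mask, bwin)
  shell_sub <- msub & !erode6(msub)
  bsub <- gauss_smooth3(shell_sub * 1.0, sigma)
  mx <- max(bsub)
  if (mx > 0) bsub <- bsub / mx
  bmap <- array(0, d)
  bmap[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- bsub
  apex_points <- find_apices(mask, root_dir)
  amap <- array(0, dim(mask))
  for (i in seq_len(nrow(apex_points))) {
    p <- apex_points[i, ]
    zi <- max(1, p[1] - r):min(d[1], p[1] + r)
    yi <- max(1, p[2] - r):min(d[2], p[2] + r)
    xi <- max(1, p[3] - r):min(d[3], p[3] + r)
    dz2 <- (zi - p[1])^2
    g <- exp(-(outer(outer(dz2, (yi - p[2])^2, "+"), (xi - p[3])^2, "+")) / (2 * sigma^2))
    amap[zi, yi, xi] <- amap[zi, yi, xi] + g
  }
  amap <- pmin(amap, 1)
  list(boundary_map = bmap, apex_map = amap, apex_points = apex_points)
}

#' Offset-field regression targets
#'
#' For every foreground voxel of `labels`, the 3D vector from the voxel to its
#' tooth's centroid (mode `"centroid"`) or to the nearest voxel of its tooth's
#' skeleton (mode `"skeleton"`). Background voxels carry zero vectors and are
#' flagged invalid.
#'
#' @param labels FDI-coded label [volume()] or integer array.
#' @param targets `"centroid"` or `"skeleton"`.
#' @param gt a `phantom_gt` (or any list with `centroids` / `skeletons` named
#'   by FDI code).
#' @return an `offset_field`: `list(vectors, valid)` with `vectors` an array
#'   of dim `(3, z, y, x)` (component order dz, dy, dx) and `valid` a logical
#'   3D array.
#' @export
make_offset_targets <- function(labels, targets = c("centroid", "skeleton"), gt) {
  targets <- match.arg(targets)
  if (is_volume(labels)) labels <- labels$voxels
  d <- dim(labels)
  vectors <- array(0, c(3L, d))
  valid <- labels > 0L
  for (fdi in sort(unique(labels[labels > 0L]))) {
    key <- as.character(fdi)
    m <- labels == fdi
    co <- mask_coords(m)
    if (targets == "centroid") {
      if (!key %in% rownames(gt$centroids))
        stopf("make_offset_targets(): label %d missing from gt centroids", fdi)
      tgt <- matrix(gt$centroids[key, ], nrow(co), 3, byrow = TRUE)
    } else {
      sk <- gt$skeletons[[key]]
      if (is.null(sk)) stopf("make_offset_targets(): label %d missing from gt skeletons", fdi)
      # nearest skeleton voxel per foreground voxel (exact, small m)
      d2 <- outer(rowSums(co^2), rowSums(sk^2), "+") - 2 * co %*% t(sk)
      tgt <- sk[max.col(-d2, ties.method = "first"), , drop = FALSE]
    }
    off <- tgt - co
    idx <- coords_to_index(co, d)
    n <- length(idx)
    vectors[cbind(1L, co)] <- off[, 1]
    vectors[cbind(2L, co)] <- off[, 2]
    vectors[cbind(3L, co)] <- off[, 3]
  }
  structure(list(vectors = vectors, valid = valid), class = "offset_field")
}
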