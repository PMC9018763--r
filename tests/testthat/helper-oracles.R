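# Independent brute-force oracles used to validate the package's metric and
# clustering implementations, plus small shared fixtures.

# Plain-R Dice / sensitivity by explicit voxel enumeration.
brute_overlap <- function(R, G) {
  inter <- 0L; nR <- 0L; nG <- 0L
  for (i in seq_along(R)) {
    if (R[i]) nR <- nR + 1L
    if (G[i]) nG <- nG + 1L
    if (R[i] && G[i]) inter <- inter + 1L
  }
  list(dice = if (nR + nG == 0L) 1 else 2 * inter / (nR + nG),
       sensitivity = if (nG == 0L) NA_real_ else inter / nG)
}

# All-pairs symmetric average surface distance in R (anisotropy-aware).
brute_asd <- function(R, G, spacing) {
  surf <- function(m) {
    d <- dim(m)
    keep <- matrix(0, 0, 3)
    for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
      if (!m[z, y, x]) next
      border <- FALSE
      for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        n <- c(z, y, x) + o
        if (any(n < 1) || any(n > d) || !m[n[1], n[2], n[3]]) { border <- TRUE; break }
      }
      if (border) keep <- rbind(keep, c(z, y, x))
    }
    keep
  }
  sR <- surf(R); sG <- surf(G)
  mmR <- sweep(sR, 2, spacing, "*")
  mmG <- sweep(sG, 2, spacing, "*")
  dRG <- vapply(seq_len(nrow(mmR)), function(i)
    sqrt(min(colSums((t(mmG) - mmR[i, ])^2))), 0)
  dGR <- vapply(seq_len(nrow(mmG)), function(i)
    sqrt(min(colSums((t(mmR) - mmG[i, ])^2))), 0)
  (mean(dRG) + mean(dGR)) / 2
}

# Literal density-peaks rules in R: cutoff-kernel rho, delta to the nearest
# denser point (ties by lower index), label propagation in decreasing rho.
brute_dpc <- function(pts, dc, min_density, min_sep) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  rho <- sapply(seq_len(n), function(i) sum(d[i, -i] <= dc))
  denser <- function(i, j) rho[j] > rho[i] || (rho[j] == rho[i] && j < i)
  delta <- numeric(n); nneigh <- integer(n)
  for (i in seq_len(n)) {
    ds <- which(vapply(seq_len(n), function(j) j != i && denser(i, j), TRUE))
    if (!length(ds)) { delta[i] <- max(d[i, ]); nneigh[i] <- 0L }
    else { j <- ds[which.min(d[i, ds])]; delta[i] <- d[i, j]; nneigh[i] <- j }
  }
  centers <- which(rho >= min_density & (delta >= min_sep | nneigh == 0L))
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  ord <- order(-rho, seq_len(n))
  for (i in ord) if (labels[i] == 0L && nneigh[i] > 0L) labels[i] <- labels[nneigh[i]]
  list(rho = rho, delta = delta, centers = centers, labels = labels)
}

# Adjusted Rand index between two integer labelings.
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nt <- comb2(sum(tab))
  expected <- si * sj / nt
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Coordinates of TRUE voxels, (z, y, x) rows — independent of package internals.
mask_coords_ref <- function(m) {
  co <- arrayInd(which(m), dim(m))
  colnames(co) <- c("z", "y", "x")
  co
}

# Memoised phantoms shared across tests.
.fixture_env <- new.env(parent = emptyenv())

fixture_phantom <- function(key = "default") {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  ph <- switch(key,
    default = generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                            teeth_per_arch = 8, seed = 7)),
    small = generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                          teeth_per_arch = 6, seed = 3)),
    stop("unknown fixture"))
  .fixture_env[[key]] <- ph
  ph
}
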