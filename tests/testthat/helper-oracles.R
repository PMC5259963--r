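# Independent oracles used to cross-check the package's implementations.

# Exhaustive between-class-variance search on the same 256-bin histogram:
# tries every cut point and maximizes sigma_b^2 directly.
brute_force_otsu <- function(slice, nbins = 256L) {
  rng <- range(slice)
  bin <- pmin(floor((slice - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L, nbins)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * (rng[2] - rng[1]) / nbins
  vals <- mids[bin]
  best_t <- NA_integer_; best_s <- -Inf
  for (t in seq_len(nbins - 1L)) {
    cut <- rng[1] + t * (rng[2] - rng[1]) / nbins
    c0 <- vals[vals < cut - 1e-12]; c1 <- vals[vals >= cut - 1e-12]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / length(vals); w1 <- 1 - w0
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best_s + 1e-15) { best_s <- s; best_t <- t }
  }
  rng[1] + best_t * (rng[2] - rng[1]) / nbins
}

# Plain queue-based breadth-first flood fill, one voxel at a time.
bfs_flood_fill <- function(mask, seed, connectivity = 6) {
  d <- dim(mask)
  offs <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  offs <- offs[rowSums(offs != 0) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  out <- array(FALSE, dim = d)
  queue <- list(seed)
  out[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (j in seq_len(nrow(offs))) {
      w <- v + as.integer(offs[j, ])
      if (any(w < 1) || any(w > d)) next
      if (mask[w[1], w[2], w[3]] && !out[w[1], w[2], w[3]]) {
        out[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
  }
  out
}

# Element stiffness by numerical quadrature: strains of the 12 nodal basis
# fields are obtained by central finite differences of the interpolated
# displacement field at the centroid, then K[j,k] = V * eps_j' D eps_k.
quadrature_element_stiffness <- function(coords, D, h = 1e-6) {
  M <- cbind(1, coords)
  V <- det(M) / 6
  shape <- function(x) as.vector(solve(t(M), c(1, x)))  # N_i(x)
  centroid <- colMeans(coords)
  strain_of <- function(uvec) {
    U <- matrix(uvec, 4, 3, byrow = TRUE)
    grad <- matrix(0, 3, 3)  # grad[i, j] = d u_i / d x_j
    for (j in 1:3) {
      ep <- em <- centroid
      ep[j] <- ep[j] + h; em[j] <- em[j] - h
      up <- as.vector(t(U) %*% shape(ep))
      um <- as.vector(t(U) %*% shape(em))
      grad[, j] <- (up - um) / (2 * h)
    }
    c(grad[1, 1], grad[2, 2], grad[3, 3],
      grad[1, 2] + grad[2, 1], grad[2, 3] + grad[3, 2],
      grad[3, 1] + grad[1, 3])
  }
  eps <- sapply(seq_len(12), function(j) {
    u <- numeric(12); u[j] <- 1; strain_of(u)
  })
  V * t(eps) %*% D %*% eps
}

# A solid box segmentation for meshing / FEM tests.
box_volume <- function(nr = 4, nc = 4, ns = 4, pitch = c(2, 2)) {
  structure(list(mask = array(TRUE, c(nr, nc, ns)), pitch = pitch,
                 provenance = list(list(step = "threshold", threshold = 0))),
            class = "segmented_volume")
}

mask_volume <- function(mask, pitch = c(2, 2)) {
  structure(list(mask = mask, pitch = pitch,
                 provenance = list(list(step = "threshold", threshold = 0))),
            class = "segmented_volume")
}

# A bright slice with a dark disc (void) of given radius at given center.
disc_slice <- function(nr, nc, center, radius_px, bright = 1, dark = 0) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  out <- matrix(bright, nr, nc)
  out[(rows - center[1])^2 + (cols - center[2])^2 <= radius_px^2] <- dark
  out
}

# Euler characteristic V - E + F of a triangulated boundary surface.
euler_characteristic <- function(mesh) {
  tr <- mesh$boundary_tris
  v <- length(unique(as.vector(tr)))
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  e <- nrow(unique(edges))
  v - e + nrow(tr)
}
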