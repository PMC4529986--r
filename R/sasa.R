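#' Shrake-Rupley accessible surface area
#'
#' Per-atom solvent-accessible surface area by test-point counting: each
#' atom is covered with a deterministic (generalized-spiral) point set on
#' its solvent-extended sphere, and a point is accessible when it falls
#' outside the extended sphere of every other atom. Before placing points
#' the coordinates are rotated into a PCA-based canonical frame, which
#' makes the result independent of the pose of the input (rigidly moved
#' copies give identical areas); the point set itself is fixed, so the
#' computation is fully deterministic.
#'
#' @param xyz n x 3 matrix of atom centers (Angstrom).
#' @param radii length-n vector of van der Waals radii (Angstrom).
#' @param probe probe radius (Angstrom).
#' @param n_points number of test points per atom.
#' @return length-n vector of per-atom accessible areas (Angstrom^2).
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0L) return(numeric(0))
  stopifnot(ncol(xyz) == 3, length(radii) == n, probe >= 0, n_points >= 1)
  xyz <- canonical_frame(xyz)
  sphere <- sphere_points(n_points)
  ext <- radii + probe
  D <- sqrt(pmax(cross_dist2(xyz, xyz), 0))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * ext[i], 2, xyz[i, ], "+")
    nbr <- which(D[i, ] < ext[i] + ext & seq_len(n) != i)
    ord <- nbr[order(D[i, nbr])]
    acc <- rep(TRUE, n_points)
    for (j in ord) {
      dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dd > ext[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * ext[i]^2 * sum(acc) / n_points
  }
  areas
}

# Deterministic, near-uniform unit-sphere point set (golden-angle spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotate centered coordinates into the eigenframe of their covariance,
# with signs fixed by third moments (falling back to the largest-magnitude
# component), right-handedness enforced on the last axis. Exact rigid
# copies of a structure map to identical canonical coordinates.
canonical_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(xyz - matrix(colMeans(xyz), n, 3, byrow = TRUE))
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:2) {
    p <- xc %*% V[, k]
    s <- sum(p^3)
    if (abs(s) < 1e-8) s <- p[which.max(abs(p))]
    if (s < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  xc %*% V
}
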