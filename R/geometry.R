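# Low-level vector geometry shared by the analysis modules.

# All-pairs Euclidean distances between two coordinate sets (m x 3, k x 3),
# optionally under the orthorhombic minimum-image convention.
.pair_dists <- function(xa, xb, box = NULL) {
  m <- nrow(xa); k <- nrow(xb)
  out <- matrix(0, m, k)
  if (is.null(box)) {
    for (d in 1:3) {
      dif <- outer(xa[, d], xb[, d], "-")
      out <- out + dif * dif
    }
  } else {
    for (d in 1:3) {
      dif <- outer(xa[, d], xb[, d], "-")
      dif <- dif - box[d] * round(dif / box[d])
      out <- out + dif * dif
    }
  }
  sqrt(out)
}

# minimum distance between two atom sets
.min_dist <- function(xa, xb, box = NULL) min(.pair_dists(xa, xb, box))

# full n x n distance matrix for one frame (optionally min-image)
.frame_dist_matrix <- function(xyz, box = NULL) .pair_dists(xyz, xyz, box)

# Dihedral angle (degrees, in (-180, 180]) defined by points p1-p2-p3-p4.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), the point set used by the Shrake-Rupley SASA routine.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Gyration tensor eigenvalues (descending, nm^2) of a weighted point set.
.gyration_eigenvalues <- function(coords, masses = NULL) {
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  w <- masses / sum(masses)
  cm <- colSums(coords * w)
  xc <- sweep(coords, 2, cm)
  s <- crossprod(xc * w, xc)  # sum_i w_i r_i r_i^T
  sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

# random unit vector
.runif_sphere <- function(n = 1L) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v * v))
}

# rotation matrix about unit axis u by angle (radians), Rodrigues form
.rotation_matrix <- function(u, angle) {
  u <- u / sqrt(sum(u * u))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}
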