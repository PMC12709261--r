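#' Kabsch-superposed RMSD between two structures
#'
#' Least-squares optimal rotation and translation (no reflection) of one
#' coordinate set onto the other, then the root-mean-square deviation.
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices with matching atom
#'   counts (nm).
#' @return RMSD in nm.
#' @export
rmsd_kabsch <- function(coords_a, coords_b) {
  coords_a <- rbind(coords_a); coords_b <- rbind(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) abort("atom-count mismatch")
  a <- sweep(coords_a, 2, colMeans(coords_a))
  b <- sweep(coords_b, 2, colMeans(coords_b))
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- a %*% t(r) - b
  sqrt(sum(diff * diff) / nrow(a))
}

# frame-pairwise RMSD matrix on a selection
.pairwise_rmsd <- function(traj, selection = NULL) {
  sel <- selection %||% .backbone_indices(traj)
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(f) frame_coords(traj, f, sel))
  m <- matrix(0, nf, nf)
  if (nf < 2L) return(m)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <- rmsd_kabsch(frames[[i]], frames[[j]])
    }
  }
  m
}

#' GROMOS-style (Daura) RMSD clustering
#'
#' Greedy neighbour-count clustering on pairwise backbone RMSD: the frame
#' with the most neighbours within the cutoff becomes a cluster centre, it
#' and its neighbours are removed, and the step repeats until no frames
#' remain. Ties on neighbour count are broken by the lowest frame index.
#'
#' @param traj A [trajectory()].
#' @param cutoff RMSD cutoff, nm (default 0.3).
#' @param selection Atom indices to superpose on; default backbone
#'   (N, CA, C), falling back to all atoms for coarse-grained input.
#' @return Object of class `daura_clusters`: `assignments` (cluster id per
#'   frame, 1 = most populated), `centers` (frame index per cluster),
#'   `sizes`, `cutoff`. `tidy()` gives per-frame rows, `glance()` cluster
#'   counts.
#' @export
daura_cluster <- function(traj, cutoff = 0.3, selection = NULL) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  rmsd <- .pairwise_rmsd(traj, selection)
  res <- .daura_from_matrix(rmsd, cutoff)
  structure(
    list(assignments = res$assignments, centers = res$centers,
         sizes = res$sizes, cutoff = cutoff),
    class = "daura_clusters"
  )
}

# clustering core, shared so it can be driven by a precomputed matrix
.daura_from_matrix <- function(rmsd, cutoff) {
  nf <- nrow(rmsd)
  assignments <- integer(nf)
  centers <- integer(0)
  sizes <- integer(0)
  remaining <- rep(TRUE, nf)
  neighbor <- rmsd <= cutoff
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    counts <- vapply(idx, function(i) sum(neighbor[i, idx]) - 1L, 1L)
    center <- idx[which.max(counts)]  # which.max takes the first = lowest index
    members <- idx[neighbor[center, idx]]
    assignments[members] <- cl
    centers[cl] <- center
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  list(assignments = assignments, centers = centers, sizes = sizes)
}

#' @export
print.daura_clusters <- function(x, ...) {
  cat(sprintf(
    "<daura_clusters> %d frames, %d clusters at %.2f nm; sizes: %s\n",
    length(x$assignments), length(x$centers), x$cutoff,
    paste(head(x$sizes, 8), collapse = ", ")
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.daura_clusters <- function(x, ...) {
  tibble(
    frame = seq_along(x$assignments),
    cluster = x$assignments,
    is_center = seq_along(x$assignments) %in% x$centers
  )
}

#' @exportS3Method generics::glance
glance.daura_clusters <- function(x, ...) {
  tibble(
    n_frames = length(x$assignments),
    n_clusters = length(x$centers),
    largest_cluster = max(x$sizes),
    cutoff = x$cutoff
  )
}

#' Boltzmann-weighted 2D conformational landscape
#'
#' Bins paired per-frame observables — eccentricity on x, beta-strand
#' proportion on y — and converts bin counts to relative free energies
#' \eqn{F = -kT \ln(n / n_{max})}, so the modal bin sits at F = 0 and empty
#' bins are masked (NA), never assigned F = 0. Replicates should be
#' concatenated before binning.
#'
#' @param x,y Equal-length numeric series (no NA/Inf).
#' @param bins Number of bins per axis: scalar or length-2 (default 50).
#' @param temperature_kT Thermal energy unit; F is reported in units of kT
#'   (default 1).
#' @param x_range,y_range Optional axis ranges (default: data range).
#' @return Object of class `fe_surface`: `x_edges`, `y_edges`, `counts`,
#'   `free_energy` (kT), `kT`. `tidy()` gives the long form (x_mid, y_mid,
#'   count, F).
#' @export
boltzmann_surface <- function(x, y, bins = 50L, temperature_kT = 1,
                              x_range = NULL, y_range = NULL) {
  if (!length(x) || length(x) != length(y)) {
    abort("x and y must be non-empty and of equal length")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("x and y must be finite")
  }
  if (length(bins) == 1L) bins <- c(bins, bins)
  x_range <- x_range %||% range(x)
  y_range <- y_range %||% range(y)
  # widen degenerate ranges so constant series still bin
  if (diff(x_range) == 0) x_range <- x_range + c(-0.5, 0.5)
  if (diff(y_range) == 0) y_range <- y_range + c(-0.5, 0.5)
  x_edges <- seq(x_range[1], x_range[2], length.out = bins[1] + 1L)
  y_edges <- seq(y_range[1], y_range[2], length.out = bins[2] + 1L)
  ix <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1L), bins[1])
  iy <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1L), bins[2])
  counts <- matrix(0L, bins[1], bins[2])
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  fe <- matrix(NA_real_, bins[1], bins[2])
  occ <- counts > 0L
  fe[occ] <- -temperature_kT * log(counts[occ] / max(counts))
  structure(
    list(x_edges = x_edges, y_edges = y_edges, counts = counts,
         free_energy = fe, kT = temperature_kT, n = length(x)),
    class = "fe_surface"
  )
}

#' @export
print.fe_surface <- function(x, ...) {
  cat(sprintf(
    "<fe_surface> %d x %d bins, %d observations, F in [0, %.2f] kT (%d empty bins masked)\n",
    nrow(x$counts), ncol(x$counts), x$n,
    max(x$free_energy, na.rm = TRUE), sum(x$counts == 0L)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fe_surface <- function(x, ...) {
  xm <- (head(x$x_edges, -1) + tail(x$x_edges, -1)) / 2
  ym <- (head(x$y_edges, -1) + tail(x$y_edges, -1)) / 2
  grid <- expand.grid(ix = seq_along(xm), iy = seq_along(ym))
  tibble(
    x_mid = xm[grid$ix], y_mid = ym[grid$iy],
    count = as.integer(x$counts[cbind(grid$ix, grid$iy)]),
    free_energy = x$free_energy[cbind(grid$ix, grid$iy)]
  )
}

#' @exportS3Method generics::glance
glance.fe_surface <- function(x, ...) {
  tibble(
    n = x$n, n_bins_x = nrow(x$counts), n_bins_y = ncol(x$counts),
    n_occupied = sum(x$counts > 0L),
    f_max = max(x$free_energy, na.rm = TRUE), kT = x$kT
  )
}

#' K-means centroids of the (eccentricity, strand-proportion) landscape
#'
#' K-means on the raw 2D points — no standardization, so centroids are
#' directly comparable to the landscape axes — taking the best of `n_init`
#' seeded restarts by total within-cluster sum of squares. Centroids are
#' sorted by eccentricity descending for stable reporting.
#'
#' @param x,y Equal-length numeric series.
#' @param k Number of centroids (1 <= k <= number of points).
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts (default 50).
#' @return Tibble: `centroid`, `eccentricity`, `beta_proportion`, `size`,
#'   with attribute `inertia` (total within-cluster SS).
#' @export
landscape_centroids <- function(x, y, k, seed = 1L, n_init = 50L) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (k < 1L || k > length(x)) abort("k must be in 1..n points")
  pts <- cbind(x, y)
  fit <- withr::with_seed(seed, kmeans(pts, centers = k, nstart = n_init,
                                       iter.max = 100L))
  ord <- order(fit$centers[, 1], decreasing = TRUE)
  out <- tibble(
    centroid = seq_len(k),
    eccentricity = fit$centers[ord, 1],
    beta_proportion = fit$centers[ord, 2],
    size = fit$size[ord]
  )
  attr(out, "inertia") <- fit$tot.withinss
  out
}
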