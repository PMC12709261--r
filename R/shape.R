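#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of points from their centre of
#' mass; unit masses when none are given (the default for coarse-grained
#' beads without element masses).
#'
#' @param coords `n x 3` coordinate matrix (nm).
#' @param masses Optional weights.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  if (!nrow(coords)) abort("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  w <- masses / sum(masses)
  cm <- colSums(coords * w)
  xc <- sweep(coords, 2, cm)
  sqrt(sum(w * rowSums(xc * xc)))
}

#' Gyration-tensor eccentricity
#'
#' Elongation descriptor from the gyration tensor
#' \eqn{S = \sum_i w_i (r_i - r_{cm})(r_i - r_{cm})^T}: with eigenvalues
#' \eqn{\lambda_{max} \ge \lambda_{mid} \ge \lambda_{min}},
#' \eqn{e = \sqrt{1 - \lambda_{min} / \lambda_{max}}} (default), which is 0
#' for a spherical distribution, approaches 1 for rods and planes, and equals
#' the classical ellipse eccentricity on uniform ellipsoids. The alternative
#' `method = "mean"` uses \eqn{1 - \lambda_{min} / \bar{\lambda}} for
#' sensitivity analysis.
#'
#' @param coords `n x 3` coordinate matrix (n >= 2).
#' @param masses Optional weights (unit masses by default).
#' @param method `"ratio"` (default) or `"mean"`.
#' @return Dimensionless eccentricity in [0, 1].
#' @export
eccentricity <- function(coords, masses = NULL, method = c("ratio", "mean")) {
  method <- match.arg(method)
  coords <- rbind(coords)
  if (nrow(coords) < 2L) abort("eccentricity needs at least 2 points")
  lam <- .gyration_eigenvalues(coords, masses)
  lam <- pmax(lam, 0)
  if (lam[1] <= 0) return(0)
  if (method == "ratio") sqrt(1 - lam[3] / lam[1]) else 1 - lam[3] / mean(lam)
}

#' Per-frame shape descriptors of a trajectory
#'
#' Radius of gyration of the whole assembly and of each chain, gyration
#' tensor eigenvalues and eccentricity, per frame. Element masses are used
#' when the topology provides them for every atom; otherwise unit masses.
#'
#' @param traj A [trajectory()].
#' @param window Optional frame indices (default: all frames; see
#'   [analysis_window()] for the convergence-window convention).
#' @return Tibble: `frame`, `time_ps`, `rg_total`, `rg_chain_<id>`...,
#'   `lambda1`, `lambda2`, `lambda3` (nm^2), `eccentricity`.
#' @export
shape_series <- function(traj, window = NULL) {
  window <- window %||% seq_len(n_frames(traj))
  if (!length(window)) abort("empty frame window")
  top <- traj$topology
  masses <- if (all(!is.na(top$mass))) top$mass
  chains <- chain_ids(traj)
  chain_rows <- lapply(chains, function(ch) which(top$chain_id == ch))
  out <- purrr::map_dfr(window, function(f) {
    xyz <- frame_coords(traj, f)
    lam <- pmax(.gyration_eigenvalues(xyz, masses), 0)
    row <- tibble(
      frame = f,
      time_ps = if (!is.null(traj$frame_times)) traj$frame_times[f] else NA_real_,
      rg_total = sqrt(sum(lam)),
      lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
      eccentricity = if (lam[1] > 0) sqrt(1 - lam[3] / lam[1]) else 0
    )
    for (ci in seq_along(chains)) {
      rows <- chain_rows[[ci]]
      row[[paste0("rg_chain_", chains[ci])]] <-
        radius_of_gyration(xyz[rows, , drop = FALSE],
                           if (!is.null(masses)) masses[rows])
    }
    row
  })
  out
}

#' Default analysis window: drop unconverged early frames
#'
#' Shape and SASA statistics are taken over the frames after the assembly has
#' compacted (by default the final 85% of frames, mirroring an analysis
#' window that starts at 0.3 of a 2 microsecond trajectory once the radius of
#' gyration has converged).
#'
#' @param traj A [trajectory()].
#' @param start_fraction Fraction of frames discarded from the start
#'   (default 0.15).
#' @return Integer frame indices.
#' @export
analysis_window <- function(traj, start_fraction = 0.15) {
  if (start_fraction < 0 || start_fraction >= 1) {
    abort("start_fraction must be in [0, 1)")
  }
  nf <- n_frames(traj)
  seq.int(floor(nf * start_fraction) + 1L, nf)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic numerical SASA: each atom's sphere of radius `r_i + probe` is
#' covered with `n_sphere_points` quasi-uniform (golden-spiral) test points;
#' the accessible fraction is the share of points falling inside no
#' neighbouring sphere, scaled by the sphere area.
#'
#' @param coords `n x 3` coordinates (nm).
#' @param radii Per-atom vdW radii (nm).
#' @param probe_radius Solvent probe radius, nm (default 0.14).
#' @param n_sphere_points Test points per atom (default 960).
#' @return Numeric vector of per-atom SASA (nm^2).
#' @export
sasa_shrake_rupley <- function(coords, radii, probe_radius = 0.14,
                               n_sphere_points = 960L) {
  coords <- rbind(coords)
  n <- nrow(coords)
  if (length(radii) != n || anyNA(radii)) {
    abort("every atom needs a vdW radius")
  }
  pts <- .sphere_points(n_sphere_points)
  ext <- radii + probe_radius
  d <- .pair_dists(coords, coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < ext[i] + ext & seq_len(n) != i)
    sp <- sweep(pts * ext[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(sp[acc, , drop = FALSE], 2, coords[j, ])
      acc[acc] <- rowSums(dj * dj) > ext[j]^2
    }
    out[i] <- mean(acc) * 4 * pi * ext[i]^2
  }
  out
}

#' Per-atom SASA over a window of frames
#'
#' Convenience wrapper running [sasa_shrake_rupley()] on each frame of a
#' window; the returned matrix can be passed to [residue_sasa_normalized()]
#' and [hydrophobic_sasa()] so the surface is computed once.
#'
#' @param traj A [trajectory()].
#' @param window Frame indices (default [analysis_window()]).
#' @param probe_radius,n_sphere_points Passed to [sasa_shrake_rupley()].
#' @return `length(window) x n_atoms` matrix of SASA values (nm^2), with the
#'   window as the `window` attribute.
#' @export
trajectory_sasa <- function(traj, window = NULL, probe_radius = 0.14,
                            n_sphere_points = 960L) {
  window <- window %||% analysis_window(traj)
  if (!length(window)) abort("empty frame window")
  out <- matrix(NA_real_, length(window), n_atoms(traj))
  for (w in seq_along(window)) {
    out[w, ] <- sasa_shrake_rupley(frame_coords(traj, window[w]),
                                   traj$topology$vdw_radius,
                                   probe_radius, n_sphere_points)
  }
  attr(out, "window") <- window
  out
}

#' Per-residue SASA normalized by residue size
#'
#' Per-residue solvent-accessible surface area (sum over the residue's
#' atoms), divided by the residue's atom count — so large and small residues
#' are comparable — with mean and standard deviation over the analysis
#' window.
#'
#' @param traj A [trajectory()].
#' @param window Frame indices (default [analysis_window()]).
#' @param probe_radius,n_sphere_points Passed to [sasa_shrake_rupley()].
#' @param per_atom_sasa Optional precomputed [trajectory_sasa()] matrix for
#'   the same window.
#' @return Tibble per (chain, residue): `residue_name`, `atom_count`,
#'   `mean_sasa`, `sd_sasa` (nm^2), `mean_normalized`, `sd_normalized`
#'   (nm^2 per atom), `hydrophobic`.
#' @export
residue_sasa_normalized <- function(traj, window = NULL, probe_radius = 0.14,
                                    n_sphere_points = 960L,
                                    per_atom_sasa = NULL) {
  window <- window %||% analysis_window(traj)
  if (!length(window)) abort("empty frame window")
  if (max(window) > n_frames(traj)) abort("window outside trajectory")
  if (is.null(per_atom_sasa)) {
    per_atom_sasa <- trajectory_sasa(traj, window, probe_radius,
                                     n_sphere_points)
  }
  top <- traj$topology
  key <- paste(top$chain_id, top$residue_index)
  res_tbl <- tibble(
    chain = top$chain_id, residue = top$residue_index,
    residue_name = top$residue_name, key = key
  )
  res_tbl <- res_tbl[!duplicated(res_tbl$key), ]
  atom_count <- as.integer(table(key)[res_tbl$key])
  per_frame <- matrix(NA_real_, length(window), nrow(res_tbl))
  for (w in seq_along(window)) {
    per_frame[w, ] <- rowsum(per_atom_sasa[w, ], key)[res_tbl$key, 1]
  }
  tibble(
    chain = res_tbl$chain, residue = res_tbl$residue,
    residue_name = res_tbl$residue_name, atom_count = atom_count,
    mean_sasa = colMeans(per_frame),
    sd_sasa = apply(per_frame, 2, sd),
    mean_normalized = colMeans(per_frame) / atom_count,
    sd_normalized = apply(per_frame, 2, sd) / atom_count,
    hydrophobic = toupper(res_tbl$residue_name) %in% hydrophobic_residues
  )
}

#' Hydrophobic solvent-accessible surface area
#'
#' Total SASA of hydrophobic residues (default set: Ala, Val, Leu, Ile, Met,
#' Phe, Pro, Trp), per frame plus the window mean and standard deviation.
#'
#' @param traj A [trajectory()].
#' @param window Frame indices (default [analysis_window()]).
#' @param hydrophobic_set Three-letter residue names counted as hydrophobic.
#' @param probe_radius,n_sphere_points Passed to [sasa_shrake_rupley()].
#' @param per_atom_sasa Optional precomputed [trajectory_sasa()] matrix for
#'   the same window.
#' @return List with `per_frame` (tibble: `frame`, `hydrophobic_sasa` nm^2)
#'   and `summary` (tibble: `mean`, `sd`, `n_frames`).
#' @export
hydrophobic_sasa <- function(traj, window = NULL,
                             hydrophobic_set = hydrophobic_residues,
                             probe_radius = 0.14, n_sphere_points = 960L,
                             per_atom_sasa = NULL) {
  window <- window %||% analysis_window(traj)
  if (!length(window)) abort("empty frame window")
  top <- traj$topology
  known <- toupper(top$residue_name) %in% names(.aa_three_rev)
  if (any(!known)) {
    warn(sprintf(
      "unknown residue name(s) excluded from hydrophobic SASA: %s",
      paste(unique(top$residue_name[!known]), collapse = ", ")
    ))
  }
  sel <- toupper(top$residue_name) %in% toupper(hydrophobic_set) & known
  if (!any(sel)) {
    vals <- rep(0, length(window))
  } else {
    if (is.null(per_atom_sasa)) {
      per_atom_sasa <- trajectory_sasa(traj, window, probe_radius,
                                       n_sphere_points)
    }
    vals <- as.numeric(per_atom_sasa[, sel, drop = FALSE] %*% rep(1, sum(sel)))
  }
  list(
    per_frame = tibble(frame = window, hydrophobic_sasa = vals),
    summary = tibble(mean = mean(vals), sd = sd(vals),
                     n_frames = length(window))
  )
}

# reverse lookup for residue-name validation
.aa_three_rev <- setNames(names(.aa_three), unname(.aa_three))
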