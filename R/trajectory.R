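#' Construct a trajectory object
#'
#' The package-wide container for multi-chain trajectories: an
#' `n_frames x n_atoms x 3` coordinate array in nanometres plus a topology
#' table naming each atom's chain, residue and element. Periodic boxes are
#' per-frame orthorhombic edge lengths; when a box is present, inter-chain
#' distances use the minimum-image convention while intra-chain distances use
#' raw coordinates (chains are kept whole).
#'
#' @param coords Numeric array `n_frames x n_atoms x 3` (nm), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param topology Data frame with one row per atom and columns `chain_id`,
#'   `residue_index` (1-based, contiguous within each chain), `residue_name`,
#'   `atom_name`; optional `element`, `vdw_radius` (nm), `mass` (u). Missing
#'   elements are guessed from atom names; missing radii use the Bondi set.
#' @param frame_times Optional numeric vector of frame times (ps).
#' @param box Optional per-frame box edge lengths: a length-3 vector
#'   (constant box) or an `n_frames x 3` matrix (nm).
#' @return An object of class `trajectory`.
#' @examples
#' top <- data.frame(
#'   chain_id = "A", residue_index = 1:2, residue_name = "ALA",
#'   atom_name = "CA"
#' )
#' xyz <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
#' traj <- trajectory(xyz, top)
#' n_frames(traj)
#' @export
trajectory <- function(coords, topology, frame_times = NULL, box = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, c(1L, nrow(coords), ncol(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("`coords` must be an n_frames x n_atoms x 3 array")
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  topology <- as_tibble(topology)
  required <- c("chain_id", "residue_index", "residue_name", "atom_name")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols)) {
    abort(paste0("topology lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(topology) != dim(coords)[2]) {
    abort(sprintf(
      "topology has %d atoms but coordinates have %d",
      nrow(topology), dim(coords)[2]
    ))
  }
  topology$chain_id <- as.character(topology$chain_id)
  topology$residue_index <- as.integer(topology$residue_index)
  if (!"element" %in% names(topology)) {
    topology$element <- .element_from_atom_name(topology$atom_name)
  }
  if (!"vdw_radius" %in% names(topology)) {
    topology$vdw_radius <- .vdw_radius_for_element(topology$element)
  }
  if (!"mass" %in% names(topology)) {
    m <- unname(.element_masses[toupper(topology$element)])
    topology$mass <- ifelse(is.na(m), NA_real_, m)
  }
  .check_residue_numbering(topology)

  n_fr <- dim(coords)[1]
  if (!is.null(frame_times)) {
    if (length(frame_times) != n_fr) abort("frame_times length != n_frames")
  }
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, n_fr, 3, byrow = TRUE)
    box <- as.matrix(box)
    if (nrow(box) == 1L && n_fr > 1L) {
      box <- matrix(box, n_fr, 3, byrow = TRUE)
    }
    if (nrow(box) != n_fr || ncol(box) != 3L) {
      abort("box must be a length-3 vector or n_frames x 3 matrix")
    }
    if (any(box <= 0)) abort("box edges must be > 0")
  }
  structure(
    list(coords = coords, topology = topology,
         frame_times = frame_times, box = box),
    class = "trajectory"
  )
}

.check_residue_numbering <- function(topology) {
  for (ch in unique(topology$chain_id)) {
    ri <- topology$residue_index[topology$chain_id == ch]
    u <- unique(ri)
    if (u[1] != 1L || !identical(u, seq_along(u))) {
      abort(sprintf(
        "chain %s: residue indices must be 1-based and contiguous", ch
      ))
    }
  }
  invisible(TRUE)
}

#' @rdname trajectory
#' @param x,traj A `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' @rdname trajectory
#' @export
chain_ids <- function(traj) unique(traj$topology$chain_id)

#' @rdname trajectory
#' @export
n_chains <- function(traj) length(chain_ids(traj))

#' @rdname trajectory
#' @export
n_residues <- function(traj) {
  max(tapply(traj$topology$residue_index, traj$topology$chain_id, max))
}

#' Coordinates of one frame
#'
#' @param traj A `trajectory`.
#' @param frame Frame index (1-based).
#' @param atoms Optional atom index vector.
#' @return `n x 3` coordinate matrix (nm).
#' @export
frame_coords <- function(traj, frame, atoms = NULL) {
  if (frame < 1L || frame > n_frames(traj)) abort("frame index out of range")
  m <- traj$coords[frame, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  if (!is.null(atoms)) m <- m[atoms, , drop = FALSE]
  m
}

#' Subset frames of a trajectory
#'
#' @param x A `trajectory`.
#' @param i Frame indices.
#' @param ... Ignored.
#' @export
`[.trajectory` <- function(x, i, ...) {
  trajectory(
    x$coords[i, , , drop = FALSE], x$topology,
    frame_times = if (!is.null(x$frame_times)) x$frame_times[i],
    box = if (!is.null(x$box)) x$box[i, , drop = FALSE]
  )
}

#' Concatenate trajectories frame-wise
#'
#' Replicate compositing: trajectories must share an identical topology; their
#' frames are stacked in order. Used wherever statistics are pooled "across
#' replicates".
#'
#' @param ... `trajectory` objects.
#' @return A single `trajectory`.
#' @export
bind_frames <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1L && is.list(trajs[[1]]) &&
      !inherits(trajs[[1]], "trajectory")) {
    trajs <- trajs[[1]]
  }
  stopifnot(length(trajs) >= 1L)
  ref <- trajs[[1]]
  for (tr in trajs[-1]) {
    if (n_atoms(tr) != n_atoms(ref)) abort("replicate atom-count mismatch")
    if (!identical(tr$topology$chain_id, ref$topology$chain_id) ||
        !identical(tr$topology$residue_index, ref$topology$residue_index)) {
      abort("replicate topology mismatch")
    }
  }
  coords <- do.call(abind3, lapply(trajs, function(t) t$coords))
  times <- if (all(!vapply(trajs, function(t) is.null(t$frame_times), TRUE))) {
    unlist(lapply(trajs, function(t) t$frame_times))
  }
  box <- if (all(!vapply(trajs, function(t) is.null(t$box), TRUE))) {
    do.call(rbind, lapply(trajs, function(t) t$box))
  }
  trajectory(coords, ref$topology, frame_times = times, box = box)
}

# bind 3D arrays along dim 1 without an abind dependency
abind3 <- function(...) {
  arrs <- list(...)
  d2 <- dim(arrs[[1]])[2]
  total <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(NA_real_, c(total, d2, 3L))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames, %d atoms, %d chains (%s), %d residues/chain max\n",
    n_frames(x), n_atoms(x), n_chains(x),
    paste(chain_ids(x), collapse = ","), n_residues(x)
  ))
  cat(if (is.null(x$box)) "  no periodic box\n" else
    sprintf("  box (frame 1): %.2f x %.2f x %.2f nm\n",
            x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

# ---- internal atom-selection helpers ---------------------------------------

# atom indices for (chain, residue); heavy_only drops hydrogens
.atom_indices <- function(traj, chain_id, residue, heavy_only = TRUE) {
  top <- traj$topology
  sel <- top$chain_id == chain_id & top$residue_index == residue
  if (heavy_only) sel <- sel & toupper(top$element) != "H"
  idx <- which(sel)
  if (!length(idx)) abort(sprintf(
    "no atoms for chain %s residue %d", chain_id, residue
  ))
  idx
}

# backbone (N, CA, C) or all-atom fallback for coarse-grained input
.backbone_indices <- function(traj) {
  top <- traj$topology
  idx <- which(toupper(top$atom_name) %in% c("N", "CA", "C"))
  if (!length(idx)) idx <- seq_len(nrow(top))
  idx
}
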