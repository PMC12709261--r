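# Chemistry-aware interaction detectors. These need side-chain (or at least
# heavy-atom) detail in the topology; coarse-grained one-bead-per-residue
# input is rejected with an explicit error.

.basic_group_atoms <- list(
  LYS = c("NZ"),
  ARG = c("NH1", "NH2", "NE"),
  HIS = c("ND1", "NE2")
)
.acidic_group_atoms <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

# Charged-group table: one row per (chain, residue, group) with its atom
# indices. N-terminal amino and C-terminal carboxylate groups are separate
# entries, so a terminal Asp can bridge via either group.
.charged_groups <- function(traj, include_his = FALSE) {
  top <- traj$topology
  groups <- list()
  add <- function(chain, res, resname, kind, label, atoms) {
    if (!length(atoms)) return()
    groups[[length(groups) + 1L]] <<- list(
      chain = chain, residue = res, residue_name = resname, kind = kind,
      label = label, atoms = atoms
    )
  }
  for (ch in chain_ids(traj)) {
    sub <- which(top$chain_id == ch)
    res_range <- range(top$residue_index[sub])
    for (r in unique(top$residue_index[sub])) {
      rows <- sub[top$residue_index[sub] == r]
      resname <- toupper(top$residue_name[rows[1]])
      nm <- toupper(top$atom_name[rows])
      basic <- .basic_group_atoms[[resname]]
      if (!is.null(basic) && (resname != "HIS" || include_his)) {
        add(ch, r, resname, "basic", paste0(resname, r, "-side"),
            rows[nm %in% basic])
      }
      acidic <- .acidic_group_atoms[[resname]]
      if (!is.null(acidic)) {
        add(ch, r, resname, "acidic", paste0(resname, r, "-side"),
            rows[nm %in% acidic])
      }
      if (r == res_range[1]) {
        add(ch, r, resname, "basic", paste0(resname, r, "-Nterm"),
            rows[nm == "N"])
      }
      if (r == res_range[2]) {
        add(ch, r, resname, "acidic", paste0(resname, r, "-Cterm"),
            rows[nm %in% c("OXT", "O")])
      }
    }
  }
  groups
}

#' Salt-bridge occupancy
#'
#' A bridge event is any basic-nitrogen to acidic-oxygen distance at or below
#' the cutoff (0.4 nm). Basic groups: Lys NZ, Arg NH1/NH2/NE, optionally His
#' ND1/NE2, and each chain's N-terminal amino nitrogen. Acidic groups: Asp
#' OD1/OD2, Glu OE1/OE2, and each chain's C-terminal carboxylate (OXT/O).
#' Terminal groups are reported separately from side-chain groups, so a
#' terminal aspartate can appear through both.
#'
#' @param traj A [trajectory()] with side-chain atoms.
#' @param cutoff N-O distance cutoff, nm (default 0.4).
#' @param mode `"intermolecular"` (bridges across chains) or `"all"`.
#' @param include_his Treat histidine as basic (default FALSE).
#' @return Tibble: basic/acidic group labels and chains, `occupancy`,
#'   `n_frames`. Pairs never in contact are omitted; an empty tibble (with a
#'   warning) if no charged groups exist.
#' @export
salt_bridges <- function(traj, cutoff = 0.4,
                         mode = c("intermolecular", "all"),
                         include_his = FALSE) {
  mode <- match.arg(mode)
  groups <- .charged_groups(traj, include_his)
  basics <- Filter(function(g) g$kind == "basic", groups)
  acids <- Filter(function(g) g$kind == "acidic", groups)
  if (!length(basics) || !length(acids)) {
    warn("no charged groups found in topology; returning empty table")
    return(tibble(
      chain_basic = character(), basic_group = character(),
      chain_acidic = character(), acidic_group = character(),
      occupancy = numeric(), n_frames = integer()
    ))
  }
  nf <- n_frames(traj)
  hits <- matrix(0L, length(basics), length(acids))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ]
    for (i in seq_along(basics)) {
      for (j in seq_along(acids)) {
        if (mode == "intermolecular" &&
            basics[[i]]$chain == acids[[j]]$chain) next
        use_box <- if (basics[[i]]$chain != acids[[j]]$chain) box else NULL
        d <- .min_dist(xyz[basics[[i]]$atoms, , drop = FALSE],
                       xyz[acids[[j]]$atoms, , drop = FALSE], use_box)
        if (d <= cutoff) hits[i, j] <- hits[i, j] + 1L
      }
    }
  }
  empty <- tibble(
    chain_basic = character(), basic_group = character(),
    chain_acidic = character(), acidic_group = character(),
    occupancy = numeric(), n_frames = integer()
  )
  if (!any(hits > 0L)) return(empty)
  out <- purrr::map_dfr(which(hits > 0L), function(k) {
    i <- (k - 1L) %% length(basics) + 1L
    j <- (k - 1L) %/% length(basics) + 1L
    tibble(
      chain_basic = basics[[i]]$chain, basic_group = basics[[i]]$label,
      chain_acidic = acids[[j]]$chain, acidic_group = acids[[j]]$label,
      occupancy = hits[i, j] / nf, n_frames = nf
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$occupancy))
}

#' Hydrogen-bond occupancy
#'
#' A bond event is a donor-heavy-atom (N or O) to acceptor (N or O) distance
#' at or below `dist_cutoff` (0.35 nm); when the donor carries a resolved
#' hydrogen, the D-H...A angle must additionally deviate from linear by at
#' most `angle_cutoff` degrees. Without hydrogens in the topology the
#' distance criterion alone is used (heavy-atom mode).
#'
#' @param traj A [trajectory()] with N/O atoms (full-atom or heavy-atom).
#' @param dist_cutoff Donor-acceptor distance cutoff, nm.
#' @param angle_cutoff Maximum deviation from linearity at H, degrees.
#' @param mode `"intermolecular"` (default) or `"all"`.
#' @return Tibble of donor/acceptor atom descriptors with `occupancy`;
#'   pairs never bonded are omitted.
#' @export
hydrogen_bonds <- function(traj, dist_cutoff = 0.35, angle_cutoff = 30,
                           mode = c("intermolecular", "all")) {
  mode <- match.arg(mode)
  top <- traj$topology
  polar <- which(toupper(top$element) %in% c("N", "O"))
  if (!length(polar) || all(toupper(top$atom_name) == "CA")) {
    abort(paste(
      "hydrogen-bond detection needs N/O atoms in the topology;",
      "coarse-grained input is not supported"
    ), class = "oligotraj_unsupported_input")
  }
  hydros <- which(toupper(top$element) == "H")
  has_h <- length(hydros) > 0L
  # attach hydrogens to the nearest polar atom of the same residue (frame 1)
  donor_h <- vector("list", length(polar))
  if (has_h) {
    xyz1 <- frame_coords(traj, 1)
    for (h in hydros) {
      same <- polar[top$chain_id[polar] == top$chain_id[h] &
                      top$residue_index[polar] == top$residue_index[h]]
      if (!length(same)) next
      d <- sqrt(rowSums(sweep(xyz1[same, , drop = FALSE], 2, xyz1[h, ])^2))
      if (min(d) <= 0.125) {
        k <- match(same[which.min(d)], polar)
        donor_h[[k]] <- c(donor_h[[k]], h)
      }
    }
  }
  nf <- n_frames(traj)
  counts <- list()
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ]
    dmat <- .pair_dists(xyz[polar, , drop = FALSE],
                        xyz[polar, , drop = FALSE], box)
    cand <- which(dmat <= dist_cutoff & upper.tri(dmat), arr.ind = TRUE)
    for (row in seq_len(nrow(cand))) {
      for (swap in c(FALSE, TRUE)) {
        if (swap && !has_h) next  # heavy-atom mode: one event per pair
        di <- if (swap) cand[row, 2] else cand[row, 1]
        ai <- if (swap) cand[row, 1] else cand[row, 2]
        d_atom <- polar[di]; a_atom <- polar[ai]
        if (mode == "intermolecular" &&
            top$chain_id[d_atom] == top$chain_id[a_atom]) next
        hs <- donor_h[[di]]
        ok <- if (is.null(hs)) !has_h else {
          any(vapply(hs, function(h) {
            v1 <- xyz[d_atom, ] - xyz[h, ]
            v2 <- xyz[a_atom, ] - xyz[h, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            (180 - ang) <= angle_cutoff
          }, TRUE))
        }
        if (ok) {
          key <- paste(d_atom, a_atom)
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  if (!length(counts)) {
    return(tibble(
      chain_donor = character(), res_donor = integer(),
      donor_atom = character(), chain_acceptor = character(),
      res_acceptor = integer(), acceptor_atom = character(),
      occupancy = numeric(), n_frames = integer()
    ))
  }
  keys <- do.call(rbind, lapply(strsplit(names(counts), " "), as.integer))
  out <- tibble(
    chain_donor = top$chain_id[keys[, 1]],
    res_donor = top$residue_index[keys[, 1]],
    donor_atom = top$atom_name[keys[, 1]],
    chain_acceptor = top$chain_id[keys[, 2]],
    res_acceptor = top$residue_index[keys[, 2]],
    acceptor_atom = top$atom_name[keys[, 2]],
    occupancy = unname(unlist(counts)) / nf,
    n_frames = nf
  )
  dplyr::arrange(out, dplyr::desc(.data$occupancy))
}

.ring_atom_sets <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Aromatic pi-stacking occupancy
#'
#' A stacking event is a ring-centroid distance at or below `dist_cutoff`
#' (0.55 nm); events are classified by the acute interplanar angle as
#' parallel (<= 30 degrees), T-shaped (>= 60 degrees) or intermediate.
#'
#' @param traj A [trajectory()] with aromatic ring atoms (Phe, Tyr, Trp, His).
#' @param dist_cutoff Centroid-centroid cutoff, nm.
#' @param mode `"intermolecular"` (default) or `"all"`.
#' @return Tibble per aromatic residue pair: `occupancy`,
#'   `parallel_fraction`, `tshaped_fraction`, `intermediate_fraction` (of
#'   stacked frames).
#' @export
pi_stacking <- function(traj, dist_cutoff = 0.55,
                        mode = c("intermolecular", "all")) {
  mode <- match.arg(mode)
  top <- traj$topology
  rings <- list()
  for (ch in chain_ids(traj)) {
    sub <- which(top$chain_id == ch)
    for (r in unique(top$residue_index[sub])) {
      rows <- sub[top$residue_index[sub] == r]
      resname <- toupper(top$residue_name[rows[1]])
      want <- .ring_atom_sets[[resname]]
      if (is.null(want)) next
      idx <- rows[match(want, toupper(top$atom_name[rows]))]
      if (anyNA(idx)) {
        abort(sprintf("residue %s%d (chain %s): ring atoms missing",
                      resname, r, ch))
      }
      rings[[length(rings) + 1L]] <- list(
        chain = ch, residue = r, label = paste0(resname, r), atoms = idx
      )
    }
  }
  if (length(rings) < 2L) {
    return(tibble(
      chain_a = character(), ring_a = character(),
      chain_b = character(), ring_b = character(),
      occupancy = numeric(), parallel_fraction = numeric(),
      tshaped_fraction = numeric(), intermediate_fraction = numeric()
    ))
  }
  nf <- n_frames(traj)
  nrings <- length(rings)
  stacked <- par_ct <- tee_ct <- matrix(0L, nrings, nrings)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    cents <- t(vapply(rings, function(rg) colMeans(xyz[rg$atoms, , drop = FALSE]),
                      numeric(3)))
    normals <- t(vapply(rings, function(rg) {
      x <- xyz[rg$atoms, , drop = FALSE]
      xc <- sweep(x, 2, colMeans(x))
      svd(xc)$v[, 3]
    }, numeric(3)))
    box <- if (!is.null(traj$box)) traj$box[f, ]
    dmat <- .pair_dists(cents, cents, box)
    for (i in seq_len(nrings - 1L)) {
      for (j in (i + 1L):nrings) {
        if (mode == "intermolecular" &&
            rings[[i]]$chain == rings[[j]]$chain) next
        if (dmat[i, j] > dist_cutoff) next
        stacked[i, j] <- stacked[i, j] + 1L
        ang <- acos(pmin(1, abs(sum(normals[i, ] * normals[j, ])))) * 180 / pi
        if (ang <= 30) par_ct[i, j] <- par_ct[i, j] + 1L
        else if (ang >= 60) tee_ct[i, j] <- tee_ct[i, j] + 1L
      }
    }
  }
  if (!any(stacked > 0L)) {
    return(tibble(
      chain_a = character(), ring_a = character(),
      chain_b = character(), ring_b = character(),
      occupancy = numeric(), parallel_fraction = numeric(),
      tshaped_fraction = numeric(), intermediate_fraction = numeric()
    ))
  }
  out <- purrr::map_dfr(which(stacked > 0L), function(k) {
    i <- (k - 1L) %% nrings + 1L
    j <- (k - 1L) %/% nrings + 1L
    s <- stacked[i, j]
    tibble(
      chain_a = rings[[i]]$chain, ring_a = rings[[i]]$label,
      chain_b = rings[[j]]$chain, ring_b = rings[[j]]$label,
      occupancy = s / nf,
      parallel_fraction = par_ct[i, j] / s,
      tshaped_fraction = tee_ct[i, j] / s,
      intermediate_fraction = (s - par_ct[i, j] - tee_ct[i, j]) / s
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$occupancy))
}
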