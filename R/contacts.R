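# Residue-residue contact machinery. Distances are minimum heavy-atom
# distances; for residues on different chains the minimum-image convention is
# applied when a periodic box is present, and the pairing is symmetrized:
# d(i, j | A, B) = min(d(i_A, j_B), d(j_A, i_B)), which makes interaction
# maps symmetric in (i, j).

#' Minimum inter-residue distance in one frame
#'
#' Minimum over all heavy-atom pairs of the two residues; minimum-image when
#' the chains differ and a periodic box is present.
#'
#' @param traj A [trajectory()].
#' @param chain_a,chain_b Chain identifiers (as in the topology).
#' @param res_i,res_j Residue indices (1-based).
#' @param frame Frame index.
#' @param heavy_only Drop hydrogens (default TRUE).
#' @return Distance in nm.
#' @export
residue_min_distance <- function(traj, chain_a, res_i, chain_b, res_j, frame,
                                 heavy_only = TRUE) {
  ia <- .atom_indices(traj, chain_a, res_i, heavy_only)
  ib <- .atom_indices(traj, chain_b, res_j, heavy_only)
  xyz <- frame_coords(traj, frame)
  box <- if (!is.null(traj$box) && chain_a != chain_b) traj$box[frame, ]
  .min_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE], box)
}

# Per-frame, per-unit distance matrix for a residue pair.
# mode "intermolecular": units are the n*(n-1)/2 chain pairs with the
# symmetrized distance; mode "intramolecular": units are the n chains.
# Returns n_frames x n_units matrix; unit labels as colnames.
.residue_pair_distances <- function(traj, res_i, res_j, mode, heavy_only = TRUE) {
  chains <- chain_ids(traj)
  nc <- length(chains)
  nf <- n_frames(traj)
  res_idx <- .residue_index_list(traj, heavy_only)
  if (mode == "intramolecular") {
    units <- chains
    out <- matrix(NA_real_, nf, nc, dimnames = list(NULL, units))
    for (f in seq_len(nf)) {
      xyz <- frame_coords(traj, f)
      for (ci in seq_len(nc)) {
        out[f, ci] <- .min_dist(
          xyz[res_idx[[ci]][[res_i]], , drop = FALSE],
          xyz[res_idx[[ci]][[res_j]], , drop = FALSE]
        )
      }
    }
  } else {
    pairs <- utils::combn(seq_len(nc), 2)
    units <- apply(pairs, 2, function(p) paste(chains[p], collapse = "-"))
    out <- matrix(NA_real_, nf, ncol(pairs), dimnames = list(NULL, units))
    for (f in seq_len(nf)) {
      xyz <- frame_coords(traj, f)
      box <- if (!is.null(traj$box)) traj$box[f, ]
      for (u in seq_len(ncol(pairs))) {
        a <- pairs[1, u]; b <- pairs[2, u]
        d1 <- .min_dist(xyz[res_idx[[a]][[res_i]], , drop = FALSE],
                        xyz[res_idx[[b]][[res_j]], , drop = FALSE], box)
        d2 <- if (res_i == res_j) d1 else
          .min_dist(xyz[res_idx[[a]][[res_j]], , drop = FALSE],
                    xyz[res_idx[[b]][[res_i]], , drop = FALSE], box)
        out[f, u] <- min(d1, d2)
      }
    }
  }
  out
}

#' Residue-residue interaction frequency
#'
#' The composite contact statistic used throughout the package to rank
#' residue-pair interactions in multimeric systems:
#' \deqn{score = \frac{N_{pairs}(d \le c)}{\mu_{d \le c}} \times
#'       \frac{N_{frames}}{total frames}}
#' where, for a hexamer, a residue pair can be evaluated over 15 peptide
#' pairs (intermolecular) or 6 chains (intramolecular). `N_pairs` counts the
#' chain pairs (or chains) that come within the cutoff in at least one frame
#' of the whole trajectory; `mu` is the mean of all per-frame, per-pair
#' distances satisfying the cutoff (pooled); `N_frames` counts frames in
#' which at least one pair satisfies the cutoff. When no interaction ever
#' occurs the score is 0 and `mu` is NA.
#'
#' @param traj A [trajectory()].
#' @param res_i,res_j Residue indices (1-based).
#' @param mode `"intermolecular"` or `"intramolecular"`.
#' @param cutoff Interaction cutoff, nm (default 0.6).
#' @return One-row tibble (an interaction record): `res_i`, `res_j`, `mode`,
#'   `n_pairs_interacting`, `mean_interacting_distance`,
#'   `n_frames_interacting`, `total_frames`, `occupancy`, `frequency_score`
#'   (1/nm).
#' @export
interaction_frequency <- function(traj, res_i, res_j,
                                  mode = c("intermolecular", "intramolecular"),
                                  cutoff = 0.6) {
  mode <- match.arg(mode)
  if (cutoff <= 0) abort("cutoff must be > 0")
  if (mode == "intermolecular" && n_chains(traj) < 2L) {
    abort("intermolecular mode needs at least 2 chains")
  }
  d <- .residue_pair_distances(traj, res_i, res_j, mode)
  .score_from_distances(d, res_i, res_j, mode, cutoff)
}

.score_from_distances <- function(d, res_i, res_j, mode, cutoff) {
  within <- d <= cutoff
  n_pairs <- sum(apply(within, 2, any))
  n_frames_hit <- sum(apply(within, 1, any))
  total <- nrow(d)
  if (n_pairs == 0L) {
    mu <- NA_real_
    score <- 0
  } else {
    mu <- mean(d[within])
    score <- (n_pairs / mu) * (n_frames_hit / total)
  }
  tibble(
    res_i = res_i, res_j = res_j, mode = mode,
    n_pairs_interacting = n_pairs,
    mean_interacting_distance = mu,
    n_frames_interacting = n_frames_hit,
    total_frames = total,
    occupancy = n_frames_hit / total,
    frequency_score = score
  )
}

#' Residue-pair interaction occupancy
#'
#' Fraction of frames in which a residue pair is within the cutoff, either
#' pooled over all chain pairs (any pair counts) or reported per chain pair.
#' Occupancies at or above the persistence threshold (0.60: contacts present
#' for more than 60% of the simulation) are flagged persistent.
#'
#' @inheritParams interaction_frequency
#' @param per_chain_pair Report each chain pair separately (default FALSE).
#' @param persistence_threshold Flagging threshold (default 0.60).
#' @return Tibble with columns `res_i`, `res_j`, `unit` (chain pair or
#'   `"any"`), `occupancy`, `persistent`.
#' @export
interaction_occupancy <- function(traj, res_i, res_j,
                                  mode = c("intermolecular", "intramolecular"),
                                  cutoff = 0.6, per_chain_pair = FALSE,
                                  persistence_threshold = 0.60) {
  mode <- match.arg(mode)
  if (cutoff <= 0) abort("cutoff must be > 0")
  d <- .residue_pair_distances(traj, res_i, res_j, mode)
  within <- d <= cutoff
  if (per_chain_pair) {
    occ <- colMeans(within)
    out <- tibble(res_i = res_i, res_j = res_j, unit = colnames(d),
                  occupancy = unname(occ))
  } else {
    out <- tibble(res_i = res_i, res_j = res_j, unit = "any",
                  occupancy = mean(apply(within, 1, any)))
  }
  dplyr::mutate(out, persistent = .data$occupancy >= persistence_threshold)
}

#' Interaction-frequency and occupancy maps over all residue pairs
#'
#' Applies [interaction_frequency()] to every residue pair and returns
#' symmetric matrices of frequency scores and occupancies. Replicates should
#' be concatenated with [bind_frames()] beforehand (composite maps across
#' replicates). In intramolecular mode the diagonal is 0 by convention; in
#' intermolecular mode the diagonal holds same-residue contacts on different
#' chains.
#'
#' @inheritParams interaction_frequency
#' @return Object of class `interaction_map`: list with `score` and
#'   `occupancy` matrices (residue x residue), `mode`, `cutoff`. `tidy()`
#'   returns the long form.
#' @export
interaction_heatmap <- function(traj,
                                mode = c("intermolecular", "intramolecular"),
                                cutoff = 0.6) {
  mode <- match.arg(mode)
  if (cutoff <= 0) abort("cutoff must be > 0")
  nr <- n_residues(traj)
  nc <- n_chains(traj)
  nf <- n_frames(traj)
  res_idx <- .residue_index_list(traj)
  single_atom <- all(vapply(res_idx, function(ch) {
    all(lengths(ch) == 1L)
  }, TRUE))

  if (mode == "intramolecular") {
    units <- seq_len(nc)
    n_units <- nc
  } else {
    pair_mat <- utils::combn(seq_len(nc), 2)
    n_units <- ncol(pair_mat)
  }
  ever <- array(FALSE, c(nr, nr, n_units))
  sum_within <- matrix(0, nr, nr)
  cnt_within <- matrix(0L, nr, nr)
  frames_hit <- matrix(0L, nr, nr)

  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    box <- if (!is.null(traj$box) && mode == "intermolecular") traj$box[f, ]
    hit <- matrix(FALSE, nr, nr)
    for (u in seq_len(n_units)) {
      if (mode == "intramolecular") {
        dmat <- .residue_block_dists(xyz, res_idx[[u]], res_idx[[u]],
                                     NULL, single_atom)
      } else {
        a <- pair_mat[1, u]; b <- pair_mat[2, u]
        dab <- .residue_block_dists(xyz, res_idx[[a]], res_idx[[b]],
                                    box, single_atom)
        dmat <- pmin(dab, t(dab))  # symmetrized chain-pair distance
      }
      w <- dmat <= cutoff
      if (mode == "intramolecular") diag(w) <- FALSE
      if (any(w)) {
        ever[, , u] <- ever[, , u] | w
        sum_within <- sum_within + ifelse(w, dmat, 0)
        cnt_within <- cnt_within + w
        hit <- hit | w
      }
    }
    frames_hit <- frames_hit + hit
  }

  n_pairs <- apply(ever, c(1, 2), sum)
  mu <- ifelse(cnt_within > 0, sum_within / cnt_within, NA_real_)
  score <- ifelse(n_pairs > 0, (n_pairs / mu) * (frames_hit / nf), 0)
  occupancy <- frames_hit / nf
  if (mode == "intramolecular") {
    diag(score) <- 0
    diag(occupancy) <- 0
  }
  labels <- .residue_labels(traj)
  dimnames(score) <- dimnames(occupancy) <- list(labels, labels)
  structure(
    list(score = score, occupancy = occupancy, mode = mode, cutoff = cutoff),
    class = "interaction_map"
  )
}

# nr x nr matrix of min distances between residues of two chains (or within
# one chain when the index lists are identical)
.residue_block_dists <- function(xyz, idx_a, idx_b, box, single_atom) {
  nr_a <- length(idx_a); nr_b <- length(idx_b)
  if (single_atom) {
    xa <- xyz[unlist(idx_a), , drop = FALSE]
    xb <- xyz[unlist(idx_b), , drop = FALSE]
    return(.pair_dists(xa, xb, box))
  }
  out <- matrix(NA_real_, nr_a, nr_b)
  all_a <- xyz[unlist(idx_a), , drop = FALSE]
  all_b <- xyz[unlist(idx_b), , drop = FALSE]
  big <- .pair_dists(all_a, all_b, box)
  ra <- rep(seq_len(nr_a), lengths(idx_a))
  rb <- rep(seq_len(nr_b), lengths(idx_b))
  for (i in seq_len(nr_a)) {
    rows <- ra == i
    for (j in seq_len(nr_b)) {
      out[i, j] <- min(big[rows, rb == j])
    }
  }
  out
}

.residue_labels <- function(traj) {
  top <- traj$topology
  first_chain <- top[top$chain_id == chain_ids(traj)[1], ]
  lab <- first_chain[!duplicated(first_chain$residue_index), ]
  paste0(lab$residue_name, lab$residue_index)
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf(
    "<interaction_map> %s, cutoff %.2f nm, %d x %d residues; max score %.3g nm^-1\n",
    x$mode, x$cutoff, nrow(x$score), ncol(x$score), max(x$score)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.interaction_map <- function(x, ...) {
  nr <- nrow(x$score)
  labels <- rownames(x$score)
  grid <- expand.grid(i = seq_len(nr), j = seq_len(nr))
  tibble(
    res_i = grid$i, res_j = grid$j,
    label_i = labels[grid$i], label_j = labels[grid$j],
    frequency_score = as.vector(x$score),
    occupancy = as.vector(x$occupancy),
    mode = x$mode
  )
}

#' Write an interaction map to CSV or JSON
#'
#' @param map An `interaction_map`.
#' @param path Output path; `.csv` writes the long form, `.json` the labelled
#'   matrices.
#' @export
write_interaction_map <- function(map, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(mode = map$mode, cutoff = map$cutoff,
           residues = rownames(map$score),
           score = map$score, occupancy = map$occupancy),
      path, digits = NA, auto_unbox = TRUE
    )
  } else {
    write_table(tidy(map), path, "csv")
  }
  invisible(path)
}
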