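#' Assign secondary structure from backbone dihedrals
#'
#' Fallback assigner for full-atom trajectories without accompanying DSSP
#' output: each residue is labelled from its (phi, psi) backbone dihedrals
#' using rectangular Ramachandran regions. Strand (E): phi in [-180, -45] and
#' psi in [45, 225 mod 360] (i.e. psi >= 45 or psi <= -135). Helix (H): phi in
#' [-100, -30] and psi in [-67, -7]. Everything else, and chain-terminal
#' residues with an undefined dihedral, is coil (C). DSSP-file ingestion
#' ([load_dssp_table()]) is the fidelity path; this assigner exists so the
#' pipeline can run on bare coordinates.
#'
#' @param traj A full-atom [trajectory()] with backbone N, CA, C atoms.
#' @return An [ss_series()] with `source = "dihedral_internal"`.
#' @export
assign_ss_dihedral <- function(traj) {
  top <- traj$topology
  chains <- chain_ids(traj)
  nr_per_chain <- vapply(chains, function(ch) {
    max(top$residue_index[top$chain_id == ch])
  }, 1L)
  nr <- max(nr_per_chain)
  bb <- lapply(chains, function(ch) {
    lapply(seq_len(nr_per_chain[[ch]]), function(r) {
      sel <- top$chain_id == ch & top$residue_index == r
      idx <- c(
        N = which(sel & toupper(top$atom_name) == "N")[1],
        CA = which(sel & toupper(top$atom_name) == "CA")[1],
        C = which(sel & toupper(top$atom_name) == "C")[1]
      )
      if (anyNA(idx)) {
        abort(paste0(
          "backbone N/CA/C atoms missing (chain ", ch, ", residue ", r,
          "); supply DSSP files or synthetic labels for coarse-grained input"
        ))
      }
      idx
    })
  })
  names(bb) <- chains
  arr <- array("C", c(n_frames(traj), length(chains), nr))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    for (ci in seq_along(chains)) {
      nres <- nr_per_chain[[ci]]
      for (r in seq_len(nres)) {
        if (r == 1L || r == nres) next  # undefined phi or psi -> coil
        a <- bb[[ci]]
        phi <- .dihedral(xyz[a[[r - 1]]["C"], ], xyz[a[[r]]["N"], ],
                         xyz[a[[r]]["CA"], ], xyz[a[[r]]["C"], ])
        psi <- .dihedral(xyz[a[[r]]["N"], ], xyz[a[[r]]["CA"], ],
                         xyz[a[[r]]["C"], ], xyz[a[[r + 1]]["N"], ])
        arr[f, ci, r] <- .ss_from_phipsi(phi, psi)
      }
    }
  }
  ss_series(arr, source = "dihedral_internal")
}

.ss_from_phipsi <- function(phi, psi) {
  if (phi >= -180 && phi <= -45 && (psi >= 45 || psi <= -135)) return("E")
  if (phi >= -100 && phi <= -30 && psi >= -67 && psi <= -7) return("H")
  "C"
}

#' Overall secondary-structure composition
#'
#' Percentages of coil, beta sheet and helix pooled over all chains, residues
#' and the selected frame window.
#'
#' @param series An [ss_series()].
#' @param window Optional frame index vector (default: all frames).
#' @return One-row tibble with columns `coil`, `sheet`, `helix` (percent,
#'   summing to 100) and `n_frames`.
#' @export
ss_composition <- function(series, window = NULL) {
  d <- dim(series)
  window <- window %||% seq_len(d[1])
  if (!length(window)) abort("empty frame window")
  lab <- series[window, , , drop = FALSE]
  n <- length(lab)
  tibble(
    coil = 100 * sum(lab == "C") / n,
    sheet = 100 * sum(lab == "E") / n,
    helix = 100 * sum(lab == "H") / n,
    n_frames = length(window)
  )
}

#' Per-residue secondary-structure propensity
#'
#' Fraction of frames each (chain, residue) spends in helix, strand and coil.
#'
#' @param series An [ss_series()].
#' @return Tibble with columns `chain`, `residue`, `helix`, `sheet`, `coil`
#'   (fractions summing to 1 per row).
#' @export
ss_propensity <- function(series) {
  d <- dim(series)
  grid <- expand.grid(chain = seq_len(d[2]), residue = seq_len(d[3]))
  res <- purrr::pmap_dfr(grid, function(chain, residue) {
    lab <- series[, chain, residue]
    tibble(
      chain = chain, residue = residue,
      helix = mean(lab == "H"), sheet = mean(lab == "E"),
      coil = mean(lab == "C")
    )
  })
  dplyr::arrange(res, .data$chain, .data$residue)
}

#' Per-frame beta-strand fraction
#'
#' Fraction of all residues (all chains pooled) labelled E in each frame —
#' the strand-content axis of the conformational landscape.
#'
#' @param series An [ss_series()].
#' @return Numeric vector, one value per frame.
#' @export
strand_fraction <- function(series) {
  apply(unclass(series) == "E", 1, mean)
}

#' Principal-component analysis of secondary-structure content
#'
#' Each frame is encoded as a binary one-hot vector over
#' (chain, residue, state) triples, mean-centered, and projected onto the
#' first two principal components. Component signs are fixed by making each
#' component's largest-magnitude loading positive, so projections are
#' reproducible across frame orderings.
#'
#' @param series An [ss_series()] with at least 3 frames.
#' @return An object of class `ss_pca`: list with `projections` (tibble:
#'   `frame`, `PC1`, `PC2`), `explained_variance` (proportions for PC1, PC2),
#'   and `degenerate` (TRUE when the series is constant; projections are then
#'   all zero). Use `tidy()`/`glance()` to extract.
#' @export
ss_pca <- function(series) {
  d <- dim(series)
  if (d[1] < 3L) abort("ss_pca needs at least 3 frames")
  states <- c("H", "E", "C")
  x <- matrix(0, d[1], d[2] * d[3] * 3L)
  col <- 0L
  for (ch in seq_len(d[2])) {
    for (r in seq_len(d[3])) {
      for (s in states) {
        col <- col + 1L
        x[, col] <- as.numeric(series[, ch, r] == s)
      }
    }
  }
  keep_var <- apply(x, 2, var)
  if (all(keep_var == 0)) {
    warn("constant secondary-structure series: PCA is degenerate")
    return(structure(list(
      projections = tibble(frame = seq_len(d[1]), PC1 = 0, PC2 = 0),
      explained_variance = c(PC1 = NA_real_, PC2 = NA_real_),
      degenerate = TRUE
    ), class = "ss_pca"))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    # one-hot features give exact |loading| ties; anchor on the lowest tied
    # index so the sign is reproducible across frame orderings
    mx <- max(abs(rot[, j]))
    anchor <- which(abs(rot[, j]) >= mx * (1 - 1e-9))[1]
    if (rot[anchor, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    projections = tibble(
      frame = seq_len(d[1]),
      PC1 = scores[, 1],
      PC2 = if (k >= 2L) scores[, 2] else 0
    ),
    explained_variance = c(PC1 = ev[1], PC2 = if (k >= 2L) ev[2] else 0),
    loadings = rot,
    degenerate = FALSE
  ), class = "ss_pca")
}

#' @export
print.ss_pca <- function(x, ...) {
  cat(sprintf(
    "<ss_pca> %d frames%s; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$projections), if (x$degenerate) " (degenerate)" else "",
    100 * x$explained_variance[1], 100 * x$explained_variance[2]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ss_pca <- function(x, ...) x$projections

#' @exportS3Method generics::glance
glance.ss_pca <- function(x, ...) {
  tibble(
    n_frames = nrow(x$projections),
    var_pc1 = x$explained_variance[[1]],
    var_pc2 = x$explained_variance[[2]],
    degenerate = x$degenerate
  )
}

#' Pairwise Hamming-distance variability of a residue window
#'
#' Quantifies secondary-structure variability of a residue window (for the
#' C-terminal analysis, residues 28-42): the label strings of every pair of
#' frames are compared and the number of differing positions recorded. All
#' frames (pooled across replicates by the caller) are paired; when the pair
#' count exceeds `max_pairs` a seeded uniform subsample is used.
#'
#' @param series An [ss_series()].
#' @param chain Chain index whose labels are compared (default 1); `NULL`
#'   pools every chain as separate label sequences.
#' @param residue_range Integer range of residues (1-based), e.g. `28:42`.
#' @param max_pairs Cap on evaluated frame pairs (default 1e6).
#' @param seed Seed for the subsample draw.
#' @return One-row tibble: `mean`, `sd`, `n_pairs`, `window_length`.
#' @export
hamming_variability <- function(series, chain = 1L, residue_range,
                                max_pairs = 1e6, seed = 1L) {
  d <- dim(series)
  if (!length(residue_range)) abort("empty residue window")
  if (min(residue_range) < 1L || max(residue_range) > d[3]) {
    abort("residue_range outside chain length")
  }
  chains <- if (is.null(chain)) seq_len(d[2]) else chain
  # rows = observation strings (frames x selected chains), cols = window
  obs <- do.call(rbind, lapply(chains, function(ch) {
    matrix(series[, ch, residue_range], d[1], length(residue_range))
  }))
  n <- nrow(obs)
  if (n < 2L) abort("need at least 2 frames")
  total_pairs <- n * (n - 1) / 2
  if (total_pairs <= max_pairs) {
    dists <- .hamming_all_pairs(obs)
  } else {
    dists <- withr::with_seed(seed, {
      i <- sample.int(n, max_pairs, replace = TRUE)
      j <- sample.int(n - 1L, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered off-diagonal pairs
      dd <- integer(max_pairs)
      for (col in seq_len(ncol(obs))) {
        dd <- dd + (obs[i, col] != obs[j, col])
      }
      dd
    })
  }
  tibble(
    mean = mean(dists), sd = sd(dists),
    n_pairs = length(dists), window_length = length(residue_range)
  )
}

.hamming_all_pairs <- function(obs) {
  n <- nrow(obs)
  acc <- matrix(0L, n, n)
  for (col in seq_len(ncol(obs))) {
    acc <- acc + outer(obs[, col], obs[, col], "!=")
  }
  acc[upper.tri(acc)]
}

#' Hamming distance between two label strings
#'
#' @param a,b Equal-length character vectors (or single strings).
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) abort("strings must have equal length")
  sum(a != b)
}

#' Intermolecular beta-strand pairing counts
#'
#' Counts, per frame, residue pairs on different chains where both residues
#' are labelled E and their minimum inter-atomic distance is within `cutoff`;
#' totals per residue aggregate over partners and frames.
#'
#' @param series An [ss_series()] whose dimensions match `traj`.
#' @param traj A [trajectory()].
#' @param cutoff Contact cutoff, nm (default 0.6).
#' @return List with `per_frame` (tibble: `frame`, `count`) and
#'   `per_residue` (tibble: `residue`, `total`).
#' @export
intermolecular_strand_pairs <- function(series, traj, cutoff = 0.6) {
  d <- dim(series)
  if (d[1] != n_frames(traj) || d[2] != n_chains(traj) ||
      d[3] != n_residues(traj)) {
    abort("series dimensions do not match the trajectory")
  }
  nc <- d[2]; nr <- d[3]
  res_idx <- .residue_index_list(traj)
  counts <- integer(d[1])
  per_res <- integer(nr)
  for (f in seq_len(d[1])) {
    is_e <- unclass(series)[f, , ] == "E"  # chains x residues
    if (sum(is_e) < 2L) next
    xyz <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ]
    for (ca in seq_len(nc - 1L)) {
      ra <- which(is_e[ca, ])
      if (!length(ra)) next
      for (cb in (ca + 1L):nc) {
        rb <- which(is_e[cb, ])
        if (!length(rb)) next
        for (i in ra) {
          xa <- xyz[res_idx[[ca]][[i]], , drop = FALSE]
          for (j in rb) {
            dmin <- .min_dist(xa, xyz[res_idx[[cb]][[j]], , drop = FALSE], box)
            if (dmin <= cutoff) {
              counts[f] <- counts[f] + 1L
              per_res[i] <- per_res[i] + 1L
              per_res[j] <- per_res[j] + 1L
            }
          }
        }
      }
    }
  }
  list(
    per_frame = tibble(frame = seq_len(d[1]), count = counts),
    per_residue = tibble(residue = seq_len(nr), total = per_res)
  )
}

# list[[chain_pos]][[residue]] -> heavy-atom indices
.residue_index_list <- function(traj, heavy_only = TRUE) {
  top <- traj$topology
  chains <- chain_ids(traj)
  keep <- if (heavy_only) toupper(top$element) != "H" else rep(TRUE, nrow(top))
  lapply(chains, function(ch) {
    nres <- max(top$residue_index[top$chain_id == ch])
    lapply(seq_len(nres), function(r) {
      which(top$chain_id == ch & top$residue_index == r & keep)
    })
  })
}
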