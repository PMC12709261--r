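#' Configuration for the synthetic hexamer-trajectory generator
#'
#' Collects every knob of the coarse-grained (one bead per residue) generator
#' in one validated object. Defaults emulate the study conditions the package
#' targets: six identical peptide chains sampled over a 2 microsecond window,
#' placed at least 1.4 nm apart (outside a typical long-range interaction
#' cutoff) in a 12.23 nm cubic box, associating into a single cluster over the
#' first 30% of frames (the window after which the oligomer radius of gyration
#' is treated as converged), with per-chain target radius of gyration 1.09 nm.
#'
#' @param n_chains Number of identical chains (default 6, a hexamer).
#' @param n_residues Residues per chain (default 42).
#' @param n_frames Number of frames (default 2000, i.e. 1 ns sampling over
#'   2 us).
#' @param bond_length Virtual C-alpha bond length, nm (default 0.38).
#' @param bead_radius Bead radius, nm (default 0.19).
#' @param box_edge Cubic box edge, nm (default 12.23).
#' @param min_initial_separation Minimum inter-chain bead distance at the
#'   first frame, nm (default 1.4).
#' @param target_rg Per-chain target radius of gyration, nm (default 1.09).
#' @param association_schedule Data frame with columns `chain` and `frame`
#'   (1-based; frame >= 2): when each chain joins the bound cluster. Chain 1
#'   seeds the cluster and needs no entry. Default: chains 2..n join at
#'   frames evenly spaced over the first 30% of the trajectory.
#' @param contact_spec Data frame with columns `res_i`, `res_j`, `chain_a`,
#'   `chain_b`, `p`: residue pairs whose per-frame contact events (bead
#'   distance <= 0.6 nm) are drawn independently with probability `p`.
#' @param ss_transition 3x3 row-stochastic matrix over states (H, E, C) for
#'   the per-residue secondary-structure Markov chain. Default has stationary
#'   distribution (H, E, C) = (0.005, 0.40, 0.595) — strand-biased,
#'   helix-poor — with persistence 0.9.
#' @param sequence One-letter sequence for the chains; default is chosen by
#'   length (42 -> amyloid-beta 42, 31 -> beta-endorphin 31, else a generic
#'   cycle).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_chains = 6L, n_residues = 42L, n_frames = 2000L,
                             bond_length = 0.38, bead_radius = 0.19,
                             box_edge = 12.23, min_initial_separation = 1.4,
                             target_rg = 1.09,
                             association_schedule = NULL,
                             contact_spec = NULL,
                             ss_transition = NULL,
                             sequence = NULL,
                             seed = 1L) {
  stopifnot(n_chains >= 1L, n_residues >= 2L, n_frames >= 1L)
  if (min_initial_separation < 0) abort("min_initial_separation must be >= 0")
  if (is.null(association_schedule)) {
    if (n_chains > 1L && n_frames >= 3L) {
      frames <- round(seq(0.05, 0.30, length.out = n_chains - 1L) * n_frames)
      association_schedule <- tibble(
        chain = 2L:n_chains, frame = pmax(2L, as.integer(frames))
      )
    } else {
      association_schedule <- tibble(chain = integer(), frame = integer())
    }
  } else {
    association_schedule <- as_tibble(association_schedule)
    stopifnot(all(c("chain", "frame") %in% names(association_schedule)))
  }
  if (nrow(association_schedule)) {
    if (any(association_schedule$frame > n_frames) ||
        any(association_schedule$frame < 2L)) {
      abort("association frames must lie in [2, n_frames]")
    }
    if (any(!association_schedule$chain %in% seq_len(n_chains)[-1])) {
      abort("association chains must be in 2..n_chains")
    }
  }
  if (is.null(contact_spec)) {
    contact_spec <- tibble(res_i = integer(), res_j = integer(),
                           chain_a = integer(), chain_b = integer(),
                           p = numeric())
  } else {
    contact_spec <- as_tibble(contact_spec)
    stopifnot(all(c("res_i", "res_j", "chain_a", "chain_b", "p") %in%
                    names(contact_spec)))
    if (any(contact_spec$p < 0 | contact_spec$p > 1)) {
      abort("contact probabilities must lie in [0, 1]")
    }
    if (any(contact_spec$res_i > n_residues | contact_spec$res_j > n_residues |
            contact_spec$res_i < 1 | contact_spec$res_j < 1)) {
      abort("contact_spec residue index out of range")
    }
    if (any(contact_spec$chain_a == contact_spec$chain_b)) {
      abort("contact_spec is intermolecular: chain_a must differ from chain_b")
    }
  }
  if (is.null(ss_transition)) {
    ss_transition <- default_ss_transition()
  }
  .check_stochastic_matrix(ss_transition)
  if (is.null(sequence)) sequence <- .default_sequence(n_residues)
  if (nchar(sequence) != n_residues) {
    abort("sequence length must equal n_residues")
  }
  structure(
    list(
      n_chains = as.integer(n_chains), n_residues = as.integer(n_residues),
      n_frames = as.integer(n_frames), bond_length = bond_length,
      bead_radius = bead_radius, box_edge = box_edge,
      min_initial_separation = min_initial_separation, target_rg = target_rg,
      association_schedule = association_schedule,
      contact_spec = contact_spec, ss_transition = ss_transition,
      sequence = sequence, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Default strand-biased secondary-structure transition matrix
#'
#' Row-stochastic 3x3 matrix over (H, E, C) with stationary distribution
#' `stationary` and single-step persistence `persistence` (each row is
#' `persistence * identity + (1 - persistence) * stationary`, so the
#' stationary distribution is exact by construction).
#'
#' @param stationary Named or positional probabilities for (H, E, C).
#' @param persistence Probability weight on remaining in the current state.
#' @return 3x3 row-stochastic matrix with dimnames (H, E, C).
#' @export
default_ss_transition <- function(stationary = c(H = 0.005, E = 0.40, C = 0.595),
                                  persistence = 0.9) {
  stopifnot(length(stationary) == 3, all(stationary >= 0),
            persistence >= 0, persistence < 1)
  p <- stationary / sum(stationary)
  m <- persistence * diag(3) + (1 - persistence) * matrix(p, 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("H", "E", "C"), c("H", "E", "C"))
  m
}

.check_stochastic_matrix <- function(m) {
  if (!is.matrix(m) || any(dim(m) != c(3L, 3L))) {
    abort("ss_transition must be a 3x3 matrix")
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    abort("ss_transition rows must be non-negative and sum to 1 (tol 1e-12)")
  }
  invisible(TRUE)
}

#' Stationary distribution of a 3-state transition matrix
#'
#' @param ss_transition Row-stochastic 3x3 matrix over (H, E, C).
#' @return Named probability vector (H, E, C) summing to 1.
#' @export
ss_stationary <- function(ss_transition) {
  .check_stochastic_matrix(ss_transition)
  e <- eigen(t(ss_transition))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  setNames(v / sum(v), c("H", "E", "C"))
}

# ---------------------------------------------------------------------------

#' Generate a single self-avoiding chain with a target radius of gyration
#'
#' Builds a self-avoiding virtual C-alpha walk (fixed bond length, hard-sphere
#' beads) and compacts or expands it by accept/reject pivot Monte-Carlo moves
#' until its radius of gyration falls within 10% of `target_rg`.
#'
#' @param n_residues Number of beads (>= 2).
#' @param target_rg Target radius of gyration, nm. Must lie between the
#'   close-packing minimum and the straight-rod maximum for the bead count.
#' @param seed Integer seed.
#' @param bond_length Bond length, nm.
#' @param bead_radius Bead radius, nm; non-bonded beads are kept at least two
#'   radii apart.
#' @param max_iter Pivot-move budget before declaring the target unreachable.
#' @return `n_residues x 3` coordinate matrix (nm) with attribute `rg`
#'   (realized radius of gyration).
#' @export
generate_chain <- function(n_residues, target_rg, seed,
                           bond_length = 0.38, bead_radius = 0.19,
                           max_iter = 20000L) {
  stopifnot(n_residues >= 2L)
  withr::with_seed(seed, {
    if (n_residues == 2L) {
      # two-bead Rg is bond_length/2 regardless of target
      x <- rbind(c(0, 0, 0), c(bond_length, 0, 0))
      attr(x, "rg") <- bond_length / 2
      return(x)
    }
    rng <- .rg_bounds(n_residues, bond_length, bead_radius)
    if (target_rg < rng[1] || target_rg > rng[2]) {
      abort(sprintf(
        "target_rg %.3f nm unreachable for %d beads (feasible ~[%.3f, %.3f] nm)",
        target_rg, n_residues, rng[1], rng[2]
      ), class = "oligotraj_infeasible_rg")
    }
    x <- .self_avoiding_walk(n_residues, bond_length, bead_radius)
    x <- .pivot_to_target_rg(x, target_rg, bond_length, bead_radius, max_iter)
    x
  })
}

.rg_bounds <- function(n, bond, radius) {
  # compact limit: beads close-packed (fraction ~0.64) in a sphere
  r_sphere <- radius * (n / 0.64)^(1 / 3)
  rg_min <- sqrt(3 / 5) * r_sphere
  rg_max <- bond * sqrt((n^2 - 1) / 12)  # straight rod of n beads
  c(rg_min, rg_max)
}

.self_avoiding_walk <- function(n, bond, radius, max_restart = 200L) {
  min_sep2 <- (2 * radius)^2 - 1e-12
  for (attempt in seq_len(max_restart)) {
    x <- matrix(0, n, 3)
    x[2, ] <- bond * .runif_sphere(1L)
    ok <- TRUE
    for (k in 3:n) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- x[k - 1, ] + bond * as.numeric(.runif_sphere(1L))
        d2 <- rowSums(sweep(x[1:(k - 2), , drop = FALSE], 2, cand)^2)
        if (all(d2 >= min_sep2)) {
          x[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(x)
  }
  abort("failed to build self-avoiding walk")
}

.chain_rg <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  sqrt(sum(xc * xc) / nrow(x))
}

.self_avoidance_ok <- function(x, radius) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  mask <- abs(row(d) - col(d)) > 1L
  all(d[mask] >= 2 * radius - 1e-12)
}

.pivot_to_target_rg <- function(x, target, bond, radius, max_iter) {
  n <- nrow(x)
  cur_rg <- .chain_rg(x)
  tol <- 0.05 * target           # aim inside the 10% contract with margin
  for (iter in seq_len(max_iter)) {
    if (abs(cur_rg - target) <= tol) break
    j <- sample(2:(n - 1), 1L)
    rot <- .rotation_matrix(as.numeric(.runif_sphere(1L)),
                            stats::rnorm(1, 0, 0.6))
    cand <- x
    tailseg <- (j + 1):n
    cand[tailseg, ] <- sweep(
      sweep(cand[tailseg, , drop = FALSE], 2, cand[j, ]) %*% t(rot),
      2, cand[j, ], "+"
    )
    new_rg <- .chain_rg(cand)
    improves <- abs(new_rg - target) < abs(cur_rg - target)
    if ((improves || stats::runif(1) < 0.02) &&
        .self_avoidance_ok(cand, radius)) {
      x <- cand
      cur_rg <- new_rg
    }
  }
  if (abs(cur_rg - target) > 0.10 * target) {
    abort(sprintf(
      "pivot compaction did not reach target_rg %.3f (achieved %.3f)",
      target, cur_rg
    ), class = "oligotraj_infeasible_rg")
  }
  attr(x, "rg") <- cur_rg
  x
}

# ---------------------------------------------------------------------------

#' Generate a synthetic multi-chain association trajectory
#'
#' Produces a coarse-grained hexamer-style trajectory with known ground truth:
#' chains start at least `min_initial_separation` apart, perform rigid-body
#' diffusion with small per-bead jitter, and join a growing bound cluster at
#' their scheduled association frame (each newly bound chain keeps an anchor
#' bead within 0.6 nm of the previously bound chain's anchor). Designated
#' residue pairs in `contact_spec` have their per-frame contact events (bead
#' distance <= 0.6 nm) drawn independently with the requested probability, so
#' downstream occupancy estimators can be validated against exact binomial
#' expectations. The first frame is the initial placement: no association or
#' contact events are applied there.
#'
#' @param config A [generator_config()].
#' @return List with elements `trajectory` (a [trajectory()]) and `truth`
#'   (class `synthetic_truth`): contact probabilities with realized per-frame
#'   event fractions, the stationary secondary-structure distribution of the
#'   configured transition matrix, realized per-chain radii of gyration, and
#'   the association schedule.
#' @export
generate_hexamer_trajectory <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, .generate_hexamer_impl(config))
}

.generate_hexamer_impl <- function(cfg) {
  nc <- cfg$n_chains; nr <- cfg$n_residues; nf <- cfg$n_frames
  chains <- vector("list", nc)
  rg_real <- numeric(nc)
  for (k in seq_len(nc)) {
    # derived sub-seed keeps the whole call reproducible from one seed
    sub_seed <- (cfg$seed * 131L + k * 7919L) %% 2147483647L
    ch <- generate_chain(nr, cfg$target_rg, sub_seed,
                         bond_length = cfg$bond_length,
                         bead_radius = cfg$bead_radius)
    rg_real[k] <- attr(ch, "rg")
    chains[[k]] <- sweep(ch, 2, colMeans(ch))  # center at origin
  }

  centers <- .place_chain_centers(chains, cfg)
  pos <- lapply(seq_len(nc), function(k) sweep(chains[[k]], 2, centers[k, ], "+"))

  # anchor bead per chain: a residue not referenced by any contact spec
  spec <- cfg$contact_spec
  used <- unique(c(spec$res_i, spec$res_j))
  anchor_candidates <- setdiff(seq_len(nr), used)
  if (!length(anchor_candidates)) {
    abort("contact_spec references every residue; no anchor bead available")
  }
  anchor <- anchor_candidates[which.min(abs(anchor_candidates - (nr + 1) / 2))]

  assoc_frame <- rep(NA_integer_, nc)
  assoc_frame[1] <- 1L
  if (nrow(cfg$association_schedule)) {
    assoc_frame[cfg$association_schedule$chain] <- cfg$association_schedule$frame
  }
  # association order: who each chain daisy-chains onto
  bound_order <- order(assoc_frame, na.last = TRUE)
  parent <- rep(NA_integer_, nc)
  for (i in seq_along(bound_order)) {
    k <- bound_order[i]
    if (!is.na(assoc_frame[k]) && k != 1L) parent[k] <- bound_order[i - 1L]
  }

  coords <- array(NA_real_, c(nf, nc * nr, 3L))
  events <- matrix(NA, nf, nrow(spec))

  # persistent rigid-body state: each frame is a rigid transform of the
  # chain's reference conformation plus fresh (non-accumulating) bead
  # jitter, so chain shape and Rg stay at their generated values
  ref_conf <- chains
  rot_state <- replicate(nc, diag(3), simplify = FALSE)
  ctr_state <- centers
  frame_pos <- vector("list", nc)

  store <- function(frame) {
    for (k in seq_len(nc)) {
      coords[frame, (k - 1L) * nr + seq_len(nr), ] <<- frame_pos[[k]]
    }
  }
  frame_pos <- pos
  store(1L)
  if (nrow(spec)) events[1L, ] <- FALSE

  sigma_free <- 0.05; sigma_bound <- 0.02; sigma_bead <- 0.005
  for (t in seq_len(nf)[-1]) {
    for (k in seq_len(nc)) {
      bound <- !is.na(assoc_frame[k]) && t >= assoc_frame[k]
      sig <- if (bound) sigma_bound else sigma_free
      d_rot <- .rotation_matrix(as.numeric(.runif_sphere(1L)),
                                stats::rnorm(1, 0, 0.05))
      rot_state[[k]] <- d_rot %*% rot_state[[k]]
      ctr <- ctr_state[k, ] + stats::rnorm(3, 0, sig)
      # reflect the centre back into the box
      ctr <- ifelse(ctr < 0, -ctr, ifelse(ctr > cfg$box_edge,
                                          2 * cfg$box_edge - ctr, ctr))
      ctr_state[k, ] <- ctr
      frame_pos[[k]] <- sweep(ref_conf[[k]] %*% t(rot_state[[k]]), 2, ctr, "+") +
        matrix(stats::rnorm(nr * 3, 0, sigma_bead), nr, 3)
    }
    # keep bound chains daisy-chained via anchor beads (the shift persists
    # through the centre state so chains stay with the cluster)
    for (k in bound_order) {
      if (k == 1L || is.na(assoc_frame[k]) || t < assoc_frame[k]) next
      p <- parent[k]
      ref <- frame_pos[[p]][anchor, ]
      v <- frame_pos[[k]][anchor, ] - ref
      d <- sqrt(sum(v * v))
      if (d < 0.40 || d > 0.58) {
        u <- if (d > 1e-9) v / d else as.numeric(.runif_sphere(1L))
        shift <- (ref + u * stats::runif(1, 0.45, 0.55)) -
          frame_pos[[k]][anchor, ]
        frame_pos[[k]] <- sweep(frame_pos[[k]], 2, shift, "+")
        ctr_state[k, ] <- ctr_state[k, ] + shift
      }
    }
    # scheduled contact events override the involved beads (frame-local)
    if (nrow(spec)) {
      for (s in seq_len(nrow(spec))) {
        a <- spec$chain_a[s]; b <- spec$chain_b[s]
        i <- spec$res_i[s]; j <- spec$res_j[s]
        ev <- stats::runif(1) < spec$p[s]
        events[t, s] <- ev
        ref <- frame_pos[[a]][i, ]
        v <- frame_pos[[b]][j, ] - ref
        d <- sqrt(sum(v * v))
        u <- if (d > 1e-9) v / d else as.numeric(.runif_sphere(1L))
        if (ev) {
          frame_pos[[b]][j, ] <- ref + u * stats::runif(1, 0.42, 0.58)
        } else if (d <= 0.62) {
          frame_pos[[b]][j, ] <- ref + u * stats::runif(1, 0.65, 0.95)
        }
        # the downstream residue-pair distance is symmetric in the two
        # orientations, so the mirrored bead pair (j on a, i on b) must be
        # kept out of contact for the event draw to control the statistic
        if (i != j) {
          ref2 <- frame_pos[[a]][j, ]
          v2 <- frame_pos[[b]][i, ] - ref2
          d2 <- sqrt(sum(v2 * v2))
          if (d2 <= 0.62) {
            u2 <- if (d2 > 1e-9) v2 / d2 else as.numeric(.runif_sphere(1L))
            frame_pos[[b]][i, ] <- ref2 + u2 * stats::runif(1, 0.65, 0.95)
          }
        }
      }
    }
    store(t)
  }

  res_names <- sequence_to_residues(cfg$sequence)
  topology <- tibble(
    chain_id = rep(LETTERS[seq_len(nc)], each = nr),
    residue_index = rep(seq_len(nr), nc),
    residue_name = rep(res_names, nc),
    atom_name = "CA",
    element = "C",
    vdw_radius = cfg$bead_radius,
    mass = NA_real_
  )
  dt_ps <- if (nf > 1) 2e6 / (nf - 1) else 0  # 2 us window
  traj <- trajectory(coords, topology,
                     frame_times = (seq_len(nf) - 1) * dt_ps,
                     box = rep(cfg$box_edge, 3))

  truth <- structure(list(
    contacts = if (nrow(spec)) {
      dplyr::mutate(spec,
        realized_occupancy = colMeans(events[-1L, , drop = FALSE]))
    } else spec,
    strand_fraction = ss_stationary(cfg$ss_transition),
    rg_per_chain = rg_real,
    association_schedule = cfg$association_schedule,
    anchor_residue = anchor,
    seed = cfg$seed
  ), class = "synthetic_truth")

  list(trajectory = traj, truth = truth)
}

.place_chain_centers <- function(chains, cfg, max_tries = 5000L) {
  nc <- length(chains)
  extents <- vapply(chains, function(x) max(sqrt(rowSums(x^2))), 1)
  margin <- max(extents) + 0.2
  lo <- margin; hi <- cfg$box_edge - margin
  if (hi <= lo) abort("box too small to place chains", class = "oligotraj_placement")
  centers <- matrix(NA_real_, nc, 3)
  placed_beads <- NULL
  for (k in seq_len(nc)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- stats::runif(3, lo, hi)
      beads <- sweep(chains[[k]], 2, ctr, "+")
      if (is.null(placed_beads) ||
          .min_dist(beads, placed_beads) >= cfg$min_initial_separation + 0.05) {
        centers[k, ] <- ctr
        placed_beads <- rbind(placed_beads, beads)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place chain %d at separation >= %.2f nm after %d tries",
        k, cfg$min_initial_separation, max_tries
      ), class = "oligotraj_placement")
    }
  }
  centers
}

# ---------------------------------------------------------------------------

#' Generate a synthetic secondary-structure series
#'
#' Simulates, independently for every (chain, residue), a 3-state Markov chain
#' over labels (H, E, C) with the given row-stochastic transition matrix,
#' started from its stationary distribution.
#'
#' @param n_frames,n_chains,n_residues Dimensions of the series.
#' @param ss_transition 3x3 row-stochastic matrix over (H, E, C).
#' @param seed Integer seed.
#' @return An `ss_series`: character array `n_frames x n_chains x n_residues`
#'   with values in {H, E, C} and attribute `source = "synthetic"`.
#' @export
generate_ss_series <- function(n_frames, n_chains, n_residues, ss_transition,
                               seed) {
  .check_stochastic_matrix(ss_transition)
  states <- c("H", "E", "C")
  withr::with_seed(seed, {
    pi0 <- ss_stationary(ss_transition)
    n_series <- n_chains * n_residues
    cum <- t(apply(ss_transition, 1, cumsum))
    cum0 <- cumsum(pi0)
    lab <- matrix(0L, n_frames, n_series)
    u <- stats::runif(n_series)
    lab[1, ] <- 1L + (u > cum0[1]) + (u > cum0[2])
    if (n_frames > 1) {
      for (t in 2:n_frames) {
        u <- stats::runif(n_series)
        prev <- lab[t - 1, ]
        lab[t, ] <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2])
      }
    }
    arr <- array(states[lab], c(n_frames, n_chains, n_residues))
    ss_series(arr, source = "synthetic")
  })
}

#' Construct a secondary-structure series object
#'
#' @param labels Character array `n_frames x n_chains x n_residues` with
#'   values in {H, E, C}.
#' @param source One of `"dssp_file"`, `"dihedral_internal"`, `"synthetic"`.
#' @return An `ss_series`.
#' @export
ss_series <- function(labels, source = c("synthetic", "dssp_file",
                                         "dihedral_internal")) {
  source <- match.arg(source)
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("labels must be an n_frames x n_chains x n_residues array")
  }
  if (!all(labels %in% c("H", "E", "C"))) {
    abort("labels must be in the reduced alphabet {H, E, C}")
  }
  structure(labels, source = source, class = "ss_series")
}

#' @export
print.ss_series <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ss_series> %d frames x %d chains x %d residues (source: %s)\n",
              d[1], d[2], d[3], attr(x, "source")))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Generate points uniform in a solid ellipsoid
#'
#' Fixture generator for shape-descriptor tests: the gyration-tensor
#' eigenvalues of a uniform solid ellipsoid with semi-axes (a, b, c) converge
#' to (a^2, b^2, c^2) / 5, so its eccentricity converges to
#' `sqrt(1 - c^2 / a^2)`.
#'
#' @param a,b,c Semi-axes, nm, with `a >= b >= c > 0`.
#' @param n_points Number of points.
#' @param seed Integer seed.
#' @return `n_points x 3` coordinate matrix.
#' @export
generate_ellipsoid_cloud <- function(a, b, c, n_points, seed) {
  if (!(a >= b && b >= c && c > 0)) abort("require a >= b >= c > 0")
  withr::with_seed(seed, {
    v <- matrix(stats::rnorm(3 * n_points), n_points, 3)
    v <- v / sqrt(rowSums(v * v))
    r <- stats::runif(n_points)^(1 / 3)
    sweep(v * r, 2, c(a, b, c), "*")
  })
}

#' Write generator ground truth to JSON
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output file.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(
      contacts = truth$contacts,
      strand_fraction = as.list(truth$strand_fraction),
      rg_per_chain = truth$rg_per_chain,
      association_schedule = truth$association_schedule,
      anchor_residue = truth$anchor_residue,
      seed = truth$seed
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read/write a generator configuration as YAML
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- unclass(config)
  out$association_schedule <- as.list(as.data.frame(out$association_schedule))
  out$contact_spec <- as.list(as.data.frame(out$contact_spec))
  out$ss_transition <- as.vector(out$ss_transition)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ss_transition)) {
    raw$ss_transition <- matrix(unlist(raw$ss_transition), 3, 3,
                                dimnames = list(c("H", "E", "C"),
                                                c("H", "E", "C")))
  }
  assoc <- raw$association_schedule
  raw$association_schedule <-
    if (length(assoc$chain)) as_tibble(lapply(assoc, unlist)) else NULL
  cs <- raw$contact_spec
  raw$contact_spec <-
    if (length(cs$res_i)) as_tibble(lapply(cs, unlist)) else NULL
  keep <- intersect(names(raw), names(formals(generator_config)))
  do.call(generator_config, raw[keep])
}
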