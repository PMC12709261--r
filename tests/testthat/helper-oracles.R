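# Independent oracles and fixture builders. Everything here is deliberately
# written from first principles (naive loops, alternative algorithms) so the
# package implementations are checked against a second, independent route.

# --- fixture builders -------------------------------------------------------

# coarse-grained trajectory from a frames x (nc*nr) x 3 array (one CA bead
# per residue, chain-major atom order)
ca_traj <- function(coords, n_chains, n_res, box = NULL, radius = 0.19,
                    sequence = NULL) {
  seq_str <- sequence %||% paste(rep("A", n_res), collapse = "")
  top <- tibble::tibble(
    chain_id = rep(LETTERS[seq_len(n_chains)], each = n_res),
    residue_index = rep(seq_len(n_res), n_chains),
    residue_name = rep(oligotraj::sequence_to_residues(seq_str), n_chains),
    atom_name = "CA", element = "C", vdw_radius = radius, mass = NA_real_
  )
  trajectory(coords, top, box = box)
}

# random coarse-grained trajectory with distances straddling the 0.6 nm cutoff
random_ca_traj <- function(n_frames, n_chains, n_res, seed, spread = 1.0,
                           box = NULL) {
  withr::with_seed(seed, {
    coords <- array(stats::runif(n_frames * n_chains * n_res * 3,
                                 0, spread), c(n_frames, n_chains * n_res, 3))
    ca_traj(coords, n_chains, n_res, box = box)
  })
}

`%||%` <- rlang::`%||%`

# --- brute-force interaction-frequency oracle -------------------------------

# naive triple-loop implementation of the residue-residue interaction
# frequency, recomputing distances from raw coordinates
naive_interaction_frequency <- function(traj, res_i, res_j, mode,
                                        cutoff = 0.6) {
  chains <- chain_ids(traj)
  nf <- n_frames(traj)
  top <- traj$topology
  atom_rows <- function(ch, r) {
    which(top$chain_id == ch & top$residue_index == r &
            toupper(top$element) != "H")
  }
  dmin <- function(f, rows_a, rows_b, wrap) {
    xyz <- traj$coords[f, , , drop = TRUE]
    dim(xyz) <- dim(traj$coords)[2:3]
    best <- Inf
    for (a in rows_a) {
      for (b in rows_b) {
        dv <- xyz[a, ] - xyz[b, ]
        if (wrap && !is.null(traj$box)) {
          bx <- traj$box[f, ]
          dv <- dv - bx * round(dv / bx)
        }
        best <- min(best, sqrt(sum(dv * dv)))
      }
    }
    best
  }
  if (mode == "intramolecular") {
    units <- lapply(chains, function(ch) list(ch = ch))
    unit_dist <- function(f, u) {
      dmin(f, atom_rows(u$ch, res_i), atom_rows(u$ch, res_j), wrap = FALSE)
    }
  } else {
    cp <- utils::combn(chains, 2)
    units <- lapply(seq_len(ncol(cp)), function(k) {
      list(a = cp[1, k], b = cp[2, k])
    })
    unit_dist <- function(f, u) {
      min(
        dmin(f, atom_rows(u$a, res_i), atom_rows(u$b, res_j), wrap = TRUE),
        dmin(f, atom_rows(u$a, res_j), atom_rows(u$b, res_i), wrap = TRUE)
      )
    }
  }
  dmat <- matrix(NA_real_, nf, length(units))
  for (f in seq_len(nf)) {
    for (u in seq_along(units)) dmat[f, u] <- unit_dist(f, units[[u]])
  }
  within <- dmat <= cutoff
  n_pairs <- sum(apply(within, 2, any))
  n_frames_hit <- sum(apply(within, 1, any))
  if (n_pairs == 0L) {
    list(score = 0, mu = NA_real_, n_pairs = 0L, n_frames = n_frames_hit)
  } else {
    mu <- mean(dmat[within])
    list(score = (n_pairs / mu) * (n_frames_hit / nf), mu = mu,
         n_pairs = n_pairs, n_frames = n_frames_hit)
  }
}

# --- quaternion (Horn) RMSD oracle ------------------------------------------

quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- crossprod(a, b)
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2], s[3,1]-s[1,3], s[1,2]-s[2,1],
    s[2,3]-s[3,2], s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1], s[3,1]+s[1,3],
    s[3,1]-s[1,3], s[1,2]+s[2,1], -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1], s[3,1]+s[1,3], s[2,3]+s[3,2], -s[1,1]-s[2,2]+s[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(a * a) + sum(b * b) - 2 * lam) / nrow(a)))
}

# --- brute-force Daura clustering oracle ------------------------------------

# re-derivation of the greedy neighbour-count algorithm from its definition,
# operating on a precomputed distance matrix
brute_daura <- function(dmat, cutoff) {
  nf <- nrow(dmat)
  assign <- rep(NA_integer_, nf)
  cl <- 0L
  repeat {
    left <- which(is.na(assign))
    if (!length(left)) break
    cl <- cl + 1L
    best <- NULL; best_n <- -1L
    for (i in left) {
      nb <- left[dmat[i, left] <= cutoff & left != i]
      if (length(nb) > best_n) { best <- i; best_n <- length(nb) }
    }
    members <- left[dmat[best, left] <= cutoff]
    assign[members] <- cl
  }
  assign
}

# --- geometry oracles -------------------------------------------------------

# direct-sum radius of gyration
direct_rg <- function(x, w = NULL) {
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cm <- c(sum(x[, 1] * w), sum(x[, 2] * w), sum(x[, 3] * w))
  s <- 0
  for (i in seq_len(n)) s <- s + w[i] * sum((x[i, ] - cm)^2)
  sqrt(s)
}

# dense random-direction SASA estimate for small atom sets (independent of
# the golden-spiral point set used by the implementation)
dense_sasa <- function(coords, radii, probe = 0.14, n_pts = 1e5, seed = 42) {
  coords <- rbind(coords)
  n <- nrow(coords)
  ext <- radii + probe
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      pts <- matrix(stats::rnorm(3 * n_pts), n_pts, 3)
      pts <- pts / sqrt(rowSums(pts * pts))
      sp <- sweep(pts * ext[i], 2, coords[i, ], "+")
      acc <- rep(TRUE, n_pts)
      for (j in seq_len(n)[-i]) {
        dj <- sweep(sp, 2, coords[j, ])
        acc <- acc & rowSums(dj * dj) > ext[j]^2
      }
      mean(acc) * 4 * pi * ext[i]^2
    }, numeric(1))
  })
}

# 6 single-residue chains with five contact atoms each: every one of the 15
# chain pairs meets at its own site, exactly d_contact apart, so the
# interaction-frequency closed case (15 pairs at 0.5 nm) is geometric
all_pairs_hexamer <- function(d_contact = 0.5, n_frames = 1) {
  pairs <- utils::combn(6, 2)
  base <- matrix(0, 30, 3)
  slot <- integer(6)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    slot[a] <- slot[a] + 1L; slot[b] <- slot[b] + 1L
    base[(a - 1) * 5 + slot[a], ] <- c(5 * k, 0, -d_contact / 2)
    base[(b - 1) * 5 + slot[b], ] <- c(5 * k, 0, d_contact / 2)
  }
  coords <- array(NA_real_, c(n_frames, 30, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- base
  top <- tibble::tibble(
    chain_id = rep(LETTERS[1:6], each = 5),
    residue_index = 1L, residue_name = "ALA",
    atom_name = rep(paste0("C", 1:5), 6), element = "C"
  )
  trajectory(coords, top)
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# plain double-loop minimum distance between two atom sets
proxy_min <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    best <- min(best, sqrt(min(rowSums(sweep(b, 2, a[i, ])^2))))
  }
  best
}

# bio3d xyz matrix from a trajectory (frame-major, Angstrom-free: raw values)
traj_to_bio3d_xyz <- function(tr) {
  nf <- n_frames(tr)
  m <- matrix(NA_real_, nf, n_atoms(tr) * 3)
  for (f in seq_len(nf)) {
    m[f, ] <- as.vector(t(frame_coords(tr, f)))
  }
  bio3d::as.xyz(m)
}

# minimal CHARMM-format DCD writer (Fortran unformatted records), used to
# build binary fixtures at test time
write_minimal_dcd <- function(tr, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(write_body, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    write_body()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  nf <- n_frames(tr); na <- n_atoms(tr)
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L
    icntrl[20] <- 24L  # CHARMM version flag
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(formatC("test dcd", width = 80, flag = "-"), con, 80, eos = NULL)
  }, 4 + 80)
  rec(function() writeBin(na, con, size = 4, endian = "little"), 4)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(tr, f)
    for (d in 1:3) {
      rec(function() {
        writeBin(as.numeric(xyz[, d]), con, size = 4, endian = "little")
      }, 4 * na)
    }
  }
  invisible(path)
}

# regular polygon ring in a given plane, for pi-stacking fixtures
ring_coords <- function(center, normal, radius = 0.14, n = 6) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- 2 * pi * (seq_len(n) - 1) / n
  t(vapply(ang, function(a) {
    center + radius * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}
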