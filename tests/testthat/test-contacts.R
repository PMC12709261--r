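# Contact machinery: minimum distances, the interaction-frequency statistic,
# occupancy and the residue-pair maps, all cross-checked against naive
# triple-loop oracles.

test_that("residue minimum distances match a brute-force atom-pair oracle", {
  withr::with_seed(14, {
    for (rep in 1:5) {
      tr <- random_ca_traj(3, 2, 4, seed = rep * 100, spread = 1.2,
                           box = c(5, 5, 5))
      for (f in 1:3) {
        d <- residue_min_distance(tr, "A", 2, "B", 3, f)
        xa <- frame_coords(tr, f)[2, , drop = FALSE]
        xb <- frame_coords(tr, f)[4 + 3, , drop = FALSE]
        dv <- xa - xb
        dv <- dv - 5 * round(dv / 5)
        expect_equal(d, sqrt(sum(dv^2)), tolerance = 1e-12)
      }
    }
  })
  # same residue with itself: zero
  tr <- random_ca_traj(1, 1, 3, seed = 2)
  expect_equal(residue_min_distance(tr, "A", 2, "A", 2, 1), 0)
  # two beads at fixed separation
  coords <- array(0, c(1, 2, 3)); coords[1, 2, 3] <- 0.5
  tr2 <- ca_traj(coords, 2, 1)
  expect_equal(residue_min_distance(tr2, "A", 1, "B", 1, 1), 0.5)
  expect_error(residue_min_distance(tr2, "A", 2, "B", 1, 1), "no atoms")
})

test_that("the all-pairs closed case gives the hand-computable score", {
  # three single-bead chains on an equilateral triangle of edge 0.5 nm:
  # every chain pair interacts at exactly 0.5 nm in every frame
  tri <- 0.5 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  coords <- array(NA_real_, c(4, 3, 3))
  for (f in 1:4) coords[f, , ] <- tri
  tr <- ca_traj(coords, 3, 1)
  rec <- interaction_frequency(tr, 1, 1, "intermolecular", cutoff = 0.6)
  expect_equal(rec$n_pairs_interacting, 3)
  expect_equal(rec$mean_interacting_distance, 0.5, tolerance = 1e-12)
  expect_equal(rec$occupancy, 1)
  expect_equal(rec$frequency_score, 3 / 0.5, tolerance = 1e-12)
})

test_that("a 6-chain system with every chain pair at 0.5 nm scores 15/0.5 = 30", {
  # single-bead chains cannot be pairwise-equidistant in 3D, but residues
  # with several atoms can: give each chain five contact atoms and park each
  # of the 15 chain pairs at its own well-separated site, 0.5 nm apart there
  tr <- all_pairs_hexamer(d_contact = 0.5, n_frames = 3)
  rec <- interaction_frequency(tr, 1, 1, "intermolecular", cutoff = 0.6)
  expect_equal(rec$n_pairs_interacting, 15)
  expect_equal(rec$mean_interacting_distance, 0.5, tolerance = 1e-12)
  expect_equal(rec$n_frames_interacting, 3)
  expect_equal(rec$occupancy, 1)
  expect_equal(rec$frequency_score, 30, tolerance = 1e-12)
})

test_that("no interaction within the cutoff yields score 0 and absent mu", {
  coords <- array(0, c(2, 2, 3))
  coords[, 2, 1] <- 5
  tr <- ca_traj(coords, 2, 1)
  rec <- interaction_frequency(tr, 1, 1, "intermolecular")
  expect_equal(rec$frequency_score, 0)
  expect_true(is.na(rec$mean_interacting_distance))
  expect_equal(rec$n_pairs_interacting, 0)
})

test_that("interaction frequency matches the naive triple-loop oracle", {
  for (seed in c(3, 17, 99)) {
    tr <- random_ca_traj(10, 6, 5, seed = seed, spread = 1.0, box = c(4, 4, 4))
    for (pair in list(c(1, 3), c(2, 2), c(4, 5))) {
      for (mode in c("intermolecular", "intramolecular")) {
        got <- interaction_frequency(tr, pair[1], pair[2], mode)
        want <- naive_interaction_frequency(tr, pair[1], pair[2], mode)
        expect_equal(got$frequency_score, want$score, tolerance = 1e-12)
        expect_equal(got$n_pairs_interacting, want$n_pairs)
        expect_equal(got$n_frames_interacting, want$n_frames)
        if (!is.na(want$mu)) {
          expect_equal(got$mean_interacting_distance, want$mu,
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("frequency score is invariant under chain relabeling and frame order", {
  tr <- random_ca_traj(8, 4, 4, seed = 7, spread = 0.9)
  base <- interaction_frequency(tr, 1, 4, "intermolecular")
  # permute chains (reorder atom blocks and relabel)
  perm <- c(3L, 1L, 4L, 2L)
  atom_perm <- as.vector(vapply(perm, function(k) (k - 1L) * 4L + 1:4,
                                integer(4)))
  tr_perm <- ca_traj(tr$coords[, atom_perm, , drop = FALSE], 4, 4)
  expect_equal(interaction_frequency(tr_perm, 1, 4,
                                     "intermolecular")$frequency_score,
               base$frequency_score, tolerance = 1e-12)
  tr_rev <- tr[rev(seq_len(8))]
  expect_equal(interaction_frequency(tr_rev, 1, 4,
                                     "intermolecular")$frequency_score,
               base$frequency_score, tolerance = 1e-12)
})

test_that("enlarging the cutoff never decreases counts or occupancy", {
  tr <- random_ca_traj(12, 3, 4, seed = 23, spread = 1.1)
  cuts <- c(0.3, 0.5, 0.7, 1.0)
  recs <- lapply(cuts, function(ct) {
    interaction_frequency(tr, 1, 3, "intermolecular", cutoff = ct)
  })
  np <- vapply(recs, function(r) r$n_pairs_interacting, 1L)
  nf <- vapply(recs, function(r) r$n_frames_interacting, 1L)
  occ <- vapply(recs, function(r) r$occupancy, 1)
  expect_true(all(diff(np) >= 0))
  expect_true(all(diff(nf) >= 0))
  expect_true(all(diff(occ) >= 0))
})

test_that("occupancy recovers generator contact probability and persistence flags", {
  run_occ <- function(p, seed) {
    spec <- data.frame(res_i = 3, res_j = 7, chain_a = 1, chain_b = 2, p = p)
    cfg <- generator_config(n_chains = 2, n_residues = 8, n_frames = 1000,
                            target_rg = 0.5, box_edge = 10,
                            contact_spec = spec, seed = seed)
    tr <- generate_hexamer_trajectory(cfg)$trajectory
    interaction_occupancy(tr, 3, 7, "intermolecular")
  }
  low <- run_occ(0.3, 41)
  expect_lt(abs(low$occupancy - 0.3), 0.03)
  expect_false(low$persistent)
  high <- run_occ(0.7, 42)
  expect_lt(abs(high$occupancy - 0.7), 0.03)
  expect_true(high$persistent)
  # always-in-contact case
  always <- run_occ(1, 43)
  expect_equal(always$occupancy, 1, tolerance = 2e-3)
  expect_true(always$persistent)
})

test_that("interaction maps agree entrywise with interaction_frequency", {
  tr <- random_ca_traj(6, 3, 4, seed = 77, spread = 0.8, box = c(4, 4, 4))
  for (mode in c("intermolecular", "intramolecular")) {
    map <- interaction_heatmap(tr, mode)
    expect_equal(map$score, t(map$score), tolerance = 1e-12)
    for (i in 1:4) {
      for (j in i:4) {
        if (mode == "intramolecular" && i == j) {
          expect_equal(map$score[i, j], 0)
          next
        }
        rec <- interaction_frequency(tr, i, j, mode)
        expect_equal(map$score[i, j], rec$frequency_score, tolerance = 1e-12)
        expect_equal(map$occupancy[i, j], rec$occupancy, tolerance = 1e-12)
      }
    }
  }
})

test_that("a single constructed contact lights exactly one symmetric entry pair", {
  coords <- array(50, c(1, 8, 3))
  coords[1, , ] <- matrix(rep(seq(0, 70, by = 10), each = 3), 8, 3)
  # chain A residue 2 and chain B residue 3 at 0.4 nm; everything else far
  coords[1, 2, ] <- c(0, 0, 0)
  coords[1, 4 + 3, ] <- c(0.4, 0, 0)
  tr <- ca_traj(coords, 2, 4)
  map <- interaction_heatmap(tr, "intermolecular")
  nz <- which(map$score > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 2)
  expect_setequal(paste(nz[, 1], nz[, 2]), c("2 3", "3 2"))
})

test_that("chain-label permutation leaves the interaction map unchanged", {
  tr <- random_ca_traj(5, 3, 3, seed = 31, spread = 0.8)
  map <- interaction_heatmap(tr, "intermolecular")
  perm <- c(2L, 3L, 1L)
  atom_perm <- as.vector(vapply(perm, function(k) (k - 1L) * 3L + 1:3,
                                integer(3)))
  tr2 <- ca_traj(tr$coords[, atom_perm, , drop = FALSE], 3, 3)
  map2 <- interaction_heatmap(tr2, "intermolecular")
  expect_equal(map2$score, map$score, tolerance = 1e-12)
})

test_that("heavy-atom reduction drops hydrogens from contact distances", {
  top <- tibble::tibble(
    chain_id = rep(c("A", "B"), each = 2),
    residue_index = 1L,
    residue_name = "GLY",
    atom_name = rep(c("CA", "HA"), 2),
    element = rep(c("C", "H"), 2)
  )
  coords <- array(0, c(1, 4, 3))
  coords[1, 1, ] <- c(0, 0, 0)      # A CA
  coords[1, 2, ] <- c(0.9, 0, 0)    # A HA (closer to B than A CA is)
  coords[1, 3, ] <- c(2, 0, 0)      # B CA
  coords[1, 4, ] <- c(1.1, 0, 0)    # B HA
  tr <- trajectory(coords, top)
  expect_equal(residue_min_distance(tr, "A", 1, "B", 1, 1), 2)
  expect_equal(residue_min_distance(tr, "A", 1, "B", 1, 1,
                                    heavy_only = FALSE), 0.2)
})
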