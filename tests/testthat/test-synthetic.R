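# Synthetic-data generator: geometry, contact statistics and secondary
# structure all come with recorded ground truth; these tests hold the
# generator to it.

test_that("generated chains respect bond lengths, excluded volume and target Rg", {
  x <- generate_chain(20, 0.8, seed = 7)
  bonds <- sqrt(rowSums((x[-1, ] - x[-20, ])^2))
  expect_true(all(abs(bonds - 0.38) < 1e-9))
  d <- as.matrix(dist(x))
  nonbonded <- abs(row(d) - col(d)) > 1
  expect_true(all(d[nonbonded] >= 2 * 0.19 - 1e-9))
  expect_lt(abs(attr(x, "rg") - 0.8) / 0.8, 0.10)
  # reported Rg equals an independent direct-sum recomputation
  expect_equal(attr(x, "rg"), direct_rg(x), tolerance = 1e-9)
})

test_that("two-bead chain has the closed-form Rg of bond_length / 2", {
  x <- generate_chain(2, 1.0, seed = 1)
  expect_equal(attr(x, "rg"), 0.19)
  expect_equal(direct_rg(x), 0.19, tolerance = 1e-12)
})

test_that("42-bead chains reach the compact-monomer Rg regime", {
  x <- generate_chain(42, 1.09, seed = 1)
  expect_gte(attr(x, "rg"), 0.98)
  expect_lte(attr(x, "rg"), 1.20)
})

test_that("unreachable target Rg raises an infeasibility error", {
  expect_error(generate_chain(10, 0.05, seed = 1),
               class = "oligotraj_infeasible_rg")
  expect_error(generate_chain(10, 50, seed = 1),
               class = "oligotraj_infeasible_rg")
})

test_that("chain generation is deterministic under a fixed seed", {
  expect_identical(generate_chain(15, 0.7, seed = 3),
                   generate_chain(15, 0.7, seed = 3))
})

test_that("hexamer trajectories start separated and associate on schedule", {
  cfg <- generator_config(n_chains = 6, n_residues = 8, n_frames = 120,
                          target_rg = 0.55, box_edge = 14, seed = 11)
  out <- generate_hexamer_trajectory(cfg)
  traj <- out$trajectory
  expect_equal(n_frames(traj), 120)
  expect_equal(n_atoms(traj), 48)
  # frame 1: all 15 chain-pair minimum distances >= 1.4 nm
  chains <- chain_ids(traj)
  xyz <- frame_coords(traj, 1)
  rows <- split(seq_len(n_atoms(traj)), traj$topology$chain_id)
  pair_min <- utils::combn(chains, 2, function(p) {
    min(as.matrix(stats::dist(rbind(xyz[rows[[p[1]]], ], xyz[rows[[p[2]]], ])))[
      seq_along(rows[[p[1]]]), length(rows[[p[1]]]) + seq_along(rows[[p[2]]])])
  })
  expect_true(all(pair_min >= 1.4))
  # after association, each scheduled chain stays near the bound cluster
  sched <- out$truth$association_schedule
  for (k in seq_len(nrow(sched))) {
    ch <- sched$chain[k]; f0 <- sched$frame[k]
    frames <- seq(f0, n_frames(traj))
    near <- vapply(frames, function(f) {
      xyzf <- frame_coords(traj, f)
      bound <- setdiff(unique(c(1L, sched$chain[sched$frame <= f])), ch)
      min(vapply(bound, function(b) {
        proxy_min(xyzf[rows[[chains[ch]]], ], xyzf[rows[[chains[b]]], ])
      }, numeric(1)))
    }, numeric(1))
    expect_gte(mean(near <= 0.6), 0.95)
  }
})

# plain min-distance helper for the association test
proxy_min <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    best <- min(best, sqrt(min(rowSums(sweep(b, 2, a[i, ])^2))))
  }
  best
}

test_that("contact events follow their Bernoulli schedule exactly", {
  spec <- data.frame(res_i = 4, res_j = 9, chain_a = 1, chain_b = 2, p = 0.5)
  cfg <- generator_config(n_chains = 2, n_residues = 10, n_frames = 2000,
                          target_rg = 0.6, box_edge = 10,
                          contact_spec = spec, seed = 3)
  out <- generate_hexamer_trajectory(cfg)
  occ <- interaction_occupancy(out$trajectory, 4, 9, "intermolecular")$occupancy
  # binomial 95% band around p at n = 2000
  expect_lt(abs(occ - 0.5), 0.03)
  # the estimator sees exactly the drawn events (frame 1 is placement)
  expect_equal(occ * 2000, out$truth$contacts$realized_occupancy * 1999,
               tolerance = 1e-9)
})

test_that("zero-probability contacts never occur", {
  spec <- data.frame(res_i = 4, res_j = 9, chain_a = 1, chain_b = 2, p = 0)
  cfg <- generator_config(n_chains = 2, n_residues = 10, n_frames = 400,
                          target_rg = 0.6, box_edge = 10,
                          contact_spec = spec, seed = 5)
  out <- generate_hexamer_trajectory(cfg)
  d <- vapply(seq_len(400), function(f) {
    residue_min_distance(out$trajectory, "A", 4, "B", 9, f)
  }, numeric(1))
  expect_true(all(d > 0.6))
})

test_that("trajectory generation is deterministic and serialization-stable", {
  cfg <- generator_config(n_chains = 3, n_residues = 6, n_frames = 20,
                          target_rg = 0.5, box_edge = 10, seed = 42)
  a <- generate_hexamer_trajectory(cfg)
  b <- generate_hexamer_trajectory(cfg)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  f1 <- tempfile(fileext = ".gro"); f2 <- tempfile(fileext = ".gro")
  write_trajectory(a$trajectory, f1)
  write_trajectory(b$trajectory, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("Markov secondary-structure series recover their stationary law", {
  m <- default_ss_transition(c(H = 0.1, E = 0.4, C = 0.5))
  expect_equal(unname(ss_stationary(m)), c(0.1, 0.4, 0.5), tolerance = 1e-12)
  ss <- generate_ss_series(10000, 1, 4, m, seed = 9)
  expect_lt(abs(mean(unclass(ss) == "E") - 0.4), 0.02)

  # uniform rows: each state near 1/3
  u <- matrix(1 / 3, 3, 3)
  ssu <- generate_ss_series(10000, 1, 2, u, seed = 2)
  for (s in c("H", "E", "C")) {
    expect_lt(abs(mean(unclass(ssu) == s) - 1 / 3), 0.02)
  }

  # identity matrix: chain absorbed in its start state forever
  ssi <- generate_ss_series(50, 2, 3, diag(3), seed = 4)
  first <- unclass(ssi)[1, , ]
  for (f in 2:50) expect_identical(unclass(ssi)[f, , ], first)
})

test_that("non-stochastic transition matrices are rejected", {
  bad <- matrix(c(0.5, 0.5, 0.1, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_error(generate_ss_series(10, 1, 1, bad, seed = 1), "sum to 1")
})

test_that("ellipsoid clouds have the closed-form eccentricity", {
  # the sphere check compares two extreme eigenvalues, whose sampling noise
  # decays only as n^(-1/4); a large cloud is needed for the isotropy limit
  sphere <- generate_ellipsoid_cloud(1, 1, 1, 6e6, seed = 1)
  expect_lte(eccentricity(sphere), 0.05)
  ell <- generate_ellipsoid_cloud(2, 1, 1, 50000, seed = 2)
  expect_lt(abs(eccentricity(ell) - sqrt(1 - 1 / 4)), 0.02)
  # near-degenerate smallest axis: eccentricity -> 1
  slab <- generate_ellipsoid_cloud(1, 1, 1e-4, 20000, seed = 3)
  expect_gt(eccentricity(slab), 0.99)
})

test_that("generator config round-trips through YAML", {
  spec <- data.frame(res_i = 2, res_j = 5, chain_a = 1, chain_b = 3, p = 0.25)
  cfg <- generator_config(n_chains = 3, n_residues = 8, n_frames = 50,
                          target_rg = 0.55, contact_spec = spec, seed = 17)
  path <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$n_frames, 50)
  expect_equal(back$contact_spec$p, 0.25)
  expect_equal(back$ss_transition, cfg$ss_transition, tolerance = 1e-12)
  # identical configs generate identical trajectories
  expect_identical(generate_hexamer_trajectory(cfg)$trajectory$coords,
                   generate_hexamer_trajectory(back)$trajectory$coords)
})
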