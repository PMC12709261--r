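# Secondary-structure metrics: dihedral assignment, composition, propensity,
# PCA, Hamming variability, intermolecular strand pairing.

# full-atom single-chain fixture with prescribed (phi, psi) per residue:
# builds N-CA-C backbones by placing consecutive peptide units with exact
# dihedrals using the NeRF (natural extension reference frame) construction
backbone_from_dihedrals <- function(phi_psi) {
  # bond lengths (nm) and angles (deg) of an idealized backbone
  place <- function(a, b, c, bond, angle, torsion) {
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    n <- c(
      (b - a)[2] * bc[3] - (b - a)[3] * bc[2],
      (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
      (b - a)[1] * bc[2] - (b - a)[2] * bc[1]
    )
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
            -bond * sin(ang) * sin(tor))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
  }
  n_res <- nrow(phi_psi)
  coords <- matrix(NA_real_, 3 * n_res, 3)
  coords[1, ] <- c(0, 0, 0)            # N1
  coords[2, ] <- c(0.1455, 0, 0)       # CA1
  coords[3, ] <- place(c(0, 0.1, 0), coords[1, ], coords[2, ],
                       0.1523, 111, 0) # C1 (phi of residue 1 is undefined)
  omega <- 180
  for (r in 2:n_res) {
    iN <- 3 * (r - 1) + 1
    # psi of previous residue fixes N(r)
    coords[iN, ] <- place(coords[iN - 3, ], coords[iN - 2, ],
                          coords[iN - 1, ], 0.1329, 116, phi_psi[r - 1, 2])
    # omega fixes CA(r)
    coords[iN + 1, ] <- place(coords[iN - 2, ], coords[iN - 1, ],
                              coords[iN, ], 0.1458, 122, omega)
    # phi of residue r fixes C(r)
    coords[iN + 2, ] <- place(coords[iN - 1, ], coords[iN, ],
                              coords[iN + 1, ], 0.1523, 111, phi_psi[r, 1])
  }
  top <- tibble::tibble(
    chain_id = "A",
    residue_index = rep(seq_len(n_res), each = 3),
    residue_name = "ALA",
    atom_name = rep(c("N", "CA", "C"), n_res),
    element = rep(c("N", "C", "C"), n_res)
  )
  trajectory(coords, top)
}

test_that("dihedral assignment labels canonical helix/strand/other geometries", {
  # middle residue carries the probed (phi, psi); flanks are extended
  probe <- function(phi, psi) {
    pp <- rbind(c(-120, 130), c(phi, psi), c(-120, 130))
    tr <- backbone_from_dihedrals(pp)
    assign_ss_dihedral(tr)[1, 1, 2]
  }
  expect_equal(probe(-57, -47), "H")    # ideal alpha helix
  expect_equal(probe(-135, 135), "E")   # ideal antiparallel strand
  expect_equal(probe(60, 45), "C")      # left-handed region
  # terminal residues have undefined dihedrals -> coil
  tr <- backbone_from_dihedrals(rbind(c(-135, 135), c(-135, 135), c(-135, 135)))
  lab <- assign_ss_dihedral(tr)
  expect_equal(lab[1, 1, 1], "C")
  expect_equal(lab[1, 1, 3], "C")
})

test_that("dihedral assignment rejects coarse-grained input", {
  tr <- random_ca_traj(2, 1, 5, seed = 1)
  expect_error(assign_ss_dihedral(tr), "DSSP")
})

test_that("composition percentages are exact on constructed series", {
  arr <- array("E", c(4, 2, 5))
  comp <- ss_composition(ss_series(arr))
  expect_equal(comp$sheet, 100)
  expect_equal(comp$coil + comp$sheet + comp$helix, 100, tolerance = 1e-9)
  arr[, , 1] <- "C"   # 1 of 5 residues coil everywhere
  comp2 <- ss_composition(ss_series(arr))
  expect_equal(comp2$coil, 20)
  expect_equal(comp2$sheet, 80)
  expect_error(ss_composition(ss_series(arr), window = integer(0)), "window")
})

test_that("composition recovers the stationary sheet fraction of a Markov series", {
  m <- default_ss_transition(c(H = 0, E = 0.4, C = 0.6))
  ss <- generate_ss_series(10000, 1, 3, m, seed = 21)
  comp <- ss_composition(ss)
  expect_lt(abs(comp$sheet - 40), 2)
  expect_equal(comp$helix, 0)
})

test_that("composition is invariant to chain permutation and frame order", {
  ss <- generate_ss_series(200, 3, 4, default_ss_transition(), seed = 5)
  base <- ss_composition(ss)
  perm <- ss_series(unclass(ss)[, c(2, 3, 1), ], source = "synthetic")
  shuf <- ss_series(unclass(ss)[sample(200), , ], source = "synthetic")
  expect_equal(ss_composition(perm)$sheet, base$sheet)
  expect_equal(ss_composition(shuf)$coil, base$coil)
})

test_that("propensities sum to one and match constructed fractions", {
  arr <- array("C", c(4, 1, 2))
  arr[, 1, 1] <- "E"                       # always strand
  arr[, 1, 2] <- c("E", "C", "E", "C")     # alternating
  pr <- ss_propensity(ss_series(arr))
  expect_equal(pr$sheet[pr$residue == 1], 1.0)
  expect_equal(pr$sheet[pr$residue == 2], 0.5)
  expect_equal(pr$coil[pr$residue == 2], 0.5)
  expect_true(all(abs(pr$helix + pr$sheet + pr$coil - 1) < 1e-12))
})

test_that("propensity estimates converge to the Markov stationary strand fraction", {
  # persistence 0.5 keeps the chain's autocorrelation short enough that the
  # +-0.02 band is several sigma at 10^4 frames
  m <- default_ss_transition(c(H = 0.05, E = 0.75, C = 0.20),
                             persistence = 0.5)
  ss <- generate_ss_series(10000, 1, 2, m, seed = 13)
  pr <- ss_propensity(ss)
  expect_true(all(abs(pr$sheet - 0.75) < 0.02))
})

test_that("PCA separates alternating structures and flags degenerate input", {
  # two alternating patterns -> one axis of variation, PC1 explains 100%
  arr <- array("C", c(10, 1, 6))
  arr[seq(1, 9, 2), 1, ] <- "E"
  p <- ss_pca(ss_series(arr))
  expect_false(p$degenerate)
  expect_equal(unname(p$explained_variance[1]), 1, tolerance = 1e-9)
  # constant series -> degenerate signal, not a crash
  expect_warning(pd <- ss_pca(ss_series(array("E", c(5, 1, 4)))),
                 "degenerate")
  expect_true(pd$degenerate)
})

test_that("PCA separates three synthetic structure regimes (k-means ARI > 0.9)", {
  mk <- function(bias, seed) {
    m <- default_ss_transition(bias, persistence = 0.5)
    unclass(generate_ss_series(60, 1, 20, m, seed = seed))
  }
  arr <- array("C", c(180, 1, 20))
  arr[1:60, , ] <- mk(c(H = 0.9, E = 0.05, C = 0.05), 1)
  arr[61:120, , ] <- mk(c(H = 0.05, E = 0.9, C = 0.05), 2)
  arr[121:180, , ] <- mk(c(H = 0.05, E = 0.05, C = 0.9), 3)
  p <- ss_pca(ss_series(arr))
  km <- withr::with_seed(4, stats::kmeans(
    cbind(p$projections$PC1, p$projections$PC2), centers = 3, nstart = 20))
  truth <- rep(1:3, each = 60)
  expect_gt(adjusted_rand_index(km$cluster, truth), 0.9)
})

test_that("PCA projections are stable (up to the sign rule) under frame reordering", {
  ss <- generate_ss_series(40, 2, 6, default_ss_transition(), seed = 8)
  p1 <- ss_pca(ss)
  ord <- rev(seq_len(40))
  p2 <- ss_pca(ss_series(unclass(ss)[ord, , ], source = "synthetic"))
  expect_equal(p2$projections$PC1, p1$projections$PC1[ord], tolerance = 1e-8)
})

test_that("Hamming variability matches direct counts and its bounds", {
  arr <- array("C", c(2, 1, 5))
  arr[1, 1, ] <- c("E", "E", "E", "C", "C")
  arr[2, 1, ] <- "C"
  expect_equal(hamming_distance("EEECC", "CCCCC"), 3)
  hv <- hamming_variability(ss_series(arr), chain = 1, residue_range = 1:5)
  expect_equal(hv$mean, 3)
  expect_equal(hv$n_pairs, 1)
  # identical frames -> 0 / 0
  same <- ss_series(array("E", c(6, 1, 4)))
  hv0 <- hamming_variability(same, 1, 1:4)
  expect_equal(hv0$mean, 0)
  expect_equal(hv0$sd, 0)
  # bounded by window length
  rnd <- generate_ss_series(80, 1, 15, default_ss_transition(), seed = 3)
  hvr <- hamming_variability(rnd, 1, 1:15)
  expect_lte(hvr$mean, 15)
  expect_gte(hvr$mean, 0)
})

test_that("Hamming subsampling is seeded and close to the exhaustive mean", {
  ss <- generate_ss_series(300, 1, 8, default_ss_transition(), seed = 10)
  full <- hamming_variability(ss, 1, 1:8)
  sub1 <- hamming_variability(ss, 1, 1:8, max_pairs = 5000, seed = 99)
  sub2 <- hamming_variability(ss, 1, 1:8, max_pairs = 5000, seed = 99)
  expect_identical(sub1, sub2)
  expect_lt(abs(sub1$mean - full$mean), 0.15)
})

test_that("intermolecular strand pairs count E-labelled contacts only", {
  # two chains of 3 residues, one frame; residues 2 (chain A) and 1 (chain B)
  # in contact at 0.5 nm
  coords <- array(10, c(1, 6, 3))
  coords[1, , ] <- matrix(c(
    0, 0, 0,   0.5, 0, 0,   1.0, 0, 0,      # chain A
    0.5, 0.5, 0,   3, 3, 3,   4, 4, 4       # chain B
  ), 6, 3, byrow = TRUE)
  tr <- ca_traj(coords, 2, 3)
  arr <- array("C", c(1, 2, 3))
  sp0 <- intermolecular_strand_pairs(ss_series(arr), tr)
  expect_equal(sp0$per_frame$count, 0)      # no E labels -> no pairs
  arr[1, 1, 2] <- "E"; arr[1, 2, 1] <- "E"
  sp1 <- intermolecular_strand_pairs(ss_series(arr), tr)
  expect_equal(sp1$per_frame$count, 1)
  expect_equal(sp1$per_residue$total, c(1, 1, 0))
  # dimension mismatch errors
  expect_error(intermolecular_strand_pairs(ss_series(array("C", c(2, 2, 3))), tr),
               "dimensions")
})

test_that("scheduled strand contacts yield the expected per-frame mean", {
  nf <- 400
  spec <- data.frame(res_i = 2, res_j = 5, chain_a = 1, chain_b = 2, p = 0.3)
  cfg <- generator_config(n_chains = 2, n_residues = 6, n_frames = nf,
                          target_rg = 0.45, box_edge = 10,
                          contact_spec = spec, seed = 31)
  out <- generate_hexamer_trajectory(cfg)
  # make exactly the scheduled pair strand-labelled in every frame
  arr <- array("C", c(nf, 2, 6))
  arr[, 1, 2] <- "E"
  arr[, 2, 5] <- "E"
  sp <- intermolecular_strand_pairs(ss_series(arr), out$trajectory)
  expect_lt(abs(mean(sp$per_frame$count) - 0.3), 0.05)
})
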