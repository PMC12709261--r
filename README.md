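# oligotraj

Trajectory analysis of amyloid oligomer simulations in R.

Amyloid peptides such as the 42-residue amyloid-β isoform (Aβ42, central
to Alzheimer's disease) and the 31-residue β-endorphin isoform (βE31, a
functional hormone-storage amyloid) both assemble into cross-β
structures, yet diverge sharply in cytotoxic potential. Molecular-dynamics
simulations of their early oligomers — typically hexamers over
microsecond windows — probe what distinguishes the two: which residue
pairs drive association, how compact and elongated the assembly becomes,
how much hydrophobic surface stays solvent-exposed, and how diverse the
sampled conformations are. oligotraj packages that comparative analysis
for computational structural biologists: it ingests multi-chain
trajectories (multi-model PDB, GRO, DCD) with optional DSSP output, and
computes the full set of oligomer descriptors with a seeded synthetic
trajectory generator for validating every stage against known ground
truth.

## The core statistic

In a hexamer a residue pair (i, j) can interact across 15 distinct
peptide pairs (intermolecular) or within each of the 6 chains
(intramolecular). oligotraj ranks residue-pair interactions with a
composite frequency score

```
score(i, j) = N_pairs(d ≤ 0.6 nm) / μ_{d ≤ 0.6}  ×  N_frames / total frames
```

where `N_pairs` counts peptide pairs ever within the 0.6 nm cutoff,
`μ` is the mean of all within-cutoff distances (pooled over frames and
pairs), and `N_frames` counts frames with at least one pair in contact.
Units are nm⁻¹; a pair never in contact scores 0. Around it sit contact
occupancy with a 60% persistence threshold, salt-bridge / hydrogen-bond /
π-stacking detection, gyration-tensor shape descriptors
(Rg, eccentricity `e = sqrt(1 − λ_min/λ_max)`), Shrake–Rupley SASA with
per-residue normalization (nm² atom⁻¹) and hydrophobic totals,
secondary-structure propensity / PCA / Hamming variability, GROMOS-style
(Daura) RMSD clustering at 0.3 nm, and Boltzmann-weighted
(eccentricity × β-strand fraction) free-energy landscapes
`F = −kT ln(n/n_max)` with K-means centroid extraction.

## Worked example

Generate a synthetic Aβ42-like hexamer trajectory with one scheduled
contact (residues 19–34 across chains 1–2 at probability 0.8), then
analyse it:

```r
library(oligotraj)

cfg <- generator_config(
  n_chains = 6, n_residues = 42, n_frames = 400,
  contact_spec = data.frame(res_i = 19, res_j = 34,
                            chain_a = 1, chain_b = 2, p = 0.8),
  seed = 42
)
sim  <- generate_hexamer_trajectory(cfg)
traj <- sim$trajectory
traj
#> <trajectory> 400 frames, 252 atoms, 6 chains (A,B,C,D,E,F), 42 residues/chain max
#>   box (frame 1): 12.23 x 12.23 x 12.23 nm

interaction_frequency(traj, 19, 34, "intermolecular")
#>   res_i res_j           mode n_pairs_interacting mean_interacting_distance
#> 1    19    34 intermolecular                   7                     0.495
#>   n_frames_interacting total_frames occupancy frequency_score
#> 1                  351          400     0.877            12.4
```

Seven of the 15 peptide pairs touch at least once; the mean in-contact
distance is 0.495 nm, and contact is present in 87.7% of frames — above
the 0.60 persistence threshold, so `interaction_occupancy()` flags the
pair as a stable contact. (The scheduled chain pair contributes p ≈ 0.8
of the frames; chance contacts in the associated cluster add the rest.)

```r
ss <- generate_ss_series(400, 6, 42, cfg$ss_transition, seed = 43)
ss_composition(ss)
#>    coil sheet helix n_frames
#> 1  59.4  40.2 0.421      400

shp <- shape_series(traj, window = analysis_window(traj))
mean(shp$rg_total); mean(shp$eccentricity)
#> 2.069 nm         0.858

landscape_centroids(shp$eccentricity,
                    strand_fraction(ss)[analysis_window(traj)],
                    k = 2, seed = 1)
#>   centroid eccentricity beta_proportion size
#> 1        1        0.975           0.419   59
#> 2        2        0.834           0.396  281
```

The composition reflects the generator's strand-biased stationary law
(40% sheet, almost no helix); the assembly is elongated (e ≈ 0.86), and
the two K-means centroids summarize the landscape in its natural units.
The full pipeline — every table family plus a manifest — runs from one
config: `run_full_analysis(analysis_config(generators = list(cfg),
seed = 1, output_dir = "report"))`, and `compare_systems()` contrasts
two systems (e.g. wild-type vs mutant) with the appropriate parametric
or rank-based test at p < 0.05. A thin command-line front-end is
provided in `exec/oligotraj` (subcommands `generate`, `report`,
`compare`).

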