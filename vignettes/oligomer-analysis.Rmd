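---
title: "Quantifying amyloid oligomer architecture: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid oligomer architecture: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotraj)
```

oligotraj analyses multi-chain molecular-dynamics trajectories of
early-stage amyloid oligomers — hexamers of peptides such as the
42-residue amyloid-beta isoform (Aβ42, cytotoxic) and the 31-residue
beta-endorphin isoform (βE31, functional) — and quantifies what
distinguishes their assembly: which residue pairs drive association, how
compact and elongated the oligomer is, how much hydrophobic surface stays
solvent-exposed, and how diverse the sampled conformations are. This
vignette documents the statistics the package computes, the parameters
that matter, and the design decisions taken where the underlying
definitions were genuinely open.

## The residue–residue interaction frequency

In a multimeric system a single residue pair (i, j) can interact many
times over: across the 15 distinct peptide pairs of a hexamer
(intermolecular) or within each of the 6 chains (intramolecular). The
package's central contact statistic compresses those observations into one
weight per residue pair:

$$\mathrm{score}(i,j) \;=\; \frac{N_{\mathrm{pairs}}(d \le c)}{\mu_{d \le c}}
  \times \frac{N_{\mathrm{frames}}}{\mathrm{total\ frames}},$$

with cutoff $c = 0.6\,$nm. $N_\mathrm{pairs}$ counts the peptide pairs
(or chains) that ever satisfy the cutoff over the whole trajectory;
$\mu_{d\le c}$ is the mean of all per-frame, per-pair distances at or
below the cutoff, pooled; $N_\mathrm{frames}$ counts frames with at least
one pair in contact. Units are 1/nm. A pair never in contact scores
exactly 0 and its $\mu$ is reported absent — this avoids a 0/0.

Two aspects of the formula are not fully pinned down by its verbal
definition, and we fixed them as follows:

* **$N_\mathrm{pairs}$ is a trajectory-level count** (a pair counts once
  if it is ever in contact), not a per-frame average. This reading keeps
  the count bounded by 15 (intermolecular) and 6 (intramolecular) for a
  hexamer, which is how the bound is usually stated.
* **The residue–residue distance is the minimum heavy-atom distance**
  (hydrogens excluded when present). It is robust across resolutions,
  from one-bead-per-residue test systems to full atomistics.
* **Intermolecular distances are symmetrized**:
  $d(i,j\,|\,A,B) = \min\{d(i_A, j_B),\, d(j_A, i_B)\}$, so interaction
  maps are symmetric matrices, matching how such maps are displayed.
* **Minimum-image convention** is applied to inter-chain distances
  whenever a periodic box is present; intra-chain distances use raw
  coordinates (chains are assumed whole).

`interaction_frequency()` computes one record; `interaction_heatmap()`
the full residue × residue matrix (replicates concatenated first with
`bind_frames()`, so the map is a composite over replicates);
`interaction_occupancy()` the fraction of frames in contact, with pairs at
or above the 0.60 persistence threshold flagged as stable contacts.

## Shape descriptors

`radius_of_gyration()` is the mass-weighted RMS distance from the centre
of mass; masses default to 1 when the topology carries none (the
coarse-grained fixtures), and element masses are used when available.

Eccentricity quantifies elongation from the gyration tensor
$S = \sum_i w_i\, (r_i - r_{cm})(r_i - r_{cm})^{\mathsf T}$ with
eigenvalues $\lambda_{max} \ge \lambda_{mid} \ge \lambda_{min}$:

$$e = \sqrt{1 - \lambda_{min}/\lambda_{max}}.$$

The literature uses several eccentricity-like descriptors and rarely
states which tensor, weighting and eigenvalue ratio were used. We chose
this form because it is bounded in $[0, 1)$ for non-degenerate point
sets, equals the classical ellipse eccentricity on uniform ellipsoids
(eigenvalues $(a^2, b^2, c^2)/5$, hence $e = \sqrt{1 - c^2/a^2}$), and
produces values in the 0.8–0.95 range for modestly elongated hexamers,
consistent with reported landscapes. The alternative
$1 - \lambda_{min}/\bar\lambda$ is available behind
`eccentricity(method = "mean")` for sensitivity analysis. A caveat for
validation work: the sphere limit $e \to 0$ converges slowly on sampled
clouds, as $n^{-1/4}$, because $e$ compares the two extreme eigenvalues;
isotropy checks therefore need millions of points, not tens of
thousands.

## Solvent-accessible surface area

`sasa_shrake_rupley()` implements the classic numerical SASA: each atom's
sphere of radius $r_i + r_\mathrm{probe}$ ($r_\mathrm{probe} =
0.14\,$nm) is covered with 960 quasi-uniform test points (a deterministic
golden-spiral set, so results are reproducible without a seed), and the
accessible fraction is the share of points inside no neighbouring
sphere. At 960 points an isolated sphere is recovered to well within 1%;
two-sphere overlap geometries agree with a $10^5$-point dense-sampling
reference within 2%. Per-atom areas partition exactly into per-residue
and total SASA.

Radii come from the topology: Bondi van der Waals radii by element, an
explicit radius for synthetic beads, and a 0.17 nm fallback (with a
warning) for unknown elements.

`residue_sasa_normalized()` divides each residue's SASA by its atom
count (nm² per atom) so large and small residues are comparable —
low values identify residues buried by hydrophobic packing.
`hydrophobic_sasa()` totals the SASA of Ala, Val, Leu, Ile, Met, Phe,
Pro and Trp (configurable); its increase under C-terminal polar mutations
is one of the package's key comparative readouts. Shape and SASA
statistics default to the final 85% of frames
(`analysis_window(start_fraction = 0.15)`), the window after the
oligomer's radius of gyration has converged and a stably compact
assembly exists; the fraction is configurable.

## Secondary structure

The fidelity path is ingesting DSSP output (`load_dssp_table()`), either
plain per-frame label strings or the GROMACS `.xpm` matrix dialect. The
8-state alphabet is reduced to three states: (H, G, I) → H (helix),
(E, B) → E (strand), everything else → C (coil). The reduction itself is
forced by working in a 3-state space; this particular mapping is the
conventional one.

When only coordinates are available, `assign_ss_dihedral()` labels
residues from backbone (φ, ψ) dihedrals using rectangular Ramachandran
regions — strand: φ ∈ [−180°, −45°], ψ ∈ [45°, 225° mod 360°]; helix:
φ ∈ [−100°, −30°], ψ ∈ [−67°, −7°]; otherwise coil; chain-terminal
residues with an undefined dihedral are coil. This assigner is a
fallback: it ignores the hydrogen-bond geometry a full DSSP uses, and we
deliberately did not re-implement that energy model.

Downstream summaries: `ss_composition()` (pooled coil/sheet/helix
percentages), `ss_propensity()` (per-residue state fractions),
`strand_fraction()` (per-frame fraction of all residues across all
chains labelled E — the strand axis of the landscape), and
`intermolecular_strand_pairs()` (counts of residue pairs on different
chains that are both strand-labelled and within the contact cutoff, the
package's proxy for intermolecular β-sheet pairing).

`ss_pca()` encodes each frame as a one-hot binary vector over
(chain, residue, state) triples, mean-centres, and projects onto the
first two principal components. Whether to one-hot encode three states or
use a per-residue strand fraction was an open choice; one-hot retains
helix/coil exchanges that a strand-only encoding collapses. One-hot
features produce exact ties in loading magnitude (a residue's E and C
indicators mirror each other), so component signs are fixed by making the
lowest-index maximal-magnitude loading positive — projections are then
reproducible across frame orderings. A constant series is reported as a
degenerate result with a warning, not an error.

`hamming_variability()` quantifies conformational lability of a residue
window (e.g. the C-terminal residues 28–42) as the mean and SD of the
Hamming distance between the window's label strings over all frame
pairs, frames pooled across replicates before pairing. Beyond $10^6$
pairs a seeded uniform subsample is used (cap configurable).

## Conformational landscape

`rmsd_kabsch()` is the SVD form of least-squares superposition with the
reflection guard, validated against an independent quaternion-based
implementation. `daura_cluster()` is the greedy neighbour-count
algorithm on the pairwise backbone RMSD matrix (default cutoff 0.3 nm):
the frame with the most neighbours becomes a centre, it and its
neighbours are removed, repeat; ties break to the lowest frame index.
The backbone selection falls back to all atoms on coarse-grained input.
The implementation is exhaustively cross-checked against a brute-force
re-derivation on random instances.

`boltzmann_surface()` bins paired per-frame observables — eccentricity
against strand fraction — and converts counts to relative free energies
$F = -k_\mathrm{B}T \ln(n/n_\mathrm{max})$, so the modal bin sits at
$F = 0$ and empty bins are masked (never silently assigned $F = 0$).
$F$ is reported in kT units (kT = 1 by default); whether to reference
the mode or normalize to probabilities is a display choice — the
count-ratio form round-trips exactly back to empirical bin
probabilities, which the tests assert. Default 50 × 50 bins over the
observed range, configurable.

`landscape_centroids()` runs K-means on the raw (eccentricity, strand
fraction) points with no standardization, so centroids are directly
readable in the landscape's natural units; the best of 50 seeded
restarts by within-cluster sum of squares is kept, and centroids are
reported sorted by eccentricity descending. `k` is user-supplied (2 and
3 are the typical choices for the two peptides); no automatic selection
is attempted because none is defined for this analysis.

## Chemistry-aware interactions

These detectors need side-chain atoms and reject one-bead input with an
explicit error:

* **Salt bridges** (`salt_bridges()`): basic nitrogen (Lys NZ, Arg
  NH1/NH2/NE, optionally His ND1/NE2, plus each chain's N-terminal amino
  nitrogen) to acidic oxygen (Asp OD1/OD2, Glu OE1/OE2, plus the
  C-terminal carboxylate) at ≤ 0.4 nm. Terminal groups are reported
  separately from side chains, so a terminal aspartate can bridge through
  both its amino and carboxylate groups.
* **Hydrogen bonds** (`hydrogen_bonds()`): donor–acceptor (N/O to N/O)
  distance ≤ 0.35 nm; when the donor carries a resolved hydrogen the
  D–H···A angle must deviate from linear by ≤ 30°; without hydrogens the
  distance criterion alone applies (heavy-atom mode).
* **π-stacking** (`pi_stacking()`): ring-centroid distance ≤ 0.55 nm for
  Phe/Tyr/Trp/His rings, classified by the acute interplanar angle as
  parallel (≤ 30°), T-shaped (≥ 60°) or intermediate.

The distance and angle cutoffs are standard literature values; they are
arguments, not constants.

## The synthetic trajectory generator

MD trajectories at the microsecond scale are not reproducible at a desk,
so every analysis stage is validated against a generator whose ground
truth is known exactly. `generate_hexamer_trajectory()` emulates the
study conditions the analyses target:

* six identical chains (one C-alpha bead per residue, bond 0.38 nm, bead
  radius 0.19 nm) built by `generate_chain()` as self-avoiding walks
  pivoted to a target radius of gyration within 10% (default 1.09 nm for
  a 42-residue chain — a compact monomer);
* initial placement at least 1.4 nm apart in a 12.23 nm cubic box (the
  separation used to start association simulations outside a long-range
  interaction cutoff);
* 2000 frames spanning a 2 μs window (1 ns sampling — the sampling
  interval of real data varies, so the frame count is a parameter);
* association of chains 2–6 onto a growing cluster at frames spread over
  the first 30% of the trajectory (mirroring the time by which the
  assembly's radius of gyration converges), implemented as a daisy-chain
  of anchor beads kept within 0.6 nm;
* per-residue 3-state secondary-structure Markov chains with a
  strand-biased stationary law — default (H, E, C) =
  (0.005, 0.40, 0.595) with single-step persistence 0.9, bracketing the
  strand-rich, helix-poor compositions reported for these peptides;
* optional `contact_spec` entries whose per-frame contact events are
  i.i.d. Bernoulli(p) draws, realized by placing the two beads inside
  (≤ 0.58 nm) or outside (> 0.6 nm) the cutoff. Because the downstream
  distance is symmetric in the two residue orientations, the generator
  also keeps the mirrored bead pair out of contact — otherwise measured
  occupancy would exceed p. Independence makes binomial confidence
  intervals exact oracles for the occupancy estimator.

Every frame is a rigid transform of the chain's reference conformation
plus fresh, non-accumulating bead jitter, so chain shape and Rg hold
exactly at their generated values for arbitrarily long trajectories.

What the generator does **not** emulate: force-field energetics,
realistic diffusion kinetics, correlated secondary-structure changes
coupled to contacts, or autocorrelated contact lifetimes (unless a
persistence parameter is introduced). Passing the recovery tests
therefore demonstrates that the estimators are correct and unbiased
under known sampling laws — not that they would be well-converged on a
given amount of real MD data.

## Numerical and statistical choices

* **Determinism.** Every stochastic routine takes a seed and uses it via
  a save/restore wrapper; no global RNG state leaks. The full pipeline is
  byte-identical across reruns of one configuration.
* **Contact-probability recovery in tests.** Each generated trajectory's
  occupancy lands inside the binomial 95% interval with probability
  0.95 by construction, so a 20-seed check demands at least 17 inside
  (the probability of fewer is below 2% under the generator's truth)
  rather than all 20 — the latter would fail a correct implementation
  about a third of the time.
* **Markov recovery tolerance.** The ±0.02 recovery band at 10⁴ frames
  assumes weak autocorrelation; with persistence 0.9 the effective
  sample size shrinks ~19-fold and the band is only ~1σ. Recovery tests
  therefore either pool several residues (independent chains) or use
  persistence 0.5; the estimator itself is unchanged.
* **Degenerate inputs.** Constant series → degenerate PCA signal; empty
  interaction sets → score 0 with absent μ and empty tables (with
  warnings), not errors; single points → Rg 0; collinear points →
  eccentricity 1; empty result tables are refused by the writers rather
  than silently creating header-only files.
* **Replicate pooling.** Statistics described as composites (interaction
  maps, landscapes, Hamming variability, the pooled composition row) are
  computed over concatenated replicate frames; per-replicate rows and a
  replicate-mean row are emitted alongside, since both pooling orders
  are defensible for composition tables.
* **Problem sizes.** The test suite and the acceptance script run the
  oracles at deliberately small scale — trajectories of 5–50 frames for
  exhaustive cross-checks, 10³–10⁴ frames for recovery statistics, a
  40-frame 3-replicate hexamer fixture for the end-to-end pipeline —
  sizes at which brute-force re-implementations remain exact references
  while the statistical bands stay several σ wide.

## The pipeline

`run_full_analysis()` drives every stage from one `analysis_config()`
(or its YAML form): secondary structure, contacts, shape and SASA,
clustering, landscape, centroids. A failed stage is logged into the
manifest and its tables marked absent — chemistry-aware detectors, for
instance, are legitimately absent on coarse-grained input — while
configuration errors abort before any computation. The manifest records
every parameter, seed, stage status, timing and collected warning, so
each number in the bundle is traceable to one module call.
`compare_systems()` puts two bundles side by side and tests each scalar
family: Welch's t-test when both samples pass Shapiro–Wilk normality and
an F-test of equal variances, otherwise a Wilcoxon rank-sum test, with
differences flagged at p < 0.05. RMSD clustering within the pipeline
subsamples evenly to `max_cluster_frames` (default 200) because the
pairwise matrix is quadratic in frames; `daura_cluster()` itself has no
such cap.

## Known limitations

* No XTC reader: trajectories enter as multi-model PDB, GRO, or
  structure + DCD.
* The dihedral secondary-structure assigner is a rectangular-region
  approximation, not DSSP; quantitative composition comparisons should
  use ingested DSSP output.
* SASA is numerical (Shrake–Rupley), not analytic (Lee–Richards arcs);
  accuracy is controlled by the point count.
* The generator's dynamics are diffusive toy dynamics; kinetics-derived
  quantities (contact on/off rates, relaxation times) are out of scope.
* Interaction-frequency scores for a residue pair with itself
  (intramolecular diagonal) are defined as 0 by convention.
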