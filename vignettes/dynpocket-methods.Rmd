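---
title: "dynpocket: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dynpocket: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpocket)
```

# Overview

`dynpocket` distils MD ensembles of a two-lobe kinase into five layers of
analysis: superposition-based flexibility metrics, essential-dynamics PCA,
interaction geometry, NMR-observable validation, and a geometric pocket
classifier over solvent-mapping probe clusters. This vignette records the
model each layer assumes, the parameters that matter (with units and
defaults), the numerical conventions, and the choices made where the
design was genuinely open. Nothing here asserts an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# Superposition and flexibility metrics

**Model.** Conformations are compared after optimal rigid-body
superposition (Kabsch): centroids matched, rotation from the SVD of the
cross-covariance with the determinant forced to +1, so reflections are
never returned. Degenerate (collinear, < 3 atom) fit sets are errors, not
best-effort fits. The test suite cross-checks the SVD route against an
independent quaternion (Kearsley smallest-eigenvalue) oracle to 1e-8 Å on
random instances.

**Selections.** The backbone atom set is fixed to {N, CA, C, O} — the
standard heavy-atom backbone convention — and recorded here because RMSD
values are not comparable across tools unless this set is pinned.
Defaults follow the kinase construct this package targets: fitting and
measurement on the backbone of non-terminal residues 14–344, author (PDB)
numbering, 1-based inclusive ranges, no renumbering. Selections resolve
deterministically in atom order and an empty selection is always an
error — never a silently empty result.

**RMSF aggregation.** Per-residue RMSF is the root-mean-square over the
residue's selected atoms *and* frames of the deviation from each atom's
time-average position. "Per residue" could also mean averaging atomic
RMSFs arithmetically; root-mean-square aggregation was chosen because it
keeps Parseval-style additivity with the per-atom variances. Reports
exclude the floppy terminal stretches (residues 4–13 and 345–354) by
default, mirroring how such profiles are usually displayed for this
kinase; `include_termini = TRUE` restores them.

**Region registry.** Six named regions (glycine-rich loop 30–38, L6 loop
93–99, αD helix 113–119, activation loop 169–183, MAP kinase insert
243–261, L16 loop 305–330) ship as the default; a region is flagged when
its mean RMSF exceeds the whole-profile mean. The threshold is
deliberately parameter-free; users wanting z-scores can compute them from
the returned per-region means.

**Strides.** RMSD/RMSF default to the trajectory's native 0.1 ns frame
spacing; the all-to-all matrix defaults to a 1 ns stride, because the
pairwise-fit matrix is quadratic in frames and the convergence-stripe
reading does not need finer sampling. The matrix uses *pairwise* fitting
(frame j onto frame i), not fitting everything to a single reference:
single-reference fitting underestimates distances between two frames that
are both far from the reference, which is exactly the regime a
convergence diagnostic cares about.

**Density estimates.** Gaussian kernel with Scott's bandwidth
(`bw = "nrd"`), 512-point grid, renormalized to integrate to 1 within
1e-3; all-identical samples degrade to a histogram with a warning
(kernel bandwidth would be zero). Histogram densities are normalized by
the exact rectangle rule over bins rather than a trapezoid over
midpoints, which would bias flat densities upward by one bin width.

# Essential dynamics

**Model.** PCA is computed on Cα atoms only, after Kabsch-aligning every
frame of every contributing run to a common reference; frames from
different runs (apo/holo, different force fields) are concatenated with
per-frame run labels. The covariance is about the ensemble mean with
**no mass weighting** — a config flag exists but is a no-op for Cα-only
ensembles (uniform carbon masses), and leaving it off keeps eigenvalues
in Å² rather than amu·Å².

**Numerics.** For 3n ≤ 3000 the symmetric eigensolver on the explicit
covariance is used; above that, the SVD of the centred data matrix, which
avoids forming a large covariance; both routes agree to tight tolerance
on the spectra. Eigenvector sign is fixed by making each mode's
largest-magnitude element positive, so projections are reproducible
across runs and platforms; ties in the projection extremes are broken by
the earliest frame index. Morphing is linear Cartesian interpolation
after Cα alignment — adequate for visualizing a mode, not a physical
path; frame-to-frame RMSD along a morph is constant by construction.

**External structures.** Crystal structures are projected after Cα
alignment to the model mean, using only residues present in both the
structure and the model's Cα set (missing residues excluded pairwise).

# Interaction geometry

Hydrogen-bond distances addressed through "the backbone amide" resolve to
the amide **nitrogen**: donor hydrogens are absent from most
crystal-derived inputs, and N–acceptor distances are the reproducible
proxy. Ring centers are unweighted geometric centroids by default; for
C/N heavy-atom rings the mass-weighted center differs negligibly, and
element masses of parameterized ligands are not guaranteed in inputs
(`mass_weight = TRUE` switches). Which of a ligand's rings stacks against
a given tyrosine is configuration, not code: ring atom sets are supplied
as `ring_spec`s, with ligand atom-name aliasing supported, because
parameterized atom names (e.g. CB5, NC1) need not match the PDB chemical
component's names.

Dihedrals follow the IUPAC convention (cis = 0°, range (−180°, 180°]),
validated against an independent cross-product formulation; this
convention is invariant under reversing the atom quadruple. Equilibrium
restraint angles are derived from several source structures by the
**circular mean** (atan2 of mean sine and cosine) — arithmetic means are
wrong near the ±180° wrap — with an explicit error when the resultant
vector is numerically zero (antipodal inputs). Whether a reference
restraint table was built by circular or arithmetic means or from a
single structure is not knowable from the table itself; the packaged
check tolerance (±2°) reflects that.

The charged-residue distance matrix uses Cα as each residue's
representative point (deterministic, always present); a charged-group
sidechain centroid is available behind a flag. Two reports are compared
by the element-wise RMS difference.

# NMR-observable comparison

Simulated values sit on the x-axis, experimental on the y-axis; the
regression is ordinary least squares over the **key intersection** only,
with unmatched records counted and reported, never silently absorbed.
`r²` is the squared Pearson correlation (identical to OLS R² for a simple
regression, asserted to 1e-10 in tests). Outliers are ranked by absolute
residual from the fitted line — with one observation per key, per-key RMS
error collapses to exactly this — and default to the top 6. For chemical
shifts the pipeline averages predictions over snapshots *then* regresses
(ensemble averaging is the physical claim being tested); per-snapshot
Pearson-R densities are exposed for RDC-style analysis where
snapshot-level agreement is the question. Prediction engines themselves
are out of scope: their tabular outputs are consumed through a declared
TSV schema, and alignment-medium settings are provenance metadata only.

# Pocket classification

Probe clusters and pocket lining residues are both reduced to spheres.
The bounding sphere is **centroid + maximum distance**, not the minimal
enclosing sphere: deterministic, cheap, and the downstream 0.75 scaling
already counteracts volume overestimation (a Ritter-style minimal sphere
sits behind `method = "minimal"`). Singleton clusters get a 0.5 Å radius
floor so the intersection volume is well defined. The lens/containment/
disjoint piecewise volume is continuous at both branch boundaries
(checked numerically to 1e-6 Å³) and is validated against a seeded
Monte-Carlo integration oracle.

The 0.75 scaling applies to the **pocket** sphere (r2) — the quantity at
risk of overestimation is the binding-site volume, since lining-residue
spheres sweep in whole residues. Assignment is argmax intersection
volume; all-zero overlap leaves the cluster unassigned; ties break by
registry order with a logged warning. Pockets flagged as ATP-site members
merge under the single label "ATP" (only the pocket named ATP carries the
flag in the packaged registry; subpocket labels are user-extensible, as
the registry is data, not code).

Consensus strength S counts probe **clusters** per pocket (not probe
poses), and the druggability threshold S ≥ 16 is evaluated **per
snapshot** by default — a pocket is druggable if any snapshot attains it —
with a pooled mode behind a flag, because whether the threshold applies
per snapshot or to pooled clusters is ambiguous in the source convention.
Pockets never hit by any cluster report `NA` ("N/A") occurrences rather
than zero, preserving the distinction between "never formed" and
"formed but empty". The snapshot stride for pocket analysis is 1 ns.

# Synthetic data: what it emulates, and what a green test means

The toy protein is two compact pseudo-residue lattices (default 180 + 174
residues = a 354-residue construct, matching the numbering of the
packaged residue registries) with one Cα-like atom per residue (backbone
quads behind a flag), centroids 30 Å apart, a hinge pivot midway between
the domains. Trajectories apply to domain 2 a hinge rotation
`A_h sin(2πt/T)` (one cycle) and a twist rotation `A_t sin(4πt/T)` (two
cycles, so the two angle series are orthogonal in time), plus Gaussian
loop displacements in the six registry regions and isotropic thermal
noise (default σ = 0.2 Å per coordinate). All generators save and restore
the session RNG state and are bit-identical functions of (spec, seed).

One subtlety is load-bearing: because every frame is later Kabsch-aligned,
the collective mode a PCA can recover is the rotation's displacement
field *projected out of the whole-structure rigid-motion subspace* —
aligning partially absorbs a single-domain rotation as global motion. The
generator therefore reports (and `calibrate_motion()` calibrates against)
the projected mode vectors and their Jacobian norms, solving
`A_rad = sqrt(2·var)/|J|` to realize stated mode variances (the canonical
test world uses hinge:twist = 9:1 Å² with noise variance 0.04 Å²). The
analytic top-2 variance fraction is `(v_h + v_t)/(v_h + v_t + 3nσ²)`,
ignoring the ~6 degrees of freedom alignment removes from the noise —
a < 1% effect at n = 354 atoms, well inside the 5% recovery tolerance.

What the generator does **not** emulate: physical energetics (kinematics
only, no force field), anharmonicity and multi-basin hopping, correlated
loop motions, solvent, or realistic probe-cluster shapes (clusters are
isotropic Gaussians; outliers sit on a far shell guaranteed outside every
pocket sphere). A green planted-mode or planted-cluster test therefore
establishes the *correctness of the computation*, not the realism of any
particular simulation — the distinction matters when comparing against
published trajectory-derived numbers, which additionally depend on
force-field and sampling choices this package does not reproduce.

# File formats and the pipeline

Multi-model PDB is parsed with fixed-width columns; alternate locations
collapse to the highest-occupancy conformer (ties by altloc letter),
waters and common monoatomic ions drop unless requested, ligand HETATMs
are kept under their component atom names, and parse errors name the
offending line. DCD (CHARMM/NAMD single-precision layout, byte order
auto-detected, optional unit-cell records skipped) is read and written
natively; **XTC is not supported** — its compressed coordinate format
needs a decompression library with no available R binding here, and
hand-rolling it was judged out of proportion when DCD and multi-model PDB
cover the ingestion contract. Pipeline configuration is nested JSON (no
YAML parser is available in the supported dependency set); runs write CSV
tables plus a manifest carrying the config hash and seeds, and identical
config + seed reproduces outputs byte-identically.

# Known limitations

* Crystal-structure checks that require downloaded PDB entries (e.g.
  reproducing a ~0.5 Å backbone RMSD between the apo and inhibitor-bound
  starting structures) are documented but not packaged: coordinates are
  third-party data and the test environment is offline. The capability is
  exercised on synthetic structures instead.
* The minimal-enclosing-sphere option is a Ritter-style approximation,
  within a few percent of optimal — acceptable because the classifier
  compares volumes across pockets, not absolute volumes.
* `charge_census` implements the neutral-pH titration convention
  (ARG/LYS +1, ASP/GLU −1, HIS 0, capped termini neutral); it is a
  bookkeeping device for counterion counts, not a pKa predictor.
* Pocket lining-residue sets in the packaged registry are 3–5 residues
  per pocket; if a different lining definition is preferred, the registry
  is a TSV and can be replaced wholesale.
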