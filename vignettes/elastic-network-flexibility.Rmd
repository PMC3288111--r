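---
title: "Elastic-network normal-mode flexibility analysis with enmaflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network normal-mode flexibility analysis with enmaflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmaflex)
```

## The model

enmaflex represents a structure as a set of nodes (one per residue at its
C-alpha, plus every heavy atom of cofactors and ligands, or one per heavy
atom in all-heavy mode) connected by identical Hookean springs. Every node
pair closer than a connectivity cutoff $R_c$ receives a spring whose rest
length is the observed distance, so the input conformation is by
construction the energy minimum — the single-parameter potential

$$E = \frac{k}{2}\sum_{(i,j):\,d^0_{ij}\le R_c}\left(d_{ij}-d^0_{ij}\right)^2 .$$

The second-derivative (Hessian) matrix of this energy at the minimum has
3x3 super-elements $-\,(k/d_{ij}^{0\,2})\,\Delta r_{ij}\Delta r_{ij}^T$ off
the diagonal and minus the row sums on the diagonal. It is positive
semidefinite; for a connected, non-degenerate free molecule its null space
is exactly the six rigid-body motions, so the first internal mode is mode
7. Eigenvalues $\lambda_j$ give vibrational frequencies
$\omega_j=\sqrt{\lambda_j}$ and eigenvectors the collective displacement
patterns.

Everything runs in reduced units: $k = 1$, $k_BT = 1$, unit node masses.
Physical masses can be supplied (`solve_modes(..., masses=)`), but the
relative quantities reported — relative frequencies and relative RMSF —
are unaffected by a global rescaling of $k$, mass, or temperature.
Frequencies are reported relative to the first internal mode; an optional
absolute scale anchors that mode at 2.5 cm$^{-1}$, the conventional order
of magnitude for the slowest protein modes (`freq_cm1` in
`mode_summary()`).

## Rotation-translation blocks

For large systems the eigenproblem is solved in the rotation-translation
block (RTB) subspace: consecutive runs of residues form blocks, each block
contributes up to six orthonormalized rigid-body basis vectors (three
translations, three rotations about the block centroid), and the Hessian
is projected as $P^THP$. By the Rayleigh–Ritz principle every projected
eigenvalue bounds the corresponding full eigenvalue from above; the slow
modes are nearly unchanged for protein-sized blocks. Degenerate blocks
keep only their well-defined rigid degrees of freedom (a single node 3, a
collinear pair 5). Hetero groups form one block per residue and lipid
surrogate nodes one block each.

The default block size is one residue per block, which makes the
projection exact for C-alpha networks (the spectrum equals the full solve
to machine precision; the test suite asserts 1e-8). Coarser blocks are a
speed/accuracy trade-off controlled by `residues_per_block`; choose
roughly `ceiling(n_residues / 2000)` to keep the projected problem below
~12,000 degrees of freedom.

## From modes to flexibility

The mean square fluctuation of node $i$ is accumulated from the $n_v$
slowest internal modes,

$$\langle \Delta r_i^2\rangle = \frac{k_BT}{m_i}
  \sum_{j=7}^{6+n_v}\frac{\|U_{ij}\|^2}{\omega_j^2},$$

with rigid modes excluded (`msf()`). The default $n_v = 100$ converges the
profile for protein-sized networks; with all internal modes included the
sum is mathematically identical to the diagonal of the Moore–Penrose
pseudo-inverse of the Hessian, which the tests verify on small systems.
Note one subtlety exercised by the C$_n$-symmetric test oligomers:
truncating the sum inside a degenerate multiplet can split symmetry-related
profiles, so symmetry comparisons should use `n_v = Inf`.

Flexibility is reported as **relative RMSF**: $\sqrt{\mathrm{MSF}}$
normalized so its mean over the reporting set is exactly 1. Computed
B-factors use the universal isotropic relation $B = (8\pi^2/3)\,
\langle\Delta r^2\rangle$; because the MSF is in reduced units, comparison
with crystallographic B-factors goes through an affine fit
(`rescale_to_experiment()`): ordinary least squares of $B_\mathrm{exp}$ on
$B_\mathrm{calc}$, where the intercept absorbs the rigid-body and lattice
disorder contribution present in X-ray B-factors but absent from
internal-mode fluctuations, and the slope converts units. OLS was chosen
over total least squares because the experimental values play the role of
the response with roughly homoscedastic error; terminal residues, which
crystallographic data resolve poorly, can be trimmed from the fit
(`exclude_termini`, default 3 per chain end).

## Regions and radial layers

`assign_regions()` resolves named residue sets (heme, substrate, catalytic
cleft, access channel, heme-proximal cavity, and the electrostatic E/P
sites used in the charged-residue census) and splits all nodes into radial
layers around the substrate centroid: inner core $r\le 15$ Å, middle layer
$15<r\le 20$ Å, outer layer $r>20$ Å by default. Layer membership uses the
residue's C-alpha position; boundary points belong to the inner of the two
adjacent layers. Region means are unweighted arithmetic means over
residue-level values (per-node values are first averaged within
multi-node residues such as the heme).

A ready-made configuration for the aromatase (CYP19A1) monomer ships in
`inst/extdata/aromatase_regions.yaml`. The access-channel and E/P-site
lists follow the published residue enumerations; the catalytic cleft is
left to the structural fallback rule (any heavy atom within 4.5 Å of the
bound steroid), and the proximal-cavity list is an explicit approximation
spanning the helix C/H' segments and the K''-L loop — the literature names
these elements without printing the exact list, so quantitative region
means there carry that caveat and the list is meant to be overridden.

The heme and substrate enter C-alpha networks with all of their heavy
atoms rather than a single centroid node: the heme region must be
populated well enough for a meaningful region mean, and per-atom inclusion
also gives the cofactor realistic local connectivity. Alternate locations
are resolved by highest occupancy (ties: first listed); hydrogens and
waters are dropped on reading.

## Crystallographic oligomers

`apply_symmetry()` expands a structure by fractional-basis symmetry
operators through the standard crystallographic orthogonalization matrix;
the trigonal group P3$_2$21 — whose 3$_2$ screw axis generates
head-to-tail P450 oligomer chains — is built in, and arbitrary operator
lists (optionally with whole lattice translations, for reaching contacting
copies in neighbouring cells) are accepted. Generated copies get fresh
chain labels, and `min_chain_distance()` provides the brute-force contact
scan used to verify interface formation. The conventional cutoffs are
10 Å for a monomer and 8 Å for oligomers; both are plain arguments.

## The bilayer-slab surrogate

For membrane-embedded analysis the package deliberately replaces an
all-atom lipid bilayer with a coarse surrogate: two square lattices of
elastic-network nodes at the head-group planes ($z=\pm15$ Å by default,
80 × 80 Å laterally, 5 Å spacing). Lipid nodes are ordinary network nodes
(unit mass, same force constant, one RTB block each); embedding removes
every lipid node within a clash radius (default 3 Å) of any protein heavy
atom and reports the removal count.

Two flat lattices alone would be mechanically degenerate under a pairwise
potential — out-of-plane displacements and leaflet shear are unresisted to
first order. The surrogate therefore adds inter-leaflet *struts*
(`membrane_struts()`): each upper-leaflet node is connected to the
lower-leaflet nodes within one lattice step laterally (the vertical strut
plus its four diagonals), standing in for the tail–tail coupling of a real
bilayer. With struts the embedded complex is a proper free system with
exactly six zero modes, which the tests assert.

What the surrogate reproduces is the qualitative membrane effect: extra
connectivity at the contact surface damps the relative RMSF of
membrane-contacting residues and shifts the intramolecular bending/twist
modes to higher mode numbers, where `match_modes()` can locate them by
cosine overlap (after projecting out net rigid motion over the shared
nodes). What it does not reproduce is anything that depends on lipid
chemistry, leaflet fluidity, or the absolute stiffness of a particular
lipid model — absolute mode indices and RMSF-ratio magnitudes of a
specific all-atom membrane model are outside its scope, and only
directions of change should be interpreted.

## Synthetic test systems

`make_zigzag_chain()`, `make_helix()`, `make_two_domain_dumbbell()`,
`make_ring_oligomer()` and `make_pseudo_bfactors()` generate structures
with known properties, and all emit legal PDB records so tests exercise
the real I/O path. Three geometric facts shape their design and are worth
knowing when building your own fixtures:

* a collinear chain has only five rigid modes;
* a *planar* network is degenerate under the pairwise potential (every
  out-of-plane displacement is a first-order zero mode), so the zigzag
  chain winds out of plane and the dumbbell linker is helical;
* sparsely connected chains (nearest-neighbour springs only) have many
  internal zero modes — unresisted bending and torsion. This is physical
  for the model, and `solve_modes()` then numbers modes after the actual
  `n_zero` with a warning.

The dumbbell is exactly mirror-symmetric (the right domain is the mirror
image of the left, and the linker winding depends on $|x|$ only), which
gives an exact symmetry oracle for MSF profiles; ring oligomers are
exactly C$_n$-symmetric. The pseudo-B-factor generator plants a known
affine transform plus Gaussian noise on a computed MSF profile so the
rescaling fit can be tested against its sampling distribution.

Passing these tests demonstrates that the machinery — network assembly,
Hessian, RTB projection, eigensolver conventions, fluctuation sums,
fits, reports — is correct. It does not demonstrate anything about real
proteins beyond what the elastic-network model itself claims; fixtures
are far smaller and more regular than a folded protein, and experimental
B-factors contain rigid-body, lattice and refinement contributions that
the affine shift only approximates.

## Numerical choices

* Zero-mode tolerance: $\lambda < 10^{-8}\lambda_{\max}$; tiny negative
  eigenvalues inside the tolerance are clamped to zero.
* Eigensolver: LAPACK dense symmetric (`eigen(symmetric = TRUE)`), on the
  RTB-projected matrix when a partition is given; back-projected
  eigenvectors remain orthonormal because the projection operator has
  orthonormal columns.
* Sparse Hessian storage above 1000 nodes, dense below.
* Coincident nodes (zero rest length) and empty networks are hard errors;
  multi-component networks and non-6 zero counts are warnings, since both
  are legitimate (disconnected oligomer sanity checks use them).
* Pair search is chunked to bound memory at ~160 MB per distance block.
* Determinism: every generator and pipeline run is a pure function of its
  configuration and seed; provenance records include an MD5 hash of the
  configuration (excluding output paths).

Problem sizes in the shipped tests and acceptance script were chosen so a
full run completes in well under a minute on one core: clouds of 10–40
nodes where a dense oracle (finite differences, SVD pseudo-inverse, full
eigensolve) is feasible, chains of 80–100 residues for fit statistics,
and a 30-residue helix in a 40 × 40 Å slab for the membrane path. The same
code paths scale to monomer/oligomer systems of a few thousand residues
via the RTB projection.

## Limitations

* Harmonic, single-minimum model: no barriers, no anharmonicity, no
  absolute amplitudes without external calibration.
* The B-factor comparison inherits everything OLS cannot capture —
  TLS-like anisotropy, local refinement restraints, and the exact choice
  of origin shift, which is under-determined by the data.
* The slab surrogate is qualitative by design (above).
* mmCIF, electron density, and assembly annotations beyond operator
  application are out of scope; PDB fixed-column format only.
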