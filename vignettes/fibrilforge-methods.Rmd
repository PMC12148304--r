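---
title: "Building crosslinked collagen fibrils: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building crosslinked collagen fibrils: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilforge)
```

Collagen I fibrils are quasicrystalline bundles of ~300 nm triple helices
staggered axially by the ~67 nm D-period and held together by lysine-derived
covalent crosslinks at the telopeptide ends. fibrilforge generates atomistic
models of such fibrils from a single triple-helix template whose PDB header
carries the unit cell, and measures the structural observables that validate
them. This vignette explains the models, the parameters that matter, and the
numerical choices; it is the package's own account of its methods.

## From unit cell to fibril: symmetry expansion

A triclinic cell $(a, b, c, \alpha, \beta, \gamma)$ defines the upper-triangular
orientation matrix

$$
C = \begin{pmatrix}
a & b\cos\gamma & c\cos\beta\\
0 & b\sin\gamma & c_{yz}\\
0 & 0 & \sqrt{c^2 - c_{xz}^2 - c_{yz}^2}
\end{pmatrix},
\qquad
c_{xz} = c\cos\beta,\;
c_{yz} = c\,\frac{\cos\alpha - \cos\beta\cos\gamma}{\sin\gamma},
$$

whose columns are the cell vectors; $\det C$ equals the closed-form triclinic
volume, which the tests verify on a thousand random cells. Symmetry copies are
rigid transforms $T(q) = Rq + t$; for the P1 collagen cell $R = I$ and $t = Cn$
with $n \in \mathbb{Z}^3$ a Bravais lattice point. A copy is part of the fibril
when any of its atoms lies within the contact distance $d_c$ of the original
molecule — the "any-atom" inclusion rule. The rule is stated ambiguously in
crystallographic tooling (any-atom vs. center distance); we use any-atom and
note that absolute copy counts can shift by small amounts between conventions.
Larger $d_c$ admits copies further out in the lattice and hence thicker
fibrils.

The candidate lattice range is bounded per dimension by
$|n_i| \le \sum_k |C^{-1}_{ik}|\,(w_k + d_c)$, where $w$ are the widths of the
template's bounding box: a translation that moves the cloud beyond its own
box dilated by $d_c$ cannot produce an included copy. This bound (rather than
one based only on the shortest cell axis) matters for collagen, where a
~300 nm molecule sits in a cell whose $c$ vector is strongly tilted. A
bounding-box distance lower bound prunes candidates before the exact
any-atom check; both checks are compared against brute-force enumeration over
$[-3,3]^3$ in the tests.

Steric clashes between copies are resolved at whole-copy granularity, greedily
in enumeration order, with the identity copy always retained: a pair of atoms
clashes when $d < f\,(r_i + r_j)$ with van der Waals radii $r$ (Bondi values,
1.7 Å for unknown elements) and overlap fraction $f = 0.6$ by default. No
factor is canonical in the literature for this filter, so it is exposed as a
parameter. Retained sets are re-checked in the tests by an $O(n^2)$ scan.

## Layer-by-layer Bravais lattice optimization

Finite fibrils are depleted at their axial boundaries: fewer molecules, fewer
closed crosslinks. The optimizer works on the lattice-point representation
$p = C^{-1}t$. The solution space $\delta = (\delta_x, \delta_y, \delta_z)$
selects $2\delta_z$ boundary $n_z$ layers — the $\delta_z$ layers adjacent to
each extreme layer, the extremes themselves excluded. Within a layer, the
occupied points span a rectangle (optionally padded by $\delta_x, \delta_y$;
a documented extension, default 0) and the unoccupied rectangle points form
the candidate set. Candidates are visited in seeded random order; a trial
molecule is the reference molecule translated to the candidate point, and it
is accepted iff some inter-crosslink atom pair to the existing system is
within the 3.0 Å (0.3 nm) noncovalent contact cutoff *and* the trial is
clash-free. Accepted molecules join the system immediately, so later
candidates see them. Layers are processed from the outermost selected layer
inward, lower block first — a deterministic order that makes reports
reproducible. With $\delta = (0,0,0)$ the system is returned unchanged, and
the optimizer never removes molecules.

"Inter-crosslink distance" is evaluated between designated reactive
side-chain atoms only (the registry's atom lists), not whole residues: the
contact criterion models chemistry available to form a bond, not generic
proximity.

## Crosslink engineering

The crosslink library (YAML, versioned, user-extensible) maps each type to
its valence and member residue codes: divalent types such as HLKNL join
exactly two residues, trivalent types such as PYD exactly three. A crosslink
*unit* in an assembled system is a connected component of the residue
proximity graph at the contact cutoff; valence bookkeeping is enforced at the
unit level, and removal always takes all members of a unit together.

Two manipulations are supported. *Mixing* assigns each molecule a class —
a crosslink type per telopeptide end, e.g. the four equal-ratio classes
div–div, tri–div, div–tri, tri–tri — by independent sampling with the given
weights; realized counts are reported and the assignment is reproducible
under its seed. Class assignment relabels the terminus site residues to the
chosen type's codes; the geometry is left untouched (a full structure-library
swap is a modeling step outside this package's scope), which is sufficient
for composition bookkeeping and downstream topology tools. *Removal* replaces
crosslink units with lysine at a user rate; the rate is interpreted as an
exact fraction (`round(rate * K)` of the `K` units, round-half-even) rather
than per-unit Bernoulli, so repeated runs give identical counts; a Bernoulli
mode is available behind a flag. Replaced residues keep their backbone and
receive an idealized lysine side chain.

Side chains — for lysine replacement and for threading substitutions — are
built by internal-coordinate extension (the standard NeRF construction) with
idealized bond lengths, 111° angles, trans dihedrals and ±120° branches.
Ring closure is not enforced for cyclic side chains and no rotamer or energy
optimization is performed; the procedure guarantees correct atom inventories
and chemically plausible, deterministic geometry, not refined packings.

## Sequence threading

Target sequences are threaded onto the template backbone under a
Gly-anchored constraint. The aligner is an in-repo affine-gap global
alignment that treats the declared helical region at triplet granularity:
deleting a helical unit removes exactly one Gly-X-Y triplet, and insertions
between two helical units are forbidden, so the glycine frame survives any
alignment by construction; telopeptides align unconstrained at residue
granularity. (An external multiple-aligner would not express this
constraint, which is the scientifically load-bearing part.) Identities below
a configurable floor (30%) raise a distant-homolog warning.

Threading copies backbone atoms (N, CA, C, O) verbatim for aligned positions
— hence per-residue backbone RMSD is exactly zero for substitution-only
threading, and the all-atom per-residue displacement stays within the 2 Å
bound asserted in the tests. Deletions remove residues; helical insertions
are rejected with an explicit error; telopeptide insertions are skipped with
a warning since there is no template backbone to place them on. Hydroxyproline
is carried as `O` in the one-letter alphabet and `HYP` in structures;
template modifications are inherited at conserved positions.

The axial rise per triplet is the along-axis distance between consecutive
glycine C$\alpha$ atoms, averaged within and then across chains; the axis is
the first principal component of all C$\alpha$ positions, which is robust to
slight supercoiling. Canonical collagen gives ≈8.6 Å per triplet.

## Assembly

Merging renumbers serials contiguously and assigns per-molecule segment
identifiers (`M001`…) with cyclic chain ids, because PDB chain identifiers
exhaust at 62 symbols; the manifest maps molecules to (segid, chains) and
makes the merge invertible, which the tests verify through a write/parse
round trip. Structures beyond 99,999 atoms switch to a wide-serial dialect
with a warning. Cutting removes residues whose C$\alpha$ leaves the axial
window (anchored at the minimal z by default — the anchor is configurable
since no convention is canonical), never splits a residue, and drops chain
fragments shorter than 3 residues. Capping adds an acetyl (ACE) group at
each N-terminus and an N-methylamide (NME) at each C-terminus at idealized
amide geometry — 6 atoms per cap, zero net formal charge — flagging rather
than capping chains with incomplete backbones.

## Structure metrics

**D-band periodicity.** One-dimensional K-means ($k = 10$ by default) on the
axial coordinates of crosslinking residues identifies the bands; adjacent
center distances below 38 nm are overlaps, above are gaps, and the D-period
is mean(overlap) + mean(gap) — robust to edge effects over a 10-cluster
banding; per-pair distances are also reported since it is not obvious whether
a single representative pair or the average is the better summary. K-means
details are never canonical: we use `stats::kmeans` with 100 restarts under a
seed and verify against an exact 1-D dynamic-programming clustering oracle in
the tests; in one dimension the global optimum is reliably attained. When the
number of distinct coordinates does not exceed $k$ the exact solution is used
directly. All distances on one side of the threshold is reported as
degenerate banding with an undefined D.

**Lateral spacing.** Molecule representative points (C$\alpha$ center of mass
within the central 50% axial slab, to suppress end effects) are projected
onto the transverse plane; for each molecule the nearest neighbor in each of
the four quadrants around it contributes a local spacing. The quadrant frame
defaults to the in-plane principal axes, making the metric invariant under
rotation about the fibril axis; for designed square lattices that frame is
degenerate and a fixed frame with explicit rotation is available. Projections
closer than 0.1 nm are merged first: molecules stacked axially in one lattice
column are one lateral site. On ideal lattices, border molecules can have
quadrants whose nearest neighbor is a second-shell point; the bulk statistics
are unaffected, and real (disordered) fibrils do not exhibit the degeneracy.

**Connectivity and density.** A molecule end counts as crosslinked when any
of its site atoms is within the contact cutoff of another molecule's site
atoms; molecules are classified both-ends / one-end / unconnected and the
fractions sum to one. Radial point density is counted in transverse shells
about the lattice origin, normalized by shell area; packing uniformity is the
standard deviation of per-cell occupancy over the layer rectangles, which the
optimizer demonstrably reduces on vacancy fixtures. The fibril radius is the
95th percentile (configurable) of transverse distances from the axis.

## Synthetic fixtures and what they do (not) show

All tests run on deterministic generators:

* `make_triple_helix()` — an ideal Gly-Pro-Hyp triple helix with exact
  2.86 Å/residue axial rise (so 8.58 Å/triplet is true by construction),
  polyproline-II-like twist, three phase-shifted chains, and a minimal
  backbone per residue.
* `make_template()` — a coarse triple helix in a collagen-like triclinic P1
  cell whose $c$ vector is tilted by one lateral pitch per period: symmetry
  expansion staggers copies by the designed ~67 nm D-period while displacing
  them laterally, exactly as the quasicrystalline packing requires.
  Telopeptide arm residues and their helical partner residues are placed so
  expansion closes crosslink contacts at 2.5 Å. The cell parameters are
  chosen on the PDB fixed-column grid (angles to 2 decimals) so the written
  CRYST1 record reproduces the geometry essentially exactly; the realized
  period (67.13 nm for the defaults) is reported by the cell itself. The
  bead spacing divides the period exactly so that axially staggered copies
  in the same lattice column register the steric clash a continuous molecule
  would. This cell is a documented synthetic stand-in — it is not any
  experimentally determined collagen cell.
* `make_fibril()` — pre-assembled lattices ("row", "grid", "bands") with
  fully specified crosslink units: divalent arms that close with lattice
  x-neighbors, three-membered trivalent junctions, and the designed-band
  arrangement whose crosslink z positions fall at 0, 27, 67, 94, … nm
  (27 nm overlap + 40 nm gap = 67 nm D).

The fixtures emulate geometry, not biochemistry: no realistic side-chain
packing, no sequence realism beyond the Gly-X-Y frame, coarse beads instead
of full atoms in the templates. Passing tests therefore demonstrate that the
algorithms recover designed ground truth — copy sets, filled vacancies, band
positions, pitches, exact crosslink arithmetic — not that models of real
collagen are accurate at the force-field level. Runs against an external
experimentally derived collagen template are a separate, optional tier that
requires obtaining that structure.

## Problem sizes and numerical choices

The test suite uses deliberately small systems: templates of ~520 coarse
beads expanded at $d_c$ = 25 Å (tens of molecules), 3×3×4 optimization grids,
10-band D-period fixtures, and 10,000-molecule statistical fixtures with
3-atom molecules; the statistical assertions use 3σ binomial bounds. Key
tolerances: 1e-9 for cell algebra round trips, 1e-3 Å (PDB precision) for
file round trips, 1e-3 lattice-integrality tolerance in `map_to_lattice`
(beyond which a translation is rejected as off-lattice rather than rounded),
0.5 nm for recovered band centers, and the acceptance bound of 0.2 Å around
the canonical 8.6 Å axial rise.

Known limitations: only P1 symmetry operations are generated (other space
groups fall back to their translational sub-lattice with a warning — the
collagen target is P1); threading cannot create insertions; idealized side
chains are unrefined; trivalent fixture arms are omitted at row boundaries so
that every generated unit is chemically complete.
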