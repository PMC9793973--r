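---
title: "Methods: pocket design by pairwise decomposition and GMEC search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket design by pairwise decomposition and GMEC search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketdesign)
```

## The design problem

Given a protein scaffold with a ligand placed in its binding pocket,
the package searches for the combination of side-chain conformations
(and optionally amino-acid identities) at a set of pocket positions,
together with a rigid ligand placement, that minimizes a decomposed
interaction energy. The search space is discrete: each design position
offers a finite list of rotamers, the ligand offers a finite list of
poses, and a design solution picks exactly one candidate per position.
The minimizer over this space is the global minimum energy conformation
(GMEC).

The backbone and all non-selected side chains are fixed throughout; the
package models no backbone flexibility and evaluates only the bound
state (no unbound-ensemble or partition-function quantities, and no
affinity prediction in physical units - only relative ranking of design
variants).

## Energy model

The total energy of an assignment decomposes exactly into

* **self terms** - interaction of one variable group (a rotamer or a
  ligand pose) with the fixed scaffold, and
* **pair terms** - interaction between two variable groups,

because every energy function used is a sum over atom pairs. This
exactness is the property the solver relies on, and it is asserted to
`1e-9` relative error in the test suite by comparing table sums against
a direct whole-system evaluation for every assignment of seeded toy
systems.

Two tracks are computed:

* **Packing track** (protein-protein, kcal/mol): 12-6 Lennard-Jones in
  Rmin/epsilon form, `E = eps ((rmin/r)^12 - 2 (rmin/r)^6)` with
  `rmin = rmin_half_i + rmin_half_j`, `eps = sqrt(eps_i eps_j)`, plus
  Coulomb `k q_i q_j / r` with `k = 332.0636 kcal A / (mol e^2)`.
  Atom pairs separated by one or two bonds are excluded and three-bond
  pairs are scaled (defaults 0.5 for LJ and 1/1.2 for Coulomb); with
  rigid backbones this matters only across the CA/CB cut of a rotamer's
  own residue and its peptide neighbors. No distance cutoff is applied:
  exact decomposability is worth more at this problem scale than the
  speed a cutoff would buy, and a cutoff would break the conservation
  property at its boundary.
* **Binding track** (protein-ligand, score units): a Vina-style
  empirical pairwise score over heavy atoms. For surface distance
  `d = r - (R_i + R_j)` the terms are two gaussians
  (`exp(-(d/0.5)^2)`, `exp(-((d-3)/2)^2)`), a quadratic repulsion
  `d^2` for `d < 0`, a hydrophobic ramp (1 below 0.5 A, 0 above
  1.5 A) for hydrophobic pairs, and an H-bond ramp (1 below -0.7 A, 0
  above 0 A) for donor-acceptor pairs; pairs beyond an 8 A
  center-center cutoff are skipped. Default weights are the published
  Vina values (-0.035579, -0.005156, 0.840245, -0.035069, -0.587439);
  all weights and the cutoff live in `vina_weights()`, so alternative
  parameterizations (e.g. Vinardo-style radii/weights) are a
  configuration, not a code change. This is interaction rescoring
  only: no rotatable-bond/entropy normalization is applied. Atom
  classes (hydrophobic, donor, acceptor) come from the parameter
  table, not from chemical perception, which keeps the scoring core
  free of cheminformatics dependencies.

In the solver objective, binding entries are multiplied by a
configurable `binding_scale` (default 50), so the objective is
`packing + 50 * binding`. Reports always carry both the raw and the
scaled binding energy, so rankings can be read on either scale.

## Flexibility sampling

**Pocket selection.** A residue is flexible when the minimum distance
from any of its side-chain heavy atoms (CB and beyond) to any ligand
heavy atom, or to the CA of a mutation position, is at most 4 A
(configurable). The side-chain-atom convention is a deliberate choice -
the shell criterion is about side-chain contact; using all atoms or CB
only would shift the shell by roughly a bond length. Residues at
segment termini, cysteines in disulfide bridges (SG-SG <= 2.3 A) and
prolines are then made static; mutation positions themselves are always
flexible unless a static rule removes them.

**Rotamers.** Side chains are rebuilt from ideal-geometry templates
(internal-coordinate tables, heavy atoms only), attached at the
residue's N/CA/C frame, with chi dihedrals taken from a
backbone-dependent rotamer library indexed by the residue's phi/psi
bin (nearest bin center, default width 10 degrees, boundary ties
toward -180). Chi application is exact by construction: rebuilding
from internal coordinates reproduces a requested chi to well under the
0.5-degree tolerance the tests assert. No post-placement minimization
is applied - relaxing rotamers into the pocket systematically favors
bulky side chains, so clash relief is delegated entirely to pruning.
Templates carry no hydrogens: chi placement, pruning, and both scoring
tracks operate on heavy atoms here, and hydrogen-free templates keep
the geometry tables small and auditable. Input scaffolds may still
contain hydrogens; they simply stay part of the fixed scaffold.

**Poses.** Each input conformer (conformer generation is upstream of
this package) is rotated intrinsically about its heavy-atom centroid in
fixed axis order x, y, z and translated, over the Cartesian product of
per-axis value lists `{-max, ..., -step, 0, step, ..., max}`. Defaults
are +/-20 degrees and +/-0.5 A with step = max, i.e. three values per
axis and 3^6 = 729 poses per conformer - the smallest grid consistent
with sampling the stated extremes; finer steps are configuration. The
transform is rigid by construction and the tests assert distance-matrix
preservation to 1e-6 A. Pose order is lexicographic in (conformer,
rotation, translation), which fixes table layout and tie-breaking.

**Pruning.** Rotamers and poses with a Lennard-Jones interaction of
100 kcal/mol or more against the fixed scaffold are discarded before
any table is computed. The threshold is interpreted as LJ-only (not
LJ + electrostatics): the quantity named is a van der Waals energy, and
an electrostatic contribution could mask a steric clash with a
favorable charge pair. A position losing all rotamers, or a pose set
losing all poses, is a hard error rather than a silent shrink.

## GMEC search

The assignment problem is written as the classic side-chain-positioning
integer linear program: binary node variables `x[p,r]` (candidate `r`
at position `p`), binary edge variables `y[p,r,q,s]` for every position
pair, constraints `sum_r x[p,r] = 1` and
`sum_s y[p,r,q,s] = x[p,r]`, objective
`sum self * x + sum pair * y`. The ligand enters as one extra position
whose candidates are the poses and whose self vector is the scaled
ligand-scaffold binding vector - this unifies rotamers and poses in one
formulation. Models can be exported in LP format (`write_lp()`) for
inspection.

The ILP is solved to proven optimality with the HiGHS mixed-integer
solver (reached through `scipy.optimize.milp` via reticulate). MILP
backends are free to return any optimum, so ties are resolved
deterministically: after the optimal value is known, a probe solve
checks whether a second optimal assignment exists at all; only then an
epsilon-free lexicographic pass fixes, position by position, the
smallest candidate index that still attains the optimum. The brute
force oracle (`brute_force_gmec()`, capped at 1e6 assignments) applies
the same tie-break, and solver-oracle identity - value and tie-broken
assignment - is asserted on 200 random instances plus 100
planted-optimum instances in the acceptance suite.

N-best enumeration re-solves with exclusion cuts
(`sum of matched node variables <= positions - 1` per previous
solution), yielding distinct assignments with non-decreasing totals;
requesting more solutions than assignments returns all of them with a
warning.

## Evaluation operators

* `rank_pair()` implements the benchmark criterion for an
  experimentally ordered pair of variants: the prediction is correct
  when the computed binding energy of the stronger binder is lower.
  Exact ties are conservatively scored incorrect (with a warning), and
  the same comparison on total energies is reported as an independent
  column.
* `pocket_rmsd()` / `ligand_rmsd()` superpose designed onto reference
  structures by least squares over all shared backbone heavy atoms
  (Kabsch, SVD-based, cross-checked against bio3d's fit in the tests)
  and report heavy-atom RMSD over flexible-residue side chains or
  ligand atoms only.

## The toy-system generator

`make_toy_system()` builds a fully synthetic design case: six residues
on an ideal alpha-helical backbone (phi = -57, psi = -47, built by
NeRF from internal coordinates), native side chains from the first
library entry, a 2-5 atom rigid "ligand" placed 4.2 A off the central
residues' CB direction, element-typed parameter tables, and a small
helix-bin rotamer library. The seed controls a +/-0.005 A coordinate
jitter and small charge jitter, so systems differ across seeds while
every geometric property (helix bin, pocket distances) is preserved;
identical specs produce byte-identical files. The library deliberately
contains one rotamer per position pointing into the helix body (so
pruning always removes something) and rotamers pointing toward the
ligand (so the binding track always has favorable contacts).

What the toys do and do not show: they exercise every contract -
parsing, geometry, decomposition, pruning, solving, reporting - but
they are chemically naive (no hydrogens, schematic charges, no real
rotamer statistics, a non-physical ligand). Passing on toys
demonstrates the machinery is correct, not that predictions on real
proteins are accurate; accuracy on real systems depends on the force
field, library and scoring inputs supplied by the user.

`make_known_optimum_instance()` plants a strictly dominant assignment
in random tables by lowering every entry the assignment touches by a
margin exceeding twice the term count (entries are bounded by 1), which
guarantees the GMEC analytically; with margin 0 the construction
degenerates to an unbiased random instance.

## Numerical choices and problem sizes

* Energies in kcal/mol, coordinates in Angstrom, angles in degrees,
  everywhere.
* Decomposition identity asserted at 1e-9 relative error; rigid-pose
  identity at 1e-6 A; chi reproduction at 0.5 degrees; PDB round-trips
  at the format's 1e-3 A precision (hence re-scoring written designs is
  asserted at 1e-2 kcal/mol).
* ILP tie detection uses a 1e-7 relative tolerance on the optimal
  value; random continuous instances have unique optima with
  probability one, and constructed tie tests use exactly representable
  values well above that tolerance.
* Alternate locations resolve to the highest occupancy (ties: first
  record); insertion codes and multi-model scaffolds are rejected
  outright rather than guessed at.
* The test and acceptance runs use deliberately small instances - two
  design positions with ~4 kept rotamers each, 1-54 poses for
  table-level checks, up to 4 x 5^4 x 10 assignments for solver
  checks - chosen so the exhaustive oracles stay exact and the whole
  suite runs in about a minute on one core.

## Caching and parallelism

Every pipeline stage hashes its inputs and configuration (MD5 over a
canonical JSON serialization, file contents by checksum); a stage is
skipped iff a stored manifest carries the same hash, so changing, say,
the pruning threshold recomputes rotamers and everything downstream but
not the pocket selection. Pair-energy blocks are embarrassingly
parallel; the block list and its order are fixed before dispatch, so
results are bit-identical for any worker count - asserted by comparing
rendered reports byte for byte.

## Known limitations

* No backbone flexibility, loop remodeling, or proline ring closure;
  tryptophan has no template.
* Rotamer groups are heavy-atom only; polar-hydrogen directionality in
  H-bonds is therefore only as good as the donor/acceptor class flags.
* The ILP backend requires a Python with scipy >= 1.9 reachable by
  reticulate.
* `brute_force_gmec()` is exact but exponential; it is a verification
  tool, not a production solver.
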