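---
title: "Methods: binding modes, order parameters and MM-GBSA energetics for ligand-DNA trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding modes, order parameters and MM-GBSA energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

quadbind analyzes trajectories of a small planar cation binding to
G-quadruplex or duplex DNA.  It answers three questions about such a
trajectory: *where* does the ligand bind (stable-complex detection,
pose clustering, top/bottom/groove classification), *how* does it get
there (per-frame order parameters, backbone torsions, base-flip
events), and *how strongly* (an MM-GBSA binding-energy decomposition
and a relative ranking of modes).  Everything is exercised against
idealized structures and scripted trajectories with exact ground
truth, generated by the package itself.

This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## Data model

A `quad_model` holds one row per atom (name, element, residue, chain,
partial charge in elementary charges, Lennard-Jones `rmin/2` and
epsilon, intrinsic Born radius from an mBondi-style set, and the HCT
descreening scale factor), the covalent bond list, per-atom roles
(receptor / ligand / ion), the ordered G-tetrad annotation (tetrad 1
nearest the 5' terminus) and the channel-ion atom indices.  A
`quad_traj` is the model plus ordered coordinate frames with strictly
increasing times (50 ps apart by convention).  Coordinates are
Angstrom, energies kcal/mol, angles degrees.  Indices are 1-based both
in memory and in files - the native R convention, applied uniformly
rather than the 0-based internal / 1-based external split common in
Python tools.

Trajectories travel as multi-model PDB (human-inspectable,
dependency-free); parameters as a whitespace-delimited sidecar table
keyed by (residue name, atom name), because PDB columns cannot carry
charge + LJ + GB cleanly; tetrads, roles and channel ions as a small
YAML annotation file.  Bonded exclusions follow the AMBER convention:
1-2 and 1-3 pairs excluded, 1-4 pairs scaled by 1/1.2 (electrostatics)
and 1/2 (LJ).

## Binding-mode identification

* **Stable complex.** Receptor-ligand atom contacts at a 3.0 A
  atom-to-atom cutoff; a frame is a stable complex when the count is
  strictly greater than 10.
* **Pose metric.** Every frame is superposed on the first frame by a
  least-squares (Kabsch/SVD) fit of the receptor backbone (P, O5',
  C5', C4', C3', O3'); the pairwise ligand RMSD is then computed with
  no further fitting, so the metric sees where the ligand sits on the
  receptor, not just its internal shape.
* **Clustering.** The Daura algorithm at a 2.0 A cutoff: the frame
  with the most neighbors seeds a family, the family is removed, and
  the scan repeats.  Ties in neighbor count go to the lowest frame
  index - the original description leaves this open, and a documented
  deterministic tie-break makes runs reproducible.  Families under 1%
  population are dropped; populations are fractions of *stable*
  frames and are never renormalized after the filter, so reported
  percentages need not sum to 100.
* **Classification.** Families are merged into modes by a geometric
  rule that replaces visual inspection: project the ligand-core
  centroid onto the tetrad stack axis (tetrad-1 centroid toward
  last-tetrad centroid, i.e. 5' to 3').  Beyond the tetrad-1 plane and
  inside the axial cylinder (max tetrad radius + 3 A) is *top*; beyond
  the last tetrad plane, *bottom*; otherwise within 6 A of the
  receptor surface, *groove*.  A pose with zero receptor contacts is
  refused and labelled *unbound*.  For duplexes the terminal base
  pairs are annotated as two-residue pseudo-tetrads and the same rule
  applies (top = stacked on the pair nearest the 5' end of chain A).

## Order parameters

Per frame: hydrogen bonds per annotated tetrad (donor-acceptor
distance <= 3.5 A and donor-H-acceptor angle >= 120 deg; guanine N1-H
and N2-H donate to O6 and N7 of the other tetrad guanines), the
plane-plane angle between the ligand core and the nearest tetrad
(folded to [0, 90] deg, since a plane-plane angle has no orientation),
the receptor backbone RMSD against the initial structure, the ligand
RMSD against the first frame after a receptor-backbone fit, the
receptor-ligand center-to-center distance R (unweighted heavy-atom
centroids), and the channel K+-K+ distance.

Backbone torsions follow the standard nucleic-acid definitions (alpha
through zeta along the sugar-phosphate backbone, chi about the
glycosidic bond, IUPAC sign convention); angles whose atoms do not
exist at chain termini are reported missing.  Histograms bin over
(-180, 180] with an optional trailing window for "last part of the
run" summaries.

**Base flips.**  The flip detector is radial rather than torsional: a
residue is flipped out when its base-ring centroid lies farther from
the stack axis than the outermost base-ring centroid of the *other*
receptor residues in the first frame, plus a 2 A margin.  Published
flip events are characterized by different torsion combinations for
different residues, so no single torsion threshold is faithful;
radial displacement is the common geometric signature, and torsion
histograms remain the reporting surface.  The per-frame state is
smoothed by a 5-frame majority filter and condensed into (flip-out,
flip-in) intervals; an interval still open at the end has a missing
flip-in frame.

## MM-GBSA energetics

The engine evaluates, for any atom subset of a frame:

* 12-6 Lennard-Jones with AMBER combination rules, no cutoff;
* vacuum Coulomb with k_e = 332.0637 kcal A / (mol e^2);
* Hawkins-Cramer-Truhlar effective Born radii: the inverse descaled
  intrinsic radius (mBondi-style radius minus a 0.09 A offset) minus
  the closed-form pairwise descreening integrals over all other
  atoms' scaled spheres, including both overlap cases.  The closed
  form is validated against an independent angular-quadrature oracle
  that integrates r^-4 analytically along rays;
* the Still pairwise generalized-Born energy with Debye-Hueckel salt
  screening, E = -(k_e/2) sum_ij q_i q_j (1/eps_in -
  exp(-0.73 kappa f_ij)/eps_out) / f_ij, with the usual effective
  distance f and self terms f_ii = R_i.  kappa comes from the
  Debye-Hueckel expression at the configured salt concentration
  (default 0.15 M), dielectric (78.5) and temperature (298.15 K);
  note that salt *increases* the magnitude of the (negative) polar
  solvation term, the Debye-Hueckel limiting behaviour;
* Shrake-Rupley solvent-accessible surface area with a deterministic
  golden-spiral point set (960 points per atom, probe 1.4 A), times a
  surface tension of 0.0072 kcal/(mol A^2).  Atomic radii are the LJ
  rmin/2 values, self-consistent with the parameter table rather than
  a second radius set.  Each atom's point set is given a
  deterministic per-index rotation so quadrature errors decorrelate
  across atoms; totals on the receptor fixtures change by ~0.1% when
  the point count doubles.  The inner loop is compiled (Rcpp) - it is
  the pipeline's hot spot, as in other structural-analysis packages.

Binding energies use the three-trajectory bookkeeping: per complex
frame, each component is evaluated for the complex, the receptor in
the complex geometry and the ligand in the complex geometry, and
differenced; the conformation term is the mean total energy of
receptor and ligand taken from the complex minus their means over
free trajectories.  When free trajectories are omitted the term is
identically zero and the estimate reduces to the standard
one-trajectory interaction energy.  The component identity (total =
VDW + SUR + GBELE + conformation) is asserted to 1e-10 on every run,
and the conformation term cancels *exactly* (not just numerically)
when the free trajectories coincide with the from-complex sub-frames,
because its mean is computed as a difference of means.  Channel ions
and solvent are excluded from all energetics (the ion-stripped
convention).  Entropy is deliberately not computed: under comparable
entropic terms the mean binding energies rank modes, which is the use
made of them.  `delta_delta_g()` reports each mode's offset from the
most favorable one.

Interior/exterior dielectrics (1.0 / 78.5), temperature and the
averaging window (default: the last 40% of frames, after the final
pose is attained) are not fixed by the protocol this reimplements;
they are exposed in `gb_settings()` / `run_config()` with the
defaults above.  Absolute agreement with published per-mode means is
out of reach regardless - those derive from microsecond explicit-
solvent ensembles - so the energetic validation surface is the
closed-form limits, the pair-sum oracles, the decomposition
identities, and the exact ranking arithmetic.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions.

* **Quadruplex.** A 22-mer A(GGGTTA)3GGG folded into three stacked
  G-tetrads (rise 3.4 A, twist 30 deg between layers), two channel K+
  on the axis midway between adjacent planes, TTA loops and the
  5'-terminal A placed outside the core with a radial clearance
  search (>= 2.5 A to everything already placed).  Base geometry is
  the ideal nucleotide geometry shipped as a plain-text template
  table, flattened onto the layer plane, with the sugar pucker
  torsion delta set to 140 deg (canonical B-form range).  The
  in-plane guanine placement is solved once, deterministically, so
  that the Hoogsteen cycle registers: each tetrad yields exactly 8
  hydrogen bonds under the package's own criteria - a verified
  construction, not an assumption.  Strand polarity patterns
  (parallel / antiparallel / hybrid) permute which guanine of each
  strand occupies which layer.
* **Duplex.** Alternating GC B-form helix (rise 3.38 A, twist 36
  deg); the cytosine placement opposite guanine is solved the same
  way, giving exactly 3 Watson-Crick bonds per pair (a bifurcation
  penalty keeps the amine from double-counting against N3).
* **Ligand.** Three linearly fused six-membered rings (planar to
  numerical precision), a ring nitrogen in the central ring, an
  anilino-style arm opposite it and two flexible cationic arms ending
  in protonated amines; partial charges sum to exactly +3.  This is
  an emulation keeping the analysis-relevant features of a
  tri-substituted acridine - planarity, core nitrogen, three arms,
  +3 charge - not an exact chemical model, and its parameter table is
  synthetic with plausible magnitudes.
* **Scripted trajectories.** The ligand follows segments of
  unbound / approach / top / bottom / groove states as a rigid body.
  Bound poses are solved by a deterministic grid search over approach
  direction, face and spin that requires a stable-complex contact
  count (> 10 with margin) while keeping every receptor-ligand heavy
  pair outside the Lennard-Jones wall (3.2 A clearance for stacking,
  2.8 A for the bumpier groove surface).  Gaussian positional noise
  of the scripted amplitude (0.3 A per coordinate in the study
  conditions) is added per frame with two physically motivated
  refinements: hydrogens ride their bonded heavy atom's displacement
  (emulating constrained X-H bonds), and bound-frame draws that
  compress any receptor-ligand heavy pair below 2.75 A are resampled
  (a Boltzmann ensemble suppresses hard-core overlap exponentially).
  Flip events displace the scripted base radially by 12 A over
  6-frame ramps.  A fixed seed gives byte-identical output.

**What the synthetic validation shows - and does not.**  Passing
tests demonstrate that the pipeline recovers planted binding-mode
populations to within a few percentage points, planted flip intervals
to within a few frames, and that every energetic primitive matches
its closed form or independent oracle.  They do not demonstrate
robustness to receptor conformational change (the generator's
receptor is rigid apart from flips), to correlated thermal motion, or
to the force-field quality of real parameter sets.  In particular the
uncorrelated noise model cannot supply Boltzmann-weighted
*intramolecular* ensembles of a folded receptor - absolute
free-molecule energies under such noise are heavy-tailed - so the
Eq-4 conformation correction is validated on controlled toy systems,
and the analysis drivers score generator output with the
one-trajectory protocol.

## Numerical choices and degenerate inputs

* Superposition uses the SVD closed form with the reflection
  corrected to determinant +1; degenerate spectra keep the +1 branch.
  Fewer than 3 non-collinear fit points is a hard error.
* Plane fitting is total least squares (smallest singular direction);
  collinear input is a hard error; the normal's sign follows the
  5'-to-3' stack axis where one is available.
* The drug-tetrad angle is reported as the folded [0, 90] deg
  plane-plane angle; published pathway plots use an unstated sign
  convention, and the folded angle is the orientation-free choice.
* Daura clustering of an empty stable set is an empty result, not an
  error: "no stable complex" is a legitimate scientific outcome, and
  the pipeline reports it with exit status 0.
* Born radii are clamped to [0.1, 1e4] A against pathological
  geometries; descaled intrinsic radii must be positive.
* Energy evaluation refuses coincident charged atoms and unmatched
  parameter tables (hard errors naming the atom).
* Problem sizes: the shipped analyses use a 600-frame scripted run
  (30 ns at the 50 ps saving interval) and score 15-25 frames per
  mode; the validation suite goes up to 2000 frames.  These sizes
  make every result reproducible on a laptop in minutes while leaving
  the statistics (population errors well under the 5-point tolerance)
  unchanged.

## Known limitations

* The geometric mode classifier assumes an annotated tetrad stack (or
  duplex terminal pairs); exotic topologies without a meaningful
  stack axis would need a custom annotation.
* Intercalation is not a recognized mode; partially intercalated
  poses classify as groove or end-stacking depending on geometry.
* Hydrogen-bond "layers" beyond the annotated tetrads are accepted
  via the annotation file but not auto-detected.
* The MM-GBSA engine has no periodic electrostatics, no PB
  cross-check and no entropy term; it is an end-point ranking tool,
  not an absolute affinity predictor.
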