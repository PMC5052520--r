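---
title: "Halogen-bond detection, occupancy and active-site screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halogen-bond detection, occupancy and active-site screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbondr)
```

## The geometric model

`xbondr` treats a halogen bond as a purely geometric event: no
energies, no electronic structure. A covalently bound halogen carries
a σ-hole — a cap of positive electrostatic potential on the extension
of the C–X bond axis — so a halogen bond is both short (inside the van
der Waals contact) and directional (the acceptor sits near the C–X
axis). Two acceptor classes are modeled.

**Point acceptors (C–X···Y).** Y is any protein O, N or S atom,
backbone or side chain. The bond criteria are

* d(X···Y) < r(X) + r(Y), the vdW-sum cutoff, and
* β = ∠(C, X, Y) > 140°,

both strict. The default radius table is Bondi's: with it the chlorine
cutoffs come out at 3.27 Å (Cl···O), 3.30 Å (Cl···N) and 3.55 Å
(Cl···S). Bondi is the default precisely because it reproduces these
standard printed cutoffs; the table is user-overridable
(`xbond_criteria(vdw_table = ...)`), and individual pairs can be
pinned with `point_cutoffs` or a key–value config file
(`read_criteria_config()`).

**π acceptors (C–X···ring).** Rings come from Phe, Tyr, His and Trp
via fixed atom-name templates (PHE/TYR: CG CD1 CD2 CE1 CE2 CZ; HIS:
CG ND1 CD2 CE1 NE2; TRP: pyrrole CG CD1 NE1 CE2 CD2 *and* benzene CD2
CE2 CZ2 CH2 CZ3 CE3, tested independently — tryptophan's two π faces
are geometrically distinct acceptors). The criteria are

* d(X···centroid) < 4.2 Å,
* α < 60°, where α is the angle between the ring normal and the
  centroid→X vector, folded into [0°, 90°] so the normal's arbitrary
  sign is irrelevant, and
* θ = ∠(C, X, centroid) > 146°,

again all strict. The literature labels α and θ on the geometric
diagram without spelling out the construction; the definitions above
follow the established convention for X···π contacts. Because any
re-filtering choice is defensible, every observation records all of
its measured quantities (d, β or α/θ, and for π bonds also the
distance to the nearest ring atom), so users can re-threshold without
re-detecting. The centroid — not the nearest ring atom — defines d,
the standard convention; the nearest-atom distance is reported
alongside.

**Ring planes.** The centroid is the arithmetic mean of the member
positions; the normal is the total-least-squares plane normal (the
singular vector of the smallest singular value of the centered
coordinates). For a planar ring this is exact; for thermally puckered
rings it minimizes the summed squared point–plane distances. Fewer
than three atoms or collinear atoms are a degenerate-ring error; a
ring whose template atoms are missing from the structure (stripped or
partially resolved residues) is skipped with a warning rather than an
error, since that is routine in MD-derived structures.

**Strictness.** All criteria use strict inequalities, so a geometry
sitting exactly on a cutoff is never a bond. There is no epsilon
slack: classification flips exactly at the boundary, and the synthetic
generator (below) therefore plants frames well away from boundaries.

## Trajectory statistics

**Key distances.** A `distance_spec` names one atom pair (each side a
selection that must resolve to exactly one atom); `distance_series()`
is the per-frame Euclidean distance and `summarize_series()` reports
mean ± SD. The SD uses the sample (n−1) denominator; at the typical
1000 frames the difference from the population form is negligible, but
the choice is stated here and the raw series is always available. A
single-frame series reports SD 0 with a warning rather than NA, so
single-snapshot screening still produces a usable summary.

**Occupancy.** For each acceptor residue, occupancy is the fraction of
frames in which at least one halogen bond to that residue is observed.
A residue is counted once per frame no matter how many of its atoms or
ring faces accept simultaneously — occupancy is a residue-level
statement ("the halogen bond formed with this residue"), not a bond
count. Point and π bonds are pooled by default (`type = "all"`) and
also broken out per type in the same table. Frames are weighted
equally; there is no time weighting. Water is excluded as an acceptor
by default — whether waters should compete as X-bond acceptors in
occupancy statistics is genuinely open, so `include_water = TRUE` is
exposed but off.

## The screening rule

A mutant–substrate candidate passes against a wild-type reference iff
*both* key-distance means (e.g. `D_C8-SG`, the nucleophilic-attack
distance, and `D_N1-HZ`, the transition-state-stabilization proxy) are
strictly shorter than the reference's. The rule compares means only,
never spreads — a deliberate mirror of how such screening is practiced,
and a documented limitation: a candidate with a marginally shorter
mean but enormous variance still passes. For conservative screening,
`screen_mutant(..., k = 1)` requires mean + k·SD to clear the
reference. Both MD averages and single-snapshot distances are
accepted (a `dist_summary` with `n_frames = 1`), since first-pass
screening is often done on one modeled conformation before committing
to a full simulation. Ranking puts passes first by ascending sum of
the two candidate means, ties broken lexicographically by label. The
in-silico mutation step itself (side-chain replacement) is out of
scope; the module consumes summaries produced elsewhere.

## σ-hole extra points

The positive extra point (EP) represents the σ-hole as an off-atom
charge site: `ep = x + offset · (x − c)/|x − c|`, collinear with C–X,
beyond the halogen, at 1.90 Å by default. `apply_ep()` appends one EP
per bonded halogen (a halogen with no carbon within 2.1 Å is a
connectivity error) and, when charges are present, moves `ep_charge`
from the parent halogen to the EP so the molecular total is conserved
to 1e-10. The EP charge has **no default**: its magnitude comes from
an external electrostatic parameterization (RESP-style fitting), and
inventing one would be inventing electrostatics. Charges travel in a
sidecar CSV because the PDB format has no charge column of usable
precision.

## The synthetic generator

`make_toy_complex()` emulates the *statistical shape* of an
enzyme–substrate MD trajectory, not its physics: a fixed 20-atom
topology (a chloro-benzyl-cyanide-like ligand — aromatic ring,
chlorine, methylene, nitrile C8≡N1 — plus a backbone-oxygen acceptor
residue, a phenylalanine ring, catalytic Cys SG and Lys HZ
pseudo-atoms, and a distant distractor), with per-frame geometry
planted to order. Defaults are the study conditions the package is
validated under: 1000 frames; a point halogen bond at 95.08% occupancy
and a ring halogen bond at 80% (the two reported dominant-partner
occupancies in the motivating system); key distances
D_C8-SG ~ N(3.76, 0.21²) Å and D_N1-HZ ~ N(2.83, 0.56²) Å, a
productive wild-type-like complex. For each planted contact exactly
⌈fraction·n⌉ seeded-sampled frames satisfy all criteria of its type;
every other frame violates the distance criterion by at least 0.3 Å
(the declared margin — 10° for angle violations — exists so
floating-point noise can never flip a frame's classification, which is
what makes planted occupancy an *exact* ground truth rather than an
approximate one). In-criteria targets must likewise sit decisively
inside the criteria or the spec is rejected. Gaussian positional
jitter (default σ = 0.05 Å) is applied only to atoms that anchor no
planted geometry. Key distances are drawn from Gaussians truncated at
0.5 Å (a physical floor; at the default parameters truncation is
never triggered in practice). One integer seed governs all
randomness, and the RNG state is restored afterwards, so generation is
reproducible and side-effect-free.

What the generator does *not* emulate — correlated dynamics, solvent,
realistic packing, force-field energetics, conformational transitions
— bounds what passing tests show: they validate the *measurement
machinery* (detection, aggregation, screening arithmetic) exactly, not
the ability of any force field to produce correct ensembles. Published
occupancy percentages from real trajectories are format precedents
here, not reproduction targets; reproducing them would require the
original crystal structure, ligand parameterization and simulations.

`wt_vs_mutant_scenario()` plants wild-type key-distance means in a
non-productive range (5.5–8 Å and 7–10 Å) and mutant means either
strictly below both (expected pass) or above on at least one (expected
fail), with ≥ 0.5 Å margins against frame-level SDs of 0.21/0.56 Å —
at 150+ frames the standard error is below 0.05 Å, so the planted
verdict is recovered with overwhelming margin.

## Structure I/O and numerical choices

PDB parsing and writing delegate to `bio3d`, with a pre-scan that
enforces this package's contracts: malformed fixed-width records fail
with the line number, and MODEL blocks with unequal atom counts are a
topology error rather than silently mangled coordinates. Elements come
from columns 77–78 when present, otherwise from the atom name under
PDB v3.3 conventions with residue context (in a standard amino acid
"CA" is a carbon; in a hetero residue "CL1" is a chlorine; "1HB" is a
hydrogen). Alternate locations other than "A"/blank are dropped for a
deterministic single-conformer analysis. Waters and hydrogens are
retained at parse time — downstream stages filter explicitly — so a
catalytic lysine's HZ hydrogen remains addressable. Coordinates
round-trip at the fixed PDB precision of 3 decimals. Donor C–X pairs
are auto-discovered as any ligand halogen with a carbon within 2.1 Å
(a stretched pair warns but is still processed); F, Cl, Br and I are
all supported, with cutoffs always computed from the active radius
table so heavier halogens need no new constants.

Degenerate inputs error early and explicitly: zero-length angle arms,
a halogen coincident with its acceptor or ring centroid, selections
resolving to the wrong multiplicity, empty trajectories.

## Validation strategy and problem sizes

The test suite checks the detector against an independently written
brute-force enumerator (law-of-cosines angles, Newell polygon normals,
grid-searched plane fits — different algorithms on purpose) on
randomized 50-atom frames; recovers planted occupancies exactly at
fractions {0, 0.5, 0.8, 1}; verifies key-distance recovery at 1000
frames against 3σ sampling bounds (|mean − μ| < 0.02 Å at σ = 0.21);
runs 20 end-to-end screening scenarios at 300 frames each against
planted verdicts; and asserts invariance of every reported quantity
under random rigid motions to 1e-6. These sizes keep the full suite
in a few seconds while leaving the sampling bounds comfortably sharp.

## Known limitations

* Detection is O(donors × acceptors) per frame with no spatial
  indexing — appropriate for active-site analyses, slow for
  proteome-scale scans.
* The screening rule inherits its literature form: means only, two
  distances, strict inequalities. It is a filter, not a ranking of
  binding affinity.
* Ring perception is template-based for the four aromatic amino
  acids; non-standard aromatic cofactors would need their own
  templates.
* Binary trajectory formats (DCD/XTC/NetCDF) are not read; convert to
  multi-MODEL PDB or a directory of PDB frames first.
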