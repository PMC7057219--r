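---
title: "Coiled-coil search models for molecular replacement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coiled-coil search models for molecular replacement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmr)
```

## The problem

Coiled-coils are bundles of two or more alpha-helices winding around a common
supercoil axis, packed through a periodic "knobs-into-holes" interface. They
are hard targets for crystallographic phasing: their elongated, self-similar
structure produces weak discrimination between correct and incorrect
molecular-replacement (MR) placements, spurious translational
non-crystallographic symmetry (tNCS) signals, and frequent reverse-orientation
traps. One successful strategy is to build many cheap ab initio decoy models
of the target, exploit the agreement between decoys to predict which regions
are reliable, and convert the decoys into a ladder of truncated, polyalanine
search ensembles for MR.

`ccmr` implements the computational core of that strategy on self-contained,
generated inputs: a Crick-parameterized structure generator and decoy
simulator, the clustering/truncation/subclustering ensembler, generators for
the distance restraints and Cn symmetry definitions used to steer unbiased
oligomeric coiled-coil modelling, asymmetric-unit preparation of oligomeric
models, a coiled-coil geometry and knobs-into-holes analyzer, and a
multi-metric triage of candidate solutions.

## Ideal helices and the Crick parameterization

An isolated alpha-helix has about 3.6 residues per turn and a rise of about
1.5 A per residue (pitch 5.4 A). `build_alpha_helix()` does not take these
numbers as inputs: it grows a chain atom-by-atom from backbone dihedrals
(default phi = -57, psi = -47, omega = 180) and ideal bond geometry, and the
helical parameters are then *measured* from the result by the geometry
analyzer. The bond lengths are the standard N-CA 1.458 A, CA-C 1.525 A,
C-N 1.329 A; for the bond angles we adopt N-CA-C = 110.0 degrees (near
tetrahedral) and C-N-CA = 120.0 degrees (the sp2 ideal), under which the
canonical dihedrals reproduce the textbook helix (3.60 residues/turn, 1.50
A/residue) to within a few parts per thousand. Extended dihedrals
(phi = psi = 180) produce a planar beta-like zigzag with exactly 2 residues
per turn, which the test suite checks against an independent closed-form
internal-to-Cartesian conversion — the dihedrals, not a hard-coded helix,
drive the geometry.

A coiled-coil is modelled as a minor helix (radius `r1`, local periodicity
`residues_per_turn` = 3.5 for the heptad repeat, rise 1.5 A per residue
along the helix) wound on a superhelical path of radius `r0` and pitch
`pitch`. The sign of `pitch` encodes supercoil handedness, negative =
left-handed (the classic case). Chain 1 is generated from the parametric
curve; chains 2..m are exact rotations of chain 1 by 360/m degrees about the
supercoil (z) axis, so Cn symmetry holds to machine precision before any
noise. Defaults (`r0` = 4.9 A, `pitch` = -140 A) give the classic
left-handed parallel dimer: the measured axial translation per alpha-helical
turn is ~5.1 A and the interhelical crossing angle ~25 degrees.

Since the parametric build produces a CA trace, backbone atoms (N, C, O, CB)
are rebuilt around it from local-frame offsets measured once on a canonical
dihedral-built helix. The default minor-helix phase (180 + 360/14 degrees)
places heptad core positions symmetrically about the inward direction, so
that a- and d-like positions face the bundle core.

## The synthetic decoy generator

`generate_decoys()` emulates the *shape* of an ab initio decoy population
that the ensembler exploits: a multi-basin distribution in conformation
space. `n_conformers` basins are placed at fixed, well-separated positions
in (r0, pitch) space (pairwise CA RMSD between basin centres at 48 residues
is at least ~2.5 A); each decoy is drawn from one basin with

* small within-basin supercoil-parameter jitter (sd 0.1 A on r0, 1 A on
  pitch, 2 degrees on minor phase),
* isotropic per-atom Gaussian noise (`sigma`, default 0.3 A), and
* extra scatter (`fray_sigma`, default 0.5 A) on `fray_len` = 5 residues at
  both termini — terminal fraying, the dominant mode of local disagreement
  between otherwise similar decoys.

These scales are chosen once so that the within-basin spread (maximum RMSD
to the basin medoid ~1.2 A) sits clearly below the default clustering
threshold (1.5 A), which in turn sits below the between-basin separation
(>= 1.9 A after noise). That separation of scales is the property the decoy
set is *designed* to exhibit: agreement across decoys predicts local
accuracy, and clustering must be able to recover the basins. Generation is a
pure function of (base, spec): a seed is part of the specification and the
same seed reproduces bit-identical coordinates.

What the generator does **not** emulate: real ab initio decoys contain
register shifts, kinks, partially unfolded termini, compact globular
misfolds and non-helical secondary structure. Passing tests on these
synthetic sets demonstrate the correctness of the ensembling machinery under
its stated assumptions, not the accuracy of any ab initio modelling program
on real sequences.

## Ensembling: cluster, score, truncate, subcluster

`generate_ensembles()` reproduces the standard search-model preparation:

1. **Clustering** (`cluster_decoys`): greedy representative-based clustering
   under a pairwise CA RMSD threshold (default 1.5 A), capped at 30 members
   per cluster (closest to the representative first) and at most 10
   clusters. The published pipelines use SPICKER for this step; its exact
   internals are not reproduced here — the observable contract (at most ten
   aligned clusters of bounded size) is. On small instances the greedy
   partition is verified against an exhaustive threshold-partition oracle.
2. **Variance profile** (`variance_profile`): per-residue CA positional
   variance across the aligned members; a singleton cluster is defined to
   have an all-zero profile.
3. **Truncation** (`truncate_cluster`): 20 nested levels; level k keeps the
   (100 - 5(k-1))% lowest-variance residues (so a 20-residue chain yields
   subsets of 20, 19, ..., 1 residues). Ties break to the lower residue
   index; duplicate sizes collapse. Nesting is guaranteed by construction.
4. **Subclustering** (`subcluster`): greedy medoid subclusters at radii 1
   and 3 A; every member lies within the radius of its medoid, and the
   largest subcluster at each (cluster, level, radius) becomes the search
   ensemble.
5. **Polyalanine treatment** (`polyalanine`): residues renamed ALA, atoms
   restricted to N, CA, C, O, CB; no CB is fabricated for glycine.

With the default configuration the pipeline emits at most 10 x 20 x 2 = 400
ensembles, with equality when every cluster, level and radius is populated —
which the default synthetic decoy set (1000 decoys, 10 basins, 48 residues)
achieves. The two radius variants are kept as distinct ensembles even when
their membership coincides, since they are distinct search-model
hypotheses. An optional `top_k_models` filter (e.g. 25) restricts clustering
to the best externally-scored decoys; the score is treated as opaque
metadata from the modelling program, not recomputed.

## Restraints for unbiased oligomeric modelling

Elongated monomeric modelling is steered by a single long-range restraint
between the terminal CA atoms with centre 1.5 n A for an n-residue chain —
the length of an ideal alpha-helix — plus removal of the
radius-of-gyration scoring bias (recorded as `-rg_reweight 0` in the flags
file). Oligomeric modelling adds one short-range restraint per residue
between cyclically adjacent symmetry copies of that residue's CA: a
flat-harmonic function centred at 10 A with flat half-width 5 A and
standard deviation 3 A, i.e. zero penalty anywhere between 5 and 15 A and
`((|x - x0| - tol)/sd)^2` outside. That window spans both core (heptad) and
solvent-exposed inter-chain distances, so the restraints direct the build
towards *some* parallel bundle without dictating register, periodicity or
geometry. Whether the original implementation restrains all copy pairs or
only adjacent copies is not documented; adjacent-only is sufficient to
define the interface and is the default here.

Restraints are serialized as
`AtomPair CA <i> CA <j> FLAT_HARMONIC <x0> <sd> <tol>` lines with symmetry
copies addressed by global residue numbering, and round-trip through the
package's own parser. Cn symmetry definitions (C2, C3, C4 — parallel
dimers, trimers, tetramers; antiparallel registers are out of scope) carry a
generator rotation of 360/order degrees about z whose order-fold composition
is the identity. `mr_keywords()` emits `PKEY TNCS USE OFF` by default:
coiled-coil internal periodicity routinely produces spurious tNCS signals
whose "correction" can preclude solution, so coiled-coil MR runs disable it.

## Asymmetric-unit preparation

When the crystallographic asymmetric unit holds fewer chains than the
modelled oligomer, `reduce_to_asu()` keeps the first `nmasu` chains in file
order (e.g. chains A and B of a tetramer — a "half-tetramer"); which chains
form the biologically relevant sub-oligomer is the user's call via chain
order. `merge_renumber()` then rewrites the retained chains as a single
chain A with strictly consecutive numbering (no gaps between copies),
conserving every atom and coordinate, and `multiplied_sequence()` builds the
matching repeated-sequence record.

## Geometry measurement and knobs-into-holes

`local_axes()` uses the classic sliding four-CA-window construction: from
the second differences of consecutive CA positions it recovers the local
rotation per residue, minor-helix radius and an axis point under each
interior residue (exact for an ideal helix). `measure_geometry()` then
reports, per chain, rise per residue along the local axis, residues per
turn, and pitch; and, for supercoiled structures, supercoil radius, axial
rise, axial pitch per alpha-helical turn, interhelical crossing angle
(between per-residue local-axis tangents of adjacent chains) and supercoil
handedness from the signed rotation of the chain axis about the central
axis, with per-window labels supporting a "mixed" call for handedness
transitions.

Two numerical choices matter. For oligomers with equal-length chains the
supercoil central axis is the per-residue mean of the chains' local axis
points, which is exact for Cn bundles. For a single supercoiled chain the
axis polyline itself must be analysed; it carries a residual wobble at the
local helical periodicity, so it is boxcar-smoothed over 7 points (two local
turns, which nulls the period-3.5 component) before a linear fit of the
axis direction (smallest principal direction of the smoothed second
differences) and a circle fit in the normal plane. Radii and phases are then
measured from the *raw* axis points against the fitted central line, which
avoids the amplitude attenuation a smoothed radius would suffer. Chains
whose measured residues/turn fall outside (3, 4.6) or rise outside (0.9,
2.2) A are reported as non-helical with `handedness = "none"` and a
diagnostic note; supercoil radii below 0.25 A are treated as straight.

Knobs-into-holes detection follows the standard centre-distance scheme: a
residue is a knob when its side-chain centre lies within the packing cutoff
of at least four residue centres of a partner chain (those four are the
hole). For polyalanine-level models the side-chain centre is the CB atom
(CA for glycine). The conventional cutoff of 7.0 A was calibrated for full
side-chain centroids; CB sits systematically closer to the backbone, so the
package default is 7.5 A, under which the canonical heptad dimer yields
exactly the a/d knob pattern (spacings 3, 4, 3, 4 — period 7 over two local
turns) with a wide margin on either side (the fourth-nearest partner centre
is at <= 7.2 A for core positions and >= 8.8 A for flanking ones). Knob
runs with gaps of at most 4 residues merge into segments; segment
orientation comes from the dot product of the chains' axis directions. A
model is an *ideal coiled-coil target* when a single uninterrupted segment
covers more than 50% of its sequence (`classify_ideal`); interrupted or
split packing fails the "single uninterrupted" clause regardless of total
coverage.

## Solution triage

No single statistic separates correct from incorrect coiled-coil MR
solutions; plausible-looking failures with high tracing CC or low R_free are
routine. `assess()` therefore only accepts a solution when *all* acceptance
rules pass — tracing CC above 30, R_free below 0.45, R - R_free gap at most
0.05, side chains placed, and map correlation at least 0.60 when a reference
comparison exists — while any hard failure (CC at or below the legacy floor
of 25, R_free or gap out of bounds, zero side chains, low map CC) rejects
outright with reasons. Everything else, including unknown gap or side-chain
information and CCs between 25 and 30, is borderline. The two published CC
conventions (25 as the legacy success indicator, 30 as the recommended
combined-rule threshold) are both exposed; 30 is the default acceptance
bar and 25 the hard floor. `demarcation()` compares the top solution's CC
against the background — the median CC of the remaining solutions (mean
optional); "background" has no standard definition, and the median is used
for robustness to outliers. A margin of at least 5 demarcates the top
solution; an accepted top solution that fails demarcation is demoted to
borderline by `triage_solutions()`. These rules are monotone: improving any
one statistic can never demote a verdict, which the test suite checks on
randomized tables.

## Problem sizes, determinism and limitations

The test and acceptance workloads use 1000 decoys of a 48-residue chain at
CA resolution for the full pipeline (a few minutes on one CPU), 28-residue
builds for geometry checks (seconds) and instances of at most 15 decoys
wherever an exhaustive oracle is the reference. All randomness flows through
explicit integer seeds; tie-breaks are fixed everywhere (lower residue
index, earlier model id, stable sorts), so every pipeline stage is a pure
function of its inputs and seed.

Known limitations: antiparallel and mixed-register bundles are generated
only for analysis tests, not supported in restraint generation; heptad
register letters (a-g) are not assigned beyond knob periodicity; the decoy
noise model is a stated stand-in rather than a calibrated model of any
modelling program's error structure; crossing-angle conventions follow the
generator (angle between adjacent chains' axis tangents), which for higher
oligomer orders differs from pairwise packing angles quoted elsewhere; and
no reflection-data quantities are computed — build completeness and map
correlations enter triage as externally supplied numbers.
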