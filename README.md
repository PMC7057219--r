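# ccmr — coiled-coil search models, restraints and solution triage for molecular replacement

Coiled-coils — two or more alpha-helices winding around a common supercoil
axis — are notoriously difficult molecular-replacement (MR) targets: their
elongated, internally periodic structure yields weak discrimination between
correct and incorrect placements, spurious translational-NCS signals, and
plausible-looking wrong solutions. A proven route around this is to generate
many cheap ab initio decoy models, use the agreement between decoys to
predict locally reliable regions, and turn the decoys into a ladder of
truncated polyalanine search ensembles.

`ccmr` implements that computational core for structural bioinformaticians
and crystallographers, end-to-end on generated inputs:

* **Structure generation** — ideal alpha-helices grown from backbone
  dihedrals (geometry is measured, never assumed), and Cn-symmetric
  coiled-coils from the Crick parameterization: a minor helix of radius
  *r1* and local periodicity 3.5 residues/turn wound on a superhelix of
  radius *r0* and signed pitch *P0* (negative = left-handed). Seeded decoy
  sets emulate a multi-basin ab initio decoy population with per-atom noise
  and terminal fraying.
* **Ensembling** — RMSD-threshold clustering (<= 10 aligned clusters of
  <= 30 decoys), per-residue variance profiles, 20 nested truncation
  levels (level *k* keeps the (100 − 5(k−1))% lowest-variance residues),
  subclustering at 1 and 3 A, polyalanine treatment: up to
  10 x 20 x 2 = 400 search ensembles.
* **Restraints** — elongation restraints centred at 1.5 *n* A between the
  terminal CA atoms, and per-residue inter-copy flat-harmonic restraints
  (`FLAT_HARMONIC`, centre 10 A, flat width ±5 A, sd 3 A — zero penalty
  from 5 to 15 A) with C2/C3/C4 symmetry definitions for unbiased
  parallel dimer/trimer/tetramer modelling, plus the `PKEY TNCS USE OFF`
  MR keyword block.
* **Asymmetric-unit preparation** — reduction of oligomers to the ASU chain
  count (e.g. a "half-tetramer") and merging into one consecutively
  numbered chain with a multiplied sequence file.
* **Geometry and packing analysis** — local helix axes, rise, residues per
  turn, pitch, supercoil radius and handedness (L/R/mixed), interhelical
  crossing angle, knobs-into-holes detection and the ideal-coiled-coil
  classifier (single uninterrupted coiled-coil covering > 50% of the
  sequence).
* **Solution triage** — combined-metric accept/borderline/reject rules over
  tracing CC, R_free, the R–R_free gap, side-chain placement and map
  correlation, with top-vs-background demarcation; no single metric can
  force acceptance.

## Worked example

```r
library(ccmr)

# classic left-handed parallel dimer and its measured geometry
dimer <- build_crick_coiled_coil(crick_params(n_res = 28, order = 2))
measure_geometry(dimer)
#> cc_geometry: rise 1.499 A/res, 3.500 res/turn, pitch 5.247 A
#>   supercoil: radius 4.89 A, axial pitch 5.125 A/turn, crossing 24.8 deg, handedness L

# knobs-into-holes: a/d core positions, 3/4 spacing, heptad period 7
kih <- detect_kih(dimer)
sort(kih$knobs$resno[kih$knobs$chain == "A"])
#> [1]  8 11 15 18 22

# seeded decoys -> clustered, truncated, subclustered polyalanine ensembles
noise <- decoy_noise_spec(n_decoys = 60, n_conformers = 3, seed = 7)
decoys <- generate_decoys(crick_params(n_res = 48, order = 1), noise)
ens <- generate_ensembles(decoys)
length(ens)
#> [1] 120        # 3 clusters x 20 truncation levels x 2 radii

# triage: a high tracing CC cannot rescue an overfit, side-chain-free build
assess(solution_stats("reversed", shelxe_cc = 51.7, r_free = 0.41,
                      r_gap = 0.13, side_chains = 0))
#> triage: reject
#>   - R-R_free gap 0.13 > 0.05 (overfitting)
#>   - no side chains placed during model building
```

The measured 1.50 A rise, 3.5 residues per local turn, ~5.1 A axial
translation per helical turn and period-7 knob pattern are outputs of the
geometry analyzer run on the generated coordinates, not inputs to it.

A thin command-line front-end is installed with the package
(`exec/ccmr`), with subcommands `generate`, `restraints`, `ensemble`,
`oligoprep`, `geom` and `triage` mirroring the functions above, e.g.

```sh
ccmr restraints --multimer-modelling trimer --sequence target.fasta --out-dir rst/
ccmr triage --stats solutions.tsv
```

## Documentation

See the vignette (`vignettes/coiled-coil-search-models.Rmd`) for the models,
algorithms, parameter choices and limitations, and the roxygen help pages
for per-function detail.
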