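# fraghar

Fragment-based Hirshfeld atom refinement (fragHAR) for macromolecular
crystallography, in R. The package takes a crystal structure, cuts it into
chemically capped residue fragments, computes aspherical atomic form factors
by Hirshfeld stockholder partitioning of a pluggable electron-density
backend, refines coordinates, displacement parameters and scale against
F² data by damped least squares, and quantifies the result with
residual-density analytics.

Everything runs offline on synthetic fixtures: a built-in generator produces
ideal-geometry toy peptides (G/A/S/C), disordered side chains, waters, an
FeS₄ metal site, and simulated reflection data, so the full pipeline is
testable without any external data or quantum-chemistry engine.

## Quick start

```r
library(fraghar)

# 1. A toy structure and simulated data
st   <- make_toy_structure(toy_spec("GAG", n_waters = 1, seed = 42))
refl <- simulate_reflections(st, d_min = 1.0, noise_frac = 0.02, seed = 42)

# 2. Fragment with hydrogen-bond capping; inspect the manifest
frags <- fragment_structure(st, fragmentation_scheme("hb"))
fragment_manifest(frags)

# 3. Aspherical form factors by Hirshfeld partitioning
hkl <- cbind(refl$h, refl$k, refl$l)
ff  <- assemble_tsc(st, frags, hkl)

# 4. Refine and analyse
fit <- refine_structure(st, refl, ff)
generics::glance(fit)

fc   <- calc_structure_factors(fit$structure, ff, hkl)
dmap <- difference_map(refl, fc, st$cell, scale = fit$scale,
                       d_min = min(hkl_resolution(st$cell, hkl)))
egross(dmap)
plot_fractal_curve(fractal_curve(dmap))
```

Or in one call:

```r
report <- run_pipeline(st, refl, mode = "hb", out_json = "report.json")
```

## Key features

- **MFCC-style fragmentation** — one fragment per residue and conformation;
  peptide neighbours are capped with CH₃CO—/—NHCH₃ groups, and the
  atom three bonds from the fragment is replaced by a junction hydrogen at
  exactly 1.094 Å along the original bond.
- **Hydrogen-bond capping** — `"hb"` adds truncated acceptor groups to
  donor fragments; `"mhb"` uses minimal OH⁻/H₂O acceptors with formal
  charge bookkeeping.
- **Metal sites** — a metal-containing residue becomes one fragment of the
  metal plus —SCH₃-capped ligands; `metal_fragment_charge()` combines the
  oxidation state with ligand cap charges (Fe(III) + 4 thiolates → −1).
  Per-fragment charges and multiplicities come from `.qS` files
  (`parse_qs()`), with charge 0 / singlet defaults.
- **Hirshfeld partitioning** — stockholder weights from four-term Gaussian
  promolecule densities, integrated on Becke multicentre grids
  (Gauss–Chebyshev radial × Gauss–Legendre angular), validated against an
  analytic Gaussian form-factor oracle to 1e-6.
- **Refinement** — Levenberg–Marquardt on F² with SHELX weights,
  X—H distance and riding-ADP constraints, distance/rigid-bond restraints,
  anisotropic ADPs, a flat solvent mask, and Hamilton R-ratio model
  comparison (`hamilton_ratio()`).
- **Residual analytics** — difference maps, gross residual electrons
  (`egross()`), and fractal-dimension curves (`fractal_curve()`).
- **I/O** — SHELX `.ins`/`.hkl` (HKLF4), PDB (via bio3d), `.tsc`
  form-factor tables, `.qS` charge files, XYZ fragments, QM input decks,
  and text map grids.

## Command line

A thin CLI wraps the package (all logic stays in package functions):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fraghar", package = "fraghar"))')
Rscript $CLI simulate --sequence GAG --d-min 1.0 --noise 0.02 --seed 1 --out work/
Rscript $CLI fragment --in work/model.ins --scheme hb --qs model.qS --out frags/
Rscript $CLI tsc      --in work/model.ins --scheme hb --hkl work/model.hkl --out model.tsc
Rscript $CLI fc       --in work/model.ins --tsc model.tsc --hkl work/model.hkl --out fc.csv
Rscript $CLI refine   --in work/model.ins --hkl work/model.hkl --tsc model.tsc --out ref/
Rscript $CLI analyze  --in ref/refined.ins --hkl work/model.hkl --tsc model.tsc \
                      --egross --fractal bins=100 --out report.json
Rscript $CLI run      --in work/model.ins --hkl work/model.hkl --scheme hb --out report.json
```

Global flags: `--seed <int>`, `--config <key=value file>`,
`--log-level quiet|info|debug`. Exit codes: 0 success, 2 input error,
3 numerical failure.

## Tests and acceptance

```r
devtools::test()          # full suite, incl. tests/testthat/test-acceptance.R
```

```sh
Rscript scripts/acceptance.R --seed 1 --out out.json   # target t3 (FeS4 charge)
```

## Documentation

See the methods vignette (`vignettes/fraghar-methods.Rmd`) for the
mathematical model, numerical choices, and documented simplifications.
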