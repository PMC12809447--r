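---
title: "Fragment Hirshfeld atom refinement: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment Hirshfeld atom refinement: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraghar)
```

This vignette documents the mathematical model behind `fraghar`, the
parameters it exposes, the scope of the synthetic data generator, the
numerical choices made, and the simplifications relative to full
quantum-crystallographic refinement.

## 1. The model

### 1.1 Fragmentation

A crystal structure is cut into one fragment per residue and realized
conformation (`fragment_structure()`). Each fragment contains:

- **Central atoms** — the residue's own atoms. With alternative
  conformations, shared (part-0) atoms are central exactly once, in the
  fragment of the lowest part, and appear in later parts' fragments only as
  environment; every atom therefore has exactly one aspherical form-factor
  owner.
- **Cap atoms** — atoms copied from bonded neighbours out to two bonds
  from the junction, giving CH₃CO— on the N-side and —NHCH₃ on the C-side
  of a peptide bond.
- **Junction hydrogens** — the atom three bonds out is replaced by a
  hydrogen placed along the original bond direction at exactly
  1.094 Å (`place_junction_hydrogen()`).

Two optional extensions model the electronic environment more closely:

- `"hb"` — hydrogen-bond acceptors of polar donor hydrogens are added as
  truncated groups (backbone carbonyl → OCH₂, hydroxyl → HOCH₃), again with
  1.094 Å junction hydrogens.
- `"mhb"` — minimal acceptors: carbonyl/carboxylate oxygen → OH⁻
  (fragment charge −1), hydroxyl oxygen → H₂O (charge 0).

A metal-containing residue becomes a single fragment: the metal plus each
coordinated ligand truncated to —SCH₃. The fragment charge is the metal
oxidation state plus the summed ligand cap charges
(`metal_fragment_charge(3L, rep(-1L, 4))` = −1 for an Fe(III) site with
four thiolates). Fragment charge and spin multiplicity otherwise default to
0 and 1 and can be overridden per residue (or per disorder part) through a
`.qS` file read by `parse_qs()`.

```{r fragments}
st <- make_toy_structure(toy_spec("GAG"))
frags <- fragment_structure(st, fragmentation_scheme("plain"))
fragment_manifest(frags)[, c("id", "n_central", "n_cap", "n_junction",
                             "charge", "multiplicity")]
```

### 1.2 Electron density

The density backend is pluggable (`density_model()`). The default is a
promolecule of spherical atoms, each a four-term Gaussian expansion

$$\rho^0_A(r) = \sum_{j=1}^{4} c_j \left(\frac{\alpha_j}{\pi}\right)^{3/2}
  e^{-\alpha_j r^2},$$

whose coefficients were fitted to standard tabulated X-ray form factors and
frozen in the package (each integrates to the atomic electron count to
better than 1e-8). A Gaussian has the analytic Fourier transform

$$f(|\mathbf{h}^*|) = \sum_j c_j\, e^{-\pi^2 |\mathbf{h}^*|^2 / \alpha_j},$$

which serves as an exact oracle for the numerical machinery
(`analytic_gaussian_ff()`, `iam_form_factor()`). An optional deformation
term adds charge-conserving bond-centred Gaussians, standing in for the
density rearrangement a quantum-chemistry engine would produce; external
engines are supported only to the extent of writing their input decks
(`write_qm_input()`).

### 1.3 Hirshfeld partitioning

Atom $A$ of a fragment receives the stockholder share of the fragment
density,

$$\rho_A(\mathbf{r}) = w_A(\mathbf{r})\,\rho_{\rm frag}(\mathbf{r}),
\qquad
w_A = \frac{\rho^0_A}{\sum_B \rho^0_B},$$

where the promolecule weights use the same Gaussian tables as the density
backend. The aspherical form factor is the numerical Fourier transform of
$\rho_A$ referenced to the atomic centre, so the stored `.tsc` values are
translation invariant; structure-factor assembly re-applies the phase
$e^{2\pi i\,\mathbf{h}\cdot\mathbf{x}_A}$.

### 1.4 Structure factors and refinement

`calc_structure_factors()` combines form factors, positions, occupancies,
isotropic or anisotropic Debye–Waller factors (SHELX U* convention),
symmetry operations, optional anomalous terms, and an optional flat solvent
mask. Refinement (`refine_structure()`) minimizes

$$\sum_{hkl} w\,(F_o^2 - s\,F_c^2)^2, \qquad
w = \frac{1}{\sigma^2 + (aP)^2 + bP},\quad
P = \frac{\max(F_o^2, 0) + 2F_c^2}{3},$$

by Levenberg–Marquardt with an analytic scale derivative and central finite
differences for structural parameters. Constraints cover fixed and shared
X—H distances and riding hydrogen ADPs; restraints cover target distances
and rigid-bond ADP differences. Convergence requires both a maximum
shift/esd below tolerance and a relative drop in the objective below 1e-4.
Models are compared with `r1()`, `wr2()`, and the Hamilton R-ratio test
(`hamilton_ratio()`), which reproduces the published crambin worked example
(ratio 1.128 for 55 extra parameters and 112 293 data).

### 1.5 Residual-density analytics

`difference_map()` synthesizes $(F_o - F_c)$ maps on an FFT grid;
`egross()` sums $\tfrac{1}{2}\sum |\rho| V_{\rm voxel}$ (gross residual
electrons) and `fractal_curve()` computes the box-counting fractal
dimension $d^f(\rho_0) = \ln N(\rho_0) / \ln N_{\rm total}^{1/3}$ as a
function of the residual-density level.

## 2. The synthetic data generator

Because no experimental data ships with the package, fixtures come from
`make_toy_structure(toy_spec(...))`:

- ideal-geometry peptides built from internal coordinates (residues G, A,
  S, C; extended backbone), with hydrogens placed;
- optional per-residue alternative conformations with occupancies that must
  sum to 1;
- lattice waters placed to avoid clashes (an impossible placement errors
  with a suggestion to enlarge the cell);
- an optional tetrahedral Fe(S–CH₃-like)₄ site (Fe–S 2.30 Å);
- P1 or P2₁ cells.

`simulate_reflections()` enumerates all symmetry-unique reflections to a
resolution limit, computes $F_o^2 = s\,|F_{\rm model}|^2(1+\varepsilon)$
with seeded Gaussian noise and a sigma floor, and is deterministic per
seed. The generator exists to exercise the pipeline, not to simulate
realistic crystals: thermal diffuse scattering, absorption, extinction,
realistic solvent disorder and twinning are all out of scope.

## 3. Numerical choices

- **Radial quadrature**: Gauss–Chebyshev with the Becke map
  $r = R_m(1+x)/(1-x)$, $R_m = \max(0.35\,\text{Å}, r_{\rm cov})$, cutoff
  12 Å; default 40 points.
- **Angular quadrature**: a Gauss–Legendre (cos θ) × uniform (φ) product
  grid, default 8 × 16 = 128 points per radial shell. This replaces the
  more common Lebedev-110 set (no table source was available offline); the
  product rule integrates the relevant spherical harmonics exactly and the
  grid is configurable (`n_theta`).
- **Multicentre weights**: Becke's smooth cell functions with 3 switching
  iterations.
- Accuracy is gated by oracles, not by grid convention: quadrature
  form factors match the analytic Gaussian transform to 1e-6, Hirshfeld
  weights sum to 1 within 1e-12, and partitioned atomic transforms re-sum
  to the direct fragment transform within 1e-5.
- **Form-factor tables** are expanded over all symmetry-transformed indices
  (`expand_hkl_by_symmetry()`) and completed Hermitian-wise, so Friedel
  mates and symmetry mates never miss a table entry.
- **Reports** serialize floats at 10 significant digits to JSON.

```{r oracle}
# quadrature vs the analytic transform for an isolated Gaussian "atom"
f_analytic <- analytic_gaussian_ff(alpha = 2, hstar_norm = 0.5)
f_analytic
```

## 4. Documented simplifications

- **Density backend**: the QM calculation is replaced by the promolecule
  (+ optional deformation) model; `write_qm_input()` produces decks for an
  external engine but nothing in the package runs one.
- **Angular grid**: product Gauss–Legendre grid instead of Lebedev-110
  (see above).
- **Hydrogen-bond search**: acceptors within two bonds of the donor
  hydrogen are excluded; only contacts inside the asymmetric unit are
  considered (no symmetry-mate search).
- **Solvent mask**: binary vdW+probe exclusion on a 0.8 Å grid with
  constant level k = 0.33 e Å⁻³ and B = 50 Å² smearing; no shrink/smoothing
  step.
- **Disorder**: shared atoms are counted once per conformation set in the
  residual-density per-atom normalization (once per part in the map
  analytics), and each fragment gets its own copy of any shared
  hydrogen-bond acceptor.
- **Problem sizes**: defaults target toy systems (tens of atoms, ~1 Å
  data, cells ≲ 20 Å). Partitioning cost grows with fragment count times
  grid size times reflection count; no FFT acceleration of the atomic
  transforms is implemented.

## 5. End to end

```{r pipeline, eval = FALSE}
st   <- make_toy_structure(toy_spec("GAG", seed = 1))
refl <- simulate_reflections(st, d_min = 1.0, noise_frac = 0.02, seed = 1)
report <- run_pipeline(st, refl, mode = "hb", out_json = "report.json")
c(r1 = report$r1, wr2 = report$wr2, egross_per_atom = report$egross_per_atom)
```

The same pipeline is available from the command line; see the README for
the `simulate`, `fragment`, `tsc`, `fc`, `refine`, `analyze` and `run`
subcommands.
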