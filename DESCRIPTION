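Package: fraghar
Title: Fragment-Based Hirshfeld Atom Refinement for Macromolecular Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for fragment-based Hirshfeld atom refinement (fragHAR)
    of macromolecular crystal structures. Provides residue-based fragmentation
    with chemical capping (including two hydrogen-bond acceptor capping schemes
    and a metal-site rule), Hirshfeld stockholder partitioning of fragment
    electron densities into aspherical atomic form factors over a pluggable
    Gaussian density backend, structure-factor assembly with anisotropic
    displacement parameters and a flat solvent-mask model, least-squares
    refinement against F-squared with SHELX-type weighting and
    Levenberg-Marquardt damping, and residual-density quality analytics
    (gross residual electrons, fractal-dimension curves, Hamilton R-ratio
    tests). Reads and writes PDB, a minimal SHELX-style instruction subset,
    HKLF4 reflection files, per-residue charge/multiplicity tables and
    tabulated scattering-factor (.tsc) exchange files. Ships a synthetic
    fixture generator (toy peptides, iron-thiolate sites, simulated
    reflections) so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
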