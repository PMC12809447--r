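# Element data: electron counts, Bondi (1964) van der Waals radii,
# Cordero (2008) covalent radii, and four-term Gaussian expansions of the
# spherical (independent-atom) electron density.
#
# The Gaussian expansions were fitted by least squares to tabulated
# International Tables spherical form factors so that
#   f0(s) = sum_j c_j exp(-4 pi^2 s^2 / alpha_j),   s = sin(theta)/lambda,
# agrees with the reference within 1% for s <= 1.0 A^-1, with
# sum_j c_j = Z exactly.  In real space the corresponding density is
#   rho0(r) = sum_j c_j (alpha_j/pi)^{3/2} exp(-alpha_j r^2)   [e A^-3],
# which integrates to Z electrons analytically.

.element_data <- list(
  H = list(
    n_electrons = 1L, vdw_radius = 1.20, covalent_radius = 0.31,
    gaussian = list(
      c = c(0.16470038, 0.28131685, 0.00570106, 0.54828171),
      alpha = c(11.21535433, 1.20709521, 131.59472535, 3.36564648))),
  C = list(
    n_electrons = 6L, vdw_radius = 1.70, covalent_radius = 0.76,
    gaussian = list(
      c = c(2.41268785, 0.94296130, 0.88983569, 1.75451517),
      alpha = c(2.84569693, 49.64943969, 154.20564245, 1.02525339))),
  N = list(
    n_electrons = 7L, vdw_radius = 1.55, covalent_radius = 0.71,
    gaussian = list(
      c = c(1.03973101, 1.99501557, 3.15255025, 0.81270317),
      alpha = c(198.94719511, 1.34720607, 3.97327789, 58.29690432))),
  O = list(
    n_electrons = 8L, vdw_radius = 1.52, covalent_radius = 0.66,
    gaussian = list(
      c = c(3.52558747, 1.14276564, 1.74059780, 1.59104909),
      alpha = c(4.00786810, 9.37089405, 159.41643070, 1.50272641))),
  S = list(
    n_electrons = 16L, vdw_radius = 1.80, covalent_radius = 1.05,
    gaussian = list(
      c = c(7.06846615, 1.64844916, 2.13360558, 5.14947911),
      alpha = c(27.30500515, 0.71432992, 354.36046385, 1.79141837))),
  Fe = list(
    n_electrons = 26L, vdw_radius = 2.00, covalent_radius = 1.32,
    gaussian = list(
      c = c(10.97180491, 8.19798251, 4.28338126, 2.54683132),
      alpha = c(8.85970821, 161.06048266, 3.14998030, 0.54847713)))
)

# Elements treated as coordinating metals by the fragmentation rules.
.default_metals <- c("Fe", "Zn", "Cu", "Ni", "Co", "Mn", "Mg", "Ca", "Na", "K")

#' Look up element properties
#'
#' Returns the shipped properties of a chemical element: electron count,
#' Bondi van der Waals radius, Cordero covalent radius and the four-term
#' Gaussian expansion of its spherical atomic density.
#'
#' @param symbol Chemical element symbol (case-insensitive, e.g. `"Fe"`).
#' @param vdw_table Optional named numeric vector overriding van der Waals
#'   radii (names are element symbols, values in Angstrom).
#' @param cov_table Optional named numeric vector overriding covalent radii.
#' @return A list with components `symbol`, `n_electrons`, `vdw_radius`,
#'   `covalent_radius` and `gaussian` (list of `c`, `alpha`).
#' @export
element_info <- function(symbol, vdw_table = NULL, cov_table = NULL) {
  sym <- normalize_element(symbol)
  info <- .element_data[[sym]]
  if (is.null(info)) {
    stop("unknown element: '", symbol, "' (shipped set: ",
         paste(names(.element_data), collapse = ", "), ")", call. = FALSE)
  }
  info$symbol <- sym
  if (!is.null(vdw_table) && sym %in% names(vdw_table)) {
    info$vdw_radius <- unname(vdw_table[[sym]])
  }
  if (!is.null(cov_table) && sym %in% names(cov_table)) {
    info$covalent_radius <- unname(cov_table[[sym]])
  }
  info
}

normalize_element <- function(symbol) {
  s <- trimws(as.character(symbol))
  paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
}

#' Table of shipped elements
#'
#' @return A tibble with one row per supported element: symbol, electron
#'   count and both radius tables (Angstrom).
#' @export
element_table <- function() {
  tibble::tibble(
    symbol = names(.element_data),
    n_electrons = vapply(.element_data, function(e) e$n_electrons, integer(1)),
    vdw_radius = vapply(.element_data, function(e) e$vdw_radius, numeric(1)),
    covalent_radius = vapply(.element_data, function(e) e$covalent_radius, numeric(1))
  )
}

#' Is an element a coordinating metal?
#'
#' @param symbol Element symbol.
#' @param metals Character vector of symbols treated as metals.
#' @return Logical.
#' @export
is_metal <- function(symbol, metals = .default_metals) {
  normalize_element(symbol) %in% metals
}
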