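# Pluggable electron-density backend.  The default model is the analytic
# Gaussian promolecule (superposition of spherical atomic densities), with
# an optional bond-centred deformation term that makes the density
# aspherical while conserving total charge.  An analytic Fourier oracle for
# isolated Gaussians validates all quadrature, and a QM-input writer emits
# decks for external engines.

#' Spherical atomic density
#'
#' Evaluates the shipped Gaussian expansion of the spherical
#' (independent-atom) density, rho0(r) = sum_j c_j (alpha_j/pi)^{3/2}
#' exp(-alpha_j r^2), in e per cubic Angstrom.
#'
#' @param element Element symbol, or a list with a `gaussian` component
#'   (`c`, `alpha`) for custom expansions.
#' @param r Radial distance(s) from the nucleus in Angstrom (>= 0).
#' @return Density values, e A^-3.
#' @examples
#' spherical_density_at("H", 0)
#' @export
spherical_density_at <- function(element, r) {
  g <- if (is.list(element)) element$gaussian else element_info(element)$gaussian
  r2 <- as.numeric(r)^2
  out <- 0
  for (j in seq_along(g$c)) {
    out <- out + g$c[j] * (g$alpha[j] / pi)^1.5 * exp(-g$alpha[j] * r2)
  }
  out
}

#' Density model
#'
#' Configures the electron-density backend used for fragment densities:
#' the analytic Gaussian promolecule, optionally augmented with
#' charge-conserving bond-centred deformation Gaussians. The deformation
#' moves `population` electrons per bond into a Gaussian of exponent
#' `beta` at the bond midpoint, withdrawing half from each bonded atom;
#' it is a synthetic stand-in that makes aspherical densities detectably
#' different from spherical ones.
#'
#' @param deformation Logical: add bond-centred deformation terms.
#' @param population Electrons moved per bond (default 0.1).
#' @param beta Deformation Gaussian exponent, A^-2 (default 8).
#' @return A `density_model` list.
#' @export
density_model <- function(deformation = FALSE, population = 0.1, beta = 8) {
  stopifnot(beta > 0, population >= 0)
  structure(list(deformation = deformation, population = population,
                 beta = beta), class = "density_model")
}

# Deformation sites for a fragment: bonds between fragment atoms, inferred
# from covalent radii on the fragment's own Cartesian geometry.
fragment_bonds <- function(fragment, tolerance = 0.4) {
  at <- fragment$atoms
  n <- nrow(at)
  if (n < 2) return(matrix(integer(), 0, 2))
  xyz <- cbind(at$x, at$y, at$z)
  rc <- vapply(at$element, function(e) element_info(e)$covalent_radius,
               numeric(1))
  d <- as.matrix(stats::dist(xyz))
  is_h <- at$element == "H"
  bonded <- d < (outer(rc, rc, `+`) + tolerance) & upper.tri(d) &
    !outer(is_h, is_h, `&`)
  which(bonded, arr.ind = TRUE)
}

# Gaussian term table for a fragment under a density model: one row per
# primitive (centre, coefficient c in electrons, exponent alpha in A^-2),
# density contribution c (alpha/pi)^{3/2} exp(-alpha |r-centre|^2).
fragment_gaussian_terms <- function(fragment, model = density_model()) {
  at <- fragment$atoms
  centres <- list(); cc <- numeric(); aa <- numeric(); owner <- integer()
  for (k in seq_len(nrow(at))) {
    g <- element_info(at$element[k])$gaussian
    for (j in seq_along(g$c)) {
      centres[[length(centres) + 1]] <- c(at$x[k], at$y[k], at$z[k])
      cc <- c(cc, g$c[j]); aa <- c(aa, g$alpha[j]); owner <- c(owner, k)
    }
  }
  if (isTRUE(model$deformation)) {
    bonds <- fragment_bonds(fragment)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      pi_ <- c(at$x[i], at$y[i], at$z[i]); pj <- c(at$x[j], at$y[j], at$z[j])
      mid <- (pi_ + pj) / 2
      centres[[length(centres) + 1]] <- mid
      cc <- c(cc, model$population); aa <- c(aa, model$beta)
      owner <- c(owner, NA_integer_)
      # withdraw half the population from each atom, same width
      centres[[length(centres) + 1]] <- pi_
      cc <- c(cc, -model$population / 2); aa <- c(aa, model$beta)
      owner <- c(owner, NA_integer_)
      centres[[length(centres) + 1]] <- pj
      cc <- c(cc, -model$population / 2); aa <- c(aa, model$beta)
      owner <- c(owner, NA_integer_)
    }
  }
  list(centres = do.call(rbind, centres), c = cc, alpha = aa, owner = owner)
}

# Evaluate a Gaussian term table at Cartesian points (n x 3). Vectorized
# over points; loops over primitives (few per atom).
eval_gaussian_terms <- function(terms, points) {
  points <- to_coord_matrix(points)
  out <- numeric(nrow(points))
  for (j in seq_along(terms$c)) {
    dv <- sweep(points, 2, terms$centres[j, ])
    out <- out + terms$c[j] * (terms$alpha[j] / pi)^1.5 *
      exp(-terms$alpha[j] * rowSums(dv^2))
  }
  out
}

#' Fragment electron density at points
#'
#' Promolecule sum over all fragment atoms (central, cap, junction and
#' hydrogen-bond extension atoms alike), plus optional deformation terms.
#'
#' @param fragment A `capped_fragment`.
#' @param points Cartesian points (n x 3 matrix or length-3 vector), Angstrom.
#' @param model A [density_model()].
#' @return Density values at the points, e A^-3.
#' @export
fragment_density_at <- function(fragment, points, model = density_model()) {
  eval_gaussian_terms(fragment_gaussian_terms(fragment, model), points)
}

#' Analytic form factor of a unit Gaussian density
#'
#' Exact Fourier transform of a normalized Gaussian density of exponent
#' `alpha` under the convention f(h) = integral of rho(r) exp(2 pi i h. r):
#' f = exp(-pi^2 |h*|^2 / alpha). Serves as the independent oracle for the
#' quadrature-based form factors.
#'
#' @param alpha Gaussian exponent, A^-2 (> 0).
#' @param hstar_norm |h*| in A^-1 (scalar or vector).
#' @return Real form-factor values.
#' @export
analytic_gaussian_ff <- function(alpha, hstar_norm) {
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  exp(-pi^2 * hstar_norm^2 / alpha)
}

#' Spherical (IAM) form factor of an element
#'
#' Analytic Fourier transform of the shipped Gaussian density expansion:
#' f0(|h*|) = sum_j c_j exp(-pi^2 |h*|^2 / alpha_j).
#'
#' @param element Element symbol.
#' @param hstar_norm |h*| values in A^-1.
#' @return Real form-factor values (electrons).
#' @export
iam_form_factor <- function(element, hstar_norm) {
  g <- element_info(element)$gaussian
  out <- 0
  for (j in seq_along(g$c)) {
    out <- out + g$c[j] * exp(-pi^2 * hstar_norm^2 / g$alpha[j])
  }
  out
}

#' Write a QM input deck for a fragment
#'
#' Generic plain-text deck: a method/basis keyword line, the charge and
#' multiplicity, and Cartesian coordinates of every fragment atom (junction
#' hydrogens appear as element H at their placed positions).
#'
#' @param fragment A `capped_fragment` with charge/multiplicity assigned.
#' @param path Output path.
#' @param method Method keyword (e.g. a DFT functional name).
#' @param basis Basis-set keyword.
#' @return Invisibly, `path`.
#' @export
write_qm_input <- function(fragment, path, method = "r2SCAN",
                           basis = "cc-pVDZ") {
  at <- fragment$atoms
  lines <- c(
    sprintf("! %s %s", method, basis),
    sprintf("* xyz %d %d", fragment$qm_charge, fragment$multiplicity),
    sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z),
    "*")
  writeLines(lines, path)
  invisible(path)
}

#' Write fragment geometry as XYZ
#'
#' Standard XYZ with the charge, multiplicity and fragment id on the
#' comment line.
#'
#' @param fragment A `capped_fragment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fragment_xyz <- function(fragment, path) {
  at <- fragment$atoms
  lines <- c(
    sprintf("%d", nrow(at)),
    sprintf("fragment %s charge=%d multiplicity=%d", fragment$id,
            fragment$qm_charge, fragment$multiplicity),
    sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z))
  writeLines(lines, path)
  invisible(path)
}
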