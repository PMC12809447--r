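# Unit cell geometry: fractional <-> Cartesian transforms and the
# reciprocal metric used to evaluate |h*| for Miller indices.

#' Construct a unit cell
#'
#' Builds a unit-cell object holding the cell constants, the standard
#' orthogonalization matrix (a along x, b in the xy plane), its inverse,
#' the cell volume and the reciprocal-basis matrix.
#'
#' @param a,b,c Cell edges in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell`.
#' @examples
#' cell <- unit_cell(10, 12, 14, 90, 100, 90)
#' cell$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  al <- alpha * pi / 180
  be <- beta * pi / 180
  ga <- gamma * pi / 180
  cos_al <- cos(al); cos_be <- cos(be); cos_ga <- cos(ga); sin_ga <- sin(ga)
  v_term <- 1 - cos_al^2 - cos_be^2 - cos_ga^2 + 2 * cos_al * cos_be * cos_ga
  if (v_term <= 0) stop("degenerate cell: angles give non-positive volume", call. = FALSE)
  volume <- a * b * c * sqrt(v_term)
  # orthogonalization matrix M: x_cart = M %*% x_frac
  M <- matrix(c(
    a, b * cos_ga, c * cos_be,
    0, b * sin_ga, c * (cos_al - cos_be * cos_ga) / sin_ga,
    0, 0, volume / (a * b * sin_ga)
  ), nrow = 3, byrow = TRUE)
  Minv <- solve(M)
  # reciprocal basis: columns are a*, b*, c* in Cartesian; h*_cart = B %*% h
  B <- t(Minv)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    volume = volume, frac_to_cart = M, cart_to_frac = Minv, recip_basis = B
  ), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4f b=%.4f c=%.4f alpha=%.2f beta=%.2f gamma=%.2f V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Convert fractional coordinates to Cartesian
#'
#' @param cell A `unit_cell`.
#' @param xyz Numeric matrix (n x 3) or length-3 vector of fractional
#'   coordinates.
#' @return Matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @export
frac_to_cart <- function(cell, xyz) {
  m <- to_coord_matrix(xyz)
  m %*% t(cell$frac_to_cart)
}

#' Convert Cartesian coordinates to fractional
#'
#' @inheritParams frac_to_cart
#' @param xyz Numeric matrix (n x 3) or length-3 vector, Angstrom.
#' @return Matrix (n x 3) of fractional coordinates.
#' @export
cart_to_frac <- function(cell, xyz) {
  m <- to_coord_matrix(xyz)
  m %*% t(cell$cart_to_frac)
}

to_coord_matrix <- function(xyz) {
  if (is.null(dim(xyz))) matrix(as.numeric(xyz), ncol = 3) else {
    stopifnot(ncol(xyz) == 3)
    unname(as.matrix(xyz))
  }
}

#' Reciprocal-space vectors for Miller indices
#'
#' Maps integer Miller triples to Cartesian reciprocal vectors h* (A^-1);
#' `hstar_norm()` gives |h*| = 1/d = 2 sin(theta)/lambda.
#'
#' @param cell A `unit_cell`.
#' @param hkl Integer matrix (n x 3) or length-3 vector.
#' @return `hkl_to_hstar()`: matrix (n x 3); `hstar_norm()`: numeric vector.
#' @export
hkl_to_hstar <- function(cell, hkl) {
  m <- to_coord_matrix(hkl)
  m %*% t(cell$recip_basis)  # row form of h* = B %*% h
}

#' @rdname hkl_to_hstar
#' @export
hstar_norm <- function(cell, hkl) {
  hs <- hkl_to_hstar(cell, hkl)
  sqrt(rowSums(hs^2))
}

#' Resolution of reflections
#'
#' @inheritParams hkl_to_hstar
#' @return d-spacings in Angstrom (1/|h*|).
#' @export
hkl_resolution <- function(cell, hkl) 1 / hstar_norm(cell, hkl)
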