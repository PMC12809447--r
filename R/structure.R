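# The crystallographic structure model: unit cell, symmetry operators,
# residue table and atom table (a tibble), plus inferred connectivity.
# Coordinates are stored fractional; all distance logic goes through the
# cell so non-orthogonal cells are handled uniformly.

#' Construct a crystal structure
#'
#' @param cell A [unit_cell()].
#' @param atoms Tibble with columns `label` (unique), `element`, `x`, `y`,
#'   `z` (fractional), `occ`, `part` (integer disorder group, 0 = ordered),
#'   `u_iso` (Angstrom^2), `u_aniso` (list column: length-6 numeric
#'   U11,U22,U33,U23,U13,U12 in the reciprocal-basis convention, or NULL),
#'   `residue_id` (integer), `residue_name`. Optional `f_prime`, `f_dp`
#'   anomalous corrections default to 0.
#' @param symops List of symmetry operators, each `list(R = 3x3 matrix,
#'   t = length-3 numeric)` acting on fractional coordinates. Default P1.
#' @param extra Character vector of verbatim instruction lines preserved for
#'   round-tripping.
#' @return An object of class `crystal_structure` with a `bonds` tibble
#'   (empty until [infer_connectivity()] fills it).
#' @export
crystal_structure <- function(cell, atoms, symops = NULL, extra = character()) {
  stopifnot(inherits(cell, "unit_cell"))
  atoms <- tibble::as_tibble(atoms)
  req <- c("label", "element", "x", "y", "z", "occ", "part",
           "u_iso", "residue_id", "residue_name")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"u_aniso" %in% names(atoms)) atoms$u_aniso <- vector("list", nrow(atoms))
  if (!"f_prime" %in% names(atoms)) atoms$f_prime <- 0
  if (!"f_dp" %in% names(atoms)) atoms$f_dp <- 0
  dup <- atoms$label[duplicated(atoms$label)]
  if (length(dup) > 0) {
    occurrences <- which(atoms$label %in% dup[1])
    stop("duplicate atom label '", dup[1], "' at atom rows ",
         paste(occurrences, collapse = " and "), call. = FALSE)
  }
  if (any(atoms$occ < 0 | atoms$occ > 1 + 1e-9)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  atoms$element <- vapply(atoms$element, normalize_element, character(1))
  atoms$part <- as.integer(atoms$part)
  atoms$residue_id <- as.integer(atoms$residue_id)
  if (is.null(symops)) symops <- list(list(R = diag(3), t = c(0, 0, 0)))
  residues <- dplyr::distinct(atoms, .data$residue_id, .data$residue_name)
  residues <- dplyr::arrange(residues, .data$residue_id)
  structure(list(
    cell = cell, symops = symops, atoms = atoms, residues = residues,
    bonds = tibble::tibble(i = character(), j = character(), length = numeric()),
    extra = extra
  ), class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %d atoms, %d residues, %d symops, %d bonds\n",
              nrow(x$atoms), nrow(x$residues), length(x$symops), nrow(x$bonds)))
  print(x$cell)
  invisible(x)
}

#' Cartesian coordinates of atoms
#'
#' @param structure A `crystal_structure`.
#' @param labels Optional atom labels to select (default all, in table order).
#' @return Matrix (n x 3) of Cartesian Angstrom coordinates, rownames = labels.
#' @export
atom_cart <- function(structure, labels = NULL) {
  at <- structure$atoms
  if (!is.null(labels)) at <- at[match(labels, at$label), , drop = FALSE]
  m <- frac_to_cart(structure$cell, cbind(at$x, at$y, at$z))
  rownames(m) <- at$label
  m
}

parts_compatible <- function(p1, p2) p1 == p2 | p1 == 0L | p2 == 0L

#' Infer covalent connectivity
#'
#' Bonds atoms i and j when their Cartesian distance is below the sum of
#' covalent radii plus `tolerance`, they are not both hydrogens, and their
#' disorder parts are compatible (equal, or one of them 0). Deterministic:
#' the bond set is independent of atom order.
#'
#' @param structure A `crystal_structure`.
#' @param tolerance Distance slack in Angstrom (default 0.4).
#' @param cov_table Optional covalent-radius override (named vector).
#' @return The structure with its `bonds` tibble filled (columns `i`, `j`
#'   with `i` < `j` lexicographically by atom-table order, and `length`).
#' @export
infer_connectivity <- function(structure, tolerance = 0.4, cov_table = NULL) {
  at <- structure$atoms
  n <- nrow(at)
  if (n < 2) {
    structure$bonds <- tibble::tibble(i = character(), j = character(),
                                      length = numeric())
    return(structure)
  }
  xyz <- atom_cart(structure)
  rc <- vapply(at$element, function(e)
    element_info(e, cov_table = cov_table)$covalent_radius, numeric(1))
  is_h <- at$element == "H"
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(rc, rc, `+`) + tolerance
  compat <- outer(at$part, at$part, parts_compatible)
  too_close <- d < 0.5 & compat & upper.tri(d)
  if (any(too_close)) {
    idx <- which(too_close, arr.ind = TRUE)[1, ]
    stop(sprintf("atoms '%s' and '%s' are %.3f A apart (< 0.5 A) in compatible parts",
                 at$label[idx[1]], at$label[idx[2]], d[idx[1], idx[2]]),
         call. = FALSE)
  }
  bonded <- d < cut & compat & !(outer(is_h, is_h, `&`)) & upper.tri(d)
  idx <- which(bonded, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  structure$bonds <- tibble::tibble(
    i = at$label[idx[, 1]], j = at$label[idx[, 2]],
    length = d[idx]
  )
  structure
}

#' Adjacency list from the bond table
#'
#' @param structure A `crystal_structure` with bonds inferred.
#' @return Named list: for each atom label, the character vector of bonded
#'   labels.
#' @keywords internal
bond_adjacency <- function(structure) {
  adj <- stats::setNames(vector("list", nrow(structure$atoms)),
                         structure$atoms$label)
  for (lab in names(adj)) adj[[lab]] <- character()
  b <- structure$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  lapply(adj, sort)
}

#' Equivalent isotropic U
#'
#' For anisotropic atoms returns the trace-equivalent isotropic U in the
#' orthogonalized frame; for isotropic atoms returns `u_iso`.
#'
#' @param structure A `crystal_structure`.
#' @return Numeric vector, one value per atom (Angstrom^2).
#' @export
u_equiv <- function(structure) {
  at <- structure$atoms
  vapply(seq_len(nrow(at)), function(k) {
    ua <- at$u_aniso[[k]]
    if (is.null(ua)) return(at$u_iso[k])
    uc <- u_star_to_cart(structure$cell, ua)
    sum(diag(uc)) / 3
  }, numeric(1))
}

# U (reciprocal-basis "U*"/SHELX convention, order U11,U22,U33,U23,U13,U12)
# to a Cartesian tensor: U_cart = (M D) U (M D)^T, D = diag(a*, b*, c*).
u_star_to_cart <- function(cell, u6) {
  U <- matrix(c(u6[1], u6[6], u6[5],
                u6[6], u6[2], u6[4],
                u6[5], u6[4], u6[3]), 3, 3)
  astar <- sqrt(colSums(cell$recip_basis^2))
  A <- cell$frac_to_cart %*% diag(astar)
  A %*% U %*% t(A)
}

u_cart_to_star <- function(cell, U_cart) {
  astar <- sqrt(colSums(cell$recip_basis^2))
  A <- cell$frac_to_cart %*% diag(astar)
  Ainv <- solve(A)
  U <- Ainv %*% U_cart %*% t(Ainv)
  c(U[1, 1], U[2, 2], U[3, 3], U[2, 3], U[1, 3], U[1, 2])
}
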