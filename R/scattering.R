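# Structure-factor assembly: Debye-Waller attenuation, symmetry expansion,
# occupancies, anomalous corrections and a flat solvent-mask contribution.

#' Debye-Waller factor
#'
#' Isotropic: exp(-2 pi^2 U |h*|^2). Anisotropic (SHELX/reciprocal-basis
#' convention, order U11,U22,U33,U23,U13,U12):
#' exp(-2 pi^2 sum_ij h_i h_j a*_i a*_j U_ij).
#'
#' @param cell A `unit_cell`.
#' @param hkl Integer matrix (n x 3) or length-3 vector.
#' @param u_iso Isotropic U (Angstrom^2), or NULL when `u_aniso` is given.
#' @param u_aniso Length-6 anisotropic U (Angstrom^2), or NULL.
#' @return Numeric vector of factors in (0, 1]; exactly 1 at h = 0.
#' @export
debye_waller <- function(cell, hkl, u_iso = NULL, u_aniso = NULL) {
  hkl <- to_coord_matrix(hkl)
  if (!is.null(u_aniso)) {
    U <- matrix(c(u_aniso[1], u_aniso[6], u_aniso[5],
                  u_aniso[6], u_aniso[2], u_aniso[4],
                  u_aniso[5], u_aniso[4], u_aniso[3]), 3, 3)
    ev <- eigen(u_star_to_cart(cell, u_aniso), symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev <= 0)) stop("anisotropic U tensor is not positive definite",
                           call. = FALSE)
    astar <- sqrt(colSums(cell$recip_basis^2))
    M <- diag(astar) %*% U %*% diag(astar)
    q <- rowSums((hkl %*% M) * hkl)
    exp(-2 * pi^2 * q)
  } else {
    if (is.null(u_iso) || u_iso <= 0) stop("isotropic U must be positive",
                                           call. = FALSE)
    exp(-2 * pi^2 * u_iso * hstar_norm(cell, hkl)^2)
  }
}

#' Expand Miller indices by the symmetry operations
#'
#' Structure-factor assembly evaluates form factors at every transformed
#' index h R_s, so a form-factor table built from a unique reflection list
#' must also carry those rows. Returns the unique union of h R_s over all
#' operations (Friedel mates are left to Hermitian completion).
#'
#' @param hkl Integer matrix (n x 3).
#' @param symops List of symmetry operations (`R`, `t`).
#' @return Integer matrix (m x 3), m >= n, original rows first.
#' @export
expand_hkl_by_symmetry <- function(hkl, symops) {
  out <- hkl
  keys <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  have <- c(keys, paste(-hkl[, 1], -hkl[, 2], -hkl[, 3]))
  for (op in symops) {
    h2 <- hkl %*% op$R
    k2 <- paste(h2[, 1], h2[, 2], h2[, 3])
    new <- !(k2 %in% have) & !duplicated(k2)
    if (any(new)) {
      out <- rbind(out, h2[new, , drop = FALSE])
      have <- c(have, k2[new], paste(-h2[new, 1], -h2[new, 2], -h2[new, 3]))
    }
  }
  out
}

ff_lookup_index <- function(table) {
  keys <- paste(table$hkl[, 1], table$hkl[, 2], table$hkl[, 3])
  stats::setNames(seq_along(keys), keys)
}

# Complex form factors for (possibly symmetry-transformed) indices;
# Hermitian completion f(-h) = conj(f(h)) when only one mate is stored.
ff_values_at <- function(table, hkl, index = ff_lookup_index(table)) {
  keys <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  neg <- paste(-hkl[, 1], -hkl[, 2], -hkl[, 3])
  i1 <- index[keys]; i2 <- index[neg]
  out <- matrix(complex(1), nrow(hkl), length(table$labels))
  direct <- !is.na(i1)
  out[direct, ] <- table$values[i1[direct], , drop = FALSE]
  mate <- is.na(i1) & !is.na(i2)
  out[mate, ] <- Conj(table$values[i2[mate], , drop = FALSE])
  if (any(is.na(i1) & is.na(i2))) {
    bad <- which(is.na(i1) & is.na(i2))[1]
    stop("form-factor table has no entry for hkl (",
         paste(hkl[bad, ], collapse = " "), ") or its Friedel mate",
         call. = FALSE)
  }
  out
}

#' Calculate complex structure factors
#'
#' F(h) = sum_s sum_A occ_A [f_A(h R_s) + f' + i f''] DW_A(h R_s)
#'        exp(2 pi i h . (R_s x_A + t_s)) + F_solv(h).
#' Atom-centred form factors come from a [form_factor_table()]; Friedel
#' mates are filled by Hermitian symmetry.
#'
#' @param structure A `crystal_structure`.
#' @param ff_table A `form_factor_table` covering every atom.
#' @param hkl Integer matrix (n x 3).
#' @param solvent Optional `solvent_mask` contribution.
#' @return Complex vector of structure factors, one per row of `hkl`.
#' @export
calc_structure_factors <- function(structure, ff_table, hkl, solvent = NULL) {
  hkl <- to_coord_matrix(hkl)
  at <- structure$atoms
  missing_ff <- setdiff(at$label, ff_table$labels)
  if (length(missing_ff) > 0) {
    stop("form-factor table lacks columns for atoms: ",
         paste(missing_ff, collapse = ", "), call. = FALSE)
  }
  col_of <- match(at$label, ff_table$labels)
  X <- cbind(at$x, at$y, at$z)
  index <- ff_lookup_index(ff_table)
  anom <- complex(real = at$f_prime, imaginary = at$f_dp)
  F_total <- complex(real = numeric(nrow(hkl)))
  for (op in structure$symops) {
    h2 <- hkl %*% op$R
    ff <- ff_values_at(ff_table, h2, index)[, col_of, drop = FALSE]
    ff <- sweep(ff, 2, anom, `+`)
    dw <- matrix(0, nrow(hkl), nrow(at))
    for (k in seq_len(nrow(at))) {
      dw[, k] <- if (is.null(at$u_aniso[[k]])) {
        debye_waller(structure$cell, h2, u_iso = at$u_iso[k])
      } else {
        debye_waller(structure$cell, h2, u_aniso = at$u_aniso[[k]])
      }
    }
    phase <- 2 * pi * (h2 %*% t(X) + matrix(hkl %*% op$t, nrow(hkl), nrow(at)))
    contrib <- ff * dw * exp(1i * phase)
    F_total <- F_total + as.vector(contrib %*% at$occ)
  }
  if (!is.null(solvent)) {
    F_total <- F_total + solvent_structure_factors(solvent, hkl)
  }
  F_total
}

#' Build a flat solvent mask
#'
#' Samples the unit cell on a regular grid; a voxel is solvent when its
#' minimum-image distance to every atom (all symmetry copies) exceeds that
#' atom's van der Waals radius plus the probe radius. The mask scatters as
#' a flat density `k` smeared by exp(-B |h*|^2 / 4).
#'
#' @param structure A `crystal_structure`.
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @param grid_spacing Target voxel edge in Angstrom (default 0.8).
#' @param k Solvent density level, e A^-3 (default 0.33).
#' @param b_smear Smearing B, Angstrom^2 (default 50).
#' @param vdw_table Optional van der Waals radius override.
#' @return A `solvent_mask`: logical array `mask`, grid dims, `cell`,
#'   `k`, `b_smear`, and `volume` (masked volume, A^3).
#' @export
build_solvent_mask <- function(structure, probe_radius = 1.4,
                               grid_spacing = 0.8, k = 0.33, b_smear = 50,
                               vdw_table = NULL) {
  stopifnot(grid_spacing > 0)
  cell <- structure$cell
  dims <- pmax(2L, as.integer(ceiling(c(cell$a, cell$b, cell$c) / grid_spacing)))
  fx <- (seq_len(dims[1]) - 1) / dims[1]
  fy <- (seq_len(dims[2]) - 1) / dims[2]
  fz <- (seq_len(dims[3]) - 1) / dims[3]
  vox <- as.matrix(expand.grid(x = fx, y = fy, z = fz))
  at <- structure$atoms
  if (nrow(at) == 0) {
    mask <- array(TRUE, dims)
  } else {
    # all symmetry copies, wrapped into the cell
    copies <- list(); radii <- numeric()
    rv <- vapply(at$element, function(e)
      element_info(e, vdw_table = vdw_table)$vdw_radius, numeric(1))
    X <- cbind(at$x, at$y, at$z)
    for (op in structure$symops) {
      xf <- (X %*% t(op$R)) + matrix(op$t, nrow(X), 3, byrow = TRUE)
      copies[[length(copies) + 1]] <- xf - floor(xf)
      radii <- c(radii, rv + probe_radius)
    }
    A <- do.call(rbind, copies)
    is_solvent <- rep(TRUE, nrow(vox))
    for (j in seq_len(nrow(A))) {
      dfrac <- sweep(vox, 2, A[j, ])
      dfrac <- dfrac - round(dfrac)  # minimum image
      dc <- frac_to_cart(cell, dfrac)
      is_solvent <- is_solvent & (rowSums(dc^2) > radii[j]^2)
      if (!any(is_solvent)) break
    }
    mask <- array(is_solvent, dims)
  }
  vol <- cell$volume * sum(mask) / prod(dims)
  structure(list(mask = mask, dims = dims, cell = cell, k = k,
                 b_smear = b_smear, volume = vol),
            class = "solvent_mask")
}

#' Solvent-mask structure factors
#'
#' F_solv(h) = k V_vox sum_voxels exp(2 pi i h . x) exp(-B |h*|^2 / 4),
#' so that F_solv(000) = k x masked volume.
#'
#' @param solvent A `solvent_mask`.
#' @param hkl Integer matrix (n x 3).
#' @return Complex vector.
#' @export
solvent_structure_factors <- function(solvent, hkl) {
  hkl <- to_coord_matrix(hkl)
  dims <- solvent$dims
  idx <- which(solvent$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(complex(real = numeric(nrow(hkl))))
  xf <- cbind((idx[, 1] - 1) / dims[1], (idx[, 2] - 1) / dims[2],
              (idx[, 3] - 1) / dims[3])
  v_vox <- solvent$cell$volume / prod(dims)
  smear <- exp(-solvent$b_smear * hstar_norm(solvent$cell, hkl)^2 / 4)
  out <- complex(real = numeric(nrow(hkl)))
  blk <- split(seq_len(nrow(hkl)), ceiling(seq_len(nrow(hkl)) / 128))
  for (b in blk) {
    phase <- 2 * pi * (hkl[b, , drop = FALSE] %*% t(xf))
    out[b] <- (cos(phase) %*% rep(1, nrow(xf))) +
      1i * (sin(phase) %*% rep(1, nrow(xf)))
  }
  solvent$k * v_vox * out * smear
}
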