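# Hirshfeld stockholder partitioning and the quadrature that turns fragment
# densities into per-atom complex aspherical form factors.  Form factors are
# computed only for the fragment's central atoms; cap, junction and
# hydrogen-bond extension atoms contribute density but receive no entry.

#' Hirshfeld stockholder weights
#'
#' w_A(r) = rho0_A(|r - R_A|) / sum_B rho0_B(|r - R_B|), using the same
#' promolecule Gaussian expansions as the density backend. Weights over all
#' fragment atoms sum to 1 at every point.
#'
#' @param fragment A `capped_fragment`.
#' @param atom_label Label of the atom whose weight is requested (or NULL
#'   for the full weight matrix).
#' @param points Cartesian points (n x 3 or length-3), Angstrom.
#' @return If `atom_label` given: numeric vector of weights in [0,1];
#'   otherwise an (n points x n atoms) matrix with columns in fragment atom
#'   order.
#' @export
hirshfeld_weight <- function(fragment, atom_label = NULL, points) {
  points <- to_coord_matrix(points)
  at <- fragment$atoms
  dens <- matrix(0, nrow(points), nrow(at))
  for (k in seq_len(nrow(at))) {
    dv <- sweep(points, 2, c(at$x[k], at$y[k], at$z[k]))
    dens[, k] <- spherical_density_at(at$element[k], sqrt(rowSums(dv^2)))
  }
  total <- rowSums(dens)
  w <- dens / total
  colnames(w) <- at$label
  if (is.null(atom_label)) w else w[, atom_label]
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (2 * e$vectors[1, ]^2)[ord])
}

# Becke switching function: three iterations of p(mu) = 1.5 mu - 0.5 mu^3,
# then s = (1 - p)/2.
becke_s <- function(mu) {
  f <- mu
  for (it in 1:3) f <- 1.5 * f - 0.5 * f^3
  (1 - f) / 2
}

#' Build a multi-centre quadrature grid
#'
#' Atom-centred product grids (Gauss-Chebyshev radial points under the
#' Becke rational mapping x Gauss-Legendre x uniform-phi angular set),
#' combined with Becke's smooth cell functions so overlapping atomic grids
#' integrate each region exactly once. Point count is linear in the number
#' of fragment atoms.
#'
#' @param fragment A `capped_fragment`.
#' @param radial_points Radial nodes per atom (default 40).
#' @param n_theta Gauss-Legendre nodes in cos(theta); the azimuthal circle
#'   gets `2 * n_theta` uniform points (default 8, i.e. 128 angular points).
#' @return A `quadrature_grid`: list with `points` (n x 3 Cartesian),
#'   `weights` (A^3, Becke cell weights included), `owner_atom` (index of
#'   the centre each point belongs to).
#' @export
build_grid <- function(fragment, radial_points = 40, n_theta = 8) {
  at <- fragment$atoms
  if (nrow(at) == 0) stop("empty fragment", call. = FALSE)
  gl <- gauss_legendre(n_theta)
  n_phi <- 2 * n_theta
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  ang_dir <- NULL; ang_w <- NULL
  for (it in seq_len(n_theta)) {
    ct <- gl$x[it]; st <- sqrt(1 - ct^2)
    ang_dir <- rbind(ang_dir, cbind(st * cos(phi), st * sin(phi),
                                    rep(ct, n_phi)))
    ang_w <- c(ang_w, rep(gl$w[it] * 2 * pi / n_phi, n_phi))
  }
  n <- radial_points
  i <- seq_len(n)
  x <- cos(i * pi / (n + 1))
  gc_w <- (pi / (n + 1)) * sin(i * pi / (n + 1))^2 / sqrt(1 - x^2)
  pts <- NULL; wts <- NULL; owner <- NULL
  centres <- cbind(at$x, at$y, at$z)
  for (k in seq_len(nrow(at))) {
    rm_ <- max(0.35, element_info(at$element[k])$covalent_radius)
    r <- rm_ * (1 + x) / (1 - x)
    drdx <- 2 * rm_ / (1 - x)^2
    w_rad <- gc_w * drdx * r^2
    keep <- r < 12  # Gaussian tails are negligible beyond this
    pk <- kronecker(r[keep], ang_dir)  # (n_rad*n_ang) x 3
    pk <- sweep(pk, 2, centres[k, ], `+`)
    # kronecker stacks one radial shell per block of angular points
    wk <- rep(w_rad[keep], each = nrow(ang_dir)) * rep(ang_w, sum(keep))
    pts <- rbind(pts, pk); wts <- c(wts, wk)
    owner <- c(owner, rep(k, nrow(pk)))
  }
  # Becke cell weights
  if (nrow(at) > 1) {
    D <- matrix(0, nrow(pts), nrow(at))
    for (k in seq_len(nrow(at))) {
      dv <- sweep(pts, 2, centres[k, ])
      D[, k] <- sqrt(rowSums(dv^2))
    }
    Rab <- as.matrix(stats::dist(centres))
    P <- matrix(1, nrow(pts), nrow(at))
    for (a in seq_len(nrow(at))) {
      for (b in seq_len(nrow(at))) {
        if (a == b) next
        mu <- (D[, a] - D[, b]) / Rab[a, b]
        P[, a] <- P[, a] * becke_s(mu)
      }
    }
    wcell <- P[cbind(seq_len(nrow(pts)), owner)] / rowSums(P)
    wts <- wts * wcell
  }
  structure(list(points = pts, weights = wts, owner_atom = owner),
            class = "quadrature_grid")
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("<quadrature_grid> %d points over %d centres\n",
              nrow(x$points), length(unique(x$owner_atom))))
  invisible(x)
}

#' Hirshfeld-partitioned aspherical atomic form factors
#'
#' For each requested atom A of the fragment,
#' f_A(h) = sum_p w_quad(p) w_A(p) rho(p) exp(2 pi i h* . (r_p - R_A)),
#' i.e. the Fourier transform of the Hirshfeld-partitioned fragment density
#' referenced to the atom's own centre (phase-free at R_A, so the values
#' are translation invariant). By default only central atoms receive form
#' factors; caps, junctions and extensions contribute density only.
#'
#' @param fragment A `capped_fragment`.
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @param cell A `unit_cell` mapping hkl to reciprocal Cartesian vectors.
#' @param model A [density_model()].
#' @param grid A `quadrature_grid` (built with defaults when NULL).
#' @param atoms `"central"` (default), `"all"`, or a character vector of
#'   fragment atom labels.
#' @param chunk_size Reflections processed per block (memory control).
#' @return A [form_factor_table()] whose labels are the *source* structure
#'   labels of the selected fragment atoms.
#' @export
atomic_form_factors <- function(fragment, hkl, cell, model = density_model(),
                                grid = NULL, atoms = "central",
                                chunk_size = 256) {
  hkl <- to_coord_matrix(hkl)
  if (nrow(hkl) == 0) stop("empty hkl list", call. = FALSE)
  if (is.null(grid)) grid <- build_grid(fragment)
  at <- fragment$atoms
  sel <- if (identical(atoms, "central")) which(at$role == "central")
         else if (identical(atoms, "all")) seq_len(nrow(at))
         else match(atoms, at$label)
  if (anyNA(sel) || length(sel) == 0) {
    stop("no matching fragment atoms for form-factor calculation", call. = FALSE)
  }
  rho <- fragment_density_at(fragment, grid$points, model)
  wH <- hirshfeld_weight(fragment, NULL, grid$points)
  W <- (grid$weights * rho) * wH[, sel, drop = FALSE]  # n_pts x m
  hstar <- hkl_to_hstar(cell, hkl)                      # n_hkl x 3
  m <- length(sel); nh <- nrow(hstar)
  fre <- matrix(0, nh, m); fim <- matrix(0, nh, m)
  centres <- cbind(at$x, at$y, at$z)[sel, , drop = FALSE]
  idx <- split(seq_len(nh), ceiling(seq_len(nh) / chunk_size))
  for (blk in idx) {
    theta <- 2 * pi * (grid$points %*% t(hstar[blk, , drop = FALSE]))
    fre[blk, ] <- crossprod(cos(theta), W)
    fim[blk, ] <- crossprod(sin(theta), W)
  }
  f <- complex(real = fre, imaginary = fim)
  dim(f) <- c(nh, m)
  # remove the phase at each atom's centre
  theta0 <- 2 * pi * (hstar %*% t(centres))  # nh x m
  f <- f * complex(argument = -theta0)
  labels <- at$source_label[sel]
  form_factor_table(labels, hkl, f)
}

#' Assemble a structure-wide form-factor table
#'
#' Runs the Hirshfeld form-factor quadrature fragment by fragment and
#' gathers one column per structure atom (atoms present in several disorder
#' conformations keep their per-part labels). Column order follows the
#' structure's atom table.
#'
#' @param structure The `crystal_structure` the fragments came from.
#' @param fragments List from [fragment_structure()].
#' @param hkl Integer matrix (n x 3).
#' @param model A [density_model()].
#' @param radial_points,n_theta Grid parameters passed to [build_grid()].
#' @param verbose Print per-fragment progress.
#' @return A [form_factor_table()] covering every structure atom.
#' @export
assemble_tsc <- function(structure, fragments, hkl, model = density_model(),
                         radial_points = 40, n_theta = 8, verbose = FALSE) {
  hkl <- expand_hkl_by_symmetry(to_coord_matrix(hkl), structure$symops)
  cols <- list()
  for (f in fragments) {
    if (!any(f$atoms$role == "central")) next
    if (verbose) message("form factors for fragment ", f$id)
    grid <- build_grid(f, radial_points = radial_points, n_theta = n_theta)
    ft <- atomic_form_factors(f, hkl, structure$cell, model = model,
                              grid = grid, atoms = "central")
    for (j in seq_along(ft$labels)) {
      lab <- ft$labels[j]
      if (!is.null(cols[[lab]])) {
        stop("atom '", lab, "' is central in more than one fragment",
             call. = FALSE)
      }
      cols[[lab]] <- ft$values[, j]
    }
  }
  missing_atoms <- setdiff(structure$atoms$label, names(cols))
  if (length(missing_atoms) > 0) {
    stop("atoms with no owning fragment: ",
         paste(missing_atoms, collapse = ", "), call. = FALSE)
  }
  labels <- structure$atoms$label
  values <- do.call(cbind, cols[labels])
  form_factor_table(labels, hkl, values)
}

#' Spherical (IAM) form-factor table
#'
#' Analytic independent-atom-model table: each atom's column depends only
#' on |h*| through its element's spherical form factor.
#'
#' @param structure A `crystal_structure`.
#' @param hkl Integer matrix (n x 3).
#' @return A [form_factor_table()].
#' @export
assemble_tsc_iam <- function(structure, hkl) {
  hkl <- expand_hkl_by_symmetry(to_coord_matrix(hkl), structure$symops)
  s <- hstar_norm(structure$cell, hkl)
  at <- structure$atoms
  values <- matrix(complex(1), nrow(hkl), nrow(at))
  for (el in unique(at$element)) {
    colv <- complex(real = iam_form_factor(el, s), imaginary = 0)
    values[, at$element == el] <- colv
  }
  form_factor_table(at$label, hkl, values)
}
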