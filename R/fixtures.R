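# Synthetic fixture generation: ideal-geometry toy peptides (G/A/S/C), water
# molecules, an iron-thiolate site, and simulated reflection data -- so the
# whole pipeline runs and is testable without any external data.

# NeRF-style internal-coordinate placement: position d bonded to c with
# given bond length, angle a(b,c,d) and dihedral (a,b,c,d), degrees.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  if (sqrt(sum(n^2)) < 1e-10) stop("collinear reference atoms", call. = FALSE)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# one-letter codes supported by the toy builder
.toy_residues <- c(G = "GLY", A = "ALA", S = "SER", C = "CYS")

#' Specify a toy structure
#'
#' @param sequence One-letter residue string from the supported set
#'   G, A, S, C (e.g. `"GAG"`); may be empty when only waters or a metal
#'   site are wanted.
#' @param conformations Named list: residue index -> numeric vector of
#'   occupancies (must sum to 1), giving that residue's side chain one PART
#'   per occupancy.
#' @param n_waters Number of water molecules to scatter on a clash-free
#'   lattice.
#' @param fe_site Add an iron ion tetrahedrally coordinated by four
#'   methanethiolate (cysteine-like) ligands.
#' @param cell Length-6 numeric (a, b, c, alpha, beta, gamma).
#' @param spacegroup `"P1"` or `"P21"`.
#' @param seed Integer seed controlling the small deterministic variations.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(sequence = "GAG", conformations = list(), n_waters = 0,
                     fe_site = FALSE, cell = c(20, 20, 20, 90, 90, 90),
                     spacegroup = c("P1", "P21"), seed = 1) {
  spacegroup <- match.arg(spacegroup)
  codes <- strsplit(toupper(sequence), "")[[1]]
  if (length(codes) > 0 && !all(codes %in% names(.toy_residues))) {
    stop("unsupported residue code(s): ",
         paste(setdiff(codes, names(.toy_residues)), collapse = ", "),
         "; supported: ", paste(names(.toy_residues), collapse = ", "),
         call. = FALSE)
  }
  for (occ in conformations) {
    if (abs(sum(occ) - 1) > 1e-9) {
      stop("conformation occupancies must sum to 1", call. = FALSE)
    }
  }
  structure(list(sequence = codes, conformations = conformations,
                 n_waters = n_waters, fe_site = fe_site, cell = cell,
                 spacegroup = spacegroup, seed = as.integer(seed)),
            class = "toy_spec")
}

# Build one residue's atoms (Cartesian), given the previous residue's
# backbone positions. Returns list(atoms = tibble(name, element, x, y, z,
# sidechain), backbone = list(N=, CA=, C=, O=)).
build_residue_atoms <- function(code, prev, first, last, phi = -140,
                                psi = 135) {
  rows <- list()
  add <- function(name, element, pos, sidechain = FALSE) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, element = element, x = pos[1], y = pos[2], z = pos[3],
      sidechain = sidechain)
  }
  if (first) {
    N <- c(0, 0, 0)
    CA <- c(1.458, 0, 0)
    C <- place_atom(c(0, 1, 0), N, CA, 1.525, 111.0, -120)
  } else {
    N <- place_atom(prev$N, prev$CA, prev$C, 1.329, 114.0, psi)
    CA <- place_atom(prev$CA, prev$C, N, 1.458, 121.7, 180)
    C <- place_atom(prev$C, N, CA, 1.525, 111.0, phi)
  }
  add("N", "N", N)
  add("CA", "C", CA)
  add("C", "C", C)
  if (first) {
    add("H1", "H", place_atom(C, CA, N, 1.01, 109.5, 60))
    add("H2", "H", place_atom(C, CA, N, 1.01, 109.5, 180))
  } else {
    # amide H trans to the carbonyl O, i.e. cis to the previous CA
    add("H", "H", place_atom(prev$CA, prev$C, N, 1.01, 119.0, 0))
  }
  O <- place_atom(N, CA, C, 1.231, 120.5, psi + 180)
  add("O", "O", O)
  if (last) {
    OXT <- place_atom(N, CA, C, 1.308, 113.0, psi)
    add("OXT", "O", OXT)
    add("HXT", "H", place_atom(CA, C, OXT, 0.98, 110.0, 180))
  }
  # CA substituents built from the two remaining tetrahedral slots
  if (code == "G") {
    add("HA2", "H", tetra_sub(N, C, CA, 1.09, 1))
    add("HA3", "H", tetra_sub(N, C, CA, 1.09, 2))
  } else {
    CB <- tetra_sub(N, C, CA, 1.530, 1)
    add("HA", "H", tetra_sub(N, C, CA, 1.09, 2))
    add("CB", "C", CB, sidechain = TRUE)
    if (code == "A") {
      for (q in 1:3) {
        add(paste0("HB", q), "H",
            place_atom(N, CA, CB, 1.09, 109.5, 60 + 120 * (q - 1)),
            sidechain = TRUE)
      }
    } else {
      xel <- if (code == "S") c("OG", "O", 1.417, 0.96) else c("SG", "S", 1.808, 1.34)
      XG <- place_atom(N, CA, CB, as.numeric(xel[3]), 110.5, 180)
      add(xel[1], xel[2], XG, sidechain = TRUE)
      add("HB2", "H", place_atom(N, CA, CB, 1.09, 109.5, 60), sidechain = TRUE)
      add("HB3", "H", place_atom(N, CA, CB, 1.09, 109.5, -60), sidechain = TRUE)
      add(if (code == "S") "HG" else "HG1", "H",
          place_atom(CA, CB, XG, as.numeric(xel[4]), 103.0, 180),
          sidechain = TRUE)
    }
  }
  list(atoms = dplyr::bind_rows(rows),
       backbone = list(N = N, CA = CA, C = C, O = O, C2 = CA))
}

# fourth tetrahedral substituent directions at centre `c` given two existing
# substituents a and b: the two remaining slots (which = 1 or 2).
tetra_sub <- function(a, b, centre, bond, which) {
  u1 <- a - centre; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- b - centre; u2 <- u2 / sqrt(sum(u2^2))
  bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
  perp <- pracma_cross(u1, u2); perp <- perp / sqrt(sum(perp^2))
  half <- 54.25 * pi / 180  # half tetrahedral angle about the bisector
  dir <- if (which == 1) cos(half) * bis + sin(half) * perp
         else cos(half) * bis - sin(half) * perp
  centre + bond * dir
}

rotate_about_axis <- function(points, origin, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  sweep_pts <- sweep(points, 2, origin)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep_pts %*% t(R), 2, origin, `+`)
}

#' Build a toy crystal structure
#'
#' Ideal-geometry extended peptide with standard bond lengths and angles,
#' hydrogens placed, optional alternative side-chain conformations (PARTs),
#' waters on a clash-free lattice and an optional tetrahedral Fe(S-CH3)4
#' site. Deterministic for a given spec (the seed controls water placement
#' order and starting isotropic ADPs).
#'
#' @param spec A [toy_spec()].
#' @return A `crystal_structure` with connectivity inferred.
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  cellv <- spec$cell
  cell <- unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  all_rows <- list()
  rid <- 0L
  prev <- NULL
  for (i in seq_along(spec$sequence)) {
    code <- spec$sequence[i]
    rid <- rid + 1L
    built <- build_residue_atoms(code, prev, first = i == 1,
                                 last = i == length(spec$sequence))
    at <- built$atoms
    at$residue_id <- rid
    at$residue_name <- .toy_residues[[code]]
    at$part <- 0L
    at$occ <- 1
    confs <- spec$conformations[[as.character(i)]]
    if (!is.null(confs) && length(confs) > 1 && any(at$sidechain)) {
      side <- at[at$sidechain, ]
      main <- at[!at$sidechain, ]
      ca <- as.numeric(main[main$name == "CA", c("x", "y", "z")])
      nn <- as.numeric(main[main$name == "N", c("x", "y", "z")])
      parts <- list()
      for (p in seq_along(confs)) {
        sp <- side
        pts <- rotate_about_axis(as.matrix(side[, c("x", "y", "z")]),
                                 ca, ca - nn, 20 * (p - 1))
        sp$x <- pts[, 1]; sp$y <- pts[, 2]; sp$z <- pts[, 3]
        sp$part <- as.integer(p)
        sp$occ <- confs[p]
        sp$name <- paste0(sp$name, letters[p])
        parts[[p]] <- sp
      }
      at <- dplyr::bind_rows(main, parts)
    }
    all_rows[[length(all_rows) + 1]] <- at
    prev <- built$backbone
  }
  pep <- if (length(all_rows) > 0) dplyr::bind_rows(all_rows) else NULL

  # iron-thiolate site: Fe + 4 methanethiolate ligands, tetrahedral
  if (spec$fe_site) {
    fe_centre <- c(-6, 0, 0)
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    rid <- rid + 1L
    all_rows[[length(all_rows) + 1]] <- tibble::tibble(
      name = "FE1", element = "Fe", x = fe_centre[1], y = fe_centre[2],
      z = fe_centre[3], sidechain = FALSE, residue_id = rid,
      residue_name = "FE", part = 0L, occ = 1)
    for (li in 1:4) {
      rid <- rid + 1L
      u <- dirs[li, ]
      s <- fe_centre + 2.30 * u
      # bent Fe-S-CB angle (109.5 deg)
      perp <- pracma_cross(u, c(0, 0, 1))
      if (sqrt(sum(perp^2)) < 1e-6) perp <- pracma_cross(u, c(0, 1, 0))
      perp <- perp / sqrt(sum(perp^2))
      th <- (180 - 109.5) * pi / 180
      cb <- s + 1.81 * (cos(th) * u + sin(th) * perp)
      rows <- list(tibble::tibble(name = "SG", element = "S", x = s[1],
                                  y = s[2], z = s[3], sidechain = FALSE,
                                  residue_id = rid, residue_name = "CYL",
                                  part = 0L, occ = 1),
                   tibble::tibble(name = "CB", element = "C", x = cb[1],
                                  y = cb[2], z = cb[3], sidechain = FALSE,
                                  residue_id = rid, residue_name = "CYL",
                                  part = 0L, occ = 1))
      for (q in 1:3) {
        hpos <- place_atom(fe_centre, s, cb, 1.09, 109.5, 60 + 120 * (q - 1))
        rows[[length(rows) + 1]] <- tibble::tibble(
          name = paste0("HB", q), element = "H", x = hpos[1], y = hpos[2],
          z = hpos[3], sidechain = FALSE, residue_id = rid,
          residue_name = "CYL", part = 0L, occ = 1)
      }
      all_rows[[length(all_rows) + 1]] <- dplyr::bind_rows(rows)
    }
  }
  mol <- dplyr::bind_rows(all_rows)

  # waters on a lattice, keeping clear of everything placed so far
  if (spec$n_waters > 0) {
    grid_pts <- as.matrix(expand.grid(
      x = seq(-cellv[1] / 2 + 2, cellv[1] / 2 - 2, by = 3.1),
      y = seq(-cellv[2] / 2 + 2, cellv[2] / 2 - 2, by = 3.1),
      z = seq(-cellv[3] / 2 + 2, cellv[3] / 2 - 2, by = 3.1)))
    placed <- 0L
    existing <- if (nrow(mol) > 0) as.matrix(mol[, c("x", "y", "z")]) else
      matrix(numeric(), 0, 3)
    for (gi in seq_len(nrow(grid_pts))) {
      if (placed >= spec$n_waters) break
      p <- grid_pts[gi, ]
      if (nrow(existing) > 0 &&
          min(sqrt(rowSums(sweep(existing, 2, p)^2))) < 3.0) next
      rid <- rid + 1L
      # seeded in-plane orientation so different seeds give different fixtures
      phi <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1),
                    3, 3)
      h1 <- p + 0.96 * as.vector(rot %*% c(1, 0, 0))
      h2 <- p + 0.96 * as.vector(
        rot %*% c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0))
      all_rows[[length(all_rows) + 1]] <- tibble::tibble(
        name = c("O", "H1", "H2"), element = c("O", "H", "H"),
        x = c(p[1], h1[1], h2[1]), y = c(p[2], h1[2], h2[2]),
        z = c(p[3], h1[3], h2[3]), sidechain = FALSE, residue_id = rid,
        residue_name = "HOH", part = 0L, occ = 1)
      existing <- rbind(existing, p)
      placed <- placed + 1L
    }
    if (placed < spec$n_waters) {
      stop("could not place ", spec$n_waters, " waters without clashes; ",
           "use a larger cell", call. = FALSE)
    }
  }
  atoms_cart <- dplyr::bind_rows(all_rows)
  if (nrow(atoms_cart) == 0) stop("empty toy spec", call. = FALSE)

  # centre in the cell and convert to fractional
  xyz <- as.matrix(atoms_cart[, c("x", "y", "z")])
  centre_target <- frac_to_cart(cell, c(0.25, 0.25, 0.25))
  if (spec$spacegroup == "P1") centre_target <- frac_to_cart(cell, c(0.5, 0.5, 0.5))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- sweep(xyz, 2, as.numeric(centre_target), `+`)
  frac <- cart_to_frac(cell, xyz)

  u_start <- ifelse(atoms_cart$element == "H", 0.04,
                    0.015 + 0.01 * (seq_len(nrow(atoms_cart)) %% 5) / 5) +
    stats::runif(nrow(atoms_cart), 0, 0.002)  # seeded per-atom variation
  atoms <- tibble::tibble(
    label = paste0(atoms_cart$name, "_", atoms_cart$residue_id),
    element = atoms_cart$element,
    x = frac[, 1], y = frac[, 2], z = frac[, 3],
    occ = atoms_cart$occ, part = atoms_cart$part, u_iso = u_start,
    u_aniso = vector("list", nrow(atoms_cart)),
    residue_id = atoms_cart$residue_id,
    residue_name = atoms_cart$residue_name)
  symops <- if (spec$spacegroup == "P21") {
    list(list(R = diag(3), t = c(0, 0, 0)), parse_symop("-X, Y+1/2, -Z"))
  } else NULL
  st <- crystal_structure(cell, atoms, symops = symops)
  st <- flag_solvent(st)
  infer_connectivity(st)
}

#' Analytic model structure factors
#'
#' Exact structure factors of the Gaussian density model (promolecule plus
#' optional bond deformation): every Gaussian primitive transforms
#' analytically, atoms carry their Debye-Waller factors and occupancies,
#' deformation primitives ride on the bonded atoms' geometric-mean
#' attenuation. Serves both as the data simulator and as an independent
#' oracle for the quadrature route.
#'
#' @param structure A `crystal_structure`.
#' @param hkl Integer matrix (n x 3).
#' @param model A [density_model()].
#' @return Complex structure factors.
#' @export
analytic_structure_factors <- function(structure, hkl,
                                       model = density_model()) {
  hkl <- to_coord_matrix(hkl)
  at <- structure$atoms
  cell <- structure$cell
  X <- cbind(at$x, at$y, at$z)
  F_total <- complex(real = numeric(nrow(hkl)))
  for (op in structure$symops) {
    h2 <- hkl %*% op$R
    s <- sqrt(rowSums((h2 %*% t(cell$recip_basis))^2))
    dw <- matrix(0, nrow(hkl), nrow(at))
    ff <- matrix(0, nrow(hkl), nrow(at))
    for (k in seq_len(nrow(at))) {
      dw[, k] <- if (is.null(at$u_aniso[[k]])) {
        debye_waller(cell, h2, u_iso = at$u_iso[k])
      } else {
        debye_waller(cell, h2, u_aniso = at$u_aniso[[k]])
      }
      ff[, k] <- iam_form_factor(at$element[k], s)
    }
    phase <- 2 * pi * (h2 %*% t(X) + matrix(hkl %*% op$t, nrow(hkl), nrow(at)))
    F_total <- F_total + as.vector((ff * dw * exp(1i * phase)) %*% at$occ)
    if (isTRUE(model$deformation)) {
      if (nrow(structure$bonds) == 0) structure <- infer_connectivity(structure)
      b <- structure$bonds
      gdef <- analytic_gaussian_ff(model$beta, s)
      for (q in seq_len(nrow(b))) {
        ki <- match(b$i[q], at$label); kj <- match(b$j[q], at$label)
        occ_b <- min(at$occ[ki], at$occ[kj])
        dwb <- sqrt(dw[, ki] * dw[, kj])
        xm <- (X[ki, ] + X[kj, ]) / 2
        ph_m <- exp(2i * pi * (h2 %*% xm + hkl %*% op$t))
        ph_i <- exp(2i * pi * (h2 %*% X[ki, ] + hkl %*% op$t))
        ph_j <- exp(2i * pi * (h2 %*% X[kj, ] + hkl %*% op$t))
        F_total <- F_total + occ_b * model$population * gdef * dwb *
          as.vector(ph_m - 0.5 * ph_i - 0.5 * ph_j)
      }
    }
  }
  F_total
}

#' Enumerate symmetry-unique reflections
#'
#' All Miller indices with resolution d >= d_min, reduced to one
#' representative per orbit under the structure's rotational symmetry and
#' Friedel inversion (the lexicographically largest member).
#'
#' @param structure A `crystal_structure` (cell + symops).
#' @param d_min Resolution limit in Angstrom (> 0).
#' @return Integer matrix (n x 3).
#' @export
unique_hkl <- function(structure, d_min) {
  stopifnot(d_min > 0)
  cell <- structure$cell
  smax <- 1 / d_min
  hmax <- ceiling(smax * c(cell$a, cell$b, cell$c))
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- g[hstar_norm(cell, g) <= smax + 1e-12, , drop = FALSE]
  if (nrow(g) == 0) stop("d_min larger than the cell: empty reflection set",
                         call. = FALSE)
  rots <- lapply(structure$symops, `[[`, "R")
  key_of <- function(m) paste(m[, 1], m[, 2], m[, 3])
  best <- key_of(g)
  best_num <- g[, 1] * 4e6 + g[, 2] * 2e3 + g[, 3]
  rep_num <- best_num
  rep_idx <- seq_len(nrow(g))
  canon <- matrix(0L, nrow(g), 3)
  canon_num <- rep(-Inf, nrow(g))
  for (R in rots) {
    for (sgn in c(1, -1)) {
      m <- sgn * (g %*% R)
      num <- m[, 1] * 4e6 + m[, 2] * 2e3 + m[, 3]
      upd <- num > canon_num
      canon[upd, ] <- m[upd, , drop = FALSE]
      canon_num[upd] <- num[upd]
    }
  }
  uniq <- !duplicated(canon_num)
  out <- canon[uniq, , drop = FALSE]
  storage.mode(out) <- "integer"
  out[order(-out[, 1], -out[, 2], -out[, 3]), , drop = FALSE]
}

#' Simulate reflection data
#'
#' Generates all symmetry-unique reflections to `d_min`, computes model
#' intensities from the analytic Gaussian density (or a supplied
#' form-factor table) and adds multiplicative Gaussian noise:
#' Fo2 = s |F|^2 (1 + eps), eps ~ N(0, noise_frac), with
#' sigma = max(noise_frac |Fo2|, floor). Deterministic per seed.
#'
#' @param structure A `crystal_structure`.
#' @param d_min Resolution limit (Angstrom).
#' @param noise_frac Relative noise level (>= 0).
#' @param seed Integer seed.
#' @param model A [density_model()] for the analytic simulator.
#' @param ff_table Optional `form_factor_table`: when given, intensities
#'   come from [calc_structure_factors()] with this table instead.
#' @param scale True intensity scale s (default 1).
#' @param sigma_floor Lower bound for sigma (default 0.01).
#' @param solvent Optional `solvent_mask` added to F.
#' @return Tibble `h,k,l,fo2,sigma` (an HKLF4-ready reflection set).
#' @export
simulate_reflections <- function(structure, d_min, noise_frac = 0, seed = 1,
                                 model = density_model(), ff_table = NULL,
                                 scale = 1, sigma_floor = 0.01,
                                 solvent = NULL) {
  stopifnot(d_min > 0, noise_frac >= 0)
  hkl <- unique_hkl(structure, d_min)
  Fc <- if (is.null(ff_table)) {
    fs <- analytic_structure_factors(structure, hkl, model)
    if (!is.null(solvent)) fs <- fs + solvent_structure_factors(solvent, hkl)
    fs
  } else {
    calc_structure_factors(structure, ff_table, hkl, solvent = solvent)
  }
  set.seed(seed)
  eps <- if (noise_frac > 0) stats::rnorm(length(Fc), 0, noise_frac) else 0
  fo2 <- scale * Mod(Fc)^2 * (1 + eps)
  sigma <- pmax(noise_frac * abs(fo2), sigma_floor)
  tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                 fo2 = fo2, sigma = sigma)
}
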