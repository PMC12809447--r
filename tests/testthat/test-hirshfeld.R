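# single-atom fragment helper
one_atom_fragment <- function(element = "C", at = c(1.0, 1.2, 0.8)) {
  structure(list(
    id = "T", charge = 0L, multiplicity = 1L, qm_charge = 0L,
    atoms = tibble::tibble(
      label = "A1", element = element, x = at[1], y = at[2], z = at[3],
      role = "central", parent_label = NA_character_,
      replaced_label = NA_character_, source_label = "A1")),
    class = "capped_fragment")
}

test_that("Gauss-Legendre rule integrates polynomials exactly", {
  gl <- gauss_legendre(6)
  expect_equal(sum(gl$w), 2, tolerance = 1e-12)
  for (p in c(2, 4, 10)) {  # exact up to degree 2n-1 = 11
    expect_equal(sum(gl$w * gl$x^p), 2 / (p + 1), tolerance = 1e-12)
  }
  expect_equal(sum(gl$w * gl$x^3), 0, tolerance = 1e-12)
})

test_that("Becke switching partitions space smoothly", {
  mu <- seq(-1, 1, by = 0.05)
  s <- becke_s(mu)
  expect_equal(becke_s(-1), 1)
  expect_equal(becke_s(1), 0)
  expect_equal(s + becke_s(-mu), rep(1, length(mu)), tolerance = 1e-12)
  expect_true(all(diff(s) <= 0))
})

test_that("Hirshfeld weights form a partition of unity", {
  at2 <- tibble::tibble(
    label = c("C1", "O1"), element = c("C", "O"),
    x = c(0, 1.23), y = c(0, 0), z = c(0, 0), role = "central",
    parent_label = NA_character_, replaced_label = NA_character_,
    source_label = c("C1", "O1"))
  frag <- structure(list(id = "CO", atoms = at2, charge = 0L,
                         multiplicity = 1L, qm_charge = 0L),
                    class = "capped_fragment")
  pts <- build_grid(frag, radial_points = 15, n_theta = 4)$points
  w <- hirshfeld_weight(frag, NULL, pts)
  expect_lt(max(abs(rowSums(w) - 1)), 1e-12)
  expect_true(all(w >= 0 & w <= 1))
  # near each nucleus the owner dominates
  wC <- hirshfeld_weight(frag, "C1", rbind(c(0.01, 0, 0)))
  expect_gt(wC, 0.5)
})

test_that("quadrature grid integrates the promolecule to the electron count", {
  frag <- one_atom_fragment("O", c(0, 0, 0))
  g <- build_grid(frag, radial_points = 40, n_theta = 8)
  rho <- fragment_density_at(frag, g$points, density_model(deformation = FALSE))
  expect_equal(sum(g$weights * rho), 8, tolerance = 1e-6)
})

test_that("numeric form factors match the analytic Gaussian oracle", {
  cell <- unit_cell(10, 10, 10, 90, 90, 90)
  frag <- one_atom_fragment("C")
  hkl <- as.matrix(expand.grid(h = 0:6, k = 0:4, l = 0:3))
  hkl <- hkl[hstar_norm(cell, hkl) <= 2, , drop = FALSE]
  g <- build_grid(frag, radial_points = 60, n_theta = 12)
  ff <- atomic_form_factors(frag, hkl, cell, density_model(deformation = FALSE), g)
  oracle <- iam_form_factor("C", hstar_norm(cell, hkl))
  expect_lt(max(Mod(ff$values[, 1] - oracle)), 1e-6)
})

test_that("form factors are translation invariant", {
  cell <- unit_cell(10, 10, 10, 90, 90, 90)
  hkl <- rbind(c(1, 0, 0), c(2, 1, 0), c(3, 2, 1))
  f1 <- one_atom_fragment("N", c(0, 0, 0))
  f2 <- one_atom_fragment("N", c(2.5, -1.0, 3.7))
  v1 <- atomic_form_factors(f1, hkl, cell, grid = build_grid(f1, 30, 6))$values
  v2 <- atomic_form_factors(f2, hkl, cell, grid = build_grid(f2, 30, 6))$values
  expect_lt(max(Mod(v1 - v2)), 1e-8)
})

test_that("partitioned form factors sum to the fragment transform", {
  cell <- unit_cell(10, 10, 10, 90, 90, 90)
  at2 <- tibble::tibble(
    label = c("C1", "O1"), element = c("C", "O"),
    x = c(0, 1.23), y = c(0, 0), z = c(0, 0), role = "central",
    parent_label = NA_character_, replaced_label = NA_character_,
    source_label = c("C1", "O1"))
  frag <- structure(list(id = "CO", atoms = at2, charge = 0L,
                         multiplicity = 1L, qm_charge = 0L),
                    class = "capped_fragment")
  hkl <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 1), c(3, 0, 2))
  g <- build_grid(frag, radial_points = 60, n_theta = 12)
  model <- density_model(deformation = TRUE, population = 0.2)
  ff <- atomic_form_factors(frag, hkl, cell, model, g, atoms = "all")
  # direct quadrature of the whole fragment density (no partitioning)
  rho <- fragment_density_at(frag, g$points, model)
  hstar <- hkl_to_hstar(cell, hkl)
  theta <- 2 * pi * (g$points %*% t(hstar))
  direct <- as.vector(crossprod(cos(theta), g$weights * rho)) +
    1i * as.vector(crossprod(sin(theta), g$weights * rho))
  # re-apply each atom's centre phase before summing the partitions
  centres <- hstar %*% t(as.matrix(at2[, c("x", "y", "z")]))
  total <- rowSums(ff$values * complex(argument = 2 * pi * centres))
  expect_lt(max(Mod(total - direct)) / max(Mod(direct)), 1e-5)
})

test_that("per-fragment grids stay bounded as the system grows", {
  st3 <- make_toy_structure(toy_spec("GGG"))
  st6 <- make_toy_structure(toy_spec("GGGGGG", cell = c(30, 20, 20, 90, 90, 90)))
  mid3 <- fragment_structure(st3)[[2]]
  mid6 <- fragment_structure(st6)[[3]]
  g3 <- build_grid(mid3, radial_points = 10, n_theta = 4)
  g6 <- build_grid(mid6, radial_points = 10, n_theta = 4)
  expect_equal(nrow(g6$points), nrow(g3$points))
})

test_that("assemble_tsc errors when an atom has no owning fragment", {
  st <- make_toy_structure(toy_spec("GA"))
  frags <- fragment_structure(st)
  hkl <- unique_hkl(st, 3)
  expect_error(assemble_tsc(st, frags[1], hkl, radial_points = 6, n_theta = 3),
               "no owning fragment")
})
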