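test_that("Debye-Waller factor is 1 at h = 0 and matches iso/aniso limits", {
  cell <- unit_cell(10, 12, 14, 90, 90, 90)
  expect_equal(debye_waller(cell, c(0, 0, 0), u_iso = 0.02), 1)
  hkl <- rbind(c(1, 2, 3), c(4, 0, 1), c(0, 5, 2))
  u <- 0.025
  iso <- debye_waller(cell, hkl, u_iso = u)
  # isotropic tensor U11=U22=U33=u in an orthogonal cell is equivalent
  aniso <- debye_waller(cell, hkl, u_aniso = c(u, u, u, 0, 0, 0))
  expect_equal(aniso, iso, tolerance = 1e-12)
  expect_equal(iso, exp(-2 * pi^2 * u * hstar_norm(cell, hkl)^2),
               tolerance = 1e-12)
})

test_that("non-positive-definite anisotropic tensors are rejected", {
  cell <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_error(debye_waller(cell, c(1, 0, 0),
                            u_aniso = c(0.01, 0.01, -0.02, 0, 0, 0)),
               "positive definite")
  expect_error(debye_waller(cell, c(1, 0, 0), u_iso = 0), "positive")
})

test_that("hkl symmetry expansion covers all transformed indices", {
  st <- make_toy_structure(toy_spec("G", cell = c(12, 12, 12, 90, 90, 90),
                                    spacegroup = "P21"))
  hkl <- unique_hkl(st, 2)
  full <- expand_hkl_by_symmetry(hkl, st$symops)
  keys <- paste(full[, 1], full[, 2], full[, 3])
  keys <- c(keys, paste(-full[, 1], -full[, 2], -full[, 3]))
  for (op in st$symops) {
    h2 <- hkl %*% op$R
    expect_true(all(paste(h2[, 1], h2[, 2], h2[, 3]) %in% keys))
  }
  expect_false(anyDuplicated(paste(full[, 1], full[, 2], full[, 3])) > 0)
})

test_that("table-based structure factors match the analytic IAM oracle", {
  st <- toy_gag()
  hkl <- unique_hkl(st, 1.5)
  ff <- assemble_tsc_iam(st, hkl)
  f_table <- calc_structure_factors(st, ff, hkl)
  f_oracle <- analytic_structure_factors(st, hkl,
                                         density_model(deformation = FALSE))
  expect_lt(max(Mod(f_table - f_oracle)) / max(Mod(f_oracle)), 1e-10)
})

test_that("Friedel symmetry holds without anomalous scattering and breaks with it", {
  st <- toy_gag()
  hkl <- rbind(c(1, 2, 3), c(2, 0, 1), c(3, 1, 2))
  both <- rbind(hkl, -hkl)
  ff <- assemble_tsc_iam(st, both)
  f <- calc_structure_factors(st, ff, both)
  expect_equal(Mod(f[1:3]), Mod(f[4:6]), tolerance = 1e-12)
  st2 <- st
  st2$atoms$f_dp[1] <- 0.5
  f2 <- calc_structure_factors(st2, ff, both)
  expect_gt(max(abs(Mod(f2[1:3]) - Mod(f2[4:6]))), 1e-6)
})

test_that("structure factors are linear in occupancy", {
  st <- toy_gag()
  hkl <- rbind(c(1, 1, 1), c(2, 1, 0))
  ff <- assemble_tsc_iam(st, hkl)
  f1 <- calc_structure_factors(st, ff, hkl)
  st$atoms$occ <- st$atoms$occ / 2
  f2 <- calc_structure_factors(st, ff, hkl)
  expect_equal(f2, f1 / 2, tolerance = 1e-12)
})

test_that("P21 symmetry makes |F| invariant under the screw rotation", {
  st <- make_toy_structure(toy_spec("GA", cell = c(12, 12, 12, 90, 90, 90),
                                    spacegroup = "P21"))
  hkl <- unique_hkl(st, 1.5)[1:25, ]
  op <- st$symops[[2]]
  both <- rbind(hkl, hkl %*% op$R)
  ff <- assemble_tsc_iam(st, both)
  f <- calc_structure_factors(st, ff, both)
  expect_equal(Mod(f[26:50]), Mod(f[1:25]), tolerance = 1e-10)
})

test_that("solvent mask scatters k x masked volume at the origin", {
  st <- make_toy_structure(toy_spec("G"))
  sm <- build_solvent_mask(st, grid_spacing = 1.0)
  expect_true(sm$volume > 0 && sm$volume < st$cell$volume)
  f000 <- solvent_structure_factors(sm, rbind(c(0, 0, 0)))
  expect_equal(Re(f000), sm$k * sm$volume, tolerance = 1e-10)
  expect_equal(Im(f000), 0, tolerance = 1e-10)
  # high-resolution terms are strongly smeared
  fhi <- solvent_structure_factors(sm, rbind(c(8, 8, 8)))
  expect_lt(Mod(fhi), Mod(f000) * 1e-3)
})

test_that("solvent contribution feeds through calc_structure_factors", {
  st <- make_toy_structure(toy_spec("G"))
  hkl <- rbind(c(1, 0, 0), c(1, 1, 1))
  ff <- assemble_tsc_iam(st, hkl)
  sm <- build_solvent_mask(st, grid_spacing = 1.2)
  f0 <- calc_structure_factors(st, ff, hkl)
  f1 <- calc_structure_factors(st, ff, hkl, solvent = sm)
  expect_equal(f1 - f0, solvent_structure_factors(sm, hkl), tolerance = 1e-10)
})
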