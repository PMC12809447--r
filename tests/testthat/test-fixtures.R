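test_that("toy structures are reproducible bit-for-bit from the spec", {
  s1 <- make_toy_structure(toy_spec("GAS", n_waters = 2, seed = 42))
  s2 <- make_toy_structure(toy_spec("GAS", n_waters = 2, seed = 42))
  expect_identical(s1$atoms, s2$atoms)
  s3 <- make_toy_structure(toy_spec("GAS", n_waters = 2, seed = 43))
  expect_false(identical(s1$atoms, s3$atoms))
})

test_that("peptide fixtures have the expected per-residue atom counts", {
  # glycine: N CA C O + H(amide) + 2 HA; termini add H1/H2 (extra amide H
  # replaced) and OXT/HXT
  st <- make_toy_structure(toy_spec("GGG"))
  counts <- table(st$atoms$residue_id)
  expect_equal(unname(counts[2]), 7L)
  expect_equal(unname(counts[1]), 8L)   # H1 + H2 instead of single H
  expect_equal(unname(counts[3]), 9L)   # + OXT + HXT
  # alanine adds CB + 3 HB; serine OG + HG in place of one HB
  sta <- make_toy_structure(toy_spec("GAG"))
  expect_equal(sum(sta$atoms$residue_id == 2), 7L + 4L - 1L)  # HA -> CB(H3)
})

test_that("ideal geometry matches the internal-coordinate targets", {
  st <- infer_connectivity(make_toy_structure(toy_spec("GAG")))
  xyz <- atom_cart(st)
  d <- function(a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  expect_equal(d("N_2", "CA_2"), 1.458, tolerance = 1e-6)
  expect_equal(d("CA_2", "C_2"), 1.525, tolerance = 1e-6)
  expect_equal(d("C_1", "N_2"), 1.329, tolerance = 1e-6)
  expect_equal(d("C_2", "O_2"), 1.231, tolerance = 1e-6)
})

test_that("disorder specs duplicate side chains with the given occupancies", {
  st <- make_toy_structure(toy_spec("GSG", conformations = list(`2` = c(0.6, 0.4))))
  p1 <- st$atoms[st$atoms$part == 1, ]
  p2 <- st$atoms[st$atoms$part == 2, ]
  expect_equal(nrow(p1), nrow(p2))
  expect_true(all(p1$occ == 0.6))
  expect_true(all(p2$occ == 0.4))
  expect_error(toy_spec("GSG", conformations = list(`2` = c(0.6, 0.5))),
               "sum to 1")
})

test_that("unsupported residues and impossible cells error clearly", {
  expect_error(toy_spec("GAX"), "residue")
  expect_error(make_toy_structure(toy_spec("GAGAGA", n_waters = 40,
                                           cell = c(8, 8, 8, 90, 90, 90))),
               "cell")
})

test_that("the Fe site is tetrahedral with four thiolate ligands", {
  st <- infer_connectivity(toy_fe())
  fe <- st$atoms$label[st$atoms$element == "Fe"]
  adj <- bond_adjacency(st)
  sg <- adj[[fe]]
  expect_length(sg, 4)
  expect_true(all(st$atoms$element[match(sg, st$atoms$label)] == "S"))
  xyz <- atom_cart(st)
  d <- vapply(sg, function(s) sqrt(sum((xyz[s, ] - xyz[fe, ])^2)), numeric(1))
  expect_equal(unname(d), rep(2.30, 4), tolerance = 1e-6)
  # tetrahedral S-Fe-S angles
  for (i in 1:3) for (j in (i + 1):4) {
    u <- xyz[sg[i], ] - xyz[fe, ]; v <- xyz[sg[j], ] - xyz[fe, ]
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(ang, 109.4712, tolerance = 1e-3)
  }
})

test_that("unique_hkl enumerates the resolution sphere like brute force", {
  st <- make_toy_structure(toy_spec("G", cell = c(12, 14, 16, 90, 90, 90)))
  d_min <- 2
  u <- unique_hkl(st, d_min)
  # brute force: all lattice points with d >= d_min, one per Friedel pair
  hmax <- ceiling(c(12, 14, 16) / d_min)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  keep <- hkl_resolution(st$cell, grid) >= d_min
  expect_equal(nrow(u), sum(keep) / 2)
  expect_true(all(hkl_resolution(st$cell, u) >= d_min))
  # no Friedel duplicates
  keys <- paste(u[, 1], u[, 2], u[, 3])
  negs <- paste(-u[, 1], -u[, 2], -u[, 3])
  expect_length(intersect(keys, negs), 0)
})

test_that("unique_hkl keeps one representative per P21 orbit", {
  st <- make_toy_structure(toy_spec("G", cell = c(12, 12, 12, 90, 90, 90),
                                    spacegroup = "P21"))
  u <- unique_hkl(st, 2.5)
  op <- st$symops[[2]]
  keys <- paste(u[, 1], u[, 2], u[, 3])
  h2 <- u %*% op$R
  i2 <- match(paste(h2[, 1], h2[, 2], h2[, 3]), keys)
  i2n <- match(paste(-h2[, 1], -h2[, 2], -h2[, 3]), keys)
  self <- seq_along(keys)
  # a transformed index (or its Friedel mate) may only hit the row it came from
  expect_false(any(!is.na(i2) & i2 != self))
  expect_false(any(!is.na(i2n) & i2n != self))
})

test_that("simulated reflections are deterministic and correctly scaled", {
  st <- toy_gag()
  r1 <- simulate_reflections(st, d_min = 1.5, noise_frac = 0.03, seed = 7)
  r2 <- simulate_reflections(st, d_min = 1.5, noise_frac = 0.03, seed = 7)
  expect_identical(r1, r2)
  r3 <- simulate_reflections(st, d_min = 1.5, noise_frac = 0.03, seed = 8)
  expect_false(identical(r1$fo2, r3$fo2))
  # noise-free: Fo2 = s |F|^2 exactly
  r0 <- simulate_reflections(st, d_min = 1.5, noise_frac = 0, seed = 1,
                             scale = 3)
  f <- analytic_structure_factors(st, cbind(r0$h, r0$k, r0$l))
  expect_equal(r0$fo2, 3 * Mod(f)^2, tolerance = 1e-12)
  expect_true(all(r0$sigma > 0))
  expect_error(simulate_reflections(st, d_min = 100), "d_min")
})

test_that("toy structures carry inferred connectivity and sane ADPs", {
  st <- toy_gag()
  expect_gt(nrow(st$bonds), 0)
  expect_true(all(st$atoms$u_iso > 0))
  expect_true(all(st$atoms$occ > 0 & st$atoms$occ <= 1))
})
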