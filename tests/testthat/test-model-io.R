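test_that("SHELX ins files roundtrip structures", {
  st <- toy_gag()
  f <- withr::local_tempfile(fileext = ".ins")
  write_structure_ins(st, f)
  st2 <- read_structure(f)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(st2$atoms$label, st$atoms$label)
  expect_equal(st2$atoms$element, st$atoms$element)
  expect_lt(max(abs(atom_cart(st2) - atom_cart(st))), 1e-5)
  expect_equal(st2$atoms$occ, st$atoms$occ, tolerance = 1e-5)
  expect_equal(st2$atoms$part, st$atoms$part)
  expect_equal(length(st2$symops), length(st$symops))
})

test_that("unknown ins instructions are preserved opaquely", {
  st <- make_toy_structure(toy_spec("G"))
  f <- withr::local_tempfile(fileext = ".ins")
  write_structure_ins(st, f)
  lines <- readLines(f)
  lines <- append(lines, "SHEL 10 0.8", after = 2)
  writeLines(lines, f)
  st2 <- read_structure(f)
  f2 <- withr::local_tempfile(fileext = ".ins")
  write_structure_ins(st2, f2)
  expect_true(any(grepl("^SHEL 10 0.8", readLines(f2))))
})

test_that("PDB files roundtrip through bio3d with cell and ADPs", {
  st <- toy_gag()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, f)
  st2 <- read_structure(f)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_lt(max(abs(atom_cart(st2) - atom_cart(st))), 1e-3)
  expect_equal(st2$cell$a, st$cell$a)
  # B factors are written with two decimals, so U carries ~1.3e-4 A^2 noise
  expect_lt(max(abs(st2$atoms$u_iso - st$atoms$u_iso)), 1e-3)
})

test_that("PDB altLoc letters become consecutive disorder parts", {
  lines <- c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       2.000   2.500   3.000  0.60 10.00           C",
    "ATOM      3  CA BALA A   1       2.100   2.400   3.100  0.40 10.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  st <- read_structure(f)
  expect_equal(st$atoms$part, c(0L, 1L, 2L))
  expect_equal(st$atoms$occ, c(1.0, 0.6, 0.4))
  # B = 10 A^2 -> U = B / (8 pi^2)
  expect_equal(st$atoms$u_iso[1], 10 / (8 * pi^2), tolerance = 1e-6)
})

test_that("hkl files roundtrip, including wide fields that touch columns", {
  refl <- tibble::tibble(h = c(1L, -2L, 10L), k = c(0L, 3L, -4L),
                         l = c(1L, -1L, 2L),
                         fo2 = c(10604.06, -3.25, 0.10),
                         sigma = c(212.08, 1.5, 0.02))
  f <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(refl, f)
  r2 <- read_hkl(f)
  expect_equal(r2$h, refl$h)
  expect_equal(r2$fo2, refl$fo2)   # negative Fo2 preserved
  expect_equal(r2$sigma, refl$sigma)
})

test_that("hkl reader stops at the 0 0 0 terminator and validates input", {
  f <- withr::local_tempfile(fileext = ".hkl")
  writeLines(c("   1   0   0   10.00    1.00",
               "   0   0   0    0.00    0.00",
               "   2   0   0   99.00    1.00"), f)
  expect_equal(nrow(read_hkl(f)), 1)
  writeLines("   1   0   0   10.00   -1.00", f)
  expect_error(read_hkl(f), "sigma")
  writeLines("   a   0   0   10.00    1.00", f)
  expect_error(read_hkl(f), "line 1")
})

test_that("qS files parse with defaults, parts, and duplicate detection", {
  f <- withr::local_tempfile(fileext = ".qS")
  writeLines(c("6 -1 6", "3 1 1 2"), f)
  qs <- parse_qs(f)
  expect_equal(nrow(qs), 2)
  expect_equal(qs$charge[qs$residue_id == 6], -1L)
  expect_equal(qs$part[qs$residue_id == 3], 2L)
  expect_true(is.na(qs$part[qs$residue_id == 6]))
  # missing file -> empty table (defaults everywhere)
  qs0 <- parse_qs(file.path(tempdir(), "no_such_file.qS"))
  expect_equal(nrow(qs0), 0)
  writeLines(c("6 -1 6", "6 0 1"), f)
  expect_error(parse_qs(f), "duplicate")
})

test_that("tsc files roundtrip complex form factors", {
  st <- toy_gag()
  hkl <- unique_hkl(st, 2.5)
  ff <- assemble_tsc_iam(st, hkl)
  f <- withr::local_tempfile(fileext = ".tsc")
  write_tsc(ff, f)
  ff2 <- read_tsc(f)
  expect_equal(ff2$labels, ff$labels)
  expect_equal(ff2$hkl, ff$hkl)
  expect_lt(max(Mod(ff2$values - ff$values)), 1e-6)
})

test_that("solvent flagging and default hydrogen ADPs work", {
  st <- flag_solvent(make_toy_structure(toy_spec("G", n_waters = 2)))
  expect_true("solvent" %in% names(st$residues))
  expect_equal(sum(st$residues$solvent), 2)  # the two waters
  st$atoms$u_iso[st$atoms$element == "H"] <- 0
  st2 <- default_hydrogen_adp(infer_connectivity(st))
  hs <- st2$atoms$element == "H"
  expect_true(all(st2$atoms$u_iso[hs] > 0))
})
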