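test_that("junction hydrogens sit exactly at the junction distance", {
  st <- infer_connectivity(toy_gag())
  frags <- fragment_structure(st)
  xyz_of <- function(f) as.matrix(f$atoms[, c("x", "y", "z")])
  for (f in frags) {
    jn <- which(f$atoms$role == "junction")
    for (j in jn) {
      p <- match(f$atoms$parent_label[j], f$atoms$label)
      d <- sqrt(sum((xyz_of(f)[j, ] - xyz_of(f)[p, ])^2))
      expect_equal(d, 1.094, tolerance = 1e-12)
    }
  }
})

test_that("a junction hydrogen lies along the original bond direction", {
  st <- infer_connectivity(toy_gag())
  f <- fragment_structure(st)[[2]]
  xyz_all <- atom_cart(st)
  j <- which(f$atoms$role == "junction")[1]
  parent <- f$atoms$parent_label[j]
  removed <- f$atoms$replaced_label[j]
  u1 <- c(f$atoms$x[j], f$atoms$y[j], f$atoms$z[j]) - xyz_all[parent, ]
  u2 <- xyz_all[removed, ] - xyz_all[parent, ]
  cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("mid-chain residue caps are CH3CO- and -NHCH3", {
  st <- infer_connectivity(toy_gag())
  f <- fragment_structure(st)[[2]]
  # N-side cap: previous residue's carbonyl C=O plus its CA turned into a
  # junction-methyl => CH3CO-; C-side: next N-H plus CA-methyl => -NHCH3
  nside <- f$atoms[grepl("_1$", f$atoms$source_label) &
                     f$atoms$role %in% c("cap", "junction"), ]
  cside <- f$atoms[grepl("_3$", f$atoms$source_label) &
                     f$atoms$role %in% c("cap", "junction"), ]
  expect_equal(composition(nside), "C2H3O1")  # CH3CO-
  expect_equal(composition(cside), "C1H4N1")  # -NHCH3
})

test_that("depth rule: first and second neighbours copied, third replaced", {
  st <- infer_connectivity(toy_gag())
  f <- fragment_structure(st)[[2]]
  caps <- f$atoms[f$atoms$role == "cap", ]
  # copied cap atoms keep their source coordinates exactly
  xyz_all <- atom_cart(st)
  for (i in seq_len(nrow(caps))) {
    expect_equal(unname(c(caps$x[i], caps$y[i], caps$z[i])),
                 unname(xyz_all[caps$source_label[i], ]), tolerance = 1e-12)
  }
  # every replaced third neighbour exists in the parent structure
  jn <- f$atoms[f$atoms$role == "junction", ]
  expect_true(all(jn$replaced_label %in% st$atoms$label))
})

test_that("fragment count equals residue count plus solvent and metal sites", {
  st <- make_toy_structure(toy_spec("GAG", n_waters = 2))
  frags <- fragment_structure(st)
  expect_length(frags, 5)
  m <- fragment_manifest(frags)
  expect_s3_class(m, "tbl_df")
  expect_setequal(m$residue_id, 1:5)
})

test_that("every atom is central in exactly one fragment", {
  st <- make_toy_structure(toy_spec("GSG", conformations = list(`2` = c(0.6, 0.4)),
                                    n_waters = 1))
  frags <- fragment_structure(st)
  central <- unlist(lapply(frags, function(f)
    f$atoms$source_label[f$atoms$role == "central"]))
  expect_equal(sort(central), sort(st$atoms$label))
  expect_false(anyDuplicated(central) > 0)
})

test_that("disordered residues yield one fragment per part", {
  st <- make_toy_structure(toy_spec("GSG", conformations = list(`2` = c(0.7, 0.3))))
  frags <- fragment_structure(st)
  m <- fragment_manifest(frags)
  expect_equal(sum(m$residue_id == 2), 2)
  expect_setequal(m$part[m$residue_id == 2], c(1L, 2L))
})

test_that("hydrogen-bond detection finds polar contacts and skips covalent ones", {
  st <- infer_connectivity(make_toy_structure(toy_spec("SAS")))
  hb <- detect_hydrogen_bonds(st)
  expect_true(nrow(hb) > 0)
  expect_true(all(hb$distance < hb$vdw_sum))
  # no acceptor within two bonds of the donor hydrogen
  adj <- bond_adjacency(st)
  for (i in seq_len(nrow(hb))) {
    one <- adj[[hb$donor_h[i]]]
    two <- unique(unlist(adj[one]))
    expect_false(hb$acceptor[i] %in% c(one, two))
  }
  # donor hydrogens are never carbon-bonded
  at <- st$atoms
  for (dh in unique(hb$donor_h)) {
    els <- at$element[match(adj[[dh]], at$label)]
    expect_false("C" %in% els)
  }
})

test_that("HB extension gives OCH2 for carbonyl and HOCH3 for serine", {
  st <- infer_connectivity(toy_gag())
  ext <- build_hb_extension(st, list(donor_h = "H_3", acceptor = "O_2"), "hb")
  expect_equal(composition(ext$atoms), "C1H2O1")  # OCH2
  expect_equal(ext$charge_delta, 0L)
  sts <- infer_connectivity(make_toy_structure(toy_spec("SAS")))
  ext2 <- build_hb_extension(sts, list(donor_h = "H_2", acceptor = "OG_1"), "hb")
  expect_equal(composition(ext2$atoms), "C1H4O1")  # HOCH3
})

test_that("mHB extension gives OH- for carbonyl and H2O for serine", {
  st <- infer_connectivity(toy_gag())
  ext <- build_hb_extension(st, list(donor_h = "H_3", acceptor = "O_2"), "mhb")
  expect_equal(composition(ext$atoms), "H1O1")
  expect_equal(ext$charge_delta, -1L)
  sts <- infer_connectivity(make_toy_structure(toy_spec("SAS")))
  ext2 <- build_hb_extension(sts, list(donor_h = "H_2", acceptor = "OG_1"), "mhb")
  expect_equal(composition(ext2$atoms), "H2O1")
  expect_equal(ext2$charge_delta, 0L)
})

test_that("metal-site fragment carries -SCH3 caps for each thiolate", {
  st <- toy_fe()
  frags <- fragment_structure(st)
  mf <- frags[[which(vapply(frags, function(f)
    any(f$atoms$element == "Fe" & f$atoms$role == "central"), logical(1)))]]
  expect_equal(sum(mf$atoms$role == "central"), 1)
  caps <- mf$atoms[mf$atoms$role != "central", ]
  expect_equal(composition(caps), "C4H12S4")  # 4 x -SCH3
  expect_equal(sum(mf$atoms$role == "junction"), 12)
})

test_that("metal fragment charge bookkeeping follows oxidation state", {
  expect_identical(metal_fragment_charge(3L, rep(-1L, 4)), -1L)
  expect_identical(metal_fragment_charge(2L, rep(-1L, 4)), -2L)
})

test_that("qS entries override defaults with part-specific precedence", {
  st <- make_toy_structure(toy_spec("GSG", conformations = list(`2` = c(0.6, 0.4))))
  qs <- tibble::tibble(residue_id = c(2L, 2L, 3L),
                       charge = c(1L, -1L, 0L),
                       multiplicity = c(1L, 2L, 3L),
                       part = c(NA_integer_, 2L, NA_integer_))
  frags <- fragment_structure(st, qs_entries = qs)
  m <- fragment_manifest(frags)
  expect_equal(m$charge[m$residue_id == 2 & m$part == 1], 1L)   # residue-level
  expect_equal(m$charge[m$residue_id == 2 & m$part == 2], -1L)  # part-specific
  expect_equal(m$multiplicity[m$residue_id == 3], 3L)
  expect_equal(m$charge[m$residue_id == 1], 0L)  # default q = 0
  expect_equal(m$multiplicity[m$residue_id == 1], 1L)  # default S = 1
})

test_that("fragment electron counts respect composition and charge", {
  st <- infer_connectivity(make_toy_structure(toy_spec("G")))
  f <- fragment_structure(st)[[1]]
  zsum <- sum(vapply(f$atoms$element, function(e)
    as.numeric(element_info(e)$n_electrons), numeric(1)))
  expect_equal(fragment_electron_count(f), zsum - f$qm_charge)
})
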