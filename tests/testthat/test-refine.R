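test_that("SHELX weights follow the published formula", {
  fo2 <- c(100, -5, 30)
  sig <- c(2, 1, 1.5)
  fc2 <- c(90, 1, 28)
  P <- (pmax(fo2, 0) + 2 * fc2) / 3
  expect_equal(shelx_weight(fo2, sig, fc2, a = 0.1, b = 0.2),
               1 / (sig^2 + (0.1 * P)^2 + 0.2 * P), tolerance = 1e-12)
  expect_error(shelx_weight(fo2, c(2, 0, 1), fc2), "sigma")
})

test_that("R1 and wR2 reproduce hand-computed values", {
  fo <- c(10, 5, 0, 8)   # zero/negative Fo excluded from R1
  fc <- c(9, 6, 1, 8)
  expect_equal(r1(fo, fc), (1 + 1 + 0) / (10 + 5 + 8))
  fo2 <- c(100, 25, 64); fc2 <- c(81, 36, 64); w <- c(1, 2, 0.5)
  expect_equal(wr2(fo2, fc2, w),
               sqrt(sum(w * (fo2 - fc2)^2) / sum(w * fo2^2)))
})

test_that("Hamilton test reproduces the published crambin worked example", {
  # R drops from 6.01 to 5.33 on adding 55 parameters (3753 -> 3808) with
  # 112293 data: ratio 1.128, overwhelmingly significant
  h <- hamilton_ratio(6.01, 5.33, 3753, 3808, 112293)
  expect_equal(round(h$ratio, 3), 1.128)
  expect_equal(h$b, 55)
  expect_true(h$significant)
  expect_lt(h$p_value, 1e-10)
  expect_gt(h$critical_ratio, 1)
})

test_that("Hamilton test handles degenerate nestings", {
  h <- hamilton_ratio(5.0, 5.0, 100, 100, 1000)
  expect_false(h$significant)
  expect_error(hamilton_ratio(5, 5, 10, 100, 50), "n_data")
})

test_that("parameter counting: scale + 3/atom + ADPs + shared groups", {
  st <- infer_connectivity(toy_gag())
  n_atoms <- nrow(st$atoms)
  expect_equal(count_parameters(st), 1L + 3L * n_atoms + n_atoms)
  st$atoms$u_aniso[[1]] <- c(0.02, 0.02, 0.02, 0, 0, 0)
  expect_equal(count_parameters(st), 1L + 3L * n_atoms + (n_atoms - 1L) + 6L)
})

test_that("converting a fixed X-H group to shared adds exactly one parameter", {
  st <- infer_connectivity(toy_gag())
  adj <- bond_adjacency(st)
  hs <- st$atoms$label[st$atoms$element == "H"][1:3]
  parents <- vapply(hs, function(h) adj[[h]][1], character(1))
  fixed <- lapply(seq_along(hs), function(i) fixed_xh(hs[i], parents[i], 1.0))
  shared <- list(shared_xh(hs, parents, 1.0))
  expect_equal(count_parameters(st, shared) - count_parameters(st, fixed), 1L)
})

test_that("a hydrogen cannot be governed by two positional constraints", {
  st <- infer_connectivity(toy_gag())
  adj <- bond_adjacency(st)
  h <- st$atoms$label[st$atoms$element == "H"][1]
  p <- adj[[h]][1]
  expect_error(count_parameters(st, list(fixed_xh(h, p, 1), fixed_xh(h, p, 1.1))),
               "more than one")
})

test_that("scale-only refinement recovers a known scale", {
  st <- toy_ga_compact()
  refl <- simulate_reflections(st, d_min = 1.2, noise_frac = 0, seed = 1,
                               scale = 2.5)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  fit <- refine_structure(st, refl, ff, refine_xyz = FALSE,
                          refine_adp = FALSE, max_cycles = 6)
  expect_equal(fit$scale, 2.5, tolerance = 1e-6)
  expect_lt(fit$wr2, 1e-8)
  expect_equal(fit$n_params, 1L)
})

test_that("noise-free refinement recovers perturbed coordinates", {
  st <- toy_ga_compact()
  refl <- simulate_reflections(st, d_min = 1.0, noise_frac = 0, seed = 1)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  stp <- st
  set.seed(11)
  cart <- atom_cart(st) + matrix(rnorm(3 * nrow(st$atoms), 0, 0.01), ncol = 3)
  frac <- cart_to_frac(st$cell, cart)
  stp$atoms$x <- frac[, 1]; stp$atoms$y <- frac[, 2]; stp$atoms$z <- frac[, 3]
  fit <- refine_structure(stp, refl, ff, max_cycles = 10, refine_adp = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$wr2, 1e-6)
  expect_lt(rmsd_translation_free(fit$structure, st), 1e-6)
})

test_that("accepted Levenberg-Marquardt steps never increase wR2", {
  st <- toy_ga_compact()
  refl <- simulate_reflections(st, d_min = 1.2, noise_frac = 0.05, seed = 9)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  stp <- st
  set.seed(12)
  cart <- atom_cart(st) + matrix(rnorm(3 * nrow(st$atoms), 0, 0.05), ncol = 3)
  frac <- cart_to_frac(st$cell, cart)
  stp$atoms$x <- frac[, 1]; stp$atoms$y <- frac[, 2]; stp$atoms$z <- frac[, 3]
  fit <- refine_structure(stp, refl, ff, max_cycles = 6, refine_adp = FALSE)
  expect_true(all(diff(fit$trace) <= 1e-8))
})

test_that("fixed X-H constraints hold the distance through refinement", {
  st <- infer_connectivity(toy_ga_compact())
  adj <- bond_adjacency(st)
  h <- st$atoms$label[st$atoms$element == "H"][1]
  p <- adj[[h]][1]
  refl <- simulate_reflections(st, d_min = 1.2, noise_frac = 0.02, seed = 3)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  fit <- refine_structure(st, refl, ff, constraints = list(fixed_xh(h, p, 1.05)),
                          max_cycles = 4, refine_adp = FALSE)
  xyz <- atom_cart(fit$structure)
  expect_equal(sqrt(sum((xyz[h, ] - xyz[p, ])^2)), 1.05, tolerance = 1e-10)
  # positions only (ADPs off): scale + 3 per unconstrained atom
  expect_equal(fit$n_params, 1L + 3L * (nrow(st$atoms) - 1L))
})

test_that("shared X-H groups refine one common distance", {
  st <- infer_connectivity(toy_ga_compact())
  adj <- bond_adjacency(st)
  hs <- st$atoms$label[st$atoms$element == "H"][1:2]
  ps <- vapply(hs, function(h) adj[[h]][1], character(1))
  refl <- simulate_reflections(st, d_min = 1.2, noise_frac = 0, seed = 3)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  fit <- refine_structure(st, refl, ff,
                          constraints = list(shared_xh(hs, ps, 1.0)),
                          max_cycles = 6, refine_adp = FALSE)
  xyz <- atom_cart(fit$structure)
  d1 <- sqrt(sum((xyz[hs[1], ] - xyz[ps[1], ])^2))
  d2 <- sqrt(sum((xyz[hs[2], ] - xyz[ps[2], ])^2))
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("riding ADPs tie hydrogen U to the parent equivalent U", {
  st <- infer_connectivity(toy_ga_compact())
  adj <- bond_adjacency(st)
  h <- st$atoms$label[st$atoms$element == "H"][1]
  p <- adj[[h]][1]
  refl <- simulate_reflections(st, d_min = 1.3, noise_frac = 0, seed = 4)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  fit <- refine_structure(st, refl, ff,
                          constraints = list(riding_adp(h, p, 1.2)),
                          max_cycles = 3, refine_xyz = FALSE)
  at <- fit$structure$atoms
  ue <- u_equiv(fit$structure)
  expect_equal(at$u_iso[at$label == h], 1.2 * ue[match(p, at$label)],
               tolerance = 1e-10)
})

test_that("distance restraints pull a bond toward the target", {
  st <- infer_connectivity(toy_ga_compact())
  b <- st$bonds[1, ]
  xyz <- atom_cart(st)
  d0 <- sqrt(sum((xyz[b$i, ] - xyz[b$j, ])^2))
  refl <- simulate_reflections(st, d_min = 1.5, noise_frac = 0.1, seed = 5)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  target <- d0 + 0.05
  fit <- refine_structure(st, refl, ff,
                          restraints = list(distance_restraint(b$i, b$j, target,
                                                               sigma = 1e-4)),
                          max_cycles = 6, refine_adp = FALSE)
  xyz2 <- atom_cart(fit$structure)
  d1 <- sqrt(sum((xyz2[b$i, ] - xyz2[b$j, ])^2))
  expect_lt(abs(d1 - target), abs(d0 - target))
})

test_that("tidy and glance return well-formed summaries", {
  st <- toy_ga_compact()
  refl <- simulate_reflections(st, d_min = 1.5, noise_frac = 0, seed = 1)
  ff <- assemble_tsc_iam(st, cbind(refl$h, refl$k, refl$l))
  fit <- refine_structure(st, refl, ff, refine_xyz = FALSE, refine_adp = FALSE,
                          max_cycles = 3)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), fit$n_params)
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("r1", "wr2", "n_params", "converged") %in% names(gl)))
})
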