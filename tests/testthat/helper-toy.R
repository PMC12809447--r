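# Shared lazy fixture cache: building toy structures is cheap, but several
# test files reuse the same ones, so memoize within a test run.
.toy_cache <- new.env(parent = emptyenv())

toy <- function(key, builder) {
  if (is.null(.toy_cache[[key]])) .toy_cache[[key]] <- builder()
  .toy_cache[[key]]
}

toy_gag <- function() toy("gag", function() make_toy_structure(toy_spec("GAG")))

toy_ga_compact <- function() toy("ga_compact", function()
  make_toy_structure(toy_spec("GA", cell = c(9, 10, 11, 90, 90, 90))))

toy_fe <- function() toy("fe", function()
  make_toy_structure(toy_spec("", fe_site = TRUE)))

# RMSD between two structures after removing the mean translation (the
# origin is free in P1: a uniform shift leaves every |F| unchanged).
rmsd_translation_free <- function(a, b) {
  d <- atom_cart(a) - atom_cart(b)
  d <- sweep(d, 2, colMeans(d))
  sqrt(mean(rowSums(d^2)))
}

# Composition string of a set of fragment atoms, e.g. "C2H3O1" -> counts by
# element, alphabetical. Used for golden capping-composition checks.
composition <- function(atoms) {
  tab <- table(atoms$element)
  paste0(names(tab), as.integer(tab), collapse = "")
}
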