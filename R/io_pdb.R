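# PDB reading/writing. Atom records go through bio3d; the CRYST1 cell is
# taken from the header. B factors convert to U via B = 8 pi^2 U, and
# altLoc letters map to consecutive PART numbers.

read_structure_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0) stop("no CRYST1 record in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(c(
    substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
    substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
  if (anyNA(vals)) stop("malformed CRYST1 record: '", cr[1], "'", call. = FALSE)
  cell <- unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6])

  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  alt <- ifelse(is.na(a$alt) | a$alt == "", "", a$alt)
  alts <- sort(unique(alt[alt != ""]))
  part <- ifelse(alt == "", 0L, match(alt, alts))
  elem <- ifelse(is.na(a$elesy) | a$elesy == "",
                 substr(trimws(a$elety), 1, 1), trimws(a$elesy))
  frac <- cart_to_frac(cell, cbind(a$x, a$y, a$z))
  label <- paste0(trimws(a$elety), "_", a$resno,
                  ifelse(alt == "", "", paste0("_", alt)))
  if (anyDuplicated(label)) {
    d <- label[duplicated(label)][1]
    stop("duplicate atom label '", d, "' at PDB atom serials ",
         paste(a$eleno[label == d], collapse = " and "), call. = FALSE)
  }
  occ <- ifelse(is.na(a$o), 1, a$o)
  u_iso <- ifelse(is.na(a$b), 0, a$b) / (8 * pi^2)
  atoms <- tibble::tibble(
    label = label, element = elem,
    x = frac[, 1], y = frac[, 2], z = frac[, 3],
    occ = occ, part = as.integer(part), u_iso = u_iso,
    u_aniso = vector("list", length(label)),
    residue_id = as.integer(a$resno), residue_name = a$resid
  )
  st <- crystal_structure(cell, atoms)
  st <- flag_solvent(st)
  default_hydrogen_adp(st)
}

#' Write a structure as a PDB file
#'
#' @param structure A `crystal_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure_pdb <- function(structure, path) {
  cell <- structure$cell
  at <- structure$atoms
  xyz <- atom_cart(structure)
  alts <- sort(unique(at$part[at$part > 0]))
  alt_letters <- stats::setNames(LETTERS[seq_along(alts)], alts)
  lines <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  for (k in seq_len(nrow(at))) {
    name <- sub("_.*$", "", at$label[k])
    altc <- if (at$part[k] > 0) alt_letters[[as.character(at$part[k])]] else " "
    lines <- c(lines, sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      "ATOM", k, substr(name, 1, 4), altc,
      substr(at$residue_name[k], 1, 3), "A", at$residue_id[k],
      xyz[k, 1], xyz[k, 2], xyz[k, 3], at$occ[k],
      8 * pi^2 * ifelse(is.na(at$u_iso[k]), 0, at$u_iso[k]),
      at$element[k]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
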