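# Minimal SHELX-style .ins/.res reader and writer.  Parsed instructions:
# TITL, CELL, ZERR, LATT, SYMM, SFAC, RESI, PART, AFIX, atom records, END.
# Everything else is preserved verbatim as opaque lines for round-tripping.

.ins_commands <- c("TITL", "CELL", "ZERR", "LATT", "SYMM", "SFAC", "UNIT",
                   "RESI", "PART", "AFIX", "HKLF", "END", "FVAR", "WGHT",
                   "L.S.", "PLAN", "FMAP", "ACTA", "BOND", "CONF", "LIST",
                   "MORE", "TEMP", "SIZE", "REM")

#' Read a structure model
#'
#' Reads a PDB file or a minimal SHELX-style .ins/.res file into a
#' [crystal_structure()]. For .ins files, atoms following a `RESI` line are
#' assigned that residue id until the next `RESI`; `PART` switches the
#' disorder group. For PDB files, altLoc letters map to consecutive PART
#' numbers and water molecules become single-molecule solvent residues.
#'
#' @param path File path.
#' @param format Either `"auto"` (by extension), `"pdb"` or `"ins"`.
#' @return A `crystal_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "ins")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "ins"
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_ins(path)
}

read_structure_ins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  # join '=' continuation lines
  lines <- character(); buf <- ""
  for (ln in raw) {
    s <- sub("\\s*=\\s*$", "", ln)
    if (grepl("=\\s*$", ln)) { buf <- paste(buf, s); next }
    lines <- c(lines, trimws(paste(buf, s))); buf <- ""
  }
  if (nzchar(buf)) lines <- c(lines, trimws(buf))

  cell <- NULL; latt <- -1L; symm_lines <- character(); sfac <- character()
  extra <- character()
  cur_resi <- 0L; cur_resn <- "UNK"; cur_part <- 0L
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- lines[li]
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "\\s+")[[1]]
    cmd <- toupper(toks[1])
    if (cmd == "CELL") {
      vals <- suppressWarnings(as.numeric(toks[-1]))
      if (length(vals) < 7 || anyNA(vals)) {
        stop("malformed CELL instruction at line ", li, ": '", ln, "'",
             call. = FALSE)
      }
      cell <- unit_cell(vals[2], vals[3], vals[4], vals[5], vals[6], vals[7])
    } else if (cmd == "LATT") {
      latt <- as.integer(toks[2])
      if (abs(latt) != 1L) {
        stop("only primitive lattices (LATT +/-1) are supported", call. = FALSE)
      }
    } else if (cmd == "SYMM") {
      symm_lines <- c(symm_lines, sub("^\\s*SYMM\\s+", "", ln, ignore.case = TRUE))
    } else if (cmd == "SFAC") {
      sfac <- toks[-1]
    } else if (cmd == "RESI") {
      cur_resi <- as.integer(toks[2])
      cur_resn <- if (length(toks) >= 3) toks[3] else "UNK"
      cur_part <- 0L
    } else if (cmd == "PART") {
      cur_part <- as.integer(toks[2])
    } else if (cmd == "END") {
      break
    } else if (cmd %in% .ins_commands) {
      extra <- c(extra, ln)
    } else if (length(toks) >= 6 &&
               !is.na(suppressWarnings(as.integer(toks[2]))) &&
               !anyNA(suppressWarnings(as.numeric(toks[3:6])))) {
      # atom record: label sfac# x y z sof [U | U11..U12]
      sfi <- as.integer(toks[2])
      if (sfi < 1 || sfi > length(sfac)) {
        stop("atom '", toks[1], "' references SFAC index ", sfi,
             " but only ", length(sfac), " scatterer types are declared",
             call. = FALSE)
      }
      vals <- as.numeric(toks[3:length(toks)])
      sof <- vals[4]
      occ <- if (sof >= 10) sof - 10 else sof
      u_iso <- NA_real_; u_aniso <- NULL
      if (length(vals) >= 10) {
        u_aniso <- vals[5:10]
        u_iso <- NA_real_
      } else if (length(vals) >= 5) {
        u_iso <- vals[5]
      }
      rows[[length(rows) + 1]] <- list(
        label = toks[1], element = sfac[sfi], x = vals[1], y = vals[2],
        z = vals[3], occ = occ, part = cur_part, u_iso = u_iso,
        u_aniso = u_aniso, residue_id = cur_resi, residue_name = cur_resn)
    } else {
      extra <- c(extra, ln)
    }
  }
  if (is.null(cell)) stop("no CELL instruction found in ", path, call. = FALSE)
  if (length(rows) == 0) stop("no atom records found in ", path, call. = FALSE)
  labs <- vapply(rows, `[[`, character(1), "label")
  if (anyDuplicated(labs)) {
    d <- labs[duplicated(labs)][1]
    stop("duplicate atom label '", d, "' at atom records ",
         paste(which(labs == d), collapse = " and "), call. = FALSE)
  }
  atoms <- tibble::tibble(
    label = labs,
    element = vapply(rows, `[[`, character(1), "element"),
    x = vapply(rows, `[[`, numeric(1), "x"),
    y = vapply(rows, `[[`, numeric(1), "y"),
    z = vapply(rows, `[[`, numeric(1), "z"),
    occ = vapply(rows, `[[`, numeric(1), "occ"),
    part = vapply(rows, function(r) as.integer(r$part), integer(1)),
    u_iso = vapply(rows, `[[`, numeric(1), "u_iso"),
    u_aniso = lapply(rows, `[[`, "u_aniso"),
    residue_id = vapply(rows, function(r) as.integer(r$residue_id), integer(1)),
    residue_name = vapply(rows, `[[`, character(1), "residue_name")
  )
  symops <- build_symops(latt, symm_lines)
  st <- crystal_structure(cell, atoms, symops = symops, extra = extra)
  st <- flag_solvent(st)
  default_hydrogen_adp(st)
}

# LATT sign convention: negative = non-centrosymmetric; positive adds the
# inversion centre at the origin.
build_symops <- function(latt, symm_lines) {
  ops <- list(list(R = diag(3), t = c(0, 0, 0)))
  for (s in symm_lines) ops <- c(ops, list(parse_symop(s)))
  if (latt > 0) {
    ops <- c(ops, lapply(ops, function(op) list(R = -op$R, t = -op$t)))
  }
  ops
}

#' Parse a symmetry operator string
#'
#' Accepts SHELX/CIF-style triplets such as `"-X, Y+1/2, -Z"`.
#'
#' @param text Operator string with three comma-separated components.
#' @return `list(R = 3x3 matrix, t = length-3 numeric)`.
#' @export
parse_symop <- function(text) {
  parts <- strsplit(text, ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator needs 3 components: ", text,
                               call. = FALSE)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (k in 1:3) {
    expr <- gsub("\\s", "", toupper(parts[k]))
    # tokenize signed terms
    expr2 <- gsub("([+-])", " \\1", expr)
    terms <- strsplit(trimws(expr2), "\\s+")[[1]]
    for (term in terms) {
      if (!nzchar(term)) next
      sign <- 1
      if (startsWith(term, "-")) { sign <- -1; term <- substring(term, 2) }
      if (startsWith(term, "+")) term <- substring(term, 2)
      if (grepl("[XYZ]", term)) {
        ax <- match(regmatches(term, regexpr("[XYZ]", term)), c("X", "Y", "Z"))
        coef <- gsub("\\*?[XYZ]\\*?", "", term)
        cf <- if (nzchar(coef)) parse_fraction(coef) else 1
        R[k, ax] <- R[k, ax] + sign * cf
      } else {
        t[k] <- t[k] + sign * parse_fraction(term)
      }
    }
  }
  list(R = R, t = t)
}

parse_fraction <- function(s) {
  if (grepl("/", s)) {
    ab <- as.numeric(strsplit(s, "/")[[1]])
    ab[1] / ab[2]
  } else as.numeric(s)
}

format_symop <- function(op) {
  axes <- c("X", "Y", "Z")
  comps <- vapply(1:3, function(k) {
    out <- ""
    for (ax in 1:3) {
      c_ <- op$R[k, ax]
      if (c_ == 0) next
      sgn <- if (c_ < 0) "-" else if (nzchar(out)) "+" else ""
      mag <- abs(c_)
      out <- paste0(out, sgn, if (mag != 1) paste0(mag, "*") else "", axes[ax])
    }
    tv <- op$t[k]
    if (abs(tv) > 1e-12) {
      fr <- format_fraction(tv)
      out <- paste0(out, if (tv > 0) "+" else "-", fr)
    }
    out
  }, character(1))
  paste(comps, collapse = ", ")
}

format_fraction <- function(x) {
  x <- abs(x)
  for (den in c(2, 3, 4, 6)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(paste0(round(num), "/", den))
  }
  format(x)
}

#' Write a structure model as a minimal .ins file
#'
#' Inverse of the .ins reader on the supported instruction subset; opaque
#' lines captured at read time are re-emitted before the atom list.
#'
#' @param structure A `crystal_structure`.
#' @param path Output path.
#' @param wavelength Wavelength written on the CELL line (Angstrom).
#' @return Invisibly, `path`.
#' @export
write_structure_ins <- function(structure, path, wavelength = 0.71073) {
  cell <- structure$cell
  at <- structure$atoms
  sfac <- unique(at$element)
  ops <- structure$symops
  # detect inversion pairing to recover the LATT sign
  has_inv <- any(vapply(ops, function(op)
    all(abs(op$R + diag(3)) < 1e-9) && all(abs(op$t) < 1e-9), logical(1)))
  latt <- if (has_inv) 1L else -1L
  base_ops <- Filter(function(op) !(all(abs(op$R - diag(3)) < 1e-9) &&
                                      all(abs(op$t) < 1e-9)), ops)
  if (has_inv) {
    base_ops <- Filter(function(op) det(op$R) > 0, base_ops)
  }
  out <- c(
    "TITL fraghar model",
    sprintf("CELL %.5f %.6f %.6f %.6f %.4f %.4f %.4f", wavelength,
            cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
    sprintf("LATT %d", latt),
    vapply(base_ops, function(op) paste("SYMM", format_symop(op)), character(1)),
    paste("SFAC", paste(sfac, collapse = " ")),
    structure$extra
  )
  cur_resi <- NA_integer_; cur_part <- 0L
  for (k in seq_len(nrow(at))) {
    if (is.na(cur_resi) || at$residue_id[k] != cur_resi) {
      cur_resi <- at$residue_id[k]
      out <- c(out, sprintf("RESI %d %s", cur_resi, at$residue_name[k]))
      cur_part <- 0L
    }
    if (at$part[k] != cur_part) {
      cur_part <- at$part[k]
      out <- c(out, sprintf("PART %d", cur_part))
    }
    sfi <- match(at$element[k], sfac)
    ua <- at$u_aniso[[k]]
    if (is.null(ua)) {
      out <- c(out, sprintf("%-8s %d %11.8f %11.8f %11.8f %10.6f %10.6f",
                            at$label[k], sfi, at$x[k], at$y[k], at$z[k],
                            10 + at$occ[k], at$u_iso[k]))
    } else {
      out <- c(out, sprintf(
        "%-8s %d %11.8f %11.8f %11.8f %10.6f %10.6f %10.6f =",
        at$label[k], sfi, at$x[k], at$y[k], at$z[k], 10 + at$occ[k],
        ua[1], ua[2]),
        sprintf("   %10.6f %10.6f %10.6f %10.6f", ua[3], ua[4], ua[5], ua[6]))
    }
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Flag solvent residues
#'
#' Marks residues with conventional water names (HOH, WAT, DOD, H2O) in a
#' logical `solvent` column of the structure's residue table.
#'
#' @param structure A `crystal_structure`.
#' @return The structure with `residues$solvent` set.
#' @export
flag_solvent <- function(structure) {
  solvent_names <- c("HOH", "WAT", "DOD", "H2O")
  structure$residues$solvent <-
    structure$residues$residue_name %in% solvent_names
  structure
}

#' Default hydrogen displacement parameters
#'
#' Riding-convention default for hydrogens read with zero or absent ADPs:
#' U_iso(H) = 1.2 x U_eq of the bonded parent atom (0.06 A^2 when the
#' hydrogen has no bonded neighbour).
#'
#' @param structure A `crystal_structure`.
#' @return The structure with hydrogen `u_iso` values filled in.
#' @export
default_hydrogen_adp <- function(structure) {
  at <- structure$atoms
  need <- at$element == "H" &
    (is.na(at$u_iso) | at$u_iso <= 0) &
    vapply(at$u_aniso, is.null, logical(1))
  if (!any(need)) return(structure)
  st <- infer_connectivity(structure)
  adj <- bond_adjacency(st)
  ueq <- u_equiv(st)
  names(ueq) <- at$label
  for (k in which(need)) {
    nb <- adj[[at$label[k]]]
    parent_u <- if (length(nb) > 0) max(ueq[nb], na.rm = TRUE) else 0.05
    if (!is.finite(parent_u) || parent_u <= 0) parent_u <- 0.05
    at$u_iso[k] <- 1.2 * parent_u
  }
  structure$atoms <- at
  structure
}
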