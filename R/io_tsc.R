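# Tabulated scattering-factor (.tsc) exchange files: per-atom complex
# aspherical form factors indexed by Miller index.

#' Construct a form-factor table
#'
#' @param labels Character vector of scatterer labels (unique).
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @param values Complex matrix (n reflections x length(labels)).
#' @return Object of class `form_factor_table`.
#' @export
form_factor_table <- function(labels, hkl, values) {
  hkl <- to_coord_matrix(hkl)
  values <- as.matrix(values)
  if (anyDuplicated(labels)) stop("scatterer labels must be unique", call. = FALSE)
  if (nrow(values) != nrow(hkl) || ncol(values) != length(labels)) {
    stop("form-factor table is not rectangular: ", nrow(hkl), " hkl x ",
         length(labels), " scatterers vs values ", nrow(values), " x ",
         ncol(values), call. = FALSE)
  }
  storage.mode(hkl) <- "integer"
  colnames(values) <- labels
  structure(list(labels = labels, hkl = hkl, values = values),
            class = "form_factor_table")
}

#' @export
print.form_factor_table <- function(x, ...) {
  cat(sprintf("<form_factor_table> %d reflections x %d scatterers\n",
              nrow(x$hkl), length(x$labels)))
  invisible(x)
}

#' Write a .tsc form-factor file
#'
#' Plain-text exchange format: header lines `TITLE:`, `SYMM:`,
#' `SCATTERERS:` (space-separated labels), then a `DATA:` block with one
#' line per reflection: `h k l re,im re,im ...`.
#'
#' @param table A `form_factor_table`.
#' @param path Output path.
#' @param title Title string for the header.
#' @return Invisibly, `path`.
#' @export
write_tsc <- function(table, path, title = "fraghar scattering factors") {
  stopifnot(inherits(table, "form_factor_table"))
  vals <- table$values
  rows <- vapply(seq_len(nrow(table$hkl)), function(i) {
    entries <- sprintf("%.10g,%.10g", Re(vals[i, ]), Im(vals[i, ]))
    paste(c(sprintf("%d %d %d", table$hkl[i, 1], table$hkl[i, 2],
                    table$hkl[i, 3]), entries), collapse = " ")
  }, character(1))
  writeLines(c(
    paste("TITLE:", title),
    "SYMM: expanded",
    paste("SCATTERERS:", paste(table$labels, collapse = " ")),
    "DATA:",
    rows), path)
  invisible(path)
}

#' Read a .tsc form-factor file
#'
#' Exact inverse of [write_tsc()].
#'
#' @param path File path.
#' @return A `form_factor_table`.
#' @export
read_tsc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sc_line <- grep("^SCATTERERS:", lines, value = TRUE)
  if (length(sc_line) == 0) {
    stop(".tsc header is missing the SCATTERERS: line", call. = FALSE)
  }
  labels <- strsplit(trimws(sub("^SCATTERERS:", "", sc_line[1])), "\\s+")[[1]]
  data_at <- grep("^DATA:", lines)
  if (length(data_at) == 0) stop(".tsc file has no DATA: block", call. = FALSE)
  body <- lines[(data_at[1] + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  hkl <- matrix(0L, n, 3)
  values <- matrix(complex(1), n, length(labels))
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(toks) != 3 + length(labels)) {
      stop(".tsc row arity mismatch at hkl '",
           paste(toks[seq_len(min(3, length(toks)))], collapse = " "),
           "': expected ", 3 + length(labels), " fields, got ", length(toks),
           call. = FALSE)
    }
    hkl[i, ] <- as.integer(toks[1:3])
    for (j in seq_along(labels)) {
      ri <- as.numeric(strsplit(toks[3 + j], ",")[[1]])
      values[i, j] <- complex(real = ri[1], imaginary = ri[2])
    }
  }
  form_factor_table(labels, hkl, values)
}
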