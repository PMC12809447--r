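# HKLF4-style reflection files and per-residue charge/multiplicity (.qS)
# tables.

#' Read an HKLF4-style reflection file
#'
#' Fixed-width SHELX HKLF4 lines `h k l Fo2 sigma` (3I4, 2F8.2); a row of
#' `0 0 0` terminates the list. Negative Fo2 values are preserved (the
#' weighting scheme clamps them later, not the reader).
#'
#' @param path File path.
#' @return A tibble with columns `h`, `k`, `l` (integer), `fo2`, `sigma`.
#' @export
read_hkl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- lines[li]
    if (!nzchar(trimws(ln))) next
    # fixed-width (3I4, 2F8.2) lines are cut by column; anything shorter
    # (hand-written test data) falls back to whitespace tokens
    if (nchar(ln) >= 20) {
      cuts <- c(1, 5, 9, 13, 21, 29)
      toks <- trimws(substring(ln, cuts[-6], pmin(cuts[-1] - 1, nchar(ln))))
      toks <- toks[nzchar(toks)]
    } else {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
    }
    if (length(toks) < 3) {
      stop("malformed reflection line ", li, ": '", ln, "'", call. = FALSE)
    }
    hkl <- suppressWarnings(as.numeric(toks[1:3]))
    if (anyNA(hkl) || any(hkl != round(hkl))) {
      stop("non-integer Miller indices at line ", li, ": '", ln, "'",
           call. = FALSE)
    }
    if (all(hkl == 0)) break
    fo2 <- suppressWarnings(as.numeric(toks[4]))
    sig <- suppressWarnings(as.numeric(toks[5]))
    if (is.na(fo2) || is.na(sig)) {
      stop("malformed intensity fields at line ", li, ": '", ln, "'",
           call. = FALSE)
    }
    if (sig <= 0) {
      stop("non-positive sigma at line ", li, ": '", ln, "'", call. = FALSE)
    }
    rows[[length(rows) + 1]] <- c(hkl, fo2, sig)
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) {
    return(tibble::tibble(h = integer(), k = integer(), l = integer(),
                          fo2 = numeric(), sigma = numeric()))
  }
  tibble::tibble(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                 l = as.integer(m[, 3]), fo2 = m[, 4], sigma = m[, 5])
}

#' Write an HKLF4-style reflection file
#'
#' @param reflections Tibble with `h`, `k`, `l`, `fo2`, `sigma`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hkl <- function(reflections, path) {
  r <- reflections
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", r$h, r$k, r$l, r$fo2, r$sigma)
  lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a per-residue charge/multiplicity (.qS) file
#'
#' Each line holds `residue_number charge multiplicity` separated by white
#' space, with an optional fourth column restricting the entry to one
#' disorder conformation (PART number). Line order is arbitrary. A missing
#' file yields an empty table, meaning every fragment keeps the defaults
#' q = 0, S = 1.
#'
#' @param path File path (may not exist).
#' @return A tibble with columns `residue_id`, `charge`, `multiplicity`,
#'   `part` (NA when the entry applies to every conformation).
#' @export
parse_qs <- function(path) {
  empty <- tibble::tibble(residue_id = integer(), charge = integer(),
                          multiplicity = integer(), part = integer())
  if (is.null(path) || !file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) < 3 || length(toks) > 4) {
      stop("qS format error at line ", li, ": expected 3 or 4 columns, got ",
           length(toks), call. = FALSE)
    }
    v <- suppressWarnings(as.integer(toks))
    if (anyNA(v)) {
      stop("qS format error at line ", li, ": non-integer token in '", ln, "'",
           call. = FALSE)
    }
    if (v[3] < 1) stop("qS line ", li, ": multiplicity must be >= 1",
                       call. = FALSE)
    rows[[length(rows) + 1]] <- list(
      residue_id = v[1], charge = v[2], multiplicity = v[3],
      part = if (length(v) == 4) v[4] else NA_integer_)
  }
  if (length(rows) == 0) return(empty)
  qs <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  key <- paste(qs$residue_id, qs$part)
  if (anyDuplicated(key)) {
    d <- qs[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop("duplicate qS entries for residue ", d$residue_id[1],
         if (!is.na(d$part[1])) paste0(" part ", d$part[1]) else "",
         call. = FALSE)
  }
  qs
}
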