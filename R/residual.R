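# Residual-density analytics: Fo-Fc difference maps, the gross residual
# electron count (e_gross), and fractal-dimension curves of the residual
# density (Meindl-Henn descriptors).

#' Construct a density map
#'
#' @param values Numeric array (nx x ny x nz) of densities in e A^-3,
#'   sampled over one unit cell.
#' @param cell The `unit_cell` the map covers.
#' @param d_min Optional resolution of the data behind the map (recorded in
#'   reports; residual metrics are resolution dependent).
#' @return A `density_map`.
#' @export
density_map <- function(values, cell, d_min = NA_real_) {
  dims <- dim(values)
  if (length(dims) != 3 || any(dims < 2)) {
    stop("density map needs a 3-d array with every dimension >= 2",
         call. = FALSE)
  }
  structure(list(values = values, dims = dims, cell = cell,
                 voxel_volume = cell$volume / prod(dims), d_min = d_min),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d x %d, voxel %.4f A^3, range [%.4g, %.4g] e/A^3\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_volume,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Fo - Fc difference map
#'
#' Fourier synthesis of the residual density using calculated phases:
#' drho(r) = (1/V) sum_h (|Fo| - |Fc|) exp(i phi_c) exp(-2 pi i h.r),
#' Friedel-completed so the map is real. |Fo| = sqrt(max(Fo^2, 0)) after
#' scaling the observations onto the calculated scale.
#'
#' @param reflections Tibble with `h,k,l,fo2` (observed, intensity scale).
#' @param fc Complex calculated structure factors, one per reflection
#'   (unscaled; the map applies `scale` to Fo^2).
#' @param cell A `unit_cell`.
#' @param grid_dims Length-3 integer grid dimensions.
#' @param scale Intensity scale s with Fo^2 ~ s |Fc|^2 (default 1).
#' @param d_min Optional resolution to record on the map.
#' @return A `density_map` of the residual density.
#' @export
difference_map <- function(reflections, fc, cell, grid_dims = c(32, 32, 32),
                           scale = 1, d_min = NA_real_) {
  if (length(fc) != nrow(reflections)) {
    stop("need one calculated structure factor per reflection", call. = FALSE)
  }
  hkl <- cbind(reflections$h, reflections$k, reflections$l)
  fo <- sqrt(pmax(reflections$fo2 / scale, 0))
  dF <- (fo - Mod(fc)) * exp(1i * Arg(fc))
  dims <- as.integer(grid_dims)
  fx <- (seq_len(dims[1]) - 1) / dims[1]
  fy <- (seq_len(dims[2]) - 1) / dims[2]
  fz <- (seq_len(dims[3]) - 1) / dims[3]
  # separable phase factors: exp(-2 pi i h x) etc., Friedel completion by
  # taking 2 Re(...) for the stored half-set (plus any explicit mates)
  vals <- array(0, dims)
  Ex <- exp(-2i * pi * outer(reflections$h, fx))   # n_hkl x nx
  Ey <- exp(-2i * pi * outer(reflections$k, fy))
  Ez <- exp(-2i * pi * outer(reflections$l, fz))
  # detect explicitly stored Friedel mates to avoid double counting
  keys <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  neg <- paste(-hkl[, 1], -hkl[, 2], -hkl[, 3])
  has_mate <- neg %in% keys
  mult <- ifelse(has_mate, 1, 2)
  mult[hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0] <- 1
  for (iz in seq_len(dims[3])) {
    W <- dF * mult * Ez[, iz]
    slab <- crossprod(Ex, W * Ey)  # nx x ny (crossprod does not conjugate)
    vals[, , iz] <- Re(slab)
  }
  vals <- vals / cell$volume
  # the mult=2 completion already folds in conj terms because the real part
  # of a Hermitian pair doubles; with mult=1 mates both terms are present
  density_map(vals, cell, d_min = d_min)
}

#' Gross residual electrons
#'
#' e_gross = 1/2 sum over voxels of |drho| x V_voxel: the number of
#' electrons that would have to relocate to reach perfect agreement with
#' the data. `egross_per_atom()` normalizes by the number of atoms in the
#' model (each disorder-part atom counted once) to compare across systems.
#'
#' @param map A `density_map` over exactly one unit cell.
#' @param n_atoms Number of atoms in the model (> 0).
#' @return Electrons (per atom for the normalized variant).
#' @export
egross <- function(map) {
  0.5 * sum(abs(map$values)) * map$voxel_volume
}

#' @rdname egross
#' @export
egross_per_atom <- function(map, n_atoms) {
  if (n_atoms <= 0) stop("n_atoms must be positive", call. = FALSE)
  egross(map) / n_atoms
}

#' Fractal-dimension curve of a residual map
#'
#' Histograms the voxel values into `n_bins` equal-width bins spanning the
#' map's range and reports d_f(rho0) = ln N(rho0) / ln(N_total^(1/3)) for
#' each non-empty bin. An ideal featureless residual map gives a narrow
#' parabola-like curve centred at rho0 = 0 peaking close to 3.
#'
#' @param map A `density_map`.
#' @param n_bins Number of bins (>= 3).
#' @return Tibble with `rho0` (bin centre, e A^-3), `count`, `df`.
#' @export
fractal_curve <- function(map, n_bins = 100) {
  stopifnot(n_bins >= 3)
  v <- as.numeric(map$values)
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant map: degenerate single-bin fractal curve")
    return(tibble::tibble(rho0 = rng[1], count = length(v), df = 3))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, nbins = n_bins)
  centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  keep <- counts > 0
  tibble::tibble(
    rho0 = centres[keep], count = counts[keep],
    df = log(counts[keep]) / log(length(v)^(1 / 3)))
}

#' Write a density map as a cube-style text grid
#'
#' @param map A `density_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map_grid <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("fraghar density map",
               sprintf("%d %d %d %.8f", map$dims[1], map$dims[2], map$dims[3],
                       map$voxel_volume)), con)
  writeLines(sprintf("%.8e", as.numeric(map$values)), con)
  invisible(path)
}
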