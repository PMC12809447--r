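# Least-squares refinement against Fo^2: SHELX-type weights, hydrogen
# constraints (fixed or shared X-H distances, riding ADPs), distance and
# rigid-bond ADP restraints, Levenberg-Marquardt damping, and the standard
# agreement statistics (R1, wR2, Hamilton R-ratio, parameter counts).

#' SHELX-type weight
#'
#' w = 1 / [sigma^2(Fo^2) + (aP)^2 + bP] with P = (max(Fo^2, 0) + 2 Fc^2)/3.
#' Fo^2 is clamped at zero only inside P.
#'
#' @param fo2 Observed intensity-scale values.
#' @param sigma Their standard uncertainties (> 0).
#' @param fc2 Calculated (scaled) intensities.
#' @param a,b Weight parameters (SHELX convention).
#' @return Numeric weights, strictly positive.
#' @export
shelx_weight <- function(fo2, sigma, fc2, a = 0.1, b = 0) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  P <- (pmax(fo2, 0) + 2 * fc2) / 3
  1 / (sigma^2 + (a * P)^2 + b * P)
}

#' Crystallographic agreement statistics
#'
#' `r1()` is the unweighted residual on |F| over reflections with Fo > 0;
#' `wr2()` is the weighted residual on F^2, the quantity the refinement
#' minimizes: sqrt(sum w (Fo^2 - Fc^2)^2 / sum w (Fo^2)^2).
#'
#' @param fo,fc Structure-factor moduli (equal length).
#' @param fo2,fc2 Intensities (equal length).
#' @param w Weights for `wr2()`.
#' @return A fraction.
#' @export
r1 <- function(fo, fc) {
  if (length(fo) == 0) stop("empty reflection list", call. = FALSE)
  keep <- fo > 0
  sum(abs(fo[keep] - fc[keep])) / sum(fo[keep])
}

#' @rdname r1
#' @export
wr2 <- function(fo2, fc2, w) {
  if (length(fo2) == 0) stop("empty reflection list", call. = FALSE)
  sqrt(sum(w * (fo2 - fc2)^2) / sum(w * fo2^2))
}

#' Hamilton R-ratio test
#'
#' Significance of the improvement from a restricted (fewer-parameter)
#' model to a free model via the R-factor-ratio test: with b = additional
#' parameters and dof = n_data - n_params_free, the statistic
#' (ratio^2 - 1) dof / b follows an F(b, dof) distribution under the null.
#'
#' @param r_restricted,r_free R values of the two nested models (> 0).
#' @param n_params_restricted,n_params_free Parameter counts.
#' @param n_data Number of observations (> n_params_free).
#' @param alpha Significance level (default 0.005).
#' @return A list: `ratio`, `b`, `dof`, `critical_ratio`, `p_value`,
#'   `significant`.
#' @export
hamilton_ratio <- function(r_restricted, r_free, n_params_restricted,
                           n_params_free, n_data, alpha = 0.005) {
  if (r_restricted <= 0 || r_free <= 0) {
    stop("R values must be positive", call. = FALSE)
  }
  if (n_data <= n_params_free) stop("n_data must exceed n_params_free",
                                    call. = FALSE)
  ratio <- r_restricted / r_free
  b <- n_params_free - n_params_restricted
  dof <- n_data - n_params_free
  if (b <= 0) {
    return(list(ratio = ratio, b = b, dof = dof, critical_ratio = NA_real_,
                p_value = NA_real_, significant = FALSE))
  }
  fstat <- max(ratio^2 - 1, 0) * dof / b
  p_value <- stats::pf(fstat, b, dof, lower.tail = FALSE)
  critical_ratio <- sqrt(1 + b * stats::qf(1 - alpha, b, dof) / dof)
  list(ratio = ratio, b = b, dof = dof, critical_ratio = critical_ratio,
       p_value = p_value, significant = ratio > critical_ratio)
}

# ---- constraints -----------------------------------------------------------

#' Hydrogen constraints
#'
#' Constructors for the three supported constraint kinds. `fixed_xh()` rides
#' a hydrogen on its parent at a fixed distance along the current bond
#' direction; `shared_xh()` makes one refinable distance shared by all
#' hydrogens of a group (each group adds exactly one parameter);
#' `riding_adp()` ties U_iso(H) to a multiple of the parent's equivalent U.
#'
#' @param h,parent Atom labels (vectors for `shared_xh`).
#' @param distance Target X-H distance (Angstrom).
#' @param hydrogens,parents Parallel label vectors for a shared group.
#' @param factor Riding-ADP multiplier (default 1.2).
#' @return A constraint list.
#' @export
fixed_xh <- function(h, parent, distance) {
  list(kind = "fixed_xh_distance", h = h, parent = parent, distance = distance)
}

#' @rdname fixed_xh
#' @export
shared_xh <- function(hydrogens, parents, distance) {
  stopifnot(length(hydrogens) == length(parents))
  list(kind = "shared_group_distance", hydrogens = hydrogens,
       parents = parents, distance = distance)
}

#' @rdname fixed_xh
#' @export
riding_adp <- function(h, parent, factor = 1.2) {
  list(kind = "riding_adp", h = h, parent = parent, factor = factor)
}

#' Distance and rigid-bond restraints
#'
#' `distance_restraint()` adds a weighted residual (d_ij - target)/sigma;
#' `rigid_bond_restraint()` restrains the difference of mean-square
#' displacement amplitudes of two (anisotropic) atoms along their bond to
#' zero within sigma.
#'
#' @param i,j Atom labels.
#' @param target Target distance (Angstrom).
#' @param sigma Restraint standard deviation (> 0).
#' @return A restraint list.
#' @export
distance_restraint <- function(i, j, target, sigma = 0.01) {
  stopifnot(sigma > 0)
  list(kind = "distance", i = i, j = j, target = target, sigma = sigma)
}

#' @rdname distance_restraint
#' @export
rigid_bond_restraint <- function(i, j, sigma = 0.001) {
  stopifnot(sigma > 0)
  list(kind = "rigid_bond_adp", i = i, j = j, sigma = sigma)
}

positionally_constrained <- function(constraints) {
  out <- character()
  for (cn in constraints) {
    if (cn$kind == "fixed_xh_distance") out <- c(out, cn$h)
    if (cn$kind == "shared_group_distance") out <- c(out, cn$hydrogens)
  }
  if (anyDuplicated(out)) {
    stop("hydrogen '", out[duplicated(out)][1],
         "' is governed by more than one positional constraint", call. = FALSE)
  }
  out
}

adp_constrained <- function(constraints) {
  unlist(lapply(constraints, function(cn)
    if (cn$kind == "riding_adp") cn$h else NULL)) %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count refined parameters
#'
#' Overall scale (1) + 3 positional parameters per unconstrained atom +
#' 6 (anisotropic) or 1 (isotropic) ADP parameters per atom without a
#' riding-ADP constraint + 1 per shared-distance hydrogen group.
#' Converting a fixed X-H group of any size to a shared distance therefore
#' adds exactly one parameter.
#'
#' @param structure A `crystal_structure`.
#' @param constraints List of constraints (see [fixed_xh()]).
#' @return Integer parameter count.
#' @export
count_parameters <- function(structure, constraints = list()) {
  at <- structure$atoms
  pos_con <- positionally_constrained(constraints)
  adp_con <- adp_constrained(constraints)
  n_pos <- 3L * sum(!(at$label %in% pos_con))
  n_adp <- sum(ifelse(at$label %in% adp_con, 0L,
                      ifelse(vapply(at$u_aniso, is.null, logical(1)), 1L, 6L)))
  n_shared <- sum(vapply(constraints, function(cn)
    cn$kind == "shared_group_distance", logical(1)))
  1L + n_pos + n_adp + as.integer(n_shared)
}

# ---- parameterization ------------------------------------------------------

# Builds the parameter map for a refinement: which entries of theta drive
# which structure fields. Directions of constrained hydrogens are frozen at
# the starting geometry (riding).
build_param_map <- function(structure, constraints, refine_xyz = TRUE,
                            refine_adp = TRUE) {
  at <- structure$atoms
  pos_con <- positionally_constrained(constraints)
  adp_con <- adp_constrained(constraints)
  entries <- list(list(what = "scale"))
  if (refine_xyz) {
    for (k in seq_len(nrow(at))) {
      if (at$label[k] %in% pos_con) next
      for (ax in 1:3) {
        entries[[length(entries) + 1]] <- list(what = "xyz", atom = k, axis = ax)
      }
    }
  }
  if (refine_adp) {
    for (k in seq_len(nrow(at))) {
      if (at$label[k] %in% adp_con) next
      if (is.null(at$u_aniso[[k]])) {
        entries[[length(entries) + 1]] <- list(what = "u_iso", atom = k)
      } else {
        for (q in 1:6) {
          entries[[length(entries) + 1]] <- list(what = "u_aniso", atom = k,
                                                 comp = q)
        }
      }
    }
  }
  shared_ids <- which(vapply(constraints, function(cn)
    cn$kind == "shared_group_distance", logical(1)))
  for (si in shared_ids) {
    entries[[length(entries) + 1]] <- list(what = "shared_distance",
                                           constraint = si)
  }
  # frozen bond directions for constrained hydrogens (fractional shift per
  # Angstrom of distance)
  xyz0 <- atom_cart(structure)
  dirs <- list()
  for (ci in seq_along(constraints)) {
    cn <- constraints[[ci]]
    if (cn$kind == "fixed_xh_distance") {
      u <- xyz0[cn$h, ] - xyz0[cn$parent, ]
      dirs[[cn$h]] <- list(parent = cn$parent, unit = u / sqrt(sum(u^2)),
                           distance = cn$distance, constraint = ci)
    } else if (cn$kind == "shared_group_distance") {
      for (q in seq_along(cn$hydrogens)) {
        u <- xyz0[cn$hydrogens[q], ] - xyz0[cn$parents[q], ]
        dirs[[cn$hydrogens[q]]] <- list(parent = cn$parents[q],
                                        unit = u / sqrt(sum(u^2)),
                                        distance = NA_real_, constraint = ci)
      }
    }
  }
  list(entries = entries, dirs = dirs, constraints = constraints)
}

theta_init <- function(structure, pmap, scale) {
  at <- structure$atoms
  vapply(pmap$entries, function(e) switch(e$what,
    scale = scale,
    xyz = c(at$x, at$y, at$z)[(e$axis - 1) * nrow(at) + e$atom],
    u_iso = at$u_iso[e$atom],
    u_aniso = at$u_aniso[[e$atom]][e$comp],
    shared_distance = pmap$constraints[[e$constraint]]$distance
  ), numeric(1))
}

apply_theta <- function(structure, pmap, theta) {
  at <- structure$atoms
  scale <- 1
  shared_d <- stats::setNames(numeric(0), character(0))
  for (q in seq_along(pmap$entries)) {
    e <- pmap$entries[[q]]
    if (e$what == "scale") scale <- theta[q]
    else if (e$what == "xyz") {
      if (e$axis == 1) at$x[e$atom] <- theta[q]
      else if (e$axis == 2) at$y[e$atom] <- theta[q]
      else at$z[e$atom] <- theta[q]
    } else if (e$what == "u_iso") at$u_iso[e$atom] <- theta[q]
    else if (e$what == "u_aniso") at$u_aniso[[e$atom]][e$comp] <- theta[q]
    else if (e$what == "shared_distance") {
      shared_d[as.character(e$constraint)] <- theta[q]
    }
  }
  structure$atoms <- at
  # constrained hydrogens ride on their (possibly shifted) parents
  if (length(pmap$dirs) > 0) {
    for (h in names(pmap$dirs)) {
      d <- pmap$dirs[[h]]
      dist <- if (is.na(d$distance)) shared_d[[as.character(d$constraint)]]
              else d$distance
      kp <- match(d$parent, at$label)
      parent_cart <- frac_to_cart(structure$cell,
                                  c(at$x[kp], at$y[kp], at$z[kp]))
      pos <- cart_to_frac(structure$cell, parent_cart + dist * d$unit)
      kh <- match(h, at$label)
      at$x[kh] <- pos[1]; at$y[kh] <- pos[2]; at$z[kh] <- pos[3]
    }
    structure$atoms <- at
  }
  # riding ADPs
  for (cn in pmap$constraints) {
    if (cn$kind == "riding_adp") {
      kh <- match(cn$h, at$label)
      structure$atoms$u_iso[kh] <- cn$factor *
        u_equiv(structure)[match(cn$parent, at$label)]
    }
  }
  list(structure = structure, scale = scale)
}

restraint_residuals <- function(structure, restraints) {
  if (length(restraints) == 0) return(numeric(0))
  xyz <- atom_cart(structure)
  at <- structure$atoms
  vapply(restraints, function(rs) {
    if (rs$kind == "distance") {
      d <- sqrt(sum((xyz[rs$i, ] - xyz[rs$j, ])^2))
      (d - rs$target) / rs$sigma
    } else if (rs$kind == "rigid_bond_adp") {
      v <- xyz[rs$j, ] - xyz[rs$i, ]
      v <- v / sqrt(sum(v^2))
      z <- vapply(c(rs$i, rs$j), function(lab) {
        k <- match(lab, at$label)
        if (is.null(at$u_aniso[[k]])) at$u_iso[k]
        else as.numeric(v %*% u_star_to_cart(structure$cell,
                                             at$u_aniso[[k]]) %*% v)
      }, numeric(1))
      (z[1] - z[2]) / rs$sigma
    } else stop("unknown restraint kind: ", rs$kind, call. = FALSE)
  }, numeric(1))
}

# ---- the refinement engine -------------------------------------------------

#' Least-squares refinement on F^2
#'
#' Gauss-Newton normal equations on the weighted residuals
#' sqrt(w) (Fo^2 - s |Fc|^2) with Levenberg-Marquardt damping (lambda x10
#' on a rejected step, /10 on an accepted one). Derivatives are numeric
#' central differences (analytic for the overall scale), restraints enter
#' as extra weighted residuals, constraints are applied by parameter
#' elimination, and SHELX-type weights are refreshed at the start of each
#' cycle.
#'
#' @param structure Starting `crystal_structure`.
#' @param reflections Tibble with `h,k,l,fo2,sigma`.
#' @param ff_table A `form_factor_table` covering the model.
#' @param weights Length-2 numeric `c(a, b)` of the SHELX weighting scheme.
#' @param constraints List of constraints ([fixed_xh()], [shared_xh()],
#'   [riding_adp()]).
#' @param restraints List of restraints ([distance_restraint()],
#'   [rigid_bond_restraint()]).
#' @param max_cycles Maximum refinement cycles (default 10).
#' @param refine_xyz,refine_adp Switch parameter classes on/off.
#' @param shift_tol Convergence threshold on max |shift|/esd (default 0.01).
#' @param wr2_tol Convergence threshold on the wR2 change (default 1e-6).
#' @param solvent Optional `solvent_mask` added to every Fc.
#' @param verbose Print per-cycle statistics.
#' @return A `fraghar_refinement`: refined structure, scale, per-cycle wR2
#'   trace, final `r1`, `wr2`, `n_params`, `n_reflections`, `converged`.
#' @export
refine_structure <- function(structure, reflections, ff_table,
                             weights = c(0.1, 0), constraints = list(),
                             restraints = list(), max_cycles = 10,
                             refine_xyz = TRUE, refine_adp = TRUE,
                             shift_tol = 0.01, wr2_tol = 1e-6,
                             solvent = NULL, verbose = FALSE) {
  hkl <- cbind(reflections$h, reflections$k, reflections$l)
  fo2 <- reflections$fo2
  sig <- reflections$sigma
  pmap <- build_param_map(structure, constraints, refine_xyz, refine_adp)
  # starting scale by unweighted least squares
  fc2_0 <- Mod(calc_structure_factors(structure, ff_table, hkl,
                                      solvent = solvent))^2
  s0 <- sum(fo2 * fc2_0) / sum(fc2_0^2)
  theta <- theta_init(structure, pmap, s0)
  n_par <- length(theta)

  fc2_of <- function(th) {
    ap <- apply_theta(structure, pmap, th)
    list(fc2 = ap$scale * Mod(calc_structure_factors(
      ap$structure, ff_table, hkl, solvent = solvent))^2,
      structure = ap$structure)
  }
  resid_of <- function(th, w) {
    ev <- fc2_of(th)
    c(sqrt(w) * (fo2 - ev$fc2), restraint_residuals(ev$structure, restraints))
  }

  lambda <- 1e-3
  trace <- numeric(0)
  converged <- FALSE
  wr2_prev <- Inf
  w <- shelx_weight(fo2, sig, pmax(s0 * fc2_0, 0), weights[1], weights[2])
  esd <- rep(NA_real_, n_par)
  for (cycle in seq_len(max_cycles)) {
    ev <- fc2_of(theta)
    w <- shelx_weight(fo2, sig, ev$fc2, weights[1], weights[2])
    r0 <- resid_of(theta, w)
    ssq0 <- sum(r0^2)
    wr2_now <- wr2(fo2, ev$fc2, w)
    trace <- c(trace, wr2_now)
    if (verbose) message(sprintf("cycle %d: wR2 = %.6g, lambda = %.1e",
                                 cycle, wr2_now, lambda))
    if (abs(wr2_prev - wr2_now) < wr2_tol) { converged <- TRUE; break }
    wr2_prev <- wr2_now
    # Jacobian: analytic for scale, central differences otherwise
    J <- matrix(0, length(r0), n_par)
    for (q in seq_len(n_par)) {
      e <- pmap$entries[[q]]
      if (e$what == "scale") {
        J[seq_along(fo2), q] <- -sqrt(w) * ev$fc2 / theta[q]
        next
      }
      step <- switch(e$what, xyz = 1e-4, u_iso = 1e-5, u_aniso = 1e-5,
                     shared_distance = 1e-4)
      tp <- theta; tp[q] <- tp[q] + step
      tm <- theta; tm[q] <- tm[q] - step
      J[, q] <- (resid_of(tp, w) - resid_of(tm, w)) / (2 * step)
    }
    A <- crossprod(J)
    g <- crossprod(J, r0)
    accepted <- FALSE
    for (try in 1:8) {
      Ad <- A + lambda * diag(pmax(diag(A), 1e-12), n_par)
      delta <- tryCatch(solve(Ad, -g), error = function(e) NULL)
      if (is.null(delta)) {
        if (try == 8) {
          stop("singular normal matrix after damping (condition ~ ",
               format(kappa(A)), ")", call. = FALSE)
        }
        lambda <- lambda * 10
        next
      }
      th_try <- theta + as.vector(delta)
      ssq_try <- sum(resid_of(th_try, w)^2)
      if (ssq_try < ssq0) {
        rel_drop <- (ssq0 - ssq_try) / max(ssq0, .Machine$double.xmin)
        theta <- th_try
        lambda <- max(lambda / 10, 1e-12)
        accepted <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    # parameter esds from the (undamped) normal matrix
    esd <- tryCatch({
      covm <- solve(A)
      sqrt(pmax(diag(covm), 0) * ssq0 / max(length(r0) - n_par, 1))
    }, error = function(e) rep(NA_real_, n_par))
    if (accepted) {
      shift_esd <- abs(as.vector(delta)) / ifelse(is.na(esd) | esd <= 0,
                                                  Inf, esd)
      # esds shrink with the goodness of fit, so far from the minimum the
      # shift/esd test alone would fire spuriously; require the step to have
      # stopped improving the fit as well
      if (max(shift_esd) < shift_tol && rel_drop < 1e-4) { converged <- TRUE }
    }
    if (!accepted) { converged <- TRUE }  # no downhill step available
    if (converged) {
      ev <- fc2_of(theta)
      w <- shelx_weight(fo2, sig, ev$fc2, weights[1], weights[2])
      trace <- c(trace, wr2(fo2, ev$fc2, w))
      break
    }
  }
  ev <- fc2_of(theta)
  w <- shelx_weight(fo2, sig, ev$fc2, weights[1], weights[2])
  final_wr2 <- wr2(fo2, ev$fc2, w)
  keep <- fo2 > 0
  final_r1 <- r1(sqrt(fo2[keep]), sqrt(pmax(ev$fc2[keep], 0)))
  ap <- apply_theta(structure, pmap, theta)
  out <- list(
    structure = ap$structure, scale = ap$scale, theta = theta, esd = esd,
    pmap = pmap, trace = trace, r1 = final_r1, wr2 = final_wr2,
    n_params = n_par, n_reflections = length(fo2),
    n_restraints = length(restraints), converged = converged,
    cycles = length(trace), weights = weights, fc2 = ev$fc2, fo2 = fo2,
    sigma = sig, hkl = hkl, w = w)
  class(out) <- "fraghar_refinement"
  out
}

#' @export
print.fraghar_refinement <- function(x, ...) {
  cat(sprintf(
    "<fraghar_refinement> %d cycles (%sconverged)\n  R1 = %.4f  wR2 = %.4f  (%d params, %d reflections, %d restraints)\n",
    x$cycles, if (x$converged) "" else "not ", x$r1, x$wr2, x$n_params,
    x$n_reflections, x$n_restraints))
  invisible(x)
}

#' Tidy a refinement result
#'
#' @param x A `fraghar_refinement`.
#' @param ... Unused.
#' @return One row per refined parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.fraghar_refinement <- function(x, ...) {
  at <- x$structure$atoms
  term <- vapply(x$pmap$entries, function(e) switch(e$what,
    scale = "scale",
    xyz = paste0(at$label[e$atom], ".", c("x", "y", "z")[e$axis]),
    u_iso = paste0(at$label[e$atom], ".Uiso"),
    u_aniso = paste0(at$label[e$atom], ".U", c("11", "22", "33", "23", "13", "12")[e$comp]),
    shared_distance = paste0("shared_d.", e$constraint)), character(1))
  tibble::tibble(term = term, estimate = x$theta, std.error = x$esd)
}

#' Glance at a refinement result
#'
#' @param x A `fraghar_refinement`.
#' @param ... Unused.
#' @return One-row tibble of fit statistics.
#' @export
glance.fraghar_refinement <- function(x, ...) {
  tibble::tibble(r1 = x$r1, wr2 = x$wr2, n_params = x$n_params,
                 n_reflections = x$n_reflections, scale = x$scale,
                 cycles = x$cycles, converged = x$converged)
}
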