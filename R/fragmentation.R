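# Residue-based fragmentation with chemical capping.  Each residue becomes
# the central unit of one capped fragment: atoms one and two bonds outside
# the residue are copied unchanged, third neighbours are replaced by
# hydrogen junction atoms placed along the cut bond at a fixed X-H
# distance.  Hydrogen-bond acceptors can be added to the donor's fragment
# in an extended (hb) or minimal (mhb) model, and metal sites follow their
# own coordination rule.

#' Fragmentation scheme settings
#'
#' @param mode One of `"plain"`, `"hb"` (extended hydrogen-bond acceptor
#'   model) or `"mhb"` (minimal acceptor model).
#' @param junction_distance X-H distance for junction hydrogens (Angstrom).
#' @param vdw_table Optional named van der Waals radius override used by the
#'   hydrogen-bond search.
#' @param metal_cutoff_extra Slack added to the covalent-radius sum when
#'   detecting metal coordination bonds (Angstrom).
#' @param metals Element symbols treated as metal centres.
#' @return A `fragmentation_scheme` list.
#' @export
fragmentation_scheme <- function(mode = c("plain", "hb", "mhb"),
                                 junction_distance = 1.094,
                                 vdw_table = NULL,
                                 metal_cutoff_extra = 0.6,
                                 metals = .default_metals) {
  mode <- match.arg(mode)
  stopifnot(junction_distance > 0)
  structure(list(mode = mode, junction_distance = junction_distance,
                 vdw_table = vdw_table, metal_cutoff_extra = metal_cutoff_extra,
                 metals = metals),
            class = "fragmentation_scheme")
}

#' Place a junction hydrogen
#'
#' Returns the point on the ray from `parent` towards `removed` at exactly
#' `distance` from `parent` -- the position of the hydrogen atom replacing
#' a cut-away third neighbour.
#'
#' @param parent Cartesian position (length 3) of the atom keeping the bond.
#' @param removed Cartesian position of the replaced atom.
#' @param distance Target X-H distance in Angstrom (default 1.094).
#' @return Length-3 Cartesian position.
#' @examples
#' place_junction_hydrogen(c(0, 0, 0), c(0, 0, 1.54))
#' @export
place_junction_hydrogen <- function(parent, removed, distance = 1.094) {
  v <- as.numeric(removed) - as.numeric(parent)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("zero-length bond vector: parent and removed positions coincide",
                      call. = FALSE)
  as.numeric(parent) + distance * v / nv
}

# Parts allowed while traversing for a fragment realizing part `p`:
# always 0 and p; for an ordered (p = 0) fragment, disordered neighbours
# contribute their first conformation.
allowed_parts <- function(p) if (p > 0L) c(0L, p) else c(0L, 1L)

#' Build capping atoms for one residue
#'
#' Breadth-first walk across every covalent bond leaving the residue:
#' first- and second-neighbour atoms are copied unchanged, each third
#' neighbour (any element) is replaced by a junction hydrogen bonded to its
#' second-neighbour parent. The walk never re-enters the central residue.
#'
#' @param structure A `crystal_structure` with connectivity inferred.
#' @param residue_id Residue to cap.
#' @param part Disorder conformation realized by the fragment (0 = ordered).
#' @param junction_distance X-H distance for junction hydrogens (Angstrom).
#' @return A tibble of cap/junction atoms with columns `label`, `element`,
#'   Cartesian `x`, `y`, `z`, `role` (`"cap"` or `"junction"`),
#'   `parent_label`, `replaced_label`, `source_label`.
#' @export
build_caps <- function(structure, residue_id, part = 0L,
                       junction_distance = 1.094) {
  at <- structure$atoms
  if (!residue_id %in% at$residue_id) {
    stop("residue ", residue_id, " not present in structure", call. = FALSE)
  }
  if (nrow(structure$bonds) == 0 && nrow(at) > 1) {
    structure <- infer_connectivity(structure)
  }
  adj <- bond_adjacency(structure)
  ok_parts <- allowed_parts(as.integer(part))
  central <- at$label[at$residue_id == residue_id & at$part %in% c(0L, as.integer(part))]
  xyz <- atom_cart(structure)
  part_of <- stats::setNames(at$part, at$label)
  in_central_res <- stats::setNames(at$residue_id == residue_id, at$label)

  visited <- central
  frontier <- central
  depth_parent <- list()   # label -> parent label for discovery
  by_depth <- list(`1` = character(), `2` = character())
  for (depth in 1:3) {
    nxt <- character(); parents <- character()
    for (lab in frontier) {
      for (nb in adj[[lab]]) {
        if (in_central_res[[nb]]) next
        if (!(part_of[[nb]] %in% ok_parts)) next
        if (nb %in% visited || nb %in% nxt) {
          if (depth == 3 && !(nb %in% visited)) {
            # ring closure at depth 3: one junction per cut bond
            nxt <- c(nxt, nb); parents <- c(parents, lab)
          }
          next
        }
        nxt <- c(nxt, nb); parents <- c(parents, lab)
      }
    }
    names(nxt) <- NULL
    if (depth < 3) {
      ord <- order(nxt)
      by_depth[[as.character(depth)]] <- nxt[ord]
      for (q in seq_along(nxt)) depth_parent[[nxt[q]]] <- parents[q]
      visited <- c(visited, nxt)
      frontier <- nxt[ord]
    } else {
      by_depth[["3"]] <- nxt
      depth3_parents <- parents
    }
  }
  copied <- c(by_depth[["1"]], by_depth[["2"]])
  cap_tbl <- tibble::tibble(
    label = copied,
    element = at$element[match(copied, at$label)],
    x = xyz[match(copied, rownames(xyz)), 1],
    y = xyz[match(copied, rownames(xyz)), 2],
    z = xyz[match(copied, rownames(xyz)), 3],
    role = "cap",
    parent_label = NA_character_,
    replaced_label = NA_character_,
    source_label = copied
  )
  jn <- by_depth[["3"]]
  if (length(jn) > 0) {
    jrows <- lapply(seq_along(jn), function(q) {
      par <- depth3_parents[q]
      pos <- place_junction_hydrogen(xyz[par, ], xyz[jn[q], ],
                                     junction_distance)
      tibble::tibble(label = sprintf("HJ_%s_%s", par, jn[q]), element = "H",
                     x = pos[1], y = pos[2], z = pos[3], role = "junction",
                     parent_label = par, replaced_label = jn[q],
                     source_label = jn[q])
    })
    cap_tbl <- dplyr::bind_rows(cap_tbl, dplyr::bind_rows(jrows))
  }
  cap_tbl
}

#' Detect hydrogen-bond contacts
#'
#' Finds oxygen or nitrogen acceptors closer to a polar hydrogen (an H not
#' bonded to carbon) than the sum of the two van der Waals radii. The
#' search is restricted to the asymmetric unit (no symmetry mates), the
#' acceptor may not be covalently bonded to the donor hydrogen nor within
#' two bonds of it, and parts must be compatible.
#'
#' @param structure A `crystal_structure` with connectivity inferred.
#' @param vdw_table Optional named van der Waals radius override.
#' @return Tibble with `donor_h`, `acceptor`, `distance`, `vdw_sum`.
#' @export
detect_hydrogen_bonds <- function(structure, vdw_table = NULL) {
  at <- structure$atoms
  if (nrow(structure$bonds) == 0 && nrow(at) > 1) {
    structure <- infer_connectivity(structure)
  }
  adj <- bond_adjacency(structure)
  xyz <- atom_cart(structure)
  elem_of <- stats::setNames(at$element, at$label)
  vdw <- vapply(unique(at$element), function(e)
    element_info(e, vdw_table = vdw_table)$vdw_radius, numeric(1))
  polar_h <- at$label[at$element == "H" &
    vapply(at$label, function(l) {
      nb <- adj[[l]]
      length(nb) > 0 && !any(elem_of[nb] == "C")
    }, logical(1))]
  acceptors <- at$label[at$element %in% c("N", "O")]
  out <- list()
  for (h in polar_h) {
    excl <- unique(c(h, adj[[h]], unlist(adj[adj[[h]]], use.names = FALSE)))
    for (acc in setdiff(acceptors, excl)) {
      if (!parts_compatible(at$part[at$label == h], at$part[at$label == acc])) next
      d <- sqrt(sum((xyz[h, ] - xyz[acc, ])^2))
      vsum <- vdw[[elem_of[[h]]]] + vdw[[elem_of[[acc]]]]
      if (d < vsum) {
        out[[length(out) + 1]] <- tibble::tibble(
          donor_h = h, acceptor = acc, distance = d, vdw_sum = vsum)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(donor_h = character(), acceptor = character(),
                          distance = numeric(), vdw_sum = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$donor_h, .data$acceptor)
}

# Closed-shell charge adjustment for the minimal acceptor model: an O
# acceptor carrying no hydrogen (carbonyl/carboxylate) becomes OH-, all
# hydroxyl O and N acceptors become neutral species.
mhb_charge_delta <- function(acceptor_element, has_h_neighbour) {
  if (acceptor_element == "O" && !has_h_neighbour) -1L else 0L
}

#' Build a hydrogen-bond acceptor extension
#'
#' Extended (`"hb"`) model: the acceptor and its directly bound atoms are
#' copied and their further neighbours become junction hydrogens (a
#' backbone carbonyl gives OCH2, a serine hydroxyl gives HOCH3). Minimal
#' (`"mhb"`) model: only the acceptor is copied, bonded hydrogens are kept
#' as junction hydrogens and bonded heavy atoms are replaced by junction
#' hydrogens (carbonyl gives OH-, serine gives H2O).
#'
#' @param structure A `crystal_structure` with connectivity inferred.
#' @param contact One row of [detect_hydrogen_bonds()] output (or a list
#'   with `donor_h`, `acceptor`).
#' @param mode `"hb"` or `"mhb"`.
#' @param junction_distance X-H distance for junction hydrogens (Angstrom).
#' @return List with `atoms` (tibble like [build_caps()] with roles
#'   `"hb_extension"`/`"hb_junction"`) and `charge_delta` (integer added to
#'   the fragment's QM charge so the extension is closed shell).
#' @export
build_hb_extension <- function(structure, contact, mode = c("hb", "mhb"),
                               junction_distance = 1.094) {
  mode <- match.arg(mode)
  if (nrow(structure$bonds) == 0) structure <- infer_connectivity(structure)
  at <- structure$atoms
  adj <- bond_adjacency(structure)
  xyz <- atom_cart(structure)
  acc <- contact$acceptor
  elem_of <- stats::setNames(at$element, at$label)
  nb <- adj[[acc]]
  if (length(nb) == 0) {
    stop("hydrogen-bond acceptor '", acc, "' has no bonded atoms", call. = FALSE)
  }
  copy_row <- function(lab, role) tibble::tibble(
    label = paste0("X_", lab), element = elem_of[[lab]],
    x = xyz[lab, 1], y = xyz[lab, 2], z = xyz[lab, 3], role = role,
    parent_label = NA_character_, replaced_label = NA_character_,
    source_label = lab)
  junction_row <- function(parent, removed) {
    pos <- place_junction_hydrogen(xyz[parent, ], xyz[removed, ],
                                   junction_distance)
    tibble::tibble(label = sprintf("HX_%s_%s", parent, removed), element = "H",
                   x = pos[1], y = pos[2], z = pos[3], role = "hb_junction",
                   parent_label = paste0("X_", parent), replaced_label = removed,
                   source_label = removed)
  }
  rows <- list(copy_row(acc, "hb_extension"))
  if (mode == "hb") {
    for (b in sort(nb)) {
      rows[[length(rows) + 1]] <- copy_row(b, "hb_extension")
      for (further in sort(setdiff(adj[[b]], c(acc, nb)))) {
        rows[[length(rows) + 1]] <- junction_row(b, further)
      }
    }
    charge_delta <- 0L
  } else {
    has_h <- any(elem_of[nb] == "H")
    for (b in sort(nb)) {
      if (elem_of[[b]] == "H") {
        rows[[length(rows) + 1]] <- copy_row(b, "hb_extension")
      } else {
        rows[[length(rows) + 1]] <- junction_row(acc, b)
      }
    }
    charge_delta <- mhb_charge_delta(elem_of[[acc]], has_h)
  }
  list(atoms = dplyr::bind_rows(rows), charge_delta = charge_delta)
}

#' Build the fragment for a metal site
#'
#' The metal ion is the central atom; for each coordinating ligand the
#' directly bound atom and its next-nearest neighbours are copied into the
#' cap, while further bonds are terminated with junction hydrogens (a
#' cysteine thiolate ligand becomes an -SCH3 cap).
#'
#' @param structure A `crystal_structure` with connectivity inferred.
#' @param metal_label Label of the metal atom.
#' @param scheme A [fragmentation_scheme()].
#' @return A `capped_fragment` (charge/multiplicity still at defaults).
#' @export
metal_site_fragment <- function(structure, metal_label,
                                scheme = fragmentation_scheme()) {
  at <- structure$atoms
  k <- match(metal_label, at$label)
  if (is.na(k)) stop("no atom labelled '", metal_label, "'", call. = FALSE)
  if (nrow(structure$bonds) == 0) structure <- infer_connectivity(structure)
  xyz <- atom_cart(structure)
  rc <- vapply(at$element, function(e) element_info(e)$covalent_radius,
               numeric(1))
  d <- sqrt(colSums((t(xyz) - xyz[k, ])^2))
  cutoff <- rc[k] + rc + scheme$metal_cutoff_extra
  lig_idx <- which(d < cutoff & seq_along(d) != k &
                     parts_compatible(at$part, at$part[k]) &
                     at$element != "H")
  central <- tibble::tibble(
    label = at$label[k], element = at$element[k],
    x = xyz[k, 1], y = xyz[k, 2], z = xyz[k, 3], role = "central",
    parent_label = NA_character_, replaced_label = NA_character_,
    source_label = at$label[k])
  if (length(lig_idx) == 0) {
    warning("metal '", metal_label, "' has no ligands within cutoff; ",
            "building a bare-ion fragment")
    caps <- central[0, ]
  } else {
    adj <- bond_adjacency(structure)
    rows <- list()
    seen <- at$label[k]
    for (li in lig_idx[order(at$label[lig_idx])]) {
      lig <- at$label[li]
      if (lig %in% seen) next
      seen <- c(seen, lig)
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = lig, element = at$element[li],
        x = xyz[lig, 1], y = xyz[lig, 2], z = xyz[lig, 3], role = "cap",
        parent_label = NA_character_, replaced_label = NA_character_,
        source_label = lig)
      second <- sort(setdiff(adj[[lig]], seen))
      for (s2 in second) {
        seen <- c(seen, s2)
        rows[[length(rows) + 1]] <- tibble::tibble(
          label = s2, element = at$element[match(s2, at$label)],
          x = xyz[s2, 1], y = xyz[s2, 2], z = xyz[s2, 3], role = "cap",
          parent_label = NA_character_, replaced_label = NA_character_,
          source_label = s2)
      }
      for (s2 in second) {
        for (s3 in sort(setdiff(adj[[s2]], seen))) {
          pos <- place_junction_hydrogen(xyz[s2, ], xyz[s3, ],
                                         scheme$junction_distance)
          rows[[length(rows) + 1]] <- tibble::tibble(
            label = sprintf("HJ_%s_%s", s2, s3), element = "H",
            x = pos[1], y = pos[2], z = pos[3], role = "junction",
            parent_label = s2, replaced_label = s3, source_label = s3)
        }
      }
    }
    caps <- dplyr::bind_rows(rows)
  }
  new_capped_fragment(
    id = paste0("M_", metal_label),
    residue_id = at$residue_id[k], residue_name = at$residue_name[k],
    part = at$part[k], atoms = dplyr::bind_rows(central, caps),
    charge = 0L, multiplicity = 1L, qm_charge = 0L)
}

#' Net formal charge of a metal-site fragment
#'
#' Charge bookkeeping for the metal rule: the fragment's net charge is the
#' metal oxidation state plus the formal charges of its capped ligands
#' (e.g. Fe(III) with four thiolate caps gives +3 + 4(-1) = -1).
#'
#' @param oxidation_state Integer oxidation state of the metal.
#' @param ligand_charges Integer vector of formal charges of the ligand caps.
#' @return Integer net charge.
#' @export
metal_fragment_charge <- function(oxidation_state, ligand_charges) {
  as.integer(oxidation_state + sum(ligand_charges))
}

new_capped_fragment <- function(id, residue_id, residue_name, part, atoms,
                                charge, multiplicity, qm_charge) {
  structure(list(id = id, residue_id = as.integer(residue_id),
                 residue_name = residue_name, part = as.integer(part),
                 atoms = atoms, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 qm_charge = as.integer(qm_charge)),
            class = "capped_fragment")
}

#' @export
print.capped_fragment <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat(sprintf("<capped_fragment> %s (residue %d%s): %s; q=%d S=%d (QM charge %d)\n",
              x$id, x$residue_id,
              if (x$part > 0) paste0(" part ", x$part) else "",
              paste(names(tab), tab, sep = "=", collapse = " "),
              x$charge, x$multiplicity, x$qm_charge))
  invisible(x)
}

#' Assign charge and multiplicity to a fragment
#'
#' Entry precedence: a (residue, part) entry beats a residue-wide entry
#' beats the defaults q = 0, S = 1. A residue-wide entry applies to all
#' conformations of a disordered residue.
#'
#' @param fragment A `capped_fragment`.
#' @param qs_entries Tibble from [parse_qs()].
#' @return The fragment with `charge`, `multiplicity` and `qm_charge`
#'   updated (any hydrogen-bond extension charge delta already present in
#'   `qm_charge` is preserved).
#' @export
assign_charge_multiplicity <- function(fragment, qs_entries) {
  delta <- fragment$qm_charge - fragment$charge
  q <- 0L; s <- 1L
  if (!is.null(qs_entries) && nrow(qs_entries) > 0) {
    hit <- qs_entries[qs_entries$residue_id == fragment$residue_id &
                        !is.na(qs_entries$part) &
                        qs_entries$part == fragment$part, ]
    if (nrow(hit) == 0) {
      hit <- qs_entries[qs_entries$residue_id == fragment$residue_id &
                          is.na(qs_entries$part), ]
    }
    if (nrow(hit) > 1) {
      stop("conflicting qS entries for residue ", fragment$residue_id,
           call. = FALSE)
    }
    if (nrow(hit) == 1) { q <- hit$charge[1]; s <- hit$multiplicity[1] }
  }
  fragment$charge <- as.integer(q)
  fragment$multiplicity <- as.integer(s)
  fragment$qm_charge <- as.integer(q + delta)
  fragment
}

#' Fragment a structure into capped QM-ready fragments
#'
#' One fragment per (residue, realized conformation): ordered residues give
#' a single fragment, residues with alternative conformations give one
#' fragment per PART. Isolated molecules (waters, ligands) become cap-free
#' fragments, metal-containing residues are routed to
#' [metal_site_fragment()], and hydrogen-bond acceptor extensions are
#' attached to donor fragments under the `"hb"`/`"mhb"` schemes.
#'
#' @param structure A `crystal_structure`.
#' @param scheme A [fragmentation_scheme()].
#' @param qs_entries Tibble from [parse_qs()] (NULL means all defaults).
#' @return List of `capped_fragment`, ordered by (residue_id, part).
#' @export
fragment_structure <- function(structure, scheme = fragmentation_scheme(),
                               qs_entries = NULL) {
  if (nrow(structure$bonds) == 0 && nrow(structure$atoms) > 1) {
    structure <- infer_connectivity(structure)
  }
  at <- structure$atoms
  if (any(is.na(at$residue_id))) {
    stop("atoms not assigned to any residue: ",
         paste(at$label[is.na(at$residue_id)], collapse = ", "), call. = FALSE)
  }
  contacts <- if (scheme$mode != "plain") {
    detect_hydrogen_bonds(structure, vdw_table = scheme$vdw_table)
  } else NULL
  xyz <- atom_cart(structure)
  frags <- list()
  for (rid in sort(unique(at$residue_id))) {
    rat <- at[at$residue_id == rid, ]
    if (any(is_metal(rat$element, scheme$metals))) {
      metal_lab <- rat$label[is_metal(rat$element, scheme$metals)][1]
      fr <- metal_site_fragment(structure, metal_lab, scheme)
      fr <- assign_charge_multiplicity(fr, qs_entries)
      frags[[length(frags) + 1]] <- fr
      next
    }
    parts <- sort(unique(rat$part[rat$part > 0L]))
    if (length(parts) == 0) parts <- 0L
    for (p in parts) {
      in_model <- rat$label[rat$part %in% c(0L, p)]
      # shared (part 0) atoms are central in the first conformation's
      # fragment only, so every (atom, part) pair is central exactly once;
      # in later conformations they still contribute density as caps
      central_lab <- if (p == parts[1]) in_model else rat$label[rat$part == p]
      shared_lab <- setdiff(in_model, central_lab)
      central_tbl <- tibble::tibble(
        label = c(central_lab, shared_lab),
        element = at$element[match(c(central_lab, shared_lab), at$label)],
        x = xyz[c(central_lab, shared_lab), 1],
        y = xyz[c(central_lab, shared_lab), 2],
        z = xyz[c(central_lab, shared_lab), 3],
        role = rep(c("central", "cap"),
                   c(length(central_lab), length(shared_lab))),
        parent_label = NA_character_, replaced_label = NA_character_,
        source_label = c(central_lab, shared_lab))
      caps <- build_caps(structure, rid, part = p,
                         junction_distance = scheme$junction_distance)
      atoms <- dplyr::bind_rows(central_tbl, caps)
      delta_total <- 0L
      if (!is.null(contacts) && nrow(contacts) > 0) {
        mine <- contacts[contacts$donor_h %in% central_lab, ]
        for (ci in seq_len(nrow(mine))) {
          if (mine$acceptor[ci] %in% atoms$source_label) next
          ext <- build_hb_extension(structure, mine[ci, ],
                                    mode = scheme$mode,
                                    junction_distance = scheme$junction_distance)
          atoms <- dplyr::bind_rows(atoms, ext$atoms)
          delta_total <- delta_total + ext$charge_delta
        }
      }
      fr <- new_capped_fragment(
        id = if (p > 0) sprintf("R%d_P%d", rid, p) else sprintf("R%d", rid),
        residue_id = rid, residue_name = rat$residue_name[1], part = p,
        atoms = atoms, charge = 0L, multiplicity = 1L, qm_charge = delta_total)
      fr <- assign_charge_multiplicity(fr, qs_entries)
      frags[[length(frags) + 1]] <- fr
    }
  }
  frags
}

#' Fragment manifest
#'
#' @param fragments List of `capped_fragment` from [fragment_structure()].
#' @return Tibble with one row per fragment: id, residue, part, atom counts
#'   by role, charge, multiplicity and QM charge.
#' @export
fragment_manifest <- function(fragments) {
  dplyr::bind_rows(lapply(fragments, function(f) {
    tibble::tibble(
      id = f$id, residue_id = f$residue_id, residue_name = f$residue_name,
      part = f$part,
      n_central = sum(f$atoms$role == "central"),
      n_cap = sum(f$atoms$role == "cap"),
      n_junction = sum(f$atoms$role %in% c("junction", "hb_junction")),
      n_hb_extension = sum(f$atoms$role == "hb_extension"),
      central_labels = paste(f$atoms$label[f$atoms$role == "central"],
                             collapse = " "),
      cap_labels = paste(f$atoms$label[f$atoms$role == "cap"], collapse = " "),
      charge = f$charge, multiplicity = f$multiplicity,
      qm_charge = f$qm_charge)
  }))
}

#' Electron count of a fragment's QM model
#'
#' @param fragment A `capped_fragment`.
#' @return Integer: sum of element electron counts minus the QM charge.
#' @export
fragment_electron_count <- function(fragment) {
  z <- vapply(fragment$atoms$element,
              function(e) element_info(e)$n_electrons, integer(1))
  as.integer(sum(z) - fragment$qm_charge)
}
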