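# Geometric detection of hydrogen bonds and van der Waals contacts
# between a ligand pose and receptor residues.

#' Interaction detection criteria
#'
#' The geometric thresholds used by contact detection. Defaults are the
#' conventional values for protein-ligand work: donor-acceptor distance
#' at most 3.5 Angstrom with a D-H...A angle of at least 120 degrees when
#' an explicit hydrogen sits on the donor, heavy-atom-only hydrogen bonds
#' at 3.5 Angstrom when a structure carries no hydrogens, and heavy-atom
#' van der Waals contacts at 4.0 Angstrom. Every threshold is exposed
#' because site mapping itself is agnostic to the upstream contact
#' definition.
#'
#' @param hb_da_max maximum donor-acceptor distance (Angstrom).
#' @param hb_angle_min minimum D-H...A angle at the hydrogen (degrees),
#'   applied only when the donor has an explicit hydrogen.
#' @param hb_heavy_only_da_max donor-acceptor distance used when the
#'   donor-side structure has no hydrogens at all (distance-only mode).
#' @param vdw_max maximum heavy-atom distance for a van der Waals contact.
#' @param exclude_hbonded_pairs_from_vdw if `TRUE` (default), an atom pair
#'   already recorded as a hydrogen bond in the same pose is not re-counted
#'   as a van der Waals contact.
#' @param s_acceptor treat sulfur as a hydrogen-bond acceptor.
#' @return Object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hb_da_max = 3.5, hb_angle_min = 120,
                                 hb_heavy_only_da_max = 3.5, vdw_max = 4.0,
                                 exclude_hbonded_pairs_from_vdw = TRUE,
                                 s_acceptor = FALSE) {
  if (any(c(hb_da_max, hb_heavy_only_da_max, vdw_max) <= 0))
    stop("distance thresholds must be positive")
  if (hb_angle_min < 0 || hb_angle_min > 180)
    stop("hb_angle_min must lie in [0, 180] degrees")
  structure(list(hb_da_max = hb_da_max, hb_angle_min = hb_angle_min,
                 hb_heavy_only_da_max = hb_heavy_only_da_max,
                 vdw_max = vdw_max,
                 exclude_hbonded_pairs_from_vdw = exclude_hbonded_pairs_from_vdw,
                 s_acceptor = s_acceptor),
            class = "interaction_criteria")
}

coords_matrix <- function(model, idx = seq_len(nrow(model$atoms))) {
  cbind(model$atoms$x[idx], model$atoms$y[idx], model$atoms$z[idx])
}

polar_indices <- function(model, criteria) {
  el <- model$atoms$element
  ok <- el %in% c("N", "O")
  if (isTRUE(criteria$s_acceptor)) ok <- ok | el == "S"
  which(ok & !model$atoms$is_hydrogen)
}

# indices of hydrogens attached (<= 1.3 A) to each heavy atom; list indexed
# by heavy-atom row
hydrogen_attachments <- function(model) {
  h_idx <- which(model$atoms$is_hydrogen)
  heavy_idx <- which(!model$atoms$is_hydrogen)
  out <- vector("list", nrow(model$atoms))
  if (length(h_idx) == 0L || length(heavy_idx) == 0L) return(out)
  hc <- coords_matrix(model, h_idx)
  for (k in seq_along(h_idx)) {
    d2 <- (model$atoms$x[heavy_idx] - hc[k, 1])^2 +
      (model$atoms$y[heavy_idx] - hc[k, 2])^2 +
      (model$atoms$z[heavy_idx] - hc[k, 3])^2
    j <- heavy_idx[which.min(d2)]
    if (min(d2) <= 1.3^2) out[[j]] <- c(out[[j]], h_idx[k])
  }
  out
}

angle_at_h_deg <- function(d, h, a) {
  v1 <- d - h
  v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Core pairwise engine: returns data.frame of contacts with receptor atom
# index, ligand atom index, and kind. Shared by the exported detectors so
# the hydrogen-bond exclusion operates on exact atom pairs.
detect_pairs <- function(pose, receptor, criteria) {
  lig <- pose$atoms
  rec <- receptor$atoms
  lig_heavy <- which(!lig$is_hydrogen)
  rec_heavy <- which(!rec$is_hydrogen)
  if (length(lig_heavy) == 0L || length(rec_heavy) == 0L)
    return(data.frame(rec_idx = integer(), lig_idx = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  lx <- coords_matrix(pose, lig_heavy)
  rx <- coords_matrix(receptor, rec_heavy)
  # all heavy-atom pair distances (fixtures and binding sites are small)
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * (rx %*% t(lx))
  d2[d2 < 0] <- 0

  lig_polar <- polar_indices(pose, criteria)
  rec_polar <- polar_indices(receptor, criteria)
  # distance-only mode applies only when the whole system is hydrogen-free;
  # in a system with explicit hydrogens, an atom without one cannot donate
  sys_has_h <- any(lig$is_hydrogen) || any(rec$is_hydrogen)
  lig_h <- hydrogen_attachments(pose)
  rec_h <- hydrogen_attachments(receptor)

  donor_ok <- function(d_model, d_idx, a_model, a_idx, has_h, attach, dist) {
    if (!has_h) return(dist <= criteria$hb_heavy_only_da_max)
    hs <- attach[[d_idx]]
    if (length(hs) == 0L) return(FALSE)
    dpos <- c(d_model$atoms$x[d_idx], d_model$atoms$y[d_idx], d_model$atoms$z[d_idx])
    apos <- c(a_model$atoms$x[a_idx], a_model$atoms$y[a_idx], a_model$atoms$z[a_idx])
    for (h in hs) {
      hpos <- c(d_model$atoms$x[h], d_model$atoms$y[h], d_model$atoms$z[h])
      if (angle_at_h_deg(dpos, hpos, apos) >= criteria$hb_angle_min) return(TRUE)
    }
    FALSE
  }

  hb <- data.frame(rec_idx = integer(), lig_idx = integer(),
                   stringsAsFactors = FALSE)
  for (ri in rec_polar) {
    for (li in lig_polar) {
      dist <- sqrt(d2[match(ri, rec_heavy), match(li, lig_heavy)])
      if (dist > criteria$hb_da_max) next
      ok <- donor_ok(receptor, ri, pose, li, sys_has_h, rec_h, dist) ||
        donor_ok(pose, li, receptor, ri, sys_has_h, lig_h, dist)
      if (ok) hb <- rbind(hb, data.frame(rec_idx = ri, lig_idx = li))
    }
  }

  within_vdw <- which(d2 <= criteria$vdw_max^2, arr.ind = TRUE)
  vdw <- data.frame(rec_idx = rec_heavy[within_vdw[, 1]],
                    lig_idx = lig_heavy[within_vdw[, 2]])
  if (isTRUE(criteria$exclude_hbonded_pairs_from_vdw) && nrow(hb) > 0L) {
    key_v <- paste(vdw$rec_idx, vdw$lig_idx)
    key_h <- paste(hb$rec_idx, hb$lig_idx)
    vdw <- vdw[!(key_v %in% key_h), , drop = FALSE]
  }
  out <- rbind(
    if (nrow(hb) > 0L) cbind(hb, kind = "HB") else NULL,
    if (nrow(vdw) > 0L) cbind(vdw, kind = "VDW") else NULL)
  if (is.null(out))
    out <- data.frame(rec_idx = integer(), lig_idx = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  out
}

pairs_to_records <- function(pairs, pose, receptor, pose_rank) {
  if (nrow(pairs) == 0L)
    return(data.frame(chain = character(), label = character(),
                      kind = character(), ligand_atom = character(),
                      protein_atom = character(), pose_rank = integer(),
                      stringsAsFactors = FALSE))
  rec <- receptor$atoms
  lig <- pose$atoms
  out <- data.frame(
    chain = rec$chain[pairs$rec_idx],
    label = rec$label[pairs$rec_idx],
    kind = as.character(pairs$kind),
    ligand_atom = lig$name[pairs$lig_idx],
    protein_atom = rec$name[pairs$rec_idx],
    pose_rank = as.integer(pose_rank),
    stringsAsFactors = FALSE)
  out[order(out$chain, out$label, out$protein_atom, out$ligand_atom,
            out$kind), , drop = FALSE]
}

#' Detect hydrogen bonds between a ligand pose and a receptor
#'
#' A donor-acceptor pair of polar atoms (N, O, optionally S) is a hydrogen
#' bond when the heavy-atom distance is within `hb_da_max` and, for a donor
#' carrying an explicit hydrogen, some D-H...A angle at the hydrogen is at
#' least `hb_angle_min`. When neither structure carries any hydrogens the
#' detection falls back to distance-only mode (a notice is emitted once
#' per call); in a system with explicit hydrogens an atom without one can
#' accept but not donate.
#'
#' @param pose ligand `structure_model`.
#' @param receptor receptor `structure_model`.
#' @param criteria an [interaction_criteria()].
#' @param pose_rank rank recorded on the returned rows.
#' @return data.frame with columns `chain`, `label`, `kind`, `ligand_atom`,
#'   `protein_atom`, `pose_rank`, ordered deterministically.
#' @export
detect_hydrogen_bonds <- function(pose, receptor,
                                  criteria = interaction_criteria(),
                                  pose_rank = 1L) {
  if (nrow(pose$atoms) == 0L || nrow(receptor$atoms) == 0L)
    stop("pose and receptor must be non-empty")
  if (!any(receptor$atoms$is_hydrogen) && !any(pose$atoms$is_hydrogen))
    message("no hydrogens present; hydrogen bonds detected by distance only")
  pairs <- detect_pairs(pose, receptor, criteria)
  pairs_to_records(pairs[pairs$kind == "HB", , drop = FALSE],
                   pose, receptor, pose_rank)
}

#' Detect van der Waals contacts between a ligand pose and a receptor
#'
#' All heavy-atom pairs within `vdw_max`. Pairs already recorded as
#' hydrogen bonds in the same pose are suppressed when
#' `exclude_hbonded_pairs_from_vdw` is set (the default), so the two
#' interaction families partition the contact pairs.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame as in [detect_hydrogen_bonds()].
#' @export
detect_vdw_contacts <- function(pose, receptor,
                                criteria = interaction_criteria(),
                                pose_rank = 1L) {
  if (nrow(pose$atoms) == 0L || nrow(receptor$atoms) == 0L)
    stop("pose and receptor must be non-empty")
  pairs <- detect_pairs(pose, receptor, criteria)
  pairs_to_records(pairs[pairs$kind == "VDW", , drop = FALSE],
                   pose, receptor, pose_rank)
}

#' Detect both interaction families for one pose
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame with both `"HB"` and `"VDW"` rows.
#' @export
detect_contacts <- function(pose, receptor,
                            criteria = interaction_criteria(),
                            pose_rank = 1L) {
  if (nrow(pose$atoms) == 0L || nrow(receptor$atoms) == 0L)
    stop("pose and receptor must be non-empty")
  pairs_to_records(detect_pairs(pose, receptor, criteria),
                   pose, receptor, pose_rank)
}

#' Residue-level contact set of a crystallographic complex
#'
#' Splits the ligand out of a complex by a selector, detects contacts
#' between the ligand and the remaining structure, and returns the
#' residue-level reference set used to score site maps: residues making at
#' least one hydrogen bond and/or one van der Waals contact with the
#' crystallographic ligand.
#'
#' @param complex `structure_model` containing receptor and ligand (read
#'   with `keep_hetero = TRUE`).
#' @param ligand_selector residue-name selector (e.g. `"LIG"`) or a chain
#'   selector of the form `"chain=X"`. Must match exactly one residue.
#' @param criteria an [interaction_criteria()].
#' @return data.frame with columns `chain`, `label`, `kind` (unique typed
#'   contacts); `unique(out$label)` is the residue-level set.
#' @export
detect_reference_contacts <- function(complex, ligand_selector,
                                      criteria = interaction_criteria()) {
  a <- complex$atoms
  if (grepl("^chain=", ligand_selector)) {
    ch <- sub("^chain=", "", ligand_selector)
    sel <- a$chain == ch
  } else {
    sel <- a$resname == ligand_selector
  }
  if (!any(sel)) stop("ligand selector '", ligand_selector, "' matches no atoms")
  lig_res <- unique(residue_key(a$chain[sel], a$resno[sel], a$insert[sel]))
  if (length(lig_res) > 1L)
    stop("ligand selector '", ligand_selector, "' matches ",
         length(lig_res), " residues; expected exactly one")
  lig <- structure_model(a[sel, , drop = FALSE], source = complex$source)
  rec <- structure_model(a[!sel, , drop = FALSE], source = complex$source)
  recs <- detect_contacts(lig, rec, criteria)
  unique(recs[, c("chain", "label", "kind")])
}
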