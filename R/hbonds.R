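#' Hydrogen-bond geometric criteria
#'
#' Defaults follow standard crystallographic practice: donor-acceptor
#' heavy-atom distance at most 3.5 Angstrom and D-H...A angle at least 120
#' degrees when the hydrogen is present. When no hydrogen is resolved on
#' either partner the check degrades to distance-only and the contact's
#' angle is recorded as `NA`.
#'
#' @param max_da_distance maximum donor-acceptor heavy-atom distance (A).
#' @param min_dha_angle minimum D-H...A angle (degrees).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 120) {
  stopifnot(max_da_distance > 0, max_da_distance < 10,
            min_dha_angle >= 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

.angle_deg <- function(a, b, c) {
  # angle at vertex b, degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.residue_label <- function(resid, resno) {
  nm <- paste0(toupper(substr(resid, 1, 1)), tolower(substr(resid, 2, 3)))
  paste0(nm, resno)
}

#' Detect receptor-ligand hydrogen bonds
#'
#' Enumerates all ligand N/O vs receptor N/O pairs within the distance
#' criterion and classifies each by directionality: `LIGAND_DONOR` when an
#' explicit hydrogen bonded (within 1.2 A) to the ligand heavy atom points
#' at the receptor atom with an acceptable D-H...A angle; `LIGAND_ACCEPTOR`
#' when the hydrogen sits on the receptor atom, or when neither partner
#' carries a hydrogen (distance-only mode, angle `NA`). A hydroxyl facing a
#' hydroxyl can yield one contact per direction.
#'
#' @param complex a [complex_structure].
#' @param criteria an [hbond_criteria] (default [hbond_criteria()]).
#' @return data.frame of class `hbond_contacts`: ligand_atom_index,
#'   receptor_atom_index, residue_label, distance (A), angle (degrees or
#'   NA), direction; sorted by ligand atom index then distance.
#' @export
detect_hbonds <- function(complex, criteria = hbond_criteria()) {
  stopifnot(inherits(complex, "complex_structure"))
  lig <- complex$ligand
  rec <- complex$receptor
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  lig_polar <- which(lig$element %in% c("N", "O"))
  rec_polar <- which(rec$element %in% c("N", "O"))
  out <- data.frame(ligand_atom_index = integer(),
                    receptor_atom_index = integer(),
                    residue_label = character(), distance = numeric(),
                    angle = numeric(), direction = character(),
                    stringsAsFactors = FALSE)
  if (length(lig_polar) == 0L || length(rec_polar) == 0L) {
    class(out) <- c("hbond_contacts", class(out))
    return(out)
  }
  lig_h <- which(lig$element == "H")
  rec_h <- which(rec$element == "H")
  # hydrogens covalently attached to a heavy atom: within 1.2 A
  attach <- function(heavy_xyz, h_idx, xyz) {
    if (length(h_idx) == 0L) return(integer())
    d <- sqrt(colSums((t(xyz[h_idx, , drop = FALSE]) - heavy_xyz)^2))
    h_idx[d <= 1.2]
  }
  for (li in lig_polar) {
    lpos <- lig_xyz[li, ]
    lh <- attach(lpos, lig_h, lig_xyz)
    d_all <- sqrt(colSums((t(rec_xyz[rec_polar, , drop = FALSE]) - lpos)^2))
    near <- rec_polar[d_all <= criteria$max_da_distance]
    for (ri in near) {
      rpos <- rec_xyz[ri, ]
      dist <- sqrt(sum((rpos - lpos)^2))
      lab <- .residue_label(rec$resid[ri], rec$resno[ri])
      rh <- attach(rpos, rec_h, rec_xyz)
      emitted <- FALSE
      if (length(lh) > 0L) {    # ligand side donates
        angs <- vapply(lh, function(h)
          .angle_deg(lpos, lig_xyz[h, ], rpos), numeric(1))
        if (any(angs >= criteria$min_dha_angle)) {
          out <- rbind(out, data.frame(
            ligand_atom_index = li, receptor_atom_index = ri,
            residue_label = lab, distance = dist, angle = max(angs),
            direction = "LIGAND_DONOR", stringsAsFactors = FALSE))
          emitted <- TRUE
        }
      }
      if (length(rh) > 0L) {    # receptor side donates
        angs <- vapply(rh, function(h)
          .angle_deg(rpos, rec_xyz[h, ], lpos), numeric(1))
        if (any(angs >= criteria$min_dha_angle)) {
          out <- rbind(out, data.frame(
            ligand_atom_index = li, receptor_atom_index = ri,
            residue_label = lab, distance = dist, angle = max(angs),
            direction = "LIGAND_ACCEPTOR", stringsAsFactors = FALSE))
          emitted <- TRUE
        }
      }
      if (!emitted && length(lh) == 0L && length(rh) == 0L) {
        # no hydrogens resolved on either partner: distance-only mode
        out <- rbind(out, data.frame(
          ligand_atom_index = li, receptor_atom_index = ri,
          residue_label = lab, distance = dist, angle = NA_real_,
          direction = "LIGAND_ACCEPTOR", stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$ligand_atom_index, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_contacts", class(out))
  out
}
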