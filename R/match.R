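#' Perceive pharmacophore feature points of a molecule
#'
#' One DONOR point per N/O heavy atom bearing an explicit O-H/N-H hydrogen
#' and one ACCEPTOR point per acceptor-qualified N/O (pyrrole-type aromatic
#' N-H excluded), each positioned at the heavy atom. A hydroxyl oxygen
#' therefore contributes both a donor and an acceptor point.
#'
#' @param mol a [molecule_record] with 3D coordinates.
#' @return data.frame with columns `kind`, `x`, `y`, `z`, `atom_index`
#'   (possibly zero rows).
#' @export
perceive_features <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("molecule has no valid 3D coordinates")
  if (nrow(xyz) > 1L && all(abs(sweep(xyz, 2, xyz[1, ])) < 1e-12))
    stop("molecule has no 3D coordinates (all atoms coincident)")
  elem <- mol$atoms$element
  hyd <- .attached_hydrogens(mol)
  arom <- .aromatic_flags(mol)
  n_h <- vapply(hyd, length, integer(1))
  is_no <- elem %in% c("N", "O")
  don <- which(is_no & n_h > 0L)
  acc <- which(is_no & !(elem == "N" & arom & n_h > 0L))
  out <- data.frame(
    kind = c(rep("DONOR", length(don)), rep("ACCEPTOR", length(acc))),
    x = c(xyz[don, 1], xyz[acc, 1]),
    y = c(xyz[don, 2], xyz[acc, 2]),
    z = c(xyz[don, 3], xyz[acc, 3]),
    atom_index = c(don, acc),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.MAX_ASSIGNMENTS <- 1e6

#' Match a molecule's features against a pharmacophore model
#'
#' Enumerates every injective, kind-respecting assignment of model features
#' to molecule feature points, superposes each candidate correspondence with
#' the Kabsch algorithm, and returns the minimum-RMSD assignment. The
#' molecule matches when every model feature is assigned and the minimum
#' RMSD does not exceed `rmsd_cutoff`. Ties are broken by the
#' lexicographically smallest correspondence (atom-index vector in model
#' feature order). A molecule lacking enough features of some kind is
#' unmatched (RMSD absent), not an error.
#'
#' @param features feature points from [perceive_features()].
#' @param model a [pharmacophore_model].
#' @param rmsd_cutoff acceptance cutoff in Angstrom (default 0.6).
#' @param conformer_id conformer id recorded in the result.
#' @return list of class `match_result`: `matched`, `rmsd` (NA when no full
#'   assignment exists), `correspondence` (named integer vector, feature
#'   label -> atom index, or NULL), `conformer_id`.
#' @export
match_pharmacophore <- function(features, model, rmsd_cutoff = 0.6,
                                conformer_id = 1L) {
  stopifnot(inherits(model, "pharmacophore_model"), rmsd_cutoff > 0)
  mf <- model$features
  ord <- c(which(mf$kind == "DONOR"), which(mf$kind == "ACCEPTOR"))
  mf <- mf[ord, , drop = FALSE]
  k_d <- sum(mf$kind == "DONOR")
  k_a <- sum(mf$kind == "ACCEPTOR")
  don <- features[features$kind == "DONOR", , drop = FALSE]
  acc <- features[features$kind == "ACCEPTOR", , drop = FALSE]
  no_match <- structure(list(matched = FALSE, rmsd = NA_real_,
                             correspondence = NULL,
                             conformer_id = as.integer(conformer_id)),
                        class = "match_result")
  if (nrow(don) < k_d || nrow(acc) < k_a) return(no_match)
  n_assign <- prod(seq.int(nrow(don), length.out = k_d, by = -1)) *
    prod(seq.int(nrow(acc), length.out = k_a, by = -1))
  if (n_assign > .MAX_ASSIGNMENTS)
    stop(sprintf("correspondence search too large (%.3g assignments; limit %g)",
                 n_assign, .MAX_ASSIGNMENTS))
  M <- as.matrix(mf[, c("x", "y", "z")])
  don_xyz <- as.matrix(don[, c("x", "y", "z")])
  acc_xyz <- as.matrix(acc[, c("x", "y", "z")])
  res <- .match_core(M, don_xyz, acc_xyz, k_d, k_a,
                     as.integer(don$atom_index),
                     as.integer(acc$atom_index))
  if (is.na(res$rmsd)) return(no_match)
  best <- res$rmsd
  corr <- stats::setNames(res$atoms, mf$label)
  structure(list(matched = best <= rmsd_cutoff, rmsd = best,
                 correspondence = corr,
                 conformer_id = as.integer(conformer_id)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched)
    cat(sprintf("<match_result> matched, RMSD %.4f A (conformer %d)\n",
                x$rmsd, x$conformer_id))
  else if (is.na(x$rmsd))
    cat("<match_result> unmatched (insufficient features)\n")
  else
    cat(sprintf("<match_result> unmatched, best RMSD %.4f A\n", x$rmsd))
  invisible(x)
}

# best match over all conformers of one compound (list of molecule_record
# sharing an id); returns the lowest-RMSD conformer's match_result
match_molecule <- function(conformers, model, rmsd_cutoff = 0.6) {
  best <- NULL
  for (mol in conformers) {
    fp <- perceive_features(mol)
    res <- match_pharmacophore(fp, model, rmsd_cutoff, mol$conformer_id)
    if (is.null(best) ||
        (!is.na(res$rmsd) && (is.na(best$rmsd) || res$rmsd < best$rmsd)))
      best <- res
  }
  best
}
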