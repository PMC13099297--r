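#' Run the hierarchical virtual-screening funnel
#'
#' Stages, in fixed order: descriptor computation, Lipinski rule-of-five
#' filtering, feature perception, all-feature pharmacophore matching.
#' Multi-conformer records (same id, several conformer ids) are matched
#' per conformer and the best conformer is reported. Hits are ranked by
#' ascending best RMSD. The run is deterministic given its inputs.
#'
#' @param library list of [molecule_record]s (possibly several conformers
#'   per id).
#' @param model a [pharmacophore_model].
#' @param rmsd_cutoff match acceptance cutoff in Angstrom (default 0.6).
#' @return object of class `funnel_report`: counts `n_input`, `n_druglike`,
#'   `n_pharm_hits` and a `per_compound` data.frame (id, stage, mw, hbd,
#'   hba, logp, lipinski, best_rmsd, matched, conformer_id) covering every
#'   input compound, hits first in RMSD order.
#' @export
run_funnel <- function(library, model, rmsd_cutoff = 0.6) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (length(library) == 0L) {
    rep_ <- data.frame(id = character(), stage = character(),
                       mw = numeric(), hbd = integer(), hba = integer(),
                       logp = numeric(), lipinski = logical(),
                       best_rmsd = numeric(), matched = logical(),
                       conformer_id = integer(), stringsAsFactors = FALSE)
    return(structure(list(n_input = 0L, n_druglike = 0L, n_pharm_hits = 0L,
                          per_compound = rep_, rmsd_cutoff = rmsd_cutoff),
                     class = "funnel_report"))
  }
  ids <- vapply(library, `[[`, "", "id")
  by_id <- split(library, factor(ids, levels = unique(ids)))
  rows <- lapply(by_id, function(confs) {
    d <- compute_descriptors(confs[[1]])
    lip <- lipinski_pass(d)
    row <- data.frame(id = confs[[1]]$id, stage = "input",
                      mw = d$mw, hbd = d$hbd, hba = d$hba, logp = d$logp,
                      lipinski = lip, best_rmsd = NA_real_,
                      matched = FALSE, conformer_id = NA_integer_,
                      stringsAsFactors = FALSE)
    if (!lip) return(row)
    row$stage <- "druglike"
    res <- match_molecule(confs, model, rmsd_cutoff)
    row$best_rmsd <- res$rmsd
    row$matched <- res$matched
    row$conformer_id <- res$conformer_id
    if (res$matched) row$stage <- "hit"
    row
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  # hits first, ascending RMSD; then druglike, then the rest, input order
  key <- match(per$stage, c("hit", "druglike", "input"))
  per <- per[order(key, ifelse(per$stage == "hit", per$best_rmsd, NA),
                   seq_len(nrow(per)), na.last = TRUE), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(n_input = length(by_id),
                 n_druglike = sum(per$lipinski),
                 n_pharm_hits = sum(per$matched),
                 per_compound = per, rmsd_cutoff = rmsd_cutoff),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> hierarchical virtual screen\n")
  cat(sprintf("  input compounds : %d\n", x$n_input))
  cat(sprintf("  drug-like       : %d\n", x$n_druglike))
  cat(sprintf("  pharmacophore hits (RMSD <= %.2f A): %d\n",
              x$rmsd_cutoff, x$n_pharm_hits))
  hits <- x$per_compound[x$per_compound$stage == "hit", , drop = FALSE]
  if (nrow(hits) > 0) {
    cat("  top hits:\n")
    top <- utils::head(hits, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-12s RMSD %.4f A\n", top$id[i], top$best_rmsd[i]))
  }
  invisible(x)
}

#' Write a funnel report as CSV
#'
#' Columns: id, stage, mw, hbd, hba, logp, lipinski, best_rmsd, matched,
#' conformer_id.
#'
#' @param report a `funnel_report`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_funnel_report <- function(report, path) {
  stopifnot(inherits(report, "funnel_report"))
  utils::write.csv(report$per_compound, path, row.names = FALSE)
  invisible(path)
}
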