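#' Guener-Henry goodness-of-hit statistics
#'
#' Computes the full enrichment bookkeeping of a decoy-set validation from
#' the four confusion counts: D molecules screened in total, of which A are
#' known actives; the model retrieves Ht hits, of which Ha are active.
#' Derived statistics are the percent yield of actives `100*Ha/Ht`, the
#' percent ratio of actives recalled `100*Ha/A`, the enrichment factor
#' `E = (Ha*D)/(Ht*A)`, false negatives `A - Ha`, false positives
#' `Ht - Ha`, and the Guener-Henry score
#' \deqn{GH = \frac{Ha\,(3A + Ht)}{4\,Ht\,A}\left(1 - \frac{Ht - Ha}{D - A}\right)}
#' which is 0 for the null model (no active retrieved) and 1 for the ideal
#' model (all actives and nothing else); a GH above 0.7 is conventionally
#' taken to indicate a reliable pharmacophore model.
#'
#' When `Ht = 0` the yield and E are undefined (flagged `NA`) and GH is 0.
#' Raw unrounded values are stored; the printed view rounds yield/ratio to
#' whole percent, E to the nearest integer and GH to two decimals.
#'
#' @param D total molecules in the screened database.
#' @param A total actives in the database (0 < A < D).
#' @param Ht total hits retrieved.
#' @param Ha active hits retrieved (Ha <= min(Ht, A)).
#' @return object of class `enrichment_stats`.
#' @export
compute_enrichment <- function(D, A, Ht, Ha) {
  D <- as.numeric(D); A <- as.numeric(A)
  Ht <- as.numeric(Ht); Ha <- as.numeric(Ha)
  if (A <= 0 || D <= A) stop("need D > A > 0")
  if (Ht < 0 || Ha < 0) stop("counts must be non-negative")
  if (Ha > Ht) stop("active hits Ha cannot exceed total hits Ht")
  if (Ha > A) stop("active hits Ha cannot exceed total actives A")
  if (Ht > D) stop("total hits Ht cannot exceed database size D")
  if (Ht - Ha > D - A)
    stop("false positives (Ht - Ha) cannot exceed the inactives (D - A)")
  if (Ht > 0) {
    yield_pct <- 100 * Ha / Ht
    E <- (Ha * D) / (Ht * A)
    gh <- (Ha * (3 * A + Ht) / (4 * Ht * A)) *
      (1 - (Ht - Ha) / (D - A))
  } else {
    yield_pct <- NA_real_
    E <- NA_real_
    gh <- 0
  }
  structure(list(
    D = D, A = A, Ht = Ht, Ha = Ha,
    yield_pct = yield_pct, ratio_pct = 100 * Ha / A, E = E,
    false_negatives = A - Ha, false_positives = Ht - Ha, GH = gh,
    rounded = list(
      yield_pct = if (is.na(yield_pct)) NA_real_ else
        round_half_away(yield_pct),
      ratio_pct = round_half_away(100 * Ha / A),
      E = if (is.na(E)) NA_real_ else round_half_away(E),
      GH = round_half_away(gh, 2))),
    class = "enrichment_stats")
}

#' @export
print.enrichment_stats <- function(x, ...) {
  cat("<enrichment_stats> decoy-set validation (GH scoring)\n")
  cat(sprintf("  Total molecules in the database (D)  %g\n", x$D))
  cat(sprintf("  Total actives in the database (A)    %g\n", x$A))
  cat(sprintf("  Total hits (Ht)                      %g\n", x$Ht))
  cat(sprintf("  Active hits (Ha)                     %g\n", x$Ha))
  cat(sprintf("  %% Yield of actives [(Ha/Ht)x100]     %s\n",
              if (is.na(x$rounded$yield_pct)) "undefined (Ht = 0)" else
                sprintf("%g%%", x$rounded$yield_pct)))
  cat(sprintf("  %% Ratio of actives [(Ha/A)x100]      %g%%\n",
              x$rounded$ratio_pct))
  cat(sprintf("  Enrichment factor (E)                %s\n",
              if (is.na(x$rounded$E)) "undefined (Ht = 0)" else
                sprintf("%g", x$rounded$E)))
  cat(sprintf("  False negatives [A-Ha]               %g\n",
              x$false_negatives))
  cat(sprintf("  False positives [Ht-Ha]              %g\n",
              x$false_positives))
  cat(sprintf("  Goodness of hit score (GH)           %.2f\n",
              x$rounded$GH))
  invisible(x)
}

#' Validate a pharmacophore model against an active/decoy set
#'
#' Screens every compound of a labelled test set with
#' [match_pharmacophore()] at the given RMSD cutoff and summarises the
#' outcome as Guener-Henry statistics: D = actives + decoys, A = actives,
#' Ht = matched compounds, Ha = matched actives.
#'
#' @param model a [pharmacophore_model].
#' @param actives list of [molecule_record]s known to be active.
#' @param decoys list of presumed-inactive [molecule_record]s; ids must be
#'   disjoint from the actives.
#' @param rmsd_cutoff match cutoff in Angstrom (default 0.6).
#' @return an `enrichment_stats` object; the per-compound matched flags are
#'   attached as attribute `confusion`.
#' @export
evaluate_model <- function(model, actives, decoys, rmsd_cutoff = 0.6) {
  if (length(actives) == 0L) stop("need at least one active")
  aid <- unique(vapply(actives, `[[`, "", "id"))
  did <- unique(vapply(decoys, `[[`, "", "id"))
  if (length(intersect(aid, did)) > 0)
    stop("active and decoy ids overlap: ",
         paste(utils::head(intersect(aid, did), 3), collapse = ", "))
  screen_set <- function(mols) {
    ids <- vapply(mols, `[[`, "", "id")
    grp <- split(mols, factor(ids, levels = unique(ids)))
    vapply(grp, function(confs)
      isTRUE(match_molecule(confs, model, rmsd_cutoff)$matched), logical(1))
  }
  m_act <- screen_set(actives)
  m_dec <- if (length(decoys) > 0) screen_set(decoys) else logical()
  stats <- compute_enrichment(D = length(aid) + length(did),
                              A = length(aid),
                              Ht = sum(m_act) + sum(m_dec),
                              Ha = sum(m_act))
  attr(stats, "confusion") <- list(active_matched = m_act,
                                   decoy_matched = m_dec)
  stats
}

#' Write enrichment statistics as JSON
#'
#' The file carries both raw and table-rounded fields.
#'
#' @param stats an `enrichment_stats`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_enrichment_json <- function(stats, path) {
  stopifnot(inherits(stats, "enrichment_stats"))
  obj <- unclass(stats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
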