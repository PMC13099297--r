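# standard atomic weights (IUPAC 2021, conventional values)
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Br = 79.904, I = 126.904
)

# Crippen-type atom-contribution logP increments. Typing is deliberately
# coarse (element + attached hydrogens + aromatic flag); values follow the
# published atom-contribution scheme's magnitudes for the common types.
.logp_contrib <- function(element, n_h, aromatic, has_double_o) {
  switch(element,
    C = if (aromatic) 0.294 else 0.141,
    H = 0.123,                    # overridden to -0.268 when on N/O
    N = if (aromatic) -0.493 else -1.019,
    O = if (has_double_o) -0.117 else if (n_h > 0) -0.389 else -0.146,
    F = 0.425, Cl = 0.642, Br = 0.882, I = 1.159,
    S = 0.255, P = 0.274,
    0.0)
}

#' Molecular descriptors for drug-likeness filtering
#'
#' Computes the four rule-of-five descriptors from an explicit-hydrogen
#' molecule record: molecular weight (sum of standard atomic weights),
#' hydrogen-bond donor count (number of N/O heavy atoms bearing at least one
#' explicit hydrogen), hydrogen-bond acceptor count (number of N and O atoms,
#' excluding pyrrole-type nitrogens, i.e. aromatic N carrying an H), and a
#' Crippen-type atom-contribution octanol/water logP estimate.
#'
#' Donor counting requires explicit hydrogens; molecules written by this
#' package always carry them.
#'
#' @param mol a [molecule_record].
#' @return object of class `descriptor_set`: list with `mw` (Dalton), `hbd`,
#'   `hba` (counts) and `logp` (dimensionless).
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  elem <- mol$atoms$element
  unknown <- setdiff(unique(elem), names(.atomic_weights))
  if (length(unknown) > 0)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  mw <- sum(.atomic_weights[elem])

  hyd <- .attached_hydrogens(mol)
  arom <- .aromatic_flags(mol)
  n_h <- vapply(hyd, length, integer(1))
  is_no <- elem %in% c("N", "O")
  hbd <- sum(is_no & n_h > 0L)
  pyrrole_type <- elem == "N" & arom & n_h > 0L
  hba <- sum(is_no & !pyrrole_type)

  # double-bonded O (carbonyl-type) for the logP table
  dbl_o <- rep(FALSE, length(elem))
  if (nrow(mol$bonds) > 0L) {
    db <- mol$bonds[mol$bonds$order == 2L, , drop = FALSE]
    dbl_o[unique(c(db$a1, db$a2))] <- TRUE
  }
  # which heavy atom each H sits on (for the heteroatom-H correction)
  h_on_hetero <- rep(FALSE, length(elem))
  for (a in which(is_no)) h_on_hetero[hyd[[a]]] <- TRUE
  logp <- 0
  for (i in seq_along(elem)) {
    if (elem[i] == "H" && h_on_hetero[i]) {
      logp <- logp - 0.268
    } else {
      logp <- logp + .logp_contrib(elem[i], n_h[i], arom[i],
                                   elem[i] == "O" && dbl_o[i])
    }
  }
  structure(list(mw = mw, hbd = hbd, hba = hba, logp = logp),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("MW %.2f  HBD %d  HBA %d  LogP %.2f\n",
              x$mw, x$hbd, x$hba, x$logp))
  invisible(x)
}

#' Lipinski rule-of-five filter
#'
#' A compound passes when all four criteria hold (inclusive bounds):
#' MW <= 500 Da, HBD <= 5, HBA <= 10 and LogP <= 5.
#'
#' @param d a `descriptor_set` (or list with mw, hbd, hba, logp).
#' @return logical.
#' @export
lipinski_pass <- function(d) {
  stopifnot(is.finite(d$mw), d$mw > 0, d$hbd >= 0, d$hba >= 0)
  d$mw <= 500 && d$hbd <= 5 && d$hba <= 10 && d$logp <= 5
}

# round half away from zero, matching the printed-table convention
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
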