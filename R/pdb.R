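#' Read a receptor-ligand complex from a PDB file
#'
#' Splits a PDB structure into receptor (polymer `ATOM` records) and ligand
#' (the `HETATM` residue named by `ligand_selector`). Waters (HOH/WAT/H2O/
#' DOD) are excluded from both sets, as are any other het groups; alternate
#' locations other than '' or 'A' are dropped.
#'
#' @param path path to a PDB file.
#' @param ligand_selector residue name of the bound ligand (e.g. `"GAL"`).
#' @return an object of class `complex_structure` with data.frame components
#'   `receptor` (element, x, y, z, resid, resno, chain, atom_name) and
#'   `ligand` (element, x, y, z, atom_name).
#' @export
read_pdb_complex <- function(path, ligand_selector) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  waters <- c("HOH", "WAT", "H2O", "DOD")
  at <- at[!(at$resid %in% waters), , drop = FALSE]
  elem <- at$elesy
  missing_el <- is.na(elem) | !nzchar(trimws(elem))
  elem[missing_el] <- substr(gsub("[0-9]", "", trimws(at$elety[missing_el])), 1, 1)
  elem <- trimws(elem)
  # normalise case: "CA" column element stays e.g. "C", "FE" -> "Fe"
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 4)))
  rec <- at$type == "ATOM"
  lig <- at$type == "HETATM" & at$resid == ligand_selector
  if (!any(lig)) stop("ligand not found: no HETATM residue named '",
                      ligand_selector, "'")
  receptor <- data.frame(element = elem[rec],
                         x = at$x[rec], y = at$y[rec], z = at$z[rec],
                         resid = at$resid[rec], resno = at$resno[rec],
                         chain = at$chain[rec], atom_name = trimws(at$elety[rec]),
                         stringsAsFactors = FALSE)
  ligand <- data.frame(element = elem[lig],
                       x = at$x[lig], y = at$y[lig], z = at$z[lig],
                       atom_name = trimws(at$elety[lig]),
                       stringsAsFactors = FALSE)
  complex_structure(receptor, ligand)
}

#' Construct a complex_structure
#'
#' @param receptor receptor atom table (element, x, y, z, resid, resno,
#'   chain, atom_name).
#' @param ligand ligand atom table (element, x, y, z, atom_name).
#' @return object of class `complex_structure`.
#' @export
complex_structure <- function(receptor, ligand) {
  receptor <- as.data.frame(receptor, stringsAsFactors = FALSE)
  ligand <- as.data.frame(ligand, stringsAsFactors = FALSE)
  if (nrow(ligand) < 1L) stop("ligand has no atoms")
  for (df in list(receptor, ligand))
    if (nrow(df) > 0 && !all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
      stop("positions must be finite")
  if (nrow(receptor) > 0 && !is.numeric(receptor$resno))
    stop("residue numbers must be numeric")
  structure(list(receptor = receptor, ligand = ligand),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure> receptor: %d atoms (%d residues); ligand: %d atoms\n",
              nrow(x$receptor),
              length(unique(paste(x$receptor$chain, x$receptor$resno))),
              nrow(x$ligand)))
  invisible(x)
}
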