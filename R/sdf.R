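#' Construct a molecule record
#'
#' A `molecule_record` is the in-memory form of one SDF molecule block:
#' an identifier, an atom table (element symbol plus Cartesian coordinates
#' in Angstrom), a bond table (atom index pair plus bond order), and a
#' conformer id so that multi-conformer libraries can carry several records
#' per compound id.
#'
#' @param id compound identifier (non-empty string).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`.
#' @param bonds data.frame with columns `a1`, `a2`, `order` (may have zero
#'   rows for a single atom).
#' @param conformer_id integer conformer index (default 1).
#' @param source_line line in the source file where the block started, or
#'   `NA` for programmatically built molecules.
#' @return an object of class `molecule_record`.
#' @export
molecule_record <- function(id, atoms, bonds = NULL, conformer_id = 1L,
                            source_line = NA_integer_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) < 1L) stop("molecule must have at least one atom")
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms))) stop("atoms needs columns element, x, y, z")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (!all(c("a1", "a2", "order") %in% names(bonds)))
      stop("bonds needs columns a1, a2, order")
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1L | idx > nrow(atoms)))
      stop("bond atom indices out of range")
  }
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 conformer_id = as.integer(conformer_id),
                 source_line = as.integer(source_line)),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s (conformer %d): %d atoms, %d bonds\n",
              x$id, x$conformer_id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# hydrogens attached (by an explicit bond) to each heavy atom; returns a
# list indexed by atom number with integer vectors of bonded H indices
.attached_hydrogens <- function(mol) {
  n <- nrow(mol$atoms)
  out <- vector("list", n)
  if (nrow(mol$bonds) == 0L) return(out)
  elem <- mol$atoms$element
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (elem[b] == "H" && elem[a] != "H") out[[a]] <- c(out[[a]], b)
    if (elem[a] == "H" && elem[b] != "H") out[[b]] <- c(out[[b]], a)
  }
  out
}

# TRUE for atoms participating in at least one aromatic (order 4) bond
.aromatic_flags <- function(mol) {
  n <- nrow(mol$atoms)
  ar <- rep(FALSE, n)
  if (nrow(mol$bonds) > 0L) {
    arb <- mol$bonds[mol$bonds$order == 4L, , drop = FALSE]
    ar[unique(c(arb$a1, arb$a2))] <- TRUE
  }
  ar
}

#' Read an SDF (V2000) library
#'
#' Parses a multi-molecule SDF file into a list of [molecule_record]s, one
#' per molecule block in file order. Blocks that fail to parse are skipped
#' with a warning naming the line where the block started; V3000 blocks are
#' rejected outright. The conformer id is taken from a `conformer_id` data
#' field when present, else 1.
#'
#' @param path path to an SDF file.
#' @return list of `molecule_record` objects; the ids of skipped blocks are
#'   attached as attribute `skipped` (data.frame of source_line, reason).
#' @export
read_sdf_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    warning("empty SDF file: ", path)
    out <- list()
    attr(out, "skipped") <- data.frame(source_line = integer(),
                                       reason = character())
    return(out)
  }
  seps <- grep("^\\$\\$\\$\\$", lines)
  if (length(seps) == 0L || seps[length(seps)] < length(lines)) {
    # tolerate a missing trailing separator
    seps <- c(seps, length(lines) + 1L)
  }
  starts <- c(1L, head(seps, -1L) + 1L)
  records <- list()
  skipped <- data.frame(source_line = integer(), reason = character())
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- seps[i] - 1L
    block <- lines[seq.int(s, min(e, length(lines)))]
    if (all(!nzchar(trimws(block)))) next
    rec <- tryCatch(.parse_sdf_block(block, s),
                    error = function(err) conditionMessage(err))
    if (is.character(rec)) {
      warning(sprintf("skipping unparseable SDF block at line %d: %s", s, rec))
      skipped <- rbind(skipped,
                       data.frame(source_line = s, reason = rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  attr(records, "skipped") <- skipped
  records
}

.parse_sdf_block <- function(block, source_line) {
  if (length(block) < 4L) stop("block too short")
  counts <- block[4L]
  if (grepl("V3000", counts)) stop("V3000 records are not supported")
  if (!grepl("V2000", counts)) stop("missing V2000 version tag")
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L)
    stop("bad counts line")
  if (length(block) < 4L + natoms + nbonds) stop("truncated block")
  at <- block[4L + seq_len(natoms)]
  x <- suppressWarnings(as.numeric(substr(at, 1L, 10L)))
  y <- suppressWarnings(as.numeric(substr(at, 11L, 20L)))
  z <- suppressWarnings(as.numeric(substr(at, 21L, 30L)))
  el <- trimws(substr(at, 31L, 34L))
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(el)))
    stop("malformed atom line")
  atoms <- data.frame(element = el, x = x, y = y, z = z,
                      stringsAsFactors = FALSE)
  bonds <- NULL
  if (nbonds > 0L) {
    bt <- block[4L + natoms + seq_len(nbonds)]
    a1 <- suppressWarnings(as.integer(substr(bt, 1L, 3L)))
    a2 <- suppressWarnings(as.integer(substr(bt, 4L, 6L)))
    ord <- suppressWarnings(as.integer(substr(bt, 7L, 9L)))
    if (any(is.na(a1) | is.na(a2) | is.na(ord)))
      stop("malformed bond line")
    bonds <- data.frame(a1 = a1, a2 = a2, order = ord)
  }
  id <- trimws(block[1L])
  if (!nzchar(id)) id <- sprintf("mol_L%d", source_line)
  conformer_id <- 1L
  fields <- .parse_sdf_datafields(block)
  if ("conformer_id" %in% names(fields)) {
    ci <- suppressWarnings(as.integer(fields[["conformer_id"]]))
    if (!is.na(ci)) conformer_id <- ci
  }
  rec <- molecule_record(id, atoms, bonds, conformer_id, source_line)
  rec$data <- fields
  rec
}

.parse_sdf_datafields <- function(block) {
  tags <- grep("^> *<", block)
  fields <- character()
  for (t in tags) {
    nm <- sub("^> *<([^>]+)>.*$", "\\1", block[t])
    val <- if (t + 1L <= length(block)) block[t + 1L] else ""
    fields[[nm]] <- val
  }
  fields
}

#' Write molecules to an SDF (V2000) file
#'
#' Coordinates are written at the format's 4-decimal precision; any named
#' entries of a record's `data` field become SDF data fields.
#'
#' @param mols a `molecule_record` or list of them.
#' @param path output path, or `NULL` to return the text invisibly.
#' @return invisibly, the SDF text as a character vector of lines.
#' @export
write_sdf_library <- function(mols, path = NULL) {
  if (inherits(mols, "molecule_record")) mols <- list(mols)
  out <- unlist(lapply(mols, .format_sdf_block), use.names = FALSE)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

.format_sdf_block <- function(mol) {
  natoms <- nrow(mol$atoms)
  nbonds <- nrow(mol$bonds)
  lines <- c(mol$id, "  pharmscreen", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                            natoms, nbonds))
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element))
  if (nbonds > 0L)
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$a1, mol$bonds$a2,
                              mol$bonds$order))
  lines <- c(lines, "M  END")
  fields <- mol$data
  fields[["conformer_id"]] <- as.character(mol$conformer_id)
  for (nm in names(fields))
    lines <- c(lines, sprintf("> <%s>", nm), fields[[nm]], "")
  c(lines, "$$$$")
}
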