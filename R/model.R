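#' Construct a pharmacophore model
#'
#' @param features data.frame with columns `label`, `kind` ("DONOR" or
#'   "ACCEPTOR"), `x`, `y`, `z` (A), `tolerance` (A) and a list-column
#'   `provenance` of residue labels.
#' @param source free-text provenance for the model.
#' @return object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features, source = "") {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) < 1L) stop("model must have at least one feature")
  if (anyDuplicated(features$label))
    stop("duplicate feature labels: ",
         paste(unique(features$label[duplicated(features$label)]),
               collapse = ", "))
  if (!all(features$kind %in% c("DONOR", "ACCEPTOR")))
    stop("feature kind must be DONOR or ACCEPTOR")
  if (any(features$tolerance <= 0)) stop("tolerances must be positive")
  if (!all(is.finite(as.matrix(features[, c("x", "y", "z")]))))
    stop("feature positions must be finite")
  if (is.null(features$provenance))
    features$provenance <- replicate(nrow(features), character(),
                                     simplify = FALSE)
  structure(list(features = features, source = source),
            class = "pharmacophore_model")
}

#' Build a structure-based pharmacophore model from hydrogen-bond contacts
#'
#' One feature is created per distinct (ligand atom, direction) pair among
#' the contacts, positioned at the ligand heavy atom. Contacts from the same
#' ligand atom and direction to several residues merge into one feature
#' whose provenance aggregates all residue labels. A ligand hydroxyl that
#' both donates and accepts yields two co-located features. Labels F1, F2,
#' ... are assigned with donors first, each group in ligand-atom-index
#' order.
#'
#' @param contacts contacts from [detect_hbonds()].
#' @param complex the [complex_structure] the contacts refer to.
#' @param tolerance feature tolerance radius in Angstrom (default 1.0).
#' @param source free-text provenance stored on the model.
#' @return a [pharmacophore_model].
#' @export
build_model <- function(contacts, complex, tolerance = 1.0,
                        source = "structure-based pharmacophore") {
  if (is.null(contacts) || nrow(contacts) == 0L)
    stop("cannot build a model from an empty contact list")
  stopifnot(inherits(complex, "complex_structure"), tolerance > 0)
  key <- paste(contacts$ligand_atom_index, contacts$direction)
  groups <- split(seq_len(nrow(contacts)), key)
  feats <- do.call(rbind, lapply(groups, function(ix) {
    li <- contacts$ligand_atom_index[ix[1]]
    dir <- contacts$direction[ix[1]]
    data.frame(
      kind = if (dir == "LIGAND_DONOR") "DONOR" else "ACCEPTOR",
      ligand_atom_index = li,
      x = complex$ligand$x[li], y = complex$ligand$y[li],
      z = complex$ligand$z[li], tolerance = tolerance,
      stringsAsFactors = FALSE)
  }))
  prov <- lapply(groups, function(ix)
    unique(contacts$residue_label[ix]))
  ord <- order(feats$kind != "DONOR", feats$ligand_atom_index)
  feats <- feats[ord, , drop = FALSE]
  prov <- prov[ord]
  feats$label <- paste0("F", seq_len(nrow(feats)))
  feats$provenance <- prov
  rownames(feats) <- NULL
  pharmacophore_model(
    feats[, c("label", "kind", "x", "y", "z", "tolerance", "provenance",
              "ligand_atom_index")],
    source = source)
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  f <- x$features
  cat(sprintf("<pharmacophore_model> %d features (%d donor, %d acceptor)\n",
              nrow(f), sum(f$kind == "DONOR"), sum(f$kind == "ACCEPTOR")))
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-3s %-8s (%7.3f, %7.3f, %7.3f)  r=%.2f A  [%s]\n",
                f$label[i], f$kind[i], f$x[i], f$y[i], f$z[i],
                f$tolerance[i], paste(f$provenance[[i]], collapse = ", ")))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

.MODEL_SCHEMA_VERSION <- 1L

#' Save or load a pharmacophore model as JSON
#'
#' The schema is versioned and the round-trip is lossless:
#' `{version, source, features: [{label, kind, position, tolerance,
#' provenance}]}`.
#'
#' @param model a [pharmacophore_model].
#' @param path file path.
#' @return `load_model` returns a [pharmacophore_model]; `save_model`
#'   returns the path invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  f <- model$features
  feats <- lapply(seq_len(nrow(f)), function(i) list(
    label = f$label[i], kind = f$kind[i],
    position = c(f$x[i], f$y[i], f$z[i]),
    tolerance = f$tolerance[i],
    provenance = as.list(f$provenance[[i]])))
  obj <- list(version = .MODEL_SCHEMA_VERSION, source = model$source,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$version) || obj$version != .MODEL_SCHEMA_VERSION)
    stop("model schema version mismatch: expected ",
         .MODEL_SCHEMA_VERSION, ", got ", obj$version)
  if (length(obj$features) < 1L) stop("model file has no features")
  feats <- do.call(rbind, lapply(obj$features, function(ft) data.frame(
    label = ft$label, kind = ft$kind,
    x = ft$position[[1]], y = ft$position[[2]], z = ft$position[[3]],
    tolerance = ft$tolerance, stringsAsFactors = FALSE)))
  feats$provenance <- lapply(obj$features, function(ft)
    unlist(ft$provenance) %||% character())
  pharmacophore_model(feats, source = obj$source %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
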