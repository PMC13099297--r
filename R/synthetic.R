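# run expr with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Specification of a synthetic receptor-ligand complex
#'
#' Describes a toy complex with a known, planted set of receptor-ligand
#' hydrogen bonds, emulating a monosaccharide bound in a polar site. Each
#' planted contact is placed strictly inside (`geometry_margin > 0`) or
#' strictly outside (`geometry_margin < 0`) the default hydrogen-bond
#' criteria, and all non-planted polar pairs are guaranteed to lie outside,
#' so the planted list is an exact oracle for [detect_hbonds()].
#'
#' @param n_planted_contacts number of planted hydrogen bonds.
#' @param directions character vector (length `n_planted_contacts`) of
#'   `"LIGAND_DONOR"` / `"LIGAND_ACCEPTOR"`.
#' @param geometry_margin Angstrom inside (+) or outside (-) the distance
#'   criterion; must be non-zero.
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @param n_waters number of far-away water molecules to include (exercises
#'   water removal on reading).
#' @return object of class `complex_spec`.
#' @export
complex_spec <- function(n_planted_contacts,
                         directions = rep("LIGAND_DONOR", n_planted_contacts),
                         geometry_margin = 0.3, seed = 1, n_waters = 0) {
  stopifnot(n_planted_contacts >= 1,
            length(directions) == n_planted_contacts,
            all(directions %in% c("LIGAND_DONOR", "LIGAND_ACCEPTOR")),
            geometry_margin != 0)
  structure(list(n_planted_contacts = as.integer(n_planted_contacts),
                 directions = directions,
                 geometry_margin = geometry_margin,
                 seed = as.integer(seed), n_waters = as.integer(n_waters)),
            class = "complex_spec")
}

# residue vocabulary of the galactose-like polar site
.acceptor_residues <- list(c("GLU", "88", "OE1"), c("GLN", "69", "OE1"),
                           c("ASN", "260", "OD1"), c("GLN", "428", "OE1"))
.donor_residues <- list(c("LYS", "294", "NZ"), c("SER", "91", "OG"))

#' Generate a synthetic receptor-ligand complex as PDB text
#'
#' Builds a polyol-like ligand (oxygens on a ring scaffold) surrounded by
#' minimal capped residues whose polar side-chain atoms realise exactly the
#' planted hydrogen bonds of the spec. Planted contacts sit
#' `geometry_margin` Angstrom inside (or outside, for negative margins) the
#' distance criterion with ideal collinear D-H...A geometry; the generator
#' asserts that every non-planted ligand/receptor polar pair is strictly
#' outside the criteria and errors on an infeasible spec.
#'
#' @param spec a [complex_spec].
#' @param path optional file to write the PDB text to.
#' @param criteria the [hbond_criteria] the guarantee is stated against
#'   (default [hbond_criteria()]).
#' @return list with `pdb` (character vector of PDB lines), `contacts`
#'   (ground-truth data.frame: ligand_atom_index, residue_label, direction,
#'   distance), and `path` when written.
#' @export
generate_complex <- function(spec, path = NULL, criteria = hbond_criteria()) {
  stopifnot(inherits(spec, "complex_spec"))
  n <- spec$n_planted_contacts
  with_seed(spec$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    tilt <- stats::runif(n, -0.25, 0.25)   # radians off the ring plane
    r_lig <- 2.5
    theta <- phase + 2 * pi * (seq_len(n) - 1) / max(n, 3)
    u <- cbind(cos(theta) * cos(tilt), sin(theta) * cos(tilt), sin(tilt))
    d_plant <- criteria$max_da_distance - spec$geometry_margin

    lig <- data.frame(element = character(), x = numeric(), y = numeric(),
                      z = numeric(), atom_name = character(),
                      stringsAsFactors = FALSE)
    rec <- data.frame(element = character(), x = numeric(), y = numeric(),
                      z = numeric(), resid = character(), resno = integer(),
                      atom_name = character(), stringsAsFactors = FALSE)
    truth <- data.frame(ligand_atom_index = integer(),
                        residue_label = character(), direction = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
    add_lig <- function(el, p, nm)
      lig[nrow(lig) + 1L, ] <<- list(el, p[1], p[2], p[3], nm)
    add_rec <- function(el, p, resid, resno, nm)
      rec[nrow(rec) + 1L, ] <<- list(el, p[1], p[2], p[3], resid,
                                     as.integer(resno), nm)
    i_acc <- 0L; i_don <- 0L
    used_resno <- integer()
    for (i in seq_len(n)) {
      o_pos <- r_lig * u[i, ]
      add_lig("O", o_pos, sprintf("O%d", i))
      o_idx <- nrow(lig)
      if (spec$directions[i] == "LIGAND_DONOR") {
        i_acc <- i_acc + 1L
        res <- .acceptor_residues[[((i_acc - 1L) %% 4L) + 1L]]
      } else {
        i_don <- i_don + 1L
        res <- .donor_residues[[((i_don - 1L) %% 2L) + 1L]]
      }
      resno <- as.integer(res[2])
      while (resno %in% used_resno) resno <- resno + 500L
      used_resno <- c(used_resno, resno)
      partner <- (r_lig + d_plant) * u[i, ]
      add_rec(substr(res[3], 1, 1), partner, res[1], resno, res[3])
      add_rec("C", (r_lig + d_plant + 1.5) * u[i, ], res[1], resno, "CB")
      add_rec("C", (r_lig + d_plant + 2.9) * u[i, ], res[1], resno, "CA")
      if (spec$directions[i] == "LIGAND_DONOR") {
        # ligand hydroxyl pointing straight at the receptor acceptor
        add_lig("H", (r_lig + 0.96) * u[i, ], sprintf("HO%d", i))
      } else {
        # receptor donor hydrogen pointing straight at the ligand oxygen
        add_rec("H", (r_lig + d_plant - 0.96) * u[i, ], res[1], resno,
                paste0("H", substr(res[3], 2, 3)))
      }
      truth[nrow(truth) + 1L, ] <- list(
        o_idx, .residue_label(res[1], resno), spec$directions[i], d_plant)
    }
    # inert ring scaffold carbons inside the oxygens
    for (i in seq_len(n))
      add_lig("C", (r_lig - 1.43) * u[i, ], sprintf("C%d", i))

    cx <- complex_structure(rec, lig)
    .assert_complex_guarantee(cx, truth, spec, criteria)

    waters <- if (spec$n_waters > 0) {
      wtheta <- stats::runif(spec$n_waters, 0, 2 * pi)
      data.frame(x = 25 * cos(wtheta), y = 25 * sin(wtheta),
                 z = stats::runif(spec$n_waters, -5, 5))
    } else NULL
    pdb <- .format_pdb(rec, lig, waters, spec$seed)
    if (!is.null(path)) writeLines(pdb, path)
    list(pdb = pdb, contacts = truth, path = path)
  })
}

.assert_complex_guarantee <- function(cx, truth, spec, criteria) {
  lig_pol <- which(cx$ligand$element %in% c("N", "O"))
  rec_pol <- which(cx$receptor$element %in% c("N", "O"))
  planted_res <- truth$residue_label
  for (li in lig_pol) {
    for (ri in rec_pol) {
      d <- sqrt(sum((as.numeric(cx$ligand[li, c("x", "y", "z")]) -
                     as.numeric(cx$receptor[ri, c("x", "y", "z")]))^2))
      lab <- .residue_label(cx$receptor$resid[ri], cx$receptor$resno[ri])
      is_planted <- any(truth$ligand_atom_index == li &
                          planted_res == lab)
      if (is_planted) {
        ok <- if (spec$geometry_margin > 0)
          d <= criteria$max_da_distance - spec$geometry_margin + 1e-9
        else d >= criteria$max_da_distance - spec$geometry_margin - 1e-9
        if (!ok) stop("infeasible spec: planted contact violates its margin")
      } else if (d <= criteria$max_da_distance + abs(spec$geometry_margin)) {
        stop("infeasible spec: non-planted polar pair inside criteria (",
             "too many contacts to place without collisions)")
      }
    }
  }
  invisible(TRUE)
}

.format_pdb <- function(rec, lig, waters, seed) {
  fmt <- function(type, serial, name, resid, chain, resno, p, el)
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, resid, chain, resno, p[1], p[2], p[3],
            1.00, 0.00, toupper(el))
  lines <- c(sprintf("REMARK 250 SYNTHETIC COMPLEX SEED %d", seed),
             "REMARK 250 GENERATED BY PHARMSCREEN (NOT AN EXPERIMENTAL STRUCTURE)")
  serial <- 0L
  for (i in seq_len(nrow(rec))) {
    serial <- serial + 1L
    lines <- c(lines, fmt("ATOM", serial, rec$atom_name[i], rec$resid[i],
                          "A", rec$resno[i],
                          c(rec$x[i], rec$y[i], rec$z[i]), rec$element[i]))
  }
  for (i in seq_len(nrow(lig))) {
    serial <- serial + 1L
    lines <- c(lines, fmt("HETATM", serial, lig$atom_name[i], "LIG",
                          "A", 900L,
                          c(lig$x[i], lig$y[i], lig$z[i]), lig$element[i]))
  }
  if (!is.null(waters)) {
    for (i in seq_len(nrow(waters))) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial, "O", "HOH", "A", 1000L + i,
                            c(waters$x[i], waters$y[i], waters$z[i]), "O"))
    }
  }
  c(lines, "END")
}

#' Specification of a synthetic screening library
#'
#' Planted actives carry feature-bearing groups whose perceived feature
#' points equal a random rigid transform of the model's feature positions
#' plus isotropic Gaussian jitter; decoys carry randomised feature sets.
#' Molecular weights are steered into `descriptor_ranges$mw` by inert
#' scaffold carbons; the remaining descriptors follow from the feature
#' composition.
#'
#' @param n_actives,n_decoys library composition.
#' @param jitter_sd per-coordinate Gaussian jitter of active feature points
#'   (Angstrom, >= 0).
#' @param descriptor_ranges list with `mw = c(lo, hi)` (Dalton).
#' @param seed RNG seed.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(n_actives, n_decoys, jitter_sd = 0.1,
                         descriptor_ranges = list(mw = c(320, 480)),
                         seed = 1) {
  stopifnot(n_actives >= 0, n_decoys >= 0, jitter_sd >= 0,
            length(descriptor_ranges$mw) == 2)
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 jitter_sd = jitter_sd,
                 descriptor_ranges = descriptor_ranges,
                 seed = as.integer(seed)),
            class = "library_spec")
}

# realise a set of oxygen feature positions (donor flag per position) as a
# bonded molecule: O (+H for donors) + anchor C per oxygen + scaffold chain
# carbons padding the molecular weight toward mw_target
.realize_molecule <- function(id, o_pos, is_donor, mw_target,
                              conformer_id = 1L, label = NULL) {
  el <- character(); xyz <- list(); b1 <- integer(); b2 <- integer()
  add_atom <- function(e, p) {
    el[length(el) + 1L] <<- e
    xyz[[length(xyz) + 1L]] <<- p
    length(el)
  }
  add_bond <- function(a, b) {
    b1[length(b1) + 1L] <<- a
    b2[length(b2) + 1L] <<- b
  }
  n_o <- nrow(o_pos)
  anchors <- integer(n_o)
  for (i in seq_len(n_o)) {
    oi <- add_atom("O", o_pos[i, ])
    if (is_donor[i]) add_bond(oi, add_atom("H", o_pos[i, ] + 0.96 * .rand_unit()))
    anchors[i] <- add_atom("C", o_pos[i, ] + 1.43 * .rand_unit())
    add_bond(oi, anchors[i])
  }
  if (n_o == 0L) anchors <- add_atom("C", stats::runif(3, -1, 1))
  for (i in seq_along(anchors)[-1]) add_bond(anchors[i - 1L], anchors[i])
  # scaffold carbons toward the target weight, chained off the last anchor
  prev <- anchors[length(anchors)]
  dirv <- .rand_unit()
  mw <- sum(.atomic_weights[el])
  while (mw < mw_target - 12) {
    ci <- add_atom("C", xyz[[prev]] + 1.5 * dirv + 0.4 * .rand_unit())
    add_bond(prev, ci)
    prev <- ci
    mw <- mw + .atomic_weights[["C"]]
  }
  m <- do.call(rbind, xyz)
  mol <- molecule_record(id,
                         data.frame(element = el, x = m[, 1], y = m[, 2],
                                    z = m[, 3], stringsAsFactors = FALSE),
                         data.frame(a1 = b1, a2 = b2,
                                    order = rep(1L, length(b1))),
                         conformer_id)
  if (!is.null(label)) mol$data <- c(label = label)
  mol
}

# a decoy is a drug-sized molecule whose polar groups decorate its own
# scaffold: a persistent random-walk carbon chain sized to the target
# molecular weight, with hydroxyl (donor) and ether-type (acceptor) oxygens
# attached to randomly chosen chain carbons
.realize_decoy <- function(id, n_don, n_acc, mw_target) {
  n_o <- n_don + n_acc
  n_c <- max(3L, ceiling((mw_target - 17 * n_o) / 12))
  pos <- matrix(0, n_c, 3)
  dirv <- .rand_unit()
  for (i in seq_len(n_c - 1L)) {
    dirv <- dirv + 0.8 * .rand_unit()
    dirv <- dirv / sqrt(sum(dirv^2))
    pos[i + 1L, ] <- pos[i, ] + 1.5 * dirv
  }
  el <- rep("C", n_c)
  xyz <- lapply(seq_len(n_c), function(i) pos[i, ])
  b1 <- seq_len(n_c - 1L); b2 <- seq_len(n_c - 1L) + 1L
  hosts <- sample(n_c, min(n_o, n_c))
  is_donor <- rep(c(TRUE, FALSE), c(n_don, n_acc))[seq_along(hosts)]
  for (j in seq_along(hosts)) {
    opos <- pos[hosts[j], ] + 1.43 * .rand_unit()
    xyz[[length(xyz) + 1L]] <- opos
    el <- c(el, "O")
    oi <- length(el)
    b1 <- c(b1, hosts[j]); b2 <- c(b2, oi)
    if (is_donor[j]) {
      xyz[[length(xyz) + 1L]] <- opos + 0.96 * .rand_unit()
      el <- c(el, "H")
      b1 <- c(b1, oi); b2 <- c(b2, length(el))
    }
  }
  m <- do.call(rbind, xyz)
  mol <- molecule_record(id,
                         data.frame(element = el, x = m[, 1], y = m[, 2],
                                    z = m[, 3], stringsAsFactors = FALSE),
                         data.frame(a1 = b1, a2 = b2,
                                    order = rep(1L, length(b1))))
  mol$data <- c(label = "decoy")
  mol
}

#' Generate a synthetic screening library with ground-truth labels
#'
#' @param model the [pharmacophore_model] the actives are planted against.
#' @param spec a [library_spec].
#' @param path optional SDF file to write the library to.
#' @return list with `molecules` (list of [molecule_record], actives first),
#'   `labels` (data.frame id, label), `sdf` (V2000 text lines), and `path`
#'   when written. A sidecar `<path>.labels.csv` is written alongside `path`.
#' @export
generate_library <- function(model, spec, path = NULL) {
  stopifnot(inherits(model, "pharmacophore_model"),
            inherits(spec, "library_spec"))
  mf <- model$features
  mpos <- as.matrix(mf[, c("x", "y", "z")])
  # co-located donor+acceptor features are realised by one hydroxyl oxygen
  key <- apply(round(mpos, 6), 1, paste, collapse = "/")
  uniq <- !duplicated(key)
  upos <- mpos[uniq, , drop = FALSE]
  udon <- vapply(key[uniq], function(k)
    any(mf$kind[key == k] == "DONOR"), logical(1))
  with_seed(spec$seed, {
    mols <- vector("list", spec$n_actives + spec$n_decoys)
    for (i in seq_len(spec$n_actives)) {
      R <- random_rotation()
      tr <- stats::runif(3, -10, 10)
      fp <- upos %*% t(R) + matrix(tr, nrow(upos), 3, byrow = TRUE) +
        matrix(stats::rnorm(3 * nrow(upos), 0, spec$jitter_sd), ncol = 3)
      mols[[i]] <- .realize_molecule(
        sprintf("active_%03d", i), fp, udon,
        stats::runif(1, spec$descriptor_ranges$mw[1],
                     spec$descriptor_ranges$mw[2]),
        label = "active")
    }
    for (i in seq_len(spec$n_decoys)) {
      n_don <- sample(0:5, 1)
      n_acc_extra <- sample(0:4, 1)
      mols[[spec$n_actives + i]] <- .realize_decoy(
        sprintf("decoy_%04d", i), n_don, n_acc_extra,
        stats::runif(1, spec$descriptor_ranges$mw[1],
                     spec$descriptor_ranges$mw[2]))
    }
    labels <- data.frame(
      id = vapply(mols, `[[`, "", "id"),
      label = rep(c("active", "decoy"), c(spec$n_actives, spec$n_decoys)),
      stringsAsFactors = FALSE)
    sdf <- write_sdf_library(mols, path)
    if (!is.null(path))
      utils::write.csv(labels, paste0(path, ".labels.csv"),
                       row.names = FALSE)
    list(molecules = mols, labels = labels, sdf = sdf, path = path)
  })
}

#' Specification of a synthetic uptake-inhibition assay
#'
#' @param true_ic50 generating IC50 (nM).
#' @param hill Hill slope.
#' @param top,bottom upper/lower asymptotes (% uptake).
#' @param noise_sd iid Gaussian noise SD (% uptake).
#' @param replicates replicates per dose.
#' @param doses dose ladder in nM; defaults to the 15-level half-log ladder
#'   0.001 to 10000.
#' @param seed RNG seed.
#' @return object of class `assay_spec`.
#' @export
assay_spec <- function(true_ic50, hill = 1, top = 100, bottom = 0,
                       noise_sd = 5, replicates = 3,
                       doses = c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3,
                                 10, 30, 100, 300, 1000, 3000, 10000),
                       seed = 1) {
  stopifnot(true_ic50 > 0, noise_sd >= 0, replicates >= 1,
            all(doses > 0))
  structure(list(true_ic50 = true_ic50, hill = hill, top = top,
                 bottom = bottom, noise_sd = noise_sd,
                 replicates = as.integer(replicates), doses = doses,
                 seed = as.integer(seed)),
            class = "assay_spec")
}

#' Simulate an uptake-inhibition dose-response dataset
#'
#' Responses are drawn as 4PL(dose; spec) plus iid Gaussian noise, one
#' observation per dose and replicate; deterministic per seed.
#'
#' @param spec an [assay_spec].
#' @param compound_id,target identifiers carried on the dataset.
#' @return a [dose_response_dataset].
#' @export
generate_assay <- function(spec, compound_id = "synthetic",
                           target = "SGLT2") {
  stopifnot(inherits(spec, "assay_spec"))
  with_seed(spec$seed, {
    dose <- rep(spec$doses, times = spec$replicates)
    repl <- rep(seq_len(spec$replicates), each = length(spec$doses))
    mu <- .pl4(log10(dose), spec$top, spec$bottom, spec$hill,
               log10(spec$true_ic50))
    resp <- mu + stats::rnorm(length(dose), 0, spec$noise_sd)
    dose_response_dataset(dose, resp, repl, compound_id, target)
  })
}
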