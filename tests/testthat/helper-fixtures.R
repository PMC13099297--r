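# Shared fixtures and independent oracles. Fixtures are generated in code;
# the oracles deliberately re-derive results by brute force so that the
# package's optimised paths are checked against slow, obviously-correct
# computations.

# the canonical 5-contact synthetic complex (4 ligand-donor + 1
# ligand-acceptor hydroxyl site) and its pharmacophore model
make_site_model <- function(seed = 1, margin = 0.3) {
  spec <- complex_spec(5, c(rep("LIGAND_DONOR", 4), "LIGAND_ACCEPTOR"),
                       geometry_margin = margin, seed = seed)
  tf <- tempfile(fileext = ".pdb")
  generate_complex(spec, tf)
  cx <- read_pdb_complex(tf, "LIG")
  list(model = build_model(detect_hbonds(cx), cx), complex = cx,
       path = tf)
}
SITE <- make_site_model()

rigid_transform <- function(xyz, R = random_rotation(),
                            t = stats::runif(3, -5, 5)) {
  sweep(as.matrix(xyz) %*% t(R), 2, -t)
}

# --- brute-force correspondence oracle ------------------------------------
# all ordered arrangements of k out of n indices (no pruning, no cleverness)
all_arrangements <- function(n, k) {
  if (k == 0) return(matrix(integer(), 1, 0))
  if (n < k) return(matrix(integer(), 0, k))
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  cmb <- utils::combn(n, k)
  do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) perms(cmb[, j])))
}

# minimum superposition RMSD over every kind-respecting injective
# assignment of model features to molecule feature points
bf_min_rmsd <- function(features, model) {
  mf <- model$features
  mf <- mf[c(which(mf$kind == "DONOR"), which(mf$kind == "ACCEPTOR")), ]
  k_d <- sum(mf$kind == "DONOR"); k_a <- sum(mf$kind == "ACCEPTOR")
  don <- features[features$kind == "DONOR", , drop = FALSE]
  acc <- features[features$kind == "ACCEPTOR", , drop = FALSE]
  if (nrow(don) < k_d || nrow(acc) < k_a) return(NA_real_)
  M <- as.matrix(mf[, c("x", "y", "z")])
  Ad <- all_arrangements(nrow(don), k_d)
  Aa <- all_arrangements(nrow(acc), k_a)
  best <- Inf
  for (i in seq_len(nrow(Ad))) for (j in seq_len(nrow(Aa))) {
    Q <- rbind(as.matrix(don[Ad[i, ], c("x", "y", "z")]),
               as.matrix(acc[Aa[j, ], c("x", "y", "z")]))
    best <- min(best, superpose_rmsd(M, Q)$rmsd)
  }
  best
}

# --- rotation-grid oracle for the Kabsch superposition --------------------
# minimises RMSD over rotations parameterised by Euler angles: coarse grid
# then Nelder-Mead polish; independent of the SVD solution
grid_min_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  euler <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  obj <- function(ang) {
    R <- euler(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc - Qc %*% t(R))^2)))
  }
  gr <- pi / 6
  grid <- expand.grid(a = seq(0, 2 * pi - gr, gr),
                      b = seq(0, pi, gr),
                      c = seq(0, 2 * pi - gr, gr))
  vals <- apply(grid, 1, obj)
  best <- Inf
  for (i in order(vals)[1:5]) {
    o <- stats::optim(as.numeric(grid[i, ]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, o$value)
  }
  best
}

# --- small hand-built molecules -------------------------------------------
mol_water <- function() {
  molecule_record("water",
    data.frame(element = c("O", "H", "H"),
               x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = c(0, 0, 0)),
    data.frame(a1 = c(1, 1), a2 = c(2, 3), order = c(1L, 1L)))
}

mol_methane <- function() {
  molecule_record("methane",
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, 1.09, -0.36, -0.36, -0.36),
               y = c(0, 0, 1.03, -0.51, -0.51),
               z = c(0, 0, 0, 0.89, -0.89)),
    data.frame(a1 = rep(1, 4), a2 = 2:5, order = rep(1L, 4)))
}

mol_benzene <- function() {
  th <- 2 * pi * (0:5) / 6
  atoms <- data.frame(
    element = c(rep("C", 6), rep("H", 6)),
    x = c(1.39 * cos(th), 2.48 * cos(th)),
    y = c(1.39 * sin(th), 2.48 * sin(th)),
    z = 0)
  bonds <- data.frame(a1 = c(1:6, 1:6),
                      a2 = c(2:6, 1, 7:12),
                      order = c(rep(4L, 6), rep(1L, 6)))
  molecule_record("benzene", atoms, bonds)
}

mol_ethanol <- function() {
  molecule_record("ethanol",
    data.frame(element = c("C", "C", "O", "H"),
               x = c(0, 1.5, 2.2, 3.1), y = c(0, 0, 1.2, 1.2),
               z = c(0, 0, 0, 0.3)),
    data.frame(a1 = c(1, 2, 3), a2 = c(2, 3, 4), order = rep(1L, 3)))
}

# pyranose-like polyol: ring oxygen (ether) + 5 hydroxyls on ring carbons
mol_pyranose <- function() {
  th <- 2 * pi * (0:5) / 6
  ring <- cbind(1.45 * cos(th), 1.45 * sin(th), 0.2 * c(1, -1))
  el <- character(); xyz <- list(); b1 <- integer(); b2 <- integer()
  add <- function(e, p) {
    el[length(el) + 1] <<- e; xyz[[length(xyz) + 1]] <<- p; length(el)
  }
  ring_idx <- integer(6)
  ring_idx[1] <- add("O", ring[1, ])            # ring ether oxygen
  for (i in 2:6) ring_idx[i] <- add("C", ring[i, ])
  for (i in 1:6) { b1 <- c(b1, ring_idx[i]); b2 <- c(b2, ring_idx[i %% 6 + 1]) }
  for (i in 2:6) {                              # hydroxyl on each carbon
    dirv <- ring[i, ] / sqrt(sum(ring[i, ]^2))
    oi <- add("O", ring[i, ] + 1.4 * dirv)
    hi <- add("H", ring[i, ] + 2.36 * dirv)
    b1 <- c(b1, ring_idx[i], oi); b2 <- c(b2, oi, hi)
  }
  m <- do.call(rbind, xyz)
  molecule_record("pyranose",
                  data.frame(element = el, x = m[, 1], y = m[, 2], z = m[, 3]),
                  data.frame(a1 = b1, a2 = b2, order = rep(1L, length(b1))))
}
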