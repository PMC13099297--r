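test_that("feature perception follows the donor/acceptor definitions", {
  fe <- perceive_features(mol_ethanol())
  expect_equal(sum(fe$kind == "DONOR"), 1)
  expect_equal(sum(fe$kind == "ACCEPTOR"), 1)
  # both sit on the hydroxyl oxygen
  expect_equal(unique(fe$atom_index), 3)

  expect_equal(nrow(perceive_features(mol_benzene())), 0)

  # pyranose-like polyol: 5 hydroxyls + ring ether oxygen
  fp <- perceive_features(mol_pyranose())
  expect_equal(sum(fp$kind == "DONOR"), 5)
  expect_equal(sum(fp$kind == "ACCEPTOR"), 6)
})

test_that("an exact rigid copy of the model matches at zero RMSD", {
  set.seed(7)
  lib <- generate_library(SITE$model, library_spec(2, 0, jitter_sd = 0,
                                                   seed = 3))
  for (mol in lib$molecules) {
    res <- match_pharmacophore(perceive_features(mol), SITE$model)
    expect_true(res$matched)
    expect_lt(res$rmsd, 1e-6)
    # correspondence covers every model feature exactly once
    expect_named(res$correspondence, SITE$model$features$label)
    expect_equal(anyDuplicated(res$correspondence), 0)
  }
})

test_that("matcher equals brute-force enumeration on jittered actives", {
  for (seed in 1:5) {
    lib <- generate_library(SITE$model,
                            library_spec(1, 1, jitter_sd = 0.2, seed = seed))
    for (mol in lib$molecules) {
      fe <- perceive_features(mol)
      got <- match_pharmacophore(fe, SITE$model)$rmsd
      want <- bf_min_rmsd(fe, SITE$model)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("a molecule with too few donors is unmatched, not an error", {
  fe <- data.frame(kind = c(rep("DONOR", 3), "ACCEPTOR"),
                   x = rnorm(4), y = rnorm(4), z = rnorm(4),
                   atom_index = 1:4)
  res <- match_pharmacophore(fe, SITE$model)
  expect_false(res$matched)
  expect_true(is.na(res$rmsd))
  expect_null(res$correspondence)
})

test_that("match RMSD is invariant to rigid motion and feature permutation", {
  set.seed(21)
  lib <- generate_library(SITE$model, library_spec(1, 0, jitter_sd = 0.15,
                                                   seed = 8))
  fe <- perceive_features(lib$molecules[[1]])
  base <- match_pharmacophore(fe, SITE$model)$rmsd
  for (rep in 1:3) {
    fe2 <- fe[sample(nrow(fe)), ]
    fe2[, c("x", "y", "z")] <- rigid_transform(fe2[, c("x", "y", "z")])
    expect_equal(match_pharmacophore(fe2, SITE$model)$rmsd, base,
                 tolerance = 1e-9)
  }
})

test_that("lowering the cutoff never turns an unmatched molecule into a hit", {
  lib <- generate_library(SITE$model, library_spec(5, 5, jitter_sd = 0.3,
                                                   seed = 13))
  for (mol in lib$molecules) {
    fe <- perceive_features(mol)
    cuts <- c(0.2, 0.4, 0.6, 1.0)
    matched <- vapply(cuts, function(cc)
      match_pharmacophore(fe, SITE$model, rmsd_cutoff = cc)$matched,
      logical(1))
    expect_true(all(diff(matched) >= 0))   # monotone in the cutoff
  }
})

test_that("oversized correspondence searches abort with a clear error", {
  set.seed(30)
  n <- 40
  fe <- data.frame(kind = rep(c("DONOR", "ACCEPTOR"), c(n, 10)),
                   x = rnorm(n + 10), y = rnorm(n + 10), z = rnorm(n + 10),
                   atom_index = seq_len(n + 10))
  expect_error(match_pharmacophore(fe, SITE$model), "too large")
})

test_that("multi-conformer compounds report their best conformer", {
  lib <- generate_library(SITE$model, library_spec(1, 0, jitter_sd = 0,
                                                   seed = 5))
  good <- lib$molecules[[1]]
  bad <- good
  bad$conformer_id <- 2L
  bad$atoms$x <- bad$atoms$x * 1.6     # stretched conformer, poor match
  rep <- run_funnel(list(bad, good), SITE$model)
  expect_equal(rep$n_pharm_hits, 1)
  hit <- rep$per_compound[rep$per_compound$stage == "hit", ]
  expect_equal(hit$conformer_id, 1L)
  expect_lt(hit$best_rmsd, 1e-6)
})
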