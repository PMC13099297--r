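test_that("complex generation is a pure function of its spec", {
  spec <- complex_spec(4, rep(c("LIGAND_DONOR", "LIGAND_ACCEPTOR"), 2),
                       seed = 6)
  a <- generate_complex(spec)
  b <- generate_complex(spec)
  expect_identical(a$pdb, b$pdb)       # byte-identical text per seed
  expect_identical(a$contacts, b$contacts)
  c2 <- generate_complex(complex_spec(4, rep(c("LIGAND_DONOR",
                                               "LIGAND_ACCEPTOR"), 2),
                                      seed = 7))
  expect_false(identical(a$pdb, c2$pdb))
})

test_that("planted geometry respects the stated margin on both sides", {
  crit <- hbond_criteria()
  inside <- generate_complex(complex_spec(3, rep("LIGAND_DONOR", 3),
                                          geometry_margin = 0.4, seed = 2))
  expect_true(all(inside$contacts$distance <=
                    crit$max_da_distance - 0.4 + 1e-9))
  outside <- generate_complex(complex_spec(3, rep("LIGAND_DONOR", 3),
                                           geometry_margin = -0.4, seed = 2))
  expect_true(all(outside$contacts$distance >=
                    crit$max_da_distance + 0.4 - 1e-9))
})

test_that("infeasible complex specs error rather than silently breaking the oracle", {
  expect_error(generate_complex(complex_spec(30, rep("LIGAND_DONOR", 30),
                                             seed = 1)),
               "infeasible")
  expect_error(complex_spec(2, rep("LIGAND_DONOR", 2), geometry_margin = 0))
})

test_that("library generation is deterministic and labelled", {
  sp <- library_spec(3, 7, jitter_sd = 0.1, seed = 11)
  a <- generate_library(SITE$model, sp)
  b <- generate_library(SITE$model, sp)
  expect_identical(a$sdf, b$sdf)
  expect_equal(a$labels$label, rep(c("active", "decoy"), c(3, 7)))
  expect_equal(sum(a$labels$label == "active"), 3)
  # zero actives: all decoys
  z <- generate_library(SITE$model, library_spec(0, 4, seed = 3))
  expect_true(all(z$labels$label == "decoy"))
})

test_that("active feature points equal a rigid transform of the model plus jitter", {
  # with zero jitter the perceived points superpose on the model exactly
  lib <- generate_library(SITE$model, library_spec(4, 0, jitter_sd = 0,
                                                   seed = 13))
  M <- as.matrix(SITE$model$features[, c("x", "y", "z")])
  for (mol in lib$molecules) {
    fe <- perceive_features(mol)
    expect_equal(match_pharmacophore(fe, SITE$model)$rmsd, 0,
                 tolerance = 1e-6)
  }
  # jittered actives deviate on the order of the jitter, not more
  libj <- generate_library(SITE$model, library_spec(10, 0, jitter_sd = 0.1,
                                                    seed = 14))
  r <- vapply(libj$molecules, function(mol)
    match_pharmacophore(perceive_features(mol), SITE$model)$rmsd,
    numeric(1))
  expect_true(all(r < 0.45))   # 0.1 A/coordinate stays well inside 0.6 A
  expect_true(mean(r) > 0.05)
})

test_that("generated molecules are written as parseable SDF with labels sidecar", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  generate_library(SITE$model, library_spec(2, 3, seed = 15), path = tf)
  expect_true(file.exists(tf))
  expect_true(file.exists(paste0(tf, ".labels.csv")))
  back <- read_sdf_library(tf)
  expect_length(back, 5)
  labels <- utils::read.csv(paste0(tf, ".labels.csv"))
  expect_equal(labels$id, vapply(back, `[[`, "", "id"))
})

test_that("assay simulation is deterministic and honours its spec", {
  sp <- assay_spec(true_ic50 = 6, noise_sd = 5, replicates = 3, seed = 8)
  a <- generate_assay(sp)
  b <- generate_assay(sp)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 15 * 3)
  expect_equal(sort(unique(a$replicate)), 1:3)
  # noise-free curve equals the 4PL exactly
  clean <- generate_assay(assay_spec(6, noise_sd = 0, replicates = 2,
                                     seed = 1))
  mu <- 0 + (100 - 0) / (1 + (clean$dose / 6)^1)
  expect_equal(clean$response, mu, tolerance = 1e-12)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  x1 <- rnorm(1)
  set.seed(123)
  invisible(generate_assay(assay_spec(1.5, seed = 77)))
  invisible(generate_library(SITE$model, library_spec(1, 1, seed = 77)))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})
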