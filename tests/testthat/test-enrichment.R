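test_that("GH bookkeeping from a reference confusion count", {
  st <- compute_enrichment(D = 2000, A = 25, Ht = 28, Ha = 23)
  expect_equal(st$rounded$yield_pct, 82)
  expect_equal(st$rounded$ratio_pct, 92)
  expect_equal(st$rounded$E, 66)
  expect_equal(st$false_negatives, 2)
  expect_equal(st$false_positives, 5)
  expect_equal(st$rounded$GH, 0.84)
  # raw values retained unrounded
  expect_equal(st$E, 23 * 2000 / (28 * 25), tolerance = 1e-12)
  expect_equal(st$yield_pct, 100 * 23 / 28, tolerance = 1e-12)
})

test_that("GH is 1 for the ideal model and 0 for the null model", {
  for (D in c(50, 2000)) {
    for (A in c(5, 25)) {
      expect_equal(compute_enrichment(D, A, Ht = A, Ha = A)$GH, 1)
      expect_equal(compute_enrichment(D, A, Ht = min(28, D - A),
                                      Ha = 0)$GH, 0)
    }
  }
})

test_that("Ht = 0 flags yield and E undefined and gives GH 0", {
  st <- compute_enrichment(2000, 25, 0, 0)
  expect_true(is.na(st$yield_pct))
  expect_true(is.na(st$E))
  expect_equal(st$GH, 0)
})

test_that("invalid confusion counts are rejected", {
  expect_error(compute_enrichment(2000, 25, 28, 29), "Ha")
  expect_error(compute_enrichment(2000, 25, 28, 26), "Ha")
  expect_error(compute_enrichment(25, 25, 5, 5), "D > A")
  expect_error(compute_enrichment(2000, 0, 5, 0), "D > A")
  expect_error(compute_enrichment(60, 55, 60, 50), "inactives")
})

test_that("GH stays in [0,1] over every valid count tuple up to D = 60", {
  for (D in 2:60) {
    for (A in seq_len(D - 1)) {
      g <- expand.grid(Ht = 0:D, Ha = 0:A)
      # Ha <= Ht and FP bounded by the number of inactives
      g <- g[g$Ha <= g$Ht & g$Ht - g$Ha <= D - A, ]
      gh <- ifelse(g$Ht == 0, 0,
                   (g$Ha * (3 * A + g$Ht) / (4 * g$Ht * A)) *
                     (1 - (g$Ht - g$Ha) / (D - A)))
      expect_true(all(gh >= -1e-12 & gh <= 1 + 1e-12),
                  info = sprintf("D=%d A=%d", D, A))
    }
  }
  # spot-check the vectorised formula against compute_enrichment
  expect_equal(compute_enrichment(60, 10, 12, 7)$GH,
               (7 * (30 + 12) / (4 * 12 * 10)) * (1 - 5 / 50))
})

test_that("GH increases in Ha with D, A, Ht fixed", {
  for (D in c(40, 60)) for (A in c(8, 15)) for (Ht in c(5, 12, 20)) {
    gh <- vapply(0:min(Ht, A), function(Ha)
      compute_enrichment(D, A, Ht, Ha)$GH, numeric(1))
    expect_true(all(diff(gh) > 0),
                info = sprintf("D=%d A=%d Ht=%d", D, A, Ht))
  }
})

test_that("evaluate_model equals GH computed from a brute-force confusion count", {
  lib <- generate_library(SITE$model, library_spec(6, 30, jitter_sd = 0.15,
                                                   seed = 31))
  actives <- lib$molecules[1:6]
  decoys <- lib$molecules[7:36]
  st <- evaluate_model(SITE$model, actives, decoys)
  # independent confusion count: match each compound one by one
  matched <- vapply(lib$molecules, function(mol)
    match_pharmacophore(perceive_features(mol), SITE$model)$matched,
    logical(1))
  expect_equal(st$Ht, sum(matched))
  expect_equal(st$Ha, sum(matched[1:6]))
  ref <- compute_enrichment(36, 6, sum(matched), sum(matched[1:6]))
  expect_equal(st$GH, ref$GH)
})

test_that("exact actives against polar-free decoys give a perfect GH", {
  lib <- generate_library(SITE$model, library_spec(5, 0, jitter_sd = 0,
                                                   seed = 37))
  decoys <- lapply(1:5, function(i)
    molecule_record(sprintf("plain_%d", i), mol_methane()$atoms,
                    mol_methane()$bonds))
  st <- evaluate_model(SITE$model, lib$molecules, decoys)
  expect_equal(st$GH, 1)
  expect_equal(st$rounded$ratio_pct, 100)
})

test_that("overlapping active/decoy ids are rejected", {
  lib <- generate_library(SITE$model, library_spec(2, 0, jitter_sd = 0,
                                                   seed = 41))
  expect_error(evaluate_model(SITE$model, lib$molecules, lib$molecules),
               "overlap")
  expect_error(evaluate_model(SITE$model, list(), lib$molecules),
               "at least one active")
})

test_that("enrichment JSON carries raw and rounded fields", {
  tf <- withr::local_tempfile(fileext = ".json")
  write_enrichment_json(compute_enrichment(2000, 25, 28, 23), tf)
  obj <- jsonlite::read_json(tf)
  expect_equal(obj$GH, 0.84392, tolerance = 1e-4)
  expect_equal(obj$rounded$GH, 0.84)
  expect_equal(obj$rounded$E, 66)
})
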