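test_that("noise-free 4PL data is recovered to 4 significant figures", {
  for (hill in c(0.5, 1, 2)) {
    d <- generate_assay(assay_spec(true_ic50 = 18.3, hill = hill,
                                   noise_sd = 0, replicates = 1, seed = 1))
    f <- fit_ic50(d)
    expect_true(f$converged)
    expect_equal(f$ic50, 18.3, tolerance = 1e-4)
    expect_equal(f$hill, hill, tolerance = 1e-4)
    expect_equal(f$top, 100, tolerance = 1e-4)
    expect_equal(f$bottom, 0, tolerance = 1e-3)
    expect_false(f$no_inhibition)
  }
})

test_that("the 4PL midpoint identity holds on noise-free data", {
  sp <- assay_spec(true_ic50 = 1.5, noise_sd = 0, replicates = 1,
                   doses = c(0.01, 0.1, 1.5, 10, 100))
  d <- generate_assay(sp)
  expect_equal(d$response[d$dose == 1.5], 50)   # (top + bottom) / 2
})

test_that("flat data is flagged as no inhibition", {
  d <- data.frame(dose = rep(c(1, 10, 100, 1000), each = 3),
                  response = 100 + rep(c(-1, 0, 1), 4))
  f <- fit_ic50(d)
  expect_true(f$no_inhibition)
  expect_false(f$converged)
  expect_true(is.na(f$ic50))
  expect_error(predict(f), "unconverged")
})

test_that("the fit is equivariant under a change of dose units", {
  d <- generate_assay(assay_spec(true_ic50 = 6, noise_sd = 3,
                                 replicates = 3, seed = 9))
  f_nM <- fit_ic50(d)
  d_pM <- as.data.frame(d)
  d_pM$dose <- d_pM$dose * 1000
  f_pM <- fit_ic50(d_pM)
  expect_equal(f_pM$ic50 / f_nM$ic50, 1000, tolerance = 1e-6)
  expect_equal(f_pM$hill, f_nM$hill, tolerance = 1e-6)
})

test_that("the model object behaves like a classed R fit", {
  d <- generate_assay(assay_spec(true_ic50 = 6, noise_sd = 5,
                                 replicates = 3, seed = 2))
  f <- fit_ic50(d)
  expect_s3_class(f, "ic50_fit")
  expect_named(coef(f), c("ic50", "hill", "top", "bottom"))
  expect_length(predict(f, data.frame(dose = c(1, 10))), 2)
  expect_equal(length(residuals(f)), nrow(d))
  expect_equal(residuals(f), d$response - fitted(f))
  expect_lt(abs(predict(f, data.frame(dose = f$ic50)) -
                  (f$top + f$bottom) / 2), 1e-9)
  sims <- simulate(f, nsim = 2, seed = 99)
  expect_equal(dim(sims), c(nrow(d), 2))
  expect_output(print(f), "IC50")
  expect_output(summary(f), "distinct doses")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(f); grDevices::dev.off()
  expect_true(file.exists(tf))
})

test_that("a 3-parameter fit honours the fixed bottom", {
  d <- generate_assay(assay_spec(true_ic50 = 20, noise_sd = 2,
                                 replicates = 3, seed = 3))
  f <- fit_ic50(d, fix_bottom = 0)
  expect_true(f$converged)
  expect_equal(f$bottom, 0)
  expect_equal(f$ic50, 20, tolerance = 0.15)
})

test_that("selectivity ratios reproduce reference potency pairs", {
  pairs <- list(c(618, 196, 3), c(152, 6, 25), c(879, 18.3, 48),
                c(5265, 1.5, 3510), c(69, 18, 4), c(3367, 3.1, 1086))
  for (p in pairs)
    expect_equal(selectivity_ratio(p[1], p[2])$selectivity_int, p[3])
  expect_equal(selectivity_ratio(7, 7)$selectivity_int, 1)
  expect_error(selectivity_ratio(-1, 5), "positive")
  # reciprocal property on raw ratios
  a <- selectivity_ratio(618, 196)$selectivity
  b <- selectivity_ratio(196, 618)$selectivity
  expect_equal(a * b, 1, tolerance = 1e-12)
})

test_that("summarize_activity assembles the per-compound table", {
  f2a <- fit_ic50(generate_assay(assay_spec(6, noise_sd = 4, seed = 11)))
  f2b <- fit_ic50(generate_assay(assay_spec(6, noise_sd = 4, seed = 12)))
  f1 <- fit_ic50(generate_assay(assay_spec(152, noise_sd = 4, seed = 13)))
  tab <- summarize_activity(list(
    list(id = "hit2", sglt2 = list(f2a, f2b), sglt1 = f1),
    list(id = "orphan", sglt2 = f2a)))
  expect_equal(nrow(tab), 2)
  expect_false(is.na(tab$sd_sglt2[1]))
  expect_true(is.na(tab$selectivity[2]))     # no SGLT1 data: blank
  expect_error(summarize_activity(list(list(id = "x", sglt1 = f1))),
               "SGLT2")
  # printed IC50 columns as direct numeric input reproduce the ratios
  printed <- list(
    list(id = "hit1", sglt2 = 196, sglt1 = 618),
    list(id = "hit2", sglt2 = 6, sglt1 = 152),
    list(id = "hit3", sglt2 = 18.3, sglt1 = 879),
    list(id = "hit4", sglt2 = 1.5, sglt1 = 5265),
    list(id = "phlorizin", sglt2 = 18, sglt1 = 69),
    list(id = "empagliflozin", sglt2 = 3.1, sglt1 = 3367))
  expect_equal(summarize_activity(printed)$selectivity,
               c(3, 25, 48, 3510, 4, 1086))
})

test_that("dose-response CSV round-trips through the readers", {
  d1 <- generate_assay(assay_spec(1.5, seed = 21), compound_id = "hit4",
                       target = "SGLT2")
  d2 <- generate_assay(assay_spec(5265, seed = 22), compound_id = "hit4",
                       target = "SGLT1")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_dose_response_csv(list(d1, d2), tf)
  back <- read_dose_response_csv(tf)
  expect_length(back, 2)
  expect_equal(attr(back[[1]], "compound_id"), "hit4")
  expect_equal(attr(back[[2]], "target"), "SGLT1")
  expect_equal(back[[1]]$response, d1$response)
})

test_that("dataset construction enforces its invariants", {
  expect_error(dose_response_dataset(c(-1, 1, 10, 100), rep(50, 4)),
               "positive")
  expect_error(dose_response_dataset(c(1, 1, 10, 10), rep(50, 4)),
               "4 distinct")
  expect_error(dose_response_dataset(c(1, 10, 100, 1000), c(50, 50, 50, NA)),
               "finite")
})
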