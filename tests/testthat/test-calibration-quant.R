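test_that("an exact line calibrates exactly", {
  x <- rep(c(0.01, 0.1, 1, 2), each = 2)
  cv <- fit_calibration(x, 2 * x, target = "t")
  expect_equal(cv$slope, 2, tolerance = 1e-9)
  expect_equal(cv$intercept, 0, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$linear_range[["high"]], 2)
  expect_equal(cv$lloq, 0.01)
  expect_error(fit_calibration(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_calibration(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("the fitted slope recovers the simulated response factor", {
  tr <- simulate_calibration_series(config = simulation_config(),
                                    seed = 41, rt_mean = 0.79)
  assay <- reference_assay()
  pk <- integrate_traces(tr, assay)
  lev <- vapply(tr, function(x) x$meta$level, numeric(1))
  cv <- fit_calibration(lev, pk$area, target = "AprBp")
  # independent check: ordinary lm on the same points gives the slope SE
  fit <- stats::lm(pk$area ~ lev)
  se <- summary(fit)$coefficients["lev", "Std. Error"]
  expect_within(cv$slope, 1e5, 3 * se)
  expect_gt(cv$r_squared, 0.9999)
  expect_equal(cv$linear_range[["high"]], 3.3)
  expect_equal(cv$lloq, 0.0033)
})

test_that("a saturated top level is excluded from the linear range", {
  tr <- simulate_calibration_series(
    config = simulation_config(saturation_level = 1.65), seed = 42,
    transition_key = "TDTNIGNTVGYR+y9", rt_mean = 1.39)
  pk <- integrate_traces(tr, reference_assay())
  lev <- vapply(tr, function(x) x$meta$level, numeric(1))
  expect_equal(linear_range(lev, pk$area)[["high"]], 1.65)
  cv <- fit_calibration(lev, pk$area, target = "GseBp")
  expect_equal(cv$linear_range[["high"]], 1.65)
  expect_within(cv$slope, 1e5, 3e2)
  # saturating every level leaves nothing to fit
  expect_error(linear_range(c(1, 2, 3), c(10, 11, 11.2)), "fewer than 3")
})

test_that("the LLOQ rule walks up past noisy or inaccurate levels", {
  lv <- rep(c(0.01, 0.1, 1), each = 3)
  clean <- 100 * lv
  expect_equal(lloq(lv, clean, slope = 100, intercept = 0), 0.01)
  # lowest level with 25% replicate CV fails cv_max = 20%
  noisy <- clean
  noisy[lv == 0.01] <- c(0.7, 1.0, 1.3) # CV ~23%
  expect_equal(lloq(lv, noisy, slope = 100, intercept = 0), 0.1)
  # a biased lowest level fails the accuracy rule
  biased <- clean
  biased[lv == 0.01] <- c(1.5, 1.51, 1.49)
  expect_equal(lloq(lv, biased, slope = 100, intercept = 0), 0.1)
  expect_warning(out <- lloq(lv, 0 * lv + c(1, 50, 100), slope = 100,
                             intercept = 0), "no calibration level")
  expect_true(is.na(out))
})

test_that("quantify_area inverts the calibration line", {
  cv <- fit_calibration(rep(c(0.01, 0.1, 1), each = 2),
                        2 * rep(c(0.01, 0.1, 1), each = 2) + 5,
                        target = "t")
  conc <- 0.4
  got <- quantify_area(cv, cv$slope * conc + cv$intercept)
  expect_equal(got$vial_conc, conc, tolerance = 1e-12)
  expect_false(got$below_lloq)
  expect_false(got$above_linear_range)
  # negative back-calculation clamps to zero and is flagged
  low <- quantify_area(cv, cv$intercept - 1)
  expect_equal(low$vial_conc, 0)
  expect_true(low$below_lloq)
  high <- quantify_area(cv, cv$slope * 10 + cv$intercept)
  expect_true(high$above_linear_range)
})

test_that("supernatant back-calculation matches the strain panel", {
  expect_within(supernatant_conc(6, 4.5, 16.5), 1.63, 0.01)
  expect_within(supernatant_conc(0.005, 1.2, 16.5), 0.00036, 1e-4)
  expect_equal(supernatant_conc(0, 4.5, 16.5), 0)
  # homogeneity of degree 1 in each argument
  expect_equal(supernatant_conc(2 * 0.3, 1.2, 16.5),
               2 * supernatant_conc(0.3, 1.2, 16.5), tolerance = 1e-12)
  expect_equal(supernatant_conc(0.3, 3 * 1.2, 16.5),
               3 * supernatant_conc(0.3, 1.2, 16.5), tolerance = 1e-12)
  expect_error(supernatant_conc(1, 1, 0), "> 0")
  expect_error(supernatant_conc(-1, 1, 16.5), ">= 0")
})

test_that("fold changes ratio concentrations and flag zero denominators", {
  expect_equal(fold_change(0.06, 0.005), 12, tolerance = 1e-12)
  expect_equal(fold_change(1.5, 0.03), 50, tolerance = 1e-12)
  expect_equal(fold_change(0.7, 0.7), 1, tolerance = 1e-12)
  nc <- fold_change(1, 0)
  expect_true(is.na(nc))
  expect_match(attr(nc, "reason"), "not computable")
})

test_that("strain_report assembles folds, ratios and missing samples", {
  sheet <- example_sample_sheet()
  results <- data.frame(
    sample_id = c("Bp3_19", "MRB046_unind", "MRB046_ind", "AT1"),
    target = "AprBp",
    area = c(5e5, 6e3, 3e4, 0),
    vial_conc = c(5.976667, 0.0634615, 0.275, 0),
    sn_conc = c(1.63, 0.005, 0.03, 0),
    detected = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  rep <- strain_report(results, sheet)
  expect_equal(rep$induction$fold[rep$induction$strain == "MRB046"], 6,
               tolerance = 1e-9)
  at1 <- rep$vs_reference[rep$vs_reference$strain == "AT1", ]
  expect_equal(at1$ratio_vs_reference, 0)
  # samples with no results are listed, not dropped
  expect_true("MRB044_unind" %in% rep$missing)
  # single-sample report still renders
  solo <- strain_report(results[1, ], sheet[1, ])
  expect_equal(nrow(solo$samples), 1L)
  expect_output(print(rep), "Induction fold-changes")
})

test_that("a zero reference concentration makes ratios not computable", {
  sheet <- example_sample_sheet()
  results <- data.frame(
    sample_id = c("Bp3_19", "MRB044_ind"), target = "AprBp",
    area = c(0, 1e5), vial_conc = c(0, 4.95), sn_conc = c(0, 1.5),
    detected = c(FALSE, TRUE), stringsAsFactors = FALSE
  )
  rep <- strain_report(results, sheet)
  expect_false(rep$vs_reference$computable)
  expect_true(is.na(rep$vs_reference$ratio_vs_reference))
})
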