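test_that("candidate filter applies length, composition and uniqueness", {
  peps <- peptide_frame(c("NAVDTANNR", "AK", "ACDEFGHIK",
                          strrep("A", 26)))
  kept <- filter_candidates(peps)
  expect_equal(kept$sequence, "NAVDTANNR")
  # idempotence
  expect_identical(filter_candidates(kept), kept)
  # methionine excluded too
  expect_equal(nrow(filter_candidates(peptide_frame("AMDEFGHIK"))), 0L)
  expect_error(filter_candidates(peps, min_len = 10, max_len = 5),
               "min_len")
})

test_that("background digest enforces proteotypicity", {
  bg <- rbind(peptide_frame(c("NAVDTANNR", "SHAREDPEPTIDEK"), "P1"),
              peptide_frame("SHAREDPEPTIDEK", "P2"))
  peps <- peptide_frame(c("NAVDTANNR", "SHAREDPEPTIDEK"))
  kept <- filter_candidates(peps, background = bg)
  expect_equal(kept$sequence, "NAVDTANNR")
  # I/L collapsing is off by default
  bg2 <- rbind(peptide_frame("AAAAILAAAK", "P1"),
               peptide_frame("AAAALIAAAK", "P2"))
  target <- peptide_frame("AAAAILAAAK")
  expect_equal(nrow(filter_candidates(target, background = bg2)), 1L)
  expect_equal(nrow(filter_candidates(target, background = bg2,
                                      collapse_il = TRUE)), 0L)
})

test_that("explicit product-ion picks reproduce the assay m/z values", {
  got <- select_product_ions("NAVDTANNR", policy = "explicit",
                             ions = c("y8", "y6", "y5"))
  expect_within(got$mz, c(860.42, 690.31, 575.28), 0.01)
  got2 <- select_product_ions("TDTNIGNTVGYR", policy = "explicit",
                              ions = c("y9", "y7", "y6"))
  expect_within(got2$mz, c(993.51, 766.38, 709.36), 0.01)
  expect_error(select_product_ions("AGK", policy = "explicit"),
               "requires 'ions'")
})

test_that("automatic pick ranks high-m/z y ions away from the precursor", {
  got <- select_product_ions("NAVDTANNR", n = 3)
  expect_true(all(got$series == "y"))
  expect_true(all(got$index >= 3))
  expect_equal(got$mz, sort(got$mz, decreasing = TRUE))
  prec <- precursor_mz("NAVDTANNR", 2)
  expect_true(all(abs(got$mz - prec) > 3))
  # asking for more ions than exist returns all with a warning
  expect_warning(all4 <- select_product_ions("AGK", n = 5),
                 "candidates")
  expect_lte(nrow(all4), 5L)
})

test_that("instrument model fits are exact on exact lines", {
  m <- fit_instrument_model(data.frame(mz = c(100, 200), ce = c(10, 20)),
                            data.frame(mz = c(100, 200), dp = c(40, 50)))
  expect_equal(m$ce_slope, 0.1, tolerance = 1e-12)
  expect_equal(m$ce_intercept, 0, tolerance = 1e-12)
  expect_equal(m$dp_slope, 0.1, tolerance = 1e-12)
  expect_error(
    fit_instrument_model(data.frame(mz = c(100, 100), ce = c(1, 2)),
                         data.frame(mz = c(100, 200), dp = c(1, 2))),
    "distinct")
  # degenerate zero-slope model predicts a constant
  m0 <- m; m0$ce_slope <- 0; m0$ce_intercept <- 5
  expect_equal(predict_params(m0, c(100, 900))$ce, c(5, 5))
})

test_that("the fitted reference model reproduces every CE and DP", {
  model <- default_instrument_model()
  prec <- reference_precursors()
  pred <- predict_params(model, prec$precursor_mz)
  expect_true(all(abs(pred$ce - prec$ce_volts) <= 0.1))
  expect_true(all(abs(pred$dp - prec$dp_volts) <= 0.1))
  expect_gt(model$ce_slope, 0)
  expect_gt(model$dp_slope, 0)
})

test_that("build_transition_table reproduces the full reference assay", {
  ref <- reference_assay()
  recs <- synthetic_protease_records()
  mature <- lapply(recs, extract_chain, kind = "mature")
  cfg <- fixture_config()
  settings <- design_settings(policy = "explicit",
                              explicit_ions = cfg$design$explicit_ions,
                              quantifier_ions = cfg$design$quantifier_ions,
                              rt = cfg$design$rt)
  assay <- build_transition_table(mature, settings)
  expect_equal(nrow(assay), nrow(ref))
  key <- function(d) paste(d$peptide, d$product_ion)
  assay <- assay[match(key(ref), key(assay)), ]
  expect_within(assay$precursor_mz, ref$precursor_mz, 0.01)
  expect_within(assay$product_mz, ref$product_mz, 0.01)
  expect_within(assay$dp_volts, ref$dp_volts, 0.1)
  expect_within(assay$ce_volts, ref$ce_volts, 0.1)
  # exactly one quantifier per peptide; the configured ones hold
  quant <- tapply(assay$quantifier, assay$peptide, sum)
  expect_true(all(quant == 1L))
  expect_true(assay$quantifier[assay$peptide == "NAVDTANNR" &
                                 assay$product_ion == "y8"])
})

test_that("a protein without cleavage sites yields itself as peptide", {
  prot <- protein_record("nk", "AGDEFGHINQSTVW")
  assay <- build_transition_table(list(prot), design_settings())
  expect_equal(unique(assay$peptide), "AGDEFGHINQSTVW")
  expect_warning(
    empty <- build_transition_table(list(protein_record("x", "AK")),
                                    design_settings()),
    "no candidate")
  expect_equal(nrow(empty), 0L)
})

test_that("transition-list export is stable and format-correct", {
  cfg <- fixture_config()
  mature <- lapply(synthetic_protease_records(), extract_chain, "mature")
  settings <- design_settings(policy = "explicit",
                              explicit_ions = cfg$design$explicit_ions,
                              rt = cfg$design$rt)
  assay <- build_transition_table(mature, settings)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_transition_list(assay, f1)
  export_transition_list(assay, f2)
  expect_identical(readLines(f1), readLines(f2))
  got <- utils::read.csv(f1)
  expect_equal(nrow(got), 18L)
  # missing retention time exports as an empty field, not 0
  assay$rt_min[1] <- NA
  f3 <- withr::local_tempfile(fileext = ".csv")
  export_transition_list(assay, f3)
  expect_match(readLines(f3)[2], ",,", fixed = TRUE)
  expect_error(export_transition_list(assay[0, ], f3), "empty")
})
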