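quiet_cfg <- function(...) {
  simulation_config(baseline_noise_sd = 0, rt_jitter_sd = 0, ...)
}

test_that("integration recovers a noiseless Gaussian area", {
  tr <- simulate_trace("NAVDTANNR+y8", 1.0, quiet_cfg(), seed = 1,
                       rt_mean = 0.79)
  pk <- integrate_peak(tr, c(0.64, 0.94))
  expect_within(pk$area / 1e5, 1, 0.005)
  expect_within(pk$apex_rt, 0.79, 0.01)
  expect_false(pk$flagged_edge)
  expect_true(pk$boundaries[["start"]] < pk$apex_rt)
  expect_true(pk$boundaries[["end"]] > pk$apex_rt)
})

test_that("a flat trace yields zero area and zero signal-to-noise", {
  tr <- simulate_trace("NAVDTANNR+y8", 0, quiet_cfg(baseline_level = 30),
                       seed = 1, rt_mean = 0.79)
  pk <- integrate_peak(tr, c(0.64, 0.94))
  expect_equal(pk$area, 0)
  expect_equal(pk$signal_to_noise, 0)
})

test_that("identical traces integrate identically", {
  cfg <- simulation_config()
  a <- integrate_peak(simulate_trace("P+y3", 0.3, cfg, seed = 7),
                      c(0.85, 1.15))
  b <- integrate_peak(simulate_trace("P+y3", 0.3, cfg, seed = 7),
                      c(0.85, 1.15))
  expect_identical(a, b)
})

test_that("area is invariant under baseline shifts and scales linearly", {
  tr <- simulate_trace("P+y3", 0.5, simulation_config(), seed = 13)
  base <- integrate_peak(tr, c(0.85, 1.15))
  shifted <- tr
  shifted$intensities <- tr$intensities + 500
  pk_s <- integrate_peak(shifted, c(0.85, 1.15))
  expect_within(pk_s$area / base$area, 1, 0.01)
  scaled <- tr
  scaled$intensities <- tr$intensities * 3
  pk_k <- integrate_peak(scaled, c(0.85, 1.15))
  expect_within(pk_k$area / (3 * base$area), 1, 0.01)
})

test_that("integration windows are validated", {
  tr <- simulate_trace("P+y3", 0.5, simulation_config(), seed = 1)
  expect_error(integrate_peak(tr, c(14, 16)), "outside")
  expect_error(integrate_peak(tr, c(1.2, 1.1)), "min < max")
})

test_that("co-elution and S/N rules decide peptide detectability", {
  cfg <- simulation_config()
  mk <- function(ion, conc, seed, rt = 1.0) {
    integrate_peak(
      simulate_trace(paste0("P+", ion), conc, cfg, seed = seed,
                     rt_mean = rt),
      c(rt - 0.15, rt + 0.15))
  }
  clean <- list(y8 = mk("y8", 1, 1), y6 = mk("y6", 0.6, 2),
                y5 = mk("y5", 0.35, 3))
  verdict <- detect_peptide(clean)
  expect_true(verdict$detected)
  expect_equal(nrow(verdict$report), 3L)
  # one baseline-only transition sinks the peptide
  weak <- clean
  weak$y5 <- mk("y5", 0, 4)
  expect_false(detect_peptide(weak)$detected)
  # apexes 0.3 min apart fail the 0.1-min co-elution default
  apart <- list(y8 = mk("y8", 1, 5, rt = 1.0),
                y6 = mk("y6", 1, 6, rt = 1.3))
  expect_false(detect_peptide(apart)$detected)
  expect_true(detect_peptide(apart, rt_tolerance = 0.5)$detected)
  expect_error(detect_peptide(clean[1]), "fewer than 2")
})

test_that("integrate_traces and detection_report work per sample", {
  assay <- reference_assay()
  sheet <- example_sample_sheet()[c(1, 2), ] # positive + negative control
  traces <- simulate_study(sheet, assay, simulation_config(), seed = 31)
  peaks <- integrate_traces(traces, assay)
  expect_equal(nrow(peaks), nrow(sheet) * nrow(assay))
  det <- detection_report(peaks)
  expect_true(all(det$detected[det$sample_id == "Bp3_19"]))
  expect_false(any(det$detected[det$sample_id == "AT1"]))
})
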