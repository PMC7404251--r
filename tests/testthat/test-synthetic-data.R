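noiseless <- function(...) {
  simulation_config(baseline_noise_sd = 0, rt_jitter_sd = 0, ...)
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

test_that("zero concentration without noise gives a flat baseline", {
  tr <- simulate_trace("NAVDTANNR+y8", 0, noiseless(baseline_level = 50),
                       seed = 1)
  expect_true(all(abs(tr$intensities - 50) < 1e-9 |
                    tr$intensities >= 50))  # only the peakless baseline
  expect_equal(max(tr$intensities) - min(tr$intensities), 0,
               tolerance = 1e-9)
})

test_that("the simulated peak area equals response * concentration", {
  cfg <- noiseless(baseline_level = 0)
  tr <- simulate_trace("NAVDTANNR+y8", 1.0, cfg, seed = 1)
  area <- trapz(tr$times, tr$intensities)
  expect_within(area / 1e5, 1, 0.005)  # within 0.5% of 1e5
  # doubling the concentration doubles the expected area
  tr2 <- simulate_trace("NAVDTANNR+y8", 2.0, cfg, seed = 1)
  expect_equal(tr2$meta$true_area / tr$meta$true_area, 2, tolerance = 1e-12)
})

test_that("traces are seed-deterministic", {
  cfg <- simulation_config()
  a <- simulate_trace("NAVDTANNR+y8", 0.5, cfg, seed = 99)
  b <- simulate_trace("NAVDTANNR+y8", 0.5, cfg, seed = 99)
  expect_identical(a$intensities, b$intensities)
  c <- simulate_trace("NAVDTANNR+y8", 0.5, cfg, seed = 100)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("trace generation validates its grid and inputs", {
  expect_error(simulate_trace("P+y1", -1, simulation_config()), ">= 0")
  expect_error(
    simulate_trace("P+y1", 1, simulation_config(grid_step = 0.02)),
    "grid too coarse")
  expect_error(
    simulate_trace("P+y1", 1, simulation_config(), rt_mean = 0.01),
    "5 peak sigma")
  expect_error(simulate_trace("NAVDTANNRy8", 1, simulation_config()),
               "transition key")
})

test_that("calibration series counts levels x replicates", {
  cfg <- simulation_config()
  tr <- simulate_calibration_series(levels = c(0.01, 0.1, 1, 2),
                                    replicates = 3, config = cfg, seed = 5)
  expect_length(tr, 12L)
  levels <- vapply(tr, function(x) x$meta$level, numeric(1))
  expect_equal(sort(unique(levels)), c(0.01, 0.1, 1, 2))
  expect_error(simulate_calibration_series(levels = c(0, 1), config = cfg),
               "> 0")
})

test_that("areas stay proportional to level unless saturation kicks in", {
  lin <- simulate_calibration_series(levels = c(0.5, 1, 2), replicates = 1,
                                     config = noiseless(baseline_level = 0),
                                     seed = 3)
  areas <- vapply(lin, function(x) trapz(x$times, x$intensities),
                  numeric(1))
  expect_within(areas / (1e5 * c(0.5, 1, 2)), c(1, 1, 1), 0.005)
  sat <- simulate_calibration_series(
    levels = c(0.5, 1, 2), replicates = 1,
    config = noiseless(baseline_level = 0, saturation_level = 1),
    seed = 3)
  sat_areas <- vapply(sat, function(x) trapz(x$times, x$intensities),
                      numeric(1))
  expect_within(sat_areas[1:2] / (1e5 * c(0.5, 1)), c(1, 1), 0.005)
  expect_lt(sat_areas[3], 2e5 * 0.99)  # top level below linear prediction
})

test_that("the bundled strain panel drives a full study simulation", {
  sheet <- example_sample_sheet()
  expect_equal(nrow(sheet), 10L)
  expect_equal(sum(sheet$induced), 4L)
  # SN truth and vial truth are linked through the vial-total constant
  expect_equal(sheet$true_vial_AprBp * sheet$total_protein_sn / 16.5,
               sheet$true_sn_AprBp, tolerance = 1e-12)
  assay <- reference_assay()
  traces <- simulate_study(sheet, assay, simulation_config(), seed = 2)
  expect_length(traces, nrow(sheet) * nrow(assay))
  # the negative control carries no analyte peak
  at1 <- Filter(function(tr) tr$sample_id == "AT1", traces)
  expect_true(all(vapply(at1, function(tr) tr$meta$concentration,
                         numeric(1)) == 0))
  expect_lt(max(vapply(at1, function(tr) max(tr$intensities), numeric(1))),
            150)  # baseline 50 + noise, nowhere near a peak
  expect_error(
    simulate_study(sheet[, setdiff(names(sheet), "true_vial_GseBp")],
                   assay, simulation_config(), seed = 2),
    "lacks column")
})

test_that("trace CSV round-trips through write_traces/read_traces", {
  cfg <- simulation_config()
  traces <- list(
    simulate_trace("NAVDTANNR+y8", 0.5, cfg, seed = 1, sample_id = "s1"),
    simulate_trace("NAVDTANNR+y6", 0.2, cfg, seed = 2, sample_id = "s1")
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_traces(traces, f)
  back <- read_traces(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$intensities, traces[[1]]$intensities,
               tolerance = 1e-6)
  expect_equal(back[[2]]$product_ion, "y6")
})
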