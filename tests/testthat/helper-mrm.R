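# Shared helpers for the test suite. All fixtures are built in code.

# Absolute-tolerance comparison (m/z and volt specs are absolute bounds).
expect_within <- function(actual, expected, tol) {
  expect_true(max(abs(actual - expected)) <= tol,
              label = sprintf("max |%s - expected| = %.4g <= %g",
                              deparse(substitute(actual)),
                              max(abs(actual - expected)), tol))
}

# Random peptide over the 20 standard residues.
random_peptide <- function(len) {
  paste(sample(names(residue_mass_table()$masses), len, replace = TRUE),
        collapse = "")
}

# Minimal peptide data frame in the tryptic_digest() layout.
peptide_frame <- function(sequences, parent_id = "P") {
  ends <- cumsum(nchar(sequences))
  data.frame(
    sequence = sequences, parent_id = parent_id,
    start = c(1L, utils::head(ends, -1L) + 1L), end = ends,
    missed_cleavages = 0L, stringsAsFactors = FALSE
  )
}

# A fast pipeline configuration: shorter run, coarser grid, 2 replicates.
fast_config <- function(seed = 1L) {
  cfg <- fixture_config(seed = seed)
  cfg$simulation <- list(run_length = 8, grid_step = 0.01)
  cfg$quantification$calibration_replicates <- 2L
  cfg
}
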