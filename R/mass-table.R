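#' Monoisotopic residue mass table
#'
#' The single source of amino-acid masses for every m/z computation in the
#' package. Residue masses are the monoisotopic masses of the 20 standard
#' amino-acid residues (i.e. the amino acid minus one water), in daltons.
#' The table also carries the two constants needed to turn residue sums into
#' ion m/z values: the monoisotopic mass of water (added once per intact
#' peptide or y ion) and the mass of a proton (added once per charge).
#'
#' Isoleucine and leucine are mass-identical but kept as distinct letters so
#' that sequence-level uniqueness checks (proteotypicity) can distinguish
#' them.
#'
#' @return An object of class `residue_mass_table`: a list with elements
#'   `masses` (named numeric vector over the 20 standard one-letter codes),
#'   `water` (18.010565 Da) and `proton` (1.007276 Da).
#' @examples
#' tbl <- residue_mass_table()
#' tbl$masses[["G"]]
#' @export
residue_mass_table <- function() {
  masses <- c(
    G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,
    V = 99.06841,  T = 101.04768, C = 103.00919, L = 113.08406,
    I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
    K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
    F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  )
  stopifnot(all(masses > 0), length(masses) == 20L)
  structure(
    list(masses = masses, water = 18.010565, proton = 1.007276),
    class = "residue_mass_table"
  )
}

#' @export
print.residue_mass_table <- function(x, ...) {
  cat("Monoisotopic residue mass table (20 standard residues)\n")
  cat("  water:", x$water, "Da   proton:", x$proton, "Da\n")
  print(round(x$masses, 5))
  invisible(x)
}

# Valid one-letter codes; everything else (incl. B, J, O, U, X, Z) is
# rejected with the offending position.
.standard_residues <- function() names(residue_mass_table()$masses)

#' Validate a residue sequence
#'
#' Checks that a sequence is a non-empty string over the 20 standard
#' amino-acid letters. Ambiguity and non-standard codes (B, J, O, U, X, Z)
#' are rejected with an error naming the first offending position, so that
#' bad FASTA input is traceable to a residue.
#'
#' @param sequence Character scalar, upper-case residue string.
#' @param id Identifier used in error messages.
#' @return The sequence, invisibly, if valid.
#' @keywords internal
validate_sequence <- function(sequence, id = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("'", id, "': sequence must be a non-empty character scalar",
         call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .standard_residues())
  if (length(bad)) {
    stop(sprintf(
      "'%s': non-standard residue '%s' at position %d",
      id, chars[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  invisible(sequence)
}
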