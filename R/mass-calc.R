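#' Monoisotopic mass of an intact peptide
#'
#' Sum of the residue monoisotopic masses plus one water (the N- and
#' C-terminal H and OH of the free peptide).
#'
#' @param sequence Residue string (upper case, standard 20-letter alphabet).
#' @param masses A [residue_mass_table()].
#' @return Monoisotopic mass in daltons.
#' @examples
#' peptide_monoisotopic_mass("NAVDTANNR") # ~973.458 Da
#' @export
peptide_monoisotopic_mass <- function(sequence, masses = residue_mass_table()) {
  validate_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(masses$masses[chars]) + masses$water
}

#' Precursor m/z of a protonated peptide
#'
#' m/z of the `[M + zH]^z+` ion: `(M + z * m_proton) / z`. MRM precursors in
#' this package default to charge 2 (tryptic peptides on a triple
#' quadrupole), but any charge >= 1 is accepted.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @param charge Positive integer charge state.
#' @return m/z in Th (Da per unit charge).
#' @examples
#' precursor_mz("NAVDTANNR", 2)    # ~487.74
#' precursor_mz("TDTNIGNTVGYR", 2) # ~655.82
#' @export
precursor_mz <- function(sequence, charge = 2L,
                         masses = residue_mass_table()) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a single integer >= 1", call. = FALSE)
  }
  (peptide_monoisotopic_mass(sequence, masses) + charge * masses$proton) /
    charge
}

#' Singly charged b and y fragment-ion series
#'
#' Enumerates all backbone fragment ions of the b series (N-terminal,
#' `sum(residues 1..i) + proton`) and y series (C-terminal,
#' `sum(residues n-i+1..n) + water + proton`) at charge 1, for
#' i = 1 .. n - 1. These are the collision-induced dissociation products
#' monitored in Q3.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @return A data frame with columns `series` ("b" or "y"), `index`,
#'   `charge` (always 1) and `mz`, ordered b1..b(n-1), y1..y(n-1).
#' @examples
#' frags <- fragment_series("NAVDTANNR")
#' frags[frags$series == "y" & frags$index == 8, "mz"] # ~860.42
#' @export
fragment_series <- function(sequence, masses = residue_mass_table()) {
  validate_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) {
    stop("fragment series requires a peptide of length >= 2", call. = FALSE)
  }
  res <- masses$masses[chars]
  b_mz <- cumsum(res)[-n] + masses$proton
  y_mz <- cumsum(rev(res))[-n] + masses$water + masses$proton
  data.frame(
    series = rep(c("b", "y"), each = n - 1L),
    index = rep(seq_len(n - 1L), 2L),
    charge = 1L,
    mz = c(unname(b_mz), unname(y_mz)),
    stringsAsFactors = FALSE
  )
}

#' Look up one fragment ion by label
#'
#' Convenience accessor for labels such as `"y8"` or `"b3"`.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @param label Ion label: series letter followed by index.
#' @return One-row data frame as in [fragment_series()].
#' @export
fragment_ion <- function(sequence, label, masses = residue_mass_table()) {
  if (!grepl("^[by][0-9]+$", label)) {
    stop("ion label must look like 'y8' or 'b3', got '", label, "'",
         call. = FALSE)
  }
  series <- substr(label, 1L, 1L)
  index <- as.integer(substring(label, 2L))
  frags <- fragment_series(sequence, masses)
  row <- frags[frags$series == series & frags$index == index, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("ion ", label, " does not exist for a peptide of length ",
         nchar(sequence), call. = FALSE)
  }
  row
}
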