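#' Reference MRM assay for the AprBp and GseBp serine proteases
#'
#' The published transition list for the two Bacillus pumilus secreted
#' serine proteases targeted by this package: the subtilisin-like protease
#' AprBp and the glutamyl endopeptidase GseBp, three proteotypic peptides
#' each with their three best product ions, as validated on a QTRAP triple
#' quadrupole. Declustering potential (DP), collision energy (CE) and
#' retention time are measured/instrument-derived metadata; the m/z columns
#' are the printed values and are reproduced by [precursor_mz()] and
#' [fragment_series()] within 0.01 Th.
#'
#' One transition per peptide is flagged as the quantifier; the remaining
#' two confirm identity by co-elution. The protein-level quantifier
#' transitions are NAVDTANNR 487.73 -> 860.42 (y8) for AprBp and
#' TDTNIGNTVGYR 655.82 -> 993.51 (y9) for GseBp.
#'
#' @return A data frame with one row per transition and columns
#'   `protein_id`, `peptide`, `precursor_mz`, `precursor_charge`,
#'   `product_ion`, `product_mz`, `product_charge`, `dp_volts`, `ce_volts`,
#'   `rt_min`, `quantifier`.
#' @export
reference_assay <- function() {
  rows <- list(
    # protein, peptide,            prec_mz, ion,  prod_mz, dp,  ce,  rt,  quant
    list("AprBp", "APAVHAQGYK", 521.27, "y7", 802.42, 69.1, 27.6, 1.03, FALSE),
    list("AprBp", "APAVHAQGYK", 521.27, "y6", 703.35, 69.1, 27.6, 1.03, FALSE),
    list("AprBp", "APAVHAQGYK", 521.27, "y5", 566.29, 69.1, 27.6, 1.03, FALSE),
    list("AprBp", "NAVDTANNR", 487.73, "y8", 860.42, 66.7, 26.4, 0.79, TRUE),
    list("AprBp", "NAVDTANNR", 487.73, "y6", 690.31, 66.7, 26.4, 0.79, FALSE),
    list("AprBp", "NAVDTANNR", 487.73, "y5", 575.28, 66.7, 26.4, 0.79, FALSE),
    list("AprBp", "LENTATPLGNSFYYGK", 887.93, "y10", 1145.56, 95.8, 40.8, 5.62, FALSE),
    list("AprBp", "LENTATPLGNSFYYGK", 887.93, "y9", 1048.50, 95.8, 40.8, 5.62, FALSE),
    list("AprBp", "LENTATPLGNSFYYGK", 887.93, "y8", 935.42, 95.8, 40.8, 5.62, FALSE),
    list("GseBp", "TDTNIGNTVGYR", 655.82, "y9", 993.51, 78.9, 32.5, 1.39, TRUE),
    list("GseBp", "TDTNIGNTVGYR", 655.82, "y7", 766.38, 78.9, 32.5, 1.39, FALSE),
    list("GseBp", "TDTNIGNTVGYR", 655.82, "y6", 709.36, 78.9, 32.5, 1.39, FALSE),
    list("GseBp", "ISGYPGDK", 418.71, "y7", 723.33, 61.6, 23.9, 1.11, FALSE),
    list("GseBp", "ISGYPGDK", 418.71, "y6", 636.29, 61.6, 23.9, 1.11, FALSE),
    list("GseBp", "ISGYPGDK", 418.71, "y4", 416.21, 61.6, 23.9, 1.11, FALSE),
    list("GseBp", "ATAAFVEFINYAK", 722.87, "y9", 1130.58, 83.8, 34.9, 6.46, FALSE),
    list("GseBp", "ATAAFVEFINYAK", 722.87, "y8", 983.51, 83.8, 34.9, 6.46, FALSE),
    list("GseBp", "ATAAFVEFINYAK", 722.87, "y7", 884.45, 83.8, 34.9, 6.46, FALSE)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      protein_id = r[[1L]], peptide = r[[2L]], precursor_mz = r[[3L]],
      precursor_charge = 2L, product_ion = r[[4L]], product_mz = r[[5L]],
      product_charge = 1L, dp_volts = r[[6L]], ce_volts = r[[7L]],
      rt_min = r[[8L]], quantifier = r[[9L]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Per-peptide rows of the reference assay
#'
#' One row per precursor (peptide) of [reference_assay()], carrying the
#' instrument parameters used to fit collision-energy and
#' declustering-potential models.
#'
#' @return Data frame with columns `protein_id`, `peptide`, `precursor_mz`,
#'   `dp_volts`, `ce_volts`, `rt_min`.
#' @export
reference_precursors <- function() {
  tab <- reference_assay()
  out <- unique(tab[, c("protein_id", "peptide", "precursor_mz", "dp_volts",
                        "ce_volts", "rt_min")])
  rownames(out) <- NULL
  out
}
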