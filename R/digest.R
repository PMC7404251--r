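#' In-silico tryptic digestion
#'
#' Cleaves a protein after every lysine (K) or arginine (R). Under the
#' default `"keil"` rule cleavage is suppressed when the following residue
#' is proline (trypsin's well-known KP/RP exception); the `"strict"` rule
#' cleaves after every K/R regardless. With `missed_cleavages = m` the
#' result contains every product spanning 0..m internal uncleaved sites, so
#' the peptide set for m is always a subset of the set for m + 1.
#'
#' @param protein A [protein_record()]; for secreted proteins pass the
#'   mature chain (see [extract_chain()]).
#' @param missed_cleavages Maximum number of internal missed cleavage
#'   sites; 0 (fully cleaved) is the assay-design default.
#' @param rule `"keil"` (no cleavage before proline) or `"strict"`.
#' @return A data frame, one row per peptide, ordered by start position then
#'   missed-cleavage count, with columns `sequence`, `parent_id`, `start`,
#'   `end` (1-based inclusive positions in the parent) and
#'   `missed_cleavages`.
#' @examples
#' rec <- protein_record("demo", "MKRAGER")
#' tryptic_digest(rec)$sequence          # "MK" "R" "AGER"
#' tryptic_digest(protein_record("p", "AKPGR"))$sequence # "AKPGR"
#' @export
tryptic_digest <- function(protein, missed_cleavages = 0L,
                           rule = c("keil", "strict")) {
  rule <- match.arg(rule)
  if (!is.numeric(missed_cleavages) || missed_cleavages < 0 ||
      missed_cleavages != round(missed_cleavages)) {
    stop("missed_cleavages must be a non-negative integer", call. = FALSE)
  }
  missed_cleavages <- as.integer(missed_cleavages)
  seq <- protein$sequence
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)

  # cleavage sites: cut after position i
  is_kr <- chars %in% c("K", "R")
  sites <- which(is_kr & seq_len(n) < n)
  if (rule == "keil") {
    sites <- sites[chars[sites + 1L] != "P"]
  }

  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  n_seg <- length(starts)

  rows <- vector("list", 0L)
  for (i in seq_len(n_seg)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > n_seg) break
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(seq, starts[i], ends[j]),
        parent_id = protein$id,
        start = starts[i],
        end = ends[j],
        missed_cleavages = m,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$missed_cleavages), , drop = FALSE]
}
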