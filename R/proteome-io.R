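#' Construct a protein record
#'
#' A `protein_record` holds one protein sequence plus optional chain
#' annotations (signal peptide, propeptide, mature chain). Secreted
#' bacterial proteases are synthesised as pre-pro-proteins; only the mature
#' chain circulates in the culture supernatant, so assay design always
#' starts from the mature chain.
#'
#' @param id Record identifier.
#' @param sequence Residue string; lower case is accepted and upper-cased.
#' @param description Free-text description.
#' @param chains List of [chain_annotation()] objects.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = "", chains = list()) {
  sequence <- toupper(sequence)
  validate_sequence(sequence, id = id)
  n <- nchar(sequence)
  kinds <- vapply(chains, function(ch) ch$kind, character(1L))
  for (ch in chains) {
    if (!inherits(ch, "chain_annotation")) {
      stop("chains must be chain_annotation objects", call. = FALSE)
    }
    if (ch$end > n) {
      stop(sprintf("chain '%s' [%d, %d] exceeds sequence length %d of '%s'",
                   ch$kind, ch$start, ch$end, n, id), call. = FALSE)
    }
  }
  structure(
    list(id = id, description = description, sequence = sequence,
         chains = chains),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record '%s' (%d aa)\n", x$id, nchar(x$sequence)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  for (ch in x$chains) {
    cat(sprintf("  %-10s %d-%d\n", ch$kind, ch$start, ch$end))
  }
  invisible(x)
}

#' Annotate a chain of a protein
#'
#' Coordinates are 1-based and inclusive on both ends, matching the
#' convention of sequence databases and of maturation annotations such as
#' "mature chain 108-381".
#'
#' @param kind One of "signal", "propeptide", "mature".
#' @param start,end 1-based inclusive residue indices, `start <= end`.
#' @return An object of class `chain_annotation`.
#' @export
chain_annotation <- function(kind = c("signal", "propeptide", "mature"),
                             start, end) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("need 1 <= start <= end, got [", start, ", ", end, "]",
         call. = FALSE)
  }
  structure(list(kind = kind, start = start, end = end),
            class = "chain_annotation")
}

#' Read protein sequences from a FASTA file
#'
#' Reads a multi-entry FASTA file (wrapped or unwrapped lines) into a list
#' of [protein_record()] objects, preserving entry order. Sequences are
#' upper-cased; non-standard residue letters are rejected with the record id
#' and offending position. Chain annotations are not parsed from headers
#' (there is no standard header dialect for them); attach them from a
#' configuration with [attach_chains()].
#'
#' @param path Path to a FASTA file.
#' @return List of `protein_record` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    records[[i]] <- protein_record(ids[i], as.character(set[[i]]),
                                   description = descs[i])
  }
  records
}

#' Attach chain annotations from a configuration
#'
#' @param records List of `protein_record` objects.
#' @param chain_config Named list mapping record id to a list of
#'   `kind = c(start, end)` entries, e.g.
#'   `list(AprBp = list(signal = c(1, 29), mature = c(108, 381)))`.
#' @return The records with chains attached; ids absent from the config are
#'   returned unchanged.
#' @export
attach_chains <- function(records, chain_config) {
  lapply(records, function(rec) {
    cfg <- chain_config[[rec$id]]
    if (is.null(cfg)) return(rec)
    chains <- lapply(names(cfg), function(kind) {
      rng <- as.integer(cfg[[kind]])
      chain_annotation(kind, rng[1L], rng[2L])
    })
    protein_record(rec$id, rec$sequence, rec$description, chains)
  })
}

#' Extract an annotated chain as a new protein record
#'
#' Slices the inclusive `[start, end]` range of the single annotation of the
#' requested kind, returning a new record whose id is suffixed with the
#' chain kind. For secreted proteases this is how the mature, supernatant
#' form is obtained from the full-length pre-pro-protein before in-silico
#' digestion.
#'
#' @param protein A `protein_record` with chain annotations.
#' @param kind Chain kind to extract.
#' @return A new `protein_record` of length `end - start + 1`.
#' @examples
#' rec <- protein_record("P1", strrep("A", 10),
#'   chains = list(chain_annotation("mature", 4, 10)))
#' extract_chain(rec, "mature")
#' @export
extract_chain <- function(protein, kind = c("signal", "propeptide",
                                            "mature")) {
  kind <- match.arg(kind)
  hits <- Filter(function(ch) ch$kind == kind, protein$chains)
  if (length(hits) == 0L) {
    stop("protein '", protein$id, "' has no '", kind, "' chain annotation",
         call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop("protein '", protein$id, "' has ", length(hits), " '", kind,
         "' chain annotations; exactly one is required", call. = FALSE)
  }
  ch <- hits[[1L]]
  protein_record(
    id = paste(protein$id, kind, sep = "_"),
    sequence = substr(protein$sequence, ch$start, ch$end),
    description = sprintf("%s chain %d-%d of %s", kind, ch$start, ch$end,
                          protein$id)
  )
}
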