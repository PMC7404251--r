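#' Filter tryptic peptides to proteotypic candidates
#'
#' Applies the standard MRM candidate rules: peptide length within
#' `[min_len, max_len]` (short peptides are not selective, long ones are
#' hard to recover from gels), exclusion of residues prone to variable
#' modification during sample processing (cysteine and methionine by
#' default), and — when a background digest is supplied — proteotypicity:
#' the peptide sequence must occur in exactly one background protein, by
#' exact string match (no I/L collapsing; see `collapse_il`).
#'
#' The filter is idempotent: applying it twice gives the same set.
#'
#' @param peptides Data frame from [tryptic_digest()].
#' @param min_len,max_len Inclusive length bounds (defaults 8 and 25).
#' @param excluded_residues Character vector of banned residues.
#' @param background Optional background digest (data frame with `sequence`
#'   and `parent_id`) used for the uniqueness check.
#' @param collapse_il If `TRUE`, treat I and L as equivalent during the
#'   uniqueness check (they are mass-identical). Default `FALSE`.
#' @return The filtered peptide data frame.
#' @export
filter_candidates <- function(peptides, min_len = 8L, max_len = 25L,
                              excluded_residues = c("C", "M"),
                              background = NULL, collapse_il = FALSE) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  len <- nchar(peptides$sequence)
  keep <- len >= min_len & len <= max_len
  if (length(excluded_residues)) {
    pat <- paste0("[", paste(excluded_residues, collapse = ""), "]")
    keep <- keep & !grepl(pat, peptides$sequence)
  }
  if (!is.null(background)) {
    canon <- function(x) if (collapse_il) gsub("I", "L", x, fixed = TRUE) else x
    bg_seq <- canon(background$sequence)
    n_parents <- vapply(canon(peptides$sequence), function(s) {
      length(unique(background$parent_id[bg_seq == s]))
    }, integer(1L), USE.NAMES = FALSE)
    keep <- keep & n_parents == 1L
  }
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select product ions for one peptide
#'
#' Two policies are available. The default `"y-prefer"` policy is an
#' automatic ranking: candidate ions are the y series with index >= 3
#' (short y1/y2 ions are unselective), any candidate within
#' `exclusion_window` Th of the precursor m/z is skipped (it would be
#' swamped by precursor leakage at unit resolution), and the survivors are
#' ranked by descending m/z; the top `n` are returned. The `"explicit"`
#' policy takes a user-supplied list of ion labels — this is how an assay
#' refined on the instrument (where relative fragment intensity decides) is
#' reproduced exactly.
#'
#' @param sequence Peptide residue string.
#' @param n Number of product ions wanted (default 3).
#' @param policy `"y-prefer"` or `"explicit"`.
#' @param ions Character vector of ion labels (e.g. `c("y8", "y6", "y5")`),
#'   required for the explicit policy; order is preserved.
#' @param precursor_charge Charge used for the exclusion window (default 2).
#' @param exclusion_window Half-width in Th around the precursor m/z within
#'   which auto-picked candidates are skipped (default 3).
#' @param masses A [residue_mass_table()].
#' @return Data frame of fragment ions (`series`, `index`, `charge`, `mz`,
#'   `label`), ranked. If fewer candidates than `n` exist, all are returned
#'   with a warning.
#' @export
select_product_ions <- function(sequence, n = 3L,
                                policy = c("y-prefer", "explicit"),
                                ions = NULL, precursor_charge = 2L,
                                exclusion_window = 3,
                                masses = residue_mass_table()) {
  policy <- match.arg(policy)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  frags <- fragment_series(sequence, masses)
  frags$label <- paste0(frags$series, frags$index)

  if (policy == "explicit") {
    if (is.null(ions)) {
      stop("explicit policy requires 'ions'", call. = FALSE)
    }
    idx <- match(ions, frags$label)
    if (anyNA(idx)) {
      stop("unknown ion label(s) for ", sequence, ": ",
           paste(ions[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    out <- frags[idx, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }

  prec <- precursor_mz(sequence, precursor_charge, masses)
  cand <- frags[frags$series == "y" & frags$index >= 3L, , drop = FALSE]
  cand <- cand[abs(cand$mz - prec) > exclusion_window, , drop = FALSE]
  cand <- cand[order(-cand$mz), , drop = FALSE]
  if (nrow(cand) < n) {
    warning(sprintf("peptide %s: only %d product-ion candidates for n = %d",
                    sequence, nrow(cand), n))
    n <- nrow(cand)
  }
  out <- utils::head(cand, n)
  rownames(out) <- NULL
  out
}

#' Fit linear collision-energy and declustering-potential models
#'
#' Triple-quadrupole acquisition software computes per-precursor collision
#' energy (CE) and declustering potential (DP) from linear functions of the
#' precursor m/z, one line per charge state: `CE = a * mz + b`,
#' `DP = c * mz + d`. This fits both lines by ordinary least squares to
#' observed (m/z, value) pairs — for example the precursor rows of
#' [reference_precursors()] — and keeps the residuals for inspection.
#'
#' @param pairs_ce Data frame or matrix with columns `mz` and `ce`.
#' @param pairs_dp Data frame or matrix with columns `mz` and `dp`.
#' @return An object of class `instrument_model` with elements `ce_slope`,
#'   `ce_intercept`, `dp_slope`, `dp_intercept`, `ce_residuals`,
#'   `dp_residuals`.
#' @export
fit_instrument_model <- function(pairs_ce, pairs_dp) {
  pairs_ce <- as.data.frame(pairs_ce)
  pairs_dp <- as.data.frame(pairs_dp)
  for (p in list(pairs_ce, pairs_dp)) {
    if (nrow(p) < 2L || length(unique(p$mz)) < 2L) {
      stop("need >= 2 distinct m/z values to fit a line", call. = FALSE)
    }
  }
  fit_ce <- stats::lm(ce ~ mz, data = pairs_ce)
  fit_dp <- stats::lm(dp ~ mz, data = pairs_dp)
  structure(
    list(
      ce_slope = unname(stats::coef(fit_ce)[2L]),
      ce_intercept = unname(stats::coef(fit_ce)[1L]),
      dp_slope = unname(stats::coef(fit_dp)[2L]),
      dp_intercept = unname(stats::coef(fit_dp)[1L]),
      ce_residuals = unname(stats::resid(fit_ce)),
      dp_residuals = unname(stats::resid(fit_dp))
    ),
    class = "instrument_model"
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("instrument_model (linear in precursor m/z)\n")
  cat(sprintf("  CE = %.5f * mz + %.3f   (max |resid| %.3f V)\n",
              x$ce_slope, x$ce_intercept, max(abs(x$ce_residuals))))
  cat(sprintf("  DP = %.5f * mz + %.3f   (max |resid| %.3f V)\n",
              x$dp_slope, x$dp_intercept, max(abs(x$dp_residuals))))
  invisible(x)
}

#' Default instrument model fitted to the reference assay
#'
#' Least-squares CE/DP lines over the six precursor rows of
#' [reference_precursors()] (2+ tryptic precursors on a QTRAP). These ship
#' as the design default and are refittable from any user-supplied pairs
#' via [fit_instrument_model()].
#'
#' @return An `instrument_model`.
#' @export
default_instrument_model <- function() {
  prec <- reference_precursors()
  fit_instrument_model(
    data.frame(mz = prec$precursor_mz, ce = prec$ce_volts),
    data.frame(mz = prec$precursor_mz, dp = prec$dp_volts)
  )
}

#' Predict collision energy and declustering potential
#'
#' Evaluates the fitted lines of an [fit_instrument_model()] at a precursor
#' m/z. Values are returned at full precision; export rounds to one decimal
#' volt ([export_transition_list()]).
#'
#' @param model An `instrument_model`.
#' @param precursor_mz Precursor m/z (vectorised).
#' @return List with numeric vectors `ce` and `dp` (volts).
#' @export
predict_params <- function(model, precursor_mz) {
  stopifnot(inherits(model, "instrument_model"))
  list(
    ce = model$ce_slope * precursor_mz + model$ce_intercept,
    dp = model$dp_slope * precursor_mz + model$dp_intercept
  )
}

#' Default assay-design settings
#'
#' Collects every tunable of [build_transition_table()] with the defaults
#' used for the bundled protease assay: fully tryptic digestion under the
#' Keil rule, candidate length 8-25, C/M exclusion, 2+ precursors, three 1+
#' y-series products per peptide.
#'
#' @param ... Named overrides of any default.
#' @return Named list of settings.
#' @export
design_settings <- function(...) {
  defaults <- list(
    missed_cleavages = 0L,
    rule = "keil",
    min_len = 8L,
    max_len = 25L,
    excluded_residues = c("C", "M"),
    collapse_il = FALSE,
    precursor_charge = 2L,
    n_products = 3L,
    policy = "y-prefer",
    explicit_ions = NULL,   # named list: peptide -> ion labels
    quantifier_ions = NULL, # named character: peptide -> ion label
    exclusion_window = 3,
    rt = NULL,              # named numeric: peptide -> retention time (min)
    model = NULL,           # instrument_model; default fitted reference
    background = NULL       # background digest for proteotypicity
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown design setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, overrides)
}

#' Build a transition table for target proteins
#'
#' The full design chain: tryptic digestion of each protein, candidate
#' filtering, per-peptide doubly protonated precursor m/z, product-ion
#' selection (automatic or explicit), CE/DP prediction from the instrument
#' model, and quantifier flagging (exactly one quantifier transition per
#' peptide; default the highest-ranked product, overridable through
#' `settings$quantifier_ions`).
#'
#' Under the explicit product-ion policy only peptides listed in
#' `settings$explicit_ions` are retained — an explicit ion list defines the
#' assay.
#'
#' @param proteins List of [protein_record()] objects (mature chains for
#'   secreted targets).
#' @param settings A [design_settings()] list.
#' @param masses A [residue_mass_table()].
#' @return Data frame with one row per transition: `protein_id`, `peptide`,
#'   `peptide_start`, `peptide_end`, `precursor_mz`, `precursor_charge`,
#'   `product_ion`, `product_mz`, `product_charge`, `dp_volts`, `ce_volts`,
#'   `rt_min` (NA when unknown), `quantifier`.
#' @export
build_transition_table <- function(proteins, settings = design_settings(),
                                   masses = residue_mass_table()) {
  model <- settings$model
  if (is.null(model)) model <- default_instrument_model()

  all_rows <- list()
  for (protein in proteins) {
    digest <- tryptic_digest(protein, settings$missed_cleavages,
                             settings$rule)
    cand <- filter_candidates(digest, settings$min_len, settings$max_len,
                              settings$excluded_residues,
                              settings$background, settings$collapse_il)
    if (settings$policy == "explicit") {
      cand <- cand[cand$sequence %in% names(settings$explicit_ions), ,
                   drop = FALSE]
    }
    if (nrow(cand) == 0L) {
      warning("protein '", protein$id, "' yields no candidate peptides")
      next
    }
    for (i in seq_len(nrow(cand))) {
      pep <- cand$sequence[i]
      prec <- precursor_mz(pep, settings$precursor_charge, masses)
      prods <- if (settings$policy == "explicit") {
        select_product_ions(pep, policy = "explicit",
                            ions = settings$explicit_ions[[pep]],
                            masses = masses)
      } else {
        select_product_ions(pep, n = settings$n_products,
                            policy = "y-prefer",
                            precursor_charge = settings$precursor_charge,
                            exclusion_window = settings$exclusion_window,
                            masses = masses)
      }
      pars <- predict_params(model, prec)
      quant_ion <- settings$quantifier_ions[[pep]]
      quant <- if (is.null(quant_ion)) {
        seq_len(nrow(prods)) == 1L
      } else {
        prods$label == quant_ion
      }
      if (sum(quant) != 1L) {
        stop("peptide ", pep, ": quantifier selection did not yield exactly",
             " one transition", call. = FALSE)
      }
      rt <- settings$rt[[pep]]
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        protein_id = protein$id,
        peptide = pep,
        peptide_start = cand$start[i],
        peptide_end = cand$end[i],
        precursor_mz = prec,
        precursor_charge = settings$precursor_charge,
        product_ion = prods$label,
        product_mz = prods$mz,
        product_charge = 1L,
        dp_volts = pars$dp,
        ce_volts = pars$ce,
        rt_min = if (is.null(rt)) NA_real_ else rt,
        quantifier = quant,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(all_rows) == 0L) {
    return(data.frame())
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out
}

#' Export a transition list as CSV
#'
#' Writes the transition table in the column layout accepted by vendor
#' acquisition software: m/z to 2 decimals, volts to 1 decimal, missing
#' retention times as empty fields. Row order is stable (protein, peptide
#' start, product rank as built), so re-export of identical input is
#' byte-identical.
#'
#' @param transitions Data frame from [build_transition_table()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_transition_list <- function(transitions, path) {
  if (nrow(transitions) == 0L) {
    stop("refusing to export an empty transition list", call. = FALSE)
  }
  fmt <- data.frame(
    protein_id = transitions$protein_id,
    peptide = transitions$peptide,
    precursor_mz = sprintf("%.2f", transitions$precursor_mz),
    precursor_charge = transitions$precursor_charge,
    product_ion = transitions$product_ion,
    product_mz = sprintf("%.2f", transitions$product_mz),
    product_charge = transitions$product_charge,
    dp_volts = sprintf("%.1f", transitions$dp_volts),
    ce_volts = sprintf("%.1f", transitions$ce_volts),
    rt_min = ifelse(is.na(transitions$rt_min), "",
                    sprintf("%.2f", transitions$rt_min)),
    quantifier = tolower(as.character(transitions$quantifier)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
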