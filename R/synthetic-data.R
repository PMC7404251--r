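#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so simulation determinism never leaks into (or depends on) the session's
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-trace sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

#' Chromatogram simulation configuration
#'
#' Parameters of the synthetic MRM trace generator. A trace is a uniform
#' time grid (default 0.005 min steps over a 15-min run, matching a 20-ms
#' dwell duty cycle) carrying one Gaussian elution peak whose area is
#' linear in analyte concentration, on an additive-noise baseline:
#' `area = response_factor * concentration` (area units per ug/mL), peak
#' standard deviation `peak_sigma` minutes, apex drawn once per trace from
#' `N(rt_mean, rt_jitter_sd)`, baseline `baseline_level` counts with
#' Gaussian noise of SD `baseline_noise_sd`, intensities floored at zero.
#'
#' Optional behaviours: detector saturation (above `saturation_level`
#' ug/mL the incremental response is compressed by
#' `saturation_compression`, emulating loss of calibration linearity at the
#' top of a dilution series) and a contaminant peak (with probability
#' `interference_probability` a second Gaussian of area `interference_area`
#' appears `interference_offset` minutes after the analyte).
#'
#' `confirmatory_scale` gives the relative response of a peptide's 1st,
#' 2nd, 3rd... product ion: fragment intensities differ per transition, the
#' quantifier being the most responsive.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  defaults <- list(
    response_factor = 1e5,       # area units per (ug/mL)
    rt_mean = 1.0,               # min; per-transition values come from assay
    rt_jitter_sd = 0.01,         # min
    peak_sigma = 0.02,           # min (~2.8 s FWHM, UHPLC-like)
    baseline_level = 50,         # counts
    baseline_noise_sd = 10,      # counts
    interference_probability = 0,
    interference_offset = 0.3,   # min
    interference_area = 1e3,     # area units
    grid_step = 0.005,           # min (20-ms dwell cycle)
    run_length = 15,             # min total run
    saturation_level = Inf,      # ug/mL; Inf = perfectly linear
    saturation_compression = 0.3,
    confirmatory_scale = c(1, 0.6, 0.35)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown simulation setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (cfg$response_factor <= 0) stop("response_factor must be > 0",
                                     call. = FALSE)
  if (cfg$peak_sigma <= 0) stop("peak_sigma must be > 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# Saturation model: linear up to saturation_level, compressed above.
effective_area <- function(concentration, config) {
  rf <- config$response_factor
  sat <- config$saturation_level
  if (concentration <= sat) {
    rf * concentration
  } else {
    rf * (sat + config$saturation_compression * (concentration - sat))
  }
}

#' Simulate one MRM chromatogram trace
#'
#' Generates the time/intensity series of a single transition in a single
#' sample under the model described in [simulation_config()]. Identical
#' `seed` and inputs give an identical trace.
#'
#' @param transition_key Character key `"<peptide>+<ion>"`, e.g.
#'   `"NAVDTANNR+y8"`, or a list with elements `peptide` and `product_ion`.
#' @param concentration Analyte concentration in ug/mL (>= 0).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param sample_id Sample identifier stored on the trace.
#' @param rt_mean Elution-time mean in minutes (defaults to
#'   `config$rt_mean`).
#' @param response_factor Area units per ug/mL (defaults to
#'   `config$response_factor`).
#' @return Object of class `chromatogram_trace`: `sample_id`, `peptide`,
#'   `product_ion`, `times`, `intensities`, and a `meta` list carrying the
#'   simulation truth (`concentration`, `rt_true`, `true_area`).
#' @export
simulate_trace <- function(transition_key, concentration,
                           config = simulation_config(), seed = 1L,
                           sample_id = "sample",
                           rt_mean = config$rt_mean,
                           response_factor = config$response_factor) {
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  key <- parse_transition_key(transition_key)
  if (4 * config$peak_sigma / config$grid_step < 8) {
    stop("grid too coarse: fewer than 8 points across +-2 peak sigma",
         call. = FALSE)
  }
  times <- seq(0, config$run_length, by = config$grid_step)
  if (rt_mean - 5 * config$peak_sigma < times[1L] ||
      rt_mean + 5 * config$peak_sigma > times[length(times)]) {
    stop("time grid does not cover rt_mean +- 5 peak sigma", call. = FALSE)
  }
  local_cfg <- config
  local_cfg$response_factor <- response_factor
  area <- effective_area(concentration, local_cfg)

  with_seed(seed, {
    rt <- stats::rnorm(1L, rt_mean, config$rt_jitter_sd)
    amp <- area / (config$peak_sigma * sqrt(2 * pi))
    y <- amp * exp(-(times - rt)^2 / (2 * config$peak_sigma^2)) +
      config$baseline_level
    if (config$interference_probability > 0 &&
        stats::runif(1L) < config$interference_probability) {
      iamp <- config$interference_area / (config$peak_sigma * sqrt(2 * pi))
      irt <- rt + config$interference_offset
      y <- y + iamp * exp(-(times - irt)^2 / (2 * config$peak_sigma^2))
    }
    if (config$baseline_noise_sd > 0) {
      y <- y + stats::rnorm(length(times), 0, config$baseline_noise_sd)
    }
    y <- pmax(y, 0)
    structure(
      list(
        sample_id = sample_id,
        peptide = key$peptide,
        product_ion = key$product_ion,
        times = times,
        intensities = y,
        meta = list(concentration = concentration, rt_true = rt,
                    true_area = area)
      ),
      class = "chromatogram_trace"
    )
  })
}

#' @export
print.chromatogram_trace <- function(x, ...) {
  cat(sprintf(
    "chromatogram_trace %s %s+%s: %d points over %.2f min (conc %.4g)\n",
    x$sample_id, x$peptide, x$product_ion, length(x$times),
    x$times[length(x$times)], x$meta$concentration))
  invisible(x)
}

parse_transition_key <- function(transition_key) {
  if (is.list(transition_key)) {
    stopifnot(!is.null(transition_key$peptide),
              !is.null(transition_key$product_ion))
    return(transition_key[c("peptide", "product_ion")])
  }
  parts <- strsplit(transition_key, "+", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    stop("transition key must be '<peptide>+<ion>', got '", transition_key,
         "'", call. = FALSE)
  }
  list(peptide = parts[1L], product_ion = parts[2L])
}

#' Default calibration levels
#'
#' The decade series 3.3 x 10^-k (k = 0..3) plus its midpoints, spanning
#' the 0.0033-3.3 ug/mL serial-dilution range of the protease calibration
#' series.
#'
#' @return Numeric vector of concentrations in ug/mL, ascending.
#' @export
default_calibration_levels <- function() {
  sort(c(3.3 * 10^-(0:3), 1.65 * 10^-(0:2)))
}

#' Simulate a calibration dilution series
#'
#' One trace per level x replicate with independent noise, for a single
#' transition. Levels default to [default_calibration_levels()]. Detector
#' saturation is controlled through `config$saturation_level`.
#'
#' @param levels Concentrations in ug/mL, all > 0.
#' @param replicates Replicates per level (>= 1).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param transition_key Transition simulated (default the AprBp
#'   quantifier).
#' @param rt_mean Elution time, minutes.
#' @return List of `chromatogram_trace` objects; each carries its nominal
#'   `level` and `replicate` in `meta`.
#' @export
simulate_calibration_series <- function(levels = default_calibration_levels(),
                                        replicates = 3L,
                                        config = simulation_config(),
                                        seed = 1L,
                                        transition_key = "NAVDTANNR+y8",
                                        rt_mean = config$rt_mean) {
  if (any(levels <= 0)) stop("calibration levels must be > 0", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  traces <- vector("list", length(levels) * replicates)
  k <- 0L
  for (i in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      tr <- simulate_trace(
        transition_key, levels[i], config,
        seed = derive_seed(seed, k),
        sample_id = sprintf("cal_L%02d_r%d", i, r),
        rt_mean = rt_mean
      )
      tr$meta$level <- levels[i]
      tr$meta$replicate <- r
      traces[[k]] <- tr
    }
  }
  traces
}

#' Bundled strain-panel sample sheet
#'
#' The simulation fixture mirroring the published strain panel: the
#' wild-type B. pumilus 3-19 positive control and the protease-deficient
#' B. subtilis AT1 negative control (both grown without inducer), plus four
#' recombinant B. subtilis strains carrying the AprBp or GseBp gene behind
#' the bacitracin-inducible LIKE expression system, each with and without
#' induction - 10 samples.
#'
#' Ground truth is defined on the supernatant (SN) scale, where all
#' published strain comparisons are stated: `true_sn_*` carries the
#' published SN concentration of each target, and `true_vial_*` is the
#' corresponding in-vial concentration through the vial-total constant
#' (16.5 ug/mL, see [supernatant_conc()]):
#' `vial = sn * 16.5 / total_protein_sn`. The derived vials agree with the
#' published vial column to within printing round-off for every row except
#' the MRB046 uninduced sample, whose published vial and SN values are
#' mutually inconsistent; there the SN value is taken as truth.
#'
#' @return Data frame with columns `sample_id`, `strain`, `induced`,
#'   `total_protein_sn`, `true_vial_AprBp`, `true_vial_GseBp`,
#'   `true_sn_AprBp`, `true_sn_GseBp`.
#' @export
example_sample_sheet <- function() {
  vial_total <- 16.5
  sheet <- data.frame(
    sample_id = c("Bp3_19", "AT1", "MRB044_unind", "MRB044_ind",
                  "MRB046_unind", "MRB046_ind", "MRB047_unind",
                  "MRB047_ind", "MRB049_unind", "MRB049_ind"),
    strain = c("B_pumilus_3-19", "AT1", "MRB044", "MRB044", "MRB046",
               "MRB046", "MRB047", "MRB047", "MRB049", "MRB049"),
    induced = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                FALSE, TRUE),
    total_protein_sn = c(4.5, 0.32, 2, 5, 1.3, 1.8, 1.2, 1.65, 2.06, 3.2),
    true_sn_AprBp = c(1.63, 0, 0.024, 1.5, 0.005, 0.03, 0, 0, 0, 0),
    true_sn_GseBp = c(1.3, 0, 0, 0, 0, 0, 0.00036, 0.005, 0.006, 0.06),
    stringsAsFactors = FALSE
  )
  sheet$true_vial_AprBp <-
    sheet$true_sn_AprBp * vial_total / sheet$total_protein_sn
  sheet$true_vial_GseBp <-
    sheet$true_sn_GseBp * vial_total / sheet$total_protein_sn
  sheet
}

#' Read / write a sample sheet
#'
#' Plain CSV mirror of the sheet format of [example_sample_sheet()].
#' @param sheet Sample-sheet data frame.
#' @param path CSV path.
#' @return `read_sample_sheet` returns the data frame; the writer returns
#'   the path invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path,
                               call. = FALSE)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  num <- grep("^(total_protein_sn|true_)", names(sheet))
  for (j in num) {
    if (any(sheet[[j]] < 0)) stop("concentrations must be >= 0",
                                  call. = FALSE)
  }
  sheet
}

# Strip a chain suffix from an assay protein id ("AprBp_mature" -> "AprBp").
target_of <- function(protein_id) {
  sub("_(signal|propeptide|mature)$", "", protein_id)
}

#' Simulate a whole study from a sample sheet and an assay
#'
#' One trace per sample x assay transition, at the sample's true in-vial
#' concentration of the transition's target protein. Negative-control
#' samples (true concentration 0) yield baseline-only traces. Within a
#' peptide, product ions respond according to
#' `config$confirmatory_scale` (quantifier strongest).
#'
#' @param sheet Sample sheet; must carry a `true_vial_<target>` column for
#'   every target protein in the assay.
#' @param assay Transition table ([build_transition_table()] or
#'   [reference_assay()]); `rt_min` supplies per-transition elution times.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List of `chromatogram_trace` objects.
#' @export
simulate_study <- function(sheet, assay, config = simulation_config(),
                           seed = 1L) {
  targets <- unique(target_of(assay$protein_id))
  needed <- paste0("true_vial_", targets)
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s) for assay target(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  traces <- vector("list", nrow(sheet) * nrow(assay))
  k <- 0L
  for (s in seq_len(nrow(sheet))) {
    for (t in seq_len(nrow(assay))) {
      k <- k + 1L
      target <- target_of(assay$protein_id[t])
      conc <- sheet[[paste0("true_vial_", target)]][s]
      # product-ion rank within its peptide sets the relative response
      pep_rows <- which(assay$peptide == assay$peptide[t])
      rank <- match(t, pep_rows)
      scale <- config$confirmatory_scale[
        min(rank, length(config$confirmatory_scale))]
      rt <- assay$rt_min[t]
      if (is.na(rt)) rt <- config$rt_mean
      traces[[k]] <- simulate_trace(
        list(peptide = assay$peptide[t], product_ion = assay$product_ion[t]),
        conc, config,
        seed = derive_seed(seed, k),
        sample_id = sheet$sample_id[s],
        rt_mean = rt,
        response_factor = config$response_factor * scale
      )
    }
  }
  traces
}

#' Write / read chromatogram traces as long CSV
#'
#' Columns `sample_id`, `peptide`, `product_ion`, `time_min`, `intensity`.
#' The reader reconstructs one `chromatogram_trace` per
#' sample/peptide/ion combination (simulation truth metadata is not
#' persisted).
#'
#' @param traces List of `chromatogram_trace` objects.
#' @param path CSV path.
#' @return The path (writer, invisibly) or a list of traces (reader).
#' @export
write_traces <- function(traces, path) {
  blocks <- lapply(traces, function(tr) {
    data.frame(
      sample_id = tr$sample_id, peptide = tr$peptide,
      product_ion = tr$product_ion, time_min = tr$times,
      intensity = tr$intensities, stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  key <- paste(df$sample_id, df$peptide, df$product_ion, sep = "\r")
  unname(lapply(split(df, factor(key, levels = unique(key))), function(b) {
    structure(
      list(sample_id = b$sample_id[1L], peptide = b$peptide[1L],
           product_ion = b$product_ion[1L], times = b$time_min,
           intensities = b$intensity, meta = list()),
      class = "chromatogram_trace"
    )
  }))
}

#' Synthetic full-length protease sequences
#'
#' The full pre-pro-protein sequences of the two target proteases are not
#' publicly deposited; only their six proteotypic peptides are published.
#' These records are synthetic stand-ins of the documented lengths (381 aa
#' for AprBp, 303 aa for GseBp) with the documented chain layout (signal
#' peptide, propeptide, mature chain) whose mature chains release exactly
#' the six published peptides - at their published positions - under fully
#' tryptic digestion and default candidate filtering. Filler segments are
#' short (7-residue) or cysteine-containing tryptic peptides, so they fall
#' out of the candidate filter.
#'
#' @return List of two [protein_record()]s (`AprBp`, `GseBp`) with chains
#'   attached.
#' @export
synthetic_protease_records <- function() {
  f <- "GASTLVK" # filler peptide: length 7, dropped by the length filter
  apr_signal <- "VLKLGALSLLAGSTLVAAPSALAQSVSHA"                 # 1-29
  apr_pro <- paste0(strrep(f, 11L), "A")                        # 30-107
  apr_mature <- paste0(strrep(f, 18L), "AGCSTLVK",              # 108-381
                       "NAVDTANNR", strrep(f, 7L),
                       "APAVHAQGYK", strrep(f, 8L),
                       "LENTATPLGNSFYYGK")
  gse_signal <- "VLSGALLLAGSTLVAAPSALAQSVHA"                    # 1-26
  gse_pro <- paste0(strrep(f, 8L), "AGSTLV")                    # 27-88
  gse_mature <- paste0(strrep(f, 14L), "AGR",                   # 89-303
                       "TDTNIGNTVGYR", strrep(f, 6L),
                       "ISGYPGDK", strrep(f, 5L), "GGDR",
                       "ATAAFVEFINYAK")
  list(
    protein_record(
      "AprBp", paste0(apr_signal, apr_pro, apr_mature),
      description = "synthetic subtilisin-like protease construct (381 aa)",
      chains = list(chain_annotation("signal", 1, 29),
                    chain_annotation("propeptide", 30, 107),
                    chain_annotation("mature", 108, 381))
    ),
    protein_record(
      "GseBp", paste0(gse_signal, gse_pro, gse_mature),
      description = "synthetic glutamyl endopeptidase construct (303 aa)",
      chains = list(chain_annotation("signal", 1, 26),
                    chain_annotation("propeptide", 27, 88),
                    chain_annotation("mature", 89, 303))
    )
  )
}

#' Write protein records as FASTA
#'
#' @param records List of `protein_record` objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    header <- if (nzchar(rec$description)) {
      paste(rec$id, rec$description)
    } else {
      rec$id
    }
    writeLines(paste0(">", header), con)
    seq <- rec$sequence
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L,
                                           nchar(seq))), con)
  }
  invisible(path)
}
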