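#' Integrate a chromatographic peak
#'
#' Detects and integrates the analyte peak of one trace inside a retention
#' time window. The trace is smoothed with a moving polynomial
#' (Savitzky-Golay) filter; the apex is the smoothed maximum within the
#' window; the baseline is the median of the signal outside the window
#' (robust to a single interference peak elsewhere in the run); peak
#' boundaries are the nearest points on each side of the apex where the
#' smoothed signal returns to the baseline; the area is the trapezoidal
#' integral of the raw signal above baseline between the boundaries; and
#' the signal-to-noise ratio is the smoothed peak height over the robust SD
#' (MAD) of the off-window smoothing residuals. A flat, noiseless trace
#' yields area 0 and S/N 0. An apex on the window edge is flagged.
#'
#' @param trace A `chromatogram_trace`.
#' @param rt_window Numeric `c(min, max)` in minutes, inside the trace's
#'   time range.
#' @param smooth_window Savitzky-Golay window length in points (odd,
#'   default 7).
#' @param smooth_order Polynomial order (default 2).
#' @return Object of class `peak_result`: `apex_rt`, `area` (intensity x
#'   minutes, baseline-subtracted, >= 0), `height`, `signal_to_noise`,
#'   `boundaries` (start/end minutes), `baseline`, `flagged_edge`.
#' @export
integrate_peak <- function(trace, rt_window, smooth_window = 7L,
                           smooth_order = 2L) {
  times <- trace$times
  y <- trace$intensities
  if (length(rt_window) != 2L || rt_window[1L] >= rt_window[2L]) {
    stop("rt_window must be c(min, max) with min < max", call. = FALSE)
  }
  if (rt_window[1L] < times[1L] || rt_window[2L] > times[length(times)]) {
    stop("rt_window lies outside the trace time range", call. = FALSE)
  }
  sm <- signal::sgolayfilt(y, p = smooth_order, n = smooth_window)
  inw <- which(times >= rt_window[1L] & times <= rt_window[2L])
  if (length(inw) < smooth_window) {
    stop("rt_window too narrow for the smoothing window", call. = FALSE)
  }
  out <- setdiff(seq_along(times), inw)
  baseline <- stats::median(y[out])

  apex_local <- which.max(sm[inw])
  apex <- inw[apex_local]
  flagged_edge <- apex_local == 1L || apex_local == length(inw)

  lo <- apex
  while (lo > inw[1L] && sm[lo - 1L] > baseline) lo <- lo - 1L
  hi <- apex
  while (hi < inw[length(inw)] && sm[hi + 1L] > baseline) hi <- hi + 1L

  idx <- lo:hi
  area <- 0
  if (length(idx) > 1L) {
    dy <- y[idx] - baseline
    area <- sum(diff(times[idx]) * (dy[-length(dy)] + dy[-1L]) / 2)
  }
  area <- max(area, 0)
  height <- max(sm[apex] - baseline, 0)
  noise <- stats::mad(y[out] - sm[out])
  sn <- if (height == 0) 0 else if (noise == 0) Inf else height / noise

  structure(
    list(apex_rt = times[apex], area = area, height = height,
         signal_to_noise = sn,
         boundaries = c(start = times[lo], end = times[hi]),
         baseline = baseline, flagged_edge = flagged_edge),
    class = "peak_result"
  )
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf(
    "peak_result: apex %.3f min, area %.4g, height %.4g, S/N %.3g%s\n",
    x$apex_rt, x$area, x$height, x$signal_to_noise,
    if (x$flagged_edge) " [apex on window edge]" else ""))
  invisible(x)
}

#' Decide peptide detectability from its transitions
#'
#' A peptide counts as detected in a sample when every one of its
#' transitions shows a peak with signal-to-noise of at least `sn_min`
#' (default 3) and all transition apexes co-elute within `rt_tolerance`
#' minutes (default 0.1). Co-elution across at least two transitions is
#' what distinguishes the analyte from an interfering signal, so fewer than
#' two transitions is an error.
#'
#' @param peaks Named list of `peak_result` objects, one per transition of
#'   the peptide in one sample (names are ion labels).
#' @param rt_tolerance Maximum apex spread in minutes.
#' @param sn_min Minimum per-transition signal-to-noise.
#' @return List with `detected` (logical) and `report` (per-transition data
#'   frame with `ion`, `apex_rt`, `sn`, `sn_pass`, plus apex spread and the
#'   co-elution verdict as attributes).
#' @export
detect_peptide <- function(peaks, rt_tolerance = 0.1, sn_min = 3) {
  if (length(peaks) < 2L) {
    stop("co-elution is undefined for fewer than 2 transitions",
         call. = FALSE)
  }
  ions <- names(peaks)
  if (is.null(ions)) ions <- paste0("T", seq_along(peaks))
  sn <- vapply(peaks, function(p) p$signal_to_noise, numeric(1L))
  apex <- vapply(peaks, function(p) p$apex_rt, numeric(1L))
  sn_pass <- sn >= sn_min
  spread <- max(apex) - min(apex)
  coelute <- spread <= rt_tolerance
  report <- data.frame(ion = ions, apex_rt = unname(apex), sn = unname(sn),
                       sn_pass = unname(sn_pass), stringsAsFactors = FALSE)
  attr(report, "apex_spread") <- spread
  attr(report, "coelute") <- coelute
  list(detected = all(sn_pass) && coelute, report = report)
}

#' Integrate a set of traces against an assay
#'
#' Convenience wrapper: integrates every trace in a window centred on its
#' transition's expected retention time and returns a per-trace peak
#' report.
#'
#' @param traces List of `chromatogram_trace` objects.
#' @param assay Transition table supplying `peptide`, `product_ion`,
#'   `rt_min` and `quantifier`.
#' @param half_width Half-width of the integration window in minutes.
#' @param smooth_window,smooth_order Passed to [integrate_peak()].
#' @return Data frame with one row per trace: `sample_id`, `peptide`,
#'   `product_ion`, `quantifier`, `apex_rt`, `area`, `height`, `sn`,
#'   `flagged_edge`.
#' @export
integrate_traces <- function(traces, assay, half_width = 0.15,
                             smooth_window = 7L, smooth_order = 2L) {
  akey <- paste(assay$peptide, assay$product_ion)
  rows <- lapply(traces, function(tr) {
    i <- match(paste(tr$peptide, tr$product_ion), akey)
    if (is.na(i)) {
      stop("trace ", tr$peptide, "+", tr$product_ion,
           " has no matching assay transition", call. = FALSE)
    }
    rt <- assay$rt_min[i]
    pk <- integrate_peak(tr, c(rt - half_width, rt + half_width),
                         smooth_window, smooth_order)
    data.frame(
      sample_id = tr$sample_id, peptide = tr$peptide,
      product_ion = tr$product_ion, quantifier = assay$quantifier[i],
      apex_rt = pk$apex_rt, area = pk$area, height = pk$height,
      sn = pk$signal_to_noise, flagged_edge = pk$flagged_edge,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sample peptide detection from a peak report
#'
#' Applies [detect_peptide()]'s rules to every sample x peptide group of an
#' [integrate_traces()] report.
#'
#' @param peak_report Data frame from [integrate_traces()].
#' @param rt_tolerance,sn_min As in [detect_peptide()].
#' @return Data frame with `sample_id`, `peptide`, `n_transitions`,
#'   `apex_spread`, `detected`.
#' @export
detection_report <- function(peak_report, rt_tolerance = 0.1, sn_min = 3) {
  groups <- split(peak_report,
                  list(peak_report$sample_id, peak_report$peptide),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    spread <- max(g$apex_rt) - min(g$apex_rt)
    data.frame(
      sample_id = g$sample_id[1L], peptide = g$peptide[1L],
      n_transitions = nrow(g), apex_spread = spread,
      detected = all(g$sn >= sn_min) && spread <= rt_tolerance &&
        nrow(g) >= 2L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}
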