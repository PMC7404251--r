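# r-squared of an (optionally weighted) lm fit, without summary.lm's
# perfect-fit warning on exact synthetic data.
fit_r2 <- function(fit) {
  y <- fit$model[[1L]]
  w <- fit$weights
  if (is.null(w)) w <- rep(1, length(y))
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  if (ss_tot == 0) return(NaN)
  1 - sum(w * stats::resid(fit)^2) / ss_tot
}

#' Determine the linear range of a calibration series
#'
#' Starting from the full level set, the highest level is dropped while the
#' coefficient of determination of a straight-line fit over the level means
#' stays below `r2_min`. The upper bound of the linear range is the highest
#' retained level - the standard way a dilution series loses its top end to
#' detector saturation. The lower bound returned here is simply the lowest
#' level; [fit_calibration()] tightens it to the LLOQ when replicate
#' information is available.
#'
#' @param levels Nominal concentrations (ug/mL), one per area measurement;
#'   replicates appear as repeated values.
#' @param areas Peak areas, same length as `levels`.
#' @param r2_min Minimum acceptable r-squared (default 0.99).
#' @return Numeric `c(low, high)`.
#' @export
linear_range <- function(levels, areas, r2_min = 0.99) {
  stopifnot(length(levels) == length(areas))
  means <- tapply(areas, levels, mean)
  lv <- sort(as.numeric(names(means)))
  mv <- as.numeric(means[as.character(lv)])
  repeat {
    if (length(lv) < 3L) {
      stop("fewer than 3 levels remain inside the linear range",
           call. = FALSE)
    }
    fit <- stats::lm(mv ~ lv)
    r2 <- fit_r2(fit)
    if (is.nan(r2)) stop("degenerate calibration: all areas equal",
                         call. = FALSE)
    if (r2 >= r2_min) break
    lv <- lv[-length(lv)]
    mv <- mv[-length(mv)]
  }
  c(low = lv[1L], high = lv[length(lv)])
}

#' Lower limit of quantification
#'
#' Standard bioanalytical rule: the LLOQ is the lowest calibration level
#' whose back-calculated concentration (through the fitted line) is within
#' `accuracy_tol` of nominal and whose replicate-area coefficient of
#' variation is at most `cv_max`. Levels are scanned in ascending order and
#' the first qualifying level is returned; `NA` with a warning if none
#' qualifies.
#'
#' @param levels,areas As in [linear_range()]; at least 2 replicates per
#'   candidate level are required for the CV criterion.
#' @param slope,intercept Fitted calibration line.
#' @param accuracy_tol Relative accuracy tolerance (default 0.20, i.e.
#'   +-20%).
#' @param cv_max Maximum replicate CV (default 0.20).
#' @return The LLOQ in ug/mL, or `NA` if no level qualifies.
#' @export
lloq <- function(levels, areas, slope, intercept,
                 accuracy_tol = 0.20, cv_max = 0.20) {
  stopifnot(length(levels) == length(areas), slope > 0)
  for (lv in sort(unique(levels))) {
    a <- areas[levels == lv]
    if (length(a) < 2L) {
      warning("level ", lv, " has < 2 replicates; skipped for LLOQ")
      next
    }
    back <- (mean(a) - intercept) / slope
    accuracy_ok <- abs(back / lv - 1) <= accuracy_tol
    cv_ok <- stats::sd(a) / mean(a) <= cv_max
    if (accuracy_ok && cv_ok) return(lv)
  }
  warning("no calibration level satisfies the LLOQ criteria")
  NA_real_
}

#' Fit a calibration curve
#'
#' Least-squares straight line (optionally 1/x-weighted, for series whose
#' information is concentrated at the low end) over the levels inside the
#' linear range, which is first determined by [linear_range()]. The LLOQ is
#' then evaluated from the replicates via [lloq()]. r-squared is reported
#' on the retained points.
#'
#' @param levels,areas Nominal concentrations and peak areas (replicates as
#'   repeated levels); at least 3 distinct levels.
#' @param weighting `"none"` or `"1/x"`.
#' @param r2_min Passed to [linear_range()].
#' @param accuracy_tol,cv_max Passed to [lloq()].
#' @param target Identifier stored on the curve.
#' @return Object of class `calibration_curve`: `target`, `slope`,
#'   `intercept`, `r_squared`, `linear_range` (low = LLOQ when
#'   determinable), `lloq`, `weighting`, `flags`.
#' @export
fit_calibration <- function(levels, areas, weighting = c("none", "1/x"),
                            r2_min = 0.99, accuracy_tol = 0.20,
                            cv_max = 0.20, target = "target") {
  weighting <- match.arg(weighting)
  stopifnot(length(levels) == length(areas))
  if (length(unique(levels)) < 3L) {
    stop("calibration requires >= 3 distinct levels", call. = FALSE)
  }
  if (length(unique(areas)) == 1L) {
    stop("degenerate calibration: all areas equal", call. = FALSE)
  }
  rng <- linear_range(levels, areas, r2_min)
  keep <- levels <= rng[["high"]]
  lv <- levels[keep]
  ar <- areas[keep]
  w <- if (weighting == "1/x") 1 / lv else NULL
  fit <- stats::lm(ar ~ lv, weights = w)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0) stop("calibration slope is not positive", call. = FALSE)
  q <- suppressWarnings(
    lloq(lv, ar, slope, intercept, accuracy_tol, cv_max)
  )
  flags <- character(0L)
  if (is.na(q)) flags <- c(flags, "no_level_meets_lloq_criteria")
  low <- if (is.na(q)) rng[["low"]] else q
  structure(
    list(target = target, slope = slope, intercept = intercept,
         r_squared = fit_r2(fit),
         linear_range = c(low = low, high = rng[["high"]]),
         lloq = q, weighting = weighting, flags = flags),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve [%s]\n", x$target))
  cat(sprintf("  area = %.5g * conc + %.5g   (r^2 = %.5f, weighting %s)\n",
              x$slope, x$intercept, x$r_squared, x$weighting))
  cat(sprintf("  linear range %.4g - %.4g ug/mL, LLOQ %.4g ug/mL\n",
              x$linear_range[["low"]], x$linear_range[["high"]], x$lloq))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a peak area to an in-vial concentration
#'
#' Inverts the calibration line: `conc = (area - intercept) / slope`.
#' Negative back-calculations are clamped to 0 and flagged `below_lloq`;
#' results under the LLOQ or above the linear range are flagged
#' accordingly.
#'
#' @param curve A [fit_calibration()] curve.
#' @param area Peak area(s).
#' @return Data frame with `vial_conc`, `below_lloq`,
#'   `above_linear_range`.
#' @export
quantify_area <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  conc <- (area - curve$intercept) / curve$slope
  below <- rep(FALSE, length(conc))
  below[conc < 0] <- TRUE
  conc[conc < 0] <- 0
  if (!is.na(curve$lloq)) below <- below | conc < curve$lloq
  above <- conc > curve$linear_range[["high"]]
  data.frame(vial_conc = conc, below_lloq = below,
             above_linear_range = above)
}

#' Back-calculate the supernatant concentration of a target
#'
#' The measured in-vial concentration reflects the target's share of the
#' fixed amount of total protein loaded per vial. Rescaling that mass
#' fraction to the culture supernatant's total-protein concentration gives
#' the secreted concentration:
#' `sn_conc = vial_conc * total_protein_sn / vial_total_conc`.
#'
#' The default `vial_total_conc` of 16.5 ug/mL is the constant implied by
#' the published strain panel (the per-vial total-protein load is not
#' reported directly); it is a configuration default, always overridable.
#'
#' @param vial_conc Target concentration in the measurement vial (ug/mL).
#' @param total_protein_sn Total protein concentration in the supernatant
#'   (ug/mL).
#' @param vial_total_conc Total protein concentration in the vial (ug/mL),
#'   > 0.
#' @return Supernatant concentration in ug/mL (vectorised).
#' @examples
#' supernatant_conc(6, 4.5)      # ~1.64
#' supernatant_conc(0.005, 1.2)  # ~0.00036
#' @export
supernatant_conc <- function(vial_conc, total_protein_sn,
                             vial_total_conc = 16.5) {
  if (any(vial_total_conc <= 0)) {
    stop("vial_total_conc must be > 0", call. = FALSE)
  }
  if (any(vial_conc < 0) || any(total_protein_sn < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  vial_conc * total_protein_sn / vial_total_conc
}

#' Fold change between two concentrations
#'
#' `conc_a / conc_b`. A zero denominator (e.g. a negative-control sample in
#' which the target was not detected) makes the ratio not computable and
#' returns `NA` carrying a `reason` attribute.
#'
#' @param conc_a Numerator concentration.
#' @param conc_b Denominator concentration.
#' @return The ratio, or flagged `NA` when `conc_b` is 0.
#' @examples
#' fold_change(0.06, 0.005) # 12
#' fold_change(1.5, 0.03)   # 50
#' @export
fold_change <- function(conc_a, conc_b) {
  if (length(conc_a) != 1L || length(conc_b) != 1L) {
    stop("fold_change takes scalar concentrations", call. = FALSE)
  }
  if (conc_b == 0) {
    return(structure(NA_real_, reason = "not computable (zero denominator)"))
  }
  conc_a / conc_b
}

#' Strain-comparison report
#'
#' Assembles per-sample quantification results into the strain-panel
#' layout: per strain and inducer state the total supernatant protein, the
#' in-vial and supernatant target concentrations; induction fold-changes
#' (induced vs uninduced supernatant concentration per strain and target);
#' and cross-strain ratios against a reference strain, matched on target.
#' Ratios with a zero denominator are reported as not computable; samples
#' present in the sheet but missing from the results are listed, never
#' silently dropped.
#'
#' @param results Data frame with one row per sample x target:
#'   `sample_id`, `target`, `area`, `vial_conc`, `sn_conc`, `detected`.
#' @param sheet Sample sheet ([example_sample_sheet()] layout).
#' @param reference_strain Strain name used for cross-strain ratios.
#' @return Object of class `strain_report`: list with `samples` (joined
#'   table), `induction` (per strain x target fold-changes),
#'   `vs_reference`, `missing`.
#' @export
strain_report <- function(results, sheet,
                          reference_strain = "B_pumilus_3-19") {
  meta <- sheet[, c("sample_id", "strain", "induced", "total_protein_sn")]
  joined <- merge(meta, results, by = "sample_id", all.x = TRUE,
                  sort = FALSE)
  missing <- unique(joined$sample_id[is.na(joined$target)])
  joined <- joined[!is.na(joined$target), , drop = FALSE]
  joined <- joined[order(joined$target, joined$strain, joined$induced), ,
                   drop = FALSE]
  rownames(joined) <- NULL

  # induction fold-changes (strains measured in both inducer states)
  ind_rows <- list()
  for (target in unique(joined$target)) {
    sub <- joined[joined$target == target, , drop = FALSE]
    for (strain in unique(sub$strain)) {
      g <- sub[sub$strain == strain, , drop = FALSE]
      if (!any(g$induced) || !any(!g$induced)) next
      num <- g$sn_conc[g$induced][1L]
      den <- g$sn_conc[!g$induced][1L]
      fc <- fold_change(num, den)
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        strain = strain, target = target, sn_uninduced = den,
        sn_induced = num, fold = as.numeric(fc),
        computable = !is.na(fc), stringsAsFactors = FALSE
      )
    }
  }
  induction <- if (length(ind_rows)) do.call(rbind, ind_rows) else
    data.frame()

  # cross-strain ratios vs the reference strain (matched target)
  ref_rows <- list()
  for (target in unique(joined$target)) {
    sub <- joined[joined$target == target, , drop = FALSE]
    ref <- sub[sub$strain == reference_strain, , drop = FALSE]
    if (nrow(ref) == 0L) next
    ref_conc <- ref$sn_conc[1L]
    others <- sub[sub$strain != reference_strain, , drop = FALSE]
    for (i in seq_len(nrow(others))) {
      fc <- if (ref_conc == 0) {
        structure(NA_real_, reason = "not computable (zero denominator)")
      } else {
        others$sn_conc[i] / ref_conc
      }
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        strain = others$strain[i], induced = others$induced[i],
        target = target, sn_conc = others$sn_conc[i],
        reference_sn_conc = ref_conc, ratio_vs_reference = as.numeric(fc),
        computable = !is.na(fc), stringsAsFactors = FALSE
      )
    }
  }
  vs_reference <- if (length(ref_rows)) do.call(rbind, ref_rows) else
    data.frame()

  structure(
    list(samples = joined, induction = induction,
         vs_reference = vs_reference, missing = missing,
         reference_strain = reference_strain),
    class = "strain_report"
  )
}

#' @export
print.strain_report <- function(x, ...) {
  cat("strain_report (reference:", x$reference_strain, ")\n\n")
  cat("Per-sample quantification:\n")
  tab <- x$samples
  tab$vial_conc <- signif(tab$vial_conc, 4)
  tab$sn_conc <- signif(tab$sn_conc, 4)
  print(tab[, c("strain", "induced", "target", "total_protein_sn",
                "vial_conc", "sn_conc", "detected")], row.names = FALSE)
  if (nrow(x$induction)) {
    cat("\nInduction fold-changes (induced / uninduced, SN scale):\n")
    tab <- x$induction
    tab$fold <- ifelse(tab$computable, signif(tab$fold, 4),
                       "not computable")
    print(tab[, c("strain", "target", "fold")], row.names = FALSE)
  }
  if (length(x$missing)) {
    cat("\nSamples in sheet without results:",
        paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}
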