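# External-standard quantification on the reference-ion signal: peak
# integration, a five-level calibration line, SE-based LOD/LOQ, and dilution
# back-calculation from the injected working solution to the extract.

#' Integrate a chromatographic trace over a window
#'
#' Trapezoidal integration of abundance against time inside the window, with
#' a zero baseline.
#'
#' @param times Retention times (minutes).
#' @param abundances Trace values (counts), same length.
#' @param window `c(start, end)` in minutes; must contain >= 2 points.
#' @return Area (counts x minutes).
#' @export
integrate_peak <- function(times, abundances, window) {
  stopifnot(length(times) == length(abundances), length(window) == 2L)
  idx <- times >= window[1] & times <= window[2]
  if (sum(idx) < 2L)
    stop("integration window contains fewer than 2 points", call. = FALSE)
  pracma::trapz(times[idx], abundances[idx])
}

#' Fit an external-standard calibration curve
#'
#' Ordinary least squares of peak area against nominal concentration over
#' all replicate points.  The detection limits follow the standard-error-of-
#' response and slope approach: `lod = 3.3 * y_se / slope` and
#' `loq = 10 * y_se / slope`, where `y_se` is the standard error of the
#' fitted y-intercept.
#'
#' @param levels Data frame with columns `concentration` (mg/L) and `area`
#'   (one row per replicate injection); >= 3 distinct concentration levels.
#' @param analyte Analyte label for the curve.
#' @return A `calibration_curve` with fields `analyte`, `slope`,
#'   `intercept`, `r_squared`, `y_se`, `lod`, `loq`, `levels`, `model` and
#'   `flags`.
#' @export
fit_calibration <- function(levels, analyte = "5-CQA") {
  stopifnot(is.data.frame(levels),
            all(c("concentration", "area") %in% names(levels)))
  if (length(unique(levels$concentration)) < 3L)
    stop("calibration needs at least 3 distinct concentration levels",
         call. = FALSE)
  model <- lm(area ~ concentration, data = levels)
  sm <- suppressWarnings(summary(model))  # exact lines trip a perfect-fit warning
  slope <- coef(model)[["concentration"]]
  y_se <- sm$coefficients["(Intercept)", "Std. Error"]
  flags <- character()
  if (slope <= 0) flags <- "invalid_curve_nonpositive_slope"
  structure(list(analyte = analyte, slope = slope,
                 intercept = coef(model)[["(Intercept)"]],
                 r_squared = sm$r.squared, y_se = y_se,
                 lod = 3.3 * y_se / slope, loq = 10 * y_se / slope,
                 levels = levels, model = model, flags = flags),
            class = "calibration_curve")
}

#' Read a calibration table from CSV
#'
#' Expected columns: `concentration` (mg/L), `area`; an optional `replicate`
#' column is ignored by the fit.
#'
#' @param path File path.
#' @param analyte Analyte label.
#' @return A `calibration_curve`.
#' @export
read_calibration <- function(path, analyte = "5-CQA") {
  if (!file.exists(path))
    stop("cannot read calibration file: ", path, call. = FALSE)
  fit_calibration(read.csv(path, stringsAsFactors = FALSE), analyte = analyte)
}

#' Convert a reference-ion peak area to concentrations
#'
#' Inverts the calibration line (`ws = (area - intercept) / slope`) to get
#' the working-solution concentration, then multiplies by the dilution
#' factor to back-calculate the extract-sample concentration.  A negative
#' inverted value is reported as 0 with flag `"<LOD"`; values below the
#' curve's limits are flagged `"<LOD"` / `"<LOQ"`.
#'
#' @param ri_area Reference-ion peak area.
#' @param curve A `calibration_curve`.
#' @param dilution_factor Extract-to-working-solution dilution factor
#'   (default 20: 50 uL diluted to 1 mL).
#' @param isomer Analyte label carried into the result.
#' @return A `quant_result` list with `isomer`, `ri_area`,
#'   `ws_concentration`, `es_concentration` (both mg/L) and `flag`
#'   (`""`, `"<LOQ"` or `"<LOD"`).
#' @export
quantify <- function(ri_area, curve, dilution_factor = 20, isomer = NA) {
  stopifnot(inherits(curve, "calibration_curve"), dilution_factor > 0)
  ws <- (ri_area - curve$intercept) / curve$slope
  flag <- ""
  if (ws < curve$lod) flag <- "<LOD" else if (ws < curve$loq) flag <- "<LOQ"
  ws <- max(ws, 0)
  structure(list(isomer = isomer, ri_area = ri_area, ws_concentration = ws,
                 es_concentration = ws * dilution_factor,
                 dilution_factor = dilution_factor, flag = flag),
            class = "quant_result")
}

#' Quantify every isomer of a reconstructed chromatogram
#'
#' Integrates each isomer's reconstructed reference-ion trace over its own
#' retention-time window and converts the area with [quantify()].  All
#' isomers are referred to the same external-standard curve: for isomeric
#' analytes the electrospray response of the shared precursor is expected to
#' be near-identical, so a single standard is an acceptable common
#' reference.
#'
#' @param chrom A `leda_chromatogram` (see [deconvolve_scanwise()]).
#' @param windows Named list of `c(start, end)` windows (minutes), one per
#'   isomer to quantify; isomers absent from the list are skipped.
#' @param curve A `calibration_curve`.
#' @param dilution_factor Dilution factor, default 20.
#' @return Data frame with one row per isomer: `isomer`, `ri_area`, `ws`,
#'   `es`, `flag`.
#' @export
quantify_deconvolved <- function(chrom, windows, curve, dilution_factor = 20) {
  stopifnot(inherits(chrom, "leda_chromatogram"))
  iso <- intersect(attr(chrom, "isomer_ids"), names(windows))
  if (!length(iso))
    stop("no isomer of the chromatogram has an integration window",
         call. = FALSE)
  rows <- lapply(iso, function(id) {
    area <- integrate_peak(chrom$rt_min, chrom[[id]], windows[[id]])
    q <- quantify(area, curve, dilution_factor, isomer = id)
    data.frame(isomer = id, ri_area = q$ri_area, ws = q$ws_concentration,
               es = q$es_concentration, flag = q$flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize replicate quantifications
#'
#' Pools per-replicate results (as returned by [quantify_deconvolved()])
#' into mean +/- sample SD per isomer, the layout of a replicate-analysis
#' results table.
#'
#' @param replicates List of data frames from [quantify_deconvolved()].
#' @return Data frame with columns `isomer`, `ws`, `ws_sd`, `es`, `es_sd`,
#'   `n`.
#' @export
summarize_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  all <- do.call(rbind, replicates)
  out <- do.call(rbind, lapply(split(all, all$isomer), function(g)
    data.frame(isomer = g$isomer[1], ws = mean(g$ws), ws_sd = sd(g$ws),
               es = mean(g$es), es_sd = sd(g$es), n = nrow(g))))
  out <- out[match(unique(all$isomer), out$isomer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve (%s): area = %.4g * conc %+ .4g\n",
              x$analyte, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.5f, y-intercept SE = %.4g\n", x$r_squared, x$y_se))
  cat(sprintf("  LOD = %.3g mg/L, LOQ = %.3g mg/L\n", x$lod, x$loq))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("%s: WS %.3g mg/L, ES %.3g mg/L (x%g)%s\n",
              ifelse(is.na(x$isomer), "analyte", x$isomer),
              x$ws_concentration, x$es_concentration, x$dilution_factor,
              ifelse(nzchar(x$flag), paste0(" [", x$flag, "]"), "")))
  invisible(x)
}
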