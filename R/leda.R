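# The LEDA core: the measured Pi/Ri ratio vector of a mixed MS/MS signal is
# modelled as a nonnegative combination of the pure isomers' characteristic
# ratio columns,
#     (Pi/Ri)_measured ~= sum_x (Pi/Ri)_x * fraction_x ,
# one equation per retained product ion.  With more retained ions than
# isomers the system is overdetermined and is solved by non-negative least
# squares; the solution fractions are the isomer proportions of the signal.

#' Measure characteristic Pi/Ri ratios from a pure-isomer peak
#'
#' For each product ion, computes the Pi/Ri ratio at every paired data point
#' across a chromatographic peak of one pure isomer and summarizes it as a
#' mean and standard deviation — one column of a [ratio_table()].
#'
#' @param points A `paired_points` collection (see [pair_events()]),
#'   restricted to the peak of one pure isomer.
#' @param product_mzs Product-ion m/z values to measure.
#' @param window Optional retention-time window `c(start, end)` in minutes;
#'   defaults to all points.
#' @param tolerance m/z matching tolerance (Th).
#' @return Data frame with columns `product_mz`, `ratio`, `sd`, `n`.
#' @export
compute_characteristic_ratios <- function(points, product_mzs, window = NULL,
                                          tolerance = 0.5) {
  if (!is.null(window))
    points <- points[points$rt_min >= window[1] & points$rt_min <= window[2], ,
                     drop = FALSE]
  points <- points[points$ri_abundance > 0, , drop = FALSE]
  if (nrow(points) < 3L)
    stop("need at least 3 paired points with positive Ri abundance",
         call. = FALSE)
  rat <- vapply(seq_len(nrow(points)), function(i) {
    vapply(product_mzs, extract_ion, numeric(1),
           peaks = points$pis[[i]], tolerance = tolerance) /
      points$ri_abundance[i]
  }, numeric(length(product_mzs)))
  rat <- matrix(rat, nrow = length(product_mzs))
  data.frame(product_mz = product_mzs,
             ratio = rowMeans(rat),
             sd = apply(rat, 1, sd),
             n = nrow(points))
}

#' Assemble the overdetermined LEDA design matrix
#'
#' Retains every product ion whose characteristic ratio reaches `threshold`
#' (default 2%) for at least one isomer; ions below the threshold everywhere
#' carry no discriminating signal above noise and are dropped.  The retained
#' system must stay overdetermined (rows >= isomers).
#'
#' @param table A [ratio_table()].
#' @param threshold Dimensionless ratio threshold, default `0.02`.
#' @return A `leda_matrix` with fields `design` (rows = retained product
#'   ions, columns = isomers), `sds`, `row_mzs`, `isomer_ids`,
#'   `reference_mz`, `group_id`, `threshold`.
#' @export
assemble_leda_matrix <- function(table, threshold = 0.02) {
  stopifnot(inherits(table, "ratio_table"), threshold >= 0, threshold <= 1)
  keep <- apply(table$ratios >= threshold, 1, any)
  m <- sum(keep); n <- length(table$isomer_ids)
  if (m < n)
    stop(sprintf(
      "underdetermined system: %d product ions retained at threshold %.3g for %d isomers",
      m, threshold, n), call. = FALSE)
  structure(list(design = table$ratios[keep, , drop = FALSE],
                 sds = table$sds[keep, , drop = FALSE],
                 row_mzs = table$product_mzs[keep],
                 isomer_ids = table$isomer_ids,
                 reference_mz = table$reference_mz,
                 group_id = table$group_id,
                 threshold = threshold),
            class = "leda_matrix")
}

#' Solve one LEDA system
#'
#' Finds the nonnegative isomer fractions minimizing the least-squares
#' residual of the ratio model.  No sum-to-one constraint is imposed, so
#' signal from unknown co-eluting species with the same precursor and
#' product ions shows up as an unassigned remainder rather than being forced
#' onto the known isomers.  When noise pushes the fraction sum above 1 the
#' fractions are renormalized to sum to 1 (flag `"overshoot_renormalized"`);
#' an all-zero measured vector returns zero fractions with flag
#' `"no_product_signal"`.
#'
#' @param matrix A `leda_matrix`.
#' @param measured Numeric vector of measured Pi/Ri ratios, one per retained
#'   product ion (same order as `matrix$row_mzs`), >= 0.
#' @param weights `"none"` (ordinary least squares, default) or `"sd"`
#'   (rows weighted by 1 / SD of the characteristic ratios).
#' @return A `leda_fit` with `fractions` (named, in \[0, 1\]),
#'   `residual_norm` (Euclidean norm of the raw fit residual), `unassigned`
#'   (`max(0, 1 - sum(fractions))`) and `flags`.
#' @export
solve_leda <- function(matrix, measured, weights = c("none", "sd")) {
  weights <- match.arg(weights)
  stopifnot(inherits(matrix, "leda_matrix"))
  A <- matrix$design
  if (length(measured) != nrow(A))
    stop(sprintf("measured vector has %d values but the system has %d rows",
                 length(measured), nrow(A)), call. = FALSE)
  if (any(measured < 0))
    stop("measured ratios must be nonnegative", call. = FALSE)
  flags <- character()
  if (kappa(A, exact = TRUE) > 1e6) flags <- c(flags, "collinear_design")
  if (all(measured == 0)) {
    frac <- setNames(rep(0, ncol(A)), matrix$isomer_ids)
    return(structure(list(fractions = frac, residual_norm = 0,
                          unassigned = 1,
                          flags = c(flags, "no_product_signal")),
                     class = "leda_fit"))
  }
  b <- as.numeric(measured)
  if (weights == "sd") {
    w <- 1 / pmax(apply(matrix$sds, 1, max), 1e-6)
    A <- A * w
    b <- b * w
  }
  fit <- pracma::lsqnonneg(A, b)
  frac <- setNames(pmax(fit$x, 0), matrix$isomer_ids)
  res <- sqrt(sum((A %*% frac - b)^2))
  if (sum(frac) > 1) {
    frac <- frac / sum(frac)
    flags <- c(flags, "overshoot_renormalized")
  }
  structure(list(fractions = frac, residual_norm = res,
                 unassigned = max(0, 1 - sum(frac)), flags = flags),
            class = "leda_fit")
}

#' Scan-by-scan deconvolution into a reconstructed chromatogram
#'
#' Applies the LEDA model to every paired data point: the measured Pi/Ri
#' vector of the point is solved for isomer fractions and the reference-ion
#' abundance is apportioned as `ri * fraction` per isomer, yielding one
#' reconstructed chromatographic trace per isomer plus a residual trace
#' `ri * (1 - sum(fractions))`.  The traces conserve the Ri signal exactly:
#' at every time, per-isomer traces + residual = Ri.  Points whose Ri falls
#' below `min_ri_frac` of the run's maximum Ri (baseline) are not
#' deconvolved; their whole Ri goes to the residual trace.
#'
#' @param points A `paired_points` collection (one segment / one group).
#' @param matrix The group's `leda_matrix`.
#' @param tolerance m/z matching tolerance (Th).
#' @param min_ri_frac Baseline gate as a fraction of the maximum Ri
#'   (default 0.01).
#' @param weights Passed to [solve_leda()].
#' @return A `leda_chromatogram` data frame with columns `rt_min`, `ri`, one
#'   column per isomer, `residual` and `gated` (logical).
#' @export
deconvolve_scanwise <- function(points, matrix, tolerance = 0.5,
                                min_ri_frac = 0.01,
                                weights = c("none", "sd")) {
  weights <- match.arg(weights)
  stopifnot(inherits(matrix, "leda_matrix"), nrow(points) > 0)
  n <- nrow(points)
  iso <- matrix$isomer_ids
  traces <- base::matrix(0, n, length(iso), dimnames = list(NULL, iso))
  residual <- numeric(n)
  gate <- min_ri_frac * max(points$ri_abundance)
  gated <- logical(n)
  for (i in seq_len(n)) {
    ri <- points$ri_abundance[i]
    if (ri <= 0) next
    if (ri < gate) {
      gated[i] <- TRUE
      residual[i] <- ri
      next
    }
    measured <- vapply(matrix$row_mzs, extract_ion, numeric(1),
                       peaks = points$pis[[i]], tolerance = tolerance) / ri
    fit <- solve_leda(matrix, measured, weights = weights)
    traces[i, ] <- ri * fit$fractions
    residual[i] <- ri * max(0, 1 - sum(fit$fractions))
  }
  out <- data.frame(rt_min = points$rt_min, ri = points$ri_abundance,
                    traces, residual = residual, gated = gated,
                    check.names = FALSE)
  attr(out, "isomer_ids") <- iso
  class(out) <- c("leda_chromatogram", "data.frame")
  out
}

#' Peak-mode deconvolution of one integrated peak
#'
#' Integrates the reference-ion trace and each retained product-ion trace
#' over the peak window (trapezoidal rule), forms the area-based Pi/Ri ratio
#' vector, and solves the LEDA system once.  The fractions are the peak
#' purity: the proportion of the peak's Ri area attributable to each isomer.
#'
#' @param points A `paired_points` collection.
#' @param matrix The group's `leda_matrix`.
#' @param window Retention-time window `c(start, end)` in minutes; defaults
#'   to the full point range.
#' @param tolerance m/z matching tolerance (Th).
#' @param weights Passed to [solve_leda()].
#' @return A `leda_fit` with additional fields `ri_area` and `isomer_areas`
#'   (`ri_area * fractions`).
#' @export
deconvolve_peak <- function(points, matrix, window = NULL, tolerance = 0.5,
                            weights = c("none", "sd")) {
  weights <- match.arg(weights)
  stopifnot(inherits(matrix, "leda_matrix"))
  if (!is.null(window))
    points <- points[points$rt_min >= window[1] & points$rt_min <= window[2], ,
                     drop = FALSE]
  if (nrow(points) < 2L)
    stop("peak window holds fewer than 2 paired points", call. = FALSE)
  t <- points$rt_min
  ri_area <- pracma::trapz(t, points$ri_abundance)
  if (ri_area <= 0)
    stop("reference-ion area over the peak window is zero", call. = FALSE)
  pi_areas <- vapply(matrix$row_mzs, function(mz) {
    tr <- vapply(points$pis, extract_ion, numeric(1), target_mz = mz,
                 tolerance = tolerance)
    pracma::trapz(t, tr)
  }, numeric(1))
  fit <- solve_leda(matrix, pi_areas / ri_area, weights = weights)
  fit$ri_area <- ri_area
  fit$isomer_areas <- ri_area * fit$fractions
  fit
}

#' Export a reconstructed chromatogram as CSV
#'
#' @param chrom A `leda_chromatogram`.
#' @param path Output file.
#' @export
write_chromatogram <- function(chrom, path) {
  write.csv(as.data.frame(chrom), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.leda_fit <- function(x, ...) {
  cat("LEDA deconvolution\n")
  for (i in seq_along(x$fractions))
    cat(sprintf("  %-12s %6.2f %%\n", names(x$fractions)[i],
                100 * x$fractions[i]))
  cat(sprintf("  unassigned   %6.2f %%   (residual norm %.3g)\n",
              100 * x$unassigned, x$residual_norm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a reconstructed chromatogram
#'
#' Reference-ion trace in black, one colored trace per isomer, residual
#' dashed grey.
#'
#' @param x A `leda_chromatogram`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.leda_chromatogram <- function(x, ...) {
  iso <- attr(x, "isomer_ids")
  cols <- grDevices::hcl.colors(length(iso), "Dark 3")
  graphics::matplot(x$rt_min, cbind(x$ri, as.matrix(x[iso]), x$residual),
                    type = "l",
                    lty = c(1, rep(1, length(iso)), 2),
                    col = c("black", cols, "grey50"),
                    xlab = "Retention time (min)", ylab = "Abundance", ...)
  graphics::legend("topright", c("Ri", iso, "residual"),
                   lty = c(1, rep(1, length(iso)), 2),
                   col = c("black", cols, "grey50"), bty = "n")
  invisible(x)
}
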