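# Energy-resolved MS/MS (ERMS): breakdown curves and CID summary statistics.
#
# An ERMS experiment acquires MS/MS spectra of one precursor at stepwise
# increasing excitation amplitudes (ExA).  Three curves describe the
# energetics of collision-induced dissociation (CID):
#   SY  — survival yield: precursor / (precursor + sum of product ions), in %
#   PiF — product-ion formation: the complement of SY, in %
#   PiY — product-ion yield: sum of product ions relative to the precursor
#         level before any fragmentation ("precursor ion max"), in %.
# PiF neglects ion losses (precursor ejection, products below the trap's
# low-mass cut-off) and so overstates CID efficiency; PiY accounts for them.

#' Construct an ERMS series
#'
#' @param compound_id Compound label.
#' @param exa_grid Strictly increasing excitation amplitudes (a.u.).
#' @param precursor Precursor-ion abundance at each grid point (counts).
#' @param products Matrix of product-ion abundances, one row per product ion
#'   (rownames = product m/z), one column per grid point; or a named list of
#'   per-ion traces.
#' @return An `erms_series`.
#' @export
erms_series <- function(compound_id, exa_grid, precursor, products) {
  if (is.list(products) && !is.matrix(products))
    products <- do.call(rbind, products)
  if (is.null(dim(products)))
    products <- matrix(products, nrow = 1,
                       dimnames = list("product", NULL))
  exa_grid <- as.numeric(exa_grid)
  stopifnot(length(exa_grid) >= 2L, all(diff(exa_grid) > 0),
            length(precursor) == length(exa_grid),
            ncol(products) == length(exa_grid))
  if (any(precursor < 0) || any(products < 0))
    stop("ERMS abundances must be nonnegative", call. = FALSE)
  structure(list(compound_id = compound_id, exa_grid = exa_grid,
                 precursor = as.numeric(precursor), products = products),
            class = "erms_series")
}

#' Read / write an ERMS series as tidy CSV
#'
#' Columns: `compound`, `exa`, `ion_mz`, `role` (`"precursor"`/`"product"`),
#' `abundance`.
#'
#' @param path File path.
#' @return `read_erms()` returns an `erms_series`.
#' @export
read_erms <- function(path) {
  if (!file.exists(path)) stop("cannot read ERMS file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "exa", "ion_mz", "role", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ERMS table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  grid <- sort(unique(df$exa))
  pre <- df[df$role == "precursor", ]
  prods <- df[df$role == "product", ]
  precursor <- pre$abundance[match(grid, pre$exa)]
  ions <- unique(prods$ion_mz)
  pm <- t(vapply(ions, function(i) {
    tr <- prods[prods$ion_mz == i, ]
    tr$abundance[match(grid, tr$exa)]
  }, numeric(length(grid))))
  rownames(pm) <- as.character(ions)
  erms_series(df$compound[1], grid, precursor, pm)
}

#' @rdname read_erms
#' @param series An `erms_series`.
#' @export
write_erms <- function(series, path) {
  stopifnot(inherits(series, "erms_series"))
  pre <- data.frame(compound = series$compound_id, exa = series$exa_grid,
                    ion_mz = NA_real_, role = "precursor",
                    abundance = series$precursor)
  prod <- do.call(rbind, lapply(rownames(series$products), function(i)
    data.frame(compound = series$compound_id, exa = series$exa_grid,
               ion_mz = as.numeric(i), role = "product",
               abundance = series$products[i, ])))
  write.csv(rbind(pre, prod), path, row.names = FALSE)
  invisible(path)
}

#' Survival yield and product-ion formation at one grid point
#'
#' `sy = 100 * precursor / (precursor + sum(products))` and
#' `pif = 100 - sy`.  A grid point with zero total ion current carries no
#' information and is returned as `NA` (flagged, never fabricated).
#'
#' @param precursor Precursor abundance (counts).
#' @param products Vector of product-ion abundances (counts).
#' @return Named numeric `c(sy =, pif =)` in percent.
#' @export
compute_sy_pif <- function(precursor, products) {
  stopifnot(precursor >= 0, all(products >= 0))
  total <- precursor + sum(products)
  if (total <= 0) return(c(sy = NA_real_, pif = NA_real_))
  sy <- 100 * precursor / total
  c(sy = sy, pif = 100 - sy)
}

#' Estimate the pre-fragmentation precursor level
#'
#' Averages the precursor abundance over the low-energy plateau — the grid
#' points where the survival yield is at least `plateau_sy` percent, i.e.
#' before the fragmentation channels activate.
#'
#' @param series An `erms_series`.
#' @param plateau_sy Plateau definition in percent SY (default 95).
#' @return Mean precursor abundance over the plateau (counts).
#' @export
estimate_precursor_max <- function(series, plateau_sy = 95) {
  stopifnot(inherits(series, "erms_series"))
  sy <- vapply(seq_along(series$exa_grid), function(i)
    compute_sy_pif(series$precursor[i], series$products[, i])[["sy"]],
    numeric(1))
  keep <- !is.na(sy) & sy >= plateau_sy
  if (!any(keep))
    stop("no grid point with SY >= ", plateau_sy,
         "%; lower 'plateau_sy' to estimate the precursor level",
         call. = FALSE)
  mean(series$precursor[keep])
}

#' Product-ion yield at one grid point
#'
#' `piy = 100 * sum(products) / precursor_max`: the fragmented signal
#' relative to the precursor level available before CID, which exposes ion
#' losses that the formation curve hides.
#'
#' @param products Vector of product-ion abundances (counts).
#' @param precursor_max Pre-fragmentation precursor level (counts), > 0.
#' @return PiY in percent.
#' @export
compute_piy <- function(products, precursor_max) {
  if (precursor_max <= 0)
    stop("precursor_max must be positive", call. = FALSE)
  stopifnot(all(products >= 0))
  100 * sum(products) / precursor_max
}

#' Build the full set of breakdown curves for an ERMS series
#'
#' Evaluates SY, PiF and PiY at every grid point and, per product ion, the
#' yield-of-formation trace (ion abundance relative to the pre-fragmentation
#' precursor level, in percent).  Grid points with zero total ion current are
#' flagged `NA` in SY/PiF and excluded from downstream summaries.
#'
#' @param series An `erms_series`.
#' @param plateau_sy Plateau definition passed to
#'   [estimate_precursor_max()].
#' @return A `breakdown_curves` list with `exa_grid`, `sy`, `pif`, `piy`,
#'   `per_ion_yield` (matrix, percent) and `precursor_max`.
#' @export
build_breakdown_curves <- function(series, plateau_sy = 95) {
  stopifnot(inherits(series, "erms_series"))
  n <- length(series$exa_grid)
  sp <- vapply(seq_len(n), function(i)
    compute_sy_pif(series$precursor[i], series$products[, i]), numeric(2))
  pmax_ <- estimate_precursor_max(series, plateau_sy)
  piy <- vapply(seq_len(n), function(i)
    compute_piy(series$products[, i], pmax_), numeric(1))
  structure(list(exa_grid = series$exa_grid, sy = sp["sy", ],
                 pif = sp["pif", ], piy = piy,
                 per_ion_yield = 100 * series$products / pmax_,
                 precursor_max = pmax_,
                 compound_id = series$compound_id),
            class = "breakdown_curves")
}

#' CID summary statistics of a breakdown-curve set
#'
#' * `sy_exa50` — the ExA at which half the precursor is fragmented: the
#'   first downward 50% crossing of the SY curve, linearly interpolated
#'   between the bracketing grid points (`NA`, with a flag, if SY never
#'   drops below 50%).
#' * `exa_max` — the grid ExA of the maximal product-ion yield (ties broken
#'   toward the lower ExA: same yield for less energy).
#' * `piy_max` — that maximal yield, in percent.
#'
#' @param curves A `breakdown_curves`.
#' @return A `cid_summary` list with fields `sy_exa50`, `exa_max`,
#'   `piy_max`, `precursor_max` and `flags`.
#' @export
estimate_cid_summary <- function(curves) {
  stopifnot(inherits(curves, "breakdown_curves"))
  ok <- !is.na(curves$sy)
  exa <- curves$exa_grid[ok]; sy <- curves$sy[ok]
  flags <- character()
  sy50 <- NA_real_
  cross <- which(sy[-length(sy)] >= 50 & sy[-1] < 50)
  if (length(cross)) {
    i <- cross[1]
    sy50 <- exa[i] + (sy[i] - 50) / (sy[i] - sy[i + 1]) * (exa[i + 1] - exa[i])
  } else if (all(sy < 50)) {
    sy50 <- exa[1]
    flags <- c(flags, "sy_below_50_everywhere")
  } else {
    flags <- c(flags, "sy_never_crosses_50")
  }
  imax <- which.max(curves$piy)  # which.max takes the first (lowest-ExA) tie
  structure(list(sy_exa50 = sy50, exa_max = curves$exa_grid[imax],
                 piy_max = curves$piy[imax],
                 precursor_max = curves$precursor_max, flags = flags),
            class = "cid_summary")
}

#' Locate the SY/PiF crossing of a breakdown-curve set
#'
#' The survival-yield and formation curves are complements that sum to 100%,
#' so wherever they cross, the shared abundance value is 50%.  This locates
#' the first crossing by linear interpolation and reports both the ExA and
#' the interpolated common abundance there — a built-in consistency check of
#' the curve computation.
#'
#' @param curves A `breakdown_curves`.
#' @return List with `exa` (a.u.) and `value` (percent) of the crossing.
#' @export
sy_pif_crossing <- function(curves) {
  stopifnot(inherits(curves, "breakdown_curves"))
  ok <- !is.na(curves$sy)
  exa <- curves$exa_grid[ok]
  d <- curves$sy[ok] - curves$pif[ok]
  i <- which(d[-length(d)] >= 0 & d[-1] < 0)
  if (!length(i))
    stop("SY and PiF curves do not cross on the sampled grid", call. = FALSE)
  i <- i[1]
  w <- d[i] / (d[i] - d[i + 1])
  x <- exa[i] + w * (exa[i + 1] - exa[i])
  val <- curves$sy[ok][i] + w * (curves$sy[ok][i + 1] - curves$sy[ok][i])
  list(exa = x, value = val)
}

#' Export breakdown curves as CSV
#'
#' Columns: `exa`, `sy`, `pif`, `piy`, then one yield column per product ion.
#'
#' @param curves A `breakdown_curves`.
#' @param path Output file.
#' @export
write_breakdown_curves <- function(curves, path) {
  df <- data.frame(exa = curves$exa_grid, sy = curves$sy, pif = curves$pif,
                   piy = curves$piy)
  ion_cols <- as.data.frame(t(curves$per_ion_yield))
  names(ion_cols) <- paste0("yield_", rownames(curves$per_ion_yield))
  write.csv(cbind(df, ion_cols), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cid_summary <- function(x, ...) {
  cat("CID summary\n")
  cat(sprintf("  SY_ExA50:      %s a.u.\n",
              ifelse(is.na(x$sy_exa50), "n/a", format(x$sy_exa50))))
  cat(sprintf("  ExA_max:       %g a.u.\n", x$exa_max))
  cat(sprintf("  PiY_max:       %.1f %%\n", x$piy_max))
  cat(sprintf("  precursor max: %.4g counts\n", x$precursor_max))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Plot breakdown curves
#'
#' SY (solid black), PiF (solid red) and PiY (dashed green) against ExA.
#'
#' @param x A `breakdown_curves`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.breakdown_curves <- function(x, ...) {
  graphics::matplot(x$exa_grid, cbind(x$sy, x$pif, x$piy), type = "l",
                    lty = c(1, 1, 2), col = c("black", "red", "darkgreen"),
                    xlab = "Excitation amplitude (a.u.)",
                    ylab = "Relative abundance (%)",
                    main = x$compound_id %||% "", ...)
  graphics::legend("right", c("SY", "PiF", "PiY"), lty = c(1, 1, 2),
                   col = c("black", "red", "darkgreen"), bty = "n")
  invisible(x)
}
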