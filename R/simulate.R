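# Seedable generators of synthetic LC-MS/MS runs and ERMS series carrying
# the statistical structure the pipeline assumes: Gaussian elution peaks,
# alternating RI/PIS events per time segment, per-isomer characteristic
# Pi/Ri fragmentation ratios, and multiplicative lognormal noise (mean 1,
# CV = noise_cv), which matches the roughly signal-independent relative
# spread of measured ratio tables.

#' Describe a synthetic LC-MS/MS run
#'
#' @param config A `leda_config` (acquisition segments).
#' @param peaks Data frame with one row per eluting isomer: columns
#'   `isomer`, `group` (must match a segment's group), `rt_min` (apex,
#'   minutes), `width_min` (Gaussian sigma, minutes), `height` (apex
#'   reference-ion abundance, counts) and optionally `tau_min`
#'   (exponential tail constant of an exponentially-modified Gaussian;
#'   0 or absent for a pure Gaussian).
#' @param ratio_tables Named list of [ratio_table()]s keyed by group.
#' @param scan_period Minutes between consecutive events (default 0.005,
#'   i.e. 0.3 s per event / 0.6 s per RI+PIS pair).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 = noiseless).
#' @param baseline Constant baseline added to the reference-ion signal
#'   (counts).
#' @param seed Default seed used by [simulate_run()].
#' @return A `run_scenario`.
#' @export
run_scenario <- function(config, peaks, ratio_tables, scan_period = 0.005,
                         noise_cv = 0, baseline = 0, seed = 1L) {
  stopifnot(inherits(config, "leda_config"), is.data.frame(peaks),
            all(c("isomer", "group", "rt_min", "width_min", "height")
                %in% names(peaks)),
            all(peaks$width_min > 0), all(peaks$height >= 0),
            scan_period > 0, noise_cv >= 0, baseline >= 0)
  groups <- vapply(config, function(s) s$group, character(1))
  bad <- setdiff(unique(peaks$group), groups)
  if (length(bad))
    stop("peak group(s) with no matching segment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!all(unique(peaks$group) %in% names(ratio_tables)))
    stop("every peak group needs a ratio table", call. = FALSE)
  if (is.null(peaks$tau_min)) peaks$tau_min <- 0
  structure(list(config = config, peaks = peaks,
                 ratio_tables = ratio_tables, scan_period = scan_period,
                 noise_cv = noise_cv, baseline = baseline,
                 seed = as.integer(seed)),
            class = "run_scenario")
}

# Elution profile: Gaussian, or exponentially-modified Gaussian when tau > 0
# (same area as the Gaussian with equal height/sigma).
elution_profile <- function(t, rt, sigma, height, tau = 0) {
  if (tau <= 0) return(height * exp(-0.5 * ((t - rt) / sigma)^2))
  area <- height * sigma * sqrt(2 * pi)
  z <- (sigma / tau - (t - rt) / sigma) / sqrt(2)
  area / (2 * tau) * exp(sigma^2 / (2 * tau^2) - (t - rt) / tau) *
    pracma::erfc(z)
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate an LC-MS/MS run
#'
#' Generates alternating RI/PIS events at `scan_period` cadence within each
#' configured segment.  At an RI event the precursor abundance is the sum of
#' the segment group's isomer elution profiles plus the baseline; at a PIS
#' event each monitored product ion carries the sum over isomers of
#' (elution profile x characteristic Pi/Ri ratio).  Every abundance is then
#' perturbed independently by multiplicative lognormal noise with the
#' scenario's CV.  Fixed seed + scenario give byte-identical output.
#'
#' @param scenario A `run_scenario`.
#' @param seed Integer seed; defaults to the scenario's.
#' @return An `msms_run`.
#' @export
simulate_run <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "run_scenario"))
  set.seed(seed)
  rows <- list()
  for (s in scenario$config) {
    pk <- scenario$peaks[scenario$peaks$group == s$group, , drop = FALSE]
    tb <- scenario$ratio_tables[[s$group]]
    times <- seq(s$rt_window[1], s$rt_window[2], by = scenario$scan_period)
    if (!length(times)) next
    events <- rep(c("RI", "PIS"), length.out = length(times))
    contrib <- vapply(seq_len(nrow(pk)), function(k)
      elution_profile(times, pk$rt_min[k], pk$width_min[k], pk$height[k],
                      pk$tau_min[k]), numeric(length(times)))
    contrib <- matrix(contrib, nrow = length(times))
    for (i in seq_along(times)) {
      if (events[i] == "RI") {
        ab <- (sum(contrib[i, ]) + scenario$baseline) *
          mult_noise(1, scenario$noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          rt_min = times[i], segment = s$segment_id, event = "RI",
          precursor_mz = s$precursor_mz, exa = s$ri_exa,
          ext_ms = s$excitation_time_ms,
          mz = s$precursor_mz, abundance = ab)
      } else {
        idx <- match(pk$isomer, tb$isomer_ids)
        if (anyNA(idx))
          stop("isomer(s) missing from ratio table '", s$group, "': ",
               paste(pk$isomer[is.na(idx)], collapse = ", "), call. = FALSE)
        ab <- as.numeric(tb$ratios[, idx, drop = FALSE] %*% contrib[i, ]) *
          mult_noise(length(tb$product_mzs), scenario$noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          rt_min = times[i], segment = s$segment_id, event = "PIS",
          precursor_mz = s$precursor_mz, exa = s$pis_exa,
          ext_ms = s$excitation_time_ms,
          mz = tb$product_mzs, abundance = ab)
      }
    }
  }
  msms_run(do.call(rbind, rows))
}

#' Describe a synthetic ERMS series
#'
#' The precursor follows a logistic survival decay
#' `s(ExA) = 1 / (1 + exp(steepness * (ExA - midpoint)))`; the fragmented
#' signal `(1 - s)` loses `ion_loss_fraction` of its current (precursor
#' ejection and ions below the trap's low-mass cut-off) and the remainder is
#' split across the product ions by `product_split`.
#'
#' @param compound_id Label.
#' @param sy_midpoint Logistic midpoint (a.u.) — the ExA of 50% survival.
#' @param sy_steepness Logistic steepness (per a.u.).
#' @param ion_loss_fraction Fraction of fragmented current lost, in \[0, 1).
#' @param product_split Named numeric (names = product m/z) summing to 1.
#' @param precursor_level Pre-fragmentation precursor abundance (counts).
#' @param exa_grid Increasing ExA grid (a.u.), default 0--50 by 2.5.
#' @param noise_cv Multiplicative lognormal noise CV.
#' @param seed Default seed for [simulate_erms()].
#' @return An `erms_scenario`.
#' @export
erms_scenario <- function(compound_id = "synthetic",
                          sy_midpoint = 21, sy_steepness = 0.4,
                          ion_loss_fraction = 0.5,
                          product_split = c("191" = 0.6, "179" = 0.25,
                                            "173" = 0.1, "135" = 0.05),
                          precursor_level = 1e6,
                          exa_grid = seq(0, 50, by = 2.5),
                          noise_cv = 0, seed = 1L) {
  stopifnot(abs(sum(product_split) - 1) < 1e-9,
            ion_loss_fraction >= 0, ion_loss_fraction < 1,
            all(diff(exa_grid) > 0), noise_cv >= 0, precursor_level > 0)
  structure(list(compound_id = compound_id, sy_midpoint = sy_midpoint,
                 sy_steepness = sy_steepness,
                 ion_loss_fraction = ion_loss_fraction,
                 product_split = product_split,
                 precursor_level = precursor_level,
                 exa_grid = as.numeric(exa_grid), noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "erms_scenario")
}

#' Simulate an ERMS series
#'
#' @param scenario An `erms_scenario`.
#' @param seed Integer seed; defaults to the scenario's.
#' @return An `erms_series`.
#' @export
simulate_erms <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "erms_scenario"))
  set.seed(seed)
  g <- scenario$exa_grid
  surv <- 1 / (1 + exp(scenario$sy_steepness * (g - scenario$sy_midpoint)))
  pre <- scenario$precursor_level * surv * mult_noise(length(g),
                                                      scenario$noise_cv)
  frag <- scenario$precursor_level * (1 - surv) *
    (1 - scenario$ion_loss_fraction)
  prods <- t(vapply(names(scenario$product_split), function(i)
    frag * scenario$product_split[[i]] *
      mult_noise(length(g), scenario$noise_cv),
    numeric(length(g))))
  erms_series(scenario$compound_id, g, pre, prods)
}

#' The bundled six-isomer demonstration scenario
#'
#' A fast-gradient two-segment run with all six caffeoylquinic isomers: the
#' three CQAs in segment 1 (precursor 353 m/z) with 4-CQA co-eluting on the
#' tail of a ten-times-higher 5-CQA peak, and the three diCQAs in segment 2
#' (precursor 515 m/z) with 3,4- and 3,5-diCQA partially overlapping.  Peak
#' areas are proportional to realistic working-solution concentrations
#' (5-CQA 6.0, 4-CQA 0.6, 3-CQA 0.6, 3,4-diCQA 6.5, 3,5-diCQA 16.5,
#' 4,5-diCQA 4.0 mg/L): the electrospray response is modelled per amount,
#' i.e. per peak area, at 2e5 * 0.05 * sqrt(2*pi) counts x min per mg/L, so
#' wider peaks are proportionally lower at the apex.
#'
#' @param noise_cv Noise CV (default 0.05).
#' @param seed Seed stored in the scenario.
#' @return A `run_scenario`.
#' @export
acmella_scenario <- function(noise_cv = 0.05, seed = 1L) {
  area_response <- 2e5 * 0.05 * sqrt(2 * pi)  # counts x min per mg/L
  conc <- c(0.6, 6.0, 0.6, 6.5, 16.5, 4.0)
  width <- c(0.05, 0.05, 0.05, 0.06, 0.06, 0.06)
  peaks <- data.frame(
    isomer = c("3-CQA", "5-CQA", "4-CQA",
               "3,4-diCQA", "3,5-diCQA", "4,5-diCQA"),
    group = c(rep("CQAs", 3), rep("diCQAs", 3)),
    rt_min = c(1.20, 2.00, 2.10, 4.60, 4.75, 6.30),
    width_min = width,
    height = area_response * conc / (width * sqrt(2 * pi)))
  run_scenario(cqa_acquisition_config(2), peaks, cqa_ratio_tables(),
               noise_cv = noise_cv, seed = seed)
}
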