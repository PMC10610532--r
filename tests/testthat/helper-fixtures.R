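# Shared fixtures and independent oracles.

table4 <- cqa_ratio_tables()

# Build a paired-points collection directly (bypassing run simulation) from a
# reference-ion trace and characteristic ratios: one pure unit test lever for
# the deconvolution layer.
make_paired <- function(times, ri_true, ratio_cols, fractions,
                        product_mzs, noise_cv = 0, segment = 1L) {
  stopifnot(ncol(ratio_cols) == length(fractions))
  noise <- function(n) {
    if (noise_cv <= 0) return(rep(1, n))
    s2 <- log(1 + noise_cv^2)
    rlnorm(n, -s2 / 2, sqrt(s2))
  }
  pis <- lapply(seq_along(times), function(i) {
    ab <- as.numeric(ratio_cols %*% (fractions * ri_true[i])) *
      noise(length(product_mzs))
    data.frame(mz = product_mzs, abundance = ab)
  })
  out <- data.frame(rt_min = times, segment = segment,
                    ri_abundance = ri_true * noise(length(times)),
                    pis = I(pis))
  class(out) <- c("paired_points", "data.frame")
  out
}

# Exhaustive simplex grid search at fixed resolution: the independent oracle
# for the non-negative least-squares solver (three-isomer systems).
grid_search_fractions <- function(design, measured, step = 0.001) {
  a <- seq(0, 1, by = step)
  g <- expand.grid(f1 = a, f2 = a)
  g <- g[g$f1 + g$f2 <= 1 + 1e-12, ]
  F <- cbind(g$f1, g$f2, 1 - g$f1 - g$f2)
  val <- rowSums((F %*% crossprod(design)) * F) -
    2 * as.numeric(F %*% crossprod(design, measured))
  F[which.min(val), ]
}

# Precomputable version for many measured vectors against one design.
grid_searcher <- function(design, step = 0.001) {
  a <- seq(0, 1, by = step)
  g <- expand.grid(f1 = a, f2 = a)
  g <- g[g$f1 + g$f2 <= 1 + 1e-12, ]
  F <- cbind(g$f1, g$f2, 1 - g$f1 - g$f2)
  M <- rowSums((F %*% crossprod(design)) * F)
  function(measured) {
    val <- M - 2 * as.numeric(F %*% crossprod(design, measured))
    F[which.min(val), ]
  }
}

# A small two-peak single-segment scenario used by several tests.
two_peak_scenario <- function(heights = c(1.2e6, 1.2e5), noise_cv = 0,
                              seed = 1L) {
  peaks <- data.frame(isomer = c("5-CQA", "4-CQA"), group = "CQAs",
                      rt_min = c(2.0, 2.1), width_min = 0.05,
                      height = heights)
  run_scenario(cqa_acquisition_config(2), peaks, table4,
               noise_cv = noise_cv, seed = seed)
}

gaussian_area <- function(height, sigma) height * sigma * sqrt(2 * pi)
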