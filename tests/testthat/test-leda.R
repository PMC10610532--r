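test_that("characteristic ratios round-trip a noiseless pure-isomer run", {
  peaks <- data.frame(isomer = "5-CQA", group = "CQAs", rt_min = 2.0,
                      width_min = 0.05, height = 1.2e6)
  sc <- run_scenario(cqa_acquisition_config(2), peaks, table4, noise_cv = 0)
  paired <- pair_events(simulate_run(sc), sc$config)
  r <- compute_characteristic_ratios(paired[paired$segment == 1, ],
                                     c(191, 179, 173, 135),
                                     window = c(1.9, 2.1))
  want <- table4$CQAs$ratios[, "5-CQA"]
  expect_true(all(abs(r$ratio - unname(want)) < 1e-4))
  expect_true(all(r$sd < 1e-4))
})

test_that("an absent product ion gives ratio 0 with SD 0", {
  pts <- make_paired(seq(0, 1, 0.05), rep(1000, 21),
                     matrix(c(0.3, 0), 2, 1,
                            dimnames = list(c("191", "179"), NULL)),
                     1, c(191, 179))
  r <- compute_characteristic_ratios(pts, c(191, 179))
  expect_equal(r$ratio[2], 0)
  expect_equal(r$sd[2], 0)
  expect_error(compute_characteristic_ratios(pts[1:2, ], c(191, 179)),
               "at least 3")
})

test_that("ratio means concentrate around truth under multiplicative noise", {
  # 30 points, 5% noise: per-seed means are ~N(truth, sd/sqrt(30)); the
  # 3-sigma band should capture ~99.7% of 200 seeds
  truth <- 0.30
  times <- seq(0, 0.29, 0.01)
  ri <- 1e6 * exp(-0.5 * ((times - 0.15) / 0.07)^2)
  hits <- 0L
  for (seed in 1:200) {
    set.seed(seed)
    pts <- make_paired(times, ri,
                       matrix(truth, 1, 1, dimnames = list("191", NULL)),
                       1, 191, noise_cv = 0.05)
    r <- compute_characteristic_ratios(pts, 191)
    if (abs(r$ratio - truth) <= 3 * r$sd / sqrt(r$n)) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("matrix assembly applies the 2% rule and keeps the system overdetermined", {
  mc <- assemble_leda_matrix(table4$CQAs)
  expect_equal(dim(mc$design), c(4L, 3L))
  expect_equal(mc$row_mzs, c(191, 179, 173, 135))
  md <- assemble_leda_matrix(table4$diCQAs)
  expect_equal(dim(md$design), c(5L, 3L))
  expect_equal(md$row_mzs, c(353, 335, 317, 299, 203))
  # an ion below threshold for every isomer is dropped
  tb <- ratio_table("g", 353, c(191, 179, 173), c("A", "B"),
                    rbind(c(0.30, 0.10), c(0.01, 0.01), c(0.05, 0.20)))
  m <- assemble_leda_matrix(tb)
  expect_equal(m$row_mzs, c(191, 173))
  # dropping below m = n isomers is an error
  tb2 <- ratio_table("g", 353, c(191, 179), c("A", "B", "C"),
                     rbind(c(0.3, 0.1, 0.2), c(0.2, 0.3, 0.1)))
  expect_error(assemble_leda_matrix(tb2, threshold = 0.35),
               "underdetermined")
})

test_that("pure-isomer columns deconvolve to identity", {
  for (tb in table4) {
    mat <- assemble_leda_matrix(tb)
    for (iso in tb$isomer_ids) {
      fit <- solve_leda(mat, mat$design[, iso])
      want <- setNames(as.numeric(tb$isomer_ids == iso), tb$isomer_ids)
      expect_equal(fit$fractions, want, tolerance = 1e-9)
      expect_lt(fit$residual_norm, 1e-12)
    }
  }
})

test_that("known mixtures are recovered and match the grid-search oracle", {
  mat <- assemble_leda_matrix(table4$CQAs)
  mixed <- 0.5 * mat$design[, "3-CQA"] + 0.5 * mat$design[, "5-CQA"]
  expect_equal(unname(mixed), c(0.265, 0.110, 0.010, 0.015))
  fit <- solve_leda(mat, mixed)
  expect_equal(unname(fit$fractions), c(0.5, 0.5, 0), tolerance = 1e-6)
  oracle <- grid_search_fractions(mat$design, mixed)
  expect_true(all(abs(fit$fractions - oracle) <= 0.002))
})

test_that("degenerate measured vectors are handled explicitly", {
  mat <- assemble_leda_matrix(table4$CQAs)
  fit <- solve_leda(mat, rep(0, 4))
  expect_equal(unname(fit$fractions), c(0, 0, 0))
  expect_true("no_product_signal" %in% fit$flags)
  expect_error(solve_leda(mat, c(0.1, 0.2)), "4 rows")
  expect_error(solve_leda(mat, c(-0.1, 0.2, 0.1, 0)), "nonnegative")
})

test_that("recovered fractions are monotone in the true share", {
  for (tb in table4) {
    mat <- assemble_leda_matrix(tb)
    shares <- seq(0, 1, 0.1)
    prev <- -1
    for (a in shares) {
      b <- (1 - a) * c(0.6, 0.4)
      truth <- c(a, b)
      measured <- as.numeric(mat$design %*% truth)
      got <- solve_leda(mat, measured)$fractions[[1]]
      expect_gte(got, prev - 1e-9)
      prev <- got
    }
  }
})

test_that("scanwise deconvolution conserves the Ri signal pointwise", {
  sc <- two_peak_scenario(noise_cv = 0.05, seed = 23)
  paired <- pair_events(simulate_run(sc), sc$config)
  pts <- paired[paired$segment == 1, ]
  mat <- assemble_leda_matrix(table4$CQAs)
  ch <- deconvolve_scanwise(pts, mat)
  iso_sum <- rowSums(as.matrix(ch[attr(ch, "isomer_ids")]))
  expect_true(all(abs(iso_sum + ch$residual - ch$ri) <= 1e-9 * pmax(ch$ri, 1)))
  expect_true(all(as.matrix(ch[attr(ch, "isomer_ids")]) >= 0))
  expect_true(all(ch$residual >= 0))
})

test_that("a pure-isomer run reconstructs onto a single trace", {
  peaks <- data.frame(isomer = "3,5-diCQA", group = "diCQAs", rt_min = 4.75,
                      width_min = 0.06, height = 2e6)
  sc <- run_scenario(cqa_acquisition_config(2), peaks, table4, noise_cv = 0)
  paired <- pair_events(simulate_run(sc), sc$config)
  pts <- paired[paired$segment == 2, ]
  ch <- deconvolve_scanwise(pts, assemble_leda_matrix(table4$diCQAs))
  # tolerance sits above the spline-interpolation floor of the Ri trace
  active <- !ch$gated & ch$ri > 0
  expect_true(all(abs(ch[["3,5-diCQA"]][active] - ch$ri[active])
                  <= 1e-3 * ch$ri[active]))
  expect_true(all(ch[["3,4-diCQA"]][active] <= 1e-3 * ch$ri[active]))
  expect_true(all(ch[["4,5-diCQA"]][active] <= 1e-3 * ch$ri[active]))
})

test_that("peak-mode deconvolution reports peak purity", {
  # single isomer: purity 1
  pts <- make_paired(seq(1.8, 2.2, 0.01),
                     1e6 * exp(-0.5 * ((seq(1.8, 2.2, 0.01) - 2) / 0.05)^2),
                     table4$CQAs$ratios[, "5-CQA", drop = FALSE], 1,
                     table4$CQAs$product_mzs)
  mat <- assemble_leda_matrix(table4$CQAs)
  fit <- deconvolve_peak(pts, mat)
  expect_equal(unname(fit$fractions), c(0, 1, 0), tolerance = 1e-9)
  # noiseless 70/30 co-eluting binary mixture through the full scan model
  peaks <- data.frame(isomer = c("3-CQA", "4-CQA"), group = "CQAs",
                      rt_min = 2.0, width_min = 0.05,
                      height = c(0.7, 0.3) * 1e6)
  sc <- run_scenario(cqa_acquisition_config(2), peaks, table4, noise_cv = 0)
  paired <- pair_events(simulate_run(sc), sc$config)
  fit2 <- deconvolve_peak(paired[paired$segment == 1, ], mat,
                          window = c(1.8, 2.2))
  expect_true(all(abs(fit2$fractions - c("3-CQA" = 0.7, "5-CQA" = 0,
                                         "4-CQA" = 0.3)) < 1e-4))
  oracle <- grid_search_fractions(mat$design,
                                  as.numeric(mat$design %*% c(0.7, 0, 0.3)))
  expect_true(all(abs(fit2$fractions - oracle) <= 0.002))
})

test_that("peak fractions equal the Ri-weighted mean of scan fractions (noiseless)", {
  peaks <- data.frame(isomer = c("5-CQA", "4-CQA"), group = "CQAs",
                      rt_min = c(2.0, 2.08), width_min = 0.05,
                      height = c(8e5, 4e5))
  sc <- run_scenario(cqa_acquisition_config(2), peaks, table4, noise_cv = 0)
  paired <- pair_events(simulate_run(sc), sc$config)
  pts <- paired[paired$segment == 1 & paired$rt_min >= 1.8 &
                  paired$rt_min <= 2.3, ]
  mat <- assemble_leda_matrix(table4$CQAs)
  fit_peak <- deconvolve_peak(pts, mat)
  ch <- deconvolve_scanwise(pts, mat, min_ri_frac = 0)
  # trapezoid quadrature weights on the shared time grid
  t <- pts$rt_min
  w <- c(diff(t) / 2, 0) + c(0, diff(t) / 2)
  iso <- attr(ch, "isomer_ids")
  weighted <- colSums(as.matrix(ch[iso]) * w) / sum(ch$ri * w)
  expect_equal(unname(fit_peak$fractions), unname(weighted),
               tolerance = 1e-4)
})

test_that("fraction errors stay small under 5% noise with 30 scans per peak", {
  # median absolute error < 0.05 across both ratio systems
  errs <- c()
  times <- seq(0, 0.29, 0.01)
  ri <- 8e5 * exp(-0.5 * ((times - 0.15) / 0.07)^2)
  for (tbl in table4) {
    mat <- assemble_leda_matrix(tbl)
    set.seed(41)
    for (k in 1:25) {
      truth <- rexp(3); truth <- truth / sum(truth)
      pts <- make_paired(times, ri, tbl$ratios, truth, tbl$product_mzs,
                         noise_cv = 0.05)
      fit <- deconvolve_peak(pts, mat)
      errs <- c(errs, abs(fit$fractions - truth))
    }
  }
  expect_lt(median(errs), 0.05)
})

test_that("ratio tables round trip through CSV", {
  f <- tempfile(fileext = ".csv")
  write_ratio_tables(table4, f)
  back <- read_ratio_tables(f)
  expect_equal(back$CQAs$ratios, table4$CQAs$ratios)
  expect_equal(back$diCQAs$sds, table4$diCQAs$sds)
  expect_equal(names(back), names(table4))
})
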