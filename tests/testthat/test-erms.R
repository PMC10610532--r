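test_that("survival yield and formation are complements of the ion current", {
  expect_equal(compute_sy_pif(100, numeric(0)), c(sy = 100, pif = 0))
  expect_equal(compute_sy_pif(50, c(20, 30)), c(sy = 50, pif = 50))
  expect_equal(compute_sy_pif(25, c(45, 30)), c(sy = 25, pif = 75))
  # complementarity holds for arbitrary nonnegative abundances
  set.seed(31)
  for (i in 1:50) {
    sp <- compute_sy_pif(rexp(1, 1e-4), rexp(sample(1:6, 1), 1e-4))
    expect_equal(unname(sp[1] + sp[2]), 100)
    expect_true(all(sp >= 0 & sp <= 100))
  }
  # a zero-current grid point is flagged, not fabricated
  expect_true(all(is.na(compute_sy_pif(0, c(0, 0)))))
})

test_that("precursor level is the mean over the pre-activation plateau", {
  flat <- erms_series("x", c(0, 5, 10), c(1000, 1000, 1000),
                      matrix(0, 1, 3, dimnames = list("191", NULL)))
  expect_equal(estimate_precursor_max(flat), 1000)
  two <- erms_series("x", c(0, 5, 10, 15), c(990, 1010, 400, 100),
                     matrix(c(0, 0, 600, 900), 1, 4,
                            dimnames = list("191", NULL)))
  expect_equal(estimate_precursor_max(two), 1000)
  # logistic decay: equals the brute-force mean over SY >= 95% points
  sc <- erms_scenario(sy_midpoint = 20, sy_steepness = 0.6,
                      ion_loss_fraction = 0.3, exa_grid = seq(0, 50, 1),
                      noise_cv = 0.03, seed = 9)
  series <- simulate_erms(sc)
  sy <- 100 * series$precursor /
    (series$precursor + colSums(series$products))
  want <- mean(series$precursor[sy >= 95])
  expect_equal(estimate_precursor_max(series), want)
  # no plateau anywhere is an estimation error
  frag <- erms_series("x", c(0, 5), c(10, 5),
                      matrix(c(90, 95), 1, dimnames = list("191", NULL)))
  expect_error(estimate_precursor_max(frag), "lower 'plateau_sy'")
})

test_that("product-ion yield is referenced to the pre-fragmentation level", {
  expect_equal(compute_piy(numeric(0), 100), 0)
  expect_equal(compute_piy(39, 100), 39)
  expect_equal(compute_piy(c(10, 20, 30), 120), 50)
  expect_error(compute_piy(c(1, 2), 0), "positive")
})

test_that("breakdown curves are conserved and expose ion losses", {
  # no fragmentation anywhere
  none <- erms_series("x", seq(0, 20, 5), rep(1000, 5),
                      matrix(0, 1, 5, dimnames = list("191", NULL)))
  cv <- build_breakdown_curves(none)
  expect_equal(cv$sy, rep(100, 5))
  expect_equal(cv$pif, rep(0, 5))
  expect_equal(cv$piy, rep(0, 5))
  # lossless: single product mirrors the precursor decay, SY + PiY = 100
  pre <- 1000 * c(1, 1, 0.8, 0.4, 0.1)
  mirr <- erms_series("x", seq(0, 20, 5), pre,
                      matrix(1000 - pre, 1, dimnames = list("191", NULL)))
  cv2 <- build_breakdown_curves(mirr)
  expect_equal(cv2$sy + cv2$piy, rep(100, 5))
  # 20% ion loss shows as a ~80% yield ceiling
  sc <- erms_scenario(sy_midpoint = 18, sy_steepness = 1,
                      ion_loss_fraction = 0.2, exa_grid = seq(0, 50, 1),
                      noise_cv = 0)
  cv3 <- build_breakdown_curves(simulate_erms(sc))
  expect_equal(max(cv3$piy), 80, tolerance = 0.01)
})

test_that("CID summary interpolates SY_ExA50 and reads ExA_max off the grid", {
  mk <- function(exa, sy, piy)
    structure(list(exa_grid = exa, sy = sy, pif = 100 - sy, piy = piy,
                   per_ion_yield = matrix(piy, 1,
                                          dimnames = list("191", NULL)),
                   precursor_max = 1000, compound_id = "x"),
              class = "breakdown_curves")
  s <- estimate_cid_summary(mk(c(20, 25), c(60, 40), c(10, 20)))
  expect_equal(s$sy_exa50, 22.5)
  s2 <- estimate_cid_summary(mk(c(15, 25, 35), c(90, 50.0001, 10),
                                c(10, 56, 40)))
  expect_equal(s2$exa_max, 25)
  expect_equal(s2$piy_max, 56)
  # ties in PiY break toward the lower ExA
  s3 <- estimate_cid_summary(mk(c(15, 25, 35), c(90, 50.0001, 10),
                                c(10, 56, 56)))
  expect_equal(s3$exa_max, 25)
  # SY never reaching 50% is flagged, not invented
  s4 <- estimate_cid_summary(mk(c(15, 25), c(90, 70), c(5, 10)))
  expect_true(is.na(s4$sy_exa50))
  expect_true("sy_never_crosses_50" %in% s4$flags)
})

test_that("CID summary is invariant under uniform abundance rescaling", {
  sc <- erms_scenario(sy_midpoint = 22, sy_steepness = 0.5,
                      ion_loss_fraction = 0.4, exa_grid = seq(0, 50, 2.5),
                      noise_cv = 0.05, seed = 13)
  series <- simulate_erms(sc)
  s1 <- estimate_cid_summary(build_breakdown_curves(series))
  scaled <- erms_series(series$compound_id, series$exa_grid,
                        series$precursor * 37.5, series$products * 37.5)
  s2 <- estimate_cid_summary(build_breakdown_curves(scaled))
  expect_equal(s1$sy_exa50, s2$sy_exa50)
  expect_equal(s1$exa_max, s2$exa_max)
  expect_equal(s1$piy_max, s2$piy_max)
})

test_that("noiseless logistic series return the generator parameters", {
  for (mid in c(18.1, 21.0, 24.4)) {
    sc <- erms_scenario(sy_midpoint = mid, sy_steepness = 0.4,
                        ion_loss_fraction = 0, exa_grid = seq(0, 50, 1),
                        noise_cv = 0)
    s <- estimate_cid_summary(build_breakdown_curves(simulate_erms(sc)))
    expect_lt(abs(s$sy_exa50 - mid), 0.1)
  }
})

test_that("the SY/PiF crossing sits at 50% abundance", {
  sc <- erms_scenario(sy_midpoint = 20.5, sy_steepness = 0.5,
                      ion_loss_fraction = 0.47, exa_grid = seq(0, 50, 2.5),
                      noise_cv = 0)
  cr <- sy_pif_crossing(build_breakdown_curves(simulate_erms(sc)))
  expect_equal(cr$value, 50)
})

test_that("ERMS series round trip through the tidy CSV format", {
  sc <- erms_scenario(compound_id = "5-CQA", sy_midpoint = 20.5,
                      noise_cv = 0.05, seed = 17)
  series <- simulate_erms(sc)
  f <- tempfile(fileext = ".csv")
  write_erms(series, f)
  back <- read_erms(f)
  expect_equal(back$exa_grid, series$exa_grid)
  expect_equal(back$precursor, series$precursor)
  expect_equal(unname(back$products), unname(series$products))
  expect_equal(back$compound_id, series$compound_id)
})
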