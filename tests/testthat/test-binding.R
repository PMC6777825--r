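test_that("predict_tm matches the closed form and the implicit equation", {
  expect_identical(predict_tm(0, 131, 72.1, 326.2), 326.2)
  # frozen value cross-checked against a numeric root-finder
  tm <- predict_tm(300, 30.9, 72.1, 326.2)
  expect_equal(tm, 333.305, tolerance = 1e-4)
  expect_equal(tm, schellman_tm_root(300, 30.9, 72.1, 326.2),
               tolerance = 1e-9)
  # substituting back satisfies the relation to ~1e-10 K
  resid <- (tm - 326.2) -
    tm * 326.2 * R_KCAL / 72.1 * log1p(300 / 30.9)
  expect_lt(abs(resid), 1e-10)
  expect_error(predict_tm(1e30, 0.001, 10, 326.2), "infeasible")
})

test_that("single-point inversion is the exact inverse of predict_tm", {
  set.seed(77)
  for (i in 1:50) {
    kd <- 10^runif(1, 0, 4)           # 1 uM .. 10 mM
    dh0 <- runif(1, 40, 120)
    t0 <- runif(1, 310, 340)
    L <- 10^runif(1, 0.5, 4.5)
    dtm <- predict_tm(L, kd, dh0, t0) - t0
    est <- estimate_kd_single_point(dtm, L, t0 = t0, dh0 = dh0)
    expect_equal(est$kd_app_uM, kd, tolerance = 1e-9)
  }
})

test_that("the printed 300 uM glutamine shift inverts to ~17.6 uM, preferred", {
  est <- estimate_kd_single_point(8.7, 300)
  expect_equal(est$kd_app_uM, 17.632, tolerance = 1e-3)
  expect_identical(est$window, "preferred")
  expect_true(est$usable)
  # kd is monotone decreasing in the shift and diverges as dTm -> 0+
  kds <- estimate_kd_single_point(c(0.001, 0.5, 2, 5, 8.7), 300)$kd_app_uM
  expect_true(all(diff(kds) < 0))
  expect_gt(kds[1], 1e5)
})

test_that("delta-Tm windows classify per the empirical thresholds", {
  est <- estimate_kd_single_point(c(-2, 0.5, 1.5, 3, 8, 12), 10000)
  expect_identical(est$window,
                   c("destabilized", "below_floor", "out_of_range",
                     "acceptable", "preferred", "out_of_range"))
  expect_identical(est$usable, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(est$kd_app_uM[est$delta_tm_K <= 0])))
})

test_that("noiseless dose-series fits recover the generating parameters", {
  L <- 10^seq(0, 3.5, length.out = 8)
  s <- data.frame(conc_uM = L, mean_tm_K = predict_tm(L, 131, 72.1, 326.2))
  f <- fit_dose_series(s, t0 = 326.2)
  expect_true(f$converged)
  expect_equal(f$kd_app_uM, 131, tolerance = 1e-6)
  expect_equal(f$dh0_kcal, 72.1, tolerance = 1e-6)
  expect_lt(f$residual_rms_K, 1e-6)

  # permuting point order leaves the fit bit-identical
  perm <- s[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  fp <- fit_dose_series(perm, t0 = 326.2)
  expect_identical(coef(f$fit), coef(fp$fit))
})

test_that("degenerate dose series are refused with clear messages", {
  L <- c(1, 10, 100, 1000)
  flat <- data.frame(conc_uM = L, mean_tm_K = rep(326.25, 4))
  expect_error(fit_dose_series(flat, 326.2), "flat")
  short <- data.frame(conc_uM = L[1:3],
                      mean_tm_K = predict_tm(L[1:3], 30, 72, 326.2))
  expect_error(fit_dose_series(short, 326.2), "4 concentration")
  dup <- data.frame(conc_uM = c(1, 1, 10, 100),
                    mean_tm_K = predict_tm(c(1, 1, 10, 100), 30, 72, 326.2))
  expect_error(fit_dose_series(dup, 326.2), "duplicate")
})

test_that("delta-Tm grows monotonically in log concentration, concave in L", {
  Llog <- 10^seq(0, 4, length.out = 40)
  dtm_log <- predict_tm(Llog, 30.9, 72.1, 326.2) - 326.2
  expect_true(all(diff(dtm_log) > 0))
  # diminishing returns in concentration itself: concave on a linear grid
  L <- seq(1, 10000, length.out = 200)
  dtm <- predict_tm(L, 30.9, 72.1, 326.2) - 326.2
  expect_true(all(diff(diff(dtm)) < 0))
})

test_that("single-point kd tolerates +/-20% enthalpy misspecification", {
  # shifts generated inside the preferred window with the true enthalpy
  # off by up to 20%, then inverted with the assumed 72.1 kcal/mol
  for (dh_true in c(59, 65, 72.1, 80, 85)) {
    dtm <- predict_tm(400, 30.9, dh_true, 326.1) - 326.1
    est <- estimate_kd_single_point(dtm, 400)
    expect_identical(est$window, "preferred")
    fold <- est$kd_app_uM / 30.9
    expect_gt(fold, 0.5)
    expect_lt(fold, 2)
  }
})

test_that("reporting estimates follow the concentration-adoption rule", {
  # glutamine-like: only the lowest concentration sits in 6-11 K
  e1 <- estimate_kd_single_point(c(8.0, 12.5, 14.0),
                                 c(100, 1000, 10000), ligand_id = "Gln")
  s1 <- select_reporting_estimate(e1)
  expect_equal(s1$conc_uM, 100)
  expect_identical(s1$window, "preferred")

  # a 9 K shift at the top concentration is preferred and wins
  e2 <- estimate_kd_single_point(c(0.5, 3, 9),
                                 c(100, 1000, 10000), ligand_id = "Ala")
  s2 <- select_reporting_estimate(e2)
  expect_equal(s2$conc_uM, 10000)

  # acceptable-only ligand: highest acceptable concentration adopted
  e3 <- estimate_kd_single_point(c(0.5, 2.5, 4.0),
                                 c(100, 1000, 10000), ligand_id = "Gly")
  s3 <- select_reporting_estimate(e3)
  expect_equal(s3$conc_uM, 10000)
  expect_identical(s3$window, "acceptable")

  # destabilized everywhere: unusable with the exclusion reason
  e4 <- estimate_kd_single_point(c(-0.5, -1, -2),
                                 c(100, 1000, 10000), ligand_id = "Lys")
  s4 <- select_reporting_estimate(e4)
  expect_false(s4$usable)
  expect_match(s4$selection_reason, "destabilized")
  expect_true(is.na(s4$kd_app_uM))

  expect_error(select_reporting_estimate(rbind(e1, e2)), "mixed")
})

test_that("noisy fits are unbiased around the generating Kd", {
  gln <- ligand_spec("Gln", "agonist", kd_true = 30.9, dh0_true = 72.1)
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 100, 300)
  kds <- vapply(1:40, function(i) {
    ds <- simulate_dose_series(gln, 326.2, concs, n_reps = 6,
                               tm_noise_sd = 0.3, seed = 100 + i)
    fit_dose_series(average_dose_series(ds), 326.2)$kd_app_uM
  }, numeric(1))
  expect_true(all(is.finite(kds)))
  expect_equal(median(kds), 30.9, tolerance = 0.25)
})
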