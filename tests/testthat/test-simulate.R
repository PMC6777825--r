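test_that("unfolded fraction is exactly one half at the transition midpoint", {
  mc <- simulate_melt_curve(list(transition_spec(53)),
                            baseline_intercept = 0, baseline_slope = 0,
                            noise_sd = 0)
  expect_equal(mc$fluorescence[mc$temperature_C == 53.0], 0.5)
})

test_that("invalid simulator inputs are rejected", {
  expect_error(simulate_melt_curve(list()), "at least one transition")
  expect_error(simulate_melt_curve(list(transition_spec(53)),
                                   grid = seq(20, 99, 0.2)), "within")
  expect_error(simulate_melt_curve(list(transition_spec(53)),
                                   grid = c(30, 29, 31)), "increasing")
  expect_error(simulate_melt_curve(list(transition_spec(53)),
                                   noise_sd = 0.1), "seed")
  expect_error(transition_spec(110), "tm_true")
})

test_that("derivative of a noiseless biphasic curve peaks at both midpoints", {
  trs <- list(transition_spec(50.0), transition_spec(58.7))
  mc <- simulate_melt_curve(trs, noise_sd = 0, quench_rate = 0)
  # oracle: analytic derivative of the closed form on the same grid
  oracle <- analytic_dfdt(mc$temperature_C, trs)
  n <- length(oracle)
  omax <- which(oracle[2:(n - 1)] > oracle[1:(n - 2)] &
                oracle[2:(n - 1)] >= oracle[3:n]) + 1L
  expect_length(omax, 2)
  expect_equal(mc$temperature_C[omax], c(50.0, 58.7), tolerance = 0.21)
  # the package caller agrees with the oracle peak positions
  tc <- call_tm(mc)
  expect_equal(nrow(tc$peaks), 2)
  expect_equal(tc$peaks$tm_C, mc$temperature_C[omax], tolerance = 0.21)
})

test_that("dose series follows the Schellman ground truth", {
  gln <- ligand_spec("Gln", "agonist", kd_true = 30.9, dh0_true = 72.1)
  ds <- simulate_dose_series(gln, t0 = 326.2, concentrations = 300,
                             n_reps = 3, tm_noise_sd = 0, seed = 1)
  expect_equal(unique(ds$tm_K) - 326.2, 7.105, tolerance = 1e-3)
  expect_equal(attr(ds, "kd_true"), 30.9)

  # predict_tm at L = 0 anchors delta-Tm at zero
  expect_identical(predict_tm(0, 30.9, 72.1, 326.2), 326.2)

  # strictly increasing delta-Tm across 1..10000 uM for any agonist
  concs <- c(1, 10, 100, 1000, 10000)
  ds2 <- simulate_dose_series(gln, 326.2, concs, n_reps = 1,
                              tm_noise_sd = 0, seed = 1)
  expect_true(all(diff(ds2$tm_K) > 0))
})

test_that("seeded simulation is reproducible and seeds decorrelate noise", {
  gln <- ligand_spec("Gln", "agonist", kd_true = 30.9)
  a <- simulate_dose_series(gln, 326.2, c(10, 100), n_reps = 4,
                            tm_noise_sd = 0.3, seed = 11)
  b <- simulate_dose_series(gln, 326.2, c(10, 100), n_reps = 4,
                            tm_noise_sd = 0.3, seed = 11)
  c <- simulate_dose_series(gln, 326.2, c(10, 100), n_reps = 4,
                            tm_noise_sd = 0.3, seed = 12)
  expect_identical(a$tm_K, b$tm_K)
  expect_false(any(a$tm_K == c$tm_K))
  # the simulator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  invisible(simulate_dose_series(gln, 326.2, 10, 2, 0.3, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("response panel follows the fixed-maximum Hill relation", {
  p <- simulate_response_panel(c(Gln = 5), drfu_max = 104.3,
                               concentrations = 5, noise_sd = 0)
  expect_equal(p$drfu, 104.3 / 2)
  p2 <- simulate_response_panel(c(X = 40), drfu_max = 104.3,
                                concentrations = 10, noise_sd = 0)
  expect_equal(p2$drfu, 20.86)
  # weak-binder limit: response vanishes as ec50 grows
  p3 <- simulate_response_panel(c(X = 1e9), drfu_max = 104.3,
                                concentrations = 10, noise_sd = 0)
  expect_lt(p3$drfu, 1e-3)
  # all noiseless responses lie strictly inside (0, drfu_max)
  p4 <- simulate_response_panel(c(A = 1, B = 10, C = 100), noise_sd = 0)
  expect_true(all(p4$drfu > 0 & p4$drfu < 104.3))
})

test_that("descriptor table covers the 20 l-amino acids with sane values", {
  d <- builtin_descriptor_table()
  expect_equal(nrow(d), 20)
  expect_false(anyNA(d))
  expect_identical(d$ligand_id[which.min(d$volume)], "Gly")
  expect_true(all(d$charge[d$ligand_id %in% c("Asp", "Glu")] < 0))
  expect_true(all(d$charge[d$ligand_id %in% c("Lys", "Arg")] > 0))
  # lossless join with a 15-ligand affinity table keyed on ligand_id
  lig15 <- setdiff(d$ligand_id, "Pro")[1:15]
  pkd <- data.frame(ligand_id = lig15, pkd = seq_along(lig15))
  joined <- merge(pkd, d, by = "ligand_id")
  expect_equal(nrow(joined), 15)
  expect_false(anyNA(joined))
})

test_that("plate simulator composes wells per ligand mode", {
  specs <- list(Gln = ligand_spec("Gln", "agonist", kd_true = 30.9),
                Lys = ligand_spec("Lys", "destabilizer"),
                DAla = ligand_spec("DAla", "inert"))
  pm <- plate_map(c("A1", "A2", "A3", "A4"),
                  c("buffer", "Gln", "Lys", "DAla"),
                  c(0, 300, 10000, 10000))
  curves <- simulate_plate(pm, specs, noise_sd = 0, seed = 1)
  calls <- call_plate_tms(curves)
  buf_tm <- calls$tm_C[calls$well_id == "A1"]
  # buffer well: single transition at the buffer Tm
  expect_false(calls$biphasic[calls$well_id == "A1"])
  expect_equal(buf_tm, 53.0, tolerance = 0.21)
  # agonist well: biphasic, right-side peak shifted up
  expect_true(calls$biphasic[calls$well_id == "A2"])
  expect_gt(calls$tm_C[calls$well_id == "A2"], buf_tm + 6)
  # destabilizer at 10 mM: adopted Tm below buffer
  expect_lt(calls$tm_C[calls$well_id == "A3"], buf_tm)
  # inert ligand at 10 mM: |delta Tm| below the 1 K reporting floor
  expect_lt(abs(calls$tm_C[calls$well_id == "A4"] - buf_tm), 1)
  expect_error(simulate_plate(plate_map("B1", "Unknown", 10), specs),
               "Unknown")
})

test_that("buffer-well Tm precision matches the instrument-scale noise", {
  pm <- plate_map(paste0("B", 1:7), rep("buffer", 7), rep(0, 7))
  curves <- simulate_plate(pm, list(), seed = 21)
  calls <- call_plate_tms(curves)
  sem <- sd(calls$tm_C) / sqrt(7)
  # order-of-magnitude check against a reported ~0.07 K s.e.m. (n = 7)
  expect_gt(sem, 0.007)
  expect_lt(sem, 0.7)
  expect_equal(mean(calls$tm_C), 53.0, tolerance = 0.3)
})
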