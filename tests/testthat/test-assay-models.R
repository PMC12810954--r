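test_that("closed-form Langmuir matches forward-Euler integration (oracle)", {
  ka <- 1.38e6; kd <- 4.296e-3; rmax <- 30; conc <- 100e-9
  sg <- simulate_sensorgram(ka, kd, rmax, conc)
  euler <- bf_euler_sensorgram(ka, kd, rmax, conc, 180, 600, sg$time, dt = 0.01)
  expect_lt(max(abs(sg$response - euler)), 0.05)
})

test_that("sensorgram limits behave physically", {
  ka <- 1e6; kd <- 1e-3; rmax <- 25
  sg <- simulate_sensorgram(ka, kd, rmax, conc = 1e-5, t_assoc = 2000, t_dissoc = 10)
  # saturating concentration: association plateau approaches Rmax
  expect_equal(max(sg$response), rmax * ka * 1e-5 / (ka * 1e-5 + kd), tolerance = 1e-6)
  expect_gt(max(sg$response), 0.99 * rmax)
  expect_equal(sg$response[sg$time == 0], 0)
  # dissociation is strictly decreasing without noise
  sg2 <- simulate_sensorgram(ka, kd, rmax, conc = 1e-7)
  dis <- sg2$response[sg2$time > 180]
  expect_true(all(diff(dis) < 0))
  expect_error(simulate_sensorgram(-1, kd, rmax, 1e-7), "positive")
  expect_error(simulate_sensorgram(ka, kd, rmax, 1e-7, noise_sd = 1), "seed")
})

test_that("noiseless global kinetic fit recovers the rates exactly", {
  ka <- 5.86e6; kd <- 7.844e-2; rmax <- 30
  concs <- 100e-9 / 3^(0:4)
  d <- dplyr::bind_rows(lapply(concs, function(cc)
    simulate_sensorgram(ka, kd, rmax, cc)))
  fit <- fit_kinetics(d)
  expect_equal(fit$ka, ka, tolerance = 1e-3)
  expect_equal(fit$kd, kd, tolerance = 1e-3)
  expect_equal(fit$rmax, rmax, tolerance = 1e-3)
  expect_equal(fit$KD, kd / ka, tolerance = 1e-9)  # derived, never refit
  expect_equal(fit$n_curves, 5L)
})

test_that("noisy global kinetic fit recovers rates within 2%", {
  ds <- make_assay_dataset(seed = 42L, melt = NULL)
  fit <- fit_kinetics(ds$sensorgrams)
  tr <- ds$truth$kinetics
  expect_lt(abs(fit$ka - tr$ka) / tr$ka, 0.02)
  expect_lt(abs(fit$kd - tr$kd) / tr$kd, 0.02)
  expect_lt(abs(fit$KD - tr$KD) / tr$KD, 0.02)
})

test_that("kinetic fit rejects degenerate inputs", {
  sg <- simulate_sensorgram(1e6, 1e-3, 30, 1e-7)
  expect_error(fit_kinetics(sg), "at least 3")
  flat <- dplyr::bind_rows(lapply(c(1e-7, 3e-8, 1e-8), function(cc) {
    s <- simulate_sensorgram(1e6, 1e-3, 30, cc)
    s$response <- 0
    s
  }))
  expect_error(fit_kinetics(flat), "flat response")
})

test_that("kd_from_rates reproduces the reported affinities", {
  expect_equal(signif(kd_from_rates(5.86e6, 7.844e-2) * 1e9, 3), 13.4)
  expect_equal(kd_from_rates(1e6, 0), 0)
  expect_error(kd_from_rates(0, 1e-3), "positive")
  expect_error(kd_from_rates(1e6, -1), "nonnegative")
})

test_that("kd_consistency flags a reported KD that disagrees with kd/ka", {
  ok <- kd_consistency(1.38e6, 4.296e-3, 3.12e-9)
  expect_true(ok$consistent)
  # rate ratio 6.13 nM vs a reported 5.22 nM is a >5% disagreement
  bad <- kd_consistency(1.63e6, 9.994e-3, 5.22e-9)
  expect_false(bad$consistent)
  expect_gt(bad$relative_difference, 0.05)
})

test_that("noiseless Boltzmann fit recovers Tm essentially exactly", {
  curve <- simulate_melt_curve(56.35)
  fit <- fit_melt_curve(curve)
  expect_equal(fit$tm, 56.35, tolerance = 1e-4)
  expect_equal(fit$slope, 2, tolerance = 1e-3)
})

test_that("the melt fit is invariant to baseline offset and scale", {
  f1 <- fit_melt_curve(simulate_melt_curve(70.39))
  f2 <- fit_melt_curve(simulate_melt_curve(70.39, f_low = 500, f_high = 1700))
  expect_equal(f1$tm, f2$tm, tolerance = 1e-6)
  expect_equal(f2$f_low, 500, tolerance = 1e-3)
  expect_equal(f2$f_high, 1700, tolerance = 1e-3)
})

test_that("noisy Boltzmann fit recovers Tm within 0.5 degC", {
  curve <- simulate_melt_curve(71.12, noise_sd = 0.02, seed = 7L)
  fit <- fit_melt_curve(curve)
  expect_lt(abs(fit$tm - 71.12), 0.5)
})

test_that("melt fitting rejects curves without a transition", {
  flat <- tibble::tibble(temperature = seq(25, 95, 0.5), fluorescence = 1)
  expect_error(fit_melt_curve(flat), "no transition")
  noise_only <- simulate_melt_curve(200, noise_sd = 0.02, seed = 3L)
  expect_error(fit_melt_curve(noise_only), "no transition")
  expect_error(fit_melt_curve(simulate_melt_curve(60)[1:5, ]), "at least 10")
})

test_that("tumor volume follows the caliper formula and endpoint", {
  v <- tumor_volume(10, 10)
  expect_equal(v$volume, 520)
  expect_false(v$endpoint_reached)
  v2 <- tumor_volume(15, 15)
  expect_equal(v2$volume, 1755)
  expect_true(v2$endpoint_reached)
  expect_equal(tumor_volume(0, 0)$volume, 0)
  # symmetric in the two calipers, vectorized
  expect_equal(tumor_volume(12, 8)$volume, tumor_volume(8, 12)$volume)
  expect_equal(tumor_volume(c(10, 15), c(10, 15))$volume, c(520, 1755))
  expect_error(tumor_volume(-1, 5), "nonnegative")
})

test_that("assay tidiers expose estimates in documented shapes", {
  ds <- make_assay_dataset(seed = 42L)
  fit <- fit_kinetics(ds$sensorgrams)
  td <- tidy(fit)
  expect_equal(td$term, c("ka", "kd", "KD", "Rmax"))
  expect_equal(glance(fit)$KD_nM, fit$KD * 1e9)
  expect_s3_class(autoplot(fit), "ggplot")
  mf <- fit_melt_curve(ds$melt)
  expect_equal(tidy(mf)$estimate[1], mf$tm)
  expect_s3_class(autoplot(mf), "ggplot")
})
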