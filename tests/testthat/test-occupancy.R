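test_that("Fe calibration statistics follow the population definition", {
  cal <- calibrate(rep(1.7, 30))
  expect_equal(cal$mean, 1.7)
  expect_equal(cal$cv, 0)
  expect_equal(cal$n, 30)
  cal2 <- calibrate(c(1.0, 1.0, 1.04))
  expect_equal(cal2$cv, 1.9, tolerance = 0.05)
  expect_silent(calibrate(c(1.0, 1.0, 1.04)))   # below the 4% quality bound
})

test_that("calibration quality gates warn at 4% and fail at 15%", {
  expect_warning(calibrate(c(1, 1.2, 0.9, 1.05)), "4%")
  expect_error(suppressWarnings(calibrate(c(1, 2, 0.4))), "15%")
  expect_error(calibrate(numeric(0)), "calibration error")
  expect_error(calibrate(c(-1, -1.2)), "non-positive")
})

test_that("occupancy conversion reproduces the hand arithmetic", {
  cal <- calibrate(c(1, 1))
  est <- function(d, mode) {
    estimate_se_occupancy(d, cal, mode = mode,
                          aperture_correction = FALSE)$se_occupancy
  }
  expect_equal(est(2.56, "mixed"), 1)
  expect_equal(est(2.56, "free"), 1)
  expect_equal(est(0.16, "mixed"), 0)
  expect_equal(est(1.36, "mixed"), 0.5)
})

test_that("free-mode never falls below mixed mode by more than r_S/r_Se", {
  cal <- calibrate(c(1, 1))
  for (d in seq(0.1, 2.56, by = 0.2)) {
    pf <- estimate_se_occupancy(d, cal, mode = "free",
                                aperture_correction = FALSE)
    pm <- estimate_se_occupancy(d, cal, mode = "mixed",
                                aperture_correction = FALSE)
    expect_gte(pf$se_occupancy + 1e-12, pm$se_occupancy - 0.24 / 3.84)
  }
  # at full Se density the two modes coincide
  pf <- estimate_se_occupancy(2.56, cal, mode = "free",
                              aperture_correction = FALSE)
  pm <- estimate_se_occupancy(2.56, cal, mode = "mixed",
                              aperture_correction = FALSE)
  expect_equal(pf$se_occupancy, pm$se_occupancy)
})

test_that("the detection floor tracks the map RMS linearly", {
  blur <- 9.0
  cal <- calibrate(rep(1.5 * aperture_fraction(1, 9 + blur), 2))
  peak <- 3.84 * (4 * pi / (9.9 + blur))^1.5
  expect_equal(detection_floor(0, cal), 0)
  expect_equal(detection_floor(0.02 * peak, cal), 0.02, tolerance = 1e-10)
  expect_equal(detection_floor(0.10 * peak, cal), 0.10, tolerance = 1e-10)
})

test_that("out-of-range estimates are clamped with flags, not silently", {
  cal <- calibrate(rep(1, 30))
  near <- estimate_se_occupancy(0.14, cal, mode = "mixed", floor = 0.02,
                                aperture_correction = FALSE)
  expect_equal(near$se_occupancy, 0)
  expect_true(near$clamped)
  expect_identical(near$flag, "")
  far <- estimate_se_occupancy(3.5, cal, mode = "mixed", floor = 0.02,
                               aperture_correction = FALSE)
  expect_false(far$clamped)
  expect_identical(far$flag, "inconsistent")
  expect_gt(far$se_occupancy, 1)
  expect_error(estimate_se_occupancy(-0.5, cal, floor = 0.02,
                                     aperture_correction = FALSE),
               "inconsistent-site")
})

test_that("occupancy estimates are invariant under map rescaling", {
  scene <- build_scene(fixture_spec(seed = 21))
  f1 <- fit_occupancy(scene)
  scaled <- scene
  scaled$map$values <- scene$map$values * 37.5
  f2 <- fit_occupancy(scaled)
  expect_equal(f2$results$se_occupancy, f1$results$se_occupancy,
               tolerance = 1e-10)
  expect_equal(f2$floor, f1$floor, tolerance = 1e-10)
})

test_that("noiseless planted occupancies are recovered within 0.01", {
  rec <- noiseless_recovery()
  expect_lt(max(abs(rec$estimate - rec$truth)), 0.01)
})

test_that("estimates increase strictly with the planted Se fraction", {
  rec <- noiseless_recovery()
  for (cp in 1:2) {
    tr <- rec[rec$site == "2B" & rec$copy_id == cp, ]
    tr <- tr[order(tr$planted_2B), ]
    expect_true(all(diff(tr$estimate) > 0))
  }
})

test_that("noisy recovery at default map noise stays within 0.05 MAE", {
  mc <- mc_replicates(100)
  expect_lte(mean(mc$mae), 0.05)
  expect_lte(max(mc$mae), 0.1)
})

test_that("copy-to-copy deviations behave as the empirical uncertainty", {
  r <- data.frame(site = c("2B", "5A", "3A", "2B", "5A", "3A"),
                  copy_id = rep(1:2, each = 3),
                  se_occupancy = c(0.5, 0.3, 0.2, 0.55, 0.3, 0.2))
  cc <- cross_copy_check(r)
  expect_equal(cc$max_dev, 0.05)
  expect_equal(cc$per_site$deviation[cc$per_site$site == "5A"], 0)
  bad <- r[-6, ]
  expect_error(cross_copy_check(bad), "pairing")
})

test_that("the remote low-occupancy site is quantified in free mode", {
  spec <- fixture_spec(remote_se = 0.15, seed = 31)
  fit <- fit_occupancy(build_scene(spec))
  rem <- fit$results[fit$results$site == "remote", ]
  expect_identical(rem$mode, "free")
  expect_lt(abs(rem$se_occupancy - 0.15), 0.05)
})
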