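test_that("noiseless competitive-inhibition data give the exact K_i", {
  d <- simulate_dixon_assay(ki = 2000, cv = 0, replicates = 1)
  fit <- dixon_ki(d)
  expect_equal(fit$ki, 2000, tolerance = 1e-6)
  expect_lt(fit$ki_mad, 1e-6)
  expect_equal(unname(coef(fit)), fit$ki)
})

test_that("the Dixon fit is invariant under velocity rescaling", {
  d <- simulate_dixon_assay(ki = 410, cv = 0.01, seed = 7)
  d2 <- d
  d2$velocity <- d2$velocity * 123.4
  expect_equal(dixon_ki(d2)$ki, dixon_ki(d)$ki, tolerance = 1e-9)
})

test_that("Dixon input validation catches degenerate tables", {
  d <- simulate_dixon_assay(cv = 0, replicates = 1)
  bad <- d
  bad$velocity[1] <- 0
  expect_error(dixon_ki(bad), "invalid-velocity")
  expect_error(dixon_ki(d[d$substrate == 20, ]), ">= 2 substrate levels")
  # exactly parallel lines: 1/v = 1 + I at both substrate levels
  par <- expand.grid(substrate = c(1, 2), inhibitor = 0:3)
  par$velocity <- 1 / (1 + par$inhibitor)
  expect_error(suppressWarnings(dixon_ki(par)), "no-intersection")
})

test_that("K_i recovery at 5% velocity noise has small median bias", {
  kis <- vapply(1:200, function(s) {
    dixon_ki(simulate_dixon_assay(ki = 2000, cv = 0.05, seed = s))$ki
  }, numeric(1))
  expect_lt(abs(median(kis) / 2000 - 1), 0.10)
})

test_that("specific activity is the slope of the linear time course", {
  expect_equal(specific_activity(0:5, 10 * (0:5), protein_mg = 1), 10)
  expect_equal(specific_activity(0:5, 10 * (0:5), protein_mg = 2), 5)
  expect_equal(specific_activity(0:5, rep(4, 6)), 0)
  expect_error(specific_activity(0:5, 10 * (0:5), protein_mg = 0), "input error")
  # noisy line: recovered within 3 standard errors
  set.seed(17)
  t <- seq(0.5, 4, by = 0.5)
  p <- 2350 * t + rnorm(length(t), 0, 100)
  se <- 100 / sqrt(sum((t - mean(t))^2))
  expect_lt(abs(specific_activity(t, p) - 2350), 3 * se)
})

test_that("lag phase is the x-intercept of the steady-state segment", {
  t <- seq(0, 8, by = 0.5)
  expect_equal(lag_phase(t, 5 * t), 0)
  expect_equal(lag_phase(t, pmax(0, 5 * (t - 3))), 3, tolerance = 1e-9)
  expect_error(lag_phase(c(0, 1, 2), c(0, 1, 2)), "insufficient-data")
  # small noise: lag recovered within 0.3 min across seeds
  lags <- vapply(1:20, function(s) {
    set.seed(s)
    lag_phase(t, pmax(0, 5 * (t - 3)) + rnorm(length(t), 0, 0.2))
  }, numeric(1))
  expect_lt(abs(median(lags) - 3), 0.3)
  expect_lt(max(abs(lags - 3)), 1)
  # the Se-labeled enzyme emulation has the longer lag
  nat <- simulate_activity_timecourse("native")
  lab <- simulate_activity_timecourse("se_labeled")
  expect_lt(lag_phase(nat$time_min, nat$product_nmol),
            lag_phase(lab$time_min, lab$product_nmol))
})

test_that("relative activity is an exact identity on itself", {
  tab <- data.frame(compound = rep(c("A", "B"), each = 3),
                    value = c(10, 11, 12, 20, 21, 22))
  expect_equal(relative_activity(tab, list(compound = "A"),
                                 list(compound = "A"))$percent, 100)
  ra <- relative_activity(tab, list(compound = "A"), list(compound = "B"))
  expect_equal(ra$percent, 100 * 11 / 21)
  expect_gt(ra$sd, 0)
  neg <- data.frame(compound = c("A", "B"), value = c(1, -2))
  expect_error(relative_activity(neg, list(compound = "A"),
                                 list(compound = "B")), "division")
})

test_that("dose optimum picks the maximal mean with sensible tie handling", {
  one <- data.frame(conc_mM = 2, value = 5)
  expect_equal(dose_optimum(one)$conc, 2)
  mono <- data.frame(conc_mM = rep(c(1, 2, 5), each = 2),
                     value = rep(c(1, 2, 3), each = 2))
  om <- dose_optimum(mono)
  expect_equal(om$conc, 5)
  expect_true(om$no_interior_max)
  tie <- data.frame(conc_mM = c(1, 2, 5), value = c(3, 3, 1))
  expect_warning(ot <- dose_optimum(tie), "tie")
  expect_equal(ot$conc, 1)
  expect_error(dose_optimum(mono[0, ]), "empty")
})

test_that("concentration units normalize to micromolar", {
  expect_equal(to_uM(1, "mM"), 1000)
  expect_equal(to_uM(2, "M"), 2e6)
  expect_equal(to_uM(5, "uM"), 5)
})
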