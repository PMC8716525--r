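test_that("penetration curve peaks at the MPPS and matches hand-evaluated points", {
  m <- mask_model(p_mpps = 0.04, d_mpps_nm = 200, curvature_k = 0.5,
                  mask_sigma = 0, defect_fraction = 0)
  expect_equal(penetration_curve(200, m), 0.04)
  # hand evaluation: 0.04 * exp(-0.5 * ln^2(0.5))
  expect_equal(penetration_curve(100, m), 0.04 * exp(-0.5 * log(0.5)^2),
               tolerance = 1e-12)
  # unimodal in log-diameter with maximum at the MPPS
  d <- exp(seq(log(90), log(7500), length.out = 200))
  p <- penetration_curve(d, m)
  expect_equal(d[which.max(p)], 200, tolerance = 0.02)
  expect_true(all(diff(p[d < 200]) > 0) && all(diff(p[d > 205]) < 0))
  # zero curvature gives a flat curve; mask_effect scales; cap at 1
  flat <- mask_model(p_mpps = 0.04, curvature_k = 0, mask_sigma = 0, defect_fraction = 0)
  expect_equal(penetration_curve(c(90, 500, 7500), flat), rep(0.04, 3))
  expect_equal(penetration_curve(200, flat, mask_effect = 50), 1)
  expect_error(penetration_curve(-5, m), "positive")
})

test_that("discretized lognormal probabilities sum to the analytic grid mass", {
  a <- aerosol_params()
  g <- size_grid()
  p <- class_probabilities(a, g)
  analytic <- plnorm(7500, log(80), log(1.8)) - plnorm(90, log(80), log(1.8))
  expect_equal(sum(p), analytic, tolerance = 1e-9)
  expect_true(all(p >= 0))
})

test_that("reference simulation is seed-deterministic with Poisson class means", {
  a <- fast_aerosol(3.3e3)
  g <- coarse_grid()
  r1 <- simulate_reference(a, g, seed = 5)
  r2 <- simulate_reference(a, g, seed = 5)
  expect_identical(r1$counts, r2$counts)
  r3 <- simulate_reference(a, g, seed = 6)
  expect_false(identical(r1$counts, r3$counts))
  # zero aerosol gives zero counts
  a0 <- aerosol_params(number_conc_per_cm3 = 0)
  expect_true(all(simulate_reference(a0, g, seed = 1)$counts == 0))
  # closed-form class probabilities as oracle: equilibrium-minute class means
  # over 200 replicates within 3 Poisson standard errors
  lam <- expected_rates(a, g)
  set.seed(99)
  acc <- matrix(0, 200, g$n_classes)
  for (i in 1:200) acc[i, ] <- simulate_reference(a, g)$counts[5, ]
  se <- sqrt(lam / 200)
  keep <- lam > 5
  expect_true(all(abs(colMeans(acc)[keep] - lam[keep]) < 3.5 * se[keep]))
  # start-up ramp scales the first minute to half the equilibrium rate
  set.seed(99)
  first <- replicate(200, sum(simulate_reference(a, g)$counts[1, ]))
  expect_equal(mean(first), 0.5 * sum(lam), tolerance = 0.05)
})

test_that("mask simulation returns planted truth and honours degenerate models", {
  a <- fast_aerosol()
  g <- size_grid()
  rates <- expected_rates(a, g)
  # transparent mask: counts statistically identical to the reference rates
  tr <- simulate_mask_measurement(rates, flat_mask(1), g, seed = 2)
  expect_equal(tr$penetration, rep(1, g$n_classes))
  tot <- sum(tr$measurement$counts[3:5, ]) / 3
  expect_equal(tot, sum(rates), tolerance = 0.01)
  # perfect filter: zero counts everywhere
  pf <- simulate_mask_measurement(rates, flat_mask(0), g, seed = 2)
  expect_true(all(pf$measurement$counts == 0))
  expect_equal(pf$penetration, rep(0, g$n_classes))
})

test_that("flame photometer noise model reproduces its stated CV", {
  expect_equal(simulate_flame_reading(8, flame_model(0)), 8)
  expect_equal(simulate_flame_reading(0, flame_model(0.05), seed = 1), 0)
  set.seed(4)
  reps <- simulate_flame_reading(rep(10, 1e4), flame_model(0.01))
  cv <- sd(reps) / mean(reps)
  expect_gt(cv, 0.008); expect_lt(cv, 0.012)
  expect_true(all(reps >= 0))
})

test_that("batch simulation has campaign shape, determinism, and binomial defects", {
  g <- coarse_grid()
  a <- fast_aerosol(330)
  camp <- simulate_batch(5, a, mask_model(), g, seed = 10)
  expect_length(camp$measurements, 6)
  expect_identical(camp$measurements[[1]]$role, "reference")
  expect_equal(nrow(camp$truth), 5)
  expect_equal(sum(camp$flame$stream == "upstream"), 1)
  expect_equal(sum(camp$flame$stream == "downstream"), 5)

  dir <- withr::local_tempdir()
  p1 <- write_campaign(simulate_batch(4, a, mask_model(), g, seed = 42), dir, "a")
  p2 <- write_campaign(simulate_batch(4, a, mask_model(), g, seed = 42), dir, "b")
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))

  # binomial oracle on the defect mixture: 50 masks at defect_fraction 0.2
  mm <- mask_model(defect_fraction = 0.2, defect_p = 0.3)
  defects <- vapply(1:100, function(s)
    sum(simulate_batch(50, a, mm, g, seed = s)$truth$is_defect), numeric(1))
  se_batch <- sqrt(50 * 0.2 * 0.8)
  expect_lt(abs(mean(defects) - 10), 3 * se_batch / sqrt(100))
  expect_true(all(abs(defects - 10) <= 5 * se_batch))
})
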