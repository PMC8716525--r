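test_that("equilibrium window drops the start-up minutes and averages the rest", {
  g <- size_grid(100, 1000, 1)
  m <- measurement("w", "reference", matrix(c(10, 50, 100, 100, 100), 5, 1), g)
  expect_equal(as.numeric(select_equilibrium_window(m)), 100)
  expect_equal(attr(select_equilibrium_window(m), "window_minutes"), 3:5)
  m2 <- measurement("w2", "reference", matrix(c(90, 100, 110), 3, 1), g)
  expect_equal(as.numeric(select_equilibrium_window(m2, 0)), 100)
  short <- measurement("w3", "reference", matrix(5, 2, 1), g)
  expect_error(select_equilibrium_window(short, 2), "need more than")
})

test_that("count-to-mass conversion matches the hand-evaluated single-class case", {
  g <- size_grid(100, 1000, 10)
  n <- c(1000, rep(0, 9))
  ms <- class_mass(n, g, density_kg_m3 = 2165, sample_flow_lpm = 0.1, dilution = 1)
  # 1000/min * pi*(1e-7 m)^3/6 * 2165 kg/m3 / 1e-4 m3/min
  expect_equal(ms$m_kg_m3[1], 1000 * pi * (1e-7)^3 / 6 * 2165 / 1e-4,
               tolerance = 1e-12)
  expect_equal(ms$m_kg_m3[1], 1.1336e-11, tolerance = 1e-4)
  expect_true(all(ms$m_kg_m3[-1] == 0))
  # linearity in dilution and counts
  expect_equal(class_mass(n, g, 2165, 0.1, dilution = 2)$m_kg_m3,
               2 * ms$m_kg_m3, tolerance = 1e-12)
  expect_equal(class_mass(2 * n, g, 2165, 0.1)$m_kg_m3, 2 * ms$m_kg_m3,
               tolerance = 1e-12)
  expect_true(all(class_mass(rep(0, 10), g)$m_kg_m3 == 0))
  expect_error(class_mass(n, g, sample_flow_lpm = 0), "positive")
  expect_error(class_mass(n, g, density_kg_m3 = -1), "positive")
})

test_that("per-class passage flags zero-reference classes and is pure arithmetic", {
  g <- size_grid(100, 1000, 3)
  ref <- class_mass(c(100, 50, 0), g)
  fil <- class_mass(c(6, 0, 0), g)
  res <- class_passage(fil, ref)
  expect_equal(res$p_class[1], 0.06)
  expect_equal(res$p_class[2], 0)
  expect_true(is.na(res$p_class[3]))          # undefined, not forced to 0 or 1
  expect_identical(res$defined, c(TRUE, TRUE, FALSE))
  ident <- class_passage(ref, ref)
  expect_equal(ident$p_class[ident$defined], rep(1, 2))
  expect_equal(ident$p_total, 1)
  g2 <- size_grid(90, 900, 3)
  expect_error(class_passage(class_mass(c(1, 1, 1), g2), ref), "different size grids")
})

test_that("total passage is the ratio of mass sums and the weighted mean of P_i", {
  g <- size_grid(100, 1000, 2)
  # masses planted directly: m_f = [1, 2], m_r = [10, 40] -> 3/50
  mk <- function(m) structure(list(m_kg_m3 = m, grid = g), class = "mass_spectrum")
  expect_equal(total_passage(mk(c(1, 2)), mk(c(10, 40))), 0.06)
  expect_error(total_passage(mk(c(1, 2)), mk(c(0, 0))), "zero total mass")
  expect_warning(total_passage(mk(c(20, 40)), mk(c(10, 40))), "exceeds 1.05")

  # algebraic identity on random spectra: P_total == sum(w_i * P_i)
  set.seed(21)
  gg <- size_grid(90, 7500, 50)
  for (i in 1:20) {
    mr <- runif(50, 0, 1e-9); mf <- runif(50) * mr
    r <- class_passage(mk2 <- structure(list(m_kg_m3 = mf, grid = gg),
                                        class = "mass_spectrum"),
                       ref2 <- structure(list(m_kg_m3 = mr, grid = gg),
                                         class = "mass_spectrum"))
    w <- mr / sum(mr)
    expect_equal(r$p_total, sum(w * r$p_class), tolerance = 1e-12)
  }
})

test_that("passage is invariant to the assumed particle density", {
  g <- coarse_grid()
  camp <- simulate_batch(2, fast_aerosol(), mask_model(), g, seed = 8)
  ref <- camp$measurements[[1]]; msk <- camp$measurements[[2]]
  for (dens in c(1, 2165, 9999.5)) {
    r <- class_passage(measurement_mass(msk, density_kg_m3 = dens),
                       measurement_mass(ref, density_kg_m3 = dens))
    if (dens == 1) base <- r
    expect_equal(r$p_class, base$p_class, tolerance = 1e-12)
    expect_equal(r$p_total, base$p_total, tolerance = 1e-12)
  }
})

test_that("increasing any filter count weakly increases total passage", {
  g <- coarse_grid()
  set.seed(3)
  ref <- class_mass(runif(12, 10, 100), g)
  n <- runif(12, 0, 50)
  p0 <- total_passage(class_mass(n, g), ref)
  for (i in c(1, 6, 12)) {
    n2 <- n; n2[i] <- n2[i] + 10
    expect_gte(total_passage(class_mass(n2, g), ref), p0)
  }
})

test_that("a transparent mask's estimated total passage concentrates at 1", {
  g <- size_grid()
  a <- fast_aerosol()            # >= 1e5 expected counts per measurement
  rates <- expected_rates(a, g)
  ref_mass <- class_mass(rates, g)   # noise-free reference spectrum
  set.seed(17)
  p <- replicate(100, {
    sim <- simulate_mask_measurement(rates, flat_mask(1), g)
    class_passage(measurement_mass(sim$measurement), ref_mass)$p_total
  })
  expect_lt(abs(mean(p) - 1), 0.01)
})

test_that("planted flat penetration is recovered without bias", {
  g <- size_grid()
  a <- fast_aerosol()
  rates <- expected_rates(a, g)
  set.seed(31)
  for (q in c(0.01, 0.06, 0.5)) {
    est <- replicate(200, {
      ref <- simulate_reference(a, g)
      sim <- simulate_mask_measurement(rates, flat_mask(q), g, ramp = a$ramp)
      class_passage(measurement_mass(sim$measurement), measurement_mass(ref))$p_total
    })
    se <- sd(est) / sqrt(200)
    expect_lt(abs(mean(est) - q), 3 * se + 1e-6)
  }
})

test_that("campaign evaluation pairs each mask with the preceding reference", {
  g <- coarse_grid()
  a <- fast_aerosol()
  c1 <- simulate_batch(2, a, flat_mask(0.02), g, seed = 1, batch_id = "b1")
  c2 <- simulate_batch(2, a, flat_mask(0.10), g, seed = 2, batch_id = "b2")
  ps <- suppressMessages(evaluate_passage(merge_campaigns(list(c1, c2))))
  expect_equal(nrow(ps$table), 4)
  expect_equal(ps$table$reference_id, c("b1_ref", "b1_ref", "b2_ref", "b2_ref"))
  expect_equal(ps$table$p_total_pct, c(2, 2, 10, 10), tolerance = 0.15)
  # a sample before any reference is a pairing error
  expect_error(evaluate_passage(rev(c1$measurements)), "before any reference")
})
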