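fake_result <- function(p_class, grid) {
  structure(list(p_class = p_class, defined = !is.na(p_class),
                 p_total = NA_real_, grid = grid),
            class = "passage_result")
}

test_that("headline passage agrees across weightings for flat profiles", {
  g <- coarse_grid()
  r <- fake_result(rep(0.06, 12), g)
  r$p_total <- 0.06
  expect_equal(mask_headline_passage(r, "mass_weighted"), 6)
  expect_equal(mask_headline_passage(r, "unweighted"), 6)
  # size-dependent profile: unweighted mean over small classes exceeds the
  # mass-weighted total when small particles pass more readily
  r2 <- fake_result(seq(0.10, 0.01, length.out = 12), g)
  r2$p_total <- 0.02   # mass sits in the large classes
  expect_gt(mask_headline_passage(r2, "unweighted"),
            mask_headline_passage(r2, "mass_weighted"))
  r3 <- fake_result(rep(NA_real_, 12), g)
  expect_error(mask_headline_passage(r3, "unweighted"), "no defined")
})

test_that("batch summary reproduces quartiles, whiskers, KDE and compliance", {
  std <- standard_spec("FFP2")
  s <- batch_summary(c(1, 2, 3, 4, 5), std)
  expect_equal(s$median_pct, 3); expect_equal(s$q1_pct, 2); expect_equal(s$q3_pct, 4)
  expect_equal(s$whisker_low_pct, 1); expect_equal(s$whisker_high_pct, 5)
  expect_true(s$compliant)

  # 1.5*IQR rule by hand: q1 2, q3 4, upper fence 7 -> 100 excluded
  s2 <- batch_summary(c(1, 2, 3, 4, 100), std)
  expect_equal(s2$whisker_high_pct, 4)
  expect_false(s2$compliant)          # mean 22 > 6
  expect_equal(s2$frac_over_limit, 0.2)

  # ties at the limit count as compliant
  s3 <- batch_summary(rep(5, 4), std)
  expect_true(s3$compliant)
  expect_true(batch_summary(rep(6, 4), std)$compliant)
  expect_false(batch_summary(rep(6.01, 4), std)$compliant)

  # KDE integrates to 1 on its grid
  set.seed(2)
  s4 <- batch_summary(rnorm(40, 5, 1), std)
  area <- sum(diff(s4$kde$x) * (head(s4$kde$y, -1) + tail(s4$kde$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)

  expect_error(batch_summary(numeric(0), std), "non-empty")
})

test_that("whisker rule equals brute-force 1.5*IQR filtering on random data", {
  std <- standard_spec("N95")
  set.seed(6)
  for (i in 1:30) {
    v <- c(rlnorm(sample(5:40, 1), 1, 0.8), if (runif(1) < 0.5) 50)
    s <- batch_summary(v, std)
    q <- unname(quantile(v, c(0.25, 0.75), type = 7))
    keep <- v[v >= q[1] - 1.5 * (q[2] - q[1]) & v <= q[2] + 1.5 * (q[2] - q[1])]
    expect_equal(s$whisker_low_pct, min(keep))
    expect_equal(s$whisker_high_pct, max(keep))
    expect_lte(s$q1_pct, s$median_pct); expect_lte(s$median_pct, s$q3_pct)
  }
})

test_that("compliance is monotone in any mask's passage", {
  std <- standard_spec("FFP2")
  set.seed(8)
  for (i in 1:20) {
    v <- runif(10, 0, 12)
    if (!batch_summary(v, std)$compliant) {
      v2 <- v; v2[sample(10, 1)] <- v2[sample(10, 1)] + runif(1, 0, 5)
      expect_false(batch_summary(pmax(v, v2), std)$compliant)
    }
  }
})

test_that("size profile summarises the per-class means by hand arithmetic", {
  g <- size_grid(90, 360.33, 3)    # three classes with lower edges 90-227 nm
  rs <- list(fake_result(c(0.02, 0.04, 0.06), g))
  sp <- size_profile(rs, g, class_range_nm = c(90, 500))
  expect_equal(sp$median_over_classes_pct, 4)
  expect_equal(sp$max_class_passage_pct, 6)
  # population std / mean: sqrt(mean((x-mu)^2)) / mu
  expect_equal(sp$rel_std_over_classes, sqrt(2 / 3) * 0.02 / 0.04, tolerance = 1e-12)
  expect_equal(sp$rel_std_over_classes, 0.408, tolerance = 1e-3)
  # flat profile has zero relative spread
  spf <- size_profile(list(fake_result(rep(0.06, 3), g)), g)
  expect_equal(spf$rel_std_over_classes, 0)
  expect_equal(spf$median_over_classes_pct, 6)
  expect_error(size_profile(rs, g, class_range_nm = c(5000, 6000)),
               "fewer than 2")
})

test_that("the batch-mean MPPS is localized within one class at high counts", {
  g <- size_grid()
  a <- aerosol_params()          # full-rate aerosol: peak localization test
  mm <- mask_model(p_mpps = 0.06, d_mpps_nm = 200, curvature_k = 1,
                   mask_sigma = 0, defect_fraction = 0)
  camp <- simulate_batch(20, a, mm, g, seed = 23)
  ps <- suppressMessages(evaluate_passage(camp))
  sp <- size_profile(ps$results, g, batch_id = "mpps")
  # penetration is planted on class lower edges: truth is the nearest edge
  k_true <- which.min(abs(g$d_min_nm - 200))
  k_est <- which.min(abs(g$d_min_nm - sp$mpps_nm))
  expect_lte(abs(k_est - k_true), 1)
})

test_that("A/B/C categorization follows the median/max rule with compliant ties", {
  g <- coarse_grid()
  std <- standard_spec("FFP2")
  prof <- function(med, mx) {
    p <- structure(list(median_over_classes_pct = med, max_class_passage_pct = mx),
                   class = "size_profile")
    p
  }
  expect_equal(categorize(prof(3, 5), std), "A")
  expect_equal(categorize(prof(3, 9), std), "B")
  expect_equal(categorize(prof(8, 12), std), "C")
  # exhaustive, mutually exclusive, ties toward compliance over a grid sweep
  for (med in seq(0, 12, by = 0.75)) {
    for (mx in seq(med, 14, by = 0.75)) {
      cat_ <- categorize(prof(med, mx), std)
      expect_true(cat_ %in% c("A", "B", "C"))
      if (med > 6) expect_equal(cat_, "C")
      else if (mx > 6) expect_equal(cat_, "B")
      else expect_equal(cat_, "A")
    }
  }
  expect_equal(categorize(prof(6, 6), std), "A")   # both ties resolve compliant
})

test_that("planted batch categories are recovered from simulated campaigns", {
  g <- size_grid()
  a <- fast_aerosol()
  std <- standard_spec("FFP2")
  models <- list(
    A = mask_model(p_mpps = 0.03, curvature_k = 0, mask_sigma = 0, defect_fraction = 0),
    B = mask_model(p_mpps = 0.09, d_mpps_nm = 400, curvature_k = 2,
                   mask_sigma = 0, defect_fraction = 0),
    C = mask_model(p_mpps = 0.20, d_mpps_nm = 200, curvature_k = 0.5,
                   mask_sigma = 0, defect_fraction = 0)
  )
  rng <- g$d_min_nm >= 90 & g$d_min_nm <= 500
  for (planted in names(models)) {
    mm <- models[[planted]]
    # truth from the noise-free curve, through the same rule
    pen <- penetration_curve(g$d_min_nm[rng], mm)
    truth <- if (100 * median(pen) > 6) "C" else if (100 * max(pen) > 6) "B" else "A"
    expect_equal(truth, planted)
    hits <- vapply(1:100, function(s) {
      camp <- simulate_batch(20, a, mm, g, seed = s)
      ps <- suppressMessages(evaluate_passage(camp))
      sp <- size_profile(ps$results, g)
      categorize(sp, std) == planted
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("the campaign report carries planted categories and totals", {
  g <- size_grid()
  a <- fast_aerosol()
  camps <- list(
    simulate_batch(6, a, mask_model(p_mpps = 0.03, curvature_k = 0, mask_sigma = 0,
                                    defect_fraction = 0), g, seed = 1, batch_id = "bA"),
    simulate_batch(6, a, mask_model(p_mpps = 0.09, d_mpps_nm = 400, curvature_k = 2,
                                    mask_sigma = 0, defect_fraction = 0),
                   g, seed = 2, batch_id = "bB"),
    simulate_batch(6, a, mask_model(p_mpps = 0.20, d_mpps_nm = 200, curvature_k = 0.5,
                                    mask_sigma = 0, defect_fraction = 0),
                   g, seed = 3, batch_id = "bC")
  )
  ps <- suppressMessages(evaluate_passage(merge_campaigns(camps)))
  rep <- campaign_report(ps, qc_only = FALSE)
  expect_equal(attr(rep, "n_batches"), 3)
  expect_equal(rep$category[match(c("bA", "bB", "bC"), rep$batch_id)],
               c("A", "B", "C"))
  expect_equal(rep$compliant[match(c("bA", "bB", "bC"), rep$batch_id)],
               c(TRUE, TRUE, FALSE))
  expect_equal(attr(rep, "n_compliant"), 2)
  # single batch: totals equal that batch's values
  ps1 <- suppressMessages(evaluate_passage(camps[[1]]))
  rep1 <- campaign_report(ps1, qc_only = FALSE)
  expect_equal(attr(rep1, "n_batches"), 1)
  expect_equal(rep1$n_masks, 6)
})
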