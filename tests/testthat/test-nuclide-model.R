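test_that("deposition-ratio vector follows the fixed scaling scheme", {
  expect_equal(unname(deposition_ratios(9.2, 1)),
               c(1, 0.7, 9.2, 8.3, 8.3, 1, 1))
  expect_equal(unname(deposition_ratios(0, 0)),
               c(0, 0, 0, 0, 0, 1, 1))
  expect_equal(unname(deposition_ratios(5.6, 1.1)),
               c(1.1, 0.77, 5.6, 9.13, 9.13, 1, 1))
  expect_error(deposition_ratios(-1, 0), "non-negative")
  expect_error(deposition_ratios(1, -0.1), "non-negative")
})

test_that("equilibrium daughters decay with their parents' half-lives", {
  T_eff <- effective_half_life(default_nuclides())
  expect_equal(T_eff[["Te-129"]], 33.6 * 24)
  expect_equal(T_eff[["I-132"]], 3.204 * 24)
  expect_equal(T_eff[["I-131"]], 8.021 * 24)
})

test_that("dose rate at t = 0 is the ratio-weighted coefficient sum and halves per half-life", {
  ns <- handset_nuclides()
  f <- deposition_ratios(9.2, 1)
  expect_equal(dose_rate(ns, 9.2, 1, 0), sum(f * ns$d0))
  # single-nuclide set: only I-131 active
  only_i <- handset_nuclides(c("Te-129m" = 0, "Te-129" = 0, "I-131" = 1,
                               "Te-132" = 0, "I-132" = 0, "Cs-134" = 0,
                               "Cs-137" = 0))
  # f for I-131 is r_i; use r_i = 1; caesium terms have zero d0
  expect_equal(dose_rate(only_i, 1, 0, 8.021 * 24), 0.5)
  expect_error(dose_rate(ns, 1, 1, -5), "non-negative")
})

test_that("dose rate is non-increasing in time", {
  m <- beta_dose_model()
  tgrid <- seq(0, hours_per_year(), length.out = 300)
  for (rt in c(0.1, 1, 50)) {
    rates <- dose_rate(m$nuclides, 9.2, rt, tgrid)
    expect_true(all(diff(rates) <= 0))
  }
})

test_that("the dose rate is the derivative of the cumulative dose", {
  m <- beta_dose_model()
  # central difference of the integral at t0 = 1 h (mSv -> uSv via 1000)
  t0 <- 1; h <- 0.01
  deriv <- (cumulative_dose(m$nuclides, 9.2, 1, t0 + h) -
              cumulative_dose(m$nuclides, 9.2, 1, t0 - h)) / (2 * h) * 1000
  expect_equal(deriv, dose_rate(m$nuclides, 9.2, 1, t0), tolerance = 1e-8)
})

test_that("closed-form cumulative dose matches adaptive quadrature and the direct-sum oracle", {
  ns <- handset_nuclides()
  for (r in list(c(0, 0), c(9.2, 1), c(200, 50), c(1.3, 0.2))) {
    cf <- cumulative_dose(ns, r[1], r[2])
    expect_equal(cf, oracle_cumulative(ns, r[1], r[2]), tolerance = 1e-12)
    q <- stats::integrate(function(t) dose_rate(ns, r[1], r[2], t),
                          0, hours_per_year(), rel.tol = 1e-12,
                          subdivisions = 2000L)$value / 1000
    expect_equal(cf, q, tolerance = 1e-10)
  }
  expect_error(cumulative_dose(ns, 1, 1, horizon_hours = 0), "positive")
})

test_that("cumulative dose vanishes as the horizon shrinks and grows with its arguments", {
  ns <- handset_nuclides()
  expect_lt(cumulative_dose(ns, 0, 0, horizon_hours = 1e-9), 1e-10)
  base <- cumulative_dose(ns, 5, 1)
  expect_gt(cumulative_dose(ns, 6, 1), base)
  expect_gt(cumulative_dose(ns, 5, 2), base)
  expect_gt(cumulative_dose(ns, 5, 1, horizon_hours = 2 * hours_per_year()),
            base)
})

test_that("the forward model is exactly linear in both ratio parameters", {
  set.seed(11)
  for (i in 1:25) {
    ns <- handset_nuclides(stats::setNames(runif(7, 0, 10),
                                           c("Te-129m", "Te-129", "I-131",
                                             "Te-132", "I-132", "Cs-134",
                                             "Cs-137")))
    c0 <- cumulative_dose(ns, 0, 0)
    c1 <- cumulative_dose(ns, 1, 0) - c0
    c2 <- cumulative_dose(ns, 0, 1) - c0
    ri <- runif(4, 0, 300); rt <- runif(4, 0, 60)
    for (k in 1:4) {
      d <- cumulative_dose(ns, ri[k], rt[k])
      expect_equal(d, c0 + c1 * ri[k] + c2 * rt[k],
                   tolerance = 1e-12)
    }
  }
})

test_that("an iodine-only dose saturates within the first year", {
  only_i <- handset_nuclides(c("Te-129m" = 0, "Te-129" = 0, "I-131" = 1,
                               "Te-132" = 0, "I-132" = 0, "Cs-134" = 0,
                               "Cs-137" = 0))
  d1 <- cumulative_dose(only_i, 9.2, 0)
  d10 <- cumulative_dose(only_i, 9.2, 0,
                         horizon_hours = 10 * hours_per_year())
  expect_equal(d1, d10, tolerance = 1e-9)
})

test_that("decay correction restores deposition-date ratios", {
  ns <- default_nuclides()
  d0 <- as.Date("2011-03-15")
  # zero interval: identity
  expect_equal(decay_correct_ratio(3, 7, "I-131", "Cs-137", d0, d0), 3 / 7)
  # one numerator half-life against an effectively stable denominator
  slow <- nuclide_set(c("Te-129m" = 10, "Te-129" = 1, "I-131" = 8.021,
                        "Te-132" = 3.204, "I-132" = 1, "Cs-134" = 1e12,
                        "Cs-137" = 1e12))
  expect_equal(decay_correct_ratio(1, 1, "Te-129m", "Cs-137",
                                   d0 + 10, d0, nuclides = slow),
               2, tolerance = 1e-9)
  # the published example: raw 17/7900 measured 91 d later -> ~5.6
  expect_equal(decay_correct_ratio(17, 7900, "I-131", "Cs-137",
                                   as.Date("2011-06-14"), d0,
                                   nuclides = ns),
               5.6, tolerance = 0.01)
  expect_error(decay_correct_ratio(1, 0, "I-131", "Cs-137", d0, d0),
               "positive")
  expect_error(decay_correct_ratio(1, 1, "I-131", "Cs-137", d0 - 1, d0),
               "precedes")
})

test_that("calibration inverts the linear surface and round-trips", {
  m <- beta_dose_model(paper_param())
  # d0 of I-131 from the r_i slope and the analytic one-year decay integral
  T_i <- 8.021 * 24
  I_i <- T_i / log(2) * (1 - 2^(-8766 / T_i))
  expect_equal(m$nuclides$d0[m$nuclides$name == "I-131"],
               1000 * 1.1165 / I_i, tolerance = 1e-12)
  expect_equal(1000 * 1.1165 / I_i, 4.02, tolerance = 1e-3)
  # all-zero targets
  z <- calibrate_coefficients(c(0, 0, 1e-12))
  expect_true(all(z$d0 <= 1e-12))
  # round trip on a 20 x 20 grid for assorted splits
  for (splits in list(c(0.5, 0.5), c(0, 1), c(1, 0), c(0.3, 0.8))) {
    cal <- calibrate_coefficients(paper_param(), te_split = splits[1],
                                  cs_split = splits[2])
    ri <- seq(0, 200, length.out = 20)
    rt <- seq(0, 50, length.out = 20)
    for (i in seq(1, 20, by = 4)) {
      for (j in seq(1, 20, by = 4)) {
        d_fwd <- cumulative_dose(cal, ri[i], rt[j])
        d_lin <- evaluate_dose(paper_param(), ri[i], rt[j])
        expect_equal(d_fwd, d_lin, tolerance = 1e-9)
      }
    }
  }
  expect_error(calibrate_coefficients(paper_param(), te_split = 1.2),
               "0, 1")
})

test_that("caesium-only limit of the calibrated model is the intercept", {
  m <- beta_dose_model(paper_param())
  expect_equal(cumulative_dose(m$nuclides, 0, 0), 50.009,
               tolerance = 1e-9)
})

test_that("nuclide-set construction validates its inputs", {
  expect_error(nuclide_set(c("I-131" = 8)), "seven")
  hl <- c("Te-129m" = 33.6, "Te-129" = 0.05, "I-131" = 8.021,
          "Te-132" = 3.204, "I-132" = 0.1, "Cs-134" = 754.3,
          "Cs-137" = 10983)
  bad <- hl; bad["I-131"] <- -1
  expect_error(nuclide_set(bad), "positive")
  expect_error(nuclide_set(hl, decay_parent = c("Te-129" = "Xx-1")),
               "unknown")
})
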