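test_that("the five strategies have the stated structure and doses", {
  ss <- dosing_strategies()
  expect_named(ss, c("a", "b", "c", "d", "e"))
  # (a), (c) and (d) all deliver 7.2 g over the 24-h day
  expect_equal(total_dose(ss$a$regimen), 7200)
  expect_equal(total_dose(ss$c$regimen), 7200)
  expect_equal(total_dose(ss$d$regimen), 7200)
  expect_equal(total_dose(ss$b$regimen), 14400)
  expect_equal(total_dose(ss$e$regimen), 7200)
  expect_true(all(ss$e$regimen$events$duration == 2))
  expect_equal(ss$c$window, c(0, 24))
  expect_equal(ss$a$window, c(20, 24))
})

test_that("a typical subject on continuous infusion stays above the breakpoint", {
  # free steady-state concentration 0.4 * 300 / 23.1 = 5.19 mg/L > 2
  m0 <- pop_model(theta = c(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8),
                  omega2 = c(), sigma2 = c(prop = 0.021, add = 0.006),
                  covariates = list())
  res <- simulate_pta(m0, "d", n = 1, mic = 2, seed = 1)
  expect_gt(res$ft[1, 1], 95)
  st <- dosing_strategy("d")
  p <- individual_params(m0)
  expect_equal(0.4 * conc_profile(st$regimen, p, 24), 5.19,
               tolerance = 0.01)
  # and the late window is entirely above the threshold
  expect_equal(fraction_time_above(st$regimen, p, 2, 0.4, c(12, 24)), 100)
})

test_that("an MIC below every free concentration gives universal attainment", {
  res <- simulate_pta(bpen_final_model(), "a", n = 500, mic = 1e-4,
                      seed = 2)
  expect_true(all(res$ft == 100))
  expect_equal(attainment_fraction(res, 1e-4, 100, "achieve"), 1)
  expect_equal(attainment_fraction(res, 1e-4, 0, "achieve"), 1)
})

test_that("attainment fractions complement and refuse off-grid MICs", {
  res <- simulate_pta(bpen_final_model(), "b", n = 2000, mic = c(1, 2),
                      seed = 3)
  for (thr in c(0, 40, 50, 98, 100)) {
    a <- attainment_fraction(res, 2, thr, "achieve")
    f <- attainment_fraction(res, 2, thr, "fail")
    expect_equal(a + f, 1)
  }
  expect_error(attainment_fraction(res, 1.5, 50), "interpolation")
})

test_that("doubling a bolus dose never lowers any subject's %fT>MIC", {
  m <- bpen_final_model()
  ra <- simulate_pta(m, "a", n = 2000, mic = c(0.5, 2), seed = 11)
  rb <- simulate_pta(m, "b", n = 2000, mic = c(0.5, 2), seed = 11)
  expect_true(all(rb$ft - ra$ft >= -1e-9))
})

test_that("PTA percentiles are monotone in MIC and runs are seed-reproducible", {
  m <- bpen_final_model()
  r1 <- simulate_pta(m, "e", n = 1500, seed = 21)
  r2 <- simulate_pta(m, "e", n = 1500, seed = 21)
  expect_identical(r1$ft, r2$ft)
  expect_true(all(diff(r1$percentiles["p50", ]) <= 1e-9))
  expect_true(all(diff(r1$percentiles["p2.5", ]) <= 1e-9))
  # attainment is monotone in MIC and in the threshold
  af <- vapply(r1$mic, function(m2)
    attainment_fraction(r1, m2, 50, "achieve"), 0)
  expect_true(all(diff(af) <= 1e-9))
  at <- vapply(c(0, 25, 50, 75, 100), function(thr)
    attainment_fraction(r1, 2, thr, "achieve"), 0)
  expect_true(all(diff(at) <= 1e-9))
})

test_that("the resampled-covariate policy widens the simulated spread", {
  m <- bpen_final_model()
  rt <- simulate_pta(m, "a", n = 3000, mic = 2, policy = "typical",
                     seed = 31)
  rr <- simulate_pta(m, "a", n = 3000, mic = 2, policy = "resample",
                     seed = 31)
  expect_gt(diff(range(rr$ft)), diff(range(rt$ft)) * 0.9)
  expect_gt(sd(rr$ft), sd(rt$ft))
})

test_that("the %fT matrix matches the scalar computation subject by subject", {
  m <- bpen_final_model()
  res <- simulate_pta(m, "e", n = 25, mic = c(0.5, 2), seed = 41)
  etas <- sample_etas(m, 25, seed = 41)
  st <- dosing_strategy("e")
  for (i in c(1, 7, 25)) {
    par <- individual_params(m, eta = etas[i, ], weight = 70,
                             creatinine = 70)
    expect_equal(unname(res$ft[i, 2]),
                 fraction_time_above(st$regimen, par, 2, 0.4, st$window),
                 tolerance = 1e-9)
  }
})
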