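test_that("derived rate constants and terminal half-life match the quadratic roots", {
  p <- pk_params(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8)
  expect_equal(p$k10, 23.1 / 15.1)
  expect_equal(p$k12, 11.1 / 15.1)
  expect_equal(p$k21, 11.1 / 9.8)
  # quadratic-root oracle
  roots <- sort(Re(polyroot(c(p$k10 * p$k21, -(p$k10 + p$k12 + p$k21), 1))))
  expect_equal(p$beta, roots[1], tolerance = 1e-12)
  expect_equal(p$alpha, roots[2], tolerance = 1e-12)
  expect_equal(p$beta, 0.625, tolerance = 1e-3)
  expect_equal(p$t_half_beta, 1.11, tolerance = 1e-3)
  expect_equal(p$alpha * p$beta, p$k10 * p$k21)
  expect_equal(p$alpha + p$beta, p$k10 + p$k12 + p$k21)
})

test_that("one-compartment collapse gives the mono-exponential identity", {
  p <- pk_params(CL = log(2), V1 = 1, Q = 0, V2 = 0)
  expect_equal(p$beta, log(2))
  expect_equal(p$t_half_beta, 1)
  expect_equal(p$k12, 0)
  expect_equal(p$k21, 0)
})

test_that("invalid disposition parameters are rejected", {
  expect_error(pk_params(0, 15), "invalid parameter")
  expect_error(pk_params(23, -1), "invalid parameter")
  expect_error(pk_params(23, 15, Q = 5, V2 = 0), "invalid parameter")
})

test_that("terminal half-life equals the slow eigenvalue of the rate matrix", {
  set.seed(41)
  for (i in 1:10) {
    p <- random_params()
    K <- matrix(c(-(p$k10 + p$k12), p$k21, p$k12, -p$k21), 2, 2,
                byrow = TRUE)
    lam <- sort(abs(eigen(K)$values))
    expect_equal(p$t_half_beta, log(2) / lam[1], tolerance = 1e-10)
  }
})

test_that("bolus and constant-infusion profiles match closed-form anchors", {
  p <- pk_params(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8)
  reg <- regimen(0, 1200, horizon = 12)
  expect_equal(conc_profile(reg, p, 0), 1200 / 15.1, tolerance = 1e-12)
  # steady state of a constant infusion is rate / CL
  ci <- regimen(0, 300 * 500, 500, horizon = 500)
  expect_equal(conc_profile(ci, p, 500), 300 / 23.1, tolerance = 1e-6)
})

test_that("superposition: two boluses equal the sum of shifted single-bolus profiles", {
  p <- pk_params(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8)
  tt <- seq(0, 10, by = 0.25)
  both <- conc_profile(regimen(c(0, 4), 1200, horizon = 12), p, tt)
  one <- conc_profile(regimen(0, 1200, horizon = 12), p, tt)
  shifted <- c(rep(0, 16), one[seq_len(length(tt) - 16)])
  expect_equal(both, one + shifted, tolerance = 1e-12)
})

test_that("analytic profiles agree with a stiff ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (i in 1:8) {
    p <- random_params()
    reg <- random_regimen()
    tt <- sort(runif(15, 0, 24))
    a <- conc_profile(reg, p, tt)
    b <- ode_conc(reg, p, tt)
    expect_lt(max(abs(a - b)) / max(b), 1e-6)
  }
})

test_that("mass balance holds analytically", {
  set.seed(43)
  for (i in 1:8) {
    p <- random_params()
    reg <- random_regimen()
    st <- pk_state(reg, p, sort(runif(10, 0, 24)))
    gap <- abs(st$administered - (st$central + st$peripheral +
                                    st$eliminated))
    expect_lt(max(gap) / max(st$administered), 1e-8)
  }
})

test_that("profiles converge to the one-compartment limit as Q -> 0", {
  tt <- seq(0.01, 12, by = 0.25)
  mono <- 1200 / 15 * exp(-(24 / 15) * tt)
  for (Q in c(1e-4, 1e-6)) {
    p <- pk_params(CL = 24, V1 = 15, Q = Q, V2 = 10)
    prof <- conc_profile(regimen(0, 1200, horizon = 12), p, tt)
    expect_equal(prof, mono, tolerance = Q)
  }
})

test_that("times outside the horizon raise a range error", {
  p <- pk_params(23.1, 15.1, 11.1, 9.8)
  reg <- regimen(0, 1200, horizon = 12)
  expect_error(conc_profile(reg, p, 13), "within")
  expect_error(fraction_time_above(reg, p, 1, window = c(0, 13)), "horizon")
})

test_that("fraction of time above MIC matches analytic crossings", {
  # constant free concentration above the threshold
  p <- pk_params(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8)
  ci <- regimen(0, 300 * 60, 60, horizon = 60)
  expect_equal(fraction_time_above(ci, p, mic = 1, unbound_fraction = 0.4,
                                   window = c(40, 60)), 100)
  # profile entirely below the threshold
  expect_equal(fraction_time_above(regimen(0, 1, horizon = 10), p, mic = 5,
                                   window = c(0, 10)), 0)
  # mono-exponential 8 exp(-log(2) t): crossing of 1 at t = 3 over [0, 4]
  pm <- pk_params(CL = log(2), V1 = 1, Q = 0, V2 = 0)
  expect_equal(fraction_time_above(regimen(0, 8, horizon = 4), pm, mic = 1,
                                   unbound_fraction = 1), 75,
               tolerance = 1e-7)
})

test_that("fraction above is grid-free: agrees with dense numerical measure", {
  set.seed(44)
  for (i in 1:5) {
    p <- random_params()
    reg <- random_regimen()
    ft <- fraction_time_above(reg, p, mic = 2, unbound_fraction = 0.4,
                              window = c(0, 24))
    tt <- seq(0, 24, length.out = 200001)
    num <- 100 * mean(0.4 * conc_profile(reg, p, tt) > 2)
    expect_equal(ft, num, tolerance = 0.05)
  }
})

test_that("fraction above is monotone in MIC and in unbound fraction", {
  set.seed(45)
  p <- random_params()
  reg <- random_regimen()
  mics <- c(0.125, 0.5, 1, 2, 4, 8)
  ft <- vapply(mics, function(m)
    fraction_time_above(reg, p, m, 0.4, c(0, 24)), 0)
  expect_true(all(diff(ft) <= 1e-9))
  fus <- c(0.1, 0.3, 0.5, 0.8, 1)
  ft2 <- vapply(fus, function(fu)
    fraction_time_above(reg, p, 2, fu, c(0, 24)), 0)
  expect_true(all(diff(ft2) >= -1e-9))
})

test_that("invalid threshold arguments are rejected", {
  p <- pk_params(23.1, 15.1, 11.1, 9.8)
  reg <- regimen(0, 1200, horizon = 12)
  expect_error(fraction_time_above(reg, p, mic = -1), "invalid parameter")
  expect_error(fraction_time_above(reg, p, 1, unbound_fraction = 0),
               "invalid parameter")
})

test_that("regimens validate and round-trip through YAML", {
  expect_error(regimen(numeric(0), numeric(0)), "at least one")
  expect_error(regimen(-1, 100), ">= 0")
  expect_error(regimen(0, 0), "> 0")
  expect_error(regimen(c(0, 10), 100, c(0, 3), horizon = 12), "horizon")
  r <- regimen(c(0, 4, 8), c(1200, 600, 2400), c(0, 2, 0), horizon = 24)
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_regimen(r, f)
  r2 <- read_regimen(f)
  expect_equal(r2$events, r$events)
  expect_equal(r2$horizon, r$horizon)
  expect_equal(total_dose(r), 4200)
})

test_that("repeated-eigenvalue disposition is handled by the limiting form", {
  # k10 = k21 = 1 with k12 -> 0 makes the discriminant vanish; the limiting
  # t exp(-t) branch must then reduce to the mono-exponential solution
  V1 <- 10
  k12 <- 1e-13
  p <- pk_params(CL = V1, V1 = V1, Q = k12 * V1, V2 = k12 * V1)
  expect_equal(p$alpha, p$beta, tolerance = 1e-6)
  reg <- regimen(c(0, 2), c(500, 800), c(0, 1), horizon = 10)
  tt <- seq(0.25, 9.75, by = 0.25)
  ref <- conc_profile(reg, pk_params(CL = V1, V1 = V1), tt)
  expect_equal(conc_profile(reg, p, tt), ref, tolerance = 1e-6)
  # the grid-free time-above computation falls back gracefully as well
  expect_equal(
    fraction_time_above(reg, p, mic = 2, unbound_fraction = 1,
                        window = c(0, 10)),
    fraction_time_above(reg, pk_params(CL = V1, V1 = V1), 2, 1, c(0, 10)),
    tolerance = 1e-5)
})
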