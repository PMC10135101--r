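test_that("the objective reduces to the closed-form normal likelihood", {
  # one observation equal to its prediction, additive variance 1, no
  # random effects: -2 log L = log(2 pi)
  m <- pop_model(theta = c(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8),
                 omega2 = c(), sigma2 = c(add = 1), covariates = list())
  reg <- regimen(0, 1200, horizon = 6)
  f1 <- conc_profile(reg, individual_params(m, weight = 70), 1,
                     pre_dose = TRUE)
  st <- pk_study(list(list(id = 1, covariates = list(weight = 70),
                           regimen = reg,
                           obs = data.frame(time = 1, dv = f1))))
  expect_equal(foce_objective(m, st), log(2 * pi), tolerance = 1e-10)
  # residual 2 with variance 4 adds log(4) + 1
  st2 <- pk_study(list(list(id = 1, covariates = list(weight = 70),
                            regimen = reg,
                            obs = data.frame(time = 1, dv = f1 + 2))))
  m2 <- pop_model(theta = m$theta, omega2 = c(), sigma2 = c(add = 4))
  expect_equal(foce_objective(m2, st2), log(2 * pi * 4) + 1,
               tolerance = 1e-10)
})

test_that("the conditional approximation agrees with quadrature on toys", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (k in 1:4) {
    toy <- make_oracle_toy(k)
    expect_lt(abs(foce_objective(toy$model, toy$study,
                                 method = "laplace") -
                    agq_ofv(toy$model, toy$study[[1]])), 0.01)
  }
})

test_that("the objective is invariant to subject order and post-horizon doses", {
  st <- generate_study(study_design(), seed = 13)
  m <- bpen_final_model()
  o1 <- foce_objective(m, st)
  o2 <- foce_objective(m, pk_study(rev(unclass(st))))
  # equality up to summation order of the per-subject contributions
  expect_equal(o1, o2, tolerance = 1e-12)
  # an extra dose after the last observation cannot change the likelihood
  aug <- lapply(unclass(st), function(s) {
    ev <- s$regimen$events
    last_obs <- max(s$obs$time)
    s$regimen <- regimen(c(ev$time, last_obs + 0.5),
                         c(ev$amount, 1200), c(ev$duration, 0),
                         horizon = last_obs + 4)
    s
  })
  expect_equal(foce_objective(m, pk_study(aug)), o1, tolerance = 1e-12)
})

test_that("noiseless data identify the fixed effects to 0.1%", {
  truth <- pop_model(theta = c(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8),
                     omega2 = c(), sigma2 = c(add = 0), covariates = list())
  st <- generate_study(study_design(truth = truth), seed = 3)
  start <- pop_model(theta = c(CL = 15, V1 = 20, Q = 8, V2 = 12),
                     omega2 = c(), sigma2 = c(add = 1e-4))
  fit <- foce_fit(start, st, fix = "sigma2.add", se = FALSE)
  expect_equal(fit$convergence, 0L)
  expect_lt(max(abs(coef(fit)[1:4] / c(23.1, 15.1, 11.1, 9.8) - 1)),
            1e-3)
})

test_that("a refit from the solution is stationary", {
  st <- generate_study(study_design(), seed = 17)
  start <- initial_estimates(st)
  fit <- foce_fit(start, st, se = FALSE, control = list(rel.tol = 1e-9))
  expect_lte(fit$ofv, fit$start_ofv)
  refit <- foce_fit(fit$model, st, se = FALSE,
                    control = list(rel.tol = 1e-9))
  expect_lt(abs(refit$ofv - fit$ofv), 0.01)
})

test_that("standard errors carry finite RSEs on a well-posed fit", {
  st <- generate_study(study_design(), seed = 11)
  start <- initial_estimates(
    st, covariates = list(cov_term("CL", "creatinine", 70, 0)))
  fit <- foce_fit(start, st, control = list(rel.tol = 1e-6))
  expect_s3_class(fit, "pkfit")
  expect_true(all(is.finite(fit$se$se)))
  expect_true(all(fit$se$rse_pct > 0))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$ofv / 2)
  expect_equal(attr(ll, "df"), 10L)
})

test_that("likelihood-ratio decisions follow the chi-square threshold", {
  # covariate step: a drop of 19.1 on 1 df is accepted
  expect_true(lrt_step(119.1, 100, 1)$accept)
  expect_equal(lrt_step(119.1, 100, 1)$delta_ofv, 19.1)
  # boundary case just below 3.84 is rejected
  expect_false(lrt_step(103.83, 100, 1)$accept)
  expect_equal(lrt_step(103.84, 100, 1)$threshold,
               qchisq(0.95, 1), tolerance = 1e-3)
  # structural 1 -> 2 compartment comparison: 104.4 on 3 df is accepted
  expect_true(lrt_step(204.4, 100, 3)$accept)
  expect_error(lrt_step(10, 5, 0), "added_params")
})

test_that("stepwise selection recovers a strong simulated creatinine effect", {
  truth <- bpen_final_model()
  truth$covariates[[1]]$value <- -0.9
  des <- study_design(truth = truth)
  st <- generate_study(des, seed = 29)
  base <- pop_model(theta = truth$theta, omega2 = truth$omega2,
                    sigma2 = truth$sigma2, covariates = list())
  sw <- stepwise_covariates(
    base, st,
    candidates = list(cov_term("CL", "creatinine", 70, 0),
                      cov_term("V1", "sex", 0, 0, type = "shift")),
    control = list(rel.tol = 1e-6))
  acc <- sw$ledger[sw$ledger$accepted, ]
  expect_true(nrow(acc) >= 1L)
  expect_equal(acc$covariate[1], "creatinine")
  expect_lt(sw$model$covariates[[1]]$value, -0.4)
  # a constant covariate carries no information and is never selected
  st2 <- pk_study(lapply(unclass(st), function(s) {
    s$covariates$albumin <- 30
    s
  }))
  sw2 <- stepwise_covariates(
    sw$model, st2, candidates = list(cov_term("CL", "albumin", 30, 0)),
    control = list(rel.tol = 1e-6))
  expect_false(any(sw2$ledger$accepted))
})

test_that("stepwise refuses silently missing covariates", {
  st <- generate_study(study_design(), seed = 31)
  st <- pk_study(lapply(unclass(st), function(s) {
    if (s$id == 3) s$covariates$albumin <- NULL
    s
  }))
  expect_error(
    stepwise_covariates(bpen_final_model(), st,
                        list(cov_term("CL", "albumin", 28, 0))),
    "missing for subject")
})

test_that("bootstrap of a degenerate resampling plan collapses to width zero", {
  truth <- pop_model(theta = c(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8),
                     omega2 = c(), sigma2 = c(add = 1e-6),
                     covariates = list())
  base <- generate_study(study_design(truth = truth), seed = 5)[[1]]
  subjects <- lapply(1:12, function(i) {
    s <- base
    s$id <- i
    s
  })
  st <- pk_study(subjects)
  start <- pop_model(theta = c(CL = 20, V1 = 12, Q = 9, V2 = 12),
                     omega2 = c(), sigma2 = c(add = 1e-4))
  fit <- foce_fit(start, st, fix = "sigma2.add", se = FALSE)
  b <- pk_bootstrap(fit, n_replicates = 5, seed = 1)
  expect_equal(b$n_failed, 0L)
  expect_equal(b$summary$lower95, b$summary$upper95, tolerance = 1e-6)
  expect_true(all(b$summary$lower95 <= b$summary$median + 1e-12 &
                    b$summary$median <= b$summary$upper95 + 1e-12))
})

test_that("bootstrap percentiles are ordered and seeded", {
  st <- generate_study(study_design(), seed = 19)
  start <- initial_estimates(st)
  fit <- foce_fit(start, st, se = FALSE, control = list(rel.tol = 1e-5))
  b1 <- pk_bootstrap(fit, n_replicates = 8, seed = 4,
                     control = list(rel.tol = 1e-5))
  b2 <- pk_bootstrap(fit, n_replicates = 8, seed = 4,
                     control = list(rel.tol = 1e-5))
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(b1$summary$lower95 <= b1$summary$median + 1e-12))
  expect_true(all(b1$summary$median <= b1$summary$upper95 + 1e-12))
})
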