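# a light fixture: data generated from the final published model and
# refitted cheaply so diagnostics have an honest pkfit to work from
fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- generate_study(study_design(), seed = 23)
      start <- initial_estimates(
        st, covariates = list(cov_term("CL", "creatinine", 70, 0)))
      cache <<- foce_fit(start, st, se = FALSE,
                         control = list(rel.tol = 1e-6))
    }
    cache
  }
})

test_that("goodness-of-fit records define residuals as stated", {
  fit <- fit_fixture()
  g <- gof_table(fit)
  expect_equal(nrow(g), 96L)
  expect_true(all(is.finite(g$iwres)))
  expect_equal(g$iwres,
               (g$dv - g$ipred) /
                 sqrt(residual_variance(g$ipred, fit$model)))
  # observation equal to its individual prediction has residual zero
  g2 <- g
  i <- 5L
  expect_equal((g2$ipred[i] - g2$ipred[i]) /
                 sqrt(residual_variance(g2$ipred[i], fit$model)), 0)
})

test_that("a subject with zero conditional modes has ipred equal to pred", {
  fit <- fit_fixture()
  fit0 <- fit
  fit0$etas[] <- 0
  p1 <- predict(fit0, type = "population")
  p2 <- predict(fit0, type = "individual")
  expect_equal(p1$pred, p2$ipred, tolerance = 1e-12)
})

test_that("an additive-only error model scales residuals by sigma", {
  # additive variance 4 and a residual of 4 give a weighted residual of 2
  truth <- pop_model(theta = c(CL = 23.1, V1 = 15.1, Q = 11.1, V2 = 9.8),
                     omega2 = c(), sigma2 = c(add = 4),
                     covariates = list())
  st <- generate_study(study_design(truth = truth), seed = 3)
  st <- pk_study(lapply(unclass(st), function(s) {
    par <- individual_params(truth, weight = s$covariates$weight)
    s$obs$dv <- conc_profile(s$regimen, par, s$obs$time, pre_dose = TRUE) + 4
    s
  }))
  fit <- foce_fit(truth, st, fix = c("theta.V1", "theta.Q", "theta.V2",
                                     "sigma2.add"),
                  se = FALSE, control = list(eval.max = 1, iter.max = 1))
  fit$model <- truth # diagnostics at the stated parameters
  g <- gof_table(fit)
  expect_equal(g$iwres, rep(2, nrow(g)), tolerance = 1e-9)
})

test_that("prediction correction is the identity within homogeneous bins", {
  fit <- fit_fixture()
  v <- pc_vpc(fit, n_sim = 120, bins = 1, max_tad = 0.3, seed = 1)
  # a single early bin: every record is corrected toward the bin median,
  # and with one bin the observed median equals the corrected median
  expect_equal(v$bins, 1L)
  expect_equal(unname(v$table$obs_p50),
               unname(median(v$pc_obs$pc_obs)))
  # corrected values are positive wherever raw values are
  raw <- predict(fit, type = "population")$dv
  tad <- unlist(lapply(seq_along(fit$data), function(i)
    penpk:::.time_after_dose(fit$data[[i]]$regimen,
                             fit$data[[i]]$obs$time)))
  expect_true(all(v$pc_obs$pc_obs[raw[tad <= 0.3] > 0] > 0))
})

test_that("the VPC is reproducible bit for bit under a fixed seed", {
  fit <- fit_fixture()
  v1 <- pc_vpc(fit, n_sim = 150, bins = 4, seed = 9)
  v2 <- pc_vpc(fit, n_sim = 150, bins = 4, seed = 9)
  expect_identical(v1$table, v2$table)
  expect_equal(sum(v1$table$n), sum(v1$pc_obs$bin == v1$pc_obs$bin))
  # bands are ordered
  expect_true(all(v1$table$sim_p50_lo <= v1$table$sim_p50_hi))
  expect_true(all(v1$table$sim_p2.5_lo <= v1$table$sim_p2.5_hi))
})

test_that("data simulated from the fitted model sit inside their own bands", {
  fit <- fit_fixture()
  v <- pc_vpc(fit, n_sim = 300, bins = 4, seed = 17)
  inside <- v$table$obs_p50 >= v$table$sim_p50_lo &
    v$table$obs_p50 <= v$table$sim_p50_hi
  expect_gte(mean(inside), 0.75)
})

test_that("folding caps the VPC domain at the requested time after dose", {
  fit <- fit_fixture()
  v <- pc_vpc(fit, n_sim = 120, bins = 4, max_tad = 4, seed = 2)
  expect_lte(max(v$pc_obs$tad), 4)
  # 6-hourly subjects contribute only their early samples
  expect_lt(sum(v$table$n), 96L)
})
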