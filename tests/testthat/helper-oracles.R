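# independent oracles and small fixtures used across the suite

# stiff numerical integration of the compartmental mass-balance ODEs,
# piecewise between dose-event boundaries (constant zero-order input within
# each piece, bolus amounts added at piece starts)
ode_conc <- function(reg, params, times) {
  ev <- reg$events
  bol <- ev[ev$duration == 0, , drop = FALSE]
  inf <- ev[ev$duration > 0, , drop = FALSE]
  rhs <- function(t, y, p) {
    list(c(p$rate - (p$k10 + p$k12) * y[1] + p$k21 * y[2],
           p$k12 * y[1] - p$k21 * y[2]))
  }
  breaks <- sort(unique(c(0, ev$time, inf$time + inf$duration,
                          max(times))))
  breaks <- breaks[breaks <= max(times) + 1e-12]
  y <- c(A1 = 0, A2 = 0)
  res <- setNames(numeric(length(times)), NULL)
  for (k in seq_len(length(breaks))) {
    a <- breaks[k]
    b <- if (k < length(breaks)) breaks[k + 1] else max(times)
    y["A1"] <- y["A1"] + sum(bol$amount[abs(bol$time - a) < 1e-12])
    res[abs(times - a) < 1e-12] <- y["A1"] / params$V1
    if (b <= a + 1e-12) next
    rate <- if (nrow(inf))
      sum(inf$amount[inf$time <= a + 1e-12 &
                       inf$time + inf$duration > a + 1e-12] /
            inf$duration[inf$time <= a + 1e-12 &
                           inf$time + inf$duration > a + 1e-12]) else 0
    inside <- times > a + 1e-12 & times < b - 1e-12
    tt <- sort(unique(c(a, times[inside], b)))
    p <- params
    p$rate <- rate
    out <- deSolve::lsoda(y, times = tt, func = rhs, parms = p,
                          rtol = 1e-11, atol = 1e-11)
    for (j in which(inside))
      res[j] <- out[which.min(abs(out[, "time"] - times[j])), "A1"] /
        params$V1
    y <- c(A1 = unname(out[nrow(out), "A1"]),
           A2 = unname(out[nrow(out), "A2"]))
  }
  res
}

# adaptive Gauss-Hermite quadrature for the marginal -2 log likelihood of
# a single subject with 1 or 2 active random effects
agq_ofv <- function(model, subj, nodes = 64) {
  om <- model$omega2
  act <- names(om)[om > 0]
  s2p <- if ("prop" %in% names(model$sigma2)) model$sigma2[["prop"]] else 0
  s2a <- if ("add" %in% names(model$sigma2)) model$sigma2[["add"]] else 0
  loglik <- function(eta) {
    if (any(abs(eta) > 5)) return(-1e8)
    e <- c(CL = 0, V1 = 0, V2 = 0)
    e[act] <- eta
    par <- individual_params(model, eta = e,
                             weight = subj$covariates$weight,
                             covariates = subj$covariates)
    f <- conc_profile(subj$regimen, par, subj$obs$time, pre_dose = TRUE)
    g <- s2p * f^2 + s2a
    sum(dnorm(subj$obs$dv, f, sqrt(g), log = TRUE)) +
      sum(dnorm(eta, 0, sqrt(unlist(om[act])), log = TRUE))
  }
  d <- length(act)
  opt <- optim(rep(0, d), function(e) -loglik(e), method = "BFGS",
               hessian = TRUE)
  mu <- opt$par
  H <- opt$hessian
  gh <- pracma::gaussHermite(nodes)
  if (d == 1) {
    xs <- mu + sqrt(2 / H[1, 1]) * gh$x
    li <- vapply(seq_along(xs), function(i) loglik(xs[i]), 0) + gh$x^2
    M <- max(li)
    -2 * (log(sum(gh$w * exp(li - M))) + M + 0.5 * log(2 / H[1, 1]))
  } else {
    Ch <- t(chol(solve(H)))
    z <- as.matrix(expand.grid(gh$x, gh$x))
    w <- as.vector(outer(gh$w, gh$w))
    lv <- vapply(seq_len(nrow(z)), function(i)
      loglik(mu + sqrt(2) * as.vector(Ch %*% z[i, ])), 0)
    li <- lv + rowSums(z^2)
    M <- max(li)
    -2 * (log(sum(w * exp(li - M))) + M + 0.5 * d * log(2) + log(det(Ch)))
  }
}

# random two-compartment parameter sets around the adult critical-care range
random_params <- function() {
  pk_params(CL = exp(rnorm(1, log(20), 0.5)),
            V1 = exp(rnorm(1, log(15), 0.4)),
            Q = exp(rnorm(1, log(10), 0.5)),
            V2 = exp(rnorm(1, log(10), 0.4)))
}

# random bolus/infusion regimen over 24 h
random_regimen <- function() {
  n_ev <- sample(2:5, 1)
  st <- sort(runif(n_ev, 0, 18))
  dur <- ifelse(runif(n_ev) < 0.5, 0, runif(n_ev, 0.5, 3))
  regimen(st, runif(n_ev, 300, 2400), dur, horizon = 24)
}

# low-noise single-subject toys where the conditional density is close to
# Gaussian ("moderate curvature"), for quadrature-agreement checks
make_oracle_toy <- function(k) {
  d2 <- 1 + (k %% 2)
  om2 <- if (d2 == 1) c(CL = runif(1, 0.01, 0.035))
  else c(CL = runif(1, 0.01, 0.035), V1 = runif(1, 0.01, 0.03))
  m <- pop_model(theta = c(CL = runif(1, 15, 30), V1 = runif(1, 12, 18),
                           Q = 11, V2 = 10),
                 omega2 = om2, sigma2 = c(prop = 0.002, add = 0.001),
                 covariates = list())
  des <- study_design(n_subjects = 1,
                      regimen_mix = data.frame(dose = 1200, interval = 4,
                                               n = 1),
                      truth = m)
  list(model = m, study = generate_study(des, seed = 300 + k))
}

# one-compartment null-effect world for likelihood-ratio calibration
null_world <- function() {
  pop_model(theta = c(CL = 23, V1 = 25), omega2 = c(CL = 0.1),
            sigma2 = c(add = 0.25), covariates = list(),
            n_compartments = 1)
}

make_null_study <- function(seed, n = 50, nobs = 4, truth = null_world()) {
  des <- study_design(n_subjects = n,
                      regimen_mix = data.frame(dose = 1200, interval = 4,
                                               n = n),
                      truth = truth)
  st <- generate_study(des, seed = seed)
  subjects <- lapply(unclass(st), function(s) {
    s$obs <- s$obs[seq_len(nobs), ]
    s
  })
  pk_study(subjects)
}
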