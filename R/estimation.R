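# FOCE-i estimation: objective, fitting, LRT, stepwise covariate search,
# non-parametric bootstrap.

# flat (offset-indexed) study layout reused across objective evaluations
.prep_subjects <- function(data) {
  for (s in data)
    if (nrow(s$obs) < 1L)
      stop(sprintf("subject %s has no observations", s$id))
  nobs <- vapply(data, function(s) nrow(s$obs), 0L)
  nev <- vapply(data, function(s) nrow(s$regimen$events), 0L)
  cov_names <- unique(unlist(lapply(data, function(s)
    names(s$covariates))))
  covs <- lapply(cov_names, function(nm)
    vapply(data, function(s) {
      x <- s$covariates[[nm]]
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, 0))
  names(covs) <- cov_names
  list(n = length(data),
       ids = vapply(data, function(s) as.character(s$id), ""),
       obs_time = unlist(lapply(data, function(s) s$obs$time)),
       obs_y = unlist(lapply(data, function(s) s$obs$dv)),
       obs_ptr = as.integer(c(0, cumsum(nobs))),
       ev_time = unlist(lapply(data, function(s) s$regimen$events$time)),
       ev_amt = unlist(lapply(data, function(s) s$regimen$events$amount)),
       ev_dur = unlist(lapply(data, function(s)
         s$regimen$events$duration)),
       ev_ptr = as.integer(c(0, cumsum(nev))),
       covs = covs, n_obs = sum(nobs))
}

# n x 4 matrix of typical (eta = 0) CL, V1, Q, V2 across the study
.tv_matrix <- function(model, prep) {
  wt <- prep$covs$weight
  if (is.null(wt) || any(!is.finite(wt)) || any(wt <= 0))
    stop("invalid covariate: weight must be positive for every subject")
  fw_cl <- (wt / model$ref_weight)^model$allo_cl
  fw_v <- (wt / model$ref_weight)^model$allo_v
  two <- model$n_compartments == 2L
  tv <- cbind(CL = model$theta[["CL"]] * fw_cl,
              V1 = model$theta[["V1"]] * fw_v,
              Q = if (two) model$theta[["Q"]] * fw_cl else
                rep(0, prep$n),
              V2 = if (two) model$theta[["V2"]] * fw_v else
                rep(0, prep$n))
  for (tm in model$covariates) {
    x <- prep$covs[[tm$cov]]
    if (is.null(x) || any(is.na(x)))
      stop(sprintf("invalid covariate: '%s' is missing", tm$cov))
    f <- if (tm$type == "power") {
      if (any(x <= 0))
        stop(sprintf("invalid covariate: '%s' must be positive", tm$cov))
      (x / tm$ref)^tm$value
    } else 1 + tm$value * x
    tv[, tm$param] <- tv[, tm$param] * f
  }
  tv
}

.model_s2 <- function(model) {
  c(prop = if ("prop" %in% names(model$sigma2)) model$sigma2[["prop"]] else 0,
    add = if ("add" %in% names(model$sigma2)) model$sigma2[["add"]] else 0)
}

.model_om2 <- function(model) {
  om <- c(CL = 0, V1 = 0, V2 = 0)
  om[names(model$omega2)] <- model$omega2
  om
}

#' FOCE-i objective function value
#'
#' The approximate -2 log marginal likelihood of a population model given a
#' study: for each subject the conditional mode of the random effects is
#' located (quasi-Newton inner optimization, gradient tolerance 1e-8 with
#' deterministic perturbed restarts), then the first-order-conditional
#' approximation with interaction (residual variance evaluated at the
#' individual prediction) is applied and summed over subjects. The
#' `log(2*pi)` constants are included, so only differences between nested
#' models are meaningful for selection.
#'
#' @param model a [pop_model()].
#' @param data a [pk_study()] in which every subject has at least one
#'   observation.
#' @param method `"foce"` (Gauss-Newton curvature, the default) or
#'   `"laplace"` (full numerical curvature of the conditional objective).
#' @param etas optional matrix of inner-optimization starting values
#'   (one row per subject), used for warm starts during fitting.
#' @param details if `TRUE`, attach the conditional modes
#'   (`attr(, "etas")`) and per-subject contributions
#'   (`attr(, "by_subject")`).
#' @return The objective function value (OFV), a scalar.
#' @export
foce_objective <- function(model, data, method = c("foce", "laplace"),
                           etas = NULL, details = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(model, "pop_model"), inherits(data, "pk_study"))
  prep <- .prep_subjects(data)
  .foce_ofv(model, prep, method, etas, details)
}

.foce_ofv <- function(model, prep, method = "foce", etas = NULL,
                      details = FALSE) {
  om2 <- .model_om2(model)
  s2 <- .model_s2(model)
  tv <- .tv_matrix(model, prep)
  if (is.null(etas)) etas <- matrix(0, prep$n, 3)
  res <- cpp_foce_study(prep$obs_time, prep$obs_y, prep$obs_ptr,
                        prep$ev_time, prep$ev_amt, prep$ev_dur,
                        prep$ev_ptr, tv, om2, s2[["prop"]], s2[["add"]],
                        method == "laplace", etas)
  bad <- !is.finite(res$by_subject)
  if (any(bad))
    stop("non-finite objective contribution for subject ",
         paste(prep$ids[bad], collapse = ", "))
  ofv <- res$ofv
  if (details) {
    eta_out <- res$etas
    dimnames(eta_out) <- list(NULL, c("CL", "V1", "V2"))
    attr(ofv, "etas") <- eta_out
    attr(ofv, "by_subject") <- res$by_subject
  }
  ofv
}

# ---------------------------------------------------------------------------
# packing the estimated parameters onto an unconstrained (mostly log) scale

.pack_model <- function(model, fix = character()) {
  par <- c()
  for (nm in names(model$theta))
    par[paste0("theta.", nm)] <- log(model$theta[[nm]])
  for (k in seq_along(model$covariates)) {
    tm <- model$covariates[[k]]
    par[paste0("cov.", tm$param, ".", tm$cov)] <- tm$value
  }
  for (nm in names(model$omega2))
    par[paste0("omega2.", nm)] <- log(max(model$omega2[[nm]], 1e-8))
  for (nm in names(model$sigma2))
    par[paste0("sigma2.", nm)] <- log(max(model$sigma2[[nm]], 1e-10))
  est <- setdiff(names(par), fix)
  if (length(setdiff(fix, names(par))))
    stop("unknown parameter(s) in fix: ",
         paste(setdiff(fix, names(par)), collapse = ", "))
  lower <- rep(-30, length(est))
  upper <- rep(30, length(est))
  names(lower) <- names(upper) <- est
  is_cov <- startsWith(est, "cov.")
  lower[is_cov] <- -10
  upper[is_cov] <- 10
  list(full = par, est = est, lower = lower, upper = upper)
}

.unpack_model <- function(model, full, p_est) {
  full[names(p_est)] <- p_est
  for (nm in names(model$theta))
    model$theta[[nm]] <- exp(full[[paste0("theta.", nm)]])
  for (k in seq_along(model$covariates)) {
    tm <- model$covariates[[k]]
    model$covariates[[k]]$value <- full[[paste0("cov.", tm$param, ".",
                                                tm$cov)]]
  }
  for (nm in names(model$omega2))
    model$omega2[[nm]] <- exp(full[[paste0("omega2.", nm)]])
  for (nm in names(model$sigma2))
    model$sigma2[[nm]] <- exp(full[[paste0("sigma2.", nm)]])
  model
}

# natural-scale named estimates of a model's estimated parameters
.natural_coefs <- function(model) {
  out <- c()
  for (nm in names(model$theta))
    out[paste0("theta.", nm)] <- unname(model$theta[[nm]])
  for (tm in model$covariates)
    out[paste0("cov.", tm$param, ".", tm$cov)] <- tm$value
  for (nm in names(model$omega2))
    out[paste0("omega2.", nm)] <- unname(model$omega2[[nm]])
  for (nm in names(model$sigma2))
    out[paste0("sigma2.", nm)] <- unname(model$sigma2[[nm]])
  out
}

#' Naive pooled initial estimates
#'
#' Crude starting values for [foce_fit()]: a pooled (no random effects)
#' log-scale least-squares fit of the structural parameters across all
#' subjects, omega^2 = 0.1 throughout and residual variances from the
#' pooled residual scatter.
#'
#' @param data a [pk_study()].
#' @param n_compartments 1 or 2.
#' @param covariates list of [cov_term()] starting at their null values.
#' @return A [pop_model()] usable as a starting point.
#' @export
initial_estimates <- function(data, n_compartments = 2,
                              covariates = list()) {
  stopifnot(inherits(data, "pk_study"))
  start <- if (n_compartments == 2) log(c(10, 20, 5, 10)) else log(c(10, 20))
  n_obs <- sum(vapply(data, function(s) nrow(s$obs), 0L))
  obj <- function(lp) {
    th <- exp(lp)
    sse <- 0
    for (s in data) {
      fw <- s$covariates$weight / 70
      ev <- s$regimen$events
      f <- cpp_conc(s$obs$time, ev$time, ev$amount, ev$duration,
                    th[1] * fw^0.75, th[2] * fw,
                    if (n_compartments == 2) th[3] * fw^0.75 else 0,
                    if (n_compartments == 2) th[4] * fw else 0, TRUE)
      sse <- sse + sum((log(pmax(s$obs$dv, 0.01)) -
                          log(pmax(f, 0.01)))^2)
    }
    sse
  }
  fit <- nlminb(start, obj, lower = log(0.1), upper = log(1000))
  th <- exp(fit$par)
  theta <- if (n_compartments == 2)
    c(CL = th[1], V1 = th[2], Q = th[3], V2 = th[4])
  else c(CL = th[1], V1 = th[2])
  om <- if (n_compartments == 2) c(CL = 0.1, V1 = 0.1, V2 = 0.1)
  else c(CL = 0.1, V1 = 0.1)
  resid_var <- exp(fit$objective / max(1, n_obs)) - 1
  pop_model(theta = theta, omega2 = om,
            sigma2 = c(prop = max(0.02, min(resid_var, 0.5)), add = 0.01),
            covariates = covariates, n_compartments = n_compartments)
}

#' Fit a population model by FOCE-i
#'
#' Minimizes [foce_objective()] over log-transformed fixed effects and
#' variance components (covariate coefficients enter untransformed) with
#' `nlminb`, warm-starting each subject's conditional mode from the
#' previous outer iteration. Standard errors come from the observed
#' information (central finite differences of the objective), transformed
#' to the natural scale by the delta method; a failed or non-positive-
#' definite information matrix is tolerated and flagged, never fatal.
#'
#' @param model starting [pop_model()] (for example from
#'   [initial_estimates()], or the previous fit for a bootstrap replicate).
#' @param data a [pk_study()].
#' @param fix character vector of packed parameter names (such as
#'   `"sigma2.add"` or `"theta.Q"`) held at their starting values.
#' @param method passed to [foce_objective()].
#' @param se compute standard errors (default `TRUE`).
#' @param control list overriding `nlminb` control values.
#' @return An object of class `"pkfit"`; see [summary.pkfit()].
#' @examples
#' \donttest{
#' study <- generate_study(study_design(), seed = 7)
#' start <- initial_estimates(study,
#'   covariates = list(cov_term("CL", "creatinine", 70, 0)))
#' fit <- foce_fit(start, study, se = FALSE)
#' coef(fit)
#' }
#' @export
foce_fit <- function(model, data, fix = character(),
                     method = c("foce", "laplace"), se = TRUE,
                     control = list()) {
  method <- match.arg(method)
  stopifnot(inherits(model, "pop_model"), inherits(data, "pk_study"))
  prep <- .prep_subjects(data)
  n_obs <- prep$n_obs
  pk <- .pack_model(model, fix)
  if (length(pk$est) >= n_obs)
    warning("as many estimated parameters as observations; ",
            "the fit is unlikely to be identifiable")
  warm <- new.env(parent = emptyenv())
  warm$etas <- matrix(0, prep$n, 3)
  n_eval <- 0L
  obj <- function(p_est) {
    m <- .unpack_model(model, pk$full, setNames(p_est, pk$est))
    val <- tryCatch(
      .foce_ofv(m, prep, method, warm$etas, details = TRUE),
      error = function(e) NULL)
    n_eval <<- n_eval + 1L
    if (is.null(val) || !is.finite(val)) return(1e10)
    warm$etas <- attr(val, "etas")
    as.numeric(val)
  }
  start <- pk$full[pk$est]
  ofv0 <- obj(start)
  ctrl <- modifyList(list(iter.max = 500, eval.max = 4000, trace = 0,
                          rel.tol = 1e-9), control)
  opt <- nlminb(start, obj, lower = pk$lower, upper = pk$upper,
                control = ctrl)
  final <- .unpack_model(model, pk$full, setNames(opt$par, pk$est))
  ofv_det <- .foce_ofv(final, prep, method, warm$etas, details = TRUE)
  boundary <- names(opt$par)[opt$par <= pk$lower + 1e-6 |
                             opt$par >= pk$upper - 1e-6]
  # nlminb reports "false convergence" when started at (or very near) the
  # optimum; a finite objective no worse than the start is still a usable
  # stationary fit
  converged <- is.finite(ofv_det) &&
    (opt$convergence == 0 ||
       as.numeric(ofv_det) <= ofv0 + 1e-6)
  se_tab <- NULL
  if (se) se_tab <- .fit_se(final, obj, opt$par, pk)
  etas <- attr(ofv_det, "etas")
  rownames(etas) <- prep$ids
  structure(list(model = final, ofv = as.numeric(ofv_det), etas = etas,
                 se = se_tab, start_model = model, start_ofv = ofv0,
                 convergence = opt$convergence, converged = converged,
                 message = opt$message,
                 boundary = boundary, n_eval = n_eval,
                 iterations = opt$iterations, method = method,
                 fix = fix, data = data, n_obs = n_obs),
            class = "pkfit")
}

.fit_se <- function(final, obj, p_hat, pk) {
  k <- length(p_hat)
  est_nat <- .natural_coefs(final)
  nm <- names(p_hat)
  H <- matrix(NA_real_, k, k)
  ok <- TRUE
  hstep <- pmax(1e-4, 1e-4 * abs(p_hat))
  f0 <- obj(p_hat)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    e <- p_hat; e[i] <- e[i] + hstep[i]; fp[i] <- obj(e)
    e[i] <- p_hat[i] - hstep[i]; fm[i] <- obj(e)
    H[i, i] <- (fp[i] + fm[i] - 2 * f0) / hstep[i]^2
  }
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      e <- p_hat
      e[i] <- e[i] + hstep[i]; e[j] <- e[j] + hstep[j]; a <- obj(e)
      e[j] <- p_hat[j] - hstep[j]; b <- obj(e)
      e[i] <- p_hat[i] - hstep[i]; cc <- obj(e)
      e[j] <- p_hat[j] + hstep[j]; d <- obj(e)
      H[i, j] <- H[j, i] <- (a - d - b + cc) / (4 * hstep[i] * hstep[j])
    }
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  se_p <- if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    ok <- FALSE
    rep(NA_real_, k)
  } else sqrt(diag(V))
  # delta method back to the natural scale (log-parameters)
  se_nat <- setNames(rep(NA_real_, length(est_nat)), names(est_nat))
  for (i in seq_len(k)) {
    nat <- est_nat[[nm[i]]]
    se_nat[nm[i]] <- if (startsWith(nm[i], "cov.")) se_p[i]
    else se_p[i] * abs(nat)
  }
  data.frame(parameter = names(est_nat),
             estimate = unname(est_nat),
             se = unname(se_nat[names(est_nat)]),
             rse_pct = unname(100 * se_nat[names(est_nat)] /
                              abs(est_nat)),
             row.names = NULL)
}

#' Likelihood-ratio test between nested fits
#'
#' Accepts the richer model when the OFV drops by at least the chi-square
#' quantile for the number of added parameters (3.84 for one parameter at
#' p < 0.05).
#'
#' @param base,candidate [foce_fit()] results or bare OFV numbers; the
#'   candidate must nest the base.
#' @param added_params number of extra parameters in the candidate.
#' @param alpha significance level.
#' @return A list with `delta_ofv`, `df`, `threshold` and logical
#'   `accept`.
#' @examples
#' lrt_step(104.4 + 100, 100, added_params = 3) # accepted
#' @export
lrt_step <- function(base, candidate, added_params = 1, alpha = 0.05) {
  get_ofv <- function(x) if (inherits(x, "pkfit")) x$ofv else as.numeric(x)
  if (added_params < 1) stop("added_params must be >= 1")
  if (inherits(base, "pkfit") && inherits(candidate, "pkfit")) {
    k_base <- length(.pack_model(base$model, base$fix)$est)
    k_cand <- length(.pack_model(candidate$model, candidate$fix)$est)
    if (k_cand - k_base != added_params)
      stop("candidate does not nest base with the stated added_params")
  }
  d <- get_ofv(base) - get_ofv(candidate)
  thr <- qchisq(1 - alpha, df = added_params)
  list(delta_ofv = d, df = added_params, threshold = thr,
       accept = d >= thr)
}

#' Forward stepwise covariate selection
#'
#' At each round every remaining candidate is added to the current model
#' (power term for continuous covariates, proportional shift for
#' categorical ones), refit, and the largest significant OFV drop
#' (chi-square, 1 df) is retained; the search stops when no candidate is
#' significant. Every tested drop is recorded in the ledger.
#'
#' @param model base [pop_model()] (already fitted values make good
#'   starting points).
#' @param data a [pk_study()].
#' @param candidates list of [cov_term()] templates (their `value` is the
#'   starting coefficient, usually 0).
#' @param alpha significance level per test.
#' @param ... passed to [foce_fit()] (for example `se = FALSE`).
#' @return A list with the selected `model`, its `fit`, and a `ledger`
#'   data frame of every tested candidate and round.
#' @export
stepwise_covariates <- function(model, data, candidates, alpha = 0.05,
                                ...) {
  stopifnot(inherits(model, "pop_model"), inherits(data, "pk_study"))
  for (tm in candidates) {
    bad <- vapply(data, function(s) {
      x <- s$covariates[[tm$cov]]
      is.null(x) || is.na(x)
    }, TRUE)
    if (any(bad))
      stop(sprintf("covariate '%s' missing for subject(s) %s", tm$cov,
                   paste(vapply(data[bad], function(s) as.character(s$id),
                                ""), collapse = ", ")))
  }
  current_fit <- foce_fit(model, data, se = FALSE, ...)
  current <- current_fit$model
  remaining <- candidates
  ledger <- data.frame(round = integer(), param = character(),
                       covariate = character(), delta_ofv = numeric(),
                       accepted = logical())
  round_i <- 0L
  while (length(remaining)) {
    round_i <- round_i + 1L
    fits <- vector("list", length(remaining))
    dofv <- rep(-Inf, length(remaining))
    for (k in seq_along(remaining)) {
      cand_model <- current
      cand_model$covariates <- c(cand_model$covariates,
                                 list(remaining[[k]]))
      fits[[k]] <- tryCatch(foce_fit(cand_model, data, se = FALSE, ...),
                            error = function(e) NULL)
      if (!is.null(fits[[k]]))
        dofv[k] <- current_fit$ofv - fits[[k]]$ofv
    }
    thr <- qchisq(1 - alpha, 1)
    best <- which.max(dofv)
    ledger <- rbind(ledger, data.frame(
      round = round_i,
      param = vapply(remaining, `[[`, "", "param"),
      covariate = vapply(remaining, `[[`, "", "cov"),
      delta_ofv = dofv,
      accepted = seq_along(remaining) == best & dofv >= thr))
    if (dofv[best] >= thr) {
      current_fit <- fits[[best]]
      current <- current_fit$model
      remaining <- remaining[-best]
    } else break
  }
  list(model = current, fit = current_fit, ledger = ledger)
}

#' Non-parametric bootstrap of a fitted model
#'
#' Resamples subjects with replacement to the original subject count,
#' refits each replicate starting from the final estimates, and summarizes
#' each parameter by its median and 2.5/97.5 percentiles over converged
#' replicates. Non-converged replicates are excluded and counted, never
#' silently dropped.
#'
#' @param fit a [foce_fit()] result.
#' @param n_replicates number of bootstrap datasets (the study analysis
#'   used 2000).
#' @param seed integer seed (required for a reproducible resampling plan).
#' @param ... passed to [foce_fit()].
#' @return An object of class `"pk_boot"` with elements `summary` (data
#'   frame of median and 95% interval per parameter), `replicates` (matrix
#'   of per-replicate estimates), `n_failed`.
#' @export
pk_bootstrap <- function(fit, n_replicates = 2000, seed = NULL, ...) {
  stopifnot(inherits(fit, "pkfit"), n_replicates >= 1)
  data <- fit$data
  n <- length(data)
  idx <- with_local_seed(seed, {
    matrix(sample.int(n, n * n_replicates, replace = TRUE), nrow = n)
  })
  est0 <- .natural_coefs(fit$model)
  reps <- matrix(NA_real_, n_replicates, length(est0),
                 dimnames = list(NULL, names(est0)))
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    boot_subjects <- unclass(data)[idx[, r]]
    for (j in seq_along(boot_subjects)) boot_subjects[[j]]$id <- j
    bdata <- pk_study(boot_subjects)
    bf <- tryCatch(foce_fit(fit$model, bdata, fix = fit$fix, se = FALSE,
                            method = fit$method, ...),
                   error = function(e) NULL)
    if (is.null(bf) || !is.finite(bf$ofv) || !bf$converged) {
      failed <- failed + 1L
    } else {
      reps[r, ] <- .natural_coefs(bf$model)
    }
  }
  used <- reps[stats::complete.cases(reps), , drop = FALSE]
  if (!nrow(used))
    stop("no bootstrap replicate converged; nothing to summarize")
  qs <- apply(used, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  summary <- data.frame(parameter = colnames(reps),
                        estimate = unname(est0),
                        median = qs[2, ], lower95 = qs[1, ],
                        upper95 = qs[3, ], row.names = NULL)
  structure(list(summary = summary, replicates = reps, n_failed = failed,
                 n_replicates = n_replicates, seed = seed),
            class = "pk_boot")
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("Non-parametric bootstrap: %d replicates (%d non-converged, excluded)\n",
              x$n_replicates, x$n_failed))
  print(transform(x$summary,
                  estimate = signif(estimate, 4),
                  median = signif(median, 4),
                  lower95 = signif(lower95, 4),
                  upper95 = signif(upper95, 4)),
        row.names = FALSE)
  invisible(x)
}
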