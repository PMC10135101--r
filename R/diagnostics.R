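# goodness-of-fit records and the prediction-corrected visual predictive
# check

#' Goodness-of-fit table
#'
#' One record per observation with the population prediction (eta = 0),
#' the individual prediction (conditional modes) and the individually
#' weighted residual `iwres = (obs - ipred) / sqrt(Var(obs | ipred))`.
#'
#' @param fit a [foce_fit()] result.
#' @return A data frame with columns `id`, `time`, `dv`, `pred`, `ipred`,
#'   `iwres`.
#' @export
gof_table <- function(fit) {
  stopifnot(inherits(fit, "pkfit"))
  pop <- predict(fit, type = "population")
  ind <- predict(fit, type = "individual")
  g <- residual_variance(ind$ipred, fit$model)
  out <- data.frame(id = pop$id, time = pop$time, dv = pop$dv,
                    pred = pop$pred, ipred = ind$ipred,
                    iwres = (pop$dv - ind$ipred) / sqrt(g))
  if (any(!is.finite(out$iwres)))
    stop("non-finite weighted residuals; residual variance may be zero")
  out
}

# time after the most recent strictly prior dose: a sample drawn at the
# instant of a dose is a trough and folds to the end of the previous
# interval
.time_after_dose <- function(reg, t) {
  starts <- reg$events$time
  vapply(t, function(ti) {
    prior <- starts[starts < ti - 1e-12]
    if (!length(prior)) ti else ti - max(prior)
  }, 0)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model-simulated replicates are corrected
#' multiplicatively by (bin median population prediction) / (record's
#' population prediction), binned on time-after-dose, and the observed
#' 2.5/50/97.5 percentiles are compared with confidence bands for the same
#' percentiles across simulated replicates. The time axis is folded to
#' time-after-dose and capped (default 4 h), so subjects on 6-hourly
#' dosing contribute their own interval's early window.
#'
#' @param fit a [foce_fit()] result.
#' @param n_sim number of simulated replicate studies (>= 100).
#' @param bins number of quantile-based bins on time-after-dose.
#' @param max_tad cap of the folded time axis (h); observations beyond it
#'   are excluded from the check.
#' @param band confidence level of the simulation bands.
#' @param seed optional integer seed.
#' @return An object of class `"pk_vpc"`: a list with the per-bin `table`
#'   (observed percentiles and simulated bands), `n_sim`, `bins` and the
#'   records used.
#' @export
pc_vpc <- function(fit, n_sim = 1000, bins = 4, max_tad = 4, band = 0.95,
                   seed = NULL) {
  stopifnot(inherits(fit, "pkfit"))
  if (n_sim < 100) stop("n_sim must be at least 100")
  pop <- predict(fit, type = "population")
  tad <- unlist(lapply(seq_along(fit$data), function(i)
    .time_after_dose(fit$data[[i]]$regimen, fit$data[[i]]$obs$time)))
  keep <- tad <= max_tad + 1e-9
  if (!any(keep)) stop("no observations within the folded time window")
  pop <- pop[keep, , drop = FALSE]
  tad <- tad[keep]
  if (any(pop$pred <= 0))
    stop("non-positive population predictions cannot be prediction-corrected")
  edges <- unique(quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  if (length(edges) - 1L < bins)
    message("empty or duplicated bins merged; using ",
            length(edges) - 1L, " bins")
  bin <- cut(tad, edges, include.lowest = TRUE)
  binmed <- tapply(pop$pred, bin, median)
  corr <- unname(binmed[bin]) / pop$pred
  pc_obs <- pop$dv * corr
  probs <- c(0.025, 0.5, 0.975)
  obs_q <- t(vapply(levels(bin), function(b)
    quantile(pc_obs[bin == b], probs, names = FALSE), numeric(3)))
  sims <- simulate(fit, nsim = n_sim, seed = seed)
  sim_q <- array(NA_real_, c(n_sim, nlevels(bin), 3))
  for (r in seq_len(n_sim)) {
    ysim <- unlist(lapply(sims[[r]], function(s) s$obs$dv))[keep]
    pc_sim <- ysim * corr
    sim_q[r, , ] <- t(vapply(levels(bin), function(b)
      quantile(pc_sim[bin == b], probs, names = FALSE), numeric(3)))
  }
  alpha <- (1 - band) / 2
  lo <- apply(sim_q, c(2, 3), quantile, probs = alpha, names = FALSE)
  hi <- apply(sim_q, c(2, 3), quantile, probs = 1 - alpha, names = FALSE)
  md <- apply(sim_q, c(2, 3), median)
  tab <- data.frame(
    bin = levels(bin),
    tad_mid = as.numeric(tapply(tad, bin, median)),
    n = as.integer(table(bin)),
    obs_p2.5 = obs_q[, 1], obs_p50 = obs_q[, 2], obs_p97.5 = obs_q[, 3],
    sim_p2.5_lo = lo[, 1], sim_p2.5_hi = hi[, 1], sim_p2.5_md = md[, 1],
    sim_p50_lo = lo[, 2], sim_p50_hi = hi[, 2], sim_p50_md = md[, 2],
    sim_p97.5_lo = lo[, 3], sim_p97.5_hi = hi[, 3], sim_p97.5_md = md[, 3],
    row.names = NULL)
  structure(list(table = tab, n_sim = n_sim, bins = nlevels(bin),
                 band = band, max_tad = max_tad, seed = seed,
                 pc_obs = data.frame(tad = tad, pc_obs = pc_obs,
                                     bin = bin)),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("Prediction-corrected VPC: %d bins, %d simulated replicates\n",
              x$bins, x$n_sim))
  cols <- c("bin", "n", "obs_p50", "sim_p50_lo", "sim_p50_hi")
  print(transform(x$table[, cols],
                  obs_p50 = signif(obs_p50, 4),
                  sim_p50_lo = signif(sim_p50_lo, 4),
                  sim_p50_hi = signif(sim_p50_hi, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.pk_vpc <- function(x, ...) {
  tab <- x$table
  pts <- x$pc_obs
  plot(pts$tad, pts$pc_obs, pch = 16, col = "grey60",
       xlab = "Time after dose (h)",
       ylab = "Prediction-corrected concentration (mg/L)", ...)
  shade <- function(lo, hi, col) {
    graphics::polygon(c(tab$tad_mid, rev(tab$tad_mid)), c(lo, rev(hi)),
                      border = NA, col = col)
  }
  shade(tab$sim_p2.5_lo, tab$sim_p2.5_hi, grDevices::adjustcolor("steelblue", 0.3))
  shade(tab$sim_p50_lo, tab$sim_p50_hi, grDevices::adjustcolor("firebrick", 0.3))
  shade(tab$sim_p97.5_lo, tab$sim_p97.5_hi, grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(tab$tad_mid, tab$obs_p50, lwd = 2)
  graphics::lines(tab$tad_mid, tab$obs_p2.5, lty = 2)
  graphics::lines(tab$tad_mid, tab$obs_p97.5, lty = 2)
  graphics::rug(tab$tad_mid, col = "orange", lwd = 2)
  invisible(x)
}
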