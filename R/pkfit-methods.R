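# S3 methods for fitted population models

#' @export
print.pkfit <- function(x, ...) {
  cat("Population PK model fitted by FOCE",
      if (x$method == "foce") "with interaction" else "(Laplace)", "\n")
  cat(sprintf("  %d subjects, %d observations; OFV %.3f\n",
              length(x$data), x$n_obs, x$ofv))
  cat(sprintf("  convergence code %d%s\n", x$convergence,
              if (length(x$boundary))
                paste0(" (boundary: ", paste(x$boundary, collapse = ", "),
                       ")") else ""))
  print(round(coef(x), 4))
  invisible(x)
}

#' Summary of a FOCE-i fit
#'
#' @param object a [foce_fit()] result.
#' @param ... unused.
#' @return Invisibly, a data frame of estimates with standard errors and
#'   percent relative standard errors where available; also printed along
#'   with the typical-subject terminal half-life.
#' @export
summary.pkfit <- function(object, ...) {
  tab <- if (!is.null(object$se)) object$se
  else data.frame(parameter = names(.natural_coefs(object$model)),
                  estimate = unname(.natural_coefs(object$model)),
                  se = NA_real_, rse_pct = NA_real_)
  cat(sprintf("FOCE-i fit: OFV %.3f over %d subjects (%d observations)\n",
              object$ofv, length(object$data), object$n_obs))
  pt <- transform(tab, estimate = signif(estimate, 4),
                  se = signif(se, 3), rse_pct = round(rse_pct, 1))
  print(pt, row.names = FALSE)
  thalf <- individual_params(object$model)$t_half_beta
  cat(sprintf("Typical terminal half-life (70 kg, reference covariates): %.3g h\n",
              thalf))
  if (length(object$boundary))
    cat("Boundary estimate(s):", paste(object$boundary, collapse = ", "),
        "\n")
  invisible(tab)
}

#' @export
coef.pkfit <- function(object, ...) .natural_coefs(object$model)

#' @export
logLik.pkfit <- function(object, ...) {
  # the OFV retains its log(2*pi) constants, so this is a true -2 log L
  # under the FOCE-i approximation
  val <- -object$ofv / 2
  attr(val, "df") <- length(.pack_model(object$model, object$fix)$est)
  attr(val, "nobs") <- object$n_obs
  class(val) <- "logLik"
  val
}

#' Predictions from a fitted population model
#'
#' @param object a [foce_fit()] result.
#' @param newdata optional [pk_study()]; defaults to the fitted data.
#' @param type `"population"` (eta = 0) or `"individual"` (conditional
#'   modes; only for the fitted data).
#' @param ... unused.
#' @return A data frame with columns `id`, `time`, `dv` and `pred` (or
#'   `ipred`).
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("population", "individual"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  stopifnot(inherits(data, "pk_study"))
  if (type == "individual" && !is.null(newdata))
    stop("individual predictions require the fitted data")
  out <- lapply(seq_along(data), function(i) {
    s <- data[[i]]
    eta <- if (type == "individual") object$etas[i, ] else c(0, 0, 0)
    par <- individual_params(object$model, eta = eta,
                             weight = s$covariates$weight,
                             covariates = s$covariates)
    f <- conc_profile(s$regimen, par, s$obs$time, pre_dose = TRUE)
    data.frame(id = s$id, time = s$obs$time, dv = s$obs$dv, fit = f)
  })
  out <- do.call(rbind, out)
  names(out)[4] <- if (type == "individual") "ipred" else "pred"
  out
}

#' @export
residuals.pkfit <- function(object, ...) {
  g <- gof_table(object)
  g$iwres
}

#' Simulate replicate studies from a fitted model
#'
#' Draws new subject random effects and residual errors at the observed
#' design (same subjects, covariates, regimens and sampling times).
#'
#' @param object a [foce_fit()] result.
#' @param nsim number of replicate studies.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` [pk_study()] objects.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  model <- object$model
  data <- object$data
  s2 <- .model_s2(model)
  with_local_seed(seed, {
    lapply(seq_len(nsim), function(r) {
      etas <- sample_etas(model, length(data))
      subjects <- lapply(seq_along(data), function(i) {
        s <- data[[i]]
        par <- individual_params(model, eta = etas[i, ],
                                 weight = s$covariates$weight,
                                 covariates = s$covariates)
        f <- conc_profile(s$regimen, par, s$obs$time, pre_dose = TRUE)
        y <- pmax(f * (1 + rnorm(length(f), 0, sqrt(s2[["prop"]]))) +
                    rnorm(length(f), 0, sqrt(s2[["add"]])), 0)
        s$obs$dv <- y
        s
      })
      pk_study(subjects)
    })
  })
}

#' @export
plot.pkfit <- function(x, ...) {
  g <- gof_table(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lim <- range(c(g$dv, g$pred, g$ipred))
  plot(g$pred, g$dv, xlab = "Population prediction (mg/L)",
       ylab = "Observed (mg/L)", xlim = lim, ylim = lim)
  graphics::abline(0, 1, lty = 2)
  plot(g$ipred, g$dv, xlab = "Individual prediction (mg/L)",
       ylab = "Observed (mg/L)", xlim = lim, ylim = lim)
  graphics::abline(0, 1, lty = 2)
  plot(g$time, g$iwres, xlab = "Time (h)", ylab = "IWRES")
  graphics::abline(h = 0, lty = 2)
  plot(g$ipred, g$iwres, xlab = "Individual prediction (mg/L)",
       ylab = "IWRES")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
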