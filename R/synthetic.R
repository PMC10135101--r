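#' Study container
#'
#' A `pk_study` is a list of subject records, each holding an id, a named
#' list of covariates (at least `weight`; `creatinine` and others as
#' available), a dosing [regimen()] and an observation data frame with
#' columns `time` (h) and `dv` (total plasma concentration, mg/L).
#'
#' @param subjects list of subject records.
#' @return An object of class `"pk_study"`.
#' @export
pk_study <- function(subjects) {
  for (s in subjects) {
    if (is.null(s$id) || is.null(s$covariates$weight) ||
        !inherits(s$regimen, "regimen") || !is.data.frame(s$obs))
      stop("each subject needs id, covariates$weight, regimen and obs")
    if (nrow(s$obs) &&
        (any(s$obs$time < 0) || any(s$obs$time > s$regimen$horizon + 1e-9)))
      stop("observation times must lie within the regimen horizon")
  }
  structure(subjects, class = "pk_study")
}

#' @export
print.pk_study <- function(x, ...) {
  nobs <- vapply(x, function(s) nrow(s$obs), 0L)
  cat(sprintf("PK study: %d subjects, %d observations\n", length(x),
              sum(nobs)))
  invisible(x)
}

#' @export
`[.pk_study` <- function(x, i) pk_study(unclass(x)[i])

# covariate generators: log-normal matched to the reported median and IQR
# of the study population (positively skewed clinical covariates), plus an
# equal sex split and a mildly variable core temperature
.covariate_specs <- list(
  weight = c(median = 70.0, q1 = 65.7, q3 = 90.0),
  creatinine = c(median = 70, q1 = 52, q3 = 103.5),
  albumin = c(median = 28, q1 = 24, q3 = 34),
  age = c(median = 57.7, q1 = 44.3, q3 = 63.2),
  height = c(median = 172.0, q1 = 163.5, q3 = 178.0),
  apache = c(median = 14, q1 = 12.5, q3 = 18)
)

.rlnorm_iqr <- function(n, med_iqr) {
  sdlog <- log(med_iqr[["q3"]] / med_iqr[["q1"]]) / (2 * qnorm(0.75))
  exp(rnorm(n, log(med_iqr[["median"]]), sdlog))
}

# per-interval sampling offsets (h) of the opportunistic design
.sampling_schedule <- list(
  "4" = list(c(0.1, 2, 3.5, 4), c(0.2, 1, 3, 4)),
  "6" = list(c(0.1, 2, 3, 6), c(0.1, 1, 5, 6))
)

#' Synthetic study design
#'
#' Describes the benzylpenicillin critical-care study emulated by
#' [generate_study()]: 12 subjects of whom eight receive 1.2 g 4-hourly,
#' two 1.2 g 6-hourly and two 2.4 g 4-hourly; two sampled dosing intervals
#' per subject with four samples each at the scheduled offsets (4-hourly:
#' 0.1, 2, 3.5, 4 then 0.2, 1, 3, 4 h; 6-hourly: 0.1, 2, 3, 6 then 0.1, 1,
#' 5, 6 h); covariates drawn from log-normal distributions matched to the
#' study population's median and interquartile range. Sampled intervals are
#' placed after `n_lead_doses` maintenance doses so observations are at
#' steady state.
#'
#' @param n_subjects total number of subjects.
#' @param regimen_mix data frame with columns `dose` (mg), `interval` (h)
#'   and `n`; `sum(n)` must equal `n_subjects`.
#' @param truth generating [pop_model()].
#' @param n_lead_doses doses given before the first sampled interval.
#' @param dropout per-observation random dropout probability (0 disables),
#'   emulating opportunistic sample loss.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(n_subjects = 12,
                         regimen_mix = data.frame(
                           dose = c(1200, 1200, 2400),
                           interval = c(4, 6, 4),
                           n = c(8, 2, 2)),
                         truth = bpen_final_model(),
                         n_lead_doses = 5,
                         dropout = 0) {
  stopifnot(inherits(truth, "pop_model"),
            all(c("dose", "interval", "n") %in% names(regimen_mix)),
            dropout >= 0, dropout < 1, n_lead_doses >= 0)
  if (sum(regimen_mix$n) != n_subjects)
    stop("regimen mix counts must sum to n_subjects")
  if (!all(as.character(regimen_mix$interval) %in%
           names(.sampling_schedule)))
    stop("no sampling schedule for interval(s) ",
         paste(setdiff(regimen_mix$interval,
                       as.numeric(names(.sampling_schedule))),
               collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 regimen_mix = regimen_mix, truth = truth,
                 n_lead_doses = as.integer(n_lead_doses),
                 dropout = dropout),
            class = "study_design")
}

#' Read a study design from YAML
#'
#' The schema mirrors the packaged default
#' (`system.file("extdata", "default_study_design.yaml", package =
#' "penpk")`): `n_subjects`, a `regimen_mix` list of
#' `{dose_mg, interval_h, n}` entries, `n_lead_doses` and `dropout`. The
#' generating model defaults to [bpen_final_model()] unless a `model`
#' file path is given alongside.
#'
#' @param path YAML file path.
#' @param truth generating [pop_model()] (overrides any default).
#' @return A [study_design()].
#' @export
read_study_design <- function(path, truth = bpen_final_model()) {
  obj <- yaml::read_yaml(path)
  mix <- do.call(rbind, lapply(obj$regimen_mix, function(x)
    data.frame(dose = x$dose_mg, interval = x$interval_h, n = x$n)))
  study_design(n_subjects = obj$n_subjects, regimen_mix = mix,
               truth = truth,
               n_lead_doses = if (is.null(obj$n_lead_doses)) 5
                              else obj$n_lead_doses,
               dropout = if (is.null(obj$dropout)) 0 else obj$dropout)
}

#' Generate a synthetic study dataset
#'
#' Draws covariates and subject random effects, doses each subject at a
#' steady pattern covering two sampled intervals, evaluates the model
#' prediction at the scheduled (pre-dose convention) times and adds
#' combined residual error `y = f (1 + eps1) + eps2`, truncated at 0.
#' Fully reproducible for a fixed seed.
#'
#' @param design a [study_design()].
#' @param seed integer seed (optional but recommended).
#' @return A [pk_study()]; the generating random effects are attached as
#'   `attr(x, "etas")`.
#' @examples
#' study <- generate_study(study_design(), seed = 1)
#' study
#' @export
generate_study <- function(design = study_design(), seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  truth <- design$truth
  with_local_seed(seed, {
    mix <- design$regimen_mix
    dose <- rep(mix$dose, mix$n)
    interval <- rep(mix$interval, mix$n)
    n <- design$n_subjects
    covs <- lapply(.covariate_specs, function(sp) .rlnorm_iqr(n, sp))
    covs$apache <- round(covs$apache)
    covs$sex <- rbinom(n, 1, 0.5)
    covs$temperature <- rnorm(n, 37.5, 0.8)
    etas <- sample_etas(truth, n)
    s2p <- if ("prop" %in% names(truth$sigma2)) truth$sigma2[["prop"]] else 0
    s2a <- if ("add" %in% names(truth$sigma2)) truth$sigma2[["add"]] else 0
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      tau <- interval[i]
      n_doses <- design$n_lead_doses + 2L
      reg <- regimen(time = seq(0, by = tau, length.out = n_doses),
                     amount = dose[i], horizon = n_doses * tau)
      sched <- .sampling_schedule[[as.character(tau)]]
      t1 <- design$n_lead_doses * tau
      times <- c(t1 + sched[[1]], t1 + tau + sched[[2]])
      sc <- lapply(covs, `[[`, i)
      par <- individual_params(truth, eta = etas[i, ], weight = sc$weight,
                               creatinine = sc$creatinine,
                               covariates = sc)
      f <- conc_profile(reg, par, times, pre_dose = TRUE)
      y <- f * (1 + rnorm(length(f), 0, sqrt(s2p))) +
        rnorm(length(f), 0, sqrt(s2a))
      y <- pmax(y, 0)
      keep <- rep(TRUE, length(times))
      if (design$dropout > 0) {
        keep <- runif(length(times)) > design$dropout
        if (!any(keep)) keep[1] <- TRUE
      }
      subjects[[i]] <- list(
        id = i, covariates = sc, regimen = reg,
        obs = data.frame(time = times[keep], dv = y[keep]))
    }
    out <- pk_study(subjects)
    attr(out, "etas") <- etas
    attr(out, "design") <- design
    attr(out, "seed") <- seed
    out
  })
}
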