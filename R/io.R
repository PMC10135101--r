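# rectangular dataset reader/writer (pharmacometric event-row layout) and
# fit reports

.dataset_cols <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "WT", "CREAT",
                   "ALB", "AGE", "SEX", "HT", "TEMP", "APACHE")
.required_cols <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "WT")

.cov_map <- c(WT = "weight", CREAT = "creatinine", ALB = "albumin",
              AGE = "age", SEX = "sex", HT = "height", TEMP = "temperature",
              APACHE = "apache")

#' Write a study as a rectangular event-row CSV
#'
#' One row per dose or observation event. Dose rows have `EVID = 1` with
#' `AMT` (mg) and `DUR` (h, 0 for bolus); observation rows have `EVID = 0`
#' with `DV` (mg/L). Covariates are repeated on every row; missing values
#' are written as `.` in the pharmacometric convention. Times are hours
#' from first dose.
#'
#' @param study a [pk_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(study, path) {
  stopifnot(inherits(study, "pk_study"))
  rows <- lapply(study, function(s) {
    ev <- s$regimen$events
    cv <- s$covariates
    covcols <- lapply(.cov_map, function(nm)
      if (is.null(cv[[nm]])) NA_real_ else as.numeric(cv[[nm]]))
    names(covcols) <- names(.cov_map)
    d <- data.frame(ID = s$id, TIME = c(ev$time, s$obs$time),
                    EVID = c(rep(1L, nrow(ev)), rep(0L, nrow(s$obs))),
                    AMT = c(ev$amount, rep(NA_real_, nrow(s$obs))),
                    DUR = c(ev$duration, rep(NA_real_, nrow(s$obs))),
                    DV = c(rep(NA_real_, nrow(ev)), s$obs$dv))
    for (nm in names(covcols)) d[[nm]] <- covcols[[nm]]
    # stable ordering: by time, observations before a simultaneous dose
    d[order(d$TIME, d$EVID), ]
  })
  out <- do.call(rbind, rows)
  out <- out[, .dataset_cols]
  for (nm in names(out)) {
    v <- out[[nm]]
    fmt <- if (is.numeric(v))
      format(v, trim = TRUE, scientific = FALSE, digits = 10)
    else as.character(v)
    out[[nm]] <- ifelse(is.na(v), ".", fmt)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rectangular event-row CSV into a study
#'
#' Validates the layout and reports every offending row: mandatory columns
#' present, non-negative and within-subject non-decreasing times, positive
#' dose amounts, and no observation before the subject's first dose.
#'
#' @param path CSV path as written by [write_dataset()].
#' @return A [pk_study()].
#' @export
read_dataset <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = TRUE)
  missing <- setdiff(.required_cols, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  d <- data.frame(ID = raw$ID, TIME = num(raw$TIME),
                  EVID = num(raw$EVID), AMT = num(raw$AMT),
                  DUR = num(raw$DUR), DV = num(raw$DV))
  for (nm in intersect(names(.cov_map), names(raw)))
    d[[nm]] <- num(raw[[nm]])
  errs <- character()
  bad <- function(rows, msg) {
    if (length(rows))
      errs <<- c(errs, sprintf("row %d: %s", rows, msg))
  }
  bad(which(!is.finite(d$TIME)), "missing or non-numeric TIME")
  bad(which(is.finite(d$TIME) & d$TIME < 0), "negative TIME")
  bad(which(!d$EVID %in% c(0, 1)), "EVID must be 0 or 1")
  bad(which(d$EVID == 1 & (!is.finite(d$AMT) | d$AMT <= 0)),
      "dose row needs positive AMT")
  bad(which(d$EVID == 0 & !is.finite(d$DV)),
      "observation row needs numeric DV")
  for (id in unique(d$ID)) {
    rows <- which(d$ID == id)
    tt <- d$TIME[rows]
    if (any(diff(tt[is.finite(tt)]) < -1e-9))
      bad(rows[which(diff(tt) < -1e-9) + 1L],
          "TIME decreases within subject")
    obs <- rows[d$EVID[rows] == 0]
    doses <- rows[d$EVID[rows] == 1]
    if (length(obs)) {
      first_dose <- if (length(doses)) min(d$TIME[doses]) else Inf
      bad(obs[d$TIME[obs] < first_dose],
          "observation without a prior dose")
    }
  }
  if (length(errs))
    stop("dataset validation failed:\n  ", paste(errs, collapse = "\n  "))
  subjects <- lapply(unique(d$ID), function(id) {
    di <- d[d$ID == id, ]
    doses <- di[di$EVID == 1, ]
    obs <- di[di$EVID == 0, ]
    covs <- lapply(names(.cov_map), function(nm)
      if (nm %in% names(di)) di[[nm]][1] else NA_real_)
    names(covs) <- unname(.cov_map[names(.cov_map)])
    covs <- covs[!vapply(covs, is.na, TRUE)]
    horizon <- max(doses$TIME + ifelse(is.finite(doses$DUR), doses$DUR, 0),
                   obs$TIME)
    list(id = id, covariates = covs,
         regimen = regimen(doses$TIME, doses$AMT,
                           ifelse(is.finite(doses$DUR), doses$DUR, 0),
                           horizon = horizon),
         obs = data.frame(time = obs$TIME, dv = obs$DV))
  })
  pk_study(subjects)
}

#' Write a fit report
#'
#' Produces a plain-text run record (`fit.txt`) and a machine-readable
#' `fit.json` holding the estimates, standard errors, OFV and convergence
#' details.
#'
#' @param fit a [foce_fit()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "pkfit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(dir, "fit.txt")
  con <- file(txt, "w")
  sink(con)
  on.exit({ sink(); close(con) })
  summary(fit)
  sink(); close(con); on.exit()
  est <- .natural_coefs(fit$model)
  obj <- list(ofv = fit$ofv, convergence = fit$convergence,
              message = fit$message, boundary = fit$boundary,
              n_subjects = length(fit$data), n_obs = fit$n_obs,
              estimates = as.list(est),
              se = if (!is.null(fit$se)) fit$se else NULL,
              etas = as.data.frame(fit$etas))
  jsonlite::write_json(obj, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
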