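#' Dosing regimen
#'
#' A regimen is an ordered set of intravenous dose events plus a simulation
#' horizon. Each event has a start time (h), an amount (mg) and an infusion
#' duration (h); `duration = 0` denotes an instantaneous bolus, `duration > 0`
#' a zero-order infusion of the full amount over that duration.
#'
#' @param time numeric vector of dose start times (h), all `>= 0`.
#' @param amount numeric vector of dose amounts (mg), all `> 0`. Recycled
#'   against `time`.
#' @param duration numeric vector of infusion durations (h), all `>= 0`.
#'   Recycled against `time`.
#' @param horizon simulation end time (h). Every dose event must end
#'   (`time + duration`) at or before the horizon. Defaults to the end of the
#'   last event.
#' @return An object of class `"regimen"`: a list with elements `events`
#'   (a data frame with columns `time`, `amount`, `duration`, sorted by
#'   `time`) and `horizon`.
#' @examples
#' # 1.2 g bolus every 4 h for 24 h
#' reg <- regimen(time = seq(0, 20, by = 4), amount = 1200, horizon = 24)
#' reg
#' @export
regimen <- function(time, amount, duration = 0, horizon = NULL) {
  if (!length(time)) stop("a regimen needs at least one dose event")
  n <- max(length(time), length(amount), length(duration))
  time <- rep_len(as.numeric(time), n)
  amount <- rep_len(as.numeric(amount), n)
  duration <- rep_len(as.numeric(duration), n)
  if (any(!is.finite(time)) || any(time < 0))
    stop("dose start times must be finite and >= 0")
  if (any(!is.finite(amount)) || any(amount <= 0))
    stop("dose amounts must be finite and > 0")
  if (any(!is.finite(duration)) || any(duration < 0))
    stop("infusion durations must be finite and >= 0")
  o <- order(time, duration)
  ev <- data.frame(time = time[o], amount = amount[o], duration = duration[o])
  end <- max(ev$time + ev$duration)
  if (is.null(horizon)) horizon <- end
  horizon <- as.numeric(horizon)
  if (!is.finite(horizon) || horizon <= 0)
    stop("horizon must be finite and > 0")
  if (end > horizon + 1e-12)
    stop("every dose event must end at or before the horizon")
  structure(list(events = ev, horizon = horizon), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Dosing regimen: %d event(s), horizon %.3g h\n",
              nrow(x$events), x$horizon))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.regimen <- function(x, ...) x$events

#' Total administered dose of a regimen
#' @param x a [regimen()].
#' @return Total amount (mg) over all events.
#' @export
total_dose <- function(x) {
  stopifnot(inherits(x, "regimen"))
  sum(x$events$amount)
}

#' Read or write a regimen as YAML
#'
#' The on-disk schema is a mapping with `horizon_h` and a list `events` of
#' `{time_h, amount_mg, duration_h}` entries.
#'
#' @param x a [regimen()].
#' @param path file path.
#' @return `read_regimen` returns a [regimen()]; `write_regimen` returns
#'   `path` invisibly.
#' @export
write_regimen <- function(x, path) {
  stopifnot(inherits(x, "regimen"))
  obj <- list(
    horizon_h = x$horizon,
    events = lapply(seq_len(nrow(x$events)), function(i)
      list(time_h = x$events$time[i], amount_mg = x$events$amount[i],
           duration_h = x$events$duration[i]))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_regimen
#' @export
read_regimen <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$events) || is.null(obj$horizon_h))
    stop("regimen file must contain 'events' and 'horizon_h'")
  regimen(time = vapply(obj$events, `[[`, 0, "time_h"),
          amount = vapply(obj$events, `[[`, 0, "amount_mg"),
          duration = vapply(obj$events, `[[`, 0, "duration_h"),
          horizon = obj$horizon_h)
}
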