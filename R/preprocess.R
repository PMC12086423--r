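#' Drop the initial hours of a wear period
#'
#' Readings from the first hours after sensor insertion are discarded
#' (default 12 h) because fresh-sensor readings are unreliable. Removal is
#' half-open: samples with `time < first_time + hours` go, the remainder is
#' untouched.
#'
#' @param trace a [glucose_trace].
#' @param hours hours to trim from the start (default 12).
#' @return The trimmed [glucose_trace].
#' @export
trim_initial <- function(trace, hours = 12) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  keep <- as.numeric(difftime(trace$time, trace$time[1], units = "hours")) >=
    hours
  trace_like(trace, keep)
}

#' Implausibility rules for CGM readings
#'
#' Three sensor-artifact detectors, all configurable:
#' * flat-line: runs of identical consecutive values lasting at least
#'   `flat_hours` (a live sensor on a 5-min cadence essentially never
#'   repeats the same value for hours);
#' * jump: absolute rate of change between adjacent samples above
#'   `jump_per_min` mg/dL per minute (both endpoints flagged);
#' * rail: runs pinned at the 40 or 400 mg/dL reporting limits for at least
#'   `rail_minutes`.
#'
#' @param flat_hours minimum duration of an identical-value run to flag.
#' @param jump_per_min maximum plausible rate of change, mg/dL per minute.
#' @param rail_minutes minimum duration pinned at a reporting rail to flag.
#' @export
implausibility_rules <- function(flat_hours = 3, jump_per_min = 15,
                                 rail_minutes = 30) {
  stopifnot(flat_hours > 0, jump_per_min > 0, rail_minutes > 0)
  structure(list(flat_hours = flat_hours, jump_per_min = jump_per_min,
                 rail_minutes = rail_minutes),
            class = "implausibility_rules")
}

# flag runs (by rle over a logical/identity grouping) whose spanned duration
# meets `min_hours`
flag_runs <- function(time, same, min_hours) {
  n <- length(same)
  flags <- rep(FALSE, n)
  r <- rle(same)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    span <- as.numeric(difftime(time[ends[j]], time[starts[j]],
                                units = "hours"))
    if (span >= min_hours) flags[starts[j]:ends[j]] <- TRUE
  }
  flags
}

#' Flag implausible readings in a trace
#'
#' @param trace a [glucose_trace] (normally already trimmed).
#' @param rules an [implausibility_rules].
#' @return The trace with its `flag` column updated (`TRUE` = implausible).
#' @export
flag_implausible <- function(trace, rules = implausibility_rules()) {
  stopifnot(inherits(trace, "glucose_trace"),
            inherits(rules, "implausibility_rules"))
  n <- nrow(trace)
  if (n == 0) return(trace)
  flags <- trace$flag

  # flat-line: identical-value runs; group ids change whenever value changes
  if (n > 1) {
    grp <- cumsum(c(TRUE, diff(trace$glucose) != 0))
    r <- rle(grp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      span <- as.numeric(difftime(trace$time[ends[j]], trace$time[starts[j]],
                                  units = "hours"))
      if (span >= rules$flat_hours) flags[starts[j]:ends[j]] <- TRUE
    }
    # jump: rate of change between adjacent samples
    dt_min <- diff(as.numeric(trace$time)) / 60
    rate <- abs(diff(trace$glucose)) / dt_min
    bad <- which(rate > rules$jump_per_min)
    flags[bad] <- TRUE
    flags[bad + 1L] <- TRUE
  }
  # rail-pinning at the reporting limits
  flags <- flags | flag_runs(trace$time, trace$glucose <= 40,
                             rules$rail_minutes / 60)
  flags <- flags | flag_runs(trace$time, trace$glucose >= 400,
                             rules$rail_minutes / 60)
  trace$flag <- flags
  trace
}

#' Quality-control filter for one wear period
#'
#' The inclusion pipeline: trim the initial hours, flag implausible
#' readings, drop flagged samples, then require strictly more than
#' `min_hours` of retained wear. Wear time is counted as retained samples
#' times the nominal cadence, so recording gaps do not count. Traces whose
#' flagged fraction (of the trimmed trace) exceeds `bulk_limit` are excluded
#' outright as bulk-implausible.
#'
#' @param trace a [glucose_trace].
#' @param trim_hours initial hours to discard (default 12).
#' @param rules an [implausibility_rules].
#' @param min_hours minimum retained hours, exclusive bound (default 96).
#' @param bulk_limit maximum tolerated flagged fraction (default 0.2).
#' @return A list of class `qc_result`: `trace` (cleaned), `hours_removed_initial`,
#'   `implausible_fraction`, `remaining_hours`, `included`,
#'   `exclusion_reason` (`"none"`, `"short_wear"` or `"implausible_bulk"`).
#' @export
qc_filter <- function(trace, trim_hours = 12,
                      rules = implausibility_rules(),
                      min_hours = 96, bulk_limit = 0.2) {
  stopifnot(inherits(trace, "glucose_trace"))
  n_raw <- nrow(trace)
  trimmed <- if (n_raw > 0) trim_initial(trace, trim_hours) else trace
  flagged <- flag_implausible(trimmed, rules)
  n_trim <- nrow(flagged)
  frac <- if (n_trim > 0) mean(flagged$flag) else 0
  clean <- trace_like(flagged, !flagged$flag)
  remaining <- nrow(clean) * attr(trace, "interval_min") / 60
  bulk <- frac > bulk_limit
  included <- remaining > min_hours && !bulk
  reason <- if (included) {
    "none"
  } else if (bulk) {
    "implausible_bulk"
  } else {
    "short_wear"
  }
  structure(list(trace = clean,
                 participant_id = attr(trace, "participant_id"),
                 session_id = attr(trace, "session_id"),
                 hours_removed_initial = (n_raw - n_trim) *
                   attr(trace, "interval_min") / 60,
                 implausible_fraction = frac,
                 remaining_hours = remaining,
                 included = included,
                 exclusion_reason = reason),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %s/%s: %.1f h retained, %s%s\n",
              x$participant_id, x$session_id, x$remaining_hours,
              if (x$included) "included" else "excluded",
              if (x$included) "" else paste0(" (", x$exclusion_reason, ")")))
  invisible(x)
}

#' Run QC over a list of traces
#'
#' @param traces list of [glucose_trace].
#' @inheritParams qc_filter
#' @return A list with `results` (list of `qc_result`) and `report`
#'   (data frame, one row per trace).
#' @export
qc_cohort <- function(traces, trim_hours = 12,
                      rules = implausibility_rules(),
                      min_hours = 96, bulk_limit = 0.2) {
  results <- lapply(traces, qc_filter, trim_hours = trim_hours,
                    rules = rules, min_hours = min_hours,
                    bulk_limit = bulk_limit)
  report <- do.call(rbind, lapply(results, function(r) {
    data.frame(participant_id = r$participant_id,
               session_id = r$session_id,
               hours_removed_initial = r$hours_removed_initial,
               implausible_fraction = r$implausible_fraction,
               remaining_hours = r$remaining_hours,
               included = r$included,
               exclusion_reason = r$exclusion_reason)
  }))
  list(results = results, report = report)
}
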