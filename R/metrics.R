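#' Percentage of time above a glucose threshold
#'
#' Sample-count proportion of readings strictly above `threshold`, in
#' percent. After quality control the cadence is uniform, so the proportion
#' of samples is the proportion of wear time.
#'
#' @param trace a [glucose_trace].
#' @param threshold mg/dL; comparison is strict (`>`).
#' @return percentage in `[0, 100]`.
#' @export
time_above <- function(trace, threshold) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  100 * mean(trace$glucose > threshold)
}

#' Percentage of time below a glucose threshold
#'
#' @inheritParams time_above
#' @param threshold mg/dL; comparison is strict (`<`).
#' @export
time_below <- function(trace, threshold) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  100 * mean(trace$glucose < threshold)
}

#' Mean nocturnal glucose (0300-0600)
#'
#' Arithmetic mean of readings whose local clock time falls in the
#' half-open window \[03:00, 06:00), pooled across all nights of the wear
#' (set `pooled = FALSE` to average nightly means instead). This window is
#' expected to approach fasting levels, which makes it a probe of additive
#' sensor offsets.
#'
#' @param trace a [glucose_trace].
#' @param pooled pool samples across nights (default) or average per-night
#'   means.
#' @return mg/dL.
#' @export
nocturnal_mean <- function(trace, pooled = TRUE) {
  stopifnot(inherits(trace, "glucose_trace"))
  hr <- as.numeric(format(trace$time, "%H")) +
    as.numeric(format(trace$time, "%M")) / 60 +
    as.numeric(format(trace$time, "%S")) / 3600
  win <- hr >= 3 & hr < 6
  if (!any(win)) stop("no readings in the 0300-0600 window")
  if (pooled) return(mean(trace$glucose[win]))
  night <- format(trace$time[win], "%Y-%m-%d")
  mean(tapply(trace$glucose[win], night, mean))
}

#' Compute the per-trace CGM metric suite
#'
#' Summarizes one QC-passed wear period into the standard discriminating
#' parameters: mean, SD (population denominator `n`), coefficient of
#' variation (100 * SD / mean), maximum, percentage of time above 140, 160,
#' 180 and 200 mg/dL (strict `>`), percentage of time below 80 and
#' 100 mg/dL (strict `<`), nocturnal 0300-0600 mean, retained wear hours
#' and days of data (hours / 24).
#'
#' @param trace a [glucose_trace] that passed QC (flagged samples already
#'   dropped); must have at least one reading in the nocturnal window.
#' @param pooled_nocturnal see [nocturnal_mean()].
#' @return A one-row data frame with columns `participant_id`, `session_id`,
#'   `lot_id`, `mean_glucose`, `sd_glucose`, `cv`, `max_glucose`, `ta140`,
#'   `ta160`, `ta180`, `ta200`, `tb80`, `tb100`, `nocturnal_mean`,
#'   `wear_hours`, `days_of_data`.
#' @export
compute_metrics <- function(trace, pooled_nocturnal = TRUE) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  g <- trace$glucose
  n <- length(g)
  m <- mean(g)
  sdp <- sqrt(sum((g - m)^2) / n)
  data.frame(
    participant_id = attr(trace, "participant_id"),
    session_id = attr(trace, "session_id"),
    lot_id = attr(trace, "lot_id"),
    mean_glucose = m,
    sd_glucose = sdp,
    cv = 100 * sdp / m,
    max_glucose = max(g),
    ta140 = time_above(trace, 140),
    ta160 = time_above(trace, 160),
    ta180 = time_above(trace, 180),
    ta200 = time_above(trace, 200),
    tb80 = time_below(trace, 80),
    tb100 = time_below(trace, 100),
    nocturnal_mean = nocturnal_mean(trace, pooled = pooled_nocturnal),
    wear_hours = n * attr(trace, "interval_min") / 60,
    days_of_data = n * attr(trace, "interval_min") / 60 / 24)
}

#' Metric table for a list of traces
#'
#' @param traces list of QC-passed [glucose_trace] objects.
#' @inheritParams compute_metrics
#' @return Data frame, one row per trace, as in [compute_metrics()].
#' @export
compute_metrics_table <- function(traces, pooled_nocturnal = TRUE) {
  do.call(rbind, lapply(traces, compute_metrics,
                        pooled_nocturnal = pooled_nocturnal))
}
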