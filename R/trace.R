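#' Construct a CGM glucose trace
#'
#' A glucose trace is one sensor wear period: a uniformly (nominally 5-minute)
#' sampled series of interstitial glucose readings in mg/dL, tagged with the
#' participant, the wear session and the sensor lot. Timestamps are local
#' clock time, stored timezone-naive (internally UTC) so that clock-time
#' logic such as the nocturnal 0300-0600 window is unaffected by daylight
#' saving.
#'
#' @param participant_id character scalar.
#' @param session_id character scalar identifying the wear period.
#' @param lot_id character scalar, sensor lot.
#' @param time `POSIXct` vector of reading timestamps, strictly increasing.
#' @param glucose numeric vector of glucose readings, mg/dL.
#' @param flag optional logical vector of per-sample QC flags (`TRUE` =
#'   implausible); defaults to all `FALSE`.
#'
#' @return An object of class `glucose_trace`: a data frame with columns
#'   `time`, `glucose`, `flag` and attributes `participant_id`, `session_id`,
#'   `lot_id`, `interval_min` (nominal cadence, minutes).
#' @export
glucose_trace <- function(participant_id, session_id, lot_id, time, glucose,
                          flag = NULL) {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  if (length(time) != length(glucose)) stop("`time` and `glucose` lengths differ")
  if (length(time) > 1L && any(diff(as.numeric(time)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (is.null(flag)) flag <- rep(FALSE, length(glucose))
  if (length(flag) != length(glucose)) stop("`flag` length mismatch")
  interval <- if (length(time) > 1L) {
    min(diff(as.numeric(time))) / 60
  } else {
    5
  }
  out <- data.frame(time = time, glucose = as.numeric(glucose),
                    flag = as.logical(flag))
  structure(out,
            participant_id = as.character(participant_id),
            session_id = as.character(session_id),
            lot_id = as.character(lot_id),
            interval_min = interval,
            class = c("glucose_trace", "data.frame"))
}

# keep trace attributes after row subsetting
trace_like <- function(template, rows) {
  out <- as.data.frame(template)[rows, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            participant_id = attr(template, "participant_id"),
            session_id = attr(template, "session_id"),
            lot_id = attr(template, "lot_id"),
            interval_min = attr(template, "interval_min"),
            class = c("glucose_trace", "data.frame"))
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<glucose_trace> participant %s, session %s, lot %s\n",
              attr(x, "participant_id"), attr(x, "session_id"),
              attr(x, "lot_id")))
  cat(sprintf("  %d readings at %g-min cadence (%.1f h), %d flagged\n",
              n, attr(x, "interval_min"),
              n * attr(x, "interval_min") / 60, sum(x$flag)))
  if (n > 0) {
    cat(sprintf("  %s .. %s, glucose %g-%g mg/dL\n",
                format(x$time[1]), format(x$time[n]),
                min(x$glucose), max(x$glucose)))
  }
  invisible(x)
}

#' Read and write CGM traces as plain CSV
#'
#' The native layout has one row per reading with columns `participant_id`,
#' `session_id`, `lot_id`, `timestamp` (ISO 8601, local clock time) and
#' `glucose_mg_dl`. `read_cgm_csv()` also accepts a Dexcom-G6-export-like
#' layout (`dialect = "dexcom"`): header preamble rows are skipped and only
#' estimated glucose value (EGV) rows are parsed, with the out-of-range
#' markers "Low"/"High" mapped to the 40/400 mg/dL reporting rails.
#'
#' @param path file path.
#' @param dialect `"native"` or `"dexcom"`.
#' @param participant_id,session_id,lot_id identifiers to attach when the
#'   dialect does not carry them (Dexcom exports identify the patient in the
#'   preamble, not per row).
#' @return `read_cgm_csv()`: a list of [glucose_trace] objects (one per
#'   participant/session pair). `write_cgm_csv()`: the path, invisibly.
#' @export
read_cgm_csv <- function(path, dialect = c("native", "dexcom"),
                         participant_id = "P1", session_id = "S1",
                         lot_id = "unknown") {
  dialect <- match.arg(dialect)
  if (dialect == "dexcom") {
    raw <- utils::read.csv(path, check.names = FALSE,
                           colClasses = "character")
    type_col <- grep("Event Type", names(raw), value = TRUE)[1]
    ts_col <- grep("Timestamp", names(raw), value = TRUE)[1]
    glu_col <- grep("Glucose Value", names(raw), value = TRUE)[1]
    if (any(is.na(c(type_col, ts_col, glu_col)))) {
      stop("not a recognizable Dexcom export: need Event Type, Timestamp and Glucose Value columns")
    }
    egv <- raw[raw[[type_col]] == "EGV", , drop = FALSE]
    g <- egv[[glu_col]]
    g[g == "Low"] <- "40"
    g[g == "High"] <- "400"
    tm <- as.POSIXct(egv[[ts_col]], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ord <- order(tm)
    return(list(glucose_trace(participant_id, session_id, lot_id,
                              tm[ord], as.numeric(g[ord]))))
  }
  df <- utils::read.csv(path, colClasses = c(participant_id = "character",
                                             session_id = "character",
                                             lot_id = "character"))
  needed <- c("participant_id", "session_id", "lot_id", "timestamp",
              "glucose_mg_dl")
  if (!all(needed %in% names(df))) {
    stop("missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  key <- paste(df$participant_id, df$session_id, sep = "\r")
  lapply(split(df, key), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    glucose_trace(d$participant_id[1], d$session_id[1], d$lot_id[1],
                  d$timestamp, d$glucose_mg_dl)
  })
}

#' @rdname read_cgm_csv
#' @param traces a [glucose_trace] or list of them.
#' @export
write_cgm_csv <- function(traces, path) {
  if (inherits(traces, "glucose_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(participant_id = attr(tr, "participant_id"),
               session_id = attr(tr, "session_id"),
               lot_id = attr(tr, "lot_id"),
               timestamp = format(tr$time, "%Y-%m-%dT%H:%M:%S"),
               glucose_mg_dl = tr$glucose)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert mg/dL to mmol/L for display
#'
#' All computation in the package is in mg/dL; this helper is for reports
#' only (divides by 18.016 and rounds to one decimal).
#' @param x glucose in mg/dL.
#' @export
mgdl_to_mmol <- function(x) round(x / 18.016, 1)

# round-half-up to `digits`, used for report-style integer percentages
# (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
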