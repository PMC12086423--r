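#' Control-anchored 100 %-specificity thresholds
#'
#' For each requested CGM metric the cutoff is the maximum observed among
#' the control traces, and a case is flagged only when its value is
#' strictly greater than the cutoff. By construction no derivation control
#' is ever flagged, so the rule has specificity 1.0 on the controls it was
#' anchored to — the "100 % specificity threshold" reading. Cutoffs are
#' kept exact (not rounded); rounded displays are for reports only.
#'
#' @param control_metrics data frame of control-trace metrics (one row per
#'   control, as from [compute_metrics_table()]).
#' @param metric_names metrics to threshold; the default set is the four
#'   parameters that discriminate early-stage type 1 diabetes (glucose SD
#'   and time above 140/160/180 mg/dL).
#' @return An object of class `cgm_thresholds`: named cutoff vector,
#'   flag direction (greater), and provenance (number of controls).
#' @export
derive_thresholds <- function(control_metrics,
                              metric_names = c("sd_glucose", "ta140",
                                               "ta160", "ta180")) {
  if (NROW(control_metrics) < 1) stop("at least one control is required")
  missing <- setdiff(metric_names, names(control_metrics))
  if (length(missing)) {
    stop("metrics absent from control table: ",
         paste(missing, collapse = ", "))
  }
  cuts <- vapply(metric_names, function(m) {
    v <- control_metrics[[m]]
    if (anyNA(v)) stop("NA in control metric ", m)
    max(v)
  }, numeric(1))
  structure(list(cutoffs = cuts,
                 direction = "greater",
                 n_controls = NROW(control_metrics)),
            class = "cgm_thresholds")
}

#' @export
print.cgm_thresholds <- function(x, ...) {
  cat(sprintf("100%%-specificity thresholds (anchored on %d controls; flag if value > cutoff)\n",
              x$n_controls))
  for (m in names(x$cutoffs)) {
    cat(sprintf("  %-12s > %.6g  (%.1f rounded)\n", m, x$cutoffs[[m]],
                round(x$cutoffs[[m]], 1)))
  }
  invisible(x)
}

#' Number of metrics above their thresholds
#'
#' @param metrics one row (or a data frame) of CGM metrics.
#' @param thresholds a [derive_thresholds()] object.
#' @return Integer vector: per row, how many thresholded metrics are
#'   strictly above their cutoff.
#' @export
count_elevated <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "cgm_thresholds"))
  missing <- setdiff(names(thresholds$cutoffs), names(metrics))
  if (length(missing)) {
    stop("metrics missing: ", paste(missing, collapse = ", "))
  }
  flags <- vapply(names(thresholds$cutoffs), function(m) {
    metrics[[m]] > thresholds$cutoffs[[m]]
  }, logical(NROW(metrics)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1)
  as.integer(rowSums(flags))
}

#' Any-k-of-m threshold rule
#'
#' Positive when at least `k` of the thresholded metrics are strictly above
#' their control-anchored cutoffs. The default `k = 2` is the
#' "any 2 parameters elevated" rule.
#'
#' @inheritParams count_elevated
#' @param k minimum number of elevated metrics (default 2).
#' @return Logical vector, one per metric row.
#' @export
any_k_rule <- function(metrics, thresholds, k = 2) {
  stopifnot(inherits(thresholds, "cgm_thresholds"))
  if (k < 1) stop("k must be at least 1")
  if (k > length(thresholds$cutoffs)) {
    stop("k exceeds the number of thresholded metrics")
  }
  count_elevated(metrics, thresholds) >= k
}

#' @export
#' @describeIn derive_thresholds per-metric flags, elevated counts and the
#'   any-k rule for new metric rows.
#' @param object a `cgm_thresholds` object.
#' @param newdata data frame of metric rows to classify.
#' @param k minimum elevated metrics for the combined rule.
#' @param ... unused.
predict.cgm_thresholds <- function(object, newdata, k = 2, ...) {
  flags <- vapply(names(object$cutoffs), function(m) {
    newdata[[m]] > object$cutoffs[[m]]
  }, logical(NROW(newdata)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1,
                                           dimnames = list(NULL, names(object$cutoffs)))
  out <- as.data.frame(flags)
  names(out) <- paste0("flag_", names(object$cutoffs))
  out$n_elevated <- as.integer(rowSums(flags))
  out$any_k <- out$n_elevated >= k
  out
}
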