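#' Confusion-matrix statistics
#'
#' Cross-tabulates a binary classifier against a binary outcome and reports
#' sensitivity, specificity, positive and negative predictive value as
#' exact percentages, with report-style integer rounding (half-up)
#' alongside. Ratios with a zero denominator are `NA`, never 0.
#'
#' @param flags logical vector, classifier positives.
#' @param outcomes logical vector, true positives.
#' @return A list of class `confusion_stats` with counts (`tp`, `fp`, `fn`,
#'   `tn`), exact percentages (`sensitivity`, `specificity`, `ppv`, `npv`)
#'   and their half-up integer roundings in `$rounded`.
#' @export
confusion_stats <- function(flags, outcomes) {
  if (length(flags) != length(outcomes)) stop("length mismatch")
  if (length(flags) < 1) stop("empty input")
  flags <- as.logical(flags); outcomes <- as.logical(outcomes)
  tp <- sum(flags & outcomes)
  fp <- sum(flags & !outcomes)
  fn <- sum(!flags & outcomes)
  tn <- sum(!flags & !outcomes)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  ex <- list(sensitivity = ratio(tp, tp + fn),
             specificity = ratio(tn, tn + fp),
             ppv = ratio(tp, tp + fp),
             npv = ratio(tn, tn + fn))
  structure(c(list(tp = tp, fp = fp, fn = fn, tn = tn), ex,
              list(rounded = lapply(ex, function(x) {
                if (is.na(x)) NA_real_ else round_half_up(x)
              }))),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("sensitivity %s%%  specificity %s%%  PPV %s%%  NPV %s%%\n",
              x$rounded$sensitivity, x$rounded$specificity,
              x$rounded$ppv, x$rounded$npv))
  invisible(x)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' Higher scores indicate cases. The AUC is computed as the Mann-Whitney
#' U statistic divided by `n_case * n_control`, with midrank handling of
#' ties, and its confidence interval from the DeLong placement-value
#' variance.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1): `TRUE` = case.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `roc_result`: `thresholds`, `sensitivity` and
#'   `fpr` vectors describing the curve (positive when score > threshold),
#'   `auc`, `ci` and the group sizes.
#' @export
roc_curve <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  x <- scores[labels]   # cases
  y <- scores[!labels]  # controls
  n1 <- length(x); n0 <- length(y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")

  r <- rank(c(x, y))  # midranks
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong placements
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  var_auc <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
    (if (n0 > 1) stats::var(v01) / n0 else 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(var_auc), 0), 1)

  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(x > t), 0)
  fpr <- vapply(thr, function(t) mean(y > t), 0)
  structure(list(thresholds = thr, sensitivity = sens, fpr = fpr,
                 auc = auc, ci = ci, var_auc = var_auc,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f); %d cases vs %d controls\n",
              x$auc, x$ci[1], x$ci[2], x$n_case, x$n_control))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  ord <- order(x$fpr, x$sensitivity)
  graphics::plot(x$fpr[ord], x$sensitivity[ord], type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Kaplan-Meier cumulative risk at a horizon
#'
#' Product-limit estimate of progression-free survival with Greenwood
#' standard errors; the cumulative risk is `1 - S(horizon)` with a linear
#' ("plain") confidence interval clipped to \[0, 100\] %.
#'
#' @param times observed times, years.
#' @param events event indicators (logical/0-1).
#' @param horizon years (default 1).
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `km_curve`: the step-function grid (`time`,
#'   `surv`, `std_err`, `n_risk`, `n_event`), `risk_pct` at the horizon and
#'   its CI in percent.
#' @export
km_estimate <- function(times, events, horizon = 1, conf_level = 0.95) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "plain", conf.int = conf_level)
  at <- summary(fit, times = horizon, extend = TRUE)
  s <- at$surv
  lo <- if (is.null(at$lower) || is.na(at$lower)) s else at$lower
  hi <- if (is.null(at$upper) || is.na(at$upper)) s else at$upper
  structure(list(time = fit$time, surv = fit$surv,
                 std_err = fit$surv * fit$std.err,  # Greenwood SE of S
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 horizon = horizon,
                 surv_at_horizon = s,
                 risk_pct = 100 * (1 - s),
                 risk_ci_pct = 100 * pmin(pmax(c(1 - hi, 1 - lo), 0), 1)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier risk at %g y: %.1f%% (95%% CI %.1f-%.1f)\n",
              x$horizon, x$risk_pct, x$risk_ci_pct[1], x$risk_ci_pct[2]))
  invisible(x)
}

#' Log-rank test across groups
#'
#' @param times observed times.
#' @param events event indicators.
#' @param group group membership (>= 2 non-empty groups).
#' @return A list: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("at least two non-empty groups required")
  sd_ <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(sd_$n) - 1
  list(chisq = sd_$chisq, df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Group comparison table for CGM metrics
#'
#' Table-1-style summary: per metric, the median (IQR) per group, a
#' Kruskal-Wallis test across all groups and pairwise Mann-Whitney tests;
#' categorical variables are compared with the chi-square test, or Fisher's
#' exact test when any expected cell count is below 5. All tests two-sided.
#'
#' @param data data frame.
#' @param group name of the grouping column.
#' @param metrics character vector of numeric columns.
#' @param categorical character vector of categorical columns (optional).
#' @return A list with `continuous` and `categorical` data frames of
#'   summaries and p-values (pairwise columns named `p_<g1>_vs_<g2>`).
#' @export
group_compare <- function(data, group, metrics, categorical = character()) {
  g <- as.factor(droplevels(as.factor(data[[group]])))
  if (nlevels(g) < 2) stop("at least two groups required")
  if (any(table(g) == 0)) stop("empty group")
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)

  cont <- do.call(rbind, lapply(metrics, function(m) {
    v <- data[[m]]
    row <- data.frame(variable = m)
    for (l in lv) {
      q <- stats::quantile(v[g == l], c(0.25, 0.5, 0.75), na.rm = TRUE)
      row[[paste0("median_", l)]] <- q[2]
      row[[paste0("iqr_", l)]] <- sprintf("%.1f-%.1f", q[1], q[3])
    }
    row$p_kruskal <- stats::kruskal.test(v, g)$p.value
    for (pr in pairs) {
      sub <- g %in% pr
      row[[paste0("p_", pr[1], "_vs_", pr[2])]] <-
        stats::wilcox.test(v[sub] ~ droplevels(g[sub]), exact = FALSE)$p.value
    }
    row
  }))

  cat_tab <- NULL
  if (length(categorical)) {
    cat_tab <- do.call(rbind, lapply(categorical, function(m) {
      v <- as.factor(data[[m]])
      row <- data.frame(variable = m)
      for (l in lv) {
        row[[paste0("n_", l)]] <- paste(table(v[g == l]), collapse = "/")
      }
      for (pr in pairs) {
        sub <- g %in% pr
        tab <- table(droplevels(g[sub]), droplevels(v[sub]))
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        p <- if (any(expected < 5)) {
          stats::fisher.test(tab)$p.value
        } else {
          stats::chisq.test(tab, correct = FALSE)$p.value
        }
        row[[paste0("p_", pr[1], "_vs_", pr[2])]] <- p
      }
      row
    }))
  }
  list(continuous = cont, categorical = cat_tab)
}

#' Correlation of the nocturnal mean with variability metrics
#'
#' Correlates the 0300-0600 mean glucose with TA140, SD and CV across
#' traces. A strong nocturnal-TA140 correlation together with a null
#' nocturnal-CV correlation is the signature of additive (not
#' multiplicative) between-sensor shifts: an additive offset moves the mean
#' and the time-above-range but leaves SD (hence barely CV) untouched.
#'
#' @param metrics metric table (needs `nocturnal_mean`, `ta140`,
#'   `sd_glucose`, `cv`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame: one row per metric with `r` and `p_value`.
#' @export
offset_correlations <- function(metrics, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (NROW(metrics) < 3) stop("at least 3 rows required")
  targets <- c("ta140", "sd_glucose", "cv")
  x <- metrics$nocturnal_mean
  if (stats::sd(x) == 0) stop("nocturnal_mean is constant")
  do.call(rbind, lapply(targets, function(m) {
    v <- metrics[[m]]
    if (stats::sd(v) == 0) stop("constant column: ", m)
    ct <- stats::cor.test(x, v, method = method, exact = FALSE)
    data.frame(metric = m, r = unname(ct$estimate), p_value = ct$p.value)
  }))
}

#' Paired-wear repeatability report
#'
#' For participants with exactly two QC-passed wear sessions: the
#' second-minus-first difference of every metric, per-threshold flag
#' concordance, concordance of the any-k rule, and the count of
#' participants whose mean glucose moved by more than `delta_mean` mg/dL
#' between wears.
#'
#' @param metrics metric table containing both sessions (rows identified by
#'   `participant_id` and `session_id`).
#' @param thresholds a [derive_thresholds()] object.
#' @param k any-k rule parameter (default 2).
#' @param delta_mean mg/dL change in mean glucose counted as discordant
#'   (default 10).
#' @return A list: `pairs` (per-participant differences and concordance),
#'   `n_pairs`, `n_delta_mean_gt` and `frac_delta_mean_gt` (mean-shift
#'   counts), `any_k_concordance` (fraction of pairs with the same any-k
#'   call in both wears).
#' @export
repeatability_report <- function(metrics, thresholds, k = 2,
                                 delta_mean = 10) {
  stopifnot(inherits(thresholds, "cgm_thresholds"))
  counts <- table(metrics$participant_id)
  ids <- names(counts)[counts == 2]
  if (!length(ids)) stop("no participant has exactly two sessions")
  met_cols <- intersect(c("mean_glucose", "sd_glucose", "cv", "max_glucose",
                          "ta140", "ta160", "ta180", "ta200", "tb80",
                          "tb100", "nocturnal_mean"), names(metrics))
  rows <- lapply(ids, function(id) {
    sub <- metrics[metrics$participant_id == id, ]
    sub <- sub[order(sub$session_id), ]
    d <- as.data.frame(as.list(
      stats::setNames(unlist(sub[2, met_cols]) - unlist(sub[1, met_cols]),
                      paste0("delta_", met_cols))))
    p1 <- predict(thresholds, sub[1, ], k = k)
    p2 <- predict(thresholds, sub[2, ], k = k)
    flag_cols <- grep("^flag_", names(p1), value = TRUE)
    conc <- mean(unlist(p1[flag_cols]) == unlist(p2[flag_cols]))
    cbind(data.frame(participant_id = id), d,
          data.frame(flag_concordance = conc,
                     any_k_first = p1$any_k, any_k_second = p2$any_k,
                     any_k_concordant = p1$any_k == p2$any_k))
  })
  pairs <- do.call(rbind, rows)
  n_gt <- sum(abs(pairs$delta_mean_glucose) > delta_mean)
  list(pairs = pairs,
       n_pairs = nrow(pairs),
       n_delta_mean_gt = n_gt,
       frac_delta_mean_gt = n_gt / nrow(pairs),
       any_k_concordance = mean(pairs$any_k_concordant))
}
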