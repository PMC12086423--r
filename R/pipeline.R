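#' Load and validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with any of the
#' blocks below; unknown keys are rejected so typos fail loudly.
#'
#' * `seed`: integer, required — the only source of randomness.
#' * `simulate`: arguments for [cohort_config()] (a cohort is always
#'   simulated; real-trace ingestion goes through [read_cgm_csv()] and the
#'   stage functions directly).
#' * `qc`: `trim_hours`, `min_hours`, `bulk_limit`, `flat_hours`,
#'   `jump_per_min`, `rail_minutes`.
#' * `thresholds`: `metric_names`.
#' * `rule`: `k`.
#' * `pps`: `horizon`, `cut_low`, `cut_high`.
#' * `write_traces`: logical, also dump the raw trace CSV (default FALSE).
#'
#' @param config named list or path to a YAML file.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "simulate", "qc", "thresholds", "rule", "pps",
             "write_traces")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  defaults <- list(seed = 20230101, simulate = list(),
                   qc = list(trim_hours = 12, min_hours = 96,
                             bulk_limit = 0.2, flat_hours = 3,
                             jump_per_min = 15, rail_minutes = 30),
                   thresholds = list(metric_names = c("sd_glucose", "ta140",
                                                      "ta160", "ta180")),
                   rule = list(k = 2),
                   pps = list(horizon = 1, cut_low = 0.19, cut_high = 0.4),
                   write_traces = FALSE)
  for (blk in setdiff(known, "simulate")) {
    if (!is.null(config[[blk]])) {
      if (is.list(defaults[[blk]])) {
        bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
        if (length(bad)) {
          stop("unknown keys in '", blk, "': ", paste(bad, collapse = ", "))
        }
        defaults[[blk]][names(config[[blk]])] <- config[[blk]]
      } else {
        defaults[[blk]] <- config[[blk]]
      }
    }
  }
  if (!is.null(config$simulate)) {
    bad <- setdiff(names(config$simulate), names(formals(cohort_config)))
    if (length(bad)) {
      stop("unknown keys in 'simulate': ", paste(bad, collapse = ", "))
    }
    defaults$simulate <- config$simulate
  }
  structure(defaults, class = "run_config")
}

#' Run the full staging and progression analysis end-to-end
#'
#' Simulate (or accept) a cohort, run CGM quality control, compute the
#' metric suite, stage every participant from OGTT/HbA1c, derive
#' control-anchored thresholds, apply the any-k rule, fit and apply the
#' Progression Prediction Score, and compute the evaluation statistics.
#' All tables are returned and, when `out_dir` is given, written as CSV/JSON
#' together with a manifest (config, seed, package version, config hash);
#' identical config + seed reproduce identical artifacts.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return Invisibly, a list with `cohort`, `qc`, `metrics` (all sessions),
#'   `participants` (staged, first-session metrics merged, score and
#'   classification columns), `thresholds`, `pps`, `evaluation` and
#'   `repeatability`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  cc <- do.call(cohort_config, sim_args)
  cohort <- simulate_cohort(cc)

  rules <- implausibility_rules(config$qc$flat_hours, config$qc$jump_per_min,
                                config$qc$rail_minutes)
  qc <- qc_cohort(cohort$traces, trim_hours = config$qc$trim_hours,
                  rules = rules, min_hours = config$qc$min_hours,
                  bulk_limit = config$qc$bulk_limit)
  kept <- Filter(function(r) r$included, qc$results)
  if (!length(kept)) stop("all traces excluded by quality control")
  metrics <- compute_metrics_table(lapply(kept, `[[`, "trace"))

  participants <- classify_cohort(cohort$participants)

  # first QC-passed session per participant drives the cross-sectional
  # analysis; repeat sessions feed the repeatability report
  first <- metrics[!duplicated(metrics$participant_id), ]
  df <- merge(participants, first, by = "participant_id")

  controls <- df[df$stage == "control", ]
  if (nrow(controls) == 0) {
    stop("no controls available for threshold derivation")
  }
  thr <- derive_thresholds(controls, config$thresholds$metric_names)
  cls <- predict(thr, df, k = config$rule$k)
  df <- cbind(df, cls)

  df$progressed_1yr <- progressed_within(df$followup_years,
                                         df$progressed_stage3,
                                         df$progression_time,
                                         config$pps$horizon)
  aab_pos <- df[df$stage != "control", ]
  fit_data <- aab_pos[!is.na(aab_pos$progressed_1yr), ]
  pps <- NULL
  if (nrow(fit_data) > 0 && length(unique(fit_data$progressed_1yr)) == 2) {
    form <- stats::reformulate(config$thresholds$metric_names,
                               response = "progressed_1yr")
    pps <- fit_pps(form, fit_data, horizon = config$pps$horizon)
    df$pps_score <- predict(pps, df)
    df$pps_band <- pps_band(df$pps_score, config$pps$cut_low,
                            config$pps$cut_high)
  }

  evaluation <- evaluate_run(df, thr, config)
  repeatability <- NULL
  if (any(table(metrics$participant_id) == 2)) {
    repeatability <- repeatability_report(
      metrics[metrics$participant_id %in%
                names(which(table(metrics$participant_id) == 2)), ],
      thr, k = config$rule$k)
  }

  result <- list(cohort = cohort, qc = qc, metrics = metrics,
                 participants = df, thresholds = thr, pps = pps,
                 evaluation = evaluation, repeatability = repeatability,
                 config = config)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  invisible(result)
}

# headline statistics for one pipeline run
evaluate_run <- function(df, thr, config) {
  out <- list()
  ctrl <- df$stage == "control"
  s2 <- df$stage == "stage2"
  if (any(ctrl) && any(s2)) {
    out$roc <- lapply(stats::setNames(nm = config$thresholds$metric_names),
                      function(m) {
                        r <- roc_curve(c(df[[m]][ctrl], df[[m]][s2]),
                                       rep(c(FALSE, TRUE),
                                           c(sum(ctrl), sum(s2))))
                        list(auc = r$auc, ci = r$ci)
                      })
    out$any_k_stage2 <- confusion_stats(df$any_k[ctrl | s2], s2[ctrl | s2])
  }
  if (sum(ctrl) >= 3) {
    out$offset_correlations <- offset_correlations(df[ctrl, ])
  }
  groups_present <- intersect(c("control", "stage1", "stage2"),
                              unique(df$stage))
  if (length(groups_present) >= 2) {
    out$group_compare <- group_compare(
      df[df$stage %in% groups_present, ], "stage",
      metrics = c("mean_glucose", "sd_glucose", "cv", "max_glucose",
                  "ta140", "ta160", "ta180", "ta200", "tb80", "tb100",
                  "nocturnal_mean", "days_of_data"),
      categorical = "sex")
  }
  known <- !is.na(df$progressed_1yr) & df$stage != "control"
  if (any(known & df$progressed_1yr)) {
    aab <- df$stage != "control"
    out$any_k_progression <- confusion_stats(df$any_k[known],
                                             df$progressed_1yr[known])
    out$km_overall <- km_estimate(df$followup_years[aab],
                                  df$progressed_stage3[aab],
                                  horizon = config$pps$horizon)
    if (!is.null(df$pps_band) && nlevels(droplevels(df$pps_band[aab])) >= 2) {
      out$km_by_band <- lapply(split(df[aab, ], df$pps_band[aab], drop = TRUE),
                               function(d) {
                                 km <- km_estimate(d$followup_years,
                                                   d$progressed_stage3,
                                                   config$pps$horizon)
                                 list(n = nrow(d), risk_pct = km$risk_pct,
                                      ci_pct = km$risk_ci_pct)
                               })
      out$logrank_bands <- logrank_test(df$followup_years[aab],
                                        df$progressed_stage3[aab],
                                        df$pps_band[aab])
    }
  }
  out
}

# serialize tables + manifest; formatting fixed so identical runs are
# byte-identical
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  part <- result$participants
  part$pps_band <- as.character(part$pps_band)
  w(part, "participants.csv")
  w(result$qc$report, "qc_report.csv")
  w(result$metrics, "metrics.csv")
  if (!is.null(result$repeatability)) {
    w(result$repeatability$pairs, "repeatability.csv")
  }
  jsonlite::write_json(
    list(cutoffs = as.list(result$thresholds$cutoffs),
         direction = result$thresholds$direction,
         n_controls = result$thresholds$n_controls,
         seed = result$config$seed),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$pps)) {
    jsonlite::write_json(
      list(coefficients = as.list(coef(result$pps)),
           n = result$pps$n, n_events = result$pps$n_events,
           horizon = result$pps$horizon,
           diagnostics = result$pps$diagnostics),
      file.path(out_dir, "pps.json"), auto_unbox = TRUE, digits = NA)
  }
  ev <- result$evaluation
  ev$any_k_stage2 <- unclass(ev$any_k_stage2)
  ev$any_k_progression <- unclass(ev$any_k_progression)
  if (!is.null(ev$km_overall)) {
    ev$km_overall <- ev$km_overall[c("horizon", "risk_pct", "risk_ci_pct")]
  }
  ev$group_compare <- NULL  # tabular; written separately
  jsonlite::write_json(ev, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(result$evaluation$group_compare)) {
    w(result$evaluation$group_compare$continuous, "group_compare.csv")
  }
  if (isTRUE(result$config$write_traces)) {
    write_cgm_csv(result$cohort$traces, file.path(out_dir, "traces.csv"))
  }
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(result$config), cfg_json, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    package = "cgmstaging",
    version = as.character(utils::packageVersion("cgmstaging")),
    seed = result$config$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    artifacts = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
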