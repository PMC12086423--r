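#' Latent glycemic state of a simulated participant
#'
#' The generator separates a participant's true glycemia from what the sensor
#' reports. The latent state is a fasting-level `baseline` (mg/dL) plus a
#' dimensionless `excursion_scale` that multiplies post-meal excursion
#' amplitudes; `group` records the intended cohort arm (islet
#' autoantibody-negative control, stage 1 or stage 2 early type 1 diabetes).
#'
#' @param baseline fasting-level glucose, mg/dL (> 0).
#' @param excursion_scale non-negative multiplier on meal excursions.
#' @param group `"control"`, `"stage1"` or `"stage2"`.
#' @return A list of class `glycemic_state`.
#' @export
glycemic_state <- function(baseline, excursion_scale = 1,
                           group = c("control", "stage1", "stage2")) {
  group <- match.arg(group)
  stopifnot(is.numeric(baseline), baseline > 0,
            is.numeric(excursion_scale), excursion_scale >= 0)
  structure(list(baseline = baseline, excursion_scale = excursion_scale,
                 group = group),
            class = "glycemic_state")
}

#' Trace-generation parameters
#'
#' Defaults describe a 10-day blinded Dexcom-G6-style wear in a pediatric
#' cohort: a mild circadian rhythm peaking in the early evening (so the
#' 0300-0600 window sits near the trough, approaching fasting levels),
#' gamma-shaped meal excursions at Poisson times restricted to 06:00-22:00,
#' first-order autoregressive physiologic noise, and a sensor error model
#' with one additive offset drawn per wear session plus white within-session
#' noise. The additive (not multiplicative) session offset is the error mode
#' that shifts mean glucose and time-above-range metrics while leaving the
#' glucose SD untouched.
#'
#' @param circadian_amplitude mg/dL, sinusoid amplitude (default 5).
#' @param circadian_peak_hour clock hour of the circadian peak (default 18).
#' @param meal_rate expected meals per day (Poisson; default 3.2).
#' @param meal_amplitude_mean mean peak height of a meal excursion at
#'   `excursion_scale = 1`, mg/dL.
#' @param meal_amplitude_sd per-meal SD of the peak height, mg/dL.
#' @param meal_peak_min minutes from meal start to excursion peak.
#' @param meal_window clock hours within which meals occur.
#' @param ar_coefficient lag-1 autocorrelation of physiologic noise at the
#'   sample cadence, in `[0, 1)`.
#' @param ar_noise_sd innovation SD of the AR(1) noise, mg/dL.
#' @param sensor_offset_sd SD of the per-session additive offset, mg/dL.
#' @param sensor_noise_sd SD of white within-session sensor noise, mg/dL.
#' @param sample_interval sampling cadence, minutes (default 5).
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(circadian_amplitude = 4,
                         circadian_peak_hour = 18,
                         meal_rate = 3.2,
                         meal_amplitude_mean = 31,
                         meal_amplitude_sd = 10,
                         meal_peak_min = 45,
                         meal_window = c(6, 22),
                         ar_coefficient = 0.9,
                         ar_noise_sd = 2.5,
                         sensor_offset_sd = 8,
                         sensor_noise_sd = 2,
                         sample_interval = 5) {
  stopifnot(circadian_amplitude >= 0, meal_rate >= 0,
            meal_amplitude_mean >= 0, meal_amplitude_sd >= 0,
            meal_peak_min > 0, length(meal_window) == 2,
            ar_coefficient >= 0, ar_coefficient < 1,
            ar_noise_sd >= 0, sensor_offset_sd >= 0, sensor_noise_sd >= 0,
            sample_interval > 0)
  structure(as.list(environment()), class = "trace_params")
}

# gamma-shaped meal pulse: peak `amp` at `dt = peak_min`, unit-normalized shape
meal_pulse <- function(dt_min, amp, peak_min) {
  y <- dt_min / peak_min
  ifelse(dt_min > 0, amp * y * exp(1 - y), 0)
}

#' Generate one CGM wear session
#'
#' Each reading is
#' `clip(baseline + circadian(t) + sum of meal excursions + AR(1) noise +
#' session offset + white noise, 40, 400)`
#' at every cadence tick, where the session offset is drawn once per session
#' from `Normal(0, sensor_offset_sd)`. Clipping at 40/400 mg/dL mirrors
#' commercial sensor reporting limits.
#'
#' @param state a [glycemic_state].
#' @param params a [trace_params].
#' @param duration wear duration in hours; must be a whole number of sampling
#'   intervals.
#' @param seed integer seed for reproducibility (`NULL` to use the current
#'   RNG state).
#' @param start `POSIXct` wear start (local clock time).
#' @param participant_id,session_id,lot_id identifiers stored on the trace.
#' @param offset force the session offset to a fixed value in mg/dL instead
#'   of drawing it (the same seed then reproduces the identical trace up to
#'   a constant shift wherever no reading hits the 40/400 rails).
#' @return A [glucose_trace].
#' @export
generate_trace <- function(state, params = trace_params(), duration = 240,
                           seed = NULL,
                           start = as.POSIXct("2023-03-06 10:00:00", tz = "UTC"),
                           participant_id = "P1", session_id = "S1",
                           lot_id = "L1", offset = NULL) {
  stopifnot(inherits(state, "glycemic_state"), inherits(params, "trace_params"))
  if (duration <= 0) stop("duration must be positive")
  n_ticks <- duration * 60 / params$sample_interval
  if (abs(n_ticks - round(n_ticks)) > 1e-9) {
    stop("sample interval must divide the duration evenly")
  }
  n <- as.integer(round(n_ticks))
  if (!is.null(seed)) set.seed(seed)

  tm <- start + (seq_len(n) - 1L) * params$sample_interval * 60
  hour <- as.numeric(format(tm, "%H")) + as.numeric(format(tm, "%M")) / 60

  # fixed draw order: offset, meals, AR innovations, white noise
  sess_offset <- if (is.null(offset)) {
    stats::rnorm(1, 0, params$sensor_offset_sd)
  } else {
    offset
  }

  circ <- params$circadian_amplitude *
    cos(2 * pi * (hour - params$circadian_peak_hour) / 24)

  # meals on every calendar day touching the wear, Poisson count per day,
  # times uniform in the meal window
  day0 <- as.POSIXct(trunc(start, "days"), tz = "UTC")
  n_days <- as.integer(ceiling(as.numeric(difftime(tm[n], day0, units = "days")))) + 1L
  g <- rep(0, n)
  t_min <- as.numeric(difftime(tm, start, units = "mins"))
  amp_mean <- params$meal_amplitude_mean * state$excursion_scale
  amp_sd <- params$meal_amplitude_sd * state$excursion_scale
  for (d in seq_len(n_days) - 1L) {
    k <- stats::rpois(1, params$meal_rate)
    if (k == 0) next
    meal_hr <- sort(stats::runif(k, params$meal_window[1], params$meal_window[2]))
    amps <- pmax(0, stats::rnorm(k, amp_mean, amp_sd))
    meal_t <- as.numeric(difftime(day0, start, units = "mins")) +
      d * 1440 + meal_hr * 60
    for (j in seq_len(k)) {
      dt <- t_min - meal_t[j]
      live <- dt > 0 & dt < 360  # pulse negligible after 6 h
      if (any(live)) {
        g[live] <- g[live] + meal_pulse(dt[live], amps[j], params$meal_peak_min)
      }
    }
  }

  # AR(1) physiologic noise, stationary start
  phi <- params$ar_coefficient
  innov <- stats::rnorm(n, 0, params$ar_noise_sd)
  x0 <- stats::rnorm(1, 0, params$ar_noise_sd / sqrt(1 - phi^2))
  ar <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                 init = x0))
  white <- stats::rnorm(n, 0, params$sensor_noise_sd)

  glu <- state$baseline + circ + g + ar + sess_offset + white
  glu <- pmin(pmax(glu, 40), 400)
  glucose_trace(participant_id, session_id, lot_id, tm, glu)
}

#' OGTT and HbA1c generation parameters
#'
#' Per-group mean/SD for plasma glucose at 0/30/60/90/120 min of an oral
#' glucose tolerance test and for HbA1c. A participant's individual
#' `excursion_scale` shifts the 120-min glucose and HbA1c upward through the
#' `g120_slope` (mg/dL per unit excursion scale) and `hba1c_slope` (% per
#' unit); both are generator conveniences linking venous glycemia to CGM
#' excursions, not claimed physiology. Group targets are chosen so that the
#' consensus staging rules reproduce the intended arms for the large
#' majority of draws while leaving realistic label noise.
#'
#' @param means named list (control/stage1/stage2) of length-5 OGTT mean
#'   vectors, mg/dL at 0/30/60/90/120 min.
#' @param sds named list of length-5 OGTT SD vectors, mg/dL.
#' @param hba1c_mean,hba1c_sd named numeric vectors, %.
#' @param g120_slope,hba1c_slope links to `excursion_scale` (see above).
#' @return A list of class `ogtt_params`.
#' @export
ogtt_params <- function(
    means = list(control = c(88, 135, 125, 110, 100),
                 stage1  = c(92, 150, 145, 128, 112),
                 stage2  = c(102, 170, 172, 160, 150)),
    sds = list(control = c(6, 18, 20, 18, 12),
               stage1  = c(7, 20, 22, 20, 13),
               stage2  = c(8, 22, 25, 25, 18)),
    hba1c_mean = c(control = 5.10, stage1 = 5.30, stage2 = 5.72),
    hba1c_sd = c(control = 0.18, stage1 = 0.15, stage2 = 0.17),
    g120_slope = 15,
    hba1c_slope = 0.15) {
  structure(as.list(environment()), class = "ogtt_params")
}

# reference excursion scale per intended group, used to centre the
# excursion-linked shifts so group means stay at their targets
.group_excursion_ref <- c(control = 1, stage1 = 1.2, stage2 = 1.85)

#' Generate an OGTT panel and HbA1c for one participant
#'
#' @param state a [glycemic_state].
#' @param params an [ogtt_params].
#' @param seed integer seed (`NULL` to use current RNG state).
#' @return A one-row data frame: `ogtt_0`, `ogtt_30`, `ogtt_60`, `ogtt_90`,
#'   `ogtt_120` (mg/dL) and `hba1c` (%).
#' @export
generate_ogtt_hba1c <- function(state, params = ogtt_params(), seed = NULL) {
  stopifnot(inherits(state, "glycemic_state"), inherits(params, "ogtt_params"))
  if (!is.null(seed)) set.seed(seed)
  g <- state$group
  mu <- params$means[[g]]
  sd <- params$sds[[g]]
  de <- state$excursion_scale - .group_excursion_ref[[g]]
  mu[5] <- mu[5] + params$g120_slope * de
  panel <- pmax(40, stats::rnorm(5, mu, sd))
  hba1c <- max(3.5, stats::rnorm(1, params$hba1c_mean[[g]] +
                                   params$hba1c_slope * de,
                                 params$hba1c_sd[[g]]))
  data.frame(ogtt_0 = panel[1], ogtt_30 = panel[2], ogtt_60 = panel[3],
             ogtt_90 = panel[4], ogtt_120 = panel[5], hba1c = hba1c)
}

#' Generate a progression time under an exponential hazard
#'
#' Event time is exponential with the given hazard; observation is censored
#' administratively at `censor_time`.
#'
#' @param hazard events per year, >= 0 (0 means never progresses).
#' @param censor_time administrative censoring time, years (> 0).
#' @param seed integer seed (`NULL` to use current RNG state).
#' @return A one-row data frame: `time` (years, observed) and `event`
#'   (logical, progressed before censoring).
#' @export
generate_progression <- function(hazard, censor_time = 1.5, seed = NULL) {
  if (hazard < 0) stop("hazard must be non-negative")
  if (censor_time <= 0) stop("censor_time must be positive")
  if (!is.null(seed)) set.seed(seed)
  t_event <- if (hazard == 0) Inf else stats::rexp(1, hazard)
  data.frame(time = min(t_event, censor_time), event = t_event <= censor_time)
}

#' Cohort simulation configuration
#'
#' Defaults emulate the structure of a public-health-screening CGM study in
#' children: 33 islet autoantibody-negative controls, 46 participants with
#' stage 1 and 18 with stage 2 presymptomatic type 1 diabetes, each wearing
#' a blinded sensor for 10 days at 5-minute cadence, with OGTT and HbA1c
#' taken at sensor placement and roughly one year of progression follow-up.
#' Group baselines and excursion scales are set so that the generated CGM
#' metric distributions order control < stage 1 < stage 2 in mean glucose,
#' SD and time-above-range, with medians near those reported for such
#' cohorts (control mean glucose ~115 mg/dL, stage 2 ~135 mg/dL). Hazards
#' correspond to roughly 44 %/year progression in stage 2 and 7 %/year in
#' stage 1.
#'
#' Between-participant heterogeneity couples the excursion scale to the
#' baseline: `excursion_i = group_scale * exp(link * z_i + eps_i)` where
#' `z_i` is the participant's standardized baseline deviation and `eps_i`
#' extra log-normal jitter. Children with higher overall glycemia therefore
#' also tend to be more variable, which reproduces the observed pattern of
#' a positive nocturnal-mean/SD correlation alongside a near-zero
#' nocturnal-mean/CV correlation.
#'
#' @param n_control,n_stage1,n_stage2 group sizes.
#' @param baseline_mean_by_group named mg/dL vector of mean latent baselines.
#' @param baseline_sd between-participant SD of the baseline, mg/dL.
#' @param excursion_by_group named vector of mean excursion scales.
#' @param excursion_sd between-participant log-scale SD of the excursion
#'   jitter.
#' @param excursion_baseline_link log-excursion shift per standardized
#'   baseline deviation (see above).
#' @param params a [trace_params] (sensor + within-day model).
#' @param ogtt an [ogtt_params].
#' @param wear_days sensor wear length, days.
#' @param hazard_by_group named vector, events/year.
#' @param censor_time administrative censoring, years.
#' @param n_repeat number of participants given a second wear session
#'   (allocated in participant order within `repeat_groups`).
#' @param repeat_gap_days days between first and second wear starts.
#' @param repeat_groups groups eligible for a repeat wear.
#' @param p_female probability a participant is female.
#' @param n_lots number of sensor lots cycled across sessions.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 33, n_stage1 = 46, n_stage2 = 18,
                          baseline_mean_by_group = c(control = 107,
                                                     stage1 = 109,
                                                     stage2 = 120),
                          baseline_sd = 5,
                          excursion_by_group = c(control = 1,
                                                 stage1 = 1.2,
                                                 stage2 = 1.85),
                          excursion_sd = 0.10,
                          excursion_baseline_link = 0.19,
                          params = trace_params(),
                          ogtt = ogtt_params(),
                          wear_days = 10,
                          hazard_by_group = c(control = 0,
                                              stage1 = 0.07,
                                              stage2 = 0.58),
                          censor_time = 1.5,
                          n_repeat = 18,
                          repeat_gap_days = 180,
                          repeat_groups = c("stage1", "stage2"),
                          p_female = 0.59,
                          n_lots = 4,
                          seed = 20230101) {
  stopifnot(n_control >= 0, n_stage1 >= 0, n_stage2 >= 0,
            baseline_sd >= 0, excursion_sd >= 0, wear_days > 0,
            all(hazard_by_group >= 0), censor_time > 0, n_repeat >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a full cohort
#'
#' Draws a participant table (demographics, autoantibody count, OGTT panel,
#' HbA1c, progression follow-up) and one or two CGM wear sessions per
#' participant from a [cohort_config]. Randomness fans out from the single
#' config seed into per-participant and per-trace substreams, so the same
#' config and seed reproduce the cohort bit-for-bit.
#'
#' @param config a [cohort_config].
#' @return A list with `participants` (data frame, one row per participant)
#'   and `traces` (list of [glucose_trace], one or two per participant).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(c("control", "stage1", "stage2"),
                c(config$n_control, config$n_stage1, config$n_stage2))
  n <- length(groups)
  if (n == 0) stop("empty cohort: all group sizes are zero")
  set.seed(config$seed)

  id <- sprintf("P%03d", seq_len(n))
  age <- 3 + stats::rbinom(n, 14, 0.5)
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  aab <- ifelse(groups == "control", 0L, sample(2:4, n, replace = TRUE))
  z <- stats::rnorm(n)
  baseline <- config$baseline_mean_by_group[groups] + config$baseline_sd * z
  excursion <- config$excursion_by_group[groups] *
    exp(config$excursion_baseline_link * z +
          stats::rnorm(n, 0, config$excursion_sd))

  # repeat-wear allocation: first n_repeat eligible participants
  eligible <- which(groups %in% config$repeat_groups)
  repeats <- eligible[seq_len(min(config$n_repeat, length(eligible)))]

  # per-draw substream seeds so later stages do not shift earlier randomness
  seed_pool <- sample.int(.Machine$integer.max - 1L, 4L * n)
  ogtt_seed <- seed_pool[seq_len(n)]
  trace_seed <- seed_pool[n + seq_len(n)]
  trace2_seed <- seed_pool[2L * n + seq_len(n)]
  prog_seed <- seed_pool[3L * n + seq_len(n)]
  start_hour <- 8 + floor(stats::runif(n, 0, 11))  # clinic placement 08-18 h
  lot <- sprintf("L%d", 1L + (seq_len(n) - 1L) %% config$n_lots)
  lot2 <- sprintf("L%d", 1L + seq_len(n) %% config$n_lots)

  parts <- vector("list", n)
  traces <- list()
  for (i in seq_len(n)) {
    st <- glycemic_state(baseline[i], excursion[i], groups[i])
    panel <- generate_ogtt_hba1c(st, config$ogtt, seed = ogtt_seed[i])
    prog <- generate_progression(config$hazard_by_group[[groups[i]]],
                                 config$censor_time, seed = prog_seed[i])
    parts[[i]] <- data.frame(
      participant_id = id[i], age = age[i], sex = sex[i],
      aab_count = aab[i], group = groups[i],
      panel,
      followup_years = prog$time,
      progressed_stage3 = prog$event,
      progression_time = ifelse(prog$event, prog$time, NA_real_))
    start1 <- as.POSIXct(sprintf("2023-03-06 %02d:00:00", start_hour[i]),
                         tz = "UTC") + (i - 1) * 86400
    traces[[length(traces) + 1L]] <- generate_trace(
      st, config$params, duration = config$wear_days * 24,
      seed = trace_seed[i], start = start1,
      participant_id = id[i], session_id = "S1", lot_id = lot[i])
    if (i %in% repeats) {
      traces[[length(traces) + 1L]] <- generate_trace(
        st, config$params, duration = config$wear_days * 24,
        seed = trace2_seed[i],
        start = start1 + config$repeat_gap_days * 86400,
        participant_id = id[i], session_id = "S2", lot_id = lot2[i])
    }
  }
  list(participants = do.call(rbind, parts), traces = traces)
}
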