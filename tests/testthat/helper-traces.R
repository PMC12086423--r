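# test fixtures are built in code; no stored data

t0 <- function(x = "2023-03-06 00:00:00") as.POSIXct(x, tz = "UTC")

# quick trace from a glucose vector at fixed cadence
make_trace <- function(values, start = t0(), interval = 5,
                       participant_id = "P1", session_id = "S1",
                       lot_id = "L1") {
  glucose_trace(participant_id, session_id, lot_id,
                start + (seq_along(values) - 1) * interval * 60, values)
}

# independent naive-loop recomputation of the metric suite; deliberately
# written sample-by-sample, sharing no code with compute_metrics()
naive_metrics <- function(trace) {
  n <- nrow(trace)
  s <- 0
  for (i in seq_len(n)) s <- s + trace$glucose[i]
  m <- s / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (trace$glucose[i] - m)^2
  sdp <- sqrt(ss / n)
  cnt <- function(f) {
    k <- 0
    for (i in seq_len(n)) if (f(trace$glucose[i])) k <- k + 1
    100 * k / n
  }
  noct_s <- 0; noct_n <- 0
  for (i in seq_len(n)) {
    h <- as.integer(format(trace$time[i], "%H"))
    if (h >= 3 && h < 6) {
      noct_s <- noct_s + trace$glucose[i]
      noct_n <- noct_n + 1
    }
  }
  list(mean_glucose = m, sd_glucose = sdp, cv = 100 * sdp / m,
       max_glucose = max(trace$glucose),
       ta140 = cnt(function(g) g > 140), ta160 = cnt(function(g) g > 160),
       ta180 = cnt(function(g) g > 180), ta200 = cnt(function(g) g > 200),
       tb80 = cnt(function(g) g < 80), tb100 = cnt(function(g) g < 100),
       nocturnal_mean = noct_s / noct_n,
       wear_hours = n * attr(trace, "interval_min") / 60)
}

# a short physiologic-looking random trace (never hits the 40/400 rails)
random_trace <- function(seed, hours = 36, baseline = NULL) {
  set.seed(seed)
  if (is.null(baseline)) baseline <- runif(1, 90, 130)
  st <- glycemic_state(baseline, runif(1, 0.5, 2))
  generate_trace(st, trace_params(), duration = hours, seed = seed + 1,
                 start = t0() + round(runif(1, 0, 1440)) * 60)
}

# brute-force AUC: concordant pairs + half ties over all case/control pairs
brute_auc <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  tot / (length(x) * length(y))
}

# hand product-limit estimator (right-censored), returns S(t) at `at`
manual_km <- function(times, events, at) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  for (t in ut) {
    if (t > at) break
    d <- sum(times == t & events == 1)
    r <- sum(times >= t)
    s <- s * (1 - d / r)
  }
  s
}

# hand two-group log-rank chi-square
manual_logrank <- function(times, events, group) {
  lv <- unique(group)
  ut <- sort(unique(times[events == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in ut) {
    d <- sum(times == t & events == 1)
    r <- sum(times >= t)
    r1 <- sum(times >= t & group == lv[1])
    d1 <- sum(times == t & events == 1 & group == lv[1])
    o1 <- o1 + d1
    e1 <- e1 + d * r1 / r
    if (r > 1) v <- v + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
  }
  (o1 - e1)^2 / v
}
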