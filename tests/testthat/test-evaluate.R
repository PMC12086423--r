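test_that("confusion statistics reproduce hand-counted examples", {
  # 11 true progressors, 9 flagged; 18 flagged in total
  flags <- rep(c(TRUE, TRUE, FALSE, FALSE), c(9, 9, 2, 44))
  truth <- rep(c(TRUE, FALSE, TRUE, FALSE), c(9, 9, 2, 44))
  cs <- confusion_stats(flags, truth)
  expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(9, 9, 2, 44))
  expect_equal(cs$rounded$sensitivity, 82)  # 9/11
  expect_equal(cs$rounded$ppv, 50)          # 9/18

  all_pos <- confusion_stats(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(all_pos$sensitivity, 100)
  expect_equal(all_pos$ppv, 100)
  expect_true(is.na(all_pos$specificity))  # no negatives: undefined, not 0

  expect_error(confusion_stats(TRUE, c(TRUE, FALSE)), "mismatch")
})

test_that("confusion ratios recompute exactly from their own counts", {
  set.seed(8)
  for (i in 1:25) {
    f <- runif(40) < 0.4
    y <- runif(40) < 0.3
    cs <- confusion_stats(f, y)
    # independent loop oracle
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in 1:40) {
      if (f[j] && y[j]) tp <- tp + 1
      if (f[j] && !y[j]) fp <- fp + 1
      if (!f[j] && y[j]) fn <- fn + 1
      if (!f[j] && !y[j]) tn <- tn + 1
    }
    expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(tp, fp, fn, tn))
    if (tp + fn > 0) expect_equal(cs$sensitivity, 100 * tp / (tp + fn))
    if (tp + fp > 0) expect_equal(cs$ppv, 100 * cs$tp / (cs$tp + cs$fp))
  }
})

test_that("AUC is exact on separated data and matches the pair oracle", {
  r <- roc_curve(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1)

  # 6-point toy set with a tie across classes
  s <- c(1, 2, 3, 3, 4, 5)
  l <- c(F, F, T, F, T, T)
  expect_equal(roc_curve(s, l)$auc, brute_auc(s, l))
  expect_equal(brute_auc(s, l), 8.5 / 9, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:9, 1)
    s <- sample(1:4, n, replace = TRUE)  # tie-rich
    l <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(roc_curve(s, l)$auc, brute_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC and DeLong CI agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- c(rnorm(25, 1), rnorm(30))
  l <- rep(c(TRUE, FALSE), c(25, 30))
  ours <- roc_curve(s, l)
  ref <- pROC::roc(l, s, direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$ci, as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
               tolerance = 1e-8)
})

test_that("null scores give AUC near one half", {
  set.seed(30)
  r <- roc_curve(rnorm(3000), runif(3000) < 0.5)
  expect_lt(abs(r$auc - 0.5), 0.04)
})

test_that("Kaplan-Meier risk equals the empirical CDF without censoring", {
  # 10 subjects, 2 events before the horizon, no one censored before it
  km <- km_estimate(times = c(0.2, 0.6, rep(2, 8)),
                    events = c(1, 1, rep(0, 8)), horizon = 1)
  expect_equal(km$risk_pct, 20)

  all_cens <- km_estimate(rep(1.2, 6), rep(FALSE, 6), horizon = 1)
  expect_equal(all_cens$risk_pct, 0)

  set.seed(44)
  t <- rexp(300, 0.8)
  km2 <- km_estimate(t, rep(TRUE, 300), horizon = 1)
  expect_equal(km2$risk_pct, 100 * mean(t <= 1), tolerance = 1e-12)
})

test_that("interleaved censoring matches the hand product-limit oracle", {
  t <- c(0.1, 0.2, 0.25, 0.4, 0.5, 0.7, 0.8, 1.1, 1.3, 1.5)
  e <- c(1,   0,   1,    1,   0,   1,   0,   1,   0,   0)
  km <- km_estimate(t, e, horizon = 1)
  # events at 0.1, 0.25, 0.4, 0.7 with risk sets 10, 8, 7, 5:
  # S(1) = (1-1/10)(1-1/8)(1-1/7)(1-1/5)
  expect_equal(km$surv_at_horizon, (9 / 10) * (7 / 8) * (6 / 7) * (4 / 5),
               tolerance = 1e-12)
  expect_equal(km$surv_at_horizon, manual_km(t, e, 1), tolerance = 1e-12)
  expect_equal(km$risk_pct, 100 * (1 - manual_km(t, e, 1)), tolerance = 1e-12)
  # survival curve is a non-increasing step function from 1
  expect_true(all(diff(c(1, km$surv)) <= 1e-12))
  expect_true(all(km$risk_ci_pct >= 0 & km$risk_ci_pct <= 100))
})

test_that("log-rank is null on identical groups and matches a hand oracle", {
  t <- c(0.3, 0.7, 1.1, 1.6)
  e <- c(1, 1, 0, 1)
  null <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_lt(null$chisq, 1e-10)

  # strong separation
  sep <- logrank_test(c(rep(0.1, 10), rep(2, 10)),
                      c(rep(1, 10), rep(0, 10)),
                      rep(c("fast", "slow"), each = 10))
  expect_lt(sep$p_value, 0.001)

  # 8-subject fixture vs the hand-computed observed/expected table
  t8 <- c(0.2, 0.5, 0.6, 1.0, 0.3, 0.8, 1.2, 1.4)
  e8 <- c(1, 1, 0, 1, 1, 0, 1, 0)
  g8 <- rep(c("x", "y"), each = 4)
  got <- logrank_test(t8, e8, g8)
  expect_equal(got$chisq, manual_logrank(t8, e8, g8), tolerance = 1e-10)
  expect_equal(got$df, 1)

  expect_error(logrank_test(t, e, rep("a", 4)), "two")
})

test_that("group comparison behaves at the null and under separation", {
  set.seed(21)
  d <- data.frame(g = rep(c("a", "b"), each = 30),
                  v = rep(sin(1:30), 2),  # identical distributions
                  w = c(rnorm(30), rnorm(30, 6)))  # 6 SD apart
  gc <- group_compare(d, "g", metrics = c("v", "w"))
  expect_gt(gc$continuous$p_a_vs_b[gc$continuous$variable == "v"], 0.99)
  expect_lt(gc$continuous$p_a_vs_b[gc$continuous$variable == "w"], 0.001)

  # p-values invariant under group relabeling
  d2 <- d
  d2$g <- factor(d$g, levels = c("b", "a"))
  gc2 <- group_compare(d2, "g", metrics = "w")
  expect_equal(gc2$continuous$p_b_vs_a,
               gc$continuous$p_a_vs_b[gc$continuous$variable == "w"])

  # categorical: expected counts rule picks Fisher for sparse tables
  d$cat <- rep(c("m", "f"), 30)
  gc3 <- group_compare(d, "g", metrics = "w", categorical = "cat")
  expect_true(is.finite(gc3$categorical$p_a_vs_b))
  expect_no_error(group_compare(d, "g", metrics = "v"))
})

test_that("offset correlations match the closed-form Pearson oracle", {
  # exactly linear: r = 1
  m <- data.frame(nocturnal_mean = 1:8, ta140 = 2 * (1:8) + 3,
                  sd_glucose = seq(2, 16, 2), cv = 3 * (1:8))
  oc <- offset_correlations(m)
  expect_equal(oc$r, rep(1, 3), tolerance = 1e-12)

  set.seed(55)
  m2 <- data.frame(nocturnal_mean = rnorm(10, 105, 8),
                   ta140 = runif(10, 0, 40), sd_glucose = rnorm(10, 18, 3),
                   cv = rnorm(10, 15, 2))
  oc2 <- offset_correlations(m2)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(oc2$r[oc2$metric == "ta140"],
               pearson(m2$nocturnal_mean, m2$ta140), tolerance = 1e-12)
  expect_equal(oc2$r[oc2$metric == "cv"],
               pearson(m2$nocturnal_mean, m2$cv), tolerance = 1e-12)

  # independent columns at large n: near-zero correlation
  set.seed(56)
  m3 <- data.frame(nocturnal_mean = rnorm(2000), ta140 = rnorm(2000),
                   sd_glucose = rnorm(2000), cv = rnorm(2000))
  expect_true(all(abs(offset_correlations(m3)$r) < 0.08))

  m2$cv <- 1
  expect_error(offset_correlations(m2), "constant")
})

test_that("paired-wear repeatability reports shifts and concordance", {
  tr1 <- random_trace(61, hours = 48, baseline = 110)
  tr2a <- glucose_trace("P1", "S2", "L2", tr1$time + 86400 * 30,
                        tr1$glucose)
  met_same <- rbind(compute_metrics(tr1), compute_metrics(tr2a))
  met_same$participant_id <- "P1"
  ctrl <- data.frame(sd_glucose = 25, ta140 = 30, ta160 = 12, ta180 = 5)
  thr <- derive_thresholds(ctrl)
  rep_same <- repeatability_report(met_same, thr)
  expect_equal(rep_same$pairs$delta_mean_glucose, 0)
  expect_equal(rep_same$any_k_concordance, 1)
  expect_equal(rep_same$n_delta_mean_gt, 0)

  # an additive +15 mg/dL second wear: mean moves 15, SD does not
  tr2b <- glucose_trace("P1", "S2", "L2", tr1$time + 86400 * 30,
                        tr1$glucose + 15)
  met_shift <- rbind(compute_metrics(tr1), compute_metrics(tr2b))
  met_shift$participant_id <- "P1"
  rep_shift <- repeatability_report(met_shift, thr)
  expect_equal(rep_shift$pairs$delta_mean_glucose, 15)
  expect_equal(rep_shift$pairs$delta_sd_glucose, 0, tolerance = 1e-12)
  expect_gte(rep_shift$pairs$delta_ta140, 0)
  expect_equal(rep_shift$n_delta_mean_gt, 1)

  expect_error(repeatability_report(compute_metrics(tr1), thr), "two sessions")
})
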