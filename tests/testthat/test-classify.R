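met_row <- function(sd = 20, ta140 = 10, ta160 = 3, ta180 = 1) {
  data.frame(sd_glucose = sd, ta140 = ta140, ta160 = ta160, ta180 = ta180)
}

test_that("cutoffs are the exact control maxima with strict flagging", {
  ctrl <- data.frame(sd_glucose = c(10, 12, 29), ta140 = c(5, 50, 20),
                     ta160 = c(0, 14, 3), ta180 = c(0, 4, 1))
  thr <- derive_thresholds(ctrl)
  expect_equal(unname(thr$cutoffs),  c(29, 50, 14, 4))
  expect_equal(count_elevated(met_row(sd = 29), thr), 0L)
  expect_equal(count_elevated(met_row(sd = 29.1), thr), 1L)

  # an all-zero control metric gives cutoff 0: any positive value flags
  z <- data.frame(sd_glucose = c(10, 12), ta140 = c(5, 6),
                  ta160 = c(1, 2), ta180 = c(0, 0))
  thrz <- derive_thresholds(z)
  expect_equal(unname(thrz$cutoffs["ta180"]), 0)
  expect_equal(count_elevated(met_row(5, 1, 0.5, 0.01), thrz), 1L)

  expect_error(derive_thresholds(ctrl[0, ]), "at least one control")
  expect_error(derive_thresholds(ctrl, c("sd_glucose", "nope")), "absent")
})

test_that("derivation controls are never flagged: specificity is exactly 1", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    ctrl <- data.frame(sd_glucose = rexp(n, 1 / 20), ta140 = runif(n, 0, 60),
                       ta160 = runif(n, 0, 20), ta180 = rexp(n, 1))
    thr <- derive_thresholds(ctrl)
    expect_identical(sum(count_elevated(ctrl, thr)), 0L)
    expect_false(any(any_k_rule(ctrl, thr, k = 1)))
  }
})

test_that("count_elevated matches a per-metric loop oracle", {
  set.seed(23)
  ctrl <- data.frame(sd_glucose = runif(20, 10, 30), ta140 = runif(20, 0, 50),
                     ta160 = runif(20, 0, 15), ta180 = runif(20, 0, 5))
  thr <- derive_thresholds(ctrl)
  cases <- data.frame(sd_glucose = runif(30, 10, 40), ta140 = runif(30, 0, 70),
                      ta160 = runif(30, 0, 25), ta180 = runif(30, 0, 9))
  got <- count_elevated(cases, thr)
  for (i in 1:30) {
    k <- 0
    for (m in names(thr$cutoffs)) {
      if (cases[[m]][i] > thr$cutoffs[[m]]) k <- k + 1
    }
    expect_equal(got[i], k)
  }
  # all metrics exactly at their cutoffs: nothing is elevated
  at <- as.data.frame(as.list(thr$cutoffs))
  expect_equal(count_elevated(at, thr), 0L)
  above <- as.data.frame(as.list(thr$cutoffs + 0.5))
  expect_equal(count_elevated(above, thr), 4L)
  expect_error(count_elevated(data.frame(sd_glucose = 1), thr), "missing")
})

test_that("the any-k rule thresholds the elevated count", {
  ctrl <- data.frame(sd_glucose = 20, ta140 = 10, ta160 = 5, ta180 = 2)
  thr <- derive_thresholds(ctrl)
  expect_true(any_k_rule(met_row(21, 11, 1, 1), thr, k = 2))   # T,T,F,F
  expect_false(any_k_rule(met_row(21, 1, 1, 1), thr, k = 2))   # T,F,F,F
  expect_false(any_k_rule(met_row(1, 1, 1, 1), thr, k = 1))    # F,F,F,F
  expect_error(any_k_rule(met_row(), thr, k = 5), "exceeds")
  expect_error(any_k_rule(met_row(), thr, k = 0), "at least 1")

  # monotone: raising any metric never flips positive -> negative
  set.seed(5)
  for (i in 1:20) {
    row <- met_row(runif(1, 10, 30), runif(1, 0, 20), runif(1, 0, 10),
                   runif(1, 0, 4))
    before <- any_k_rule(row, thr, 2)
    row$ta140 <- row$ta140 + 25
    expect_true(!before || any_k_rule(row, thr, 2))
  }
})

test_that("predict() on thresholds returns flags, counts and the rule", {
  ctrl <- data.frame(sd_glucose = 20, ta140 = 10, ta160 = 5, ta180 = 2)
  thr <- derive_thresholds(ctrl)
  p <- predict(thr, rbind(met_row(25, 15, 1, 1), met_row(1, 1, 1, 1)))
  expect_equal(p$n_elevated, c(2L, 0L))
  expect_equal(p$any_k, c(TRUE, FALSE))
  expect_equal(p$flag_sd_glucose, c(TRUE, FALSE))
})

test_that("a null logistic fit recovers the intercept-only model", {
  set.seed(71)
  n <- 4000
  d <- data.frame(sd_glucose = rnorm(n, 20, 4), ta140 = runif(n, 0, 40),
                  ta160 = runif(n, 0, 15), ta180 = rexp(n, 1),
                  y = runif(n) < 0.3)
  fit <- fit_pps(y ~ sd_glucose + ta140 + ta160 + ta180, d)
  se <- sqrt(diag(vcov(fit)))
  for (m in c("sd_glucose", "ta140", "ta160", "ta180")) {
    expect_lt(abs(coef(fit)[m]), 3.5 * se[m])
  }
  # intercept consistent with logit of the event rate at covariate means
  eta_bar <- mean(predict(fit, d, type = "link"))
  expect_lt(abs(eta_bar - qlogis(mean(d$y))), 0.05)
})

test_that("known logistic coefficients are recovered within 3 SE", {
  set.seed(42)
  n <- 2000
  beta <- c(`(Intercept)` = -6, sd_glucose = 0.1, ta140 = 0.05,
            ta160 = 0.08, ta180 = 0.2)
  d <- data.frame(sd_glucose = rnorm(n, 20, 5), ta140 = runif(n, 0, 40),
                  ta160 = runif(n, 0, 15), ta180 = rexp(n, 0.5))
  eta <- beta[1] + as.matrix(d) %*% beta[-1]
  d$y <- runif(n) < plogis(eta)
  fit <- fit_pps(y ~ sd_glucose + ta140 + ta160 + ta180, d)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - beta) < 3 * se))
  expect_identical(fit$diagnostics$method, "ml")
})

test_that("zero coefficients score everyone at exactly 0.5", {
  d <- data.frame(sd_glucose = rnorm(20, 20), ta140 = runif(20),
                  ta160 = runif(20), ta180 = runif(20),
                  y = rep(c(TRUE, FALSE), 10))
  fit <- fit_pps(y ~ sd_glucose + ta140 + ta160 + ta180, d)
  fit$coefficients[] <- 0
  expect_equal(unname(predict(fit, d)), rep(0.5, 20))
})

test_that("complete separation falls back to a recorded ridge fit", {
  d <- data.frame(sd_glucose = c(rnorm(30, 15, 1), rnorm(30, 40, 1)),
                  ta140 = runif(60, 0, 10), ta160 = runif(60, 0, 5),
                  ta180 = runif(60, 0, 2),
                  y = rep(c(FALSE, TRUE), each = 30))
  fit <- fit_pps(y ~ sd_glucose + ta140 + ta160 + ta180, d)
  expect_identical(fit$diagnostics$method, "ridge")
  expect_true(fit$diagnostics$separation)
  expect_true(all(is.finite(coef(fit))))
  # still an excellent in-sample discriminator
  expect_gt(roc_curve(fit$fitted, d$y)$auc, 0.99)
})

test_that("scores are monotone in a metric with positive coefficient", {
  set.seed(3)
  n <- 500
  d <- data.frame(sd_glucose = rnorm(n, 22, 5), ta140 = runif(n, 0, 40),
                  ta160 = runif(n, 0, 15), ta180 = rexp(n, 0.7))
  d$y <- runif(n) < plogis(-7 + 0.25 * d$sd_glucose + 0.05 * d$ta140)
  fit <- fit_pps(y ~ sd_glucose + ta140 + ta160 + ta180, d)
  expect_gt(coef(fit)["sd_glucose"], 0)
  grid <- data.frame(sd_glucose = seq(10, 40, 5), ta140 = 10, ta160 = 3,
                     ta180 = 1)
  expect_true(all(diff(predict(fit, grid)) > 0))
})

test_that("single-class outcomes are rejected", {
  d <- data.frame(sd_glucose = rnorm(10, 20), ta140 = runif(10),
                  ta160 = runif(10), ta180 = runif(10), y = rep(TRUE, 10))
  expect_error(fit_pps(y ~ sd_glucose + ta140 + ta160 + ta180, d),
               "single class")
})

test_that("risk bands use the published boundaries", {
  expect_equal(as.character(pps_band(c(0, 0.18999, 0.19, 0.3, 0.4, 0.4001, 1))),
               c("low", "low", "mid", "mid", "mid", "high", "high"))
  expect_error(pps_band(1.2), "\\[0, 1\\]")
  expect_error(pps_band(-0.1), "\\[0, 1\\]")
})

test_that("the one-year outcome handles events and early censoring", {
  out <- progressed_within(followup_years = c(0.4, 0.4, 1.3, 2),
                           progressed = c(TRUE, FALSE, FALSE, TRUE),
                           progression_time = c(0.4, NA, NA, 2),
                           horizon = 1)
  expect_identical(out, c(TRUE, NA, FALSE, FALSE))
})
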