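#' Binary one-year progression outcome
#'
#' Builds the outcome used by the Progression Prediction Score: `TRUE` if
#' the participant progressed to clinical (stage 3) diabetes within
#' `horizon` years of the CGM wear, `FALSE` if followed at least `horizon`
#' years without progressing, and `NA` (excluded from the fit) when
#' censored before the horizon without an event.
#'
#' @param followup_years observed follow-up, years.
#' @param progressed event indicator (logical).
#' @param progression_time event time, years (NA when no event).
#' @param horizon years (default 1).
#' @return Logical vector with `NA` for indeterminate participants.
#' @export
progressed_within <- function(followup_years, progressed, progression_time,
                              horizon = 1) {
  event_in <- progressed & !is.na(progression_time) &
    progression_time <= horizon
  ifelse(event_in, TRUE,
         ifelse(followup_years >= horizon, FALSE, NA))
}

#' Fit the composite Progression Prediction Score
#'
#' Maximum-likelihood logistic regression of progression within a fixed
#' horizon on a set of CGM parameters (by default glucose SD, TA140, TA160
#' and TA180, in their natural units — no standardization, so coefficients
#' are per mg/dL or per percentage point). The score of a participant is
#' the fitted probability `logistic(intercept + sum(coef * metric))`.
#'
#' With few progressors the likelihood can be separable; in that case the
#' fit falls back to a small ridge penalty (`penalty/2 * sum(beta^2)` on
#' the non-intercept coefficients, per-observation scale) and records this
#' in the diagnostics rather than returning divergent coefficients.
#'
#' @param formula model formula, e.g.
#'   `progressed_1yr ~ sd_glucose + ta140 + ta160 + ta180`.
#' @param data data frame containing the outcome and metrics; rows with an
#'   `NA` outcome are dropped.
#' @param horizon years, stored as metadata (default 1).
#' @param penalty ridge penalty used only on separation (default 1e-3).
#' @return An object of class `pps`: coefficients, fitted scores, the
#'   underlying fit, sample sizes and convergence diagnostics.
#' @export
fit_pps <- function(formula, data, horizon = 1, penalty = 1e-3) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; cannot fit a progression score")
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(!is.finite(X))) stop("non-finite metric values")

  g <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  p <- g$fitted.values
  separated <- !g$converged || any(p < 1e-8 | p > 1 - 1e-8) ||
    any(abs(g$coefficients[-1]) > 50)

  method <- "ml"
  coefs <- g$coefficients
  vcov_ <- tryCatch(chol2inv(chol(crossprod(X * sqrt(p * (1 - p))))),
                    error = function(e) NULL)
  if (separated) {
    method <- "ridge"
    pen <- rep(penalty, ncol(X))
    pen[1] <- 0  # intercept unpenalized
    negll <- function(b) {
      eta <- drop(X %*% b)
      sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
        sum(pen * b^2) / 2
    }
    grad <- function(b) {
      mu <- stats::plogis(drop(X %*% b))
      drop(crossprod(X, mu - y)) + pen * b
    }
    opt <- stats::optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    coefs <- stats::setNames(opt$par, colnames(X))
    mu <- stats::plogis(drop(X %*% coefs))
    H <- crossprod(X * sqrt(mu * (1 - mu))) + diag(pen)
    vcov_ <- chol2inv(chol(H))
    p <- mu
  }
  if (!is.null(vcov_)) dimnames(vcov_) <- list(colnames(X), colnames(X))

  structure(list(coefficients = coefs,
                 vcov = vcov_,
                 fitted = as.numeric(p),
                 y = y,
                 terms = attr(mf, "terms"),
                 formula = formula,
                 n = length(y),
                 n_events = sum(y),
                 horizon = horizon,
                 diagnostics = list(method = method,
                                    separation = separated,
                                    converged = if (method == "ml") g$converged else TRUE,
                                    penalty = if (method == "ridge") penalty else 0)),
            class = "pps")
}

#' @export
print.pps <- function(x, digits = 4, ...) {
  cat(sprintf("Progression Prediction Score (logistic, %s fit)\n",
              x$diagnostics$method))
  cat(sprintf("  %d participants, %d progressed within %g year(s)\n",
              x$n, x$n_events, x$horizon))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.pps <- function(object, ...) object$coefficients

#' @export
vcov.pps <- function(object, ...) object$vcov

#' @export
summary.pps <- function(object, ...) {
  se <- if (is.null(object$vcov)) rep(NA_real_, length(object$coefficients))
        else sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab,
                 n = object$n, n_events = object$n_events,
                 horizon = object$horizon,
                 diagnostics = object$diagnostics),
            class = "summary.pps")
}

#' @export
print.summary.pps <- function(x, ...) {
  cat(sprintf("Progression Prediction Score (%s fit; horizon %g y; n = %d, events = %d)\n",
              x$diagnostics$method, x$horizon, x$n, x$n_events))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
#' @describeIn fit_pps scores (`type = "response"`), linear predictor
#'   (`"link"`) or risk bands (`"band"`) for new metric rows; without
#'   `newdata`, the in-sample fitted values.
#' @param object a `pps` object.
#' @param newdata data frame of metric rows.
#' @param type `"response"`, `"link"` or `"band"`.
#' @param ... unused.
predict.pps <- function(object, newdata = NULL,
                        type = c("response", "link", "band"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) {
    stats::qlogis(object$fitted)
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                    na.action = stats::na.pass))
    drop(X %*% object$coefficients)
  }
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         band = pps_band(stats::plogis(eta)))
}

#' @export
residuals.pps <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "response") return(r)
  d <- -2 * (object$y * log(object$fitted) +
               (1 - object$y) * log(1 - object$fitted))
  sign(r) * sqrt(pmax(d, 0))
}

#' @export
simulate.pps <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, stats::rbinom(object$n, 1,
                                                     object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.pps <- function(x, ...) {
  graphics::stripchart(x$fitted ~ factor(x$y, c(0, 1),
                                         c("no progression", "progressed")),
                       vertical = TRUE, method = "jitter", pch = 19,
                       ylab = "Progression Prediction Score", ...)
  graphics::abline(h = c(0.19, 0.4), lty = 2, col = "grey40")
  invisible(x)
}

#' Risk bands for a Progression Prediction Score
#'
#' `low` for scores < 0.19, `mid` for 0.19-0.4 (both endpoints inclusive),
#' `high` above 0.4.
#'
#' @param score numeric scores in `[0, 1]`.
#' @param cut_low,cut_high band boundaries (defaults 0.19 and 0.4).
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
pps_band <- function(score, cut_low = 0.19, cut_high = 0.4) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]")
  }
  factor(ifelse(score < cut_low, "low",
                ifelse(score <= cut_high, "mid", "high")),
         levels = c("low", "mid", "high"))
}
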