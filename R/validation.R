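#' Harrell's concordance index
#'
#' Over all comparable pairs — pairs whose smaller observed time is an event
#' (tied times are not comparable) — counts 1 for a concordant pair, 0.5 for
#' a tied score and 0 for a discordant pair, and returns the concordant mass
#' divided by the number of comparable pairs.  Scores are oriented so that a
#' HIGHER score predicts LONGER survival (e.g. predicted median survival
#' time for an AFT model, or the negated linear predictor for a Cox model).
#'
#' @param scores numeric predictions, higher = longer predicted survival.
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @return concordance in \[0, 1\].
#' @export
harrell_c <- function(scores, times, events) {
  stopifnot(length(scores) == length(times),
            length(times) == length(events))
  num <- 0; den <- 0
  for (i in which(events == 1)) {
    ## records observed to outlive record i
    j <- times > times[i]
    if (!any(j)) next
    den <- den + sum(j)
    num <- num + sum(scores[j] > scores[i]) + 0.5 * sum(scores[j] == scores[i])
  }
  if (den == 0) stop("no comparable pairs: concordance undefined",
                     call. = FALSE)
  num / den
}

#' Kaplan-Meier product-limit estimator
#'
#' Thin wrapper around [survival::survfit()] returning a right-continuous
#' step function with S(0) = 1.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @return a function `S(t)` vectorized over `t`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) >= 1)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  stepfun(sf$time, c(1, sf$surv), right = FALSE)
}

#' Calibration table at a fixed horizon
#'
#' Sorts the cohort by predicted survival probability at the horizon, cuts
#' it into `n_bins` equal-count bins, and reports per bin the mean predicted
#' probability and the Kaplan-Meier observed probability at the horizon.
#' This is the data behind a calibration plot: points near the diagonal
#' indicate agreement between predicted and observed survival.
#'
#' @param predicted vector of predicted S(horizon | x), one per record (use
#'   [predict_survival()] for AFT fits or [cox_predict_survival()] for Cox).
#' @param cohort a [cohort_table()] (the held-out records being binned).
#' @param horizon months at which calibration is assessed.
#' @param n_bins number of equal-count bins (default 10).
#' @return data frame with columns `bin`, `mean_predicted`, `km_observed`,
#'   `n`; attribute `flagged` lists bins where the KM curve is undefined at
#'   the horizon (no information before it) and is carried from the last
#'   defined value.
#' @export
calibration_table <- function(predicted, cohort, horizon, n_bins = 10) {
  n <- nrow(cohort)
  stopifnot(length(predicted) == n, n_bins >= 1)
  ord <- order(predicted)
  bin <- rep(seq_len(n_bins), diff(round(seq(0, n, length.out = n_bins + 1))))
  bin <- bin[order(ord)]           # bin id back in record order
  flagged <- integer(0)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    km <- km_estimate(cohort$time[sel], cohort$event[sel])
    obs <- km(horizon)
    if (max(cohort$time[sel]) < horizon && cohort$event[sel][
          which.max(cohort$time[sel])] == 0)
      flagged <<- c(flagged, b)
    data.frame(bin = b, mean_predicted = mean(predicted[sel]),
               km_observed = obs, n = sum(sel))
  })
  out <- do.call(rbind, rows)
  attr(out, "flagged") <- flagged
  out
}

#' RMSE of predicted median survival time
#'
#' Root-mean-square difference between predicted median survival time and
#' the observed time, over UNCENSORED records only (censored times are lower
#' bounds and would need an imputation convention).
#'
#' @param predicted_median predicted median survival times (months).
#' @param cohort a [cohort_table()].
#' @return RMSE in months.
#' @export
rmse_pred <- function(predicted_median, cohort) {
  d <- cohort$event == 1
  if (!any(d)) stop("no uncensored records: RMSE undefined", call. = FALSE)
  sqrt(mean((predicted_median[d] - cohort$time[d])^2))
}

#' Predicted survival probabilities from a Cox fit
#'
#' Breslow baseline survival from the training fit, raised to
#' `exp(linear predictor)` for each new record.
#'
#' @param fit a [fit_cox()] result.
#' @param cohort a [cohort_table()] of new records.
#' @param time horizon in months.
#' @return vector of S(time | x).
#' @export
cox_predict_survival <- function(fit, cohort, time) {
  X <- encode_design(cohort)
  nm <- names(fit$coefficients)
  lp <- drop(X[, nm, drop = FALSE] %*% fit$coefficients) -
    sum(fit$model$means * fit$coefficients)
  bh <- survival::basehaz(fit$model, centered = TRUE)
  H0 <- c(0, bh$hazard)[findInterval(time, c(0, bh$time))]
  exp(-H0 * exp(lp))
}

#' Validate a fitted model on a held-out cohort
#'
#' Computes the Harrell C-index (risk score = predicted median survival for
#' AFT fits, negated linear predictor for Cox), the RMSE of predicted median
#' survival over uncensored records (AFT only), and the calibration table at
#' the cohort's censoring horizon.
#'
#' @param fit an `aft_fit` or `cox_fit`.
#' @param cohort held-out [cohort_table()].
#' @param n_bins calibration bins (default 10).
#' @return object of class `validation_report`: list with `c_index`, `rmse`
#'   (`NA` for Cox), `calibration`, `horizon`, `n`.
#' @export
validate_model <- function(fit, cohort, n_bins = 10) {
  horizon <- attr(cohort, "horizon")
  if (inherits(fit, "aft_fit")) {
    med <- predict_median(fit, cohort)
    ci <- harrell_c(med, cohort$time, cohort$event)
    rmse <- rmse_pred(med, cohort)
    pred <- predict_survival(fit, cohort, horizon)
  } else if (inherits(fit, "cox_fit")) {
    X <- encode_design(cohort)
    lp <- drop(X[, names(fit$coefficients), drop = FALSE] %*%
                 fit$coefficients)
    ci <- harrell_c(-lp, cohort$time, cohort$event)
    rmse <- NA_real_
    pred <- cox_predict_survival(fit, cohort, horizon)
  } else stop("unsupported fit class", call. = FALSE)
  structure(list(c_index = ci, rmse = rmse,
                 calibration = calibration_table(pred, cohort, horizon,
                                                 n_bins),
                 horizon = horizon, n = nrow(cohort)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation (n = %d, horizon %d): C-index = %.3f, RMSE = %s\n",
              x$n, x$horizon, x$c_index,
              if (is.na(x$rmse)) "-" else sprintf("%.3f", x$rmse)))
  invisible(x)
}
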