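#' Cox proportional-hazards comparison arm
#'
#' Fits a Cox model on the dummy-encoded design via [survival::coxph()] with
#' Efron tie handling (month-granularity survival data is heavily tied).
#' The reported AIC/BIC use the partial log-likelihood, so they are
#' comparable only in the loose sense conventionally used when a Cox arm is
#' tabulated next to parametric fits.
#'
#' @param cohort a [cohort_table()].
#' @return object of class `cox_fit`: list with `coefficients`, `se`,
#'   `loglik` (partial, at the optimum), `n`, `k`, `aic`, `bic` and the
#'   underlying `coxph` object (`model`).
#' @export
fit_cox <- function(cohort) {
  if (sum(cohort$event) == 0) stop("no events: cannot fit a Cox model",
                                   call. = FALSE)
  if (length(unique(cohort$time[cohort$event == 1])) < 2)
    stop("need at least 2 distinct event times", call. = FALSE)
  X <- encode_design(cohort)
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    message("dropping constant design column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0 || qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  fit <- survival::coxph(survival::Surv(cohort$time, cohort$event) ~ X,
                         ties = "efron")
  if (any(abs(coef(fit)) > 15))
    warning("possible monotone likelihood (separation): ",
            "coefficient(s) escaping to the boundary")
  k <- length(coef(fit))
  ll <- fit$loglik[2]
  ic <- information_criteria(ll, k, nrow(cohort))
  structure(list(
    coefficients = setNames(as.numeric(coef(fit)), colnames(X)),
    se = setNames(sqrt(diag(vcov(fit))), colnames(X)),
    loglik = ll, n = nrow(cohort), k = k,
    aic = ic["aic"], bic = ic["bic"],
    model = fit, cohort_specs = attr(cohort, "specs")),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, partial logLik = %.2f, AIC = %.1f\n",
              x$n, x$loglik, x$aic))
  print(data.frame(term = names(x$coefficients),
                   coef = x$coefficients, se = x$se), row.names = FALSE)
  invisible(x)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Refits the Cox model on the cohort's factor columns so each covariate
#' (not each indicator column) gets one test, then applies
#' [survival::cox.zph()] with the Kaplan-Meier time transform: scaled
#' Schoenfeld residuals are correlated with `1 - KM(t)`, giving a 1-df
#' chi-square per covariate plus a global test.
#'
#' @param cohort a [cohort_table()].
#' @return object of class `ph_test`: data frame of per-variable p-values
#'   with a final `GLOBAL` row.
#' @export
schoenfeld_ph_test <- function(cohort) {
  specs <- attr(cohort, "specs")
  vars <- vapply(specs, `[[`, "", "name")
  if (sum(cohort$event) <= length(vars))
    stop("fewer events than covariates: PH test unavailable", call. = FALSE)
  df <- as.data.frame(cohort)
  fml <- reformulate(vars, response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = df, ties = "efron")
  zp <- survival::cox.zph(fit, transform = "km")
  out <- data.frame(variable = rownames(zp$table),
                    chisq = zp$table[, "chisq"],
                    df = zp$table[, "df"],
                    p = zp$table[, "p"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ph_test", "data.frame")
  out
}

#' LASSO variable screening with a penalized Cox likelihood
#'
#' L1-penalized Cox partial likelihood over a lambda grid;
#' lambda is chosen by cross-validated partial-likelihood deviance
#' ([glmnet::cv.glmnet()] with `family = "cox"`).  A categorical variable
#' counts as selected if any of its indicator columns has a nonzero
#' coefficient at the chosen lambda.
#'
#' @param cohort a [cohort_table()].
#' @param lambda optional decreasing lambda grid; `NULL` lets glmnet choose.
#' @param cv_folds number of cross-validation folds (>= 2), default 10.
#' @param seed integer seed controlling fold assignment.
#' @return character vector of selected variable names (spec order).
#' @export
lasso_select <- function(cohort, lambda = NULL, cv_folds = 10, seed = 1) {
  if (cv_folds < 2) stop("cv_folds must be at least 2", call. = FALSE)
  if (!is.null(lambda) && length(lambda) == 0)
    stop("empty lambda grid", call. = FALSE)
  X <- encode_design(cohort)
  keep <- apply(X, 2, function(v) diff(range(v)) > 0)
  X <- X[, keep, drop = FALSE]
  y <- survival::Surv(cohort$time, cohort$event)
  foldid <- with_seed(seed,
                      sample(rep_len(seq_len(cv_folds), nrow(cohort))))
  cv <- glmnet::cv.glmnet(X, y, family = "cox", lambda = lambda,
                          foldid = foldid)
  b <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
  nz <- names(b)[b != 0]
  specs <- attr(cohort, "specs")
  sel <- vapply(specs, function(sp) {
    cols <- if (sp$kind == "continuous") sp$name
            else paste0(sp$name, "=", setdiff(sp$levels, sp$reference))
    any(cols %in% nz)
  }, TRUE)
  vapply(specs, `[[`, "", "name")[sel]
}
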