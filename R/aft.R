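#' Accelerated failure time model specification
#'
#' @param family baseline family: `"zbln"`, `"lognormal"` or `"weibull"`.
#' @param columns design-matrix column names (from [encode_design()]) to
#'   include; `NULL` means all columns.
#' @return an object of class `aft_model_spec`.
#' @export
aft_model_spec <- function(family = c("zbln", "lognormal", "weibull"),
                           columns = NULL) {
  family <- match.arg(family)
  structure(list(family = family, columns = columns),
            class = "aft_model_spec")
}

## Parameter packing, one code path for the three families:
##   theta = (mu0, beta[1..p], log sigma[, log a])   (log a only for zbln)
## The linear predictor eta = mu0 + X beta is the location of log-time
## (AFT convention T = T0 * exp(x'beta)), so positive beta lengthens
## survival.  z = (log t - eta)/sigma is the standardized log-time residual.
n_ancillary <- function(family) if (family == "zbln") 2L else 1L

#' Negative log-likelihood of a right-censored AFT model
#'
#' Returns \eqn{-\sum_i [\delta_i \log f(t_i;\eta_i) +
#' (1-\delta_i)\log S(t_i;\eta_i)]} with \eqn{\eta_i = \mu_0 + x_i'\beta}
#' the location of log-time.  The packed parameter vector is
#' `c(mu0, beta, log sigma)` for the log-normal and Weibull families and
#' `c(mu0, beta, log sigma, log a)` for the ZBLN family.  Non-finite
#' evaluations return a large penalty rather than propagating `NaN` into the
#' optimizer.
#'
#' @param theta packed parameter vector (see Details).
#' @param design numeric design matrix, one row per record.
#' @param times positive times (months).
#' @param events 0/1 event indicators.
#' @param family `"zbln"`, `"lognormal"` or `"weibull"`.
#' @return scalar negative log-likelihood.
#' @export
aft_neg_loglik <- function(theta, design, times, events, family) {
  p <- ncol(design)
  stopifnot(length(theta) == 1 + p + n_ancillary(family),
            nrow(design) == length(times), length(times) == length(events))
  mu0 <- theta[1]
  beta <- theta[seq_len(p) + 1]
  sigma <- exp(theta[2 + p])
  a <- if (family == "zbln") exp(theta[3 + p]) else 1
  eta <- mu0 + drop(design %*% beta)
  z <- (log(times) - eta) / sigma
  d <- events == 1

  if (!all(is.finite(c(sigma, a))) || sigma <= 0 || a <= 0) return(1e10)
  ll <- numeric(length(z))
  if (family == "weibull") {
    ll[d] <- z[d] - exp(z[d]) - theta[2 + p] - log(times[d])
    ll[!d] <- -exp(z[!d])
  } else {
    u <- -pnorm(z, lower.tail = FALSE, log.p = TRUE)
    ll[d] <- dnorm(z[d], log = TRUE) - theta[2 + p] - log(times[d]) +
      (a - 1) * log(u[d]) - lgamma(a)
    ll[!d] <- suppressWarnings(
      pgamma(u[!d], shape = a, lower.tail = FALSE, log.p = TRUE))
  }
  out <- -sum(ll)
  if (!is.finite(out)) 1e10 else out
}

## Analytic gradient of aft_neg_loglik.  The only non-closed-form piece is
## d log Q(a, u) / da for censored ZBLN records, taken by central finite
## difference in a (two vectorized pgamma calls).
aft_neg_loglik_grad <- function(theta, design, times, events, family) {
  p <- ncol(design)
  mu0 <- theta[1]
  beta <- theta[seq_len(p) + 1]
  sigma <- exp(theta[2 + p])
  a <- if (family == "zbln") exp(theta[3 + p]) else 1
  eta <- mu0 + drop(design %*% beta)
  z <- (log(times) - eta) / sigma
  d <- events == 1

  dll_dz <- numeric(length(z))
  dll_da <- NULL
  if (family == "weibull") {
    ez <- exp(z)
    dll_dz[d] <- 1 - ez[d]
    dll_dz[!d] <- -ez[!d]
  } else {
    u <- -pnorm(z, lower.tail = FALSE, log.p = TRUE)
    log_h <- dnorm(z, log = TRUE) - pnorm(z, lower.tail = FALSE, log.p = TRUE)
    h <- exp(log_h)
    dll_dz[d] <- -z[d] + (a - 1) * h[d] / u[d]
    logQ <- pgamma(u[!d], shape = a, lower.tail = FALSE, log.p = TRUE)
    ## d log Q / du = -u^(a-1) e^(-u) / (Gamma(a) Q(a,u))
    logD <- (a - 1) * log(u[!d]) - u[!d] - lgamma(a) - logQ
    dll_dz[!d] <- -exp(logD + log_h[!d])
    if (family == "zbln") {
      dll_da <- numeric(length(z))
      dll_da[d] <- log(u[d]) - digamma(a)
      eps <- 1e-5 * max(a, 1)
      dll_da[!d] <- (pgamma(u[!d], shape = a + eps, lower.tail = FALSE,
                            log.p = TRUE) -
                     pgamma(u[!d], shape = a - eps, lower.tail = FALSE,
                            log.p = TRUE)) / (2 * eps)
    }
  }

  g_eta <- dll_dz * (-1 / sigma)
  g_mu0 <- sum(g_eta)
  g_beta <- drop(crossprod(design, g_eta))
  g_logsig <- sum(dll_dz * (-z)) - sum(d)   # chain rule through log sigma
  g <- c(g_mu0, g_beta, g_logsig)
  if (family == "zbln") g <- c(g, sum(dll_da) * a)
  out <- unname(-g)
  out[!is.finite(out)] <- 0
  out
}

#' Fit a right-censored AFT model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of the censored AFT likelihood with
#' analytic gradients, in unconstrained coordinates
#' `(mu0, beta, log sigma[, log a])`.  Initialisation comes from a
#' least-squares regression of log-time on the design over uncensored
#' records; the ZBLN family additionally multi-starts the generator shape
#' over `a` in `{0.5, 1, 2, 4, 8}` from the fitted log-normal solution.
#' Standard errors come from the inverse of a finite-difference observed
#' information (Hessian of the negative log-likelihood) at the optimum,
#' delta-method-transformed for the ancillary parameters.
#'
#' Constant design columns (zero variance) are dropped with a message: their
#' effect is not identified and is absorbed by the intercept.
#'
#' @param cohort a [cohort_table()].
#' @param spec an [aft_model_spec()].
#' @param seed integer; kept in the result for provenance (the fit itself is
#'   deterministic given the data).
#' @return an object of class `aft_fit`: list with `family`, `coefficients`
#'   (named, log-time units), `intercept`, `sigma`, `a` (ZBLN only), `shape`
#'   (Weibull only, `1/sigma`), `loglik`, `n`, `k`, `aic`, `bic`, `se`
#'   (named, same order as the packed vector, natural scale for
#'   `sigma`/`a`), `converged`, `iterations`, `dropped` (names of constant
#'   columns removed).
#' @export
fit_aft <- function(cohort, spec, seed = 1) {
  stopifnot(inherits(spec, "aft_model_spec"))
  X <- encode_design(cohort)
  if (!is.null(spec$columns)) {
    miss <- setdiff(spec$columns, colnames(X))
    if (length(miss))
      stop("unknown design column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    X <- X[, spec$columns, drop = FALSE]
  }
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  dropped <- colnames(X)[const]
  if (length(dropped)) {
    message("dropping constant design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) stop("empty design after dropping constant columns",
                         call. = FALSE)
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("design matrix is rank deficient", call. = FALSE)

  times <- cohort$time; events <- cohort$event
  fit <- aft_mle(X, times, events, spec$family)

  p <- ncol(X)
  k <- 1 + p + n_ancillary(spec$family)
  n <- length(times)
  theta <- unname(fit$par)
  sigma <- exp(theta[2 + p])

  ## observed information; delta method maps log-scale se to natural scale
  se <- rep(NA_real_, k)
  se_ok <- FALSE
  H <- tryCatch(
    optimHess(theta, aft_neg_loglik, aft_neg_loglik_grad,
              design = X, times = times, events = events,
              family = spec$family),
    error = function(e) NULL)
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (all(ev > 0)) {
      se <- sqrt(diag(solve(H)))
      se_ok <- TRUE
    }
  }
  if (!se_ok)
    warning("observed information not positive definite; ",
            "standard errors unavailable")
  scale_fix <- rep(1, k)
  scale_fix[2 + p] <- sigma                      # d sigma / d log sigma
  if (spec$family == "zbln") scale_fix[3 + p] <- exp(theta[3 + p])
  se <- se * scale_fix
  names(se) <- c("(Intercept)", colnames(X), "sigma",
                 if (spec$family == "zbln") "a")

  out <- list(
    family = spec$family,
    intercept = theta[1],
    coefficients = setNames(theta[seq_len(p) + 1], colnames(X)),
    sigma = sigma,
    a = if (spec$family == "zbln") exp(theta[3 + p]) else NULL,
    shape = if (spec$family == "weibull") 1 / sigma else NULL,
    loglik = -fit$value,
    n = n, k = k,
    aic = information_criteria(-fit$value, k, n)["aic"],
    bic = information_criteria(-fit$value, k, n)["bic"],
    se = se,
    converged = fit$convergence == 0,
    iterations = fit$counts[["function"]],
    dropped = dropped,
    seed = seed)
  class(out) <- "aft_fit"
  out
}

## Shared MLE driver.  Returns the best optim() result across starts.
aft_mle <- function(X, times, events, family) {
  p <- ncol(X)
  d <- events == 1
  if (sum(d) < p + 2)
    stop("too few uncensored records to fit ", p, " coefficients",
         call. = FALSE)
  ## least-squares start on uncensored log-times
  lt <- log(times[d])
  ls <- lm.fit(cbind(1, X[d, , drop = FALSE]), lt)
  beta0 <- ls$coefficients
  beta0[!is.finite(beta0)] <- 0
  s0 <- max(sd(ls$residuals), 1e-2)

  base <- c(beta0, log(s0))
  starts <- list(base)
  if (family == "zbln") {
    ## refine the lognormal solution first, then sweep the generator shape
    ln <- aft_mle(X, times, events, "lognormal")
    starts <- lapply(c(0.5, 1, 2, 4, 8),
                     function(a) c(ln$par, log(a)))
  } else if (family == "weibull") {
    starts <- list(base, c(beta0, log(s0 / 2)))
  }

  fits <- list()
  for (st in starts) {
    fit <- tryCatch(
      optim(st, aft_neg_loglik, aft_neg_loglik_grad,
            design = X, times = times, events = events, family = family,
            method = "BFGS",
            control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value)) fits <- c(fits, list(fit))
  }
  if (length(fits) == 0)
    stop("AFT fit failed to converge from every start (family ", family, ")",
         call. = FALSE)
  if (family == "zbln")
    select_ridge_tiebreak(fits, a_index = p + 3)
  else
    fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("%s AFT fit: n = %d, logLik = %.2f, AIC = %.1f, BIC = %.1f\n",
              x$family, x$n, x$loglik, x$aic, x$bic))
  tab <- acceleration_factors(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Akaike and Bayesian information criteria
#'
#' `aic = 2k - 2 logLik`, `bic = k log(n) - 2 logLik`; the model with the
#' lowest values is considered the best fit.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters (>= 1).
#' @param n number of observations (>= 1).
#' @return named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(loglik, k, n) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  c(aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik)
}

#' Acceleration factors of a fitted AFT model
#'
#' `AF = exp(coefficient)`, reported to 3 decimals in the printed table.  An
#' AF above 1 means the level is associated with longer survival than its
#' reference; below 1, shorter.  If covariate specs are supplied, reference
#' levels are interleaved as `(Ref)` rows with AF exactly 1.
#'
#' @param fit an [fit_aft()] result.
#' @param specs optional list of [covariate_spec()]s used to add reference
#'   rows.
#' @return data frame with columns `term`, `estimate`, `AF`, `p`.
#' @export
acceleration_factors <- function(fit, specs = NULL) {
  if (!fit$converged) warning("model fit did not converge")
  est <- fit$coefficients
  pv <- wald_tests(fit)
  tab <- data.frame(term = names(est),
                    estimate = unname(est),
                    AF = round(exp(unname(est)), 3),
                    p = unname(pv[names(est)]),
                    stringsAsFactors = FALSE)
  if (is.null(specs)) return(tab)
  out <- NULL
  for (sp in specs) {
    if (sp$kind == "continuous") {
      out <- rbind(out, tab[tab$term == sp$name, ])
    } else {
      ref <- data.frame(term = paste0(sp$name, "=", sp$reference, " (Ref)"),
                        estimate = 0, AF = 1, p = NA_real_,
                        stringsAsFactors = FALSE)
      lev <- tab[tab$term %in% paste0(sp$name, "=",
                                      setdiff(sp$levels, sp$reference)), ]
      out <- rbind(out, ref, lev)
    }
  }
  rownames(out) <- NULL
  out
}

#' Wald tests for AFT coefficients
#'
#' Two-sided normal p-values `2 * (1 - pnorm(|beta / se|))` per regression
#' coefficient.  Unavailable standard errors yield `NA`.
#'
#' @param fit an [fit_aft()] result.
#' @return named vector of p-values, one per coefficient.
#' @export
wald_tests <- function(fit) {
  est <- fit$coefficients
  se <- fit$se[names(est)]
  z <- est / se
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  setNames(as.numeric(p), names(est))
}

#' Predicted survival probabilities and median survival times
#'
#' `predict_survival` evaluates \eqn{S(t \mid x)} at the requested horizon
#' for every record; `predict_median` returns the predicted median survival
#' time in months.  Both use the fitted location
#' \eqn{\eta_i = \mu_0 + x_i'\beta}.
#'
#' @param fit an [fit_aft()] result.
#' @param cohort a [cohort_table()] providing covariates.
#' @param time horizon in months at which to evaluate survival; a scalar,
#'   or one value per record.
#' @return numeric vector, one value per record.
#' @export
predict_survival <- function(fit, cohort, time) {
  eta <- aft_linear_predictor(fit, cohort)
  switch(fit$family,
    weibull = exp(-exp((log(time) - eta) / fit$sigma)),
    lognormal = plnorm(time, eta, fit$sigma, lower.tail = FALSE),
    zbln = pgamma(-plnorm(time, eta, fit$sigma, lower.tail = FALSE,
                          log.p = TRUE),
                  shape = fit$a, lower.tail = FALSE))
}

#' @rdname predict_survival
#' @export
predict_median <- function(fit, cohort) {
  eta <- aft_linear_predictor(fit, cohort)
  switch(fit$family,
    weibull = exp(eta + fit$sigma * log(log(2))),
    lognormal = exp(eta),
    zbln = exp(eta + fit$sigma * qnorm(-expm1(-qgamma(0.5, fit$a)))))
}

aft_linear_predictor <- function(fit, cohort) {
  X <- encode_design(cohort)
  nm <- names(fit$coefficients)
  miss <- setdiff(nm, colnames(X))
  if (length(miss))
    stop("cohort design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fit$intercept + drop(X[, nm, drop = FALSE] %*% fit$coefficients)
}
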