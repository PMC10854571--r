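test_that("with all coefficients zero the AFT likelihood reduces to the baseline", {
  co <- toy_cohort(n = 80, seed = 1)
  X <- encode_design(co)
  t <- co$time; ev <- co$event
  for (fam in c("zbln", "lognormal", "weibull")) {
    th <- c(1.4, rep(0, ncol(X)), log(0.9), if (fam == "zbln") log(2))
    got <- aft_neg_loglik(th, X, t, ev, fam)
    base <- switch(fam,
      zbln = -sum(dzbln(t[ev == 1], 2, 1.4, 0.9, log = TRUE)) -
        sum(pzbln(t[ev == 0], 2, 1.4, 0.9, lower.tail = FALSE,
                  log.p = TRUE)),
      lognormal = -sum(dlnorm(t[ev == 1], 1.4, 0.9, log = TRUE)) -
        sum(plnorm(t[ev == 0], 1.4, 0.9, lower.tail = FALSE, log.p = TRUE)),
      weibull = -sum(dweibull(t[ev == 1], 1 / 0.9, exp(1.4), log = TRUE)) -
        sum(pweibull(t[ev == 0], 1 / 0.9, exp(1.4), lower.tail = FALSE,
                     log.p = TRUE)))
    expect_equal(got, base, tolerance = 1e-10)
  }
})

test_that("fully censored records near time zero contribute no likelihood", {
  X <- matrix(rnorm(10), 10, 1)
  t <- rep(1e-9, 10); ev <- rep(0, 10)
  for (fam in c("zbln", "lognormal", "weibull")) {
    th <- c(0.5, 0.2, log(1), if (fam == "zbln") log(1.5))
    expect_equal(aft_neg_loglik(th, X, t, ev, fam), 0, tolerance = 1e-6)
  }
})

test_that("analytic gradients match numerical differentiation", {
  co <- toy_cohort(n = 120, seed = 2)
  X <- encode_design(co)
  with_seed_test(3, {
    for (fam in c("zbln", "lognormal", "weibull")) {
      for (i in 1:7) {
        k <- 1 + ncol(X) + if (fam == "zbln") 2 else 1
        th <- c(rnorm(1 + ncol(X), 0, 0.5), log(runif(1, 0.4, 2)),
                if (fam == "zbln") log(runif(1, 0.5, 3)))[1:k]
        g_analytic <- zblnaft:::aft_neg_loglik_grad(th, X, co$time,
                                                    co$event, fam)
        g_numeric <- numDeriv::grad(aft_neg_loglik, th, design = X,
                                    times = co$time, events = co$event,
                                    family = fam)
        expect_equal(g_analytic, g_numeric, tolerance = 1e-5)
      }
    }
  })
})

test_that("log-normal and Weibull fits agree with an independent survreg fit", {
  co <- toy_cohort(n = 400, seed = 4)
  X <- encode_design(co)
  for (fam in c("lognormal", "weibull")) {
    mine <- fit_aft(co, aft_model_spec(fam))
    ref <- survival::survreg(
      survival::Surv(co$time, co$event) ~ X,
      dist = if (fam == "lognormal") "lognormal" else "weibull")
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-6)
    expect_equal(unname(mine$intercept), unname(coef(ref)[1]),
                 tolerance = 1e-4)
    expect_equal(unname(mine$coefficients), unname(coef(ref)[-1]),
                 tolerance = 1e-4)
    expect_equal(mine$sigma, unname(ref$scale), tolerance = 1e-3)
    # standard errors from the observed information agree too
    expect_equal(unname(mine$se[2:(1 + ncol(X))]),
                 unname(sqrt(diag(vcov(ref)))[2:(1 + ncol(X))]),
                 tolerance = 1e-3)
  }
})

test_that("the ZBLN family never fits worse than its log-normal special case", {
  for (s in c(6, 7)) {
    co <- toy_cohort(n = 300, seed = s)
    fz <- fit_aft(co, aft_model_spec("zbln"))
    fl <- fit_aft(co, aft_model_spec("lognormal"))
    expect_gte(fz$loglik, fl$loglik - 1e-6)
  }
})

test_that("reported AIC and BIC satisfy their defining identities", {
  co <- toy_cohort(n = 200, seed = 8)
  f <- fit_aft(co, aft_model_spec("zbln"))
  expect_equal(f$k, length(f$coefficients) + 2 + 1)
  expect_equal(unname(f$aic), 2 * f$k - 2 * f$loglik, tolerance = 1e-10)
  expect_equal(unname(f$bic), f$k * log(f$n) - 2 * f$loglik,
               tolerance = 1e-10)

  ic <- information_criteria(-10, 2, 100)
  expect_equal(unname(ic["aic"]), 24)
  expect_equal(unname(ic["bic"]), 2 * log(100) + 20, tolerance = 1e-10)
  expect_error(information_criteria(-10, 0, 100), "k")
  with_seed_test(9, for (i in 1:10) {
    k <- sample(1:30, 1); n <- sample(2:10000, 1); ll <- rnorm(1, -500, 100)
    ic <- information_criteria(ll, k, n)
    expect_equal(unname(ic["bic"] - ic["aic"]), k * (log(n) - 2),
                 tolerance = 1e-10)
  })
})

test_that("time rescaling shifts the intercept by log(c) and nothing else", {
  co <- toy_cohort(n = 500, seed = 10)
  f1 <- fit_aft(co, aft_model_spec("zbln"))
  df <- as.data.frame(co)
  cc <- 60 / 36       # censored records land exactly on the wider horizon
  df$time <- df$time * cc
  co2 <- cohort_table(df, attr(co, "specs"), 60)
  f2 <- fit_aft(co2, aft_model_spec("zbln"))
  expect_equal(f2$intercept - f1$intercept, log(cc), tolerance = 1e-3)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-4)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-3)
  expect_equal(f2$a, f1$a, tolerance = 0.02)
})

test_that("acceleration factors are exp(estimate) with reference rows at 1", {
  fake <- structure(list(
    family = "zbln",
    coefficients = c("group=B" = 0.414, "x" = 0, "group=C" = -0.320),
    se = c("(Intercept)" = 0.1, "group=B" = 0.1, "x" = 0.1,
           "group=C" = 0.1),
    converged = TRUE), class = "aft_fit")
  tab <- acceleration_factors(fake)
  expect_equal(tab$AF, c(1.513, 1.000, 0.726))
  specs <- list(covariate_spec("group", "categorical", c("A", "B", "C"),
                               reference = "A"),
                covariate_spec("x", "continuous"))
  tab2 <- acceleration_factors(fake, specs)
  expect_identical(tab2$term[1], "group=A (Ref)")
  expect_equal(tab2$AF[1], 1)
  expect_equal(tab2$estimate[1], 0)
})

test_that("Wald p-values follow the two-sided normal law and decrease in |z|", {
  fake <- structure(list(
    family = "lognormal",
    coefficients = c(b1 = 0.1959964, b2 = 0),
    se = c("(Intercept)" = 1, b1 = 0.1, b2 = 0.3),
    converged = TRUE), class = "aft_fit")
  p <- wald_tests(fake)
  expect_equal(unname(p["b1"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(p["b2"]), 1)
  zs <- seq(0.1, 5, length.out = 50)
  ps <- 2 * pnorm(zs, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("rank-deficient designs are refused", {
  co <- toy_cohort(n = 50, seed = 12)
  df <- as.data.frame(co)
  df$dup <- df$age
  specs <- c(toy_specs(), list(covariate_spec("dup", "continuous")))
  co2 <- cohort_table(df, specs, 36)
  expect_error(fit_aft(co2, aft_model_spec("lognormal")), "rank deficient")
})

test_that("predicted medians and survival probabilities are coherent", {
  co <- toy_cohort(n = 300, seed = 14)
  for (fam in c("zbln", "lognormal", "weibull")) {
    f <- fit_aft(co, aft_model_spec(fam))
    med <- predict_median(f, co)
    # S(median | x) = 1/2 by definition of the median (time vectorizes
    # elementwise against the records)
    s_at_med <- predict_survival(f, co, med)
    expect_equal(s_at_med, rep(0.5, nrow(co)), tolerance = 1e-8)
  }
})
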