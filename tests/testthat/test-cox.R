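make_cox_toy <- function() {
  # covariate deliberately not monotone in time, so the partial
  # likelihood has an interior maximum
  specs <- list(covariate_spec("x", "continuous"))
  cohort_table(data.frame(time = 1:5, event = c(1, 1, 0, 1, 1),
                          x = c(1, 0, 1, 0, 1)),
               specs, 36)
}

test_that("Cox fit maximizes the partial likelihood (brute-force oracle)", {
  co <- make_cox_toy()
  fit <- fit_cox(co)
  # independent brute-force partial likelihood over risk sets (no ties)
  pl <- function(b) {
    x <- co$x; t <- co$time; ev <- co$event
    ll <- 0
    for (i in which(ev == 1)) {
      risk <- t >= t[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  grid <- seq(-6, 6, by = 1e-3)
  b_star <- grid[which.max(vapply(grid, pl, 0))]
  expect_equal(unname(fit$coefficients), b_star, tolerance = 2e-3)
  expect_equal(fit$loglik, pl(unname(fit$coefficients)), tolerance = 1e-8)
  expect_equal(unname(fit$aic), 2 * fit$k - 2 * fit$loglik,
               tolerance = 1e-10)
})

test_that("null partial likelihood is minus the sum of log risk-set sizes", {
  co <- make_cox_toy()
  fit <- fit_cox(co)
  expected <- -sum(vapply(which(co$event == 1),
                          function(i) log(sum(co$time >= co$time[i])), 0))
  expect_equal(fit$model$loglik[1], expected, tolerance = 1e-10)
})

test_that("degenerate Cox designs are refused", {
  specs <- list(covariate_spec("x", "continuous"))
  co <- cohort_table(data.frame(time = 1:5, event = c(1, 1, 0, 1, 1),
                                x = rep(2, 5)), specs, 36)
  expect_error(suppressMessages(fit_cox(co)), "rank deficient|empty design")
  co2 <- cohort_table(data.frame(time = 1:5, event = rep(0, 5),
                                 x = rnorm(5)), specs, 36)
  expect_error(fit_cox(co2), "no events")
})

test_that("Cox estimates are invariant to monotone time transforms", {
  co <- with_seed_test(31, {
    n <- 400
    age <- round(runif(n, 40, 85))
    group <- sample(c("A", "B"), n, replace = TRUE)
    t <- pmin(exp(0.6 + 0.4 * (group == "B") + rnorm(n, 0, 0.5)), 7.7)
    cohort_table(data.frame(time = t, event = rbinom(n, 1, 0.8),
                            age = age, group = group), toy_specs(), 60)
  })
  f1 <- fit_cox(co)
  df <- as.data.frame(co)
  df$time <- df$time^2          # still below the 60-month horizon
  f2 <- fit_cox(cohort_table(df, attr(co, "specs"), 60))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-4)
})

test_that("score test at beta = 0 equals the log-rank statistic", {
  with_seed_test(33, {
    n <- 80
    g <- rep(c("A", "B"), each = n / 2)
    t <- round(rexp(n, ifelse(g == "B", 0.15, 0.1)) * 100) / 100 + 1e-4
    t <- t + seq_len(n) * 1e-6            # break ties
    ev <- rbinom(n, 1, 0.8)
    df <- data.frame(time = pmin(t, 36), event = as.integer(ev & t <= 36),
                     g = g)
    co <- cohort_table(df, list(covariate_spec("g", "categorical",
                                               c("A", "B"))), 36)
    fit <- fit_cox(co)
    sc_test <- fit$model$score
    lr <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
    expect_equal(unname(sc_test), unname(lr$chisq), tolerance = 1e-6)
  })
})

test_that("Schoenfeld test keeps p-values in [0,1] and flags crossing hazards", {
  co <- toy_cohort(n = 300, seed = 35)
  ph <- schoenfeld_ph_test(co)
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  expect_true("GLOBAL" %in% ph$variable)

  # strong non-proportionality: the group effect reverses sign at the
  # median event time (piecewise exponential hazards)
  with_seed_test(36, {
    n <- 2000
    g <- rep(c(0, 1), each = n / 2)
    lam1 <- ifelse(g == 1, 0.4, 0.1)     # before the switch
    lam2 <- ifelse(g == 1, 0.05, 0.2)    # after the switch
    t0 <- 6
    t1 <- rexp(n, lam1)
    t <- ifelse(t1 < t0, t1, t0 + rexp(n, lam2))
    df <- data.frame(time = pmin(t, 60), event = as.integer(t <= 60),
                     g = ifelse(g == 1, "exposed", "control"))
    co2 <- cohort_table(df, list(covariate_spec("g", "categorical",
                                                c("control", "exposed"))),
                        60)
    ph2 <- schoenfeld_ph_test(co2)
    expect_lt(ph2$p[ph2$variable == "g"], 0.001)
  })
})

test_that("LASSO screening selects everything at tiny lambda and nothing at huge lambda", {
  co <- toy_cohort(n = 300, seed = 37)
  sel_all <- lasso_select(co, lambda = c(1e-4, 5e-5), cv_folds = 3, seed = 1)
  expect_setequal(sel_all, c("age", "group"))
  sel_none <- lasso_select(co, lambda = c(20, 10), cv_folds = 3, seed = 1)
  expect_length(sel_none, 0)
  expect_error(lasso_select(co, lambda = numeric(0)), "empty")
  expect_error(lasso_select(co, cv_folds = 1), "cv_folds")
})

test_that("LASSO recovers true effects against pure-noise covariates", {
  hits <- 0
  for (s in 1:20) {
    co <- with_seed_test(400 + s, {
      n <- 3000
      df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                       n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                       n4 = rnorm(n), n5 = rnorm(n))
      eta <- 0.6 * df$x1 - 0.5 * df$x2 + 0.7 * df$x3
      t <- rexp(n, 0.08 * exp(eta))
      df$time <- pmin(t, 36); df$event <- as.integer(t <= 36)
      cohort_table(df, lapply(names(df)[1:8], covariate_spec), 36)
    })
    sel <- lasso_select(co, cv_folds = 10, seed = s)
    if (all(c("x1", "x2", "x3") %in% sel)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
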