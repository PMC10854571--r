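# Shared fixtures and a cache for the expensive multi-seed fit suites, so
# the parameter-recovery and model-selection checks reuse the same cohorts
# and fitted models.

toy_specs <- function() {
  list(covariate_spec("age", "continuous"),
       covariate_spec("group", "categorical", c("A", "B"), reference = "A"))
}

toy_cohort <- function(n = 60, seed = 42, horizon = 36) {
  with_seed_test(seed, {
    age <- round(runif(n, 40, 85))
    group <- sample(c("A", "B"), n, replace = TRUE)
    tstar <- exp(1.5 + 0.4 * (group == "B") + rnorm(n, 0, 0.8))
    cohort_table(
      data.frame(time = pmin(tstar, horizon),
                 event = as.integer(tstar <= horizon),
                 age = age, group = group),
      toy_specs(), horizon)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent O(n^2) concordance oracle: plain double loop over ordered
# pairs, comparable iff the earlier time is an event
brute_force_c <- function(scores, times, events) {
  n <- length(times); num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (scores[j] > scores[i]) num <- num + 1
      else if (scores[j] == scores[i]) num <- num + 0.5
    }
  }
  num / den
}

# 20-seed suite on the default scenario (n = 5000): ZBLN, log-normal and
# Weibull fits per seed, computed once per test run.
.fit_cache <- new.env(parent = emptyenv())

recovery_suite <- function() {
  if (!is.null(.fit_cache$suite)) return(.fit_cache$suite)
  seeds <- 1:20
  suite <- lapply(seeds, function(s) {
    sc <- default_scenario(horizon = 36, n = 5000, seed = s)
    co <- generate_cohort(sc)
    list(scenario = sc,
         zbln = suppressMessages(fit_aft(co, aft_model_spec("zbln"),
                                         seed = s)),
         lognormal = suppressMessages(fit_aft(co,
                                              aft_model_spec("lognormal"),
                                              seed = s)),
         weibull = suppressMessages(fit_aft(co, aft_model_spec("weibull"),
                                            seed = s)))
  })
  .fit_cache$suite <- suite
  suite
}
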