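#' Covariate specifications for the lung-cancer metastasis cohort
#'
#' The nine covariates of the study model with their level sets and the
#' reference levels of the reported multivariate model (race: American
#' Indian, gender: Male, treatment: No Treatment, histology: Epithelial
#' Neoplasms, primary site: Main Bronchus, grade: Well-Differentiated,
#' metastases: Bone Only).
#'
#' @return list of [covariate_spec()] objects in model order.
#' @export
lung_covariate_specs <- function() {
  list(
    covariate_spec("age", "continuous"),
    covariate_spec("race", "categorical",
                   c("American Indian", "Asian", "Black", "White"),
                   reference = "American Indian"),
    covariate_spec("gender", "categorical", c("Male", "Female"),
                   reference = "Male"),
    covariate_spec("treatment", "categorical",
                   c("No Treatment", "Monotherapy", "Bimodal Therapy",
                     "Trimodal Therapy"),
                   reference = "No Treatment"),
    covariate_spec("histology", "categorical",
                   c("Epithelial Neoplasms", "Squamous Cell Neoplasms",
                     "Adenomas and Adenocarcinomas", "Others"),
                   reference = "Epithelial Neoplasms"),
    covariate_spec("primary_site", "categorical",
                   c("Main Bronchus", "Upper Lobe", "Middle Lobe",
                     "Lower Lobe", "Lung NOS", "Overlapping Lesion of Lung"),
                   reference = "Main Bronchus"),
    covariate_spec("grade", "categorical",
                   c("Well-Differentiated", "Moderately Differentiated",
                     "Poorly Differentiated", "Undifferentiated"),
                   reference = "Well-Differentiated"),
    covariate_spec("tisp", "continuous"),
    covariate_spec("metastases", "categorical",
                   c("Bone Only", "Bone and Brain", "Brain Only"),
                   reference = "Bone Only"))
}

## Published cohort composition (percent of patients per level), renormalized
## to sum to one.
lung_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    race = norm(c("American Indian" = 0.005, "Asian" = 0.079,
                  "Black" = 0.111, "White" = 0.805)),
    gender = norm(c("Male" = 0.56, "Female" = 0.44)),
    treatment = norm(c("No Treatment" = 0.28, "Monotherapy" = 0.042,
                       "Bimodal Therapy" = 0.60, "Trimodal Therapy" = 0.086)),
    histology = norm(c("Epithelial Neoplasms" = 0.25,
                       "Squamous Cell Neoplasms" = 0.17,
                       "Adenomas and Adenocarcinomas" = 0.55,
                       "Others" = 0.038)),
    primary_site = norm(c("Main Bronchus" = 0.049, "Upper Lobe" = 0.53,
                          "Middle Lobe" = 0.042, "Lower Lobe" = 0.26,
                          "Lung NOS" = 0.010,
                          "Overlapping Lesion of Lung" = 0.10)),
    grade = norm(c("Well-Differentiated" = 0.043,
                   "Moderately Differentiated" = 0.23,
                   "Poorly Differentiated" = 0.63,
                   "Undifferentiated" = 0.097)),
    metastases = norm(c("Bone Only" = 0.48, "Bone and Brain" = 0.17,
                        "Brain Only" = 0.35)))
}

## Multivariate 3-year model coefficients used as the generating truth,
## named by design column.
lung_coefficients <- function() {
  c("age" = -0.003,
    "race=Asian" = 0.414, "race=Black" = -0.047, "race=White" = 0.023,
    "gender=Female" = 0.066,
    "treatment=Monotherapy" = -0.347,
    "treatment=Bimodal Therapy" = 1.238,
    "treatment=Trimodal Therapy" = 1.237,
    "histology=Squamous Cell Neoplasms" = -0.132,
    "histology=Adenomas and Adenocarcinomas" = 0.016,
    "histology=Others" = -0.355,
    "primary_site=Upper Lobe" = 0.183,
    "primary_site=Middle Lobe" = -0.706,
    "primary_site=Lower Lobe" = -0.012,
    "primary_site=Lung NOS" = -0.823,
    "primary_site=Overlapping Lesion of Lung" = -0.027,
    "grade=Moderately Differentiated" = 0.164,
    "grade=Poorly Differentiated" = -0.122,
    "grade=Undifferentiated" = -0.345,
    "tisp" = 0.202,
    "metastases=Bone and Brain" = -0.320,
    "metastases=Brain Only" = 0.007)
}

#' Default SEER-like generator scenario
#'
#' A scenario reproducing the published cohort's covariate composition
#' (marginals drawn independently), with age truncated-normal
#' (mean 66, sd 11, range 20-95, rounded to years), TISP degenerate at 1,
#' a ZBLN-AFT time-to-event mechanism using the published 3-year
#' multivariate coefficients, and administrative censoring at the chosen
#' horizon.  The intercept `meanlog` was calibrated
#' once by bisection (at the chosen `a = 2`, `sdlog = 1.75`) so that
#' simulated cohorts have a median survival of 5 months, and is frozen
#' here; see the methods vignette for why the published censoring fraction
#' is not a second calibration target.
#'
#' @param horizon administrative censoring horizon, 36 or 60 months.
#' @param n cohort size (default the published cohort size, 20412).
#' @param seed integer seed.
#' @return object of class `generator_scenario`.
#' @export
default_scenario <- function(horizon = 36, n = 20412, seed = 1) {
  if (!horizon %in% c(36, 60)) stop("horizon must be 36 or 60",
                                    call. = FALSE)
  structure(list(
    n = n, seed = seed,
    marginals = lung_marginals(),
    age_mean = 66, age_sd = 11, age_range = c(20, 95),
    tisp_geom_prob = NULL,
    coefficients = lung_coefficients(),
    baseline = list(a = 2, meanlog = -0.773, sdlog = 1.75),
    horizon = horizon),
    class = "generator_scenario")
}

#' Generate a synthetic cohort from a scenario
#'
#' Covariates are drawn independently from the scenario marginals; the
#' latent death time is ZBLN with location
#' \eqn{\mu_0 + x'\beta} (log-months) and the scenario's `(a, sdlog)`;
#' follow-up is administratively censored at the horizon: recorded time is
#' `min(T, horizon)` and the event flag is `T <= horizon`.  Reproducible
#' given the scenario seed; the caller's RNG state is left untouched.
#'
#' @param scenario a [default_scenario()]-style object (class
#'   `generator_scenario`).
#' @return a [cohort_table()].
#' @export
generate_cohort <- function(scenario) {
  sc <- scenario
  stopifnot(inherits(sc, "generator_scenario"))
  specs <- lung_covariate_specs()
  with_seed(sc$seed, {
    n <- sc$n
    lo <- pnorm(sc$age_range[1], sc$age_mean, sc$age_sd)
    hi <- pnorm(sc$age_range[2], sc$age_mean, sc$age_sd)
    age <- round(qnorm(runif(n, lo, hi), sc$age_mean, sc$age_sd))
    tisp <- if (!length(sc$tisp_geom_prob)) rep(1, n)
            else 1 + rgeom(n, sc$tisp_geom_prob)
    df <- data.frame(age = age, tisp = tisp)
    for (v in names(sc$marginals)) {
      m <- sc$marginals[[v]]
      df[[v]] <- sample(names(m), n, replace = TRUE, prob = m)
    }
    df$time <- 1; df$event <- 1         # placeholders for validation below
    cohort0 <- cohort_table(df, specs, sc$horizon)
    X <- encode_design(cohort0)
    b <- sc$coefficients[colnames(X)]
    eta <- sc$baseline$meanlog + drop(X %*% b)
    y <- rgamma(n, shape = sc$baseline$a, rate = 1)
    tstar <- exp(eta + sc$baseline$sdlog * qnorm(-expm1(-y)))
    df$event <- as.integer(tstar <= sc$horizon)
    df$time <- pmin(tstar, sc$horizon)
    cohort_table(df, specs, sc$horizon)
  })
}

#' Re-censor a cohort at a shorter administrative horizon
#'
#' Derives the 36-month view of a 60-month cohort (one extraction,
#' two censoring horizons): deaths after the new horizon become censored at
#' it, censored times are truncated to it.
#'
#' @param cohort a [cohort_table()].
#' @param horizon new horizon, at most the cohort's current horizon.
#' @return a [cohort_table()] with the new horizon.
#' @export
recensor_cohort <- function(cohort, horizon) {
  if (horizon > attr(cohort, "horizon"))
    stop("cannot extend follow-up beyond the recorded horizon",
         call. = FALSE)
  df <- as.data.frame(cohort)
  df$event <- as.integer(df$event == 1 & df$time <= horizon)
  df$time <- pmin(df$time, horizon)
  cohort_table(df, attr(cohort, "specs"), horizon)
}

#' Read or write a generator scenario as JSON
#'
#' @param scenario a `generator_scenario`.
#' @param path JSON file path.
#' @return `read_scenario` a `generator_scenario`; `write_scenario` the
#'   path, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  sc <- unclass(scenario)
  sc$marginals <- lapply(sc$marginals, as.list)   # keep level names in JSON
  sc$coefficients <- as.list(sc$coefficients)
  sc <- sc[!vapply(sc, is.null, TRUE)]
  jsonlite::write_json(sc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc$marginals <- lapply(sc$marginals, unlist)
  sc$coefficients <- unlist(sc$coefficients)
  sc$age_range <- unlist(sc$age_range)
  if (!length(sc$tisp_geom_prob)) sc$tisp_geom_prob <- NULL
  structure(sc, class = "generator_scenario")
}
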