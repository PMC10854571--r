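#' Declare a cohort covariate
#'
#' A covariate is either continuous (age, TISP count) or categorical with an
#' ordered set of level labels and a declared reference level.  Reference
#' levels follow the reported multivariate model (e.g. race: American Indian,
#' treatment: No Treatment), not the raw extraction codes.
#'
#' @param name variable name, matching the cohort CSV column.
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels ordered character vector of level labels (categorical only).
#' @param reference reference level; defaults to the first level.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, kind = c("continuous", "categorical"),
                           levels = NULL, reference = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0)
      stop("categorical covariate '", name, "' needs levels", call. = FALSE)
    if (anyDuplicated(levels))
      stop("duplicate levels for '", name, "'", call. = FALSE)
    if (is.null(reference)) reference <- levels[1]
    if (!reference %in% levels)
      stop("reference '", reference, "' is not a level of '", name, "'",
           call. = FALSE)
  } else {
    levels <- NULL; reference <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels,
                 reference = reference),
            class = "covariate_spec")
}

#' Assemble a validated cohort table
#'
#' Bundles one-row-per-patient survival data with its covariate metadata and
#' the administrative censoring horizon.  Validation enforces positive times,
#' 0/1 event flags, declared categorical levels, and that censored records do
#' not outlive the horizon (the definition of administrative censoring).
#'
#' @param data data frame with columns `time` (months, > 0), `event` (0/1)
#'   and one column per covariate spec.
#' @param specs list of [covariate_spec()] objects.
#' @param horizon administrative censoring horizon in months, 36 or 60.
#' @return an object of class `cohort_table`: the validated data frame with
#'   attributes `specs` and `horizon`.
#' @export
cohort_table <- function(data, specs, horizon) {
  if (!horizon %in% c(36, 60))
    stop("horizon must be 36 or 60 months", call. = FALSE)
  need <- c("time", "event", vapply(specs, `[[`, "", "name"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  bad <- function(rows, what)
    stop("invalid cohort rows (", what, "): ",
         paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) ", ...", call. = FALSE)

  data$time <- as.numeric(data$time)
  data$event <- as.integer(data$event)
  if (any(i <- which(!is.finite(data$time) | data$time <= 0)))
    bad(i, "time must be positive")
  if (any(i <- which(!data$event %in% c(0, 1))))
    bad(i, "event must be 0 or 1")
  if (any(i <- which(data$event == 0 & data$time > horizon)))
    bad(i, "censored time exceeds horizon")
  for (sp in specs) {
    v <- data[[sp$name]]
    if (sp$kind == "categorical") {
      unknown <- setdiff(unique(as.character(v)), sp$levels)
      if (length(unknown))
        stop("unknown level(s) for '", sp$name, "': ",
             paste(unknown, collapse = ", "), " (rows ",
             paste(utils::head(which(as.character(v) %in% unknown), 5),
                   collapse = ", "), ")", call. = FALSE)
      data[[sp$name]] <- factor(as.character(v),
                                levels = ref_first_levels(sp))
    } else {
      if (any(i <- which(!is.finite(v))))
        bad(i, paste0("non-finite ", sp$name))
      data[[sp$name]] <- as.numeric(v)
    }
  }
  data <- data[c("time", "event", vapply(specs, `[[`, "", "name"))]
  rownames(data) <- NULL
  structure(data, specs = specs, horizon = as.numeric(horizon),
            class = c("cohort_table", "data.frame"))
}

ref_first_levels <- function(sp)
  c(sp$reference, setdiff(sp$levels, sp$reference))

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d records, horizon %d months, %d covariates\n",
              nrow(x), attr(x, "horizon"), length(attr(x, "specs"))))
  cat(sprintf("  events: %d (%.1f%%)\n", sum(x$event), 100 * mean(x$event)))
  invisible(x)
}

#' Read and write cohort CSV files
#'
#' Plain comma-separated UTF-8 files with a header row: columns `time`,
#' `event`, then one column per covariate.  `read_cohort` validates every
#' row against the supplied specs (see [cohort_table()]); `write_cohort`
#' writes times with full precision so a round trip is the identity.
#'
#' @param path CSV file path.
#' @param specs list of [covariate_spec()] objects.
#' @param horizon administrative censoring horizon (36 or 60 months).
#' @param zero_time `"error"` (default) rejects rows with `time == 0`;
#'   `"remap"` records them as 0.5 months — registry extracts record whole
#'   months, so a death in the month of diagnosis appears as a zero even
#'   though log-time models need positive support.
#' @param cohort a `cohort_table`.
#' @return `read_cohort` a validated [cohort_table()]; `write_cohort` the
#'   path, invisibly.
#' @export
read_cohort <- function(path, specs, horizon,
                        zero_time = c("error", "remap")) {
  zero_time <- match.arg(zero_time)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"time" %in% names(df))
    stop("missing column(s): time", call. = FALSE)
  if (zero_time == "remap")
    df$time[!is.na(df$time) & df$time == 0] <- 0.5
  cohort_table(df, specs, horizon)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (sp in attr(cohort, "specs"))
    if (sp$kind == "categorical") df[[sp$name]] <- as.character(df[[sp$name]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read covariate specs and horizon from a JSON config
#'
#' The config is an object with a `horizon` field and a `covariates` array of
#' `{name, kind, levels, reference}` objects.
#'
#' @param path JSON file path.
#' @return list with elements `specs` (list of [covariate_spec()]) and
#'   `horizon`.
#' @export
read_cohort_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(cfg$covariates)), function(i) {
    row <- cfg$covariates[i, ]
    covariate_spec(row$name, row$kind,
                   levels = unlist(row$levels), reference = row$reference)
  })
  list(specs = specs, horizon = cfg$horizon)
}

#' Dummy-encode a cohort into a design matrix
#'
#' Continuous covariates pass through unchanged; a categorical covariate with
#' L levels contributes L-1 indicator columns, omitting the declared
#' reference level.  Column order is deterministic: covariates in spec
#' order, levels in declared order.  Column names are `name` for continuous
#' covariates and `name=level` for indicators.
#'
#' @param cohort a [cohort_table()].
#' @return numeric matrix with one row per record.
#' @export
encode_design <- function(cohort) {
  specs <- attr(cohort, "specs")
  cols <- list()
  for (sp in specs) {
    v <- cohort[[sp$name]]
    if (sp$kind == "continuous") {
      cols[[sp$name]] <- as.numeric(v)
    } else {
      if (length(sp$levels) < 2)
        stop("categorical covariate '", sp$name,
             "' has a single level: degenerate design", call. = FALSE)
      for (lv in setdiff(sp$levels, sp$reference))
        cols[[paste0(sp$name, "=", lv)]] <- as.numeric(v == lv)
    }
  }
  do.call(cbind, cols)
}

#' Split a cohort into training and validation parts
#'
#' Random disjoint partition with `round(n * train_fraction)` training
#' records, reproducible given the seed.
#'
#' @param cohort a [cohort_table()].
#' @param train_fraction proportion in (0, 1); default 0.7.
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`, both `cohort_table`s.
#' @export
split_cohort <- function(cohort, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)", call. = FALSE)
  n <- nrow(cohort)
  if (n < 2) stop("cannot split a cohort with fewer than 2 records",
                  call. = FALSE)
  n_train <- round(n * train_fraction)
  idx <- with_seed(seed, sample.int(n, n_train))
  specs <- attr(cohort, "specs"); horizon <- attr(cohort, "horizon")
  list(train = cohort_table(as.data.frame(cohort)[idx, , drop = FALSE],
                            specs, horizon),
       test = cohort_table(as.data.frame(cohort)[-idx, , drop = FALSE],
                           specs, horizon))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
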