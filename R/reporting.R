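## Cohort file I/O, descriptive statistics and the file-based pipeline.
## The cohort CSV dialect: comma-delimited, UTF-8, "." decimal mark, header
## row, columns id, time_days, event, diagnosis, sex, bmi_cat, age_years,
## hb_pre, n_recurrence.  Unknown extra columns are preserved and ignored.

COHORT_REQUIRED_COLS <- c("id", "time_days", "event", "diagnosis", "sex",
                          "bmi_cat", "age_years", "hb_pre", "n_recurrence")
DIAGNOSIS_LEVELS <- c("ALL", "MM", "NHL", "HD", "AML")
SEX_LEVELS <- c("female", "male")
BMI_LEVELS <- c("Obese", "UW", "NW", "OW")

#' Read and write cohort CSV files
#'
#' `read_cohort()` loads a cohort file, types the columns (factors with the
#' reporting reference levels ALL / female / Obese first) and validates the
#' schema.  Rows with missing or blank required fields are dropped with a
#' message recording the exclusion count, mirroring registry curation where
#' incomplete records are excluded.  `write_cohort()` writes the same
#' dialect back.
#'
#' @param path File path.
#' @return `read_cohort()`: a typed data frame of survival records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("time_days", "age_years", "hb_pre", "n_recurrence", "event")) {
    v <- raw[[col]]
    bad <- which(!is.na(v) & v != "" & is.na(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop("malformed numeric field '", col, "' at data row(s) ",
           paste(head(bad, 5), collapse = ", "))
    raw[[col]] <- suppressWarnings(as.numeric(v))
  }
  complete <- stats::complete.cases(raw[COHORT_REQUIRED_COLS]) &
    raw$diagnosis %in% DIAGNOSIS_LEVELS &
    raw$sex %in% SEX_LEVELS &
    raw$bmi_cat %in% BMI_LEVELS &
    raw$event %in% c(0, 1) &
    raw$time_days >= 0
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message("read_cohort: excluded ", n_dropped,
            " incomplete or invalid row(s) of ", nrow(raw))
  out <- raw[complete, , drop = FALSE]
  if (nrow(out) == 0) stop("no valid rows remain after exclusions")
  out$diagnosis <- factor(out$diagnosis, levels = DIAGNOSIS_LEVELS)
  out$sex <- factor(out$sex, levels = SEX_LEVELS)
  out$bmi_cat <- factor(out$bmi_cat, levels = BMI_LEVELS)
  out$event <- as.integer(out$event)
  rownames(out) <- NULL
  out
}

#' @rdname read_cohort
#' @param records A cohort data frame.
#' @export
write_cohort <- function(records, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  write.csv(records, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Frequency table of a categorical covariate
#'
#' Counts and percentages (1 decimal) by level, the building block of a
#' patient-characteristics table.
#'
#' @param records Cohort data frame.
#' @param factor_name One of `diagnosis`, `sex`, `bmi_cat`.
#' @return A data frame: `level`, `count`, `percent`.
#' @examples
#' freqs <- data.frame(diagnosis = rep(c("MM", "ALL"), c(3, 1)),
#'                     sex = "male", bmi_cat = "NW")
#' frequency_table(freqs, "diagnosis")
#' @export
frequency_table <- function(records, factor_name) {
  valid <- c("diagnosis", "sex", "bmi_cat")
  if (!factor_name %in% valid)
    stop("unknown factor '", factor_name, "'; valid factors: ",
         paste(valid, collapse = ", "))
  v <- records[[factor_name]]
  tab <- table(if (is.factor(v)) droplevels(v) else v)
  data.frame(level = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 1),
             row.names = NULL)
}

#' Descriptive summary of a cohort
#'
#' Mean follow-up time with a normal-approximation 95% confidence interval
#' (mean +/- 1.96 sd / sqrt(n)), the event count and percentage, and the
#' means of the continuous covariates.
#'
#' @param records Cohort data frame (n >= 2).
#' @return A list: `n`, `mean_time`, `mean_time_ci` (length 2),
#'   `n_events`, `event_percent`, `covariate_means`.
#' @export
descriptive_summary <- function(records) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records")
  m <- mean(records$time_days)
  half <- qnorm(0.975) * sd(records$time_days) / sqrt(n)
  n_ev <- sum(records$event == 1)
  list(n = n, mean_time = m, mean_time_ci = c(m - half, m + half),
       n_events = n_ev, event_percent = round(100 * n_ev / n, 1),
       covariate_means = c(
         age_years = mean(records$age_years),
         hb_pre = mean(records$hb_pre),
         n_recurrence = mean(records$n_recurrence)))
}

pipeline_log <- function(..., logfile = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run one step of the file-based analysis pipeline
#'
#' Subcommands: `"simulate"` writes a synthetic cohort CSV from a
#' [cohort_config()] and a seed; `"fit"` fits the LEG cure model with the
#' full covariate set and writes the Wald summary CSV plus a fit log;
#' `"km"` writes Kaplan-Meier curve CSVs and PNG plots (overall, or
#' stratified by diagnosis, sex, or age dichotomized at 35 years with the
#' boundary in the younger group); `"report"` writes frequency tables and
#' the descriptive summary.  Every stochastic step logs its seed; a JSON
#' run-metadata file is written alongside the artifacts.
#'
#' @param command One of `"simulate"`, `"fit"`, `"km"`, `"report"`.
#' @param input Input cohort CSV (all commands except `simulate`).
#' @param output_dir Directory for artifacts (created if needed).
#' @param config A [cohort_config()] for `simulate`.
#' @param seed Integer seed for `simulate`.
#' @param by Stratification for `km`: `"none"`, `"diagnosis"`, `"sex"`,
#'   `"age35"`.
#' @param level Confidence level for `fit`.
#' @param n Cohort size override for `simulate`.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "km", "report"),
                         input = NULL, output_dir = ".",
                         config = cohort_config(), seed = 1L,
                         by = c("none", "diagnosis", "sex", "age35"),
                         level = 0.95, n = NULL) {
  command <- match.arg(command)
  by <- match.arg(by)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  logfile <- file.path(output_dir, paste0(command, ".log"))
  written <- character(0)

  need_input <- function() {
    if (is.null(input)) stop("command '", command, "' requires `input`")
    read_cohort(input)
  }

  if (command == "simulate") {
    if (!is.null(n)) config <- utils::modifyList(config, list(n = as.integer(n)))
    class(config) <- "cohort_config"
    pipeline_log("simulate: n = ", config$n, ", seed = ", seed,
                 logfile = logfile)
    path <- file.path(output_dir, "cohort.csv")
    generate_cohort(config, seed = seed, path = path)
    written <- c(written, path)
  } else if (command == "fit") {
    dat <- need_input()
    pipeline_log("fit: n = ", nrow(dat), ", events = ", sum(dat$event),
                 logfile = logfile)
    fit <- legcure(survival::Surv(time_days, event) ~ diagnosis + sex +
                     bmi_cat + age_years + hb_pre + n_recurrence, data = dat)
    if (!fit$converged)
      stop("LEG fit did not converge",
           if (fit$boundary) " (boundary: no events observed)" else "")
    s <- summary(fit, level = level)
    path <- file.path(output_dir, "wald_summary.csv")
    tab <- s$table
    tab$level <- sub("^(diagnosis|sex|bmi_cat)", "", tab$term)
    tab <- tab[c("term", "level", "estimate", "se", "z", "p_value",
                 "odds_ratio", "ci_low", "ci_high", "significant")]
    write.csv(tab, path, row.names = FALSE)
    pipeline_log(sprintf("fit: loglik = %.3f, lambda = %.6g, cure fraction = %.1f%%",
                         fit$loglik, fit$lambda,
                         cure_fraction(fit, dat)$mean_percent),
                 logfile = logfile)
    written <- c(written, path)
  } else if (command == "km") {
    dat <- need_input()
    strata <- switch(by,
      none = NULL,
      diagnosis = as.character(dat$diagnosis),
      sex = as.character(dat$sex),
      age35 = ifelse(dat$age_years < 35, "age<35", "age>=35"))
    pipeline_log("km: by = ", by, logfile = logfile)
    km <- km_fit(dat$time_days, dat$event, strata = strata)
    path <- file.path(output_dir, paste0("km_", by, ".csv"))
    write.csv(as.data.frame(km), path, row.names = FALSE)
    figpath <- file.path(output_dir, paste0("km_", by, ".png"))
    png(figpath, width = 800, height = 600)
    plot(km, main = paste("Kaplan-Meier survival,", by))
    dev.off()
    written <- c(written, path, figpath)
  } else if (command == "report") {
    dat <- need_input()
    pipeline_log("report: n = ", nrow(dat), logfile = logfile)
    freq <- do.call(rbind, lapply(c("diagnosis", "sex", "bmi_cat"), function(f) {
      tb <- frequency_table(dat, f)
      cbind(factor = f, tb)
    }))
    fpath <- file.path(output_dir, "frequency_table.csv")
    write.csv(freq, fpath, row.names = FALSE)
    ds <- descriptive_summary(dat)
    dpath <- file.path(output_dir, "descriptives.csv")
    write.csv(data.frame(
      statistic = c("n", "mean_time_days", "mean_time_ci_low",
                    "mean_time_ci_high", "n_events", "event_percent",
                    paste0("mean_", names(ds$covariate_means))),
      value = c(ds$n, ds$mean_time, ds$mean_time_ci, ds$n_events,
                ds$event_percent, unname(ds$covariate_means))),
      dpath, row.names = FALSE)
    written <- c(written, fpath, dpath)
  }

  meta <- file.path(output_dir, paste0(command, "_run.json"))
  jsonlite::write_json(list(
    command = command, seed = seed, by = by,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("legcure")),
    files = written), meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, meta))
}
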