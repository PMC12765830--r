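#' Write a trial dataset to delimited text
#'
#' Serialises a `trial_dataset` to a directory of long-format CSV files plus
#' a JSON run configuration naming them and recording the assessment grid:
#' `participants.csv`, `assessments.csv` (one row per participant and
#' assessment), `rescues.csv`, `pca.csv` and `config.json`. Missing scores
#' are written as empty fields, never as 0 or a sentinel value, so that
#' missingness survives a round trip. Times are written in hours at minute
#' resolution.
#'
#' @param ds A validated `trial_dataset`.
#' @param dir Output directory; created if needed.
#' @return `dir`, invisibly. `read_trial_csv(write_trial_csv(ds, dir))`
#'   reproduces `ds` at value level.
#' @seealso [read_trial_csv()]
#' @export
write_trial_csv <- function(ds, dir) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }

  p <- ds$participants
  a <- ds$assessments
  long <- data.frame(
    id = a$id,
    arm = p$arm[match(a$id, p$id)],
    randomized = p$randomized[match(a$id, p$id)],
    treated = p$treated[match(a$id, p$id)],
    time_h = format_hours(a$time_min),
    pi = a$pi,
    pr = a$pr,
    night_sleep = a$night_sleep,
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, file.path(dir, "assessments.csv"),
                   row.names = FALSE, na = "")

  pt <- p[, c("id", "arm", "randomized", "treated", "completed",
              "satisfaction_participant", "satisfaction_investigator")]
  utils::write.csv(pt, file.path(dir, "participants.csv"),
                   row.names = FALSE, na = "")

  r <- ds$rescues
  utils::write.csv(
    data.frame(id = r$id, time_h = format_hours(r$time_min), drug = r$drug,
               dose = r$dose, stringsAsFactors = FALSE),
    file.path(dir, "rescues.csv"), row.names = FALSE, na = "")

  pc <- ds$pca
  utils::write.csv(
    data.frame(id = pc$id, time_h = format_hours(pc$time_min),
               accepted = pc$accepted, stringsAsFactors = FALSE),
    file.path(dir, "pca.csv"), row.names = FALSE, na = "")

  jsonlite::write_json(
    list(
      files = list(participants = "participants.csv",
                   assessments = "assessments.csv",
                   rescues = "rescues.csv",
                   pca = "pca.csv"),
      schedule_h = minutes_to_hours(ds$schedule_min)
    ),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

# hours with enough digits that round(x * 60) recovers the exact minute
format_hours <- function(time_min) {
  formatC(time_min / 60, digits = 10, format = "g")
}

#' Read a trial dataset from delimited text
#'
#' Reads the CSV dialect written by [write_trial_csv()]: a directory (or its
#' `config.json`) naming the participants, assessments, rescue and PCA
#' tables. All tables are validated on read; malformed rows are reported
#' with their row numbers.
#'
#' @param path Directory containing `config.json`, or the path of the JSON
#'   config itself.
#' @return A validated `trial_dataset`. A header-only assessments file
#'   yields a dataset with zero participants.
#' @export
read_trial_csv <- function(path) {
  if (dir.exists(path)) {
    config_path <- file.path(path, "config.json")
  } else {
    config_path <- path
  }
  if (!file.exists(config_path)) {
    stop("no run configuration found at ", config_path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  dir <- dirname(config_path)

  pt <- read_table_checked(file.path(dir, cfg$files$participants),
                           c("id", "arm", "randomized", "treated"))
  a <- read_table_checked(file.path(dir, cfg$files$assessments),
                          c("id", "time_h", "pi", "pr", "night_sleep"))
  r <- read_table_checked(file.path(dir, cfg$files$rescues),
                          c("id", "time_h", "drug", "dose"))
  pc <- read_table_checked(file.path(dir, cfg$files$pca),
                           c("id", "time_h", "accepted"))

  check_integerish(a$pi, "pi", cfg$files$assessments)
  check_integerish(a$pr, "pr", cfg$files$assessments)
  a$pi <- as.integer(a$pi)
  a$pr <- as.integer(a$pr)
  a$night_sleep <- as.logical(a$night_sleep)

  pt$randomized <- as.logical(pt$randomized)
  pt$treated <- as.logical(pt$treated)
  if (!is.null(pt$completed)) pt$completed <- as.logical(pt$completed)

  trial_dataset(
    participants = pt,
    assessments = a[, c("id", "time_h", "pi", "pr", "night_sleep")],
    rescues = r,
    pca = pc,
    schedule = as.numeric(cfg$schedule_h)
  )
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("file ", basename(path), " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

check_integerish <- function(x, name, file) {
  bad <- which(!is.na(x) & x != round(x))
  if (length(bad)) {
    stop("non-integer ", name, " in ", file, " at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}
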