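#' Protocol assessment schedule
#'
#' The nominal post-dose assessment grid of the trial design, in hours from
#' Time 0 (the start of the loading-dose infusion). The grid contains the
#' baseline at 0 h, the end-of-loading-infusion assessment at 10 min, and the
#' scheduled assessments at 20 min, 30 min, 45 min, 1, 1.5, 2, 3, 4, 5, 6, 8,
#' 10, 12, 18 and 24 h. Interval weights over the grid sum to exactly 24 h,
#' which is what gives the summed pain intensity difference over 24 h its
#' theoretical range of -240 to 240 on a 0-10 pain scale.
#'
#' All times are quantized to whole minutes internally; the grid is returned
#' in hours (e.g. 20 min is `1/3`).
#'
#' @return Numeric vector of assessment times in hours, strictly increasing,
#'   starting at 0 and ending at 24.
#' @export
#' @examples
#' protocol_schedule()
protocol_schedule <- function() {
  protocol_schedule_min() / 60
}

# schedule in integer minutes; all interval arithmetic is done on this grid so
# weights are exact integers and SPID/TOTPAR need a single division by 60
protocol_schedule_min <- function() {
  c(0L, 10L, 20L, 30L, 45L, 60L, 90L, 120L, 180L, 240L, 300L, 360L,
    480L, 600L, 720L, 1080L, 1440L)
}

#' Convert between hours and whole minutes
#'
#' Times in this package are quantized to whole minutes so that interval
#' weights on the assessment grid are exact. `hours_to_minutes()` rounds to
#' the nearest minute; `minutes_to_hours()` is the exact inverse.
#'
#' @param hours,minutes Numeric vectors.
#' @return Integer minutes, or numeric hours.
#' @keywords internal
hours_to_minutes <- function(hours) {
  as.integer(round(hours * 60))
}

minutes_to_hours <- function(minutes) {
  minutes / 60
}

#' Trial arm labels
#'
#' The four arms of the emulated design: placebo, two doses of the
#' investigational analgesic, and the active comparator.
#'
#' @return Character vector of arm labels in protocol order.
#' @export
trial_arms <- function() {
  c("placebo", "tegileridine_0_75", "tegileridine_1_0", "morphine")
}

#' Assemble a trial dataset
#'
#' Bundles the per-participant tables of an acute-pain trial into a validated
#' `trial_dataset` object: one row per participant in `participants`, long
#' format pain assessments in `assessments`, and event logs for rescue
#' medication and patient-controlled-analgesia (PCA) demands.
#'
#' @param participants Data frame with columns `id`, `arm` (one of
#'   [trial_arms()]), `randomized`, `treated`, `completed` (logicals), and
#'   optionally `satisfaction_participant`, `satisfaction_investigator`
#'   (integer 0-10 or `NA`).
#' @param assessments Data frame with columns `id`, `time_h` (hours from Time
#'   0), `pi` (pain intensity NRS, integer 0-10 or `NA`), `pr` (pain relief
#'   Likert, integer 0-4 or `NA`; undefined at time 0) and `night_sleep`
#'   (logical: the assessment fell in the participant's night-sleep period).
#' @param rescues Data frame with columns `id`, `time_h`, `drug`
#'   (`"parecoxib"` or `"sufentanil"`) and `dose` (positive; mg for
#'   parecoxib, micrograms for sufentanil). May be empty.
#' @param pca Data frame with columns `id`, `time_h`, `accepted` (logical:
#'   the pump delivered the demand dose). May be empty.
#' @param schedule Nominal assessment grid in hours; defaults to
#'   [protocol_schedule()].
#'
#' @return An object of class `trial_dataset`: a list with elements
#'   `participants`, `assessments`, `rescues`, `pca` (times stored as integer
#'   minutes in `time_min` alongside `time_h`) and `schedule_min`.
#' @seealso [read_trial_csv()], [simulate_trial()], [select_analysis_set()]
#' @export
trial_dataset <- function(participants, assessments,
                          rescues = empty_rescues(),
                          pca = empty_pca(),
                          schedule = protocol_schedule()) {
  participants <- as.data.frame(participants)
  assessments <- as.data.frame(assessments)
  rescues <- as.data.frame(rescues)
  pca <- as.data.frame(pca)

  for (col in c("satisfaction_participant", "satisfaction_investigator")) {
    if (is.null(participants[[col]])) {
      participants[[col]] <- rep(NA_integer_, nrow(participants))
    }
  }
  if (is.null(participants$completed)) {
    participants$completed <- rep(TRUE, nrow(participants))
  }

  assessments$time_min <- hours_to_minutes(assessments$time_h)
  assessments$time_h <- minutes_to_hours(assessments$time_min)
  if (nrow(rescues)) {
    rescues$time_min <- hours_to_minutes(rescues$time_h)
    rescues$time_h <- minutes_to_hours(rescues$time_min)
  } else {
    rescues <- empty_rescues()
  }
  if (nrow(pca)) {
    pca$time_min <- hours_to_minutes(pca$time_h)
    pca$time_h <- minutes_to_hours(pca$time_min)
  } else {
    pca <- empty_pca()
  }

  ds <- structure(
    list(
      participants = participants,
      assessments = assessments,
      rescues = rescues,
      pca = pca,
      schedule_min = hours_to_minutes(schedule)
    ),
    class = "trial_dataset"
  )
  validate_trial_dataset(ds)
}

empty_rescues <- function() {
  data.frame(id = character(), time_h = numeric(), drug = character(),
             dose = numeric(), time_min = integer(),
             stringsAsFactors = FALSE)
}

empty_pca <- function() {
  data.frame(id = character(), time_h = numeric(), accepted = logical(),
             time_min = integer(), stringsAsFactors = FALSE)
}

#' Validate a trial dataset
#'
#' Checks the typed invariants of the trial tables: pain intensity an integer
#' in 0-10 when present, pain relief an integer in 0-4, assessment times
#' non-negative and strictly increasing within participant, baseline (time 0)
#' present with pain intensity >= 4 (the moderate-to-severe inclusion
#' criterion), rescue doses positive, and the schedule anchored at 0 and
#' 24 h. Violations are reported with the offending row numbers.
#'
#' @param ds A `trial_dataset`.
#' @param require_baseline_severity If `TRUE` (default) enforce baseline
#'   pain intensity >= 4 for every participant.
#' @return `ds`, invisibly usable, if valid; otherwise an error listing every
#'   violated invariant.
#' @export
validate_trial_dataset <- function(ds, require_baseline_severity = TRUE) {
  stopifnot(inherits(ds, "trial_dataset"))
  p <- ds$participants
  a <- ds$assessments
  problems <- character()

  need_p <- c("id", "arm", "randomized", "treated")
  miss <- setdiff(need_p, names(p))
  if (length(miss)) {
    stop("participants table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  need_a <- c("id", "time_min", "pi", "pr", "night_sleep")
  miss <- setdiff(need_a, names(a))
  if (length(miss)) {
    stop("assessments table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  if (anyDuplicated(p$id)) {
    problems <- c(problems, paste0(
      "duplicated participant id(s): ",
      paste(unique(p$id[duplicated(p$id)]), collapse = ", ")))
  }
  bad_arm <- which(!p$arm %in% trial_arms())
  if (length(bad_arm)) {
    problems <- c(problems, paste0(
      "unknown arm in participants row(s) ",
      paste(bad_arm, collapse = ", ")))
  }

  bad <- which(!is.na(a$pi) & (a$pi != round(a$pi) | a$pi < 0 | a$pi > 10))
  if (length(bad)) {
    problems <- c(problems, paste0(
      "pain intensity outside integer 0-10 in assessment row(s) ",
      paste(bad, collapse = ", ")))
  }
  bad <- which(!is.na(a$pr) & (a$pr != round(a$pr) | a$pr < 0 | a$pr > 4))
  if (length(bad)) {
    problems <- c(problems, paste0(
      "pain relief outside integer 0-4 in assessment row(s) ",
      paste(bad, collapse = ", ")))
  }
  bad <- which(a$time_min < 0)
  if (length(bad)) {
    problems <- c(problems, paste0(
      "negative assessment time in row(s) ", paste(bad, collapse = ", ")))
  }
  bad <- which(!a$id %in% p$id)
  if (length(bad)) {
    problems <- c(problems, paste0(
      "assessment row(s) for unknown participant: ",
      paste(bad, collapse = ", ")))
  }

  sched <- ds$schedule_min
  if (length(sched) < 2 || sched[1] != 0L || sched[length(sched)] != 1440L ||
      any(diff(sched) <= 0)) {
    problems <- c(problems,
                  "schedule must be strictly increasing from 0 to 24 h")
  }
  off_grid <- which(!a$time_min %in% sched)
  if (length(off_grid)) {
    problems <- c(problems, paste0(
      "assessment time off the protocol grid in row(s) ",
      paste(off_grid, collapse = ", ")))
  }

  if (nrow(a)) {
    f <- factor(a$id, levels = unique(a$id))
    nonincreasing <- tapply(a$time_min, f, function(t) any(diff(t) <= 0))
    bad_ids <- names(nonincreasing)[nonincreasing]
    if (length(bad_ids)) {
      problems <- c(problems, paste0(
        "assessment times not strictly increasing for participant(s) ",
        paste(bad_ids, collapse = ", ")))
    }
    base_rows <- a$time_min == 0L
    no_base <- setdiff(levels(f), a$id[base_rows])
    if (length(no_base)) {
      problems <- c(problems, paste0(
        "no baseline (time 0) assessment for participant(s) ",
        paste(no_base, collapse = ", ")))
    }
    base_pi <- a$pi[base_rows]
    base_ids <- a$id[base_rows]
    if (anyNA(base_pi)) {
      problems <- c(problems, paste0(
        "missing baseline pain intensity for participant(s) ",
        paste(base_ids[is.na(base_pi)], collapse = ", ")))
    }
    if (require_baseline_severity) {
      low <- !is.na(base_pi) & base_pi < 4
      if (any(low)) {
        problems <- c(problems, paste0(
          "baseline pain intensity below 4 for participant(s) ",
          paste(base_ids[low], collapse = ", "), " (inclusion criterion)"))
      }
    }
  }

  r <- ds$rescues
  if (nrow(r)) {
    bad <- which(r$dose <= 0)
    if (length(bad)) {
      problems <- c(problems, paste0(
        "non-positive rescue dose in row(s) ", paste(bad, collapse = ", ")))
    }
    bad <- which(!r$drug %in% c("parecoxib", "sufentanil"))
    if (length(bad)) {
      problems <- c(problems, paste0(
        "unknown rescue drug in row(s) ", paste(bad, collapse = ", ")))
    }
    bad <- which(r$time_min <= 0)
    if (length(bad)) {
      problems <- c(problems, paste0(
        "rescue event at time <= 0 in row(s) ", paste(bad, collapse = ", ")))
    }
  }

  if (length(problems)) {
    stop("invalid trial dataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  ds
}

#' @export
print.trial_dataset <- function(x, ...) {
  p <- x$participants
  cat("<trial_dataset>\n")
  cat("  participants:", nrow(p), "\n")
  if (nrow(p)) {
    tab <- table(factor(p$arm, levels = trial_arms()))
    cat("  per arm:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  cat("  assessments:", nrow(x$assessments),
      " rescue events:", nrow(x$rescues),
      " PCA presses:", nrow(x$pca), "\n")
  cat("  schedule:", length(x$schedule_min), "points over (0, 24] h\n")
  invisible(x)
}

#' Number of participants
#' @param ds A `trial_dataset`.
#' @return Integer count.
#' @export
n_participants <- function(ds) {
  nrow(ds$participants)
}

#' Select an analysis population
#'
#' Subsets a trial dataset to one of the standard analysis sets: the full
#' analysis set (`"FAS"`: randomized participants who received study
#' treatment, the population for efficacy), the intention-to-treat population
#' (`"ITT"`: all randomized participants), or the safety population
#' (`"SAFETY"`: all treated participants).
#'
#' @param ds A `trial_dataset` with `randomized` and `treated` flags.
#' @param set One of `"FAS"`, `"ITT"`, `"SAFETY"`.
#' @return A `trial_dataset` restricted to the selected participants.
#' @export
#' @examples
#' ds <- simulate_trial(simulation_config(n_per_arm = 3), seed = 1)
#' select_analysis_set(ds, "FAS")
select_analysis_set <- function(ds, set = c("FAS", "ITT", "SAFETY")) {
  set <- match.arg(set)
  p <- ds$participants
  keep <- switch(set,
    FAS = p$randomized & p$treated,
    ITT = p$randomized,
    SAFETY = p$treated
  )
  subset_participants(ds, p$id[keep])
}

subset_participants <- function(ds, ids) {
  out <- ds
  out$participants <- ds$participants[ds$participants$id %in% ids, ,
                                      drop = FALSE]
  out$assessments <- ds$assessments[ds$assessments$id %in% ids, ,
                                    drop = FALSE]
  out$rescues <- ds$rescues[ds$rescues$id %in% ids, , drop = FALSE]
  out$pca <- ds$pca[ds$pca$id %in% ids, , drop = FALSE]
  rownames(out$participants) <- NULL
  rownames(out$assessments) <- NULL
  rownames(out$rescues) <- NULL
  rownames(out$pca) <- NULL
  out
}

#' Per-arm participant counts
#'
#' @param ds A `trial_dataset`.
#' @return Named integer vector over the four protocol arms.
#' @export
arm_sizes <- function(ds) {
  tab <- table(factor(ds$participants$arm, levels = trial_arms()))
  stats::setNames(as.integer(tab), names(tab))
}
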