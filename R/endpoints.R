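#' Imputation policy for pain scores
#'
#' Parameters of the protocol's three imputation regimes for missing pain
#' intensity (PI) and pain relief (PR) scores, applied in this precedence:
#'
#' 1. *Rescue-window rule*: points within `(rescue_time, rescue_time +
#'    window]` — 6 h for parecoxib, 2 h for sufentanil — take the last score
#'    recorded before the rescue, so that rescue analgesia is not credited
#'    to the study drug. When two rescue windows overlap, the later rescue's
#'    pre-rescue score governs from its own event time.
#' 2. *Night-sleep rule* (outside rescue windows): a missing PI during
#'    night sleep is set to `night_pi_value` (default NRS 3); a missing PR
#'    takes the previous PR score.
#' 3. *Last observation carried forward* for all other missing scores.
#'
#' By default the rescue-window rule fills only missing points;
#' `strict_rescue = TRUE` additionally overwrites observed post-rescue
#' scores inside the window with the pre-rescue score. In mode
#' `"sensitivity_no_rescue_imputation"` the rescue rule is disabled
#' entirely and post-rescue scores are used as recorded — the protocol's
#' sensitivity analysis.
#'
#' @param night_pi_value NRS value imputed for missing night-sleep PI
#'   (integer 0-10, default 3).
#' @param parecoxib_window,sufentanil_window Carry-back windows in hours
#'   after a rescue dose (> 0; defaults 6 and 2).
#' @param mode `"primary"` or `"sensitivity_no_rescue_imputation"`.
#' @param strict_rescue Logical; replace observed scores inside rescue
#'   windows as well (default `FALSE`).
#' @return An object of class `imputation_policy`.
#' @export
imputation_policy <- function(night_pi_value = 3L,
                              parecoxib_window = 6,
                              sufentanil_window = 2,
                              mode = c("primary",
                                       "sensitivity_no_rescue_imputation"),
                              strict_rescue = FALSE) {
  mode <- match.arg(mode)
  stopifnot(night_pi_value == round(night_pi_value),
            night_pi_value >= 0, night_pi_value <= 10,
            parecoxib_window > 0, sufentanil_window > 0)
  structure(list(night_pi_value = as.integer(night_pi_value),
                 parecoxib_window = parecoxib_window,
                 sufentanil_window = sufentanil_window,
                 mode = mode, strict_rescue = strict_rescue),
            class = "imputation_policy")
}

rescue_window_h <- function(drug, policy) {
  ifelse(drug == "parecoxib", policy$parecoxib_window,
         policy$sufentanil_window)
}

# imputation core on plain vectors; t_min strictly increasing with t_min[1]
# == 0 and pi[1] observed, r_t / r_w the rescue times and windows in minutes
impute_core <- function(t_min, pi_obs, pr_obs, night, r_t, r_w, policy) {
  n <- length(t_min)
  pi_out <- pi_obs
  pr_out <- pr_obs
  pi_src <- ifelse(is.na(pi_obs), NA_character_, "observed")
  pr_src <- ifelse(is.na(pr_obs), NA_character_, "observed")
  pr_src[1] <- "observed"  # PR undefined at baseline; NA there is not missing

  # governing rescue for each point: the latest rescue whose window
  # (r, r + w] contains it, or 0
  governing <- integer(n)
  if (length(r_t)) {
    for (k in seq_len(n)) {
      hits <- which(r_t < t_min[k] & t_min[k] <= r_t + r_w)
      governing[k] <- if (length(hits)) max(hits) else 0L
    }
  }

  # score recorded before a rescue: last observed value at or before it
  pre_rescue <- function(obs, r_time) {
    k <- which(t_min <= r_time & !is.na(obs))
    if (length(k)) obs[max(k)] else NA_integer_
  }

  for (k in seq_len(n)[-1L]) {
    g <- governing[k]
    in_rescue <- g > 0L
    if (is.na(pi_out[k]) || (in_rescue && policy$strict_rescue)) {
      if (in_rescue) {
        val <- pre_rescue(pi_obs, r_t[g])
        if (is.na(val)) {
          stop("no observed pain intensity before the rescue at ",
               minutes_to_hours(r_t[g]), " h", call. = FALSE)
        }
        pi_out[k] <- val
        pi_src[k] <- "rescue_rule"
      } else if (isTRUE(night[k])) {
        pi_out[k] <- policy$night_pi_value
        pi_src[k] <- "night_rule"
      } else {
        prev <- which(!is.na(pi_out[seq_len(k - 1L)]))
        pi_out[k] <- pi_out[max(prev)]
        pi_src[k] <- "locf"
      }
    }

    if (is.na(pr_out[k]) || (in_rescue && policy$strict_rescue)) {
      if (in_rescue) {
        val <- pre_rescue(pr_obs, r_t[g])
        if (is.na(val)) {
          stop("no observed pain relief before the rescue at ",
               minutes_to_hours(r_t[g]), " h", call. = FALSE)
        }
        pr_out[k] <- val
        pr_src[k] <- "rescue_rule"
      } else {
        prev <- if (k > 2L) which(!is.na(pr_out[2:(k - 1L)])) + 1L
                else integer(0)
        if (!length(prev)) {
          stop("no preceding pain relief score to carry ",
               ifelse(isTRUE(night[k]), "into the night window", "forward"),
               " at ", minutes_to_hours(t_min[k]), " h", call. = FALSE)
        }
        pr_out[k] <- pr_out[max(prev)]
        pr_src[k] <- if (isTRUE(night[k])) "night_rule" else "locf"
      }
    }
  }
  list(pi = pi_out, pr = pr_out, pi_src = pi_src, pr_src = pr_src)
}

#' Impute a participant's pain score series
#'
#' Applies the [imputation_policy()] rules to one participant's assessment
#' series, producing a complete `score_series`: pain intensity and pain
#' relief at every assessment time with per-point provenance (`observed`,
#' `rescue_rule`, `night_rule` or `locf`). Pain relief is undefined at time
#' 0 and left `NA` there.
#'
#' @param assessments Data frame for one participant with columns
#'   `time_min` (or `time_h`), `pi`, `pr`, `night_sleep`, time-ordered.
#' @param rescues Data frame of the participant's rescue events with
#'   columns `time_min` (or `time_h`) and `drug`; may be empty.
#' @param policy An [imputation_policy()].
#' @return A data frame of class `score_series` with columns `time_min`,
#'   `time_h`, `pi`, `pr`, `pi_src`, `pr_src`. Re-imputing the output
#'   leaves its times and scores unchanged.
#' @export
#' @examples
#' a <- data.frame(time_h = c(0, 1, 2), pi = c(6L, NA, 4L),
#'                 pr = c(NA, 2L, NA), night_sleep = FALSE)
#' impute_series(a, policy = imputation_policy())
impute_series <- function(assessments, rescues = NULL,
                          policy = imputation_policy()) {
  a <- as.data.frame(assessments)
  if (is.null(a$time_min)) a$time_min <- hours_to_minutes(a$time_h)
  if (is.null(a$night_sleep)) a$night_sleep <- FALSE
  a <- a[order(a$time_min), , drop = FALSE]
  n <- nrow(a)
  if (n == 0L) stop("empty assessment series", call. = FALSE)
  if (a$time_min[1] != 0L || is.na(a$pi[1])) {
    stop("participant unevaluable: baseline pain intensity at time 0 ",
         "is required", call. = FALSE)
  }

  if (is.null(rescues) || nrow(rescues) == 0L ||
      policy$mode == "sensitivity_no_rescue_imputation") {
    r_t <- integer(0)
    r_w <- integer(0)
  } else {
    r <- as.data.frame(rescues)
    if (is.null(r$time_min)) r$time_min <- hours_to_minutes(r$time_h)
    ord <- order(r$time_min)
    r_t <- r$time_min[ord]
    r_w <- hours_to_minutes(rescue_window_h(r$drug[ord], policy))
  }

  night <- rep_len(as.logical(a$night_sleep), n)
  imp <- impute_core(a$time_min, as.integer(a$pi), as.integer(a$pr),
                     night, r_t, r_w, policy)

  structure(
    data.frame(time_min = a$time_min,
               time_h = minutes_to_hours(a$time_min),
               pi = imp$pi, pr = imp$pr,
               pi_src = imp$pi_src, pr_src = imp$pr_src,
               night_sleep = night,
               stringsAsFactors = FALSE),
    class = c("score_series", "data.frame")
  )
}

grid_index <- function(series, t_h, what) {
  t_min <- hours_to_minutes(t_h)
  k <- match(t_min, series$time_min)
  if (is.na(k)) {
    stop(what, " = ", t_h, " h is not on the assessment grid",
         call. = FALSE)
  }
  k
}

# time-weighted sums on vectors; indices i0 < i1 into the grid; results in
# exact integer score-minutes (the rational score-hours times 60)
spid_core <- function(t_min, pi, i0, i1) {
  pid <- pi - pi[1L]
  sel <- (i0 + 1L):i1
  sum(pid[sel] * (t_min[sel] - t_min[sel - 1L]))
}

totpar_core <- function(t_min, pr, i0, i1) {
  sel <- (i0 + 1L):i1
  sum(pr[sel] * (t_min[sel] - t_min[sel - 1L]))
}

#' Summed pain intensity difference over a time window
#'
#' Computes the time-weighted composite `SPID` over `(t_start, t_end]`:
#' the sum over grid points t in the window of
#' `(PI_t - PI_0) * (t - t_prev)`, where `t_prev` is the preceding grid
#' point and PI_0 is the baseline pain intensity. Time 0 carries no weight
#' (no interval ends there) and the baseline difference is identically 0.
#' Interval weights are computed in whole minutes and divided by 60 once,
#' so they sum to the window length exactly. More negative SPID means
#' greater cumulative pain reduction; on the full 24-h protocol grid the
#' theoretical range is -240 to 240.
#'
#' All interval arithmetic is carried out in exact integer score-minutes
#' (every grid time is a whole minute, so every weight is a whole number of
#' minutes); the single division by 60 happens only when reporting in
#' hours. `units = "minutes"` returns the exact integer value, on which
#' identities such as the window decomposition
#' `SPID(0,24] = SPID(0,12] + SPID(12,24]` hold without any rounding.
#'
#' @param series A complete `score_series` (see [impute_series()]).
#' @param t_start,t_end Window bounds in hours; both must be grid points
#'   (`t_start` may be 0).
#' @param units `"hours"` (default; NRS-hours, the reporting scale) or
#'   `"minutes"` (exact integer NRS-minutes).
#' @return SPID over the window.
#' @export
#' @examples
#' s <- impute_series(data.frame(time_h = c(0, 0.5, 1, 2),
#'                               pi = c(5L, 4L, 3L, 2L),
#'                               pr = c(NA, 1L, 2L, 3L),
#'                               night_sleep = FALSE))
#' compute_spid(s, 0, 2)  # -4.5
compute_spid <- function(series, t_start = 0, t_end = 24,
                         units = c("hours", "minutes")) {
  units <- match.arg(units)
  stopifnot(t_start < t_end)
  if (anyNA(series$pi)) {
    stop("series has missing pain intensity; impute first", call. = FALSE)
  }
  if (series$time_min[1] != 0L) {
    stop("series must start at time 0", call. = FALSE)
  }
  i0 <- grid_index(series, t_start, "t_start")
  i1 <- grid_index(series, t_end, "t_end")
  s_min <- spid_core(series$time_min, series$pi, i0, i1)
  if (units == "minutes") as.integer(s_min) else s_min / 60
}

#' Total pain relief over a time window
#'
#' Computes `TOTPAR` over `(t_start, t_end]`: the sum over grid points t in
#' the window of `PR_t * (t - t_prev)`. Pain relief is on the 0-4 Likert
#' scale, so on the full 24-h grid TOTPAR ranges from 0 to 96; larger
#' values mean greater relief. TOTPAR is non-decreasing in the horizon.
#'
#' Like [compute_spid()], the sum is accumulated in exact integer
#' score-minutes and divided by 60 only for reporting in hours.
#'
#' @inheritParams compute_spid
#' @return TOTPAR over the window (>= 0).
#' @export
compute_totpar <- function(series, t_start = 0, t_end = 24,
                           units = c("hours", "minutes")) {
  units <- match.arg(units)
  stopifnot(t_start < t_end)
  if (anyNA(series$pr[-1L])) {
    stop("series has missing pain relief; impute first", call. = FALSE)
  }
  i0 <- grid_index(series, t_start, "t_start")
  i1 <- grid_index(series, t_end, "t_end")
  s_min <- totpar_core(series$time_min, series$pr, i0, i1)
  if (units == "minutes") as.integer(s_min) else s_min / 60
}

#' Per-participant endpoint panel
#'
#' Imputes every participant's score series once and computes the full set
#' of protocol endpoints from it: SPID and TOTPAR over (0,6], (0,12],
#' (0,18], (0,24] and (12,24]; the no-rescue indicator over (0,24]; and
#' time to first rescue (censored at 24 h for non-users). The interval
#' decomposition is exact: `spid_24 = spid_12 + spid_12_24` holds for every
#' participant, and likewise for TOTPAR.
#'
#' @param ds A validated `trial_dataset`.
#' @param policy An [imputation_policy()].
#' @return A data frame of class `endpoint_panel`, one row per participant,
#'   with columns `id`, `arm`, `baseline_pi`, `spid_6`, `spid_12`,
#'   `spid_18`, `spid_24`, `spid_12_24`, `totpar_6` ... `totpar_12_24`,
#'   `no_rescue`, `rescue_time_h`, `rescue_event`, and imputation
#'   provenance tallies (`n_night_rule`, `n_rescue_rule`, `n_locf`).
#' @export
compute_endpoint_panel <- function(ds, policy = imputation_policy()) {
  stopifnot(inherits(ds, "trial_dataset"))
  p <- ds$participants
  a <- ds$assessments
  n_p <- nrow(p)

  a_idx <- split(seq_len(nrow(a)), factor(a$id, levels = p$id))
  r_idx <- split(seq_len(nrow(ds$rescues)),
                 factor(ds$rescues$id, levels = p$id))
  a_t <- a$time_min
  a_pi <- as.integer(a$pi)
  a_pr <- as.integer(a$pr)
  a_night <- as.logical(a$night_sleep)
  r_time <- ds$rescues$time_min
  r_drug <- ds$rescues$drug

  horiz <- c(6, 12, 18, 24) * 60L
  out <- list(
    baseline_pi = integer(n_p),
    spid_6 = numeric(n_p), spid_12 = numeric(n_p), spid_18 = numeric(n_p),
    spid_24 = numeric(n_p), spid_12_24 = numeric(n_p),
    totpar_6 = numeric(n_p), totpar_12 = numeric(n_p),
    totpar_18 = numeric(n_p), totpar_24 = numeric(n_p),
    totpar_12_24 = numeric(n_p),
    no_rescue = logical(n_p), rescue_time_h = numeric(n_p),
    rescue_event = logical(n_p),
    n_night_rule = integer(n_p), n_rescue_rule = integer(n_p),
    n_locf = integer(n_p)
  )

  for (i in seq_len(n_p)) {
    ai <- a_idx[[i]]
    ord <- ai[order(a_t[ai])]
    t_i <- a_t[ord]
    if (!length(t_i) || t_i[1] != 0L || is.na(a_pi[ord[1]])) {
      stop("participant ", p$id[i], ": baseline pain intensity at time 0 ",
           "is required", call. = FALSE)
    }
    ri <- r_idx[[i]]
    if (length(ri) && policy$mode != "sensitivity_no_rescue_imputation") {
      rord <- ri[order(r_time[ri])]
      r_t <- r_time[rord]
      r_w <- hours_to_minutes(rescue_window_h(r_drug[rord], policy))
    } else {
      r_t <- integer(0)
      r_w <- integer(0)
    }

    imp <- tryCatch(
      impute_core(t_i, a_pi[ord], a_pr[ord], a_night[ord], r_t, r_w,
                  policy),
      error = function(e) {
        stop("participant ", p$id[i], ": ", conditionMessage(e),
             call. = FALSE)
      }
    )

    hi <- match(horiz, t_i)
    if (anyNA(hi)) {
      stop("participant ", p$id[i],
           ": protocol horizon missing from the assessment grid",
           call. = FALSE)
    }
    out$baseline_pi[i] <- imp$pi[1L]
    out$spid_6[i] <- spid_core(t_i, imp$pi, 1L, hi[1]) / 60
    out$spid_12[i] <- spid_core(t_i, imp$pi, 1L, hi[2]) / 60
    out$spid_18[i] <- spid_core(t_i, imp$pi, 1L, hi[3]) / 60
    out$spid_24[i] <- spid_core(t_i, imp$pi, 1L, hi[4]) / 60
    out$spid_12_24[i] <- spid_core(t_i, imp$pi, hi[2], hi[4]) / 60
    out$totpar_6[i] <- totpar_core(t_i, imp$pr, 1L, hi[1]) / 60
    out$totpar_12[i] <- totpar_core(t_i, imp$pr, 1L, hi[2]) / 60
    out$totpar_18[i] <- totpar_core(t_i, imp$pr, 1L, hi[3]) / 60
    out$totpar_24[i] <- totpar_core(t_i, imp$pr, 1L, hi[4]) / 60
    out$totpar_12_24[i] <- totpar_core(t_i, imp$pr, hi[2], hi[4]) / 60

    r_all <- r_time[ri]
    out$no_rescue[i] <- !any(r_all > 0L & r_all <= 1440L)
    out$rescue_event[i] <- length(r_all) > 0L
    out$rescue_time_h[i] <- if (length(r_all)) {
      minutes_to_hours(min(r_all))
    } else {
      24
    }
    out$n_night_rule[i] <- sum(imp$pi_src == "night_rule", na.rm = TRUE) +
      sum(imp$pr_src == "night_rule", na.rm = TRUE)
    out$n_rescue_rule[i] <- sum(imp$pi_src == "rescue_rule", na.rm = TRUE) +
      sum(imp$pr_src == "rescue_rule", na.rm = TRUE)
    out$n_locf[i] <- sum(imp$pi_src == "locf", na.rm = TRUE) +
      sum(imp$pr_src == "locf", na.rm = TRUE)
  }

  panel <- data.frame(id = p$id, arm = p$arm, out,
                      stringsAsFactors = FALSE)
  class(panel) <- c("endpoint_panel", "data.frame")
  panel
}

first_rescue_time <- function(rescues) {
  if (nrow(rescues) == 0L) {
    list(time_h = 24, event = FALSE)
  } else {
    list(time_h = minutes_to_hours(min(rescues$time_min)), event = TRUE)
  }
}

#' Per-arm responder proportions
#'
#' The fraction of participants in each arm whose (imputed) pain intensity
#' at a given assessment time is at or below a threshold — e.g. the
#' proportion with NRS <= 3, the conventional definition of mild pain, used
#' in the trial's post hoc responder analysis over the first 6 h.
#'
#' @param ds A `trial_dataset`.
#' @param time Assessment time in hours; must be on the protocol grid.
#' @param threshold NRS threshold in \[0, 10\] (default 3).
#' @param policy An [imputation_policy()].
#' @return Data frame with one row per arm: `arm`, `k` responders, `n`,
#'   `proportion`.
#' @export
responder_proportion <- function(ds, time, threshold = 3,
                                 policy = imputation_policy()) {
  stopifnot(threshold >= 0, threshold <= 10)
  t_min <- hours_to_minutes(time)
  if (!t_min %in% ds$schedule_min) {
    stop("time = ", time, " h is not on the protocol grid", call. = FALSE)
  }
  p <- ds$participants
  resp <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    pid <- p$id[i]
    s <- impute_series(ds$assessments[ds$assessments$id == pid, ,
                                      drop = FALSE],
                       ds$rescues[ds$rescues$id == pid, , drop = FALSE],
                       policy)
    resp[i] <- s$pi[s$time_min == t_min] <= threshold
  }
  arms <- factor(p$arm, levels = trial_arms())
  k <- tapply(resp, arms, sum)
  n <- tapply(resp, arms, length)
  k[is.na(k)] <- 0
  n[is.na(n)] <- 0
  data.frame(arm = trial_arms(), k = as.integer(k), n = as.integer(n),
             proportion = ifelse(n > 0, k / n, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}
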