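#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval for a binomial proportion from beta-distribution
#' quantiles: lower bound `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`),
#' upper bound `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`). The
#' interval's coverage is at least the nominal level for every true
#' proportion.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A list of class `proportion_ci` with elements `k`, `n`,
#'   `estimate`, `level`, `lo`, `hi`.
#' @export
#' @examples
#' clopper_pearson(103, 131)  # (0.706, 0.853)
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L,
            k == round(k), n == round(n), n >= 1,
            level > 0, level < 1)
  if (k < 0 || k > n) {
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  }
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(k = as.integer(k), n = as.integer(n), estimate = k / n,
                 level = level, lo = lo, hi = hi),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI, %.1f-%.1f)\n",
              x$k, x$n, 100 * x$estimate, round(100 * x$level),
              100 * x$lo, 100 * x$hi))
  invisible(x)
}

#' Proportion of participants not requiring rescue medication
#'
#' For each arm, the fraction of participants with zero rescue events over
#' (0, 24] hours, with exact Clopper-Pearson intervals and Fisher's exact
#' test of each arm against a reference arm. The denominator is the full
#' analysis-set arm size.
#'
#' @param ds A `trial_dataset` (typically the full analysis set).
#' @param reference Arm compared against (default `"placebo"`).
#' @param level Confidence level for the intervals.
#' @return Data frame with one row per arm: `arm`, `k` (no-rescue count),
#'   `n`, `proportion`, `lo`, `hi`, and `p_vs_reference` (Fisher's exact
#'   two-sided p; `NA` for the reference arm itself).
#' @export
no_rescue_proportion <- function(ds, reference = "placebo", level = 0.95) {
  stopifnot(inherits(ds, "trial_dataset"), reference %in% trial_arms())
  p <- ds$participants
  arms_present <- trial_arms()[trial_arms() %in% p$arm]
  if (!length(arms_present)) stop("empty dataset", call. = FALSE)

  rescued_ids <- unique(ds$rescues$id[ds$rescues$time_min > 0L &
                                        ds$rescues$time_min <= 1440L])
  rows <- lapply(arms_present, function(arm) {
    ids <- p$id[p$arm == arm]
    if (!length(ids)) stop("empty arm: ", arm, call. = FALSE)
    k <- sum(!ids %in% rescued_ids)
    ci <- clopper_pearson(k, length(ids), level)
    data.frame(arm = arm, k = k, n = length(ids),
               proportion = ci$estimate, lo = ci$lo, hi = ci$hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  ref <- out[out$arm == reference, ]
  if (nrow(ref) == 0L) {
    stop("reference arm ", reference, " not present", call. = FALSE)
  }
  out$p_vs_reference <- vapply(seq_len(nrow(out)), function(i) {
    if (out$arm[i] == reference) return(NA_real_)
    tab <- matrix(c(out$k[i], out$n[i] - out$k[i],
                    ref$k, ref$n - ref$k), nrow = 2, byrow = TRUE)
    # a zero margin (nobody, or everybody, rescued in both arms) carries
    # no information about a difference
    if (any(colSums(tab) == 0)) return(1)
    fisher_exact_2x2(tab)$p
  }, numeric(1))
  out
}

#' Time to first rescue medication
#'
#' One row per participant: the time of the earliest rescue event, or 24 h
#' with a censoring flag for participants who never used rescue medication.
#' A rescue recorded after 24 h counts as an event at its recorded time.
#'
#' @param ds A `trial_dataset`.
#' @return Data frame with columns `id`, `arm`, `time_h`, `event`.
#' @export
time_to_first_rescue <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  p <- ds$participants
  rows <- lapply(seq_len(nrow(p)), function(i) {
    r_i <- ds$rescues[ds$rescues$id == p$id[i], , drop = FALSE]
    ttr <- first_rescue_time(r_i)
    data.frame(id = p$id[i], arm = p$arm[i], time_h = ttr$time_h,
               event = ttr$event, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate of the rescue-free curve
#'
#' Product-limit estimate of the probability of remaining rescue-free,
#' computed with [survival::survfit()]. With no censoring before the last
#' event the estimate equals the empirical survival function.
#'
#' @param sample Data frame with columns `time_h` and `event` (see
#'   [time_to_first_rescue()]).
#' @return Data frame with columns `time_h`, `n_risk`, `n_event`,
#'   `survival`: the right-continuous step function evaluated at each
#'   event or censoring time.
#' @export
km_estimate <- function(sample) {
  stopifnot(nrow(sample) >= 1L, all(c("time_h", "event") %in% names(sample)))
  fit <- survival::survfit(
    survival::Surv(time_h, event) ~ 1,
    data = data.frame(time_h = sample$time_h,
                      event = as.integer(sample$event))
  )
  data.frame(time_h = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-sample log-rank test
#'
#' Unstratified log-rank comparison of two time-to-rescue samples, with the
#' standard hypergeometric variance for tied event times and no continuity
#' correction, via [survival::survdiff()]. Returns the 1-df chi-square
#' statistic and its two-sided p value.
#'
#' @param a,b Data frames with columns `time_h`, `event`.
#' @return List with elements `statistic` and `p`.
#' @export
logrank_test <- function(a, b) {
  stopifnot(nrow(a) >= 1L, nrow(b) >= 1L)
  d <- data.frame(
    time_h = c(a$time_h, b$time_h),
    event = as.integer(c(a$event, b$event)),
    grp = rep(c("a", "b"), c(nrow(a), nrow(b)))
  )
  if (sum(d$event) == 0L) {
    # no events anywhere: no information, the test is degenerate
    return(list(statistic = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time_h, event) ~ grp, data = d)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cumulative rescue-medication consumption
#'
#' Per-arm, per-drug mean (SD) of each participant's total dose over
#' (0, 24] hours, with the zero-fill convention: participants who never
#' used the drug contribute 0 and stay in the denominator, so the mean is
#' over all participants in the arm.
#'
#' @param ds A `trial_dataset`.
#' @return Data frame with one row per arm and drug: `arm`, `drug`, `n`,
#'   `mean`, `sd`.
#' @export
cumulative_rescue_consumption <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  r <- ds$rescues
  if (nrow(r) && any(r$dose <= 0)) {
    stop("rescue doses must be positive", call. = FALSE)
  }
  p <- ds$participants
  arms_present <- trial_arms()[trial_arms() %in% p$arm]
  drugs <- c("parecoxib", "sufentanil")
  out <- expand.grid(arm = arms_present, drug = drugs,
                     stringsAsFactors = FALSE)
  out <- out[order(match(out$arm, trial_arms())), ]
  res <- lapply(seq_len(nrow(out)), function(i) {
    ids <- p$id[p$arm == out$arm[i]]
    in_window <- r$drug == out$drug[i] & r$time_min > 0L &
      r$time_min <= 1440L
    totals <- vapply(ids, function(pid) {
      sum(r$dose[in_window & r$id == pid])
    }, numeric(1))
    data.frame(arm = out$arm[i], drug = out$drug[i], n = length(ids),
               mean = mean(totals),
               sd = if (length(totals) > 1) stats::sd(totals) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
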