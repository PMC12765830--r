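#' Participant disposition accounting
#'
#' CONSORT-style counts for a trial dataset: randomized, treated and
#' completed participants per arm, and the sizes of the standard analysis
#' populations (full analysis set, intention-to-treat, safety).
#'
#' @param ds A `trial_dataset` with disposition flags populated.
#' @return A list of class `consort_accounting` with elements `total`,
#'   `per_arm` (data frame: arm, randomized, treated, completed) and
#'   `analysis_sets` (named counts).
#' @export
consort_accounting <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  p <- ds$participants
  arms <- factor(p$arm, levels = trial_arms())
  per_arm <- data.frame(
    arm = trial_arms(),
    randomized = as.integer(tapply(p$randomized, arms, sum,
                                   default = 0L)),
    treated = as.integer(tapply(p$treated, arms, sum, default = 0L)),
    completed = as.integer(tapply(p$completed, arms, sum, default = 0L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      total = nrow(p),
      per_arm = per_arm,
      analysis_sets = c(
        FAS = sum(p$randomized & p$treated),
        ITT = sum(p$randomized),
        SAFETY = sum(p$treated)
      )
    ),
    class = "consort_accounting"
  )
}

#' @export
print.consort_accounting <- function(x, ...) {
  cat("Participant disposition\n")
  cat(sprintf("  records: %d; FAS %d, ITT %d, SAFETY %d\n", x$total,
              x$analysis_sets["FAS"], x$analysis_sets["ITT"],
              x$analysis_sets["SAFETY"]))
  print(x$per_arm, row.names = FALSE)
  invisible(x)
}

#' Analyse an acute-pain trial dataset
#'
#' The package's central fitting step: selects the analysis population,
#' imputes every participant's score series under the imputation policy,
#' computes the per-participant endpoint panel, runs the fixed-sequence
#' gatekept analysis of the primary endpoint and nominal t comparisons for
#' every SPID/TOTPAR horizon, and derives the rescue-medication outcomes
#' (no-rescue proportions with exact intervals and Fisher tests,
#' Kaplan-Meier time to first rescue with log-rank tests against the
#' reference arm, zero-filled consumption summaries).
#'
#' @param ds A validated `trial_dataset`.
#' @param policy An [imputation_policy()].
#' @param plan A [gatekeeping_plan()].
#' @param analysis_set `"FAS"` (default), `"ITT"` or `"SAFETY"`.
#' @param reference Reference arm for the nominal comparisons (default
#'   `"placebo"`).
#' @param variance_mode Passed to the t comparisons.
#' @return An object of class `trial_analysis`: a list with components
#'   `consort`, `panel` (endpoint panel), `primary` (gatekept comparisons),
#'   `secondary` (nominal comparisons for all endpoints and arms),
#'   `no_rescue`, `survival` (per-arm Kaplan-Meier curves), `logrank`
#'   (per-arm tests vs the reference), `consumption`, and the settings
#'   used. Methods: `print`, `summary`, `coef`, `plot`.
#' @export
#' @examples
#' ds <- simulate_trial(simulation_config(n_per_arm = 20), seed = 7)
#' fit <- analyze_trial(ds)
#' fit
analyze_trial <- function(ds, policy = imputation_policy(),
                          plan = gatekeeping_plan(),
                          analysis_set = "FAS",
                          reference = "placebo",
                          variance_mode = "pooled") {
  stopifnot(inherits(ds, "trial_dataset"))
  consort <- consort_accounting(ds)
  pop <- select_analysis_set(ds, analysis_set)
  panel <- compute_endpoint_panel(pop, policy)

  primary <- gatekept_primary_analysis(panel, plan,
                                       variance_mode = variance_mode)

  endpoints <- c("spid_6", "spid_12", "spid_18", "spid_24", "spid_12_24",
                 "totpar_6", "totpar_12", "totpar_18", "totpar_24",
                 "totpar_12_24")
  test_arms <- setdiff(unique(panel$arm), reference)
  test_arms <- trial_arms()[trial_arms() %in% test_arms]
  secondary <- do.call(rbind, lapply(endpoints, function(ep) {
    do.call(rbind, lapply(test_arms, function(arm) {
      two_sample_t(panel[[ep]][panel$arm == arm],
                   panel[[ep]][panel$arm == reference],
                   variance_mode = variance_mode,
                   endpoint = ep, contrast = paste(arm, "vs", reference))
    }))
  }))
  class(secondary) <- c("comparison_result", "data.frame")

  no_rescue <- no_rescue_proportion(pop, reference = reference)
  ttr <- time_to_first_rescue(pop)
  arms_present <- trial_arms()[trial_arms() %in% ttr$arm]
  surv <- lapply(stats::setNames(nm = arms_present), function(arm) {
    km_estimate(ttr[ttr$arm == arm, , drop = FALSE])
  })
  lr <- lapply(stats::setNames(nm = setdiff(arms_present, reference)),
               function(arm) {
                 logrank_test(ttr[ttr$arm == arm, , drop = FALSE],
                              ttr[ttr$arm == reference, , drop = FALSE])
               })

  structure(
    list(consort = consort, panel = panel, primary = primary,
         secondary = secondary, no_rescue = no_rescue,
         time_to_rescue = ttr, survival = surv, logrank = lr,
         consumption = cumulative_rescue_consumption(pop),
         settings = list(policy = policy, plan = plan,
                         analysis_set = analysis_set,
                         reference = reference,
                         variance_mode = variance_mode)),
    class = "trial_analysis"
  )
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("Acute-pain trial analysis (", x$settings$analysis_set,
      " population, imputation mode ", x$settings$policy$mode, ")\n\n",
      sep = "")
  cat("Primary endpoint, fixed-sequence gatekeeping at alpha ",
      x$settings$plan$alpha, ":\n", sep = "")
  print(x$primary)
  cat("\nNo-rescue proportions:\n")
  nr <- x$no_rescue
  for (i in seq_len(nrow(nr))) {
    cat(sprintf("  %-18s %3d/%3d = %5.1f%% (95%% CI, %.1f-%.1f)%s\n",
                nr$arm[i], nr$k[i], nr$n[i], 100 * nr$proportion[i],
                100 * nr$lo[i], 100 * nr$hi[i],
                ifelse(is.na(nr$p_vs_reference[i]), "",
                       paste0("  p ", format_p(nr$p_vs_reference[i])))))
  }
  invisible(x)
}

#' @export
summary.trial_analysis <- function(object, ...) {
  cat("Arm sizes (analysis population):\n")
  tab <- table(factor(object$panel$arm, levels = trial_arms()))
  print(tab)
  cat("\n")
  print(make_summary_table(object))
  invisible(object)
}

#' @export
coef.trial_analysis <- function(object, ...) {
  stats::setNames(object$primary$difference, object$primary$contrast)
}

#' @export
plot.trial_analysis <- function(x, ...) {
  arms <- names(x$survival)
  cols <- stats::setNames(seq_along(arms), arms)
  plot(NULL, xlim = c(0, 24), ylim = c(0, 1),
       xlab = "Hours from Time 0",
       ylab = "Proportion rescue-free",
       main = "Time to first rescue medication")
  for (arm in arms) {
    s <- x$survival[[arm]]
    graphics::lines(c(0, s$time_h), c(1, s$survival), type = "s",
                    col = cols[arm], lwd = 2)
  }
  graphics::legend("bottomleft", legend = arms, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Publication-style endpoint summary table
#'
#' One row per SPID/TOTPAR endpoint: per-arm mean (SD), and for each
#' non-reference arm the difference with the reference (SE), its
#' confidence interval and p value, with the trial's rendering rules
#' (scores to 2 decimals, p to 3 decimals with a `<0.001` floor, the
#' reference arm's contrast cells rendered `ND`).
#'
#' @param fit A `trial_analysis`.
#' @return Data frame of formatted character cells, one row per endpoint
#'   and statistic, one column per arm.
#' @export
make_summary_table <- function(fit) {
  stopifnot(inherits(fit, "trial_analysis"))
  panel <- fit$panel
  cmp <- rbind(
    fit$primary[, names(fit$secondary)[names(fit$secondary) %in%
                                         names(fit$primary)]],
    fit$secondary
  )
  reference <- fit$settings$reference
  arms <- trial_arms()[trial_arms() %in% unique(panel$arm)]
  endpoints <- unique(fit$secondary$endpoint)

  rows <- list()
  for (ep in endpoints) {
    vals <- lapply(stats::setNames(nm = arms), function(arm) {
      v <- panel[[ep]][panel$arm == arm]
      sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
    })
    diffs <- lapply(stats::setNames(nm = arms), function(arm) {
      if (arm == reference) return("ND")
      r <- cmp[cmp$endpoint == ep &
                 cmp$contrast == paste(arm, "vs", reference), ][1, ]
      sprintf("%.2f (%.2f)", r$difference, r$se)
    })
    cis <- lapply(stats::setNames(nm = arms), function(arm) {
      if (arm == reference) return("ND")
      r <- cmp[cmp$endpoint == ep &
                 cmp$contrast == paste(arm, "vs", reference), ][1, ]
      sprintf("(%.2f to %.2f); p %s", r$lo, r$hi, format_p(r$p))
    })
    rows[[length(rows) + 1L]] <-
      c(list(endpoint = ep, statistic = "mean (SD)"), vals)
    rows[[length(rows) + 1L]] <-
      c(list(endpoint = ep, statistic = "difference (SE)"), diffs)
    rows[[length(rows) + 1L]] <-
      c(list(endpoint = ep, statistic = "95% CI; p"), cis)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline and write its outputs
#'
#' End-to-end orchestration: obtain a dataset (simulate one from a
#' [simulation_config()], or read one with [read_trial_csv()]), run
#' [analyze_trial()], and write the report bundle to an output directory:
#' `endpoints.csv` (per-participant panel), `comparisons.csv`,
#' `no_rescue.csv`, `survival.csv` (per-arm Kaplan-Meier curves),
#' `consumption.csv`, `summary_table.csv`, `design.csv` and a plain-text
#' `run_log.txt` recording the policy mode, analysis set, seed,
#' imputation-provenance tallies and package version. Deterministic for a
#' fixed seed.
#'
#' @param config List with elements: exactly one of `simulation` (a
#'   [simulation_config()]) or `input` (path for [read_trial_csv()]);
#'   optional `policy`, `plan`, `design`, `analysis_set`, `seed`.
#' @param out_dir Output directory, created if needed.
#' @return The `trial_analysis` object, invisibly.
#' @export
run_full_analysis <- function(config, out_dir) {
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    stop("config must contain exactly one of 'simulation' or 'input'",
         call. = FALSE)
  }
  policy <- config$policy %||% imputation_policy()
  plan <- config$plan %||% gatekeeping_plan()
  dspec <- config$design %||% design_spec()
  analysis_set <- config$analysis_set %||% "FAS"
  seed <- config$seed %||% 1L

  ds <- if (has_sim) {
    simulate_trial(config$simulation, seed = seed)
  } else {
    read_trial_csv(config$input)
  }

  fit <- analyze_trial(ds, policy = policy, plan = plan,
                       analysis_set = analysis_set)
  dsn <- design_summary(dspec)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     na = "")
  }
  w(fit$panel, "endpoints.csv")
  w(rbind(fit$primary[, names(fit$secondary)[names(fit$secondary) %in%
                                               names(fit$primary)]],
          fit$secondary),
    "comparisons.csv")
  w(fit$no_rescue, "no_rescue.csv")
  surv <- do.call(rbind, lapply(names(fit$survival), function(arm) {
    cbind(arm = arm, fit$survival[[arm]])
  }))
  w(surv, "survival.csv")
  w(fit$consumption, "consumption.csv")
  w(make_summary_table(fit), "summary_table.csv")
  w(data.frame(n_evaluable = dsn$n_evaluable, n_planned = dsn$n_planned,
               n_total = dsn$n_total, power_achieved = dsn$power_achieved),
    "design.csv")

  log_lines <- c(
    paste0("paintrial version: ",
           as.character(utils::packageVersion("paintrial"))),
    paste0("analysis set: ", analysis_set),
    paste0("imputation mode: ", policy$mode),
    paste0("strict rescue replacement: ", policy$strict_rescue),
    paste0("seed: ", seed),
    paste0("participants analysed: ", nrow(fit$panel)),
    paste0("imputed points (night rule): ", sum(fit$panel$n_night_rule)),
    paste0("imputed points (rescue rule): ", sum(fit$panel$n_rescue_rule)),
    paste0("imputed points (LOCF): ", sum(fit$panel$n_locf))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
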