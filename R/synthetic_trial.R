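#' Specify a treatment arm for simulation
#'
#' An arm is described by the maximal expected reduction in pain intensity it
#' produces (`effect`, NRS units), the exponential onset time constant
#' (`onset_tau`, hours), and its patient-controlled-analgesia (PCA) dosing
#' parameters. The default PCA parameters mirror the emulated protocol: a
#' demand dose of one pump unit with a 0.3-units-per-hour ceiling, i.e. at
#' most 6 accepted demands in any trailing hour, under a 10-minute lockout.
#'
#' @param label Arm label, one of [trial_arms()].
#' @param effect Maximal expected pain-intensity reduction, in [0, 10].
#' @param onset_tau Onset time constant in hours (> 0): the expected drop at
#'   time t is `effect * (1 - exp(-t / onset_tau))`.
#' @param pca_dose Size of one PCA demand dose, in drug units.
#' @param hourly_cap Maximum accepted demands in any trailing 60-minute
#'   window (>= 1).
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(label, effect, onset_tau, pca_dose = 0.05,
                     hourly_cap = 6L) {
  stopifnot(label %in% trial_arms(), effect >= 0, effect <= 10,
            onset_tau > 0, hourly_cap >= 1)
  structure(list(label = label, effect = effect, onset_tau = onset_tau,
                 pca_dose = pca_dose, hourly_cap = as.integer(hourly_cap)),
            class = "arm_spec")
}

default_arm_specs <- function() {
  list(
    arm_spec("placebo",           effect = 2.2, onset_tau = 2.0),
    arm_spec("tegileridine_0_75", effect = 2.7, onset_tau = 0.8),
    arm_spec("tegileridine_1_0",  effect = 3.0, onset_tau = 0.8),
    arm_spec("morphine",          effect = 3.1, onset_tau = 1.2,
             pca_dose = 1.0)
  )
}

#' Configure the synthetic-trial generator
#'
#' Parameters of the four-arm acute-pain trial the simulator emulates:
#' moderate-to-severe baseline pain (NRS >= 4), arm-specific exponential
#' onset of analgesia with integer-rounded noisy assessments on the protocol
#' grid, rescue medication triggered by sustained high pain, PCA demands
#' under lockout and hourly-cap rules, night-time assessment missingness and
#' a small dropout rate.
#'
#' @param arms List of four [arm_spec()] objects, one per protocol arm.
#' @param n_per_arm Participants randomized per arm (default 132, the
#'   planned per-arm size of the emulated design).
#' @param baseline_mean,baseline_sd Mean and SD of the latent baseline pain
#'   score, discretized and truncated to the integers 4..10.
#' @param effect_sd Between-participant SD of the maximal analgesic
#'   response, in NRS units: each participant's effect is drawn from
#'   `Normal(effect, effect_sd)` truncated to \[0, 10\]. This is the main
#'   source of the endpoint's between-patient spread.
#' @param noise_sd Assessment-to-assessment noise on the pain scale, in NRS
#'   units, before rounding.
#' @param rescue_threshold Pain-intensity value at or above which a rescue
#'   dose may be requested at an assessment.
#' @param rescue_prob Per-assessment probability of requesting rescue when
#'   at or above threshold.
#' @param rescue_effect Pain-intensity reduction (NRS units) during the
#'   rescue drug's effect window (6 h for parecoxib, 2 h for sufentanil).
#' @param night_window Two hours `(start, end]` during which assessments are
#'   night-sleep flagged; defaults to 10-16 h post dose.
#' @param missing_rate_night Probability that a night-window assessment is
#'   missed (the participant is asleep).
#' @param missing_rate_other Probability that any other post-baseline
#'   assessment is missing.
#' @param dropout_rate Probability a participant is flagged as not
#'   completing the study.
#' @param pca_rate_per_pi Demand-press intensity: expected presses per hour
#'   per NRS point of current pain.
#' @param pca_pi_coupling Optional pain-intensity decrement per recent
#'   accepted PCA demand; 0 (off) by default.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(arms = default_arm_specs(),
                              n_per_arm = 132L,
                              baseline_mean = 5.0,
                              baseline_sd = 1.2,
                              effect_sd = 1.3,
                              noise_sd = 0.8,
                              rescue_threshold = 5,
                              rescue_prob = 0.30,
                              rescue_effect = 2,
                              night_window = c(10, 16),
                              missing_rate_night = 0.25,
                              missing_rate_other = 0.02,
                              dropout_rate = 0.015,
                              pca_rate_per_pi = 0.4,
                              pca_pi_coupling = 0) {
  stopifnot(length(arms) == 4L,
            all(vapply(arms, inherits, logical(1), "arm_spec")),
            n_per_arm >= 1,
            missing_rate_night >= 0, missing_rate_night <= 1,
            missing_rate_other >= 0, missing_rate_other <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            rescue_prob >= 0, rescue_prob <= 1, effect_sd >= 0,
            length(night_window) == 2L, night_window[1] < night_window[2])
  structure(
    list(arms = arms, n_per_arm = as.integer(n_per_arm),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         effect_sd = effect_sd, noise_sd = noise_sd, rescue_threshold = rescue_threshold,
         rescue_prob = rescue_prob, rescue_effect = rescue_effect,
         night_window = night_window,
         missing_rate_night = missing_rate_night,
         missing_rate_other = missing_rate_other,
         dropout_rate = dropout_rate,
         pca_rate_per_pi = pca_rate_per_pi,
         pca_pi_coupling = pca_pi_coupling),
    class = "simulation_config"
  )
}

#' Apply PCA pump acceptance rules to a press sequence
#'
#' A demand press is delivered ("accepted") only if it falls inside the
#' dosing window, arrives at least one lockout interval after the previous
#' accepted press, and does not bring the number of accepted presses in the
#' trailing 60 minutes above the hourly cap. The protocol defaults are a
#' dosing window of 30 min to 24 h post dose, a 10-minute lockout, and an
#' hourly cap of 6 (a 0.3-units/h ceiling at 0.05 units per demand). The cap
#' is enforced on a sliding trailing window, not on clock hours.
#'
#' @param press_times Sorted ascending press times, hours from Time 0.
#' @param window_start,window_end Dosing window `(window_start, window_end]`
#'   in hours.
#' @param lockout Lockout interval in hours (default 10 min).
#' @param hourly_cap Maximum accepted presses in any trailing hour.
#' @return Data frame with columns `time_h`, `time_min`, `accepted`.
#' @export
#' @examples
#' # presses every 5 minutes: lockout thins them to every 10 minutes
#' apply_pca_rules(seq(1, 2, by = 5 / 60))
apply_pca_rules <- function(press_times, window_start = 0.5,
                            window_end = 24, lockout = 10 / 60,
                            hourly_cap = 6L) {
  if (is.unsorted(press_times, strictly = FALSE)) {
    stop("press_times must be sorted ascending", call. = FALSE)
  }
  t_min <- hours_to_minutes(press_times)
  w0 <- hours_to_minutes(window_start)
  w1 <- hours_to_minutes(window_end)
  lock <- hours_to_minutes(lockout)

  accepted <- logical(length(t_min))
  acc_times <- integer(0)
  for (i in seq_along(t_min)) {
    t <- t_min[i]
    if (t <= w0 || t > w1) next
    if (length(acc_times) && t - acc_times[length(acc_times)] < lock) next
    in_hour <- sum(acc_times > t - 60L & acc_times <= t)
    if (in_hour + 1L > hourly_cap) next
    accepted[i] <- TRUE
    acc_times <- c(acc_times, t)
  }
  data.frame(time_h = minutes_to_hours(t_min), time_min = t_min,
             accepted = accepted)
}

# deterministic per-participant substream: depends only on the master seed,
# the arm index and the within-arm counter, so per-arm results do not depend
# on the order in which arms are simulated
participant_seed <- function(seed, arm_idx, j) {
  (abs(as.integer(seed)) %% 1000003L) * 2011L +
    arm_idx * 500009L + j * 7L
}

#' Simulate one trial participant
#'
#' Draws a single participant under the trajectory model: a baseline NRS
#' score of at least 4, pain intensity at each protocol assessment
#' `clamp(round(baseline - effect * (1 - exp(-t/tau)) + noise))` with rescue
#' medication (parecoxib first, then sufentanil) lowering pain during the
#' drug's effect window, pain relief a monotone map of the achieved drop
#' clamped to the 0-4 Likert scale, PCA demand presses thinned by the pump
#' rules, and night-window missingness.
#'
#' @param config A [simulation_config()].
#' @param arm An [arm_spec()].
#' @param seed Integer seed for this participant's private random stream.
#' @param id Participant identifier.
#' @return A list with elements `participant` (one-row data frame),
#'   `assessments`, `rescues` and `pca` data frames in the [trial_dataset()]
#'   column layout.
#' @export
simulate_participant <- function(config, arm, seed, id = "P1") {
  core <- simulate_participant_core(config, arm, seed)
  resc_df <- if (length(core$rescue_time_h)) {
    data.frame(id = id, time_h = core$rescue_time_h,
               drug = core$rescue_drug, dose = core$rescue_dose,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), time_h = numeric(), drug = character(),
               dose = numeric(), stringsAsFactors = FALSE)
  }
  pca_df <- if (length(core$pca_time_h)) {
    data.frame(id = id, time_h = core$pca_time_h,
               accepted = core$pca_accepted, stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), time_h = numeric(), accepted = logical(),
               stringsAsFactors = FALSE)
  }
  list(
    participant = data.frame(
      id = id, arm = arm$label, randomized = TRUE, treated = TRUE,
      completed = core$completed,
      satisfaction_participant = core$sat_p,
      satisfaction_investigator = core$sat_i,
      stringsAsFactors = FALSE),
    assessments = data.frame(
      id = id, time_h = core$time_h, pi = core$pi, pr = core$pr,
      night_sleep = core$night, stringsAsFactors = FALSE),
    rescues = resc_df,
    pca = pca_df
  )
}

simulate_participant_core <- function(config, arm, seed) {
  stopifnot(inherits(config, "simulation_config"), inherits(arm, "arm_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647L))

  sched <- protocol_schedule_min()
  t_h <- sched / 60
  n_t <- length(sched)

  baseline <- draw_baseline(config)
  # participant-level analgesic response: maximal drop for this individual
  effect_i <- min(10, max(0, stats::rnorm(1, arm$effect, config$effect_sd)))
  noise <- c(0, stats::rnorm(n_t - 1L, 0, config$noise_sd))

  pi_obs <- integer(n_t)
  pi_obs[1] <- baseline
  rescues <- list()
  parecoxib_given <- 0L

  for (k in 2L:n_t) {
    drop_k <- effect_i * (1 - exp(-t_h[k] / arm$onset_tau))
    rescue_red <- 0
    for (r in rescues) {
      if (t_h[k] > r$time_h && t_h[k] <= r$time_h + r$window_h) {
        rescue_red <- max(rescue_red, config$rescue_effect)
      }
    }
    val <- baseline - drop_k - rescue_red + noise[k]
    pi_obs[k] <- as.integer(min(10, max(0, round(val))))

    if (pi_obs[k] >= config$rescue_threshold &&
        stats::runif(1) < config$rescue_prob) {
      if (parecoxib_given < 2L) {
        parecoxib_given <- parecoxib_given + 1L
        rescues[[length(rescues) + 1L]] <-
          list(time_h = t_h[k], drug = "parecoxib", dose = 40, window_h = 6)
      } else {
        rescues[[length(rescues) + 1L]] <-
          list(time_h = t_h[k], drug = "sufentanil", dose = 5, window_h = 2)
      }
    }
  }

  pr_obs <- c(NA_integer_,
              pmin(4L, pmax(0L, baseline - pi_obs[-1L])))

  # PCA demand presses: piecewise-constant Poisson intensity proportional to
  # current pain, then pump lockout / window / hourly-cap thinning
  press <- numeric(0)
  for (k in 1L:(n_t - 1L)) {
    lambda <- config$pca_rate_per_pi * pi_obs[k] * (t_h[k + 1L] - t_h[k])
    m <- stats::rpois(1, lambda)
    if (m > 0) press <- c(press, sort(stats::runif(m, t_h[k], t_h[k + 1L])))
  }
  pca <- apply_pca_rules(press, hourly_cap = arm$hourly_cap)

  if (config$pca_pi_coupling > 0 && any(pca$accepted)) {
    acc <- pca$time_h[pca$accepted]
    for (k in 2L:n_t) {
      recent <- sum(acc > t_h[k] - 1 & acc <= t_h[k])
      pi_obs[k] <- as.integer(max(0, pi_obs[k] -
                                    round(config$pca_pi_coupling * recent)))
    }
  }

  # missingness: baseline always observed; night-window points are flagged
  # and dropped at the night rate, others at the background rate
  night <- t_h > config$night_window[1] & t_h <= config$night_window[2]
  night[1] <- FALSE
  u <- stats::runif(n_t)
  missing <- rep(FALSE, n_t)
  missing[-1L] <- ifelse(night[-1L], u[-1L] < config$missing_rate_night,
                         u[-1L] < config$missing_rate_other)
  # the end-of-infusion assessment is investigator-administered in person,
  # so the series always has an observed PR before any later gap
  missing[2L] <- FALSE
  pi_out <- ifelse(missing, NA_integer_, pi_obs)
  pr_out <- ifelse(missing, NA_integer_, pr_obs)
  pr_out[1] <- NA_integer_

  mean_pi <- mean(pi_obs[-1L])
  sat_p <- as.integer(min(10, max(0, round(10 - mean_pi +
                                             stats::rnorm(1, 0, 1)))))
  sat_i <- as.integer(min(10, max(0, round(10 - mean_pi +
                                             stats::rnorm(1, 0, 1)))))
  completed <- stats::runif(1) >= config$dropout_rate

  list(
    time_h = t_h, pi = pi_out, pr = pr_out, night = night,
    rescue_time_h = vapply(rescues, `[[`, numeric(1), "time_h"),
    rescue_drug = vapply(rescues, `[[`, character(1), "drug"),
    rescue_dose = vapply(rescues, `[[`, numeric(1), "dose"),
    pca_time_h = pca$time_h, pca_accepted = pca$accepted,
    completed = completed, sat_p = sat_p, sat_i = sat_i
  )
}

draw_baseline <- function(config) {
  for (try in 1:10000) {
    b <- as.integer(round(stats::rnorm(1, config$baseline_mean,
                                       config$baseline_sd)))
    if (b >= 4L && b <= 10L) return(b)
  }
  stop("baseline distribution places essentially no mass on 4..10",
       call. = FALSE)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a four-arm acute-pain trial
#'
#' Draws `n_per_arm` participants per arm under [simulate_participant()]'s
#' trajectory model. Each participant uses a private random substream
#' derived from the master seed, the arm index and the within-arm counter,
#' so results are reproducible participant by participant and independent of
#' arm order.
#'
#' @param config A [simulation_config()].
#' @param seed Master integer seed.
#' @return A validated `trial_dataset`.
#' @export
#' @examples
#' ds <- simulate_trial(simulation_config(n_per_arm = 5), seed = 42)
#' arm_sizes(ds)
simulate_trial <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  n_total <- 4L * config$n_per_arm
  parts <- vector("list", n_total)
  ids <- character(n_total)
  arms <- character(n_total)
  idx <- 0L
  for (arm_idx in seq_along(config$arms)) {
    arm <- config$arms[[arm_idx]]
    for (j in seq_len(config$n_per_arm)) {
      idx <- idx + 1L
      ids[idx] <- sprintf("%s-%04d", abbreviate_arm(arm$label), j)
      arms[idx] <- arm$label
      parts[[idx]] <- simulate_participant_core(
        config, arm, seed = participant_seed(seed, arm_idx, j))
    }
  }

  pull <- function(field) lapply(parts, `[[`, field)
  n_assess <- lengths(pull("time_h"))
  n_resc <- lengths(pull("rescue_time_h"))
  n_pca <- lengths(pull("pca_time_h"))

  trial_dataset(
    participants = data.frame(
      id = ids, arm = arms, randomized = TRUE, treated = TRUE,
      completed = vapply(parts, `[[`, logical(1), "completed"),
      satisfaction_participant = vapply(parts, `[[`, integer(1), "sat_p"),
      satisfaction_investigator = vapply(parts, `[[`, integer(1), "sat_i"),
      stringsAsFactors = FALSE),
    assessments = data.frame(
      id = rep(ids, n_assess),
      time_h = unlist(pull("time_h")),
      pi = unlist(pull("pi")), pr = unlist(pull("pr")),
      night_sleep = unlist(pull("night")), stringsAsFactors = FALSE),
    rescues = data.frame(
      id = rep(ids, n_resc),
      time_h = as.numeric(unlist(pull("rescue_time_h"))),
      drug = as.character(unlist(pull("rescue_drug"))),
      dose = as.numeric(unlist(pull("rescue_dose"))),
      stringsAsFactors = FALSE),
    pca = data.frame(
      id = rep(ids, n_pca),
      time_h = as.numeric(unlist(pull("pca_time_h"))),
      accepted = as.logical(unlist(pull("pca_accepted"))),
      stringsAsFactors = FALSE)
  )
}

abbreviate_arm <- function(label) {
  switch(label,
         placebo = "PBO",
         tegileridine_0_75 = "T075",
         tegileridine_1_0 = "T100",
         morphine = "MOR")
}
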