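#' Trial design assumptions
#'
#' The assumed endpoint summaries and operating characteristics behind the
#' sample-size calculation: mean (SD) of the primary endpoint in the active
#' and control arms, two-sided alpha, target power, the dropout rate used
#' to inflate the evaluable size, and the number of arms. The defaults are
#' the emulated trial's planning assumptions (SPID-scale means 88 and 70
#' with SDs 45 and 40, alpha 0.05, power 0.90, 10% dropout, four arms).
#'
#' @param mean_active,sd_active Assumed endpoint mean and SD, active arm.
#' @param mean_control,sd_control Assumed endpoint mean and SD, control.
#' @param alpha Two-sided type-I error level.
#' @param power Target power.
#' @param dropout_rate Expected dropout fraction in \[0, 1).
#' @param arms Number of equally allocated arms.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(mean_active = 88, sd_active = 45,
                        mean_control = 70, sd_control = 40,
                        alpha = 0.05, power = 0.90,
                        dropout_rate = 0.10, arms = 4L) {
  stopifnot(sd_active > 0, sd_control > 0,
            alpha > 0, alpha < 1, power > 0, power < 1,
            dropout_rate >= 0, dropout_rate < 1, arms >= 1)
  structure(list(mean_active = mean_active, sd_active = sd_active,
                 mean_control = mean_control, sd_control = sd_control,
                 alpha = alpha, power = power,
                 dropout_rate = dropout_rate, arms = as.integer(arms)),
            class = "design_spec")
}

#' Evaluable sample size per group
#'
#' Two-group sample size under the normal (z) approximation with unequal
#' variances and equal allocation:
#' `n = ceil((z_{1-alpha/2} + z_{power})^2 (sd1^2 + sd0^2) / delta^2)`,
#' where delta is the assumed difference in means. Under the emulated
#' trial's assumptions this gives 118 evaluable participants per group for
#' 90% power at two-sided alpha 0.05.
#'
#' @param spec A [design_spec()].
#' @return Integer evaluable n per group.
#' @export
#' @examples
#' sample_size_two_groups(design_spec())  # 118
sample_size_two_groups <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  delta <- spec$mean_active - spec$mean_control
  if (delta == 0) {
    stop("mean_active must differ from mean_control", call. = FALSE)
  }
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  as.integer(ceiling(z^2 * (spec$sd_active^2 + spec$sd_control^2) /
                       delta^2))
}

#' Inflate an evaluable size for dropout
#'
#' Planned per-group size `ceil(n / (1 - rate))`, so that the expected
#' number of evaluable participants after dropout is at least `n`.
#'
#' @param n Evaluable participants per group.
#' @param rate Dropout fraction in \[0, 1).
#' @return Integer planned n per group.
#' @export
#' @examples
#' inflate_for_dropout(118, 0.10)  # 132
inflate_for_dropout <- function(n, rate) {
  stopifnot(n >= 1, rate >= 0)
  if (rate >= 1) stop("dropout rate must be below 1", call. = FALSE)
  as.integer(ceiling(n / (1 - rate)))
}

#' Planned total sample size
#'
#' @param n_per_group Planned participants per group.
#' @param arms Number of equally allocated arms.
#' @return Integer total.
#' @export
planned_total <- function(n_per_group, arms) {
  stopifnot(n_per_group >= 1, arms >= 1,
            n_per_group == round(n_per_group), arms == round(arms))
  as.integer(n_per_group) * as.integer(arms)
}

#' Achieved power at a given per-group size
#'
#' Power of the two-sided z test at per-group size n under the same normal
#' approximation as [sample_size_two_groups()]:
#' `Phi(|delta| / sqrt((sd1^2 + sd0^2) / n) - z_{1-alpha/2})`. At delta = 0
#' this reduces to one rejection tail, alpha / 2. Monotone increasing in n.
#'
#' @param spec A [design_spec()].
#' @param n Evaluable participants per group (>= 2).
#' @return Achieved power in (0, 1).
#' @export
power_at_n <- function(spec, n) {
  stopifnot(inherits(spec, "design_spec"), n >= 2)
  delta <- abs(spec$mean_active - spec$mean_control)
  se <- sqrt((spec$sd_active^2 + spec$sd_control^2) / n)
  stats::pnorm(delta / se - stats::qnorm(1 - spec$alpha / 2))
}

#' Design summary
#'
#' Evaluable, planned and total sample sizes plus achieved power for a
#' design specification.
#'
#' @param spec A [design_spec()].
#' @return A list of class `design_summary` with elements `n_evaluable`,
#'   `n_planned`, `n_total`, `power_achieved`.
#' @export
design_summary <- function(spec = design_spec()) {
  n_ev <- sample_size_two_groups(spec)
  n_pl <- inflate_for_dropout(n_ev, spec$dropout_rate)
  structure(
    list(n_evaluable = n_ev,
         n_planned = n_pl,
         n_total = planned_total(n_pl, spec$arms),
         power_achieved = power_at_n(spec, n_ev),
         spec = spec),
    class = "design_summary"
  )
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Two-group design (z approximation)\n")
  cat(sprintf("  assumed means %.1f vs %.1f, SDs %.1f / %.1f\n",
              x$spec$mean_active, x$spec$mean_control,
              x$spec$sd_active, x$spec$sd_control))
  cat(sprintf("  two-sided alpha %.3f, target power %.2f\n",
              x$spec$alpha, x$spec$power))
  cat(sprintf("  evaluable n per group: %d (achieved power %.3f)\n",
              x$n_evaluable, x$power_achieved))
  cat(sprintf("  planned n per group after %.0f%% dropout: %d\n",
              100 * x$spec$dropout_rate, x$n_planned))
  cat(sprintf("  planned total over %d arms: %d\n",
              x$spec$arms, x$n_total))
  invisible(x)
}
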