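#' Two-sample t comparison of an endpoint
#'
#' Group t test between two arms of endpoint values, reported as the
#' trial's contrast quadruple: difference of means, its standard error, a
#' t-based confidence interval, and the two-sided p value. The default is
#' the pooled-variance (classical) test, with Welch's unequal-variance form
#' available; the confidence interval uses the t quantile at the
#' corresponding degrees of freedom. If both samples are constant with
#' equal means there is no evidence against equality and p is defined as 1.
#'
#' @param x,y Numeric samples of endpoint values, each of size >= 2; the
#'   reported difference is `mean(x) - mean(y)`.
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @param level Confidence level, default 0.95.
#' @param endpoint,contrast Optional labels carried into the result.
#' @return A one-row data frame of class `comparison_result` with columns
#'   `endpoint`, `contrast`, `n_x`, `n_y`, `mean_x`, `mean_y`,
#'   `difference`, `se`, `df`, `lo`, `hi`, `p`, `status` (`"nominal"`
#'   until set by the gatekeeping procedure).
#' @export
#' @examples
#' two_sample_t(rnorm(20, -61, 28), rnorm(20, -50, 29))
two_sample_t <- function(x, y, variance_mode = c("pooled", "welch"),
                         level = 0.95, endpoint = "endpoint",
                         contrast = "x vs y") {
  variance_mode <- match.arg(variance_mode)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample must have at least 2 observations", call. = FALSE)
  }
  t_from_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y),
                 variance_mode = variance_mode, level = level,
                 endpoint = endpoint, contrast = contrast)
}

#' Two-sample t comparison from summary statistics
#'
#' The same contrast machinery as [two_sample_t()] operating on published
#' summary statistics (per-arm mean, SD and n), as needed to reproduce a
#' trial report's difference / SE / CI / p columns without participant
#' data.
#'
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Per-arm summaries.
#' @inheritParams two_sample_t
#' @return A `comparison_result` (see [two_sample_t()]).
#' @export
t_from_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                           variance_mode = c("pooled", "welch"),
                           level = 0.95, endpoint = "endpoint",
                           contrast = "x vs y") {
  variance_mode <- match.arg(variance_mode)
  stopifnot(n_x >= 2, n_y >= 2, sd_x >= 0, sd_y >= 0,
            level > 0, level < 1)
  diff <- mean_x - mean_y
  if (variance_mode == "pooled") {
    df <- n_x + n_y - 2
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
  } else {
    v <- sd_x^2 / n_x + sd_y^2 / n_y
    se <- sqrt(v)
    df <- v^2 / (sd_x^4 / (n_x^2 * (n_x - 1)) +
                   sd_y^4 / (n_y^2 * (n_y - 1)))
  }
  if (se == 0) {
    # both samples constant: equal means carry no evidence, unequal means
    # are separated with certainty
    p <- if (diff == 0) 1 else 0
    tstat <- if (diff == 0) 0 else sign(diff) * Inf
    lo <- hi <- diff
  } else {
    tstat <- diff / se
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    q <- stats::qt(1 - (1 - level) / 2, df)
    lo <- diff - q * se
    hi <- diff + q * se
  }
  structure(
    data.frame(endpoint = endpoint, contrast = contrast,
               n_x = n_x, n_y = n_y, mean_x = mean_x, mean_y = mean_y,
               difference = diff, se = se, df = df, lo = lo, hi = hi,
               p = p, status = "nominal", stringsAsFactors = FALSE),
    class = c("comparison_result", "data.frame")
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s, %s [%s]\n", x$endpoint[i], x$contrast[i], x$status[i]))
    cat(sprintf("  difference %.2f (SE %.2f), %s, p %s\n",
                x$difference[i], x$se[i],
                sprintf("95%% CI (%.2f to %.2f)", x$lo[i], x$hi[i]),
                format_p(x$p[i])))
  }
  invisible(x)
}

format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("= %.3f", p))
}

#' Fixed-sequence gatekeeping plan
#'
#' An ordered list of (test arm, reference arm) hypotheses and a familywise
#' two-sided alpha. Hypotheses are tested in the fixed order, each at the
#' full alpha; a hypothesis is confirmatory only while every earlier one
#' has rejected, after which the remaining tests are exploratory. The
#' default plan mirrors the emulated trial: the 1.0 mg dose against
#' placebo first, then the 0.75 mg dose against placebo.
#'
#' @param hypotheses List of length-2 character vectors
#'   `c(test_arm, reference_arm)`, in testing order.
#' @param alpha Familywise two-sided level in (0, 1), default 0.05.
#' @return An object of class `gatekeeping_plan`.
#' @export
gatekeeping_plan <- function(hypotheses = list(
                               c("tegileridine_1_0", "placebo"),
                               c("tegileridine_0_75", "placebo")),
                             alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, length(hypotheses) >= 1,
            all(vapply(hypotheses, length, integer(1)) == 2L))
  structure(list(hypotheses = hypotheses, alpha = alpha),
            class = "gatekeeping_plan")
}

#' Gatekept analysis of the primary endpoint
#'
#' Runs the plan's hypotheses in order on an endpoint panel: a two-sample t
#' test of the endpoint between each test arm and its reference, all at the
#' plan's alpha. The first hypothesis is confirmatory; each later one is
#' confirmatory only if every preceding test rejected at alpha, and
#' exploratory otherwise. The p values themselves are unadjusted — the
#' fixed sequence is what controls the familywise type-I error at alpha.
#'
#' @param panel An `endpoint_panel` (see [compute_endpoint_panel()]), or
#'   any data frame with an `arm` column and the endpoint column.
#' @param plan A [gatekeeping_plan()].
#' @param endpoint Name of the endpoint column (default `"spid_24"`).
#' @param variance_mode Passed to [two_sample_t()].
#' @return A `comparison_result` data frame with one row per hypothesis,
#'   `status` set to `"confirmatory"` or `"exploratory"`, and a logical
#'   `significant` column (p < alpha).
#' @export
gatekept_primary_analysis <- function(panel, plan = gatekeeping_plan(),
                                      endpoint = "spid_24",
                                      variance_mode = "pooled") {
  stopifnot(inherits(plan, "gatekeeping_plan"),
            endpoint %in% names(panel), "arm" %in% names(panel))
  rows <- vector("list", length(plan$hypotheses))
  gate_open <- TRUE
  for (i in seq_along(plan$hypotheses)) {
    h <- plan$hypotheses[[i]]
    x <- panel[[endpoint]][panel$arm == h[1]]
    y <- panel[[endpoint]][panel$arm == h[2]]
    if (!length(x) || !length(y)) {
      stop("arm missing from panel: ",
           paste(h[!c(length(x), length(y))], collapse = ", "),
           call. = FALSE)
    }
    cmp <- two_sample_t(x, y, variance_mode = variance_mode,
                        level = 1 - plan$alpha, endpoint = endpoint,
                        contrast = paste(h[1], "vs", h[2]))
    cmp$status <- if (gate_open) "confirmatory" else "exploratory"
    cmp$significant <- cmp$p < plan$alpha
    gate_open <- gate_open && cmp$significant
    rows[[i]] <- cmp
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples: exact p by enumeration of
#' the rank distribution when the combined size is at most 20 and there are
#' no ties, and the normal approximation with the tie-corrected variance
#' otherwise (no continuity correction). Used for cumulative
#' rescue-medication consumption and satisfaction scores.
#'
#' @param x,y Numeric samples, non-empty.
#' @return List with elements `statistic` (the rank-sum W of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  list(statistic = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test with fixed margins: p is the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one (the
#' conventional two-sided definition), via [stats::fisher.test()].
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with elements `p` and `odds_ratio` (conditional MLE).
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p  # 1/3
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)),
            all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  }
  ft <- stats::fisher.test(table)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}
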