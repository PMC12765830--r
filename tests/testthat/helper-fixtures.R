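# fixtures and independent oracles used across the test files

# complete assessment table for one participant on an arbitrary grid
make_assessments <- function(id, time_h, pi, pr, night = FALSE) {
  data.frame(id = id, time_h = time_h, pi = as.integer(pi),
             pr = as.integer(pr), night_sleep = night,
             stringsAsFactors = FALSE)
}

# small well-formed dataset: one participant per arm, flat series
tiny_dataset <- function() {
  grid <- protocol_schedule()
  n_t <- length(grid)
  ids <- c("A1", "A2", "A3", "A4")
  arms <- trial_arms()
  assessments <- do.call(rbind, lapply(seq_along(ids), function(i) {
    make_assessments(ids[i], grid,
                     pi = c(5L, rep(4L, n_t - 1L)),
                     pr = c(NA, rep(2L, n_t - 1L)))
  }))
  trial_dataset(
    participants = data.frame(id = ids, arm = arms, randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = assessments,
    rescues = data.frame(id = "A1", time_h = 2, drug = "parecoxib",
                         dose = 40, stringsAsFactors = FALSE)
  )
}

# dataset with disposition flags mirroring a 528-randomized / 526-treated
# flow: one untreated participant in the placebo arm and one in the second
# active-dose arm; assessments kept minimal (baseline + 24 h)
consort_like_dataset <- function() {
  n <- 132L
  ids <- sprintf("S%04d", seq_len(4L * n))
  arms <- rep(trial_arms(), each = n)
  treated <- rep(TRUE, 4L * n)
  treated[1L] <- FALSE                       # placebo, not treated
  treated[2L * n + 1L] <- FALSE              # 1.0 mg arm, not treated
  grid <- c(0, 6, 12, 18, 24)
  assessments <- data.frame(
    id = rep(ids, each = 5L),
    time_h = rep(grid, times = 4L * n),
    pi = rep(c(5L, 4L, 4L, 4L, 4L), times = 4L * n),
    pr = rep(c(NA_integer_, 2L, 2L, 2L, 2L), times = 4L * n),
    night_sleep = FALSE, stringsAsFactors = FALSE
  )
  trial_dataset(
    participants = data.frame(id = ids, arm = arms, randomized = TRUE,
                              treated = treated, stringsAsFactors = FALSE),
    assessments = assessments,
    schedule = grid
  )
}

# random complete score series on the protocol grid
random_series <- function() {
  grid <- protocol_schedule()
  n_t <- length(grid)
  impute_series(make_assessments(
    "R", grid,
    pi = c(sample(4:10, 1), sample(0:10, n_t - 1L, replace = TRUE)),
    pr = c(NA, sample(0:4, n_t - 1L, replace = TRUE))
  ))
}

# naive per-point loop oracle for the time-weighted sums
spid_oracle <- function(series, t_start, t_end) {
  acc <- 0
  base <- series$pi[series$time_h == 0]
  for (k in seq_len(nrow(series))[-1L]) {
    t <- series$time_h[k]
    if (t > t_start && t <= t_end) {
      acc <- acc + (series$pi[k] - base) * (t - series$time_h[k - 1L])
    }
  }
  acc
}

totpar_oracle <- function(series, t_start, t_end) {
  acc <- 0
  for (k in seq_len(nrow(series))[-1L]) {
    t <- series$time_h[k]
    if (t > t_start && t <= t_end) {
      acc <- acc + series$pr[k] * (t - series$time_h[k - 1L])
    }
  }
  acc
}

# brute-force check that an accepted/rejected PCA marking satisfies all
# three pump constraints simultaneously and is maximal (greedy first-come)
pca_constraints_hold <- function(res, window_start = 0.5, window_end = 24,
                                 lockout = 10 / 60, hourly_cap = 6) {
  acc <- res$time_h[res$accepted]
  eps <- 1e-9
  in_window <- all(acc - window_start > eps) && all(acc <= window_end + eps)
  spaced <- !any(diff(acc) < lockout - eps)
  capped <- all(vapply(acc, function(t) {
    sum(acc > t - 1 - eps & acc <= t + eps) <= hourly_cap
  }, logical(1)))
  in_window && spaced && capped
}

# exhaustive hypergeometric enumeration for the two-sided Fisher p
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
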