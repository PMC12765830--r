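night_fixture <- function() {
  # missing scores at the night-flagged 12 h point, complete elsewhere
  make_assessments("N1", c(0, 6, 10, 12, 18, 24),
                   pi = c(6L, 5L, 5L, NA, 4L, 4L),
                   pr = c(NA, 2L, 2L, NA, 3L, 3L),
                   night = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
}

test_that("missing night-sleep scores take NRS 3 and the previous relief", {
  s <- impute_series(night_fixture())
  k <- which(s$time_h == 12)
  expect_equal(s$pi[k], 3L)
  expect_equal(s$pi_src[k], "night_rule")
  expect_equal(s$pr[k], 2L)
  expect_equal(s$pr_src[k], "night_rule")
})

test_that("scores missing after a rescue carry the last pre-rescue value", {
  a <- make_assessments("R1", c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 18, 24),
                        pi = c(7L, 6L, 6L, NA, NA, NA, 5L, 5L, 5L, 5L, 5L,
                               5L),
                        pr = c(NA, 1L, 1L, NA, NA, NA, 2L, 2L, 2L, 2L, 2L,
                               2L))
  r <- data.frame(id = "R1", time_h = 2.5, drug = "parecoxib", dose = 40,
                  stringsAsFactors = FALSE)
  s <- impute_series(a, r)
  k <- which(s$time_h %in% c(3, 4, 5))
  expect_equal(s$pi[k], c(6L, 6L, 6L), ignore_attr = TRUE)
  expect_equal(unique(s$pi_src[k]), "rescue_rule")
  expect_equal(s$pr[k], c(1L, 1L, 1L), ignore_attr = TRUE)
  # 6 h is still inside the window (2.5, 8.5] but observed: the primary
  # mode keeps observed values
  expect_equal(s$pi[s$time_h == 6], 5L)
  expect_equal(s$pi_src[s$time_h == 6], "observed")
})

test_that("the sufentanil window is 2 h and windows follow the later rescue", {
  a <- make_assessments("R2", c(0, 1, 2, 3, 4, 5, 6, 8),
                        pi = c(7L, 6L, NA, NA, NA, NA, NA, 4L),
                        pr = c(NA, 1L, NA, NA, NA, NA, NA, 3L))
  r <- data.frame(id = "R2", time_h = c(1.5, 3.5),
                  drug = c("sufentanil", "parecoxib"),
                  dose = c(5, 40), stringsAsFactors = FALSE)
  s <- impute_series(a, r)
  # sufentanil window (1.5, 3.5]: points 2, 3 use the pre-rescue value at 1 h
  expect_equal(s$pi[s$time_h %in% c(2, 3)], c(6L, 6L), ignore_attr = TRUE)
  # the later parecoxib rescue governs (3.5, 9.5]: its own pre-rescue
  # observation is still the 1 h score (nothing observed since)
  expect_equal(s$pi[s$time_h %in% c(4, 5, 6)], c(6L, 6L, 6L),
               ignore_attr = TRUE)
  expect_equal(unique(s$pi_src[s$time_h %in% 2:6]), "rescue_rule")
})

test_that("rescue rule outranks the night rule where windows overlap", {
  a <- make_assessments("R3", c(0, 6, 10, 12, 18, 24),
                        pi = c(6L, 5L, NA, NA, 4L, 4L),
                        pr = c(NA, 2L, NA, NA, 3L, 3L),
                        night = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  r <- data.frame(id = "R3", time_h = 9, drug = "parecoxib", dose = 40,
                  stringsAsFactors = FALSE)
  s <- impute_series(a, r)
  # both 10 h and 12 h are night-flagged, but they sit in (9, 15]: the
  # rescue rule wins and carries the 6 h observation
  expect_equal(s$pi[s$time_h %in% c(10, 12)], c(5L, 5L), ignore_attr = TRUE)
  expect_equal(unique(s$pi_src[s$time_h %in% c(10, 12)]), "rescue_rule")
  # 18 h is outside the rescue window and observed
  expect_equal(s$pi_src[s$time_h == 18], "observed")
})

test_that("plain gaps fall back to last observation carried forward", {
  a <- make_assessments("L1", c(0, 1, 2, 3),
                        pi = c(5L, 4L, NA, NA), pr = c(NA, 2L, NA, NA))
  s <- impute_series(a)
  expect_equal(s$pi, c(5L, 4L, 4L, 4L))
  expect_equal(s$pi_src, c("observed", "observed", "locf", "locf"))
  expect_equal(s$pr[-1], c(2L, 2L, 2L))
})

test_that("sensitivity mode leaves post-rescue observations as recorded", {
  a <- make_assessments("S1", c(0, 1, 2, 3, 4),
                        pi = c(7L, 6L, NA, 2L, 2L),
                        pr = c(NA, 1L, NA, 4L, 4L))
  r <- data.frame(id = "S1", time_h = 1.5, drug = "parecoxib", dose = 40,
                  stringsAsFactors = FALSE)
  s_primary <- impute_series(a, r)
  s_sens <- impute_series(a, r, imputation_policy(
    mode = "sensitivity_no_rescue_imputation"))
  # primary: the missing 2 h point is governed by the rescue
  expect_equal(s_primary$pi_src[s_primary$time_h == 2], "rescue_rule")
  # sensitivity: the rescue window is ignored, the gap is plain LOCF
  expect_equal(s_sens$pi_src[s_sens$time_h == 2], "locf")
  expect_equal(s_sens$pi[s_sens$time_h == 2], 6L)
  # observed post-rescue improvements are kept in both modes by default
  expect_equal(s_primary$pi[s_primary$time_h == 3], 2L)
  expect_equal(s_sens$pi[s_sens$time_h == 3], 2L)

  # strict variant replaces observed in-window scores with pre-rescue ones
  s_strict <- impute_series(a, r, imputation_policy(strict_rescue = TRUE))
  expect_equal(s_strict$pi[s_strict$time_h %in% c(2, 3, 4)],
               c(6L, 6L, 6L), ignore_attr = TRUE)
})

test_that("complete series pass through unchanged with observed provenance", {
  a <- make_assessments("C1", c(0, 1, 2), pi = c(5L, 4L, 3L),
                        pr = c(NA, 1L, 2L))
  s <- impute_series(a)
  expect_equal(s$pi, a$pi)
  expect_equal(s$pr, a$pr)
  expect_true(all(s$pi_src == "observed"))
})

test_that("imputation errors are raised for unevaluable participants", {
  expect_error(
    impute_series(make_assessments("B", c(0, 1), pi = c(NA, 4L),
                                   pr = c(NA, 2L))),
    "baseline")
  # first post-baseline point night-flagged and missing: no PR to carry
  expect_error(
    impute_series(make_assessments("B", c(0, 12, 24), pi = c(6L, NA, 5L),
                                   pr = c(NA, NA, 2L),
                                   night = c(FALSE, TRUE, FALSE))),
    "no preceding pain relief")
})

test_that("imputation is idempotent at value level on random gappy series", {
  set.seed(11)
  grid <- protocol_schedule()
  n_t <- length(grid)
  for (rep in 1:50) {
    pi <- c(sample(4:10, 1), sample(0:10, n_t - 1L, replace = TRUE))
    pr <- c(NA, sample(0:4, n_t - 1L, replace = TRUE))
    drop <- c(FALSE, FALSE, stats::runif(n_t - 2L) < 0.3)
    pi[drop] <- NA
    pr[drop] <- NA
    night <- grid > 10 & grid <= 16
    a <- make_assessments("P", grid, pi, pr, night)
    r <- if (rep %% 2 == 0) {
      data.frame(id = "P", time_h = 3, drug = "parecoxib", dose = 40,
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }
    s1 <- impute_series(a, r)
    s2 <- impute_series(s1, r)
    expect_identical(s2$pi, s1$pi)
    expect_identical(s2$pr, s1$pr)
    expect_identical(s2$time_min, s1$time_min)
  }
})

test_that("the worked two-hour windows reproduce the hand expansion", {
  s <- impute_series(make_assessments("W", c(0, 0.5, 1, 2),
                                      pi = c(5L, 4L, 3L, 2L),
                                      pr = c(NA, 1L, 2L, 3L)))
  expect_equal(compute_spid(s, 0, 2),
               (2 - 5) * (2 - 1) + (3 - 5) * (1 - 0.5) + (4 - 5) * 0.5)
  expect_equal(compute_spid(s, 0, 2), -4.5)
  expect_equal(compute_totpar(s, 0, 2), 3 * 1 + 2 * 0.5 + 1 * 0.5)
})

test_that("flat pain gives zero SPID and extreme series reach the bounds", {
  grid <- protocol_schedule()
  n_t <- length(grid)
  flat <- impute_series(make_assessments("F", grid, rep(6L, n_t),
                                         c(NA, rep(0L, n_t - 1L))))
  expect_equal(compute_spid(flat, 0, 24), 0)
  expect_equal(compute_totpar(flat, 0, 24), 0)

  worst <- impute_series(make_assessments("X", grid,
                                          c(0L, rep(10L, n_t - 1L)),
                                          c(NA, rep(4L, n_t - 1L))))
  expect_equal(compute_spid(worst, 0, 24), 240)
  expect_equal(compute_totpar(worst, 0, 24), 96)

  best <- impute_series(make_assessments("Y", grid,
                                         c(10L, rep(0L, n_t - 1L)),
                                         c(NA, rep(4L, n_t - 1L))))
  expect_equal(compute_spid(best, 0, 24), -240)
})

test_that("window bounds must lie on the assessment grid", {
  s <- impute_series(make_assessments("G", c(0, 1, 2), pi = c(5L, 4L, 3L),
                                      pr = c(NA, 1L, 2L)))
  expect_error(compute_spid(s, 0, 1.5), "not on the assessment grid")
  expect_error(compute_totpar(s, 0.25, 2), "not on the assessment grid")
})

test_that("SPID and TOTPAR match the naive loop oracle on random series", {
  set.seed(23)
  for (rep in 1:1000) {
    s <- random_series()
    expect_equal(compute_spid(s, 0, 24), spid_oracle(s, 0, 24))
    expect_equal(compute_totpar(s, 0, 24), totpar_oracle(s, 0, 24))
  }
  # spot-check interior windows too
  set.seed(24)
  for (rep in 1:50) {
    s <- random_series()
    expect_equal(compute_spid(s, 6, 18), spid_oracle(s, 6, 18))
    expect_equal(compute_totpar(s, 12, 24), totpar_oracle(s, 12, 24))
  }
})

test_that("SPID is additive over adjacent windows, exactly", {
  set.seed(37)
  for (rep in 1:1000) {
    s <- random_series()
    # exact integer identity on the score-minute scale
    expect_identical(compute_spid(s, 0, 24, units = "minutes"),
                     compute_spid(s, 0, 12, units = "minutes") +
                       compute_spid(s, 12, 24, units = "minutes"))
    expect_equal(compute_spid(s, 0, 24),
                 compute_spid(s, 0, 12) + compute_spid(s, 12, 24))
  }
})

test_that("lowering any single pain score never increases SPID", {
  set.seed(41)
  for (rep in 1:50) {
    s <- random_series()
    k <- sample(2:nrow(s), 1)
    if (s$pi[k] == 0) next
    s2 <- s
    s2$pi[k] <- s2$pi[k] - sample(seq_len(s$pi[k]), 1)
    expect_lte(compute_spid(s2, 0, 24), compute_spid(s, 0, 24))
  }
})

test_that("endpoint panels decompose exactly and respect theoretical bounds", {
  cfg <- simulation_config(n_per_arm = 125)
  ds <- simulate_trial(cfg, seed = 57)
  pan <- compute_endpoint_panel(ds)
  expect_equal(nrow(pan), 500L)

  expect_equal(pan$spid_24, pan$spid_12 + pan$spid_12_24)
  expect_equal(pan$totpar_24, pan$totpar_12 + pan$totpar_12_24)
  # the decomposition is exact on the integer score-minute scale
  policy0 <- imputation_policy()
  for (pid in sample(pan$id, 20)) {
    s <- impute_series(ds$assessments[ds$assessments$id == pid, ],
                       ds$rescues[ds$rescues$id == pid, ], policy0)
    expect_identical(compute_spid(s, 0, 24, units = "minutes"),
                     compute_spid(s, 0, 12, units = "minutes") +
                       compute_spid(s, 12, 24, units = "minutes"))
  }
  expect_true(all(pan$spid_24 >= -240 & pan$spid_24 <= 240))
  expect_true(all(pan$totpar_24 >= 0 & pan$totpar_24 <= 96))
  # TOTPAR non-decreasing in the horizon
  expect_true(all(pan$totpar_6 <= pan$totpar_12))
  expect_true(all(pan$totpar_12 <= pan$totpar_18))
  expect_true(all(pan$totpar_18 <= pan$totpar_24))

  # brute-force recomputation, participant by participant
  policy <- imputation_policy()
  for (pid in sample(pan$id, 25)) {
    s <- impute_series(ds$assessments[ds$assessments$id == pid, ],
                       ds$rescues[ds$rescues$id == pid, ], policy)
    expect_equal(pan$spid_24[pan$id == pid], spid_oracle(s, 0, 24))
    expect_equal(pan$totpar_18[pan$id == pid], totpar_oracle(s, 0, 18))
  }
})

test_that("a flat participant scores zero on every endpoint", {
  grid <- protocol_schedule()
  n_t <- length(grid)
  ds <- trial_dataset(
    participants = data.frame(id = "Z", arm = "placebo", randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = make_assessments("Z", grid, rep(5L, n_t),
                                   c(NA, rep(0L, n_t - 1L))))
  pan <- compute_endpoint_panel(ds)
  spid_cols <- grep("^spid", names(pan), value = TRUE)
  totpar_cols <- grep("^totpar", names(pan), value = TRUE)
  expect_true(all(pan[, c(spid_cols, totpar_cols)] == 0))
  expect_true(pan$no_rescue)
})

test_that("panel errors are tagged with the participant id", {
  grid <- c(0, 6, 12, 18, 24)
  ds <- trial_dataset(
    participants = data.frame(id = c("OK", "BAD"), arm = "placebo",
                              randomized = TRUE, treated = TRUE,
                              stringsAsFactors = FALSE),
    assessments = rbind(
      make_assessments("OK", grid, c(5L, 4L, 4L, 4L, 4L),
                       c(NA, 1L, 1L, 1L, 1L)),
      # first post-baseline relief missing with nothing to carry forward
      make_assessments("BAD", grid, c(5L, NA, 4L, 4L, 4L),
                       c(NA, NA, 1L, 1L, 1L))),
    schedule = grid)
  expect_error(compute_endpoint_panel(ds), "BAD")
})

test_that("responder proportions count imputed scores at or below threshold", {
  grid <- c(0, 1, 24)
  ids <- c("a", "b", "c", "d")
  pis <- c(2L, 3L, 4L, 5L)
  assessments <- do.call(rbind, lapply(seq_along(ids), function(i) {
    make_assessments(ids[i], grid, c(5L, pis[i], pis[i]), c(NA, 1L, 1L))
  }))
  ds <- trial_dataset(
    participants = data.frame(id = ids, arm = "placebo", randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = assessments, schedule = grid)
  rp <- responder_proportion(ds, time = 1, threshold = 3)
  expect_equal(rp$proportion[rp$arm == "placebo"], 0.5)
  expect_error(responder_proportion(ds, time = 1.5), "not on the protocol")

  # degenerate arms: all zero pain vs all severe pain
  ds0 <- trial_dataset(
    participants = data.frame(id = "z", arm = "placebo", randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = make_assessments("z", grid, c(5L, 0L, 0L), c(NA, 4L, 4L)),
    schedule = grid)
  expect_equal(responder_proportion(ds0, 1)$proportion[1], 1)
  ds10 <- trial_dataset(
    participants = data.frame(id = "w", arm = "placebo", randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = make_assessments("w", grid, c(5L, 10L, 10L),
                                   c(NA, 0L, 0L)),
    schedule = grid)
  expect_equal(responder_proportion(ds10, 1)$proportion[1], 0)
})
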