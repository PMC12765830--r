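test_that("Clopper-Pearson bounds hit 0 and 1 exactly at the boundaries", {
  ci0 <- clopper_pearson(0, 20)
  expect_identical(ci0$lo, 0)
  expect_lt(ci0$hi, 1)
  ci1 <- clopper_pearson(20, 20)
  expect_identical(ci1$hi, 1)
  expect_gt(ci1$lo, 0)
  expect_error(clopper_pearson(21, 20), "k must satisfy")
})

test_that("Clopper-Pearson reproduces the published 103/131 interval", {
  ci <- clopper_pearson(103, 131, 0.95)
  expect_equal(round(ci$lo, 3), 0.706)
  expect_equal(round(ci$hi, 3), 0.853)
  # and agrees with the exact binomial test's interval
  bt <- stats::binom.test(103, 131)$conf.int
  expect_equal(c(ci$lo, ci$hi), as.numeric(bt))
})

test_that("Clopper-Pearson coverage is at least nominal for all n up to 30", {
  # brute-force binomial coverage over a grid of true proportions
  p_grid <- seq(0.01, 0.99, by = 0.01)
  for (n in 1:30) {
    bounds <- vapply(0:n, function(k) {
      ci <- clopper_pearson(k, n, 0.95)
      c(ci$lo, ci$hi)
    }, numeric(2))
    for (p in p_grid) {
      cover <- sum(stats::dbinom(0:n, n, p)[bounds[1, ] <= p &
                                              p <= bounds[2, ]])
      expect_gte(cover, 0.95)
    }
  }
})

test_that("no-rescue proportions use arm denominators with exact intervals", {
  grid <- c(0, 24)
  ids <- sprintf("q%02d", 1:8)
  arms <- rep(c("placebo", "tegileridine_1_0"), each = 4)
  assessments <- do.call(rbind, lapply(ids, function(i) {
    make_assessments(i, grid, c(5L, 4L), c(NA, 2L))
  }))
  # everyone in placebo rescues, nobody in the active arm
  resc <- data.frame(id = ids[1:4], time_h = 3, drug = "parecoxib",
                     dose = 40, stringsAsFactors = FALSE)
  ds <- trial_dataset(
    participants = data.frame(id = ids, arm = arms, randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = assessments, rescues = resc, schedule = grid)
  nr <- no_rescue_proportion(ds)
  pl <- nr[nr$arm == "placebo", ]
  ac <- nr[nr$arm == "tegileridine_1_0", ]
  expect_equal(pl$proportion, 0)
  expect_identical(pl$lo, 0)
  expect_equal(ac$proportion, 1)
  expect_identical(ac$hi, 1)
  expect_true(is.na(pl$p_vs_reference))
  expect_false(is.na(ac$p_vs_reference))
})

test_that("Fisher p for no-rescue contrasts matches exhaustive enumeration", {
  tab <- matrix(c(103, 131 - 103, 53, 130 - 53), nrow = 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab)$p, fisher_oracle(tab),
               tolerance = 1e-10)
})

test_that("first rescue times censor non-users at 24 h and keep late events", {
  grid <- c(0, 24)
  ids <- c("r1", "r2", "r3")
  assessments <- do.call(rbind, lapply(ids, function(i) {
    make_assessments(i, grid, c(6L, 5L), c(NA, 1L))
  }))
  resc <- data.frame(
    id = c("r1", "r1", "r3"),
    time_h = c(5, 9, 24 + 5 / 60),
    drug = "parecoxib", dose = 40, stringsAsFactors = FALSE)
  ds <- trial_dataset(
    participants = data.frame(id = ids, arm = "placebo", randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = assessments, rescues = resc, schedule = grid)
  ttr <- time_to_first_rescue(ds)
  expect_equal(ttr$time_h[ttr$id == "r1"], 5)
  expect_true(ttr$event[ttr$id == "r1"])
  expect_equal(ttr$time_h[ttr$id == "r2"], 24)
  expect_false(ttr$event[ttr$id == "r2"])
  # recorded at 24 h 5 min: an event at its recorded time, beyond the
  # 24 h plotting window but retained in the analysis
  expect_true(ttr$event[ttr$id == "r3"])
  expect_gt(ttr$time_h[ttr$id == "r3"], 24)
  # but it does not count against the (0, 24] no-rescue proportion
  nr <- no_rescue_proportion(ds)
  expect_equal(nr$k[nr$arm == "placebo"], 2L)
})

test_that("Kaplan-Meier estimate matches hand product-limit values", {
  # all censored: survival identically 1
  s0 <- km_estimate(data.frame(time_h = rep(24, 5), event = FALSE))
  expect_true(all(s0$survival == 1))

  # events at 2 and 4 among four, two censored at 24
  km <- km_estimate(data.frame(time_h = c(2, 4, 24, 24),
                               event = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(km$survival[km$time_h == 2], 0.75)
  expect_equal(km$survival[km$time_h == 4], 0.5)

  # no censoring: one minus the empirical distribution function
  times <- c(1, 3, 7, 12, 20)
  km2 <- km_estimate(data.frame(time_h = times, event = TRUE))
  expect_equal(km2$survival, 1 - seq_along(times) / length(times))
})

test_that("log-rank is null on identical samples and detects separation", {
  a <- data.frame(time_h = c(2, 5, 9, 24), event = c(TRUE, TRUE, TRUE,
                                                     FALSE))
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  b <- data.frame(time_h = rep(24, 6), event = FALSE)
  c_ <- data.frame(time_h = c(1, 2, 3), event = TRUE)
  sep <- logrank_test(c_, b)
  expect_gt(sep$statistic, 0)
  expect_lt(sep$p, 0.05)

  # symmetric under label swap
  swapped <- logrank_test(b, c_)
  expect_equal(sep$statistic, swapped$statistic)
  expect_equal(sep$p, swapped$p)
})

test_that("log-rank chi-square p agrees with a permutation p on small n", {
  set.seed(61)
  a <- data.frame(time_h = c(1, 4, 6, 10, 24, 24),
                  event = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  b <- data.frame(time_h = c(3, 8, 15, 24, 24, 24),
                  event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  obs <- logrank_test(a, b)$statistic
  pool <- rbind(a, b)
  n_perm <- 2000
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(nrow(pool), nrow(a))
    stat <- logrank_test(pool[idx, ], pool[-idx, ])$statistic
    if (stat >= obs - 1e-12) exceed <- exceed + 1L
  }
  p_perm <- exceed / n_perm
  p_chisq <- logrank_test(a, b)$p
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_perm - p_chisq), 4 * mc_se + 0.02)
})

test_that("consumption means zero-fill non-users over the whole arm", {
  grid <- c(0, 24)
  ids <- sprintf("c%02d", 1:4)
  assessments <- do.call(rbind, lapply(ids, function(i) {
    make_assessments(i, grid, c(6L, 5L), c(NA, 1L))
  }))
  resc <- data.frame(id = c("c03", "c04"), time_h = c(2, 3),
                     drug = "parecoxib", dose = c(2, 2),
                     stringsAsFactors = FALSE)
  ds <- trial_dataset(
    participants = data.frame(id = ids, arm = "placebo", randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = assessments, rescues = resc, schedule = grid)
  cc <- cumulative_rescue_consumption(ds)
  par <- cc[cc$drug == "parecoxib", ]
  expect_equal(par$mean, 1.0)  # {0, 0, 2, 2} over 4 participants
  expect_equal(par$sd, stats::sd(c(0, 0, 2, 2)))
  # a drug nobody used: mean 0, sd 0
  suf <- cc[cc$drug == "sufentanil", ]
  expect_equal(suf$mean, 0)
  expect_equal(suf$sd, 0)
})

test_that("consumption is invariant to arm size bookkeeping of non-users", {
  # one user of 5 units among five participants: mean 1.0
  grid <- c(0, 24)
  ids <- sprintf("u%02d", 1:5)
  assessments <- do.call(rbind, lapply(ids, function(i) {
    make_assessments(i, grid, c(6L, 5L), c(NA, 1L))
  }))
  resc <- data.frame(id = "u01", time_h = 2, drug = "sufentanil", dose = 5,
                     stringsAsFactors = FALSE)
  ds <- trial_dataset(
    participants = data.frame(id = ids, arm = "morphine", randomized = TRUE,
                              treated = TRUE, stringsAsFactors = FALSE),
    assessments = assessments, rescues = resc, schedule = grid)
  cc <- cumulative_rescue_consumption(ds)
  expect_equal(cc$mean[cc$drug == "sufentanil"], 1.0)
})
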