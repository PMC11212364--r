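# The truncated wave criterion.

test_that("median estimate branches: exact, midpoint, fallback, bound", {
  e <- true_median_estimate(c(2, 4), 9)
  expect_equal(e$estimate, 4)       # any T >= 9 leaves median{2,4,T} = 4
  expect_true(e$exact)
  expect_equal(e$method, "include-exact")

  e2 <- true_median_estimate(c(2, 10), 5)
  expect_equal(e2$median_low, 5)
  expect_equal(e2$median_high, 10)
  expect_equal(e2$estimate, 7.5)
  expect_equal(e2$method, "midpoint")
  expect_false(e2$exact)

  e3 <- true_median_estimate(numeric(0), 30)
  expect_equal(e3$estimate, 30)
  expect_equal(e3$method, "lower-bound")
  expect_equal(e3$median_high, Inf)

  e4 <- true_median_estimate(7, 3)
  expect_equal(e4$estimate, 7)
  expect_equal(e4$method, "fallback")

  expect_error(true_median_estimate(c(2, -1), 5), "positive")
  expect_error(true_median_estimate(c(2, 3), 0), "positive")
})

test_that("mean policies: include, exclude, longest-include", {
  expect_equal(mean_with_truncation(c(2, 4), 9, "include")$value, 5)
  li <- mean_with_truncation(c(2, 10), 5, "longest-include")
  expect_equal(li$value, 6)                 # 5 < 10: excluded
  expect_equal(li$flag, "excluded-not-longest")
  expect_equal(mean_with_truncation(c(2, 4), 9, "longest-include")$value, 5)
  ex <- mean_with_truncation(numeric(0), 30, "exclude")
  expect_true(is.na(ex$value))
})

test_that("midpoint estimate matches the brute-force enumerated range", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    u <- rlnorm(k, log(10), 1)
    tobs <- rlnorm(1, log(10), 1)
    rng <- brute_median_range(u, tobs)
    est <- true_median_estimate(u, tobs)
    expect_equal(est$median_low, rng[1], tolerance = 1e-12)
    expect_equal(est$median_high, rng[2], tolerance = 1e-12)
    expect_equal(est$estimate, mean(rng), tolerance = 1e-9)
  }
})

test_that("estimate is monotone in the observed truncated duration", {
  set.seed(12)
  for (i in 1:20) {
    u <- rlnorm(sample(2:6, 1), log(10), 1)
    tt <- sort(rlnorm(10, log(10), 1))
    ests <- vapply(tt, function(x) true_median_estimate(u, x)$estimate,
                   numeric(1))
    expect_true(all(diff(ests) >= -1e-12))
  }
})

test_that("including a truncated period always underestimates the mean", {
  set.seed(13)
  for (i in 1:20) {
    u <- rlnorm(sample(0:6, 1), log(10), 1)
    tobs <- rlnorm(1, log(10), 1)
    inc <- mean_with_truncation(u, tobs, "include")$value
    for (true_dur in tobs * runif(5, 1, 10))
      expect_true(inc <= mean(c(u, true_dur)) + 1e-12)
  }
})

test_that("the criterion adjusts only the truncated waveform in a recording", {
  # prior complete E2s of 2 and 10 min; recording ends mid-E2 at 5 min
  lab <- c("Np", "C", "E1", "E2", "E1", "E2", "C", "E1", "E2")
  durs <- c(5, 5, 1, 2, 1, 10, 5, 1, 5)
  rec <- make_rec(lab, durs)
  v_on <- compute_variables(rec, truncated_criterion = TRUE)
  v_off <- compute_variables(rec, truncated_criterion = FALSE)
  expect_equal(var_value(v_on, "m_E2"), 7.5)   # midpoint of [5, 10]
  expect_equal(var_value(v_on, "a_E2"), 6)     # longest-include: excluded
  expect_equal(var_value(v_off, "m_E2"), 5)
  expect_equal(var_value(v_off, "a_E2"), mean(c(2, 10, 5)))
  # counts and sums always include the observed truncated duration
  expect_equal(var_value(v_on, "n_E2"), 3)
  expect_equal(var_value(v_on, "s_E2"), 17)
  # a recording ending in Np leaves E2 statistics untouched
  rec2 <- make_rec(c("Np", "C", "E1", "E2", "E1", "E2", "C", "Np"),
                   c(5, 5, 1, 2, 1, 10, 5, 451))
  w_on <- compute_variables(rec2, truncated_criterion = TRUE)
  w_off <- compute_variables(rec2, truncated_criterion = FALSE)
  for (a in c("n_E2", "a_E2", "m_E2", "s_E2", "mx_E2"))
    expect_equal(var_value(w_on, a), var_value(w_off, a))
  expect_false(var_value(w_on, "m_Np") == var_value(w_off, "m_Np"))
})
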