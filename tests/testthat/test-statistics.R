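test_that("temperament score is the ratio of closed-form intensities", {
  # build a trajectory with a prescribed number of events and exposure in
  # each state: n_leave departures over min_cov covered minutes, n_ret
  # returns over min_exp exposed minutes
  build <- function(n_leave, min_cov, n_ret, min_exp) {
    stopifnot(n_leave == n_ret)  # alternation forces equal counts
    times <- numeric(0); t <- 0; states <- integer(0)
    for (i in seq_len(n_leave)) {
      states <- c(states, 1L); times <- c(times, t); t <- t + min_cov / n_leave
      states <- c(states, 2L); times <- c(times, t); t <- t + min_exp / n_ret
    }
    # end back under cover with a zero-length final visit so counts and
    # exposures are exactly as prescribed
    states <- c(states, 1L); times <- c(times, t)
    trajectory(individual_state_space(), states, times * 60, t * 60)
  }
  tr2 <- build(12, 30, 12, 60)
  sc2 <- temperament_score(tr2)
  expect_equal(sc2$leave_rate, 0.4, tolerance = 1e-9)
  expect_equal(sc2$return_rate, 0.2, tolerance = 1e-9)
  expect_equal(sc2$score, 2.0, tolerance = 1e-9)

  # symmetric fish: equal rates give score 1
  tr3 <- build(10, 20, 10, 20)
  expect_equal(temperament_score(tr3)$score, 1.0, tolerance = 1e-9)

  # zero exposure to the exposed state is undefined
  tr4 <- trajectory(individual_state_space(), 1L, 0, 600)
  expect_error(temperament_score(tr4), class = "pairlead_undefined_score")
})

test_that("temperament score is invariant to the time unit", {
  log <- simulate_individual_session(0.9, 1.8, 60, seed = 5)
  tr <- encode_individual(log, "bold")
  slow <- trajectory(individual_state_space(), tr$visits$state,
                     tr$visits$time * 60, tr$end_time * 60)
  expect_equal(temperament_score(tr)$score, temperament_score(slow)$score,
               tolerance = 1e-12)
})

test_that("scores from repeated sessions of the same fish correlate positively", {
  # 40 simulated fish, heterogeneous true rates, two sessions each
  set.seed(42)
  leave <- rlnorm(40, log(0.6), 0.5)
  ret <- rlnorm(40, log(1.5), 0.3)
  score <- function(i, s) {
    log <- simulate_individual_session(leave[i], ret[i], 60,
                                       seed = 7000 + 2 * i + s)
    temperament_score(encode_individual(log, "bold"))$score
  }
  s1 <- vapply(1:40, score, numeric(1), s = 0)
  s2 <- vapply(1:40, score, numeric(1), s = 1)
  expect_gt(cor(s1, s2), 0)
})

test_that("runs z-score matches the closed-form oracle and its symmetry", {
  oracle <- function(labels) {
    n1 <- sum(labels == labels[1]); n2 <- length(labels) - n1
    N <- n1 + n2
    R <- 1 + sum(diff(as.integer(factor(labels))) != 0)
    mu <- 2 * n1 * n2 / N + 1
    (R - mu) / sqrt(2 * n1 * n2 * (2 * n1 * n2 - N) / (N^2 * (N - 1)))
  }
  clumped <- rep(c("B", "S"), each = 4)
  alternating <- rep(c("B", "S"), 4)
  expect_equal(runs_z_score(clumped), oracle(clumped))
  expect_equal(runs_z_score(clumped), -2.2913, tolerance = 1e-4)
  expect_equal(runs_z_score(alternating), +2.2913, tolerance = 1e-4)
  expect_error(runs_z_score(rep("B", 4)), class = "pairlead_undefined_runs")

  # null mean over random permutations of a fixed multiset is ~0
  set.seed(7)
  labels <- rep(c("B", "S"), c(12, 8))
  zs <- replicate(10000, runs_z_score(sample(labels)))
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("exact sign test doubles the smaller binomial tail", {
  expect_equal(round(sign_binomial_test(16, 20), 3), 0.012)
  expect_equal(sign_binomial_test(10, 20), 1.0)
  expect_equal(sign_binomial_test(20, 20), 2 * 0.5^20, tolerance = 1e-12)
  # agrees with the standard exact test at p = 1/2
  for (k in c(0, 3, 9, 14, 20))
    expect_equal(sign_binomial_test(k, 20),
                 stats::binom.test(k, 20)$p.value, tolerance = 1e-9)
  # symmetry and monotonicity in |k - n/2|
  for (n in 1:25) {
    p <- vapply(0:n, sign_binomial_test, numeric(1), n = n)
    expect_equal(p, rev(p), tolerance = 1e-12)
    upper <- p[(floor(n / 2) + 1):(n + 1)]
    expect_true(all(diff(upper) <= 1e-12))
  }
})

test_that("descriptives recover design quantities on simulated cohorts", {
  # a fish with 54 completed trips in one hour reports 54 trips/h
  ev <- do.call(make_log, c(lapply(0:107, function(i) {
    c(10 + i * 30, "bold", if (i %% 2 == 0) "leave" else "return")
  }), list(duration = 3600)))
  d1 <- descriptives(list(ev))
  expect_equal(d1$fish$trips_per_hour[d1$fish$fish == "bold"], 54)

  # simulated cohort: observed trips/h within 3 SE of the stationary
  # expectation of the generating chain
  study <- sim_trajs(8, 60, seed = 161)$study
  d <- descriptives(study$logs)
  expected <- expected_trips_per_hour(default_pair_rates())[["mean"]]
  expect_lt(abs(d$summary$trips_per_hour_mean - expected),
            3 * d$summary$trips_per_hour_se)
  expect_true(all(d$position_changes >= 0))
})

test_that("symmetric pairs initiate equally often", {
  # identical leave/return intensities for both fish: bold initiation share
  # should be 1/2 on average across pairs
  r <- default_pair_rates()
  sym <- r
  # mirror: bold edges get the shy value of the mirrored edge and vice versa
  mirror <- c(q1_5 = "q2_9", q2_5 = "q1_9", q3_5 = "q4_9", q4_5 = "q3_9",
              q5_6 = "q9_10", q5_1 = "q9_2", q8_6 = "q12_10", q8_3 = "q12_4",
              q11_10 = "q7_6", q11_4 = "q7_3", q6_7 = "q10_11",
              q6_8 = "q10_12")
  for (a in names(mirror)) {
    b <- mirror[[a]]
    m <- mean(c(r[[a]], r[[b]]))
    sym[a] <- m
    sym[b] <- m
  }
  shares <- vapply(1:60, function(i) {
    log <- simulate_pair_session(sym, 20, seed = 5000 + i)
    rec <- initiation_sequence(encode_pair(log, SP))
    mean(rec$initiator == "bold")
  }, numeric(1))
  se <- sd(shares) / sqrt(length(shares))
  expect_lt(abs(mean(shares) - 0.5), 3 * se)
})
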