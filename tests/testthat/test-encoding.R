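test_that("encode_individual transcribes events and handles degenerate logs", {
  log <- make_log(c(10, "bold", "leave"), c(30, "bold", "return"))
  tr <- encode_individual(log, "bold")
  expect_equal(tr$visits$state, c(1L, 2L, 1L))
  expect_equal(tr$visits$time, c(0, 10, 30))
  expect_equal(tr$end_time, 60)

  empty <- session_log("p1", "s1", "transparent", 60, NULL)
  tr0 <- encode_individual(empty, "shy")
  expect_equal(tr0$visits$state, 1L)
  expect_equal(tr0$visits$time, 0)
})

test_that("malformed logs are rejected with the offending event index", {
  err <- tryCatch(
    make_log(c(10, "bold", "leave"), c(20, "bold", "leave")),
    pairlead_malformed_log = function(c) c)
  expect_s3_class(err, "pairlead_malformed_log")
  expect_equal(err$index, 2L)
  expect_error(make_log(c(5, "shy", "return")), class = "pairlead_malformed_log")
  expect_error(make_log(c(10, "bold", "leave"), c(10, "shy", "leave")),
               class = "pairlead_malformed_log")
})

test_that("encode_pair folds events through the status-update rules", {
  log <- make_log(c(10, "bold", "leave"), c(15, "shy", "leave"),
                  c(40, "shy", "return"), c(50, "bold", "return"))
  tr <- encode_pair(log, SP)
  expect_equal(tr$visits$state, c(NA, 5L, 6L, 8L, 3L))
  expect_equal(tr$visits$time, c(0, 10, 15, 40, 50))
  expect_equal(tr$end_time, 60)

  # failed initiation passes back through state 1
  log2 <- make_log(c(10, "bold", "leave"), c(20, "bold", "return"),
                   c(30, "shy", "leave"))
  tr2 <- encode_pair(log2, SP)
  expect_equal(tr2$visits$state, c(NA, 5L, 1L, 9L))
  expect_error(encode_pair(make_log(c(1, "bold", "leave"),
                                    partition = "opaque")))
})

test_that("individual encoding agrees with the location collapse of the pair encoding", {
  log <- sim_trajs(1, 20, seed = 31)$study$logs[[1]]
  pair <- encode_pair(log, SP)
  loc <- project_location(pair, LS)
  for (f in c("bold", "shy")) {
    ind <- encode_individual(log, f)
    # compare location at each pair-visit time (post-unknown)
    v <- loc$visits[!is.na(loc$visits$state), ]
    combo <- LS$states$combo[v$state]
    out <- if (f == "bold") combo %in% c("BE", "EE") else combo %in% c("SE", "EE")
    at <- function(t) ind$visits$state[max(which(ind$visits$time <= t))]
    expect_equal(out, vapply(v$time, at, integer(1)) == 2L)
  }
})

test_that("one-step projection is mechanical and commutes with location collapse", {
  log <- make_log(c(10, "bold", "leave"), c(15, "shy", "leave"),
                  c(40, "shy", "return"), c(50, "bold", "return"))
  pair <- encode_pair(log, SP)
  os <- project_one_step(pair, OS)
  lbl <- function(id) paste(OS$states$combo[id], OS$states$prev[id], sep = "|")
  known <- os$visits$state[!is.na(os$visits$state)]
  expect_equal(vapply(known, lbl, character(1)),
               c("BE|CC", "EE|BE", "BE|EE", "CC|BE"))
  expect_equal(os$visits$time, pair$visits$time)  # identical visit times
  # projection then collapse == direct collapse
  a <- project_location(os, LS)
  b <- project_location(pair, LS)
  expect_equal(a$visits, b$visits)
})

test_that("initiation records carry the right initiators and outcomes", {
  log <- make_log(c(10, "bold", "leave"), c(15, "shy", "leave"),
                  c(40, "shy", "return"), c(50, "bold", "return"))
  rec <- initiation_sequence(encode_pair(log, SP))
  expect_equal(rec$time, 10)
  expect_equal(rec$initiator, "bold")
  expect_true(rec$success)

  log2 <- make_log(c(10, "bold", "leave"), c(20, "bold", "return"),
                   c(30, "shy", "leave"))
  rec2 <- initiation_sequence(encode_pair(log2, SP))
  expect_equal(rec2$initiator, c("bold", "shy"))
  expect_equal(rec2$success, c(FALSE, NA))  # second trip unresolved at censoring
})

test_that("initiation count equals entries into the solo-unjoined states from safety", {
  for (seed in 1:5) {
    tr <- sim_trajs(1, 30, seed = 40 + seed)$trajs[[1]]
    s <- tr$visits$state
    prev <- c(NA, s[-length(s)])
    expected <- sum(!is.na(s) & s %in% c(5L, 9L) & (is.na(prev) | prev %in% 1:4))
    expect_equal(nrow(initiation_sequence(tr)), expected)
  }
})

test_that("position changes count moves between the join and the final two returns", {
  # join, immediate termination accepted: 0 changes
  tr <- make_traj(c(NA, 5, 6, 8, 3), c(0, 10, 15, 40, 50), 60)
  expect_equal(trip_position_changes(tr), 0L)
  # one termination attempt + one re-join: 2 changes
  tr2 <- make_traj(c(NA, 5, 6, 8, 6, 8, 3), c(0, 10, 15, 20, 25, 30, 35), 60)
  expect_equal(trip_position_changes(tr2), 2L)
  # no join at all -> empty
  tr3 <- make_traj(c(NA, 5, 1, 9, 2), c(0, 10, 20, 30, 40), 60)
  expect_equal(trip_position_changes(tr3), integer(0))
  # oracle: enumerate visits between EE-entry and CC-entry on simulated data
  for (seed in 1:5) {
    t <- sim_trajs(1, 20, seed = 50 + seed)$trajs[[1]]
    s <- t$visits$state
    counts <- integer(0); open <- NA
    for (i in seq_along(s)) {
      if (is.na(s[i])) next
      if (is.na(open) && s[i] %in% c(6, 10)) open <- i
      else if (!is.na(open) && s[i] %in% 1:4) {
        counts <- c(counts, i - open - 2L); open <- NA
      }
    }
    expect_equal(trip_position_changes(t), counts)
  }
})

test_that("known exposure is duration minus the unknown prefix", {
  for (seed in 1:5) {
    log <- sim_trajs(1, 15, seed = 60 + seed)$study$logs[[1]]
    tr <- encode_pair(log, SP)
    first <- tr$visits$time[2]
    expect_equal(known_exposure(tr), log$duration_s - first)
  }
})

test_that("CSV round trip preserves logs and reports line-numbered errors", {
  study <- sim_trajs(2, 10, seed = 71, sessions = 2)$study
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_logs(study$logs, path)
  back <- read_session_logs(path)
  expect_length(back, 4)
  for (i in seq_along(back)) {
    a <- study$logs[[i]]; b <- back[[i]]
    expect_equal(b$events$fish, a$events$fish)
    expect_equal(b$events$time_s, a$events$time_s, tolerance = 1e-12)
    expect_equal(b$duration_s, a$duration_s)
  }
  # tied timestamps: rejected by default, resolved with an epsilon on request
  tied <- data.frame(pair_id = "p", session_id = "s", partition = "transparent",
                     duration_s = 60, fish = c("bold", "shy"),
                     time_s = c(10, 10), action = c("leave", "leave"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tied, path2, row.names = FALSE)
  expect_error(read_session_logs(path2), "line")
  fixed <- read_session_logs(path2, tie_epsilon = 1e-4)
  expect_equal(fixed[[1]]$events$time_s, c(10, 10.0001))
})

test_that("simulate -> serialize -> encode reproduces the simulated state sequence", {
  rates <- default_pair_rates()
  for (seed in 1:25) {
    log <- simulate_pair_session(rates, 10, seed = 100 + seed)
    path <- tempfile(fileext = ".csv")
    write_session_logs(log, path)
    back <- read_session_logs(path)[[1]]
    tr <- encode_pair(back, SP)
    expect_identical(tr$visits$state[-1], attr(log, "states")[-1])
    unlink(path)
  }
})
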