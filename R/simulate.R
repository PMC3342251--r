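#' Simulate one pair session from the 12-state chain
#'
#' Exact (Gillespie-style) simulation: from the current state, the sojourn
#' is exponential with the state's total exit rate and the next edge is
#' chosen with probability proportional to its intensity.  The chain starts
#' in a both-covered state (state 1 by convention; the pre-first-event
#' status is unobservable and is encoded as "unknown" on re-reading, so the
#' choice only affects the first sojourn's rates).  Events are serialized
#' to per-fish leave/return records in seconds.
#'
#' @param rates named per-edge intensities, per minute: names are the full
#'   tying scheme's class labels (`q1_5`, `q5_6`, ...), one per edge of the
#'   12-state space.
#' @param minutes session length in minutes.
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @param pair_id,session_id identifiers for the resulting log.
#' @param start_state initial state id (a both-covered state, 1-4).
#' @param space optionally a prebuilt [pair_state_space()].
#' @return a `session_log` (transparent partition) with attributes
#'   `states` and `state_times_s`: the simulated state sequence including
#'   the start state.
#' @export
simulate_pair_session <- function(rates, minutes, seed = NULL,
                                  pair_id = "pair1", session_id = "s1",
                                  start_state = 1L,
                                  space = pair_state_space()) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  e <- space$edges
  full_labels <- paste0("q", e$from, "_", e$to)
  q <- rates[full_labels]
  if (anyNA(q)) stop("rates must be named by full-scheme class labels; missing: ",
                     paste(full_labels[is.na(q)], collapse = ", "))
  if (any(q < 0)) stop("negative intensity")
  ns <- nrow(space$states)
  out_edges <- lapply(seq_len(ns), function(s) which(e$from == s))
  exit <- vapply(out_edges, function(ix) sum(q[ix]), numeric(1))
  stopifnot(start_state %in% space$states$id[space$states$combo == "CC"])

  cap <- 256L
  ev_time <- numeric(cap); ev_fish <- character(cap); ev_act <- character(cap)
  st_seq <- integer(cap + 1L); st_time <- numeric(cap + 1L)
  s <- as.integer(start_state)
  st_seq[1] <- s; st_time[1] <- 0
  t <- 0; k <- 0L
  repeat {
    if (exit[s] <= 0) break          # absorbing under these rates
    t <- t + rexp(1, exit[s])
    if (t >= minutes) break
    ix <- out_edges[[s]]
    j <- if (length(ix) == 1L) ix else
      ix[1L + (runif(1) * exit[s] > q[ix[1]])]
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      length(ev_time) <- cap; length(ev_fish) <- cap; length(ev_act) <- cap
      length(st_seq) <- cap + 1L; length(st_time) <- cap + 1L
    }
    ev_time[k] <- t * 60
    ev_fish[k] <- e$mover[j]
    ev_act[k] <- e$move[j]
    s <- e$to[j]
    st_seq[k + 1L] <- s; st_time[k + 1L] <- t * 60
  }
  events <- data.frame(time_s = ev_time[seq_len(k)],
                       fish = ev_fish[seq_len(k)],
                       action = ev_act[seq_len(k)],
                       stringsAsFactors = FALSE)
  log <- session_log(pair_id, session_id, "transparent", minutes * 60, events)
  attr(log, "states") <- st_seq[seq_len(k + 1L)]
  attr(log, "state_times_s") <- st_time[seq_len(k + 1L)]
  log
}

#' Simulate one fish's session from the two-state chain
#'
#' Alternating-renewal simulation of a single fish moving between cover and
#' the exposed area: exponential sojourns under cover at `leave_rate` and
#' exposed at `return_rate` (per minute), starting under cover.
#'
#' @param leave_rate,return_rate intensities per minute, >= 0.
#' @param minutes session length in minutes.
#' @param seed optional integer seed.
#' @param fish `"bold"` or `"shy"` label for the event records.
#' @param pair_id,session_id,partition identifiers for the resulting log.
#' @return a `session_log`.
#' @export
simulate_individual_session <- function(leave_rate, return_rate, minutes,
                                        seed = NULL, fish = "bold",
                                        pair_id = "fish1", session_id = "s1",
                                        partition = "opaque") {
  stopifnot(leave_rate >= 0, return_rate >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- 0; exposed <- FALSE
  times <- numeric(0); acts <- character(0)
  repeat {
    rate <- if (exposed) return_rate else leave_rate
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= minutes) break
    times <- c(times, t * 60)
    acts <- c(acts, if (exposed) "return" else "leave")
    exposed <- !exposed
  }
  session_log(pair_id, session_id, partition, minutes * 60,
              data.frame(time_s = times, fish = fish, action = acts,
                         stringsAsFactors = FALSE))
}

#' Stationary distribution of a CTMC over a space
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` for the generator built from per-edge
#' intensities.
#'
#' @param space a `ctmc_space`.
#' @param edge_rates named intensities, names = full-scheme class labels of
#'   the space.
#' @return named numeric vector over state ids.
#' @export
stationary_distribution <- function(space, edge_rates) {
  e <- space$edges
  labels <- paste0("q", e$from, "_", e$to)
  q <- edge_rates[labels]
  stopifnot(!anyNA(q))
  ns <- nrow(space$states)
  Q <- matrix(0, ns, ns)
  Q[cbind(e$from, e$to)] <- q
  diag(Q) <- -rowSums(Q)
  A <- t(Q)
  A[ns, ] <- 1
  b <- c(rep(0, ns - 1L), 1)
  pi <- solve(A, b)
  setNames(pi, space$states$id)
}

#' Expected completed trips per fish per hour under given intensities
#'
#' A completed trip ends with a return to cover, so the long-run trip rate
#' of a fish is the stationary flow through its return edges.  Returns the
#' per-hour rate for each fish and their mean, computed from the stationary
#' distribution of the 12-state chain.
#'
#' @param edge_rates named per-edge intensities (per minute) over the pair
#'   space.
#' @param space optionally a prebuilt [pair_state_space()].
#' @return named vector `c(bold=, shy=, mean=)`, trips per hour.
#' @export
expected_trips_per_hour <- function(edge_rates, space = pair_state_space()) {
  pi <- stationary_distribution(space, edge_rates)
  e <- space$edges
  labels <- paste0("q", e$from, "_", e$to)
  flow <- pi[as.character(e$from)] * edge_rates[labels] * 60
  bold <- sum(flow[e$mover == "bold" & e$move == "return"])
  shy <- sum(flow[e$mover == "shy" & e$move == "return"])
  c(bold = bold, shy = shy, mean = (bold + shy) / 2)
}
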