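#' Trajectory over a state space
#'
#' A right-censored realisation of a continuous-time chain: an ordered
#' sequence of (state, entry time) visits plus the censoring time.  The
#' state of a leading visit may be `NA` ("unknown"): the interval before
#' the first observed event, whose status variables are undefined.  Unknown
#' visits carry no likelihood exposure.
#'
#' @param space a `ctmc_space`.
#' @param states integer vector of state ids (`NA` allowed only as a
#'   leading prefix).
#' @param times entry times in seconds, strictly increasing, first >= 0.
#' @param end_time censoring time in seconds, >= the last entry time.
#' @param pair_id,session_id optional provenance identifiers.
#' @return an object of class `ctmc_trajectory`.
#' @export
trajectory <- function(space, states, times, end_time,
                       pair_id = NA_character_, session_id = NA_character_) {
  stopifnot(inherits(space, "ctmc_space"),
            length(states) == length(times))
  if (length(times)) {
    stopifnot(times[1] >= 0, end_time >= times[length(times)])
    if (length(times) > 1L) stopifnot(all(diff(times) > 0))
    na <- is.na(states)
    if (any(na)) stopifnot(all(which(na) == seq_len(sum(na))))
    known <- states[!na]
    if (length(known) > 1L) {
      lab <- paste0(known[-length(known)], "->", known[-1])
      bad <- !(lab %in% space$edges$label)
      if (any(bad)) stop("not an edge of '", space$name, "': ",
                         lab[which(bad)[1]])
    }
  }
  structure(list(space = space,
                 visits = data.frame(state = as.integer(states),
                                     time = as.numeric(times)),
                 end_time = as.numeric(end_time),
                 pair_id = pair_id, session_id = session_id),
            class = "ctmc_trajectory")
}

#' @export
print.ctmc_trajectory <- function(x, ...) {
  cat(sprintf("<ctmc_trajectory on %s: %d visits, censored at %.1f s>\n",
              x$space$name, nrow(x$visits), x$end_time))
  invisible(x)
}

#' Encode one fish's events as a two-state trajectory
#'
#' Transcribes a fish's leave/return events into a trajectory over the
#' cover/exposed space, starting in cover at time 0 and censored at the
#' session end.  Used for temperament scoring.
#'
#' @param log a `session_log`.
#' @param fish `"bold"` or `"shy"`.
#' @return a `ctmc_trajectory` over [individual_state_space()].
#' @export
encode_individual <- function(log, fish = c("bold", "shy")) {
  fish <- match.arg(fish)
  validate_session_log(log)
  e <- log$events[log$events$fish == fish, ]
  states <- c(1L, ifelse(e$action == "leave", 2L, 1L))
  times <- c(0, e$time_s)
  trajectory(individual_state_space(), states, times, log$duration_s,
             log$pair_id, log$session_id)
}

#' Encode a pair session as a 12-state trajectory
#'
#' Folds the interleaved events of both fish through the pair-state update
#' rules.  The interval before the first event is emitted as a leading
#' visit with unknown (`NA`) state, because the status variables (who
#' initiated the previous trip, whether it was joined) are unobserved
#' there; the first departure defines the first initiator with
#' `joined = FALSE`.  The unknown prefix is excluded from likelihood
#' exposure downstream.
#'
#' @param log a `session_log` with `partition = "transparent"`.
#' @param space optionally a prebuilt [pair_state_space()] (saves rebuild
#'   time in loops).
#' @return a `ctmc_trajectory` over the 12-state pair space.
#' @export
encode_pair <- function(log, space = pair_state_space()) {
  validate_session_log(log)
  if (log$partition != "transparent")
    stop("encode_pair needs a transparent-partition session (fish must see each other)")
  e <- log$events
  n <- nrow(e)
  TT <- .target_matrix(space)
  states <- integer(n)
  if (n > 0L) {
    fish_idx <- match(e$fish, .FISH)
    s <- if (e$fish[1] == "bold") 5L else 9L
    states[1] <- s
    if (n > 1L) for (i in 2:n) {
      s <- TT[s, fish_idx[i]]
      states[i] <- s
    }
  }
  trajectory(space, c(NA_integer_, states), c(0, e$time_s), log$duration_s,
             log$pair_id, log$session_id)
}

## 12 x 2 successor matrix: TT[state, fish] (fish 1 = bold, 2 = shy)
.target_matrix <- function(space) {
  TT <- matrix(NA_integer_, nrow(space$states), 2L)
  e <- space$edges
  TT[cbind(e$from, match(e$mover, .FISH))] <- e$to
  TT
}

.COMBO_OF_STATE <- NULL  # built lazily below

.pair_combos <- function(space) space$states$combo[order(space$states$id)]

#' Project a 12-state trajectory onto the one-step-memory space
#'
#' Replaces each visit's status variables by the previous location
#' combination: visit i of the result is (current location combination,
#' location combination of visit i-1).  The predecessor of the first
#' post-unknown visit is both-covered (both fish start under cover).  Visit
#' times are unchanged.
#'
#' @param pair_traj trajectory over the 12-state pair space.
#' @param space optionally a prebuilt [one_step_state_space()].
#' @return a `ctmc_trajectory` over the 8-state one-step-memory space.
#' @export
project_one_step <- function(pair_traj, space = one_step_state_space()) {
  stopifnot(inherits(pair_traj, "ctmc_trajectory"),
            pair_traj$space$name == "pair12")
  v <- pair_traj$visits
  combos <- .pair_combos(pair_traj$space)
  known <- which(!is.na(v$state))
  new_states <- rep(NA_integer_, nrow(v))
  if (length(known)) {
    cur <- combos[v$state[known]]
    prev <- c("CC", cur[-length(cur)])
    key <- paste(space$states$combo, space$states$prev)
    new_states[known] <- space$states$id[match(paste(cur, prev), key)]
  }
  trajectory(space, new_states, v$time, pair_traj$end_time,
             pair_traj$pair_id, pair_traj$session_id)
}

#' Collapse a 12-state trajectory to the location-only space
#'
#' Drops the status variables, keeping only the two fish's locations.
#' Visit times are unchanged.
#'
#' @param pair_traj trajectory over the 12-state pair space.
#' @param space optionally a prebuilt [location_state_space()].
#' @return a `ctmc_trajectory` over the 4-state location space.
#' @export
project_location <- function(pair_traj, space = location_state_space()) {
  stopifnot(inherits(pair_traj, "ctmc_trajectory"))
  v <- pair_traj$visits
  new_states <- rep(NA_integer_, nrow(v))
  known <- !is.na(v$state)
  src_combo <- switch(pair_traj$space$name,
                      pair12 = .pair_combos(pair_traj$space),
                      onestep8 = pair_traj$space$states$combo[
                        order(pair_traj$space$states$id)],
                      stop("cannot collapse space '", pair_traj$space$name, "'"))
  new_states[known] <- match(src_combo[v$state[known]], space$states$combo)
  trajectory(space, new_states, v$time, pair_traj$end_time,
             pair_traj$pair_id, pair_traj$session_id)
}

.CC <- 1:4
.EE <- c(6L, 10L)
.SOLO_JOINED <- c(7L, 8L, 11L, 12L)

#' Initiation events of a pair trajectory
#'
#' An initiation is a departure from a both-covered (or unknown initial)
#' state: one fish first leaves cover after both were in safety.  It is
#' successful if the partner joins (the pair reaches a both-out state)
#' before both fish are back under cover.  A trip still unresolved at the
#' censoring time yields `success = NA`; such records are excluded from
#' sequence statistics but their exposure stays in the likelihood.
#'
#' @param pair_traj trajectory over the 12-state pair space.
#' @return data frame with columns `time`, `initiator`, `success`.
#' @export
initiation_sequence <- function(pair_traj) {
  stopifnot(inherits(pair_traj, "ctmc_trajectory"),
            pair_traj$space$name == "pair12")
  v <- pair_traj$visits
  s <- v$state
  n <- length(s)
  ## a departure from safety: entry into 5 or 9 whose predecessor is a
  ## both-covered state or the unknown initial interval (or no predecessor)
  prev_state <- if (n) c(NA_integer_, s[-n]) else integer(0)
  from_safety <- is.na(prev_state) | prev_state %in% .CC
  starts <- which(!is.na(s) & s %in% c(5L, 9L) & from_safety)
  if (!length(starts))
    return(data.frame(time = numeric(0), initiator = character(0),
                      success = logical(0)))
  res <- lapply(starts, function(i) {
    succ <- NA
    if (i < n) for (j in (i + 1):n) {
      if (s[j] %in% .EE) { succ <- TRUE; break }
      if (s[j] %in% .CC) { succ <- FALSE; break }
    }
    data.frame(time = v$time[i],
               initiator = if (s[i] == 5L) "bold" else "shy",
               success = succ, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Within-trip position changes of joint trips
#'
#' For each completed joint trip (from the join — first entry into a
#' both-out state — until both fish are next back under cover), counts the
#' location-change events strictly between the join and the final two
#' returns that end the trip.  These are termination attempts and
#' re-joinings: a count of 0 means the trip ended at the first termination
#' (one fish returned, the other followed straight back).  Trips still in
#' progress at the censoring time are dropped.
#'
#' @param pair_traj trajectory over the 12-state pair space.
#' @return integer vector, one count per completed joint trip.
#' @export
trip_position_changes <- function(pair_traj) {
  stopifnot(inherits(pair_traj, "ctmc_trajectory"),
            pair_traj$space$name == "pair12")
  s <- pair_traj$visits$state
  counts <- integer(0)
  in_trip <- FALSE
  start <- NA_integer_
  for (i in seq_along(s)) {
    if (is.na(s[i])) next
    if (!in_trip && s[i] %in% .EE) {
      in_trip <- TRUE
      start <- i
    } else if (in_trip && s[i] %in% .CC) {
      counts <- c(counts, (i - start) - 2L)
      in_trip <- FALSE
    }
  }
  counts
}

#' Total known exposure of a trajectory
#'
#' Time covered by visits with a known state, in seconds (session duration
#' minus the unknown prefix).
#'
#' @param traj a `ctmc_trajectory`.
#' @return numeric seconds.
#' @export
known_exposure <- function(traj) {
  v <- traj$visits
  if (!nrow(v)) return(0)
  d <- diff(c(v$time, traj$end_time))
  sum(d[!is.na(v$state)])
}
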