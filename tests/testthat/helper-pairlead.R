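# Shared fixtures: spaces and schemes are deterministic, build them once.
SP <- pair_state_space()
OS <- one_step_state_space()
LS <- location_state_space()
SCH_FULL <- tying_scheme(SP, "full")
SCH_IO <- tying_scheme(SP, "initiator_only")
SCH_MF <- tying_scheme(SP, "memory_free")

# quick session-log builder: events as list of c(time, fish, action)
make_log <- function(..., duration = 60, pair_id = "p1", session_id = "s1",
                     partition = "transparent") {
  ev <- list(...)
  events <- data.frame(
    time_s = vapply(ev, function(e) as.numeric(e[[1]]), numeric(1)),
    fish = vapply(ev, function(e) e[[2]], character(1)),
    action = vapply(ev, function(e) e[[3]], character(1)),
    stringsAsFactors = FALSE)
  session_log(pair_id, session_id, partition, duration, events)
}

# trajectory straight from a state/time sequence over the pair space
make_traj <- function(states, times, end_time, space = SP) {
  trajectory(space, states, times, end_time, pair_id = "p1")
}

# small simulated study + encoded trajectories, reused across tests
sim_trajs <- function(n_pairs, minutes, seed, sessions = 1L,
                      scheme = "full", coefficient_truth = NULL) {
  cfg <- study_config(n_pairs = n_pairs, sessions_per_pair = sessions,
                      session_minutes = minutes,
                      generating_scheme = scheme,
                      coefficient_truth = coefficient_truth, seed = seed)
  study <- make_study(cfg)
  trajs <- lapply(study$logs, encode_pair, space = SP)
  list(study = study, trajs = trajs,
       pair_ids = vapply(trajs, function(t) t$pair_id, character(1)))
}
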