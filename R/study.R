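#' Default per-edge intensities of the synthetic-study generator
#'
#' Illustrative per-minute intensities over the 24 edges of the 12-state
#' pair space, chosen so that the simulated behaviour has the qualitative
#' structure the model family is built for: the bold fish leaves cover
#' faster and returns slower than the shy fish; both fish leave faster and
#' return slower when the partner is out; the initiator of the current trip
#' is more resolute (slower to return, slower to follow a partner's
#' termination) than the follower; a successful initiation raises the
#' propensity to initiate again, and failure lowers it for the shy fish
#' only.  The overall magnitude is calibrated so a pair makes roughly 54
#' completed trips per fish per hour and a joint trip carries on average
#' about 0.8 within-trip position changes.
#'
#' These values are package fixtures for simulation studies, not estimates
#' from any real data set.
#'
#' @return named numeric vector of length 24 (full-scheme class labels).
#' @export
default_pair_rates <- function() {
  c(## departures from both-covered states (initiations)
    q1_5 = 2.115, q2_5 = 0.583, q3_5 = 2.188, q4_5 = 1.167,   # bold leaves
    q1_9 = 0.583, q2_9 = 0.511, q3_9 = 0.656, q4_9 = 1.021,   # shy leaves
    ## bold out alone, bold initiated (unjoined 5 / joined 8)
    q5_6 = 3.209, q5_1 = 3.647, q8_6 = 1.750, q8_3 = 3.355,
    ## bold out alone after a shy-led trip
    q11_10 = 1.167, q11_4 = 4.376,
    ## shy out alone, shy initiated (unjoined 9 / joined 12)
    q9_10 = 3.647, q9_2 = 5.105, q12_10 = 1.605, q12_4 = 4.668,
    ## shy out alone after a bold-led trip
    q7_6 = 2.480, q7_3 = 5.835,
    ## both out: terminations
    q6_7 = 1.021, q6_8 = 2.188, q10_11 = 1.313, q10_12 = 1.896)
}

#' Configuration of a synthetic pair study
#'
#' Bundles and validates everything the generator needs: the experimental
#' design (number of pairs, sessions per pair, session length), the
#' generating model (a tying scheme with per-class base intensities and
#' optional log-linear covariate effects), the distribution of temperament
#' scores, and the root seed.  Within each pair the larger drawn score is
#' labelled bold, mirroring how pairs are labelled in practice.
#'
#' @param n_pairs number of pairs.
#' @param sessions_per_pair transparent sessions per pair.
#' @param session_minutes session length in minutes.
#' @param generating_scheme `"full"`, `"initiator_only"` or `"memory_free"`.
#' @param base_rates named per-class intensities (per minute) of the
#'   generating scheme; defaults to [default_pair_rates()] (full scheme).
#' @param coefficient_truth optional named list: covariate name
#'   (`x_bold`/`x_shy`) -> named vector of log-linear effects over classes
#'   of the generating scheme.
#' @param temperament_meanlog,temperament_sdlog log-normal parameters of
#'   the individual temperament-score distribution.
#' @param seed integer root seed; per-session streams are derived from it.
#' @return a validated object of class `study_config`.  Validation
#'   failures are collected and signalled together as an error of class
#'   `pairlead_config_error`.
#' @export
study_config <- function(n_pairs = 20L, sessions_per_pair = 2L,
                         session_minutes = 60,
                         generating_scheme = "full",
                         base_rates = NULL,
                         coefficient_truth = NULL,
                         temperament_meanlog = -1.0,
                         temperament_sdlog = 0.5,
                         seed = 1L) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1 ||
      n_pairs != round(n_pairs)) note("n_pairs must be a positive integer")
  if (!is.numeric(sessions_per_pair) || length(sessions_per_pair) != 1L ||
      sessions_per_pair < 1 || sessions_per_pair != round(sessions_per_pair))
    note("sessions_per_pair must be a positive integer")
  if (!is.numeric(session_minutes) || length(session_minutes) != 1L ||
      session_minutes <= 0) note("session_minutes must be > 0")
  if (!generating_scheme %in% c("full", "initiator_only", "memory_free"))
    note("generating_scheme must be full, initiator_only or memory_free")
  if (!is.numeric(temperament_sdlog) || temperament_sdlog < 0)
    note("temperament_sdlog must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L) note("seed must be an integer")

  space <- pair_state_space()
  scheme <- if (generating_scheme %in% c("full", "initiator_only", "memory_free"))
    tying_scheme(space, generating_scheme) else NULL
  if (is.null(base_rates)) {
    base_rates <- default_pair_rates()
    if (!is.null(scheme) && generating_scheme != "full") {
      ## pool the default full-model rates down to the coarser scheme
      full <- tying_scheme(space, "full")
      base_rates <- tapply(base_rates[full$class],
                           factor(scheme$class, levels = scheme$classes),
                           mean)
      base_rates <- setNames(as.numeric(base_rates), scheme$classes)
    }
  }
  if (!is.null(scheme)) {
    miss <- setdiff(scheme$classes, names(base_rates))
    if (length(miss)) note(paste0("base_rates missing classes: ",
                                  paste(miss, collapse = ", ")))
    if (any(base_rates < 0, na.rm = TRUE)) note("base_rates must be >= 0")
    if (!length(miss)) {
      edge_rates <- setNames(base_rates[scheme$class],
                             paste0("q", space$edges$from, "_", space$edges$to))
      exit <- rowsum(edge_rates, space$edges$from)
      trapped <- which(exit[, 1] <= 0)
      if (length(trapped))
        note(paste0("trapped state(s) with all-zero exit rates: ",
                    paste(rownames(exit)[trapped], collapse = ", ")))
    }
  }
  if (!is.null(coefficient_truth)) {
    if (!is.list(coefficient_truth) ||
        !all(names(coefficient_truth) %in% c("x_bold", "x_shy")))
      note("coefficient_truth must be a named list over x_bold/x_shy")
    else if (!is.null(scheme)) {
      for (v in names(coefficient_truth)) {
        bad <- setdiff(names(coefficient_truth[[v]]), scheme$classes)
        if (length(bad)) note(paste0("coefficient_truth$", v,
                                     ": unknown class(es) ",
                                     paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(problems))
    stop(errorCondition(paste0("invalid study configuration:\n  - ",
                               paste(problems, collapse = "\n  - ")),
                        problems = problems,
                        class = c("pairlead_config_error", "error")))
  structure(list(n_pairs = as.integer(n_pairs),
                 sessions_per_pair = as.integer(sessions_per_pair),
                 session_minutes = session_minutes,
                 generating_scheme = generating_scheme,
                 base_rates = base_rates,
                 coefficient_truth = coefficient_truth,
                 temperament_meanlog = temperament_meanlog,
                 temperament_sdlog = temperament_sdlog,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a complete synthetic study
#'
#' Draws per-pair temperament scores (two log-normal draws per pair; the
#' larger is labelled bold), derives per-pair edge intensities from the
#' generating scheme's base rates through the log-linear covariate model
#' (covariates centered at their across-pair means, the same convention the
#' fitting code uses), and simulates all transparent sessions with
#' per-session seeds drawn from the root seed.  The returned truth record
#' is sufficient to recompute every generated rate.
#'
#' @param config a [study_config()].
#' @return an object of class `pairlead_study`: list with `logs` (flat
#'   list of `session_log`s), `covariates` (data frame `pair_id`, `x_bold`,
#'   `x_shy`) and `truth` (base rates, per-pair edge-rate matrix,
#'   centering, per-session seeds, config echo).
#' @export
make_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  pair_ids <- sprintf("pair%02d", seq_len(n))
  draws <- matrix(stats::rlnorm(2 * n, config$temperament_meanlog,
                                config$temperament_sdlog), ncol = 2)
  x_bold <- pmax(draws[, 1], draws[, 2])
  x_shy <- pmin(draws[, 1], draws[, 2])
  covariates <- data.frame(pair_id = pair_ids, x_bold = x_bold,
                           x_shy = x_shy, stringsAsFactors = FALSE)
  centering <- c(x_bold = mean(x_bold), x_shy = mean(x_shy))

  space <- pair_state_space()
  scheme <- tying_scheme(space, config$generating_scheme)
  full_labels <- paste0("q", space$edges$from, "_", space$edges$to)
  base_edge <- setNames(as.numeric(config$base_rates[scheme$class]),
                        full_labels)

  ## per-pair edge rates through the log-linear model
  logm <- matrix(0, n, length(full_labels))
  if (!is.null(config$coefficient_truth)) {
    for (v in names(config$coefficient_truth)) {
      cf <- config$coefficient_truth[[v]]
      beta_edge <- setNames(numeric(length(full_labels)), full_labels)
      for (cl in names(cf))
        beta_edge[scheme$class == cl] <- cf[[cl]]
      xc <- covariates[[v]] - centering[[v]]
      logm <- logm + outer(xc, beta_edge)
    }
  }
  pair_rates <- sweep(exp(logm), 2, base_edge, "*")
  dimnames(pair_rates) <- list(pair_ids, full_labels)

  session_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                     n * config$sessions_per_pair),
                          nrow = n,
                          dimnames = list(pair_ids, NULL))
  logs <- list()
  for (i in seq_len(n)) for (s in seq_len(config$sessions_per_pair)) {
    logs[[length(logs) + 1L]] <- simulate_pair_session(
      pair_rates[i, ], config$session_minutes,
      seed = session_seeds[i, s], pair_id = pair_ids[i],
      session_id = paste0("s", s), space = space)
  }
  structure(list(logs = logs, covariates = covariates,
                 truth = list(config = unclass(config),
                              base_edge_rates = base_edge,
                              pair_edge_rates = pair_rates,
                              centering = centering,
                              session_seeds = session_seeds)),
            class = "pairlead_study")
}

#' @export
print.pairlead_study <- function(x, ...) {
  cat(sprintf("<pairlead_study: %d pairs, %d sessions, scheme '%s'>\n",
              nrow(x$covariates), length(x$logs),
              x$truth$config$generating_scheme))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the event-log CSV dialect read by [read_session_logs()], the
#' covariate table (`pair_id,x_bold,x_shy`) and the truth record as JSON.
#'
#' @param study a `pairlead_study`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_session_logs(study$logs, file.path(dir, "events.csv"))
  write.csv(study$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- study$truth
  truth$session_seeds <- as.data.frame(truth$session_seeds)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
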