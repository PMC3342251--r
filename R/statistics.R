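#' Temperament score of a fish
#'
#' Fits the two-state (cover/exposed) chain to one fish's trajectory by
#' closed-form MLE and returns the temperament score: the ratio of the
#' leaving intensity to the returning intensity.  Higher scores indicate
#' bolder behaviour (more time spent exposed).  The score is a ratio of
#' rates, hence invariant to the time unit.
#'
#' @param x a `ctmc_trajectory` over the two-state space, or a
#'   `session_log` (then `fish` selects the individual).
#' @param fish used when `x` is a `session_log`.
#' @return list with `leave_rate`, `return_rate` (per minute) and `score`.
#'   Zero exposure to either state signals an error of class
#'   `pairlead_undefined_score`.
#' @export
temperament_score <- function(x, fish = c("bold", "shy")) {
  if (inherits(x, "session_log")) x <- encode_individual(x, match.arg(fish))
  stopifnot(inherits(x, "ctmc_trajectory"), x$space$name == "indiv2")
  sch <- tying_scheme(x$space, "full")   # classes q1_2 (leave), q2_1 (return)
  st <- sufficient_stats(x, sch)
  if (any(st$E_min == 0))
    stop(errorCondition(
      "temperament score undefined: zero exposure to cover or to the exposed area",
      class = c("pairlead_undefined_score", "error")))
  leave <- st$n[["q1_2"]] / st$E_min[["q1_2"]]
  ret <- st$n[["q2_1"]] / st$E_min[["q2_1"]]
  list(leave_rate = leave, return_rate = ret, score = leave / ret)
}

#' Wald-Wolfowitz runs z-score of a binary sequence
#'
#' Measures clumping in an ordered sequence of binary labels (here, the
#' initiator identities of successive initiation events).  With `n1` and
#' `n2` labels of each kind (`N = n1 + n2`) and `R` observed runs,
#' `z = (R - mu) / sigma` with `mu = 2 n1 n2 / N + 1` and
#' `sigma^2 = 2 n1 n2 (2 n1 n2 - N) / (N^2 (N - 1))`.  Negative z means
#' fewer runs than expected by chance, i.e. runs of consecutive
#' initiations by the same fish.
#'
#' @param labels vector with exactly two distinct values present.
#' @return the z-score.
#' @export
runs_z_score <- function(labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L)
    stop(errorCondition("runs test undefined: sequence contains a single label",
                        class = c("pairlead_undefined_runs", "error")))
  if (length(tab) > 2L) stop("runs test needs a binary sequence")
  n1 <- as.numeric(tab[1]); n2 <- as.numeric(tab[2])
  N <- n1 + n2
  R <- 1 + sum(labels[-1] != labels[-length(labels)])
  mu <- 2 * n1 * n2 / N + 1
  sig2 <- 2 * n1 * n2 * (2 * n1 * n2 - N) / (N^2 * (N - 1))
  (R - mu) / sqrt(sig2)
}

#' Exact two-sided binomial sign test at probability one half
#'
#' Doubles the smaller tail of the Binomial(n, 1/2) distribution at the
#' observed count and caps at 1.  Used for the across-pair sign test on
#' runs-test scores (e.g. 16 of 20 pairs with negative scores).
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n number of trials, >= 1.
#' @return the exact two-sided p-value.
#' @export
#' @examples
#' sign_binomial_test(16, 20)  # 0.0118...
sign_binomial_test <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

.se <- function(x) stats::sd(x) / sqrt(length(x))

#' Descriptive summaries of a set of pair sessions
#'
#' Computes the study-level descriptive quantities from
#' transparent-partition session logs: per fish, completed trips (out of
#' and back into cover) per hour; per pair, initiation counts and
#' recruitment-success proportions by fish, the runs z-score of the
#' initiator sequence, and the within-trip position-change counts of
#' completed joint trips.  Sessions of a pair are pooled (concatenated in
#' session order for the initiation sequence).
#'
#' @param logs list of `session_log`s (only transparent sessions are used).
#' @param include_failed should failed initiations enter the runs-test
#'   sequence (default `TRUE`)?  Unresolved final trips are always
#'   excluded.
#' @return an object of class `pairlead_descriptives`: list with data
#'   frames `fish` (pair, fish, trips_per_hour), `pairs` (initiations,
#'   successes, runs z), vector `position_changes`, and `summary` (means
#'   with standard errors; trips/hour SE is across fish, position-change
#'   SE across joint trips).
#' @export
descriptives <- function(logs, include_failed = TRUE) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  by_pair <- split_by_pair(logs, partition = "transparent")
  if (!length(by_pair)) stop("no transparent-partition sessions supplied")
  space <- pair_state_space()

  fish_rows <- list()
  pair_rows <- list()
  changes <- integer(0)
  for (pid in names(by_pair)) {
    sess <- by_pair[[pid]]
    hours <- sum(vapply(sess, function(l) l$duration_s, numeric(1))) / 3600
    for (f in .FISH) {
      trips <- sum(vapply(sess, function(l)
        sum(l$events$fish == f & l$events$action == "return"), numeric(1)))
      fish_rows[[paste(pid, f)]] <- data.frame(
        pair_id = pid, fish = f, trips_per_hour = trips / hours,
        stringsAsFactors = FALSE)
    }
    inits <- do.call(rbind, lapply(sess, function(l)
      initiation_sequence(encode_pair(l, space))))
    resolved <- inits[!is.na(inits$success), , drop = FALSE]
    seq_labels <- if (include_failed) resolved$initiator else
      resolved$initiator[resolved$success]
    z <- if (length(unique(seq_labels)) == 2L) runs_z_score(seq_labels) else NA_real_
    pair_rows[[pid]] <- data.frame(
      pair_id = pid,
      n_initiations = nrow(resolved),
      n_init_bold = sum(resolved$initiator == "bold"),
      n_init_shy = sum(resolved$initiator == "shy"),
      success_bold = mean(resolved$success[resolved$initiator == "bold"]),
      success_shy = mean(resolved$success[resolved$initiator == "shy"]),
      runs_z = z, stringsAsFactors = FALSE)
    changes <- c(changes, unlist(lapply(sess, function(l)
      trip_position_changes(encode_pair(l, space)))))
  }
  fish <- do.call(rbind, fish_rows); rownames(fish) <- NULL
  pairs <- do.call(rbind, pair_rows); rownames(pairs) <- NULL
  zs <- pairs$runs_z[!is.na(pairs$runs_z)]
  summary <- list(
    trips_per_hour_mean = mean(fish$trips_per_hour),
    trips_per_hour_se = .se(fish$trips_per_hour),
    position_changes_mean = if (length(changes)) mean(changes) else NA_real_,
    position_changes_se = if (length(changes) > 1) .se(changes) else NA_real_,
    position_changes_range = if (length(changes)) range(changes) else c(NA, NA),
    init_share_bold_mean = mean(pairs$n_init_bold / pairs$n_initiations),
    n_pairs_negative_runs = sum(zs < 0),
    n_pairs_with_runs = length(zs),
    runs_sign_p = if (length(zs)) sign_binomial_test(sum(zs < 0), length(zs))
                  else NA_real_)
  structure(list(fish = fish, pairs = pairs, position_changes = changes,
                 summary = summary),
            class = "pairlead_descriptives")
}

#' @export
print.pairlead_descriptives <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Trips per fish per hour: %.1f +/- %.1f (mean +/- SE, n = %d fish)\n",
              s$trips_per_hour_mean, s$trips_per_hour_se, nrow(x$fish)))
  if (!is.na(s$position_changes_mean))
    cat(sprintf("Position changes per joint trip: %.0f-%.0f, mean %.1f +/- %.1f (n = %d trips)\n",
                s$position_changes_range[1], s$position_changes_range[2],
                s$position_changes_mean, s$position_changes_se,
                length(x$position_changes)))
  cat(sprintf("Bold initiation share: %.2f; pairs with negative runs z: %d of %d (sign test p = %.3g)\n",
              s$init_share_bold_mean, s$n_pairs_negative_runs,
              s$n_pairs_with_runs, s$runs_sign_p))
  invisible(x)
}
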