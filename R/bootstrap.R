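#' Nonparametric bootstrap over pairs
#'
#' Resamples the independent sampling units (pairs) with replacement and
#' re-applies an estimator to each replicate, giving percentile confidence
#' intervals for intensities, intensity ratios, covariate coefficients or
#' any other deterministic function of the data.  For a ratio of two
#' intensities the two-sided p-value against equality is
#' `2 * min(share of replicates <= null, share >= null)`, floored at `2/B`.
#'
#' The estimator receives a list of units (with repetition); to keep large
#' bootstraps cheap, precompute per-pair objects (encoded trajectories or
#' sufficient statistics) once and pass those as the units.
#'
#' @param units list of per-pair data objects (session-log lists, encoded
#'   trajectories, sufficient statistics, ...).
#' @param estimator function taking a list of units and returning a named
#'   numeric vector.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; the whole procedure is reproducible from it.
#' @param level confidence level for the percentile intervals.
#' @param null optional null value(s) for two-sided p-values (e.g. 1 for a
#'   rate ratio, 0 for a log-linear coefficient); recycled across
#'   quantities.
#' @param max_retries estimator failures on a replicate are recorded and
#'   the replicate redrawn, up to this many times in total.
#' @return an object of class `ctmc_boot`: `t0` (full-data estimate),
#'   `replicates` (B x q matrix), `ci` (2 x q), `p` (if `null` given),
#'   `B`, `seed`, `level`, `n_retries`.
#' @export
ctmc_bootstrap <- function(units, estimator, B = 1000L, seed,
                           level = 0.95, null = NULL,
                           max_retries = 10L * B) {
  stopifnot(is.list(units), length(units) >= 1L, B >= 1L)
  t0 <- estimator(units)
  q <- length(t0)
  if (is.null(names(t0))) names(t0) <- paste0("stat", seq_len(q))
  reps <- matrix(NA_real_, B, q, dimnames = list(NULL, names(t0)))
  n <- length(units)
  set.seed(as.integer(seed))
  retries <- 0L
  failures <- character(0)
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(estimator(units[idx]), error = function(e) e)
    if (inherits(est, "error")) {
      retries <- retries + 1L
      failures <- c(failures, conditionMessage(est))
      if (retries > max_retries)
        stop("bootstrap: estimator failed on too many replicates; last error: ",
             failures[length(failures)])
      next
    }
    reps[b, ] <- est
    b <- b + 1L
  }
  alpha <- (1 - level) / 2
  ci <- apply(reps, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE,
              names = TRUE)
  p <- NULL
  if (!is.null(null)) {
    null <- rep_len(null, q)
    p <- vapply(seq_len(q), function(j) {
      lo <- mean(reps[, j] <= null[j])
      hi <- mean(reps[, j] >= null[j])
      min(1, max(2 * min(lo, hi), 2 / B))
    }, numeric(1))
    names(p) <- names(t0)
  }
  structure(list(t0 = t0, replicates = reps, ci = ci, p = p,
                 B = B, seed = seed, level = level,
                 n_retries = retries),
            class = "ctmc_boot")
}

#' @export
print.ctmc_boot <- function(x, ...) {
  cat(sprintf("<ctmc_boot: B = %d, level = %.2f, seed = %s>\n",
              x$B, x$level, format(x$seed)))
  tab <- data.frame(estimate = x$t0,
                    lower = x$ci[1, ], upper = x$ci[2, ])
  if (!is.null(x$p)) tab$p <- x$p
  print(round(tab, 4))
  invisible(x)
}

#' Write bootstrap replicates to CSV
#'
#' @param boot a `ctmc_boot`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_boot_replicates <- function(boot, path) {
  write.csv(as.data.frame(boot$replicates), path, row.names = FALSE)
  invisible(path)
}

#' Parametric bootstrap over pairs
#'
#' Alternative to the nonparametric scheme: simulates `B` synthetic studies
#' from fitted per-pair edge intensities and re-applies the estimator to
#' each.  Provided for sensitivity checks; the pair-resampling bootstrap is
#' the primary inference path.
#'
#' @param pair_rates named list: pair id -> named per-edge intensity vector
#'   (per minute) over the 12-state pair space edges.
#' @param session_minutes,sessions_per_pair design of each synthetic study.
#' @param estimator function of a list of per-pair `session_log` lists.
#' @param B,seed,level as in [ctmc_bootstrap()].
#' @return a `ctmc_boot` (without `t0`; the observed estimate comes from the
#'   real data).
#' @export
parametric_bootstrap <- function(pair_rates, session_minutes,
                                 sessions_per_pair, estimator,
                                 B = 1000L, seed, level = 0.95) {
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             B * length(pair_rates) * sessions_per_pair,
                             replace = TRUE),
                  nrow = B)
  space <- pair_state_space()
  one <- function(b) {
    k <- 0L
    units <- lapply(seq_along(pair_rates), function(i) {
      lapply(seq_len(sessions_per_pair), function(s) {
        k <<- k + 1L
        simulate_pair_session(pair_rates[[i]], session_minutes,
                              seed = seeds[b, k],
                              pair_id = names(pair_rates)[i],
                              session_id = paste0("s", s), space = space)
      })
    })
    estimator(units)
  }
  first <- one(1L)
  reps <- matrix(NA_real_, B, length(first),
                 dimnames = list(NULL, names(first)))
  reps[1, ] <- first
  if (B > 1L) for (b in 2:B) reps[b, ] <- one(b)
  alpha <- (1 - level) / 2
  ci <- apply(reps, 2, quantile, probs = c(alpha, 1 - alpha))
  structure(list(t0 = NULL, replicates = reps, ci = ci, p = NULL,
                 B = B, seed = seed, level = level, n_retries = 0L),
            class = "ctmc_boot")
}
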