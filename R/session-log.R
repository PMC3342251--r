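#' Timestamped leave/return event log for one session of one pair
#'
#' A session log stores the raw observations the whole analysis consumes:
#' for each fish in a pair, the times (in seconds from the session start)
#' at which it left or returned to cover.  Both fish start under cover, so
#' per fish the actions must strictly alternate beginning with `leave`;
#' timestamps must be strictly increasing and distinct across the two fish
#' (the model's single-mover dynamics cannot order simultaneous events).
#'
#' @param pair_id,session_id identifiers.
#' @param partition `"transparent"` (fish see each other) or `"opaque"`.
#' @param duration_s session length in seconds, > 0.
#' @param events data frame with columns `time_s`, `fish`
#'   (`"bold"`/`"shy"`), `action` (`"leave"`/`"return"`); may have zero
#'   rows.  Rows are sorted by time.
#' @return an object of class `session_log`.
#' @export
session_log <- function(pair_id, session_id,
                        partition = c("transparent", "opaque"),
                        duration_s, events) {
  partition <- match.arg(partition)
  stopifnot(is.numeric(duration_s), length(duration_s) == 1L, duration_s > 0)
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(time_s = numeric(0), fish = character(0),
                         action = character(0), stringsAsFactors = FALSE)
  }
  events <- events[order(events$time_s), c("time_s", "fish", "action")]
  rownames(events) <- NULL
  log <- structure(list(pair_id = as.character(pair_id),
                        session_id = as.character(session_id),
                        partition = partition,
                        duration_s = as.numeric(duration_s),
                        events = events),
                   class = "session_log")
  validate_session_log(log)
  log
}

.malformed <- function(msg, index = NA_integer_) {
  stop(errorCondition(paste0("malformed log", if (!is.na(index))
    sprintf(" (event %d)", index), ": ", msg),
    index = index, class = c("pairlead_malformed_log", "error")))
}

#' Validate a session log
#'
#' Checks the structural invariants of a [session_log()]: valid field
#' values, timestamps inside `[0, duration_s]`, strictly increasing and
#' duplicate-free event times, and per-fish strict leave/return alternation
#' starting with `leave`.  Violations signal an error of class
#' `pairlead_malformed_log` carrying the offending event index.
#'
#' @param log a `session_log`.
#' @return `TRUE`, invisibly.
#' @export
validate_session_log <- function(log) {
  stopifnot(inherits(log, "session_log"))
  e <- log$events
  if (nrow(e) == 0L) return(invisible(TRUE))
  bad <- which(!e$fish %in% .FISH)
  if (length(bad)) .malformed(paste0("unknown fish '", e$fish[bad[1]], "'"), bad[1])
  bad <- which(!e$action %in% c("leave", "return"))
  if (length(bad)) .malformed(paste0("unknown action '", e$action[bad[1]], "'"), bad[1])
  bad <- which(e$time_s < 0 | e$time_s > log$duration_s)
  if (length(bad)) .malformed("event time outside [0, duration]", bad[1])
  if (nrow(e) > 1L) {
    d <- diff(e$time_s)
    bad <- which(d <= 0)
    if (length(bad)) .malformed("event times must be strictly increasing and distinct across fish",
                                bad[1] + 1L)
  }
  for (f in .FISH) {
    idx <- which(e$fish == f)
    if (!length(idx)) next
    acts <- e$action[idx]
    expected <- rep_len(c("leave", "return"), length(acts))
    bad <- which(acts != expected)
    if (length(bad)) .malformed(sprintf(
      "%s fish: expected '%s' (actions must alternate starting with 'leave')",
      f, expected[bad[1]]), idx[bad[1]])
  }
  invisible(TRUE)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log %s/%s (%s): %d events over %.0f s>\n",
              x$pair_id, x$session_id, x$partition, nrow(x$events),
              x$duration_s))
  invisible(x)
}

#' Read session logs from the event-log CSV dialect
#'
#' The on-disk format is one CSV with header
#' `pair_id,session_id,partition,duration_s,fish,time_s,action`; every row
#' is one event, grouped into sessions by (pair_id, session_id).  A session
#' with no events can be declared by a single row with empty `fish`,
#' `time_s` and `action`.  Validation failures are reported with the
#' offending CSV line number.
#'
#' Digitised logs sometimes carry tied timestamps that the strict
#' single-mover ordering rejects; `tie_epsilon` (seconds) resolves them
#' deterministically by shifting the second and later events of a tie
#' forward by successive multiples of the epsilon.
#'
#' @param path CSV file path.
#' @param tie_epsilon `NULL` (default: ties are an error) or a small
#'   positive offset in seconds.
#' @return a named list of `session_log` objects, names `pair_id/session_id`.
#' @export
read_session_logs <- function(path, tie_epsilon = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(pair_id = "character",
                                session_id = "character"))
  need <- c("pair_id", "session_id", "partition", "duration_s",
            "fish", "time_s", "action")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event-log CSV is missing columns: ",
                         paste(miss, collapse = ", "))
  df$line <- seq_len(nrow(df)) + 1L   # header is line 1
  key <- paste(df$pair_id, df$session_id, sep = "/")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    dur <- unique(g$duration_s)
    prt <- unique(g$partition)
    if (length(dur) != 1L || length(prt) != 1L)
      stop(sprintf("lines %s: duration/partition must be constant within session %s/%s",
                   paste(range(g$line), collapse = "-"),
                   g$pair_id[1], g$session_id[1]))
    g <- g[!(is.na(g$time_s) & (is.na(g$fish) | g$fish == "")), ]
    if (nrow(g) && !is.null(tie_epsilon)) {
      g <- g[order(g$time_s), ]
      tie <- ave(g$time_s, g$time_s, FUN = seq_along) - 1
      g$time_s <- g$time_s + tie * tie_epsilon
    }
    tryCatch(
      session_log(g$pair_id[1], g$session_id[1], prt, dur,
                  data.frame(time_s = g$time_s, fish = g$fish,
                             action = g$action, stringsAsFactors = FALSE)),
      pairlead_malformed_log = function(c) {
        idx <- c$index
        line <- if (!is.na(idx) && idx <= nrow(g)) g$line[order(g$time_s)][idx] else NA
        stop(sprintf("%s [CSV line %s]", conditionMessage(c), line),
             call. = FALSE)
      })
  })
  out
}

#' Write session logs in the event-log CSV dialect
#'
#' @param logs a `session_log` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_logs <- function(logs, path) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  rows <- lapply(logs, function(l) {
    if (nrow(l$events) == 0L) {
      data.frame(pair_id = l$pair_id, session_id = l$session_id,
                 partition = l$partition, duration_s = l$duration_s,
                 fish = "", time_s = NA_real_, action = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pair_id = l$pair_id, session_id = l$session_id,
                 partition = l$partition, duration_s = l$duration_s,
                 fish = l$events$fish, time_s = l$events$time_s,
                 action = l$events$action, stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group session logs by pair
#'
#' @param logs list of `session_log` objects.
#' @param partition optionally keep only one partition type.
#' @return a named list (one element per pair id, in first-appearance
#'   order) of lists of `session_log`s.
#' @export
split_by_pair <- function(logs, partition = NULL) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  if (!is.null(partition))
    logs <- Filter(function(l) l$partition == partition, logs)
  ids <- vapply(logs, function(l) l$pair_id, character(1))
  split(logs, factor(ids, levels = unique(ids)))
}
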