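#' @importFrom stats optim pchisq pbinom quantile rexp runif setNames aggregate
#' @importFrom utils read.csv write.csv
NULL

.LOCS <- c("cover", "exposed")
.FISH <- c("bold", "shy")

## location-combination code for a pair: CC, BE (bold out alone),
## SE (shy out alone), EE (both out)
.combo <- function(loc_bold, loc_shy) {
  b <- loc_bold == "exposed"
  s <- loc_shy == "exposed"
  ifelse(b & s, "EE", ifelse(b, "BE", ifelse(s, "SE", "CC")))
}

.new_space <- function(name, states, edges) {
  edges$label <- paste0(edges$from, "->", edges$to)
  rownames(states) <- NULL
  rownames(edges) <- NULL
  structure(list(name = name, states = states, edges = edges),
            class = "ctmc_space")
}

#' Pair state space for two fish with initiator memory
#'
#' Builds the 12-state space describing a pair of fish (labelled bold and
#' shy by temperament) moving between cover and an exposed foraging area.
#' A state records four binary variables: the location of each fish
#' (\emph{location variables}) plus the identity of the fish that initiated
#' the current trip out of cover and whether its partner has joined it
#' (\emph{status variables}).  Of the 16 raw combinations only 12 are
#' feasible: when both fish are exposed the partner has by definition
#' joined, and an unjoined solo excursion can only be the initiator's own.
#'
#' Each state has exactly two outgoing edges (one possible move per fish),
#' giving 24 directed transitions.  The canonical state numbering is fixed
#' so that, e.g., state 1 is both-covered/initiator bold/unjoined, state 5
#' is bold out alone on its own initiative, state 6 is both out after a
#' bold-led departure, and state 12 is shy out alone after a shy-led joint
#' trip.
#'
#' @return A `ctmc_space` object with elements `states` (data frame with
#'   columns `id`, `loc_bold`, `loc_shy`, `initiator`, `joined`, `combo`)
#'   and `edges` (data frame with columns `from`, `to`, `mover`, `move`,
#'   `partner_loc`, `initiator`, `label`).
#' @seealso [transition_target()], [tying_scheme()], [one_step_state_space()]
#' @export
#' @examples
#' sp <- pair_state_space()
#' nrow(sp$states)  # 12
#' nrow(sp$edges)   # 24
pair_state_space <- function() {
  grid <- expand.grid(loc_bold = .LOCS, loc_shy = .LOCS,
                      initiator = .FISH, joined = c(FALSE, TRUE),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  keep <- pair_state_feasible(grid)
  states <- grid[keep, , drop = FALSE]
  states$combo <- .combo(states$loc_bold, states$loc_shy)
  key <- paste(states$combo, states$initiator, states$joined)
  canon <- c("CC bold FALSE" = 1L, "CC shy FALSE" = 2L,
             "CC bold TRUE"  = 3L, "CC shy TRUE"  = 4L,
             "BE bold FALSE" = 5L, "EE bold TRUE" = 6L,
             "SE bold TRUE"  = 7L, "BE bold TRUE" = 8L,
             "SE shy FALSE"  = 9L, "EE shy TRUE"  = 10L,
             "BE shy TRUE"   = 11L, "SE shy TRUE" = 12L)
  states$id <- unname(canon[key])
  stopifnot(!anyNA(states$id), nrow(states) == 12L)
  states <- states[order(states$id),
                   c("id", "loc_bold", "loc_shy", "initiator", "joined", "combo")]

  edges <- do.call(rbind, lapply(states$id, function(id) {
    st <- states[states$id == id, ]
    do.call(rbind, lapply(.FISH, function(f) {
      loc <- if (f == "bold") st$loc_bold else st$loc_shy
      move <- if (loc == "cover") "leave" else "return"
      to <- .pair_target(states, id, f)
      partner <- if (f == "bold") st$loc_shy else st$loc_bold
      data.frame(from = id, to = to, mover = f, move = move,
                 partner_loc = partner, initiator = st$initiator,
                 stringsAsFactors = FALSE)
    }))
  }))
  .new_space("pair12", states, edges)
}

#' Feasibility of raw pair-state field combinations
#'
#' Applies the two structural rules that cut the 16 raw combinations of
#' (location bold, location shy, initiator, joined) down to the 12 feasible
#' pair states: both fish exposed implies `joined`, and a solo unjoined
#' excursion must be the initiator's.
#'
#' @param fields data frame with columns `loc_bold`, `loc_shy`,
#'   `initiator`, `joined`.
#' @return logical vector, one entry per row.
#' @export
pair_state_feasible <- function(fields) {
  b <- fields$loc_bold == "exposed"
  s <- fields$loc_shy == "exposed"
  ok_both <- !(b & s & !fields$joined)
  solo <- xor(b, s)
  exposed_fish <- ifelse(b, "bold", "shy")
  ok_solo <- !(solo & !fields$joined & exposed_fish != fields$initiator)
  ok_both & ok_solo
}

## successor of `id` when `mover` toggles its location, applying the
## status-update rules:
##  (a) a departure from both-covered resets initiator := mover, joined := FALSE
##  (b) the non-initiator leaving cover while the initiator is out joins the trip
##  (c) every other move leaves the status variables untouched
.pair_target <- function(states, id, mover) {
  st <- states[states$id == id, ]
  mover_loc <- if (mover == "bold") st$loc_bold else st$loc_shy
  move <- if (mover_loc == "cover") "leave" else "return"
  new_lb <- st$loc_bold
  new_ls <- st$loc_shy
  if (mover == "bold") new_lb <- setdiff(.LOCS, new_lb) else
    new_ls <- setdiff(.LOCS, new_ls)
  init <- st$initiator
  joined <- st$joined
  if (st$loc_bold == "cover" && st$loc_shy == "cover" && move == "leave") {
    init <- mover
    joined <- FALSE
  } else if (move == "leave" && mover != st$initiator) {
    init_loc <- if (st$initiator == "bold") st$loc_bold else st$loc_shy
    if (init_loc == "exposed") joined <- TRUE
  }
  hit <- states$id[states$loc_bold == new_lb & states$loc_shy == new_ls &
                     states$initiator == init & states$joined == joined]
  stopifnot(length(hit) == 1L)
  hit
}

#' Successor state under a single fish's move
#'
#' Applies the pair-state update rules to one move: the mover's location is
#' toggled; a departure from a both-covered state makes the mover the new
#' initiator of an (as yet unjoined) trip; a departure by the non-initiator
#' while the initiator is out marks the trip as joined; all other moves
#' preserve the status variables.
#'
#' @param space the 12-state pair space from [pair_state_space()].
#' @param state integer state id (1--12).
#' @param mover `"bold"` or `"shy"`.
#' @param move `"leave"` or `"return"`; must be consistent with the mover's
#'   current location or an error of class `pairlead_invalid_move` is
#'   signalled.
#' @return the successor state id.
#' @export
#' @examples
#' sp <- pair_state_space()
#' transition_target(sp, 1, "bold", "leave")  # 5
#' transition_target(sp, 5, "shy", "leave")   # 6: partner joins
transition_target <- function(space, state, mover, move) {
  stopifnot(inherits(space, "ctmc_space"), space$name == "pair12")
  mover <- match.arg(mover, .FISH)
  move <- match.arg(move, c("leave", "return"))
  st <- space$states[space$states$id == state, ]
  if (nrow(st) != 1L) stop("unknown state id: ", state)
  loc <- if (mover == "bold") st$loc_bold else st$loc_shy
  expected <- if (loc == "cover") "leave" else "return"
  if (move != expected) {
    stop(errorCondition(
      sprintf("invalid move: %s fish is %s in state %d and cannot %s",
              mover, loc, state, move),
      class = c("pairlead_invalid_move", "error")))
  }
  .pair_target(space$states, state, mover)
}

#' Location-only pair state space
#'
#' The 4-state space obtained by dropping the status variables: states are
#' the four location combinations (both covered, bold out alone, shy out
#' alone, both out) with the 8 single-mover edges between them.  This is
#' the state space of the memory-free model.
#'
#' @return a `ctmc_space` with 4 states and 8 edges; `states$combo` holds
#'   the location code (`CC`, `BE`, `SE`, `EE`).
#' @export
location_state_space <- function() {
  states <- data.frame(id = 1:4, combo = c("CC", "BE", "SE", "EE"),
                       stringsAsFactors = FALSE)
  states$loc_bold <- ifelse(states$combo %in% c("BE", "EE"), "exposed", "cover")
  states$loc_shy <- ifelse(states$combo %in% c("SE", "EE"), "exposed", "cover")
  edges <- do.call(rbind, lapply(states$id, function(id) {
    st <- states[id, ]
    do.call(rbind, lapply(.FISH, function(f) {
      loc <- if (f == "bold") st$loc_bold else st$loc_shy
      move <- if (loc == "cover") "leave" else "return"
      nb <- st$loc_bold
      ns <- st$loc_shy
      if (f == "bold") nb <- setdiff(.LOCS, nb) else ns <- setdiff(.LOCS, ns)
      to <- states$id[states$loc_bold == nb & states$loc_shy == ns]
      partner <- if (f == "bold") st$loc_shy else st$loc_bold
      data.frame(from = id, to = to, mover = f, move = move,
                 partner_loc = partner, stringsAsFactors = FALSE)
    }))
  }))
  .new_space("loc4", states, edges)
}

#' One-step-memory pair state space
#'
#' The 8-state alternative in which the only memory carried is the
#' immediately preceding location configuration: a state is a pair
#' (current location combination, previous location combination), where the
#' previous combination must be reachable from the current one by a single
#' fish's move.  Both-covered can only have been preceded by one fish out
#' alone; one fish out alone by both-covered or both-out; both-out by one
#' fish out alone.  That yields 8 states and 16 single-mover edges; an
#' edge's target records the edge's source location combination as its
#' "previous" component.
#'
#' @return a `ctmc_space` with 8 states (`states$combo`, `states$prev`)
#'   and 16 edges.
#' @export
one_step_state_space <- function() {
  pred <- list(CC = c("BE", "SE"), BE = c("CC", "EE"),
               SE = c("CC", "EE"), EE = c("BE", "SE"))
  states <- do.call(rbind, lapply(names(pred), function(cur) {
    data.frame(combo = cur, prev = pred[[cur]], stringsAsFactors = FALSE)
  }))
  states <- data.frame(id = seq_len(nrow(states)), states,
                       stringsAsFactors = FALSE)
  ## moves act on the current location combination only
  combo_move <- function(cur, fish) {
    b <- cur %in% c("BE", "EE")
    s <- cur %in% c("SE", "EE")
    if (fish == "bold") b <- !b else s <- !s
    if (b && s) "EE" else if (b) "BE" else if (s) "SE" else "CC"
  }
  edges <- do.call(rbind, lapply(states$id, function(id) {
    st <- states[states$id == id, ]
    do.call(rbind, lapply(.FISH, function(f) {
      nxt <- combo_move(st$combo, f)
      to <- states$id[states$combo == nxt & states$prev == st$combo]
      stopifnot(length(to) == 1L)
      b_out <- st$combo %in% c("BE", "EE")
      s_out <- st$combo %in% c("SE", "EE")
      loc <- if (f == "bold") b_out else s_out
      move <- if (loc) "return" else "leave"
      data.frame(from = id, to = to, mover = f, move = move,
                 stringsAsFactors = FALSE)
    }))
  }))
  .new_space("onestep8", states, edges)
}

#' Two-state single-fish space (cover / exposed)
#'
#' @return a `ctmc_space` with states 1 = cover, 2 = exposed and the two
#'   edges `leave` (1 to 2) and `return` (2 to 1).
#' @export
individual_state_space <- function() {
  states <- data.frame(id = 1:2, location = c("cover", "exposed"),
                       stringsAsFactors = FALSE)
  edges <- data.frame(from = c(1L, 2L), to = c(2L, 1L),
                      mover = "self", move = c("leave", "return"),
                      stringsAsFactors = FALSE)
  .new_space("indiv2", states, edges)
}

#' @export
print.ctmc_space <- function(x, ...) {
  cat(sprintf("<ctmc_space '%s': %d states, %d edges>\n",
              x$name, nrow(x$states), nrow(x$edges)))
  invisible(x)
}

#' Parameter-tying scheme over a state space's edges
#'
#' Assigns every directed edge of a space to a rate-parameter class.  Three
#' schemes express the nested model family for the 12-state pair space:
#' \describe{
#'   \item{full}{every edge has its own intensity (24 classes): rates may
#'     depend on locations, on who initiated the current trip, and on
#'     whether the partner joined.}
#'   \item{initiator_only}{rates depend on (mover, move, partner location,
#'     initiator identity) but not on the joined flag (16 classes).}
#'   \item{memory_free}{rates depend only on (mover, move, partner
#'     location) — the pure location model (8 classes).}
#' }
#' On spaces without status variables only `"full"` is meaningful (each
#' edge its own class).
#'
#' @param space a `ctmc_space`.
#' @param name one of `"full"`, `"initiator_only"`, `"memory_free"`.
#' @return a `tying_scheme`: list with `name`, `space_name`, `class`
#'   (character vector parallel to `space$edges`), `classes` (unique class
#'   labels in first-appearance order) and `n_classes`.
#' @export
#' @examples
#' sp <- pair_state_space()
#' tying_scheme(sp, "memory_free")$n_classes  # 8
tying_scheme <- function(space, name = c("full", "initiator_only", "memory_free")) {
  stopifnot(inherits(space, "ctmc_space"))
  name <- match.arg(name)
  e <- space$edges
  if (name == "full") {
    cls <- paste0("q", e$from, "_", e$to)
  } else {
    if (is.null(e$partner_loc) || (name == "initiator_only" && is.null(e$initiator)))
      stop("scheme '", name, "' requires a pair space with status variables")
    cls <- paste(e$mover, e$move, "partner", e$partner_loc, sep = "_")
    if (name == "initiator_only")
      cls <- paste(cls, "init", e$initiator, sep = "_")
  }
  structure(list(name = name, space_name = space$name,
                 class = setNames(cls, e$label),
                 classes = unique(cls), n_classes = length(unique(cls))),
            class = "tying_scheme")
}

#' @export
print.tying_scheme <- function(x, ...) {
  cat(sprintf("<tying_scheme '%s' on %s: %d classes over %d edges>\n",
              x$name, x$space_name, x$n_classes, length(x$class)))
  invisible(x)
}

#' Serialize a state space (and optionally a tying scheme) to JSON
#'
#' Audit-friendly description of a space: states with their fields, edges
#' with mover/move labels, and the class assignment if a scheme is given.
#'
#' @param space a `ctmc_space`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @param scheme optional `tying_scheme` on the same space.
#' @return the JSON string, invisibly when written to a file.
#' @export
space_to_json <- function(space, path = NULL, scheme = NULL) {
  edges <- space$edges
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "tying_scheme"),
              scheme$space_name == space$name)
    edges$class <- unname(scheme$class[edges$label])
  }
  obj <- list(name = space$name, states = space$states, edges = edges)
  if (!is.null(scheme)) obj$scheme <- scheme$name
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
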