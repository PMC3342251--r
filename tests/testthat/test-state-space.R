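test_that("feasibility filter keeps exactly the 12 pair states", {
  grid <- expand.grid(loc_bold = c("cover", "exposed"),
                      loc_shy = c("cover", "exposed"),
                      initiator = c("bold", "shy"),
                      joined = c(FALSE, TRUE), stringsAsFactors = FALSE)
  # independent statement of the two rules
  ok <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    both_out <- g$loc_bold == "exposed" && g$loc_shy == "exposed"
    solo_out <- xor(g$loc_bold == "exposed", g$loc_shy == "exposed")
    exposed <- if (g$loc_bold == "exposed") "bold" else "shy"
    ok[i] <- !(both_out && !g$joined) &&
      !(solo_out && !g$joined && exposed != g$initiator)
  }
  expect_equal(sum(ok), 12)
  expect_equal(sum(!ok), 4)
  expect_equal(pair_state_feasible(grid), ok)

  key <- function(df) sort(paste(df$loc_bold, df$loc_shy, df$initiator, df$joined))
  expect_equal(key(SP$states), key(grid[ok, ]))
  # both exposed & unjoined is never a state
  expect_false(any(SP$states$loc_bold == "exposed" &
                     SP$states$loc_shy == "exposed" & !SP$states$joined))
})

test_that("the edge set has out-degree 2, 24 edges, and is strongly connected", {
  expect_equal(nrow(SP$edges), 24)
  expect_true(all(table(SP$edges$from) == 2))
  # each edge changes exactly one fish's location
  st <- SP$states
  for (i in seq_len(nrow(SP$edges))) {
    a <- st[st$id == SP$edges$from[i], ]
    b <- st[st$id == SP$edges$to[i], ]
    expect_equal((a$loc_bold != b$loc_bold) + (a$loc_shy != b$loc_shy), 1)
  }
  # strong connectivity by BFS from every state
  adj <- split(SP$edges$to, SP$edges$from)
  reach <- function(s) {
    seen <- s
    frontier <- s
    while (length(frontier)) {
      nxt <- setdiff(unlist(adj[as.character(frontier)]), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen)
  }
  for (s in st$id) expect_equal(reach(s), 1:12)
})

test_that("canonical numbering resolves every transition subscript used in the analysis", {
  cases <- list(
    # initiations and failed initiations
    c(1, "bold", "leave", 5), c(2, "bold", "leave", 5),
    c(3, "bold", "leave", 5), c(4, "bold", "leave", 5),
    c(1, "shy", "leave", 9), c(2, "shy", "leave", 9),
    c(3, "shy", "leave", 9), c(4, "shy", "leave", 9),
    # joins
    c(5, "shy", "leave", 6), c(8, "shy", "leave", 6), c(11, "shy", "leave", 10),
    c(7, "bold", "leave", 6), c(9, "bold", "leave", 10), c(12, "bold", "leave", 10),
    # returns from solo excursions
    c(5, "bold", "return", 1), c(8, "bold", "return", 3), c(11, "bold", "return", 4),
    c(9, "shy", "return", 2), c(7, "shy", "return", 3), c(12, "shy", "return", 4),
    # terminations of joint trips
    c(6, "bold", "return", 7), c(6, "shy", "return", 8),
    c(10, "shy", "return", 11), c(10, "bold", "return", 12))
  for (cs in cases) {
    expect_equal(transition_target(SP, as.integer(cs[1]), cs[2], cs[3]),
                 as.integer(cs[4]),
                 label = sprintf("q_%s,%s via %s %s", cs[1], cs[4], cs[2], cs[3]))
  }
  expect_equal(length(cases), 24)  # the full edge set is pinned down
})

test_that("inconsistent moves are rejected", {
  expect_error(transition_target(SP, 5, "bold", "leave"),
               class = "pairlead_invalid_move")
  expect_error(transition_target(SP, 1, "shy", "return"),
               class = "pairlead_invalid_move")
})

test_that("tying schemes have the right class structure", {
  expect_equal(SCH_FULL$n_classes, 24)
  expect_equal(SCH_IO$n_classes, 16)
  expect_equal(SCH_MF$n_classes, 8)

  # memory-free: all bold departures with partner covered share one class
  lab <- function(s, f, e) e$label[e$from == s & e$mover == f]
  mfc <- SCH_MF$class
  bold_cc <- vapply(1:4, function(s) mfc[[lab(s, "bold", SP$edges)]], character(1))
  expect_length(unique(bold_cc), 1)

  # initiator-only: 1->5 and 3->5 share (both initiator bold); 2->5 does not
  ioc <- SCH_IO$class
  expect_equal(ioc[["1->5"]], ioc[["3->5"]])
  expect_false(ioc[["1->5"]] == ioc[["2->5"]])

  # classes never mix mover or move direction, in any scheme
  for (sch in list(SCH_FULL, SCH_IO, SCH_MF)) {
    agg <- tapply(paste(SP$edges$mover, SP$edges$move), sch$class,
                  function(x) length(unique(x)))
    expect_true(all(agg == 1))
  }

  expect_equal(SCH_FULL$n_classes - SCH_MF$n_classes, 16)
  expect_error(tying_scheme(SP, "bogus"))
})

test_that("one-step-memory space has 8 states and 16 edges with the prev rule", {
  expect_equal(nrow(OS$states), 8)
  expect_equal(nrow(OS$edges), 16)
  # infeasible: both-covered cannot be preceded by both-out (single mover)
  expect_false(any(OS$states$combo == "CC" & OS$states$prev == "EE"))
  expect_false(any(OS$states$combo == "EE" & OS$states$prev == "CC"))
  # successor's prev component equals the edge's source location combination
  for (i in seq_len(nrow(OS$edges))) {
    src <- OS$states[OS$states$id == OS$edges$from[i], ]
    dst <- OS$states[OS$states$id == OS$edges$to[i], ]
    expect_equal(dst$prev, src$combo)
  }
  expect_true(all(table(OS$edges$from) == 2))
})

test_that("collapsing status variables recovers the location-only space", {
  expect_equal(nrow(LS$states), 4)
  expect_equal(nrow(LS$edges), 8)
  # the 24 pair edges map onto the 8 location edges consistently with the
  # memory-free classes: same class <=> same collapsed edge
  combo_of <- SP$states$combo[order(SP$states$id)]
  loc_edge <- paste(combo_of[SP$edges$from], combo_of[SP$edges$to], sep = ">")
  expect_equal(length(unique(loc_edge)), 8)
  expect_true(all(tapply(loc_edge, SCH_MF$class, function(x) length(unique(x))) == 1))
  expect_true(all(tapply(SCH_MF$class, loc_edge, function(x) length(unique(x))) == 1))
})

test_that("state spaces serialize to JSON with states, edges and classes", {
  txt <- space_to_json(SP, scheme = SCH_MF)
  obj <- jsonlite::fromJSON(txt)
  expect_equal(nrow(obj$states), 12)
  expect_equal(nrow(obj$edges), 24)
  expect_equal(length(unique(obj$edges$class)), 8)
})
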