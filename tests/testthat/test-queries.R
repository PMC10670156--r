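apt_async <- build_stg(apt_model(), "asynchronous")
apt_sync <- build_stg(apt_model(), "synchronous")
p_T <- "T+ and A- and P-"        # the {T} community persists alone
p_collapse <- "A- and P- and T-" # the empty community

test_that("reachability verdicts and witnesses match the worked example", {
  res <- query_reachable(apt_async, p_T)
  expect_true(res$verdict)
  expect_true(edenr:::witness_is_valid(apt_async, res$witness))
  shown <- vapply(res$witness$states, function(k)
    format_state(apt_async$model, apt_async$states[[k]]), character(1))
  expect_equal(unname(shown), c("APT", "AT", "T"))

  # reachability is reflexive: the initial state reaches itself
  res0 <- query_reachable(apt_async, "A+ and P+ and T+")
  expect_true(res0$verdict)
  expect_length(res0$witness$labels, 0)

  # synchronously, {T} is never reached
  expect_false(query_reachable(apt_sync, p_T)$verdict)
})

test_that("invariance fails with a counterexample path to the collapse", {
  res <- query_invariantly(apt_async, paste0("not (", p_collapse, ")"))
  expect_false(res$verdict)
  expect_true(edenr:::witness_is_valid(apt_async, res$witness))
  last <- res$witness$states[length(res$witness$states)]
  expect_equal(format_state(apt_async$model, apt_async$states[[last]]), "∅")

  expect_true(query_invariantly(apt_async, "A+ or A-")$verdict)  # tautology
  tog <- build_stg(toggle_model())
  expect_true(query_invariantly(tog, "M = 0 or M = 1")$verdict)
})

test_that("collapse is avoidable asynchronously but not synchronously", {
  res <- query_avoidable(apt_async, p_collapse)
  expect_true(res$verdict)
  expect_true(edenr:::witness_is_valid(apt_async, res$witness))
  last <- res$witness$states[length(res$witness$states)]
  expect_equal(format_state(apt_async$model, apt_async$states[[last]]), "T")

  expect_false(query_avoidable(apt_sync, p_collapse)$verdict)

  # an unsatisfiable predicate is trivially avoidable
  expect_true(query_avoidable(apt_async, "A+ and A-")$verdict)
})

test_that("avoidance can be witnessed by a lasso through a non-terminal cycle", {
  # M toggles forever; D is an absorbing collapse reachable at any time
  m <- eden_model(
    c(D = 1, M = 1),
    list(eden_rule("R1", condition = c(M = 0, D = 0), realization = c(M = 1)),
         eden_rule("R2", condition = c(M = 1, D = 0), realization = c(M = 0)),
         eden_rule("R3", condition = c(M = 1, D = 0), realization = c(D = 1))),
    initial = c(M = 0))
  g <- build_stg(m)
  res <- query_avoidable(g, "D+")
  expect_true(res$verdict)
  expect_false(is.na(res$witness$loop_to))  # no deadlock avoids D: must cycle
  expect_true(edenr:::witness_is_valid(g, res$witness))
})

test_that("stability detects terminal components inside the predicate", {
  expect_true(query_stable(apt_async, "T+")$verdict)      # deadlock {T}
  expect_false(query_stable(apt_async, "P+")$verdict)     # P never persists
  tog <- build_stg(toggle_model())
  expect_true(query_stable(tog, "M = 0 or M = 1")$verdict) # terminal SCC
  expect_false(query_stable(tog, "M+")$verdict)            # SCC leaves M+
})

test_that("the extinction of P is necessary but not sufficient for {T}", {
  nec <- query_event_necessary(apt_async, "R1", p_T)
  expect_true(nec$verdict)

  suf <- query_event_sufficient(apt_async, "R1", p_T)
  expect_false(suf$verdict)
  expect_true(edenr:::witness_is_valid(apt_async, suf$witness))
  # the counterexample fires R1 yet ends in the collapse
  fired <- unlist(suf$witness$labels)
  expect_true("R1" %in% fired)
  last <- suf$witness$states[length(suf$witness$states)]
  expect_equal(format_state(apt_async$model, apt_async$states[[last]]), "∅")
})

test_that("a rule absent from every edge is not necessary for a reachable outcome", {
  # R4 never fires on any path to {AP}
  res <- query_event_necessary(apt_async, "R4", "A+ and P+ and T-")
  expect_false(res$verdict)
  expect_true(edenr:::witness_is_valid(apt_async, res$witness))
  expect_error(query_event_necessary(apt_async, "R9", p_T), "unknown rule")
})

test_that("invariantly(p) is the negation of reachable(not p) on random graphs", {
  for (seed in 1:12) {
    m <- random_model(2 + seed %% 5, 3 + seed %% 7, 6000 + seed)
    g <- build_stg(m)
    v <- m$variables$name[1 + seed %% nrow(m$variables)]
    for (expr in c(paste0(v, "+"), paste0(v, "-"))) {
      lhs <- query_invariantly(g, expr)$verdict
      rhs <- !query_reachable(g, paste0("not ", expr))$verdict
      expect_identical(lhs, rhs)
    }
  }
})

test_that("avoidable is monotone: enlarging the avoided set never flips false to true", {
  # p1 implies p2 (p2 avoided-set is larger); avoidable(p2) => avoidable(p1)
  for (seed in 1:10) {
    m <- random_model(3, 4 + seed %% 6, 7000 + seed)
    g <- build_stg(m)
    p1 <- "V1+ and V2+"
    p2 <- "V1+"
    a1 <- query_avoidable(g, p1)$verdict
    a2 <- query_avoidable(g, p2)$verdict
    expect_true(!a2 || a1)
  }
})

test_that("explicit state-set predicates behave like their atom equivalents", {
  p_set <- state_set_predicate(list(c(T = 1)), apt_model())
  res <- query_reachable(apt_async, p_set)
  expect_true(res$verdict)
  expect_identical(
    res$witness$states,
    query_reachable(apt_async, p_T)$witness$states)
})

test_that("the full published narrative holds simultaneously on the fixture", {
  expect_true(query_reachable(apt_async, p_T)$verdict &&
              query_reachable(apt_async, p_collapse)$verdict &&
              query_event_necessary(apt_async, "R1", p_T)$verdict &&
              !query_event_sufficient(apt_async, "R1", p_T)$verdict)
})

test_that("malformed predicates are rejected with a message", {
  expect_error(parse_predicate("X9+", apt_model()), "undeclared variable")
  expect_error(parse_predicate("A+ and", apt_model()), "parse error")
  expect_error(parse_predicate("A >= 7", apt_model()), "Boolean|domain")
})
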