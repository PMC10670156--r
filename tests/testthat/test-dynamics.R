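test_that("enabledness is effect-bearing and matches the worked example", {
  m <- apt_model()
  expect_equal(enabled_rules(m, st(A = 1, P = 1, T = 1)), c("R1", "R2", "R3"))
  expect_equal(enabled_rules(m, st(A = 0, P = 0, T = 1)), character(0))
  expect_equal(enabled_rules(m, st(A = 1, P = 0, T = 1)), c("R2", "R4"))

  # condition holds but realization is a no-op => not enabled
  mv <- germination_models()$multivalued
  expect_equal(enabled_rules(mv, st(M = 2, S1 = 1, S2 = 1)), character(0))
  expect_equal(enabled_rules(mv, st(M = 1, S1 = 0, S2 = 1)), c("R1", "R4"))
})

test_that("fire_rule applies realizations atomically and rejects non-enabled rules", {
  m <- apt_model()
  expect_equal(fire_rule(m, st(A = 1, P = 1, T = 1), "R2"),
               st(A = 1, P = 1, T = 0))
  gb <- germination_models()$boolean
  expect_equal(fire_rule(gb, st(M = 1, S = 0), "R1"), st(M = 1, S = 1))

  multi <- eden_model(
    c(X = 1, Y = 1, Z = 1),
    list(eden_rule("R1", condition = c(X = 1),
                   realization = c(Y = 1, Z = 0))),
    initial = c(X = 1, Z = 1))
  expect_equal(fire_rule(multi, st(X = 1, Y = 0, Z = 1), "R1"),
               st(X = 1, Y = 1, Z = 0))

  expect_error(fire_rule(m, st(A = 0, P = 0, T = 1), "R1"), "not enabled")
  expect_error(fire_rule(m, st(A = 1, P = 1, T = 1), "R9"), "unknown rule")
})

test_that("asynchronous successors merge labels per target state", {
  m <- apt_model()
  succ <- successors(m, st(A = 1, P = 1, T = 1), "asynchronous")
  targets <- lapply(succ, `[[`, "state")
  labels <- lapply(succ, `[[`, "labels")
  expect_length(succ, 2)
  i_ap <- which(vapply(targets, identical, logical(1), st(A = 1, P = 1, T = 0)))
  i_at <- which(vapply(targets, identical, logical(1), st(A = 1, P = 0, T = 1)))
  expect_equal(labels[[i_ap]], c("R2", "R3"))  # merged alternative firings
  expect_equal(labels[[i_at]], "R1")
  expect_length(successors(m, st(A = 0, P = 0, T = 1), "asynchronous"), 0)
})

test_that("synchronous successors fire all enabled rules at once", {
  m <- apt_model()
  succ <- successors(m, st(A = 1, P = 1, T = 1), "synchronous")
  expect_length(succ, 1)
  expect_equal(succ[[1]]$state, st(A = 1, P = 0, T = 0))
  expect_equal(succ[[1]]$labels, c("R1", "R2", "R3"))
})

test_that("synchronous write conflicts error by default and branch on request", {
  m <- eden_model(
    c(A = 1, B = 1),
    list(eden_rule("R1", condition = c(A = 1), realization = c(B = 1)),
         eden_rule("R2", condition = c(A = 1), realization = c(B = 0, A = 0))),
    initial = c(A = 1, B = 0))
  expect_error(successors(m, st(A = 1, B = 0), "synchronous"),
               "conflict.*R1.*R2.*'B'")
  expect_error(build_stg(m, "synchronous"), "conflict")

  branched <- successors(m, st(A = 1, B = 0), "synchronous",
                         on_conflict = "branch")
  targets <- lapply(branched, `[[`, "state")
  expect_length(branched, 2)  # one per maximal conflict-free subset
  expect_true(any(vapply(targets, identical, logical(1), st(A = 1, B = 1))))
  expect_true(any(vapply(targets, identical, logical(1), st(A = 0, B = 0))))
})

test_that("the asynchronous STG of the disassembly model matches the published facts", {
  g <- build_stg(apt_model(), "asynchronous")
  expect_length(g$states, 6)
  expect_equal(nrow(g$transitions), 6)
  m <- g$model
  dl <- vapply(deadlock_states(g), function(k) format_state(m, g$states[[k]]),
               character(1))
  expect_setequal(unname(dl), c("T", "∅"))
})

test_that("the synchronous STG of the disassembly model is a path to the empty state", {
  g <- build_stg(apt_model(), "synchronous")
  expect_length(g$states, 3)
  expect_equal(nrow(g$transitions), 2)
  m <- g$model
  dl <- vapply(deadlock_states(g), function(k) format_state(m, g$states[[k]]),
               character(1))
  expect_equal(unname(dl), "∅")
  # out-degree <= 1 everywhere: deterministic dynamics
  expect_true(all(table(g$transitions$from) <= 1))
})

test_that("a model with no rules yields a single-state graph", {
  m <- eden_model(c(A = 1), list(), initial = c(A = 1))
  g <- build_stg(m)
  expect_length(g$states, 1)
  expect_equal(nrow(g$transitions), 0)
})

test_that("exceeding max_states aborts explicitly", {
  expect_error(build_stg(apt_model(), "asynchronous", max_states = 3),
               "max_states")
})

test_that("rebuilding the same model and mode yields an identical graph", {
  for (mode in c("asynchronous", "synchronous")) {
    g1 <- build_stg(apt_model(), mode)
    g2 <- build_stg(apt_model(), mode)
    expect_identical(g1, g2)
  }
})

test_that("no transition is a self-loop in either mode", {
  for (seed in 1:15) {
    m <- random_model(n_vars = 2 + seed %% 5, n_rules = 3 + seed %% 7,
                      seed = 500 + seed)
    g <- build_stg(m, "asynchronous")
    expect_false(any(g$transitions$from == g$transitions$to))
    gs <- tryCatch(build_stg(m, "synchronous"), error = function(e) NULL)
    if (!is.null(gs)) {
      expect_false(any(gs$transitions$from == gs$transitions$to))
    }
  }
})

test_that("engine graphs equal the brute-force transition relation on random models", {
  for (seed in 1:40) {
    m <- random_model(n_vars = 1 + seed %% 6, n_rules = seed %% 9,
                      seed = 1000 + seed)
    for (mode in c("asynchronous", "synchronous")) {
      oracle <- oracle_reachable_graph(m, mode)
      if (!is.null(oracle$conflict_state)) {
        expect_error(build_stg(m, mode), "conflict")
      } else {
        g <- build_stg(m, mode)
        expect_identical(stg_as_sets(g), oracle)
      }
    }
  }
})

test_that("asynchronous edges are exactly the single-rule firings", {
  for (seed in c(3, 9, 21)) {
    m <- random_model(n_vars = 4, n_rules = 6, seed = seed)
    g <- build_stg(m, "asynchronous")
    for (i in seq_len(nrow(g$transitions))) {
      s <- g$states[[g$transitions$from[i]]]
      t <- g$states[[g$transitions$to[i]]]
      realizing <- Filter(function(lab) {
        lab %in% enabled_rules(m, s) && identical(fire_rule(m, s, lab), t)
      }, vapply(m$rules, `[[`, character(1), "label"))
      expect_equal(g$transitions$labels[[i]], sort(unlist(realizing)))
    }
  }
})

test_that("the synchronous endpoint of the disassembly model is an asynchronous deadlock", {
  ga <- build_stg(apt_model(), "asynchronous")
  gs <- build_stg(apt_model(), "synchronous")
  expect_true(all(deadlock_states(gs) %in% deadlock_states(ga)))
})
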