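fmt_keys <- function(g, keys) {
  sort(vapply(keys, function(k) format_state(g$model, g$states[[k]]),
              character(1), USE.NAMES = FALSE))
}

comp_by_kind <- function(topo, kind) {
  Filter(function(co) co$kind == kind, topo$components)
}

test_that("SCC detection matches the mutual-reachability oracle on fixtures", {
  g <- build_stg(apt_model())
  sccs <- find_sccs(g)
  expect_false(any(attr(sccs, "nontrivial")))  # all six states trivial
  expect_length(sccs, 6)

  t <- build_stg(toggle_model())
  tsccs <- find_sccs(t)
  expect_length(tsccs, 1)
  expect_true(all(attr(tsccs, "nontrivial")))
  expect_length(tsccs[[1]], 4)

  one <- build_stg(eden_model(c(A = 1), list(), initial = c(A = 0)))
  expect_length(find_sccs(one), 1)

  for (g2 in list(g, t, build_stg(cycle3_model()))) {
    expect_identical(lapply(find_sccs(g2), identity), oracle_sccs(g2))
  }
})

test_that("SCCs agree with the brute-force oracle on random graphs", {
  for (seed in 1:20) {
    m <- random_model(n_vars = 2 + seed %% 5, n_rules = 4 + seed %% 8,
                      seed = 2000 + seed)
    g <- build_stg(m, "asynchronous")
    expect_identical(lapply(find_sccs(g), identity), oracle_sccs(g))
  }
})

test_that("component classification reproduces the disassembly example", {
  g <- build_stg(apt_model())
  topo <- classify_components(g)

  dls <- comp_by_kind(topo, "deadlock")
  expect_length(dls, 2)
  expect_setequal(unlist(lapply(dls, function(co) fmt_keys(g, co$members))),
                  c("T", "∅"))

  basins <- comp_by_kind(topo, "basin")
  expect_length(basins, 2)
  members <- lapply(basins, function(co) fmt_keys(g, co$members))
  i_strong <- which(vapply(basins, `[[`, logical(1), "strong"))
  expect_length(i_strong, 1)
  expect_setequal(members[[i_strong]], c("A", "AP"))
  expect_length(basins[[i_strong]]$attractor_key, 1)  # only the empty state
  i_weak <- setdiff(seq_along(basins), i_strong)
  expect_setequal(members[[i_weak]], c("APT", "AT"))
  expect_length(basins[[i_weak]]$attractor_key, 2)  # both deadlocks

  expect_length(comp_by_kind(topo, "cyclic_scc"), 0)
  expect_length(comp_by_kind(topo, "complex_scc"), 0)
})

test_that("cyclic and complex SCCs are told apart by internal degree", {
  t <- classify_components(build_stg(toggle_model()))
  expect_length(comp_by_kind(t, "complex_scc"), 1)
  expect_length(t$components, 1)  # no deadlocks, no basins

  c3 <- classify_components(build_stg(cycle3_model()))
  expect_length(comp_by_kind(c3, "cyclic_scc"), 1)
  expect_length(c3$components, 1)
})

test_that("components partition the state set on fixtures and random models", {
  graphs <- list(build_stg(apt_model()), build_stg(toggle_model()),
                 build_stg(cycle3_model()),
                 build_stg(germination_models()$multivalued))
  for (seed in 1:15) {
    graphs[[length(graphs) + 1L]] <-
      build_stg(random_model(2 + seed %% 6, 3 + seed %% 8, 3000 + seed))
  }
  for (g in graphs) {
    topo <- classify_components(g)
    all_members <- unlist(lapply(topo$components, `[[`, "members"))
    expect_equal(sort(all_members), sort(names(g$states)))
    expect_false(anyDuplicated(all_members) > 0)
  }
})

test_that("basin attractor keys equal brute-force reachable-deadlock sets", {
  # on deadlock-only fixtures, the attractor key of a basin must list
  # exactly the deadlocks its states can reach
  graphs <- list(build_stg(apt_model()))
  for (seed in 1:12) {
    graphs[[length(graphs) + 1L]] <-
      build_stg(random_model(2 + seed %% 5, 2 + seed %% 7, 4000 + seed))
  }
  for (g in graphs) {
    topo <- classify_components(g)
    per_state <- oracle_reachable_deadlocks(g)
    dl_comp <- comp_by_kind(topo, "deadlock")
    key_of_deadlock <- stats::setNames(
      vapply(dl_comp, `[[`, character(1), "id"),
      vapply(dl_comp, function(co) co$members[[1]], character(1)))
    for (co in comp_by_kind(topo, "basin")) {
      for (s in co$members) {
        oracle_ids <- sort(unname(key_of_deadlock[per_state[[s]]]))
        expect_identical(
          sort(intersect(co$attractor_key, unname(key_of_deadlock))),
          oracle_ids)
      }
    }
  }
})

test_that("the hierarchical transition graph condenses the disassembly STG", {
  g <- build_stg(apt_model())
  htg <- build_htg(g)
  expect_length(htg$nodes, 4)  # 2 deadlocks + 2 basins
  expect_equal(nrow(htg$edges), 3)
  # weak basin -> strong basin, weak basin -> {T}, strong basin -> {empty}
  topo <- htg$topology
  id_of <- stats::setNames(
    vapply(topo$components, `[[`, character(1), "id"),
    vapply(topo$components, function(co)
      paste(fmt_keys(g, co$members), collapse = "+"), character(1)))
  e <- paste(htg$edges$from, "->", htg$edges$to)
  expect_setequal(e, c(
    paste(id_of[["APT+AT"]], "->", id_of[["A+AP"]]),
    paste(id_of[["APT+AT"]], "->", id_of[["T"]]),
    paste(id_of[["A+AP"]], "->", id_of[["∅"]])
  ))
})

test_that("HTG of a single-SCC or single-state graph is one node, no edges", {
  for (g in list(build_stg(toggle_model()),
                 build_stg(eden_model(c(A = 1), list(), initial = c(A = 1))))) {
    htg <- build_htg(g)
    expect_length(htg$nodes, 1)
    expect_equal(nrow(htg$edges), 0)
  }
})

test_that("the HTG is acyclic and partitions states on random models", {
  for (seed in 1:20) {
    m <- random_model(2 + seed %% 6, 3 + seed %% 9, 5000 + seed)
    g <- build_stg(m, "asynchronous")
    htg <- build_htg(g)  # acyclicity asserted internally
    all_members <- unlist(lapply(htg$topology$components, `[[`, "members"))
    expect_setequal(all_members, names(g$states))
    # crossing rule: every HTG edge backed by a state-level transition
    cmap <- htg$topology$state_component
    crossings <- unique(paste(cmap[g$transitions$from],
                              cmap[g$transitions$to]))
    crossings <- crossings[vapply(strsplit(crossings, " "), function(x)
      x[1] != x[2], logical(1))]
    expect_setequal(paste(htg$edges$from, htg$edges$to), crossings)
  }
})

test_that("trajectory enumeration matches the published counts", {
  tr <- count_trajectories(build_stg(apt_model(), "asynchronous"))
  expect_equal(tr$count, 3)
  expect_equal(tr$level, "state")
  g <- build_stg(apt_model())
  shown <- vapply(tr$trajectories, function(t)
    paste(vapply(t$states, function(k) format_state(g$model, g$states[[k]]),
                 character(1)), collapse = ">"), character(1))
  expect_setequal(shown, c("APT>AP>A>∅", "APT>AT>A>∅", "APT>AT>T"))

  expect_equal(count_trajectories(build_stg(apt_model(), "synchronous"))$count, 1)

  zero <- build_stg(eden_model(c(A = 1), list(), initial = c(A = 1)))
  expect_equal(count_trajectories(zero)$count, 1)

  # cyclic STG falls back to component-level paths (finite by acyclicity)
  tcyc <- count_trajectories(build_stg(toggle_model()))
  expect_equal(tcyc$level, "component")
  expect_equal(tcyc$count, 1)
})

test_that("trajectory explosion is guarded by an explicit cap", {
  expect_error(count_trajectories(build_stg(apt_model()), max_trajectories = 2),
               "max_trajectories")
})
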