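# Execution semantics. Two update modes:
#   asynchronous — exactly one enabled rule fires per transition; since a
#     single rule may set several variables at once, this realizes the
#     partially synchronous scheduling of multi-variable events.
#   synchronous  — all enabled rules fire simultaneously in one transition.
# Enabledness is effect-bearing: a rule whose condition holds but whose
# realization would not change the state is NOT enabled, so the graphs
# contain no self-loops and a deadlock is exactly "no enabled rule".

state_key <- function(s) paste(unname(s), collapse = ",")

check_state <- function(m, s) {
  if (is.null(names(s)) || !setequal(names(s), m$variables$name)) {
    stop("state must assign a level to exactly the model's variables",
         call. = FALSE)
  }
  s <- as.integer(s[m$variables$name])
  names(s) <- m$variables$name
  maxlev <- m$variables$max_level
  if (any(s < 0L | s > maxlev)) {
    stop("state level out of domain for ",
         paste(names(s)[s < 0L | s > maxlev], collapse = ", "), call. = FALSE)
  }
  s
}

atom_holds <- function(op, have, want) {
  switch(op,
    ">=" = have >= want,
    ">"  = have >  want,
    "<=" = have <= want,
    "<"  = have <  want,
    "="  = have == want,
    stop("unknown operator: ", op, call. = FALSE)
  )
}

condition_holds <- function(r, s) {
  have <- unname(s[r$condition$variable])
  all(mapply(atom_holds, r$condition$op, have, r$condition$level))
}

apply_realization <- function(r, s) {
  s[r$realization$variable] <- r$realization$level
  s
}

#' Rules enabled in a state
#'
#' A rule is enabled when its condition holds and firing it would change
#' the state (effect-bearing enabledness). A state with no enabled rule is
#' a deadlock (stable state).
#'
#' @param m an `eden_model`.
#' @param s a state (named integer vector over the model's variables).
#' @return sorted character vector of enabled rule labels.
#' @export
enabled_rules <- function(m, s) {
  s <- check_state(m, s)
  labs <- character(0)
  for (r in m$rules) {
    if (condition_holds(r, s) && !identical(apply_realization(r, s), s)) {
      labs <- c(labs, r$label)
    }
  }
  sort(labs)
}

#' Fire a single rule
#'
#' Applies the rule's realization atomically; all other variables are
#' unchanged. Firing a rule that is not enabled in `s` is an error.
#'
#' @inheritParams enabled_rules
#' @param label label of an enabled rule.
#' @return the successor state.
#' @export
fire_rule <- function(m, s, label) {
  s <- check_state(m, s)
  r <- get_rule(m, label)
  if (!condition_holds(r, s)) {
    stop("rule ", label, " is not enabled: condition does not hold", call. = FALSE)
  }
  t <- apply_realization(r, s)
  if (identical(t, s)) {
    stop("rule ", label, " is not enabled: realization has no effect", call. = FALSE)
  }
  t
}

#' Successor states under an update mode
#'
#' Asynchronous mode returns one entry per distinct target state over all
#' enabled rules, with the labels of every rule realizing that target
#' merged onto it. Synchronous mode returns at most one entry: the state
#' obtained by applying the union of all enabled realizations, labeled
#' with the full fired set. An empty result means `s` is a deadlock.
#'
#' @inheritParams enabled_rules
#' @param mode `"asynchronous"` or `"synchronous"`.
#' @param on_conflict what to do when two synchronously enabled rules
#'   assign different levels to one variable: `"error"` (default) stops,
#'   naming the rules and the variable; `"branch"` explores every maximal
#'   conflict-free subset of the enabled rules, yielding one successor per
#'   subset (an extension beyond plain synchronous semantics).
#' @return a list of `list(state, labels)` entries, sorted by target
#'   state key.
#' @export
successors <- function(m, s, mode = c("asynchronous", "synchronous"),
                       on_conflict = c("error", "branch")) {
  mode <- match.arg(mode)
  on_conflict <- match.arg(on_conflict)
  s <- check_state(m, s)
  en <- enabled_rules(m, s)
  if (length(en) == 0L) return(list())
  if (mode == "asynchronous") {
    by_target <- list()
    for (lab in en) {
      t <- apply_realization(get_rule(m, lab), s)
      k <- state_key(t)
      if (is.null(by_target[[k]])) {
        by_target[[k]] <- list(state = t, labels = lab)
      } else {
        by_target[[k]]$labels <- c(by_target[[k]]$labels, lab)
      }
    }
    out <- by_target[order(names(by_target))]
    return(unname(lapply(out, function(e) {
      list(state = e$state, labels = sort(e$labels))
    })))
  }
  # synchronous
  subsets <- if (on_conflict == "error") {
    conflict <- sync_conflict(m, en)
    if (!is.null(conflict)) {
      stop(sprintf(
        "synchronous conflict: rules %s and %s assign different levels to variable '%s'",
        conflict$rule1, conflict$rule2, conflict$variable), call. = FALSE)
    }
    list(en)
  } else {
    max_conflict_free_subsets(m, en)
  }
  by_target <- list()
  for (sub in subsets) {
    t <- s
    for (lab in sub) t <- apply_realization(get_rule(m, lab), t)
    k <- state_key(t)
    if (identical(t, s)) next  # cannot happen for effect-bearing rules
    if (is.null(by_target[[k]])) {
      by_target[[k]] <- list(state = t, labels = sub)
    } else {
      by_target[[k]]$labels <- sort(unique(c(by_target[[k]]$labels, sub)))
    }
  }
  out <- by_target[order(names(by_target))]
  unname(lapply(out, function(e) list(state = e$state, labels = sort(e$labels))))
}

# first conflicting pair among enabled rules, or NULL
sync_conflict <- function(m, labels) {
  assigns <- list()  # variable -> list(level, rule)
  for (lab in labels) {
    r <- get_rule(m, lab)
    for (i in seq_len(nrow(r$realization))) {
      v <- r$realization$variable[i]
      lev <- r$realization$level[i]
      prev <- assigns[[v]]
      if (!is.null(prev) && prev$level != lev) {
        return(list(rule1 = prev$rule, rule2 = lab, variable = v))
      }
      if (is.null(prev)) assigns[[v]] <- list(level = lev, rule = lab)
    }
  }
  NULL
}

# maximal subsets of pairwise-compatible rules (compatibility = no variable
# assigned two different levels); maximal cliques of the compatibility graph
max_conflict_free_subsets <- function(m, labels) {
  n <- length(labels)
  if (n == 1L) return(list(labels))
  compat <- matrix(TRUE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      compat[i, j] <- compat[j, i] <-
        is.null(sync_conflict(m, c(labels[i], labels[j])))
    }
  }
  diag(compat) <- FALSE
  ig <- igraph::graph_from_adjacency_matrix(compat, mode = "undirected")
  cliques <- igraph::max_cliques(ig)
  subs <- lapply(cliques, function(cl) sort(labels[as.integer(cl)]))
  subs[order(vapply(subs, paste, character(1), collapse = ","))]
}

#' Build the exhaustive state-transition graph
#'
#' Breadth-first closure of [successors()] from all initial states: every
#' reachable state becomes a node, every possible rule firing a labeled
#' transition (possibilistic exploration — all trajectories compatible
#' with the rules are computed, with no probabilities or durations).
#' States are dequeued in canonical sorted order and rules tried in label
#' order, so rebuilding from the same model and mode yields an identical
#' graph.
#'
#' @param m a valid `eden_model`.
#' @param mode `"asynchronous"` (default) or `"synchronous"`.
#' @param max_states abort with an explicit error (never truncate
#'   silently) when the exploration exceeds this many states.
#' @param on_conflict see [successors()].
#' @return an object of class `eden_stg` with fields `model`, `mode`,
#'   `states` (named list of states keyed by canonical key, sorted),
#'   `transitions` (data frame `from`, `to`, `labels` list-column),
#'   `initial` (keys of the initial states).
#' @examples
#' g <- build_stg(apt_model())
#' g
#' @export
build_stg <- function(m, mode = c("asynchronous", "synchronous"),
                      max_states = 1e6, on_conflict = c("error", "branch")) {
  mode <- match.arg(mode)
  on_conflict <- match.arg(on_conflict)
  diags <- validate_model(m)
  if (length(diags) > 0L) {
    stop("invalid model:\n  ", paste(diags, collapse = "\n  "), call. = FALSE)
  }
  states <- list()
  edges_from <- character(0); edges_to <- character(0); edges_lab <- list()
  init_keys <- sort(unique(vapply(m$initial, state_key, character(1))))
  for (s in m$initial) states[[state_key(s)]] <- check_state(m, s)
  frontier <- init_keys
  while (length(frontier) > 0L) {
    frontier <- sort(frontier)
    key <- frontier[[1]]
    frontier <- frontier[-1]
    succ <- successors(m, states[[key]], mode, on_conflict)
    for (e in succ) {
      tk <- state_key(e$state)
      if (is.null(states[[tk]])) {
        states[[tk]] <- e$state
        frontier <- c(frontier, tk)
        if (length(states) > max_states) {
          stop(sprintf(
            "state space exceeds max_states = %d: exploration aborted (partial graph discarded)",
            as.integer(max_states)), call. = FALSE)
        }
      }
      edges_from <- c(edges_from, key)
      edges_to <- c(edges_to, tk)
      edges_lab[[length(edges_lab) + 1L]] <- e$labels
    }
  }
  states <- states[order(names(states))]
  transitions <- data.frame(from = edges_from, to = edges_to,
                            stringsAsFactors = FALSE)
  transitions$labels <- edges_lab
  if (nrow(transitions) > 0L) {
    ord <- order(transitions$from, transitions$to)
    transitions <- transitions[ord, , drop = FALSE]
    rownames(transitions) <- NULL
  }
  structure(list(model = m, mode = mode, states = states,
                 transitions = transitions, initial = init_keys),
            class = "eden_stg")
}

#' Deadlock (stable) states of a state-transition graph
#' @param g an `eden_stg`.
#' @return sorted character vector of state keys with no outgoing
#'   transition.
#' @export
deadlock_states <- function(g) {
  sort(setdiff(names(g$states), unique(g$transitions$from)))
}

#' Look up a state of an STG by key or by (partial) assignment
#' @param g an `eden_stg`.
#' @param s a state key, or a named (possibly partial) level vector with
#'   unlisted variables defaulting to 0.
#' @return the canonical state key.
#' @export
stg_state_key <- function(g, s) {
  if (is.character(s) && length(s) == 1L && s %in% names(g$states)) return(s)
  k <- state_key(complete_state(s, g$model$variables))
  if (!k %in% names(g$states)) {
    stop("state ", k, " is not in the graph", call. = FALSE)
  }
  k
}

#' @export
print.eden_stg <- function(x, ...) {
  dl <- deadlock_states(x)
  cat(sprintf("State-transition graph (%s mode): %d states, %d transitions\n",
              x$mode, length(x$states), nrow(x$transitions)))
  cat(sprintf("initial: %s\n",
              paste(vapply(x$initial, function(k) format_state(x$model, x$states[[k]]),
                           character(1)), collapse = ", ")))
  cat(sprintf("deadlocks: %s\n",
              if (length(dl) == 0L) "none"
              else paste(vapply(dl, function(k) format_state(x$model, x$states[[k]]),
                                character(1)), collapse = ", ")))
  invisible(x)
}
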