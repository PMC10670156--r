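# Model-checking query patterns over a computed STG. Instead of a general
# temporal-logic front end, a fixed set of named patterns covers the
# ecological questions of interest: is a state reachable, does a property
# hold invariantly, is a collapse avoidable, is a community stable, and is
# an event (rule) a necessary or a sufficient condition for an outcome.
# Verdicts come with witness trajectories: a proving path, or a
# counterexample (possibly lasso-shaped: a path plus a cycle the system
# can repeat forever, since no fairness is assumed on non-terminal cycles).

#' Build a state predicate
#'
#' Parses a Boolean expression over condition atoms, e.g.
#' `"T+ and A- and P-"` or `"not (M >= 1 or S2+)"`. Atoms use the model
#' file syntax (`v+`, `v-`, `v >= k`, ...); connectives are `and`, `or`,
#' `not` with parentheses.
#'
#' @param expr expression string.
#' @param m the `eden_model` the predicate speaks about.
#' @return an object of class `eden_predicate`.
#' @seealso [state_set_predicate()] for an explicit set of states.
#' @export
parse_predicate <- function(expr, m) {
  toks <- tokenize_pred(expr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(val) {
    t <- peek()
    if (is.null(t) || t != val) {
      stop("predicate parse error: expected '", val, "' near position ", pos,
           " in: ", expr, call. = FALSE)
    }
    advance()
  }
  dom <- stats::setNames(m$variables$max_level, m$variables$name)
  parse_or <- function() {
    left <- parse_and()
    while (!is.null(peek()) && peek() == "or") {
      advance()
      left <- pred_node("or", args = list(left, parse_and()))
    }
    left
  }
  parse_and <- function() {
    left <- parse_not()
    while (!is.null(peek()) && peek() == "and") {
      advance()
      left <- pred_node("and", args = list(left, parse_not()))
    }
    left
  }
  parse_not <- function() {
    t <- peek()
    if (!is.null(t) && t == "not") {
      advance()
      return(pred_node("not", args = list(parse_not())))
    }
    if (!is.null(t) && t == "(") {
      advance()
      inner <- parse_or()
      expect(")")
      return(inner)
    }
    parse_atom_pred()
  }
  parse_atom_pred <- function() {
    v <- peek()
    if (is.null(v) || !grepl(paste0("^", IDENT_RE, "$"), v)) {
      stop("predicate parse error: expected an atom near position ", pos,
           " in: ", expr, call. = FALSE)
    }
    advance()
    if (!v %in% names(dom)) {
      stop("predicate refers to undeclared variable '", v, "'", call. = FALSE)
    }
    op <- peek()
    if (is.null(op) || !op %in% c("+", "-", ">=", "<=", "=", "<", ">")) {
      stop("predicate parse error: expected an operator after '", v, "'",
           call. = FALSE)
    }
    advance()
    if (op %in% c("+", "-")) {
      lev <- if (op == "+") 1L else 0L
      op <- "="
    } else {
      lt <- peek()
      if (is.null(lt) || !grepl("^[0-9]+$", lt)) {
        stop("predicate parse error: expected a level after '", v, " ", op, "'",
             call. = FALSE)
      }
      advance()
      lev <- as.integer(lt)
    }
    if (lev < 0L || lev > dom[[v]]) {
      stop("predicate level ", lev, " out of domain 0..", dom[[v]],
           " for '", v, "'", call. = FALSE)
    }
    pred_node("atom", variable = v, op = op, level = lev)
  }
  p <- parse_or()
  if (!is.null(peek())) {
    stop("predicate parse error: trailing input near '", peek(), "' in: ",
         expr, call. = FALSE)
  }
  p
}

tokenize_pred <- function(expr) {
  pat <- paste0("(", IDENT_RE, "|[0-9]+|>=|<=|[()=<>+-])")
  starts <- gregexpr(pat, expr)[[1]]
  if (starts[1] == -1L) stop("empty predicate", call. = FALSE)
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  covered <- sum(nchar(toks))
  stripped <- gsub("\\s", "", expr)
  if (nchar(stripped) != covered) {
    stop("predicate parse error: unrecognized characters in: ", expr,
         call. = FALSE)
  }
  toks
}

pred_node <- function(type, ...) {
  structure(list(type = type, ...), class = "eden_predicate")
}

#' Predicate holding on an explicit set of states
#'
#' @param states list of states (named level vectors, possibly partial —
#'   missing variables default to 0) or character vector of state keys.
#' @param m the `eden_model`.
#' @return an `eden_predicate`.
#' @export
state_set_predicate <- function(states, m) {
  keys <- if (is.character(states)) states else {
    vapply(if (is.list(states)) states else list(states),
           function(s) state_key(complete_state(s, m$variables)), character(1))
  }
  pred_node("states", keys = sort(unique(keys)))
}

eval_predicate <- function(p, s) {
  switch(p$type,
    atom = atom_holds(p$op, unname(s[[p$variable]]), p$level),
    and = all(vapply(p$args, eval_predicate, logical(1), s = s)),
    or = any(vapply(p$args, eval_predicate, logical(1), s = s)),
    not = !eval_predicate(p$args[[1]], s),
    states = state_key(s) %in% p$keys,
    stop("unknown predicate node type: ", p$type, call. = FALSE)
  )
}

as_predicate <- function(p, m) {
  if (inherits(p, "eden_predicate")) return(p)
  if (is.character(p) && length(p) == 1L) return(parse_predicate(p, m))
  stop("predicate must be an eden_predicate or an expression string",
       call. = FALSE)
}

# keys of STG states satisfying p
pred_keys <- function(g, p) {
  keys <- names(g$states)
  keys[vapply(g$states, function(s) eval_predicate(p, s), logical(1))]
}

# -- path machinery ----------------------------------------------------------

# shortest path from any of `from` to any of `targets`, restricted to
# `allowed` keys (NULL = all); deterministic (sorted expansion).
# Returns list(states, labels) or NULL; a from-state already in targets
# gives a length-0 path.
shortest_path <- function(g, from, targets, allowed = NULL,
                          drop_label = NULL) {
  if (!is.null(allowed)) from <- intersect(from, allowed)
  from <- sort(from)
  if (length(from) == 0L) return(NULL)
  hit <- intersect(from, targets)
  if (length(hit) > 0L) {
    return(list(states = sort(hit)[1], labels = list()))
  }
  tr <- g$transitions
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(allowed)) keep <- keep & tr$from %in% allowed & tr$to %in% allowed
  if (!is.null(drop_label)) {
    keep <- keep & !vapply(tr$labels, function(ls) drop_label %in% ls, logical(1))
  }
  tr <- tr[keep, , drop = FALSE]
  adj <- split(seq_len(nrow(tr)), tr$from)
  parent <- stats::setNames(rep(NA_character_, length(from)), from)
  parent_edge <- list()
  queue <- from
  while (length(queue) > 0L) {
    cur <- queue[[1]]; queue <- queue[-1]
    idx <- adj[[cur]]
    if (is.null(idx)) next
    idx <- idx[order(tr$to[idx])]
    for (i in idx) {
      nxt <- tr$to[i]
      if (!nxt %in% names(parent)) {
        parent[nxt] <- cur
        parent_edge[[nxt]] <- tr$labels[[i]]
        if (nxt %in% targets) {
          states <- nxt; labels <- list()
          while (!is.na(parent[[states[1]]])) {
            labels <- c(list(parent_edge[[states[1]]]), labels)
            states <- c(parent[[states[1]]], states)
          }
          return(list(states = states, labels = labels))
        }
        queue <- c(queue, nxt)
      }
    }
  }
  NULL
}

# keys reachable from `from` within `allowed` (NULL = all), including from
reachable_keys <- function(g, from, allowed = NULL) {
  if (!is.null(allowed)) from <- intersect(from, allowed)
  tr <- g$transitions
  if (!is.null(allowed)) {
    tr <- tr[tr$from %in% allowed & tr$to %in% allowed, , drop = FALSE]
  }
  adj <- split(tr$to, tr$from)
  seen <- from
  queue <- from
  while (length(queue) > 0L) {
    cur <- queue[[1]]; queue <- queue[-1]
    nxt <- setdiff(adj[[cur]], seen)
    seen <- c(seen, nxt)
    queue <- c(queue, nxt)
  }
  sort(seen)
}

# Does a maximal (possibly infinite) run avoiding the complement of
# `allowed` exist from some state in `within`? A run is maximal when it
# ends in a full-STG deadlock or can cycle forever. Returns NULL or a
# witness list(states, labels, loop_to) where loop_to (if non-NA) is the
# index the final step returns to (lasso).
avoiding_run <- function(g, from, allowed) {
  reach <- reachable_keys(g, from, allowed)
  if (length(reach) == 0L) return(NULL)
  dls <- intersect(deadlock_states(g), reach)
  if (length(dls) > 0L) {
    w <- shortest_path(g, from, dls, allowed = allowed)
    w$loop_to <- NA_integer_
    return(w)
  }
  # look for a cycle inside the restricted reachable sub-graph
  tr <- g$transitions
  tr <- tr[tr$from %in% reach & tr$to %in% reach, , drop = FALSE]
  if (nrow(tr) == 0L) return(NULL)
  ig <- igraph::graph_from_data_frame(
    tr[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = reach, stringsAsFactors = FALSE))
  memb <- igraph::components(ig, mode = "strong")$membership
  sizes <- table(memb)
  cyc_states <- sort(names(memb)[memb %in% as.integer(names(sizes)[sizes > 1L])])
  if (length(cyc_states) == 0L) return(NULL)
  entry <- shortest_path(g, from, cyc_states, allowed = allowed)
  anchor <- entry$states[length(entry$states)]
  scc <- sort(names(memb)[memb == memb[[anchor]]])
  # one loop: anchor -> successor in SCC -> ... -> anchor
  succ_idx <- which(tr$from == anchor & tr$to %in% scc)
  first <- tr$to[succ_idx][order(tr$to[succ_idx])][1]
  back <- shortest_path(g, first, anchor, allowed = scc)
  loop_states <- c(anchor, back$states)
  loop_labels <- c(tr$labels[succ_idx][order(tr$to[succ_idx])][1], back$labels)
  list(
    states = c(entry$states, loop_states[-1]),
    labels = c(entry$labels, loop_labels),
    loop_to = length(entry$states)
  )
}

query_result <- function(verdict, pattern, g, witness = NULL, note = NULL) {
  structure(list(verdict = verdict, pattern = pattern, witness = witness,
                 note = note, stg = g),
            class = "eden_query_result")
}

#' @export
print.eden_query_result <- function(x, ...) {
  cat(sprintf("query '%s': %s\n", x$pattern, if (x$verdict) "TRUE" else "FALSE"))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  if (!is.null(x$witness)) {
    m <- x$stg$model
    steps <- vapply(x$witness$states,
                    function(k) format_state(m, x$stg$states[[k]]), character(1))
    cat("  witness:", paste(steps, collapse = " -> "))
    if (!is.null(x$witness$loop_to) && !is.na(x$witness$loop_to)) {
      cat(sprintf(" (loops back to step %d)", x$witness$loop_to))
    }
    cat("\n")
  }
  invisible(x)
}

# -- the query patterns ------------------------------------------------------

#' Is a state satisfying the predicate reachable?
#'
#' True when some reachable state satisfies `p`; the witness is a shortest
#' path from an initial state to such a state (length 0 when an initial
#' state itself satisfies `p`).
#'
#' @param g an `eden_stg`.
#' @param p an `eden_predicate` or expression string (see
#'   [parse_predicate()]).
#' @return an `eden_query_result`.
#' @export
query_reachable <- function(g, p) {
  p <- as_predicate(p, g$model)
  targets <- pred_keys(g, p)
  if (length(targets) == 0L) return(query_result(FALSE, "reachable", g))
  w <- shortest_path(g, g$initial, targets)
  query_result(!is.null(w), "reachable", g, witness = w)
}

#' Does the predicate hold in every reachable state?
#'
#' The witness, when the verdict is false, is a shortest path to a
#' violating state. Dual of [query_reachable()]: `invariantly(p)` equals
#' `not reachable(not p)`.
#'
#' @inheritParams query_reachable
#' @return an `eden_query_result`.
#' @export
query_invariantly <- function(g, p) {
  p <- as_predicate(p, g$model)
  bad <- setdiff(names(g$states), pred_keys(g, p))
  if (length(bad) == 0L) return(query_result(TRUE, "invariantly", g))
  w <- shortest_path(g, g$initial, bad)
  query_result(FALSE, "invariantly", g, witness = w,
               note = "a reachable state violates the predicate")
}

#' Can the system forever avoid the predicate?
#'
#' True when some maximal trajectory from an initial state never enters a
#' `p`-state: it reaches a deadlock outside `p`, or can cycle forever
#' outside `p`. The witness is such a trajectory (a lasso when it cycles).
#' This is the "is a collapse avoidable?" pattern with `p` describing the
#' collapse.
#'
#' @inheritParams query_reachable
#' @return an `eden_query_result`.
#' @export
query_avoidable <- function(g, p) {
  p <- as_predicate(p, g$model)
  allowed <- setdiff(names(g$states), pred_keys(g, p))
  w <- avoiding_run(g, g$initial, allowed)
  query_result(!is.null(w), "avoidable", g, witness = w)
}

#' Is the predicate stable — does the system settle inside it?
#'
#' True when some reachable terminal component (a deadlock or a terminal
#' SCC) lies entirely within `p`: once entered, the system stays in
#' `p`-states forever. The witness is a shortest path to that component.
#'
#' @inheritParams query_reachable
#' @return an `eden_query_result`.
#' @export
query_stable <- function(g, p) {
  p <- as_predicate(p, g$model)
  topo <- classify_components(g)
  good <- pred_keys(g, p)
  for (co in topo$components) {
    if (co$terminal && all(co$members %in% good)) {
      w <- shortest_path(g, g$initial, co$members)
      return(query_result(TRUE, "stable", g, witness = w,
                          note = paste0("terminal component ", co$id,
                                        " lies within the predicate")))
    }
  }
  query_result(FALSE, "stable", g,
               note = "no reachable terminal component lies within the predicate")
}

#' Is an event a necessary condition for an outcome?
#'
#' True when every path from an initial state to a state satisfying `p`
#' contains a transition fired by rule `label`. Vacuously true when no
#' `p`-state is reachable; false with an empty-path counterexample when an
#' initial state already satisfies `p`. Evaluated over histories from the
#' initial states, matching the historical-explanation reading: "without
#' this event, the outcome cannot have happened".
#'
#' @inheritParams query_reachable
#' @param label a rule label of the model.
#' @return an `eden_query_result`; the witness of a false verdict is a
#'   path reaching `p` without the event.
#' @export
query_event_necessary <- function(g, label, p) {
  if (!label %in% rule_labels(g$model)) {
    stop("unknown rule label: ", label, call. = FALSE)
  }
  p <- as_predicate(p, g$model)
  targets <- pred_keys(g, p)
  if (length(targets) == 0L) {
    return(query_result(TRUE, "event_necessary", g,
                        note = "vacuous: the outcome is unreachable"))
  }
  w <- shortest_path(g, g$initial, targets, drop_label = label)
  if (is.null(w)) {
    return(query_result(TRUE, "event_necessary", g))
  }
  query_result(FALSE, "event_necessary", g, witness = w,
               note = paste0("the outcome is reachable without rule ", label))
}

#' Is an event a sufficient condition for an outcome?
#'
#' True when every maximal path from an initial state that contains a
#' transition fired by rule `label` reaches a state satisfying `p` at some
#' point. A false verdict carries a counterexample: a maximal path through
#' the event that never meets `p` (ending in a deadlock, or lasso-shaped
#' when it can cycle outside `p` forever).
#'
#' @inheritParams query_event_necessary
#' @return an `eden_query_result`.
#' @export
query_event_sufficient <- function(g, label, p) {
  if (!label %in% rule_labels(g$model)) {
    stop("unknown rule label: ", label, call. = FALSE)
  }
  p <- as_predicate(p, g$model)
  allowed <- setdiff(names(g$states), pred_keys(g, p))
  # p-avoiding prefix closure from the initial states
  pre <- reachable_keys(g, g$initial, allowed)
  tr <- g$transitions
  has_label <- vapply(tr$labels, function(ls) label %in% ls, logical(1))
  cand <- which(has_label & tr$from %in% pre & tr$to %in% allowed)
  cand <- cand[order(tr$from[cand], tr$to[cand])]
  for (i in cand) {
    cont <- avoiding_run(g, tr$to[i], allowed)
    if (!is.null(cont)) {
      prefix <- shortest_path(g, g$initial, tr$from[i], allowed = allowed)
      states <- c(prefix$states, tr$to[i], cont$states[-1])
      labels <- c(prefix$labels, tr$labels[i], cont$labels)
      loop_to <- if (is.na(cont$loop_to)) NA_integer_ else
        length(prefix$states) + cont$loop_to
      return(query_result(FALSE, "event_sufficient", g,
                          witness = list(states = states, labels = labels,
                                         loop_to = loop_to),
                          note = paste0("a maximal path fires rule ", label,
                                        " yet never reaches the outcome")))
    }
  }
  query_result(TRUE, "event_sufficient", g)
}

# re-validate a witness as an actual labeled path of g (used by tests)
witness_is_valid <- function(g, w) {
  if (is.null(w)) return(FALSE)
  st <- w$states
  if (!all(st %in% names(g$states))) return(FALSE)
  if (length(st) == 1L) return(length(w$labels) == 0L)
  if (length(w$labels) != length(st) - 1L) return(FALSE)
  for (i in seq_len(length(st) - 1L)) {
    hit <- g$transitions$from == st[i] & g$transitions$to == st[i + 1L]
    if (!any(hit)) return(FALSE)
    if (!all(w$labels[[i]] %in% g$transitions$labels[which(hit)[1]][[1]])) {
      return(FALSE)
    }
  }
  if (!is.null(w$loop_to) && !is.na(w$loop_to)) {
    anchor <- st[w$loop_to]
    if (!any(g$transitions$from == st[length(st)] &
             g$transitions$to == anchor) && st[length(st)] != anchor) {
      return(FALSE)
    }
  }
  TRUE
}
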