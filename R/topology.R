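# Topological reading of a state-transition graph:
#   deadlock    — single state with no successor (stable state)
#   cyclic SCC  — non-trivial strongly connected component whose induced
#                 sub-graph is a single directed cycle (discrete analogue
#                 of a limit cycle)
#   complex SCC — non-trivial SCC with branching internal structure
#   basin       — transient states outside all of the above that share the
#                 same set of reachable terminal components; "strong" when
#                 that set is a single attractor
# The hierarchical transition graph (HTG) condenses these components; its
# edges are the irreversible crossings between them, and it is acyclic by
# construction.

stg_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$transitions[, c("from", "to"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = names(g$states), stringsAsFactors = FALSE)
  )
}

#' Strongly connected components of an STG
#'
#' An SCC is a maximal set of mutually reachable states: any change within
#' it is reversible. Singleton states without internal structure are
#' reported as trivial components.
#'
#' @param g an `eden_stg`.
#' @return a list of character vectors of state keys (members, sorted),
#'   ordered by smallest member; attribute-free, with non-trivial
#'   components flagged via the `nontrivial` attribute on the list.
#' @export
find_sccs <- function(g) {
  memb <- igraph::components(stg_igraph(g), mode = "strong")$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, function(x) sort(unname(x)))
  ord <- order(vapply(comps, `[[`, character(1), 1L))
  comps <- unname(comps[ord])
  attr(comps, "nontrivial") <- vapply(comps, length, integer(1)) > 1L
  comps
}

scc_is_cyclic <- function(g, members) {
  sub <- g$transitions[g$transitions$from %in% members &
                         g$transitions$to %in% members, , drop = FALSE]
  outd <- table(factor(sub$from, levels = members))
  ind <- table(factor(sub$to, levels = members))
  all(outd == 1L) && all(ind == 1L)
}

#' Classify every state of an STG into a topological component
#'
#' Deadlocks and non-trivial SCCs are the persistent structures; all
#' remaining (transient) states are grouped into basins keyed by the exact
#' set of terminal components (deadlocks and terminal SCCs) they can
#' reach. A basin whose key is a single attractor is flagged strong: its
#' fate is determined even though its states are transient.
#'
#' @param g an `eden_stg`.
#' @return an object of class `eden_topology`: list with `components`
#'   (each `list(id, kind, members, attractor_key, strong, terminal)`,
#'   sorted by kind then smallest member), `state_component` (named map
#'   from state key to component id), `terminal_ids`, and the `stg`.
#' @export
classify_components <- function(g) {
  keys <- names(g$states)
  ig <- stg_igraph(g)
  memb <- igraph::components(ig, mode = "strong")$membership[keys]
  scc_members <- lapply(split(keys, memb), sort)
  scc_ids <- names(scc_members)
  # condensation edges between distinct SCCs
  efrom <- as.character(memb[g$transitions$from])
  eto <- as.character(memb[g$transitions$to])
  cross <- efrom != eto
  cond_edges <- unique(data.frame(from = efrom[cross], to = eto[cross],
                                  stringsAsFactors = FALSE))
  has_out <- scc_ids %in% cond_edges$from
  names(has_out) <- scc_ids
  sizes <- vapply(scc_members, length, integer(1))
  is_terminal_scc <- !has_out  # deadlocks and terminal SCCs alike

  # Persistent structures: deadlocks and non-trivial SCCs (terminal or not).
  # Reachable-set DP in reverse topological order over the condensation:
  # reach_term = reachable terminal components (the attractor key);
  # reach_pers = reachable persistent structures. Basins are grouped by
  # reach_pers, not reach_term alone: grouping by the terminal set only can
  # put states on both sides of a non-terminal SCC into one basin and
  # create a cycle in the condensed graph, while the persistent signature
  # provably cannot (an edge into an SCC a same-signature state also
  # reaches would make that state part of the SCC).
  is_persistent <- sizes > 1L | !has_out
  names(is_persistent) <- scc_ids
  reach_term <- stats::setNames(vector("list", length(scc_ids)), scc_ids)
  reach_pers <- reach_term
  if (length(scc_ids) > 0L) {
    cond_ig <- igraph::graph_from_data_frame(
      cond_edges, directed = TRUE,
      vertices = data.frame(name = scc_ids, stringsAsFactors = FALSE))
    topo <- igraph::topo_sort(cond_ig, mode = "out")$name
    for (sid in rev(topo)) {
      succ <- cond_edges$to[cond_edges$from == sid]
      acc_t <- unlist(reach_term[succ], use.names = FALSE)
      acc_p <- unlist(reach_pers[succ], use.names = FALSE)
      if (is_terminal_scc[[sid]]) acc_t <- c(acc_t, sid)
      if (is_persistent[[sid]]) acc_p <- c(acc_p, sid)
      reach_term[[sid]] <- sort(unique(acc_t))
      reach_pers[[sid]] <- sort(unique(acc_p))
    }
  }

  comps <- list()
  basin_states <- list()  # attractor key string -> keys
  basin_attr <- list()
  for (sid in scc_ids) {
    mem <- scc_members[[sid]]
    if (sizes[[sid]] > 1L) {
      kind <- if (scc_is_cyclic(g, mem)) "cyclic_scc" else "complex_scc"
      comps[[length(comps) + 1L]] <- list(
        kind = kind, members = mem, scc = sid,
        attractor_scc = character(0), terminal = !has_out[[sid]])
    } else if (!has_out[[sid]]) {
      comps[[length(comps) + 1L]] <- list(
        kind = "deadlock", members = mem, scc = sid,
        attractor_scc = character(0), terminal = TRUE)
    } else {
      akey <- paste(reach_pers[[sid]], collapse = "|")
      basin_states[[akey]] <- c(basin_states[[akey]], mem)
      basin_attr[[akey]] <- reach_term[[sid]]
    }
  }
  for (akey in names(basin_states)) {
    comps[[length(comps) + 1L]] <- list(
      kind = "basin", members = sort(basin_states[[akey]]), scc = NA_character_,
      attractor_scc = basin_attr[[akey]], terminal = FALSE)
  }

  kind_rank <- c(deadlock = 1L, cyclic_scc = 2L, complex_scc = 3L, basin = 4L)
  firsts <- vapply(comps, function(co) co$members[[1]], character(1))
  comps <- comps[order(kind_rank[vapply(comps, `[[`, character(1), "kind")], firsts)]

  ids <- vapply(comps, function(co) paste0(co$kind, ":", co$members[[1]]),
                character(1))
  scc_to_id <- stats::setNames(
    ids[!vapply(comps, function(co) is.na(co$scc), logical(1))],
    vapply(comps[!vapply(comps, function(co) is.na(co$scc), logical(1))],
           `[[`, character(1), "scc"))
  components <- vector("list", length(comps))
  state_component <- character(0)
  for (i in seq_along(comps)) {
    co <- comps[[i]]
    akey <- if (co$kind == "basin") sort(unname(scc_to_id[co$attractor_scc]))
            else character(0)
    components[[i]] <- list(
      id = ids[[i]], kind = co$kind, members = co$members,
      attractor_key = akey,
      strong = co$kind == "basin" && length(akey) == 1L,
      terminal = co$terminal
    )
    state_component[co$members] <- ids[[i]]
  }
  structure(list(
    components = components,
    state_component = state_component[keys],
    terminal_ids = ids[vapply(components, `[[`, logical(1), "terminal")],
    stg = g
  ), class = "eden_topology")
}

#' @export
print.eden_topology <- function(x, ...) {
  m <- x$stg$model
  fmt_set <- function(keys) {
    paste0("{", paste(vapply(keys, function(k) format_state(m, x$stg$states[[k]]),
                             character(1)), collapse = "; "), "}")
  }
  cat(sprintf("Topology of %s STG: %d states in %d components\n",
              x$stg$mode, length(x$stg$states), length(x$components)))
  for (co in x$components) {
    extra <- if (co$kind == "basin") {
      paste0(if (co$strong) " (strong)" else "",
             " -> attractors: ", paste(co$attractor_key, collapse = ", "))
    } else if (co$terminal) " (terminal)" else ""
    cat(sprintf("  %s %s%s\n", co$kind, fmt_set(co$members), extra))
  }
  invisible(x)
}

#' Build the hierarchical transition graph
#'
#' Condenses the STG onto its topological components. There is an edge
#' between two components exactly when some state-level transition crosses
#' from one to the other; every such crossing is irreversible, so the HTG
#' is acyclic (asserted on every build).
#'
#' @param g an `eden_stg`, or an `eden_topology` already computed from one.
#' @return an object of class `eden_htg`: list with `nodes` (component
#'   ids), `edges` (data frame `from`, `to`), and the `topology`.
#' @export
build_htg <- function(g) {
  topo <- if (inherits(g, "eden_topology")) g else classify_components(g)
  stg <- topo$stg
  cf <- topo$state_component[stg$transitions$from]
  ct <- topo$state_component[stg$transitions$to]
  cross <- cf != ct
  edges <- unique(data.frame(from = unname(cf[cross]), to = unname(ct[cross]),
                             stringsAsFactors = FALSE))
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- vapply(topo$components, `[[`, character(1), "id")
  if (nrow(edges) > 0L) {
    ig <- igraph::graph_from_data_frame(
      edges, directed = TRUE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    if (!igraph::is_dag(ig)) {
      stop("internal error: hierarchical transition graph contains a cycle",
           call. = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges, topology = topo),
            class = "eden_htg")
}

#' @export
print.eden_htg <- function(x, ...) {
  cat(sprintf("Hierarchical transition graph: %d components, %d irreversible transitions\n",
              length(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s -> %s\n", x$edges$from[i], x$edges$to[i]))
  }
  invisible(x)
}

#' Enumerate alternative trajectories
#'
#' A trajectory is a maximal simple path starting from the initial
#' state(s). On an acyclic STG trajectories are enumerated at state level
#' (each ends in a deadlock) with the rule labels of every step; when the
#' STG contains cycles they are enumerated on the hierarchical transition
#' graph, which is finite and acyclic, as sequences of components.
#'
#' @param g an `eden_stg`.
#' @param max_trajectories abort with an explicit error beyond this count.
#' @return an object of class `eden_trajectories`: list with `count`,
#'   `level` (`"state"` or `"component"`), and `trajectories` (each a
#'   `list(states, labels)` or `list(components)`), in deterministic order.
#' @export
count_trajectories <- function(g, max_trajectories = 10000) {
  topo <- classify_components(g)
  nontrivial <- any(vapply(topo$components, function(co)
    co$kind %in% c("cyclic_scc", "complex_scc"), logical(1)))
  if (!nontrivial) {
    adj <- split(seq_len(nrow(g$transitions)), g$transitions$from)
    trajs <- list()
    walk <- function(key, states, labels) {
      idx <- adj[[key]]
      if (is.null(idx)) {
        if (length(trajs) >= max_trajectories) {
          stop(sprintf("more than max_trajectories = %d trajectories: enumeration aborted",
                       as.integer(max_trajectories)), call. = FALSE)
        }
        trajs[[length(trajs) + 1L]] <<- list(states = states, labels = labels)
        return(invisible())
      }
      idx <- idx[order(g$transitions$to[idx])]
      for (i in idx) {
        walk(g$transitions$to[i], c(states, g$transitions$to[i]),
             c(labels, g$transitions$labels[i]))
      }
    }
    for (k in g$initial) walk(k, k, list())
    return(structure(list(count = length(trajs), level = "state",
                          trajectories = trajs, stg = g),
                     class = "eden_trajectories"))
  }
  htg <- build_htg(topo)
  adj <- split(htg$edges$to, htg$edges$from)
  adj <- lapply(adj, sort)
  starts <- sort(unique(unname(topo$state_component[g$initial])))
  trajs <- list()
  walk <- function(id, path) {
    succ <- adj[[id]]
    if (is.null(succ) || length(succ) == 0L) {
      if (length(trajs) >= max_trajectories) {
        stop(sprintf("more than max_trajectories = %d trajectories: enumeration aborted",
                     as.integer(max_trajectories)), call. = FALSE)
      }
      trajs[[length(trajs) + 1L]] <<- list(components = path)
      return(invisible())
    }
    for (nx in succ) walk(nx, c(path, nx))
  }
  for (s in starts) walk(s, s)
  structure(list(count = length(trajs), level = "component",
                 trajectories = trajs, stg = g),
            class = "eden_trajectories")
}

#' @export
print.eden_trajectories <- function(x, ...) {
  cat(sprintf("%d alternative trajectories (%s level)\n", x$count, x$level))
  m <- x$stg$model
  for (tr in x$trajectories) {
    if (x$level == "state") {
      steps <- vapply(tr$states, function(k) format_state(m, x$stg$states[[k]]),
                      character(1))
      cat(" ", paste(steps, collapse = " -> "), "\n")
    } else {
      cat(" ", paste(tr$components, collapse = " -> "), "\n")
    }
  }
  invisible(x)
}
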