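# Brute-force oracles, written independently of the engine: they evaluate
# rules by direct enumeration over the full state space and never call
# build_stg()/successors(). Used to cross-check the engine on small models.

oracle_all_states <- function(m) {
  doms <- lapply(m$variables$max_level, function(k) 0:k)
  names(doms) <- m$variables$name
  grid <- do.call(expand.grid, c(doms, KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) {
    s <- as.integer(grid[i, ])
    names(s) <- m$variables$name
    s
  })
}

oracle_key <- function(s) paste(unname(s), collapse = ",")

oracle_cond_holds <- function(rule, s) {
  ok <- TRUE
  for (i in seq_len(nrow(rule$condition))) {
    v <- s[[rule$condition$variable[i]]]
    k <- rule$condition$level[i]
    ok <- ok && switch(rule$condition$op[i],
      ">=" = v >= k, ">" = v > k, "<=" = v <= k, "<" = v < k, "=" = v == k)
  }
  ok
}

oracle_apply <- function(rule, s) {
  for (i in seq_len(nrow(rule$realization))) {
    s[[rule$realization$variable[i]]] <- rule$realization$level[i]
  }
  s
}

oracle_enabled <- function(m, s) {
  labs <- character(0)
  for (r in m$rules) {
    if (oracle_cond_holds(r, s) && !identical(oracle_apply(r, s), s)) {
      labs <- c(labs, r$label)
    }
  }
  sort(labs)
}

# successors of one state as a named list target_key -> sorted labels;
# synchronous conflicts reported as attr(result, "conflict") = TRUE
oracle_successors <- function(m, s, mode) {
  en <- oracle_enabled(m, s)
  out <- list()
  if (length(en) == 0L) return(out)
  if (mode == "asynchronous") {
    for (lab in en) {
      r <- Filter(function(x) x$label == lab, m$rules)[[1]]
      k <- oracle_key(oracle_apply(r, s))
      out[[k]] <- sort(c(out[[k]], lab))
    }
    return(out)
  }
  assigned <- list()
  t <- s
  for (lab in en) {
    r <- Filter(function(x) x$label == lab, m$rules)[[1]]
    for (i in seq_len(nrow(r$realization))) {
      v <- r$realization$variable[i]; lev <- r$realization$level[i]
      if (!is.null(assigned[[v]]) && assigned[[v]] != lev) {
        res <- list()
        attr(res, "conflict") <- TRUE
        return(res)
      }
      assigned[[v]] <- lev
      t[[v]] <- lev
    }
  }
  if (!identical(t, s)) out[[oracle_key(t)]] <- en
  out
}

# reachable sub-graph of the full transition relation, by naive BFS over
# the 2^n enumeration; returns list(states, edges) with edges as strings
# "from|to|lab1,lab2", or list(conflict_state = key) when a reachable
# state has a synchronous write conflict
oracle_reachable_graph <- function(m, mode) {
  all_states <- oracle_all_states(m)
  names(all_states) <- vapply(all_states, oracle_key, character(1))
  init <- sort(unique(vapply(m$initial, oracle_key, character(1))))
  seen <- init
  queue <- init
  edges <- character(0)
  while (length(queue) > 0L) {
    k <- queue[[1]]; queue <- queue[-1]
    succ <- oracle_successors(m, all_states[[k]], mode)
    if (isTRUE(attr(succ, "conflict"))) {
      return(list(conflict_state = k))
    }
    for (tk in names(succ)) {
      edges <- c(edges, paste0(k, "|", tk, "|",
                               paste(succ[[tk]], collapse = ",")))
      if (!tk %in% seen) {
        seen <- c(seen, tk)
        queue <- c(queue, tk)
      }
    }
  }
  list(states = sort(seen), edges = sort(unique(edges)))
}

stg_as_sets <- function(g) {
  edges <- if (nrow(g$transitions) == 0L) character(0) else {
    labs <- vapply(g$transitions$labels, paste, character(1), collapse = ",")
    paste0(g$transitions$from, "|", g$transitions$to, "|", labs)
  }
  list(states = sort(names(g$states)), edges = sort(edges))
}

# pairwise reachability by iterated squaring of the Boolean adjacency
# matrix (states reach themselves); independent of igraph
oracle_reach_matrix <- function(g) {
  keys <- names(g$states)
  n <- length(keys)
  reach <- diag(TRUE, n)
  dimnames(reach) <- list(keys, keys)
  for (i in seq_len(nrow(g$transitions))) {
    reach[g$transitions$from[i], g$transitions$to[i]] <- TRUE
  }
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# SCCs as sorted member lists from the pairwise-reachability oracle
oracle_sccs <- function(g) {
  reach <- oracle_reach_matrix(g)
  mutual <- reach & t(reach)
  keys <- rownames(mutual)
  comps <- unique(lapply(keys, function(k) sort(keys[mutual[k, ]])))
  comps[order(vapply(comps, `[[`, character(1), 1L))]
}

# per-state set of reachable deadlock keys (brute force)
oracle_reachable_deadlocks <- function(g) {
  reach <- oracle_reach_matrix(g)
  dls <- setdiff(rownames(reach), unique(g$transitions$from))
  lapply(stats::setNames(rownames(reach), rownames(reach)),
         function(k) sort(dls[reach[k, dls]]))
}

# state from a compact spec like c(A=1,P=1,T=1)
st <- function(...) {
  v <- c(...)
  stats::setNames(as.integer(v), names(v))
}
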