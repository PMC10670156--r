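# Graph exports: GraphML and DOT via igraph, plus a plain TSV edge list.
# Node attribute = readable state string; edge attribute = comma-joined
# sorted rule labels. All outputs are byte-identical across reruns.

stg_igraph_attr <- function(g, ascii = FALSE) {
  labs <- vapply(g$states, function(s) format_state(g$model, s, ascii),
                 character(1))
  ig <- igraph::graph_from_data_frame(
    g$transitions[, c("from", "to"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = names(g$states), state = unname(labs),
                          stringsAsFactors = FALSE)
  )
  if (nrow(g$transitions) > 0L) {
    igraph::E(ig)$labels <- vapply(g$transitions$labels, paste,
                                   character(1), collapse = ",")
  }
  ig
}

#' Export a state-transition graph
#'
#' @param g an `eden_stg`.
#' @param path output file path.
#' @param ascii render the empty Boolean state as `-` instead of `∅`.
#' @return `path`, invisibly.
#' @name stg-export
NULL

#' @rdname stg-export
#' @export
write_stg_graphml <- function(g, path, ascii = FALSE) {
  igraph::write_graph(stg_igraph_attr(g, ascii), path, format = "graphml")
  invisible(path)
}

#' @rdname stg-export
#' @export
write_stg_dot <- function(g, path, ascii = TRUE) {
  igraph::write_graph(stg_igraph_attr(g, ascii), path, format = "dot")
  invisible(path)
}

#' @rdname stg-export
#' @export
write_stg_tsv <- function(g, path, ascii = FALSE) {
  labs <- vapply(g$states, function(s) format_state(g$model, s, ascii),
                 character(1))
  df <- data.frame(
    source = unname(labs[g$transitions$from]),
    target = unname(labs[g$transitions$to]),
    labels = vapply(g$transitions$labels, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a topology summary as JSON
#'
#' Components with kind, members (readable state strings), attractor key
#' and strong flag, in deterministic order.
#'
#' @param topo an `eden_topology`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @param ascii see [write_stg_graphml()].
#' @return JSON string (invisibly when written to `path`).
#' @export
topology_to_json <- function(topo, path = NULL, ascii = FALSE) {
  m <- topo$stg$model
  obj <- list(
    mode = topo$stg$mode,
    n_states = length(topo$stg$states),
    components = lapply(topo$components, function(co) {
      list(
        id = co$id, kind = co$kind,
        members = unname(vapply(co$members, function(k)
          format_state(m, topo$stg$states[[k]], ascii), character(1))),
        attractor_key = co$attractor_key,
        strong = co$strong, terminal = co$terminal
      )
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

htg_igraph <- function(htg) {
  igraph::graph_from_data_frame(
    htg$edges, directed = TRUE,
    vertices = data.frame(name = htg$nodes, stringsAsFactors = FALSE))
}

#' Export a hierarchical transition graph
#' @param htg an `eden_htg`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_htg_graphml <- function(htg, path) {
  igraph::write_graph(htg_igraph(htg), path, format = "graphml")
  invisible(path)
}

#' @rdname write_htg_graphml
#' @export
write_htg_dot <- function(htg, path) {
  igraph::write_graph(htg_igraph(htg), path, format = "dot")
  invisible(path)
}
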