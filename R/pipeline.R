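# End-to-end pipeline: parse/validate -> build STG -> topology -> HTG ->
# trajectories -> exports + text summary. Deterministic: identical config
# gives byte-identical outputs (everything sorted, no timestamps in any
# export).

#' Pipeline configuration
#'
#' @param model an `eden_model` or a path to a model file.
#' @param mode update mode, `"asynchronous"` (default) or `"synchronous"`.
#' @param max_states explicit abort threshold for state-space exploration
#'   (default 1e6; exceeding it is an error, never silent truncation).
#' @param max_trajectories abort threshold for trajectory enumeration.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   file exports and only return the in-memory bundle.
#' @param formats subset of `c("graphml", "dot", "tsv", "json")`.
#' @param ascii use ASCII state rendering in exports and the summary.
#' @param on_conflict synchronous write-conflict policy, see
#'   [successors()].
#' @return a `run_config` list.
#' @export
run_config <- function(model, mode = c("asynchronous", "synchronous"),
                       max_states = 1e6, max_trajectories = 10000,
                       out_dir = NULL,
                       formats = c("graphml", "dot", "tsv", "json"),
                       ascii = FALSE,
                       on_conflict = c("error", "branch")) {
  structure(list(
    model = model, mode = match.arg(mode),
    max_states = max_states, max_trajectories = max_trajectories,
    out_dir = out_dir,
    formats = match.arg(formats, several.ok = TRUE),
    ascii = ascii, on_conflict = match.arg(on_conflict)
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Builds the state-transition graph, classifies its topology, condenses
#' it into the hierarchical transition graph, enumerates trajectories,
#' writes the requested exports and a plain-text summary.
#'
#' @param cfg a [run_config()], or anything accepted as its `model`
#'   argument (then with default settings).
#' @param ... passed to [run_config()] when `cfg` is a model.
#' @return invisibly, a bundle list with `model`, `stg`, `topology`,
#'   `htg`, `trajectories`, `summary` (character vector of report lines)
#'   and `files` (paths written).
#' @examples
#' b <- run_pipeline(apt_model())
#' cat(b$summary, sep = "\n")
#' @export
run_pipeline <- function(cfg, ...) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg, ...)
  m <- cfg$model
  if (is.character(m)) m <- read_model(m)
  diags <- validate_model(m)
  if (length(diags) > 0L) {
    stop("invalid model:\n  ", paste(diags, collapse = "\n  "), call. = FALSE)
  }
  g <- build_stg(m, cfg$mode, max_states = cfg$max_states,
                 on_conflict = cfg$on_conflict)
  topo <- classify_components(g)
  htg <- build_htg(topo)
  trajs <- count_trajectories(g, max_trajectories = cfg$max_trajectories)
  summary <- pipeline_summary(g, topo, htg, trajs, ascii = cfg$ascii)

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(name) file.path(cfg$out_dir, name)
    if ("graphml" %in% cfg$formats) {
      files <- c(files, write_stg_graphml(g, p("stg.graphml"), cfg$ascii),
                 write_htg_graphml(htg, p("htg.graphml")))
    }
    if ("dot" %in% cfg$formats) {
      files <- c(files, write_stg_dot(g, p("stg.dot")),
                 write_htg_dot(htg, p("htg.dot")))
    }
    if ("tsv" %in% cfg$formats) {
      files <- c(files, write_stg_tsv(g, p("stg_edges.tsv"), cfg$ascii))
    }
    if ("json" %in% cfg$formats) {
      topology_to_json(topo, p("topology.json"), cfg$ascii)
      files <- c(files, p("topology.json"))
      writeLines(model_to_json(m), p("model.json"), useBytes = TRUE)
      files <- c(files, p("model.json"))
    }
    writeLines(summary, p("summary.txt"), useBytes = TRUE)
    files <- c(files, p("summary.txt"))
  }
  invisible(list(model = m, stg = g, topology = topo, htg = htg,
                 trajectories = trajs, summary = summary, files = files))
}

pipeline_summary <- function(g, topo, htg, trajs, ascii = FALSE) {
  m <- g$model
  fs <- function(k) format_state(m, g$states[[k]], ascii)
  set_str <- function(keys) {
    paste0("{", paste(vapply(keys, fs, character(1)), collapse = "; "), "}")
  }
  dl <- deadlock_states(g)
  lines <- c(
    sprintf("model: %d variables, %d rules (%s)", nrow(m$variables),
            length(m$rules),
            if (is_boolean_model(m)) "Boolean" else "multivalued"),
    sprintf("update mode: %s", g$mode),
    sprintf("states: %d  transitions: %d", length(g$states),
            nrow(g$transitions)),
    sprintf("deadlocks (stable states): %d%s", length(dl),
            if (length(dl) > 0L)
              paste0("  ", paste(vapply(dl, fs, character(1)), collapse = ", "))
            else ""),
    sprintf("transient (non-deadlock) states: %d",
            length(g$states) - length(dl))
  )
  for (co in topo$components) {
    if (co$kind == "deadlock") next
    tag <- switch(co$kind,
      cyclic_scc = "cyclic SCC",
      complex_scc = "complex SCC",
      basin = if (co$strong) "strong basin" else "basin")
    extra <- if (co$kind == "basin") {
      paste0(" -> ", paste(co$attractor_key, collapse = ", "))
    } else if (co$terminal) " (terminal)" else ""
    lines <- c(lines, sprintf("%s %s%s", tag, set_str(co$members), extra))
  }
  lines <- c(lines,
             sprintf("hierarchical transition graph: %d components, %d irreversible transitions",
                     length(htg$nodes), nrow(htg$edges)),
             sprintf("alternative trajectories (%s level): %d", trajs$level,
                     trajs$count))
  for (tr in trajs$trajectories) {
    lines <- c(lines, if (trajs$level == "state") {
      paste(" ", paste(vapply(tr$states, fs, character(1)), collapse = " -> "))
    } else {
      paste(" ", paste(tr$components, collapse = " -> "))
    })
  }
  lines
}
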