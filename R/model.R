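# An eden_model is a plain list:
#   variables: data.frame(name, max_level), sorted by name (canonical order)
#   rules:     list of rule objects, sorted by label; each rule is
#              list(label, condition = data.frame(variable, op, level),
#                   realization = data.frame(variable, level))
#   initial:   list of states; a state is a named integer vector covering
#              every variable, names in canonical (sorted) order
# All levels are integers 0..max_level; Boolean variables have max_level 1
# and "v+"/"v-" is sugar for "v = 1"/"v = 0".

#' Construct a qualitative rule-network model
#'
#' A model is a set of leveled variables, a set of labeled if-then rules and
#' one or more initial states. Each variable takes an integer level in
#' `0..max_level`; a variable with `max_level = 1` is Boolean
#' (absent/present). A rule fires when its condition (a conjunction of
#' threshold atoms) holds and its realization would change the state; the
#' realization then sets its target variables to new levels atomically.
#'
#' @param variables named integer vector: names are variable names, values
#'   the maximum level of each variable (1 for Boolean).
#' @param rules list of rules built with [eden_rule()].
#' @param initial a single state or a list of states. A state may be given
#'   partially as a named integer vector; unnamed variables default to 0.
#' @return an object of class `eden_model`.
#' @seealso [eden_rule()], [parse_model()], [validate_model()]
#' @examples
#' m <- eden_model(
#'   variables = c(M = 1, S = 1),
#'   rules = list(
#'     eden_rule("R1", condition = c(M = 1), realization = c(S = 1)),
#'     eden_rule("R2", condition = c(M = 0), realization = c(S = 0))
#'   ),
#'   initial = c(M = 1)
#' )
#' @export
eden_model <- function(variables, rules = list(), initial) {
  stopifnot(is.numeric(variables), !is.null(names(variables)))
  ord <- order(names(variables))
  vars <- data.frame(
    name = names(variables)[ord],
    max_level = as.integer(variables[ord]),
    stringsAsFactors = FALSE
  )
  rules <- lapply(rules, as_eden_rule)
  labs <- vapply(rules, function(r) r$label, character(1))
  rules <- rules[order(labs)]
  if (!is.list(initial) || !is.null(names(initial))) initial <- list(initial)
  initial <- lapply(initial, function(s) complete_state(s, vars))
  m <- structure(
    list(variables = vars, rules = rules, initial = initial),
    class = "eden_model"
  )
  diags <- validate_model(m)
  if (length(diags) > 0L) {
    stop("invalid model:\n  ", paste(diags, collapse = "\n  "), call. = FALSE)
  }
  m
}

#' Construct a single rule
#'
#' @param label rule label (e.g. `"R1"`), mandatory and unique in a model.
#' @param condition either a named integer vector (read as equality atoms;
#'   for Boolean variables `c(M = 1)` means "M present") or a data frame
#'   with columns `variable`, `op`, `level` where `op` is one of
#'   `>=`, `>`, `<=`, `<`, `=`.
#' @param realization named integer vector of target levels, at most one
#'   per variable; applied atomically when the rule fires.
#' @return an object of class `eden_rule`.
#' @export
eden_rule <- function(label, condition, realization) {
  if (is.numeric(condition) && !is.null(names(condition))) {
    condition <- data.frame(
      variable = names(condition), op = "=",
      level = as.integer(condition), stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(condition),
            all(c("variable", "op", "level") %in% names(condition)))
  stopifnot(is.numeric(realization), !is.null(names(realization)))
  r <- structure(list(
    label = as.character(label),
    condition = canon_atoms(condition),
    realization = data.frame(
      variable = names(realization)[order(names(realization))],
      level = as.integer(realization[order(names(realization))]),
      stringsAsFactors = FALSE
    )
  ), class = "eden_rule")
  r
}

as_eden_rule <- function(r) {
  if (inherits(r, "eden_rule")) return(r)
  stop("rules must be built with eden_rule()", call. = FALSE)
}

canon_atoms <- function(df) {
  df$variable <- as.character(df$variable)
  df$op <- as.character(df$op)
  df$level <- as.integer(df$level)
  df <- df[order(df$variable, df$op, df$level), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# complete a possibly partial named vector into a full canonical state
complete_state <- function(s, vars) {
  full <- stats::setNames(integer(nrow(vars)), vars$name)
  if (length(s) > 0L) {
    if (is.null(names(s)) || any(names(s) == "")) {
      stop("states must be named vectors of levels", call. = FALSE)
    }
    unknown <- setdiff(names(s), vars$name)
    if (length(unknown) > 0L) {
      stop("state refers to undeclared variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    full[names(s)] <- as.integer(s)
  }
  full
}

#' Validate a model against its structural invariants
#'
#' Checks every invariant the execution engine relies on: unique nonempty
#' variable names without whitespace, levels at least Boolean, unique rule
#' labels, nonempty conditions and realizations referencing declared
#' variables within their domains, no contradictory realization
#' (two levels for one variable), Boolean variables constrained via
#' equality atoms only, and initial states that are total in-domain
#' assignments. A model with an empty diagnostic list can be executed
#' without runtime domain errors.
#'
#' @param m an `eden_model` (possibly hand-assembled).
#' @return character vector of diagnostics; empty when the model is valid.
#' @export
validate_model <- function(m) {
  out <- character(0)
  say <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  vars <- m$variables
  if (any(vars$name == "" | grepl("\\s", vars$name))) {
    say("variable names must be nonempty and contain no whitespace")
  }
  if (anyDuplicated(vars$name)) {
    say("duplicate variable name(s): ",
        paste(unique(vars$name[duplicated(vars$name)]), collapse = ", "))
  }
  bad <- vars$name[vars$max_level < 1L]
  if (length(bad) > 0L) {
    say("variable(s) with maximum level < 1: ", paste(bad, collapse = ", "))
  }
  maxlev <- stats::setNames(vars$max_level, vars$name)
  labs <- vapply(m$rules, function(r) r$label, character(1))
  if (anyDuplicated(labs)) {
    say("duplicate rule label(s): ",
        paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  for (r in m$rules) {
    if (nrow(r$condition) == 0L) say("rule ", r$label, ": empty condition")
    if (nrow(r$realization) == 0L) say("rule ", r$label, ": empty realization")
    for (df in list(r$condition, r$realization)) {
      unk <- setdiff(df$variable, vars$name)
      if (length(unk) > 0L) {
        say("rule ", r$label, ": undeclared variable(s): ",
            paste(unk, collapse = ", "))
      }
    }
    known_c <- r$condition[r$condition$variable %in% vars$name, , drop = FALSE]
    oob <- known_c$level < 0L | known_c$level > maxlev[known_c$variable]
    if (any(oob)) {
      say("rule ", r$label, ": condition level out of domain for ",
          paste(known_c$variable[oob], collapse = ", "))
    }
    boolc <- known_c$variable %in% vars$name[vars$max_level == 1L]
    if (any(boolc & known_c$op != "=")) {
      say("rule ", r$label,
          ": Boolean variables take only equality atoms (use +/-): ",
          paste(known_c$variable[boolc & known_c$op != "="], collapse = ", "))
    }
    known_r <- r$realization[r$realization$variable %in% vars$name, , drop = FALSE]
    oob <- known_r$level < 0L | known_r$level > maxlev[known_r$variable]
    if (any(oob)) {
      say("rule ", r$label, ": realization level out of domain for ",
          paste(known_r$variable[oob], collapse = ", "))
    }
    dup <- unique(r$realization$variable[duplicated(r$realization$variable)])
    if (length(dup) > 0L) {
      say("rule ", r$label, ": contradictory realization, variable(s) ",
          paste(dup, collapse = ", "), " assigned more than once")
    }
  }
  if (length(m$initial) == 0L) say("at least one initial state is required")
  for (i in seq_along(m$initial)) {
    s <- m$initial[[i]]
    if (!identical(sort(names(s)), vars$name) &&
        !identical(names(s), vars$name)) {
      say("initial state ", i, " is not a total assignment")
      next
    }
    oob <- s < 0L | s > maxlev[names(s)]
    if (any(oob)) {
      say("initial state ", i, ": level out of domain for ",
          paste(names(s)[oob], collapse = ", "))
    }
  }
  out
}

is_boolean_model <- function(m) all(m$variables$max_level == 1L)

rule_labels <- function(m) vapply(m$rules, function(r) r$label, character(1))

get_rule <- function(m, label) {
  for (r in m$rules) if (r$label == label) return(r)
  stop("unknown rule label: ", label, call. = FALSE)
}

#' @export
print.eden_model <- function(x, ...) {
  kind <- if (is_boolean_model(x)) "Boolean" else "multivalued"
  cat(sprintf("Qualitative rule network (%s): %d variables, %d rules, %d initial state(s)\n",
              kind, nrow(x$variables), length(x$rules), length(x$initial)))
  cat("variables:",
      paste0(x$variables$name,
             ifelse(x$variables$max_level > 1L,
                    paste0("[0..", x$variables$max_level, "]"), ""),
             collapse = " "), "\n")
  for (r in x$rules) cat(" ", format_rule(x, r), "\n")
  for (s in x$initial) cat("initial:", format_state(x, s), "\n")
  invisible(x)
}
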