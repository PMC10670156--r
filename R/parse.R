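# Plain-text model format
#
#   variable <name> [levels 0..<k>]     # omitted levels => Boolean 0..1
#   rule <LABEL>: <atom> [and <atom>]* >> <assign> [, <assign>]*
#   initial: <assign> [, <assign>]*     # unlisted variables default to 0
#
#   atom:   <name>+ | <name>- | <name> (>=|>|<=|<|=) <int>
#   assign: <name>+ | <name>- | <name> = <int>
#   '#' starts a comment; blank lines are ignored.

IDENT_RE <- "[A-Za-z_][A-Za-z0-9_.]*"

#' Parse a plain-text model file
#'
#' Reads the rule-network model format (see Details) into an
#' [eden_model()]. Syntax and semantic problems (undeclared variables,
#' out-of-domain levels, duplicate rule labels, contradictory
#' realizations) are reported with the offending line and token.
#'
#' @details The format is line oriented: `variable M levels 0..2` declares
#' a variable (omitting the `levels` clause declares a Boolean variable),
#' `rule R1: M >= 1 >> S1+` declares a labeled rule whose condition is a
#' conjunction of atoms joined by `and` and whose realization is a
#' comma-separated list of assignments, and `initial: A+, P+, T+` declares
#' an initial state (variables not listed default to level 0; the line may
#' be repeated for multiple initial states). `v+` / `v-` abbreviate
#' `v = 1` / `v = 0`. `#` starts a comment.
#'
#' @param text model file content as a single string or character vector
#'   of lines.
#' @return a validated `eden_model`. Parsing, serializing with
#'   [serialize_model()] and re-parsing is the identity.
#' @export
parse_model <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  vars <- character(0); maxlev <- integer(0)
  rule_lines <- list()
  init_lines <- list()
  perr <- function(i, msg) {
    stop(sprintf("line %d: %s", i, msg), call. = FALSE)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (grepl("^variable\\b", ln)) {
      mm <- regmatches(ln, regexec(
        paste0("^variable\\s+(", IDENT_RE, ")\\s*(?:levels\\s+0\\s*\\.\\.\\s*([0-9]+))?$"),
        ln))[[1]]
      if (length(mm) == 0L) perr(i, paste0("malformed variable declaration: '", ln, "'"))
      k <- if (mm[3] == "") 1L else as.integer(mm[3])
      if (k < 1L) perr(i, paste0("variable ", mm[2], ": maximum level must be >= 1"))
      vars <- c(vars, mm[2]); maxlev <- c(maxlev, k)
    } else if (grepl("^rule\\b", ln)) {
      mm <- regmatches(ln, regexec(
        paste0("^rule\\s+(", IDENT_RE, ")\\s*:\\s*(.*?)\\s*>>\\s*(.*)$"), ln))[[1]]
      if (length(mm) == 0L) perr(i, paste0("malformed rule (expected 'rule LABEL: cond >> realization'): '", ln, "'"))
      rule_lines[[length(rule_lines) + 1L]] <-
        list(line = i, label = mm[2], cond = mm[3], real = mm[4])
    } else if (grepl("^initial\\s*:", ln)) {
      init_lines[[length(init_lines) + 1L]] <-
        list(line = i, body = trimws(sub("^initial\\s*:", "", ln)))
    } else {
      perr(i, paste0("unrecognized line: '", ln, "'"))
    }
  }
  if (length(vars) == 0L) stop("no variables declared", call. = FALSE)
  if (anyDuplicated(vars)) {
    stop("duplicate variable declaration: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "), call. = FALSE)
  }
  dom <- stats::setNames(maxlev, vars)

  seen <- character(0)
  rules <- lapply(rule_lines, function(rl) {
    if (rl$label %in% seen) perr(rl$line, paste0("duplicate rule label '", rl$label, "'"))
    seen <<- c(seen, rl$label)
    atoms <- strsplit(rl$cond, "\\band\\b")[[1]]
    atoms <- trimws(atoms)
    if (length(atoms) == 0L || any(atoms == "")) {
      perr(rl$line, paste0("rule ", rl$label, ": empty condition"))
    }
    cond <- do.call(rbind, lapply(atoms, parse_atom, dom = dom,
                                  line = rl$line, where = paste0("rule ", rl$label)))
    assigns <- trimws(strsplit(rl$real, ",", fixed = TRUE)[[1]])
    if (length(assigns) == 0L || any(assigns == "")) {
      perr(rl$line, paste0("rule ", rl$label, ": empty realization"))
    }
    real <- do.call(rbind, lapply(assigns, parse_assign, dom = dom,
                                  line = rl$line, where = paste0("rule ", rl$label)))
    if (anyDuplicated(real$variable)) {
      perr(rl$line, paste0("rule ", rl$label, ": contradictory realization, variable '",
                           real$variable[duplicated(real$variable)][1],
                           "' assigned more than once"))
    }
    eden_rule(rl$label, cond, stats::setNames(real$level, real$variable))
  })

  if (length(init_lines) == 0L) {
    stop("no initial state declared (add an 'initial:' line)", call. = FALSE)
  }
  initial <- lapply(init_lines, function(il) {
    if (il$body == "") return(stats::setNames(integer(0), character(0)))
    assigns <- trimws(strsplit(il$body, ",", fixed = TRUE)[[1]])
    df <- do.call(rbind, lapply(assigns, parse_assign, dom = dom,
                                line = il$line, where = "initial state"))
    stats::setNames(df$level, df$variable)
  })

  eden_model(variables = dom, rules = rules, initial = initial)
}

parse_atom <- function(tok, dom, line, where) {
  mm <- regmatches(tok, regexec(paste0("^(", IDENT_RE, ")\\s*([+-]|>=|<=|=|<|>)\\s*([0-9]+)?$"), tok))[[1]]
  if (length(mm) == 0L || (mm[3] %in% c("+", "-") && mm[4] != "") ||
      (!(mm[3] %in% c("+", "-")) && mm[4] == "")) {
    stop(sprintf("line %d: %s: malformed atom '%s'", line, where, tok), call. = FALSE)
  }
  v <- mm[2]
  if (!v %in% names(dom)) {
    stop(sprintf("line %d: %s: undeclared variable '%s'", line, where, v), call. = FALSE)
  }
  if (mm[3] == "+") { op <- "="; lev <- 1L }
  else if (mm[3] == "-") { op <- "="; lev <- 0L }
  else { op <- mm[3]; lev <- as.integer(mm[4]) }
  if (lev < 0L || lev > dom[[v]]) {
    stop(sprintf("line %d: %s: level %d out of domain 0..%d for '%s'",
                 line, where, lev, dom[[v]], v), call. = FALSE)
  }
  if (dom[[v]] == 1L && op != "=") {
    stop(sprintf("line %d: %s: Boolean variable '%s' takes only '+'/'-' or '= 0/1'",
                 line, where, v), call. = FALSE)
  }
  data.frame(variable = v, op = op, level = lev, stringsAsFactors = FALSE)
}

parse_assign <- function(tok, dom, line, where) {
  df <- parse_atom(tok, dom, line, where)
  if (df$op != "=") {
    stop(sprintf("line %d: %s: assignment must use '=' (or +/-), got '%s'",
                 line, where, tok), call. = FALSE)
  }
  data.frame(variable = df$variable, level = df$level, stringsAsFactors = FALSE)
}

#' Serialize a model to the plain-text format
#'
#' The output re-parses to an identical model: variables in canonical
#' (sorted) order, rules in label order, Boolean assignments rendered with
#' the `+`/`-` sugar.
#'
#' @param m a valid `eden_model`.
#' @return a single string (model file content).
#' @export
serialize_model <- function(m) {
  diags <- validate_model(m)
  if (length(diags) > 0L) {
    stop("refusing to serialize invalid model:\n  ",
         paste(diags, collapse = "\n  "), call. = FALSE)
  }
  out <- character(0)
  for (i in seq_len(nrow(m$variables))) {
    v <- m$variables[i, ]
    out <- c(out, if (v$max_level == 1L) paste("variable", v$name)
                  else sprintf("variable %s levels 0..%d", v$name, v$max_level))
  }
  maxlev <- stats::setNames(m$variables$max_level, m$variables$name)
  fmt_atom <- function(v, op, lev) {
    if (maxlev[[v]] == 1L && op == "=") paste0(v, if (lev == 1L) "+" else "-")
    else paste(v, op, lev)
  }
  for (r in m$rules) {
    cond <- paste(mapply(fmt_atom, r$condition$variable, r$condition$op,
                         r$condition$level), collapse = " and ")
    real <- paste(mapply(fmt_atom, r$realization$variable,
                         rep("=", nrow(r$realization)), r$realization$level),
                  collapse = ", ")
    out <- c(out, sprintf("rule %s: %s >> %s", r$label, cond, real))
  }
  for (s in m$initial) {
    nz <- s[s != 0L]
    body <- paste(mapply(fmt_atom, names(nz), rep("=", length(nz)),
                         unname(nz)), collapse = ", ")
    out <- c(out, paste0("initial: ", body))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read a model file from disk
#' @param path path to a model file.
#' @return an `eden_model`.
#' @export
read_model <- function(path) {
  parse_model(readLines(path, warn = FALSE))
}

#' Write a model file to disk
#' @param m an `eden_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  writeLines(sub("\n$", "", serialize_model(m)), path)
  invisible(path)
}

#' JSON serialization of a model
#'
#' Stable key order for programmatic interchange; `model_from_json()`
#' inverts it exactly.
#'
#' @param m an `eden_model`.
#' @return a JSON string.
#' @export
model_to_json <- function(m) {
  obj <- list(
    variables = lapply(seq_len(nrow(m$variables)), function(i) {
      list(name = m$variables$name[i], max_level = m$variables$max_level[i])
    }),
    rules = lapply(m$rules, function(r) {
      list(
        label = r$label,
        condition = lapply(seq_len(nrow(r$condition)), function(i) {
          list(variable = r$condition$variable[i], op = r$condition$op[i],
               level = r$condition$level[i])
        }),
        realization = lapply(seq_len(nrow(r$realization)), function(i) {
          list(variable = r$realization$variable[i],
               level = r$realization$level[i])
        })
      )
    }),
    initial = lapply(m$initial, as.list)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname model_to_json
#' @param json JSON string produced by `model_to_json()`.
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  vars <- stats::setNames(
    vapply(obj$variables, function(v) as.integer(v$max_level), integer(1)),
    vapply(obj$variables, function(v) v$name, character(1))
  )
  rules <- lapply(obj$rules, function(r) {
    cond <- do.call(rbind, lapply(r$condition, function(a) {
      data.frame(variable = a$variable, op = a$op, level = as.integer(a$level),
                 stringsAsFactors = FALSE)
    }))
    real <- stats::setNames(
      vapply(r$realization, function(a) as.integer(a$level), integer(1)),
      vapply(r$realization, function(a) a$variable, character(1))
    )
    eden_rule(r$label, cond, real)
  })
  initial <- lapply(obj$initial, function(s) {
    stats::setNames(vapply(s, as.integer, integer(1)), names(s))
  })
  eden_model(vars, rules, initial)
}

# -- display helpers ---------------------------------------------------------

#' Render a state as a readable string
#'
#' Boolean models render as the set of present variables (`"APT"`, with
#' the empty community as `"∅"` or `"-"` in ASCII mode); multivalued
#' models render as `name=level` pairs.
#'
#' @param m the model the state belongs to.
#' @param s a state (named integer vector).
#' @param ascii use `-` instead of `∅` for the empty Boolean state.
#' @return a single string.
#' @export
format_state <- function(m, s, ascii = FALSE) {
  s <- s[m$variables$name]
  if (is_boolean_model(m)) {
    present <- names(s)[s == 1L]
    if (length(present) == 0L) return(if (ascii) "-" else "∅")
    return(paste(present, collapse = ""))
  }
  paste(paste0(names(s), "=", unname(s)), collapse = ",")
}

format_rule <- function(m, r) {
  maxlev <- stats::setNames(m$variables$max_level, m$variables$name)
  fmt <- function(v, op, lev) {
    if (maxlev[[v]] == 1L && op == "=") paste0(v, if (lev == 1L) "+" else "-")
    else paste(v, op, lev)
  }
  paste0(r$label, ": ",
         paste(mapply(fmt, r$condition$variable, r$condition$op,
                      r$condition$level), collapse = " and "),
         " >> ",
         paste(mapply(fmt, r$realization$variable,
                      rep("=", nrow(r$realization)), r$realization$level),
               collapse = ", "))
}
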