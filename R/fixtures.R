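# Built-in models. The APT community-disassembly model is the worked
# example used throughout the documentation; the germination pair
# illustrates the Boolean vs multivalued threshold representations; the
# toggle and three-cycle models exercise the SCC classifier; random
# Boolean models drive the property tests against brute-force oracles.

#' The APT protist community-disassembly model
#'
#' Three protist species — an amoeba (A), a paramecium (P) and a
#' tetrahymena (T) — interact negatively: A eats and depends on P, A eats
#' T, and P outcompetes T (unidirectionally). Each interaction can drive
#' an extinction, captured as one rule per cause:
#' \itemize{
#'   \item R1: `A+ and P+ >> P-` (A eats P to extinction)
#'   \item R2: `A+ and T+ >> T-` (A eats T to extinction)
#'   \item R3: `P+ and T+ >> T-` (P outcompetes T)
#'   \item R4: `A+ and P- >> A-` (A starves without its prey P)
#' }
#' From the full community `{APT}`, asynchronous execution yields six
#' states with two stable end states, `{T}` and the empty community, and
#' three alternative extinction sequences; synchronous execution is
#' deterministic and collapses straight to the empty community.
#'
#' @return an `eden_model`.
#' @examples
#' g <- build_stg(apt_model())
#' deadlock_states(g)
#' @export
apt_model <- function() {
  eden_model(
    variables = c(A = 1, P = 1, T = 1),
    rules = list(
      eden_rule("R1", condition = c(A = 1, P = 1), realization = c(P = 0)),
      eden_rule("R2", condition = c(A = 1, T = 1), realization = c(T = 0)),
      eden_rule("R3", condition = c(P = 1, T = 1), realization = c(T = 0)),
      eden_rule("R4", condition = c(A = 1, P = 0), realization = c(A = 0))
    ),
    initial = c(A = 1, P = 1, T = 1)
  )
}

#' Seed-germination models: Boolean and multivalued
#'
#' Soil moisture M gates seedling emergence. In the Boolean model a single
#' functionality threshold makes moisture either sufficient (M+) or not
#' (M-) for germination of a single seedling pool S. The multivalued model
#' distinguishes two species' moisture requirements with levels 0, 1 and 2
#' of M: species 1 germinates from level 1 (`M >= 1 >> S1+`), the more
#' demanding species 2 only from level 2 (`M >= 2 >> S2+`), with the
#' mirror-image die-back rules below each threshold. The Boolean
#' abstraction collapses the two pools into one: if moisture suffices for
#' one species it suffices for all.
#'
#' @return a list with elements `boolean` and `multivalued`, each an
#'   `eden_model`.
#' @export
germination_models <- function() {
  boolean <- eden_model(
    variables = c(M = 1, S = 1),
    rules = list(
      eden_rule("R1", condition = c(M = 1), realization = c(S = 1)),
      eden_rule("R2", condition = c(M = 0), realization = c(S = 0))
    ),
    initial = c(M = 1)
  )
  multivalued <- eden_model(
    variables = c(M = 2, S1 = 1, S2 = 1),
    rules = list(
      eden_rule("R1",
                condition = data.frame(variable = "M", op = ">=", level = 1),
                realization = c(S1 = 1)),
      eden_rule("R2",
                condition = data.frame(variable = "M", op = ">=", level = 2),
                realization = c(S2 = 1)),
      eden_rule("R3",
                condition = data.frame(variable = "M", op = "<", level = 1),
                realization = c(S1 = 0)),
      eden_rule("R4",
                condition = data.frame(variable = "M", op = "<", level = 2),
                realization = c(S2 = 0))
    ),
    initial = c(M = 1)
  )
  list(boolean = boolean, multivalued = multivalued)
}

#' Toggle model: a four-state complex SCC
#'
#' M flips freely between absent and present and drags S along with a
#' delay, so all four states of the (M, S) plane are mutually reachable
#' with branching internal structure — a complex SCC and no deadlock.
#'
#' @return an `eden_model`.
#' @export
toggle_model <- function() {
  eden_model(
    variables = c(M = 1, S = 1),
    rules = list(
      eden_rule("R1", condition = c(M = 0), realization = c(M = 1)),
      eden_rule("R2", condition = c(M = 1), realization = c(M = 0)),
      eden_rule("R3", condition = c(M = 1), realization = c(S = 1)),
      eden_rule("R4", condition = c(M = 0), realization = c(S = 0))
    ),
    initial = c(M = 0, S = 0)
  )
}

#' Three-phase cycle model: a cyclic SCC
#'
#' One variable with levels 0, 1, 2 advanced cyclically
#' (0 to 1, 1 to 2, 2 back to 0): the STG is a single directed 3-cycle,
#' the discrete analogue of a limit cycle.
#'
#' @return an `eden_model`.
#' @export
cycle3_model <- function() {
  eden_model(
    variables = c(V = 2),
    rules = list(
      eden_rule("R1", condition = c(V = 0), realization = c(V = 1)),
      eden_rule("R2", condition = c(V = 1), realization = c(V = 2)),
      eden_rule("R3", condition = c(V = 2), realization = c(V = 0))
    ),
    initial = c(V = 0)
  )
}

#' Random Boolean model for property testing
#'
#' Generates a reproducible Boolean model: `n_vars` variables `V1..Vn`,
#' `n_rules` rules with 1–3 condition atoms and 1–2 realization
#' assignments each, and one random initial state. The caller's RNG state
#' is left untouched; the same seed always yields the identical model.
#'
#' @param n_vars number of Boolean variables (>= 1).
#' @param n_rules number of rules (>= 0).
#' @param seed integer seed.
#' @return an `eden_model`.
#' @export
random_model <- function(n_vars, n_rules, seed) {
  stopifnot(n_vars >= 1, n_rules >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  vnames <- paste0("V", seq_len(n_vars))
  rules <- lapply(seq_len(n_rules), function(i) {
    nc <- sample.int(min(3L, n_vars), 1L)
    cvars <- sort(sample(vnames, nc))
    cond <- stats::setNames(sample(0:1, nc, replace = TRUE), cvars)
    nr <- sample.int(min(2L, n_vars), 1L)
    rvars <- sort(sample(vnames, nr))
    real <- stats::setNames(sample(0:1, nr, replace = TRUE), rvars)
    eden_rule(sprintf("R%02d", i), condition = cond, realization = real)
  })
  initial <- stats::setNames(sample(0:1, n_vars, replace = TRUE), vnames)
  eden_model(stats::setNames(rep(1L, n_vars), vnames), rules, initial)
}

#' Fixture catalog
#'
#' Named access to every built-in model, for scripting and the
#' command-line `fixtures` subcommand.
#'
#' @param name one of `"apt"`, `"germination_boolean"`,
#'   `"germination_multivalued"`, `"toggle"`, `"cycle3"`.
#' @return an `eden_model`.
#' @export
fixture_model <- function(name = c("apt", "germination_boolean",
                                   "germination_multivalued", "toggle",
                                   "cycle3")) {
  name <- match.arg(name)
  switch(name,
    apt = apt_model(),
    germination_boolean = germination_models()$boolean,
    germination_multivalued = germination_models()$multivalued,
    toggle = toggle_model(),
    cycle3 = cycle3_model()
  )
}
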