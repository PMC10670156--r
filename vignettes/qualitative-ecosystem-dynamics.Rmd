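---
title: "Qualitative discrete-event modeling of ecosystem dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative discrete-event modeling of ecosystem dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edenr)
```

## Why a qualitative, possibilistic model

Continuous ecosystem models need rate parameters that are costly or
impossible to estimate; probabilistic models need justified distributions.
`edenr` takes the logical-modeling route long established for gene
regulatory networks: variables are abstracted to a small number of levels
separated by *functionality thresholds* — the level above which a variable
can cause or prevent qualitative change in others. A Boolean variable is
simply the one-threshold case (absent/present). Changes are *discrete
events*: a rule

```
rule R1: M >= 1 >> S1+
```

says that when moisture reaches its first threshold, seedlings of species
1 *may* emerge. "May" is the heart of the semantics: hidden variables
(temperature, dispersal, chance) can delay or prevent any event, so the
engine never asks how likely a firing is. It computes **all** trajectories
compatible with the rules — possibilism, i.e. non-probabilistic
non-determinism. The price is exponential state-space growth; the
framework is therefore meant for coarse-grained community descriptions
(a handful to a few dozen variables), not individual-based detail.

## The rule language

A model is plain text: variable declarations (with an optional
`levels 0..k` clause), labeled rules, and one or more `initial:` lines.
Conditions are pure conjunctions of threshold atoms; disjunction is
written as several rules sharing a realization, which matches the
one-rule-per-cause style of ecological narratives and keeps every cause
separately addressable by label in queries. Realizations are absolute
assignments (set `S` to 1), not increments, and may touch several
variables at once. Boolean `v+`/`v-` is pure sugar for `v = 1`/`v = 0`;
internally every variable is integer-leveled, so there is a single code
path. For Boolean variables only equality atoms are accepted — a
relational atom on a two-level domain invites off-by-one confusion and
adds nothing.

Parsing, serializing and re-parsing is the identity on valid models
(property-tested on random models), and `validate_model()` guarantees
that a clean model executes without runtime domain errors.

## Update modes and the state-transition graph

Two schedulings are implemented, chosen by `build_stg(m, mode)`:

* **asynchronous** — exactly one enabled rule fires per transition.
  Because one rule may set several variables simultaneously, this is the
  *partially synchronous* regime: simultaneity within an event, full
  timing freedom between events. No third engine mode is needed.
* **synchronous** — all enabled rules fire at once. Nothing in the rule
  language prevents two simultaneously enabled rules from assigning
  different levels to one variable; the engine treats that as a hard
  error naming both rules and the variable, because silently picking a
  winner would fabricate dynamics. An opt-in `on_conflict = "branch"`
  policy instead branches over every maximal conflict-free subset of the
  enabled rules (maximal cliques of the pairwise-compatibility graph);
  it is documented as an extension and off by default.

Enabledness is *effect-bearing*: a rule whose condition holds but whose
realization would not change the state is not enabled. This removes all
self-loops, makes "deadlock = no enabled rule" exact, and matches the view
that events are qualitative changes.

The STG is the breadth-first closure of the successor relation from the
initial states. States are dequeued in canonical (sorted-key) order and
rules tried in label order, so rebuilding is byte-identical — important
both for diffable outputs and for honest regression tests. Parallel rule
firings that produce the same target are merged onto one edge carrying
all their labels. Exploration beyond `max_states` (default 1e6; state
spaces in this formalism can grow far beyond desk scale) aborts with an
explicit error rather than returning a silently truncated graph.

## Topology: deadlocks, SCCs, basins, and the HTG

`classify_components()` assigns every state to exactly one component:

* **deadlock** — a single state with no successor: a stable state.
* **cyclic SCC** — a non-trivial strongly connected component whose
  induced sub-graph is a single directed cycle (every member has internal
  in- and out-degree 1): the discrete analogue of a limit cycle.
* **complex SCC** — any other non-trivial SCC: several interleaved
  feedback loops.
* **basin** — the remaining transient states, grouped by fate.

Two readings deserve a note. First, "not part of an SCC" is read as "not
part of a *non-trivial* SCC": every state is trivially its own SCC, so
the literal reading would leave basins empty. Second, basin *grouping*
uses the full persistent signature of a state — the exact set of
reachable deadlocks **and** non-trivial SCCs, terminal or not — while the
reported `attractor_key` is its terminal subset (the attractors the state
can end in), with `strong = TRUE` when that set is a single attractor.
Grouping by the terminal subset alone looks equivalent but is subtly
wrong: when a non-terminal SCC lies between two transient states that
share the same terminal fate, a terminal-only grouping merges them into
one basin and creates a basin → SCC → basin cycle in the condensed graph.
With the persistent signature this cannot happen — an edge from a basin
into an SCC that a same-signature state also lies downstream of would
force that state into the SCC itself — so the hierarchical transition
graph is acyclic by construction. It is nevertheless asserted on every
build, and the property suite checks it on random models. In graphs whose
only persistent structures are terminal (the common case, including the
worked example) the two groupings coincide exactly.

The **HTG** has the components as nodes and an edge wherever at least one
state-level transition crosses between two components; every such edge is
an irreversible change. Non-terminal SCCs remain their own nodes rather
than being folded into basins, so reversible regimes stay visible even
when they are escapable.

**Trajectories** are maximal simple paths from the initial state(s). On
an acyclic STG they are enumerated at state level with per-step rule
labels, and each ends in a deadlock. Under cycles "a trajectory" has no
finite state-level meaning, so the enumeration moves to the HTG, which is
finite and acyclic; the count is then over component sequences. Both
enumerations are capped (`max_trajectories`, default 10,000) with an
explicit error.

## Query patterns

Temporal-logic syntax is a real adoption barrier, so the query layer is a
fixed set of named patterns rather than a CTL/LTL front end. Predicates
are Boolean combinations of threshold atoms (`"T+ and A- and P-"`) or
explicit state sets.

* `query_reachable(g, p)` — some reachable state satisfies `p`; witness:
  a shortest path (ties broken by canonical state order).
* `query_invariantly(g, p)` — all reachable states satisfy `p`; equal to
  the negation of `query_reachable(g, not p)` (property-tested).
* `query_avoidable(g, p)` — some maximal trajectory never enters `p`.
* `query_stable(g, p)` — some reachable terminal component lies entirely
  inside `p`.
* `query_event_necessary(g, label, p)` — every path from an initial state
  to a `p`-state fires the rule; evaluated over histories from the
  initial states (the historical-explanation reading).
* `query_event_sufficient(g, label, p)` — every maximal path that fires
  the rule reaches `p` at some point.

"Maximal path" requires care under cycles. No fairness is assumed: a run
that can cycle forever inside any SCC — terminal or not — counts as
maximal, so a sufficiency counterexample or an avoidance witness may be
lasso-shaped (a stem plus a cycle, reported with the loop-back index).
Concretely, a predicate-avoiding maximal run exists from a state exactly
when, inside the sub-graph induced by the avoiding states, that state
reaches a deadlock of the full graph or any cycle. Every witness
re-validates as an actual labeled path of the STG; the test suite asserts
this for each pattern.

These six patterns are this package's renderings of informally stated
ecological questions ("is a collapse avoidable?", "is this state always
preceded by that disturbance?"); the formalizations — in particular
necessity over initial-state histories and the unfair maximal-path
semantics — are design choices and are documented as such.

## The worked example as a joint oracle

The community-disassembly model (`apt_model()`) is reconstructed from its
interaction narrative: A eats P (R1), A eats T (R2), P outcompetes T
(R3), and A starves without P (R4), each as a conjunction-of-presence
rule. The reconstruction is accepted only because it jointly reproduces
every published fact about the system, which the central regression test
asserts as a conjunction: R1–R3 and only they are enabled in the full
community; the transition to `{AP}` merges the alternative firings R2 and
R3; asynchronous execution gives six states, two stable states (`{T}`,
`∅`) and four transient states, with exactly three extinction sequences;
synchronous execution is deterministic and reaches only `∅`; and the
extinction of P is necessary but not sufficient for `{T}` to persist.

```{r apt}
b <- run_pipeline(apt_model())
cat(b$summary, sep = "\n")
```

## Synthetic models and what the tests show

`random_model(n_vars, n_rules, seed)` generates Boolean models with 1–3
condition atoms and 1–2 realization assignments per rule — the same
granularity as hand-written ecological rules — plus a random initial
state, reproducibly under a seed and without touching the caller's RNG.
The property suite compares the engine's reachable STG against a
brute-force transition relation enumerated over all `2^n` states by an
independent code path (naive loops, no shared machinery, no igraph), in
both update modes, including the conflict cases, on models of up to 8
variables (256 states). Problem sizes — 200 models in the acceptance
suite, 40 in the unit suite, up to 50-state graphs for the
pairwise-reachability SCC oracle — keep the whole suite in the
ten-second range while still exercising every structural case observed
to occur (deadlock-free graphs, multiple basins, nested SCCs, write
conflicts).

What the random models do *not* emulate: multivalued thresholds (covered
by the germination fixture and domain-enumeration oracles instead),
structured interaction topologies (food webs have far more correlated
rule sets than uniform sampling produces), and any notion of rates or
likelihood — the framework's own abstraction. A green suite therefore
certifies the semantics and the graph algorithms, not the ecological
adequacy of any particular rule set.

## Numerical and degenerate-input choices

* Determinism everywhere: sorted state keys, label-ordered rule trial,
  components ordered by kind then smallest member, byte-identical reruns
  (asserted over the full export bundle).
* Zero-rule models are valid: one state, zero transitions, one
  trajectory.
* An all-zero initial state serializes to a bare `initial:` line, which
  the parser accepts.
* `max_states` and `max_trajectories` violations are errors, never
  truncation; synchronous write conflicts are errors unless branching is
  requested explicitly.
* Witness ties are broken by shortest length, then canonical state
  order.

## Limitations

No probabilities, rates, delays or priorities — by design. No symbolic
(decision-diagram) state representation: exploration is explicit, so the
practical ceiling is around a million states. Component-level trajectory
counts under cycles are coarser than state-level ones, and the two
notions coincide only on acyclic STGs. The HTG is the only aggregation
implemented; other condensation schemes exist but are out of scope.
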