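# edenr — qualitative discrete-event networks for ecosystem dynamics

`edenr` models how ecosystems change qualitatively — species going extinct,
seeds germinating, communities reassembling — without rate parameters,
population sizes or probability distributions. It is aimed at ecologists
working in data-poor settings who can state *which* interactions drive
*which* qualitative changes, but not how fast or how likely.

## The model

An ecosystem is described by **variables** with small integer levels
(Boolean in the common case: a species is present, `v+`, or absent, `v-`;
multivalued when several functionality thresholds matter, e.g. soil
moisture at levels 0, 1, 2) and by labeled **if-then rules**

```
rule R1: A+ and P+ >> P-
```

whose left side is a conjunction of threshold conditions and whose right
side sets one or more variables to new levels atomically. A rule whose
condition holds *may* fire — nothing forces it — so the semantics is
**possibilistic**: every trajectory compatible with the rules is computed,
regardless of likelihood.

Rules are executed under an update mode:

- **asynchronous** (default): one rule per step. Since a single rule may
  set several variables at once, this is a partially synchronous
  scheduling of events.
- **synchronous**: all enabled rules fire simultaneously; contradictory
  simultaneous assignments are an error by default (an opt-in policy
  branches over all maximal conflict-free rule subsets).

Exhaustive breadth-first exploration yields the **state-transition graph**
(STG): nodes are reachable states, edges are rule-labeled transitions.
Its topology is then read ecologically:

- **deadlocks** — stable states (non-invadable communities);
- **cyclic / complex SCCs** — reversible regimes (discrete limit cycles,
  or tangles of feedback loops);
- **basins** — transient states grouped by the set of attractors they can
  reach ("strong" when that fate is unique);
- the **hierarchical transition graph** (HTG) — the acyclic condensation
  of these components, whose edges are the irreversible changes.

A fixed set of model-checking **query patterns** answers the questions
ecologists actually ask: is a collapse avoidable, is a productive state
reachable and stable, is a given event a necessary or a sufficient
condition for an outcome — each with a witness trajectory.

## Worked example: community disassembly

Three protists — an amoeba `A`, a paramecium `P`, a tetrahymena `T` —
interact negatively: A eats and depends on P, A eats T, P outcompetes T.
Four rules capture the possible extinctions:

```r
library(edenr)
m <- apt_model()
b <- run_pipeline(m)
cat(b$summary, sep = "\n")
```

```
model: 3 variables, 4 rules (Boolean)
update mode: asynchronous
states: 6  transitions: 6
deadlocks (stable states): 2  ∅, T
transient (non-deadlock) states: 4
strong basin {A; AP} -> deadlock:0,0,0
basin {AT; APT} -> deadlock:0,0,0, deadlock:0,0,1
hierarchical transition graph: 4 components, 3 irreversible transitions
alternative trajectories (state level): 3
  APT -> AT -> T
  APT -> AT -> A -> ∅
  APT -> AP -> A -> ∅
```

Starting from the full community `{APT}` there are exactly three
alternative extinction sequences ending in two stable communities: `{T}`
alone, or total collapse `∅`. The transient states split into a basin
with indeterminate fate (`{APT, AT}` can still end either way) and a
strong basin (`{AP, A}` is doomed to collapse). Under synchronous update
the dynamics are deterministic and only `∅` is reached — scheduling
assumptions, not interaction structure, decide whether the experimentally
observed `{T}` end state is predicted:

```r
deadlock_states(build_stg(m, "synchronous"))   # only the empty community
```

The query layer gives the historical explanation:

```r
g <- build_stg(m)
query_event_necessary(g, "R1", "T+ and A- and P-")   # TRUE
query_event_sufficient(g, "R1", "T+ and A- and P-")  # FALSE, with witness
```

the extinction of P (rule R1) is a necessary but not a sufficient
condition for `{T}` to persist.

## Command line

```sh
Rscript inst/cli/eden.R fixtures apt -o apt.eden
Rscript inst/cli/eden.R run -m apt.eden -o out/          # exports + summary
Rscript inst/cli/eden.R query -m apt.eden --pattern precedes \
    --rule R1 --predicate "T+ and A- and P-"
```

Exports: GraphML and DOT (states and rule labels as attributes), a TSV
edge list, topology JSON, and a plain-text summary; all outputs are
deterministic and diffable.
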