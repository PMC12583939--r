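---
title: "Modeling schedules of activities as directed property graphs"
author: "soagraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling schedules of activities as directed property graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soagraph)
```

## The model

A clinical study protocol's schedule of activities (SoA) is conventionally a
square table: visits as columns with timings, activities as rows with X
marks. That form cannot express what real protocols require at run time —
conditional branching, repeated activities, treatment cycles (ubiquitous in
oncology), unscheduled visits, or the participant's right to withdraw at any
point. `soagraph` models the SoA instead as a directed property graph:

* **Nodes** are *interactions* (visits, telephone contacts) or *activities*
  (tasks performed at an interaction). Each carries identity (`id`, a UUID;
  `alias`, a legible label such as `V1`), naming, a `planned_timing` day
  offset, an optional permitted `planned_window`, and a structural `role`.
  Boundary roles delimit the schedule: instantiation start/finish (IS/IF)
  for a subject's whole schedule, activity start/finish (AS/AF) for a
  visit's task sequence, cycle start/finish (CS/CF) for a repeatable
  treatment block. One interaction is the `referenceTimepoint`, the
  schedule's t(zero).
* **Edges** are transitions. `delay` is the wait in whole days before
  moving from source to target; `window` its permitted variance;
  `rules` a conditional rule set that must resolve to `TRUE` for the path
  to be selectable; `primary_path` marks the protocol's explicit main
  schedule; `origin` records whether the edge was authored or added by
  implied-path expansion.

Activity subgraphs are stored hierarchically — one small AS→…→AF graph per
interaction — rather than flattened into one graph. That mirrors the visual
containment of schedule diagrams and maps directly onto nested actions in
the FHIR serialization.

## Timing

All computation uses signed integer day offsets with 0 at the reference
timepoint. Protocol day labels are presentation only and follow the
one-based, no-day-zero convention: offset 0 renders "Day 1", offset 27
"Day 28", and screening offsets are negative days. `day_label()` and
`day_offset()` convert between the two; nothing else in the package touches
labels.

Planned timings are node attributes, but the day on which a node occurs
along any particular path is the running sum of the delays of the edges
actually traversed. On the primary path the two must agree:

> plannedTiming(Vn) = sum(transitionDelay) from the reference timepoint to Vn

`check_timing_consistency()` evaluates this equation for every primary-path
node with a stated timing (screening nodes before the reference are handled
by reverse summation; unscheduled and boundary nodes have no planned timing
and are excluded). A violation is reported as data, not an error: in
practice it usually indicates an inconsistency in the protocol itself,
which is precisely the quality-assurance signal this representation is
designed to surface.

Only the default `start_to_start` transition type participates in day
arithmetic. The other three vocabulary values (`start_to_finish`,
`finish_to_start`, `finish_to_finish`) are stored, validated and
round-tripped, but raise an explicit "not implemented for timing" error if
used in a walk: no worked semantics exist for them yet and silently guessing
would be worse.

```{r timing}
g <- example_fig1()
planned_day(g, "V3")
day_label(planned_day(g, "V3"))
check_timing_consistency(g)
```

## Implied paths

A protocol's explicit schedule leaves many permitted paths implicit.
`expand_implied_paths()` materializes them as `origin = "implied"` edges:

* **Withdrawal**: an edge from every visit to IF. The guard itself is
  enforced at walk time: once a subject's `withdrawn` flag is true, every
  transition except those entering IF is unavailable (the general
  `{"withdrawn": false}` requirement on all transitions), so the only
  remaining route is the exit.
* **Unscheduled visits**: paired `Vn → U` and `U → Vn` edges for every
  post-reference visit. Each return edge carries an auto-generated rule
  pair — `interactions_exist` over the visits before `Vn` on the primary
  path and `interactions_not_exist` over `Vn` and everything after — so at
  run time exactly one forward return is available and no backward return
  ever is. The two lists partition the primary-path aliases.
* **Unscheduled repeats**: a self-loop on U (default delay one day) so
  unscheduled visits may occur on consecutive days, as "as required" use
  implies. This is configurable off via `expansion_policy()`.

Expansion is idempotent and never mutates explicit elements. Edges to and
from U are restricted to post-reference visits; whether a subject may take
an unscheduled visit during screening is not specified by the source
material, and the conservative reading was chosen.

## The rule engine

Rules use a deliberately human-readable syntax: a comma-separated sequence
of single-pair objects, e.g.

```
{"interactions_exist": ["IS", "V1", "V2"]}, {"interactions_not_exist": ["V3", "V4", "V5", "V6", "IF"]}
```

The parser accepts single, double and typographic quotes (protocol prose
mixes all three) and canonicalizes to double quotes; `text/x-soa-rule` is
the media-type label used when the text is carried inside FHIR condition
expressions. Built-in functions:

| function | semantics |
|---|---|
| `interactions_exist` | every listed alias is in the subject's history |
| `interactions_not_exist` | none is |
| `maxRepeats` *n* | the edge's target has executed fewer than *n* times |
| `n_cycles` *"<k"* | the prospective cycle index satisfies the comparison |
| anything else | a subject flag compared for equality |

Design choices worth stating explicitly:

* **Conjunction.** Multiple clauses on one edge are ANDed; an empty rule
  set is true. Disjunction is expressed structurally by parallel edges —
  the syntax deliberately has no OR.
* **`maxRepeats` counts total executions** and holds while count < *n*, so
  "repeat three times" pairs with `{"maxRepeats": 4}`: four executions in
  total.
* **`n_cycles` is evaluated against the *prospective* cycle**
  (completed + 1). A cycle is complete when the walker reaches the
  cycle-finish node. `"<6"` therefore permits starting cycles 1–5 and
  refuses cycle 6: a maximum of five cycles. Supported operators are
  `<, <=, =, >, >=` with an integer operand.
* **Open vocabulary.** Unknown function names are flag clauses compared
  against the context, with `"true"`/`"false"` strings (any case) coerced
  to logicals and other strings compared literally. This is what lets
  protocol-specific conditions (`consentObtained`, `record_AE`,
  `continue_to_OLE`, `studyPhase`, …) work without registration.
* **Missing flags** evaluate `FALSE` with a warning in the default lenient
  mode, or raise in strict mode.

## The walker

`simulate_walk()` traverses a graph for one subject. At each node the
outgoing edges whose rules evaluate true (after the withdrawal guard) are
available in a deterministic order — primary edge first, explicit before
implied, then by target alias — and exactly one is taken; the actual day
advances by the traversed edge's delay (or an explicit actual-delay
override when the real-world wait differed). An empty availability set at a
non-terminal node is a *stall*, reported with full context rather than
thrown: stalls are protocol inconsistencies the model is meant to expose.

Unscheduled-visit policies insert detours mechanically: an unscheduled day
strictly between two planned visits leaves the planned calendar unchanged
(the subject returns to the next visit on its planned day); an unscheduled
visit landing *on* a planned visit's day pushes that visit back by the
`U → Vn` edge delay (default one day) — the minimum-spacing behavior that
shifts a Day 28 visit to Day 29.

```{r walk}
g4 <- example_fig4()
w <- simulate_walk(g4, walk_policy(unscheduled_days = c(7, 26, 27)))
walk_calendar(g4, w)
```

## FHIR R5 mapping

`to_plan_definition()` serializes a graph into a single R5 PlanDefinition:
interaction nodes become `action`s, transitions become `action.action`s,
and two extensions — `soaTimePoint` on node actions, `soaTransition` on
edge sub-actions — carry the attributes the base resource has no elements
for. Each rule clause becomes one `action.condition` of kind
`applicability` with the clause text as its expression;
`groupingBehavior = "logical-group"` with
`selectionBehavior = "exactly-one"` restricts selection to a single path.
Activity subgraphs nest inside their interaction's action; activity actions
link to stub ActivityDefinitions (emitted by `emit_stub_context()`) through
`definitionCanonical`, the conformant R5 element for binding an action to a
task definition — scheduling stays fully separated from task content.

The extension element names are the attribute names of the model verbatim;
the published profile artifacts are not reproduced here, so
`validate_plan_definition()` is a structural check reconstructed from the
mapping itself and is flagged as such. Delays and windows serialize as
integer day quantities, never ISO-8601 strings, which is what makes the
round trip bit-exact. Serialization is canonical: stable key order and
stable ids make two conversions of the same graph byte-identical.
Translation of rule text into FHIRPath or CQL, FHIR Shorthand emission, and
live server interaction are out of scope.

```{r fhir}
roundtrip_check(example_fig2b())
```

## Synthetic schedules

`generate_random_soa()` draws visit chains with random delays and derives
planned timings *from* the delays, so every generated graph satisfies the
consistency equation and all structural invariants by construction.
Optional features — screening visit, windows, durations, subtypes, an
unscheduled node (expanded), a conditional activity subgraph with an
early-exit rule and a repeat self-loop, a cycle block with a cycle-limit
rule — give the generator the same design coverage as the worked examples.
`soa_corpus()` cycles four design classes (linear, unscheduled,
conditional, cyclic); 25 graphs are used in the round-trip suites,
matching the scale at which the approach was originally validated while
keeping the default test run in seconds. Defaults (between-visit delays of
1–14 days, windows of 0–3 days, two to eight visits) are typical of early
phase outpatient schedules.

What the generator deliberately does not emulate: multi-arm branching at
the interaction level, protocol amendments mid-study, calendar effects
(weekends, time zones — the model is whole-day offsets only), and
footnote-style conditions in the tabular form (conditions must be added on
the graph; the tabular grammar has no place for them). Passing round-trip
and walker suites on this corpus therefore demonstrates representational
fidelity and rule semantics, not coverage of every protocol idiom found in
practice.

## Worked-example reconstructions

The fixtures reconstruct the worked examples deterministically:

* `example_table1()` / `example_fig1()` — the six-visit example study. The
  published table elides visits 4 and 5; they are interpolated as weekly
  (Day 14, Day 21) and documented as reconstruction.
* `example_fig2a()` / `example_fig2b()` — explicit vs fully expanded visit
  graph.
* `example_fig4()` — the unscheduled-visit timing example: five visits with
  V5 planned on Day 28 and a one-day unscheduled push, reproducing the
  Day 28 → Day 29 shift. The original figure is an image; delays were
  reconstructed from the visit table and the caption.
* `example_bp_repeat()` / `example_fig8_cycles()` — the repeat and cycle
  templates. `example_fig8_cycles(0)` degenerates to a linear study (the
  block emitted once, no cycle boundaries), taking the view that "no
  cycles" means no repetition machinery at all.

## Numerical and degenerate-input choices

* Windows default to `(0, 0)` when absent; `plannedDuration` never affects
  day arithmetic.
* Screening ranges ("−Days 28 to 1") map to `planned_timing` = earliest
  day with the window spanning the range, keeping the consistency equation
  single-valued.
* Degenerate single-visit studies (IS→V1→IF) are legal; a single-node
  fragment can be serialized with `to_plan_definition(validate = FALSE)`.
* Tie-breaks in the walker are deterministic (primary, explicit, target
  alias, edge id), so greedy and scripted walks are reproducible without a
  seed; only `"random"` mode consumes RNG.
* Timing text outside the grammar (`Day N`, `Days A to B`, `−Days A to B`,
  `As required`) is an error, not a guess.

## Known limitations

Single-subject walks only (no cohort statistics); in-memory model only (no
graph database backend); R5 only, no R4 back-port; rule text is carried,
not compiled, into FHIR; non-default transition types have no timing
semantics yet; whether activity subgraphs may contain unscheduled
activities is left open — fixtures only use the documented early-exit
pattern.
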