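# soagraph

Clinical study protocols define *what* data to collect and *when* in a
schedule of activities (SoA) — traditionally a square table of visits and
activities. Tables cannot express what protocols actually require at run
time: conditional branching, repeated measurements, treatment cycles
(essential in oncology), unscheduled visits, or withdrawal at any point.
`soagraph` is for study designers, protocol digitization teams, and
clinical-systems engineers who need SoAs that are *computable*: it models
the SoA as a directed property graph and exchanges it losslessly with FHIR
R5.

**The model.** Interactions (visits) and activities are nodes; transitions
are edges carrying a `transitionDelay` (days to wait before moving from
source to target), an optional permitted window, and a `transitionRule` —
a conditional expression that must resolve to `TRUE` for the path to be
selectable, written as human-readable `{"function": inputs}` pairs:

```
{"interactions_exist": ["IS","V1","V2"]}, {"interactions_not_exist": ["V3","V4","V5","V6","IF"]}
```

Planned timings are anchored by the key consistency identity

> plannedTiming(Vn) = Σ transitionDelay from the referenceTimepoint to Vn

checked by `check_timing_consistency()`; the day a visit *actually* occurs
is the running delay sum along the path actually walked, unscheduled
detours included. A per-subject walker evaluates edge rules against the
subject's runtime context (visit history, execution counts, completed
cycles, flags) and enforces single-path selection. For FHIR interchange,
visits map to `PlanDefinition.action`, transitions to
`PlanDefinition.action.action`, with the `soaTimePoint` and `soaTransition`
extensions carrying graph attributes and each rule clause riding as an
applicability condition — bidirectionally, with no information loss.

## Worked example

```r
library(soagraph)

g <- example_fig1()              # 6 planned visits, 1 unscheduled, activities
planned_day(g, "V3")
#> [1] 6
day_label(planned_day(g, "V3"))
#> [1] "Day 7"
check_timing_consistency(g)
#> timing consistent: 6 node(s) checked, 0 violations

# expand implied paths (withdrawal routes, unscheduled-visit routes),
# then walk the schedule with unscheduled visits on days 8, 27 and 28:
g4 <- example_fig4()
w <- simulate_walk(g4, walk_policy(unscheduled_days = c(7, 26, 27)))
print(w)
#> <soa_walk> subject-1 on soa-unscheduled-timing: finished after 9 step(s), 0 cycle(s)
#>   IS(D-28) > V1(D-28) > V2(D1) > V3(D7) > U(D8) > V4(D14) > U(D27) > U(D28) > V5(D29) > IF(D29)
```

The first unscheduled visit (Day 8) falls between planned visits and leaves
the schedule untouched; the third lands on V5's planned day (Day 28) and
pushes V5 to Day 29 — the timing cannot be recovered from planned values
alone, only from the delays of the edges actually taken.

```r
# repeat and cycle rules
wb <- simulate_walk(example_bp_repeat(), walk_policy(prefer_loops = TRUE))
sum(wb$trajectory$alias == "BP")     # {"maxRepeats": 4} -> 4 executions
#> [1] 4
wc <- simulate_walk(example_fig8_cycles(5), walk_policy(prefer_loops = TRUE))
wc$completed_cycles                  # {"n_cycles": "<6"} -> 5 cycles
#> [1] 5

# lossless FHIR R5 round trip
roundtrip_check(example_fig2b())
#> graphs are structurally identical (empty diff)
```

I/O: native JSON (`write_soa_json`/`read_soa_json`), protocol-style CSV
tables (`read_tabular_soa` + `table_to_graph`), GraphML for visual editing
(`write_graphml`/`read_graphml`), and FHIR (`to_plan_definition` /
`from_plan_definition` / `emit_stub_context`). A command-line wrapper lives
at `inst/cli/soagraph.R` (`validate`, `to-fhir`, `from-fhir`, `roundtrip`,
`simulate`, `fixtures`, `convert`).

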