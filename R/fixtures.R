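# Worked-example fixtures and the seeded random SoA generator. Every
# fixture is constructed deterministically in code (node/edge ids come from
# a locally seeded RNG), so the whole package is testable without any
# external data.

#' The example study's tabular SoA
#'
#' A six-visit study with a screening window (days -28 to -1 before the
#' reference day), weekly on-study visits, one "as required" unscheduled
#' column, and seven activities. The published table elides the timings of
#' visits 4 and 5; this reconstruction interpolates them as weekly
#' (Day 14, Day 21).
#'
#' @return an [soa_table()].
#' @export
example_table1 <- function() {
  visit_id <- c("1", "2", "3", "4", "5", "6", "U")
  timing <- c("-Days 28 to 1", "Day 1", "Day 7", "Day 14", "Day 21",
              "Day 28", "As required")
  phase <- c("Screening", rep("Study period", 5), "Unscheduled")
  acts <- c("Demographics", "Medical history",
            "Inclusion and exclusion criteria", "Vital signs", "Procedure",
            "Concomitant medication", "AE and SAE")
  marks <- rbind(
    c(1, 0, 0, 0, 0, 0, 0),   # Demographics
    c(1, 0, 0, 0, 0, 0, 0),   # Medical history
    c(1, 0, 1, 0, 0, 0, 0),   # Inclusion and exclusion criteria
    c(1, 1, 1, 1, 1, 1, 1),   # Vital signs
    c(1, 1, 0, 0, 0, 0, 0),   # Procedure
    c(1, 1, 1, 1, 1, 1, 1),   # Concomitant medication
    c(1, 1, 1, 1, 1, 1, 1)    # AE and SAE
  ) == 1
  soa_table(visit_id, timing, acts, marks, phase = phase)
}

#' Example study schedule graphs
#'
#' `example_fig1()` is the full example study: six planned visits, one
#' unscheduled visit, and per-visit activity subgraphs, built from
#' [example_table1()]. `example_fig2a()` is its interaction-level view (the
#' protocol's explicitly defined schedule, with the unscheduled visit
#' floating). `example_fig2b()` is the expanded version with all implied
#' permitted paths (withdrawal routes and unscheduled-visit routes) added by
#' [expand_implied_paths()].
#'
#' @return an `soa_graph`.
#' @export
example_fig1 <- function() {
  with_seed(101, {
    g <- table_to_graph(example_table1(), graph_id = "soa-example-study",
                        title = "Example study SoA")
    # early-exit paths in the screening visit's activity subgraph: when the
    # inclusion/exclusion review fails, the visit finishes early
    sgid <- names(g$subgraphs)[vapply(names(g$subgraphs), function(i)
      node_alias(g, i) == "V1", TRUE)]
    sg <- g$subgraphs[[sgid]]
    amap <- alias_map(sg$nodes)
    crit <- amap[["Inclusion and exclusion criteria"]]
    vs <- amap[["Vital signs"]]
    af <- amap[["AF"]]
    for (eid in names(sg$edges)) {
      e <- sg$edges[[eid]]
      if (e$source == crit && e$target == vs)
        sg$edges[[eid]]$rules <- parse_rule_set('{"if_criteria_met": true}')
    }
    exit_edge <- soa_transition(crit, af, delay = 0L,
                                rules = '{"if_criteria_met": false}',
                                id = new_uuid())
    sg$edges[[exit_edge$id]] <- exit_edge
    g$subgraphs[[sgid]] <- sg
    g
  })
}

#' @rdname example_fig1
#' @export
example_fig2a <- function() {
  g <- example_fig1()
  g$subgraphs <- list()
  g$graph_id <- "soa-example-study-visits"
  g$title <- "Example study SoA (visit level)"
  g
}

#' @rdname example_fig1
#' @export
example_fig2b <- function() {
  with_seed(103, expand_implied_paths(example_fig2a()))
}

#' The unscheduled-visit timing example
#'
#' A reconstruction of the worked timing example: screening at days -28 to
#' -1, reference visit V2 at Day 1, then V3 (Day 7), V4 (Day 14) and V5
#' (Day 28), with an unscheduled node and all implied paths expanded
#' (unscheduled-to-next-visit delay of one day). Walking it with
#' unscheduled visits on days 8, 27 and 28 pushes V5 from Day 28 to Day 29,
#' while the first unscheduled visit alone leaves the planned schedule
#' unchanged.
#'
#' @return an expanded `soa_graph`.
#' @export
example_fig4 <- function() {
  with_seed(104, {
    nodes <- list(
      soa_node("IS", role = "instantiation_start"),
      soa_node("V1", planned_timing = -28L, planned_window = c(0L, 27L),
               subtype = "clinic visit", name = "Screening"),
      soa_node("V2", planned_timing = 0L, reference_timepoint = TRUE,
               subtype = "clinic visit"),
      soa_node("V3", planned_timing = 6L, subtype = "clinic visit"),
      soa_node("V4", planned_timing = 13L, subtype = "clinic visit"),
      soa_node("V5", planned_timing = 27L, subtype = "clinic visit"),
      soa_node("U", role = "unscheduled", subtype = "clinic visit"),
      soa_node("IF", role = "instantiation_finish"))
    edges <- list(
      soa_transition("IS", "V1", delay = 0L, primary_path = TRUE),
      soa_transition("V1", "V2", delay = 28L, primary_path = TRUE),
      soa_transition("V2", "V3", delay = 6L, primary_path = TRUE),
      soa_transition("V3", "V4", delay = 7L, primary_path = TRUE),
      soa_transition("V4", "V5", delay = 14L, primary_path = TRUE),
      soa_transition("V5", "IF", delay = 0L, primary_path = TRUE))
    g <- build_graph(nodes, edges, graph_id = "soa-unscheduled-timing",
                     title = "Unscheduled-visit timing example")
    expand_implied_paths(g)
  })
}

#' Minimal repeated-activity graph
#'
#' One activity (a blood pressure measurement) between the activity
#' start/finish boundaries, with a self-loop carrying the repeat rule
#' `{"maxRepeats": 4}`: the measurement may be repeated three times, for
#' four executions in total, after which the self-loop becomes unavailable.
#'
#' @return an activity-level `soa_graph`.
#' @export
example_bp_repeat <- function() {
  with_seed(105, {
    nodes <- list(
      soa_node("AS", type = "activity", role = "activity_start"),
      soa_node("BP", type = "activity", name = "Blood pressure measurement"),
      soa_node("AF", type = "activity", role = "activity_finish"))
    edges <- list(
      soa_transition("AS", "BP", delay = 0L, primary_path = TRUE),
      soa_transition("BP", "BP", delay = 0L, rules = '{"maxRepeats": 4}'),
      soa_transition("BP", "AF", delay = 0L, primary_path = TRUE))
    build_graph(nodes, edges, graph_id = "soa-bp-repeat",
                title = "Repeated blood pressure measurement")
  })
}

#' Treatment-cycle template graph
#'
#' The cycle template: instantiation boundaries, a baseline visit, and a
#' treatment cycle delimited by cycle start/finish nodes, with a return
#' edge from cycle finish to cycle start carrying the cycle-limit rule
#' `{"n_cycles": "<max_cycles+1>"}` (e.g. `"<6"` limits the study to a
#' maximum of five cycles). `max_cycles = 0` degenerates to a linear study:
#' the visit block is emitted once, without cycle boundaries or a return
#' edge.
#'
#' @param max_cycles maximum number of completed treatment cycles.
#' @return an `soa_graph`.
#' @export
example_fig8_cycles <- function(max_cycles = 5L) {
  stopifnot(max_cycles >= 0L)
  cyclic <- max_cycles > 0L
  with_seed(106, {
    nodes <- list(
      soa_node("IS", role = "instantiation_start"),
      soa_node("V1", planned_timing = 0L, reference_timepoint = TRUE,
               name = "Baseline"),
      soa_node("CS", role = if (cyclic) "cycle_start" else "regular",
               planned_timing = 1L),
      soa_node("C1", planned_timing = 2L, name = "Treatment"),
      soa_node("C2", planned_timing = 8L, name = "Assessment"),
      soa_node("CF", role = if (cyclic) "cycle_finish" else "regular",
               planned_timing = 9L),
      soa_node("IF", role = "instantiation_finish"))
    edges <- list(
      soa_transition("IS", "V1", delay = 0L, primary_path = TRUE),
      soa_transition("V1", "CS", delay = 1L, primary_path = TRUE),
      soa_transition("CS", "C1", delay = 1L, primary_path = TRUE),
      soa_transition("C1", "C2", delay = 6L, primary_path = TRUE),
      soa_transition("C2", "CF", delay = 1L, primary_path = TRUE),
      soa_transition("CF", "IF", delay = 0L, primary_path = TRUE))
    if (cyclic)
      edges <- c(edges, list(soa_transition(
        "CF", "CS", delay = 1L,
        rules = sprintf('{"n_cycles": "<%d"}', max_cycles + 1L))))
    build_graph(nodes, edges, graph_id = "soa-cycle-template",
                title = sprintf("Cycle template (max %d cycles)", max_cycles))
  })
}

#' Parameters for the random SoA generator
#'
#' @param n_visits number of planned on-study visits (>= 1).
#' @param has_unscheduled add an unscheduled node and expand implied paths.
#' @param n_conditional_activities number of activities placed in a
#'   conditional subgraph (with an early-exit rule and a repeat self-loop).
#' @param n_cycles if > 0, append a treatment-cycle block limited to this
#'   many cycles.
#' @param delay_range inclusive range of between-visit delays, days.
#' @param window_range inclusive range of window bounds, days.
#' @param seed integer seed; generation is a pure function of params + seed.
#' @return a list of class `soa_generator_params`.
#' @export
soa_generator_params <- function(n_visits = 6L, has_unscheduled = FALSE,
                                 n_conditional_activities = 0L,
                                 n_cycles = 0L, delay_range = c(1L, 14L),
                                 window_range = c(0L, 3L), seed = 1L) {
  stopifnot(n_visits >= 1L, n_conditional_activities >= 0L, n_cycles >= 0L)
  structure(list(n_visits = as.integer(n_visits),
                 has_unscheduled = isTRUE(has_unscheduled),
                 n_conditional_activities = as.integer(n_conditional_activities),
                 n_cycles = as.integer(n_cycles),
                 delay_range = as.integer(delay_range),
                 window_range = as.integer(window_range),
                 seed = as.integer(seed)),
            class = "soa_generator_params")
}

rint <- function(range) sample(seq(range[1], range[2]), 1L)

#' Generate a random, internally consistent SoA graph
#'
#' Planned timings are derived from the randomly drawn transition delays, so
#' every generated graph satisfies the planned-timing consistency equation
#' by construction, along with every structural invariant. Optional design
#' features (screening visit, windows, durations, subtypes, unscheduled
#' node, conditional activity subgraph, cycle block) give the generator the
#' same design coverage as the worked examples.
#'
#' @param params an [soa_generator_params()].
#' @return an `soa_graph`.
#' @examples
#' g <- generate_random_soa(soa_generator_params(n_visits = 4, seed = 42))
#' check_timing_consistency(g)
#' @export
generate_random_soa <- function(params = soa_generator_params()) {
  stopifnot(inherits(params, "soa_generator_params"))
  p <- params
  with_seed(p$seed, {
    nodes <- list(soa_node("IS", role = "instantiation_start"))
    edges <- list()
    subtypes <- c("clinic visit", "telephone call", "home visit", NA)

    has_screening <- runif(1) < 0.5
    prev <- "IS"
    if (has_screening) {
      scr_days <- rint(c(14L, 28L))
      nodes <- c(nodes, list(soa_node(
        "SCR", planned_timing = -scr_days,
        planned_window = c(0L, scr_days - 1L), name = "Screening",
        subtype = "clinic visit")))
      edges <- c(edges, list(soa_transition("IS", "SCR", delay = 0L,
                                            primary_path = TRUE)))
      edges <- c(edges, list(soa_transition("SCR", "V1", delay = scr_days,
                                            primary_path = TRUE)))
      prev <- NULL
    } else {
      edges <- c(edges, list(soa_transition("IS", "V1", delay = 0L,
                                            primary_path = TRUE)))
    }

    day <- 0L
    for (i in seq_len(p$n_visits)) {
      al <- paste0("V", i)
      win <- if (runif(1) < 0.5) sort(c(rint(p$window_range), rint(p$window_range)))
      nodes <- c(nodes, list(soa_node(
        al, planned_timing = day, reference_timepoint = i == 1L,
        planned_window = win,
        planned_duration = if (runif(1) < 0.3) rint(c(1L, 24L)) else NA_real_,
        subtype = sample(subtypes, 1L),
        description = if (runif(1) < 0.3) paste("Scheduled contact", i)
        else NA_character_)))
      if (i < p$n_visits) {
        d <- rint(p$delay_range)
        ewin <- if (runif(1) < 0.4) sort(c(rint(p$window_range), rint(p$window_range)))
        edges <- c(edges, list(soa_transition(
          al, paste0("V", i + 1L), delay = d, window = ewin,
          primary_path = TRUE)))
        day <- day + d
      }
    }
    last <- paste0("V", p$n_visits)

    if (p$n_cycles > 0L) {
      d1 <- rint(p$delay_range); d2 <- rint(p$delay_range)
      nodes <- c(nodes, list(
        soa_node("CS", role = "cycle_start", planned_timing = day + d1),
        soa_node("CT", name = "Cycle treatment",
                 planned_timing = day + d1 + d2),
        soa_node("CF", role = "cycle_finish",
                 planned_timing = day + d1 + d2 + 1L)))
      edges <- c(edges, list(
        soa_transition(last, "CS", delay = d1, primary_path = TRUE),
        soa_transition("CS", "CT", delay = d2, primary_path = TRUE),
        soa_transition("CT", "CF", delay = 1L, primary_path = TRUE),
        soa_transition("CF", "CS", delay = d1,
                       rules = sprintf('{"n_cycles": "<%d"}', p$n_cycles + 1L))))
      last <- "CF"
    }

    if (p$has_unscheduled)
      nodes <- c(nodes, list(soa_node("U", role = "unscheduled",
                                      subtype = "clinic visit")))

    nodes <- c(nodes, list(soa_node("IF", role = "instantiation_finish")))
    edges <- c(edges, list(soa_transition(last, "IF", delay = 0L,
                                          primary_path = TRUE)))

    subgraphs <- list()
    if (p$n_conditional_activities > 0L) {
      acts <- paste("Assessment", seq_len(p$n_conditional_activities))
      snodes <- c(list(soa_node("AS", type = "activity", role = "activity_start")),
                  lapply(acts, function(a) soa_node(a, type = "activity")),
                  list(soa_node("AF", type = "activity", role = "activity_finish")))
      chain <- c("AS", acts, "AF")
      sedges <- lapply(seq_len(length(chain) - 1L), function(i) {
        rules <- if (chain[i] == acts[1])
          parse_rule_set('{"if_criteria_met": true}') else rule_set()
        soa_transition(chain[i], chain[i + 1L], delay = 0L, rules = rules,
                       primary_path = TRUE)
      })
      sedges <- c(sedges, list(
        soa_transition(acts[1], "AF", delay = 0L,
                       rules = '{"if_criteria_met": false}'),
        soa_transition(acts[1], acts[1], delay = 0L,
                       rules = sprintf('{"maxRepeats": %d}', rint(c(2L, 4L))))))
      subgraphs[[paste0("V", sample.int(p$n_visits, 1L))]] <-
        list(nodes = snodes, edges = sedges)
    }

    g <- build_graph(nodes, edges, subgraphs = subgraphs,
                     graph_id = paste0("soa-random-", p$seed),
                     title = sprintf("Randomized SoA (seed %d)", p$seed),
                     metadata = list(generator = "generate_random_soa",
                                     seed = as.character(p$seed)))
    if (p$has_unscheduled) g <- expand_implied_paths(g)
    g
  })
}

#' A seeded corpus of SoA designs
#'
#' Generates `n` graphs cycling through four design classes — simple linear,
#' unscheduled-visit, conditional-branch, and cyclic — with varied sizes.
#' This is the corpus used to exercise the FHIR round trip across the range
#' of schedule features.
#'
#' @param n number of graphs (>= 4 recommended to cover all classes).
#' @param seed base seed; graph `i` uses seed `seed * 1000 + i`.
#' @return a named list of `soa_graph` objects, names carrying the design
#'   class.
#' @export
soa_corpus <- function(n = 25L, seed = 1L) {
  designs <- c("linear", "unscheduled", "conditional", "cyclic")
  out <- list()
  for (i in seq_len(n)) {
    cls <- designs[(i - 1L) %% length(designs) + 1L]
    s <- seed * 1000L + i
    par <- switch(cls,
      linear = soa_generator_params(n_visits = 2L + (i %% 6L), seed = s),
      unscheduled = soa_generator_params(n_visits = 3L + (i %% 5L),
                                         has_unscheduled = TRUE, seed = s),
      conditional = soa_generator_params(n_visits = 3L + (i %% 4L),
                                         n_conditional_activities = 1L + (i %% 3L),
                                         seed = s),
      cyclic = soa_generator_params(n_visits = 2L + (i %% 4L),
                                    n_cycles = 2L + (i %% 5L), seed = s))
    out[[paste0(cls, "-", i)]] <- generate_random_soa(par)
  }
  out
}
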