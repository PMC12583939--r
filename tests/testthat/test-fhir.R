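find_action <- function(pd, id) {
  for (a in pd$action) if (identical(a$id, id)) return(a)
  NULL
}

transition_subs <- function(act) {
  Filter(function(s) !is.null(s$extension) &&
           grepl("soa-transition$", s$extension[[1]]$url),
         act$action %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("visits map to actions and transitions to sub-actions with conditions", {
  g <- example_fig2b()
  pd <- to_plan_definition(g)
  expect_equal(pd$resourceType, "PlanDefinition")
  # action count equals interaction node count, sub-action count edge count
  expect_length(pd$action, length(g$nodes))
  n_subs <- sum(vapply(pd$action, function(a) length(transition_subs(a)), 0L))
  expect_equal(n_subs, length(g$edges))

  # V2's action: sub-actions for V2>V3, V2>IF (withdrawal), V2>U
  v2 <- find_action(pd, alias_id(g, "V2"))
  subs <- transition_subs(v2)
  sub_targets <- vapply(subs, function(s) {
    tr <- s$extension[[1]]
    for (x in tr$extension) if (x$url == "target") return(x$valueString)
    ""
  }, "")
  expect_setequal(vapply(sub_targets, function(i) node_alias_of(g, i), ""),
                  c("V3", "IF", "U"))
  expect_equal(v2$groupingBehavior, "logical-group")
  expect_equal(v2$selectionBehavior, "exactly-one")

  # rule clauses ride as applicability conditions, one per clause
  u_id <- alias_id(g, "U")
  u_act <- find_action(pd, u_id)
  v3_sub <- Filter(function(s) {
    tr <- s$extension[[1]]
    any(vapply(tr$extension, function(x)
      identical(x$url, "target") && identical(x$valueString, alias_id(g, "V3")),
      TRUE))
  }, transition_subs(u_act))[[1]]
  expect_length(v3_sub$condition, 2L)
  expect_equal(v3_sub$condition[[1]]$kind, "applicability")
  expect_equal(v3_sub$condition[[1]]$expression$language, "text/x-soa-rule")
  expect_match(v3_sub$condition[[1]]$expression$expression,
               "interactions_exist")
})

test_that("a single node serializes to one action with no sub-actions", {
  g <- structure(list(
    graph_id = "soa-single", title = "One interaction",
    nodes = setNames(list(soa_node("IS", role = "instantiation_start",
                                   id = "n1")), "n1"),
    edges = list(), subgraphs = list(), metadata = list()),
    class = "soa_graph")
  pd <- to_plan_definition(g, validate = FALSE)
  expect_length(pd$action, 1L)
  expect_null(pd$action[[1]]$action)
})

test_that("graph to PlanDefinition to graph recovers every fixture exactly", {
  fixtures <- list(example_fig1(), example_fig2b(), example_fig4(),
                   example_fig8_cycles(5), example_bp_repeat())
  for (g in fixtures) {
    d <- roundtrip_check(g)
    expect_equal(nrow(d), 0L, label = g$graph_id)
  }
})

test_that("a randomized corpus round trips with empty diffs", {
  corp <- soa_corpus(25, seed = 3)
  classes <- sub("-[0-9]+$", "", names(corp))
  expect_setequal(unique(classes),
                  c("linear", "unscheduled", "conditional", "cyclic"))
  for (nm in names(corp))
    expect_equal(nrow(roundtrip_check(corp[[nm]])), 0L, label = nm)
})

test_that("round trips hold across 100 seeded random graphs", {
  ok <- 0L
  for (s in 1:100) {
    par <- soa_generator_params(
      n_visits = 2L + s %% 5L,
      has_unscheduled = s %% 3L == 0L,
      n_conditional_activities = s %% 4L,
      n_cycles = if (s %% 5L == 0L) 3L else 0L,
      seed = 20000L + s)
    if (nrow(roundtrip_check(generate_random_soa(par))) == 0L) ok <- ok + 1L
  }
  expect_equal(ok, 100L)
})

test_that("information loss is localized and named by the diff", {
  with_local_seed(21, {
    n <- list(soa_node("IS", role = "instantiation_start"),
              soa_node("V1", planned_timing = 0L, reference_timepoint = TRUE),
              soa_node("IF", role = "instantiation_finish"))
    e <- list(soa_transition("IS", "V1", delay = 0, primary_path = TRUE),
              soa_transition("V1", "IF", delay = 7, window = c(1L, 2L),
                             primary_path = TRUE, id = "edge-windowed"))
    g <- build_graph(n, e)
  })
  pd <- to_plan_definition(g)
  # deliberately drop the transitionWindow from the serialized document
  doc <- jsonlite::fromJSON(fhir_json(pd), simplifyVector = FALSE)
  for (i in seq_along(doc$action)) {
    for (j in seq_along(doc$action[[i]]$action %||% list())) {
      ext <- doc$action[[i]]$action[[j]]$extension[[1]]
      keep <- Filter(function(x) !identical(x$url, "transitionWindow"),
                     ext$extension)
      doc$action[[i]]$action[[j]]$extension[[1]]$extension <- keep
    }
  }
  g2 <- from_plan_definition(doc)
  d <- diff_graphs(g, g2)
  expect_equal(nrow(d), 1L)
  expect_equal(d$id, "edge-windowed")
  expect_equal(d$field, "window")
})

test_that("documents missing required extensions fail with the action named", {
  g <- minimal_graph()
  doc <- jsonlite::fromJSON(fhir_json(to_plan_definition(g)),
                            simplifyVector = FALSE)
  bad <- doc
  bad$action[[2]]$extension <- NULL
  expect_error(from_plan_definition(bad), bad$action[[2]]$id)
  expect_error(from_plan_definition(list(resourceType = "Bundle")),
               "not a FHIR PlanDefinition")
})

test_that("serialization is canonical and conforms to the shipped profile check", {
  g <- example_fig1()
  j1 <- as.character(fhir_json(to_plan_definition(g)))
  j2 <- as.character(fhir_json(to_plan_definition(g)))
  expect_identical(j1, j2)
  for (gx in list(example_fig1(), example_fig2b(), example_fig8_cycles(5)))
    expect_equal(nrow(validate_plan_definition(to_plan_definition(gx))), 0L,
                 label = gx$graph_id)
  # the profile check notices a stripped extension
  doc <- jsonlite::fromJSON(j1, simplifyVector = FALSE)
  doc$action[[1]]$extension <- NULL
  expect_true(any(grepl("soaTimePoint",
                        validate_plan_definition(doc)$message)))
})

test_that("stub bundles resolve every activity-definition link", {
  b <- emit_stub_context(example_fig1())
  kinds <- vapply(b$entry, function(en) en$resource$resourceType, "")
  expect_equal(kinds[1:2], c("PlanDefinition", "ResearchStudy"))
  # one ActivityDefinition per distinct activity name
  expect_equal(sum(kinds == "ActivityDefinition"), 7L)
  expect_true(stub_references_resolve(b))
  # a graph without activities bundles the PlanDefinition and study only
  b2 <- emit_stub_context(example_fig2a())
  expect_length(b2$entry, 2L)
  expect_true(stub_references_resolve(b2))
})
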