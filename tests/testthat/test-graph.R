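test_that("a minimal visit chain builds and validates cleanly", {
  g <- minimal_graph()
  expect_s3_class(g, "soa_graph")
  expect_length(g$nodes, 3L)
  expect_equal(nrow(validate_graph(g)), 0L)
  # ids are v4 UUIDs, aliases stay legible
  expect_match(names(g$nodes)[1],
               "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
})

test_that("structural defects are rejected with the offending element named", {
  n <- list(soa_node("IS", role = "instantiation_start"),
            soa_node("V1", planned_timing = 0L, reference_timepoint = TRUE),
            soa_node("IF", role = "instantiation_finish"))
  e_ok <- list(soa_transition("IS", "V1", delay = 0, primary_path = TRUE),
               soa_transition("V1", "IF", delay = 0, primary_path = TRUE))
  # dangling endpoint: error names the edge
  bad <- soa_transition("V1", "VX", delay = 1, id = "edge-dangling")
  expect_error(build_graph(n, c(e_ok, list(bad))), "edge-dangling")
  # missing instantiation boundaries
  expect_error(build_graph(n[2], list()), "instantiation_start")
  # duplicate node ids
  dup <- list(soa_node("A", role = "instantiation_start", id = "x"),
              soa_node("B", role = "instantiation_finish", id = "x"))
  expect_error(build_graph(dup, list()), "duplicate")
  # unscheduled nodes must not carry planned timing
  expect_error(soa_node("U", role = "unscheduled", planned_timing = 3L),
               "unscheduled")
})

test_that("validation findings are data, not errors", {
  g <- minimal_graph()
  # a second reference timepoint
  g2 <- g
  iid <- names(g2$nodes)[3]
  g2$nodes[[iid]]$reference_timepoint <- TRUE
  rep <- validate_graph(g2)
  expect_true(any(grepl("referenceTimepoint", rep$message)))
  # unreachable finish: drop the V1 -> IF edge
  g3 <- g
  if_id <- alias_id(g, "IF")
  g3$edges <- Filter(function(e) e$target != if_id, g3$edges)
  rep3 <- validate_graph(g3)
  expect_true(any(grepl("not reachable", rep3$message)))
  expect_equal(rep3$id[grepl("not reachable", rep3$message)], if_id)
  # cross-check with the igraph reachability oracle
  ig <- as_igraph(g3)
  expect_true(is.infinite(igraph::distances(ig, v = "IS", to = "IF",
                                            mode = "out")[1, 1]))
})

test_that("implied-path expansion adds withdrawal and unscheduled routes", {
  a <- example_fig2a()
  b <- expand_implied_paths(a)
  eb <- soa_edges(b)
  # every explicit node and edge is preserved untouched
  expect_true(all(names(a$edges) %in% names(b$edges)))
  for (eid in names(a$edges)) expect_identical(a$edges[[eid]], b$edges[[eid]])
  expect_identical(a$nodes, b$nodes)
  # every visit gains a route to IF and a route pair with U
  for (v in c("V1", "V2", "V3", "V4", "V5", "V6"))
    expect_true(any(eb$source == v & eb$target == "IF"), label = v)
  for (v in c("V2", "V3", "V4", "V5", "V6")) {
    expect_true(any(eb$source == v & eb$target == "U"), label = v)
    expect_true(any(eb$source == "U" & eb$target == v), label = v)
  }
  expect_true(all(eb$origin[!eb$id %in% names(a$edges)] == "implied"))
  # idempotence: expanding again adds nothing
  b2 <- expand_implied_paths(b)
  expect_equal(sort(names(b2$edges)), sort(names(b$edges)))
})

test_that("auto-generated unscheduled return rules partition the primary path", {
  b <- example_fig2b()
  chain_aliases <- vapply(primary_chain(b), function(i) node_alias_of(b, i), "")
  u_id <- soa_nodes(b)$id[soa_nodes(b)$role == "unscheduled"]
  if_id <- alias_id(b, "IF")
  returns <- Filter(function(e) e$source == u_id && e$target != u_id &&
                      e$target != if_id, b$edges)
  expect_gt(length(returns), 0L)
  for (e in returns) {
    expect_equal(vapply(e$rules$clauses, `[[`, "", "fun"),
                 c("interactions_exist", "interactions_not_exist"))
    exist <- e$rules$clauses[[1]]$arg
    not_exist <- e$rules$clauses[[2]]$arg
    expect_setequal(c(exist, not_exist), chain_aliases)  # union = all
    expect_length(intersect(exist, not_exist), 0L)       # disjoint
  }
  # the published worked example: the rule pair on U -> V3
  v3 <- alias_id(b, "V3")
  e3 <- Filter(function(e) e$source == u_id && e$target == v3, b$edges)[[1]]
  expect_equal(e3$rules$clauses[[1]]$arg, c("IS", "V1", "V2"))
  expect_equal(e3$rules$clauses[[2]]$arg, c("V3", "V4", "V5", "V6", "IF"))
})

test_that("after expansion every node lies on an instantiation path", {
  for (g in list(example_fig2b(), expand_implied_paths(example_fig4()))) {
    on_path <- nodes_on_is_if_paths(g)   # exhaustive enumeration oracle
    expect_setequal(on_path, soa_nodes(g)$alias)
  }
})

test_that("expansion errors when the policy names an absent unscheduled node", {
  g <- minimal_graph()
  expect_error(expand_implied_paths(g, expansion_policy(unscheduled = "U")),
               "absent unscheduled node")
  # with no unscheduled node present, default policy just adds withdrawal
  g2 <- with_local_seed(12, build_graph(
    nodes = list(soa_node("IS", role = "instantiation_start"),
                 soa_node("V1", planned_timing = 0L, reference_timepoint = TRUE),
                 soa_node("V2", planned_timing = 7L),
                 soa_node("IF", role = "instantiation_finish")),
    edges = list(soa_transition("IS", "V1", delay = 0, primary_path = TRUE),
                 soa_transition("V1", "V2", delay = 7, primary_path = TRUE),
                 soa_transition("V2", "IF", delay = 0, primary_path = TRUE))))
  e <- soa_edges(expand_implied_paths(g2))
  expect_true(any(e$source == "V1" & e$target == "IF" & e$origin == "implied"))
  # an explicit V1 -> IF edge in the minimal chain is left alone (no duplicate)
  em <- soa_edges(expand_implied_paths(g))
  expect_equal(sum(em$source == "V1" & em$target == "IF"), 1L)
})

test_that("activity subgraphs are validated with activity boundaries", {
  n <- list(soa_node("IS", role = "instantiation_start"),
            soa_node("V1", planned_timing = 0L, reference_timepoint = TRUE),
            soa_node("IF", role = "instantiation_finish"))
  e <- list(soa_transition("IS", "V1", delay = 0, primary_path = TRUE),
            soa_transition("V1", "IF", delay = 0, primary_path = TRUE))
  sg_bad <- list(nodes = list(soa_node("A1", type = "activity")),
                 edges = list())
  expect_error(build_graph(n, e, subgraphs = list(V1 = sg_bad)),
               "activity_start")
})
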