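# Shared helpers and independent oracles for the test suite.

# Evaluate expr under a fixed seed without clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Node id for an alias, via the exported accessor.
alias_id <- function(g, alias) {
  df <- soa_nodes(g)
  df$id[df$alias == alias]
}

node_alias_of <- function(g, id) {
  df <- soa_nodes(g)
  df$alias[df$id == id]
}

# Minimal three-node schedule used in many structural tests.
minimal_graph <- function() {
  with_local_seed(11, build_graph(
    nodes = list(
      soa_node("IS", role = "instantiation_start"),
      soa_node("V1", planned_timing = 0L, reference_timepoint = TRUE),
      soa_node("IF", role = "instantiation_finish")),
    edges = list(
      soa_transition("IS", "V1", delay = 0L, primary_path = TRUE),
      soa_transition("V1", "IF", delay = 0L, primary_path = TRUE)),
    graph_id = "soa-minimal", title = "Minimal SoA"))
}

# soa_graph -> igraph, for reachability / path-enumeration oracles.
as_igraph <- function(g) {
  nodes <- soagraph::soa_nodes(g)
  edges <- soagraph::soa_edges(g)
  igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = TRUE,
    vertices = nodes$alias)
}

# Exhaustive-path oracle: aliases of nodes lying on at least one simple
# IS -> IF path (self-loops are never part of a simple path).
nodes_on_is_if_paths <- function(g) {
  ig <- as_igraph(g)
  paths <- igraph::all_simple_paths(ig, from = "IS", to = "IF",
                                    mode = "out")
  unique(unlist(lapply(paths, names)))
}

# Random rule-set generator for parse/serialize and evaluation properties.
random_rule_set <- function(max_clauses = 4L) {
  k <- sample.int(max_clauses + 1L, 1L) - 1L
  clauses <- lapply(seq_len(k), function(i) {
    kind <- sample(c("exist", "not_exist", "maxRepeats", "n_cycles",
                     "flag_bool", "flag_str"), 1L)
    switch(kind,
      exist = rule_clause("interactions_exist",
                          sample(c("IS", "V1", "V2", "V3"),
                                 sample.int(3L, 1L))),
      not_exist = rule_clause("interactions_not_exist",
                              sample(c("V4", "V5", "IF"), sample.int(2L, 1L))),
      maxRepeats = rule_clause("maxRepeats", sample.int(5L, 1L)),
      n_cycles = rule_clause("n_cycles",
                             paste0(sample(c("<", "<=", "=", ">", ">="), 1L),
                                    sample.int(6L, 1L))),
      flag_bool = rule_clause(sample(c("consentObtained", "record_AE",
                                       "withdrawn"), 1L),
                              sample(c(TRUE, FALSE), 1L)),
      flag_str = rule_clause("studyPhase",
                             sample(c("onStudy", "screening"), 1L)))
  })
  rule_set(clauses)
}

random_context <- function() {
  n <- sample.int(5L, 1L)
  hist <- sample(c("IS", "V1", "V2", "V3", "V4", "V5", "IF"), n)
  soa_context(
    history = hist, days = sort(sample.int(30L, n)),
    counts = setNames(sample(0:5, n, replace = TRUE), hist),
    completed_cycles = sample(0:6, 1L),
    flags = list(consentObtained = sample(c(TRUE, FALSE), 1L),
                 record_AE = sample(c(TRUE, FALSE), 1L),
                 withdrawn = sample(c(TRUE, FALSE), 1L),
                 studyPhase = sample(c("onStudy", "screening"), 1L)))
}

# Dummy edge (with a target alias) for clause evaluation outside a graph.
dummy_edge <- function(target = "V1") {
  soa_transition("SRC", target, delay = 0L, id = "edge-dummy")
}
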