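# The SoA graph container: an interaction-level directed graph (visits and
# contacts, delimited by instantiation start/finish nodes) plus, per
# interaction, an optional activity subgraph delimited by activity
# start/finish nodes. Subgraphs are stored hierarchically, mirroring the
# visual containment of schedule diagrams and the nested-action layout of
# the FHIR mapping.

#' Assemble and validate a schedule-of-activities graph
#'
#' Nodes and edges may be authored with human-readable aliases; `build_graph`
#' assigns missing opaque ids (UUID v4), resolves edge endpoints from aliases
#' to ids, attaches activity subgraphs, and validates the result. Structural
#' problems (duplicate ids, dangling edge endpoints, missing boundary nodes)
#' raise an error carrying the validation report.
#'
#' @param nodes list of [soa_node()] objects (interaction level).
#' @param edges list of [soa_transition()] objects whose `source`/`target`
#'   name node aliases (or ids).
#' @param subgraphs named list keyed by interaction alias; each element is a
#'   `list(nodes = ..., edges = ...)` describing that visit's activity
#'   sequence, delimited by one `activity_start` and one `activity_finish`
#'   node.
#' @param graph_id,title identifier and display title of the study schedule.
#' @param metadata free-form named list of annotations.
#' @return an object of class `soa_graph`.
#' @examples
#' g <- build_graph(
#'   nodes = list(
#'     soa_node("IS", role = "instantiation_start"),
#'     soa_node("V1", planned_timing = 0, reference_timepoint = TRUE),
#'     soa_node("IF", role = "instantiation_finish")),
#'   edges = list(
#'     soa_transition("IS", "V1", delay = 0, primary_path = TRUE),
#'     soa_transition("V1", "IF", delay = 0, primary_path = TRUE)))
#' g
#' @export
build_graph <- function(nodes, edges, subgraphs = list(),
                        graph_id = NULL, title = "Untitled SoA",
                        metadata = list()) {
  if (length(nodes) == 0L) stop("an SoA graph requires at least one node")
  for (n in nodes) if (!inherits(n, "soa_node")) stop("nodes must be soa_node objects")
  for (e in edges) if (!inherits(e, "soa_transition")) stop("edges must be soa_transition objects")

  if (is.null(graph_id)) graph_id <- new_uuid()
  nodes <- assign_ids(nodes)
  edges <- assign_ids(edges)
  node_list <- setNames(nodes, vapply(nodes, `[[`, "", "id"))
  amap <- alias_map(node_list)
  edge_list <- setNames(lapply(edges, resolve_endpoints, amap = amap,
                               ids = names(node_list)),
                        vapply(edges, `[[`, "", "id"))

  sub_list <- list()
  if (length(subgraphs)) {
    if (is.null(names(subgraphs)) || any(!nzchar(names(subgraphs))))
      stop("subgraphs must be named by interaction alias")
    for (al in names(subgraphs)) {
      if (!al %in% names(amap))
        stop("subgraph attached to unknown interaction '", al, "'")
      sg <- subgraphs[[al]]
      sn <- assign_ids(sg$nodes)
      se <- assign_ids(sg$edges %||% list())
      snl <- setNames(sn, vapply(sn, `[[`, "", "id"))
      samap <- alias_map(snl)
      sel <- setNames(lapply(se, resolve_endpoints, amap = samap,
                             ids = names(snl)),
                      vapply(se, `[[`, "", "id"))
      sub_list[[amap[[al]]]] <- list(nodes = snl, edges = sel)
    }
  }

  g <- structure(
    list(graph_id = graph_id, title = title, nodes = node_list,
         edges = edge_list, subgraphs = sub_list, metadata = metadata),
    class = "soa_graph"
  )
  rep <- validate_graph(g)
  if (any(rep$severity == "error"))
    stop("invalid SoA graph:\n",
         paste(sprintf("  [%s] %s %s: %s", rep$severity, rep$element,
                       rep$id, rep$message), collapse = "\n"))
  g
}

assign_ids <- function(objs) {
  lapply(objs, function(o) {
    if (is.null(o$id)) o$id <- new_uuid()
    o
  })
}

alias_map <- function(node_list) {
  setNames(names(node_list), vapply(node_list, `[[`, "", "alias"))
}

resolve_endpoints <- function(e, amap, ids) {
  for (fld in c("source", "target")) {
    v <- e[[fld]]
    if (v %in% ids) next
    if (v %in% names(amap)) e[[fld]] <- amap[[v]]
    # unknown endpoints are left as-is; validate_graph reports them
  }
  e
}

node_alias <- function(g, id) g$nodes[[id]]$alias

node_by_alias <- function(g, alias) {
  for (n in g$nodes) if (n$alias == alias) return(n)
  NULL
}

out_edges <- function(g, node_id, explicit_only = FALSE) {
  sel <- Filter(function(e) e$source == node_id &&
                  (!explicit_only || e$origin == "explicit"), g$edges)
  unname(sel)
}

role_node <- function(nodes, role) {
  hits <- Filter(function(n) n$role == role, nodes)
  unname(hits)
}

# breadth-first reachability over a chosen edge subset
reachable_from <- function(nodes, edges, start_id) {
  seen <- start_id
  frontier <- start_id
  adj <- split(vapply(edges, `[[`, "", "target"),
               vapply(edges, `[[`, "", "source"))
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Validate an SoA graph
#'
#' Checks every structural invariant: unique node/edge ids and aliases,
#' edges referencing existing nodes, exactly one instantiation (or, for a
#' pure activity graph, activity) start and finish, at most one reference
#' timepoint, unscheduled nodes without planned timing, at most one outgoing
#' primary-path edge per node, reachability of the finish node along
#' explicit edges, and the same invariants inside every activity subgraph.
#' Findings are data, not errors: an empty report means a valid graph.
#'
#' @param g an `soa_graph`.
#' @return a data frame of class `soa_validation` with columns `severity`,
#'   `element`, `id`, `message`.
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "soa_graph"))
  top_level <- if (any(vapply(g$nodes, `[[`, "", "type") == "interaction"))
    "interaction" else "activity"
  f <- validate_level(g$nodes, g$edges, level = top_level)
  for (iid in names(g$subgraphs)) {
    sg <- g$subgraphs[[iid]]
    if (!iid %in% names(g$nodes))
      f <- add_finding(f, "error", "subgraph", iid,
                       "activity subgraph attached to unknown interaction")
    sf <- validate_level(sg$nodes, sg$edges, level = "activity")
    if (nrow(sf)) {
      sf$message <- paste0("[subgraph ", if (iid %in% names(g$nodes))
        node_alias(g, iid) else iid, "] ", sf$message)
      f <- rbind(f, sf)
    }
  }
  structure(f, class = c("soa_validation", "data.frame"))
}

new_findings <- function() {
  data.frame(severity = character(), element = character(),
             id = character(), message = character())
}

add_finding <- function(f, severity, element, id, message) {
  rbind(f, data.frame(severity = severity, element = element, id = id,
                      message = message))
}

validate_level <- function(nodes, edges, level = c("interaction", "activity")) {
  level <- match.arg(level)
  f <- new_findings()
  ids <- names(nodes)
  if (anyDuplicated(ids))
    f <- add_finding(f, "error", "node", ids[duplicated(ids)][1],
                     "duplicate node id")
  aliases <- vapply(nodes, `[[`, "", "alias")
  if (anyDuplicated(aliases))
    f <- add_finding(f, "error", "node", aliases[duplicated(aliases)][1],
                     "duplicate node alias")
  eids <- names(edges)
  if (anyDuplicated(eids))
    f <- add_finding(f, "error", "edge", eids[duplicated(eids)][1],
                     "duplicate edge id")

  for (e in edges) {
    for (fld in c("source", "target"))
      if (!e[[fld]] %in% ids)
        f <- add_finding(f, "error", "edge", e$id,
                         paste0(fld, " references unknown node '", e[[fld]], "'"))
  }

  start_role <- if (level == "interaction") "instantiation_start" else "activity_start"
  finish_role <- if (level == "interaction") "instantiation_finish" else "activity_finish"
  starts <- role_node(nodes, start_role)
  finishes <- role_node(nodes, finish_role)
  if (length(starts) != 1L)
    f <- add_finding(f, "error", "graph", "",
                     sprintf("expected exactly one %s node, found %d",
                             start_role, length(starts)))
  if (length(finishes) != 1L)
    f <- add_finding(f, "error", "graph", "",
                     sprintf("expected exactly one %s node, found %d",
                             finish_role, length(finishes)))

  refs <- Filter(function(n) n$reference_timepoint, nodes)
  if (length(refs) > 1L)
    f <- add_finding(f, "error", "node", refs[[2]]$id,
                     "more than one referenceTimepoint node")

  for (n in nodes)
    if (n$role == "unscheduled" && !is.na(n$planned_timing))
      f <- add_finding(f, "error", "node", n$id,
                       "unscheduled node carries a planned timing")

  # at most one outgoing primary-path edge per node
  prim_src <- vapply(Filter(function(e) e$primary_path, edges), `[[`, "", "source")
  dup <- prim_src[duplicated(prim_src)]
  if (length(dup))
    f <- add_finding(f, "error", "node", dup[1],
                     "more than one outgoing primaryPath edge")

  # finish reachable from start along explicit edges
  if (length(starts) == 1L && length(finishes) == 1L &&
      !any(f$severity == "error")) {
    seen <- reachable_from(nodes, Filter(function(e) e$origin == "explicit", edges),
                           starts[[1]]$id)
    if (!finishes[[1]]$id %in% seen)
      f <- add_finding(f, "error", "node", finishes[[1]]$id,
                       paste0(finishes[[1]]$alias,
                              " is not reachable from ", starts[[1]]$alias,
                              " along explicit edges"))
  }
  f
}

#' @export
print.soa_validation <- function(x, ...) {
  if (nrow(x) == 0L) cat("valid SoA graph: no findings\n")
  else {
    cat(nrow(x), "finding(s):\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s %s: %s\n", x$severity[i], x$element[i],
                  x$id[i], x$message[i]))
  }
  invisible(x)
}

#' Interaction nodes and edges as data frames
#'
#' @param g an `soa_graph`.
#' @return `soa_nodes()`: one row per interaction node; `soa_edges()`: one
#'   row per transition with aliases, delay and canonical rule text.
#' @export
soa_nodes <- function(g) {
  stopifnot(inherits(g, "soa_graph"))
  do.call(rbind, lapply(g$nodes, function(n) data.frame(
    id = n$id, alias = n$alias, type = n$type, role = n$role,
    name = n$name, planned_timing = n$planned_timing,
    reference_timepoint = n$reference_timepoint,
    row.names = NULL)))
}

#' @rdname soa_nodes
#' @export
soa_edges <- function(g) {
  stopifnot(inherits(g, "soa_graph"))
  do.call(rbind, lapply(g$edges, function(e) data.frame(
    id = e$id, source = node_alias(g, e$source) %||% e$source,
    target = node_alias(g, e$target) %||% e$target,
    delay = e$delay, type = e$type, primary_path = e$primary_path,
    origin = e$origin, rules = serialize_rule_set(e$rules),
    row.names = NULL)))
}

#' @export
print.soa_graph <- function(x, ...) {
  n_act <- sum(vapply(x$subgraphs, function(s) length(s$nodes), 0L))
  cat(sprintf("<soa_graph> '%s' (%s)\n", x$title, x$graph_id))
  cat(sprintf("  %d interactions, %d transitions, %d activity subgraph(s) (%d activity nodes)\n",
              length(x$nodes), length(x$edges), length(x$subgraphs), n_act))
  chain <- tryCatch(primary_chain(x), error = function(e) NULL)
  if (!is.null(chain))
    cat("  primary path:", paste(vapply(chain, function(i) node_alias(x, i), ""),
                                 collapse = " > "), "\n")
  invisible(x)
}

#' @export
summary.soa_graph <- function(object, ...) {
  print(object)
  rep <- validate_graph(object)
  print(rep)
  tr <- check_timing_consistency(object)
  print(tr)
  invisible(object)
}

#' Policy controlling implied-path expansion
#'
#' @param withdrawal add an implied edge from every visit to the
#'   instantiation-finish node: the participant's right to leave the study at
#'   any point.
#' @param unscheduled add paired routes between every post-reference visit
#'   and the unscheduled node, with auto-generated history rules on each
#'   return edge so only the next forward visit is selectable. `TRUE` uses
#'   the graph's unscheduled node when one exists; an alias names the node
#'   explicitly and is an error when absent.
#' @param unscheduled_delay delay, in days, on edges leaving the unscheduled
#'   node; this is the minimum spacing by which an unscheduled visit landing
#'   on a planned visit's day pushes that visit back.
#' @param unscheduled_self_loop allow consecutive unscheduled visits via an
#'   implied self-loop on the unscheduled node.
#' @param withdrawal_delay delay on implied withdrawal edges.
#' @return a list of class `soa_expansion_policy`.
#' @export
expansion_policy <- function(withdrawal = TRUE, unscheduled = TRUE,
                             unscheduled_delay = 1L,
                             unscheduled_self_loop = TRUE,
                             withdrawal_delay = 0L) {
  stopifnot(isTRUE(unscheduled) || isFALSE(unscheduled) ||
              is_string(unscheduled))
  structure(list(withdrawal = withdrawal, unscheduled = unscheduled,
                 unscheduled_delay = as.integer(unscheduled_delay),
                 unscheduled_self_loop = isTRUE(unscheduled_self_loop),
                 withdrawal_delay = as.integer(withdrawal_delay)),
            class = "soa_expansion_policy")
}

#' Expand protocol-implied paths
#'
#' A protocol's explicit schedule leaves many permitted paths implicit: the
#' participant may withdraw at any point, and an "as required" unscheduled
#' visit may be taken between planned visits but must return forward, never
#' to an earlier visit. This adds those paths as `origin = "implied"` edges:
#'
#' * a withdrawal edge from every visit (and the unscheduled node) to the
#'   instantiation-finish node;
#' * paired `Vn -> U` and `U -> Vn` edges for every post-reference visit,
#'   each return edge carrying an `interactions_exist` /
#'   `interactions_not_exist` rule pair over the primary-path visit aliases
#'   so that at runtime only the next not-yet-visited planned visit is
#'   available;
#' * optionally a self-loop on the unscheduled node so unscheduled visits
#'   may repeat on consecutive days.
#'
#' The operation is idempotent and never removes or mutates explicit nodes
#' or edges.
#'
#' @param g a valid `soa_graph`.
#' @param policy an [expansion_policy()].
#' @return a new `soa_graph` with implied edges added.
#' @export
expand_implied_paths <- function(g, policy = expansion_policy()) {
  stopifnot(inherits(g, "soa_graph"))
  chain <- primary_chain(g)
  chain_aliases <- vapply(chain, function(i) node_alias(g, i), "")
  finish <- role_node(g$nodes, "instantiation_finish")[[1]]
  u_nodes <- role_node(g$nodes, "unscheduled")
  if (is.character(policy$unscheduled)) {
    u <- node_by_alias(g, policy$unscheduled)
    if (is.null(u) || u$role != "unscheduled")
      stop("expansion policy references absent unscheduled node '",
           policy$unscheduled, "'")
    u_nodes <- list(u)
  }
  use_unscheduled <- !isFALSE(policy$unscheduled) && length(u_nodes) > 0L
  if (use_unscheduled && length(u_nodes) > 1L)
    stop("implied-path expansion supports at most one unscheduled node")

  pairs <- vapply(g$edges, function(e) paste(e$source, e$target), "")
  add <- list()
  add_edge <- function(lst, e) {
    key <- paste(e$source, e$target)
    if (key %in% pairs) return(lst)
    pairs <<- c(pairs, key)
    c(lst, list(e))
  }

  visit_ids <- chain[!vapply(chain, function(i)
    g$nodes[[i]]$role %in% c("instantiation_start", "instantiation_finish"),
    TRUE)]

  if (policy$withdrawal) {
    wd_sources <- c(visit_ids, vapply(u_nodes, `[[`, "", "id"))
    for (vid in wd_sources) {
      add <- add_edge(add, soa_transition(
        vid, finish$id, delay = policy$withdrawal_delay,
        origin = "implied", id = new_uuid()))
    }
  }

  if (use_unscheduled) {
    u <- u_nodes[[1]]
    ref_idx <- reference_index(g, chain)
    post_ref <- visit_ids[vapply(visit_ids, function(i)
      match(i, chain) >= ref_idx, TRUE)]
    for (vid in post_ref) {
      add <- add_edge(add, soa_transition(
        vid, u$id, delay = policy$unscheduled_delay,
        origin = "implied", id = new_uuid()))
      k <- match(vid, chain)
      exist <- chain_aliases[seq_len(k - 1L)]
      not_exist <- chain_aliases[k:length(chain_aliases)]
      rs <- rule_set(rule_clause("interactions_exist", exist),
                     rule_clause("interactions_not_exist", not_exist))
      add <- add_edge(add, soa_transition(
        u$id, vid, delay = policy$unscheduled_delay, rules = rs,
        origin = "implied", id = new_uuid()))
    }
    if (policy$unscheduled_self_loop)
      add <- add_edge(add, soa_transition(
        u$id, u$id, delay = policy$unscheduled_delay,
        origin = "implied", id = new_uuid()))
  }

  if (length(add)) {
    add <- setNames(add, vapply(add, `[[`, "", "id"))
    g$edges <- c(g$edges, add)
  }
  g
}

# Index (within the primary chain) of the reference timepoint node.
reference_index <- function(g, chain = primary_chain(g)) {
  ref <- Filter(function(n) n$reference_timepoint, g$nodes)
  if (length(ref) != 1L) stop("graph has no unique referenceTimepoint node")
  idx <- match(ref[[1]]$id, chain)
  if (is.na(idx)) stop("referenceTimepoint node is not on the primary path")
  idx
}

#' Promote a visit's activity subgraph to a walkable graph
#'
#' Extracts the activity subgraph attached to an interaction as a standalone
#' `soa_graph` (delimited by its activity start/finish nodes) so the walker
#' can traverse the within-visit activity sequence, e.g. to exercise
#' early-exit or repeat rules.
#'
#' @param g an `soa_graph`.
#' @param interaction interaction alias or node id owning the subgraph.
#' @return an activity-level `soa_graph`.
#' @export
activity_graph <- function(g, interaction) {
  stopifnot(inherits(g, "soa_graph"))
  iid <- if (interaction %in% names(g$nodes)) interaction else {
    n <- node_by_alias(g, interaction)
    if (is.null(n)) stop("unknown interaction '", interaction, "'")
    n$id
  }
  sg <- g$subgraphs[[iid]]
  if (is.null(sg))
    stop("interaction '", node_alias(g, iid), "' has no activity subgraph")
  structure(
    list(graph_id = paste0(g$graph_id, ":", node_alias(g, iid)),
         title = paste0(g$title, " / ", node_alias(g, iid), " activities"),
         nodes = sg$nodes, edges = sg$edges, subgraphs = list(),
         metadata = list()),
    class = "soa_graph"
  )
}

#' The primary schedule path
#'
#' Follows `primary_path` edges from the instantiation-start node. Each
#' interaction node may carry at most one outgoing primary edge, so the
#' chain is unique.
#'
#' @param g an `soa_graph`.
#' @return character vector of node ids, in schedule order.
#' @export
primary_chain <- function(g) {
  starts <- role_node(g$nodes, "instantiation_start")
  if (length(starts) != 1L) {
    starts <- role_node(g$nodes, "activity_start")
    if (length(starts) != 1L) stop("graph has no unique start node")
  }
  chain <- starts[[1]]$id
  cur <- chain
  repeat {
    nxt <- Filter(function(e) e$primary_path, out_edges(g, cur))
    if (length(nxt) == 0L) break
    cur <- nxt[[1]]$target
    if (cur %in% chain) stop("primary path contains a cycle")
    chain <- c(chain, cur)
  }
  chain
}
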