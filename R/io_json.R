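# Native SoA graph document: JSON with top-level
# {graphID, title, nodes[], edges[], activitySubgraphs{}, metadata{}}.
# A JSON-Schema description of the format ships in
# inst/extdata/soa-graph-schema.json.

node_to_list <- function(n) {
  out <- list(id = n$id, alias = n$alias, type = n$type)
  if (!is.na(n$subtype)) out$subtype <- n$subtype
  out$name <- n$name
  if (!is.na(n$description)) out$description <- n$description
  if (!is.na(n$planned_timing)) out$plannedTiming <- n$planned_timing
  out$referenceTimepoint <- n$reference_timepoint
  if (!is.null(n$planned_window))
    out$plannedWindow <- list(earlier = n$planned_window[1],
                              later = n$planned_window[2])
  if (!is.na(n$planned_duration)) out$plannedDuration <- n$planned_duration
  out$role <- n$role
  out
}

list_to_node <- function(x) {
  soa_node(
    alias = x$alias, type = x$type, name = x$name %||% x$alias,
    role = x$role %||% "regular",
    planned_timing = x$plannedTiming %||% NA_integer_,
    reference_timepoint = isTRUE(x$referenceTimepoint),
    planned_window = if (!is.null(x$plannedWindow))
      c(x$plannedWindow$earlier, x$plannedWindow$later),
    planned_duration = x$plannedDuration %||% NA_real_,
    subtype = x$subtype %||% NA_character_,
    description = x$description %||% NA_character_,
    id = x$id
  )
}

edge_to_list <- function(e) {
  out <- list(id = e$id, source = e$source, target = e$target,
              transitionDelay = e$delay)
  if (!is.null(e$window))
    out$transitionWindow <- list(earlier = e$window[1], later = e$window[2])
  out$transitionType <- e$type
  rt <- serialize_rule_set(e$rules)
  if (nzchar(rt)) out$transitionRule <- rt
  out$primaryPath <- e$primary_path
  out$origin <- e$origin
  out
}

list_to_edge <- function(x) {
  soa_transition(
    source = x$source, target = x$target, delay = x$transitionDelay,
    window = if (!is.null(x$transitionWindow))
      c(x$transitionWindow$earlier, x$transitionWindow$later),
    type = x$transitionType %||% "start_to_start",
    rules = parse_rule_set(x$transitionRule %||% ""),
    primary_path = isTRUE(x$primaryPath),
    origin = x$origin %||% "explicit",
    id = x$id
  )
}

#' Write / read the native SoA graph JSON document
#'
#' @param g an `soa_graph`.
#' @param path output file; when `NULL`, the JSON text is returned.
#' @return `write_soa_json()`: the JSON text, invisibly when written to a
#'   file. `read_soa_json()`: an `soa_graph`.
#' @export
write_soa_json <- function(g, path = NULL) {
  stopifnot(inherits(g, "soa_graph"))
  doc <- list(
    graphID = g$graph_id, title = g$title,
    nodes = lapply(unname(g$nodes), node_to_list),
    edges = lapply(unname(g$edges), edge_to_list),
    activitySubgraphs = lapply(g$subgraphs, function(sg) list(
      nodes = lapply(unname(sg$nodes), node_to_list),
      edges = lapply(unname(sg$edges), edge_to_list))),
    metadata = g$metadata
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname write_soa_json
#' @param x a file path or JSON text.
#' @export
read_soa_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  for (fld in c("graphID", "nodes", "edges"))
    if (is.null(doc[[fld]])) stop("not an SoA graph document: missing ", fld)
  nodes <- lapply(doc$nodes, list_to_node)
  edges <- lapply(doc$edges, list_to_edge)
  subs <- lapply(doc$activitySubgraphs %||% list(), function(sg) {
    sn <- lapply(sg$nodes, list_to_node)
    se <- lapply(sg$edges, list_to_edge)
    list(nodes = setNames(sn, vapply(sn, `[[`, "", "id")),
         edges = setNames(se, vapply(se, `[[`, "", "id")))
  })
  structure(
    list(graph_id = doc$graphID, title = doc$title %||% "Untitled SoA",
         nodes = setNames(nodes, vapply(nodes, `[[`, "", "id")),
         edges = setNames(edges, vapply(edges, `[[`, "", "id")),
         subgraphs = subs,
         metadata = doc$metadata %||% list()),
    class = "soa_graph"
  )
}
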