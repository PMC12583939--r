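# GraphML read/write for visual editing (yEd-compatible): every node and
# edge attribute travels in <data> keys, rule text rides on the edge, and a
# minimal yFiles graphics section colors nodes by role so exported files
# open as a readable two-level layout. Activity subgraphs use GraphML's
# nested <graph> inside the owning interaction's <node>.

GRAPHML_NODE_KEYS <- c("alias", "type", "subtype", "name", "description",
                       "plannedTiming", "referenceTimepoint",
                       "plannedWindowEarlier", "plannedWindowLater",
                       "plannedDuration", "role")
GRAPHML_EDGE_KEYS <- c("transitionDelay", "transitionWindowEarlier",
                       "transitionWindowLater", "transitionType",
                       "transitionRule", "primaryPath", "origin")

role_color <- function(role, type) {
  if (role %in% c("instantiation_start", "activity_start", "cycle_start"))
    return("#99FF99")
  if (role %in% c("instantiation_finish", "activity_finish", "cycle_finish"))
    return("#FF9999")
  if (role == "unscheduled") return("#99CCFF")
  if (type == "activity") return("#FFFF99")
  "#CCCCFF"
}

node_data_values <- function(n) {
  v <- list(alias = n$alias, type = n$type, subtype = n$subtype,
            name = n$name, description = n$description,
            plannedTiming = n$planned_timing,
            referenceTimepoint = tolower(as.character(n$reference_timepoint)),
            plannedWindowEarlier = if (!is.null(n$planned_window)) n$planned_window[1],
            plannedWindowLater = if (!is.null(n$planned_window)) n$planned_window[2],
            plannedDuration = n$planned_duration, role = n$role)
  Filter(function(x) !is.null(x) && !is.na(x), v)
}

edge_data_values <- function(e) {
  rt <- serialize_rule_set(e$rules)
  v <- list(transitionDelay = e$delay,
            transitionWindowEarlier = if (!is.null(e$window)) e$window[1],
            transitionWindowLater = if (!is.null(e$window)) e$window[2],
            transitionType = e$type,
            transitionRule = if (nzchar(rt)) rt,
            primaryPath = tolower(as.character(e$primary_path)),
            origin = e$origin)
  Filter(function(x) !is.null(x) && !is.na(x), v)
}

add_data <- function(parent, values, key_ids) {
  for (nm in names(values))
    xml2::xml_add_child(parent, "data", as.character(values[[nm]]),
                        key = key_ids[[nm]])
}

write_graphml_node <- function(parent, n, key_ids, subgraph = NULL) {
  nd <- xml2::xml_add_child(parent, "node", id = n$id)
  add_data(nd, node_data_values(n), key_ids)
  gfx <- xml2::xml_add_child(nd, "data", key = "d_gfx")
  shp <- xml2::xml_add_child(gfx, "y:ShapeNode")
  xml2::xml_add_child(shp, "y:Fill", color = role_color(n$role, n$type))
  xml2::xml_add_child(shp, "y:NodeLabel", n$alias)
  if (!is.null(subgraph)) {
    sg <- xml2::xml_add_child(nd, "graph", id = paste0(n$id, ":activities"),
                              edgedefault = "directed")
    for (sn in subgraph$nodes) write_graphml_node(sg, sn, key_ids)
    for (se in subgraph$edges) write_graphml_edge(sg, se, key_ids)
  }
  nd
}

write_graphml_edge <- function(parent, e, key_ids) {
  ed <- xml2::xml_add_child(parent, "edge", id = e$id,
                            source = e$source, target = e$target)
  add_data(ed, edge_data_values(e), key_ids)
  rt <- serialize_rule_set(e$rules)
  if (nzchar(rt)) {
    gfx <- xml2::xml_add_child(ed, "data", key = "d_egfx")
    pl <- xml2::xml_add_child(gfx, "y:PolyLineEdge")
    xml2::xml_add_child(pl, "y:EdgeLabel", rt)
  }
  ed
}

#' Write / read an SoA graph as GraphML
#'
#' Lossless for every node and edge attribute (carried in GraphML data
#' keys; rule text as an edge attribute and as a yEd edge label). Unknown
#' data keys encountered on reading are preserved under
#' `metadata$graphml_unknown` rather than dropped.
#'
#' @param g an `soa_graph`.
#' @param path output (or input) `.graphml` file.
#' @return `write_graphml()` returns `path` invisibly; `read_graphml()`
#'   returns an `soa_graph`.
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "soa_graph"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns",
    "xmlns:y" = "http://www.yworks.com/xml/graphml")
  key_ids <- c(
    setNames(paste0("dn", seq_along(GRAPHML_NODE_KEYS)), GRAPHML_NODE_KEYS),
    setNames(paste0("de", seq_along(GRAPHML_EDGE_KEYS)), GRAPHML_EDGE_KEYS))
  for (nm in GRAPHML_NODE_KEYS)
    xml2::xml_add_child(doc, "key", id = key_ids[[nm]], `for` = "node",
                        attr.name = nm, attr.type = "string")
  for (nm in GRAPHML_EDGE_KEYS)
    xml2::xml_add_child(doc, "key", id = key_ids[[nm]], `for` = "edge",
                        attr.name = nm, attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "dg1", `for` = "graph",
                      attr.name = "title", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "d_gfx", `for` = "node",
                      yfiles.type = "nodegraphics")
  xml2::xml_add_child(doc, "key", id = "d_egfx", `for` = "edge",
                      yfiles.type = "edgegraphics")
  gr <- xml2::xml_add_child(doc, "graph", id = g$graph_id,
                            edgedefault = "directed")
  xml2::xml_add_child(gr, "data", g$title, key = "dg1")
  for (n in g$nodes)
    write_graphml_node(gr, n, key_ids, subgraph = g$subgraphs[[n$id]])
  for (e in g$edges) write_graphml_edge(gr, e, key_ids)
  xml2::write_xml(doc, path)
  invisible(path)
}

graphml_node_from_xml <- function(nd, key_names) {
  vals <- list()
  unknown <- list()
  for (d in xml2::xml_find_all(nd, "./data")) {
    k <- xml2::xml_attr(d, "key")
    nm <- key_names[[k]] %||% NA_character_
    if (is.na(nm)) next
    if (nm == "<graphics>") next
    vals[[nm]] <- xml2::xml_text(d)
  }
  win <- if (!is.null(vals$plannedWindowEarlier))
    as.integer(c(vals$plannedWindowEarlier, vals$plannedWindowLater))
  soa_node(
    alias = vals$alias, type = vals$type %||% "interaction",
    name = vals$name %||% vals$alias, role = vals$role %||% "regular",
    planned_timing = as.integer(vals$plannedTiming %||% NA),
    reference_timepoint = identical(vals$referenceTimepoint, "true"),
    planned_window = win,
    planned_duration = as.numeric(vals$plannedDuration %||% NA),
    subtype = vals$subtype %||% NA_character_,
    description = vals$description %||% NA_character_,
    id = xml2::xml_attr(nd, "id")
  )
}

graphml_edge_from_xml <- function(ed, key_names) {
  vals <- list()
  for (d in xml2::xml_find_all(ed, "./data")) {
    nm <- key_names[[xml2::xml_attr(d, "key")]] %||% NA_character_
    if (is.na(nm) || nm == "<graphics>") next
    vals[[nm]] <- xml2::xml_text(d)
  }
  win <- if (!is.null(vals$transitionWindowEarlier))
    as.integer(c(vals$transitionWindowEarlier, vals$transitionWindowLater))
  soa_transition(
    source = xml2::xml_attr(ed, "source"),
    target = xml2::xml_attr(ed, "target"),
    delay = as.integer(vals$transitionDelay),
    window = win, type = vals$transitionType %||% "start_to_start",
    rules = parse_rule_set(vals$transitionRule %||% ""),
    primary_path = identical(vals$primaryPath, "true"),
    origin = vals$origin %||% "explicit",
    id = xml2::xml_attr(ed, "id")
  )
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  known <- c(GRAPHML_NODE_KEYS, GRAPHML_EDGE_KEYS, "title")
  key_names <- list()
  unknown_keys <- character()
  for (k in xml2::xml_find_all(doc, "./key")) {
    id <- xml2::xml_attr(k, "id")
    nm <- xml2::xml_attr(k, "attr.name")
    if (!is.na(xml2::xml_attr(k, "yfiles.type"))) {
      key_names[[id]] <- "<graphics>"
    } else if (!is.na(nm) && nm %in% known) {
      key_names[[id]] <- nm
    } else {
      key_names[[id]] <- "<graphics>"   # opaque; collected below
      unknown_keys <- c(unknown_keys, nm %||% id)
    }
  }
  gr <- xml2::xml_find_first(doc, "./graph")
  title <- "Untitled SoA"
  for (d in xml2::xml_find_all(gr, "./data"))
    if (identical(key_names[[xml2::xml_attr(d, "key")]], "title"))
      title <- xml2::xml_text(d)

  nodes <- list(); edges <- list(); subgraphs <- list()
  for (nd in xml2::xml_find_all(gr, "./node")) {
    n <- graphml_node_from_xml(nd, key_names)
    nodes[[n$id]] <- n
    sg <- xml2::xml_find_first(nd, "./graph")
    if (!inherits(sg, "xml_missing")) {
      sn <- list(); se <- list()
      for (snd in xml2::xml_find_all(sg, "./node")) {
        x <- graphml_node_from_xml(snd, key_names)
        sn[[x$id]] <- x
      }
      for (sed in xml2::xml_find_all(sg, "./edge")) {
        x <- graphml_edge_from_xml(sed, key_names)
        se[[x$id]] <- x
      }
      subgraphs[[n$id]] <- list(nodes = sn, edges = se)
    }
  }
  for (ed in xml2::xml_find_all(gr, "./edge")) {
    e <- graphml_edge_from_xml(ed, key_names)
    edges[[e$id]] <- e
  }
  metadata <- list()
  if (length(unknown_keys))
    metadata$graphml_unknown <- as.list(unknown_keys)
  structure(
    list(graph_id = xml2::xml_attr(gr, "id"), title = title,
         nodes = nodes, edges = edges, subgraphs = subgraphs,
         metadata = metadata),
    class = "soa_graph"
  )
}
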