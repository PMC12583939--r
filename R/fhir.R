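# FHIR R5 PlanDefinition mapping. Interaction nodes map to
# PlanDefinition.action, transitions to PlanDefinition.action.action; the
# soaTimePoint and soaTransition extensions carry the node and edge
# attributes the base resource has no elements for, and each rule clause is
# carried as one action.condition (kind "applicability") whose expression
# text is the canonical rule dialect. groupingBehavior "logical-group" with
# selectionBehavior "exactly-one" restricts path selection to one path.
# Activity subgraphs are emitted as a nested action group per interaction.

#' FHIR mapping profile
#'
#' @param extension_base_url canonical URL prefix under which the
#'   `soa-time-point` and `soa-transition` StructureDefinitions live; must
#'   be stable across a round trip.
#' @param rule_language media-type label for rule expression text. The rule
#'   dialect is illustrative, not directly executable in a FHIR environment;
#'   translation to FHIRPath or CQL is downstream tooling.
#' @param nest_activities emit activity subgraphs as nested action groups.
#' @return a list of class `soa_mapping_profile`.
#' @export
mapping_profile <- function(extension_base_url = "http://example.org/fhir/soa",
                            rule_language = "text/x-soa-rule",
                            nest_activities = TRUE) {
  stopifnot(is_string(extension_base_url), nzchar(extension_base_url))
  structure(list(base = sub("/$", "", extension_base_url),
                 rule_language = rule_language,
                 nest_activities = isTRUE(nest_activities)),
            class = "soa_mapping_profile")
}

profile_urls <- function(profile) {
  list(timepoint = paste0(profile$base, "/StructureDefinition/soa-time-point"),
       transition = paste0(profile$base, "/StructureDefinition/soa-transition"),
       activity_group = paste0(profile$base, "/StructureDefinition/soa-activity-group"),
       metadata = paste0(profile$base, "/StructureDefinition/soa-graph-metadata"))
}

ext <- function(url, ...) c(list(url = url), list(...))

timepoint_extension <- function(n, urls) {
  sub <- list(ext("alias", valueString = n$alias),
              ext("type", valueCode = n$type))
  if (!is.na(n$subtype)) sub <- c(sub, list(ext("subtype", valueString = n$subtype)))
  sub <- c(sub, list(ext("name", valueString = n$name)))
  if (!is.na(n$description))
    sub <- c(sub, list(ext("description", valueString = n$description)))
  if (!is.na(n$planned_timing))
    sub <- c(sub, list(ext("plannedTiming", valueInteger = n$planned_timing)))
  sub <- c(sub, list(ext("referenceTimepoint", valueBoolean = n$reference_timepoint)))
  if (!is.null(n$planned_window))
    sub <- c(sub, list(ext("plannedWindow", extension = list(
      ext("earlier", valueInteger = n$planned_window[1]),
      ext("later", valueInteger = n$planned_window[2])))))
  if (!is.na(n$planned_duration))
    sub <- c(sub, list(ext("plannedDuration", valueDecimal = n$planned_duration)))
  sub <- c(sub, list(ext("role", valueCode = n$role)))
  ext(urls$timepoint, extension = sub)
}

transition_extension <- function(e, urls) {
  sub <- list(ext("target", valueString = e$target),
              ext("transitionDelay", valueInteger = e$delay))
  if (!is.null(e$window))
    sub <- c(sub, list(ext("transitionWindow", extension = list(
      ext("earlier", valueInteger = e$window[1]),
      ext("later", valueInteger = e$window[2])))))
  sub <- c(sub, list(ext("transitionType", valueCode = e$type),
                     ext("primaryPath", valueBoolean = e$primary_path),
                     ext("origin", valueCode = e$origin)))
  ext(urls$transition, extension = sub)
}

edge_action <- function(e, urls, profile) {
  act <- list(id = e$id, extension = list(transition_extension(e, urls)))
  if (n_clauses(e$rules) > 0L)
    act$condition <- lapply(e$rules$clauses, function(cl) list(
      kind = "applicability",
      expression = list(language = profile$rule_language,
                        expression = serialize_clause(cl))))
  act
}

node_action <- function(n, edges, urls, profile, subgraph = NULL,
                        activity = FALSE) {
  out <- lapply(edges, function(e) if (e$source == n$id)
    edge_action(e, urls, profile) else NULL)
  out <- Filter(Negate(is.null), out)
  act <- list(id = n$id, title = n$name)
  if (!is.na(n$description)) act$description <- n$description
  act$extension <- list(timepoint_extension(n, urls))
  if (activity && n$role == "regular")   # boundary nodes are not tasks
    act$definitionCanonical <- paste0("ActivityDefinition/", slugify(n$name))
  act$groupingBehavior <- "logical-group"
  act$selectionBehavior <- "exactly-one"
  sub_actions <- unname(out)
  if (!is.null(subgraph) && profile$nest_activities) {
    grp <- list(id = paste0(n$id, ":activities"),
                extension = list(ext(urls$activity_group, valueBoolean = TRUE)),
                groupingBehavior = "logical-group",
                selectionBehavior = "exactly-one",
                action = unname(lapply(subgraph$nodes, function(sn)
                  node_action(sn, subgraph$edges, urls, profile,
                              activity = TRUE))))
    sub_actions <- c(sub_actions, list(grp))
  }
  if (length(sub_actions)) act$action <- sub_actions
  act
}

#' Convert an SoA graph to a FHIR R5 PlanDefinition
#'
#' One top-level action per interaction node (carrying a `soaTimePoint`
#' extension), one sub-action per outgoing transition (carrying a
#' `soaTransition` extension plus one applicability condition per rule
#' clause), and — when the profile nests activities — one nested action
#' group per activity subgraph, whose activity actions link to
#' ActivityDefinition stubs via `definitionCanonical` (see
#' [emit_stub_context()]). Serialization through [fhir_json()] is canonical:
#' converting the same graph twice yields byte-identical documents.
#'
#' @param g a valid `soa_graph`.
#' @param profile a [mapping_profile()].
#' @param validate refuse to map a structurally invalid graph (default);
#'   disable to serialize fragments, e.g. a single node.
#' @return a `plan_definition` list ready for [fhir_json()].
#' @export
to_plan_definition <- function(g, profile = mapping_profile(),
                               validate = TRUE) {
  stopifnot(inherits(g, "soa_graph"), inherits(profile, "soa_mapping_profile"))
  if (validate) {
    rep <- validate_graph(g)
    if (any(rep$severity == "error"))
      stop("cannot map an invalid graph to FHIR; run validate_graph() first")
  }
  urls <- profile_urls(profile)
  pd <- list(resourceType = "PlanDefinition", id = g$graph_id,
             url = paste0(profile$base, "/PlanDefinition/", g$graph_id),
             title = g$title, status = "draft")
  if (length(g$metadata))
    pd$extension <- list(ext(urls$metadata, valueString = as.character(
      jsonlite::toJSON(g$metadata, auto_unbox = TRUE, digits = NA))))
  pd$action <- unname(lapply(g$nodes, function(n)
    node_action(n, g$edges, urls, profile,
                subgraph = g$subgraphs[[n$id]])))
  structure(pd, class = "plan_definition")
}

#' Serialize a FHIR resource to canonical JSON
#'
#' @param x a `plan_definition` or bundle list.
#' @param path optional output file.
#' @return the JSON text (invisibly when written to `path`).
#' @export
fhir_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.plan_definition <- function(x, ...) {
  n_act <- length(x$action)
  n_sub <- sum(vapply(x$action, function(a)
    length(Filter(function(s) !is.null(s$extension) &&
                    grepl("soa-transition$", s$extension[[1]]$url),
                  a$action %||% list())), 0L))
  cat(sprintf("<PlanDefinition> %s '%s': %d action(s), %d transition sub-action(s)\n",
              x$id, x$title, n_act, n_sub))
  invisible(x)
}

find_extension <- function(obj, url) {
  for (e in obj$extension %||% list()) if (identical(e$url, url)) return(e)
  NULL
}

sub_ext_value <- function(e, name) {
  for (s in e$extension %||% list()) {
    if (identical(s$url, name)) {
      vals <- s[setdiff(names(s), c("url", "extension"))]
      if (length(vals)) return(vals[[1]])
      return(s$extension)
    }
  }
  NULL
}

window_from_ext <- function(e, name) {
  w <- sub_ext_value(e, name)
  if (is.null(w)) return(NULL)
  get1 <- function(nm) {
    for (s in w) if (identical(s$url, nm)) return(s$valueInteger)
    NA_integer_
  }
  c(get1("earlier"), get1("later"))
}

node_from_action <- function(act, urls) {
  tp <- find_extension(act, urls$timepoint)
  if (is.null(tp))
    stop("action '", act$id %||% "<no id>",
         "' is missing the soaTimePoint extension")
  soa_node(
    alias = sub_ext_value(tp, "alias"),
    type = sub_ext_value(tp, "type"),
    name = sub_ext_value(tp, "name"),
    role = sub_ext_value(tp, "role") %||% "regular",
    planned_timing = sub_ext_value(tp, "plannedTiming") %||% NA_integer_,
    reference_timepoint = isTRUE(sub_ext_value(tp, "referenceTimepoint")),
    planned_window = window_from_ext(tp, "plannedWindow"),
    planned_duration = sub_ext_value(tp, "plannedDuration") %||% NA_real_,
    subtype = sub_ext_value(tp, "subtype") %||% NA_character_,
    description = sub_ext_value(tp, "description") %||% NA_character_,
    id = act$id
  )
}

edge_from_action <- function(sub, source_id, urls) {
  tr <- find_extension(sub, urls$transition)
  clauses <- lapply(sub$condition %||% list(), function(cond) {
    expr <- cond$expression$expression
    if (is.null(expr)) stop("condition without expression on sub-action '",
                            sub$id %||% "<no id>", "'")
    rs <- parse_rule_set(expr)
    if (n_clauses(rs) != 1L)
      stop("condition expression is not a single clause: ", expr)
    rs$clauses[[1]]
  })
  tgt <- sub_ext_value(tr, "target")
  if (is.null(tgt)) stop("soaTransition extension on sub-action '",
                         sub$id %||% "<no id>", "' has no target")
  soa_transition(
    source = source_id, target = tgt,
    delay = sub_ext_value(tr, "transitionDelay"),
    window = window_from_ext(tr, "transitionWindow"),
    type = sub_ext_value(tr, "transitionType") %||% "start_to_start",
    rules = rule_set(clauses),
    primary_path = isTRUE(sub_ext_value(tr, "primaryPath")),
    origin = sub_ext_value(tr, "origin") %||% "explicit",
    id = sub$id
  )
}

is_transition_action <- function(sub, urls) !is.null(find_extension(sub, urls$transition))
is_activity_group <- function(sub, urls) !is.null(find_extension(sub, urls$activity_group))

#' Reconstruct an SoA graph from a FHIR R5 PlanDefinition
#'
#' Inverse of [to_plan_definition()]: nodes come back from actions, edges
#' from transition sub-actions (rule text parsed back into rule sets), and
#' activity subgraphs from nested activity groups. Missing extensions,
#' unparseable condition expressions and dangling transition targets are
#' errors naming the offending action.
#'
#' @param doc a PlanDefinition as a list, JSON text, or file path.
#' @param profile the [mapping_profile()] the document was produced with.
#' @return an `soa_graph`.
#' @export
from_plan_definition <- function(doc, profile = mapping_profile()) {
  if (is.character(doc)) doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  if (!identical(doc$resourceType, "PlanDefinition"))
    stop("document is not a FHIR PlanDefinition")
  urls <- profile_urls(profile)
  metadata <- list()
  md <- find_extension(doc, urls$metadata)
  if (!is.null(md))
    metadata <- jsonlite::fromJSON(md$valueString, simplifyVector = FALSE)

  nodes <- list(); edges <- list(); subgraphs <- list()
  for (act in doc$action %||% list()) {
    n <- node_from_action(act, urls)
    nodes[[n$id]] <- n
    for (sub in act$action %||% list()) {
      if (is_transition_action(sub, urls)) {
        e <- edge_from_action(sub, n$id, urls)
        edges[[e$id]] <- e
      } else if (is_activity_group(sub, urls)) {
        sn <- list(); se <- list()
        for (aact in sub$action %||% list()) {
          an <- node_from_action(aact, urls)
          sn[[an$id]] <- an
          for (asub in aact$action %||% list())
            if (is_transition_action(asub, urls)) {
              ae <- edge_from_action(asub, an$id, urls)
              se[[ae$id]] <- ae
            }
        }
        subgraphs[[n$id]] <- list(nodes = sn, edges = se)
      }
    }
  }
  for (e in edges)
    if (!e$target %in% names(nodes))
      stop("transition sub-action '", e$id, "' targets unknown node '",
           e$target, "'")
  structure(
    list(graph_id = doc$id, title = doc$title %||% "Untitled SoA",
         nodes = nodes, edges = edges, subgraphs = subgraphs,
         metadata = metadata),
    class = "soa_graph"
  )
}

#' Round-trip structural-equivalence check
#'
#' Converts the graph to a PlanDefinition, parses it back, and diffs the
#' result against the original attribute by attribute. An empty diff is the
#' operational definition of "no SoA information loss".
#'
#' @param g an `soa_graph`.
#' @param profile a [mapping_profile()].
#' @return an `soa_diff` (see [diff_graphs()]).
#' @export
roundtrip_check <- function(g, profile = mapping_profile()) {
  diff_graphs(g, from_plan_definition(to_plan_definition(g, profile), profile))
}

#' Validate a PlanDefinition against the SoA profile
#'
#' A structural profile check, reconstructed from the extension layout this
#' package emits (the formally published profile artifacts are not
#' reproduced here): resource type, presence and completeness of the
#' soaTimePoint extension on every action and the soaTransition extension on
#' every transition sub-action, applicability conditions in the profile's
#' rule language, the grouping/selection behaviors that restrict selection
#' to one path, and resolvable transition targets.
#'
#' @param doc a PlanDefinition list, JSON text, or file path.
#' @param profile a [mapping_profile()].
#' @return an `soa_validation` data frame; empty means conformant.
#' @export
validate_plan_definition <- function(doc, profile = mapping_profile()) {
  if (is.character(doc)) doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  urls <- profile_urls(profile)
  f <- new_findings()
  if (!identical(doc$resourceType, "PlanDefinition"))
    f <- add_finding(f, "error", "resource", doc$id %||% "",
                     "resourceType is not PlanDefinition")
  node_ids <- character()
  check_action <- function(f, act, where) {
    tp <- find_extension(act, urls$timepoint)
    if (is.null(tp))
      return(add_finding(f, "error", "action", act$id %||% "",
                         paste0(where, " action lacks soaTimePoint extension")))
    for (req in c("alias", "type", "name", "role"))
      if (is.null(sub_ext_value(tp, req)))
        f <- add_finding(f, "error", "action", act$id %||% "",
                         paste0("soaTimePoint missing required element '", req, "'"))
    if (!identical(act$groupingBehavior, "logical-group") ||
        !identical(act$selectionBehavior, "exactly-one"))
      f <- add_finding(f, "warning", "action", act$id %||% "",
                       "grouping/selection behaviors do not restrict selection to one path")
    f
  }
  check_sub <- function(f, sub) {
    tr <- find_extension(sub, urls$transition)
    if (is.null(tr))
      return(add_finding(f, "error", "sub-action", sub$id %||% "",
                         "transition sub-action lacks soaTransition extension"))
    for (req in c("target", "transitionDelay", "transitionType", "origin"))
      if (is.null(sub_ext_value(tr, req)))
        f <- add_finding(f, "error", "sub-action", sub$id %||% "",
                         paste0("soaTransition missing required element '", req, "'"))
    for (cond in sub$condition %||% list()) {
      if (!identical(cond$kind, "applicability"))
        f <- add_finding(f, "error", "sub-action", sub$id %||% "",
                         "condition kind is not 'applicability'")
      if (!identical(cond$expression$language, profile$rule_language))
        f <- add_finding(f, "error", "sub-action", sub$id %||% "",
                         "condition expression language mismatch")
    }
    f
  }
  targets <- character()
  for (act in doc$action %||% list()) {
    node_ids <- c(node_ids, act$id %||% "")
    f <- check_action(f, act, "top-level")
    for (sub in act$action %||% list()) {
      if (is_activity_group(sub, urls)) {
        for (aact in sub$action %||% list()) {
          f <- check_action(f, aact, "activity")
          for (asub in aact$action %||% list())
            f <- check_sub(f, asub)
        }
      } else {
        f <- check_sub(f, sub)
        tr <- find_extension(sub, urls$transition)
        if (!is.null(tr)) {
          tg <- sub_ext_value(tr, "target")
          if (!is.null(tg)) targets <- c(targets, tg)
        }
      }
    }
  }
  for (tg in setdiff(targets, node_ids))
    f <- add_finding(f, "error", "sub-action", tg,
                     "transition target does not resolve to an action")
  structure(f, class = c("soa_validation", "data.frame"))
}

#' Emit the PlanDefinition with its referenced stub resources
#'
#' Bundles the PlanDefinition with a minimal ResearchStudy stub and one
#' ActivityDefinition stub per distinct activity name, so every
#' `definitionCanonical` link on an activity action resolves inside the one
#' Bundle. The stubs carry identity only; full task modeling belongs to
#' dedicated definitional resources.
#'
#' @param g a valid `soa_graph`.
#' @param profile a [mapping_profile()].
#' @return a `fhir_bundle` list.
#' @export
emit_stub_context <- function(g, profile = mapping_profile()) {
  pd <- to_plan_definition(g, profile)
  act_names <- unique(unlist(lapply(g$subgraphs, function(sg)
    vapply(Filter(function(n) n$role == "regular", sg$nodes), `[[`, "", "name")),
    use.names = FALSE))
  entries <- list(
    list(resource = unclass(pd)),
    list(resource = list(resourceType = "ResearchStudy",
                         id = paste0(g$graph_id, "-study"),
                         title = g$title, status = "active")))
  for (nm in act_names)
    entries <- c(entries, list(list(resource = list(
      resourceType = "ActivityDefinition", id = slugify(nm),
      name = gsub("[^A-Za-z0-9]", "", nm), title = nm, status = "active"))))
  structure(list(resourceType = "Bundle", type = "collection",
                 entry = entries),
            class = "fhir_bundle")
}

#' Do all activity-definition links in a bundle resolve?
#'
#' @param bundle a `fhir_bundle` from [emit_stub_context()].
#' @return `TRUE` if every `definitionCanonical` on an activity action
#'   resolves to an ActivityDefinition entry in the bundle.
#' @export
stub_references_resolve <- function(bundle) {
  ids <- vapply(bundle$entry, function(en)
    if (identical(en$resource$resourceType, "ActivityDefinition"))
      en$resource$id else NA_character_, "")
  ids <- ids[!is.na(ids)]
  refs <- character()
  collect <- function(act) {
    if (!is.null(act$definitionCanonical))
      refs <<- c(refs, act$definitionCanonical)
    for (sub in act$action %||% list()) collect(sub)
  }
  pd <- bundle$entry[[1]]$resource
  for (act in pd$action %||% list()) collect(act)
  all(sub("^ActivityDefinition/", "", refs) %in% ids)
}
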