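TRANSITION_TYPES <- c("start_to_start", "start_to_finish",
                      "finish_to_start", "finish_to_finish")
EDGE_ORIGINS <- c("explicit", "implied")

#' Create a schedule transition (edge)
#'
#' A directed edge from one node to another. `delay` is the wait, in whole
#' days, before moving from the source to the target node; summed along a
#' path it yields the day on which each node occurs. `rules` is a conditional
#' rule set that must resolve to `TRUE` at runtime for the path to be
#' selectable (see [parse_rule_set()]).
#'
#' @param source,target node aliases (resolved to ids by [build_graph()]) or
#'   node ids.
#' @param delay signed integer days to wait before moving source to target.
#' @param window optional length-2 non-negative integer vector: permitted
#'   delay variance `c(earlier, later)`.
#' @param type timing relationship between the two nodes; only the default
#'   `"start_to_start"` participates in day arithmetic (the other three
#'   values are stored and round-tripped).
#' @param rules an `soa_rule_set` or a rule string accepted by
#'   [parse_rule_set()]; empty means unconditionally available.
#' @param primary_path logical; `TRUE` marks the protocol's explicit main
#'   schedule edge (at most one outgoing per interaction node).
#' @param origin `"explicit"` (authored) or `"implied"` (added by
#'   [expand_implied_paths()]).
#' @param id opaque unique identifier; assigned by [build_graph()] when
#'   `NULL`.
#' @return an object of class `soa_transition`.
#' @examples
#' soa_transition("V1", "V2", delay = 28, primary_path = TRUE)
#' soa_transition("U", "V3", delay = 1,
#'   rules = '{"interactions_exist": ["IS","V1","V2"]}')
#' @export
soa_transition <- function(source, target, delay = 0L, window = NULL,
                           type = "start_to_start",
                           rules = rule_set(),
                           primary_path = FALSE,
                           origin = "explicit",
                           id = NULL) {
  type <- match.arg(type, TRANSITION_TYPES)
  origin <- match.arg(origin, EDGE_ORIGINS)
  stopifnot(is_string(source), is_string(target))
  if (is.character(rules)) rules <- parse_rule_set(rules)
  if (!inherits(rules, "soa_rule_set")) stop("rules must be an soa_rule_set")
  delay <- as.integer(delay)
  if (is.na(delay)) stop("transition delay is required on every edge")
  if (!is.null(window)) {
    window <- as.integer(window)
    if (length(window) != 2L || any(is.na(window)) || any(window < 0L))
      stop("transition window must be two non-negative integers")
  }
  structure(
    list(id = id, source = source, target = target, delay = delay,
         window = window, type = type, rules = rules,
         primary_path = isTRUE(primary_path), origin = origin),
    class = "soa_transition"
  )
}

#' @export
print.soa_transition <- function(x, ...) {
  r <- serialize_rule_set(x$rules)
  cat(sprintf("<soa_transition> %s -> %s (%+dd)%s%s%s\n",
              x$source, x$target, x$delay,
              if (x$primary_path) " [primary]" else "",
              if (x$origin == "implied") " [implied]" else "",
              if (nzchar(r)) paste0(" when ", r) else ""))
  invisible(x)
}
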