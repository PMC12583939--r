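# Path-timing engine. Planned timings are node attributes, but the day on
# which a node occurs along any particular path is the running sum of the
# transition delays actually traversed. On the primary path the two must
# agree: plannedTiming(Vn) = sum(transitionDelay) from the reference
# timepoint to Vn — the schedule's key internal consistency check.

#' Computed day offsets along the primary path
#'
#' @param g an `soa_graph` with a unique reference timepoint on its primary
#'   path.
#' @return named integer vector of day offsets (0 at the reference node),
#'   one per primary-chain node id, including negative offsets for
#'   screening nodes before the reference.
#' @export
chain_days <- function(g) {
  chain <- primary_chain(g)
  ref_idx <- reference_index(g, chain)
  delays <- integer(0)
  if (length(chain) > 1L) {
    delays <- vapply(seq_len(length(chain) - 1L), function(i) {
      e <- Filter(function(e) e$primary_path && e$target == chain[i + 1L],
                  out_edges(g, chain[i]))
      check_timing_type(e[[1]])
      e[[1]]$delay
    }, 0L)
  }
  pos <- c(0L, cumsum(delays))          # relative to chain start
  days <- pos - pos[ref_idx]            # re-zeroed at the reference node
  setNames(days, chain)
}

check_timing_type <- function(e) {
  if (e$type != "start_to_start")
    stop("transitionType '", e$type, "' is not implemented for timing ",
         "arithmetic (edge ", e$id, ")")
  invisible(e)
}

#' Planned day offset of a primary-path node
#'
#' The sum of `delay` over primary-path edges from the reference timepoint to
#' the node; nodes before the reference (screening) yield negative offsets by
#' reverse summation.
#'
#' @param g an `soa_graph`.
#' @param node a node alias or node id on the primary path.
#' @return a signed integer day offset (0 = reference day; see [day_label()]).
#' @examples
#' g <- example_fig1()
#' planned_day(g, "V3")           # offset 6, i.e. "Day 7"
#' day_label(planned_day(g, "V3"))
#' @export
planned_day <- function(g, node) {
  days <- chain_days(g)
  id <- if (node %in% names(g$nodes)) node else {
    n <- node_by_alias(g, node)
    if (is.null(n)) stop("unknown node '", node, "'")
    n$id
  }
  if (!id %in% names(days))
    stop("node '", node, "' is not on the primary path")
  unname(days[[id]])
}

#' Check the planned-timing consistency equation
#'
#' For every primary-path node with a stated planned timing, compares the
#' stored value with the computed delay sum from the reference timepoint.
#' Unscheduled and boundary nodes (null planned timing) are excluded. A
#' non-zero delta usually indicates a protocol inconsistency — exactly the
#' kind of specification defect this representation surfaces.
#'
#' @param g an `soa_graph`.
#' @return an object of class `soa_timing_report`: a per-node data frame
#'   (`alias`, `planned_timing`, `computed_sum`, `delta`) with attribute
#'   `violations` (node ids with non-zero delta).
#' @export
check_timing_consistency <- function(g) {
  days <- chain_days(g)
  rows <- list()
  for (id in names(days)) {
    n <- g$nodes[[id]]
    if (is.na(n$planned_timing)) next
    rows[[id]] <- data.frame(
      id = id, alias = n$alias, planned_timing = n$planned_timing,
      computed_sum = unname(days[[id]]),
      delta = n$planned_timing - unname(days[[id]]))
  }
  per_node <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(id = character(), alias = character(),
                  planned_timing = integer(), computed_sum = integer(),
                  delta = integer())
  structure(per_node, violations = per_node$id[per_node$delta != 0L],
            class = c("soa_timing_report", "data.frame"))
}

#' @export
print.soa_timing_report <- function(x, ...) {
  v <- attr(x, "violations")
  if (length(v) == 0L)
    cat("timing consistent:", nrow(x), "node(s) checked, 0 violations\n")
  else {
    cat("timing INCONSISTENT:", length(v), "violation(s)\n")
    print.data.frame(x[x$delta != 0L, c("alias", "planned_timing",
                                        "computed_sum", "delta")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Actual day offsets along a traversed path
#'
#' Unlike planned timing, the day a visit actually occurs depends on the
#' edges actually taken — unscheduled detours included — and is the running
#' sum of their delays. Accepts either a completed walk (see [simulate_walk()])
#' or an explicit sequence of edge ids with optional per-step actual-delay
#' overrides (the real-world wait when it differed from the planned delay).
#'
#' @param g an `soa_graph`.
#' @param steps an `soa_walk` object, or a character vector of edge ids.
#' @param actual_delays optional integer vector, one per step, overriding the
#'   edge delays (`NA` = use the edge's `delay`).
#' @param start_day day offset of the starting node; defaults to the
#'   instantiation-start position on the primary chain.
#' @return a data frame with one row per node occurrence: `occurrence`,
#'   `alias`, `node_id`, `edge_id`, `day`.
#' @export
actual_day <- function(g, steps, actual_delays = NULL, start_day = NULL) {
  if (inherits(steps, "soa_walk")) return(steps$trajectory)
  stopifnot(is.character(steps))
  if (is.null(actual_delays)) actual_delays <- rep(NA_integer_, length(steps))
  stopifnot(length(actual_delays) == length(steps))
  edges <- lapply(steps, function(eid) {
    e <- g$edges[[eid]]
    if (is.null(e)) stop("no matching edge '", eid, "' in graph")
    e
  })
  start_id <- if (length(edges)) edges[[1]]$source else primary_chain(g)[1]
  if (is.null(start_day)) {
    days <- tryCatch(chain_days(g), error = function(e) NULL)
    start_day <- if (!is.null(days) && start_id %in% names(days))
      unname(days[[start_id]]) else 0L
  }
  traj <- data.frame(occurrence = 1L, alias = node_alias(g, start_id),
                     node_id = start_id, edge_id = NA_character_,
                     day = as.integer(start_day))
  day <- as.integer(start_day)
  cur <- start_id
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    if (e$source != cur)
      stop("edge ", e$id, " does not start at current node ",
           node_alias(g, cur))
    check_timing_type(e)
    d <- actual_delays[i]
    if (is.na(d)) d <- e$delay
    day <- day + as.integer(d)
    cur <- e$target
    traj <- rbind(traj, data.frame(
      occurrence = nrow(traj) + 1L, alias = node_alias(g, cur),
      node_id = cur, edge_id = e$id, day = day))
  }
  traj
}

#' Is an actual timing inside its permitted window?
#'
#' Windows are `(earlier, later)` non-negative variances around a planned
#' value (a node's planned timing or an edge's delay): the actual value is
#' acceptable iff `planned - earlier <= actual <= planned + later`. A
#' missing window means no variance is permitted.
#'
#' @param planned planned day offset or delay.
#' @param window length-2 non-negative integer vector, or `NULL` for (0, 0).
#' @param actual observed value(s).
#' @return logical, vectorized over `actual`.
#' @examples
#' check_window(7, c(1, 1), 8)   # TRUE: inside the later bound
#' check_window(7, c(0, 0), 8)   # FALSE: no variance permitted
#' @export
check_window <- function(planned, window = NULL, actual) {
  if (is.null(window)) window <- c(0L, 0L)
  stopifnot(length(window) == 2L, all(window >= 0L))
  actual >= planned - window[1] & actual <= planned + window[2]
}
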