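# Per-subject schedule walker. A walk is a dynamic traversal of the SoA
# graph: at each node the outgoing edges whose rules evaluate TRUE against
# the subject's runtime context are available, exactly one is taken, and the
# actual day advances by the traversed edge's delay. Repeats, treatment
# cycles, unscheduled detours, and withdrawal all fall out of the same
# mechanism.

#' Start a subject walk
#'
#' @param g an `soa_graph`.
#' @param subject_id identifier recorded on the walk.
#' @param flags initial subject flags (e.g. `list(consentObtained = TRUE)`).
#' @return an object of class `soa_walk` positioned at the start node, whose
#'   day offset is taken from the primary-chain timing when computable
#'   (e.g. a screening start sits at a negative offset), else 0.
#' @export
start_walk <- function(g, subject_id = "subject-1", flags = list()) {
  chain <- primary_chain(g)
  start_id <- chain[1]
  days <- tryCatch(chain_days(g), error = function(e) NULL)
  day0 <- if (!is.null(days)) unname(days[[start_id]]) else 0L
  al <- node_alias(g, start_id)
  structure(
    list(subject_id = subject_id, graph_id = g$graph_id,
         current = start_id, day = day0,
         trajectory = data.frame(occurrence = 1L, alias = al,
                                 node_id = start_id, edge_id = NA_character_,
                                 day = day0),
         counts = setNames(1L, al), completed_cycles = 0L,
         flags = flags, status = "active", stall_message = NULL),
    class = "soa_walk"
  )
}

walk_context <- function(state) {
  soa_context(history = state$trajectory$alias, days = state$trajectory$day,
              counts = state$counts,
              completed_cycles = state$completed_cycles,
              flags = state$flags)
}

finish_role_for <- function(g) {
  if (any(vapply(g$nodes, `[[`, "", "type") == "interaction"))
    "instantiation_finish" else "activity_finish"
}

#' Transitions currently available to a subject
#'
#' The outgoing edges of the current node whose rule sets evaluate `TRUE`
#' against the subject's context, after the global implied withdrawal guard:
#' once the subject's `withdrawn` flag is `TRUE`, every transition except
#' those leading to the finish node is unavailable, so the only remaining
#' route is the (implied) exit. Results are deterministically ordered:
#' primary-path edge first, then explicit before implied, then by target
#' alias and edge id. An empty result at a non-terminal node is a stall —
#' a protocol inconsistency surfaced by the model, not a crash.
#'
#' @param g an `soa_graph`.
#' @param state an `soa_walk`.
#' @param strict passed to the rule engine: error (rather than `FALSE`) on
#'   flags missing from the context.
#' @return a list of `soa_transition` objects, possibly empty.
#' @export
available_transitions <- function(g, state, strict = FALSE) {
  stopifnot(inherits(state, "soa_walk"))
  if (state$status != "active") return(list())
  ctx <- walk_context(state)
  fin_role <- finish_role_for(g)
  withdrawn <- isTRUE(state$flags$withdrawn) ||
    identical(tolower(as.character(state$flags$withdrawn %||% "")), "true")
  cand <- out_edges(g, state$current)
  keep <- Filter(function(e) {
    if (withdrawn && g$nodes[[e$target]]$role != fin_role) return(FALSE)
    evaluate_rule_set(e$rules, ctx, e, strict = strict,
                      target_alias = node_alias(g, e$target))
  }, cand)
  ord <- order(!vapply(keep, `[[`, TRUE, "primary_path"),
               vapply(keep, `[[`, "", "origin") == "implied",
               vapply(keep, function(e) node_alias(g, e$target), ""),
               vapply(keep, `[[`, "", "id"))
  keep[ord]
}

#' Take one transition
#'
#' Moves the subject along `edge`: the actual day advances by the edge's
#' delay (or an explicit `actual_delay` when the real-world wait differed),
#' the target's execution count increments, arrival at a cycle-finish node
#' completes a treatment cycle, and arrival at the finish node ends the walk
#' (status `"withdrawn"` when the withdrawal flag is set, else
#' `"finished"`).
#'
#' @param g an `soa_graph`.
#' @param state an active `soa_walk`.
#' @param edge an `soa_transition`, or an edge id.
#' @param actual_delay optional integer overriding the edge's planned delay
#'   for this traversal.
#' @param check when `TRUE` (default) the edge must currently be available.
#' @return the updated `soa_walk`.
#' @export
step_walk <- function(g, state, edge, actual_delay = NULL, check = TRUE) {
  if (is.character(edge)) edge <- g$edges[[edge]] %||%
      stop("unknown edge id '", edge, "'")
  if (check) {
    avail_ids <- vapply(available_transitions(g, state), `[[`, "", "id")
    if (!edge$id %in% avail_ids)
      stop("edge ", edge$id, " (", node_alias(g, edge$source), " -> ",
           node_alias(g, edge$target), ") is not currently available")
  }
  check_timing_type(edge)
  d <- if (is.null(actual_delay)) edge$delay else as.integer(actual_delay)
  state$day <- state$day + d
  state$current <- edge$target
  al <- node_alias(g, edge$target)
  state$trajectory <- rbind(state$trajectory, data.frame(
    occurrence = nrow(state$trajectory) + 1L, alias = al,
    node_id = edge$target, edge_id = edge$id, day = state$day))
  state$counts[al] <- (if (al %in% names(state$counts)) state$counts[[al]] else 0L) + 1L
  tgt_role <- g$nodes[[edge$target]]$role
  if (tgt_role == "cycle_finish")
    state$completed_cycles <- state$completed_cycles + 1L
  if (tgt_role == finish_role_for(g))
    state$status <- if (isTRUE(state$flags$withdrawn)) "withdrawn" else "finished"
  state
}

#' Walk policy
#'
#' @param mode `"greedy_primary"` (follow the primary path, taking permitted
#'   detours per the options below), `"scripted"` (follow `script`, a
#'   character vector of target aliases, then fall back to greedy), or
#'   `"random"` (uniform choice among available transitions; seeded).
#' @param script ordered target aliases for `"scripted"` mode.
#' @param prefer_loops when `TRUE`, self-loops and cycle-return edges are
#'   preferred whenever their rules permit (repeat an activity while its
#'   `maxRepeats` allows; start another treatment cycle while `n_cycles`
#'   allows).
#' @param unscheduled_days integer day offsets on which the subject takes an
#'   unscheduled visit (requires an expanded graph with an unscheduled node).
#'   An unscheduled visit strictly between two planned visits leaves the
#'   planned schedule unchanged; one landing on a planned visit's day pushes
#'   that visit back by the unscheduled node's outgoing delay.
#' @param flag_schedule list of `list(day =, flags = list(...))`: flag
#'   changes applied once the walk reaches the given day (e.g. withdrawal).
#' @param flags initial subject flags.
#' @param max_steps safety bound on walk length.
#' @return a list of class `soa_walk_policy`.
#' @export
walk_policy <- function(mode = c("greedy_primary", "scripted", "random"),
                        script = character(), prefer_loops = FALSE,
                        unscheduled_days = integer(),
                        flag_schedule = list(), flags = list(),
                        max_steps = 500L) {
  mode <- match.arg(mode)
  if (mode == "scripted" && length(script) == 0L)
    stop("scripted mode requires a script")
  structure(list(mode = mode, script = as.character(script),
                 prefer_loops = isTRUE(prefer_loops),
                 unscheduled_days = sort(as.integer(unscheduled_days)),
                 flag_schedule = flag_schedule, flags = flags,
                 max_steps = as.integer(max_steps)),
            class = "soa_walk_policy")
}

is_loop_edge <- function(g, e, chain) {
  if (e$target == e$source) return(TRUE)
  si <- match(e$source, chain); ti <- match(e$target, chain)
  !is.na(si) && !is.na(ti) && ti <= si
}

#' Simulate a complete subject walk
#'
#' Deterministic for a fixed policy and seed. The walk ends at the finish
#' node (`"finished"`/`"withdrawn"`) or stalls (`"stalled"`) when no
#' transition is available at a non-terminal node — the latter is reported
#' as a finding with full context rather than an error, since a stall is a
#' protocol inconsistency the model is designed to surface.
#'
#' @param g a valid (and, for unscheduled-visit policies, expanded)
#'   `soa_graph`.
#' @param policy a [walk_policy()].
#' @param seed integer seed (used by `"random"` mode).
#' @param subject_id identifier recorded on the walk.
#' @return a terminal `soa_walk`.
#' @examples
#' g <- expand_implied_paths(example_fig1())
#' w <- simulate_walk(g, walk_policy("greedy_primary"))
#' w$trajectory[, c("alias", "day")]
#' @export
simulate_walk <- function(g, policy = walk_policy(), seed = NULL,
                          subject_id = "subject-1") {
  stopifnot(inherits(policy, "soa_walk_policy"))
  if (!is.null(seed)) set.seed(seed)
  state <- start_walk(g, subject_id, flags = policy$flags)
  chain <- primary_chain(g)
  days <- tryCatch(chain_days(g), error = function(e) NULL)
  pending_u <- policy$unscheduled_days
  pending_flags <- policy$flag_schedule
  script <- policy$script
  u_node <- role_node(g$nodes, "unscheduled")
  u_id <- if (length(u_node)) u_node[[1]]$id else NULL

  for (step_i in seq_len(policy$max_steps)) {
    if (state$status != "active") break

    # apply any flag changes that have come due
    due <- vapply(pending_flags, function(fc) state$day >= fc$day, TRUE)
    for (fc in pending_flags[due])
      state$flags <- modifyList(state$flags, fc$flags)
    pending_flags <- pending_flags[!due]

    avail <- available_transitions(g, state)
    if (length(avail) == 0L) {
      state$status <- "stalled"
      state$stall_message <- paste0(
        "no available transition at non-terminal node '",
        node_alias(g, state$current), "' on day ", state$day,
        " (history: ", paste(state$trajectory$alias, collapse = " > "), ")")
      break
    }

    chosen <- NULL
    actual <- NULL

    if (policy$mode == "random") {
      chosen <- avail[[sample.int(length(avail), 1L)]]
    } else if (policy$mode == "scripted" && length(script)) {
      want <- script[1]
      hit <- Filter(function(e) node_alias(g, e$target) == want, avail)
      if (length(hit)) {
        chosen <- hit[[1]]
        script <- script[-1]
      }
    }

    # unscheduled-visit insertion: take a detour to U when the next pending
    # unscheduled day falls on or before the next planned visit's day
    if (is.null(chosen) && policy$mode != "random" &&
        !is.null(u_id) && !is.null(days)) {
      fin_role <- finish_role_for(g)
      nxt_planned <- Filter(function(e) e$target %in% names(days) &&
                              e$target != state$current &&
                              g$nodes[[e$target]]$role != fin_role, avail)
      p <- if (length(nxt_planned))
        min(vapply(nxt_planned, function(e) unname(days[[e$target]]), 0L))
      else NA_integer_
      u <- if (length(pending_u)) pending_u[1] else NA_integer_
      if (!is.na(u) && !is.na(p) && u > state$day && u <= p) {
        to_u <- Filter(function(e) e$target == u_id, avail)
        if (length(to_u)) {
          chosen <- to_u[[1]]
          actual <- u - state$day
          pending_u <- pending_u[-1]
        }
      } else if (state$current == u_id && length(nxt_planned)) {
        # leave U for the next planned visit, on its planned day if still
        # reachable, otherwise pushed back by the edge delay
        chosen <- nxt_planned[[1]]
        p_t <- unname(days[[chosen$target]])
        if (p_t > state$day + chosen$delay) actual <- p_t - state$day
      }
    }

    if (is.null(chosen) && policy$prefer_loops) {
      loops <- Filter(function(e) is_loop_edge(g, e, chain), avail)
      if (length(loops)) chosen <- loops[[1]]
    }

    if (is.null(chosen)) {
      fwd <- Filter(function(e) !is_loop_edge(g, e, chain), avail)
      if (length(fwd) == 0L) fwd <- avail
      chosen <- fwd[[1]]
      # keep to the planned calendar on the first pass along the chain
      if (!is.null(days) && chosen$target %in% names(days) &&
          is.null(actual) &&
          !is.na(g$nodes[[chosen$target]]$planned_timing) &&
          !node_alias(g, chosen$target) %in% state$trajectory$alias) {
        p_t <- unname(days[[chosen$target]])
        if (p_t > state$day) actual <- p_t - state$day
      }
    }

    state <- step_walk(g, state, chosen, actual_delay = actual, check = FALSE)
  }
  if (state$status == "active") {
    state$status <- "stalled"
    state$stall_message <- "walk exceeded max_steps without terminating"
  }
  state
}

#' @export
print.soa_walk <- function(x, ...) {
  cat(sprintf("<soa_walk> %s on %s: %s after %d step(s), %d cycle(s)\n",
              x$subject_id, x$graph_id, x$status,
              nrow(x$trajectory) - 1L, x$completed_cycles))
  cat(" ", paste(sprintf("%s(D%d)", x$trajectory$alias,
                         day_label(x$trajectory$day, numeric = TRUE)),
                 collapse = " > "), "\n")
  if (!is.null(x$stall_message)) cat("  stall:", x$stall_message, "\n")
  invisible(x)
}

#' Per-visit calendar of a walk
#'
#' @param g the walked `soa_graph`.
#' @param walk an `soa_walk`.
#' @return a data frame: `alias`, `occurrence`, `day` (internal offset),
#'   `protocol_day` (label per [day_label()]), `planned_day` where defined,
#'   and `on_schedule` per the node's planned window.
#' @export
walk_calendar <- function(g, walk) {
  traj <- walk$trajectory
  days <- tryCatch(chain_days(g), error = function(e) NULL)
  planned <- vapply(traj$node_id, function(id) {
    if (!is.null(days) && id %in% names(days) &&
        !is.na(g$nodes[[id]]$planned_timing)) unname(days[[id]])
    else NA_integer_
  }, 0L)
  on_sched <- mapply(function(id, p, a) {
    if (is.na(p)) return(NA)
    check_window(p, g$nodes[[id]]$planned_window, a)
  }, traj$node_id, planned, traj$day)
  data.frame(alias = traj$alias, occurrence = traj$occurrence,
             day = traj$day, protocol_day = day_label(traj$day),
             planned_day = planned, on_schedule = unlist(on_sched),
             row.names = NULL)
}
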