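NODE_TYPES <- c("interaction", "activity")
NODE_ROLES <- c("regular", "instantiation_start", "instantiation_finish",
                "activity_start", "activity_finish",
                "cycle_start", "cycle_finish", "unscheduled")

#' Create a schedule-of-activities node
#'
#' A node is either an *interaction* (a study event involving the participant:
#' a visit, a telephone call) or an *activity* (a task performed at an
#' interaction: vital signs, a blood draw). Planned timing is a signed integer
#' day offset from the schedule's reference timepoint (see [day_label()] for
#' the protocol-day rendering convention); boundary and unscheduled nodes
#' carry no planned timing.
#'
#' @param alias short human-readable label unique within its graph level
#'   (e.g. `"V1"`, `"U"`, `"IS"`); kept distinct from the opaque `id` so
#'   printed schedules stay legible.
#' @param type `"interaction"` or `"activity"`.
#' @param name protocol name; defaults to the alias.
#' @param role structural role: `"regular"`, the instantiation boundaries
#'   `"instantiation_start"`/`"instantiation_finish"` (IS/IF), the activity
#'   boundaries `"activity_start"`/`"activity_finish"` (AS/AF), the treatment
#'   cycle boundaries `"cycle_start"`/`"cycle_finish"` (CS/CF), or
#'   `"unscheduled"`.
#' @param planned_timing signed integer day offset from the reference
#'   timepoint, or `NA` (boundary/unscheduled nodes).
#' @param reference_timepoint logical; `TRUE` marks the schedule's t(zero)
#'   node (at most one per interaction graph).
#' @param planned_window optional length-2 non-negative integer vector
#'   `c(earlier, later)`: permitted timing variance in days.
#' @param planned_duration optional duration of the interaction/activity in
#'   hours.
#' @param subtype,description optional free text.
#' @param id opaque unique identifier; a UUID is assigned by [build_graph()]
#'   when `NULL`.
#' @return an object of class `soa_node`.
#' @examples
#' soa_node("V2", planned_timing = 0, reference_timepoint = TRUE,
#'          subtype = "clinic visit")
#' @export
soa_node <- function(alias, type = c("interaction", "activity"),
                     name = alias, role = "regular",
                     planned_timing = NA_integer_,
                     reference_timepoint = FALSE,
                     planned_window = NULL,
                     planned_duration = NA_real_,
                     subtype = NA_character_, description = NA_character_,
                     id = NULL) {
  type <- match.arg(type)
  role <- match.arg(role, NODE_ROLES)
  stopifnot(is_string(alias))
  if (!is.null(planned_window)) {
    planned_window <- as.integer(planned_window)
    if (length(planned_window) != 2L || any(is.na(planned_window)) ||
        any(planned_window < 0L))
      stop("planned_window must be two non-negative integers (earlier, later)")
  }
  if (role == "unscheduled" && !is.na(planned_timing))
    stop("unscheduled nodes have no planned timing (node '", alias, "')")
  structure(
    list(
      id = id, alias = alias, type = type, subtype = as.character(subtype),
      name = as.character(name), description = as.character(description),
      planned_timing = as.integer(planned_timing),
      reference_timepoint = isTRUE(reference_timepoint),
      planned_window = planned_window,
      planned_duration = as.numeric(planned_duration),
      role = role
    ),
    class = "soa_node"
  )
}

#' @export
print.soa_node <- function(x, ...) {
  tm <- if (is.na(x$planned_timing)) "-" else day_label(x$planned_timing)
  cat(sprintf("<soa_node> %s [%s/%s] %s%s\n", x$alias, x$type, x$role, tm,
              if (x$reference_timepoint) " (reference)" else ""))
  invisible(x)
}
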