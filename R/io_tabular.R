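# Tabular SoA: the square protocol table (visits as columns with timings,
# activities as rows with X marks) as found in study protocols, read from
# and written to CSV.

#' Construct a tabular SoA
#'
#' @param visit_id character vector of visit ids (column order).
#' @param timing_text visit timing labels: `"Day N"`, `"Days A to B"`
#'   (a window), `"-Days A to B"` (a pre-reference screening range), or
#'   `"As required"` (unscheduled). Any other text is an error, not a guess.
#' @param activities character vector of activity names (row order).
#' @param marks logical matrix, `length(activities)` x `length(visit_id)`:
#'   which activity is performed at which visit.
#' @param phase optional phase labels, one per visit column.
#' @return an object of class `soa_table`.
#' @export
soa_table <- function(visit_id, timing_text, activities, marks,
                      phase = NULL) {
  visit_id <- as.character(visit_id)
  if (anyDuplicated(visit_id))
    stop("duplicate visit id: ", visit_id[duplicated(visit_id)][1])
  stopifnot(length(timing_text) == length(visit_id))
  marks <- as.matrix(marks)
  if (nrow(marks) != length(activities) || ncol(marks) != length(visit_id))
    stop("marks matrix must be activities x visits")
  if (is.null(phase)) phase <- rep("", length(visit_id))
  parsed <- lapply(timing_text, parse_timing_text)
  visits <- data.frame(
    visit_id = visit_id, timing_text = as.character(timing_text),
    offset = vapply(parsed, function(p) p$offset %||% NA_integer_, 0L),
    window_earlier = vapply(parsed, function(p) (p$window %||% c(NA_integer_, NA))[1], 0L),
    window_later = vapply(parsed, function(p) (p$window %||% c(NA, NA_integer_))[2], 0L),
    unscheduled = vapply(parsed, function(p) isTRUE(p$unscheduled), TRUE),
    phase = as.character(phase))
  for (i in seq_along(activities)) {
    if (!nzchar(trimws(activities[i])))
      stop("unnamed activity in row ", i)
    if (!any(marks[i, ]))
      stop("activity '", activities[i], "' has no visit marks")
  }
  dimnames(marks) <- list(activities, visit_id)
  structure(list(visits = visits, activities = as.character(activities),
                 marks = marks),
            class = "soa_table")
}

# The timing-text grammar. Offsets follow the one-based no-day-zero
# convention: "Day 1" is the reference day, internal offset 0.
parse_timing_text <- function(txt) {
  t <- trimws(txt)
  t <- gsub("–|−", "-", t)   # en-dash / minus sign
  if (tolower(t) == "as required")
    return(list(offset = NA_integer_, window = NULL, unscheduled = TRUE))
  m <- regmatches(t, regexec("^Day ([0-9]+)$", t))[[1]]
  if (length(m))
    return(list(offset = day_offset(as.integer(m[2])), window = NULL,
                unscheduled = FALSE))
  m <- regmatches(t, regexec("^Days ([0-9]+) to ([0-9]+)$", t))[[1]]
  if (length(m)) {
    o <- sort(day_offset(as.integer(m[2:3])))
    return(list(offset = o[1], window = c(0L, o[2] - o[1]),
                unscheduled = FALSE))
  }
  m <- regmatches(t, regexec("^-Days ([0-9]+) to ([0-9]+)$", t))[[1]]
  if (length(m)) {
    # days before the reference day: "-Days 28 to 1" spans offsets -28..-1
    o <- sort(day_offset(-as.integer(m[2:3])))
    return(list(offset = o[1], window = c(0L, o[2] - o[1]),
                unscheduled = FALSE))
  }
  stop("unparseable visit timing text: '", txt, "'")
}

#' @export
print.soa_table <- function(x, ...) {
  cat(sprintf("<soa_table> %d visit(s) (%d unscheduled), %d activities\n",
              nrow(x$visits), sum(x$visits$unscheduled), length(x$activities)))
  invisible(x)
}

#' Read / write a tabular SoA CSV
#'
#' The CSV mirrors the protocol layout: a `Phase` row, a `Visit ID` row, a
#' `Visit timing` row, an `Activity` marker row, then one row per activity
#' with `X` marks under the visits at which it occurs. Timing text is kept
#' verbatim alongside the parsed day offsets.
#'
#' @param path CSV file path.
#' @return `read_tabular_soa()`: an `soa_table`.
#' @export
read_tabular_soa <- function(path) {
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE)
  labels <- trimws(raw[[1]])
  row_of <- function(lab) {
    i <- match(lab, labels)
    if (is.na(i)) stop("tabular SoA is missing the '", lab, "' row")
    i
  }
  id_row <- row_of("Visit ID")
  tm_row <- row_of("Visit timing")
  act_row <- row_of("Activity")
  ph_row <- match("Phase", labels)
  cols <- which(nzchar(trimws(as.character(raw[id_row, -1])))) + 1L
  visit_id <- trimws(as.character(raw[id_row, cols]))
  timing <- trimws(as.character(raw[tm_row, cols]))
  phase <- if (!is.na(ph_row)) trimws(as.character(raw[ph_row, cols]))
  acts <- labels[(act_row + 1L):nrow(raw)]
  marks <- t(vapply(seq_along(acts), function(i) {
    toupper(trimws(as.character(raw[act_row + i, cols]))) == "X"
  }, logical(length(cols))))
  soa_table(visit_id, timing, acts, marks, phase = phase)
}

#' @rdname read_tabular_soa
#' @param t an `soa_table`.
#' @export
write_tabular_soa <- function(t, path) {
  stopifnot(inherits(t, "soa_table"))
  nvis <- nrow(t$visits)
  rows <- rbind(
    c("Phase", t$visits$phase),
    c("Visit ID", t$visits$visit_id),
    c("Visit timing", t$visits$timing_text),
    c("Activity", rep("", nvis)))
  for (i in seq_along(t$activities))
    rows <- rbind(rows, c(t$activities[i], ifelse(t$marks[i, ], "X", "")))
  write.table(rows, path, sep = ",", row.names = FALSE, col.names = FALSE,
              qmethod = "double")
  invisible(path)
}

#' Convert a tabular SoA into a schedule graph
#'
#' Builds the interaction chain `IS -> V<id> ... -> IF` with primary-path
#' edges whose delays are derived from the parsed timing offsets (so the
#' planned-timing consistency check holds by construction), an unscheduled
#' node for each "As required" column (left floating: its routes are added
#' by [expand_implied_paths()]), and one activity subgraph per visit in
#' which each X mark becomes an activity node between the activity
#' start/finish boundaries, in row order.
#'
#' @param t an `soa_table`.
#' @param graph_id,title identifiers for the new graph.
#' @return an `soa_graph`.
#' @export
table_to_graph <- function(t, graph_id = NULL, title = "Tabular SoA") {
  stopifnot(inherits(t, "soa_table"))
  sched <- t$visits[!t$visits$unscheduled, ]
  if (nrow(sched) == 0L) stop("tabular SoA has no scheduled visits")
  sched <- sched[order(sched$offset), ]
  if (!any(sched$offset == 0L))
    stop("no visit at the reference day (Day 1); cannot anchor timings")

  mk_alias <- function(vid) if (grepl("^[0-9]+$", vid)) paste0("V", vid) else vid
  nodes <- list(soa_node("IS", role = "instantiation_start"))
  for (i in seq_len(nrow(sched))) {
    v <- sched[i, ]
    win <- if (!is.na(v$window_earlier)) c(v$window_earlier, v$window_later)
    nodes <- c(nodes, list(soa_node(
      mk_alias(v$visit_id), planned_timing = v$offset,
      reference_timepoint = v$offset == 0L, planned_window = win,
      subtype = "clinic visit")))
  }
  uns <- t$visits[t$visits$unscheduled, ]
  for (i in seq_len(nrow(uns)))
    nodes <- c(nodes, list(soa_node(uns$visit_id[i], role = "unscheduled",
                                    subtype = "clinic visit")))
  nodes <- c(nodes, list(soa_node("IF", role = "instantiation_finish")))

  aliases <- c("IS", mk_alias_vec <- vapply(sched$visit_id, mk_alias, ""), "IF")
  offs <- c(sched$offset[1], sched$offset, sched$offset[nrow(sched)])
  edges <- lapply(seq_len(length(aliases) - 1L), function(i) {
    soa_transition(aliases[i], aliases[i + 1L],
                   delay = offs[i + 1L] - offs[i], primary_path = TRUE)
  })

  subgraphs <- list()
  for (j in seq_len(ncol(t$marks))) {
    vid <- colnames(t$marks)[j]
    acts <- t$activities[t$marks[, j]]
    if (length(acts) == 0L) next
    al <- if (vid %in% uns$visit_id) vid else mk_alias(vid)
    snodes <- c(list(soa_node("AS", type = "activity", role = "activity_start")),
                lapply(acts, function(a) soa_node(a, type = "activity")),
                list(soa_node("AF", type = "activity", role = "activity_finish")))
    chain <- c("AS", acts, "AF")
    sedges <- lapply(seq_len(length(chain) - 1L), function(i)
      soa_transition(chain[i], chain[i + 1L], delay = 0L,
                     primary_path = TRUE))
    subgraphs[[al]] <- list(nodes = snodes, edges = sedges)
  }

  build_graph(nodes, edges, subgraphs = subgraphs, graph_id = graph_id,
              title = title)
}
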