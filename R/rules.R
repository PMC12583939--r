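# Conditional-scheduling rule engine.
#
# A rule set is an ordered list of single-pair clauses written as
#   {"function": inputs}, {"function": inputs}, ...
# Each clause resolves to TRUE or FALSE against a subject's runtime context;
# the rule set is the conjunction (AND) of its clauses — disjunction is
# expressed structurally by parallel edges, never inside one rule set.

BUILTIN_FUNCTIONS <- c("interactions_exist", "interactions_not_exist",
                       "maxRepeats", "n_cycles")

#' Construct a rule clause
#'
#' @param fun function name token. Built-ins: `interactions_exist` /
#'   `interactions_not_exist` (membership of visit aliases in the subject's
#'   interaction history), `maxRepeats` (cap on total executions of the
#'   edge's target node), `n_cycles` (comparison against the prospective
#'   treatment-cycle index). Any other name is a subject flag compared for
#'   equality against the context.
#' @param arg the clause argument: a logical, an integer, a comparison string
#'   such as `"<6"`, a string literal, or a character vector of node aliases.
#' @return an object of class `soa_rule_clause`.
#' @export
rule_clause <- function(fun, arg) {
  stopifnot(is_string(fun), nzchar(fun))
  if (fun %in% c("interactions_exist", "interactions_not_exist")) {
    if (!is.character(arg)) stop(fun, " requires a list of node aliases")
    arg <- as.character(arg)
  } else if (fun == "maxRepeats") {
    if (is.character(arg)) arg <- suppressWarnings(as.integer(arg))
    if (!is.numeric(arg) || length(arg) != 1L || is.na(arg))
      stop("maxRepeats requires a single integer")
    arg <- as.integer(arg)
  } else if (fun == "n_cycles") {
    arg <- parse_comparison(arg)$text
  } else {
    if (length(arg) != 1L) stop("flag clause '", fun, "' requires a scalar")
    if (is.character(arg)) {
      lowered <- tolower(arg)
      if (lowered %in% c("true", "false")) arg <- identical(lowered, "true")
    }
  }
  structure(list(fun = fun, arg = arg), class = "soa_rule_clause")
}

#' Construct a rule set
#'
#' @param ... `soa_rule_clause` objects, in evaluation order.
#' @return an object of class `soa_rule_set`. An empty rule set always
#'   evaluates `TRUE`.
#' @export
rule_set <- function(...) {
  clauses <- list(...)
  if (length(clauses) == 1L && is.list(clauses[[1]]) &&
      !inherits(clauses[[1]], "soa_rule_clause"))
    clauses <- clauses[[1]]
  for (cl in clauses)
    if (!inherits(cl, "soa_rule_clause")) stop("all elements must be rule clauses")
  structure(list(clauses = clauses), class = "soa_rule_set")
}

n_clauses <- function(rs) length(rs$clauses)

# comparison grammar for n_cycles: <, <=, =, ==, >, >= followed by an integer
parse_comparison <- function(x) {
  if (is.numeric(x)) x <- paste0("=", format(x))
  if (!is_string(x)) stop("comparison must be a string like \"<6\"")
  m <- regmatches(x, regexec("^\\s*(<=|>=|==|<|>|=)\\s*(-?[0-9]+)\\s*$", x))[[1]]
  if (length(m) == 0L) stop("malformed comparison: ", x)
  op <- m[2]
  if (op == "==") op <- "="
  list(op = op, value = as.integer(m[3]), text = paste0(op, m[3]))
}

apply_comparison <- function(value, cmp) {
  switch(cmp$op,
         "<"  = value < cmp$value,
         "<=" = value <= cmp$value,
         "="  = value == cmp$value,
         ">"  = value > cmp$value,
         ">=" = value >= cmp$value)
}

#' Parse conditional-scheduling rule text
#'
#' Accepts the human-readable syntax used on schedule edges: a comma-separated
#' sequence of single-pair objects, e.g.
#' `{'interactions_exist': ['IS','V1','V2']}, {'maxRepeats': 4}`.
#' Single, double, and typographic quotes are all accepted; serialization via
#' [serialize_rule_set()] canonicalizes to double quotes. A trailing comma is
#' tolerated. The empty string parses to an empty rule set.
#'
#' @param text rule text, or `NA`/`""` for the empty rule set.
#' @return an `soa_rule_set`.
#' @examples
#' rs <- parse_rule_set("{'studyPhase':'onStudy'}, {'sampleObtained':'true'}")
#' serialize_rule_set(rs)
#' @export
parse_rule_set <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) ||
      !nzchar(trimws(text)))
    return(rule_set())
  txt <- text
  # normalize typographic quotes, then single quotes, to plain double quotes
  for (q in c("‘", "’", "“", "”", "'")) {
    txt <- gsub(q, "\"", txt, fixed = TRUE)
  }
  txt <- sub(",\\s*$", "", trimws(txt))
  parsed <- tryCatch(
    jsonlite::fromJSON(paste0("[", txt, "]"), simplifyVector = FALSE),
    error = function(e) stop("malformed rule text: ", conditionMessage(e),
                             call. = FALSE)
  )
  clauses <- lapply(parsed, function(obj) {
    if (!is.list(obj) || length(obj) != 1L || is.null(names(obj)))
      stop("each rule clause must be a single {\"function\": inputs} pair")
    arg <- obj[[1]]
    if (is.list(arg)) arg <- vapply(arg, as.character, character(1))
    rule_clause(names(obj), arg)
  })
  rule_set(clauses)
}

serialize_arg <- function(arg) {
  if (is.logical(arg)) return(if (arg) "true" else "false")
  if (is.numeric(arg)) return(format(arg, scientific = FALSE))
  if (length(arg) > 1L)
    return(paste0("[", paste0("\"", arg, "\"", collapse = ", "), "]"))
  paste0("\"", arg, "\"")
}

#' Serialize a rule set to canonical rule text
#'
#' The canonical dialect uses double quotes and `, ` separators;
#' `parse_rule_set(serialize_rule_set(rs))` is structurally equal to `rs`.
#'
#' @param rs an `soa_rule_set`.
#' @return a single string; `""` for the empty rule set.
#' @export
serialize_rule_set <- function(rs) {
  stopifnot(inherits(rs, "soa_rule_set"))
  if (n_clauses(rs) == 0L) return("")
  paste(vapply(rs$clauses, serialize_clause, character(1)), collapse = ", ")
}

serialize_clause <- function(cl) {
  sprintf("{\"%s\": %s}", cl$fun, serialize_arg(cl$arg))
}

#' @export
print.soa_rule_set <- function(x, ...) {
  if (n_clauses(x) == 0L) cat("<soa_rule_set> (empty: always true)\n")
  else cat("<soa_rule_set>", serialize_rule_set(x), "\n")
  invisible(x)
}

#' @export
format.soa_rule_set <- function(x, ...) serialize_rule_set(x)

#' Create a runtime evaluation context
#'
#' The context against which edge rules are evaluated while a subject walks
#' the schedule: which interactions have occurred and on which days, how many
#' times each node has executed, how many treatment cycles are complete, and
#' the subject's flags (consent, withdrawal, eligibility, ...).
#'
#' @param history character vector of visited interaction aliases, in order.
#' @param days integer actual day offsets matching `history` (non-decreasing).
#' @param counts named integer vector: executions per node alias.
#' @param completed_cycles number of fully completed treatment cycles.
#' @param flags named list of subject flags (logical or string values).
#' @return an object of class `soa_context`.
#' @export
soa_context <- function(history = character(), days = NULL,
                        counts = integer(), completed_cycles = 0L,
                        flags = list()) {
  if (is.null(days)) days <- rep(NA_integer_, length(history))
  stopifnot(length(days) == length(history))
  if (length(days) > 1L && !all(diff(days[!is.na(days)]) >= 0L))
    stop("history days must be non-decreasing")
  if (any(counts < 0L)) stop("execution counts must be non-negative")
  structure(
    list(history = as.character(history), days = as.integer(days),
         counts = counts, completed_cycles = as.integer(completed_cycles),
         flags = flags),
    class = "soa_context"
  )
}

#' Evaluate a single rule clause
#'
#' Built-in semantics: `interactions_exist` is true when every listed alias
#' appears in the context's interaction history (vacuously true for an empty
#' list); `interactions_not_exist` when none does; `maxRepeats n` while the
#' execution count of the edge's target node is below `n`; `n_cycles "<k"`
#' compares the prospective cycle index (`completed_cycles + 1`) using the
#' stated operator. Any other function name is a subject flag compared for
#' equality, with `"true"`/`"false"` strings coerced to logicals.
#'
#' @param clause an `soa_rule_clause`.
#' @param ctx an [soa_context()].
#' @param edge the `soa_transition` being considered (supplies the target
#'   node for `maxRepeats`); may be `NULL` for flag/history clauses.
#' @param strict in strict mode a flag absent from the context is an error;
#'   in lenient mode (default) it evaluates `FALSE` with a warning.
#' @param target_alias alias of the edge's target node, if `edge` endpoints
#'   are ids; defaults to `edge$target`.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_clause <- function(clause, ctx, edge = NULL, strict = FALSE,
                            target_alias = NULL) {
  stopifnot(inherits(clause, "soa_rule_clause"), inherits(ctx, "soa_context"))
  fun <- clause$fun
  if (fun == "interactions_exist")
    return(all(clause$arg %in% ctx$history))
  if (fun == "interactions_not_exist")
    return(!any(clause$arg %in% ctx$history))
  if (fun == "maxRepeats") {
    tgt <- target_alias %||% edge$target
    if (is.null(tgt)) stop("maxRepeats requires the governing edge's target")
    count <- if (tgt %in% names(ctx$counts)) ctx$counts[[tgt]] else 0L
    return(count < clause$arg)
  }
  if (fun == "n_cycles")
    return(apply_comparison(ctx$completed_cycles + 1L,
                            parse_comparison(clause$arg)))
  # open-vocabulary flag clause
  val <- ctx$flags[[fun]]
  if (is.null(val)) {
    if (strict) stop("flag '", fun, "' missing from evaluation context")
    warning("flag '", fun, "' missing from context; clause evaluates FALSE",
            call. = FALSE)
    return(FALSE)
  }
  if (is.character(val) && tolower(val) %in% c("true", "false"))
    val <- identical(tolower(val), "true")
  isTRUE(identical(val, clause$arg)) ||
    (is.character(val) && is.character(clause$arg) && val == clause$arg)
}

#' Evaluate a rule set
#'
#' The conjunction of its clauses: every clause must resolve `TRUE` for the
#' edge's path to be selectable. An empty rule set is `TRUE`.
#'
#' @inheritParams evaluate_clause
#' @param rs an `soa_rule_set`.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_rule_set <- function(rs, ctx, edge = NULL, strict = FALSE,
                              target_alias = NULL) {
  stopifnot(inherits(rs, "soa_rule_set"))
  for (cl in rs$clauses) {
    if (!evaluate_clause(cl, ctx, edge, strict = strict,
                         target_alias = target_alias))
      return(FALSE)
  }
  TRUE
}
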