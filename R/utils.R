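#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils head modifyList read.csv write.csv write.table
NULL

# Generate a version-4 UUID from R's RNG stream (deterministic under set.seed).
new_uuid <- function() {
  hex <- c(0:9, letters[1:6])
  d <- sample(hex, 32L, replace = TRUE)
  d[13] <- "4"                                   # version nibble
  d[17] <- sample(c("8", "9", "a", "b"), 1L)     # variant nibble
  paste0(
    paste(d[1:8], collapse = ""), "-",
    paste(d[9:12], collapse = ""), "-",
    paste(d[13:16], collapse = ""), "-",
    paste(d[17:20], collapse = ""), "-",
    paste(d[21:32], collapse = "")
  )
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render an internal day offset as a protocol day label
#'
#' Internally all timings are signed integer offsets with 0 at the
#' `referenceTimepoint` node. Protocols conventionally label the reference day
#' "Day 1" and use no day zero, so offset 0 renders as day 1, offset 6 as
#' day 7, and negative (screening) offsets render as negative days.
#'
#' @param offset integer vector of internal day offsets.
#' @param numeric if `TRUE` return the numeric day, otherwise a "Day N" label.
#' @return character labels, or integers when `numeric = TRUE`.
#' @examples
#' day_label(c(-28, 0, 6, 27))
#' day_label(28, numeric = TRUE)  # the day after "Day 28"
#' @export
day_label <- function(offset, numeric = FALSE) {
  day <- ifelse(offset >= 0, offset + 1L, as.integer(offset))
  if (numeric) return(as.integer(day))
  paste0("Day ", day)
}

#' Parse a protocol day label back to an internal offset
#'
#' Inverse of [day_label()]: "Day 1" maps to offset 0, "Day 28" to 27 and
#' negative days map to themselves.
#'
#' @param day integer protocol day (no day zero).
#' @return integer internal offsets.
#' @export
day_offset <- function(day) {
  day <- as.integer(day)
  if (any(day == 0L, na.rm = TRUE)) stop("protocol day labels have no day 0")
  ifelse(day > 0L, day - 1L, day)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

slugify <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "-", x))
  gsub("^-|-$", "", x)
}
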