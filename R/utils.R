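`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "kbgraph_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "kbgraph_error")))
}

#' Convert a camelCase identifier to snake_case
#'
#' Used for the relational-dump dialect: class and slot names become
#' table and column names (\code{EntityWithAccessionedSequence} ->
#' \code{entity_with_accessioned_sequence}).
#'
#' @param x character vector of camelCase identifiers.
#' @return character vector in snake_case.
#' @keywords internal
snakeCase <- function(x) {
  tolower(gsub("(?<=[a-z0-9])(?=[A-Z])", "_", x, perl = TRUE))
}

## sample() with the size-1 surprise removed
samplePick <- function(x, k = 1L, replace = FALSE) {
  if (length(x) == 0L) return(x[0L])
  x[sample.int(length(x), k, replace = replace)]
}

## deterministic sort for integer id sets
idSort <- function(x) sort(unique(as.integer(x)))

isScalarPrimitive <- function(v) {
  length(v) == 1L && (is.character(v) || is.numeric(v) || is.logical(v)) && !is.na(v)
}
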