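# Shared helpers: classed conditions, text tokenization, local RNG scope.

#' Entity classes recognized in annotation files
#'
#' The six bioentity classes produced by abstract-level concept annotators.
#' Unknown classes are preserved on parse but flagged in the QC report.
#'
#' @format A character vector of length 6.
#' @export
ENTITY_CLASSES <- c("Species", "Chemical", "Disease", "Gene", "Mutation", "CellLine")

# -- conditions ---------------------------------------------------------------

stop_litnet <- function(msg, class, call. = FALSE, ...) {
  stop(structure(
    class = c(class, "litnet_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  ))
}

stop_format <- function(msg, ...) stop_litnet(msg, "litnet_format_error", ...)
stop_validation <- function(msg, ...) stop_litnet(msg, "litnet_validation_error", ...)
stop_lookup <- function(msg, ...) stop_litnet(msg, "litnet_lookup_error", ...)
stop_parse <- function(msg, pos = NA_integer_) {
  stop_litnet(msg, "litnet_parse_error", position = pos)
}
stop_usage <- function(msg) stop_litnet(msg, "litnet_usage_error")
stop_structural <- function(msg, ...) stop_litnet(msg, "litnet_structural_error", ...)

# -- tokenization -------------------------------------------------------------

#' Tokenize free text for query matching
#'
#' Case-folds and splits on runs of non-alphanumeric characters, so hyphens
#' split ("anti-inflammatory" yields two tokens) and punctuation is stripped.
#' This is the single tokenizer shared by query parsing and evaluation.
#'
#' @param x a character scalar.
#' @return character vector of lower-case tokens (possibly empty).
#' @export
tokenize_text <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# -- RNG scope ----------------------------------------------------------------

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Read a whole text source (path, connection, or literal text given as a
# character vector with a "text" marker) into one string with \n endings.
read_text <- function(x) {
  if (inherits(x, "connection")) {
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  } else if (is.character(x) && length(x) == 1L && !grepl("[\n\t|]", x) && file.exists(x)) {
    txt <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    txt <- paste(x, collapse = "\n")
  }
  gsub("\r\n?", "\n", txt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
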