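# Boolean keyword query language: AND / OR / NOT (case-insensitive,
# standalone tokens), double-quoted phrases, trailing-asterisk truncation,
# parentheses, implicit AND for bare adjacency. Precedence NOT > AND > OR,
# all operators binary and left-associative; NOT is PubMed-style `l NOT r`.

# -- lexer --------------------------------------------------------------------

# Token stream: list of list(type, value, pos); types: lparen, rparen,
# phrase (value = token vector), word (value = raw word), eof.
lex_query <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "lparen", pos = i); i <- i + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "rparen", pos = i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[[j]] != "\"") j <- j + 1L
      if (j > n) stop_parse(sprintf("unbalanced quote starting at position %d", i), pos = i)
      body <- paste(chars[seq.int(i + 1L, length.out = j - i - 1L)], collapse = "")
      ptoks <- tokenize_text(body)
      if (!length(ptoks)) stop_parse(sprintf("empty phrase at position %d", i), pos = i)
      toks[[length(toks) + 1L]] <- list(type = "phrase", value = ptoks, pos = i)
      i <- j + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()\"]$", chars[[j]], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    toks[[length(toks) + 1L]] <- list(type = "word", value = word, pos = i)
    i <- j
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", pos = n + 1L)
  toks
}

ast_node <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "litnet_query_ast")
}

# Turn a raw word token into a leaf AST node.
word_to_leaf <- function(word, pos) {
  truncated <- grepl("\\*$", word)
  if (truncated) word <- sub("\\*+$", "", word)
  toks <- tokenize_text(word)
  if (!length(toks)) stop_parse(sprintf("term at position %d has no searchable characters", pos), pos = pos)
  if (truncated) {
    if (length(toks) > 1L) {
      stop_parse(sprintf("truncated term at position %d must be a single token", pos), pos = pos)
    }
    return(ast_node("truncated", prefix = toks))
  }
  if (length(toks) == 1L) ast_node("term", token = toks) else ast_node("phrase", tokens = toks)
}

is_operator_word <- function(tok) {
  tok$type == "word" && toupper(tok$value) %in% c("AND", "OR", "NOT")
}

#' Parse a Boolean keyword query
#'
#' Grammar: `OR` binds loosest, then `AND` (bare adjacency of two terms is
#' an implicit AND), then the binary `NOT`; parentheses group; `"..."` is a
#' contiguous phrase; a trailing `*` makes a term a prefix (truncation)
#' match. Operators are recognized case-insensitively when they stand
#' alone. A leading or dangling operator, or unbalanced quotes or
#' parentheses, is a parse error reporting the character position.
#'
#' @param text non-empty query string.
#' @return a `litnet_query_ast`: nested list with `kind` in term, phrase,
#'   truncated, and, or, not.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop_parse("empty query", pos = 1L)
  toks <- lex_query(text)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }

  parse_primary <- function() {
    t <- peek()
    if (t$type == "lparen") {
      advance()
      node <- parse_or()
      if (peek()$type != "rparen") {
        stop_parse(sprintf("unbalanced parenthesis opened at position %d", t$pos), pos = t$pos)
      }
      advance()
      return(node)
    }
    if (t$type == "phrase") { advance(); return(ast_node("phrase", tokens = t$value)) }
    if (t$type == "word") {
      if (is_operator_word(t)) {
        stop_parse(sprintf("operator '%s' at position %d has no left operand",
                           toupper(t$value), t$pos), pos = t$pos)
      }
      advance()
      return(word_to_leaf(t$value, t$pos))
    }
    if (t$type == "rparen") stop_parse(sprintf("unmatched ')' at position %d", t$pos), pos = t$pos)
    stop_parse(sprintf("unexpected end of query at position %d", t$pos), pos = t$pos)
  }

  parse_not <- function() {
    left <- parse_primary()
    while (peek()$type == "word" && toupper(peek()$value) == "NOT") {
      op <- advance()
      if (peek()$type %in% c("eof", "rparen")) {
        stop_parse(sprintf("dangling NOT at position %d", op$pos), pos = op$pos)
      }
      left <- ast_node("not", left = left, right = parse_primary())
    }
    left
  }

  parse_and <- function() {
    left <- parse_not()
    repeat {
      t <- peek()
      if (t$type == "word" && toupper(t$value) == "AND") {
        op <- advance()
        if (peek()$type %in% c("eof", "rparen")) {
          stop_parse(sprintf("dangling AND at position %d", op$pos), pos = op$pos)
        }
        left <- ast_node("and", left = left, right = parse_not())
      } else if (t$type %in% c("lparen", "phrase") ||
                 (t$type == "word" && toupper(t$value) != "OR")) {
        # implicit AND on adjacency (a bare NOT here is consumed by parse_not)
        left <- ast_node("and", left = left, right = parse_not())
      } else {
        return(left)
      }
    }
  }

  parse_or <- function() {
    left <- parse_and()
    while (peek()$type == "word" && toupper(peek()$value) == "OR") {
      op <- advance()
      if (peek()$type %in% c("eof", "rparen")) {
        stop_parse(sprintf("dangling OR at position %d", op$pos), pos = op$pos)
      }
      left <- ast_node("or", left = left, right = parse_and())
    }
    left
  }

  node <- parse_or()
  if (peek()$type != "eof") {
    t <- peek()
    stop_parse(sprintf("unexpected input at position %d", t$pos), pos = t$pos)
  }
  node
}

#' @export
print.litnet_query_ast <- function(x, ...) {
  fmt <- function(n) {
    switch(n$kind,
      term = n$token,
      truncated = paste0(n$prefix, "*"),
      phrase = paste0("\"", paste(n$tokens, collapse = " "), "\""),
      and = paste0("(", fmt(n$left), " AND ", fmt(n$right), ")"),
      or = paste0("(", fmt(n$left), " OR ", fmt(n$right), ")"),
      not = paste0("(", fmt(n$left), " NOT ", fmt(n$right), ")"))
  }
  cat(fmt(x), "\n")
  invisible(x)
}

# -- evaluation ---------------------------------------------------------------

# Token vectors of every document's title + " " + abstract.
corpus_tokens <- function(corpus) {
  lapply(corpus$documents, function(d) tokenize_text(offset_text(d)))
}

phrase_in_tokens <- function(tokens, phrase) {
  k <- length(phrase)
  if (k == 1L) return(phrase %in% tokens)
  n <- length(tokens)
  if (n < k) return(FALSE)
  starts <- which(tokens == phrase[1])
  for (s in starts) {
    if (s + k - 1L <= n && all(tokens[s:(s + k - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

#' Evaluate a query against a corpus
#'
#' Matches over the case-folded, punctuation-stripped tokens of each
#' document's title plus abstract: a term is token equality, a truncated
#' term is a token prefix match, a phrase is a contiguous token run; AND,
#' OR and NOT are set intersection, union and difference over matching
#' pmids.
#'
#' @param corpus a `litnet_corpus`.
#' @param ast a `litnet_query_ast` (or query string, parsed on the fly).
#' @return sorted character vector of matching pmids.
#' @export
evaluate_query <- function(corpus, ast) {
  stopifnot(inherits(corpus, "litnet_corpus"))
  if (is.character(ast)) ast <- parse_query(ast)
  toks <- corpus_tokens(corpus)
  pmids <- names(toks)
  if (is.null(pmids)) pmids <- character()

  eval_node <- function(node) {
    switch(node$kind,
      term = pmids[vapply(toks, function(tt) node$token %in% tt, logical(1))],
      truncated = pmids[vapply(toks, function(tt) any(startsWith(tt, node$prefix)), logical(1))],
      phrase = pmids[vapply(toks, phrase_in_tokens, logical(1), phrase = node$tokens)],
      and = intersect(eval_node(node$left), eval_node(node$right)),
      or = union(eval_node(node$left), eval_node(node$right)),
      not = setdiff(eval_node(node$left), eval_node(node$right)),
      stop_usage(sprintf("unknown AST node kind '%s'", node$kind)))
  }
  sort(unique(eval_node(ast)))
}
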