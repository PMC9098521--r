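# PubTator-format corpus I/O and identifier normalization.
#
# The on-disk dialect is per document:
#   PMID|t|<title>
#   PMID|a|<abstract>          (optional)
#   PMID<TAB>start<TAB>end<TAB>mention<TAB>class<TAB>identifier   (0+ lines)
#   <blank line>
# Offsets are 0-based half-open into title + " " + abstract.

empty_annotations <- function() {
  data.frame(
    pmid = character(), start = integer(), end = integer(),
    mention = character(), entity_class = character(), raw_id = character(),
    stringsAsFactors = FALSE
  )
}

new_document <- function(pmid, title, abstract = "", annotations = empty_annotations()) {
  structure(
    list(pmid = pmid, title = title, abstract = abstract, annotations = annotations),
    class = "litnet_document"
  )
}

new_corpus <- function(documents = list(), qc = empty_qc()) {
  structure(list(documents = documents, qc = qc), class = "litnet_corpus")
}

empty_qc <- function() {
  data.frame(pmid = character(), line = integer(), issue = character(),
             stringsAsFactors = FALSE)
}

#' Text a document's annotation offsets index into
#'
#' Offsets address the concatenation of title, a single space, and abstract.
#'
#' @param doc a document from a corpus.
#' @return character scalar.
#' @export
offset_text <- function(doc) paste(doc$title, doc$abstract, sep = " ")

#' @export
print.litnet_corpus <- function(x, ...) {
  n_ann <- sum(vapply(x$documents, function(d) nrow(d$annotations), integer(1)))
  cat(sprintf("<litnet_corpus: %d documents, %d annotations, %d QC issues>\n",
              length(x$documents), n_ann, nrow(x$qc)))
  invisible(x)
}

#' Parse PubTator-format annotated literature
#'
#' Reads the plain-text annotation dialect (title line, optional abstract
#' line, tab-separated annotation rows, blank separator) into a corpus.
#' Unparseable annotation rows are never silently dropped: they are recorded
#' in the QC report (`$qc`, columns pmid/line/issue). In lenient mode (the
#' default) annotation offsets that do not reproduce the mention are also
#' only QC-flagged, because real annotator exports contain drifted offsets;
#' with `strict_offsets = TRUE` they raise a validation error.
#'
#' @param x path, connection, or character vector of lines.
#' @param strict_offsets validate that `[start,end)` of
#'   [offset_text()] equals the mention, erroring on mismatch.
#' @return a `litnet_corpus`: `$documents` is a named list (pmid ->
#'   document, insertion order preserved), `$qc` the QC report.
#' @export
parse_pubtator <- function(x, strict_offsets = FALSE) {
  txt <- read_text(x)
  if (!nzchar(txt)) return(new_corpus())
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]

  docs <- list()
  qc <- list()
  cur <- NULL
  cur_ann <- list()

  flush_doc <- function() {
    if (is.null(cur)) return()
    ann <- if (length(cur_ann)) do.call(rbind, cur_ann) else empty_annotations()
    cur$annotations <- ann
    if (!is.null(docs[[cur$pmid]])) {
      stop_format(sprintf("duplicate pmid '%s'", cur$pmid))
    }
    docs[[cur$pmid]] <<- cur
    cur <<- NULL
    cur_ann <<- list()
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) { flush_doc(); next }

    m <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(m) == 4L) {
      pmid <- m[2]; kind <- m[3]; body <- m[4]
      if (kind == "t") {
        flush_doc()
        cur <- new_document(pmid, title = body)
      } else {
        if (is.null(cur) || cur$pmid != pmid) {
          stop_format(sprintf("line %d: abstract line for '%s' without matching title", i, pmid))
        }
        cur$abstract <- body
      }
      next
    }

    if (grepl("\t", line, fixed = TRUE)) {
      if (is.null(cur)) {
        stop_format(sprintf("line %d: annotation line before any title line", i))
      }
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) != 6L) {
        qc[[length(qc) + 1L]] <- data.frame(
          pmid = cur$pmid, line = i,
          issue = sprintf("annotation line has %d fields, expected 6", length(fields)),
          stringsAsFactors = FALSE)
        next
      }
      start <- suppressWarnings(as.integer(fields[2]))
      end <- suppressWarnings(as.integer(fields[3]))
      if (is.na(start) || is.na(end) || start < 0L || start >= end || !nzchar(fields[4])) {
        qc[[length(qc) + 1L]] <- data.frame(
          pmid = cur$pmid, line = i, issue = "invalid offsets or empty mention",
          stringsAsFactors = FALSE)
        next
      }
      if (fields[1] != cur$pmid) {
        qc[[length(qc) + 1L]] <- data.frame(
          pmid = cur$pmid, line = i, issue = "annotation pmid differs from document pmid",
          stringsAsFactors = FALSE)
        next
      }
      if (!(fields[5] %in% ENTITY_CLASSES)) {
        qc[[length(qc) + 1L]] <- data.frame(
          pmid = cur$pmid, line = i,
          issue = sprintf("unknown entity class '%s'", fields[5]),
          stringsAsFactors = FALSE)
      }
      cur_ann[[length(cur_ann) + 1L]] <- data.frame(
        pmid = fields[1], start = start, end = end, mention = fields[4],
        entity_class = fields[5], raw_id = fields[6], stringsAsFactors = FALSE)
      next
    }

    stop_format(sprintf("line %d: malformed line '%s'", i, substr(line, 1, 60)))
  }
  flush_doc()

  qc_df <- if (length(qc)) do.call(rbind, qc) else empty_qc()
  corpus <- new_corpus(docs, qc_df)
  validate_offsets(corpus, strict = strict_offsets)
}

# Offset check over a whole corpus: strict -> error, lenient -> QC rows.
validate_offsets <- function(corpus, strict = FALSE) {
  for (doc in corpus$documents) {
    txt <- offset_text(doc)
    ann <- doc$annotations
    if (!nrow(ann)) next
    got <- substring(txt, ann$start + 1L, ann$end)
    bad <- which(got != ann$mention | ann$end > nchar(txt))
    for (k in bad) {
      msg <- sprintf("offset [%d,%d) reads '%s', mention is '%s'",
                     ann$start[k], ann$end[k], got[k], ann$mention[k])
      if (strict) {
        stop_validation(sprintf("pmid %s: %s", doc$pmid, msg))
      }
      corpus$qc <- rbind(corpus$qc, data.frame(
        pmid = doc$pmid, line = NA_integer_, issue = msg, stringsAsFactors = FALSE))
    }
  }
  corpus
}

#' Serialize a corpus to PubTator text
#'
#' Canonical writer: title line, abstract line (always written, possibly
#' empty), annotation rows in stored order, one terminating blank line per
#' document, `\n` endings. `parse_pubtator(write_pubtator(corpus))`
#' reproduces the corpus exactly.
#'
#' @param corpus a `litnet_corpus`.
#' @param path optional file path; when given the text is also written there.
#' @return the serialized text, invisibly when `path` is given.
#' @export
write_pubtator <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "litnet_corpus"))
  out <- character()
  for (doc in corpus$documents) {
    out <- c(out, paste0(doc$pmid, "|t|", doc$title),
             paste0(doc$pmid, "|a|", doc$abstract))
    ann <- doc$annotations
    if (nrow(ann)) {
      out <- c(out, paste(ann$pmid, ann$start, ann$end, ann$mention,
                          ann$entity_class, ann$raw_id, sep = "\t"))
    }
    out <- c(out, "")
  }
  txt <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    return(invisible(txt))
  }
  txt
}

#' Normalize a raw annotation identifier to typed entity identifiers
#'
#' Splits composite identifiers on `;` and `|`, strips a `MESH:` prefix
#' case-insensitively, and types the result: a bare integer with class
#' Species becomes a TaxID, a `D`/`C`-prefixed MeSH code with class
#' Chemical or Disease becomes a MeSH UI, `-` or empty yields nothing, and
#' anything else is kept under namespace `other` with `flagged = TRUE`.
#' Total function: never errors, order of composite parts is preserved.
#'
#' @param raw_id verbatim identifier field from an annotation row.
#' @param entity_class the annotation's entity class.
#' @return data.frame with columns namespace, accession, entity_class, key
#'   (`"namespace:accession"`), flagged; zero rows for unidentified input.
#' @export
normalize_identifier <- function(raw_id, entity_class) {
  empty <- data.frame(namespace = character(), accession = character(),
                      entity_class = character(), key = character(),
                      flagged = logical(), stringsAsFactors = FALSE)
  if (is.na(raw_id)) return(empty)
  parts <- strsplit(raw_id, "[;|]")[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts) & parts != "-"]
  if (!length(parts)) return(empty)

  one <- function(p) {
    acc <- sub("^(?i)mesh:", "", p, perl = TRUE)
    if (grepl("^[0-9]+$", acc) && identical(entity_class, "Species")) {
      ns <- "taxid"; flag <- FALSE
    } else if (grepl("^[CD][0-9]{6,9}$", acc) &&
               entity_class %in% c("Chemical", "Disease")) {
      ns <- "mesh"; flag <- FALSE
    } else {
      ns <- "other"; flag <- TRUE
    }
    data.frame(namespace = ns, accession = acc, entity_class = entity_class,
               key = paste0(ns, ":", acc), flagged = flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(parts, one))
}

# Normalized entities of one document, restricted to `classes`; deduplicated
# on key, keeping first-seen metadata.
document_entities <- function(doc, classes = ENTITY_CLASSES) {
  ann <- doc$annotations
  ann <- ann[ann$entity_class %in% classes, , drop = FALSE]
  if (!nrow(ann)) {
    return(data.frame(namespace = character(), accession = character(),
                      entity_class = character(), key = character(),
                      mention = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    ids <- normalize_identifier(ann$raw_id[i], ann$entity_class[i])
    if (nrow(ids)) ids$mention <- ann$mention[i]
    ids
  })
  ids <- do.call(rbind, rows)
  if (is.null(ids) || !nrow(ids)) {
    return(data.frame(namespace = character(), accession = character(),
                      entity_class = character(), key = character(),
                      mention = character(), stringsAsFactors = FALSE))
  }
  ids[!duplicated(ids$key), c("namespace", "accession", "entity_class", "key", "mention")]
}

#' Index entities to the documents that mention them
#'
#' Maps every normalized entity identifier occurring in the corpus (for the
#' selected classes) to the set of pmids whose documents carry at least one
#' annotation normalizing to it. Multiple mentions within one document
#' contribute that pmid once.
#'
#' @param corpus a `litnet_corpus`.
#' @param classes entity classes to include (default: all six).
#' @return named list, entity key -> sorted character vector of pmids, with
#'   attribute `entities`: data.frame(key, namespace, accession,
#'   entity_class, mention) of first-seen metadata, sorted by key.
#' @export
entity_document_index <- function(corpus, classes = ENTITY_CLASSES) {
  stopifnot(inherits(corpus, "litnet_corpus"))
  idx <- list()
  meta <- list()
  for (doc in corpus$documents) {
    ents <- document_entities(doc, classes)
    for (i in seq_len(nrow(ents))) {
      k <- ents$key[i]
      idx[[k]] <- c(idx[[k]], doc$pmid)
      if (is.null(meta[[k]])) meta[[k]] <- ents[i, , drop = FALSE]
    }
  }
  keys <- sort(names(idx))
  idx <- lapply(idx[keys], function(p) sort(unique(p)))
  ents <- if (length(meta)) do.call(rbind, meta[keys]) else
    data.frame(namespace = character(), accession = character(),
               entity_class = character(), key = character(),
               mention = character(), stringsAsFactors = FALSE)
  rownames(ents) <- NULL
  attr(idx, "entities") <- ents
  idx
}

#' Write the corpus QC report
#'
#' Tab-separated text with columns pmid, line, issue.
#'
#' @param corpus a `litnet_corpus`.
#' @param path output file path.
#' @return the report data.frame, invisibly.
#' @export
write_qc_report <- function(corpus, path) {
  utils::write.table(corpus$qc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(corpus$qc)
}
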