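# Independent brute-force oracles. These deliberately re-derive results
# from first principles (explicit loops over documents, parent maps and
# strings) so they never share code paths with the implementations they
# check.

# entity -> pmid sets by scanning every (document, annotation) pair
oracle_entity_index <- function(corpus, classes = ENTITY_CLASSES) {
  out <- list()
  for (doc in corpus$documents) {
    ann <- doc$annotations
    seen <- character()
    for (i in seq_len(nrow(ann))) {
      if (!(ann$entity_class[i] %in% classes)) next
      ids <- normalize_identifier(ann$raw_id[i], ann$entity_class[i])
      for (k in ids$key) {
        if (k %in% seen) next
        seen <- c(seen, k)
        out[[k]] <- sort(unique(c(out[[k]], doc$pmid)))
      }
    }
  }
  out[order(names(out))]
}

# co-occurrence by double loop over documents x unordered entity pairs
oracle_cooc <- function(corpus, pmids, classes = ENTITY_CLASSES) {
  node_pm <- list(); edge_pm <- list()
  for (pm in pmids) {
    doc <- corpus$documents[[pm]]
    keys <- character()
    ann <- doc$annotations
    for (i in seq_len(nrow(ann))) {
      if (!(ann$entity_class[i] %in% classes)) next
      keys <- union(keys, normalize_identifier(ann$raw_id[i], ann$entity_class[i])$key)
    }
    keys <- sort(keys)
    for (k in keys) node_pm[[k]] <- union(node_pm[[k]], pm)
    if (length(keys) >= 2) {
      for (i in 1:(length(keys) - 1)) {
        for (j in (i + 1):length(keys)) {
          ek <- paste(keys[i], keys[j], sep = "|")
          edge_pm[[ek]] <- union(edge_pm[[ek]], pm)
        }
      }
    }
  }
  list(node_pmids = lapply(node_pm[order(names(node_pm))], sort),
       edge_pmids = lapply(edge_pm[order(names(edge_pm))], sort))
}

# naive per-document Boolean matcher (returns TRUE/FALSE for one document)
oracle_match_doc <- function(tokens, ast) {
  has_phrase <- function(ph) {
    k <- length(ph); n <- length(tokens)
    if (n < k) return(FALSE)
    for (s in seq_len(n - k + 1)) if (all(tokens[s:(s + k - 1)] == ph)) return(TRUE)
    FALSE
  }
  switch(ast$kind,
    term = ast$token %in% tokens,
    truncated = any(substr(tokens, 1, nchar(ast$prefix)) == ast$prefix),
    phrase = has_phrase(ast$tokens),
    and = oracle_match_doc(tokens, ast$left) && oracle_match_doc(tokens, ast$right),
    or = oracle_match_doc(tokens, ast$left) || oracle_match_doc(tokens, ast$right),
    not = oracle_match_doc(tokens, ast$left) && !oracle_match_doc(tokens, ast$right))
}

oracle_eval_query <- function(corpus, ast) {
  hit <- vapply(corpus$documents, function(d) {
    oracle_match_doc(tokenize_text(paste(d$title, d$abstract)), ast)
  }, logical(1))
  sort(names(corpus$documents)[hit])
}

# induced-subtree node set: union of explicit parent-walks
oracle_subtree_nodes <- function(taxonomy, hits, root) {
  nodes <- root
  for (h in hits) {
    if (!(h %in% names(taxonomy$parent))) next
    path <- h
    cur <- h
    while (cur != taxonomy$root && cur != root) {
      cur <- taxonomy$parent[[cur]]
      path <- c(path, cur)
    }
    if (cur == root) nodes <- union(nodes, path)
  }
  sort(nodes)
}

# mesh-forest node set: prefix closure of hit tree numbers + letters + root
oracle_mesh_nodes <- function(mesh, hits, categories = c("C", "D")) {
  closure <- character()
  for (ui in hits) {
    if (!(ui %in% names(mesh$tree_numbers))) next
    for (tn in mesh$tree_numbers[[ui]]) {
      if (!(substr(tn, 1, 1) %in% categories)) next
      parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
      for (k in seq_along(parts)) {
        closure <- union(closure, paste(parts[1:k], collapse = "."))
      }
    }
  }
  sort(unique(c("MeSH", substr(closure, 1, 1), closure)))
}

# connected components by flood fill over an adjacency list
oracle_components <- function(net) {
  ids <- names(net$nodes)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (e in net$edges) {
    adj[[e$from]] <- c(adj[[e$from]], e$to)
    adj[[e$to]] <- c(adj[[e$to]], e$from)
  }
  seen <- character(); sizes <- integer()
  for (v in ids) {
    if (v %in% seen) next
    queue <- v; comp <- character()
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (x %in% comp) next
      comp <- c(comp, x)
      queue <- c(queue, setdiff(adj[[x]], comp))
    }
    seen <- c(seen, comp)
    sizes <- c(sizes, length(comp))
  }
  list(n = length(sizes), max_size = if (length(sizes)) max(sizes) else 0L)
}

# allied-species recommendation by scanning reference species x hit anchors
oracle_recommend <- function(hits, ref_taxids, taxonomy, rank = "genus") {
  anchor_of <- function(t) {
    cur <- t
    while (cur != taxonomy$root) {
      cur <- taxonomy$parent[[cur]]
      if (taxonomy$rank[[cur]] == rank) return(cur)
    }
    NA_character_
  }
  anchors <- unique(stats::na.omit(vapply(hits, anchor_of, character(1))))
  out <- list()
  for (a in sort(anchors)) {
    rec <- character()
    for (r in ref_taxids) {
      if (r %in% hits) next
      cur <- r; under <- FALSE
      while (cur != taxonomy$root) {
        cur <- taxonomy$parent[[cur]]
        if (cur == a) { under <- TRUE; break }
      }
      if (under) rec <- c(rec, r)
    }
    if (length(rec)) out[[a]] <- sort(rec)
  }
  out
}

# random query AST over a vocabulary (used with a fixed seed)
random_ast <- function(vocab, depth = 3) {
  kinds <- if (depth <= 0) c("term", "truncated", "phrase") else
    c("term", "truncated", "phrase", "and", "or", "not", "and", "or")
  kind <- sample(kinds, 1)
  leaf_tok <- function() sample(vocab, 1)
  node <- switch(kind,
    term = list(kind = "term", token = leaf_tok()),
    truncated = {
      tok <- leaf_tok()
      list(kind = "truncated", prefix = substr(tok, 1, max(1, nchar(tok) - 2)))
    },
    phrase = list(kind = "phrase", tokens = sample(vocab, sample(1:2, 1))),
    list(kind = kind, left = random_ast(vocab, depth - 1),
         right = random_ast(vocab, depth - 1)))
  structure(node, class = "litnet_query_ast")
}
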