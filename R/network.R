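# Co-occurrence / hierarchy networks: construction, set algebra, basic
# properties, common-node similarity, and Gephi-compatible export.
#
# A litnet_coocnet stores nodes and edges as named lists sorted by key.
# Node: list(node_id, label, entity_class, doc_count, pmids, attrs).
# Edge (key "u|v", u < v): list(from, to, pmids, weight). `pmids` may be
# NULL for networks whose provenance is unknown (e.g. re-imported GEXF);
# whenever pmids is present, weight == length(pmids) is enforced.

edge_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

new_coocnet <- function(nodes = list(), edges = list(), provenance = list()) {
  if (length(nodes)) nodes <- nodes[order(names(nodes))]
  if (length(edges)) edges <- edges[order(names(edges))]
  net <- structure(list(nodes = nodes, edges = edges, provenance = provenance),
                   class = "litnet_coocnet")
  validate_coocnet(net)
}

validate_coocnet <- function(net) {
  for (e in net$edges) {
    if (!(e$from %in% names(net$nodes)) || !(e$to %in% names(net$nodes))) {
      stop_validation(sprintf("edge %s-%s has endpoint outside node set", e$from, e$to))
    }
    if (e$from == e$to) stop_validation(sprintf("self-loop on %s", e$from))
    if (!is.null(e$pmids) && e$weight != length(e$pmids)) {
      stop_validation(sprintf("edge %s-%s: weight %d != %d supporting pmids",
                              e$from, e$to, e$weight, length(e$pmids)))
    }
  }
  net
}

#' @export
print.litnet_coocnet <- function(x, ...) {
  cat(sprintf("<litnet_coocnet: %d nodes, %d edges>\n",
              length(x$nodes), length(x$edges)))
  invisible(x)
}

#' Node table of a network
#'
#' @param net a `litnet_coocnet`.
#' @return data.frame(node_id, label, entity_class, doc_count, category,
#'   common) sorted by node_id.
#' @export
network_nodes <- function(net) {
  if (!length(net$nodes)) {
    return(data.frame(node_id = character(), label = character(),
                      entity_class = character(), doc_count = integer(),
                      category = character(), common = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(net$nodes, function(nd) data.frame(
    node_id = nd$node_id, label = nd$label,
    entity_class = nd$entity_class %||% NA_character_,
    doc_count = as.integer(nd$doc_count %||% 0L),
    category = nd$attrs$category %||% NA_character_,
    common = nd$attrs$common %||% NA,
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Edge table of a network
#'
#' @param net a `litnet_coocnet`.
#' @return data.frame(from, to, weight) sorted by edge key.
#' @export
network_edges <- function(net) {
  if (!length(net$edges)) {
    return(data.frame(from = character(), to = character(), weight = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(net$edges, function(e) data.frame(
    from = e$from, to = e$to, weight = as.integer(e$weight),
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Build a document-level co-occurrence network
#'
#' Nodes are the normalized entities (of the selected classes) occurring in
#' the selected documents, with `doc_count` the number of distinct
#' supporting documents. Two distinct entities are linked iff at least one
#' selected document mentions both; the edge carries exactly those pmids
#' and `weight = |pmids|`. Self-loops are excluded; unidentified mentions
#' (`-`/empty identifiers) never enter the network.
#'
#' @param corpus a `litnet_corpus`.
#' @param pmids documents to use (default: all); typically the result of
#'   [evaluate_query()].
#' @param classes entity classes to include.
#' @param query_text optional provenance string.
#' @return a `litnet_coocnet`.
#' @export
build_cooc_network <- function(corpus, pmids = names(corpus$documents),
                               classes = ENTITY_CLASSES, query_text = NA_character_) {
  stopifnot(inherits(corpus, "litnet_corpus"))
  pmids <- intersect(as.character(pmids), names(corpus$documents))
  node_pmids <- list(); node_meta <- list(); epmids <- list()

  for (pm in pmids) {
    ents <- document_entities(corpus$documents[[pm]], classes)
    for (i in seq_len(nrow(ents))) {
      k <- ents$key[i]
      node_pmids[[k]] <- c(node_pmids[[k]], pm)
      if (is.null(node_meta[[k]])) node_meta[[k]] <- ents[i, , drop = FALSE]
      else if (ents$mention[i] < node_meta[[k]]$mention) node_meta[[k]]$mention <- ents$mention[i]
    }
    keys <- ents$key
    if (length(keys) >= 2L) {
      keys <- sort(keys)
      for (i in seq_len(length(keys) - 1L)) {
        for (j in seq.int(i + 1L, length(keys))) {
          ek <- edge_key(keys[i], keys[j])
          epmids[[ek]] <- c(epmids[[ek]], pm)
        }
      }
    }
  }

  nodes <- lapply(names(node_pmids), function(k) {
    p <- sort(unique(node_pmids[[k]]))
    m <- node_meta[[k]]
    list(node_id = k, label = m$mention, entity_class = m$entity_class,
         doc_count = length(p), pmids = p, attrs = list())
  })
  names(nodes) <- names(node_pmids)
  edges <- lapply(names(epmids), function(ek) {
    uv <- strsplit(ek, "|", fixed = TRUE)[[1]]
    p <- sort(unique(epmids[[ek]]))
    list(from = uv[1], to = uv[2], pmids = p, weight = length(p))
  })
  names(edges) <- names(epmids)
  new_coocnet(nodes, edges,
              provenance = list(query_text = query_text, corpus_id = NA_character_))
}

#' Render a hierarchy tree as a network
#'
#' Graph form of [induced_subtree()] / [mesh_forest()]: one node per tree
#' node (labelled `"<id>: <name>"` for taxa, `"<tree number>: <heading>"`
#' for MeSH), parent-child edges, node attributes carrying the category
#' (hit/ancestor/recommended) and doc_count. Tree edges have no supporting
#' documents (weight 0).
#'
#' @param hits named vector, entity accession (taxid or MeSH UI, optionally
#'   prefixed `taxid:` / `mesh:`) -> document count.
#' @param ontology a `litnet_taxonomy` or `litnet_meshtree`.
#' @param ... passed on to the tree builder (`root`, `categories`, ...).
#' @return a `litnet_coocnet` that is a forest.
#' @export
build_hierarchy_network <- function(hits, ontology, ...) {
  ids <- names(hits)
  if (is.null(ids)) { ids <- as.character(hits); hits <- stats::setNames(rep(0L, length(ids)), ids) }
  ns <- sub(":.*$", "", ids)
  has_prefix <- ids != ns
  if (any(has_prefix)) {
    pref <- unique(ns[has_prefix])
    if (length(pref) > 1L || any(!has_prefix)) {
      stop_usage("hits mix identifier namespaces; supply one namespace at a time")
    }
    expected <- if (inherits(ontology, "litnet_taxonomy")) "taxid" else "mesh"
    if (pref != expected) {
      stop_usage(sprintf("hits are '%s' ids but the ontology expects '%s'", pref, expected))
    }
    names(hits) <- sub("^[a-z]+:", "", ids)
  }

  tree <- if (inherits(ontology, "litnet_taxonomy")) {
    induced_subtree(ontology, names(hits), doc_counts = hits, ...)
  } else if (inherits(ontology, "litnet_meshtree")) {
    mesh_forest(ontology, names(hits), doc_counts = hits, ...)
  } else {
    stop_usage("ontology must be a litnet_taxonomy or litnet_meshtree")
  }
  tree_as_network(tree)
}

#' Convert a hierarchy tree to a network
#'
#' @param tree a `litnet_hiertree`.
#' @return a `litnet_coocnet` with parent-child edges.
#' @export
tree_as_network <- function(tree) {
  nodes <- list(); edges <- list()
  rec <- function(node) {
    nodes[[node$node_id]] <<- list(
      node_id = node$node_id, label = node$label, entity_class = NA_character_,
      doc_count = as.integer(node$payload$doc_count %||% 0L), pmids = NULL,
      attrs = list(category = node$category))
    for (ch in node$children) {
      ek <- edge_key(node$node_id, ch$node_id)
      edges[[ek]] <<- list(from = min(node$node_id, ch$node_id),
                           to = max(node$node_id, ch$node_id),
                           pmids = character(), weight = 0L)
      rec(ch)
    }
  }
  rec(tree$root)
  new_coocnet(nodes, edges)
}

# Merge two node records for the same node_id (union semantics).
merge_node <- function(a, b) {
  pm <- if (is.null(a$pmids) && is.null(b$pmids)) NULL else
    sort(unique(c(a$pmids, b$pmids)))
  dc <- if (!is.null(pm)) length(pm) else max(a$doc_count %||% 0L, b$doc_count %||% 0L)
  attrs <- utils::modifyList(b$attrs %||% list(), a$attrs %||% list())
  list(node_id = a$node_id, label = a$label,
       entity_class = a$entity_class %||% b$entity_class,
       doc_count = dc, pmids = pm, attrs = attrs)
}

merge_edge <- function(a, b) {
  pm <- if (is.null(a$pmids) && is.null(b$pmids)) NULL else
    sort(unique(c(a$pmids, b$pmids)))
  w <- if (!is.null(pm)) length(pm) else max(a$weight, b$weight)
  list(from = a$from, to = a$to, pmids = pm, weight = w)
}

#' Combine networks with set operations
#'
#' `union_networks`: node and edge sets are united; an edge present in both
#' inputs gets the union of its supporting pmid sets and its weight is
#' recomputed from that union, so documents matched by both inputs are not
#' double-counted. `intersect_networks`: nodes and edges present in both
#' (supporting pmids united). `difference_networks`: nodes of `a` not in
#' `b`, plus the edges of `a` whose endpoints both survive.
#'
#' @param a,b `litnet_coocnet` objects over comparable node-id spaces.
#' @return a `litnet_coocnet`.
#' @export
union_networks <- function(a, b) {
  nodes <- a$nodes
  for (k in names(b$nodes)) {
    nodes[[k]] <- if (is.null(nodes[[k]])) b$nodes[[k]] else merge_node(nodes[[k]], b$nodes[[k]])
  }
  edges <- a$edges
  for (k in names(b$edges)) {
    edges[[k]] <- if (is.null(edges[[k]])) b$edges[[k]] else merge_edge(edges[[k]], b$edges[[k]])
  }
  new_coocnet(nodes, edges, provenance = list(op = "union"))
}

#' @rdname union_networks
#' @export
intersect_networks <- function(a, b) {
  nk <- intersect(names(a$nodes), names(b$nodes))
  ek <- intersect(names(a$edges), names(b$edges))
  nodes <- lapply(stats::setNames(nk, nk), function(k) merge_node(a$nodes[[k]], b$nodes[[k]]))
  edges <- lapply(stats::setNames(ek, ek), function(k) merge_edge(a$edges[[k]], b$edges[[k]]))
  new_coocnet(nodes, edges, provenance = list(op = "intersect"))
}

#' @rdname union_networks
#' @export
difference_networks <- function(a, b) {
  nk <- setdiff(names(a$nodes), names(b$nodes))
  nodes <- a$nodes[nk]
  edges <- Filter(function(e) e$from %in% nk && e$to %in% nk, a$edges)
  new_coocnet(nodes, edges, provenance = list(op = "difference"))
}

#' Union of two networks with shared nodes flagged
#'
#' Returns `union_networks(a, b)` with a boolean node attribute `common`
#' marking nodes present in both inputs; the attribute travels into GEXF
#' exports so shared bioentities can be coloured in Gephi.
#'
#' @param a,b `litnet_coocnet` objects.
#' @return a `litnet_coocnet`.
#' @export
highlight_common <- function(a, b) {
  u <- union_networks(a, b)
  shared <- intersect(names(a$nodes), names(b$nodes))
  for (k in names(u$nodes)) u$nodes[[k]]$attrs$common <- k %in% shared
  u
}

#' Basic properties of a network
#'
#' @param net a `litnet_coocnet`.
#' @return list with n_nodes, n_edges, density (2E / N(N-1), 0 when N < 2),
#'   mean_degree (2E / N), n_components and max_component_size.
#' @export
network_properties <- function(net) {
  n <- length(net$nodes); m <- length(net$edges)
  if (n == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L, density = 0, mean_degree = 0,
                n_components = 0L, max_component_size = 0L))
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(names(net$nodes))
  if (m > 0L) {
    ed <- network_edges(net)
    g <- igraph::add_edges(g, rbind(ed$from, ed$to))
  }
  comp <- igraph::components(g)
  list(n_nodes = n, n_edges = m,
       density = if (n >= 2L) 2 * m / (n * (n - 1)) else 0,
       mean_degree = 2 * m / n,
       n_components = comp$no,
       max_component_size = max(comp$csize))
}

#' Similarity of two networks by common nodes
#'
#' True positives are the node ids present in both networks; `fp` the
#' query-only and `fn` the reference-only nodes. Precision, recall, F1 and
#' Jaccard follow; a zero denominator yields 0, except that comparing two
#' empty networks flags every metric as undefined (`NA`).
#'
#' @param query,reference `litnet_coocnet` objects.
#' @return a `litnet_similarity` list: tp, fp, fn, precision, recall, f1,
#'   jaccard, undefined.
#' @export
compare_networks <- function(query, reference) {
  qk <- names(query$nodes) %||% character()
  rk <- names(reference$nodes) %||% character()
  tp <- length(intersect(qk, rk))
  fp <- length(setdiff(qk, rk))
  fn <- length(setdiff(rk, qk))
  if (length(qk) == 0L && length(rk) == 0L) {
    return(structure(list(tp = 0L, fp = 0L, fn = 0L, precision = NA_real_,
                          recall = NA_real_, f1 = NA_real_, jaccard = NA_real_,
                          undefined = TRUE), class = "litnet_similarity"))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  jaccard <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, jaccard = jaccard, undefined = FALSE),
            class = "litnet_similarity")
}

#' @export
print.litnet_similarity <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d precision=%.4g recall=%.4g f1=%.4g jaccard=%.4g\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$jaccard))
  invisible(x)
}

#' Network summary as tab-separated text
#'
#' @param net a `litnet_coocnet`.
#' @param path output file path.
#' @return the stats list, invisibly.
#' @export
write_network_summary <- function(net, path) {
  st <- network_properties(net)
  df <- data.frame(property = names(st), value = unlist(st, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(st)
}
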