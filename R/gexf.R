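# Gephi-compatible exchange formats. GEXF 1.2draft is written and read;
# GraphML is write-only. Per-edge pmid provenance is deliberately NOT in
# either format (documented lossy): a re-imported network keeps weights but
# has unknown supporting-document sets.

GEXF_NS <- "http://www.gexf.net/1.2draft"

gexf_attr_decl <- data.frame(
  id = c("0", "1", "2", "3"),
  title = c("entity_class", "category", "doc_count", "common"),
  type = c("string", "string", "integer", "boolean"),
  stringsAsFactors = FALSE
)

#' Export a network as GEXF
#'
#' Writes GEXF 1.2draft, undirected, with typed node attvalues
#' (entity_class, category, doc_count, common), the node label, and the
#' edge weight. Node ids are written verbatim as GEXF node ids.
#' Supporting-pmid sets are not representable in GEXF and are dropped.
#'
#' @param net a `litnet_coocnet`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_gexf <- function(net, path) {
  stopifnot(inherits(net, "litnet_coocnet"))
  doc <- xml2::xml_new_root("gexf", xmlns = GEXF_NS, version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_len(nrow(gexf_attr_decl))) {
    xml2::xml_add_child(attrs, "attribute", id = gexf_attr_decl$id[i],
                        title = gexf_attr_decl$title[i], type = gexf_attr_decl$type[i])
  }
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (nd in net$nodes) {
    n_el <- xml2::xml_add_child(nodes_el, "node", id = nd$node_id,
                                label = nd$label %||% nd$node_id)
    av <- xml2::xml_add_child(n_el, "attvalues")
    put <- function(id, value) {
      if (!is.null(value) && !is.na(value)) {
        xml2::xml_add_child(av, "attvalue", `for` = id, value = as.character(value))
      }
    }
    put("0", nd$entity_class)
    put("1", nd$attrs$category %||% NULL)
    put("2", as.integer(nd$doc_count %||% 0L))
    put("3", if (is.null(nd$attrs$common)) NULL else tolower(as.character(nd$attrs$common)))
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  i <- 0L
  for (e in net$edges) {
    xml2::xml_add_child(edges_el, "edge", id = paste0("e", i), source = e$from,
                        target = e$to, weight = as.character(e$weight))
    i <- i + 1L
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a GEXF network
#'
#' Reads files produced by [export_gexf()] (and other undirected GEXF
#' 1.x files with the same node attributes). Edge provenance is unknown
#' after import: edge pmid sets are `NULL` and only weights survive. A
#' directed or malformed file is a format error.
#'
#' @param path GEXF file path.
#' @return a `litnet_coocnet`.
#' @export
import_gexf <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_format(sprintf("cannot read GEXF '%s': %s", path, conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "gexf") stop_format("not a GEXF document (root element mismatch)")
  xml2::xml_ns_strip(doc)
  graph <- xml2::xml_find_first(doc, ".//graph")
  if (inherits(graph, "xml_missing")) stop_format("GEXF file has no <graph> element")
  det <- xml2::xml_attr(graph, "defaultedgetype")
  if (!is.na(det) && det == "directed") stop_format("directed GEXF graphs are not supported")

  # attribute id -> title mapping (fall back to our canonical declaration)
  titles <- stats::setNames(gexf_attr_decl$title, gexf_attr_decl$id)
  for (a in xml2::xml_find_all(graph, "./attributes[@class='node']/attribute")) {
    titles[[xml2::xml_attr(a, "id")]] <- xml2::xml_attr(a, "title")
  }

  nodes <- list()
  for (n_el in xml2::xml_find_all(graph, "./nodes/node")) {
    id <- xml2::xml_attr(n_el, "id")
    if (is.na(id)) stop_format("GEXF node without id")
    lab <- xml2::xml_attr(n_el, "label")
    vals <- list()
    for (av in xml2::xml_find_all(n_el, "./attvalues/attvalue")) {
      ti <- titles[[xml2::xml_attr(av, "for")]]
      if (!is.null(ti)) vals[[ti]] <- xml2::xml_attr(av, "value")
    }
    attrs <- list()
    if (!is.null(vals$category)) attrs$category <- vals$category
    if (!is.null(vals$common)) attrs$common <- identical(vals$common, "true")
    nodes[[id]] <- list(
      node_id = id, label = if (is.na(lab)) id else lab,
      entity_class = vals$entity_class %||% NA_character_,
      doc_count = as.integer(vals$doc_count %||% 0L),
      pmids = NULL, attrs = attrs)
  }

  edges <- list()
  for (e_el in xml2::xml_find_all(graph, "./edges/edge")) {
    u <- xml2::xml_attr(e_el, "source"); v <- xml2::xml_attr(e_el, "target")
    if (is.na(u) || is.na(v)) stop_format("GEXF edge without source/target")
    w <- xml2::xml_attr(e_el, "weight")
    ek <- edge_key(u, v)
    edges[[ek]] <- list(from = min(u, v), to = max(u, v), pmids = NULL,
                        weight = if (is.na(w)) 1L else as.integer(as.numeric(w)))
  }
  new_coocnet(nodes, edges, provenance = list(source = path))
}

#' Export a network as GraphML
#'
#' Write-only companion to [export_gexf()] with the same node attributes
#' and edge weights.
#'
#' @param net a `litnet_coocnet`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_graphml <- function(net, path) {
  stopifnot(inherits(net, "litnet_coocnet"))
  doc <- xml2::xml_new_root("graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydef <- function(id, dom, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom, attr.name = id, attr.type = type)
  }
  keydef("label", "node", "string")
  keydef("entity_class", "node", "string")
  keydef("category", "node", "string")
  keydef("doc_count", "node", "int")
  keydef("common", "node", "boolean")
  keydef("weight", "edge", "int")
  graph <- xml2::xml_add_child(doc, "graph", edgedefault = "undirected")
  for (nd in net$nodes) {
    n_el <- xml2::xml_add_child(graph, "node", id = nd$node_id)
    put <- function(key, value) {
      if (!is.null(value) && !is.na(value)) {
        d <- xml2::xml_add_child(n_el, "data", key = key)
        xml2::xml_text(d) <- as.character(value)
      }
    }
    put("label", nd$label %||% nd$node_id)
    put("entity_class", nd$entity_class)
    put("category", nd$attrs$category %||% NULL)
    put("doc_count", as.integer(nd$doc_count %||% 0L))
    put("common", if (is.null(nd$attrs$common)) NULL else tolower(as.character(nd$attrs$common)))
  }
  for (e in net$edges) {
    e_el <- xml2::xml_add_child(graph, "edge", source = e$from, target = e$to)
    d <- xml2::xml_add_child(e_el, "data", key = "weight")
    xml2::xml_text(d) <- as.character(e$weight)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
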