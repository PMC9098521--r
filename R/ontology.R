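# NCBI-taxonomy dump and MeSH tree-structure loaders, plus induced
# hierarchies over sets of hit identifiers.

#' Load an NCBI taxonomy dump
#'
#' Parses the classic dump dialect: fields separated by `\t|\t`, records
#' terminated by `\t|`. From `nodes.dmp` only taxid, parent and rank are
#' used; from `names.dmp` only rows with name class "scientific name"
#' define labels. Nodes lacking a scientific name are labelled
#' `taxid:<id>` and flagged; a name row whose taxid is absent from the
#' nodes file is flagged; a parent-pointer cycle is a structural error
#' naming the cycle.
#'
#' @param nodes path/connection/lines of the nodes dump.
#' @param names path/connection/lines of the names dump.
#' @return a `litnet_taxonomy`: named character vectors `parent`, `rank`,
#'   `name` (indexed by taxid), `root` taxid, and `warnings`.
#' @export
load_taxonomy_dump <- function(nodes, names) {
  parse_dump <- function(x) {
    txt <- read_text(x)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
  }

  warnings <- character()
  nrows <- parse_dump(nodes)
  taxid <- vapply(nrows, `[`, character(1), 1L)
  parent <- vapply(nrows, `[`, character(1), 2L)
  rank <- vapply(nrows, function(r) if (length(r) >= 3L) r[3L] else "no rank", character(1))
  names(parent) <- taxid
  names(rank) <- taxid

  # root: its own parent, or parent absent from the node set
  is_root <- parent == taxid | !(parent %in% taxid)
  if (sum(is_root) != 1L) {
    stop_structural(sprintf("expected exactly one root, found %d", sum(is_root)))
  }
  root <- taxid[is_root]
  parent[root] <- root

  # cycle check: walk parents from every node, short-circuiting on nodes
  # already proven to reach the root
  done <- stats::setNames(logical(length(taxid)), taxid)
  done[root] <- TRUE
  for (t in taxid) {
    if (done[[t]]) next
    path <- character()
    cur <- t
    while (!done[[cur]]) {
      if (cur %in% path) {
        cyc <- c(path[which(path == cur)[1]:length(path)], cur)
        stop_structural(paste0("cycle in parent pointers: ",
                               paste(cyc, collapse = " -> ")))
      }
      path <- c(path, cur)
      cur <- parent[[cur]]
    }
    done[path] <- TRUE
  }

  name <- stats::setNames(rep(NA_character_, length(taxid)), taxid)
  for (r in parse_dump(names)) {
    if (length(r) < 4L) next
    if (r[4L] != "scientific name") next
    tid <- r[1L]
    if (!(tid %in% taxid)) {
      warnings <- c(warnings, sprintf("name row for unknown taxid %s", tid))
      next
    }
    name[[tid]] <- r[2L]
  }
  unnamed <- names(name)[is.na(name)]
  if (length(unnamed)) {
    warnings <- c(warnings, sprintf("no scientific name for taxid %s", unnamed))
    name[unnamed] <- paste0("taxid:", unnamed)
  }

  structure(list(parent = parent, rank = rank, name = name,
                 root = unname(root), warnings = warnings),
            class = "litnet_taxonomy")
}

#' @export
print.litnet_taxonomy <- function(x, ...) {
  cat(sprintf("<litnet_taxonomy: %d nodes, root %s (%s)>\n",
              length(x$parent), x$root, x$name[[x$root]]))
  invisible(x)
}

#' Ancestors of a taxon, nearest first
#'
#' Follows parent pointers from (and excluding) `taxid` up to and including
#' the root.
#'
#' @param taxonomy a `litnet_taxonomy`.
#' @param taxid a taxid present in the taxonomy.
#' @return character vector of taxids; empty for the root itself.
#' @export
ancestors <- function(taxonomy, taxid) {
  taxid <- as.character(taxid)
  if (!(taxid %in% names(taxonomy$parent))) {
    stop_lookup(sprintf("unknown taxid '%s'", taxid))
  }
  out <- character()
  cur <- taxid
  while (cur != taxonomy$root) {
    cur <- taxonomy$parent[[cur]]
    out <- c(out, cur)
  }
  out
}

#' Load MeSH descriptor records
#'
#' Two dialects: `ascii` is the descriptor-record format (records start at
#' `*NEWRECORD`, with `MH = `, repeatable `MN = `, and `UI = ` lines);
#' `tsv` is a 3-column fallback (ui, heading, comma-joined tree numbers).
#' A duplicate UI or a tree number claimed by two UIs is a format error;
#' descriptors with zero tree numbers are retained but unplaceable
#' (flagged in `warnings`).
#'
#' @param x path/connection/lines.
#' @param dialect `"tsv"` or `"ascii"`.
#' @return a `litnet_meshtree`: `heading` (ui -> heading), `tree_numbers`
#'   (ui -> character vector), `positions` (tree number -> ui), `warnings`.
#' @export
load_mesh <- function(x, dialect = c("tsv", "ascii")) {
  dialect <- match.arg(dialect)
  txt <- read_text(x)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]

  recs <- list()  # each: list(ui, heading, tns)
  if (dialect == "tsv") {
    for (i in seq_along(lines)) {
      if (!nzchar(lines[[i]])) next
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 2L) stop_format(sprintf("line %d: expected >= 2 tab-separated fields", i))
      tns <- if (length(f) >= 3L && nzchar(f[3])) strsplit(f[3], ",", fixed = TRUE)[[1]] else character()
      recs[[length(recs) + 1L]] <- list(ui = f[1], heading = f[2], tns = trimws(tns))
    }
  } else {
    cur <- NULL
    flush <- function() if (!is.null(cur)) recs[[length(recs) + 1L]] <<- cur
    for (line in lines) {
      if (grepl("^\\*NEWRECORD", line)) {
        flush(); cur <- list(ui = NA_character_, heading = NA_character_, tns = character())
      } else if (grepl("^MH = ", line)) {
        cur$heading <- sub("^MH = ", "", line)
      } else if (grepl("^MN = ", line)) {
        cur$tns <- c(cur$tns, sub("^MN = ", "", line))
      } else if (grepl("^UI = ", line)) {
        cur$ui <- sub("^UI = ", "", line)
      }
    }
    flush()
    bad <- vapply(recs, function(r) is.na(r$ui) || is.na(r$heading), logical(1))
    if (any(bad)) stop_format("record missing UI or MH line")
  }

  warnings <- character()
  heading <- character(); tree_numbers <- list(); positions <- character()
  for (r in recs) {
    if (r$ui %in% names(heading)) stop_format(sprintf("duplicate ui '%s'", r$ui))
    heading[[r$ui]] <- r$heading
    tree_numbers[[r$ui]] <- r$tns
    if (!length(r$tns)) {
      warnings <- c(warnings, sprintf("descriptor %s has no tree number (unplaceable)", r$ui))
    }
    for (tn in r$tns) {
      if (tn %in% names(positions)) {
        stop_format(sprintf("tree number '%s' claimed by both %s and %s",
                            tn, positions[[tn]], r$ui))
      }
      positions[[tn]] <- r$ui
    }
  }
  structure(list(heading = heading, tree_numbers = tree_numbers,
                 positions = positions, warnings = warnings),
            class = "litnet_meshtree")
}

#' @export
print.litnet_meshtree <- function(x, ...) {
  cat(sprintf("<litnet_meshtree: %d descriptors, %d tree positions>\n",
              length(x$heading), length(x$positions)))
  invisible(x)
}

# -- HierTree -----------------------------------------------------------------

new_hiernode <- function(node_id, label, category, payload = list()) {
  list(node_id = node_id, label = label, category = category,
       payload = payload, children = list())
}

# Assemble a litnet_hiertree from flat node/parent tables; children are
# ordered lexicographically by node_id for deterministic serialization.
assemble_hiertree <- function(nodes, parent_of, root_id, reports = list()) {
  kids <- if (length(parent_of)) split(names(parent_of), unname(parent_of)) else list()
  build <- function(id) {
    nd <- nodes[[id]]
    ch <- sort(kids[[id]] %||% character())
    nd$children <- lapply(ch, build)
    nd
  }
  structure(list(root = build(root_id), reports = reports),
            class = "litnet_hiertree")
}

#' Flatten a hierarchy tree to a node table
#'
#' @param tree a `litnet_hiertree`.
#' @return data.frame(node_id, label, category, depth, doc_count) in
#'   depth-first (sorted-children) order.
#' @export
hiertree_nodes <- function(tree) {
  rows <- list()
  rec <- function(node, depth) {
    rows[[length(rows) + 1L]] <<- data.frame(
      node_id = node$node_id, label = node$label, category = node$category,
      depth = depth, doc_count = as.integer(node$payload$doc_count %||% 0L),
      stringsAsFactors = FALSE)
    for (ch in node$children) rec(ch, depth + 1L)
  }
  rec(tree$root, 0L)
  do.call(rbind, rows)
}

#' @export
print.litnet_hiertree <- function(x, ...) {
  nd <- hiertree_nodes(x)
  cat(sprintf("<litnet_hiertree: %d nodes (%d hits, %d recommended)>\n",
              nrow(nd), sum(nd$category == "hit"), sum(nd$category == "recommended")))
  invisible(x)
}

#' Induced subtree of a taxonomy over a hit set
#'
#' The minimal tree containing the hit taxa plus all their ancestors up to
#' the chosen root: node set = root, hits, and every ancestor of a hit that
#' lies below the root on a hit-to-root path. Hit nodes get category
#' `"hit"` (internal hits allowed), the rest `"ancestor"`. Labels are
#' `"<taxid>: <scientific name>"`. Hits absent from the taxonomy are
#' reported and skipped; hits whose ancestor path does not reach `root`
#' are reported as out-of-clade and excluded.
#'
#' @param taxonomy a `litnet_taxonomy`.
#' @param hits character vector of hit taxids.
#' @param root root taxid of the subtree (default: taxonomy root).
#' @param doc_counts optional named vector (taxid -> document count) carried
#'   into node payloads.
#' @return a `litnet_hiertree`; skipped/out-of-clade ids are in
#'   `$reports`.
#' @export
induced_subtree <- function(taxonomy, hits, root = taxonomy$root, doc_counts = NULL) {
  root <- as.character(root)
  if (!(root %in% names(taxonomy$parent))) stop_lookup(sprintf("unknown root taxid '%s'", root))
  hits <- unique(as.character(hits))

  unknown <- hits[!(hits %in% names(taxonomy$parent))]
  hits <- setdiff(hits, unknown)

  keep <- character()
  out_of_clade <- character()
  parent_of <- character()
  for (h in hits) {
    if (h == root) { keep <- c(keep, h); next }
    anc <- ancestors(taxonomy, h)
    pos <- match(root, anc)
    if (is.na(pos)) { out_of_clade <- c(out_of_clade, h); next }
    chain <- c(h, anc[seq_len(pos)])  # h .. root inclusive
    keep <- c(keep, chain)
    for (i in seq_len(length(chain) - 1L)) parent_of[[chain[i]]] <- chain[i + 1L]
  }
  hits <- setdiff(hits, out_of_clade)
  keep <- unique(c(root, keep))

  nodes <- lapply(keep, function(id) {
    payload <- list()
    if (!is.null(doc_counts) && id %in% names(doc_counts)) {
      payload$doc_count <- as.integer(doc_counts[[id]])
    }
    new_hiernode(id,
                 label = paste0(id, ": ", taxonomy$name[[id]]),
                 category = if (id %in% hits) "hit" else "ancestor",
                 payload = payload)
  })
  names(nodes) <- keep
  assemble_hiertree(nodes, parent_of, root,
                    reports = list(skipped = unknown, out_of_clade = out_of_clade))
}

#' MeSH tree-number forest over a hit set
#'
#' Every hit descriptor contributes one node per owned tree number whose
#' top-level letter is in `categories` (a descriptor with positions in both
#' the C and D branches appears once per branch). Ancestor positions are
#' materialized by truncating dotted codes; node identity is the tree
#' number, labels are `"<tree number>: <heading>"` with the heading of the
#' UI owning that position (falling back to the tree number itself for
#' unowned ancestor positions). The branches are united under per-letter
#' category roots (`Diseases [C]`, `Chemicals and Drugs [D]`) and one
#' synthetic root node `MeSH`.
#'
#' @param mesh a `litnet_meshtree`.
#' @param hits character vector of MeSH UIs.
#' @param categories top-level letters to keep (default C and D).
#' @param doc_counts optional named vector (ui -> document count).
#' @return a `litnet_hiertree`; UIs absent from `mesh` are in
#'   `$reports$skipped`.
#' @export
mesh_forest <- function(mesh, hits, categories = c("C", "D"), doc_counts = NULL) {
  hits <- unique(as.character(hits))
  unknown <- hits[!(hits %in% names(mesh$heading))]
  hits <- setdiff(hits, unknown)

  category_label <- function(L) {
    switch(L, C = "Diseases [C]", D = "Chemicals and Drugs [D]",
           paste0("Category [", L, "]"))
  }

  hit_tns <- character()
  for (ui in hits) {
    tns <- mesh$tree_numbers[[ui]]
    tns <- tns[substr(tns, 1, 1) %in% categories]
    hit_tns <- c(hit_tns, tns)
  }
  hit_tns <- unique(hit_tns)

  # prefix closure of hit tree numbers, plus single-letter category roots
  closure <- character()
  letters_used <- character()
  parent_of <- character()
  for (tn in hit_tns) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
    chain <- vapply(seq_along(parts), function(k) paste(parts[1:k], collapse = "."),
                    character(1))
    letter <- substr(chain[1], 1, 1)
    letters_used <- unique(c(letters_used, letter))
    closure <- unique(c(closure, chain))
    parent_of[[chain[1]]] <- letter
    if (length(chain) > 1L) {
      for (i in 2:length(chain)) parent_of[[chain[i]]] <- chain[i - 1L]
    }
    parent_of[[letter]] <- "MeSH"
  }

  nodes <- list(MeSH = new_hiernode("MeSH", "MeSH", "ancestor"))
  for (L in letters_used) nodes[[L]] <- new_hiernode(L, category_label(L), "ancestor")
  for (id in closure) {
    owner <- if (id %in% names(mesh$positions)) mesh$positions[[id]] else NA_character_
    head_lab <- if (!is.na(owner)) mesh$heading[[owner]] else id
    payload <- list()
    if (!is.na(owner) && !is.null(doc_counts) && owner %in% names(doc_counts)) {
      payload$doc_count <- as.integer(doc_counts[[owner]])
    }
    nodes[[id]] <- new_hiernode(
      id, label = paste0(id, ": ", head_lab),
      category = if (id %in% hit_tns) "hit" else "ancestor",
      payload = payload)
  }
  assemble_hiertree(nodes, parent_of, "MeSH", reports = list(skipped = unknown))
}

#' Restrict hit taxa to a clade
#'
#' Keeps the hits whose ancestor path contains `clade` (or that equal
#' `clade`). Hits absent from the taxonomy are dropped.
#'
#' @param taxonomy a `litnet_taxonomy`.
#' @param hits character vector of taxids.
#' @param clade taxid of the clade to filter by.
#' @return character vector, subset of `hits`.
#' @export
filter_clade <- function(taxonomy, hits, clade) {
  clade <- as.character(clade)
  if (!(clade %in% names(taxonomy$parent))) stop_lookup(sprintf("unknown clade '%s'", clade))
  hits <- as.character(hits)
  hits <- hits[hits %in% names(taxonomy$parent)]
  keep <- vapply(hits, function(h) h == clade || clade %in% ancestors(taxonomy, h),
                 logical(1))
  unname(hits[keep])
}

#' Serialize a hierarchy tree as nested text
#'
#' `indented` writes one `label [category] (doc_count)` line per node, two
#' spaces per depth level; `json` writes a nested structure with node_id,
#' label, category, doc_count and children. Children are in sorted order,
#' so output is deterministic.
#'
#' @param tree a `litnet_hiertree`.
#' @param format `"indented"` or `"json"`.
#' @return character scalar.
#' @export
tree_to_nested <- function(tree, format = c("indented", "json")) {
  format <- match.arg(format)
  if (format == "indented") {
    lines <- character()
    rec <- function(node, depth) {
      lines[[length(lines) + 1L]] <<- sprintf(
        "%s%s [%s] (%d)", strrep("  ", depth), node$label, node$category,
        as.integer(node$payload$doc_count %||% 0L))
      for (ch in node$children) rec(ch, depth + 1L)
    }
    rec(tree$root, 0L)
    paste0(paste(lines, collapse = "\n"), "\n")
  } else {
    rec <- function(node) {
      list(node_id = node$node_id, label = node$label, category = node$category,
           doc_count = as.integer(node$payload$doc_count %||% 0L),
           children = lapply(node$children, rec))
    }
    as.character(jsonlite::toJSON(rec(tree$root), auto_unbox = TRUE, pretty = TRUE))
  }
}
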