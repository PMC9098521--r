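# Allied-species recommendation: species from a curated reference list
# (e.g. a national plant-extract-bank catalogue) that share a taxonomic
# rank node -- genus by default -- with literature-hit species are
# candidates for similar bioactivity.

#' Resolve raw species names against a taxonomy
#'
#' Exact, case-insensitive match on scientific names. Unmatched names are
#' retained without a taxid; a name shared by two or more taxids is
#' ambiguous and left unresolved. Both cases appear in the `status`
#' column; fuzzy matching and synonyms are out of scope.
#'
#' @param names character vector of raw scientific names, or a path to a
#'   UTF-8 text file with one name per line (`#` comments allowed).
#' @param taxonomy a `litnet_taxonomy`.
#' @param source_name provenance label for the list.
#' @return a `litnet_reference_list`: data.frame(raw_name, taxid, status)
#'   with status in resolved/unmatched/ambiguous, plus attribute
#'   `source_name`.
#' @export
match_names <- function(names, taxonomy, source_name = "reference") {
  if (length(names) == 1L && !grepl("\n", names) && file.exists(names)) {
    source_name <- names
    names <- readLines(names, warn = FALSE, encoding = "UTF-8")
  }
  names <- trimws(names)
  names <- names[nzchar(names) & !startsWith(names, "#")]

  folded <- tolower(taxonomy$name)
  counts <- table(folded)
  rows <- lapply(names, function(nm) {
    key <- tolower(nm)
    n_match <- if (key %in% names(counts)) counts[[key]] else 0L
    if (n_match == 0L) {
      data.frame(raw_name = nm, taxid = NA_character_, status = "unmatched",
                 stringsAsFactors = FALSE)
    } else if (n_match > 1L) {
      data.frame(raw_name = nm, taxid = NA_character_, status = "ambiguous",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(raw_name = nm, taxid = names(taxonomy$name)[match(key, folded)],
                 status = "resolved", stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(raw_name = character(), taxid = character(), status = character(),
               stringsAsFactors = FALSE)
  structure(out, source_name = source_name,
            class = c("litnet_reference_list", "data.frame"))
}

# Nearest strict ancestor of `taxid` whose rank equals `rank`; NA if none.
anchor_at_rank <- function(taxonomy, taxid, rank) {
  for (t in ancestors(taxonomy, taxid)) {
    if (identical(unname(taxonomy$rank[[t]]), rank)) return(t)
  }
  NA_character_
}

#' Recommend allied species from a reference list
#'
#' For each distinct anchor node of the requested rank found above the hit
#' species, the recommendation is the set of resolved reference species
#' below that anchor that are not themselves hits. Anchors with nothing to
#' recommend are omitted; output is sorted by anchor taxid and invariant to
#' input ordering. Hits with no ancestor of the requested rank are skipped
#' (NCBI ranks are irregular) and listed in the `skipped` attribute.
#'
#' @param hits character vector of hit species taxids.
#' @param ref a `litnet_reference_list` from [match_names()].
#' @param taxonomy a `litnet_taxonomy`.
#' @param rank anchor rank (default `"genus"`; `"family"` also meaningful).
#' @return list of `litnet_recommendation` objects, each with `anchor`,
#'   `anchor_name`, `hit_species`, `recommended_species`.
#' @export
recommend_allied <- function(hits, ref, taxonomy, rank = "genus") {
  hits <- unique(as.character(hits))
  known <- hits[hits %in% names(taxonomy$parent)]
  skipped <- setdiff(hits, known)

  anchors <- list()
  no_anchor <- character()
  for (h in sort(known)) {
    a <- anchor_at_rank(taxonomy, h, rank)
    if (is.na(a)) { no_anchor <- c(no_anchor, h); next }
    anchors[[a]] <- c(anchors[[a]], h)
  }
  if (!length(anchors) && length(known)) {
    warning(sprintf("no hit has an ancestor of rank '%s'", rank))
  }

  ref_taxids <- unique(ref$taxid[ref$status == "resolved"])
  ref_taxids <- ref_taxids[ref_taxids %in% names(taxonomy$parent)]

  recs <- list()
  for (a in sort(names(anchors))) {
    under <- ref_taxids[vapply(ref_taxids, function(t) {
      t != a && a %in% ancestors(taxonomy, t)
    }, logical(1))]
    recommended <- sort(setdiff(under, hits))
    if (!length(recommended)) next
    recs[[length(recs) + 1L]] <- structure(
      list(anchor = a, anchor_name = unname(taxonomy$name[[a]]),
           hit_species = sort(anchors[[a]]), recommended_species = recommended),
      class = "litnet_recommendation")
  }
  attr(recs, "skipped") <- sort(c(skipped, no_anchor))
  recs
}

#' @export
print.litnet_recommendation <- function(x, ...) {
  cat(sprintf("<%s (%s): %d hit species, %d recommended>\n",
              x$anchor_name, x$anchor, length(x$hit_species),
              length(x$recommended_species)))
  invisible(x)
}

#' Add recommended species to a hierarchy network
#'
#' Each recommended species becomes a node (category `"recommended"`,
#' doc_count 0) linked to its anchor rank node, mirroring the display of
#' reference-list-only species attached to their genus. The anchor must
#' already be a node of the network.
#'
#' @param tree_net a hierarchy `litnet_coocnet` containing the anchors.
#' @param recs recommendations from [recommend_allied()].
#' @param taxonomy a `litnet_taxonomy` (for labels).
#' @return the augmented `litnet_coocnet`.
#' @export
annotate_recommendations <- function(tree_net, recs, taxonomy) {
  nodes <- tree_net$nodes
  edges <- tree_net$edges
  for (rec in recs) {
    if (!(rec$anchor %in% names(nodes))) {
      stop_lookup(sprintf("anchor node '%s' (%s) is not in the network",
                          rec$anchor, rec$anchor_name))
    }
    for (sp in rec$recommended_species) {
      if (!(sp %in% names(nodes))) {
        nodes[[sp]] <- list(
          node_id = sp, label = paste0(sp, ": ", taxonomy$name[[sp]]),
          entity_class = NA_character_, doc_count = 0L, pmids = NULL,
          attrs = list(category = "recommended"))
      }
      ek <- edge_key(rec$anchor, sp)
      if (is.null(edges[[ek]])) {
        edges[[ek]] <- list(from = min(rec$anchor, sp), to = max(rec$anchor, sp),
                            pmids = character(), weight = 0L)
      }
    }
  }
  new_coocnet(nodes, edges, provenance = tree_net$provenance)
}

#' Write a recommendation report
#'
#' Tab-separated text: anchor taxid, anchor name, hit count, recommended
#' taxid, recommended name; one row per recommended species.
#'
#' @param recs recommendations from [recommend_allied()].
#' @param taxonomy a `litnet_taxonomy`.
#' @param path output file path.
#' @return the report data.frame, invisibly.
#' @export
write_recommendation_report <- function(recs, taxonomy, path) {
  rows <- list()
  for (rec in recs) {
    for (sp in rec$recommended_species) {
      rows[[length(rows) + 1L]] <- data.frame(
        anchor_taxid = rec$anchor, anchor_name = rec$anchor_name,
        hit_count = length(rec$hit_species), recommended_taxid = sp,
        recommended_name = unname(taxonomy$name[[sp]]), stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(anchor_taxid = character(), anchor_name = character(),
               hit_count = integer(), recommended_taxid = character(),
               recommended_name = character(), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
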