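# Seeded fixture generators: synthetic taxonomy dumps, MeSH tables,
# annotated corpora and reference species lists, each with recorded ground
# truth, so the whole pipeline is testable offline. Identifiers are drawn
# from a reserved synthetic range (taxids 9,000,000+, UIs D9xxxxxx) to
# avoid collision with real NCBI/MeSH identifiers in examples.

#' Describe a synthetic fixture world
#'
#' Defaults emulate a small abstract-level literature slice: 200 annotated
#' abstracts over 50 bioentities (6 genera x 5 species plus 20 MeSH
#' descriptors), 2-6 entity mentions per document, with query keywords
#' planted into titles/abstracts so Boolean queries have known answers.
#' Identical specs produce byte-identical artifacts.
#'
#' @param seed integer seed; the only source of randomness.
#' @param n_genera,species_per_genus taxonomy shape.
#' @param n_mesh_descriptors MeSH descriptors over the C and D branches.
#' @param n_docs corpus size.
#' @param entities_per_doc inclusive range of entity mentions per document.
#' @param keyword_terms terms planted into document text; the last two also
#'   form the planted contiguous phrase.
#' @param n_misspelled misspelled names in the reference list.
#' @return a `litnet_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 7L, n_genera = 6L, species_per_genus = 5L,
                         n_mesh_descriptors = 20L, n_docs = 200L,
                         entities_per_doc = c(2L, 6L),
                         keyword_terms = c("amentoflavone", "flavonoid",
                                           "antioxidant", "skin", "aging"),
                         n_misspelled = 3L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L, n_mesh_descriptors >= 1L,
            n_docs >= 1L, length(entities_per_doc) == 2L,
            entities_per_doc[1] >= 1L, entities_per_doc[2] >= entities_per_doc[1])
  structure(list(seed = as.integer(seed), n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 n_mesh_descriptors = as.integer(n_mesh_descriptors),
                 n_docs = as.integer(n_docs),
                 entities_per_doc = as.integer(entities_per_doc),
                 keyword_terms = keyword_terms,
                 n_misspelled = as.integer(n_misspelled)),
            class = "litnet_fixture_spec")
}

#' Generate a synthetic taxonomy dump
#'
#' Linear spine root -> kingdom -> family, then `n_genera` genera each with
#' `species_per_genus` species; deterministic names (`"Genus3 species2"`).
#'
#' @param spec a `litnet_fixture_spec`.
#' @return list with `nodes_dmp` and `names_dmp` text and `gt` (depths,
#'   genus -> species map, spine ids, name table).
#' @export
make_taxonomy <- function(spec) {
  root <- "9000001"; kingdom <- "9000002"; family <- "9000003"
  rows <- list(
    list(root, root, "no rank", "Synthetica biota", 0L),
    list(kingdom, root, "kingdom", "Plantae synthetica", 1L),
    list(family, kingdom, "family", "Syntheticaceae", 2L))
  genus_species <- list()
  for (i in seq_len(spec$n_genera)) {
    g <- as.character(9001000L + i)
    rows[[length(rows) + 1L]] <- list(g, family, "genus", paste0("Genus", i), 3L)
    sp <- character()
    for (j in seq_len(spec$species_per_genus)) {
      s <- as.character(9010000L + i * 100L + j)
      rows[[length(rows) + 1L]] <- list(s, g, "species",
                                        paste0("Genus", i, " species", j), 4L)
      sp <- c(sp, s)
    }
    genus_species[[g]] <- sp
  }
  ids <- vapply(rows, function(r) r[[1]], character(1))
  nodes_dmp <- paste0(vapply(rows, function(r)
    paste(r[[1]], r[[2]], r[[3]], sep = "\t|\t"), character(1)), "\t|", collapse = "\n")
  names_dmp <- paste0(vapply(rows, function(r)
    paste(r[[1]], r[[4]], "", "scientific name", sep = "\t|\t"), character(1)),
    "\t|", collapse = "\n")
  gt <- list(
    root = root, kingdom = kingdom, family = family,
    depths = stats::setNames(vapply(rows, function(r) r[[5]], integer(1)), ids),
    names = stats::setNames(vapply(rows, function(r) r[[4]], character(1)), ids),
    ranks = stats::setNames(vapply(rows, function(r) r[[3]], character(1)), ids),
    genus_species = genus_species,
    species = unlist(genus_species, use.names = FALSE))
  list(nodes_dmp = paste0(nodes_dmp, "\n"), names_dmp = paste0(names_dmp, "\n"), gt = gt)
}

#' Generate a synthetic MeSH descriptor table
#'
#' Descriptors alternate between the D (chemicals) and C (diseases)
#' branches; every fifth descriptor owns a second tree number in the other
#' branch, exercising multi-position hits.
#'
#' @param spec a `litnet_fixture_spec`.
#' @return list with `mesh_tsv` text and `gt` (per-ui tree numbers,
#'   headings, entity classes, total position count).
#' @export
make_mesh <- function(spec) {
  uis <- sprintf("D9%06d", seq_len(spec$n_mesh_descriptors))
  tns <- list(); heading <- character(); class <- character()
  for (k in seq_len(spec$n_mesh_descriptors)) {
    b <- if (k %% 2L == 1L) "D" else "C"
    g <- (k - 1L) %/% 4L + 1L
    pos <- (k - 1L) %% 4L
    tn <- sprintf("%s%02d.%03d", b, g, 100L + pos)
    own <- tn
    if (k %% 5L == 0L) {
      other <- if (b == "D") "C" else "D"
      own <- c(own, sprintf("%s%02d.%03d", other, 50L + g, 100L + pos))
    }
    tns[[uis[k]]] <- own
    heading[[uis[k]]] <- paste0("Descriptor", k)
    class[[uis[k]]] <- if (b == "D") "Chemical" else "Disease"
  }
  mesh_tsv <- paste0(paste(uis, heading[uis],
                           vapply(tns[uis], paste, character(1), collapse = ","),
                           sep = "\t", collapse = "\n"), "\n")
  list(mesh_tsv = mesh_tsv,
       gt = list(tree_numbers = tns, headings = heading, classes = class,
                 n_positions = length(unlist(tns))))
}

FILLER_WORDS <- c(
  "study", "sample", "analysis", "method", "cells", "extract", "assay",
  "activity", "result", "compound", "effect", "protein", "pathway", "tissue",
  "model", "control", "growth", "response", "dose", "treatment")

#' Generate a synthetic annotated corpus
#'
#' Documents carry planted keyword terms (each always followed by a filler
#' word, so the only contiguous keyword pair is the deliberately planted
#' phrase), plus entity mentions sampled with replacement (duplicates
#' exercise per-document deduplication) whose offsets are exact. Ground
#' truth records the entity -> pmid and unordered-pair -> pmid sets and the
#' planted-term pmid sets.
#'
#' @param spec a `litnet_fixture_spec`.
#' @param tax result of [make_taxonomy()].
#' @param mesh result of [make_mesh()].
#' @return list with `pubtator` text and `gt`.
#' @export
make_corpus <- function(spec, tax = make_taxonomy(spec), mesh = make_mesh(spec)) {
  species <- tax$gt$species
  pool <- rbind(
    data.frame(key = paste0("taxid:", species), accession = species,
               mention = unname(tax$gt$names[species]), entity_class = "Species",
               raw_id = species, stringsAsFactors = FALSE),
    data.frame(key = paste0("mesh:", names(mesh$gt$headings)),
               accession = names(mesh$gt$headings),
               mention = unname(mesh$gt$headings),
               entity_class = unname(mesh$gt$classes[names(mesh$gt$headings)]),
               raw_id = paste0("MESH:", names(mesh$gt$headings)),
               stringsAsFactors = FALSE))

  terms <- spec$keyword_terms
  phrase <- utils::tail(terms, 2L)

  with_local_seed(spec$seed, {
    entity_pmids <- list(); pair_pmids <- list()
    term_pmids <- stats::setNames(vector("list", length(terms)), terms)
    phrase_pmids <- character()
    docs <- list()

    for (d in seq_len(spec$n_docs)) {
      pmid <- as.character(33000000L + d)
      fill <- function(n) sample(FILLER_WORDS, n, replace = TRUE)

      title_toks <- fill(sample(3:5, 1))
      planted <- terms[stats::runif(length(terms)) < 0.25]
      for (t in planted) {
        title_toks <- c(title_toks, t, fill(1))
        term_pmids[[t]] <- c(term_pmids[[t]], pmid)
      }
      title <- paste(title_toks, collapse = " ")

      # abstract: entity-mention blocks + optional planted phrase
      k <- sample(seq.int(spec$entities_per_doc[1], spec$entities_per_doc[2]), 1)
      picks <- sample(nrow(pool), k, replace = TRUE)
      pieces <- fill(2)
      ann_piece <- integer()  # piece index of each sampled mention
      for (p in picks) {
        pieces <- c(pieces, pool$mention[p], fill(1))
        ann_piece <- c(ann_piece, length(pieces) - 1L)
      }
      if (stats::runif(1) < 0.15) {
        pieces <- c(pieces, phrase, fill(1))
        phrase_pmids <- c(phrase_pmids, pmid)
        for (t in phrase) term_pmids[[t]] <- c(term_pmids[[t]], pmid)
      }
      abstract <- paste(pieces, collapse = " ")
      piece_start <- cumsum(c(0L, utils::head(nchar(pieces) + 1L, -1L)))
      base <- nchar(title) + 1L

      ann <- do.call(rbind, lapply(seq_along(picks), function(i) {
        p <- picks[i]
        s <- base + piece_start[ann_piece[i]]
        data.frame(pmid = pmid, start = s, end = s + nchar(pool$mention[p]),
                   mention = pool$mention[p], entity_class = pool$entity_class[p],
                   raw_id = pool$raw_id[p], stringsAsFactors = FALSE)
      }))
      if (stats::runif(1) < 0.1) ann <- rbind(ann, ann[sample(nrow(ann), 1), ])

      docs[[pmid]] <- new_document(pmid, title, abstract, ann)

      keys <- sort(unique(pool$key[picks]))
      for (kk in keys) entity_pmids[[kk]] <- c(entity_pmids[[kk]], pmid)
      if (length(keys) >= 2L) {
        for (i in seq_len(length(keys) - 1L)) {
          for (j in seq.int(i + 1L, length(keys))) {
            ek <- edge_key(keys[i], keys[j])
            pair_pmids[[ek]] <- c(pair_pmids[[ek]], pmid)
          }
        }
      }
    }

    corpus <- new_corpus(docs)
    gt <- list(entity_pmids = entity_pmids[order(names(entity_pmids))],
               pair_pmids = pair_pmids[order(names(pair_pmids))],
               term_pmids = lapply(term_pmids, function(p) sort(unique(p))),
               phrase = phrase, phrase_pmids = sort(unique(phrase_pmids)),
               pool = pool)
    list(pubtator = write_pubtator(corpus), corpus = corpus, gt = gt)
  })
}

#' Generate a synthetic reference species list
#'
#' Draws roughly 60% of each genus's species into the list and appends
#' `n_misspelled` names that resolve to nothing.
#'
#' @param spec a `litnet_fixture_spec`.
#' @param tax result of [make_taxonomy()].
#' @return list with `reference_txt` text and `gt` (resolved name -> taxid,
#'   misspelled names).
#' @export
make_reference_list <- function(spec, tax = make_taxonomy(spec)) {
  with_local_seed(spec$seed + 1000L, {
    names_out <- character(); resolved <- character()
    for (g in names(tax$gt$genus_species)) {
      sp <- tax$gt$genus_species[[g]]
      n_take <- max(1L, round(0.6 * length(sp)))
      take <- sort(sample(sp, n_take))
      for (s in take) {
        nm <- unname(tax$gt$names[[s]])
        names_out <- c(names_out, nm)
        resolved[[nm]] <- s
      }
    }
    misspelled <- sprintf("Genus%d speciex%d", seq_len(spec$n_misspelled) + 90L,
                          seq_len(spec$n_misspelled))
    names_out <- c(names_out, misspelled)
    txt <- paste0("# synthetic reference species list\n",
                  paste(names_out, collapse = "\n"), "\n")
    list(reference_txt = txt,
         gt = list(resolved = resolved, misspelled = misspelled))
  })
}

#' Write a complete fixture set to a directory
#'
#' Emits corpus.pubtator, nodes.dmp, names.dmp, mesh.tsv, reference.txt and
#' groundtruth.json. Re-running with the same spec reproduces every file
#' byte for byte.
#'
#' @param spec a `litnet_fixture_spec`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_fixture_set <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tax <- make_taxonomy(spec)
  mesh <- make_mesh(spec)
  corp <- make_corpus(spec, tax, mesh)
  ref <- make_reference_list(spec, tax)

  put <- function(name, text) {
    path <- file.path(dir, name)
    con <- file(path, open = "wb"); on.exit(close(con))
    writeChar(text, con, eos = NULL)
    path
  }
  paths <- c(
    corpus = put("corpus.pubtator", corp$pubtator),
    nodes = put("nodes.dmp", tax$nodes_dmp),
    names = put("names.dmp", tax$names_dmp),
    mesh = put("mesh.tsv", mesh$mesh_tsv),
    reference = put("reference.txt", ref$reference_txt))
  gt <- list(taxonomy = list(root = tax$gt$root, depths = as.list(tax$gt$depths),
                             genus_species = tax$gt$genus_species),
             mesh = list(n_positions = mesh$gt$n_positions),
             corpus = list(entity_pmids = corp$gt$entity_pmids,
                           pair_pmids = corp$gt$pair_pmids,
                           term_pmids = corp$gt$term_pmids,
                           phrase = corp$gt$phrase,
                           phrase_pmids = corp$gt$phrase_pmids),
             reference = ref$gt)
  gt_path <- file.path(dir, "groundtruth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, groundtruth = gt_path))
}
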