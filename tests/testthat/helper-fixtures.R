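# Shared fixture world, built once per test run (seed 7 throughout, as the
# generator default).

FIX <- local({
  spec <- fixture_spec(seed = 7)
  tax <- make_taxonomy(spec)
  mesh <- make_mesh(spec)
  corp <- make_corpus(spec, tax, mesh)
  ref <- make_reference_list(spec, tax)
  list(
    spec = spec, tax = tax, mesh = mesh, corp = corp, ref = ref,
    corpus = parse_pubtator(corp$pubtator),
    taxonomy = load_taxonomy_dump(tax$nodes_dmp, tax$names_dmp),
    meshtree = load_mesh(mesh$mesh_tsv, "tsv")
  )
})

# tiny 3-document hand-built corpus used across files
tiny_pubtator <- function() {
  paste(
    "101|t|Amentoflavone in Genus1 species1",
    "101|a|The extract showed strong activity in cells.",
    "101\t0\t13\tAmentoflavone\tChemical\tMESH:D9000001",
    "101\t17\t32\tGenus1 species1\tSpecies\t9010101",
    "",
    "102|t|A second study",
    "102|a|No annotated species here.",
    "",
    "103|t|Skin aging review",
    "103|a|Discussion of Genus2 species1 and a disease.",
    "103\t32\t47\tGenus2 species1\tSpecies\t9010201",
    "103\t54\t61\tdisease\tDisease\tMESH:D9000002",
    "",
    sep = "\n")
}

# small network built directly from explicit node/edge sets, for set-op and
# similarity fixtures
make_net <- function(ids, edges = list()) {
  corpus_docs <- list()
  # realize as a synthetic corpus: one doc per edge (both entities), one doc
  # per isolated node
  pm <- 0L
  lines <- character()
  covered <- character()
  for (e in edges) {
    pm <- pm + 1L
    pmid <- sprintf("%d", 500 + pm)
    title <- "t"
    ments <- paste0("M", gsub("[^A-Za-z0-9]", "", e))
    abstract <- paste(ments, collapse = " ")
    starts <- cumsum(c(0L, utils::head(nchar(ments) + 1L, -1L))) + nchar(title) + 1L
    lines <- c(lines, paste0(pmid, "|t|", title), paste0(pmid, "|a|", abstract),
               vapply(1:2, function(i) paste(pmid, starts[i], starts[i] + nchar(ments[i]),
                                             ments[i], "Species",
                                             sub("^taxid:", "", e[i]), sep = "\t"),
                      character(1)),
               "")
    covered <- union(covered, e)
  }
  for (id in setdiff(ids, covered)) {
    pm <- pm + 1L
    pmid <- sprintf("%d", 500 + pm)
    ment <- paste0("M", gsub("[^A-Za-z0-9]", "", id))
    lines <- c(lines, paste0(pmid, "|t|t"), paste0(pmid, "|a|", ment),
               paste(pmid, 2L, 2L + nchar(ment), ment, "Species",
                     sub("^taxid:", "", id), sep = "\t"),
               "")
  }
  build_cooc_network(parse_pubtator(lines))
}

# random co-occurrence network from a random pmid subset of the fixture corpus
random_subnet <- function(corpus, frac = 0.3) {
  pm <- names(corpus$documents)
  build_cooc_network(corpus, sample(pm, ceiling(frac * length(pm))))
}
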