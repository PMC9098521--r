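toy_nodes <- c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tgenus\t|", "3\t|\t2\t|\tspecies\t|")
toy_names <- c("1\t|\tRootia\t|\t\t|\tscientific name\t|",
               "2\t|\tGen\t|\t\t|\tscientific name\t|",
               "3\t|\tGen sp\t|\t\t|\tscientific name\t|")

test_that("load_taxonomy_dump parses the dump dialect", {
  tx <- load_taxonomy_dump(toy_nodes, toy_names)
  expect_equal(length(tx$parent), 3L)
  expect_equal(tx$root, "1")
  expect_equal(ancestors(tx, "3"), c("2", "1"))
  expect_equal(unname(tx$name[["3"]]), "Gen sp")

  # missing scientific name -> placeholder label + warning entry
  tx2 <- load_taxonomy_dump(toy_nodes, toy_names[-2])
  expect_equal(unname(tx2$name[["2"]]), "taxid:2")
  expect_true(any(grepl("no scientific name", tx2$warnings)))

  # name row for an unknown taxid -> warning, not error
  tx3 <- load_taxonomy_dump(toy_nodes, c(toy_names, "9\t|\tGhost\t|\t\t|\tscientific name\t|"))
  expect_true(any(grepl("unknown taxid 9", tx3$warnings)))
})

test_that("parent-pointer cycles are a structural error", {
  cyc_nodes <- c("1\t|\t1\t|\tno rank\t|", "2\t|\t3\t|\tgenus\t|", "3\t|\t2\t|\tgenus\t|")
  expect_error(load_taxonomy_dump(cyc_nodes, toy_names), class = "litnet_structural_error")
})

test_that("ancestors walks to the root and rejects unknown ids", {
  tx <- FIX$taxonomy
  expect_equal(ancestors(tx, tx$root), character())
  for (s in FIX$tax$gt$species[c(1, 10, 25)]) {
    expect_length(ancestors(tx, s), FIX$tax$gt$depths[[s]])
  }
  expect_error(ancestors(tx, "424242"), class = "litnet_lookup_error")
})

test_that("load_mesh handles both dialects and rejects conflicts", {
  mt <- load_mesh("D000001\tX\tD02.092", "tsv")
  expect_equal(unname(mt$positions[["D02.092"]]), "D000001")

  ascii <- c("*NEWRECORD", "MH = X", "MN = D02.092", "MN = C04.557", "UI = D000001", "")
  ma <- load_mesh(ascii, "ascii")
  expect_equal(sort(ma$tree_numbers[["D000001"]]), c("C04.557", "D02.092"))

  expect_error(load_mesh(c("D1\tX\tC01", "D2\tY\tC01"), "tsv"), class = "litnet_format_error")
  expect_error(load_mesh(c("D1\tX\tC01", "D1\tY\tC02"), "tsv"), class = "litnet_format_error")

  noplace <- load_mesh(c("D1\tX\tC01", "D2\tY\t"), "tsv")
  expect_true(any(grepl("unplaceable", noplace$warnings)))

  # fixture: positions count equals the generator's emitted tree numbers
  expect_equal(length(FIX$meshtree$positions), FIX$mesh$gt$n_positions)
})

test_that("induced_subtree builds minimal ancestor-closed trees", {
  tx <- FIX$taxonomy
  t1 <- induced_subtree(tx, hits = tx$root)
  expect_equal(nrow(hiertree_nodes(t1)), 1L)

  toy <- load_taxonomy_dump(toy_nodes, toy_names)
  t2 <- induced_subtree(toy, "3")
  nd <- hiertree_nodes(t2)
  expect_equal(nd$node_id, c("1", "2", "3"))
  expect_equal(nd$category, c("ancestor", "ancestor", "hit"))
  expect_equal(nd$label[3], "3: Gen sp")

  # hits absent from taxonomy are skipped with a report
  t3 <- induced_subtree(tx, c("424242", FIX$tax$gt$species[1]))
  expect_equal(t3$reports$skipped, "424242")

  # hits outside the chosen clade are reported out-of-clade
  g1 <- names(FIX$tax$gt$genus_species)[1]
  other_sp <- FIX$tax$gt$genus_species[[2]][1]
  t4 <- induced_subtree(tx, c(FIX$tax$gt$genus_species[[g1]][1], other_sp), root = g1)
  expect_equal(t4$reports$out_of_clade, other_sp)

  expect_error(induced_subtree(tx, "9010101", root = "424242"),
               class = "litnet_lookup_error")
})

test_that("induced_subtree equals the brute-force closure and is monotone", {
  tx <- FIX$taxonomy
  withr::with_seed(11, {
    hits <- sample(FIX$tax$gt$species, 12)
    tr <- induced_subtree(tx, hits)
    nd <- hiertree_nodes(tr)
    expect_equal(sort(nd$node_id), oracle_subtree_nodes(tx, hits, tx$root))
    net <- tree_as_network(tr)
    expect_equal(length(net$edges), nrow(nd) - 1L)

    sub_hits <- hits[1:5]
    nd_sub <- hiertree_nodes(induced_subtree(tx, sub_hits))
    expect_true(all(nd_sub$node_id %in% nd$node_id))
  })
})

test_that("mesh_forest materializes truncation chains per eligible tree number", {
  mt <- load_mesh(c("D000001\tNeoplasm\tC04.557", "D000002\tBoth\tC01.100,D02.200"), "tsv")
  f1 <- mesh_forest(mt, "D000001")
  nd <- hiertree_nodes(f1)
  expect_equal(sort(nd$node_id), c("C", "C04", "C04.557", "MeSH"))
  expect_equal(nd$category[nd$node_id == "C04.557"], "hit")
  expect_equal(nd$label[nd$node_id == "C"], "Diseases [C]")
  expect_equal(nd$label[nd$node_id == "C04.557"], "C04.557: Neoplasm")

  # a descriptor with positions in both branches appears as two hit nodes
  f2 <- mesh_forest(mt, "D000002")
  nd2 <- hiertree_nodes(f2)
  expect_equal(sum(nd2$category == "hit"), 2L)
  expect_setequal(nd2$node_id[nd2$category == "hit"], c("C01.100", "D02.200"))

  # category restriction drops the other branch
  f3 <- mesh_forest(mt, "D000002", categories = "C")
  expect_equal(sum(hiertree_nodes(f3)$category == "hit"), 1L)

  f4 <- mesh_forest(mt, c("D000001", "D999999"))
  expect_equal(f4$reports$skipped, "D999999")
})

test_that("mesh_forest node set equals the brute-force prefix closure", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      hits <- sample(names(FIX$meshtree$heading), 8)
      nd <- hiertree_nodes(mesh_forest(FIX$meshtree, hits))
      expect_equal(sort(nd$node_id), oracle_mesh_nodes(FIX$meshtree, hits))
    }
  })
})

test_that("filter_clade keeps exactly the hits under the clade", {
  tx <- FIX$taxonomy
  hits <- FIX$tax$gt$species[c(1:4, 10:12)]
  expect_setequal(filter_clade(tx, hits, tx$root), hits)
  # clade = a leaf not among hits -> empty
  expect_length(filter_clade(tx, hits[1:3], FIX$tax$gt$species[20]), 0L)

  g3 <- names(FIX$tax$gt$genus_species)[3]
  expect_setequal(filter_clade(tx, FIX$tax$gt$species, g3),
                  FIX$tax$gt$genus_species[[g3]])
  expect_error(filter_clade(tx, hits, "424242"), class = "litnet_lookup_error")
})

test_that("tree_to_nested serializes deterministically in both formats", {
  toy <- load_taxonomy_dump(toy_nodes, toy_names)
  tr <- induced_subtree(toy, "3", doc_counts = c("3" = 5L))
  txt <- tree_to_nested(tr, "indented")
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(lines, 3L)
  expect_equal(lines[1], "1: Rootia [ancestor] (0)")
  expect_equal(lines[3], "    3: Gen sp [hit] (5)")

  js <- jsonlite::fromJSON(tree_to_nested(tr, "json"), simplifyVector = FALSE)
  expect_equal(js$node_id, "1")
  expect_equal(js$children[[1]]$children[[1]]$doc_count, 5L)

  # line count equals node count on the fixture
  tr2 <- induced_subtree(FIX$taxonomy, FIX$tax$gt$species[1:10])
  expect_length(strsplit(tree_to_nested(tr2), "\n")[[1]],
                nrow(hiertree_nodes(tr2)))
})
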