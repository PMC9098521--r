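test_that("build_cooc_network links entities co-mentioned in a document", {
  two <- parse_pubtator(c("1|t|T", "1|a|Genus1 species1 and Descriptor1",
                          "1\t2\t17\tGenus1 species1\tSpecies\t9010101",
                          "1\t22\t33\tDescriptor1\tChemical\tMESH:D9000001", ""))
  net <- build_cooc_network(two)
  expect_length(net$nodes, 2L)
  expect_length(net$edges, 1L)
  expect_equal(net$edges[[1]]$weight, 1L)
  expect_equal(net$edges[[1]]$pmids, "1")
  expect_equal(net$nodes[["taxid:9010101"]]$doc_count, 1L)

  one <- parse_pubtator(c("1|t|T", "1|a|Genus1 species1",
                          "1\t2\t17\tGenus1 species1\tSpecies\t9010101", ""))
  net1 <- build_cooc_network(one)
  expect_length(net1$nodes, 1L)
  expect_length(net1$edges, 0L)

  expect_length(build_cooc_network(parse_pubtator(""))$nodes, 0L)
})

test_that("cooc edge weights and node doc_counts match the brute-force double loop", {
  net <- build_cooc_network(FIX$corpus)
  oracle <- oracle_cooc(FIX$corpus, names(FIX$corpus$documents))
  expect_equal(names(net$edges), names(oracle$edge_pmids))
  for (ek in names(net$edges)) {
    expect_equal(net$edges[[ek]]$pmids, oracle$edge_pmids[[ek]])
    expect_equal(net$edges[[ek]]$weight, length(oracle$edge_pmids[[ek]]))
  }
  expect_equal(names(net$nodes), names(oracle$node_pmids))
  for (k in names(net$nodes)) {
    expect_equal(net$nodes[[k]]$doc_count, length(oracle$node_pmids[[k]]))
  }
  # generator ground truth agrees too
  expect_equal(lapply(net$edges, `[[`, "pmids"),
               lapply(FIX$corp$gt$pair_pmids, sort))
})

test_that("build_hierarchy_network renders trees with field-style labels", {
  counts <- stats::setNames(c(3L, 1L), FIX$tax$gt$species[1:2])
  net <- build_hierarchy_network(counts, FIX$taxonomy)
  lab <- net$nodes[[FIX$tax$gt$species[1]]]$label
  expect_match(lab, "^9[0-9]+: Genus1 species1$")
  expect_equal(net$nodes[[FIX$tax$gt$species[1]]]$attrs$category, "hit")
  expect_equal(net$nodes[[FIX$tax$gt$species[1]]]$doc_count, 3L)
  expect_equal(length(net$edges), length(net$nodes) - 1L)

  mnet <- build_hierarchy_network(
    stats::setNames(2L, names(FIX$meshtree$heading)[1]), FIX$meshtree)
  hit_labels <- vapply(mnet$nodes, `[[`, character(1), "label")
  expect_true(any(grepl("^D01\\.100: Descriptor1$", hit_labels)))

  # single hit = root -> 1 node, 0 edges
  rnet <- build_hierarchy_network(stats::setNames(0L, FIX$taxonomy$root), FIX$taxonomy)
  expect_length(rnet$nodes, 1L)
  expect_length(rnet$edges, 0L)

  expect_error(
    build_hierarchy_network(stats::setNames(c(1L, 1L), c("taxid:1", "mesh:D1")), FIX$taxonomy),
    class = "litnet_usage_error")
})

test_that("set operations satisfy the stated algebra", {
  withr::with_seed(17, {
    A <- random_subnet(FIX$corpus)
    expect_equal(names(union_networks(A, A)$nodes), names(A$nodes))
    expect_equal(names(intersect_networks(A, A)$nodes), names(A$nodes))
    expect_length(difference_networks(A, A)$nodes, 0L)

    for (i in 1:10) {
      a <- random_subnet(FIX$corpus)
      b <- random_subnet(FIX$corpus)
      u <- union_networks(a, b); x <- intersect_networks(a, b)
      d <- difference_networks(a, b)
      # set-algebra oracle over explicit name sets
      expect_setequal(names(u$nodes), union(names(a$nodes), names(b$nodes)))
      expect_setequal(names(x$nodes), intersect(names(a$nodes), names(b$nodes)))
      expect_setequal(names(d$nodes), setdiff(names(a$nodes), names(b$nodes)))
      expect_setequal(names(u$edges), union(names(a$edges), names(b$edges)))
      expect_setequal(names(x$edges), intersect(names(a$edges), names(b$edges)))
      # inclusion-exclusion and partition of nodes(a)
      expect_equal(length(u$nodes), length(a$nodes) + length(b$nodes) - length(x$nodes))
      expect_setequal(c(names(d$nodes), names(x$nodes)), names(a$nodes))
      # weights recomputed from united pmid sets (no double counting)
      for (ek in names(u$edges)) {
        expect_equal(u$edges[[ek]]$weight,
                     length(union(if (is.null(a$edges[[ek]])) character() else a$edges[[ek]]$pmids,
                                  if (is.null(b$edges[[ek]])) character() else b$edges[[ek]]$pmids)))
      }
    }
  })
})

test_that("set operations commute on node/edge sets and provenance is exact", {
  withr::with_seed(18, {
    a <- random_subnet(FIX$corpus)
    b <- random_subnet(FIX$corpus)
    expect_equal(names(union_networks(a, b)$nodes), names(union_networks(b, a)$nodes))
    expect_equal(names(intersect_networks(a, b)$edges), names(intersect_networks(b, a)$edges))

    # union of pmid selections == union of per-selection networks
    pa <- sample(names(FIX$corpus$documents), 40)
    pb <- sample(names(FIX$corpus$documents), 40)
    direct <- build_cooc_network(FIX$corpus, union(pa, pb))
    viaop <- union_networks(build_cooc_network(FIX$corpus, pa),
                            build_cooc_network(FIX$corpus, pb))
    expect_equal(names(direct$nodes), names(viaop$nodes))
    expect_equal(lapply(direct$edges, `[[`, "pmids"), lapply(viaop$edges, `[[`, "pmids"))
  })
})

test_that("highlight_common flags exactly the shared nodes", {
  a <- make_net(c("A", "B", "C"), list(c("A", "B")))
  b <- make_net(c("X", "Y"), list(c("X", "Y")))
  h <- highlight_common(a, b)
  expect_false(any(vapply(h$nodes, function(n) n$attrs$common, logical(1))))

  h2 <- highlight_common(a, a)
  expect_true(all(vapply(h2$nodes, function(n) n$attrs$common, logical(1))))

  c1 <- make_net(c("A", "B", "C", "D", "E", "F"))
  c2 <- make_net(c("C", "D", "E", "F", "G"))
  h3 <- highlight_common(c1, c2)
  expect_equal(sum(vapply(h3$nodes, function(n) n$attrs$common, logical(1))), 4L)
})

test_that("network_properties matches closed forms and the flood-fill oracle", {
  empty <- build_cooc_network(parse_pubtator(""))
  st0 <- network_properties(empty)
  expect_equal(st0$n_nodes, 0L)
  expect_equal(st0$density, 0)
  expect_equal(st0$n_components, 0L)

  tri <- make_net(c("A", "B", "C"), list(c("A", "B"), c("B", "C"), c("A", "C")))
  st <- network_properties(tri)
  expect_equal(st$density, 1.0)
  expect_equal(st$n_components, 1)
  expect_equal(st$mean_degree, 2)

  net <- build_cooc_network(FIX$corpus, names(FIX$corpus$documents)[1:40])
  st2 <- network_properties(net)
  oc <- oracle_components(net)
  expect_equal(st2$n_components, oc$n)
  expect_equal(st2$max_component_size, oc$max_size)
  expect_equal(st2$density, 2 * st2$n_edges / (st2$n_nodes * (st2$n_nodes - 1)))
})

test_that("compare_networks computes common-node similarity", {
  A <- make_net(c("A", "B", "C"), list(c("A", "B")))
  self <- compare_networks(A, A)
  expect_equal(self$precision, 1.0)
  expect_equal(self$recall, 1.0)
  expect_equal(self$f1, 1.0)
  expect_equal(self$jaccard, 1.0)

  B <- make_net(c("X", "Y"))
  disj <- compare_networks(A, B)
  expect_equal(disj$tp, 0L)
  expect_equal(disj$precision, 0)
  expect_equal(disj$jaccard, 0)

  # symmetry: tp symmetric, precision/recall swap
  s1 <- compare_networks(A, B); s2 <- compare_networks(B, A)
  expect_equal(s1$tp, s2$tp)
  expect_equal(s1$precision, s2$recall)
  expect_equal(s1$f1, s2$f1)

  both_empty <- compare_networks(build_cooc_network(parse_pubtator("")),
                                 build_cooc_network(parse_pubtator("")))
  expect_true(both_empty$undefined)
  expect_true(is.na(both_empty$precision))
})

test_that("GEXF round-trips and GraphML exports are well-formed", {
  f <- withr::local_tempfile(fileext = ".gexf")
  empty <- build_cooc_network(parse_pubtator(""))
  export_gexf(empty, f)
  expect_length(import_gexf(f)$nodes, 0L)

  net <- highlight_common(build_cooc_network(FIX$corpus, names(FIX$corpus$documents)[1:30]),
                          build_cooc_network(FIX$corpus, names(FIX$corpus$documents)[20:50]))
  export_gexf(net, f)
  back <- import_gexf(f)
  expect_equal(names(back$nodes), names(net$nodes))
  expect_equal(names(back$edges), names(net$edges))
  for (k in names(net$nodes)) {
    expect_equal(back$nodes[[k]]$label, net$nodes[[k]]$label)
    expect_equal(back$nodes[[k]]$entity_class, net$nodes[[k]]$entity_class)
    expect_equal(back$nodes[[k]]$doc_count, net$nodes[[k]]$doc_count)
    expect_equal(back$nodes[[k]]$attrs$common, net$nodes[[k]]$attrs$common)
  }
  for (ek in names(net$edges)) {
    expect_equal(back$edges[[ek]]$weight, net$edges[[ek]]$weight)
    expect_null(back$edges[[ek]]$pmids)  # provenance documented lossy
  }

  # directed files are rejected
  bad <- withr::local_tempfile(fileext = ".gexf")
  writeLines(c('<?xml version="1.0"?>',
               '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
               '<graph defaultedgetype="directed"><nodes/><edges/></graph></gexf>'), bad)
  expect_error(import_gexf(bad), class = "litnet_format_error")
  notxml <- withr::local_tempfile(fileext = ".gexf")
  writeLines("junk {", notxml)
  expect_error(import_gexf(notxml), class = "litnet_format_error")

  g <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, g)
  doc <- xml2::read_xml(g)
  xml2::xml_ns_strip(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//node")), length(net$nodes))
  expect_equal(length(xml2::xml_find_all(doc, ".//edge")), length(net$edges))
})

test_that("every operation preserves the weight = |pmids| invariant", {
  withr::with_seed(19, {
    a <- random_subnet(FIX$corpus); b <- random_subnet(FIX$corpus)
    for (net in list(a, union_networks(a, b), intersect_networks(a, b),
                     difference_networks(a, b), highlight_common(a, b))) {
      for (e in net$edges) expect_equal(e$weight, length(e$pmids))
      for (e in net$edges) {
        expect_gte(net$nodes[[e$from]]$doc_count, e$weight)
        expect_gte(net$nodes[[e$to]]$doc_count, e$weight)
      }
    }
  })
})
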