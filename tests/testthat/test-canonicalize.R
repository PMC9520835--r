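parkinsons_pre <- function(model) {
  ids <- c("MONDO:0005180", "DOID:14330", "EFO:0002508", "MESH:D010300",
           "CHEBI:599400")
  nodes <- data.frame(
    id = ids,
    name = c("Parkinson disease", "Parkinson's disease", "", "", "levodopa"),
    category = c(rep("biolink:Disease", 4), "biolink:SmallMolecule"),
    iri = "", description = "",
    provided_by = c("KGSOURCE:ont", "KGSOURCE:ont", "KGSOURCE:tsv",
                    "KGSOURCE:tsv", "KGSOURCE:tsv"),
    publications = "", stringsAsFactors = FALSE)
  edges <- empty_edges()
  edges[1, ] <- list("DOID:14330", "biolink:same_as", "MONDO:0005180",
                     "xref", "KGSOURCE:ont", "")
  edges[2, ] <- list("DOID:14330", "biolink:same_as", "EFO:0002508",
                     "xref", "KGSOURCE:tsv", "")
  edges[3, ] <- list("MESH:D010300", "biolink:same_as", "MONDO:0005180",
                     "xref", "KGSOURCE:tsv", "")
  edges[4, ] <- list("CHEBI:599400", "biolink:treats", "DOID:14330",
                     "treats_condition", "KGSOURCE:tsv", "PMID:9")
  g <- graph_document(nodes, kgbuildr:::orient_edges(model, edges),
                      build_info = list(stage = "pre_merge_graph"))
  g
}

test_that("synonym chains collapse into one block (components, not cliques)", {
  model <- mini_model()
  g <- parkinsons_pre(model)
  part <- build_partition(g, model)
  sizes <- lengths(part$blocks)
  expect_equal(sort(sizes), c(1L, 4L))
  big <- part$blocks[[which(sizes == 4L)]]
  expect_setequal(big, c("MONDO:0005180", "DOID:14330", "EFO:0002508",
                         "MESH:D010300"))
  expect_error(build_partition(g, model, "biolink:bogus"),
               class = "kg_lookup_error")
})

test_that("graphs without equivalence edges partition into singletons", {
  set.seed(3)
  model <- mini_model()
  g <- random_graph(30, model = model)
  g$edges <- g$edges[g$edges$predicate != "biolink:same_as", , drop = FALSE]
  part <- build_partition(g, model)
  expect_true(all(lengths(part$blocks) == 1L))
  expect_equal(length(part$blocks), nrow(g$nodes))
})

test_that("partition equals the transitive-closure oracle on random graphs", {
  model <- mini_model()
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    ids <- sprintf("N%d:%04d", sample.int(4, n, TRUE), sample.int(9999L, n))
    ids <- unique(ids)
    n <- length(ids)
    m <- rpois(1, n / 2)
    edges <- empty_edges()
    if (m > 0)
      edges <- data.frame(subject = sample(ids, m, TRUE),
                          predicate = sample(c("biolink:same_as",
                                               "biolink:exact_match",
                                               "biolink:treats"), m, TRUE),
                          object = sample(ids, m, TRUE), relation = "r",
                          provided_by = "KGSOURCE:a", publications = "",
                          stringsAsFactors = FALSE)
    nodes <- data.frame(id = ids, name = "", category = "biolink:NamedThing",
                        iri = "", description = "", provided_by = "KGSOURCE:a",
                        publications = "", stringsAsFactors = FALSE)
    g <- graph_document(nodes, kgbuildr:::orient_edges(model, edges))
    part <- build_partition(g, model)
    eq <- g$edges[g$edges$predicate %in% c("biolink:same_as",
                                           "biolink:exact_match"), ]
    want <- oracle_partition(ids, eq$subject, eq$object)
    expect_identical(part$blocks, want)
  }
})

test_that("canonical identifier election follows prefix priority, then lexicographic order", {
  model <- mini_model()
  block <- data.frame(id = c("MESH:D010300", "DOID:14330", "MONDO:0005180"),
                      name = "", category = "biolink:Disease",
                      provided_by = "KGSOURCE:a", stringsAsFactors = FALSE)
  expect_identical(choose_canonical(block, model)$id, "MONDO:0005180")

  single <- block[1, , drop = FALSE]
  expect_identical(choose_canonical(single, model)$id, "MESH:D010300")

  # both prefixes unlisted for the category: lexicographically smaller CURIE
  tie <- data.frame(id = c("ZZZ:9", "AAA:1"), name = "",
                    category = "biolink:PhenotypicFeature",
                    provided_by = "KGSOURCE:a", stringsAsFactors = FALSE)
  expect_identical(choose_canonical(tie, model)$id, "AAA:1")

  # dominant category via source precedence picks that member's category
  mixed <- data.frame(id = c("CHEBI:10", "DRUGBANK:DB1"), name = "",
                      category = c("biolink:SmallMolecule", "biolink:Drug"),
                      provided_by = c("KGSOURCE:late", "KGSOURCE:early"),
                      stringsAsFactors = FALSE)
  ranks <- c("KGSOURCE:early" = 1L, "KGSOURCE:late" = 2L)
  got <- choose_canonical(mixed, model, source_ranks = ranks)
  expect_identical(got$category, "biolink:Drug")
  expect_identical(got$id, "DRUGBANK:DB1")   # Drug priority: DRUGBANK first
})

test_that("canonical graph remaps edges, merges annotations and drops equivalence self-loops", {
  model <- mini_model()
  g <- parkinsons_pre(model)
  part <- build_partition(g, model)
  res <- build_canonical_graph(g, part, model)
  cg <- res$graph
  expect_equal(nrow(cg$nodes), 2L)
  dis <- cg$nodes[cg$nodes$category == "biolink:Disease", ]
  expect_identical(dis$id, "MONDO:0005180")
  expect_setequal(strsplit(dis$equivalent_identifiers, "|", fixed = TRUE)[[1]],
                  c("MONDO:0005180", "DOID:14330", "EFO:0002508",
                    "MESH:D010300"))
  expect_identical(res$log$dropped_equivalence_self_loops, 3L)
  # the treats edge now points at the canonical disease id
  expect_equal(nrow(cg$edges), 1L)
  expect_identical(cg$edges$object, "MONDO:0005180")
  expect_identical(cg$edges$subject, "CHEBI:599400")
  expect_identical(cg$edges$publications, "PMID:9")
  expect_true(validate_graph(model, cg)$ok)

  # identifier conservation
  expect_setequal(unlist(strsplit(cg$nodes$equivalent_identifiers, "|",
                                  fixed = TRUE)), g$nodes$id)
  expect_error(build_canonical_graph(
    graph_document(rbind(g$nodes,
                         data.frame(id = "X:1", name = "", category = "c",
                                    iri = "", description = "",
                                    provided_by = "", publications = "",
                                    stringsAsFactors = FALSE)),
                   g$edges), part, model),
    class = "kg_consistency_error")
})

test_that("a pre graph without equivalence edges canonicalizes to itself", {
  model <- mini_model()
  set.seed(13)
  g <- random_graph(25, n_edges = 40, model = model)
  g$edges <- g$edges[g$edges$predicate != "biolink:same_as", , drop = FALSE]
  g$edges <- coalesce_edges(g$edges)
  part <- build_partition(g, model)
  res <- build_canonical_graph(g, part, model)
  expect_equal(nrow(res$graph$nodes), nrow(g$nodes))
  expect_equal(nrow(res$graph$edges), nrow(g$edges))
  expect_true(all(res$graph$nodes$equivalent_identifiers ==
                    res$graph$nodes$id))
})
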