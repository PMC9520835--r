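one_hop_fixture <- function(model) {
  nodes <- empty_nodes(canonical = TRUE)
  nodes[1, ] <- list("MONDO:0007034", "Adams-Oliver-like disease",
                     "biolink:Disease", "", "", "KGSOURCE:a", "",
                     "biolink:Disease", "MONDO:0007034|DOID:0060227", "")
  nodes[2, ] <- list("NCBIGene:1", "gene one", "biolink:Gene", "", "",
                     "KGSOURCE:a|KGSOURCE:b", "", "biolink:Gene",
                     "NCBIGene:1", "")
  nodes[3, ] <- list("NCBIGene:2", "gene two", "biolink:Gene", "", "",
                     "KGSOURCE:a", "", "biolink:Gene", "NCBIGene:2", "")
  nodes[4, ] <- list("NCBIGene:3", "gene three", "biolink:Gene", "", "",
                     "KGSOURCE:a", "", "biolink:Gene", "NCBIGene:3", "")
  nodes[5, ] <- list("CHEBI:9", "some drug", "biolink:SmallMolecule", "", "",
                     "KGSOURCE:a", "", "biolink:SmallMolecule", "CHEBI:9", "")
  edges <- empty_edges()
  edges[1, ] <- list("NCBIGene:1", "biolink:associated_with",
                     "MONDO:0007034", "r", "KGSOURCE:a|KGSOURCE:b", "")
  edges[2, ] <- list("NCBIGene:2", "biolink:associated_with",
                     "MONDO:0007034", "r", "KGSOURCE:a", "")
  edges[3, ] <- list("NCBIGene:3", "biolink:related_to",
                     "MONDO:0007034", "r", "KGSOURCE:a", "")
  edges[4, ] <- list("CHEBI:9", "biolink:treats", "MONDO:0007034", "r",
                     "KGSOURCE:a", "")
  graph_document(nodes, edges, list(stage = "canonical_graph"))
}

test_that("the index resolves equivalent identifiers and mirrors linear scans", {
  model <- mini_model()
  g <- one_hop_fixture(model)
  idx <- index_graph(g, model)
  expect_identical(unname(idx$alias["DOID:0060227"]), "MONDO:0007034")
  expect_true(is.na(idx$alias["DOID:99999"]))

  dup <- g
  dup$nodes <- rbind(dup$nodes, dup$nodes[1, ])
  expect_error(index_graph(dup, model), class = "kg_index_error")

  set.seed(55)
  for (rep in 1:5) {
    rg <- random_graph(40, n_edges = 80, canonical = TRUE, model = model)
    ix <- index_graph(rg, model)
    for (id in sample(rg$nodes$id, 5)) {
      want_out <- which(rg$edges$subject == id)
      expect_identical(sort(ix$out_adj[[id]]), sort(want_out))
      want_in <- which(rg$edges$object == id)
      expect_identical(sort(ix$in_adj[[id]]), sort(want_in))
    }
  }
})

test_that("one-hop answering honors ids, category closure and predicate closure", {
  model <- mini_model()
  g <- one_hop_fixture(model)
  idx <- index_graph(g, model)
  # genes related (via descendants of related_to) to the disease, queried
  # through a non-canonical identifier
  q <- query_graph(
    qnodes = list(n0 = list(ids = "DOID:0060227"),
                  n1 = list(categories = "biolink:Gene")),
    qedges = list(e0 = list(subject = "n1", object = "n0",
                            predicates = "biolink:related_to")))
  res <- answer_one_hop(idx, q)
  expect_equal(nrow(res$results), 3L)
  expect_setequal(res$results$n1,
                  c("NCBIGene:1", "NCBIGene:2", "NCBIGene:3"))
  expect_equal(nrow(res$knowledge_graph$nodes), 4L)
  expect_equal(nrow(res$knowledge_graph$edges), 3L)
  # ranking: multi-source edge first, remainder lexicographic
  expect_identical(res$results$n1[1], "NCBIGene:1")

  # category constraint matching nothing
  q2 <- query_graph(
    qnodes = list(n0 = list(ids = "MONDO:0007034"),
                  n1 = list(categories = "biolink:PhenotypicFeature")),
    qedges = list(e0 = list(subject = "n1", object = "n0")))
  res2 <- answer_one_hop(idx, q2)
  expect_equal(nrow(res2$results), 0L)
  expect_equal(nrow(res2$knowledge_graph$nodes), 0L)

  # hierarchical category matching: ChemicalEntity covers SmallMolecule
  q3 <- query_graph(
    qnodes = list(n0 = list(ids = "MONDO:0007034"),
                  n1 = list(categories = "biolink:ChemicalEntity")),
    qedges = list(e0 = list(subject = "n1", object = "n0",
                            predicates = "biolink:treats")))
  expect_identical(answer_one_hop(idx, q3)$results$n1, "CHEBI:9")
})

test_that("symmetric predicates match in either orientation", {
  model <- mini_model()
  nodes <- empty_nodes(canonical = TRUE)
  nodes[1, ] <- list("CHEBI:1", "", "biolink:SmallMolecule", "", "",
                     "KGSOURCE:a", "", "biolink:SmallMolecule", "CHEBI:1", "")
  nodes[2, ] <- list("CHEBI:2", "", "biolink:SmallMolecule", "", "",
                     "KGSOURCE:a", "", "biolink:SmallMolecule", "CHEBI:2", "")
  edges <- empty_edges()
  edges[1, ] <- list("CHEBI:1", "biolink:interacts_with", "CHEBI:2", "r",
                     "KGSOURCE:a", "")
  g <- graph_document(nodes, edges, list(stage = "canonical_graph"))
  idx <- index_graph(g, model)
  q <- query_graph(qnodes = list(n0 = list(ids = "CHEBI:2"),
                                 n1 = list()),
                   qedges = list(e0 = list(subject = "n0", object = "n1",
                                           predicates =
                                             "biolink:interacts_with")))
  res <- answer_one_hop(idx, q)
  expect_equal(nrow(res$results), 1L)
  expect_identical(res$results$n1, "CHEBI:1")
})

test_that("malformed queries are rejected with validation errors", {
  expect_error(query_graph(list(n0 = list(ids = "A:1")),
                           list(e0 = list(subject = "n0", object = "n1"))),
               class = "kg_query_validation_error")
  expect_error(query_graph(list(n0 = list(ids = "A:1"),
                                n1 = list(), n2 = list()),
                           list(e0 = list(subject = "n0", object = "n1"))),
               class = "kg_query_validation_error")
  expect_error(query_graph(list(n0 = list(), n1 = list()),
                           list(e0 = list(subject = "n0", object = "n1"))),
               class = "kg_query_validation_error")
})

test_that("answers equal the brute-force evaluator on random graphs and queries", {
  model <- mini_model()
  set.seed(99)
  for (rep in 1:15) {
    g <- random_graph(sample(20:60, 1), n_edges = 80, canonical = TRUE,
                      model = model)
    idx <- index_graph(g, model)
    seed_node <- sample(nrow(g$nodes), 1)
    seed_ids <- strsplit(g$nodes$equivalent_identifiers[seed_node], "|",
                         fixed = TRUE)[[1]]
    qn1 <- switch(sample(3, 1),
                  list(categories = sample(rand_categories, 1)),
                  list(ids = sample(g$nodes$id, 2)),
                  list())
    qe <- list(subject = "n0", object = "n1")
    if (stats::runif(1) < 0.7)
      qe$predicates <- sample(c("biolink:related_to", "biolink:treats",
                                "biolink:interacts_with"), 1)
    q <- query_graph(qnodes = list(n0 = list(ids = sample(seed_ids, 1)),
                                   n1 = qn1),
                     qedges = list(e0 = qe))
    res <- answer_one_hop(idx, q)
    expect_identical(binding_keys(res, "n0", "n1", "e0"),
                     oracle_one_hop(g, q, model))
    # knowledge_graph minimality
    expect_setequal(res$knowledge_graph$nodes$id,
                    unique(c(res$results$n0, res$results$n1)))
  }
})

test_that("TRAPI-style messages round-trip through JSON", {
  model <- mini_model()
  g <- one_hop_fixture(model)
  idx <- index_graph(g, model)
  msg <- tempfile(fileext = ".json")
  writeLines('{
    "message": {"query_graph": {
      "nodes": {"n0": {"ids": ["MONDO:0007034"]},
                "n1": {"categories": ["biolink:Gene"]}},
      "edges": {"e0": {"subject": "n1", "object": "n0",
                        "predicates": ["biolink:related_to"]}}}}}', msg)
  q <- read_query_json(msg)
  res <- answer_one_hop(idx, q)
  out <- tempfile(fileext = ".json")
  write_response_json(res, out)
  parsed <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  expect_length(parsed$message$results, 3L)
  expect_length(parsed$message$knowledge_graph$nodes, 4L)
})
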