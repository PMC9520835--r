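test_that("a minimal model with only the two roots loads", {
  path <- write_model_yaml(c(
    "version: t",
    "categories:",
    "  biolink:NamedThing: []",
    "predicates:",
    "  biolink:related_to: []"))
  m <- load_model(path)
  expect_length(m$categories$nodes, 1L)
  expect_length(m$predicates$nodes, 1L)
  expect_identical(m$categories$root, "biolink:NamedThing")
})

test_that("inverse pairs carry exactly one canonical member", {
  m <- mini_model()
  expect_equal(nrow(m$inverse_pairs), 3L)
  hp <- m$inverse_pairs[m$inverse_pairs$a == "biolink:has_part" |
                        m$inverse_pairs$b == "biolink:has_part", ]
  expect_identical(hp$canonical, "biolink:has_part")
  expect_identical(unname(m$noncanonical_map["biolink:part_of"]),
                   "biolink:has_part")

  bad <- write_model_yaml(c(
    "categories:", "  biolink:NamedThing: []",
    "predicates:", "  biolink:related_to: [biolink:has_part, biolink:part_of]",
    "inverse_pairs:",
    "  - pair: [biolink:has_part, biolink:part_of]",
    "    canonical: biolink:treats"))
  expect_error(load_model(bad), class = "kg_model_consistency_error")
})

test_that("hierarchy defects are rejected with specific errors", {
  cyc <- write_model_yaml(c(
    "categories:", "  biolink:NamedThing: []",
    "predicates:",
    "  'biolink:a': ['biolink:b']",
    "  'biolink:b': ['biolink:a']"))
  expect_error(load_model(cyc), class = "kg_model_cycle_error")

  no_root <- write_model_yaml(c(
    "categories: {}",
    "predicates:", "  biolink:related_to: []"))
  expect_error(load_model(no_root), class = "kg_model_schema_error")

  sym_in_pair <- write_model_yaml(c(
    "categories:", "  biolink:NamedThing: []",
    "predicates:", "  biolink:related_to: [biolink:has_part, biolink:part_of]",
    "inverse_pairs:",
    "  - pair: [biolink:has_part, biolink:part_of]",
    "    canonical: biolink:has_part",
    "symmetric: [biolink:part_of]"))
  expect_error(load_model(sym_in_pair), class = "kg_model_consistency_error")
})

test_that("hierarchy closure expands reflexively and transitively", {
  m <- mini_model()
  expect_setequal(expand_category(m, "biolink:NamedThing"),
                  m$categories$nodes)
  expect_identical(expand_category(m, "biolink:PhenotypicFeature"),
                   "biolink:PhenotypicFeature")
  expect_setequal(expand_category(m, "biolink:DiseaseOrPhenotypicFeature"),
                  c("biolink:DiseaseOrPhenotypicFeature", "biolink:Disease",
                    "biolink:PhenotypicFeature"))
  expect_setequal(expand_predicate(m, "biolink:interacts_with"),
                  c("biolink:interacts_with",
                    "biolink:physically_interacts_with"))
  expect_error(expand_category(m, "biolink:Unicorn"),
               class = "kg_lookup_error")
  # closure of a node is a superset of each child closure plus the node
  for (nm in m$categories$nodes) {
    cl <- expand_category(m, nm)
    for (kid in m$categories$children[[nm]] %||% character(0))
      expect_true(all(c(nm, expand_category(m, kid)) %in% cl))
  }
})

test_that("relation mapping echoes the original phrasing and falls back to root", {
  m <- mini_model()
  r <- map_relation(m, "fixtureDrugDB", "treats_condition")
  expect_identical(r$predicate, "biolink:treats")
  expect_identical(r$relation, "treats_condition")
  expect_message(r2 <- map_relation(m, "srcX", "frobnicates"),
                 class = "kg_unmapped_relation")
  expect_identical(r2$predicate, "biolink:related_to")
  expect_identical(r2$relation, "frobnicates")
  expect_identical(suppressMessages(map_relation(m, "srcX", "frobnicates")),
                   suppressMessages(map_relation(m, "srcX", "frobnicates")))
})

test_that("orientation swaps non-canonical inverse members and is idempotent", {
  m <- mini_model()
  e <- data.frame(subject = "MONDO:1", predicate = "biolink:treated_by",
                  object = "DRUGBANK:DB1", relation = "x", provided_by = "",
                  publications = "", stringsAsFactors = FALSE)
  o <- orient_assertion(m, e)
  expect_identical(o$subject, "DRUGBANK:DB1")
  expect_identical(o$predicate, "biolink:treats")
  expect_identical(o$object, "MONDO:1")

  already <- data.frame(subject = "A:1", predicate = "biolink:has_part",
                        object = "B:2", relation = "", provided_by = "",
                        publications = "", stringsAsFactors = FALSE)
  expect_identical(orient_assertion(m, already), already)

  e$predicate <- "biolink:frobnicates"
  expect_error(orient_assertion(m, e), class = "kg_lookup_error")

  set.seed(42)
  preds <- c("biolink:treats", "biolink:treated_by", "biolink:part_of",
             "biolink:interacts_with", "biolink:same_as",
             "biolink:related_to")
  edges <- data.frame(
    subject = sprintf("P%d:%d", sample.int(5, 1000, TRUE),
                      sample.int(50, 1000, TRUE)),
    predicate = sample(preds, 1000, TRUE),
    object = sprintf("P%d:%d", sample.int(5, 1000, TRUE),
                     sample.int(50, 1000, TRUE)),
    relation = "r", provided_by = "", publications = "",
    stringsAsFactors = FALSE)
  once <- kgbuildr:::orient_edges(m, edges)
  twice <- kgbuildr:::orient_edges(m, once)
  expect_identical(once, twice)
  expect_false(any(once$predicate %in% names(m$noncanonical_map)))
})

test_that("graph validation reports category, predicate, inverse and CURIE defects", {
  m <- mini_model()
  nodes <- empty_nodes()
  nodes[1, ] <- list("X:1", "", "biolink:Unicorn", "", "", "s", "")
  g <- graph_document(nodes, empty_edges())
  r <- validate_graph(m, g)
  expect_false(r$ok)
  expect_equal(nrow(r$violations), 1L)
  expect_identical(r$violations$rule, "category_in_model")

  nodes2 <- empty_nodes()
  nodes2[1, ] <- list("A:1", "", "biolink:Disease", "", "", "s", "")
  nodes2[2, ] <- list("B:2", "", "biolink:Disease", "", "", "s", "")
  edges2 <- empty_edges()
  edges2[1, ] <- list("A:1", "biolink:part_of", "B:2", "r", "s", "")
  r2 <- validate_graph(m, graph_document(nodes2, edges2))
  expect_false(r2$ok)
  expect_identical(r2$violations$rule, "canonical_inverse_member")

  nodes3 <- nodes2
  nodes3$id[1] <- "noprefix"
  edges3 <- edges2
  edges3$predicate <- "biolink:treats"
  edges3$subject <- "noprefix"
  r3 <- validate_graph(m, graph_document(nodes3, edges3))
  expect_setequal(r3$violations$rule, "curie_well_formed")
})
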