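iri_map_t <- list(EX = "http://example.org/onto#",
                  MESH = "http://id.nlm.nih.gov/mesh/")

ont_src <- function(path, format = "ontology_ttl") {
  source_config(name = "fixtureOnt", version = "2024-01", path = path,
                format = format, rank = 1L,
                default_category = "biolink:Disease")
}

ttl_fixture <- function() {
  path <- tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix ex: <http://example.org/onto#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix oboInOwl: <http://www.geneontology.org/formats/oboInOwl#> .",
    "",
    "# a tiny disease hierarchy",
    "ex:C001 a owl:Class ;",
    '    rdfs:label "root disease" .',
    "ex:C002 a owl:Class ;",
    '    rdfs:label "mid disease" ;',
    "    rdfs:subClassOf ex:C001 ;",
    '    oboInOwl:hasDbXref "MESH:D010300" .',
    "ex:C003 a owl:Class ;",
    '    rdfs:label "leaf disease" ;',
    "    rdfs:subClassOf ex:C002 ."), path)
  path
}

test_that("ontology TTL ingestion yields one node per class and edges per axiom", {
  model <- mini_model()
  g <- ingest_ontology(ont_src(ttl_fixture()), model, iri_map_t)
  # 3 classes + the source node
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$edges), 3L)
  expect_setequal(g$edges$predicate[g$edges$relation == "rdfs:subClassOf"],
                  "biolink:subclass_of")
  xref <- g$edges[g$edges$relation == "oboInOwl:hasDbXref", ]
  expect_equal(nrow(xref), 1L)
  expect_identical(xref$predicate, "biolink:same_as")
  # symmetric same_as is normalized, so compare as a set
  expect_setequal(c(xref$subject, xref$object), c("EX:C002", "MESH:D010300"))
  expect_true(all(g$edges$provided_by == "KGSOURCE:fixtureOnt"))
  expect_true(validate_graph(model, g)$ok)
})

test_that("RDF/XML ingestion matches the TTL reader on equivalent content", {
  model <- mini_model()
  xml_path <- tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"',
    '         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">',
    '  <owl:Class rdf:about="http://example.org/onto#C001">',
    "    <rdfs:label>root disease</rdfs:label>",
    "  </owl:Class>",
    '  <owl:Class rdf:about="http://example.org/onto#C002">',
    "    <rdfs:label>mid disease</rdfs:label>",
    '    <rdfs:subClassOf rdf:resource="http://example.org/onto#C001"/>',
    "    <oboInOwl:hasDbXref>MESH:D010300</oboInOwl:hasDbXref>",
    "  </owl:Class>",
    '  <owl:Class rdf:about="http://example.org/onto#C003">',
    "    <rdfs:label>leaf disease</rdfs:label>",
    '    <rdfs:subClassOf rdf:resource="http://example.org/onto#C002"/>',
    "  </owl:Class>",
    "</rdf:RDF>"), xml_path)
  g_xml <- ingest_ontology(ont_src(xml_path, "ontology_rdfxml"), model,
                           iri_map_t)
  g_ttl <- ingest_ontology(ont_src(ttl_fixture()), model, iri_map_t)
  expect_true(kgbuildr:::graph_equal(g_xml, g_ttl))
})

test_that("empty ontologies and unmapped IRI prefixes are handled", {
  model <- mini_model()
  empty <- tempfile(fileext = ".ttl")
  writeLines("@prefix ex: <http://example.org/onto#> .", empty)
  g <- ingest_ontology(ont_src(empty), model, iri_map_t)
  expect_equal(nrow(g$nodes), 1L)   # just the source node
  expect_equal(nrow(g$edges), 0L)

  stray <- tempfile(fileext = ".ttl")
  writeLines(c("@prefix zz: <http://nowhere.org/> .",
               "zz:X a owl:Class ."), stray)
  expect_error(ingest_ontology(ont_src(stray), model, iri_map_t),
               class = "kg_unmapped_prefix_error")
})

test_that("triple TSV ingestion repairs bare ids, maps relations and skips bad rows", {
  model <- mini_model()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("subject\trelation\tobject\tpublications",
               "CHEBI:46195\ttreats_condition\tDOID:14330\tPMID:123",
               "CHEMBL112\ttreats_condition\tDOID:14330\t",
               "only\ttwo",
               "CHEBI:1\tfrobnicates\tDOID:2\t"), path)
  src <- source_config(name = "fixtureDrugDB", version = "1", path = path,
                       format = "triple_tsv", rank = 2L,
                       prefix_rules = list("^CHEMBL[0-9]+$" = "CHEMBL.COMPOUND"),
                       category_map = list(CHEBI = "biolink:SmallMolecule",
                                           DOID = "biolink:Disease"))
  g <- ingest_tsv_triples(src, model, list())
  log <- attr(g, "log")
  expect_equal(log$detail[log$event == "rows_skipped_bad_columns"], "1")
  expect_equal(log$detail[log$event == "relations_unmapped"], "1")
  e1 <- g$edges[g$edges$subject == "CHEBI:46195", ]
  expect_identical(e1$predicate, "biolink:treats")
  expect_identical(e1$relation, "treats_condition")
  expect_identical(e1$publications, "PMID:123")
  expect_true("CHEMBL.COMPOUND:CHEMBL112" %in% g$edges$subject)
  expect_true("CHEMBL.COMPOUND:CHEMBL112" %in% g$nodes$id)
  # unmapped relation fell back to the root predicate
  expect_identical(g$edges$predicate[g$edges$relation == "frobnicates"],
                   "biolink:related_to")
  expect_identical(
    g$nodes$category[g$nodes$id == "CHEBI:46195"], "biolink:SmallMolecule")
  expect_true(validate_graph(model, g)$ok)

  hdr_only <- tempfile(fileext = ".tsv")
  writeLines("subject\trelation\tobject", hdr_only)
  src$path <- hdr_only
  g2 <- ingest_tsv_triples(src, model, list())
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(nrow(g2$nodes), 1L)  # source node only
})

test_that("record ingestion materializes records, not link targets", {
  model <- mini_model()
  path <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(id = "DB00316", name = "acetaminophen", category = "drug",
         links = list(list(relation = "targets", target = "NCBIGene:1"),
                      list(relation = "targets", target = "NCBIGene:2"))),
    list(id = "DB99999", name = "mystery", category = "potion", links = list()),
    list(id = "DB00316", name = "dup", category = "drug",
         links = list(list(relation = "targets", target = "NCBIGene:3"))),
    list(name = "no id", category = "drug", links = list())),
    auto_unbox = TRUE), path)
  src <- source_config(name = "drugrecs", version = "9", path = path,
                       format = "record_json", rank = 3L,
                       prefix_rules = list("^DB[0-9]+$" = "DRUGBANK"),
                       category_map = list(drug = "biolink:Drug"))
  g <- ingest_records(src, model, list())
  log <- attr(g, "log")
  # 2 distinct records + source node; 3 link edges (dup folded in)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(sum(g$edges$subject == "DRUGBANK:DB00316"), 3L)
  expect_equal(log$detail[log$event == "records_skipped_no_id"], "1")
  expect_equal(log$detail[log$event == "records_merged_duplicate_id"], "1")
  expect_equal(log$detail[log$event == "records_category_fallback"], "1")
  expect_identical(g$nodes$category[g$nodes$id == "DRUGBANK:DB99999"],
                   model$categories$root)
  expect_false(any(c("NCBIGene:1", "NCBIGene:2") %in% g$nodes$id))
})

test_that("source nodes embed the version and stamp all provenance", {
  src <- ont_src(ttl_fixture())
  sn <- build_source_node(src)
  expect_identical(sn$name, "fixtureOnt v2024-01")
  expect_identical(sn$id, "KGSOURCE:fixtureOnt")
  g <- ingest_ontology(src, mini_model(), iri_map_t)
  expect_true(all(g$edges$provided_by == "KGSOURCE:fixtureOnt"))
  expect_true(all(g$nodes$provided_by == "KGSOURCE:fixtureOnt"))
})
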