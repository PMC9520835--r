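# Synthetic knowledge-source suite with exact ground-truth manifests, plus a
# scale-free degree-sequence graph generator for the statistics tests.
#
# The suite emulates the structure of a real multi-source build with no
# downloads: one ontology source (class hierarchy + cross-references), one
# publication-annotated triple TSV source (NLP-co-occurrence style), and one
# record-oriented XML source (drug-database style). Synonymy is planted by
# emitting the same concept under different identifier prefixes joined by
# xref / same_as assertions; duplicate triples are planted across sources;
# dangling links point at identifiers no source declares.

#' Generate a synthetic knowledge-source suite
#'
#' Writes one file per source in its declared format, a semantic-model
#' document, and a build config in rank order, and returns a manifest whose
#' values are exact functions of the parameters and seed (generator
#' bookkeeping): the planted synonym cliques, the expected pre-merge node and
#' edge counts, the expected canonical node and edge counts, and the planted
#' duplicate-triple and dangling-link counts. Running the full pipeline on
#' the emitted files must reproduce the manifest exactly; that is the
#' package's main integration check.
#'
#' Concepts are split into diseases (ontology classes under a random
#' subclass tree, with DOID alias classes cross-referenced in the ontology
#' and MESH aliases asserted as same_as triples in the TSV source), drugs
#' (records in the XML source, with CHEBI aliases via TSV same_as triples;
#' record ids are emitted bare and repaired via a prefix rule), and genes
#' (declared by TSV association triples, with UniProtKB aliases).
#'
#' @param params List overriding any of: `n_concepts` (50), `n_sources`
#'   (3; 2 drops the record source and with it all danglers/duplicates),
#'   `synonym_rate` (0.3, per alias opportunity), `duplicate_rate` (0.1,
#'   fraction of treats triples re-asserted by the record source),
#'   `dangler_rate` (0.05, per drug record), `publication_rate` (0.5, per
#'   TSV assertion).
#' @param seed Integer seed; one pseudo-random stream drives the whole suite.
#' @param dir Output directory (created).
#' @return The `suite_manifest` (list), invisibly also written as
#'   `manifest.json` in `dir`.
#' @export
generate_source_suite <- function(params = list(), seed = 1L, dir) {
  p <- utils::modifyList(list(n_concepts = 50L, n_sources = 3L,
                              synonym_rate = 0.3, duplicate_rate = 0.1,
                              dangler_rate = 0.05, publication_rate = 0.5),
                         params)
  rates <- c(p$synonym_rate, p$duplicate_rate, p$dangler_rate,
             p$publication_rate)
  if (any(rates < 0 | rates > 1))
    kg_stop("kg_parameter_error", "rates must lie in [0, 1]")
  if (p$n_concepts < p$n_sources || p$n_sources < 2L)
    kg_stop("kg_parameter_error",
            "need n_concepts >= n_sources >= 2 (got %d, %d)",
            p$n_concepts, p$n_sources)
  if (p$n_sources > 3L)
    kg_stop("kg_parameter_error", "at most 3 sources are supported")
  has_record <- p$n_sources >= 3L
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)

  n <- p$n_concepts
  n_dis <- max(2L, ceiling(0.4 * n))
  n_drug <- max(1L, ceiling(0.3 * n))
  n_gene <- n - n_dis - n_drug
  if (n_gene < 1L) { n_gene <- 1L; n_dis <- n - n_drug - 1L }

  mondo <- sprintf("MONDO:%07d", seq_len(n_dis))
  doid <- sprintf("DOID:%05d", seq_len(n_dis))
  mesh <- sprintf("MESH:D%06d", seq_len(n_dis))
  dbid <- sprintf("DB%05d", seq_len(n_drug))          # bare, repaired at ingest
  drugbank <- paste0("DRUGBANK:", dbid)
  chebi <- sprintf("CHEBI:%05d", seq_len(n_drug))
  ncbigene <- sprintf("NCBIGene:%05d", seq_len(n_gene))
  uniprot <- sprintf("UniProtKB:P%05d", seq_len(n_gene))

  has_doid <- stats::runif(n_dis) < p$synonym_rate
  has_mesh <- stats::runif(n_dis) < p$synonym_rate
  has_chebi <- stats::runif(n_drug) < p$synonym_rate
  has_uniprot <- stats::runif(n_gene) < p$synonym_rate

  # clique map: every alias resolves to its concept's index
  cliques <- c(
    lapply(seq_len(n_dis), function(i)
      c(mondo[i], if (has_doid[i]) doid[i], if (has_mesh[i]) mesh[i])),
    lapply(seq_len(n_drug), function(j)
      c(drugbank[j], if (has_chebi[j]) chebi[j])),
    lapply(seq_len(n_gene), function(k)
      c(ncbigene[k], if (has_uniprot[k]) uniprot[k])))
  block_of <- stats::setNames(rep(seq_along(cliques), lengths(cliques)),
                              unlist(cliques))
  pick_member <- function(ids) ids[sample.int(length(ids), 1L)]

  # bookkeeping accumulators: oriented edge keys per emitted assertion
  emitted <- list()
  emit <- function(subject, predicate, object, source, symmetric = FALSE,
                   inverse_to = NULL, dangling = FALSE) {
    # generator-side orientation: inverse relations swap; symmetric sorts
    if (!is.null(inverse_to)) {
      tmp <- subject; subject <- object; object <- tmp
      predicate <- inverse_to
    }
    if (symmetric && str_gt(subject, object)) {
      tmp <- subject; subject <- object; object <- tmp
    }
    emitted[[length(emitted) + 1L]] <<-
      data.frame(subject = subject, predicate = predicate, object = object,
                 source = source, dangling = dangling,
                 stringsAsFactors = FALSE)
  }

  # --- ontology source (TTL): MONDO tree + DOID alias classes + xrefs -----
  parent_idx <- c(NA_integer_,
                  vapply(2:n_dis, function(i) sample.int(i - 1L, 1L),
                         integer(1)))
  ttl <- c("@prefix obo: <http://purl.obolibrary.org/obo/> .",
           "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
           "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
           "@prefix oboInOwl: <http://www.geneontology.org/formats/oboInOwl#> .",
           "")
  obo_term <- function(curie) paste0("obo:", sub(":", "_", curie))
  for (i in seq_len(n_dis)) {
    st <- paste0(obo_term(mondo[i]), " a owl:Class ;\n",
                 sprintf('    rdfs:label "Disease %d"', i))
    if (!is.na(parent_idx[i])) {
      st <- paste0(st, " ;\n    rdfs:subClassOf ",
                   obo_term(mondo[parent_idx[i]]))
      emit(mondo[i], "biolink:subclass_of", mondo[parent_idx[i]], "diseaseont")
    }
    if (has_doid[i]) {
      st <- paste0(st, sprintf(' ;\n    oboInOwl:hasDbXref "%s"', doid[i]))
      emit(mondo[i], "biolink:same_as", doid[i], "diseaseont",
           symmetric = TRUE)
    }
    ttl <- c(ttl, paste0(st, " ."))
    if (has_doid[i])
      ttl <- c(ttl, paste0(obo_term(doid[i]), " a owl:Class ."))
  }
  writeLines(ttl, file.path(dir, "diseaseont.ttl"), useBytes = TRUE)
  ont_ids <- c(mondo, doid[has_doid])

  # --- TSV triple source: xrefs, treats, gene-disease associations --------
  pub_counter <- 0L
  next_pub <- function() {
    pub_counter <<- pub_counter + 1L
    sprintf("PMID:%d", 10000L + pub_counter)
  }
  tsv_rows <- list()
  tsv_add <- function(s, r, o, pubs = "") {
    tsv_rows[[length(tsv_rows) + 1L]] <<- c(s, r, o, pubs)
  }
  for (i in which(has_mesh))
    { tsv_add(mondo[i], "xref_to", mesh[i])
      emit(mondo[i], "biolink:same_as", mesh[i], "semtriples",
           symmetric = TRUE) }
  for (j in which(has_chebi))
    { tsv_add(drugbank[j], "xref_to", chebi[j])
      emit(drugbank[j], "biolink:same_as", chebi[j], "semtriples",
           symmetric = TRUE) }
  for (k in which(has_uniprot))
    { tsv_add(ncbigene[k], "xref_to", uniprot[k])
      emit(ncbigene[k], "biolink:same_as", uniprot[k], "semtriples",
           symmetric = TRUE) }

  treats_disease <- sample.int(n_dis, n_drug, replace = TRUE)
  treats_target_id <- character(n_drug)   # the member id the TSV row names
  for (j in seq_len(n_drug)) {
    member <- pick_member(cliques[[treats_disease[j]]])
    treats_target_id[j] <- member
    pubs <- if (stats::runif(1) < p$publication_rate) next_pub() else ""
    if (stats::runif(1) < 0.3) {
      tsv_add(member, "condition_treated_by", drugbank[j], pubs)
      emit(member, "biolink:treated_by", drugbank[j], "semtriples",
           inverse_to = "biolink:treats")
    } else {
      tsv_add(drugbank[j], "treats_condition", member, pubs)
      emit(drugbank[j], "biolink:treats", member, "semtriples")
    }
  }
  assoc_disease <- sample.int(n_dis, n_gene, replace = TRUE)
  for (k in seq_len(n_gene)) {
    member <- pick_member(cliques[[assoc_disease[k]]])
    pubs <- if (stats::runif(1) < p$publication_rate) next_pub() else ""
    tsv_add(ncbigene[k], "gene_associated_with", member, pubs)
    emit(ncbigene[k], "biolink:associated_with", member, "semtriples")
  }
  tsv_mat <- do.call(rbind, tsv_rows)
  tsv_lines <- c("subject\trelation\tobject\tpublications",
                 apply(tsv_mat, 1, paste, collapse = "\t"))
  writeLines(tsv_lines, file.path(dir, "semtriples.tsv"), useBytes = TRUE)
  tsv_ids <- unique(c(tsv_mat[, 1], tsv_mat[, 3]))

  # --- record source (XML, drug-database style) ---------------------------
  n_duplicates <- 0L; n_danglers <- 0L
  rec_ids <- character(0)
  if (has_record) {
    is_dup <- stats::runif(n_drug) < p$duplicate_rate
    is_dangler <- stats::runif(n_drug) < p$dangler_rate
    target_gene <- sample.int(n_gene, n_drug, replace = TRUE)
    recs <- c("<records>")
    for (j in seq_len(n_drug)) {
      links <- character(0)
      gene_member <- pick_member(cliques[[n_dis + n_drug + target_gene[j]]])
      links <- c(links, sprintf('    <link relation="targets" target="%s"/>',
                                gene_member))
      emit(drugbank[j], "biolink:affects", gene_member, "drugrecs")
      if (is_dup[j]) {
        links <- c(links, sprintf('    <link relation="treats" target="%s"/>',
                                  treats_target_id[j]))
        emit(drugbank[j], "biolink:treats", treats_target_id[j], "drugrecs")
        n_duplicates <- n_duplicates + 1L
      }
      if (is_dangler[j]) {
        phantom <- sprintf("UniProtKB:Q%05d", j)
        links <- c(links, sprintf('    <link relation="targets" target="%s"/>',
                                  phantom))
        emit(drugbank[j], "biolink:affects", phantom, "drugrecs",
             dangling = TRUE)
        n_danglers <- n_danglers + 1L
      }
      recs <- c(recs,
                "  <record>",
                sprintf("    <id>%s</id>", dbid[j]),
                sprintf("    <name>Drug %d</name>", j),
                "    <category>drug</category>",
                links,
                "  </record>")
    }
    recs <- c(recs, "</records>")
    writeLines(recs, file.path(dir, "drugrecs.xml"), useBytes = TRUE)
    rec_ids <- drugbank
  }

  # --- model + config -----------------------------------------------------
  file.copy(system.file("extdata", "model_mini.yaml", package = "kgbuildr"),
            file.path(dir, "model.yaml"), overwrite = TRUE)
  writeLines(suite_config_yaml(has_record), file.path(dir, "config.yaml"),
             useBytes = TRUE)

  # --- manifest from bookkeeping ------------------------------------------
  em <- do.call(rbind, emitted)
  source_ids <- paste0("KGSOURCE:",
                       c("diseaseont", "semtriples",
                         if (has_record) "drugrecs"))
  declared <- unique(c(ont_ids, tsv_ids, rec_ids, source_ids))
  kept <- em[!em$dangling, , drop = FALSE]
  keys <- paste(kept$subject, kept$object, kept$predicate, sep = "\r")
  eq_pred <- kept$predicate == "biolink:same_as"
  block_key <- paste(block_of[kept$subject], block_of[kept$object],
                     kept$predicate, sep = "\r")[!eq_pred]

  manifest <- list(
    seed = seed,
    params = p,
    true_cliques = unname(lapply(cliques[lengths(cliques) > 1L], sort_c)),
    expected_node_count_pre = length(declared),
    expected_edge_count_pre = length(unique(keys)),
    expected_canonical_count = length(cliques) + length(source_ids),
    expected_canonical_edge_count = length(unique(block_key)),
    planted_duplicates = nrow(kept) - length(unique(keys)),
    planted_danglers = n_danglers)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "manifest.json"), useBytes = TRUE)
  class(manifest) <- "suite_manifest"
  manifest
}

suite_config_yaml <- function(has_record) {
  c("model: model.yaml",
    "iri_map:",
    "  MONDO: 'http://purl.obolibrary.org/obo/MONDO_'",
    "  DOID: 'http://purl.obolibrary.org/obo/DOID_'",
    "  MESH: 'http://id.nlm.nih.gov/mesh/'",
    "  CHEBI: 'http://purl.obolibrary.org/obo/CHEBI_'",
    "  DRUGBANK: 'https://go.drugbank.com/drugs/'",
    "  NCBIGene: 'http://www.ncbi.nlm.nih.gov/gene/'",
    "  UniProtKB: 'http://www.uniprot.org/uniprot/'",
    "  PMID: 'http://www.ncbi.nlm.nih.gov/pubmed/'",
    "  KGSOURCE: 'urn:kgsource:'",
    "sources:",
    "  - name: diseaseont",
    "    version: '2026-01'",
    "    path: diseaseont.ttl",
    "    format: ontology_ttl",
    "    rank: 1",
    "    default_category: biolink:Disease",
    "  - name: semtriples",
    "    version: '5.1'",
    "    path: semtriples.tsv",
    "    format: triple_tsv",
    "    rank: 2",
    "    category_map:",
    "      MESH: biolink:Disease",
    "      CHEBI: biolink:SmallMolecule",
    "      DRUGBANK: biolink:Drug",
    "      NCBIGene: biolink:Gene",
    "      UniProtKB: biolink:Protein",
    if (has_record) c(
    "  - name: drugrecs",
    "    version: '9.4'",
    "    path: drugrecs.xml",
    "    format: record_xml",
    "    rank: 3",
    "    prefix_rules:",
    "      '^DB[0-9]+$': DRUGBANK",
    "    category_map:",
    "      drug: biolink:Drug"))
}

#' @export
print.suite_manifest <- function(x, ...) {
  cat(sprintf(paste0("<suite_manifest> seed %d: %d pre nodes, %d pre edges, ",
                     "%d canonical nodes, %d cliques, %d duplicates, ",
                     "%d danglers\n"),
              x$seed, x$expected_node_count_pre, x$expected_edge_count_pre,
              x$expected_canonical_count, length(x$true_cliques),
              x$planted_duplicates, x$planted_danglers))
  invisible(x)
}

#' Generate a configuration-model graph with a power-law degree sequence
#'
#' Draws a degree sequence from the discrete power law `p(k) ~ k^-exponent`
#' (`k >= 1`, truncated at `n`) by inverse-CDF sampling, forces the total
#' degree even by incrementing one node, and realizes edges by
#' configuration-model stub matching. Multi-edges and self-loops are kept
#' (the pre-canonicalized graph is a multigraph by construction before
#' coalescing), so the realized total-degree sequence equals the drawn one
#' exactly and the handshake identity holds by construction.
#'
#' @param n Node count (>= 100).
#' @param exponent Target power-law exponent (> 1).
#' @param seed Integer seed.
#' @return A [graph_document()] whose nodes are `SF:<i>` and whose edges all
#'   carry the root predicate.
#' @export
generate_scale_free_graph <- function(n, exponent, seed = 1L) {
  if (n < 100L)
    kg_stop("kg_parameter_error", "need n >= 100 (got %d)", n)
  if (!is.finite(exponent) || exponent <= 1)
    kg_stop("kg_parameter_error", "exponent must exceed 1 (got %s)",
            format(exponent))
  set.seed(seed)
  kmax <- n
  pk <- (seq_len(kmax))^(-exponent)
  cdf <- cumsum(pk) / sum(pk)
  deg <- findInterval(stats::runif(n), cdf) + 1L
  if (sum(deg) %% 2L == 1L) deg[1L] <- deg[1L] + 1L
  stubs <- rep.int(seq_len(n), deg)
  stubs <- stubs[sample.int(length(stubs))]
  half <- length(stubs) / 2L
  a <- stubs[seq_len(half) * 2L - 1L]
  b <- stubs[seq_len(half) * 2L]
  label <- sprintf("SF:%07d", seq_len(n))
  nodes <- data.frame(id = label, name = "", category = "biolink:NamedThing",
                      iri = "", description = "",
                      provided_by = "KGSOURCE:synthetic", publications = "",
                      stringsAsFactors = FALSE)
  edges <- data.frame(subject = label[a], predicate = "biolink:related_to",
                      object = label[b], relation = "related_to",
                      provided_by = "KGSOURCE:synthetic", publications = "",
                      stringsAsFactors = FALSE)
  graph_document(nodes, edges,
                 build_info = list(stage = "synthetic_scale_free",
                                   seed = seed, exponent = exponent))
}
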