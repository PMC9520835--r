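# Per-format ETL: raw knowledge-source files -> graph documents in the
# standard schema. Each source is described by a source config entry in the
# build configuration; sources are loaded in the order given by their rank,
# with rank precedence applied later at merge time (lower rank = loaded
# earlier = higher precedence for category assignment).

#' Create a source configuration
#'
#' @param name Unique source name (also the relation-map namespace unless
#'   `relation_namespace` is given).
#' @param version Source version string, embedded in the source node's name.
#' @param path Path to the source file.
#' @param format One of `"ontology_ttl"`, `"ontology_rdfxml"`,
#'   `"triple_tsv"`, `"record_xml"`, `"record_json"`.
#' @param rank Integer precedence; lower = loaded earlier, higher precedence.
#' @param prefix_rules Named list mapping a regular expression (matched
#'   against bare, colon-less identifiers) to the CURIE prefix used to repair
#'   them, e.g. `list("^CHEMBL[0-9]+$" = "CHEMBL.COMPOUND")`.
#' @param relation_namespace Source name used in relation-map lookups.
#' @param category_map Named list mapping either CURIE prefixes (triple/
#'   ontology sources) or record category hints (record sources) to model
#'   categories.
#' @param default_category Category assigned when `category_map` has no entry;
#'   defaults to the model's root category at ingest time.
#' @param equivalence_predicate Predicate used for ontology cross-references
#'   (default `biolink:same_as`); configurable per source because xrefs are
#'   not always equivalence-grade.
#' @return A `source_config` object.
#' @export
source_config <- function(name, version, path, format, rank,
                          prefix_rules = list(),
                          relation_namespace = name,
                          category_map = list(),
                          default_category = NULL,
                          equivalence_predicate = "biolink:same_as") {
  format <- match.arg(format, c("ontology_ttl", "ontology_rdfxml",
                                "triple_tsv", "record_xml", "record_json"))
  structure(list(name = name, version = version, path = path, format = format,
                 rank = as.integer(rank), prefix_rules = prefix_rules,
                 relation_namespace = relation_namespace,
                 category_map = category_map,
                 default_category = default_category,
                 equivalence_predicate = equivalence_predicate),
            class = "source_config")
}

#' Read a build configuration
#'
#' The build configuration is a YAML document with keys `model` (path to the
#' semantic-model document), `iri_map` (CURIE prefix -> IRI base, used both to
#' expand node ids to IRIs and to compress ontology IRIs to CURIEs) and
#' `sources` (list of [source_config()] entries in rank order). Ranks and
#' names must be unique.
#'
#' @param path Path to the build config YAML.
#' @return List with elements `model_path`, `iri_map`, `sources`.
#' @export
read_build_config <- function(path) {
  doc <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  sources <- lapply(doc$sources, function(s) {
    source_config(name = s$name, version = as.character(s$version),
                  path = resolve(s$path), format = s$format, rank = s$rank,
                  prefix_rules = s$prefix_rules %||% list(),
                  relation_namespace = s$relation_namespace %||% s$name,
                  category_map = s$category_map %||% list(),
                  default_category = s$default_category,
                  equivalence_predicate =
                    s$equivalence_predicate %||% "biolink:same_as")
  })
  ranks <- vapply(sources, function(s) s$rank, integer(1))
  names_ <- vapply(sources, function(s) s$name, character(1))
  if (anyDuplicated(ranks))
    kg_stop("kg_config_error", "duplicate source ranks: %s",
            paste(ranks[duplicated(ranks)], collapse = ", "))
  if (anyDuplicated(names_))
    kg_stop("kg_config_error", "duplicate source names: %s",
            paste(names_[duplicated(names_)], collapse = ", "))
  sources <- sources[order(ranks)]
  list(model_path = if (!is.null(doc$model)) resolve(doc$model) else NULL,
       iri_map = doc$iri_map %||% list(),
       sources = sources)
}

# IRI handling ---------------------------------------------------------------

expand_iri <- function(ids, iri_map) {
  if (!length(iri_map)) return(rep("", length(ids)))
  pfx <- curie_prefix(ids)
  base <- unlist(iri_map)[pfx]
  ifelse(is.na(base), "", paste0(base, sub("^[^:]*:", "", ids)))
}

# Compress an IRI to a CURIE using the longest matching IRI base.
compress_iri <- function(iris, iri_map) {
  bases <- unlist(iri_map)
  ord <- order(nchar(bases), decreasing = TRUE)
  bases <- bases[ord]
  out <- rep(NA_character_, length(iris))
  for (i in seq_along(bases)) {
    hit <- is.na(out) & startsWith(iris, bases[[i]])
    out[hit] <- paste0(names(bases)[i], ":",
                       substring(iris[hit], nchar(bases[[i]]) + 1L))
  }
  if (anyNA(out))
    kg_stop("kg_unmapped_prefix_error",
            "IRI with no configured CURIE prefix: %s",
            iris[which(is.na(out))[1]])
  out
}

# Bare-identifier repair: ids without a ":" are matched against the source's
# prefix rules; the first matching rule supplies the prefix. Returns NA for
# irreparable ids (caller logs and skips).
repair_ids <- function(ids, prefix_rules) {
  bare <- !grepl(":", ids, fixed = TRUE)
  if (!any(bare)) return(ids)
  out <- ids
  fixed <- rep(FALSE, length(ids))
  for (pat in names(prefix_rules)) {
    hit <- bare & !fixed & grepl(pat, ids)
    out[hit] <- paste0(prefix_rules[[pat]], ":", ids[hit])
    fixed <- fixed | hit
  }
  out[bare & !fixed] <- NA_character_
  out
}

# Source nodes ---------------------------------------------------------------

#' Build the retrieval-source node for a source
#'
#' Every source contributes one node representing the source database itself;
#' its `name` embeds the source version (template `"<name> v<version>"`), so
#' builds are versionable by inspecting the graph alone. The node id is the
#' stable CURIE `KGSOURCE:<name>`. Every node and edge ingested from the
#' source lists this id in `provided_by`.
#'
#' @param src A [source_config()].
#' @param category Model category for source nodes.
#' @return One-row node data frame.
#' @export
build_source_node <- function(src, category = "biolink:InformationContentEntity") {
  data.frame(id = paste0("KGSOURCE:", src$name),
             name = paste0(src$name, " v", src$version),
             category = category, iri = "", description = "",
             provided_by = paste0("KGSOURCE:", src$name),
             publications = "", stringsAsFactors = FALSE)
}

# Category assignment for a vector of CURIEs: per-prefix category map, then
# per-source default, then model root.
assign_categories <- function(ids, src, model) {
  out <- rep(src$default_category %||% model$categories$root, length(ids))
  cm <- src$category_map
  if (length(cm)) {
    pfx <- curie_prefix(ids)
    hit <- pfx %in% names(cm)
    out[hit] <- unlist(cm)[pfx[hit]]
  }
  out
}

# Dispatcher -----------------------------------------------------------------

#' Ingest one source into a graph document
#'
#' Dispatches on the source's `format` to [ingest_ontology()],
#' [ingest_tsv_triples()] or [ingest_records()]. The returned document always
#' contains the source node (see [build_source_node()]); every node and edge
#' carries the source node id in `provided_by`; all edges are oriented with
#' [orient_assertion()] semantics. A per-stage log data frame is attached as
#' attribute `"log"` (skipped rows, unmapped relations, ignored axioms).
#'
#' @param src A [source_config()].
#' @param model A [load_model()] result.
#' @param iri_map Named list prefix -> IRI base (from the build config).
#' @return A [graph_document()].
#' @export
ingest_source <- function(src, model, iri_map = list()) {
  switch(src$format,
         ontology_ttl = ,
         ontology_rdfxml = ingest_ontology(src, model, iri_map),
         triple_tsv = ingest_tsv_triples(src, model, iri_map),
         record_xml = ,
         record_json = ingest_records(src, model, iri_map))
}

finish_ingest <- function(src, model, nodes, edges, log, iri_map) {
  source_id <- paste0("KGSOURCE:", src$name)
  if (nrow(nodes)) {
    nodes$iri <- expand_iri(nodes$id, iri_map)
    nodes$provided_by <- source_id
  }
  if (nrow(edges)) {
    edges$provided_by <- source_id
    edges <- orient_edges(model, edges)
  }
  nodes <- rbind(nodes, build_source_node(src))
  g <- graph_document(nodes, edges,
                      build_info = list(stage = paste0("ingest:", src$name),
                                        source_name = src$name,
                                        source_rank = src$rank,
                                        source_versions =
                                          stats::setNames(list(src$version),
                                                          src$name)))
  attr(g, "log") <- log
  g
}

# Ontology ingestion ---------------------------------------------------------

#' Ingest an ontology source (constrained TTL or RDF/XML subset)
#'
#' Interprets only the constructs the build consumes: class declarations,
#' `rdfs:label`, `rdfs:subClassOf` (preserved as `biolink:subclass_of` edges
#' rather than flattened) and cross-reference annotations
#' (`oboInOwl:hasDbXref`), which become equivalence edges using the source's
#' configured equivalence predicate (default `biolink:same_as`) so that
#' synonymy lives on edges for the partition stage. All other axioms are
#' ignored and counted in the attached log. Class IRIs are compressed to
#' CURIEs via the build config's `iri_map`; an IRI with no configured prefix
#' is an error.
#'
#' @inheritParams ingest_source
#' @return A [graph_document()].
#' @export
ingest_ontology <- function(src, model, iri_map = list()) {
  parsed <- if (src$format == "ontology_ttl")
    parse_ttl_subset(src$path) else parse_rdfxml_subset(src$path)
  log <- kg_log_df()
  if (parsed$n_ignored)
    log <- kg_log_add(log, "ignored_axioms", as.character(parsed$n_ignored))

  cls <- parsed$classes  # data.frame: iri, label
  ids <- if (nrow(cls)) compress_iri(cls$iri, iri_map) else character(0)
  nodes <- if (length(ids)) data.frame(
    id = ids, name = cls$label,
    category = assign_categories(ids, src, model),
    iri = "", description = "", provided_by = "", publications = "",
    stringsAsFactors = FALSE) else empty_nodes()

  sub <- parsed$subclass  # data.frame: child_iri, parent_iri
  sub_edges <- if (nrow(sub)) data.frame(
    subject = compress_iri(sub$child_iri, iri_map),
    predicate = "biolink:subclass_of",
    object = compress_iri(sub$parent_iri, iri_map),
    relation = "rdfs:subClassOf", provided_by = "", publications = "",
    stringsAsFactors = FALSE) else empty_edges()

  xr <- parsed$xref  # data.frame: iri, target_curie
  xref_edges <- if (nrow(xr)) data.frame(
    subject = compress_iri(xr$iri, iri_map),
    predicate = src$equivalence_predicate,
    object = xr$target_curie,
    relation = "oboInOwl:hasDbXref", provided_by = "", publications = "",
    stringsAsFactors = FALSE) else empty_edges()

  finish_ingest(src, model, nodes, rbind(sub_edges, xref_edges), log, iri_map)
}

# Constrained Turtle reader. Accepted statements:
#   @prefix p: <iri> .
#   p:Class a owl:Class ; rdfs:label "..." ;
#       rdfs:subClassOf p:Other ; oboInOwl:hasDbXref "CURIE" .
# Comments (#...) and blank lines are skipped; other predicates within a
# statement are counted as ignored.
parse_ttl_subset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("^\\s*#.*$", "", lines)
  prefix_lines <- grep("^\\s*@prefix\\s", lines, value = TRUE)
  prefixes <- list()
  for (pl in prefix_lines) {
    m <- regmatches(pl, regexec("@prefix\\s+([A-Za-z0-9._-]*):\\s*<([^>]*)>", pl))[[1]]
    if (length(m) == 3) prefixes[[m[2]]] <- m[3]
  }
  body <- paste(lines[!grepl("^\\s*@prefix\\s", lines)], collapse = "\n")
  # statements end with "." at end of line
  statements <- strsplit(body, "\\s\\.\\s*(\n|$)")[[1]]
  statements <- statements[nzchar(trimws(statements))]

  expand_term <- function(tok) {
    tok <- trimws(tok)
    if (startsWith(tok, "<")) return(sub("^<([^>]*)>$", "\\1", tok))
    m <- regmatches(tok, regexec("^([A-Za-z0-9._-]*):(.*)$", tok))[[1]]
    if (length(m) == 3 && !is.null(prefixes[[m[2]]]))
      return(paste0(prefixes[[m[2]]], m[3]))
    tok
  }
  unquote <- function(tok) sub('^"(.*)"$', "\\1", trimws(tok))

  classes <- list(); subclass <- list(); xref <- list(); n_ignored <- 0L
  for (st in statements) {
    st <- trimws(gsub("\n", " ", st))
    m <- regmatches(st, regexec("^(\\S+)\\s+(.*)$", st))[[1]]
    if (length(m) != 3) {
      kg_stop("kg_parse_error", "unparseable TTL statement: '%s'",
              substr(st, 1, 60))
    }
    subj_iri <- expand_term(m[2])
    po_parts <- strsplit(m[3], "\\s*;\\s*")[[1]]
    is_class <- FALSE; label <- ""
    for (po in po_parts) {
      pm <- regmatches(po, regexec("^(\\S+)\\s+(.*)$", trimws(po)))[[1]]
      if (length(pm) != 3)
        kg_stop("kg_parse_error", "unparseable TTL predicate-object: '%s'", po)
      pred <- pm[2]; obj <- pm[3]
      if (pred == "a" && grepl("owl:Class|Class>$", obj)) {
        is_class <- TRUE
      } else if (pred %in% c("rdfs:label")) {
        label <- unquote(obj)
      } else if (pred %in% c("rdfs:subClassOf")) {
        subclass[[length(subclass) + 1L]] <-
          c(child = subj_iri, parent = expand_term(obj))
      } else if (grepl("hasDbXref$", pred)) {
        xref[[length(xref) + 1L]] <- c(iri = subj_iri, target = unquote(obj))
      } else {
        n_ignored <- n_ignored + 1L
      }
    }
    if (is_class)
      classes[[length(classes) + 1L]] <- c(iri = subj_iri, label = label)
  }
  shape_ontology(classes, subclass, xref, n_ignored)
}

parse_rdfxml_subset <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    kg_stop("kg_parse_error", "unparseable RDF/XML (%s): %s",
                            path, conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  cls_nodes <- xml2::xml_find_all(doc, ".//owl:Class", ns)
  classes <- list(); subclass <- list(); xref <- list(); n_ignored <- 0L
  for (cn in cls_nodes) {
    iri <- xml2::xml_attr(cn, "about")
    if (is.na(iri)) next
    label <- xml2::xml_text(xml2::xml_find_first(cn, "./rdfs:label", ns))
    classes[[length(classes) + 1L]] <-
      c(iri = iri, label = if (is.na(label)) "" else label)
    for (ch in xml2::xml_children(cn)) {
      nm <- xml2::xml_name(ch)
      if (nm == "subClassOf") {
        parent <- xml2::xml_attr(ch, "resource")
        if (!is.na(parent))
          subclass[[length(subclass) + 1L]] <- c(child = iri, parent = parent)
      } else if (nm == "hasDbXref") {
        xref[[length(xref) + 1L]] <- c(iri = iri, target = xml2::xml_text(ch))
      } else if (nm != "label") {
        n_ignored <- n_ignored + 1L
      }
    }
  }
  shape_ontology(classes, subclass, xref, n_ignored)
}

shape_ontology <- function(classes, subclass, xref, n_ignored) {
  to_df <- function(lst, cols) {
    if (!length(lst))
      return(as.data.frame(stats::setNames(rep(list(character(0)),
                                               length(cols)), cols),
                           stringsAsFactors = FALSE))
    m <- do.call(rbind, lst)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    stats::setNames(df, cols)
  }
  list(classes = to_df(classes, c("iri", "label")),
       subclass = to_df(subclass, c("child_iri", "parent_iri")),
       xref = to_df(xref, c("iri", "target_curie")),
       n_ignored = n_ignored)
}

# Triple TSV ingestion -------------------------------------------------------

#' Ingest a triple TSV source
#'
#' Expects a header row with columns `subject`, `relation`, `object` and
#' optionally `publications` ("|"-separated publication CURIEs). Bare ids are
#' repaired via the source's prefix rules; rows with a wrong column count or
#' an irreparable bare id are logged and skipped (never fatal). Relations are
#' normalized through the relation map (unmapped relations fall back to the
#' predicate-tree root, counted in the log) with the original phrasing kept
#' in `relation`; edges are oriented; a node is materialized for every
#' mentioned identifier with its category assigned from the source's
#' per-prefix category map.
#'
#' @inheritParams ingest_source
#' @return A [graph_document()].
#' @export
ingest_tsv_triples <- function(src, model, iri_map = list()) {
  lines <- readLines(src$path, encoding = "UTF-8", warn = FALSE)
  log <- kg_log_df()
  if (!length(lines))
    kg_stop("kg_parse_error", "empty TSV file (no header): %s", src$path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("subject", "relation", "object")
  if (!all(need %in% header))
    kg_stop("kg_parse_error", "TSV header must contain %s; found: %s",
            paste(need, collapse = ", "), paste(header, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  # sentinel keeps trailing empty fields that strsplit would drop
  parts <- strsplit(paste0(body, "\x01"), "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) {
    p[length(p)] <- sub("\x01$", "", p[length(p)])
    p
  })
  nc <- lengths(parts)
  bad_rows <- nc != length(header)
  if (any(bad_rows))
    log <- kg_log_add(log, "rows_skipped_bad_columns",
                      as.character(sum(bad_rows)))
  parts <- parts[!bad_rows]

  get_col <- function(col) {
    j <- match(col, header)
    vapply(parts, function(p) p[j], character(1))
  }
  subject <- if (length(parts)) get_col("subject") else character(0)
  relation <- if (length(parts)) get_col("relation") else character(0)
  object <- if (length(parts)) get_col("object") else character(0)
  pubs <- if ("publications" %in% header && length(parts))
    get_col("publications") else character(length(subject))
  pubs[is.na(pubs)] <- ""

  subject <- repair_ids(subject, src$prefix_rules)
  object <- repair_ids(object, src$prefix_rules)
  irrep <- is.na(subject) | is.na(object)
  if (any(irrep))
    log <- kg_log_add(log, "rows_skipped_bare_id", as.character(sum(irrep)))
  subject <- subject[!irrep]; relation <- relation[!irrep]
  object <- object[!irrep]; pubs <- pubs[!irrep]

  mapped <- map_relations(model, src$relation_namespace, relation)
  if (mapped$n_unmapped)
    log <- kg_log_add(log, "relations_unmapped",
                      as.character(mapped$n_unmapped))
  edges <- if (length(subject)) data.frame(
    subject = subject, predicate = mapped$predicate, object = object,
    relation = relation, provided_by = "", publications = pubs,
    stringsAsFactors = FALSE) else empty_edges()
  ids <- unique(c(subject, object))
  nodes <- if (length(ids)) data.frame(
    id = ids, name = "", category = assign_categories(ids, src, model),
    iri = "", description = "", provided_by = "", publications = "",
    stringsAsFactors = FALSE) else empty_nodes()
  finish_ingest(src, model, nodes, edges, log, iri_map)
}

# Record ingestion -----------------------------------------------------------

#' Ingest a record-oriented source (XML or JSON)
#'
#' Each record carries an id, a name, a category hint and typed links to
#' other identifiers. One concept node is materialized per record (link
#' targets are *not* materialized; links to identifiers that no source
#' declares become dangling edges and are screened at merge); one assertion
#' per link, relation-mapped through the source's relation namespace and
#' oriented. Category hints are mapped through the source's `category_map`;
#' unknown hints fall back to the model root with a logged warning. Records
#' without an id are logged and skipped; duplicate record ids are merged into
#' the first occurrence (name kept, links unioned) and logged.
#'
#' JSON layout: a top-level array of objects
#' `{id, name, category, links: [{relation, target, publications?}]}`.
#' XML layout: `<records><record><id/><name/><category/>
#' <link relation="..." target="..." publications="..."/></record></records>`.
#'
#' @inheritParams ingest_source
#' @return A [graph_document()].
#' @export
ingest_records <- function(src, model, iri_map = list()) {
  records <- if (src$format == "record_json") {
    jsonlite::fromJSON(src$path, simplifyVector = FALSE)
  } else {
    doc <- tryCatch(xml2::read_xml(src$path),
                    error = function(e)
                      kg_stop("kg_parse_error", "unparseable XML (%s): %s",
                              src$path, conditionMessage(e)))
    lapply(xml2::xml_find_all(doc, ".//record"), function(rec) {
      links <- lapply(xml2::xml_find_all(rec, "./link"), function(lk) {
        list(relation = xml2::xml_attr(lk, "relation"),
             target = xml2::xml_attr(lk, "target"),
             publications = xml2::xml_attr(lk, "publications"))
      })
      txt <- function(xp) {
        n <- xml2::xml_find_first(rec, xp)
        if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
      }
      list(id = txt("./id"), name = txt("./name"),
           category = txt("./category"), links = links)
    })
  }

  log <- kg_log_df()
  no_id <- vapply(records, function(r) is.null(r$id) || !nzchar(r$id),
                  logical(1))
  if (any(no_id))
    log <- kg_log_add(log, "records_skipped_no_id", as.character(sum(no_id)))
  records <- records[!no_id]

  ids <- vapply(records, function(r) as.character(r$id), character(1))
  ids <- repair_ids(ids, src$prefix_rules)
  irrep <- is.na(ids)
  if (any(irrep))
    log <- kg_log_add(log, "records_skipped_bare_id",
                      as.character(sum(irrep)))
  records <- records[!irrep]; ids <- ids[!irrep]

  dup <- duplicated(ids)
  if (any(dup)) {
    log <- kg_log_add(log, "records_merged_duplicate_id",
                      as.character(sum(dup)))
    # fold duplicate records' links into the first occurrence
    for (i in which(dup)) {
      first <- match(ids[i], ids)
      records[[first]]$links <- c(records[[first]]$links, records[[i]]$links)
    }
    records <- records[!dup]; ids <- ids[!dup]
  }

  hints <- vapply(records, function(r) as.character(r$category %||% ""),
                  character(1))
  cats <- character(length(hints))
  known <- hints %in% names(src$category_map)
  cats[known] <- unlist(src$category_map)[hints[known]]
  if (any(!known)) {
    cats[!known] <- model$categories$root
    log <- kg_log_add(log, "records_category_fallback",
                      as.character(sum(!known)))
  }
  nodes <- data.frame(
    id = ids,
    name = vapply(records, function(r) as.character(r$name %||% ""),
                  character(1)),
    category = cats, iri = "", description = "", provided_by = "",
    publications = "", stringsAsFactors = FALSE)

  edge_rows <- list()
  skipped_links <- 0L
  for (i in seq_along(records)) {
    for (lk in records[[i]]$links) {
      target <- repair_ids(as.character(lk$target), src$prefix_rules)
      if (is.na(target)) { skipped_links <- skipped_links + 1L; next }
      pubs <- lk$publications
      pubs <- if (is.null(pubs) || is.na(pubs)) "" else as.character(pubs)
      edge_rows[[length(edge_rows) + 1L]] <-
        data.frame(subject = ids[i], relation = as.character(lk$relation),
                   object = target, publications = pubs,
                   stringsAsFactors = FALSE)
    }
  }
  if (skipped_links)
    log <- kg_log_add(log, "links_skipped_bare_id",
                      as.character(skipped_links))
  edges <- if (length(edge_rows)) {
    e <- do.call(rbind, edge_rows)
    mapped <- map_relations(model, src$relation_namespace, e$relation)
    if (mapped$n_unmapped)
      log <- kg_log_add(log, "relations_unmapped",
                        as.character(mapped$n_unmapped))
    data.frame(subject = e$subject, predicate = mapped$predicate,
               object = e$object, relation = e$relation, provided_by = "",
               publications = e$publications, stringsAsFactors = FALSE)
  } else empty_edges()

  finish_ingest(src, model, nodes, edges, log, iri_map)
}
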