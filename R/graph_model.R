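# Core graph data types and their serializations.
#
# A graph document is the unit of exchange between all pipeline stages: a list
# with elements `nodes` (data frame), `edges` (data frame) and `build_info`
# (list). Multivalued fields are stored as "|"-joined strings (see utils.R).
#
# Node columns:  id, name, category, iri, description, provided_by, publications
#   (canonicalized graphs additionally: all_categories, equivalent_identifiers,
#    all_names)
# Edge columns:  subject, predicate, object, relation, provided_by, publications

NODE_COLS <- c("id", "name", "category", "iri", "description",
               "provided_by", "publications")
CANON_EXTRA_COLS <- c("all_categories", "equivalent_identifiers", "all_names")
EDGE_COLS <- c("subject", "predicate", "object", "relation",
               "provided_by", "publications")

#' Parse a compact URI (CURIE)
#'
#' Splits an identifier such as `"DOID:14330"` on its first `":"` into a
#' prefix (the identifier namespace, e.g. `DOID`) and a local id. Identifiers
#' lacking a namespace separator (such as a bare `CHEMBL112`) are rejected:
#' bare ids must be repaired to full CURIEs by the ingesting ETL module via a
#' per-source prefix rule, so that all downstream identifier handling is
#' uniform.
#'
#' @param text A single identifier string.
#' @return An object of class `curie`: a list with elements `prefix` and
#'   `local_id`. `format()`/`print()` render the `prefix:local_id` form.
#' @examples
#' parse_curie("DOID:14330")
#' parse_curie("UMLS:C0000970")$prefix
#' @export
parse_curie <- function(text) {
  if (length(text) != 1L || !is.character(text))
    kg_stop("kg_malformed_curie", "expected a single character string")
  i <- regexpr(":", text, fixed = TRUE)
  if (i < 0L)
    kg_stop("kg_malformed_curie",
            "malformed CURIE (no namespace separator): '%s'", text)
  prefix <- substr(text, 1L, i - 1L)
  local <- substr(text, i + 1L, nchar(text))
  if (!nzchar(prefix) || !nzchar(local))
    kg_stop("kg_malformed_curie",
            "malformed CURIE (empty prefix or local part): '%s'", text)
  structure(list(prefix = prefix, local_id = local), class = "curie")
}

#' @export
format.curie <- function(x, ...) paste0(x$prefix, ":", x$local_id)

#' @export
print.curie <- function(x, ...) {
  cat("<curie>", format(x), "\n")
  invisible(x)
}

# Vectorized validity check and prefix extraction (no error).
curie_ok <- function(x) {
  i <- regexpr(":", x, fixed = TRUE)
  i > 1L & i < nchar(x)
}

curie_prefix <- function(x) sub(":.*$", "", x)

#' Construct an empty node / edge table
#'
#' @param canonical For `empty_nodes()`, include the extra columns carried by
#'   canonicalized graphs (`all_categories`, `equivalent_identifiers`,
#'   `all_names`).
#' @return A zero-row data frame with the standard column set.
#' @export
empty_nodes <- function(canonical = FALSE) {
  cols <- if (canonical) c(NODE_COLS, CANON_EXTRA_COLS) else NODE_COLS
  as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                stringsAsFactors = FALSE)
}

#' @rdname empty_nodes
#' @export
empty_edges <- function() {
  as.data.frame(stats::setNames(rep(list(character(0)), length(EDGE_COLS)),
                                EDGE_COLS),
                stringsAsFactors = FALSE)
}

#' Create a graph document
#'
#' The common container passed between pipeline stages: concept nodes, assertion
#' edges, and build metadata. Nodes and edges are plain data frames with
#' "|"-joined multivalued fields; this keeps every stage a data-frame
#' transformation and makes serialized forms diffable.
#'
#' @param nodes Node data frame (see [empty_nodes()] for the column set).
#' @param edges Edge data frame (see [empty_edges()]).
#' @param build_info Named list of build metadata (model version, source
#'   versions, stage name, timestamp).
#' @return An object of class `graph_document`.
#' @export
graph_document <- function(nodes = empty_nodes(), edges = empty_edges(),
                           build_info = list()) {
  missing_n <- setdiff(NODE_COLS, names(nodes))
  if (length(missing_n))
    kg_stop("kg_schema_error", "nodes table lacks column(s): %s",
            paste(missing_n, collapse = ", "))
  missing_e <- setdiff(EDGE_COLS, names(edges))
  if (length(missing_e))
    kg_stop("kg_schema_error", "edges table lacks column(s): %s",
            paste(missing_e, collapse = ", "))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, build_info = build_info),
            class = "graph_document")
}

#' @export
print.graph_document <- function(x, ...) {
  cat(sprintf("<graph_document> %d nodes, %d edges (stage: %s)\n",
              nrow(x$nodes), nrow(x$edges),
              x$build_info$stage %||% "unspecified"))
  invisible(x)
}

is_canonical_graph <- function(graph) {
  all(CANON_EXTRA_COLS %in% names(graph$nodes))
}

# Deterministic row order used by both writers: nodes by id, edges by
# (subject, object, predicate).
sort_graph <- function(graph) {
  if (nrow(graph$nodes))
    graph$nodes <- graph$nodes[order_c(graph$nodes$id), , drop = FALSE]
  if (nrow(graph$edges))
    graph$edges <- graph$edges[order_c(graph$edges$subject, graph$edges$object,
                                       graph$edges$predicate), , drop = FALSE]
  rownames(graph$nodes) <- NULL
  rownames(graph$edges) <- NULL
  graph
}

# JSON serialization ---------------------------------------------------------

# Top-level keys `nodes` and `edges` (plus `build_info`); each node/edge is an
# object whose multivalued fields are arrays. The machine-readable schema is
# shipped at inst/extdata/graph_document_schema.json.

#' Write / read the JSON serialization of a graph document
#'
#' The graph is serialized as a JSON object with keys `nodes` and `edges`
#' (plus `build_info`), each node/edge an object whose multivalued fields
#' (`relation`, `provided_by`, `publications`, and the canonical-node set
#' fields) are arrays. Writing is deterministic: nodes are ordered by id and
#' edges by (subject, object, predicate), so the same graph always yields a
#' byte-identical file. `read_graph_json(write_graph_json(g))` reproduces `g`
#' up to row ordering.
#'
#' @param graph A [graph_document()].
#' @param path File path to write to / read from.
#' @return `write_graph_json()` returns `path` invisibly; `read_graph_json()`
#'   returns a [graph_document()].
#' @export
write_graph_json <- function(graph, path) {
  graph <- sort_graph(graph)
  multi_node <- c("provided_by", "publications", CANON_EXTRA_COLS)
  node_list <- df_to_objects(graph$nodes, multi_node)
  edge_list <- df_to_objects(graph$edges,
                             c("relation", "provided_by", "publications"))
  doc <- list(nodes = node_list, edges = edge_list,
              build_info = graph$build_info)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

df_to_objects <- function(df, multi_cols) {
  n <- nrow(df)
  if (!n) return(list())
  cols <- names(df)
  pre <- lapply(cols, function(cl) {
    if (cl %in% multi_cols) pv_split(df[[cl]]) else df[[cl]]
  })
  names(pre) <- cols
  lapply(seq_len(n), function(i) {
    lapply(pre, function(v) if (is.list(v)) v[[i]] else v[[i]])
  })
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("nodes", "edges", "build_info")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    kg_stop("kg_schema_error", "unknown top-level key(s): %s (at $.%s)",
            paste(extra, collapse = ", "), extra[1])
  for (key in c("nodes", "edges"))
    if (is.null(doc[[key]]))
      kg_stop("kg_schema_error", "missing required key '%s' (at $.%s)",
              key, key)
  canonical <- length(doc$nodes) > 0 &&
    all(CANON_EXTRA_COLS %in% names(doc$nodes[[1]]))
  node_cols <- if (canonical) c(NODE_COLS, CANON_EXTRA_COLS) else NODE_COLS
  nodes <- objects_to_df(doc$nodes, node_cols, "nodes",
                         if (canonical) c("provided_by", "publications",
                                          CANON_EXTRA_COLS)
                         else c("provided_by", "publications"))
  edges <- objects_to_df(doc$edges, EDGE_COLS, "edges",
                         c("relation", "provided_by", "publications"))
  graph_document(nodes, edges, doc$build_info %||% list())
}

objects_to_df <- function(objs, cols, what, multi_cols) {
  n <- length(objs)
  out <- stats::setNames(rep(list(character(n)), length(cols)), cols)
  for (i in seq_len(n)) {
    o <- objs[[i]]
    for (cl in cols) {
      v <- o[[cl]]
      if (is.null(v)) {
        if (cl %in% multi_cols) v <- character(0)
        else kg_stop("kg_schema_error",
                     "missing required field '%s' (at $.%s[%d].%s)",
                     cl, what, i - 1L, cl)
      }
      out[[cl]][i] <- if (cl %in% multi_cols)
        paste(unlist(v), collapse = "|") else as.character(v)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# KGX-style TSV serialization ------------------------------------------------

#' Write / read the two-file KGX-style TSV serialization
#'
#' Emits `nodes.tsv` and `edges.tsv` in `dir` with fixed header order
#' (`nodes`: id, name, category, iri, description, provided_by, publications;
#' `edges`: subject, predicate, object, relation, provided_by, publications;
#' canonicalized graphs append all_categories, equivalent_identifiers and
#' all_names to the node file). Multivalued fields are joined with `"|"`.
#' The dialect uses no quoting: values containing a tab, newline or `"|"`
#' are rejected at write time rather than escaped, which keeps round trips
#' bit-exact and files diffable. Writing is deterministic (same row ordering
#' as the JSON writer).
#'
#' @param graph A [graph_document()].
#' @param dir Directory for the file pair (created if absent).
#' @return `write_kgx_tsv()` returns `dir` invisibly; `read_kgx_tsv()` returns
#'   a [graph_document()].
#' @export
write_kgx_tsv <- function(graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  graph <- sort_graph(graph)
  node_cols <- if (is_canonical_graph(graph)) c(NODE_COLS, CANON_EXTRA_COLS)
               else NODE_COLS
  check_tsv_values(graph$nodes, node_cols, graph$nodes$id, "node")
  check_tsv_values(graph$edges, EDGE_COLS,
                   paste(graph$edges$subject, graph$edges$predicate,
                         graph$edges$object), "edge")
  write_tsv_plain(graph$nodes[, node_cols, drop = FALSE],
                  file.path(dir, "nodes.tsv"))
  write_tsv_plain(graph$edges[, EDGE_COLS, drop = FALSE],
                  file.path(dir, "edges.tsv"))
  invisible(dir)
}

# Forbidden characters inside a single value: tab, newline, and "|" (which is
# reserved as the multivalued-field separator). Multivalued columns are stored
# pre-joined, so for them only tab/newline are checked.
check_tsv_values <- function(df, cols, labels, what) {
  multi <- c("relation", "provided_by", "publications", CANON_EXTRA_COLS)
  for (cl in cols) {
    pat <- if (cl %in% multi) "[\t\n\r]" else "[\t\n\r|]"
    bad <- grepl(pat, df[[cl]])
    if (any(bad)) {
      i <- which(bad)[1]
      kg_stop("kg_serialization_error",
              "forbidden character in %s '%s', field '%s'",
              what, labels[i], cl)
    }
  }
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' @rdname write_kgx_tsv
#' @export
read_kgx_tsv <- function(dir) {
  nodes <- read_tsv_plain(file.path(dir, "nodes.tsv"))
  edges <- read_tsv_plain(file.path(dir, "edges.tsv"))
  missing_n <- setdiff(NODE_COLS, names(nodes))
  if (length(missing_n))
    kg_stop("kg_schema_error", "nodes.tsv lacks column(s): %s",
            paste(missing_n, collapse = ", "))
  graph_document(nodes, edges,
                 build_info = list(stage = "kgx_import"))
}

read_tsv_plain <- function(path) {
  if (!file.exists(path))
    kg_stop("kg_schema_error", "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- stats::setNames(rep(list(character(length(body))), length(header)),
                         header)
  for (i in seq_along(body)) {
    p <- parts[[i]]
    length(p) <- length(header)          # trailing empty fields
    p[is.na(p)] <- ""
    for (j in seq_along(header)) out[[j]][i] <- p[j]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Equality up to row order, used by tests and idempotence checks.
graph_equal <- function(a, b, ignore_build_info = TRUE) {
  a <- sort_graph(a); b <- sort_graph(b)
  cols_a <- sort_c(names(a$nodes)); cols_b <- sort_c(names(b$nodes))
  if (!identical(cols_a, cols_b)) return(FALSE)
  identical(a$nodes[, cols_a, drop = FALSE], b$nodes[, cols_a, drop = FALSE]) &&
    identical(a$edges[, sort_c(names(a$edges)), drop = FALSE],
              b$edges[, sort_c(names(b$edges)), drop = FALSE]) &&
    (ignore_build_info || identical(a$build_info, b$build_info))
}
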