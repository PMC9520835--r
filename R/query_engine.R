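# In-memory one-hop query answering over a canonicalized graph, in the style
# of a TRAPI (Translator Reasoner API) message: a query graph of two
# constrained nodes and one edge is answered with result bindings plus the
# knowledge-graph slice they reference.

#' Index a canonicalized graph for one-hop querying
#'
#' Builds the in-memory structures behind [answer_one_hop()]: node lookup by
#' id *and* by any member of `equivalent_identifiers` (so queries phrased
#' with a non-canonical identifier resolve to the canonical node), and
#' adjacency lists of edge rows per endpoint. Index answers are by
#' construction identical to a linear scan of the underlying graph.
#'
#' @param graph A canonicalized [graph_document()].
#' @param model A [load_model()] result.
#' @return A `graph_index`.
#' @export
index_graph <- function(graph, model) {
  ids <- graph$nodes$id
  if (anyDuplicated(ids))
    kg_stop("kg_index_error", "duplicate node id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  alias <- stats::setNames(ids, ids)
  if ("equivalent_identifiers" %in% names(graph$nodes)) {
    eq <- pv_split(graph$nodes$equivalent_identifiers)
    alias_ids <- unlist(eq, use.names = FALSE)
    alias_canon <- rep(ids, lengths(eq))
    keep <- !alias_ids %in% ids     # canonical ids map to themselves
    alias <- c(alias, stats::setNames(alias_canon[keep], alias_ids[keep]))
  }
  e <- graph$edges
  out_adj <- split(seq_len(nrow(e)), factor(e$subject, levels = ids))
  in_adj <- split(seq_len(nrow(e)), factor(e$object, levels = ids))
  structure(list(graph = graph, model = model, alias = alias,
                 out_adj = out_adj, in_adj = in_adj,
                 edge_key = paste(e$subject, e$predicate, e$object,
                                  sep = "--")),
            class = "graph_index")
}

#' @export
print.graph_index <- function(x, ...) {
  cat(sprintf("<graph_index> %d nodes (%d resolvable identifiers), %d edges\n",
              nrow(x$graph$nodes), length(x$alias), nrow(x$graph$edges)))
  invisible(x)
}

#' Construct a one-hop query graph
#'
#' @param qnodes Named list of qnode constraint lists; each may contain `ids`
#'   (character vector of CURIEs) and/or `categories` (character vector of
#'   category names). Exactly two qnodes, at least one constrained by `ids`.
#' @param qedges Named list with exactly one qedge: a list with `subject` and
#'   `object` (qnode keys) and optionally `predicates`.
#' @return A `query_graph`.
#' @export
query_graph <- function(qnodes, qedges) {
  q <- structure(list(qnodes = qnodes, qedges = qedges),
                 class = "query_graph")
  validate_query(q)
  q
}

validate_query <- function(q) {
  if (length(q$qnodes) != 2L)
    kg_stop("kg_query_validation_error",
            "one-hop query requires exactly 2 qnodes (found %d)",
            length(q$qnodes))
  if (length(q$qedges) != 1L)
    kg_stop("kg_query_validation_error",
            "one-hop query requires exactly 1 qedge (found %d)",
            length(q$qedges))
  qe <- q$qedges[[1]]
  if (is.null(qe$subject) || is.null(qe$object) ||
      !qe$subject %in% names(q$qnodes) || !qe$object %in% names(q$qnodes))
    kg_stop("kg_query_validation_error",
            "qedge endpoints must reference existing qnodes")
  has_ids <- any(vapply(q$qnodes, function(n)
    !is.null(n$ids) && length(n$ids) > 0, logical(1)))
  if (!has_ids)
    kg_stop("kg_query_validation_error",
            "at least one qnode must be constrained by ids")
  invisible(q)
}

#' Answer a one-hop query
#'
#' A graph edge matches the query edge iff (a) its predicate lies in the
#' descendant closure of some listed predicate (any predicate when the
#' constraint is omitted); (b) each endpoint satisfies its qnode — id
#' membership after equivalent-identifier resolution, and/or category in the
#' descendant closure of a listed category (a node's `all_categories` are all
#' eligible); and (c) the edge direction matches the qedge subject-to-object
#' direction, except that edges with a symmetric predicate match in either
#' orientation. Results are deduplicated and deterministically ordered: by
#' descending provenance-source count of the bound edge, then lexicographic
#' binding key.
#'
#' @param index A [index_graph()] result.
#' @param query A [query_graph()].
#' @return A `result_set`: list with `results` (data frame, one column per
#'   qnode/qedge key holding bound node ids / edge keys) and
#'   `knowledge_graph` (a [graph_document()] slice containing exactly the
#'   bound nodes and edges).
#' @export
answer_one_hop <- function(index, query) {
  validate_query(query)
  model <- index$model
  graph <- index$graph
  qe_key <- names(query$qedges)[1]
  qe <- query$qedges[[1]]
  sub_key <- qe$subject; obj_key <- qe$object
  qn_sub <- query$qnodes[[sub_key]]
  qn_obj <- query$qnodes[[obj_key]]

  pred_set <- if (!is.null(qe$predicates) && length(qe$predicates))
    unique(unlist(lapply(qe$predicates, function(p)
      expand_predicate(model, p)))) else NULL
  cat_closure <- function(cats) {
    if (is.null(cats) || !length(cats)) return(NULL)
    unique(unlist(lapply(cats, function(cc) expand_category(model, cc))))
  }
  sub_cats <- cat_closure(qn_sub$categories)
  obj_cats <- cat_closure(qn_obj$categories)
  resolve_ids <- function(qn) {
    if (is.null(qn$ids) || !length(qn$ids)) return(NULL)
    hits <- index$alias[unlist(qn$ids)]
    unique(hits[!is.na(hits)])
  }
  sub_ids <- resolve_ids(qn_sub)
  obj_ids <- resolve_ids(qn_obj)

  node_cats <- if ("all_categories" %in% names(graph$nodes))
    pv_split(graph$nodes$all_categories) else as.list(graph$nodes$category)
  names(node_cats) <- graph$nodes$id
  node_ok <- function(node_id, want_ids, want_cats) {
    (is.null(want_ids) || node_id %in% want_ids) &&
      (is.null(want_cats) || any(node_cats[[node_id]] %in% want_cats))
  }

  # candidate edges: adjacency of an id-constrained qnode, else all edges
  cand <- if (!is.null(sub_ids) || !is.null(obj_ids)) {
    seed <- unique(c(sub_ids, obj_ids))
    unique(unlist(c(index$out_adj[seed], index$in_adj[seed]),
                  use.names = FALSE))
  } else seq_len(nrow(graph$edges))
  cand <- sort(cand)

  rows <- list()
  for (i in cand) {
    es <- graph$edges$subject[i]; eo <- graph$edges$object[i]
    ep <- graph$edges$predicate[i]
    if (!is.null(pred_set) && !ep %in% pred_set) next
    forward <- node_ok(es, sub_ids, sub_cats) && node_ok(eo, obj_ids, obj_cats)
    backward <- ep %in% model$symmetric_predicates &&
      node_ok(eo, sub_ids, sub_cats) && node_ok(es, obj_ids, obj_cats)
    if (forward)
      rows[[length(rows) + 1L]] <- c(sub = es, obj = eo, edge = i)
    if (backward && !(forward && es == eo))
      rows[[length(rows) + 1L]] <- c(sub = eo, obj = es, edge = i)
  }

  if (!length(rows)) {
    results <- stats::setNames(
      as.data.frame(rep(list(character(0)), 3)),
      c(sub_key, obj_key, qe_key))
    kg <- graph_document(
      graph$nodes[0, , drop = FALSE], graph$edges[0, , drop = FALSE],
      build_info = list(stage = "query_slice"))
    return(structure(list(results = results, knowledge_graph = kg),
                     class = "result_set"))
  }
  m <- do.call(rbind, rows)
  edge_idx <- as.integer(m[, "edge"])
  results <- stats::setNames(
    data.frame(m[, "sub"], m[, "obj"], index$edge_key[edge_idx],
               stringsAsFactors = FALSE),
    c(sub_key, obj_key, qe_key))
  dup <- duplicated(do.call(paste, c(results, sep = "\r")))
  results <- results[!dup, , drop = FALSE]
  edge_idx <- edge_idx[!dup]

  # ranking: provenance-source count desc, then lexicographic binding key
  n_src <- lengths(pv_split(graph$edges$provided_by[edge_idx]))
  bind_key <- do.call(paste, c(results, sep = "\r"))
  ord <- order_c(-n_src, bind_key)
  results <- results[ord, , drop = FALSE]
  edge_idx <- edge_idx[ord]
  rownames(results) <- NULL

  bound_nodes <- unique(c(results[[sub_key]], results[[obj_key]]))
  kg <- graph_document(
    graph$nodes[graph$nodes$id %in% bound_nodes, , drop = FALSE],
    graph$edges[sort(unique(edge_idx)), , drop = FALSE],
    build_info = list(stage = "query_slice"))
  structure(list(results = results, knowledge_graph = kg),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> %d result(s); knowledge_graph: %d nodes, %d edges\n",
              nrow(x$results), nrow(x$knowledge_graph$nodes),
              nrow(x$knowledge_graph$edges)))
  invisible(x)
}

# TRAPI-style message JSON ----------------------------------------------------

#' Read a query message / write a response message (TRAPI-style JSON)
#'
#' The query message mirrors the TRAPI skeleton:
#' `{"message": {"query_graph": {"nodes": {...}, "edges": {...}}}}`.
#' The response carries `results` (bindings) and `knowledge_graph`.
#'
#' @param path For `read_query_json()`, path to (or literal text of) the
#'   query message; for `write_response_json()`, the output path.
#' @param result_set An [answer_one_hop()] result.
#' @return `read_query_json()` returns a [query_graph()].
#' @export
read_query_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  qg <- doc$message$query_graph
  if (is.null(qg))
    kg_stop("kg_query_validation_error",
            "message lacks a query_graph")
  qnodes <- lapply(qg$nodes, function(n)
    list(ids = as.character(unlist(n$ids)),
         categories = as.character(unlist(n$categories))))
  qedges <- lapply(qg$edges, function(e)
    list(subject = e$subject, object = e$object,
         predicates = as.character(unlist(e$predicates))))
  query_graph(qnodes, qedges)
}

#' @rdname read_query_json
#' @export
write_response_json <- function(result_set, path) {
  kg <- sort_graph(result_set$knowledge_graph)
  doc <- list(message = list(
    results = lapply(seq_len(nrow(result_set$results)), function(i)
      as.list(result_set$results[i, , drop = FALSE])),
    knowledge_graph = list(
      nodes = df_to_objects(kg$nodes,
                            c("provided_by", "publications",
                              CANON_EXTRA_COLS)),
      edges = df_to_objects(kg$edges,
                            c("relation", "provided_by", "publications")))))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}
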