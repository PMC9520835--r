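# Merge per-source graph documents into the pre-canonicalized graph:
# node unification by identical CURIE, rank precedence for categories and
# names, provenance-preserving edge coalescing, dangling-edge screening.

#' Merge per-source graph documents into the pre-canonicalized graph
#'
#' Nodes with identical ids are unified: the category comes from the
#' highest-precedence (lowest-rank) source that provides the node, with
#' conflicting assignments logged; name and description take the first
#' non-empty value in precedence order; `provided_by` and `publications` are
#' unioned. Edges are then coalesced on (subject, object, predicate) with
#' [coalesce_edges()] and edges whose endpoints are not present in the graph
#' are screened out with [screen_dangling()] and logged rather than silently
#' materialized as bare nodes (which would corrupt category statistics).
#'
#' @param parts List of [graph_document()]s in source-rank order (as produced
#'   by [ingest_source()]; each part's `build_info$source_rank` is used for
#'   precedence).
#' @param model A [load_model()] result (used to re-orient nothing here, but
#'   kept for interface symmetry and validation by callers).
#' @return List with elements `graph` (the merged [graph_document()]) and
#'   `log` (a `merge_log`: `dangling_edges`, `category_conflicts`,
#'   `coalesced_count`).
#' @export
merge_graphs <- function(parts, model = NULL) {
  if (!length(parts))
    return(list(graph = graph_document(), log = new_merge_log()))
  ranks <- vapply(parts, function(p)
    as.integer(p$build_info$source_rank %||% NA_integer_), integer(1))
  if (anyNA(ranks)) ranks[is.na(ranks)] <- seq_along(parts)[is.na(ranks)]
  if (anyDuplicated(ranks))
    kg_stop("kg_config_error", "duplicate source ranks in merge inputs: %s",
            paste(ranks[duplicated(ranks)], collapse = ", "))
  parts <- parts[order(ranks)]
  ranks <- sort(ranks)
  # canonical row order per part: downstream logs and first-seen payload
  # unions are then independent of how parts were produced or reloaded
  parts <- lapply(parts, sort_graph)

  all_nodes <- do.call(rbind, lapply(seq_along(parts), function(i) {
    n <- parts[[i]]$nodes
    if (nrow(n)) n$._rank <- ranks[i]
    n
  }))
  all_edges <- do.call(rbind, lapply(parts, function(p) p$edges))
  n_edges_in <- nrow(all_edges)

  # node unification in precedence order
  ord <- order(all_nodes$._rank)
  all_nodes <- all_nodes[ord, , drop = FALSE]
  f <- factor(all_nodes$id, levels = unique(all_nodes$id))
  winner <- !duplicated(all_nodes$id)

  first_nonempty <- function(x) {
    tapply(x, f, function(v) {
      nz <- v[nzchar(v)]
      if (length(nz)) nz[1] else ""
    })
  }
  nodes <- data.frame(
    id = levels(f),
    name = as.character(first_nonempty(all_nodes$name)),
    category = all_nodes$category[winner][match(levels(f),
                                                all_nodes$id[winner])],
    iri = as.character(first_nonempty(all_nodes$iri)),
    description = as.character(first_nonempty(all_nodes$description)),
    provided_by = as.character(pv_collapse(all_nodes$provided_by, f)[levels(f)]),
    publications = as.character(pv_collapse(all_nodes$publications,
                                            f)[levels(f)]),
    stringsAsFactors = FALSE)

  # category-conflict log
  conflicts <- do.call(rbind, lapply(split(seq_len(nrow(all_nodes)), f),
                                     function(idx) {
    cats <- all_nodes$category[idx]
    if (length(unique(cats)) > 1L)
      data.frame(id = all_nodes$id[idx[1]], winner = cats[1],
                 losers = paste(unique(cats[-1]), collapse = "|"),
                 loser_ranks = paste(all_nodes$._rank[idx][-1],
                                     collapse = "|"),
                 stringsAsFactors = FALSE)
  }))
  if (is.null(conflicts))
    conflicts <- data.frame(id = character(0), winner = character(0),
                            losers = character(0), loser_ranks = character(0),
                            stringsAsFactors = FALSE)

  edges <- coalesce_edges(all_edges)
  coalesced_count <- n_edges_in - nrow(edges)

  build_info <- list(
    stage = "pre_merge_graph",
    model_version = if (!is.null(model)) model$version else NULL,
    source_versions = do.call(c, lapply(parts, function(p)
      p$build_info$source_versions)),
    build_timestamp = ""
  )
  g <- graph_document(nodes, edges, build_info)
  screened <- screen_dangling(g)

  log <- new_merge_log(dangling_edges = screened$removed,
                       category_conflicts = conflicts,
                       coalesced_count = coalesced_count)
  list(graph = screened$graph, log = log)
}

new_merge_log <- function(dangling_edges = NULL, category_conflicts = NULL,
                          coalesced_count = 0L) {
  if (is.null(dangling_edges)) {
    dangling_edges <- empty_edges()
    dangling_edges$reason <- character(0)
  }
  if (is.null(category_conflicts))
    category_conflicts <- data.frame(id = character(0), winner = character(0),
                                     losers = character(0),
                                     loser_ranks = character(0),
                                     stringsAsFactors = FALSE)
  structure(list(dangling_edges = dangling_edges,
                 category_conflicts = category_conflicts,
                 coalesced_count = as.integer(coalesced_count)),
            class = "merge_log")
}

#' @export
print.merge_log <- function(x, ...) {
  cat(sprintf(paste0("<merge_log> %d coalesced, %d dangling, ",
                     "%d category conflict(s)\n"),
              x$coalesced_count, nrow(x$dangling_edges),
              nrow(x$category_conflicts)))
  invisible(x)
}

#' Coalesce duplicate edges
#'
#' Joins edges that have the same end nodes and the same predicate into a
#' single edge whose `relation`, `provided_by` and `publications` are
#' ordered-set unions (first-seen order) of the duplicates' values, so the
#' provenance of every coalesced assertion is preserved. Assumes edges are
#' already oriented (canonical inverse direction, symmetric predicates
#' normalized), which makes the (subject, object, predicate) key well
#' defined.
#'
#' @param edges Edge data frame.
#' @return Edge data frame with one row per (subject, object, predicate).
#' @export
coalesce_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- paste(edges$subject, edges$object, edges$predicate, sep = "\r")
  f <- factor(key, levels = unique(key))
  first <- !duplicated(key)
  out <- edges[first, , drop = FALSE]
  out$relation <- as.character(pv_collapse(edges$relation, f)[levels(f)])
  out$provided_by <- as.character(pv_collapse(edges$provided_by, f)[levels(f)])
  out$publications <- as.character(pv_collapse(edges$publications,
                                               f)[levels(f)])
  rownames(out) <- NULL
  out
}

#' Screen dangling edges
#'
#' Removes edges whose subject or object identifier has no corresponding node
#' in the graph and returns them for logging and offline investigation.
#'
#' @param graph A [graph_document()].
#' @return List with `graph` (only edges with both endpoints present) and
#'   `removed` (the screened edges, with a `reason` column).
#' @export
screen_dangling <- function(graph) {
  ids <- graph$nodes$id
  miss_s <- !(graph$edges$subject %in% ids)
  miss_o <- !(graph$edges$object %in% ids)
  bad <- miss_s | miss_o
  removed <- graph$edges[bad, , drop = FALSE]
  removed$reason <- ifelse(miss_s[bad] & miss_o[bad], "both endpoints missing",
                           ifelse(miss_s[bad], "subject missing",
                                  "object missing"))
  rownames(removed) <- NULL
  graph$edges <- graph$edges[!bad, , drop = FALSE]
  rownames(graph$edges) <- NULL
  list(graph = graph, removed = removed)
}

#' Write the merge log as TSV sidecar files
#'
#' @param log A `merge_log` from [merge_graphs()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_merge_log <- function(log, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_plain(log$dangling_edges, file.path(dir, "dangling_edges.tsv"))
  write_tsv_plain(log$category_conflicts,
                  file.path(dir, "category_conflicts.tsv"))
  write_tsv_plain(data.frame(coalesced_count = log$coalesced_count),
                  file.path(dir, "coalesced.tsv"))
  invisible(dir)
}
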