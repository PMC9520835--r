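# Canonicalization: collapse semantically equivalent concepts (different
# identifiers for one concept, linked by equivalence-grade edges) into single
# canonical nodes. Five steps: load the pre graph, partition its nodes into
# equivalence blocks, elect a canonical identifier per block, remap edges to
# canonical identifiers, and merge edges sharing (subject, object, predicate).

#' Partition graph nodes into equivalence blocks
#'
#' Blocks are the connected components of the undirected subgraph induced by
#' edges whose predicate lies in the descendant closure of the equivalence
#' predicates (default `biolink:same_as` and its descendants, e.g.
#' `biolink:exact_match`). Connected components — not literal graph-theoretic
#' cliques — are used because synonymy is asserted in transitive chains
#' (MONDO to DOID, DOID to MESH, ...) that a clique criterion would shatter.
#' Nodes with no equivalence edge form singleton blocks. Implemented with
#' union-find (path halving + union by size).
#'
#' @param graph A pre-canonicalized [graph_document()].
#' @param model A [load_model()] result.
#' @param equivalence_predicates Character vector of predicate names; each is
#'   expanded to its descendant closure.
#' @return An `equivalence_partition`: list with `blocks` (list of character
#'   vectors of node ids, each sorted; blocks ordered by first member) and
#'   `block_of` (named integer vector id -> block index).
#' @export
build_partition <- function(graph, model,
                            equivalence_predicates = "biolink:same_as") {
  eq_set <- unique(unlist(lapply(equivalence_predicates, function(p)
    expand_predicate(model, p))))
  ids <- graph$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)

  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]   # path halving
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri == rj) return(invisible())
    if (size[ri] < size[rj]) { tmp <- ri; ri <- rj; rj <- tmp }
    parent[rj] <<- ri
    size[ri] <<- size[ri] + size[rj]
    invisible()
  }

  eq_edges <- graph$edges[graph$edges$predicate %in% eq_set, , drop = FALSE]
  si <- idx[eq_edges$subject]; oi <- idx[eq_edges$object]
  keep <- !is.na(si) & !is.na(oi)
  for (k in which(keep)) union_(si[k], oi[k])

  root <- vapply(seq_len(n), find, integer(1))
  blocks_raw <- split(ids, root)
  blocks <- lapply(blocks_raw, sort_c)
  blocks <- blocks[order_c(vapply(blocks, `[`, character(1), 1))]
  names(blocks) <- NULL
  block_of <- integer(n)
  for (b in seq_along(blocks)) block_of[idx[blocks[[b]]]] <- b
  names(block_of) <- ids
  structure(list(blocks = blocks, block_of = block_of),
            class = "equivalence_partition")
}

#' @export
print.equivalence_partition <- function(x, ...) {
  sizes <- lengths(x$blocks)
  cat(sprintf("<equivalence_partition> %d block(s) over %d id(s); %d non-singleton\n",
              length(x$blocks), sum(sizes), sum(sizes > 1L)))
  invisible(x)
}

#' Elect the canonical identifier of an equivalence block
#'
#' Among block members, picks the id whose CURIE prefix has the best
#' (lowest-index) position in the model's prefix-priority list for the
#' block's dominant category; prefixes absent from the list rank after all
#' listed prefixes, and ties break by lexicographic CURIE order, so election
#' is deterministic. If the dominant category has no priority list, the
#' nearest ancestor category with one is used.
#'
#' The dominant category is taken from the member provided by the
#' highest-precedence source when `source_ranks` is supplied (named vector
#' source-node id -> rank); otherwise the most frequent member category wins
#' (ties by lexicographic order).
#'
#' @param block Data frame of member nodes (rows from a pre-graph node table).
#' @param model A [load_model()] result.
#' @param source_ranks Optional named integer vector mapping source-node ids
#'   to ranks.
#' @return List with `id` (the elected CURIE) and `category` (the dominant
#'   category used for the lookup).
#' @export
choose_canonical <- function(block, model, source_ranks = NULL) {
  stopifnot(nrow(block) >= 1L)
  dom_cat <- dominant_category(block, source_ranks)
  prio <- priority_for_category(model, dom_cat)
  pfx <- curie_prefix(block$id)
  rank <- match(pfx, prio)
  rank[is.na(rank)] <- length(prio) + 1L
  ord <- order_c(rank, block$id)
  list(id = block$id[ord[1]], category = dom_cat)
}

dominant_category <- function(block, source_ranks = NULL) {
  if (!is.null(source_ranks)) {
    best <- vapply(pv_split(block$provided_by), function(srcs) {
      r <- source_ranks[srcs]
      if (all(is.na(r))) Inf else min(r, na.rm = TRUE)
    }, numeric(1))
    ord <- order_c(best, block$id)
    return(block$category[ord[1]])
  }
  tab <- table(block$category)
  cand <- names(tab)[tab == max(tab)]
  sort_c(cand)[1]
}

priority_for_category <- function(model, category) {
  for (cat in c(category, tree_ancestors(model$categories, category))) {
    p <- model$prefix_priority[[cat]]
    if (!is.null(p) && length(p)) return(as.character(unlist(p)))
  }
  character(0)
}

#' Build the canonicalized graph
#'
#' Steps 3-5 of canonicalization: one canonical concept per partition block,
#' annotated with the identifiers of its synonymous nodes
#' (`equivalent_identifiers`) and information merged from them
#' (`all_categories`, `all_names`, unioned provenance and publications,
#' source-tagged concatenated descriptions); every pre-graph edge is remapped
#' to canonical endpoint identifiers and edges sharing (subject, object,
#' predicate) are merged with [coalesce_edges()]. Equivalence edges that
#' become self-loops under remapping are dropped (they carried only the
#' synonymy, which the block already encodes) and counted; substantive
#' (non-equivalence) self-loops are retained and counted, since dropping them
#' would silently destroy assertions.
#'
#' @param pre The pre-canonicalized [graph_document()].
#' @param partition An `equivalence_partition` from [build_partition()]
#'   covering all of `pre`'s node ids.
#' @param model A [load_model()] result.
#' @param equivalence_predicates As in [build_partition()] (used to decide
#'   which self-loops to drop).
#' @param source_ranks Optional, see [choose_canonical()].
#' @return List with `graph` (canonicalized [graph_document()]) and `log`
#'   (block size table, dropped equivalence self-loop count, retained
#'   substantive self-loop count).
#' @export
build_canonical_graph <- function(pre, partition, model,
                                  equivalence_predicates = "biolink:same_as",
                                  source_ranks = NULL) {
  ids <- pre$nodes$id
  if (!all(ids %in% names(partition$block_of)) ||
      length(partition$block_of) != length(ids))
    kg_stop("kg_consistency_error",
            "partition does not cover the graph's node ids")
  eq_set <- unique(unlist(lapply(equivalence_predicates, function(p)
    expand_predicate(model, p))))

  node_tab <- pre$nodes
  node_block <- partition$block_of[node_tab$id]
  blocks <- split(seq_len(nrow(node_tab)), node_block)

  canon_rows <- lapply(blocks, function(rows) {
    b <- node_tab[rows, , drop = FALSE]
    elect <- choose_canonical(b, model, source_ranks)
    canon_row <- b[b$id == elect$id, , drop = FALSE]
    names_all <- sort_c(unique(b$name[nzchar(b$name)]))
    name <- if (nzchar(canon_row$name)) canon_row$name
            else if (length(names_all)) names_all[1] else ""
    desc <- b$description[nzchar(b$description)]
    desc_ids <- b$id[nzchar(b$description)]
    data.frame(
      id = elect$id,
      name = name,
      category = elect$category,
      iri = canon_row$iri,
      description = paste(sprintf("[%s] %s", desc_ids, desc),
                          collapse = "; "),
      provided_by = paste(unique(unlist(pv_split(b$provided_by))),
                          collapse = "|"),
      publications = paste(unique(unlist(pv_split(b$publications))),
                           collapse = "|"),
      all_categories = paste(sort_c(unique(b$category)), collapse = "|"),
      equivalent_identifiers = paste(sort_c(b$id), collapse = "|"),
      all_names = paste(names_all, collapse = "|"),
      stringsAsFactors = FALSE)
  })
  nodes <- do.call(rbind, canon_rows)
  rownames(nodes) <- NULL

  # canonical id of each block, then remap edges
  canon_of_block <- nodes$id[match(seq_along(partition$blocks),
                                   as.integer(names(blocks)))]
  id_to_canon <- stats::setNames(
    canon_of_block[partition$block_of[ids]], ids)

  edges <- pre$edges
  n_dropped_eq <- 0L
  n_self <- 0L
  if (nrow(edges)) {
    edges$subject <- unname(id_to_canon[edges$subject])
    edges$object <- unname(id_to_canon[edges$object])
    self <- edges$subject == edges$object
    eq_self <- self & edges$predicate %in% eq_set
    n_dropped_eq <- sum(eq_self)
    edges <- edges[!eq_self, , drop = FALSE]
    n_self <- sum(edges$subject == edges$object)
    # symmetric predicates may need re-normalizing after remapping
    edges <- orient_edges(model, edges)
    edges <- coalesce_edges(edges)
  }

  build_info <- pre$build_info
  build_info$stage <- "canonical_graph"
  g <- graph_document(nodes, edges, build_info)
  log <- structure(list(
    block_sizes = table(lengths(partition$blocks)),
    dropped_equivalence_self_loops = n_dropped_eq,
    retained_self_loops = n_self), class = "canonicalization_log")
  list(graph = g, log = log)
}

#' @export
print.canonicalization_log <- function(x, ...) {
  cat(sprintf("<canonicalization_log> dropped %d equivalence self-loop(s), retained %d substantive self-loop(s)\n",
              x$dropped_equivalence_self_loops, x$retained_self_loops))
  cat("block sizes:\n")
  print(x$block_sizes)
  invisible(x)
}
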