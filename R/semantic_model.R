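# The semantic layer: category and predicate hierarchies, inverse-pair
# orientation, relation normalization, and identifier-prefix priorities.
# This is a declarative, self-contained stand-in for a Biolink-style model:
# the pipeline needs the hierarchies, the inverse/symmetric predicate
# bookkeeping, the relation map and the prefix priority lists, and nothing
# else of the full model.

#' Load a semantic model
#'
#' Reads the declarative YAML model document defining the semantic layer:
#' `categories` and `predicates` (each a mapping parent -> children, forming a
#' rooted tree), `inverse_pairs` (a list of `{pair: [a, b], canonical: a}`
#' entries; only the canonical member of each pair is allowed in built
#' graphs), `symmetric` (predicates with no subject/object direction),
#' `relation_map` (entries `{source, relation, predicate}` normalizing each
#' source's relationship phrasing to a model predicate), `prefix_priority`
#' (category -> ordered CURIE prefix list, used for canonical-identifier
#' election) and `version`.
#'
#' @param path Path to the model YAML document.
#' @return An object of class `semantic_model`.
#' @examples
#' model <- load_model(system.file("extdata", "model_mini.yaml",
#'                                 package = "kgbuildr"))
#' model$version
#' @export
load_model <- function(path) {
  doc <- yaml::read_yaml(path)
  categories <- parse_tree(doc$categories, "category")
  predicates <- parse_tree(doc$predicates, "predicate")

  inv <- doc$inverse_pairs %||% list()
  inverse_pairs <- data.frame(a = character(0), b = character(0),
                              canonical = character(0),
                              stringsAsFactors = FALSE)
  for (entry in inv) {
    pair <- unlist(entry$pair)
    canon <- entry$canonical
    if (length(pair) != 2L || is.null(canon) || sum(pair == canon) != 1L)
      kg_stop("kg_model_consistency_error",
              "inverse pair [%s] must flag exactly one canonical member",
              paste(pair, collapse = ", "))
    inverse_pairs <- rbind(inverse_pairs,
                           data.frame(a = pair[1], b = pair[2],
                                      canonical = canon,
                                      stringsAsFactors = FALSE))
  }

  symmetric <- as.character(unlist(doc$symmetric %||% list()))

  rm_entries <- doc$relation_map %||% list()
  relation_map <- data.frame(
    source = vapply(rm_entries, function(e) e$source, character(1)),
    relation = vapply(rm_entries, function(e) e$relation, character(1)),
    predicate = vapply(rm_entries, function(e) e$predicate, character(1)),
    stringsAsFactors = FALSE)

  model <- structure(list(
    categories = categories,
    predicates = predicates,
    inverse_pairs = inverse_pairs,
    symmetric_predicates = symmetric,
    relation_map = relation_map,
    prefix_priority = doc$prefix_priority %||% list(),
    version = doc$version %||% "unversioned"
  ), class = "semantic_model")

  # fast lookup: non-canonical inverse member -> canonical partner
  noncanon <- ifelse(inverse_pairs$canonical == inverse_pairs$a,
                     inverse_pairs$b, inverse_pairs$a)
  model$noncanonical_map <- stats::setNames(inverse_pairs$canonical, noncanon)

  validate_model(model)
  model
}

# parent -> children mapping into a tree structure with explicit root.
parse_tree <- function(mapping, what) {
  if (is.null(mapping) || !length(mapping))
    kg_stop("kg_model_schema_error", "missing root %s: empty '%s' section",
            what, if (what == "category") "categories" else "predicates")
  parents <- names(mapping)
  children_all <- character(0)
  parent_of <- character(0)
  for (p in parents) {
    kids <- as.character(unlist(mapping[[p]]))
    if (anyDuplicated(kids))
      kg_stop("kg_model_schema_error", "duplicate child under %s '%s'", what, p)
    dup <- intersect(kids, children_all)
    if (length(dup))
      kg_stop("kg_model_schema_error",
              "%s '%s' has more than one parent", what, dup[1])
    children_all <- c(children_all, kids)
    parent_of[kids] <- p
  }
  nodes <- unique(c(parents, children_all))
  # cycle check first: walk parent links from every node; a revisit is a cycle
  for (n in nodes) {
    seen <- character(0)
    cur <- n
    while (cur %in% names(parent_of)) {
      if (cur %in% seen)
        kg_stop("kg_model_cycle_error", "cycle in %s hierarchy: %s",
                what, paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  roots <- setdiff(nodes, names(parent_of))
  if (length(roots) != 1L)
    kg_stop("kg_model_schema_error",
            "missing root %s: expected exactly one %s without a parent, found %d (%s)",
            what, what, length(roots), paste(roots, collapse = ", "))
  children <- lapply(stats::setNames(parents, parents),
                     function(p) as.character(unlist(mapping[[p]])))
  list(nodes = nodes, root = roots, parent = parent_of, children = children)
}

validate_model <- function(model) {
  preds <- model$predicates$nodes
  used <- unique(c(model$relation_map$predicate,
                   model$inverse_pairs$a, model$inverse_pairs$b,
                   model$symmetric_predicates))
  unknown <- setdiff(used, preds)
  if (length(unknown))
    kg_stop("kg_model_consistency_error",
            "predicate(s) not in the predicate tree: %s",
            paste(unknown, collapse = ", "))
  in_pairs <- unique(c(model$inverse_pairs$a, model$inverse_pairs$b))
  clash <- intersect(model$symmetric_predicates, in_pairs)
  if (length(clash))
    kg_stop("kg_model_consistency_error",
            "symmetric predicate(s) appear in an inverse pair: %s",
            paste(clash, collapse = ", "))
  invisible(model)
}

#' @export
print.semantic_model <- function(x, ...) {
  cat(sprintf(paste0("<semantic_model> version %s: %d categories, ",
                     "%d predicates, %d inverse pairs, %d symmetric, ",
                     "%d relation mappings\n"),
              x$version, length(x$categories$nodes),
              length(x$predicates$nodes), nrow(x$inverse_pairs),
              length(x$symmetric_predicates), nrow(x$relation_map)))
  invisible(x)
}

# Hierarchy closure ----------------------------------------------------------

tree_expand <- function(tree, name, what) {
  if (!name %in% tree$nodes)
    kg_stop("kg_lookup_error", "unknown %s: '%s'", what, name)
  out <- name
  frontier <- name
  while (length(frontier)) {
    kids <- unlist(tree$children[frontier], use.names = FALSE)
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  out
}

tree_ancestors <- function(tree, name) {
  out <- character(0)
  cur <- name
  while (!is.na(tree$parent[cur] %||% NA_character_) &&
         !is.na(tree$parent[cur])) {
    cur <- tree$parent[[cur]]
    out <- c(out, cur)
  }
  out
}

#' Expand a category or predicate to its descendant closure
#'
#' Returns the reflexive-transitive closure of a hierarchy node: the node
#' itself plus all of its descendants. Used for hierarchical matching in the
#' query engine and for expanding the equivalence-predicate set during
#' canonicalization.
#'
#' @param model A [load_model()] result.
#' @param category,predicate Name present in the respective tree.
#' @return Character vector of names (the node first, then descendants in
#'   breadth-first order).
#' @export
expand_category <- function(model, category) {
  tree_expand(model$categories, category, "category")
}

#' @rdname expand_category
#' @export
expand_predicate <- function(model, predicate) {
  tree_expand(model$predicates, predicate, "predicate")
}

# Relation normalization -----------------------------------------------------

#' Normalize a source relation to a model predicate
#'
#' Looks up `(source, relation)` in the model's relation map. The original
#' source phrasing is always preserved and returned unchanged so it can be
#' stored in the edge's `relation` property. When the pair is unmapped, the
#' relation falls back to the predicate-tree root (the most general
#' relationship type) and a log message of class `kg_unmapped_relation` is
#' emitted; unmapped relations are a logged fallback, never an error.
#'
#' @param model A [load_model()] result.
#' @param source Source name used as the relation namespace.
#' @param relation The source's original relation string.
#' @return List with elements `predicate` and `relation`.
#' @export
map_relation <- function(model, source, relation) {
  hit <- model$relation_map$source == source &
    model$relation_map$relation == relation
  if (any(hit)) {
    list(predicate = model$relation_map$predicate[which(hit)[1]],
         relation = relation)
  } else {
    kg_note("kg_unmapped_relation",
            "unmapped relation ('%s', '%s'): falling back to %s",
            source, relation, model$predicates$root)
    list(predicate = model$predicates$root, relation = relation)
  }
}

# Vectorized form used by ingest modules; returns predicates plus the count of
# fallbacks (callers record it in their stage log).
map_relations <- function(model, source, relations) {
  rm <- model$relation_map[model$relation_map$source == source, , drop = FALSE]
  idx <- match(relations, rm$relation)
  pred <- rm$predicate[idx]
  n_unmapped <- sum(is.na(pred))
  pred[is.na(pred)] <- model$predicates$root
  list(predicate = pred, n_unmapped = n_unmapped)
}

# Orientation ----------------------------------------------------------------

#' Orient an assertion into canonical predicate direction
#'
#' Two normalizations are applied so that edge-coalescing keys are well
#' defined. First, if the predicate is the non-canonical member of an inverse
#' pair (e.g. `part_of` when `has_part` is canonical), subject and object are
#' swapped and the predicate replaced by the canonical member, so only one
#' member of each inverted pair ever appears in a built graph. Second,
#' symmetric predicates are stored in a single normalized direction
#' (subject <= object lexicographically). The operation is idempotent.
#'
#' @param model A [load_model()] result.
#' @param edge One-row edge data frame (see [empty_edges()]).
#' @return The oriented edge.
#' @export
orient_assertion <- function(model, edge) {
  unknown <- setdiff(edge$predicate, model$predicates$nodes)
  if (length(unknown))
    kg_stop("kg_lookup_error", "unknown predicate: '%s'", unknown[1])
  orient_edges(model, edge)
}

# Vectorized orientation over an edge table (no predicate existence check;
# ingest paths only produce model predicates).
orient_edges <- function(model, edges) {
  if (!nrow(edges)) return(edges)
  canon <- model$noncanonical_map[edges$predicate]
  flip <- !is.na(canon)
  if (any(flip)) {
    s <- edges$subject[flip]
    edges$subject[flip] <- edges$object[flip]
    edges$object[flip] <- s
    edges$predicate[flip] <- canon[flip]
  }
  sym <- edges$predicate %in% model$symmetric_predicates &
    str_gt(edges$subject, edges$object)
  if (any(sym)) {
    s <- edges$subject[sym]
    edges$subject[sym] <- edges$object[sym]
    edges$object[sym] <- s
  }
  edges
}

# Graph validation -----------------------------------------------------------

#' Validate a graph against the semantic model
#'
#' Checks every node's category against the category tree, every edge's
#' predicate against the predicate tree, flags edges using the non-canonical
#' member of an inverse pair, and flags malformed CURIEs (node ids and edge
#' endpoints). Findings are returned, not raised.
#'
#' @param model A [load_model()] result.
#' @param graph A [graph_document()].
#' @return A `validation_report`: list with `ok` (logical) and `violations`
#'   (data frame with columns entity, field, value, rule).
#' @export
validate_graph <- function(model, graph) {
  v <- list()
  add <- function(entity, field, value, rule) {
    if (length(entity))
      v[[length(v) + 1L]] <<- data.frame(entity = entity, field = field,
                                         value = value, rule = rule,
                                         stringsAsFactors = FALSE)
  }
  nodes <- graph$nodes; edges <- graph$edges
  bad_cat <- !(nodes$category %in% model$categories$nodes)
  add(nodes$id[bad_cat], "category", nodes$category[bad_cat],
      "category_in_model")
  bad_id <- !curie_ok(nodes$id)
  add(nodes$id[bad_id], "id", nodes$id[bad_id], "curie_well_formed")
  bad_pred <- !(edges$predicate %in% model$predicates$nodes)
  add(paste(edges$subject[bad_pred], edges$object[bad_pred]), "predicate",
      edges$predicate[bad_pred], "predicate_in_model")
  noncanon <- edges$predicate %in% names(model$noncanonical_map)
  add(paste(edges$subject[noncanon], edges$object[noncanon]), "predicate",
      edges$predicate[noncanon], "canonical_inverse_member")
  for (fld in c("subject", "object")) {
    bad <- !curie_ok(edges[[fld]])
    add(edges[[fld]][bad], fld, edges[[fld]][bad], "curie_well_formed")
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(entity = character(0), field = character(0),
               value = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("<validation_report> ok\n")
  else {
    cat(sprintf("<validation_report> %d violation(s)\n", nrow(x$violations)))
    print(utils::head(x$violations, 10))
  }
  invisible(x)
}
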