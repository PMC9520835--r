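# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's own data paths: partition by boolean matrix closure,
# one-hop answering by naive edge scan, coalescing by split/apply.

mini_model <- function() {
  load_model(system.file("extdata", "model_mini.yaml", package = "kgbuildr"))
}

write_model_yaml <- function(lines) {
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}

# A small assortment of prefixes/categories/predicates for random graphs.
rand_prefixes <- c("MONDO", "DOID", "MESH", "CHEBI", "DRUGBANK", "NCBIGene")
rand_categories <- c("biolink:Disease", "biolink:Drug", "biolink:Gene",
                     "biolink:SmallMolecule", "biolink:NamedThing")
rand_predicates <- c("biolink:related_to", "biolink:treats",
                     "biolink:associated_with", "biolink:affects",
                     "biolink:interacts_with", "biolink:subclass_of")

random_graph <- function(n_nodes = 50, n_edges = 2 * n_nodes,
                         canonical = FALSE, model = NULL) {
  ids <- sprintf("%s:%05d", sample(rand_prefixes, n_nodes, replace = TRUE),
                 sample.int(99999L, n_nodes))
  ids <- unique(ids)
  n <- length(ids)
  maybe_pv <- function(pool, p_two = 0.3) {
    vapply(seq_len(n), function(i) {
      k <- 1L + (stats::runif(1) < p_two)
      paste(sample(pool, k), collapse = "|")
    }, character(1))
  }
  nodes <- data.frame(
    id = ids,
    name = ifelse(stats::runif(n) < 0.8,
                  sprintf("concept %d with spaces", seq_len(n)), ""),
    category = sample(rand_categories, n, replace = TRUE),
    iri = sprintf("http://example.org/%d", seq_len(n)),
    description = ifelse(stats::runif(n) < 0.3, "some description; text", ""),
    provided_by = maybe_pv(c("KGSOURCE:a", "KGSOURCE:b", "KGSOURCE:c")),
    publications = ifelse(stats::runif(n) < 0.4,
                          sprintf("PMID:%d", sample.int(99999L, n)), ""),
    stringsAsFactors = FALSE)
  if (canonical) {
    alias <- sprintf("ALIAS:%05d", sample.int(99999L, n))
    nodes$all_categories <- ifelse(
      stats::runif(n) < 0.3,
      paste(nodes$category, "biolink:NamedThing", sep = "|"),
      nodes$category)
    nodes$equivalent_identifiers <- ifelse(
      stats::runif(n) < 0.5, paste(nodes$id, alias, sep = "|"), nodes$id)
    nodes$all_names <- nodes$name
  }
  m <- n_edges
  si <- sample.int(n, m, replace = TRUE)
  oi <- sample.int(n, m, replace = TRUE)
  edges <- data.frame(
    subject = ids[si],
    predicate = sample(rand_predicates, m, replace = TRUE),
    object = ids[oi],
    relation = sample(c("rel_a", "rel_b", "rel_a|rel_b"), m, replace = TRUE),
    provided_by = sample(c("KGSOURCE:a", "KGSOURCE:a|KGSOURCE:b"), m,
                         replace = TRUE),
    publications = ifelse(stats::runif(m) < 0.3,
                          sprintf("PMID:%d", sample.int(99999L, m)), ""),
    stringsAsFactors = FALSE)
  if (!is.null(model)) edges <- kgbuildr:::orient_edges(model, edges)
  g <- graph_document(nodes, edges, build_info = list(stage = "test"))
  kgbuildr:::sort_graph(g)
}

# Oracle 1: equivalence partition by boolean reachability-matrix closure.
oracle_partition <- function(ids, eq_subject, eq_object) {
  n <- length(ids)
  R <- diag(TRUE, n)
  si <- match(eq_subject, ids); oi <- match(eq_object, ids)
  for (k in seq_along(si)) {
    R[si[k], oi[k]] <- TRUE
    R[oi[k], si[k]] <- TRUE
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comp_key <- apply(R, 1, function(r) paste(which(r), collapse = ","))
  blocks <- split(ids, comp_key)
  blocks <- lapply(blocks, function(b) sort(b, method = "radix"))
  unname(blocks[order(vapply(blocks, `[`, character(1), 1),
                      method = "radix")])
}

# Oracle 2: descendant closure by direct recursion over the children lists.
oracle_closure <- function(tree, name) {
  kids <- tree$children[[name]]
  out <- name
  for (k in kids) out <- c(out, oracle_closure(tree, k))
  unique(out)
}

# Oracle 3: one-hop answering by naive scan over every edge and orientation.
oracle_one_hop <- function(graph, query, model) {
  qe_key <- names(query$qedges)[1]
  qe <- query$qedges[[1]]
  qn_s <- query$qnodes[[qe$subject]]
  qn_o <- query$qnodes[[qe$object]]
  cats_of <- function(id) {
    i <- match(id, graph$nodes$id)
    if ("all_categories" %in% names(graph$nodes))
      strsplit(graph$nodes$all_categories[i], "|", fixed = TRUE)[[1]]
    else graph$nodes$category[i]
  }
  resolve <- function(qid) {
    if (qid %in% graph$nodes$id) return(qid)
    if (!"equivalent_identifiers" %in% names(graph$nodes))
      return(NA_character_)
    for (i in seq_len(nrow(graph$nodes)))
      if (qid %in% strsplit(graph$nodes$equivalent_identifiers[i], "|",
                            fixed = TRUE)[[1]])
        return(graph$nodes$id[i])
    NA_character_
  }
  want_ids <- function(qn) {
    if (is.null(qn$ids) || !length(qn$ids)) return(NULL)
    r <- vapply(qn$ids, resolve, character(1))
    unique(r[!is.na(r)])
  }
  want_cats <- function(qn) {
    if (is.null(qn$categories) || !length(qn$categories)) return(NULL)
    unique(unlist(lapply(qn$categories, function(cc)
      oracle_closure(model$categories, cc))))
  }
  ws <- want_ids(qn_s); wo <- want_ids(qn_o)
  cs <- want_cats(qn_s); co <- want_cats(qn_o)
  pred_ok <- if (is.null(qe$predicates) || !length(qe$predicates)) NULL
  else unique(unlist(lapply(qe$predicates, function(pp)
    oracle_closure(model$predicates, pp))))
  fits <- function(id, wids, wcats)
    (is.null(wids) || id %in% wids) &&
    (is.null(wcats) || any(cats_of(id) %in% wcats))
  res <- character(0)
  for (i in seq_len(nrow(graph$edges))) {
    es <- graph$edges$subject[i]; eo <- graph$edges$object[i]
    ep <- graph$edges$predicate[i]
    if (!is.null(pred_ok) && !ep %in% pred_ok) next
    ekey <- paste(es, ep, eo, sep = "--")
    if (fits(es, ws, cs) && fits(eo, wo, co))
      res <- c(res, paste(es, eo, ekey, sep = "\r"))
    if (ep %in% model$symmetric_predicates &&
        fits(eo, ws, cs) && fits(es, wo, co))
      res <- c(res, paste(eo, es, ekey, sep = "\r"))
  }
  sort(unique(res), method = "radix")
}

binding_keys <- function(result_set, sub_key, obj_key, edge_key) {
  if (!nrow(result_set$results)) return(character(0))
  sort(paste(result_set$results[[sub_key]], result_set$results[[obj_key]],
             result_set$results[[edge_key]], sep = "\r"), method = "radix")
}

# Oracle 4: group-by coalescing via split/apply.
oracle_coalesce <- function(edges) {
  key <- paste(edges$subject, edges$object, edges$predicate, sep = "\r")
  grp <- split(seq_len(nrow(edges)), factor(key, levels = unique(key)))
  do.call(rbind, lapply(grp, function(idx) {
    uni <- function(col) paste(unique(unlist(
      strsplit(edges[[col]][idx], "|", fixed = TRUE))), collapse = "|")
    data.frame(subject = edges$subject[idx[1]],
               predicate = edges$predicate[idx[1]],
               object = edges$object[idx[1]],
               relation = uni("relation"), provided_by = uni("provided_by"),
               publications = uni("publications"), stringsAsFactors = FALSE)
  }))
}

dir_digest <- function(dir, exclude = c("build_log.tsv", "checksums.tsv")) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% exclude]
  files <- sort(files)
  stats::setNames(unname(tools::md5sum(files)),
                  substring(files, nchar(dir) + 2L))
}
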