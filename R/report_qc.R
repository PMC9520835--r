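# QC reporting and graph statistics: build reports, cross-build drift
# comparison, degree histograms with discrete power-law fitting, and
# meta-triple tabulation.

#' Compute a build report
#'
#' Counts nodes by providing source and by category, and edges by providing
#' source and by predicate, plus totals. Per-source counts attribute a node
#' or edge once per providing source, so their sum may exceed the totals;
#' per-category and per-predicate counts each sum exactly to the totals.
#'
#' @param graph A [graph_document()].
#' @param stage Stage marker, e.g. `"pre_merge"` or `"post_merge"`.
#' @return A `build_report`: list of named count vectors
#'   (`nodes_by_source`, `nodes_by_category`, `edges_by_source`,
#'   `edges_by_predicate`) plus `totals` and `stage`.
#' @export
compute_report <- function(graph, stage = "post_merge") {
  count_by <- function(x) {
    if (!length(x)) return(stats::setNames(integer(0), character(0)))
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  }
  count_multi <- function(pv) count_by(unlist(pv_split(pv)))
  structure(list(
    nodes_by_source = count_multi(graph$nodes$provided_by),
    nodes_by_category = count_by(graph$nodes$category),
    edges_by_source = count_multi(graph$edges$provided_by),
    edges_by_predicate = count_by(graph$edges$predicate),
    totals = c(nodes = nrow(graph$nodes), edges = nrow(graph$edges)),
    stage = stage), class = "build_report")
}

#' @export
print.build_report <- function(x, ...) {
  cat(sprintf("<build_report> stage %s: %d nodes, %d edges\n",
              x$stage, x$totals["nodes"], x$totals["edges"]))
  invisible(x)
}

#' Flag anomalously large count changes between two build reports
#'
#' For every key in every count family of either report, flags the key when
#' the new/old ratio (or its inverse) strictly exceeds `fold` — the
#' "more than three-fold" drift rule used to surface systemic problems to a
#' build supervisor before a build goes into production. A key present in
#' only one report is always flagged with reason `"appeared"` or
#' `"vanished"` (a ratio against zero is undefined).
#'
#' @param old,new `build_report`s from [compute_report()].
#' @param fold Flagging threshold (> 1); default 3.
#' @return Data frame of flags: family, key, old, new, ratio, reason.
#' @export
compare_reports <- function(old, new, fold = 3) {
  stopifnot(fold > 1)
  families <- c("nodes_by_source", "nodes_by_category",
                "edges_by_source", "edges_by_predicate")
  rows <- list()
  for (fam in families) {
    o <- old[[fam]]; n <- new[[fam]]
    keys <- unique(c(names(o), names(n)))
    for (k in keys) {
      ov <- if (k %in% names(o)) o[[k]] else 0L
      nv <- if (k %in% names(n)) n[[k]] else 0L
      if (ov == 0L && nv == 0L) next
      reason <- NULL
      ratio <- NA_real_
      if (ov == 0L) reason <- "appeared"
      else if (nv == 0L) reason <- "vanished"
      else {
        ratio <- max(nv / ov, ov / nv)
        if (ratio > fold)
          reason <- if (nv > ov) "increase" else "decrease"
      }
      if (!is.null(reason))
        rows[[length(rows) + 1L]] <-
          data.frame(family = fam, key = k, old = ov, new = nv,
                     ratio = ratio, reason = reason, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(family = character(0), key = character(0),
                  old = integer(0), new = integer(0), ratio = numeric(0),
                  reason = character(0), stringsAsFactors = FALSE)
}

#' Total-degree histogram of a graph
#'
#' The degree of a node is the number of edge endpoints referencing it
#' (in + out); a self-loop contributes 2. Nodes referenced by no edge appear
#' at degree 0. Satisfies the handshake identity:
#' `sum(k * counts[k]) == 2 * |edges|`.
#'
#' @param graph A [graph_document()].
#' @return A `degree_histogram`: list with `counts` (named integer vector,
#'   names are degrees) and `n` (node count).
#' @export
degree_histogram <- function(graph) {
  n <- nrow(graph$nodes)
  endpoint_idx <- match(c(graph$edges$subject, graph$edges$object),
                        graph$nodes$id)
  deg <- tabulate(endpoint_idx, nbins = n)
  tab <- table(deg)
  structure(list(counts = stats::setNames(as.integer(tab), names(tab)),
                 n = n), class = "degree_histogram")
}

#' @export
print.degree_histogram <- function(x, ...) {
  cat(sprintf("<degree_histogram> %d nodes, degrees %s..%s\n", x$n,
              names(x$counts)[1], names(x$counts)[length(x$counts)]))
  invisible(x)
}

#' Fit a discrete power law to a degree histogram
#'
#' Models tail degrees `k >= xmin` as `p(k) ~ k^-alpha` and estimates the
#' exponent. `method = "mle"` (default) maximizes the exact discrete (zeta)
#' log-likelihood numerically; `method = "approx"` uses the closed-form
#' approximation `alpha = 1 + n / sum(log(k / (xmin - 1/2)))`, which is fast
#' but substantially biased at small `xmin` (at `xmin = 1` it understates
#' heavy-tailed exponents by several tenths), so the exact MLE is the
#' default. Degenerate input — all fitted degrees equal — yields a fit
#' flagged `degenerate` under `"approx"` and an estimation error under
#' `"mle"`; fewer than 2 distinct degrees at/above `xmin` is always an
#' estimation error.
#'
#' @param hist A [degree_histogram()].
#' @param xmin Minimum degree included in the fit (default 1; degrees below
#'   `max(xmin, 1)` are excluded).
#' @param method `"mle"` or `"approx"`.
#' @return A `power_law_fit`: list with `alpha`, `xmin`, `n_tail`, `method`,
#'   `degenerate`.
#' @export
fit_power_law <- function(hist, xmin = 1L, method = c("mle", "approx")) {
  method <- match.arg(method)
  xmin <- max(as.integer(xmin), 1L)
  k <- as.integer(names(hist$counts))
  cnt <- as.integer(hist$counts)
  keep <- k >= xmin
  k <- k[keep]; cnt <- cnt[keep]
  k <- k[cnt > 0L]; cnt <- cnt[cnt > 0L]
  if (length(k) < 2L)
    kg_stop("kg_estimation_error",
            "need at least 2 distinct degrees >= xmin to fit (found %d)",
            length(k))
  n_tail <- sum(cnt)
  degenerate <- FALSE
  if (method == "approx") {
    s <- sum(cnt * log(k / (xmin - 0.5)))
    if (s <= 0) degenerate <- TRUE
    alpha <- if (degenerate) Inf else 1 + n_tail / s
  } else {
    slk <- sum(cnt * log(k))
    nll <- function(a) n_tail * log(hurwitz_zeta(a, xmin)) + a * slk
    opt <- stats::optimize(nll, interval = c(1.000001, 25))
    alpha <- opt$minimum
    if (alpha > 24.9) degenerate <- TRUE
  }
  structure(list(alpha = alpha, xmin = xmin, n_tail = n_tail,
                 method = method, degenerate = degenerate),
            class = "power_law_fit")
}

# Hurwitz zeta: sum_{j >= xmin} j^-a, via the Riemann zeta minus the head.
hurwitz_zeta <- function(a, xmin) {
  z <- pracma::zeta(a)
  if (xmin > 1L) z <- z - sum((1:(xmin - 1L))^(-a))
  z
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.4f (xmin = %d, n_tail = %d, %s%s)\n",
              x$alpha, x$xmin, x$n_tail, x$method,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Tabulate meta-triples
#'
#' A meta-triple is a distinct (subject category, predicate, object category)
#' pattern; meta-triple counts measure a graph's semantic richness. Each edge
#' increments every cell in the Cartesian product of the subject node's
#' categories and the object node's categories (nodes carrying
#' `all_categories` contribute all of them; otherwise the primary category is
#' used), so an edge between multi-category nodes contributes
#' `|cats(subject)| * |cats(object)|` cells — which is why canonicalization,
#' which produces multi-category nodes, increases the meta-triple count.
#'
#' @param graph A [graph_document()] (typically canonicalized).
#' @return A `meta_triple_table`: list with `cells` (data frame
#'   subject_category, predicate, object_category, count) and `distinct`
#'   (number of non-empty cells).
#' @export
count_meta_triples <- function(graph) {
  node_cats <- if ("all_categories" %in% names(graph$nodes))
    pv_split(graph$nodes$all_categories) else as.list(graph$nodes$category)
  names(node_cats) <- graph$nodes$id
  keys <- character(0)
  if (nrow(graph$edges)) {
    per_edge <- lapply(seq_len(nrow(graph$edges)), function(i) {
      cs <- node_cats[[graph$edges$subject[i]]]
      co <- node_cats[[graph$edges$object[i]]]
      if (is.null(cs) || is.null(co)) return(character(0))
      as.vector(outer(cs, co, function(a, b)
        paste(a, graph$edges$predicate[i], b, sep = "\r")))
    })
    keys <- unlist(per_edge, use.names = FALSE)
  }
  if (length(keys)) {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    cells <- data.frame(
      subject_category = vapply(parts, `[`, character(1), 1),
      predicate = vapply(parts, `[`, character(1), 2),
      object_category = vapply(parts, `[`, character(1), 3),
      count = as.integer(tab), stringsAsFactors = FALSE)
    cells <- cells[order_c(cells$subject_category, cells$predicate,
                           cells$object_category), , drop = FALSE]
    rownames(cells) <- NULL
  } else {
    cells <- data.frame(subject_category = character(0),
                        predicate = character(0),
                        object_category = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(cells = cells, distinct = nrow(cells)),
            class = "meta_triple_table")
}

#' @export
print.meta_triple_table <- function(x, ...) {
  cat(sprintf("<meta_triple_table> %d distinct meta-triple(s), %d edge contribution(s)\n",
              x$distinct, sum(x$cells$count)))
  invisible(x)
}

#' Serialize a build report
#'
#' Writes the report both as structured text (one table per count family)
#' and machine-readable JSON.
#'
#' @param report A [compute_report()] result.
#' @param path Output path without extension; `<path>.txt` and `<path>.json`
#'   are written.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(list(
    stage = report$stage,
    totals = as.list(report$totals),
    nodes_by_source = as.list(report$nodes_by_source),
    nodes_by_category = as.list(report$nodes_by_category),
    edges_by_source = as.list(report$edges_by_source),
    edges_by_predicate = as.list(report$edges_by_predicate)),
    auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, paste0(path, ".json"), useBytes = TRUE)
  txt <- c(sprintf("build report (stage: %s)", report$stage),
           sprintf("total nodes: %d", report$totals["nodes"]),
           sprintf("total edges: %d", report$totals["edges"]))
  for (fam in c("nodes_by_source", "nodes_by_category",
                "edges_by_source", "edges_by_predicate")) {
    txt <- c(txt, "", paste0("[", fam, "]"))
    v <- report[[fam]]
    if (length(v))
      txt <- c(txt, paste0(names(v), "\t", unname(v)))
  }
  writeLines(txt, paste0(path, ".txt"), useBytes = TRUE)
  invisible(path)
}
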