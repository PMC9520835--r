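# Config-driven staged build runner: per-source ingest stages feed a single
# merge stage, then canonicalization, then the report/statistics stages.
# Source files are digested (content hashes, not timestamps) so that a
# rebuild can skip re-ingesting unchanged sources: their previously written
# stage outputs are reused and everything from the merge step onward reruns.

#' Plan a staged build
#'
#' Builds the stage DAG for a build config: one `ingest:<source>` stage per
#' source (in rank order), then `merge`, `canonicalize` and `report`. An
#' ingest stage is skippable iff its source file's checksum matches the
#' previous build's checksum and its output exists; merge and later stages
#' always run.
#'
#' @param config_path Path to the build config YAML (see
#'   [read_build_config()]).
#' @param out_dir Output directory for build artifacts.
#' @param previous_checksums Named character vector (file -> md5) from a
#'   previous build, or `NULL`; defaults to reading
#'   `<out_dir>/checksums.tsv` when present.
#' @return A `build_plan`: list with `stages` (data frame: name, inputs,
#'   outputs, skippable), `checksums` (current source digests), `config`,
#'   `config_path`, `out_dir`.
#' @export
plan_build <- function(config_path, out_dir,
                       previous_checksums = NULL) {
  config <- read_build_config(config_path)
  if (is.null(previous_checksums)) {
    ck_path <- file.path(out_dir, "checksums.tsv")
    if (file.exists(ck_path)) {
      df <- read_tsv_plain(ck_path)
      previous_checksums <- stats::setNames(df$md5, df$file)
    } else previous_checksums <- character(0)
  }
  src_paths <- vapply(config$sources, function(s) s$path, character(1))
  checksums <- stats::setNames(unname(tools::md5sum(src_paths)), src_paths)

  ingest_out <- file.path(out_dir, "ingest",
                          paste0(vapply(config$sources, function(s) s$name,
                                        character(1)), ".json"))
  stages <- data.frame(
    name = c(paste0("ingest:", vapply(config$sources, function(s) s$name,
                                      character(1))),
             "merge", "canonicalize", "report"),
    inputs = c(src_paths,
               paste(ingest_out, collapse = "|"),
               file.path(out_dir, "graph_pre.json"),
               paste(file.path(out_dir, c("graph_pre.json",
                                          "graph_canonical.json")),
                     collapse = "|")),
    outputs = c(ingest_out,
                paste(file.path(out_dir, c("graph_pre.json",
                                           "graph_pre_kgx",
                                           "merge_log")), collapse = "|"),
                file.path(out_dir, "graph_canonical.json"),
                paste(file.path(out_dir, c("report_pre.json",
                                           "report_canonical.json",
                                           "meta_triples.tsv",
                                           "degree_histogram.tsv")),
                      collapse = "|")),
    stringsAsFactors = FALSE)
  check_plan_acyclic(stages)
  n_src <- length(src_paths)
  skippable <- c(vapply(seq_len(n_src), function(i) {
    prev <- previous_checksums[src_paths[i]]
    !is.na(prev %||% NA) && !is.na(checksums[src_paths[i]]) &&
      identical(unname(prev), unname(checksums[src_paths[i]])) &&
      file.exists(ingest_out[i])
  }, logical(1)), rep(FALSE, 3L))
  stages$skippable <- skippable
  structure(list(stages = stages, checksums = checksums, config = config,
                 config_path = config_path, out_dir = out_dir),
            class = "build_plan")
}

# Kahn topological check over stage file dependencies.
check_plan_acyclic <- function(stages) {
  prod_of <- list()
  for (i in seq_len(nrow(stages)))
    for (f in strsplit(stages$outputs[i], "|", fixed = TRUE)[[1]])
      prod_of[[f]] <- i
  deps <- lapply(seq_len(nrow(stages)), function(i) {
    ins <- strsplit(stages$inputs[i], "|", fixed = TRUE)[[1]]
    unique(unlist(prod_of[ins]))
  })
  done <- rep(FALSE, nrow(stages))
  repeat {
    ready <- which(!done & vapply(deps, function(d) all(done[d]), logical(1)))
    if (!length(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done))
    kg_stop("kg_plan_error", "cyclic or unsatisfiable stage dependency at: %s",
            paste(stages$name[!done], collapse = ", "))
  invisible(stages)
}

#' @export
print.build_plan <- function(x, ...) {
  cat(sprintf("<build_plan> %d stage(s), %d skippable\n",
              nrow(x$stages), sum(x$stages$skippable)))
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %s%s\n", x$stages$name[i],
                if (x$stages$skippable[i]) " [skip]" else ""))
  invisible(x)
}

#' Run a planned build
#'
#' Executes the stages of a [plan_build()] plan in dependency order,
#' skipping up-to-date ingest stages (their previous outputs are loaded from
#' disk). Independent ingest stages may run concurrently (`workers > 1`, via
#' forked processes); outputs are byte-identical regardless of worker count
#' because results are collected in rank order and all writers are
#' deterministic. A structured per-stage log (status, seconds, record
#' counts) is written to `<out_dir>/build_log.tsv` along with the new source
#' checksums; a stage failure aborts its dependents with the stage name in
#' the error.
#'
#' Artifacts: per-source ingest JSON, merged pre-graph JSON + KGX TSV pair +
#' merge log, canonicalized graph JSON, pre/canonical build reports,
#' meta-triple table, degree histogram.
#'
#' @param plan A [plan_build()] result.
#' @param workers Number of parallel workers for ingest stages.
#' @return Invisibly, a list with the merged and canonical graphs, logs and
#'   report objects.
#' @export
run_build <- function(plan, workers = 1L) {
  out_dir <- plan$out_dir
  dir.create(file.path(out_dir, "ingest"), recursive = TRUE,
             showWarnings = FALSE)
  config <- plan$config
  model <- load_model(config$model_path)
  stage_log <- list()
  note <- function(stage, status, secs, nodes = NA_integer_,
                   edges = NA_integer_) {
    stage_log[[length(stage_log) + 1L]] <<-
      data.frame(stage = stage, status = status,
                 seconds = sprintf("%.3f", secs),
                 nodes = as.character(nodes), edges = as.character(edges),
                 stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      note(stage, "failed", proc.time()[["elapsed"]] - t0)
      write_build_log(stage_log, plan, out_dir)
      kg_stop("kg_stage_failure", "stage '%s' failed: %s", stage,
              conditionMessage(e))
    })
    note(stage, "ok", proc.time()[["elapsed"]] - t0,
         if (inherits(res, "graph_document")) nrow(res$nodes) else NA,
         if (inherits(res, "graph_document")) nrow(res$edges) else NA)
    res
  }

  n_src <- length(config$sources)
  ingest_rows <- seq_len(n_src)
  ingest_out <- plan$stages$outputs[ingest_rows]
  do_ingest <- function(i) {
    src <- config$sources[[i]]
    if (plan$stages$skippable[i]) {
      g <- read_graph_json(ingest_out[i])
      g$build_info$source_rank <- src$rank       # ranks are not serialized
      g$build_info$source_name <- src$name
      g
    } else {
      g <- ingest_source(src, model, config$iri_map)
      write_graph_json(g, ingest_out[i])
      g
    }
  }
  parts <- if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(ingest_rows, function(i)
      tryCatch(do_ingest(i), error = function(e) e), mc.cores = workers)
    for (i in ingest_rows) {
      t0 <- proc.time()[["elapsed"]]
      if (inherits(res[[i]], "error")) {
        note(plan$stages$name[i], "failed", 0)
        write_build_log(stage_log, plan, out_dir)
        kg_stop("kg_stage_failure", "stage '%s' failed: %s",
                plan$stages$name[i], conditionMessage(res[[i]]))
      }
      note(plan$stages$name[i],
           if (plan$stages$skippable[i]) "skipped" else "ok",
           proc.time()[["elapsed"]] - t0,
           nrow(res[[i]]$nodes), nrow(res[[i]]$edges))
    }
    res
  } else {
    lapply(ingest_rows, function(i) {
      if (plan$stages$skippable[i]) {
        g <- do_ingest(i)
        note(plan$stages$name[i], "skipped", 0, nrow(g$nodes), nrow(g$edges))
        g
      } else run_stage(plan$stages$name[i], function() do_ingest(i))
    })
  }

  merged <- run_stage("merge", function() {
    m <- merge_graphs(parts, model)
    write_graph_json(m$graph, file.path(out_dir, "graph_pre.json"))
    write_kgx_tsv(m$graph, file.path(out_dir, "graph_pre_kgx"))
    write_merge_log(m$log, file.path(out_dir, "merge_log"))
    attr(m$graph, "merge_log") <- m$log
    m$graph
  })
  merge_log <- attr(merged, "merge_log")

  source_ranks <- stats::setNames(
    vapply(config$sources, function(s) s$rank, integer(1)),
    paste0("KGSOURCE:", vapply(config$sources, function(s) s$name,
                               character(1))))
  canonical <- run_stage("canonicalize", function() {
    part <- build_partition(merged, model)
    cg <- build_canonical_graph(merged, part, model,
                                source_ranks = source_ranks)
    write_graph_json(cg$graph, file.path(out_dir, "graph_canonical.json"))
    attr(cg$graph, "canonicalization_log") <- cg$log
    attr(cg$graph, "partition") <- part
    cg$graph
  })

  reports <- run_stage("report", function() {
    rep_pre <- compute_report(merged, "pre_merge")
    rep_can <- compute_report(canonical, "post_merge")
    write_report(rep_pre, file.path(out_dir, "report_pre"))
    write_report(rep_can, file.path(out_dir, "report_canonical"))
    mt <- count_meta_triples(canonical)
    write_tsv_plain(mt$cells, file.path(out_dir, "meta_triples.tsv"))
    dh <- degree_histogram(canonical)
    write_tsv_plain(data.frame(degree = names(dh$counts),
                               count = unname(dh$counts)),
                    file.path(out_dir, "degree_histogram.tsv"))
    list(pre = rep_pre, canonical = rep_can, meta_triples = mt,
         degree_histogram = dh)
  })

  write_build_log(stage_log, plan, out_dir)
  invisible(list(pre_graph = merged, canonical_graph = canonical,
                 merge_log = merge_log,
                 canonicalization_log = attr(canonical,
                                             "canonicalization_log"),
                 partition = attr(canonical, "partition"),
                 reports = reports, out_dir = out_dir))
}

write_build_log <- function(stage_log, plan, out_dir) {
  log_df <- if (length(stage_log)) do.call(rbind, stage_log) else
    data.frame(stage = character(0), status = character(0),
               seconds = character(0), nodes = character(0),
               edges = character(0), stringsAsFactors = FALSE)
  write_tsv_plain(log_df, file.path(out_dir, "build_log.tsv"))
  write_tsv_plain(data.frame(file = names(plan$checksums),
                             md5 = unname(plan$checksums),
                             stringsAsFactors = FALSE),
                  file.path(out_dir, "checksums.tsv"))
  invisible(out_dir)
}

#' Plan and run a full build in one call
#'
#' @inheritParams plan_build
#' @inheritParams run_build
#' @return See [run_build()].
#' @export
build_all <- function(config_path, out_dir, workers = 1L,
                      previous_checksums = NULL) {
  run_build(plan_build(config_path, out_dir, previous_checksums), workers)
}
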