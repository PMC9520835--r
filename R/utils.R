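# Internal helpers shared across modules.

# Multivalued text fields (relation, provided_by, publications, ...) are stored
# as "|"-joined strings inside graph data frames; these helpers convert between
# that storage form and character vectors. "" means the empty set.

pv_split <- function(x) {
  out <- strsplit(x, "|", fixed = TRUE)
  out[!nzchar(x)] <- list(character(0))
  out
}

pv_join <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = "|"), character(1))
}

# Elementwise ordered-set union of two pipe-vectors (first-seen order kept).
pv_union <- function(a, b) {
  pv_join(Map(function(x, y) unique(c(x, y)), pv_split(a), pv_split(b)))
}

# Ordered-set union within groups: collapse pipe-vector x by factor f,
# preserving first-seen order of elements.
pv_collapse <- function(x, f) {
  parts <- pv_split(x)
  grp <- split(parts, f)
  vapply(grp, function(g) paste(unique(unlist(g, use.names = FALSE)),
                                collapse = "|"), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Package conditions ---------------------------------------------------------

kg_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "kgbuildr_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

kg_note <- function(class, fmt, ...) {
  message(structure(class = c(class, "kgbuildr_message", "message", "condition"),
                    list(message = paste0(sprintf(fmt, ...), "\n"))))
}

# Log accumulator used by ingest/merge stages: a plain data frame of events.
kg_log_df <- function() {
  data.frame(event = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

kg_log_add <- function(log, event, detail) {
  rbind(log, data.frame(event = event, detail = detail,
                        stringsAsFactors = FALSE))
}

# Deterministic string sort (byte order, locale-independent).
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

# Elementwise byte-order "a > b" for strings (locale-independent).
str_gt <- function(a, b) {
  out <- logical(length(a))
  ne <- a != b
  for (i in which(ne)) {
    out[i] <- order(c(a[i], b[i]), method = "radix")[1] == 2L
  }
  out
}
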