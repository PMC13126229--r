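#' Document-centric trial collections
#'
#' Trial records are stored as self-standing documents preserving each
#' register's own data model, in a backend-agnostic collection. Two backends
#' implement the contract: the embedded single-file backend (one serialized
#' JSON document per line of an NDJSON file, survives sessions) and the
#' in-memory reference backend. Both expose identical behaviour; documents
#' are normalised through JSON serialisation on upsert so that what a reader
#' gets never depends on the backend.
#'
#' @name docstore
NULL

#' Open (or create) a trial collection
#'
#' @param path File path for the embedded single-file backend; `NULL` selects
#'   the in-memory backend.
#' @param name Collection name.
#' @param backend `"file"` or `"memory"`; inferred from `path` by default.
#' @return A `trial_collection`.
#' @examples
#' col <- open_collection() # in-memory
#' @export
open_collection <- function(path = NULL, name = "trials",
                            backend = if (is.null(path)) "memory" else "file") {
  backend <- match.arg(backend, c("file", "memory"))
  assert_that(backend == "memory" || !is.null(path),
              "the file backend needs a `path`", "regharvest_argument_error")
  env <- new.env(parent = emptyenv())
  env$docs <- list()
  env$meta <- list()
  env$closed <- FALSE
  col <- structure(list(name = name, backend = backend, path = path, env = env),
                   class = "trial_collection")
  if (backend == "file" && file.exists(path)) {
    for (line in readLines(path, warn = FALSE)) {
      if (!nzchar(line)) next
      doc <- jsonlite::fromJSON(line, simplifyVector = FALSE)
      env$docs[[doc[["_id"]]]] <- doc
    }
    mpath <- paste0(path, ".meta")
    if (file.exists(mpath)) {
      env$meta <- lapply(readLines(mpath, warn = FALSE),
                         jsonlite::fromJSON, simplifyVector = FALSE)
    }
  }
  col
}

#' @export
print.trial_collection <- function(x, ...) {
  cat(sprintf("<trial_collection '%s' (%s backend): %d document(s), %d query-history entr%s>\n",
              x$name, x$backend, length(x$env$docs), length(x$env$meta),
              if (length(x$env$meta) == 1) "y" else "ies"))
  invisible(x)
}

check_open <- function(col) {
  assert_that(inherits(col, "trial_collection"), "not a trial_collection",
              "regharvest_argument_error")
  if (isTRUE(col$env$closed)) {
    abort("operation on a closed collection",
          class = c("regharvest_closed_error", "regharvest_error"))
  }
  invisible(col)
}

#' Close a collection
#'
#' Subsequent operations fail cleanly.
#' @param col A `trial_collection`.
#' @return The collection, invisibly.
#' @export
close_collection <- function(col) {
  col$env$closed <- TRUE
  invisible(col)
}

doc_serialize <- function(doc) {
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

doc_normalize <- function(doc) {
  jsonlite::fromJSON(doc_serialize(doc), simplifyVector = FALSE)
}

persist_docs <- function(col) {
  if (col$backend != "file") return(invisible(NULL))
  lines <- vapply(col$env$docs, function(d) as.character(doc_serialize(d)), character(1))
  writeLines(unname(lines), col$path)
  invisible(NULL)
}

persist_meta <- function(col) {
  if (col$backend != "file") return(invisible(NULL))
  lines <- vapply(col$env$meta, function(m) as.character(doc_serialize(m)), character(1))
  writeLines(unname(lines), paste0(col$path, ".meta"))
  invisible(NULL)
}

col_upsert <- function(col, doc) {
  check_open(col)
  assert_that(!is.null(doc[["_id"]]) && nzchar(doc[["_id"]]),
              "document must carry a non-empty `_id`", "regharvest_argument_error")
  col$env$docs[[doc[["_id"]]]] <- doc_normalize(doc)
  persist_docs(col)
  invisible(doc[["_id"]])
}

col_get <- function(col, id) {
  check_open(col)
  col$env$docs[[id]]
}

col_ids <- function(col) {
  check_open(col)
  names(col$env$docs) %||% character(0)
}

col_docs <- function(col) {
  check_open(col)
  col$env$docs
}

col_delete <- function(col, id) {
  check_open(col)
  col$env$docs[[id]] <- NULL
  persist_docs(col)
  invisible(NULL)
}

col_append_meta <- function(col, entry) {
  check_open(col)
  col$env$meta[[length(col$env$meta) + 1]] <- doc_normalize(entry)
  persist_meta(col)
  invisible(length(col$env$meta))
}

#' Query history of a collection
#'
#' Every load or update appends one immutable provenance entry, so a
#' collection can be reproduced from its own metadata.
#'
#' @param col A `trial_collection`.
#' @return A tibble with `index`, `query_url`, `register`, `timestamp`
#'   and `record_count`.
#' @export
query_history <- function(col) {
  check_open(col)
  purrr::imap_dfr(col$env$meta, function(m, i) {
    tibble::tibble(index = i, query_url = m$query_url, register = m$register,
                   timestamp = m$timestamp, record_count = m$record_count)
  })
}

#' @importFrom generics glance
#' @export
generics::glance

#' Summarise a collection
#'
#' @param x A `trial_collection`.
#' @param ... Unused.
#' @return One-row tibble: documents, registers, annotated documents,
#'   query-history length.
#' @method glance trial_collection
#' @export
glance.trial_collection <- function(x, ...) {
  docs <- col_docs(x)
  tibble::tibble(
    n_documents = length(docs),
    n_registers = length(unique(vapply(docs, function(d) d$register, character(1)))),
    n_annotated = sum(vapply(docs, function(d) nzchar(d$annotation %||% ""), logical(1))),
    n_queries = length(x$env$meta)
  )
}
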