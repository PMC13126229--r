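#' Loading register records into a collection
#'
#' Records matching a query are parsed into documents preserving the source
#' data model and upserted into a collection. Every load appends an immutable
#' query-history entry, re-loading overwrites record content while preserving
#' user annotations, and historic record versions can be captured either from
#' the source (CTGOV-style version ladders) or by pushing the stored record
#' onto its history before an update (CTIS-style).
#'
#' @name ingest
NULL

as_array <- function(x) {
  if (is.null(x)) list() else if (is_array_node(x)) x else list(x)
}

# Parse one payload into a list of (record_id, content) pairs.
parse_payload <- function(register, body) {
  if (register %in% c("CTGOV", "CTIS")) {
    tree <- json_to_tree(body)
    recs <- if (register == "CTGOV") as_array(tree$studies) else as_array(tree$data)
    lapply(recs, function(content) {
      id <- if (register == "CTGOV") {
        content$protocolSection$identificationModule$nctId
      } else {
        content$ctNumber
      }
      list(record_id = id, content = content)
    })
  } else if (register == "EUCTR") {
    tree <- xml_to_tree(body)
    lapply(as_array(tree$trial), function(content) {
      list(record_id = content$identification$full_id, content = content)
    })
  } else {
    tree <- xml_to_tree(body)
    lapply(as_array(tree$fullTrial), function(ft) {
      content <- ft$trial
      list(record_id = content$isrctn, content = content)
    })
  }
}

apply_annotation <- function(existing, text, mode) {
  if (!nzchar(text)) return(existing %||% "")
  existing <- existing %||% ""
  switch(mode,
    replace = text,
    prepend = if (nzchar(existing)) paste(text, existing) else text,
    append  = if (nzchar(existing)) paste(existing, text) else text
  )
}

# Member-state preference shared by euctr_protocols_all = FALSE and the
# deduplication concept: the requested member state when available, else the
# alphabetically first.
pick_member_state <- function(available, prefer = NULL) {
  available <- sort(available)
  if (!is.null(prefer) && prefer %in% available) prefer else available[1]
}

#' Load the results of a register query into a collection
#'
#' Each matching record is parsed into a document and upserted; a
#' query-history entry is appended. Re-loading a record overwrites its content
#' but preserves any user annotation. With `euctr_protocols_all = FALSE` a
#' single member-state record is kept per EUCTR trial (the preferred member
#' state, alphabetically first by default).
#'
#' @param spec A `query_spec`, search URL, or one row of [generate_queries()].
#' @param store A `trial_collection`.
#' @param source A register source.
#' @param with_results Also retrieve results-related data where the register
#'   provides it in structured form (CTGOV always includes results).
#' @param euctr_protocols_all Keep every member-state record of an EUCTR trial
#'   (default) or just one.
#' @param ctgov_history Historic versions to capture for CTGOV records: a
#'   count `k` (equally spaced from first to current version), a range
#'   `"n:m"`, `"ALL"`, or `NULL` for none.
#' @param prefer_member_state Member-state code preferred when
#'   `euctr_protocols_all = FALSE`.
#' @param documents_path If set, trial documents are materialised under this
#'   directory (see [fetch_documents()]).
#' @param documents_regexp Pattern selecting documents to fetch with content;
#'   `NULL` creates empty placeholder files for every available document.
#' @param annotation_text Text attached to every record loaded by this call.
#' @param annotation_mode How `annotation_text` combines with an existing
#'   annotation: `"append"` (default, single-space separated), `"prepend"`, or
#'   `"replace"`.
#' @return A `load_result`: `n_loaded`, `ids_loaded`, `ids_failed`, `query`.
#' @export
load_query <- function(spec, store, source,
                       with_results = FALSE,
                       euctr_protocols_all = TRUE,
                       ctgov_history = NULL,
                       prefer_member_state = NULL,
                       documents_path = NULL,
                       documents_regexp = NULL,
                       annotation_text = "",
                       annotation_mode = c("append", "prepend", "replace")) {
  annotation_mode <- match.arg(annotation_mode)
  spec <- as_query_spec(spec)
  check_open(store)
  canonical <- canonicalize_criteria(spec$register, spec$criteria)
  record_ids <- src_search(source, spec$register, canonical)
  trial_ids <- unique(if (spec$register == "EUCTR") sub("-[A-Z]{2}$", "", record_ids) else record_ids)

  ids_loaded <- character(0)
  ids_failed <- character(0)
  now <- Sys.time()
  for (tid in trial_ids) {
    pl <- src_fetch(source, spec$register, tid, with_results = with_results)
    if (is.null(pl)) {
      ids_failed <- c(ids_failed, tid)
      next
    }
    recs <- tryCatch(parse_payload(spec$register, pl$body), error = function(e) NULL)
    if (is.null(recs)) {
      ids_failed <- c(ids_failed, tid)
      next
    }
    if (spec$register == "EUCTR" && !euctr_protocols_all && length(recs) > 1) {
      ms <- sub("^.*-([A-Z]{2})$", "\\1", vapply(recs, function(r) r$record_id, character(1)))
      keep <- pick_member_state(ms, prefer_member_state)
      recs <- recs[ms == keep]
    }
    history <- NULL
    if (spec$register == "CTGOV" && !is.null(ctgov_history) &&
        !identical(ctgov_history, "NONE")) {
      available <- src_versions_count(source, "CTGOV", tid)
      idx <- select_history_versions(available, ctgov_history)
      history <- lapply(idx, function(i) {
        vp <- src_fetch_version(source, "CTGOV", tid, i)
        vrec <- parse_payload("CTGOV", vp$body)[[1]]
        list(version_date = as.character(src_version_date(source, "CTGOV", tid, i)),
             content = vrec$content)
      })
    }
    for (r in recs) {
      existing <- col_get(store, r$record_id)
      doc <- list(
        `_id` = r$record_id,
        register = spec$register,
        content = r$content,
        annotation = apply_annotation(existing$annotation, annotation_text, annotation_mode),
        history = history %||% existing$history %||% list(),
        last_import = format(now, "%Y-%m-%dT%H:%M:%S")
      )
      col_upsert(store, doc)
      ids_loaded <- c(ids_loaded, r$record_id)
    }
  }
  col_append_meta(store, list(
    query_url = spec$url,
    register = spec$register,
    timestamp = as.numeric(now),
    timestamp_iso = format(now, "%Y-%m-%dT%H:%M:%S"),
    record_count = length(ids_loaded)
  ))
  if (!is.null(documents_path)) {
    fetch_documents(spec, source, documents_path, documents_regexp)
  }
  structure(list(n_loaded = length(ids_loaded), ids_loaded = ids_loaded,
                 ids_failed = ids_failed, query = spec),
            class = "load_result")
}

#' @export
print.load_result <- function(x, ...) {
  cat(sprintf("<load_result %s: %d loaded, %d failed>\n",
              x$query$register, x$n_loaded, length(x$ids_failed)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a load result
#'
#' @param x A `load_result`.
#' @param ... Unused.
#' @return A tibble with `record_id` and `outcome` (`"loaded"`/`"failed"`).
#' @method tidy load_result
#' @export
tidy.load_result <- function(x, ...) {
  tibble::tibble(
    record_id = c(x$ids_loaded, x$ids_failed),
    outcome = rep(c("loaded", "failed"), c(length(x$ids_loaded), length(x$ids_failed)))
  )
}

#' Re-run a previous query to capture updates
#'
#' Re-executes the query behind an existing query-history entry, restricted to
#' records changed since that entry's timestamp (full reload when the source
#' cannot filter by date). With `ctis_history = TRUE` the stored current
#' content of each updated CTIS record is pushed onto its history array before
#' the record is updated.
#'
#' @param index 1-based index into [query_history()].
#' @param store A `trial_collection`.
#' @param source A register source.
#' @param ctis_history Capture the pre-update CTIS record as a historic
#'   version.
#' @param ... Further options passed to [load_query()].
#' @return A `load_result`.
#' @export
update_query <- function(index, store, source, ctis_history = FALSE, ...) {
  check_open(store)
  meta <- store$env$meta
  assert_that(length(index) == 1 && index >= 1 && index <= length(meta),
              sprintf("no query-history entry %s", index), "regharvest_argument_error")
  entry <- meta[[index]]
  spec <- parse_query_url(entry$query_url)
  canonical <- canonicalize_criteria(spec$register, spec$criteria)

  # restrict to records changed since the entry, where the source supports it
  changed_keys <- NULL
  if (inherits(source, "fixture_source")) {
    matched <- src_match_seeds(source, spec$register, canonical)
    changed_keys <- names(matched)[vapply(matched, function(s) {
      as.numeric(src_modified_at(source, s$seed_key)) > as.numeric(entry$timestamp)
    }, logical(1))]
    if (length(changed_keys) == 0) {
      col_append_meta(store, list(query_url = spec$url, register = spec$register,
                                  timestamp = as.numeric(Sys.time()),
                                  timestamp_iso = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                  record_count = 0L))
      return(structure(list(n_loaded = 0L, ids_loaded = character(0),
                            ids_failed = character(0), query = spec),
                       class = "load_result"))
    }
  }

  if (ctis_history && spec$register == "CTIS") {
    for (id in col_ids(store)) {
      doc <- col_get(store, id)
      if (doc$register != "CTIS") next
      s <- seed_for_record(source, "CTIS", id)
      if (is.null(s) || (!is.null(changed_keys) && !s$seed_key %in% changed_keys)) next
      doc$history <- c(doc$history %||% list(), list(list(
        version_date = doc$content$lastUpdated %||% doc$last_import,
        content = doc$content
      )))
      col_upsert(store, doc)
    }
  }

  if (!is.null(changed_keys)) {
    restricted <- restrict_source(source, changed_keys)
    load_query(spec, store, restricted, ...)
  } else {
    load_query(spec, store, source, ...)
  }
}

# A view of a fixture source limited to given seed keys (the transport-level
# "changed since" filter).
restrict_source <- function(source, seed_keys) {
  env <- new.env(parent = emptyenv())
  env$seeds <- source$env$seeds[seed_keys]
  env$modified_at <- source$env$modified_at[seed_keys]
  structure(list(dir = source$dir, env = env), class = "fixture_source")
}

#' Select historic record versions
#'
#' Given `available` versions (1 = first, `available` = current), returns the
#' version indices selected by `request`: a count `k` picks `k` indices
#' equally spaced from the first to the current version (round-half-up
#' spacing, always including both ends for `k >= 2`); a string `"n:m"` picks
#' the n-th to the m-th version; `"ALL"` (or `TRUE`) picks every version;
#' `"NONE"` (or `NULL`) picks none.
#'
#' @param available Number of available versions (>= 1).
#' @param request Count, `"n:m"`, `"ALL"`/`TRUE`, or `"NONE"`/`NULL`.
#' @return Integer vector of version indices.
#' @export
select_history_versions <- function(available, request) {
  assert_that(length(available) == 1 && available >= 1,
              "`available` must be a positive count", "regharvest_argument_error")
  if (is.null(request) || identical(request, "NONE")) return(integer(0))
  if (isTRUE(request) || identical(request, "ALL")) return(seq_len(available))
  if (is.character(request) && grepl("^\\d+:\\d+$", request)) {
    nm <- as.integer(strsplit(request, ":")[[1]])
    assert_that(nm[1] >= 1 && nm[2] >= nm[1] && nm[2] <= available,
                sprintf("range %s outside 1..%d", request, available),
                "regharvest_argument_error")
    return(seq.int(nm[1], nm[2]))
  }
  if (is.numeric(request) && length(request) == 1) {
    k <- as.integer(request)
    assert_that(k >= 1, "`request` count must be positive", "regharvest_argument_error")
    if (k == 1) return(as.integer(available))
    if (k >= available) return(seq_len(available))
    return(unique(as.integer(round_half_up(seq(1, available, length.out = k)))))
  }
  abort("`request` must be a count, 'n:m', 'ALL'/TRUE or 'NONE'/NULL",
        class = c("regharvest_argument_error", "regharvest_error"))
}

#' Materialise trial documents on disk
#'
#' With `documents_regexp = NULL`, an empty placeholder file is created for
#' every document the source offers (so the set of available documents can be
#' surveyed before downloading anything); with a pattern, only matching
#' documents are fetched with content. File names preserve register naming
#' (`<register>_<record>_<document>`), and repeated calls are idempotent.
#'
#' @param spec A `query_spec`, search URL, or one row of [generate_queries()].
#' @param source A register source.
#' @param documents_path Writable output directory (checked before any
#'   transport activity).
#' @param documents_regexp Pattern selecting documents to download, or `NULL`
#'   for placeholders only.
#' @return Character vector of file paths.
#' @export
fetch_documents <- function(spec, source, documents_path, documents_regexp = NULL) {
  spec <- as_query_spec(spec)
  if (!dir.exists(documents_path)) {
    ok <- dir.create(documents_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create '%s'", documents_path),
                   class = c("regharvest_io_error", "regharvest_error"))
  }
  if (file.access(documents_path, 2) != 0) {
    abort(sprintf("'%s' is not writable", documents_path),
          class = c("regharvest_io_error", "regharvest_error"))
  }
  canonical <- canonicalize_criteria(spec$register, spec$criteria)
  record_ids <- src_search(source, spec$register, canonical)
  trial_ids <- unique(if (spec$register == "EUCTR") sub("-[A-Z]{2}$", "", record_ids) else record_ids)
  paths <- character(0)
  for (tid in trial_ids) {
    for (nm in src_documents(source, spec$register, tid)) {
      dest <- file.path(documents_path, paste(spec$register, tid, nm, sep = "_"))
      if (is.null(documents_regexp) || identical(documents_regexp, "NONE")) {
        file.create(dest) # zero-byte placeholder
        paths <- c(paths, dest)
      } else if (grepl(documents_regexp, nm)) {
        writeLines(src_fetch_document(source, spec$register, tid, nm), dest)
        paths <- c(paths, dest)
      }
    }
  }
  paths
}
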