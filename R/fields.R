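#' Field discovery and wide-table extraction
#'
#' Documents are addressed by dotted field paths; arrays are traversed
#' implicitly (no positional indices in the path). Extraction produces a tidy
#' wide table, one row per record, with typed scalar columns or ordered
#' sequences where a path crosses arrays.
#'
#' @name field-extraction
NULL

#' Discover field paths in a collection
#'
#' Lists every dotted path present in the inspected documents, tagged with the
#' registers it occurs in.
#'
#' @param col A `trial_collection`.
#' @param sample `"all"` inspects every document, `"sample"` up to ten per
#'   register (first in id order, deterministic).
#' @param name_pattern Optional regular expression filtering paths by name.
#' @return A tibble with `path` and a `registers` list-column (sorted codes).
#' @export
find_fields <- function(col, sample = c("all", "sample"), name_pattern = NULL) {
  sample <- match.arg(sample)
  docs <- col_docs(col)
  if (length(docs) == 0) {
    abort("collection is empty", class = c("regharvest_empty_collection_error",
                                           "regharvest_error"))
  }
  regs <- vapply(docs, function(d) d$register, character(1))
  if (sample == "sample") {
    keep <- unlist(lapply(split(names(docs), regs), function(ids) utils::head(sort(ids), 10)))
    docs <- docs[keep]
    regs <- regs[keep]
  }
  seen <- list()
  for (i in seq_along(docs)) {
    for (p in tree_paths(docs[[i]]$content)) {
      seen[[p]] <- union(seen[[p]], regs[[i]])
    }
  }
  out <- tibble::tibble(
    path = sort(names(seen)),
    registers = lapply(sort(names(seen)), function(p) sort(seen[[p]]))
  )
  if (!is.null(name_pattern)) {
    out <- out[grepl(name_pattern, out$path, ignore.case = TRUE), ]
  }
  out
}

# Column-typing heuristic: a column is a date when at least 90% of its
# non-missing values are ISO-8601; integer/real by lossless parse of all
# values; flag for register boolean literals; otherwise text. Sequences
# (paths crossing arrays with multiple leaves) are never coerced.
FLAG_LITERALS_TRUE <- c("true", "yes")
FLAG_LITERALS_FALSE <- c("false", "no")

type_scalar_column <- function(values) {
  chr <- vapply(values, function(v) {
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
  }, character(1))
  chr <- normalize_missing(chr)
  present <- chr[!is.na(chr)]
  if (length(present) == 0) return(rep(NA_character_, length(chr)))
  if (mean(is_iso_date(present)) >= 0.9) {
    return(as_date_safe(chr))
  }
  low <- tolower(present)
  if (all(low %in% c(FLAG_LITERALS_TRUE, FLAG_LITERALS_FALSE))) {
    out <- rep(NA, length(chr))
    out[!is.na(chr)] <- tolower(chr[!is.na(chr)]) %in% FLAG_LITERALS_TRUE
    return(out)
  }
  num <- suppressWarnings(as.numeric(present))
  if (!anyNA(num)) {
    full <- suppressWarnings(as.numeric(chr))
    if (all(num == trunc(num)) && all(abs(num) < .Machine$integer.max)) {
      return(as.integer(full))
    }
    return(full)
  }
  chr
}

#' Extract fields and concepts into a wide table
#'
#' One row per record; one column per requested path, plus the output columns
#' of any requested harmonised trial concepts. A path absent from a record
#' yields a missing cell; a path crossing arrays yields an ordered sequence
#' (list-column, nesting preserved), never silently the first element.
#'
#' @param col A `trial_collection`.
#' @param paths Character vector of dotted field paths (`"_id"` is always
#'   included).
#' @param calculate Character vector of trial-concept names (see
#'   [concept_registry()]); each concept appends its output column(s).
#' @return A `trial_wide_tbl` (tibble subclass) keyed by `_id`.
#' @export
get_fields <- function(col, paths = character(0), calculate = character(0)) {
  assert_that(length(paths) > 0 || length(calculate) > 0,
              "request at least one path or concept", "regharvest_argument_error")
  docs <- col_docs(col)
  ids <- names(docs) %||% character(0)
  out <- tibble::tibble(`_id` = ids)
  for (p in setdiff(paths, "_id")) {
    cells <- lapply(docs, function(d) tree_extract(d$content, p))
    n_leaves <- vapply(cells, function(x) length(extraction_leaves(x)$identifier), integer(1))
    if (any(n_leaves > 1)) {
      out[[p]] <- unname(cells) # sequence column, nesting preserved
    } else {
      out[[p]] <- type_scalar_column(lapply(cells, function(x) {
        lv <- extraction_leaves(x)$value
        if (length(lv)) lv[[1]] else NULL
      }))
    }
  }
  if (length(calculate) > 0) {
    cc <- calculate_concepts(docs, calculate)
    out <- dplyr::bind_cols(out, cc)
  }
  class(out) <- c("trial_wide_tbl", class(out))
  out
}

#' Render one stored trial as an indented text tree
#'
#' A textual, stable rendering of a record's structure: every leaf appears
#' exactly once, with array elements indexed in document order.
#'
#' @param col A `trial_collection`.
#' @param record_id Stored record id.
#' @return A single string (lines joined with newline).
#' @export
show_trial_tree <- function(col, record_id) {
  doc <- col_get(col, record_id)
  if (is.null(doc)) {
    abort(sprintf("no record '%s' in collection", record_id),
          class = c("regharvest_not_found_error", "regharvest_error"))
  }
  header <- sprintf("%s (%s)", record_id, doc$register)
  paste(c(header, tree_render(doc$content, indent = 1)), collapse = "\n")
}

#' Export a wide table as CSV
#'
#' Sequence cells are joined with `" / "`.
#'
#' @param table A wide table from [get_fields()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_wide_csv <- function(table, path) {
  flat <- dplyr::mutate(tibble::as_tibble(table), dplyr::across(
    dplyr::where(is.list),
    ~vapply(.x, function(cell) {
      vals <- extraction_values(cell)
      if (is.null(vals)) NA_character_ else paste(vals, collapse = " / ")
    }, character(1))
  ))
  utils::write.csv(flat, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a wide table as NDJSON
#'
#' Sequence cells are serialized as JSON arrays (flattened, document order).
#'
#' @inheritParams export_wide_csv
#' @return `path`, invisibly.
#' @export
export_wide_ndjson <- function(table, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (r in seq_len(nrow(table))) {
    row <- lapply(as.list(table[r, ]), function(v) {
      if (is.list(v)) {
        vals <- extraction_values(v[[1]])
        if (is.null(vals)) NULL else vals
      } else if (inherits(v, "Date")) as.character(v) else v
    })
    writeLines(jsonlite::toJSON(drop_nulls(row), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}
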