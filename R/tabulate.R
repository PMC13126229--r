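#' Long-format reshaping and cross-register merging
#'
#' Nested extractions are exploded to a long table of
#' (`_id`, `name`, `identifier`, `value`) rows, where `identifier` is the
#' dotted positional index through the arrays a path crosses (`"2.1"` = second
#' element of the outer array, first of the inner). Values nested at related
#' positions can then be selected by name and co-indexed where-clauses, and
#' same-typed columns from different registers merged into one variable.
#'
#' @name tabulate
NULL

#' Explode a wide table to long format
#'
#' Every leaf value of every sequence cell appears exactly once; scalar cells
#' get identifier `"1"`.
#'
#' @param table A wide table from [get_fields()] (must contain `_id`).
#' @return A tibble with `_id`, `name`, `identifier`, `value` (character).
#' @export
trials_to_long <- function(table) {
  assert_that("_id" %in% names(table), "table must contain an `_id` column",
              "regharvest_argument_error")
  cols <- setdiff(names(table), "_id")
  out <- purrr::map_dfr(cols, function(cn) {
    col <- table[[cn]]
    purrr::map_dfr(seq_len(nrow(table)), function(r) {
      cell <- if (is.list(col)) col[[r]] else col[r]
      if (is.list(col)) {
        lv <- extraction_leaves(cell)
        if (length(lv$identifier) == 0) return(NULL)
        tibble::tibble(`_id` = table[["_id"]][r], name = cn,
                       identifier = lv$identifier,
                       value = vapply(lv$value, as.character, character(1)))
      } else {
        if (is.na(cell)) return(NULL)
        tibble::tibble(`_id` = table[["_id"]][r], name = cn,
                       identifier = "1", value = as.character(cell))
      }
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(`_id` = character(0), name = character(0),
                          identifier = character(0), value = character(0))
  }
  class(out) <- c("trial_long_tbl", class(out))
  out
}

id_components <- function(x) strsplit(x, ".", fixed = TRUE)

# Longest-common-array-prefix match: two identifiers are co-indexed when
# their first min(depth_a, depth_b) components agree.
identifiers_coindexed <- function(a, b) {
  ca <- strsplit(a, ".", fixed = TRUE)[[1]]
  cb <- strsplit(b, ".", fixed = TRUE)[[1]]
  k <- min(length(ca), length(cb))
  identical(ca[seq_len(k)], cb[seq_len(k)])
}

#' Select long rows by name, optionally gated by a co-indexed where-clause
#'
#' Returns the rows whose `name` matches `value_pattern`. When a where-clause
#' is given, a row is kept only if the same record has a row matching
#' `where_pattern` (and, if set, `where_value`) whose identifier shares its
#' array-position prefix with the candidate row — i.e. both sit in the same
#' branch of the nested structure.
#'
#' @param rows A long table from [trials_to_long()].
#' @param value_pattern Regular expression on `name` selecting value rows.
#' @param where_pattern Optional regular expression on `name` for the gating
#'   rows.
#' @param where_value Optional value the gating rows must equal (as character),
#'   or a predicate function on the character value.
#' @return The filtered long tibble.
#' @export
name_to_value <- function(rows, value_pattern, where_pattern = NULL,
                          where_value = NULL) {
  assert_that(is.character(value_pattern) && nzchar(value_pattern),
              "`value_pattern` must be a non-empty pattern", "regharvest_argument_error")
  hits <- rows[grepl(value_pattern, rows$name), , drop = FALSE]
  if (is.null(where_pattern)) return(hits)
  gate <- rows[grepl(where_pattern, rows$name), , drop = FALSE]
  if (!is.null(where_value)) {
    keep <- if (is.function(where_value)) {
      vapply(gate$value, function(v) isTRUE(where_value(v)), logical(1))
    } else {
      gate$value == as.character(where_value)
    }
    gate <- gate[keep, , drop = FALSE]
  }
  if (nrow(gate) == 0 || nrow(hits) == 0) return(hits[0, , drop = FALSE])
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    g <- gate[gate[["_id"]] == hits[["_id"]][i], , drop = FALSE]
    any(vapply(g$identifier, identifiers_coindexed, logical(1),
               b = hits$identifier[i]))
  }, logical(1))
  hits[keep, , drop = FALSE]
}

#' Merge same-typed columns into one variable
#'
#' Registers record the same information under different fields; this merges
#' the chosen columns row-wise into a new variable, joining non-missing values
#' with `" / "`. An optional `levels` mapping re-labels merged values
#' afterwards; an unmapped level is left verbatim with a logged notice.
#' Missing means an absent path, an empty string, or a register null literal.
#'
#' @param table A wide table.
#' @param columns Column names to merge (must exist and share type).
#' @param new_name Name of the merged column.
#' @param levels Optional named character vector/list mapping old values to
#'   new ones.
#' @return The table with `new_name` appended.
#' @export
merge_relevel <- function(table, columns, new_name, levels = NULL) {
  missing_cols <- setdiff(columns, names(table))
  assert_that(length(missing_cols) == 0,
              sprintf("column(s) not in table: %s", paste(missing_cols, collapse = ", ")),
              "regharvest_argument_error")
  types <- vapply(columns, function(cn) class(table[[cn]])[1], character(1))
  assert_that(length(unique(types)) == 1,
              sprintf("columns must share one type, got: %s",
                      paste(unique(types), collapse = ", ")),
              "regharvest_argument_error")
  vals <- lapply(columns, function(cn) normalize_missing(as.character(table[[cn]])))
  merged <- vapply(seq_len(nrow(table)), function(r) {
    present <- stats::na.omit(vapply(vals, `[`, character(1), r))
    if (length(present) == 0) NA_character_ else paste(present, collapse = " / ")
  }, character(1))
  if (!is.null(levels)) {
    levels <- unlist(levels)
    mapped <- unname(levels[merged])
    unmapped <- !is.na(merged) & is.na(mapped)
    if (any(unmapped)) {
      inform(sprintf("merge_relevel: %d value(s) not in `levels`, left verbatim: %s",
                     sum(unmapped),
                     paste(utils::head(unique(merged[unmapped]), 5), collapse = ", ")))
    }
    merged <- ifelse(is.na(mapped) , merged, mapped)
  }
  table[[new_name]] <- merged
  table
}

#' Export a long table as CSV
#'
#' Columns `_id`, `name`, `identifier`, `value`.
#'
#' @param rows A long table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_long_csv <- function(rows, path) {
  utils::write.csv(tibble::as_tibble(rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Plot the distribution of a long-format variable
#'
#' Bar chart of value frequencies for rows whose `name` matches a pattern; a
#' quick look at value sets across registers.
#'
#' @param object A `trial_long_tbl`.
#' @param name_pattern Pattern selecting the variable to plot (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_long_tbl
#' @export
autoplot.trial_long_tbl <- function(object, name_pattern = ".", ...) {
  df <- object[grepl(name_pattern, object$name), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "records") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
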