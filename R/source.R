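#' Fixture register source
#'
#' A register source is the transport abstraction behind query counting,
#' loading and document retrieval: it can list the records matching a query,
#' fetch record payloads (current or historic versions) and fetch attached
#' documents. The required implementation is the fixture-directory source
#' built from synthetic seeds: payload files are rendered to disk alongside
#' an NDJSON truth manifest, and the source answers queries from them
#' deterministically. A live HTTP adapter can implement the same surface but
#' is deliberately out of the tested path.
#'
#' @name register-source
NULL

#' Build a fixture source from synthetic seeds
#'
#' Renders every seed into every register it is registered in, writes the
#' payload files and a truth manifest under `dir`, and returns a source object
#' serving them.
#'
#' @param seeds List of `trial_seed` objects.
#' @param dir Directory for payload files (created if needed).
#' @return A `fixture_source`.
#' @export
fixture_source <- function(seeds, dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(parent = emptyenv())
  env$seeds <- stats::setNames(seeds, vapply(seeds, function(s) s$seed_key, character(1)))
  env$modified_at <- stats::setNames(rep(Sys.time(), length(seeds)), names(env$seeds))
  src <- structure(list(dir = dir, env = env), class = "fixture_source")
  for (s in seeds) write_fixture_files(src, s)
  write_seed_manifest(seeds, file.path(dir, "manifest.ndjson"))
  src
}

write_fixture_files <- function(src, seed) {
  for (reg in names(seed$ids)) {
    pl <- render_register(seed, reg)
    ext <- if (pl$format == "JSON") "json" else "xml"
    writeLines(pl$body, file.path(src$dir, sprintf("%s_%s.%s", reg, seed$seed_key, ext)))
  }
  invisible(NULL)
}

#' @export
print.fixture_source <- function(x, ...) {
  cat(sprintf("<fixture_source: %d trials at %s>\n", length(x$env$seeds), x$dir))
  invisible(x)
}

src_seeds <- function(source) as.list(source$env$seeds)

# Seeds registered in `register` that match canonical criteria.
src_match_seeds <- function(source, register, criteria) {
  seeds <- src_seeds(source)
  keep <- vapply(seeds, function(s) {
    if (!register %in% names(s$ids)) return(FALSE)
    seed_matches(s, register, criteria)
  }, logical(1))
  seeds[keep]
}

seed_matches <- function(s, register, cr) {
  ci_contains <- function(hay, needle) {
    any(grepl(needle, hay, ignore.case = TRUE, fixed = FALSE))
  }
  if (!is.null(cr$condition) &&
      !ci_contains(c(s$condition, s$title), cr$condition)) return(FALSE)
  if (!is.null(cr$intervention) &&
      !ci_contains(c(s$intervention_names, s$substance), cr$intervention)) return(FALSE)
  if (!is.null(cr$search_phrase) && !ci_contains(s$title, cr$search_phrase)) return(FALSE)
  if (!is.null(cr$phase) && !(s$phase %in% cr$phase)) return(FALSE)
  if (!is.null(cr$recruitment_status) &&
      !(s$status[[register]] %in% cr$recruitment_status)) return(FALSE)
  if (!is.null(cr$countries) && !any(s$countries %in% cr$countries)) return(FALSE)
  if (!is.null(cr$start_date_from) &&
      s$start_dates$planned < as.Date(cr$start_date_from)) return(FALSE)
  if (!is.null(cr$start_date_to) &&
      s$start_dates$planned > as.Date(cr$start_date_to)) return(FALSE)
  TRUE
}

# Record ids matching a query: one id per trial, except EUCTR where each
# member-state record counts ("<eudract>-<MS>").
src_search <- function(source, register, criteria) {
  seeds <- src_match_seeds(source, register, criteria)
  unlist(lapply(seeds, function(s) {
    if (register == "EUCTR") paste0(s$ids[["EUCTR"]], "-", s$member_states)
    else s$ids[[register]]
  }), use.names = FALSE) %||% character(0)
}

seed_for_record <- function(source, register, record_id) {
  trial_id <- if (register == "EUCTR") sub("-[A-Z]{2}$", "", record_id) else record_id
  for (s in src_seeds(source)) {
    if (register %in% names(s$ids) && s$ids[[register]] == trial_id) return(s)
  }
  NULL
}

# Fetch current payload text for one trial (all member-state records for
# EUCTR). Results sections are included per `with_results`, except CTGOV where
# results always travel with the record.
src_fetch <- function(source, register, trial_id, with_results = FALSE) {
  s <- seed_for_record(source, register, trial_id)
  if (is.null(s)) return(NULL)
  include <- with_results || register == "CTGOV"
  render_register(s, register, include_results = include)
}

src_versions_count <- function(source, register, trial_id) {
  s <- seed_for_record(source, register, trial_id)
  if (is.null(s)) 0L else nrow(s$versions)
}

src_fetch_version <- function(source, register, trial_id, index) {
  s <- seed_for_record(source, register, trial_id)
  if (is.null(s)) return(NULL)
  render_register(s, register, version_index = index, include_results = FALSE)
}

src_version_date <- function(source, register, trial_id, index) {
  s <- seed_for_record(source, register, trial_id)
  s$versions$version_date[index]
}

src_modified_at <- function(source, seed_key) source$env$modified_at[[seed_key]]

src_documents <- function(source, register, trial_id) {
  s <- seed_for_record(source, register, trial_id)
  if (is.null(s)) character(0) else s$documents
}

src_fetch_document <- function(source, register, trial_id, name) {
  s <- seed_for_record(source, register, trial_id)
  sprintf("placeholder content for %s (%s)", name, s$seed_key)
}

#' Advance a fixture trial to a new record version
#'
#' Emulates the register updating a record after the initial load: appends a
#' version with a new planned enrollment, marks the trial as modified now, and
#' rewrites its payload files. Used to exercise update queries and
#' historic-version capture.
#'
#' @param source A `fixture_source`.
#' @param seed_key Key of the trial to advance.
#' @param planned_n New planned enrollment for the added version.
#' @param version_date Date of the new version (defaults to one day after the
#'   previous version).
#' @return The updated `trial_seed`, invisibly.
#' @export
advance_fixture <- function(source, seed_key, planned_n,
                            version_date = NULL) {
  s <- source$env$seeds[[seed_key]]
  assert_that(!is.null(s), sprintf("no fixture trial '%s'", seed_key),
              "regharvest_argument_error")
  last <- max(s$versions$version_date)
  version_date <- as.Date(version_date %||% (last + 1))
  assert_that(version_date > last, "version dates must be strictly increasing",
              "regharvest_argument_error")
  s$versions <- dplyr::bind_rows(
    s$versions,
    tibble::tibble(version_date = version_date, planned_n = as.integer(planned_n))
  )
  s$planned_n <- as.integer(planned_n)
  source$env$seeds[[seed_key]] <- s
  source$env$modified_at[[seed_key]] <- Sys.time()
  write_fixture_files(source, s)
  invisible(s)
}
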