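#' Register query grammars
#'
#' High-level search parameters are translated into each register's own query
#' grammar, and register search URLs are parsed back into canonical query
#' specifications. The four grammars (key names, value encodings, vocabulary
#' codes, the interventional-medicines filter clause) are frozen in
#' `inst/extdata/grammars.yaml`; composed URLs are canonical (criteria ordered
#' lexicographically by key) so that parse and compose round-trip exactly.
#'
#' @name query-grammars
NULL

grammar <- function(register = NULL) {
  g <- regharvest_config("grammars")$registers
  if (is.null(register)) g else g[[register]]
}

#' A register query specification
#'
#' @param register Register code.
#' @param criteria Named list of register-native criteria.
#' @return A `query_spec` with `register`, `criteria` (ordered mapping) and
#'   the canonical `url`.
#' @export
query_spec <- function(register, criteria) {
  criteria <- criteria[order(names(criteria))]
  criteria <- lapply(criteria, function(v) if (is.atomic(v)) unname(v) else v)
  structure(list(register = register, criteria = criteria,
                 url = compose_url(register, criteria)),
            class = "query_spec")
}

#' @export
print.query_spec <- function(x, ...) {
  cat(sprintf("<query_spec %s>\n  %s\n", x$register, x$url))
  invisible(x)
}

#' Generate register-specific search queries
#'
#' Translates high-level search parameters into one query per requested
#' register. By default each query carries the register's frozen filter clause
#' restricting results to interventional trials with medicines; setting
#' `only_med_interv_trials = FALSE` removes the clause.
#'
#' @param condition,intervention,search_phrase Free-text criteria.
#' @param phase Canonical phases, a subset of
#'   `c("1", "1_2", "2", "2_3", "3", "4")`.
#' @param recruitment_status Canonical statuses, a subset of
#'   `c("ongoing", "completed", "ended_early", "other")`.
#' @param countries Two-letter country codes.
#' @param start_date_from,start_date_to ISO dates bounding the trial start.
#' @param only_med_interv_trials Keep the interventional-medicines filter
#'   clause (default `TRUE`).
#' @param registers Registers to target (default all four).
#' @return A tibble with one row per register: `register`, `url`, and a
#'   `spec` list-column of `query_spec` objects.
#' @examples
#' generate_queries(condition = "cancer")$url
#' @export
generate_queries <- function(condition = NULL, intervention = NULL,
                             phase = NULL, recruitment_status = NULL,
                             countries = NULL, search_phrase = NULL,
                             start_date_from = NULL, start_date_to = NULL,
                             only_med_interv_trials = TRUE,
                             registers = REGISTERS) {
  bad <- setdiff(toupper(registers), REGISTERS)
  assert_that(length(bad) == 0,
              sprintf("unsupported register(s): %s", paste(bad, collapse = ", ")),
              "regharvest_argument_error")
  registers <- REGISTERS[REGISTERS %in% toupper(registers)]
  params <- drop_nulls(list(
    condition = condition, intervention = intervention, phase = phase,
    recruitment_status = recruitment_status, countries = countries,
    search_phrase = search_phrase,
    start_date_from = start_date_from, start_date_to = start_date_to
  ))
  assert_that(length(params) > 0, "at least one search criterion must be set",
              "regharvest_argument_error")
  if (!is.null(start_date_from) && !is.null(start_date_to)) {
    assert_that(as.Date(start_date_from) <= as.Date(start_date_to),
                "start_date_from must not be after start_date_to",
                "regharvest_argument_error")
  }
  if (!is.null(phase)) {
    assert_that(all(phase %in% CANONICAL_PHASES),
                sprintf("unknown phase value(s): %s",
                        paste(setdiff(phase, CANONICAL_PHASES), collapse = ", ")),
                "regharvest_argument_error")
  }
  if (!is.null(recruitment_status)) {
    assert_that(all(recruitment_status %in% CANONICAL_STATUS),
                sprintf("unknown status value(s): %s",
                        paste(setdiff(recruitment_status, CANONICAL_STATUS), collapse = ", ")),
                "regharvest_argument_error")
  }
  specs <- lapply(registers, function(reg) {
    query_spec(reg, native_criteria(reg, params, only_med_interv_trials))
  })
  tibble::tibble(
    register = registers,
    url = vapply(specs, function(s) s$url, character(1)),
    spec = specs
  )
}

# canonical params -> register-native criteria mapping
native_criteria <- function(register, p, med_clause = TRUE) {
  g <- grammar(register)
  cr <- list()
  if (register == "CTGOV") {
    if (!is.null(p$condition)) cr$cond <- p$condition
    if (!is.null(p$intervention)) cr$intr <- p$intervention
    if (!is.null(p$search_phrase)) cr$term <- p$search_phrase
    if (!is.null(p$countries)) cr$country <- paste(sort(p$countries), collapse = ",")
    if (!is.null(p$start_date_from) || !is.null(p$start_date_to)) {
      cr$start <- paste0(p$start_date_from %||% "", "_", p$start_date_to %||% "")
    }
    facets <- character(0)
    if (!is.null(p$phase)) {
      toks <- sort(unique(unlist(strsplit(unlist(g$phase_tokens[p$phase]), " "))))
      facets <- c(facets, paste0("phase:", paste(toks, collapse = " ")))
    }
    if (!is.null(p$recruitment_status)) {
      toks <- sort(unique(unlist(g$status_tokens[p$recruitment_status])))
      facets <- c(facets, paste0("status:", paste(toks, collapse = " ")))
    }
    if (med_clause) facets <- c(facets, g$medicines_clause)
    if (length(facets)) cr$aggFilters <- paste(sort(facets), collapse = ",")
  } else if (register == "EUCTR") {
    if (!is.null(p$condition)) cr$query <- p$condition
    if (!is.null(p$intervention)) cr$intr <- p$intervention
    if (!is.null(p$search_phrase)) cr$phrase <- p$search_phrase
    if (!is.null(p$phase)) cr$phase <- sort(unlist(g$phase_tokens[p$phase]))
    if (!is.null(p$recruitment_status)) cr$status <- sort(unlist(g$status_tokens[p$recruitment_status]))
    if (!is.null(p$countries)) cr$country <- sort(p$countries)
    if (!is.null(p$start_date_from)) cr$dateFrom <- as.character(p$start_date_from)
    if (!is.null(p$start_date_to)) cr$dateTo <- as.character(p$start_date_to)
    if (med_clause) cr[[g$medicines_clause$key]] <- g$medicines_clause$value
  } else if (register == "CTIS") {
    k <- g$criteria_keys
    if (!is.null(p$condition)) cr[[k$condition]] <- p$condition
    if (!is.null(p$intervention)) cr[[k$intervention]] <- p$intervention
    if (!is.null(p$search_phrase)) cr[[k$search_phrase]] <- p$search_phrase
    if (!is.null(p$countries)) cr[[k$countries]] <- sort(p$countries)
    if (!is.null(p$phase)) cr$trialPhaseCode <- sort(unlist(g$phase_codes[p$phase]))
    if (!is.null(p$recruitment_status)) {
      cr$status <- sort(unique(unlist(g$status_codes[p$recruitment_status])))
    }
    if (!is.null(p$start_date_from)) cr[[k$date_from]] <- as.character(p$start_date_from)
    if (!is.null(p$start_date_to)) cr[[k$date_to]] <- as.character(p$start_date_to)
    if (med_clause) cr[[g$medicines_clause$key]] <- g$medicines_clause$value
  } else if (register == "ISRCTN") {
    if (!is.null(p$search_phrase)) cr$q <- p$search_phrase
    fk <- g$filter_keys
    items <- character(0)
    add <- function(key, vals) paste0(key, ":", vals)
    if (!is.null(p$condition)) items <- c(items, add(fk$condition, p$condition))
    if (!is.null(p$intervention)) items <- c(items, add(fk$intervention, p$intervention))
    if (!is.null(p$phase)) items <- c(items, add("phase", unlist(g$phase_tokens[p$phase])))
    if (!is.null(p$recruitment_status)) {
      items <- c(items, add("overallStatus", unlist(g$status_tokens[p$recruitment_status])))
    }
    if (!is.null(p$countries)) items <- c(items, add(fk$countries, p$countries))
    if (!is.null(p$start_date_from)) items <- c(items, add(fk$date_from, as.character(p$start_date_from)))
    if (!is.null(p$start_date_to)) items <- c(items, add(fk$date_to, as.character(p$start_date_to)))
    if (med_clause) items <- c(items, strsplit(g$medicines_clause, ",")[[1]])
    if (length(items)) cr$filters <- paste(sort(items), collapse = ",")
  }
  cr
}

enc <- function(x) vapply(as.character(x), URLencode, character(1), reserved = TRUE)

# register-native criteria -> canonical URL text (keys lexicographic,
# vector values repeated in sorted order)
compose_url <- function(register, criteria) {
  g <- grammar(register)
  criteria <- criteria[order(names(criteria))]
  if (register == "CTIS") {
    json <- jsonlite::toJSON(criteria, auto_unbox = TRUE, digits = NA)
    return(paste0(g$base, "#searchCriteria=", URLencode(as.character(json), reserved = TRUE)))
  }
  parts <- unlist(lapply(names(criteria), function(k) {
    vals <- criteria[[k]]
    paste0(k, "=", enc(if (length(vals) > 1) sort(as.character(vals)) else vals))
  }))
  paste0(g$base, if (length(parts)) "?" else "", paste(parts, collapse = "&"))
}

#' Parse a register search URL
#'
#' Identifies the register from the URL's host and path and decodes the
#' search criteria, including percent-decoding and fragment-embedded JSON
#' criteria (the CTIS `#searchCriteria={...}` form, typographic quotes
#' tolerated).
#'
#' @param url Search URL text.
#' @return A `query_spec` whose `url` is the canonical recomposition; parsing
#'   a composed URL returns the identical criteria mapping.
#' @export
parse_query_url <- function(url) {
  assert_that(is.character(url) && length(url) == 1 && nzchar(url),
              "`url` must be a single non-empty string", "regharvest_argument_error")
  register <- infer_register(url)
  if (is.na(register)) {
    abort(sprintf("cannot identify a supported register from '%s'", url),
          class = c("regharvest_unknown_register_error", "regharvest_error"))
  }
  if (register == "CTIS") {
    m <- regexpr("#searchCriteria=", url, fixed = TRUE)
    criteria <- list()
    if (m > 0) {
      frag <- substring(url, m + attr(m, "match.length"))
      frag <- URLdecode(frag)
      frag <- gsub("[“”]", '"', frag) # typographic quotes in print
      criteria <- tryCatch(
        jsonlite::fromJSON(frag, simplifyVector = FALSE),
        error = function(e) {
          abort(sprintf("malformed searchCriteria at offset %d: %s",
                        as.integer(m), conditionMessage(e)),
                class = c("regharvest_parse_error", "regharvest_error"))
        }
      )
      criteria <- lapply(criteria, function(v) {
        if (is.list(v)) unlist(v, use.names = FALSE) else v
      })
    }
    return(query_spec("CTIS", criteria))
  }
  qs <- sub("^[^?]*\\??", "", url)
  qs <- sub("#.*$", "", qs)
  criteria <- list()
  if (nzchar(qs)) {
    for (kv in strsplit(qs, "&", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) {
        abort(sprintf("malformed query component '%s' at offset %d",
                      kv, as.integer(regexpr(kv, url, fixed = TRUE))),
              class = c("regharvest_parse_error", "regharvest_error"))
      }
      k <- substring(kv, 1, eq - 1)
      v <- URLdecode(substring(kv, eq + 1))
      criteria[[k]] <- c(criteria[[k]], v)
    }
  }
  query_spec(register, criteria)
}

infer_register <- function(url) {
  if (!grepl("^https?://", url)) return(NA_character_)
  host <- sub("^https?://([^/?#]+).*$", "\\1", url)
  for (reg in REGISTERS) {
    if (host %in% grammar(reg)$hosts) return(reg)
  }
  NA_character_
}

# register-native criteria -> canonical criteria used for record matching
canonicalize_criteria <- function(register, cr) {
  g <- grammar(register)
  out <- list()
  invert <- function(map, values) {
    hits <- names(map)[vapply(map, function(v) any(v %in% values), logical(1))]
    if (length(hits)) hits else NULL
  }
  if (register == "CTGOV") {
    out$condition <- cr$cond
    out$intervention <- cr$intr
    out$search_phrase <- cr$term
    if (!is.null(cr$country)) out$countries <- strsplit(cr$country, ",")[[1]]
    if (!is.null(cr$start)) {
      ft <- strsplit(cr$start, "_", fixed = TRUE)[[1]]
      if (length(ft) >= 1 && nzchar(ft[1])) out$start_date_from <- ft[1]
      if (length(ft) >= 2 && nzchar(ft[2])) out$start_date_to <- ft[2]
    }
    if (!is.null(cr$aggFilters)) {
      for (facet in strsplit(cr$aggFilters, ",")[[1]]) {
        kv <- strsplit(facet, ":", fixed = TRUE)[[1]]
        if (kv[1] == "phase") {
          toks <- strsplit(kv[2], " ")[[1]]
          # a facet token matches any canonical phase whose token set meets it
          out$phase <- names(g$phase_tokens)[vapply(g$phase_tokens, function(t) {
            any(strsplit(t, " ")[[1]] %in% toks)
          }, logical(1))]
        } else if (kv[1] == "status") {
          out$recruitment_status <- invert(g$status_tokens, strsplit(kv[2], " ")[[1]])
        } else if (facet == g$medicines_clause) {
          out$only_med_interv_trials <- TRUE
        }
      }
    }
  } else if (register == "EUCTR") {
    out$condition <- cr$query
    out$intervention <- cr$intr
    out$search_phrase <- cr$phrase
    if (!is.null(cr$phase)) out$phase <- invert(g$phase_tokens, cr$phase)
    if (!is.null(cr$status)) out$recruitment_status <- invert(g$status_tokens, cr$status)
    out$countries <- cr$country
    out$start_date_from <- cr$dateFrom
    out$start_date_to <- cr$dateTo
    if (!is.null(cr[[g$medicines_clause$key]])) out$only_med_interv_trials <- TRUE
  } else if (register == "CTIS") {
    k <- g$criteria_keys
    out$condition <- cr[[k$condition]]
    out$intervention <- cr[[k$intervention]]
    out$search_phrase <- cr[[k$search_phrase]]
    out$countries <- cr[[k$countries]]
    if (!is.null(cr$trialPhaseCode)) out$phase <- invert(g$phase_codes, cr$trialPhaseCode)
    if (!is.null(cr$status)) {
      codes <- as.numeric(cr$status)
      out$recruitment_status <- names(g$status_codes)[vapply(g$status_codes, function(v) {
        all(unlist(v) %in% codes)
      }, logical(1))]
    }
    out$start_date_from <- cr[[k$date_from]]
    out$start_date_to <- cr[[k$date_to]]
    if (!is.null(cr[[g$medicines_clause$key]])) out$only_med_interv_trials <- TRUE
  } else if (register == "ISRCTN") {
    out$search_phrase <- cr$q
    fk <- g$filter_keys
    if (!is.null(cr$filters)) {
      items <- strsplit(cr$filters, ",")[[1]]
      med_items <- strsplit(g$medicines_clause, ",")[[1]]
      if (all(med_items %in% items)) out$only_med_interv_trials <- TRUE
      items <- setdiff(items, med_items)
      for (it in items) {
        colon <- regexpr(":", it, fixed = TRUE)
        key <- substring(it, 1, colon - 1)
        val <- substring(it, colon + 1)
        if (key == fk$condition) out$condition <- val
        else if (key == fk$intervention) out$intervention <- val
        else if (key == "phase") out$phase <- c(out$phase, invert(g$phase_tokens, val))
        else if (key == "overallStatus") {
          out$recruitment_status <- c(out$recruitment_status, invert(g$status_tokens, val))
        } else if (key == fk$countries) out$countries <- c(out$countries, val)
        else if (key == fk$date_from) out$start_date_from <- val
        else if (key == fk$date_to) out$start_date_to <- val
      }
    }
  }
  drop_nulls(out)
}

as_query_spec <- function(spec) {
  if (inherits(spec, "query_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1) return(parse_query_url(spec))
  if (is.data.frame(spec) && nrow(spec) == 1 && "spec" %in% names(spec)) {
    return(spec$spec[[1]])
  }
  abort("`spec` must be a query_spec, a search URL, or one row of generate_queries()",
        class = c("regharvest_argument_error", "regharvest_error"))
}

#' Count records matching a query without storing them
#'
#' For EUCTR the count is of member-state records, a multiple of the number of
#' trials.
#'
#' @param spec A `query_spec`, a search URL, or one row of
#'   [generate_queries()].
#' @param source A register source (see [fixture_source()]).
#' @return Integer record count.
#' @export
count_trials <- function(spec, source) {
  spec <- as_query_spec(spec)
  canonical <- canonicalize_criteria(spec$register, spec$criteria)
  length(src_search(source, spec$register, canonical))
}

#' Harvest active-substance synonyms from a source
#'
#' Scans the source's records for intervention/substance fields naming the
#' query substance and returns the de-duplicated, case-folded spellings found.
#'
#' @param substance Substance name (non-empty text).
#' @param source A register source.
#' @return Character vector of synonyms (possibly empty), sorted.
#' @export
substance_synonyms <- function(substance, source) {
  assert_that(is.character(substance) && length(substance) == 1 && nzchar(substance),
              "`substance` must be non-empty text", "regharvest_argument_error")
  found <- character(0)
  for (s in src_seeds(source)) {
    spellings <- unname(s$intervention_names)
    if (tolower(s$substance) == tolower(substance) ||
        any(grepl(substance, spellings, ignore.case = TRUE))) {
      found <- c(found, spellings)
    }
  }
  sort(unique(tolower(found)))
}
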