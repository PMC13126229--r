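#' Render seeds into register dialects
#'
#' A `trial_seed` is rendered into any register it is registered in, producing
#' a payload in that register's wire format: JSON for CTGOV (v2-API style) and
#' CTIS (public-API style), XML for EUCTR and ISRCTN. EUCTR renders one record
#' per participating member state, identifiers suffixed with the member-state
#' code. Co-registered registers' identifiers are embedded as secondary
#' identifiers. The exact field names and nesting are frozen in the dialect
#' reference (`inst/extdata/dialect-reference.md`).
#'
#' @name dialect-rendering
NULL

vocab <- function() regharvest_config("vocabularies")

render_yn <- function(x) if (isTRUE(x)) "Yes" else "No"

status_literal <- function(register, canonical) {
  vocab()$status_render[[register]][[canonical]]
}

phase_literal <- function(register, canonical) {
  vocab()$phase_render[[register]][[canonical]]
}

euctr_phase_flags <- function(canonical) {
  flags <- list(
    "1"   = c("Yes", "No", "No", "No"),
    "1_2" = c("Yes", "Yes", "No", "No"),
    "2"   = c("No", "Yes", "No", "No"),
    "2_3" = c("No", "Yes", "Yes", "No"),
    "3"   = c("No", "No", "Yes", "No"),
    "4"   = c("No", "No", "No", "Yes")
  )[[canonical]]
  list(human_pharmacology = flags[1], exploratory = flags[2],
       confirmatory = flags[3], therapeutic_use = flags[4])
}

# register-keyed seed fields fall back to the first value, so seeds whose id
# set was edited after generation still render
seed_status <- function(seed, register) {
  if (register %in% names(seed$status)) seed$status[[register]] else seed$status[[1]]
}

seed_iname <- function(seed, register) {
  v <- seed$intervention_names
  if (register %in% names(v)) v[[register]] else unname(v[1])
}

seed_version <- function(seed, version_index = NULL) {
  nv <- nrow(seed$versions)
  if (is.null(version_index)) version_index <- nv
  assert_that(version_index >= 1 && version_index <= nv,
              sprintf("version_index %s outside 1..%d", version_index, nv),
              "regharvest_argument_error")
  list(
    index = version_index,
    is_current = version_index == nv,
    planned_n = seed$versions$planned_n[version_index],
    version_date = seed$versions$version_date[version_index]
  )
}

secondary_ids <- function(seed, exclude) {
  ids <- seed$ids[setdiff(names(seed$ids), exclude)]
  ids
}

#' Render one seed into one register's payload
#'
#' @param seed A `trial_seed`.
#' @param register One of `"CTGOV"`, `"CTIS"`, `"EUCTR"`, `"ISRCTN"`; must be a
#'   register the seed is registered in.
#' @param version_index Optional historic version to render (1-based into the
#'   seed's version ladder); default is the current (last) version. Historic
#'   versions carry that version's planned enrollment and an ongoing status.
#' @param include_results Include the structured results section where the
#'   dialect has one (CTGOV and EUCTR only).
#' @return A `register_payload`: list with `register`, `format` (`"XML"` or
#'   `"JSON"`), `body` (text) and `record_count` (member-state records for
#'   EUCTR, trials otherwise).
#' @export
render_register <- function(seed, register, version_index = NULL,
                            include_results = TRUE) {
  register <- toupper(register)
  assert_that(register %in% REGISTERS,
              sprintf("unknown register '%s'", register), "regharvest_argument_error")
  if (!register %in% names(seed$ids)) {
    abort(sprintf("seed %s is not registered in %s", seed$seed_key, register),
          class = c("regharvest_not_registered_error", "regharvest_error"))
  }
  v <- seed_version(seed, version_index)
  switch(register,
    CTGOV  = payload("CTGOV", "JSON",
                     jsonlite::toJSON(list(studies = list(render_ctgov(seed, v, include_results))),
                                      auto_unbox = TRUE, digits = NA, null = "null"),
                     1L),
    CTIS   = payload("CTIS", "JSON",
                     jsonlite::toJSON(list(data = list(render_ctis(seed, v))),
                                      auto_unbox = TRUE, digits = NA, null = "null"),
                     1L),
    EUCTR  = {
      recs <- lapply(seed$member_states, function(ms) render_euctr(seed, ms, v, include_results))
      payload("EUCTR", "XML", tree_to_xml(list(trial = recs), "trials"),
              length(seed$member_states))
    },
    ISRCTN = payload("ISRCTN", "XML",
                     tree_to_xml(list("@totalCount" = "1",
                                      fullTrial = list(trial = render_isrctn(seed, v))),
                                 "allTrials"),
                     1L)
  )
}

payload <- function(register, format, body, record_count) {
  structure(list(register = register, format = format,
                 body = as.character(body), record_count = record_count),
            class = "register_payload")
}

#' @export
print.register_payload <- function(x, ...) {
  cat(sprintf("<register_payload %s %s, %d record(s), %d chars>\n",
              x$register, x$format, x$record_count, nchar(x$body)))
  invisible(x)
}

# ---- CTGOV (JSON, v2-API style) --------------------------------------------

render_ctgov <- function(seed, v, include_results = TRUE) {
  st <- if (v$is_current) seed_status(seed, "CTGOV") else "ongoing"
  actual <- seed$start_dates$actual
  sec <- secondary_ids(seed, "CTGOV")
  sec_types <- c(EUCTR = "EudraCT Number", CTIS = "CTIS Number", ISRCTN = "Registry Identifier")
  sponsors <- seed$sponsors
  class_lit <- ifelse(sponsors$class == "commercial", "INDUSTRY", "OTHER")
  enrol_actual <- v$is_current && st %in% c("completed", "ended_early") && !is.na(seed$actual_n)

  study <- list(
    protocolSection = list(
      identificationModule = list(
        nctId = seed$ids[["CTGOV"]],
        briefTitle = seed$title,
        secondaryIdInfos = if (length(sec)) {
          unname(purrr::imap(sec, function(id, reg) list(id = id, type = unname(sec_types[reg]))))
        }
      ),
      statusModule = drop_nulls(list(
        overallStatus = status_literal("CTGOV", st),
        whyStopped = if (st == "ended_early") "Stopped early by sponsor",
        startDateStruct = list(
          date = as.character(if (!is.null(actual)) actual else seed$start_dates$planned),
          type = if (!is.null(actual)) "ACTUAL" else "ESTIMATED"
        ),
        studyFirstSubmitDate = as.character(seed$versions$version_date[1]),
        completionDateStruct = if (v$is_current && !is.null(seed$end_date)) {
          list(date = as.character(seed$end_date), type = "ACTUAL")
        },
        lastUpdateSubmitDate = as.character(v$version_date),
        resultsFirstPostDateStruct = if (v$is_current && !is.null(seed$results) && include_results) {
          list(date = as.character(seed$end_date %||% seed$start_dates$planned + 400))
        }
      )),
      designModule = list(
        studyType = "INTERVENTIONAL",
        phases = as.list(phase_literal("CTGOV", seed$phase)),
        designInfo = list(
          allocation = if (seed$randomised) "RANDOMIZED" else "NON_RANDOMIZED",
          interventionModel = if (seed$arms > 1) "PARALLEL" else "SINGLE_GROUP"
        ),
        enrollmentInfo = list(
          count = if (enrol_actual) seed$actual_n else v$planned_n,
          type = if (enrol_actual) "ACTUAL" else "ESTIMATED"
        )
      ),
      armsInterventionsModule = list(
        armGroups = lapply(seq_len(seed$arms), function(a) {
          list(label = sprintf("Arm %d", a))
        }),
        interventions = list(list(type = "DRUG", name = seed_iname(seed, "CTGOV")))
      ),
      sponsorCollaboratorsModule = drop_nulls(list(
        leadSponsor = list(name = sponsors$name[1], class = class_lit[1]),
        collaborators = if (nrow(sponsors) > 1) {
          lapply(2:nrow(sponsors), function(j) list(name = sponsors$name[j], class = class_lit[j]))
        }
      )),
      conditionsModule = list(conditions = list(seed$condition)),
      contactsLocationsModule = if (!is.null(seed$sites)) list(
        locations = purrr::pmap(seed$sites, function(name, country) {
          list(facility = name, country = country)
        })
      ),
      outcomesModule = drop_nulls(list(
        primaryOutcomes = endpoint_list(seed, "primary", c("measure", "description", "timeFrame")),
        secondaryOutcomes = endpoint_list(seed, "secondary", c("measure", "description", "timeFrame"))
      )),
      eligibilityModule = list(
        minimumAge = sprintf("%d Years", seed$min_age),
        maximumAge = sprintf("%d Years", seed$max_age)
      ),
      descriptionModule = list(briefSummary = seed$objectives_text)
    ),
    hasResults = v$is_current && !is.null(seed$results) && include_results
  )
  if (length(seed$documents)) {
    study$documentSection <- list(largeDocumentModule = list(
      largeDocs = lapply(seed$documents, function(d) list(filename = d))
    ))
  }
  if (isTRUE(study$hasResults)) {
    prim <- seed$endpoints[seed$endpoints$type == "primary", ]
    study$resultsSection <- list(outcomeMeasuresModule = list(outcomeMeasures = c(
      list(list(type = "PRIMARY", title = prim$title[1],
                analyses = list(list(pValue = as.character(seed$results$p_value),
                                     statisticalMethod = seed$results$method)))),
      list(list(type = "SECONDARY", title = "Key secondary endpoint",
                analyses = list(list(pValue = as.character(seed$results$secondary_p_value),
                                     statisticalMethod = seed$results$method))))
    )))
  }
  study
}

endpoint_list <- function(seed, type, field_names) {
  eps <- seed$endpoints[seed$endpoints$type == type, ]
  if (nrow(eps) == 0) return(NULL)
  lapply(seq_len(nrow(eps)), function(j) {
    stats::setNames(list(eps$title[j], eps$description[j], eps$timeframe[j]), field_names)
  })
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

# ---- CTIS (JSON, public-API style) -----------------------------------------

render_ctis <- function(seed, v) {
  st <- if (v$is_current) seed_status(seed, "CTIS") else "ongoing"
  actual <- seed$start_dates$actual
  sec <- secondary_ids(seed, "CTIS")
  enrol_actual <- v$is_current && st %in% c("completed", "ended_early") && !is.na(seed$actual_n)
  drop_nulls(list(
    ctNumber = seed$ids[["CTIS"]],
    title = seed$title,
    conditions = as.list(seed$condition),
    overallStatus = status_literal("CTIS", st),
    recruitmentStatus = if (st == "ongoing") "Recruiting" else "Closed",
    trialPhase = phase_literal("CTIS", seed$phase),
    secondaryIdentifiers = if (length(sec)) {
      unname(purrr::imap(sec, function(id, reg) list(register = reg, id = id)))
    },
    startDate = drop_nulls(list(
      plannedDate = as.character(seed$start_dates$planned),
      actualDate = if (!is.null(actual)) as.character(actual),
      decisionDate = as.character(seed$start_dates$decision_ctis)
    )),
    endDate = if (v$is_current && !is.null(seed$end_date)) as.character(seed$end_date),
    recruitment = drop_nulls(list(
      plannedSubjects = v$planned_n,
      actualSubjects = if (enrol_actual) seed$actual_n
    )),
    sponsors = purrr::pmap(seed$sponsors, function(name, class) {
      list(name = name, type = if (class == "commercial") "Commercial" else "Non-Commercial")
    }),
    sites = if (!is.null(seed$sites)) purrr::pmap(seed$sites, function(name, country) {
      list(name = name, country = country)
    }),
    countries = as.list(seed$countries),
    population = list(minimumAge = seed$min_age, maximumAge = seed$max_age),
    randomised = seed$randomised,
    interventions = list(list(name = seed_iname(seed, "CTIS"))),
    objectives = seed$objectives_text,
    endpoints = drop_nulls(list(
      primary = endpoint_list(seed, "primary", c("title", "description", "timeframe")),
      secondary = endpoint_list(seed, "secondary", c("title", "description", "timeframe"))
    )),
    documents = if (length(seed$documents)) lapply(seed$documents, function(d) list(title = d)),
    lastUpdated = as.character(v$version_date)
  ))
}

# ---- EUCTR (XML, one record per member state) ------------------------------

render_euctr <- function(seed, member_state, v, include_results = TRUE) {
  st <- if (v$is_current) seed_status(seed, "EUCTR") else "ongoing"
  sec <- secondary_ids(seed, "EUCTR")
  sec_fields <- list()
  if ("CTGOV" %in% names(sec)) sec_fields$nct_number <- sec[["CTGOV"]]
  if ("CTIS" %in% names(sec)) sec_fields$ctis_number <- sec[["CTIS"]]
  if ("ISRCTN" %in% names(sec)) sec_fields$isrctn_number <- sec[["ISRCTN"]]

  tree <- drop_nulls(list(
    "@country" = member_state,
    identification = c(list(
      eudract_number = seed$ids[["EUCTR"]],
      full_id = paste0(seed$ids[["EUCTR"]], "-", member_state)
    ), sec_fields),
    sponsors = list(sponsor = purrr::pmap(seed$sponsors, function(name, class) {
      list(name = name,
           status = if (class == "commercial") "Commercial" else "Non-Commercial")
    })),
    trial_information = list(
      full_title = seed$title,
      medical_condition = seed$condition,
      main_objective = seed$objectives_text,
      randomised = render_yn(seed$randomised),
      trial_phase = euctr_phase_flags(seed$phase)
    ),
    imp = list(product = list(list(name = seed_iname(seed, "EUCTR")))),
    population = list(
      age_groups = list(
        children = render_yn("children" %in% age_groups_from_range(seed$min_age, seed$max_age)),
        adults = render_yn("adults" %in% age_groups_from_range(seed$min_age, seed$max_age)),
        elderly = render_yn("elderly" %in% age_groups_from_range(seed$min_age, seed$max_age))
      ),
      planned_subjects = as.character(v$planned_n)
    ),
    trial_dates = drop_nulls(list(
      planned_start_date = as.character(seed$start_dates$planned),
      actual_start_date = if (!is.null(seed$start_dates$actual)) as.character(seed$start_dates$actual),
      date_of_competent_authority_decision =
        as.character(seed$start_dates$authority_decision[[member_state]]),
      global_end_of_trial_date = if (v$is_current && !is.null(seed$end_date)) as.character(seed$end_date)
    )),
    trial_status = status_literal("EUCTR", st),
    participating_countries = list(country = lapply(seed$countries, function(cc) {
      list(code = cc, eea = render_yn(cc %in% EEA_COUNTRIES))
    })),
    endpoints = drop_nulls(list(
      primary_endpoint = endpoint_list(seed, "primary", c("title", "description", "timeframe")),
      secondary_endpoint = endpoint_list(seed, "secondary", c("title", "description", "timeframe"))
    )),
    record_last_updated = as.character(v$version_date)
  ))
  has_results_section <- v$is_current && include_results &&
    (!is.null(seed$results) || !is.na(seed$actual_n))
  if (has_results_section) {
    prim <- seed$endpoints[seed$endpoints$type == "primary", ]
    tree$results <- drop_nulls(list(
      actual_enrollment = if (!is.na(seed$actual_n)) as.character(seed$actual_n),
      end_of_trial_status = status_literal("EUCTR", st),
      publication_date = if (!is.null(seed$results)) {
        as.character((seed$end_date %||% seed$start_dates$planned) + 180)
      },
      primary_analysis = if (!is.null(seed$results)) list(list(
        endpoint_title = prim$title[1],
        p_value = as.character(seed$results$p_value),
        statistical_method = seed$results$method
      ))
    ))
  }
  tree
}

# ---- ISRCTN (XML) ----------------------------------------------------------

render_isrctn <- function(seed, v) {
  st <- if (v$is_current) seed_status(seed, "ISRCTN") else "ongoing"
  sec <- secondary_ids(seed, "ISRCTN")
  sec_id <- function(reg) if (reg %in% names(sec)) sec[[reg]] else NULL
  refs <- drop_nulls(list(
    eudraCTNumber = sec_id("EUCTR"),
    clinicalTrialsGovNumber = sec_id("CTGOV"),
    ctisNumber = sec_id("CTIS")
  ))
  prim <- seed$endpoints[seed$endpoints$type == "primary", ]
  enrol_actual <- v$is_current && st %in% c("completed", "ended_early") && !is.na(seed$actual_n)
  drop_nulls(list(
    isrctn = seed$ids[["ISRCTN"]],
    dateAssigned = as.character(seed$versions$version_date[1]),
    externalRefs = if (length(refs)) refs,
    trialDescription = list(
      title = seed$title,
      studyHypothesis = seed$objectives_text
    ),
    trialDesign = drop_nulls(list(
      overallStatus = status_literal("ISRCTN", st),
      recruitmentStatus = if (st == "ongoing") "Recruiting" else "No longer recruiting",
      primaryStudyDesign = "Interventional",
      studyDesign = paste0(if (seed$randomised) "Randomised " else "Non-randomised ",
                           "parallel-group trial"),
      trialPhase = phase_literal("ISRCTN", seed$phase),
      overallStartDate = as.character(seed$start_dates$planned),
      overallEndDate = if (v$is_current && !is.null(seed$end_date)) as.character(seed$end_date)
    )),
    conditions = list(condition = list(list(description = seed$condition))),
    interventions = list(intervention = list(list(
      interventionType = "Drug",
      drugNames = seed_iname(seed, "ISRCTN")
    ))),
    participants = drop_nulls(list(
      recruitmentCountries = list(country = as.list(seed$countries)),
      targetEnrolment = as.character(v$planned_n),
      totalFinalEnrolment = if (enrol_actual) as.character(seed$actual_n),
      totalCentres = if (!is.null(seed$sites)) as.character(nrow(seed$sites)),
      lowerAgeLimit = as.character(seed$min_age),
      upperAgeLimit = as.character(seed$max_age)
    )),
    outcomes = list(primaryOutcome = lapply(seq_len(nrow(prim)), function(j) {
      list(description = paste0(prim$title[j], ": ", prim$description[j]),
           timepoints = prim$timeframe[j])
    })),
    sponsors = list(sponsor = purrr::pmap(seed$sponsors, function(name, class) {
      list(organisation = name,
           sponsorType = if (class == "commercial") "Industry" else "University/hospital")
    })),
    lastUpdated = as.character(v$version_date)
  ))
}

# ---- tree -> XML serialisation ---------------------------------------------

# Inverse of xml_to_tree for trees following the canonical convention: a key
# whose value is an unnamed list emits one element per entry under that key;
# "@"-prefixed keys become attributes.
tree_to_xml <- function(tree, root) {
  doc <- xml2::xml_new_root(root)
  fill <- function(node, t) {
    for (nm in names(t)) {
      v <- t[[nm]]
      if (is.null(v)) next
      if (startsWith(nm, "@")) {
        xml2::xml_set_attr(node, substring(nm, 2), as.character(v))
      } else if (is_array_node(v)) {
        for (el in v) {
          child <- xml2::xml_add_child(node, nm)
          if (is.list(el)) fill(child, el) else xml2::xml_set_text(child, as.character(el))
        }
      } else if (is.list(v)) {
        fill(xml2::xml_add_child(node, nm), v)
      } else {
        xml2::xml_set_text(xml2::xml_add_child(node, nm), as.character(v))
      }
    }
  }
  fill(xml2::xml_root(doc), tree)
  as.character(doc)
}

#' Write placeholder document files for a seed
#'
#' One small content file is created per entry in the seed's document
#' manifest, named in register style (`<seed_key>_<document>`); repeated calls
#' overwrite idempotently.
#'
#' @param seed A `trial_seed`.
#' @param directory Writable output directory.
#' @return Character vector of file paths (empty when the seed lists no
#'   documents).
#' @export
render_documents <- function(seed, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", directory),
                   class = c("regharvest_io_error", "regharvest_error"))
  }
  if (file.access(directory, 2) != 0) {
    abort(sprintf("directory '%s' is not writable", directory),
          class = c("regharvest_io_error", "regharvest_error"))
  }
  paths <- character(0)
  for (d in seed$documents) {
    p <- file.path(directory, paste0(seed$seed_key, "_", d))
    writeLines(sprintf("placeholder content for %s (%s)", d, seed$seed_key), p)
    paths <- c(paths, p)
  }
  paths
}
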