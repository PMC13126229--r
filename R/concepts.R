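#' Harmonised trial concepts
#'
#' Clinical-trial concepts — the start date, the recruitment status, the
#' sample size, the sponsor type and so on — require analysing several
#' register fields against register-specific value sets. The twenty
#' pre-defined concepts here encapsulate those per-register rules behind one
#' deterministic calculator each: names are `"f."`-prefixed, and a `likely`
#' prefix marks concepts that can only be approximated from register data.
#' Every calculator is total over missing input (missing in, missing out;
#' never an error), and the vocabulary/pattern tables backing them ship in
#' `inst/extdata/vocabularies.yaml`.
#'
#' @name trial-concepts
NULL

# ---- per-document extraction helpers ---------------------------------------

x1 <- function(doc, path) {
  v <- extraction_values(tree_extract(doc$content, path))
  if (is.null(v) || length(v) == 0) NA_character_ else as.character(v[[1]])
}

xall <- function(doc, path) {
  v <- extraction_values(tree_extract(doc$content, path))
  if (is.null(v)) character(0) else as.character(v)
}

# subtree access without the leaf restriction (arrays mapped through)
tree_subtree <- function(node, path) {
  comps <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(n, cs) {
    if (is.null(n) || length(cs) == 0) return(n)
    if (is_array_node(n)) return(lapply(n, rec, cs))
    if (!is.list(n)) return(NULL)
    rec(n[[cs[1]]], cs[-1])
  }
  rec(node, comps)
}

norm_lit <- function(x) tolower(trimws(as.character(x)))

lookup_vocab <- function(table, register, literal, default = NA_character_,
                         notice = TRUE) {
  if (is.na(literal)) return(NA_character_)
  hit <- table[[register]][[norm_lit(literal)]]
  if (is.null(hit)) {
    if (notice) {
      inform(sprintf("unmapped %s literal '%s'; using '%s'",
                     register, literal, default))
    }
    return(default)
  }
  hit
}

parse_years <- function(x) {
  if (is.na(x)) return(NA_integer_)
  n <- suppressWarnings(as.integer(sub("^\\s*(\\d+).*$", "\\1", x)))
  n
}

# ---- individual concept calculators ----------------------------------------

concept_start_date <- function(doc) {
  d <- switch(doc$register,
    CTGOV = x1(doc, "protocolSection.statusModule.startDateStruct.date") %theni%
            x1(doc, "protocolSection.statusModule.studyFirstSubmitDate"),
    EUCTR = x1(doc, "trial_dates.actual_start_date") %theni%
            x1(doc, "trial_dates.planned_start_date") %theni%
            x1(doc, "trial_dates.date_of_competent_authority_decision"),
    CTIS  = x1(doc, "startDate.actualDate") %theni%
            x1(doc, "startDate.plannedDate") %theni%
            x1(doc, "startDate.decisionDate"),
    ISRCTN = x1(doc, "trialDesign.overallStartDate") %theni%
             x1(doc, "dateAssigned"),
    NA_character_
  )
  as_date_safe(d)
}

concept_status <- function(doc) {
  st <- vocab()$status
  reg <- doc$register
  lit <- switch(reg,
    CTGOV = x1(doc, "protocolSection.statusModule.overallStatus") %theni%
            x1(doc, "protocolSection.statusModule.lastKnownStatus"),
    EUCTR = x1(doc, "trial_status") %theni%
            x1(doc, "results.end_of_trial_status"),
    CTIS  = x1(doc, "overallStatus") %theni% x1(doc, "recruitmentStatus"),
    ISRCTN = x1(doc, "trialDesign.overallStatus") %theni%
             x1(doc, "trialDesign.recruitmentStatus"),
    NA_character_
  )
  if (is.na(lit)) return(NA_character_)
  mapped <- lookup_vocab(st, reg, lit, default = NA_character_, notice = FALSE)
  if (is.na(mapped)) {
    # unmapped literal: an early-stop reason still identifies ended_early
    if (reg == "CTGOV" && !is.na(x1(doc, "protocolSection.statusModule.whyStopped"))) {
      return("ended_early")
    }
    inform(sprintf("unmapped %s status literal '%s'; using 'other'", reg, lit))
    return("other")
  }
  # registers leave records "ongoing" after the trial has globally ended
  if (mapped == "ongoing") {
    ended <- switch(reg,
      EUCTR = !is.na(x1(doc, "trial_dates.global_end_of_trial_date")),
      ISRCTN = !is.na(x1(doc, "trialDesign.overallEndDate")),
      FALSE)
    if (isTRUE(ended)) return("completed")
  }
  mapped
}

concept_phase <- function(doc) {
  ph <- vocab()$phase
  reg <- doc$register
  lit <- switch(reg,
    CTGOV = {
      toks <- xall(doc, "protocolSection.designModule.phases")
      if (length(toks) == 0) NA_character_ else paste(tolower(toks), collapse = "/")
    },
    EUCTR = {
      flags <- c(x1(doc, "trial_information.trial_phase.human_pharmacology"),
                 x1(doc, "trial_information.trial_phase.exploratory"),
                 x1(doc, "trial_information.trial_phase.confirmatory"),
                 x1(doc, "trial_information.trial_phase.therapeutic_use"))
      if (all(is.na(flags))) NA_character_ else {
        paste(ifelse(norm_lit(flags) == "yes", "y", "n"), collapse = "")
      }
    },
    CTIS = x1(doc, "trialPhase"),
    ISRCTN = x1(doc, "trialDesign.trialPhase"),
    NA_character_
  )
  lookup_vocab(ph, reg, lit, default = "other")
}

concept_population <- function(doc) {
  reg <- doc$register
  groups <- if (reg == "EUCTR") {
    fl <- c(children = x1(doc, "population.age_groups.children"),
            adults = x1(doc, "population.age_groups.adults"),
            elderly = x1(doc, "population.age_groups.elderly"))
    if (all(is.na(fl))) return(NA_character_)
    names(fl)[norm_lit(fl) == "yes"]
  } else {
    lo_hi <- switch(reg,
      CTGOV = c(x1(doc, "protocolSection.eligibilityModule.minimumAge"),
                x1(doc, "protocolSection.eligibilityModule.maximumAge")),
      CTIS  = c(x1(doc, "population.minimumAge"), x1(doc, "population.maximumAge")),
      ISRCTN = c(x1(doc, "participants.lowerAgeLimit"),
                 x1(doc, "participants.upperAgeLimit")),
      c(NA_character_, NA_character_)
    )
    lo <- parse_years(lo_hi[1])
    hi <- parse_years(lo_hi[2])
    if (is.na(lo) && is.na(hi)) return(NA_character_)
    age_groups_from_range(lo %theni% 0L, hi %theni% 99L)
  }
  if (length(groups) == 0) NA_character_ else paste(groups, collapse = "+")
}

concept_sample_size <- function(doc, status = NULL) {
  status <- status %||% concept_status(doc)
  reg <- doc$register
  planned <- switch(reg,
    CTGOV = {
      if (identical(x1(doc, "protocolSection.designModule.enrollmentInfo.type"), "ESTIMATED"))
        x1(doc, "protocolSection.designModule.enrollmentInfo.count") else NA_character_
    },
    EUCTR = x1(doc, "population.planned_subjects"),
    CTIS  = x1(doc, "recruitment.plannedSubjects"),
    ISRCTN = x1(doc, "participants.targetEnrolment"),
    NA_character_
  )
  achieved <- switch(reg,
    CTGOV = {
      if (identical(x1(doc, "protocolSection.designModule.enrollmentInfo.type"), "ACTUAL"))
        x1(doc, "protocolSection.designModule.enrollmentInfo.count") else NA_character_
    },
    EUCTR = x1(doc, "results.actual_enrollment"),
    CTIS  = x1(doc, "recruitment.actualSubjects"),
    ISRCTN = x1(doc, "participants.totalFinalEnrolment"),
    NA_character_
  )
  # achieved numbers once the trial has ended, planned numbers while it runs;
  # never silently the planned count for an ended trial
  chosen <- if (!is.na(status) && status %in% c("completed", "ended_early")) achieved else planned
  suppressWarnings(as.integer(chosen))
}

concept_sponsor_type <- function(doc) {
  sc <- vocab()$sponsor_class
  reg <- doc$register
  lits <- switch(reg,
    CTGOV = c(x1(doc, "protocolSection.sponsorCollaboratorsModule.leadSponsor.class"),
              xall(doc, "protocolSection.sponsorCollaboratorsModule.collaborators.class")),
    EUCTR = xall(doc, "sponsors.sponsor.status"),
    CTIS  = xall(doc, "sponsors.type"),
    ISRCTN = xall(doc, "sponsors.sponsor.sponsorType"),
    character(0)
  )
  lits <- lits[!is.na(lits)]
  if (length(lits) == 0) return(NA_character_)
  classes <- unique(vapply(lits, function(l) {
    lookup_vocab(sc, reg, l, default = "non_commercial")
  }, character(1)))
  if (all(c("commercial", "non_commercial") %in% classes)) "mixed" else classes[1]
}

concept_num_sites <- function(doc) {
  reg <- doc$register
  if (reg == "CTGOV") {
    n <- length(xall(doc, "protocolSection.contactsLocationsModule.locations.facility"))
    list(numSites = if (n == 0) NA_integer_ else n,
         numSitesIncomplete = if (n == 0) NA else FALSE)
  } else if (reg == "CTIS") {
    n <- length(xall(doc, "sites.name"))
    list(numSites = if (n == 0) NA_integer_ else n,
         numSitesIncomplete = if (n == 0) NA else FALSE)
  } else if (reg == "EUCTR") {
    # EUCTR has no site numbers for non-EEA countries: the count is an
    # EEA-derived lower bound, flagged incomplete when non-EEA countries occur
    eea <- xall(doc, "participating_countries.country.eea")
    if (length(eea) == 0) {
      list(numSites = NA_integer_, numSitesIncomplete = NA)
    } else {
      list(numSites = sum(norm_lit(eea) == "yes"),
           numSitesIncomplete = any(norm_lit(eea) == "no"))
    }
  } else {
    n <- suppressWarnings(as.integer(x1(doc, "participants.totalCentres")))
    list(numSites = n, numSitesIncomplete = if (is.na(n)) NA else FALSE)
  }
}

# frozen endpoint-string separators: " == " joins the title/definition/
# timeframe components of one endpoint, " ;; " joins multiple endpoints
EP_COMPONENT_SEP <- " == "
EP_ENDPOINT_SEP <- " ;; "

primary_endpoint_nodes <- function(doc) {
  path <- switch(doc$register,
    CTGOV = "protocolSection.outcomesModule.primaryOutcomes",
    EUCTR = "endpoints.primary_endpoint",
    CTIS  = "endpoints.primary",
    ISRCTN = "outcomes.primaryOutcome",
    return(list())
  )
  as_array(tree_subtree(doc$content, path))
}

concept_primary_endpoint_description <- function(doc) {
  fields <- switch(doc$register,
    CTGOV = c("measure", "description", "timeFrame"),
    EUCTR = c("title", "description", "timeframe"),
    CTIS  = c("title", "description", "timeframe"),
    ISRCTN = c("description", "timepoints"),
    return(NA_character_)
  )
  eps <- primary_endpoint_nodes(doc)
  if (length(eps) == 0) return(NA_character_)
  strs <- vapply(eps, function(e) {
    comps <- unlist(lapply(fields, function(f) e[[f]]))
    comps <- comps[!is.na(normalize_missing(comps))]
    if (length(comps) == 0) NA_character_ else paste(comps, collapse = EP_COMPONENT_SEP)
  }, character(1))
  strs <- strs[!is.na(strs)]
  if (length(strs) == 0) NA_character_ else paste(strs, collapse = EP_ENDPOINT_SEP)
}

#' Classify an endpoint description as change-from-baseline
#'
#' Case-insensitive pattern match (pattern shipped in the vocabulary file)
#' deciding whether an endpoint text likely describes a
#' difference-from-baseline variable.
#'
#' @param text Endpoint description text (vectorised).
#' @return Logical; `NA` for missing text.
#' @export
classify_endpoint_change_from_baseline <- function(text) {
  pat <- vocab()$change_from_baseline_pattern
  out <- grepl(pat, text, ignore.case = TRUE)
  out[is.na(text)] <- NA
  out
}

concept_objectives <- function(doc) {
  txt <- switch(doc$register,
    CTGOV = x1(doc, "protocolSection.descriptionModule.briefSummary"),
    EUCTR = x1(doc, "trial_information.main_objective"),
    CTIS  = x1(doc, "objectives"),
    ISRCTN = x1(doc, "trialDescription.studyHypothesis"),
    NA_character_
  )
  if (is.na(txt)) return(NA_character_)
  pats <- vocab()$objectives_patterns
  tags <- names(pats)[vapply(pats, function(p) grepl(p, txt, ignore.case = TRUE), logical(1))]
  if (length(tags) == 0) NA_character_ else paste(tags, collapse = "+")
}

concept_title <- function(doc) {
  switch(doc$register,
    CTGOV = x1(doc, "protocolSection.identificationModule.briefTitle"),
    EUCTR = x1(doc, "trial_information.full_title"),
    CTIS  = x1(doc, "title"),
    ISRCTN = x1(doc, "trialDescription.title"),
    NA_character_
  )
}

concept_platform <- function(doc) {
  v <- vocab()
  txt <- c(concept_title(doc),
           switch(doc$register,
                  ISRCTN = x1(doc, "trialDesign.studyDesign"),
                  CTGOV = x1(doc, "protocolSection.designModule.designInfo.interventionModel"),
                  NA_character_))
  txt <- txt[!is.na(txt)]
  if (length(txt) == 0) return(NA)
  if (any(grepl(v$platform_pattern, txt, ignore.case = TRUE))) return(TRUE)
  arms <- length(xall(doc, "protocolSection.armsInterventionsModule.armGroups.label"))
  arms >= v$platform_min_arms &&
    any(grepl(v$shared_control_pattern, txt, ignore.case = TRUE))
}

concept_endpoint_results <- function(doc) {
  if (doc$register == "CTGOV") {
    oms <- as_array(tree_subtree(doc$content,
                                 "resultsSection.outcomeMeasuresModule.outcomeMeasures"))
    for (om in oms) {
      if (identical(om$type, "PRIMARY")) {
        an <- as_array(om$analyses)
        if (length(an) > 0) {
          return(list(p_value = suppressWarnings(as.numeric(an[[1]]$pValue)),
                      method = as.character(an[[1]]$statisticalMethod %||% NA_character_)))
        }
      }
    }
  } else if (doc$register == "EUCTR") {
    p <- x1(doc, "results.primary_analysis.p_value")
    if (!is.na(p)) {
      return(list(p_value = suppressWarnings(as.numeric(p)),
                  method = x1(doc, "results.primary_analysis.statistical_method")))
    }
  }
  # CTIS and ISRCTN publish no structured results
  list(p_value = NA_real_, method = NA_character_)
}

concept_has_results <- function(doc) {
  switch(doc$register,
    CTGOV = isTRUE(doc$content$hasResults),
    EUCTR = !is.na(x1(doc, "results.primary_analysis.p_value")),
    FALSE
  )
}

concept_results_date <- function(doc) {
  d <- switch(doc$register,
    CTGOV = x1(doc, "protocolSection.statusModule.resultsFirstPostDateStruct.date"),
    EUCTR = x1(doc, "results.publication_date"),
    NA_character_
  )
  as_date_safe(d)
}

concept_num_test_arms <- function(doc) {
  n <- switch(doc$register,
    CTGOV = length(unique(xall(doc, "protocolSection.armsInterventionsModule.interventions.name"))),
    EUCTR = length(unique(xall(doc, "imp.product.name"))),
    CTIS  = length(unique(xall(doc, "interventions.name"))),
    ISRCTN = length(unique(xall(doc, "interventions.intervention.drugNames"))),
    0L
  )
  if (n == 0) NA_integer_ else as.integer(n)
}

concept_is_med_interv <- function(doc) {
  switch(doc$register,
    CTGOV = identical(x1(doc, "protocolSection.designModule.studyType"), "INTERVENTIONAL") &&
            "DRUG" %in% xall(doc, "protocolSection.armsInterventionsModule.interventions.type"),
    ISRCTN = identical(x1(doc, "trialDesign.primaryStudyDesign"), "Interventional") &&
             "Drug" %in% xall(doc, "interventions.intervention.interventionType"),
    # EUCTR and CTIS carry interventional medicines trials by construction
    TRUE
  )
}

concept_assignment <- function(doc) {
  reg <- doc$register
  lit <- switch(reg,
    CTGOV = x1(doc, "protocolSection.designModule.designInfo.allocation"),
    EUCTR = x1(doc, "trial_information.randomised"),
    CTIS  = x1(doc, "randomised"),
    ISRCTN = x1(doc, "trialDesign.studyDesign"),
    NA_character_
  )
  if (is.na(lit)) return(NA_character_)
  l <- norm_lit(lit)
  if (reg == "CTGOV") {
    if (l == "randomized") "randomised" else "non_randomised"
  } else if (reg == "ISRCTN") {
    if (grepl("^non-randomised", l)) "non_randomised"
    else if (grepl("randomised", l)) "randomised"
    else NA_character_
  } else {
    if (l %in% c("yes", "true")) "randomised" else "non_randomised"
  }
}

concept_end_date <- function(doc) {
  d <- switch(doc$register,
    CTGOV = x1(doc, "protocolSection.statusModule.completionDateStruct.date"),
    EUCTR = x1(doc, "trial_dates.global_end_of_trial_date"),
    CTIS  = x1(doc, "endDate"),
    ISRCTN = x1(doc, "trialDesign.overallEndDate"),
    NA_character_
  )
  as_date_safe(d)
}

# ---- deduplication ---------------------------------------------------------

# All trial identifiers carried by a document: its own register-native id
# (EUCTR ids normalised by stripping the member-state suffix) plus every
# secondary cross-reference.
doc_identifiers <- function(doc) {
  own <- doc[["_id"]]
  if (doc$register == "EUCTR") own <- sub("-[A-Z]{2}$", "", own)
  sec <- switch(doc$register,
    CTGOV = xall(doc, "protocolSection.identificationModule.secondaryIdInfos.id"),
    CTIS  = xall(doc, "secondaryIdentifiers.id"),
    EUCTR = c(x1(doc, "identification.nct_number"),
              x1(doc, "identification.ctis_number"),
              x1(doc, "identification.isrctn_number")),
    ISRCTN = c(x1(doc, "externalRefs.eudraCTNumber"),
               x1(doc, "externalRefs.clinicalTrialsGovNumber"),
               x1(doc, "externalRefs.ctisNumber")),
    character(0)
  )
  unique(c(own, sec[!is.na(sec)]))
}

#' Flag one preferred record per unique trial
#'
#' A trial may be registered in several registers, and EUCTR stores one record
#' per participating member state; counting records therefore over-counts
#' trials. Records are grouped into equivalence classes by union-find over
#' shared identifiers (register-native ids plus secondary cross-references)
#' and exactly one record per class is flagged, chosen by register preference,
#' then preferred member state, then lexicographic record id. The result is
#' invariant under record permutation.
#'
#' @param col A `trial_collection`, or a named list of documents.
#' @param prefer_register Register preference order for the surviving record.
#' @param prefer_member_state Two-letter code preferred among EUCTR
#'   member-state records (default: alphabetically first).
#' @return Named logical vector, one element per record id.
#' @export
is_unique_trial <- function(col,
                            prefer_register = c("CTGOV", "CTIS", "EUCTR", "ISRCTN"),
                            prefer_member_state = NULL) {
  docs <- if (inherits(col, "trial_collection")) col_docs(col) else col
  ids <- names(docs)
  n <- length(docs)
  if (n == 0) return(stats::setNames(logical(0), character(0)))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  ident <- lapply(docs, doc_identifiers)
  owner <- list()
  for (i in seq_len(n)) {
    for (k in ident[[i]]) {
      if (is.null(owner[[k]])) owner[[k]] <- i else union_(owner[[k]], i)
    }
  }
  classes <- vapply(seq_len(n), find, integer(1))
  flags <- stats::setNames(rep(FALSE, n), ids)
  for (cl in unique(classes)) {
    members <- which(classes == cl)
    reg <- vapply(members, function(i) docs[[i]]$register, character(1))
    pr <- match(reg, prefer_register)
    pr[is.na(pr)] <- length(prefer_register) + 1
    ms_rank <- vapply(seq_along(members), function(j) {
      if (reg[j] == "EUCTR" && !is.null(prefer_member_state)) {
        ms <- sub("^.*-([A-Z]{2})$", "\\1", ids[members[j]])
        if (identical(ms, prefer_member_state)) 0L else 1L
      } else 0L
    }, integer(1))
    ord <- order(pr, ms_rank, ids[members])
    flags[members[ord[1]]] <- TRUE
  }
  flags
}

# ---- registry --------------------------------------------------------------

concept_defs <- function() {
  list(
    list(name = "f.isUniqueTrial", approximate = FALSE,
         output = c(isUniqueTrial = "flag"),
         paths = list(
           CTGOV = c("protocolSection.identificationModule.nctId",
                     "protocolSection.identificationModule.secondaryIdInfos.id"),
           EUCTR = c("identification.eudract_number", "identification.nct_number",
                     "identification.ctis_number", "identification.isrctn_number"),
           CTIS = c("ctNumber", "secondaryIdentifiers.id"),
           ISRCTN = c("isrctn", "externalRefs.eudraCTNumber",
                      "externalRefs.clinicalTrialsGovNumber", "externalRefs.ctisNumber"))),
    list(name = "f.startDate", approximate = FALSE,
         output = c(startDate = "date"),
         paths = list(
           CTGOV = c("protocolSection.statusModule.startDateStruct.date",
                     "protocolSection.statusModule.startDateStruct.type",
                     "protocolSection.statusModule.studyFirstSubmitDate"),
           EUCTR = c("trial_dates.actual_start_date", "trial_dates.planned_start_date",
                     "trial_dates.date_of_competent_authority_decision"),
           CTIS = c("startDate.actualDate", "startDate.plannedDate", "startDate.decisionDate"),
           ISRCTN = c("trialDesign.overallStartDate", "dateAssigned"))),
    list(name = "f.statusRecruitment", approximate = FALSE,
         output = c(statusRecruitment = "text"),
         paths = list(
           CTGOV = c("protocolSection.statusModule.overallStatus",
                     "protocolSection.statusModule.lastKnownStatus",
                     "protocolSection.statusModule.whyStopped"),
           EUCTR = c("trial_status", "results.end_of_trial_status",
                     "trial_dates.global_end_of_trial_date"),
           CTIS = c("overallStatus", "recruitmentStatus"),
           ISRCTN = c("trialDesign.overallStatus", "trialDesign.recruitmentStatus",
                      "trialDesign.overallEndDate"))),
    list(name = "f.sampleSize", approximate = FALSE,
         output = c(sampleSize = "integer"),
         paths = list(
           CTGOV = c("protocolSection.designModule.enrollmentInfo.count",
                     "protocolSection.designModule.enrollmentInfo.type"),
           EUCTR = c("population.planned_subjects", "results.actual_enrollment"),
           CTIS = c("recruitment.plannedSubjects", "recruitment.actualSubjects"),
           ISRCTN = c("participants.targetEnrolment", "participants.totalFinalEnrolment"))),
    list(name = "f.sponsorType", approximate = FALSE,
         output = c(sponsorType = "text"),
         paths = list(
           CTGOV = c("protocolSection.sponsorCollaboratorsModule.leadSponsor.class",
                     "protocolSection.sponsorCollaboratorsModule.collaborators.class"),
           EUCTR = "sponsors.sponsor.status",
           CTIS = "sponsors.type",
           ISRCTN = "sponsors.sponsor.sponsorType")),
    list(name = "f.numSites", approximate = FALSE,
         output = c(numSites = "integer", numSitesIncomplete = "flag"),
         paths = list(
           CTGOV = "protocolSection.contactsLocationsModule.locations.facility",
           EUCTR = c("participating_countries.country.code", "participating_countries.country.eea"),
           CTIS = "sites.name",
           ISRCTN = "participants.totalCentres")),
    list(name = "f.trialPhase", approximate = FALSE,
         output = c(trialPhase = "text"),
         paths = list(
           CTGOV = "protocolSection.designModule.phases",
           EUCTR = c("trial_information.trial_phase.human_pharmacology",
                     "trial_information.trial_phase.exploratory",
                     "trial_information.trial_phase.confirmatory",
                     "trial_information.trial_phase.therapeutic_use"),
           CTIS = "trialPhase",
           ISRCTN = "trialDesign.trialPhase")),
    list(name = "f.trialPopulation", approximate = FALSE,
         output = c(trialPopulation = "text"),
         paths = list(
           CTGOV = c("protocolSection.eligibilityModule.minimumAge",
                     "protocolSection.eligibilityModule.maximumAge"),
           EUCTR = c("population.age_groups.children", "population.age_groups.adults",
                     "population.age_groups.elderly"),
           CTIS = c("population.minimumAge", "population.maximumAge"),
           ISRCTN = c("participants.lowerAgeLimit", "participants.upperAgeLimit"))),
    list(name = "f.trialObjectives", approximate = TRUE,
         output = c(trialObjectives = "text"),
         paths = list(
           CTGOV = "protocolSection.descriptionModule.briefSummary",
           EUCTR = "trial_information.main_objective",
           CTIS = "objectives",
           ISRCTN = "trialDescription.studyHypothesis")),
    list(name = "f.primaryEndpointDescription", approximate = FALSE,
         output = c(primaryEndpointDescription = "text"),
         paths = list(
           CTGOV = c("protocolSection.outcomesModule.primaryOutcomes.measure",
                     "protocolSection.outcomesModule.primaryOutcomes.description",
                     "protocolSection.outcomesModule.primaryOutcomes.timeFrame"),
           EUCTR = c("endpoints.primary_endpoint.title", "endpoints.primary_endpoint.description",
                     "endpoints.primary_endpoint.timeframe"),
           CTIS = c("endpoints.primary.title", "endpoints.primary.description",
                    "endpoints.primary.timeframe"),
           ISRCTN = c("outcomes.primaryOutcome.description", "outcomes.primaryOutcome.timepoints"))),
    list(name = "f.likelyChangeFromBaselineEndpoint", approximate = TRUE,
         output = c(likelyChangeFromBaselineEndpoint = "flag"),
         paths = list(
           CTGOV = "protocolSection.outcomesModule.primaryOutcomes.measure",
           EUCTR = "endpoints.primary_endpoint.title",
           CTIS = "endpoints.primary.title",
           ISRCTN = "outcomes.primaryOutcome.description")),
    list(name = "f.primaryEndpointResults", approximate = FALSE,
         output = c(endpointResultsPValue = "real", endpointResultsMethod = "text"),
         paths = list(
           CTGOV = c("resultsSection.outcomeMeasuresModule.outcomeMeasures.analyses.pValue",
                     "resultsSection.outcomeMeasuresModule.outcomeMeasures.analyses.statisticalMethod"),
           EUCTR = c("results.primary_analysis.p_value", "results.primary_analysis.statistical_method"),
           CTIS = character(0),
           ISRCTN = character(0))),
    list(name = "f.likelyPlatformTrial", approximate = TRUE,
         output = c(likelyPlatformTrial = "flag"),
         paths = list(
           CTGOV = c("protocolSection.identificationModule.briefTitle",
                     "protocolSection.armsInterventionsModule.armGroups.label",
                     "protocolSection.designModule.designInfo.interventionModel"),
           EUCTR = "trial_information.full_title",
           CTIS = "title",
           ISRCTN = c("trialDescription.title", "trialDesign.studyDesign"))),
    list(name = "f.trialTitle", approximate = FALSE,
         output = c(trialTitle = "text"),
         paths = list(
           CTGOV = "protocolSection.identificationModule.briefTitle",
           EUCTR = "trial_information.full_title",
           CTIS = "title",
           ISRCTN = "trialDescription.title")),
    list(name = "f.hasResults", approximate = FALSE,
         output = c(hasResults = "flag"),
         paths = list(
           CTGOV = "hasResults",
           EUCTR = "results.primary_analysis.p_value",
           CTIS = character(0),
           ISRCTN = character(0))),
    list(name = "f.resultsDate", approximate = FALSE,
         output = c(resultsDate = "date"),
         paths = list(
           CTGOV = "protocolSection.statusModule.resultsFirstPostDateStruct.date",
           EUCTR = "results.publication_date",
           CTIS = character(0),
           ISRCTN = character(0))),
    list(name = "f.numTestArmsSubstances", approximate = TRUE,
         output = c(numTestArmsSubstances = "integer"),
         paths = list(
           CTGOV = "protocolSection.armsInterventionsModule.interventions.name",
           EUCTR = "imp.product.name",
           CTIS = "interventions.name",
           ISRCTN = "interventions.intervention.drugNames")),
    list(name = "f.isMedIntervTrial", approximate = FALSE,
         output = c(isMedIntervTrial = "flag"),
         paths = list(
           CTGOV = c("protocolSection.designModule.studyType",
                     "protocolSection.armsInterventionsModule.interventions.type"),
           EUCTR = character(0),
           CTIS = character(0),
           ISRCTN = c("trialDesign.primaryStudyDesign",
                      "interventions.intervention.interventionType"))),
    list(name = "f.assignmentType", approximate = FALSE,
         output = c(assignmentType = "text"),
         paths = list(
           CTGOV = "protocolSection.designModule.designInfo.allocation",
           EUCTR = "trial_information.randomised",
           CTIS = "randomised",
           ISRCTN = "trialDesign.studyDesign")),
    list(name = "f.trialEndDate", approximate = FALSE,
         output = c(trialEndDate = "date"),
         paths = list(
           CTGOV = "protocolSection.statusModule.completionDateStruct.date",
           EUCTR = "trial_dates.global_end_of_trial_date",
           CTIS = "endDate",
           ISRCTN = "trialDesign.overallEndDate"))
  )
}

#' The harmonised trial-concept registry
#'
#' @return A tibble with one row per pre-defined concept: `name`
#'   (`"f."`-prefixed, `likely` marking approximations), `approximate`,
#'   `output_columns` (list of name->type), and `required_paths` (list of
#'   register->paths consulted).
#' @examples
#' nrow(concept_registry())
#' @export
concept_registry <- function() {
  defs <- concept_defs()
  tibble::tibble(
    name = vapply(defs, `[[`, character(1), "name"),
    approximate = vapply(defs, `[[`, logical(1), "approximate"),
    output_columns = lapply(defs, `[[`, "output"),
    required_paths = lapply(defs, `[[`, "paths")
  )
}

# distinct source field paths jointly declared by the start-date and
# recruitment-status calculators (spans well over 20 register fields)
start_status_field_paths <- function() {
  defs <- concept_defs()
  nm <- vapply(defs, `[[`, character(1), "name")
  two <- defs[nm %in% c("f.startDate", "f.statusRecruitment")]
  sort(unique(unlist(lapply(two, `[[`, "paths"))))
}

concept_calculators <- function() {
  list(
    "f.startDate" = function(docs, status) {
      as.Date(vapply(docs, function(d) as.character(concept_start_date(d)), character(1)),
              format = "%Y-%m-%d")
    },
    "f.statusRecruitment" = function(docs, status) status,
    "f.sampleSize" = function(docs, status) {
      vapply(seq_along(docs), function(i) concept_sample_size(docs[[i]], status[i]), integer(1))
    },
    "f.sponsorType" = function(docs, status) vapply(docs, concept_sponsor_type, character(1)),
    "f.trialPhase" = function(docs, status) vapply(docs, concept_phase, character(1)),
    "f.trialPopulation" = function(docs, status) vapply(docs, concept_population, character(1)),
    "f.trialObjectives" = function(docs, status) vapply(docs, concept_objectives, character(1)),
    "f.primaryEndpointDescription" = function(docs, status) {
      vapply(docs, concept_primary_endpoint_description, character(1))
    },
    "f.likelyChangeFromBaselineEndpoint" = function(docs, status) {
      classify_endpoint_change_from_baseline(
        vapply(docs, concept_primary_endpoint_description, character(1)))
    },
    "f.likelyPlatformTrial" = function(docs, status) vapply(docs, concept_platform, logical(1)),
    "f.trialTitle" = function(docs, status) vapply(docs, concept_title, character(1)),
    "f.hasResults" = function(docs, status) vapply(docs, concept_has_results, logical(1)),
    "f.resultsDate" = function(docs, status) {
      as.Date(vapply(docs, function(d) as.character(concept_results_date(d)), character(1)),
              format = "%Y-%m-%d")
    },
    "f.numTestArmsSubstances" = function(docs, status) vapply(docs, concept_num_test_arms, integer(1)),
    "f.isMedIntervTrial" = function(docs, status) vapply(docs, concept_is_med_interv, logical(1)),
    "f.assignmentType" = function(docs, status) vapply(docs, concept_assignment, character(1)),
    "f.trialEndDate" = function(docs, status) {
      as.Date(vapply(docs, function(d) as.character(concept_end_date(d)), character(1)),
              format = "%Y-%m-%d")
    }
  )
}

normalise_concept_name <- function(x) {
  ifelse(startsWith(x, "f."), x, paste0("f.", x))
}

# Compute requested concepts over a document list; returns a tibble of the
# concepts' output columns (rows in document order).
calculate_concepts <- function(docs, names) {
  reg_names <- vapply(concept_defs(), `[[`, character(1), "name")
  wanted <- normalise_concept_name(names)
  unknown <- setdiff(wanted, reg_names)
  assert_that(length(unknown) == 0,
              sprintf("unknown concept(s): %s\nvalid concepts: %s",
                      paste(unknown, collapse = ", "),
                      paste(reg_names, collapse = ", ")),
              "regharvest_argument_error")
  docs <- unname(docs) # positional; ids re-attached by caller order
  status <- vapply(docs, concept_status, character(1))
  calcs <- concept_calculators()
  out <- tibble::tibble(.rows = length(docs))
  for (w in wanted) {
    if (w == "f.isUniqueTrial") {
      named_docs <- stats::setNames(docs, vapply(docs, `[[`, character(1), "_id"))
      fl <- is_unique_trial(named_docs)
      out$isUniqueTrial <- unname(fl)
    } else if (w == "f.numSites") {
      ns <- lapply(docs, concept_num_sites)
      out$numSites <- vapply(ns, function(x) x$numSites %||% NA_integer_, integer(1))
      out$numSitesIncomplete <- vapply(ns, function(x) as.logical(x$numSitesIncomplete), logical(1))
    } else if (w == "f.primaryEndpointResults") {
      er <- lapply(docs, concept_endpoint_results)
      out$endpointResultsPValue <- vapply(er, function(x) x$p_value %||% NA_real_, numeric(1))
      out$endpointResultsMethod <- vapply(er, function(x) {
        m <- x$method
        if (is.null(m) || length(m) == 0) NA_character_ else as.character(m)
      }, character(1))
    } else {
      out[[sub("^f\\.", "", w)]] <- calcs[[w]](docs, status)
    }
  }
  out
}
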