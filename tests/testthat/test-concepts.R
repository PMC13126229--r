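test_that("the registry lists twenty uniquely named concepts with documented paths", {
  reg <- concept_registry()
  expect_identical(nrow(reg), 20L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_true(all(startsWith(reg$name, "f.")))
  # approximate concepts are flagged in their names
  expect_true(all(grepl("likely", reg$name[reg$name %in%
    c("f.likelyPlatformTrial", "f.likelyChangeFromBaselineEndpoint")])))
  # every required path is documented in the dialect reference
  ref <- paste(readLines(system.file("extdata", "dialect-reference.md",
                                     package = "regharvest")), collapse = "\n")
  for (paths in reg$required_paths) {
    for (p in unlist(paths)) {
      expect_true(grepl(p, ref, fixed = TRUE), info = p)
    }
  }
})

test_that("start date and recruitment status jointly span more than twenty fields", {
  expect_gt(length(regharvest:::start_status_field_paths()), 20)
})

stub <- function(register, content) make_doc(register, content, "S1")

test_that("status vocabulary mapping follows the per-register tables", {
  expect_identical(regharvest:::concept_status(stub("CTGOV", list(
    protocolSection = list(statusModule = list(overallStatus = "Recruiting"))))),
    "ongoing")
  expect_identical(regharvest:::concept_status(stub("EUCTR", list(
    trial_status = "Prematurely Ended"))), "ended_early")
  expect_message(
    got <- regharvest:::concept_status(stub("CTIS", list(overallStatus = "Bizarre"))),
    "unmapped")
  expect_identical(got, "other")
  expect_identical(regharvest:::concept_status(stub("CTGOV", list())), NA_character_)
})

test_that("phase literals map onto the canonical scale", {
  expect_identical(regharvest:::concept_phase(stub("CTGOV", list(
    protocolSection = list(designModule = list(phases = list("Phase 1", "Phase 2")))))),
    "1_2")
  expect_identical(regharvest:::concept_phase(stub("EUCTR", list(
    trial_information = list(trial_phase = list(
      human_pharmacology = "No", exploratory = "Yes", confirmatory = "Yes",
      therapeutic_use = "No"))))), "2_3")
  expect_identical(regharvest:::concept_phase(stub("ISRCTN", list(
    trialDesign = list(trialPhase = "Not Applicable")))), "other")
})

test_that("sample size honours the recruitment-status rule", {
  ctis <- function(status, planned, actual = NULL) {
    stub("CTIS", list(
      overallStatus = status,
      recruitment = regharvest:::drop_nulls(list(plannedSubjects = planned,
                                                 actualSubjects = actual))))
  }
  expect_identical(regharvest:::concept_sample_size(ctis("Ended", 150, 120)), 120L)
  expect_identical(regharvest:::concept_sample_size(ctis("Ongoing", 150)), 150L)
  # ended without an achieved count: missing, never silently the planned number
  expect_identical(regharvest:::concept_sample_size(ctis("Ended", 150)), NA_integer_)
})

test_that("sponsor rosters with both classes yield 'mixed'", {
  mixed <- stub("EUCTR", list(sponsors = list(sponsor = list(
    list(name = "A", status = "Commercial"),
    list(name = "B", status = "Non-Commercial")))))
  expect_identical(regharvest:::concept_sponsor_type(mixed), "mixed")
  allc <- stub("CTIS", list(sponsors = list(list(name = "A", type = "Commercial"))))
  expect_identical(regharvest:::concept_sponsor_type(allc), "commercial")
  expect_identical(regharvest:::concept_sponsor_type(stub("CTGOV", list())), NA_character_)
})

test_that("EUCTR site counts are EEA-derived with a completeness flag", {
  doc <- stub("EUCTR", list(participating_countries = list(country = list(
    list(code = "BE", eea = "Yes"), list(code = "DE", eea = "Yes"),
    list(code = "US", eea = "No")))))
  ns <- regharvest:::concept_num_sites(doc)
  expect_identical(ns$numSites, 2L)
  expect_true(ns$numSitesIncomplete)
  ctgov <- stub("CTGOV", list(protocolSection = list(contactsLocationsModule =
    list(locations = list(list(facility = "a"), list(facility = "b"),
                          list(facility = "c"), list(facility = "d"))))))
  expect_identical(regharvest:::concept_num_sites(ctgov)$numSites, 4L)
  expect_true(is.na(regharvest:::concept_num_sites(stub("CTIS", list()))$numSites))
})

test_that("endpoint descriptions use the frozen separators", {
  doc <- stub("CTIS", list(endpoints = list(primary = list(
    list(title = "t", description = "d", timeframe = "f"),
    list(title = "t2", description = "d2", timeframe = "f2")))))
  expect_identical(regharvest:::concept_primary_endpoint_description(doc),
                   "t == d == f ;; t2 == d2 == f2")
  single <- stub("CTIS", list(endpoints = list(primary = list(
    list(title = "t", description = "d", timeframe = "f")))))
  expect_identical(regharvest:::concept_primary_endpoint_description(single),
                   "t == d == f")
  expect_identical(regharvest:::concept_primary_endpoint_description(stub("CTIS", list())),
                   NA_character_)
})

test_that("change-from-baseline classification is pattern-driven", {
  expect_true(classify_endpoint_change_from_baseline("Change from baseline in HbA1c at week 24"))
  expect_true(classify_endpoint_change_from_baseline("Mean DIFFERENCE from baseline"))
  expect_false(classify_endpoint_change_from_baseline("Overall survival"))
  expect_identical(classify_endpoint_change_from_baseline(NA_character_), NA)
})

test_that("age boundaries map onto population groups", {
  doc <- stub("CTGOV", list(protocolSection = list(eligibilityModule =
    list(minimumAge = "18 Years", maximumAge = "99 Years"))))
  expect_identical(regharvest:::concept_population(doc), "adults+elderly")
  kid <- stub("CTIS", list(population = list(minimumAge = 2, maximumAge = 17)))
  expect_identical(regharvest:::concept_population(kid), "children")
})

test_that("objective tags and platform markers match their patterns", {
  doc <- stub("CTIS", list(objectives = "to determine the maximum tolerated dose"))
  expect_match(regharvest:::concept_objectives(doc), "dose_finding")
  plat <- stub("CTIS", list(title = "A platform trial of everything"))
  expect_true(regharvest:::concept_platform(plat))
  # arm-count route: many arms plus a shared-control marker
  arms <- stub("CTGOV", list(protocolSection = list(
    identificationModule = list(briefTitle = "A trial with a shared control arm"),
    armsInterventionsModule = list(armGroups = lapply(1:5, function(i) list(label = i))))))
  expect_true(regharvest:::concept_platform(arms))
  plain <- stub("CTIS", list(title = "A parallel trial of one drug"))
  expect_false(regharvest:::concept_platform(plain))
})

test_that("dedup flags exactly one record per identifier equivalence class", {
  docs <- list(
    `NCT00000001` = make_doc("CTGOV", list(protocolSection = list(
      identificationModule = list(
        nctId = "NCT00000001",
        secondaryIdInfos = list(list(id = "2010-000001-01", type = "EudraCT Number"))))),
      "NCT00000001"),
    `2010-000001-01-BE` = make_doc("EUCTR", list(identification = list(
      eudract_number = "2010-000001-01", full_id = "2010-000001-01-BE")),
      "2010-000001-01-BE"),
    `2010-000001-01-DE` = make_doc("EUCTR", list(identification = list(
      eudract_number = "2010-000001-01", full_id = "2010-000001-01-DE")),
      "2010-000001-01-DE"),
    `2010-000001-01-AT` = make_doc("EUCTR", list(identification = list(
      eudract_number = "2010-000001-01", full_id = "2010-000001-01-AT")),
      "2010-000001-01-AT")
  )
  fl <- is_unique_trial(docs)
  expect_identical(sum(fl), 1L)
  expect_true(fl[["NCT00000001"]]) # CTGOV preferred by default

  # preference order and member state are honoured
  fl2 <- is_unique_trial(docs, prefer_register = c("EUCTR", "CTGOV", "CTIS", "ISRCTN"),
                         prefer_member_state = "DE")
  expect_true(fl2[["2010-000001-01-DE"]])

  # permutation invariance and idempotence
  perm <- docs[c(3, 1, 4, 2)]
  expect_identical(sort(names(which(is_unique_trial(perm)))),
                   sort(names(which(fl))))
  expect_identical(is_unique_trial(docs), fl)

  single <- docs[1]
  expect_true(is_unique_trial(single)[[1]])
  unrelated <- list(
    A = make_doc("CTGOV", list(protocolSection = list(identificationModule =
      list(nctId = "NCT00000009"))), "NCT00000009"),
    B = make_doc("ISRCTN", list(isrctn = "ISRCTN00000001"), "ISRCTN00000001"))
  expect_identical(sum(is_unique_trial(unrelated)), 2L)
})

test_that("calculators are total over documents missing their fields", {
  empty <- list(make_doc("CTGOV", list(), "E1"), make_doc("CTIS", list(x = 1), "E2"))
  names(empty) <- c("E1", "E2")
  all_names <- concept_registry()$name
  out <- regharvest:::calculate_concepts(empty, all_names)
  expect_identical(nrow(out), 2L)
  # boolean concepts with defined fallbacks aside, everything is missing
  expect_true(is.na(out$startDate[1]))
  expect_true(is.na(out$sampleSize[1]))
  expect_true(is.na(out$sponsorType[1]))
  expect_true(is.na(out$primaryEndpointDescription[1]))
})

test_that("every seeded ground-truth value is recovered from every dialect", {
  co <- test_cohort()
  seeds <- seeds_keyed(co$seeds)
  tbl <- get_fields(co$col, paths = "_id", calculate = c(
    "statusRecruitment", "startDate", "sampleSize", "sponsorType", "trialPhase",
    "trialPopulation", "trialObjectives", "numSites",
    "likelyChangeFromBaselineEndpoint", "likelyPlatformTrial",
    "primaryEndpointResults", "trialTitle", "assignmentType"))
  docs <- regharvest:::col_docs(co$col)
  checked <- 0L
  for (i in seq_len(nrow(tbl))) {
    id <- tbl[["_id"]][i]
    reg <- docs[[id]]$register
    s <- Find(function(x) {
      reg %in% names(x$ids) &&
        x$ids[[reg]] == (if (reg == "EUCTR") sub("-[A-Z]{2}$", "", id) else id)
    }, co$seeds)
    expect_false(is.null(s), info = id)
    e <- expected_from_seed(s, reg)
    info <- paste(s$seed_key, reg)
    expect_identical(tbl$trialPhase[i], e$phase, info = info)
    expect_identical(tbl$statusRecruitment[i], e$status, info = info)
    expect_identical(tbl$sampleSize[i], e$sample_size, info = info)
    expect_identical(tbl$sponsorType[i], e$sponsor_type, info = info)
    expect_identical(tbl$numSites[i], e$n_sites, info = info)
    expect_identical(tbl$numSitesIncomplete[i], e$sites_incomplete, info = info)
    expect_identical(tbl$likelyChangeFromBaselineEndpoint[i], e$cfb, info = info)
    expect_identical(tbl$trialPopulation[i], e$population, info = info)
    expect_identical(tbl$trialObjectives[i], e$objectives, info = info)
    expect_identical(tbl$trialTitle[i], e$title, info = info)
    expect_identical(tbl$assignmentType[i], e$assignment, info = info)
    expect_equal(tbl$startDate[i], e$start_date, info = info)
    expect_identical(tbl$likelyPlatformTrial[i], s$is_platform, info = info)
    if (!is.na(e$p_value)) {
      expect_identical(tbl$endpointResultsPValue[i], e$p_value, info = info)
      expect_identical(tbl$endpointResultsMethod[i], e$method, info = info)
      checked <- checked + 1L
    } else {
      expect_true(is.na(tbl$endpointResultsPValue[i]), info = info)
    }
  }
  expect_gt(checked, 0) # the cohort contains trials with structured results
})
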