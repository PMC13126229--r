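#' Synthetic register-record seeds
#'
#' The generator produces ground-truth trials ("seeds") from which the four
#' register dialects are rendered. A seed carries everything the downstream
#' concept calculators are supposed to recover: register identifiers with
#' cross-references, EUCTR member-state multiplicity, planned vs achieved
#' enrollment, mixed sponsor rosters, nested endpoints with
#' change-from-baseline flags, structured results (p-values and methods),
#' historic record versions and attached-document manifests.
#'
#' Each seed is drawn from its own pseudo-random stream keyed on the global
#' seed and the trial index, so enlarging a cohort never perturbs trials
#' already generated.
#'
#' @name synthetic-seeds
NULL

CANONICAL_PHASES <- c("1", "1_2", "2", "2_3", "3", "4")
CANONICAL_STATUS <- c("ongoing", "completed", "ended_early", "other")

# Substance spelling variants: the variant used differs by register, which is
# what substance-synonym harvesting is exercised against.
SUBSTANCE_SYNONYMS <- list(
  imatinib      = c("imatinib", "Imatinib mesylate", "Glivec"),
  semaglutide   = c("semaglutide", "Semaglutide injection", "Ozempic"),
  adalimumab    = c("adalimumab", "Adalimumab biosimilar", "Humira"),
  pembrolizumab = c("pembrolizumab", "Pembrolizumab (MK-3475)", "Keytruda"),
  metformin     = c("metformin", "Metformin hydrochloride")
)

SEED_CONDITIONS <- c(
  "breast cancer", "type 2 diabetes mellitus", "rheumatoid arthritis",
  "severe asthma", "advanced melanoma", "chronic heart failure"
)

NON_EEA_POOL <- c("US", "GB", "CH", "JP", "CA")

OBJECTIVE_TEMPLATES <- c(
  safety           = "to assess the safety and tolerability of the investigational medicine",
  efficacy         = "to evaluate the efficacy of the investigational medicine",
  dose_finding     = "to determine the maximum tolerated dose",
  pharmacokinetics = "to characterise the pharmacokinetic profile",
  pharmacodynamics = "to explore pharmacodynamic markers of response"
)

STAT_METHODS <- c("log-rank", "ANCOVA", "Cochran-Mantel-Haenszel", "t-test", "Wilcoxon rank-sum")

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

seed_stream <- function(base_seed, i) {
  (as.integer(base_seed) %% 65011L) * 32749L + i * 7919L
}

#' Generate ground-truth synthetic trials
#'
#' @param n Number of trials to generate (positive integer).
#' @param cross_registration_rate Probability that a trial is registered in
#'   more than one register, with the other registers' identifiers embedded as
#'   secondary identifiers.
#' @param seed Integer seed; identical `(n, cross_registration_rate, seed)`
#'   yield identical output.
#' @return A list of `trial_seed` objects.
#' @examples
#' seeds <- generate_seeds(3, cross_registration_rate = 0.5, seed = 42)
#' seeds[[1]]$ids
#' @export
generate_seeds <- function(n, cross_registration_rate = 0.5, seed = 1L) {
  assert_that(length(n) == 1 && !is.na(n) && n >= 1 && n == as.integer(n),
              "`n` must be a positive integer", "regharvest_argument_error")
  assert_that(cross_registration_rate >= 0 && cross_registration_rate <= 1,
              "`cross_registration_rate` must be a probability",
              "regharvest_argument_error")
  with_preserved_rng(
    lapply(seq_len(n), function(i) make_seed(i, cross_registration_rate, seed))
  )
}

rand_id <- function(register) {
  switch(register,
    CTGOV  = sprintf("NCT%08d", sample.int(99999999L, 1)),
    EUCTR  = sprintf("%04d-%06d-%02d", sample(2004:2019, 1),
                     sample.int(999999L, 1), sample(10:99, 1)),
    CTIS   = sprintf("%04d-%06d-%02d-%02d", sample(2022:2025, 1),
                     sample(500000:999999, 1), sample(10:99, 1),
                     sample(0:99, 1)),
    ISRCTN = sprintf("ISRCTN%08d", sample.int(99999999L, 1))
  )
}

make_seed <- function(i, rate, base_seed) {
  set.seed(seed_stream(base_seed, i))
  seed_key <- sprintf("T%04d", i)

  primary <- sample(REGISTERS, 1)
  registers <- primary
  if (rate > 0 && runif(1) < rate) {
    extra <- sample(setdiff(REGISTERS, primary), sample(1:3, 1))
    registers <- c(primary, extra)
  }
  registers <- REGISTERS[REGISTERS %in% registers]
  ids <- vapply(registers, rand_id, character(1))

  member_states <- if ("EUCTR" %in% registers) sort(sample(EEA_COUNTRIES, sample(1:4, 1))) else character(0)

  phase <- sample(CANONICAL_PHASES, 1)
  status_value <- sample(CANONICAL_STATUS, 1, prob = c(0.45, 0.35, 0.15, 0.05))
  status <- stats::setNames(rep(status_value, length(registers)), registers)

  planned_n <- sample(20:500, 1)
  actual_n <- NA_integer_
  if (status_value %in% c("completed", "ended_early") && runif(1) > 0.15) {
    actual_n <- min(as.integer(round(planned_n * runif(1, 0.5, 1.2))), 3L * planned_n)
  }

  # every fifth trial gets a forced mixed roster (commercial + non-commercial)
  if (i %% 5 == 0) {
    sponsors <- tibble::tibble(
      name = c(sprintf("Orion Pharma %02d AG", i %% 90), sprintf("University Hospital %02d", i %% 90)),
      class = c("commercial", "non_commercial")
    )
  } else {
    k <- sample(1:2, 1)
    cls <- sample(c("commercial", "non_commercial"), k, replace = TRUE)
    sponsors <- tibble::tibble(
      name = ifelse(cls == "commercial",
                    sprintf("Pharma %02d-%d GmbH", i %% 90, seq_len(k)),
                    sprintf("Research Institute %02d-%d", i %% 90, seq_len(k))),
      class = cls
    )
  }

  countries <- unique(c(member_states,
                        sample(EEA_COUNTRIES, sample(0:2, 1)),
                        if (runif(1) < 0.3) sample(NON_EEA_POOL, sample(1:2, 1))))
  if (length(countries) == 0) countries <- sample(EEA_COUNTRIES, 1)
  countries <- sort(countries)

  sites <- NULL
  if (any(c("CTGOV", "CTIS") %in% registers)) {
    ns <- sample(1:6, 1)
    sites <- tibble::tibble(
      name = sprintf("Site %s %02d", LETTERS[seq_len(ns)], i %% 90),
      country = sample(countries, ns, replace = TRUE)
    )
  }

  planned_start <- as.Date("2015-01-01") + sample(0:3200, 1)
  actual_start <- if (runif(1) < 0.75) planned_start + sample(0:60, 1) else NULL
  decision_euctr <- if (length(member_states)) {
    stats::setNames(planned_start - sample(30:150, length(member_states), replace = TRUE),
                    member_states)
  } else NULL
  start_dates <- list(
    planned = planned_start,
    actual = actual_start,
    authority_decision = decision_euctr,
    decision_ctis = planned_start - sample(20:90, 1)
  )
  end_date <- if (status_value %in% c("completed", "ended_early")) {
    planned_start + sample(200:1200, 1)
  } else NULL

  n_primary <- sample(1:2, 1)
  n_secondary <- sample(0:2, 1)
  mk_endpoint <- function(type, j) {
    cfb <- runif(1) < 0.3
    marker <- sample(c("HbA1c", "FEV1", "tumour size", "DAS28", "NT-proBNP"), 1)
    title <- if (cfb) {
      sprintf("Change from baseline in %s at week %d", marker, sample(c(12, 24, 52), 1))
    } else {
      sample(c("Overall survival", "Objective response rate",
               "Time to first exacerbation", "Proportion achieving remission"), 1)
    }
    tibble::tibble(
      type = type,
      title = title,
      description = sprintf("%s assessed by central review (%s %d)", title, "panel", j),
      timeframe = sample(c("Week 12", "Week 24", "Month 12", "36 months"), 1),
      is_change_from_baseline = cfb
    )
  }
  endpoints <- dplyr::bind_rows(
    purrr::map(seq_len(n_primary), ~mk_endpoint("primary", .x)),
    purrr::map(seq_len(n_secondary), ~mk_endpoint("secondary", .x))
  )

  results <- NULL
  if (status_value %in% c("completed", "ended_early") &&
      any(c("CTGOV", "EUCTR") %in% registers) && runif(1) < 0.7) {
    p <- round(runif(1, 0.001, 0.5), 3)
    results <- list(
      p_value = p,
      method = sample(STAT_METHODS, 1),
      secondary_p_value = round(min(0.99, p * 1.7), 3)
    )
  }

  n_versions <- sample(1:3, 1)
  vdates <- sort(planned_start - sample(30:400, n_versions)) # strictly increasing w.h.p.
  vdates <- vdates + seq_len(n_versions) # enforce strict increase
  vplanned <- c(if (n_versions > 1) pmax(10L, planned_n + sample(c(-80L, -40L, 40L, 80L), n_versions - 1, replace = TRUE)),
                planned_n)
  versions <- tibble::tibble(version_date = vdates, planned_n = as.integer(vplanned))

  documents <- sprintf("%s.pdf", sample(c("Protocol", "SAP", "ICF", "CSR-Synopsis"),
                                        sample(0:3, 1)))

  substance <- sample(names(SUBSTANCE_SYNONYMS), 1)
  syns <- SUBSTANCE_SYNONYMS[[substance]]
  intervention_names <- stats::setNames(
    syns[(match(registers, REGISTERS) - 1L) %% length(syns) + 1L], registers)

  is_platform <- runif(1) < 0.1
  arms <- if (is_platform) sample(4:6, 1) else sample(1:3, 1)
  randomised <- if (phase %in% c("2_3", "3", "4")) runif(1) < 0.9 else runif(1) < 0.5

  condition <- sample(SEED_CONDITIONS, 1)
  title <- sprintf("A %s%s trial of %s in %s",
                   if (randomised) "randomised " else "",
                   if (is_platform) "platform" else "clinical",
                   syns[1], condition)

  tags <- unique(c(sample(c("efficacy", "safety"), 1),
                   sample(names(OBJECTIVE_TEMPLATES), sample(0:2, 1))))
  tags <- names(OBJECTIVE_TEMPLATES)[names(OBJECTIVE_TEMPLATES) %in% tags]
  objectives_text <- paste(unname(OBJECTIVE_TEMPLATES[tags]), collapse = "; ")

  min_age <- sample(c(0L, 12L, 18L, 18L, 18L), 1)
  max_age <- sample(c(17L, 64L, 75L, 99L), 1)
  if (max_age <= min_age) max_age <- 99L

  structure(list(
    seed_key = seed_key,
    ids = ids,
    member_states = member_states,
    phase = phase,
    status = status,
    planned_n = planned_n,
    actual_n = actual_n,
    sponsors = sponsors,
    countries = countries,
    sites = sites,
    start_dates = start_dates,
    end_date = end_date,
    endpoints = endpoints,
    results = results,
    versions = versions,
    documents = documents,
    condition = condition,
    substance = substance,
    intervention_names = intervention_names,
    title = title,
    objectives_text = objectives_text,
    objective_tags = tags,
    is_platform = is_platform,
    arms = arms,
    randomised = randomised,
    min_age = min_age,
    max_age = max_age
  ), class = "trial_seed")
}

#' @export
print.trial_seed <- function(x, ...) {
  cat(sprintf("<trial_seed %s> %s\n", x$seed_key, x$title))
  cat("  ids:", paste(names(x$ids), x$ids, sep = "=", collapse = "  "), "\n")
  cat(sprintf("  phase %s, status %s, planned n=%d\n",
              x$phase, x$status[[1]], x$planned_n))
  invisible(x)
}

# Age-group truth used both by the generator's manifest and the population
# concept's expectations.
age_groups_from_range <- function(min_age, max_age) {
  grp <- character(0)
  if (min_age < 18) grp <- c(grp, "children")
  if (min_age <= 64 && max_age >= 18) grp <- c(grp, "adults")
  if (max_age >= 65) grp <- c(grp, "elderly")
  grp
}

#' Tabulate the ground truth of a seed cohort
#'
#' One row per seed with the scalars the harmonised concepts are expected to
#' recover, suitable for joining against extracted tables in tests.
#'
#' @param seeds List of `trial_seed` objects.
#' @return A tibble.
#' @export
seeds_manifest <- function(seeds) {
  purrr::map_dfr(seeds, function(s) {
    tibble::tibble(
      seed_key = s$seed_key,
      registers = list(names(s$ids)),
      ids = list(s$ids),
      condition = s$condition,
      phase = s$phase,
      status = s$status[[1]],
      planned_n = s$planned_n,
      actual_n = s$actual_n,
      sponsor_type = if (all(s$sponsors$class == "commercial")) "commercial"
                     else if (all(s$sponsors$class == "non_commercial")) "non_commercial"
                     else "mixed",
      n_sites = if (is.null(s$sites)) NA_integer_ else nrow(s$sites),
      n_member_states = length(s$member_states),
      planned_start = s$start_dates$planned,
      substance = s$substance,
      synonyms = list(unname(s$intervention_names)),
      n_documents = length(s$documents),
      n_versions = nrow(s$versions),
      is_platform = s$is_platform,
      age_groups = list(age_groups_from_range(s$min_age, s$max_age)),
      p_value = if (is.null(s$results)) NA_real_ else s$results$p_value,
      results_method = if (is.null(s$results)) NA_character_ else s$results$method
    )
  })
}

#' Write a seed-cohort truth manifest as NDJSON
#'
#' @param seeds List of `trial_seed` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seed_manifest <- function(seeds, path) {
  man <- seeds_manifest(seeds)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in seq_len(nrow(man))) {
    row <- as.list(man[r, ])
    row <- lapply(row, function(v) if (is.list(v)) v[[1]] else v)
    row$planned_start <- as.character(row$planned_start)
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null", digits = NA), con)
  }
  invisible(path)
}
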