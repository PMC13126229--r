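three_ms_source <- function() {
  seeds <- generate_seeds(4, 0, seed = 17)
  s <- seeds[[1]]
  s$ids <- c(EUCTR = "2013-000002-22")
  s$member_states <- c("AT", "BE", "DE")
  s$start_dates$authority_decision <- stats::setNames(
    as.Date("2013-03-01") + 0:2, s$member_states)
  s$condition <- "pemphigus"
  s$status <- c(EUCTR = "ongoing")
  seeds[[1]] <- s
  list(src = fixture_source(seeds, withr::local_tempdir(.local_envir = parent.frame())),
       seeds = seeds)
}

test_that("loading zero matches still appends a provenance entry", {
  fx <- three_ms_source()
  col <- open_collection()
  q <- generate_queries(condition = "no-match-here", registers = "CTGOV")
  res <- load_query(q$spec[[1]], col, fx$src)
  expect_identical(res$n_loaded, 0L)
  expect_identical(nrow(query_history(col)), 1L)
  expect_identical(tidy(res), tibble::tibble(record_id = character(0), outcome = character(0)))
})

test_that("EUCTR loads every member-state record, or a single preferred one", {
  fx <- three_ms_source()
  q <- generate_queries(condition = "pemphigus", registers = "EUCTR")

  col_all <- open_collection()
  res <- load_query(q$spec[[1]], col_all, fx$src)
  expect_identical(res$n_loaded, 3L)
  expect_true(all(startsWith(res$ids_loaded, "2013-000002-22-")))

  col_one <- open_collection()
  res1 <- load_query(q$spec[[1]], col_one, fx$src, euctr_protocols_all = FALSE)
  expect_identical(res1$ids_loaded, "2013-000002-22-AT") # alphabetically first
  res_be <- load_query(q$spec[[1]], open_collection(), fx$src,
                       euctr_protocols_all = FALSE, prefer_member_state = "BE")
  expect_identical(res_be$ids_loaded, "2013-000002-22-BE")
})

test_that("re-loading overwrites content while maintaining user annotations", {
  s <- generate_seeds(1, 0, seed = 23)[[1]]
  # force a completed CTGOV trial with structured results
  s$ids <- c(CTGOV = "NCT00000123")
  s$status <- c(CTGOV = "completed")
  s$actual_n <- s$planned_n - 5L
  s$results <- list(p_value = 0.031, method = "log-rank", secondary_p_value = 0.05)
  src <- fixture_source(list(s), withr::local_tempdir())
  col <- open_collection()
  q <- generate_queries(condition = ".", registers = "CTGOV")

  load_query(q$spec[[1]], col, src, annotation_text = "NME:x")
  id <- s$ids[["CTGOV"]]
  expect_identical(regharvest:::col_get(col, id)$annotation, "NME:x")

  load_query(q$spec[[1]], col, src, with_results = TRUE)
  doc <- regharvest:::col_get(col, id)
  expect_identical(doc$annotation, "NME:x")
  expect_true(isTRUE(doc$content$hasResults))

  # annotation modes, single-space separated
  load_query(q$spec[[1]], col, src, annotation_text = "extra")
  expect_identical(regharvest:::col_get(col, id)$annotation, "NME:x extra")
  load_query(q$spec[[1]], col, src, annotation_text = "first", annotation_mode = "prepend")
  expect_identical(regharvest:::col_get(col, id)$annotation, "first NME:x extra")
  load_query(q$spec[[1]], col, src, annotation_text = "only", annotation_mode = "replace")
  expect_identical(regharvest:::col_get(col, id)$annotation, "only")
})

test_that("loading an identical payload twice is idempotent up to last_import", {
  fx <- three_ms_source()
  q <- generate_queries(condition = "pemphigus", registers = "EUCTR")
  col <- open_collection()
  load_query(q$spec[[1]], col, fx$src)
  before <- regharvest:::col_docs(col)
  load_query(q$spec[[1]], col, fx$src)
  after <- regharvest:::col_docs(col)
  strip <- function(d) d[setdiff(names(d), "last_import")]
  expect_equal(lapply(before, strip), lapply(after, strip))
  expect_identical(nrow(query_history(col)), 2L)
})

test_that("historic-version selection matches the minimal-deviation oracle", {
  expect_identical(select_history_versions(10, "2:3"), 2:3)
  expect_identical(select_history_versions(10, "ALL"), 1:10)
  expect_identical(select_history_versions(10, TRUE), 1:10)
  expect_identical(select_history_versions(10, 3), c(1L, 6L, 10L))
  expect_identical(select_history_versions(5, NULL), integer(0))
  expect_identical(select_history_versions(7, 1), 7L)
  for (available in c(2, 5, 9, 10, 17)) {
    for (k in 2:min(available, 6)) {
      got <- select_history_versions(available, k)
      expect_identical(got, oracle_spacing(available, k),
                       info = sprintf("available=%d k=%d", available, k))
      expect_identical(got[1], 1L)
      expect_identical(got[length(got)], as.integer(available))
    }
  }
  expect_error(select_history_versions(10, "5:3"), class = "regharvest_argument_error")
  expect_error(select_history_versions(10, "2:11"), class = "regharvest_argument_error")
})

test_that("CTGOV loads capture the requested version ladder", {
  s <- generate_seeds(1, 0, seed = 29)[[1]]
  s$ids <- c(CTGOV = "NCT00000456")
  s$status <- c(CTGOV = "ongoing")
  s$versions <- tibble::tibble(
    version_date = as.Date("2019-01-01") + c(0, 120, 360),
    planned_n = c(60L, 90L, s$planned_n)
  )
  src <- fixture_source(list(s), withr::local_tempdir())
  col <- open_collection()
  q <- generate_queries(condition = ".", registers = "CTGOV")
  load_query(q$spec[[1]], col, src, ctgov_history = "ALL")
  doc <- regharvest:::col_get(col, s$ids[["CTGOV"]])
  expect_length(doc$history, nrow(s$versions))
  dates <- vapply(doc$history, function(h) h$version_date, character(1))
  expect_identical(dates, as.character(s$versions$version_date))
  first_planned <- doc$history[[1]]$content$protocolSection$designModule$enrollmentInfo$count
  expect_equal(as.integer(first_planned), s$versions$planned_n[1])
})

test_that("CTIS updates push the stored record onto its history first", {
  s <- generate_seeds(1, 0, seed = 37)[[1]]
  s$ids <- c(CTIS = "2023-500123-11-00")
  s$status <- c(CTIS = "ongoing")
  src <- fixture_source(list(s), withr::local_tempdir())
  col <- open_collection()
  q <- generate_queries(condition = ".", registers = "CTIS")
  load_query(q$spec[[1]], col, src)
  id <- s$ids[["CTIS"]]
  n0 <- s$planned_n

  # update with no changed records: nothing loaded, no history growth
  res0 <- update_query(1, col, src, ctis_history = TRUE)
  expect_identical(res0$n_loaded, 0L)
  expect_length(regharvest:::col_get(col, id)$history, 0)

  advance_fixture(src, s$seed_key, planned_n = n0 + 40L)
  res1 <- update_query(2, col, src, ctis_history = TRUE)
  expect_identical(res1$n_loaded, 1L)
  doc1 <- regharvest:::col_get(col, id)
  expect_length(doc1$history, 1)
  expect_equal(doc1$history[[1]]$content$recruitment$plannedSubjects, n0)
  expect_equal(doc1$content$recruitment$plannedSubjects, n0 + 40L)

  advance_fixture(src, s$seed_key, planned_n = n0 + 80L)
  update_query(3, col, src, ctis_history = TRUE)
  doc2 <- regharvest:::col_get(col, id)
  expect_length(doc2$history, 2)
  dates <- vapply(doc2$history, function(h) h$version_date, character(1))
  expect_true(all(diff(as.Date(substr(dates, 1, 10))) >= 0))

  expect_error(update_query(99, col, src), class = "regharvest_argument_error")
})

test_that("document fetching honours the placeholder/pattern contract", {
  seeds <- generate_seeds(3, 0, seed = 41)
  s <- seeds[[1]]
  s$documents <- c("Protocol.pdf", "SAP.pdf", "ICF.pdf")
  src <- fixture_source(list(s), withr::local_tempdir())
  reg <- names(s$ids)[1]
  q_all <- generate_queries(condition = ".", registers = reg)

  dir1 <- withr::local_tempdir()
  paths <- fetch_documents(q_all$spec[[1]], src, dir1)
  expect_length(paths, 3)
  expect_true(all(file.size(paths) == 0)) # placeholders are empty

  dir2 <- withr::local_tempdir()
  got <- fetch_documents(q_all$spec[[1]], src, dir2, documents_regexp = "^SAP")
  expect_length(got, 1)
  expect_gt(file.size(got), 0)

  again <- fetch_documents(q_all$spec[[1]], src, dir2, documents_regexp = "^SAP")
  expect_identical(sort(list.files(dir2)), sort(basename(got)))
  expect_identical(sort(again), sort(got))
})

test_that("an unwritable documents path errors before any transport", {
  seeds <- generate_seeds(1, 0, seed = 43)
  src <- fixture_source(seeds, withr::local_tempdir())
  reg <- names(seeds[[1]]$ids)[1]
  q <- generate_queries(condition = ".", registers = reg)
  # a path whose parent is a plain file can never become a directory
  blocker <- withr::local_tempfile()
  file.create(blocker)
  expect_error(fetch_documents(q$spec[[1]], src, file.path(blocker, "docs")),
               class = "regharvest_io_error")
})
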