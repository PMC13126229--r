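long_fixture_table <- function() {
  col <- open_collection()
  regharvest:::col_upsert(col, make_doc(
    "CTGOV", list(a = list(b = 1L), c = list(list(d = 2L), list(d = 3L))), "D1"))
  regharvest:::col_upsert(col, make_doc(
    "CTIS", list(a = list(b = 5L), c = list(list(d = 7L))), "D2"))
  get_fields(col, paths = c("a.b", "c.d"))
}

test_that("sequence cells explode to one long row per leaf", {
  rows <- trials_to_long(long_fixture_table())
  d1 <- rows[rows$`_id` == "D1" & rows$name == "c.d", ]
  expect_identical(d1$identifier, c("1", "2"))
  expect_identical(d1$value, c("2", "3"))
  scalar <- rows[rows$name == "a.b", ]
  expect_identical(unique(scalar$identifier), "1")
})

test_that("an all-scalar table yields exactly rows x columns long rows", {
  tbl <- tibble::tibble(`_id` = c("A", "B", "C"), x = 1:3, y = c("u", "v", "w"))
  rows <- trials_to_long(tbl)
  expect_identical(nrow(rows), 6L)
  empty <- trials_to_long(tibble::tibble(`_id` = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("reshaping is lossless: leaf multisets agree with the oracle", {
  co <- test_cohort()
  paths <- c("protocolSection.outcomesModule.primaryOutcomes.measure",
             "endpoints.primary.title", "sponsors.sponsor.status",
             "participating_countries.country.code", "sites.name")
  tbl <- get_fields(co$col, paths = paths)
  rows <- trials_to_long(tbl)
  docs <- regharvest:::col_docs(co$col)
  for (p in paths) {
    expected <- unlist(lapply(docs, function(d) {
      lv <- oracle_leaves(d$content)
      lv$value[lv$path == p]
    }), use.names = FALSE)
    got <- rows$value[rows$name == p]
    expect_identical(sort(got), sort(as.character(expected)), info = p)
  }
})

test_that("where-clauses keep only co-indexed rows", {
  co <- test_cohort()
  tbl <- get_fields(co$col, paths = c(
    "resultsSection.outcomeMeasuresModule.outcomeMeasures.type",
    "resultsSection.outcomeMeasuresModule.outcomeMeasures.analyses.pValue"))
  rows <- trials_to_long(tbl)
  got <- name_to_value(rows, value_pattern = "pValue$",
                       where_pattern = "\\.type$", where_value = "PRIMARY")
  # brute-force filter over the long table
  expected <- do.call(rbind, lapply(split(rows, rows$`_id`), function(rr) {
    prim <- rr[grepl("\\.type$", rr$name) & rr$value == "PRIMARY", ]
    vals <- rr[grepl("pValue$", rr$name), ]
    keep <- vapply(seq_len(nrow(vals)), function(i) {
      any(vapply(prim$identifier, function(g) {
        ka <- strsplit(vals$identifier[i], ".", fixed = TRUE)[[1]]
        kb <- strsplit(g, ".", fixed = TRUE)[[1]]
        k <- min(length(ka), length(kb))
        identical(ka[seq_len(k)], kb[seq_len(k)])
      }, logical(1)))
    }, logical(1))
    vals[keep, ]
  }))
  expect_gt(nrow(got), 0) # cohort contains trials with structured results
  expect_identical(sort(paste(got$`_id`, got$identifier, got$value)),
                   sort(paste(expected$`_id`, expected$identifier, expected$value)))
  # p-values gated on PRIMARY exclude the secondary-endpoint analyses
  all_p <- name_to_value(rows, "pValue$")
  expect_lt(nrow(got), nrow(all_p))

  expect_identical(nrow(name_to_value(rows, "pValue$", "\\.type$", "NO_SUCH")), 0L)
  expect_identical(name_to_value(rows, "pValue$"), all_p)
})

test_that("merge_relevel joins with ' / ' and applies level mappings", {
  tbl <- tibble::tibble(
    `_id` = c("A", "B", "C"),
    eu = c("BE", "BE", NA),
    us = c("DE", NA, NA)
  )
  merged <- merge_relevel(tbl, c("eu", "us"), "country")
  expect_identical(merged$country, c("BE / DE", "BE", NA))

  relab <- merge_relevel(tbl[2, ], c("eu", "us"), "country", levels = c(BE = "Belgium"))
  expect_identical(relab$country, "Belgium")
  expect_message(
    merge_relevel(tbl[1, ], c("eu", "us"), "country", levels = c(BE = "Belgium")),
    "left verbatim")

  # single column, no levels: identity on values
  one <- merge_relevel(tbl, "eu", "eu2")
  expect_identical(one$eu2, tbl$eu)

  # register null literals normalise to missing before merging
  lit <- tibble::tibble(`_id` = "A", x = "NULL", y = "FR")
  expect_identical(merge_relevel(lit, c("x", "y"), "z")$z, "FR")

  bad <- tibble::tibble(`_id` = "A", a = 1L, b = "x")
  expect_error(merge_relevel(bad, c("a", "b"), "m"), class = "regharvest_argument_error")
  expect_error(merge_relevel(bad, c("a", "nope"), "m"), class = "regharvest_argument_error")
})

test_that("long tables export to CSV with the documented columns", {
  rows <- trials_to_long(long_fixture_table())
  path <- withr::local_tempfile(fileext = ".csv")
  export_long_csv(rows, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(back), c("_id", "name", "identifier", "value"))
  expect_identical(nrow(back), nrow(rows))
})
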