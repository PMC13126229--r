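nested_doc <- function(id = "D1") {
  make_doc("CTGOV", list(a = list(b = 1L), c = list(list(d = 2L), list(d = 3L))), id)
}

test_that("find_fields discovers every dotted path, with register tags", {
  col <- open_collection()
  regharvest:::col_upsert(col, nested_doc())
  f <- find_fields(col)
  expect_setequal(f$path, c("a.b", "c.d"))
  expect_identical(f$registers[[1]], "CTGOV")

  regharvest:::col_upsert(col, make_doc("CTIS", list(a = list(b = 9L), date_x = "2020-01-01"), "D2"))
  f2 <- find_fields(col)
  expect_identical(f2$registers[f2$path == "a.b"][[1]], c("CTGOV", "CTIS"))
  expect_identical(find_fields(col, name_pattern = "date")$path, "date_x")

  expect_error(find_fields(open_collection()), class = "regharvest_empty_collection_error")
})

test_that("sampled and full discovery agree on homogeneous fixtures", {
  co <- test_cohort()
  expect_identical(find_fields(co$col, sample = "sample"),
                   find_fields(co$col, sample = "all"))
})

test_that("get_fields extracts typed scalars and ordered sequences", {
  col <- open_collection()
  regharvest:::col_upsert(col, nested_doc())
  ids <- get_fields(col, paths = "_id")
  expect_identical(names(ids), "_id")
  expect_identical(ids[["_id"]], "D1")

  tbl <- get_fields(col, paths = c("a.b", "c.d"))
  expect_identical(tbl[["a.b"]], 1L)
  expect_true(is.list(tbl[["c.d"]]))
  expect_equal(regharvest:::extraction_values(tbl[["c.d"]][[1]]), c(2, 3))

  expect_error(get_fields(col), class = "regharvest_argument_error")
  err <- tryCatch(get_fields(col, calculate = "noSuchConcept"), error = identity)
  expect_s3_class(err, "regharvest_argument_error")
  expect_match(conditionMessage(err), "f.isUniqueTrial", fixed = TRUE)
})

test_that("the typing heuristic yields dates, integers, flags and text", {
  col <- open_collection()
  for (i in 1:3) {
    regharvest:::col_upsert(col, make_doc("CTGOV", list(
      d = sprintf("2020-01-%02d", i), n = as.character(i * 10),
      f = c("Yes", "No", "Yes")[i], t = paste0("free text ", i),
      r = sprintf("%d.5", i)
    ), paste0("R", i)))
  }
  tbl <- get_fields(col, paths = c("d", "n", "f", "t", "r"))
  expect_s3_class(tbl$d, "Date")
  expect_type(tbl$n, "integer")
  expect_type(tbl$f, "logical")
  expect_identical(tbl$f, c(TRUE, FALSE, TRUE))
  expect_type(tbl$t, "character")
  expect_type(tbl$r, "double")
})

test_that("calculated concepts append exactly their output columns", {
  co <- test_cohort()
  tbl <- get_fields(co$col, paths = "_id",
                    calculate = c("statusRecruitment", "startDate"))
  expect_identical(names(tbl), c("_id", "statusRecruitment", "startDate"))
})

test_that("trial trees render stably with every leaf exactly once", {
  col <- open_collection()
  regharvest:::col_upsert(col, make_doc("CTIS", list(a = 1L), "T1"))
  txt <- show_trial_tree(col, "T1")
  expect_length(strsplit(txt, "\n")[[1]], 2)

  regharvest:::col_upsert(col, nested_doc("T2"))
  tree_txt <- show_trial_tree(col, "T2")
  leaves <- oracle_leaves(regharvest:::col_get(col, "T2")$content)
  for (v in leaves$value) {
    expect_identical(sum(grepl(paste0(": ", v, "$"),
                               strsplit(tree_txt, "\n")[[1]])), 1L)
  }
  expect_identical(show_trial_tree(col, "T2"), tree_txt)
  expect_error(show_trial_tree(col, "missing"), class = "regharvest_not_found_error")
})

test_that("documents round-trip through upsert and survive reopening (file backend)", {
  path <- withr::local_tempfile(fileext = ".ndjson")
  col <- open_collection(path)
  doc <- nested_doc()
  doc$annotation <- "note"
  regharvest:::col_upsert(col, doc)
  got <- regharvest:::col_get(col, "D1")
  expect_equal(got$content, doc$content)
  expect_identical(got$annotation, "note")

  reopened <- open_collection(path)
  expect_equal(regharvest:::col_get(reopened, "D1"), got)
})

test_that("file and memory backends give identical extraction results", {
  seeds <- generate_seeds(6, 0.5, seed = 13)
  src <- fixture_source(seeds, withr::local_tempdir())
  q <- generate_queries(condition = ".")
  cols <- list(open_collection(), open_collection(withr::local_tempfile(fileext = ".ndjson")))
  for (col in cols) {
    for (i in seq_len(nrow(q))) load_query(q$spec[[i]], col, src, with_results = TRUE)
  }
  f1 <- find_fields(cols[[1]])
  f2 <- find_fields(cols[[2]])
  expect_identical(f1, f2)
  t1 <- get_fields(cols[[1]], paths = utils::head(f1$path, 25), calculate = "trialPhase")
  t2 <- get_fields(cols[[2]], paths = utils::head(f1$path, 25), calculate = "trialPhase")
  expect_equal(t1, t2)
})

test_that("operations on a closed collection fail cleanly", {
  col <- open_collection()
  regharvest:::col_upsert(col, nested_doc())
  close_collection(col)
  expect_error(get_fields(col, paths = "_id"), class = "regharvest_closed_error")
  expect_error(regharvest:::col_upsert(col, nested_doc("D9")),
               class = "regharvest_closed_error")
})
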