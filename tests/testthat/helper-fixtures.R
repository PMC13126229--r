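# Shared fixture cohort (built once per test session) and independent
# brute-force oracles used to cross-check the library's extraction paths.

.fixture_cache <- new.env(parent = emptyenv())

# The study conditions: 50 synthetic trials, cross-registration rate 0.5,
# EUCTR member-state multiplicity, loaded into one collection with results.
test_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    seeds <- generate_seeds(50, cross_registration_rate = 0.5, seed = 1)
    src <- fixture_source(seeds, file.path(tempdir(), "regharvest-fixtures"))
    col <- open_collection()
    q <- generate_queries(condition = ".")
    for (i in seq_len(nrow(q))) {
      load_query(q$spec[[i]], col, src, with_results = TRUE)
    }
    .fixture_cache$cohort <- list(seeds = seeds, src = src, col = col, queries = q)
  }
  .fixture_cache$cohort
}

seed_by_key <- function(seeds, key) {
  seeds[[which(vapply(seeds, function(s) s$seed_key, character(1)) == key)]]
}

seeds_keyed <- function(seeds) {
  stats::setNames(seeds, vapply(seeds, function(s) s$seed_key, character(1)))
}

make_doc <- function(register, content, id = "X1") {
  list(`_id` = id, register = register, content = content)
}

# Independent traversal oracle: iterative stack walk enumerating every leaf
# with its dotted path (array levels contribute no path component), in
# document order.
oracle_leaves <- function(tree) {
  out_path <- character(0)
  out_value <- character(0)
  stack <- list(list(node = tree, path = character(0)))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (is.list(node)) {
      nms <- names(node)
      for (i in rev(seq_along(node))) {
        p <- if (!is.null(nms) && nzchar(nms[i])) c(top$path, nms[i]) else top$path
        stack[[length(stack) + 1]] <- list(node = node[[i]], path = p)
      }
    } else if (!is.null(node) && length(top$path) > 0) {
      out_path <- c(out_path, paste(top$path, collapse = "."))
      out_value <- c(out_value, as.character(node))
    }
  }
  data.frame(path = out_path, value = out_value, stringsAsFactors = FALSE)
}

# Random nested documents for the extraction-equivalence property.
random_tree <- function(depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(switch(sample(3, 1),
                  sample(1000, 1),
                  paste0("v", sample(99, 1)),
                  sample(c(TRUE, FALSE), 1)))
  }
  n <- sample(1:3, 1)
  if (stats::runif(1) < 0.35) {
    lapply(seq_len(n), function(i) random_tree(depth - 1))
  } else {
    stats::setNames(lapply(seq_len(n), function(i) random_tree(depth - 1)),
                    paste0("k", sample(9, n)))
  }
}

random_doc_content <- function() {
  stats::setNames(lapply(1:3, function(i) random_tree(3)), c("alpha", "beta", "gamma"))
}

# Brute-force minimal-deviation spacing oracle for historic-version counts:
# each ideal equally spaced position is resolved to the nearest index,
# half-way ties rounding up.
oracle_spacing <- function(available, k) {
  ideal <- seq(1, available, length.out = k)
  unique(vapply(ideal, function(p) {
    lo <- floor(p)
    hi <- ceiling(p)
    as.integer(if (p - lo < hi - p) lo else hi)
  }, integer(1)))
}

# Expected concept values derived from a seed, per register dialect.
expected_from_seed <- function(s, register) {
  status <- s$status[[register]]
  achieved <- if (status %in% c("completed", "ended_early")) s$actual_n else NA_integer_
  expected_n <- if (status %in% c("completed", "ended_early")) achieved else s$planned_n
  groups <- character(0)
  if (s$min_age < 18) groups <- c(groups, "children")
  if (s$min_age <= 64 && s$max_age >= 18) groups <- c(groups, "adults")
  if (s$max_age >= 65) groups <- c(groups, "elderly")
  n_sites <- switch(register,
    CTGOV = if (is.null(s$sites)) NA_integer_ else nrow(s$sites),
    CTIS  = if (is.null(s$sites)) NA_integer_ else nrow(s$sites),
    EUCTR = sum(s$countries %in% regharvest:::EEA_COUNTRIES),
    ISRCTN = if (is.null(s$sites)) NA_integer_ else nrow(s$sites)
  )
  prim <- s$endpoints[s$endpoints$type == "primary", ]
  list(
    phase = s$phase,
    status = status,
    sample_size = as.integer(expected_n),
    sponsor_type = if (all(s$sponsors$class == "commercial")) "commercial"
                   else if (all(s$sponsors$class == "non_commercial")) "non_commercial"
                   else "mixed",
    n_sites = n_sites,
    sites_incomplete = if (register == "EUCTR") {
      any(!s$countries %in% regharvest:::EEA_COUNTRIES)
    } else if (is.na(n_sites)) NA else FALSE,
    cfb = any(prim$is_change_from_baseline),
    population = paste(groups, collapse = "+"),
    objectives = paste(s$objective_tags, collapse = "+"),
    title = s$title,
    assignment = if (s$randomised) "randomised" else "non_randomised",
    start_date = switch(register,
      CTGOV = as.Date(s$start_dates$actual %||% s$start_dates$planned),
      EUCTR = as.Date(s$start_dates$actual %||% s$start_dates$planned),
      CTIS  = as.Date(s$start_dates$actual %||% s$start_dates$planned),
      ISRCTN = as.Date(s$start_dates$planned)
    ),
    p_value = if (!is.null(s$results) && register %in% c("CTGOV", "EUCTR")) s$results$p_value else NA_real_,
    method = if (!is.null(s$results) && register %in% c("CTGOV", "EUCTR")) s$results$method else NA_character_
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Randomised canonical search parameters for round-trip properties.
random_params <- function() {
  p <- list()
  if (runif(1) < 0.8) p$condition <- sample(c("cancer", "diabetes", "asthma"), 1)
  if (runif(1) < 0.4) p$intervention <- sample(c("imatinib", "metformin"), 1)
  if (runif(1) < 0.4) p$phase <- sort(sample(c("1", "1_2", "2", "2_3", "3", "4"),
                                             sample(1:2, 1)))
  if (runif(1) < 0.4) p$recruitment_status <- sort(sample(
    c("ongoing", "completed", "ended_early", "other"), sample(1:2, 1)))
  if (runif(1) < 0.4) p$countries <- sort(sample(c("BE", "DE", "FR", "US"), sample(1:2, 1)))
  if (runif(1) < 0.3) p$search_phrase <- "platform trial"
  if (runif(1) < 0.3) {
    p$start_date_from <- "2018-01-01"
    p$start_date_to <- "2022-12-31"
  }
  if (length(p) == 0) p$condition <- "cancer"
  p
}
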