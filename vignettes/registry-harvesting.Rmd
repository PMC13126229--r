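---
title: "Harvesting and harmonising clinical trial registry records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harvesting and harmonising clinical trial registry records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regharvest)
```

## The problem and the design principles

Clinical trial registries are complementary, not redundant: CTGOV, EUCTR,
CTIS and ISRCTN differ in legal scope, record structure and value sets, and
a research question about, say, sample sizes by sponsor type typically needs
all of them. Three principles shape this package.

First, *records are kept in their source data model*. Mapping four evolving
registries onto one target schema is a standardisation problem this package
deliberately does not attempt; instead every record is stored as a nested
document (JSON-style tree) exactly as parsed from its register dialect, and
harmonisation happens late, at analysis time, through explicit per-register
rules.

Second, *analysis variables are operational rules, not schema fields*. Each
of the twenty concepts in `concept_registry()` declares the register fields
it consults and a deterministic reduction of them. The function names carry
the epistemics: `f.sampleSize` can be computed exactly from register data,
while `f.likelyPlatformTrial` is a pattern-based approximation and says so.
None of these rules has been validated against register populations by a
formal approach; they are plausibility-checked operational definitions, and
the vocabulary tables behind them are shipped as configuration
(`inst/extdata/vocabularies.yaml`) precisely so register drift is a data
update, not a code change.

Third, *everything is testable offline*. Live registries change
continuously, which makes them useless as test oracles. The synthetic
generator is therefore a first-class module: it draws ground-truth trials
and renders them into all four dialects, and the test suite asserts that
the whole pipeline — query, load, extract, harmonise — recovers the seeded
truth exactly.

## The document tree and path extraction

All payloads normalise to one tree convention: objects are named lists,
arrays are unnamed lists, leaves are scalars. XML maps onto it by a frozen
rule — repeated sibling elements become ordered arrays, attributes become
`"@"`-prefixed fields, and mixed content (text next to child elements) is
rejected rather than guessed at. A dotted path addresses leaves without
positional indices; a path that crosses arrays yields the ordered sequence
of leaves, never silently the first element. The long format makes array
positions explicit: identifier `"2.1"` is the first inner element of the
second outer element, and a where-clause in `name_to_value()` gates rows on
a *longest-common-array-prefix* match — two rows are co-indexed when their
identifiers agree on the first `min(depth_a, depth_b)` components. Worked
example: a p-value at `…outcomeMeasures.analyses.pValue` with identifier
`"1.1"` is kept by a where-row `…outcomeMeasures.type == "PRIMARY"` with
identifier `"1"`, and dropped if the matching type row is `"2"`.

Column typing in `get_fields()` is heuristic and deliberately conservative:
a column becomes a date when at least 90% of its non-missing values are
ISO-8601 (tolerating stray free text in date fields), integer/real only by
lossless parse of *all* values, logical for register boolean literals
(`true/false`, `Yes/No`), text otherwise; sequences are never coerced. One
subtlety: flattening a mixed-type sequence falls back to per-leaf character
conversion, because vector coercion would silently turn `FALSE` into `0`.

## Storage backends

The collection contract (upsert, get, enumerate, append-only query history)
is backend-agnostic. Two backends ship: an embedded single-file store — one
serialized JSON document per line of an NDJSON file, human-inspectable and
durable across sessions — and an in-memory reference backend. Documents are
normalised through JSON serialisation on upsert so both backends return
byte-identical structures; the backend-interchangeability test runs the
same extraction surface over both and asserts identical results.

## The synthetic study conditions

The generator's defaults are the study conditions the tests and the
acceptance script use: cohorts of **50 trials**, **cross-registration rate
0.5** (each trial carries a second, third or fourth register with the other
ids embedded as secondary identifiers), EUCTR trials spread over **1–4
member states**, planned enrollments of 20–500 with achieved enrollment
present for most (85%) ended trials, a forced commercial + non-commercial
sponsor roster on every fifth trial so the `mixed` sponsor type is always
exercised, 30% change-from-baseline primary endpoints, structured results
(p-value in (0, 0.5], method label) for 70% of ended CTGOV/EUCTR trials,
1–3 historic versions per record, and 10% platform-style titles. Each trial
is drawn from its own random stream keyed on (seed, index), so enlarging a
cohort never perturbs earlier trials — a property the tests assert.

What the generator emulates is the *structure* real harvesting has to cope
with: dialect heterogeneity, member-state multiplicity, cross-references,
version ladders, nested endpoint arrays, document manifests. What it does
not emulate: free-text messiness (titles and objectives come from
templates, so pattern-based concepts classify them perfectly), incomplete
or contradictory cross-references, register-side search semantics
(relevance ranking, stemming), and schema drift. Passing the recovery
suite therefore demonstrates that the pipeline is lossless and the rules
are implemented as specified — not that the approximate concepts would
reach the same accuracy on real registry text.

## Numerical and procedural choices

- **Historic-version spacing.** A count `k` selects `k` version indices
  equally spaced from first to current, computed by round-half-up on
  `seq(1, available, length.out = k)`; ties round up, both ends always
  included. Spacing is over version *index*, not calendar time — with
  per-version dates both readings are defensible, index spacing is the
  deterministic one — and the tests pin it to a brute-force
  minimal-deviation oracle.
- **Deduplication tie-breaks.** One record per identifier-equivalence class
  survives, by register preference (default `CTGOV, CTIS, EUCTR, ISRCTN`),
  then preferred member state (default: alphabetically first), then
  lexicographic id. The defaults are not canonical — no single right order
  exists — but they are deterministic, documented, and overridable; the
  same member-state rule drives `euctr_protocols_all = FALSE` at load time
  so the two features can never disagree.
- **Frozen separators.** Endpoint descriptions join components with
  `" == "` and endpoints with `" ;; "`; merged register variables join with
  `" / "`. Missing means an absent path, an empty string, or a register
  null literal, all normalised before merging.
- **Canonical query URLs.** Criteria are ordered lexicographically by key
  when composing, which makes parse∘compose the identity and composed URLs
  reproducible. CTIS criteria travel as fragment-embedded JSON; the parser
  tolerates typographic quotes as they appear in print. The CTIS status
  code set for `ongoing` is `[3,4]` following the register's published URL
  form; the remaining code assignments are frozen reconstructions in the
  grammar table.
- **Update semantics.** "Changed since" filtering asks the source for
  records modified after the history entry's timestamp and falls back to a
  full reload when a source cannot filter by date. With `ctis_history`,
  the stored record is pushed onto its history array *before* the update,
  so version capture depends on when the user re-runs the query — an
  intrinsic property of snapshot-based history.
- **Degenerate inputs.** Every concept calculator is total: missing fields
  yield missing values, never errors; unmapped status literals map to
  `other` with a logged notice; an ended trial without an achieved
  enrollment reports a missing sample size rather than silently the
  planned one.

## Problem sizes

The default test run builds one 50-trial cohort (~140 register records)
shared across suites, 200 randomised nested documents for the
extraction-equivalence property, and 45 randomised query round-trips; the
whole suite completes in well under a minute on a single CPU, and the
acceptance script re-derives its numbers from a fresh cohort in a few
seconds. These sizes were chosen so that every property is exercised across
all four dialects with comfortable margin while keeping iteration fast.

## Known limitations

Live register transport is out of scope by design: the source interface is
defined, the fixture source is the required implementation, and any HTTP
adapter would sit behind the same surface but outside the tested path. The
grammar and dialect tables are reconstructions at the granularity the
concepts need, not full register schemas; `substance_synonyms()` implements
a documented stand-in semantics (case-folded harvest of intervention
spellings from matching records). Results-related data are structured only
in the CTGOV and EUCTR dialects — from CTIS and ISRCTN the results concepts
are defined but return missing values.
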