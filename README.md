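# regharvest

Harvest, store and harmonise clinical trial registry records.

Systematic research on registered clinical trials — trend analyses, evidence
mapping, transparency audits — usually has to span several registries:
ClinicalTrials.gov (CTGOV), the EU Clinical Trials Register (EUCTR), the EU
Clinical Trials Information System (CTIS) and the ISRCTN registry. Their
records differ in wire format (JSON vs XML), in structure, and in value
sets; a trial may be registered in more than one of them, and EUCTR stores
one record *per participating EU member state*, so naive record counts
over-count trials. `regharvest` is an R toolkit for that workflow, aimed at
trial methodologists and health-policy researchers:

- **Query building** — translate high-level search parameters (condition,
  intervention, phase, recruitment status, countries, dates) into each
  register's own query grammar and back (`generate_queries()`,
  `parse_query_url()`, `count_trials()`), with the four grammars frozen in a
  shipped configuration table.
- **Document-centric storage** — load matching records into a collection
  that preserves each register's own data model as a nested document
  (`load_query()`, `open_collection()`), with append-only query-history
  provenance, annotations that survive re-loads, and historic record
  versions (CTGOV version ladders via `ctgov_history`; CTIS snapshots pushed
  onto a history array on update).
- **Field extraction** — discover dotted field paths across registers
  (`find_fields()`) and extract typed wide tables (`get_fields()`), long
  tables (`trials_to_long()`, `name_to_value()`), and cross-register merges
  (`merge_relevel()`, values joined with `" / "`).
- **Twenty harmonised trial concepts** — `concept_registry()` lists
  deterministic calculators (`f.startDate`, `f.statusRecruitment`,
  `f.sampleSize`, `f.sponsorType`, `f.isUniqueTrial`, …) that reduce
  heterogeneous register fields to analysis variables; `likely`-prefixed
  names mark concepts that can only be approximated.
- **Synthetic register fixtures** — `generate_seeds()` and
  `fixture_source()` render ground-truth trials into all four dialects
  (cross-registrations with secondary identifiers, member-state
  multiplicity, planned vs achieved enrollment, mixed sponsor rosters,
  nested endpoints, versions, document manifests), so the entire pipeline is
  testable offline against known truth.

## The deduplication model

Counting *unique trials* is the methodological core. Every stored record
carries a set of trial identifiers: its register-native id (EUCTR ids
normalised by stripping the member-state suffix) plus the secondary
cross-references registers embed for co-registrations. `f.isUniqueTrial`
forms equivalence classes by union–find over shared identifiers,

```
record i ~ record j  ⇔  ids(i) ∩ ids(j) ≠ ∅   (transitive closure)
```

and flags exactly one record per class, chosen by register preference order
(default CTGOV > CTIS > EUCTR > ISRCTN), then preferred member state, then
lexicographic id — a deterministic, permutation-invariant rule. Downstream
concepts are per-record operational rules; for example the sample size is
the *achieved* enrollment once a trial has completed or ended early and the
*planned* enrollment while it runs (never silently the planned number for an
ended trial), and the sponsor type reduces the roster's class set, with
`mixed` when commercial and non-commercial sponsors co-occur.

## Worked example

```r
library(regharvest)
library(dplyr)

seeds <- generate_seeds(20, cross_registration_rate = 0.5, seed = 42)
src   <- fixture_source(seeds)           # renders all four dialects to disk

queries <- generate_queries(condition = "cancer")
col <- open_collection()                 # in-memory; give a path to persist
for (i in seq_len(nrow(queries))) {
  res <- load_query(queries$spec[[i]], col, src, with_results = TRUE)
  cat(sprintf("%-6s %d record(s) loaded\n", queries$register[i], res$n_loaded))
}
#> CTGOV  2 record(s) loaded
#> CTIS   1 record(s) loaded
#> EUCTR  12 record(s) loaded
#> ISRCTN 1 record(s) loaded

glance(col)
#> # A tibble: 1 × 4
#>   n_documents n_registers n_annotated n_queries
#>         <int>       <int>       <int>     <int>
#> 1          16           4           0         4

tbl <- get_fields(col, paths = "_id",
                  calculate = c("isUniqueTrial", "trialPhase",
                                "statusRecruitment", "sampleSize", "sponsorType"))
tbl |> filter(isUniqueTrial) |> count(sponsorType)
#> # A tibble: 3 × 2
#>   sponsorType        n
#>   <chr>          <int>
#> 1 commercial         2
#> 2 mixed              3
#> 3 non_commercial     1
```

Sixteen register records collapse to six unique "cancer" trials (EUCTR's
twelve records are member-state variants of three trials, some of them also
registered elsewhere); the cross-tabulation runs on one flagged record per
trial, so nothing is double-counted.

A command-line wrapper covering the same workflow
(`gen-fixtures`, `query`, `load`, `dedupe`, `calc`, …) is installed at
`inst/cli/regharvest`; see `regharvest help`.

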