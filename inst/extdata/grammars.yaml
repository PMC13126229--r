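# Frozen query-grammar table for the four supported registers.
#
# Searches differ greatly between registers, and registers change over time;
# all register-specific key names, value encodings and vocabulary codes used
# when composing or parsing search URLs are therefore isolated here, versioned
# separately from code. Grammars are modelled on the registers' public search
# URLs where these are documented (CTGOV v2 "aggFilters" facets, ISRCTN
# "filters=" items, EUCTR ctr-search parameters, CTIS fragment-embedded
# "searchCriteria=" JSON) and are frozen reconstructions where they are not.
version: 1
registers:
  CTGOV:
    base: "https://clinicaltrials.gov/search"
    hosts: ["clinicaltrials.gov", "www.clinicaltrials.gov"]
    # canonical criterion -> query parameter
    params:
      condition: cond
      intervention: intr
      search_phrase: term
      countries: country          # comma-joined country codes
      date_range: start           # "YYYY-MM-DD_YYYY-MM-DD"
    # facets carried inside the comma-joined aggFilters parameter
    medicines_clause: "studyType:int"
    phase_tokens:   {"1": "1", "1_2": "1 2", "2": "2", "2_3": "2 3", "3": "3", "4": "4"}
    status_tokens:  {ongoing: rec, completed: com, ended_early: ter, other: oth}
  EUCTR:
    base: "https://www.clinicaltrialsregister.eu/ctr-search/search"
    hosts: ["www.clinicaltrialsregister.eu", "clinicaltrialsregister.eu"]
    params:
      condition: query
      intervention: intr
      search_phrase: phrase
      date_from: dateFrom
      date_to: dateTo
    # country and phase/status are repeated parameters
    medicines_clause: {key: category, value: interventional-medicines}
    phase_tokens:
      "1": phase-one
      "1_2": phase-one-two
      "2": phase-two
      "2_3": phase-two-three
      "3": phase-three
      "4": phase-four
    status_tokens:  {ongoing: ongoing, completed: completed, ended_early: prematurely-ended, other: other}
  CTIS:
    base: "https://euclinicaltrials.eu/ctis-public/search"
    hosts: ["euclinicaltrials.eu", "www.euclinicaltrials.eu"]
    # criteria travel as URL-fragment-embedded JSON: "#searchCriteria={...}"
    criteria_keys:
      condition: medicalCondition
      intervention: interventionName
      search_phrase: containAll
      countries: msc
      date_from: eeaStartDateFrom
      date_to: eeaStartDateTo
    medicines_clause: {key: onlyMedIntervTrials, value: true}
    # ongoing -> [3,4] follows the register's published example URL form;
    # the remaining codes are frozen reconstructions
    status_codes:   {ongoing: [3, 4], completed: [8], ended_early: [6], other: [1]}
    phase_codes:    {"1": 1, "1_2": 2, "2": 3, "2_3": 4, "3": 5, "4": 6}
  ISRCTN:
    base: "https://www.isrctn.com/search"
    hosts: ["www.isrctn.com", "isrctn.com"]
    params:
      search_phrase: q
    # everything else travels inside the comma-joined "filters" parameter as
    # "name:value" items
    filter_keys:
      condition: condition
      intervention: intervention
      countries: recruitmentCountry
      date_from: overallStartDateFrom
      date_to: overallStartDateTo
    medicines_clause: "primaryStudyDesign:Interventional,interventionType:Drug"
    phase_tokens:
      "1": "Phase I"
      "1_2": "Phase I/II"
      "2": "Phase II"
      "2_3": "Phase II/III"
      "3": "Phase III"
      "4": "Phase IV"
    status_tokens:  {ongoing: Ongoing, completed: Completed, ended_early: Stopped, other: Suspended}
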