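# Vocabulary and pattern tables used by the harmonised trial-concept
# calculators. Registers evolve their value sets; keeping every mapping here,
# versioned separately from code, localises any register drift to this file.
#
# All literal keys are matched case-insensitively after lower-casing and
# whitespace normalisation. A literal absent from its table maps to "other"
# (recruitment status) or to a missing value (phase), with a logged notice.
version: 1

status:
  # register literal (normalised) -> {ongoing, completed, ended_early, other}
  CTGOV:
    recruiting: ongoing
    active_not_recruiting: ongoing
    enrolling_by_invitation: ongoing
    not_yet_recruiting: ongoing
    completed: completed
    terminated: ended_early
    withdrawn: ended_early
    suspended: other
    unknown: other
  EUCTR:
    ongoing: ongoing
    restarted: ongoing
    completed: completed
    "prematurely ended": ended_early
    suspended: other
    "not authorised": other
  CTIS:
    ongoing: ongoing
    "ongoing, recruiting": ongoing
    "ongoing, recruitment ended": ongoing
    authorised: ongoing
    ended: completed
    "prematurely ended": ended_early
    revoked: other
    expired: other
  ISRCTN:
    ongoing: ongoing
    "no longer recruiting": ongoing
    completed: completed
    stopped: ended_early
    suspended: other

# Literals a renderer uses for each canonical status (one per register).
status_render:
  CTGOV:  {ongoing: RECRUITING, completed: COMPLETED, ended_early: TERMINATED, other: UNKNOWN}
  EUCTR:  {ongoing: Ongoing, completed: Completed, ended_early: Prematurely Ended, other: Suspended}
  CTIS:   {ongoing: Ongoing, completed: Ended, ended_early: Prematurely Ended, other: Revoked}
  ISRCTN: {ongoing: Ongoing, completed: Completed, ended_early: Stopped, other: Suspended}

phase:
  # normalised literal -> {1, 1_2, 2, 2_3, 3, 4}
  CTGOV:
    "phase1": "1"
    "phase1/phase2": "1_2"
    "phase2": "2"
    "phase2/phase3": "2_3"
    "phase3": "3"
    "phase4": "4"
    "phase 1": "1"
    "phase 1/phase 2": "1_2"
    "phase 2": "2"
    "phase 2/phase 3": "2_3"
    "phase 3": "3"
    "phase 4": "4"
  # EUCTR records phase as four yes/no protocol flags; the key is the
  # concatenated y/n pattern (human pharmacology, exploratory, confirmatory,
  # therapeutic use)
  EUCTR:
    "ynnn": "1"
    "yynn": "1_2"
    "nynn": "2"
    "nyyn": "2_3"
    "nnyn": "3"
    "nnny": "4"
  CTIS:
    "phase i": "1"
    "phase i and phase ii": "1_2"
    "phase ii": "2"
    "phase ii and phase iii": "2_3"
    "phase iii": "3"
    "phase iv": "4"
  ISRCTN:
    "phase i": "1"
    "phase i/ii": "1_2"
    "phase ii": "2"
    "phase ii/iii": "2_3"
    "phase iii": "3"
    "phase iv": "4"
    "not applicable": other

phase_render:
  CTGOV:  {"1": ["PHASE1"], "1_2": ["PHASE1", "PHASE2"], "2": ["PHASE2"], "2_3": ["PHASE2", "PHASE3"], "3": ["PHASE3"], "4": ["PHASE4"]}
  CTIS:   {"1": "Phase I", "1_2": "Phase I and Phase II", "2": "Phase II", "2_3": "Phase II and Phase III", "3": "Phase III", "4": "Phase IV"}
  ISRCTN: {"1": "Phase I", "1_2": "Phase I/II", "2": "Phase II", "2_3": "Phase II/III", "3": "Phase III", "4": "Phase IV"}

sponsor_class:
  # register literal -> {commercial, non_commercial}
  CTGOV:
    industry: commercial
    nih: non_commercial
    other: non_commercial
    other_gov: non_commercial
    network: non_commercial
    fed: non_commercial
    indiv: non_commercial
  EUCTR:
    commercial: commercial
    "non-commercial": non_commercial
  CTIS:
    commercial: commercial
    "non-commercial": non_commercial
  ISRCTN:
    industry: commercial
    "university/hospital": non_commercial
    charity: non_commercial
    government: non_commercial
    "research organisation": non_commercial

# Keyword patterns (case-insensitive regular expressions) that tag the
# free-text study objectives.
objectives_patterns:
  safety: "safety|tolerab"
  efficacy: "efficacy|effectiveness"
  dose_finding: "dose[- ]finding|maximum tolerated dose|dose[- ]escalation"
  pharmacokinetics: "pharmacokinetic"
  pharmacodynamics: "pharmacodynamic"

# Pattern flagging primary endpoints that are likely expressed as a
# difference from a participant's baseline measurement.
change_from_baseline_pattern: "(change|difference|reduction|Δ|delta)[[:space:]]+from[[:space:]]+baseline"

# Markers of master-protocol (platform/umbrella/basket) designs in titles or
# design text; the arm-count route additionally requires at least
# `platform_min_arms` arms plus a shared-control marker.
platform_pattern: "platform|umbrella|basket|master[[:space:]]+protocol"
shared_control_pattern: "shared[[:space:]]+(control|placebo)|common[[:space:]]+control"
platform_min_arms: 4
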